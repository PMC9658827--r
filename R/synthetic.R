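# Seeded synthetic fixtures: two-chain complexes, docking ensembles with
# planted interface hydrogen bonds, and trajectory replicates with planted
# per-residue contact probabilities and COM-distance distributions. These
# stand in for undeposited docking/MD data; the planted truths are the
# oracles the analysis stages are validated against. Physical realism is a
# non-goal: geometries are built to satisfy the planted statistics exactly.

# glycine-like backbone heavy atoms (local coordinates, Angstroms)
.gly_template <- rbind(
  N  = c(-1.458, 0.000, 0.000),
  CA = c(0.000, 0.000, 0.000),
  C  = c(0.551, 1.420, 0.000),
  O  = c(1.780, 1.500, 0.000)
)
.gly_elements <- c("N", "C", "C", "O")

residue_rows <- function(chain, resno, resname, names, elements, coords) {
  tibble(
    name = names, element = elements,
    resno = resno, resname = resname, chain = chain,
    x = unname(coords[, 1]), y = unname(coords[, 2]), z = unname(coords[, 3])
  )
}

#' Generate a synthetic two-chain complex
#'
#' Two parallel strands of glycine-like residues (N, CA, C, O backbone
#' atoms), with small seeded coordinate jitter, whose closest inter-chain
#' heavy-atom approach is adjusted to `separation` within 0.1 Angstroms.
#' Deterministic for a given seed.
#'
#' @param n_per_chain Residues per chain (>= 1).
#' @param separation Target closest heavy-atom approach between chains,
#'   Angstroms (> 0).
#' @param seed Integer seed.
#' @return A `complex_model` with chains `"A"` (residues 1..n) and `"B"`
#'   (residues 101..100+n).
#' @export
generate_complex <- function(n_per_chain, separation = 4.0, seed = 1) {
  if (n_per_chain < 1) abort("n_per_chain must be >= 1")
  if (!is.numeric(separation) || separation <= 0) {
    abort("separation must be a positive distance in Angstroms",
          class = "mdcontact_parameter_error")
  }
  withr::local_seed(seed)
  one_chain <- function(chain, resno0, y_off) {
    dplyr::bind_rows(lapply(seq_len(n_per_chain), function(i) {
      coords <- .gly_template +
        matrix(c(3.8 * (i - 1), y_off, 0), 4, 3, byrow = TRUE) +
        matrix(rnorm(12, sd = 0.05), 4, 3)
      residue_rows(chain, resno0 + i, "GLY", rownames(.gly_template),
                   .gly_elements, coords)
    }))
  }
  a <- one_chain("A", 0, 0)
  b <- one_chain("B", 100, separation + 4)
  for (iter in 1:100) {
    dmin <- sqrt(min(dist2_mat(xyz_matrix(a), xyz_matrix(b))))
    if (abs(dmin - separation) < 0.02) break
    b$y <- b$y + (separation - dmin)
  }
  stopifnot(abs(dmin - separation) <= 0.1)
  as_complex_model(dplyr::bind_rows(a, b),
                   model_id = sprintf("complex_s%d", seed))
}

#' Specification of a docking ensemble with planted hydrogen-bond counts
#'
#' @param planted_counts Intended interface hydrogen-bond count per model:
#'   a named integer vector (names are model IDs) or a data frame with
#'   columns `model_id` and `hbond_count`.
#' @param seed Integer seed.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(planted_counts, seed = 1) {
  if (is.data.frame(planted_counts)) {
    counts <- tibble(model_id = as.character(planted_counts$model_id),
                     hbond_count = as.integer(planted_counts$hbond_count))
  } else {
    ids <- names(planted_counts)
    if (is.null(ids)) ids <- as.character(seq_along(planted_counts))
    counts <- tibble(model_id = ids,
                     hbond_count = as.integer(planted_counts))
  }
  if (nrow(counts) == 0 || any(counts$hbond_count < 0)) {
    abort("planted counts must be a non-empty set of non-negative integers",
          class = "mdcontact_parameter_error")
  }
  structure(list(planted_counts = counts, seed = seed),
            class = "ensemble_spec")
}

# A-chain residue oriented with its backbone N pointing up (+y), and a
# B-chain residue with its carbonyl O pointing down, so a planted bond is a
# single linear N...O pair at 2.9 A with every other cross pair > 3.5 A.
.donor_template <- rbind(
  CA = c(0.000, 0.000, 0.000),
  N  = c(0.000, 1.458, 0.000),
  C  = c(1.313, -0.760, 0.000),
  O  = c(1.313, -1.990, 0.000)
)
.donor_elements <- c("C", "N", "C", "O")
.acceptor_template <- rbind(
  O  = c(0.000, 0.000, 0.000),
  C  = c(0.000, 1.230, 0.000),
  CA = c(1.350, 1.950, 0.000),
  N  = c(1.350, 3.410, 0.000)
)
.acceptor_elements <- c("O", "C", "C", "N")

#' Generate a docking ensemble with planted interface hydrogen bonds
#'
#' Each model carries exactly its planted number of geometrically valid
#' cross-chain hydrogen bonds (backbone N...O pairs at 2.9 Angstroms,
#' linear when hydrogens are emitted) and no accidental extras; every model
#' is verified against [detect_interface_hbonds()] at default criteria
#' before being returned.
#'
#' @param spec An [ensemble_spec()], or anything `ensemble_spec()` accepts.
#' @param n_per_chain Residues per chain; defaults to one more than the
#'   largest planted count. Planting more bonds than residues is a capacity
#'   error.
#' @param hydrogens Emit an explicit hydrogen on each planted donor
#'   (collinear with the N...O axis)? Default `FALSE`.
#' @param seed Seed used when `spec` is not already an `ensemble_spec`.
#' @return Named list of `complex_model` objects in spec order.
#' @export
generate_ensemble <- function(spec, n_per_chain = NULL, hydrogens = FALSE,
                              seed = 1) {
  if (!inherits(spec, "ensemble_spec")) spec <- ensemble_spec(spec, seed = seed)
  counts <- spec$planted_counts
  k_max <- max(counts$hbond_count)
  if (is.null(n_per_chain)) n_per_chain <- max(k_max, 1) + 1
  if (k_max > n_per_chain) {
    abort(sprintf(
      "cannot plant %d hydrogen bonds with only %d residues per chain",
      k_max, n_per_chain
    ), class = "mdcontact_capacity_error")
  }
  withr::local_seed(spec$seed)
  models <- lapply(seq_len(nrow(counts)), function(m) {
    k <- counts$hbond_count[m]
    rows <- list()
    for (j in seq_len(n_per_chain)) {
      off <- c(10 * (j - 1), 0, 0)
      a_coords <- .donor_template + matrix(off, 4, 3, byrow = TRUE)
      a <- residue_rows("A", j, "GLY", rownames(.donor_template),
                        .donor_elements, a_coords)
      if (hydrogens && j <= k) {
        a <- dplyr::bind_rows(a, tibble(
          name = "H", element = "H", resno = j, resname = "GLY", chain = "A",
          x = off[1], y = 2.458, z = 0
        ))
      }
      b_y <- if (j <= k) 1.458 + 2.9 else 25
      b_coords <- .acceptor_template +
        matrix(c(10 * (j - 1), b_y, 0), 4, 3, byrow = TRUE)
      b <- residue_rows("B", 100 + j, "GLY", rownames(.acceptor_template),
                        .acceptor_elements, b_coords)
      rows[[j]] <- dplyr::bind_rows(a, b)
    }
    atoms <- dplyr::bind_rows(rows)
    jit <- matrix(rnorm(3 * nrow(atoms), sd = 0.02), ncol = 3)
    atoms$x <- atoms$x + jit[, 1]
    atoms$y <- atoms$y + jit[, 2]
    atoms$z <- atoms$z + jit[, 3]
    atoms <- dplyr::arrange(atoms, .data$chain, .data$resno)
    model <- as_complex_model(atoms, model_id = counts$model_id[m])
    got <- count_interface_hbonds(model)
    if (got != k) {
      abort(sprintf(
        "internal error: planted %d hydrogen bonds in model '%s' but detected %d",
        k, counts$model_id[m], got
      ))
    }
    model
  })
  setNames(models, counts$model_id)
}

#' Specification of a synthetic trajectory replicate
#'
#' Declares, per planted ligand-chain residue, a per-frame contact
#' probability `p` (independent Bernoulli draws), and a per-frame
#' COM-to-closest-partner-residue distance distribution Normal(`mu`,
#' `sigma`^2) truncated below at 0.1 Angstroms.
#'
#' @param n_frames Number of frames (>= 1).
#' @param ligand_residues Data frame with columns `resno`, `p`, `mu`,
#'   `sigma` and optionally `resname` (default `"GLY"`), one row per
#'   planted ligand residue.
#' @param background_residues Number of additional ligand-chain residues
#'   held more than 10 Angstroms from the partner chain in every frame.
#' @param frame_jitter Standard deviation (Angstroms) of the isotropic
#'   per-frame coordinate noise; applied so that planted COM distances are
#'   preserved exactly. Keep below ~0.1 to preserve the contact margins.
#' @param seed Integer seed; all randomness flows from this one stream.
#' @param replicate_id Replicate label; defaults to `"rep_seed<seed>"`.
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(n_frames, ligand_residues,
                            background_residues = 0, frame_jitter = 0.02,
                            seed = 1, replicate_id = NULL) {
  lr <- as_tibble(ligand_residues)
  if (!all(c("resno", "p", "mu", "sigma") %in% names(lr))) {
    abort("ligand_residues needs columns resno, p, mu, sigma",
          class = "mdcontact_parameter_error")
  }
  if (!"resname" %in% names(lr)) lr$resname <- "GLY"
  ok <- n_frames >= 1 && background_residues >= 0 && frame_jitter >= 0 &&
    all(lr$p >= 0 & lr$p <= 1) && all(lr$mu > 0) && all(lr$sigma >= 0) &&
    !anyDuplicated(lr$resno)
  if (!ok) {
    abort("invalid trajectory spec: need n_frames >= 1, 0 <= p <= 1, mu > 0, sigma >= 0, distinct resno",
          class = "mdcontact_parameter_error")
  }
  if (is.null(replicate_id)) replicate_id <- sprintf("rep_seed%d", seed)
  structure(
    list(n_frames = as.integer(n_frames), ligand_residues = lr,
         background_residues = as.integer(background_residues),
         frame_jitter = frame_jitter, seed = seed,
         replicate_id = replicate_id),
    class = "trajectory_spec"
  )
}

# truncated-normal draws via inverse CDF (lower truncation at `lower`)
rtruncnorm_low <- function(n, mu, sigma, lower = 0.1) {
  if (sigma == 0) return(rep(max(mu, lower), n))
  qnorm(runif(n, pnorm(lower, mu, sigma), 1), mu, sigma)
}

#' Generate a synthetic trajectory replicate with planted contact statistics
#'
#' Builds an `md_trajectory` realising the spec: for each planted ligand
#' residue, each frame is independently a contact frame with probability
#' `p` (closest heavy-atom pair placed below 4.5 Angstroms) or a
#' non-contact frame (every heavy atom at least 6 Angstroms from the
#' partner chain), while the residue's center of mass sits at the drawn
#' truncated-normal distance from its nearest partner residue's center of
#' mass, exactly (asserted to 0.05 Angstroms). Planted ligand residues are
#' two-equal-mass-atom dumbbells whose arm length and orientation are
#' chosen per frame; this is the geometry that lets the COM distance and
#' the atomic-contact state be controlled independently. Partner-chain
#' anchor residues are compact four-atom clusters with exactly placed
#' centers of mass, 15 Angstroms apart.
#'
#' @param spec A [trajectory_spec()].
#' @param path Optional file path; when given, the trajectory is also
#'   written as a multi-model PDB.
#' @param validate Re-measure the planted COM distances with the analysis
#'   code and assert agreement within 0.05 Angstroms? Default `TRUE`.
#' @return An `md_trajectory` (ligand chain `"A"`, partner chain `"B"`)
#'   with the planted truth table attached as attribute `"truth"`.
#' @export
generate_trajectory <- function(spec, path = NULL, validate = TRUE) {
  stopifnot(inherits(spec, "trajectory_spec"))
  withr::local_seed(spec$seed)
  lr <- spec$ligand_residues
  n <- spec$n_frames
  n_lig <- nrow(lr)
  jit <- spec$frame_jitter

  slots <- list()   # per-atom metadata, in within-frame order
  coords <- list()  # per-atom n x 3 coordinate matrices
  truth <- list()
  add_slot <- function(meta, m) {
    slots[[length(slots) + 1]] <<- meta
    coords[[length(coords) + 1]] <<- m
  }
  jitter_mat <- function() matrix(rnorm(3 * n, sd = jit), ncol = 3)

  d_list <- list()
  for (i in seq_len(n_lig)) {
    anchor <- c(15 * (i - 1), 0, 0)
    contact <- rbinom(n, 1, lr$p[i]) == 1
    d <- rtruncnorm_low(n, lr$mu[i], lr$sigma[i])
    d_list[[i]] <- d
    # contact frames: arms along the inter-chain axis, near atom ~2.5 A
    # (adaptive for large d); non-contact: arms perpendicular, every atom
    # pushed to >= ~6.25 A from the partner cluster
    arm <- ifelse(contact, pmax(0.5, d - 2.5), sqrt(pmax(6.6^2 - d^2, 0.25)))
    com <- cbind(anchor[1], d, 0)
    dir <- cbind(0, ifelse(contact, 1, 0), ifelse(contact, 0, 1))
    e <- if (jit > 0) jitter_mat() else matrix(0, n, 3)
    a1 <- com + arm * dir + e
    a2 <- com - arm * dir - e
    meta <- residue_rows("A", lr$resno[i], lr$resname[i], c("C1", "C2"),
                         c("C", "C"), matrix(0, 2, 3))[, 1:5]
    add_slot(meta[1, ], a1)
    add_slot(meta[2, ], a2)
    truth[[i]] <- tibble(
      residue = residue_label(lr$resname[i], lr$resno[i]),
      resno = lr$resno[i], p = lr$p[i], mu = lr$mu[i], sigma = lr$sigma[i],
      planted_contacts = sum(contact), planted_mean = mean(d),
      planted_sd = sd_pop(d)
    )
  }
  for (j in seq_len(spec$background_residues)) {
    anchor <- c(15 * (j - 1) + 5, 25, 0)
    e <- if (jit > 0) jitter_mat() else matrix(0, n, 3)
    base <- matrix(anchor, n, 3, byrow = TRUE)
    meta <- residue_rows("A", 5000 + j, "GLY", c("C1", "C2"),
                         c("C", "C"), matrix(0, 2, 3))[, 1:5]
    add_slot(meta[1, ], base + cbind(0, 0, 0.5) [rep(1, n), ] + e)
    add_slot(meta[2, ], base - cbind(0, 0, 0.5)[rep(1, n), ] - e)
  }
  # partner anchors: compact clusters, COM exactly at (15(i-1), 0, 0)
  p_template <- .gly_template * 0.12
  p_mass <- element_mass(.gly_elements)
  p_template <- sweep(p_template, 2, colSums(p_template * p_mass) / sum(p_mass))
  for (i in seq_len(n_lig)) {
    anchor <- c(15 * (i - 1), 0, 0)
    ek <- replicate(4, if (jit > 0) jitter_mat() else matrix(0, n, 3),
                    simplify = FALSE)
    shift <- Reduce(`+`, Map(function(e, m) e * m, ek, p_mass)) / sum(p_mass)
    for (k in 1:4) {
      m <- matrix(anchor + p_template[k, ], n, 3, byrow = TRUE) +
        ek[[k]] - shift
      meta <- residue_rows("B", 1000 + i, "GLY",
                           rownames(.gly_template)[k], .gly_elements[k],
                           matrix(0, 1, 3))[, 1:5]
      add_slot(meta, m)
    }
  }

  meta <- dplyr::bind_rows(slots)
  n_slot <- nrow(meta)
  atoms <- meta[rep(seq_len(n_slot), times = n), ]
  atoms$serial <- rep(seq_len(n_slot), times = n)
  atoms$frame <- rep(seq_len(n), each = n_slot)
  xs <- vapply(coords, function(m) m[, 1], numeric(n))
  ys <- vapply(coords, function(m) m[, 2], numeric(n))
  zs <- vapply(coords, function(m) m[, 3], numeric(n))
  atoms$x <- as.vector(t(xs))
  atoms$y <- as.vector(t(ys))
  atoms$z <- as.vector(t(zs))
  traj <- new_trajectory(atoms, replicate_id = spec$replicate_id)
  attr(traj, "truth") <- dplyr::bind_rows(truth)

  if (validate && n_lig > 0) {
    # geometric-realisation tolerance: measured COM distance must match the
    # drawn value to 0.05 A on every frame of every planted residue
    ser <- com_distance_series(traj, "A", "B")
    for (i in seq_len(n_lig)) {
      got <- ser$distance[ser$resno == lr$resno[i]][order(ser$frame[ser$resno == lr$resno[i]])]
      if (max(abs(got - d_list[[i]])) > 0.05) {
        abort(sprintf(
          "internal error: planted COM distances for residue %d not realised within 0.05 A",
          lr$resno[i]
        ))
      }
    }
  }
  if (!is.null(path)) write_trajectory(traj, path)
  traj
}
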