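# Per-residue contact dynamics over a trajectory: center-of-mass distance
# series to the closest partner residue, contact persistence fractions, and
# replicate aggregation.

#' Contact relevance criteria
#'
#' Criteria used to call a ligand-chain residue relevant over a replicate:
#' it must be in atomic contact with the partner chain for more than
#' `persistence_threshold` of the frames, and (in `persistence_and_com`
#' mode) its mean center-of-mass distance to the closest partner residue
#' must be below `com_distance_threshold`. Both comparisons are strict.
#' The atomic-contact gate and the COM metric are deliberately distinct:
#' a residue can touch the partner chain in most frames while its COM sits
#' beyond 5 Angstroms, so the two thresholds are configured separately.
#'
#' @param persistence_threshold Fraction of frames required in contact
#'   (default 0.80).
#' @param com_distance_threshold Mean COM distance threshold in Angstroms
#'   (default 5.0), used in `persistence_and_com` mode.
#' @param atomic_contact_cutoff Heavy-atom distance defining per-frame
#'   contact, Angstroms (default 4.5).
#' @param criteria_mode `"persistence_only"` (default) or
#'   `"persistence_and_com"`.
#' @return A `contact_criteria` list.
#' @export
contact_criteria <- function(persistence_threshold = 0.80,
                             com_distance_threshold = 5.0,
                             atomic_contact_cutoff = 4.5,
                             criteria_mode = c("persistence_only",
                                               "persistence_and_com")) {
  criteria_mode <- match.arg(criteria_mode)
  stopifnot(
    persistence_threshold > 0, persistence_threshold <= 1,
    com_distance_threshold > 0, atomic_contact_cutoff > 0
  )
  structure(
    list(
      persistence_threshold = persistence_threshold,
      com_distance_threshold = com_distance_threshold,
      atomic_contact_cutoff = atomic_contact_cutoff,
      criteria_mode = criteria_mode
    ),
    class = "contact_criteria"
  )
}

#' Mass-weighted center of mass of a residue
#'
#' @param atoms Atom tibble (rows of a `complex_model`) for one residue.
#' @param heavy_only Exclude hydrogens? Default `FALSE`: the physical COM
#'   includes hydrogens when present.
#' @return Numeric length-3 vector (Angstroms).
#' @examples
#' atoms <- tibble::tibble(
#'   name = c("C1", "C2"), element = "C", resno = 1, resname = "GLY",
#'   chain = "A", x = c(0, 2), y = 0, z = 0
#' )
#' residue_center_of_mass(as_complex_model(atoms))
#' @export
residue_center_of_mass <- function(atoms, heavy_only = FALSE) {
  if (heavy_only) atoms <- atoms[!atoms$is_hydrogen, ]
  if (nrow(atoms) == 0 || sum(atoms$mass) <= 0) {
    abort("zero total mass: cannot compute center of mass",
          class = "mdcontact_mass_error")
  }
  w <- atoms$mass / sum(atoms$mass)
  c(sum(w * atoms$x), sum(w * atoms$y), sum(w * atoms$z))
}

# COM table for one chain of one frame: one row per residue, sorted by
# residue number (so ties in distance resolve to the lowest resno).
chain_com_table <- function(atoms, chain, heavy_only = FALSE) {
  a <- atoms[atoms$chain == chain, ]
  if (heavy_only) a <- a[!a$is_hydrogen, ]
  if (nrow(a) == 0) {
    abort(sprintf("chain '%s' has no atoms", chain),
          class = "mdcontact_lookup_error")
  }
  ord <- order(a$resno)
  a <- a[ord, ]
  g <- factor(a$resno, levels = unique(a$resno))
  wm <- rowsum(cbind(a$mass * a$x, a$mass * a$y, a$mass * a$z), g)
  m <- rowsum(a$mass, g)
  first <- !duplicated(a$resno)
  list(
    resno = a$resno[first],
    resname = a$resname[first],
    com = wm / as.vector(m)
  )
}

#' Per-frame minimum COM distance of a residue to the partner chain
#'
#' Distance between the residue's center of mass and the center of mass of
#' the closest partner-chain residue; ties go to the lowest partner residue
#' number.
#'
#' @param frame A `complex_model` (one trajectory frame).
#' @param resno Residue number of the ligand-chain residue.
#' @param chain Chain ID the residue belongs to.
#' @param partner_chain Chain ID of the partner chain.
#' @param heavy_only Exclude hydrogens from COMs? Default `FALSE`.
#' @return Tibble with `distance` (Angstroms), `partner_resno`,
#'   `partner_resname`.
#' @export
per_frame_min_com_distance <- function(frame, resno, chain, partner_chain,
                                       heavy_only = FALSE) {
  res <- as_tibble(frame)[frame$chain == chain & frame$resno == resno, ]
  if (nrow(res) == 0) {
    abort(sprintf("no residue %s on chain '%s'", resno, chain),
          class = "mdcontact_lookup_error")
  }
  com <- residue_center_of_mass(res, heavy_only = heavy_only)
  p <- chain_com_table(as_tibble(frame), partner_chain, heavy_only = heavy_only)
  d <- sqrt(colSums((t(p$com) - com)^2))
  j <- unname(which.min(d))
  tibble(distance = unname(d[j]), partner_resno = p$resno[j],
         partner_resname = p$resname[j])
}

#' Is a residue in atomic contact with the partner chain?
#'
#' `TRUE` iff any heavy atom of the residue lies strictly within `cutoff` of
#' any heavy atom of the partner chain.
#'
#' @inheritParams per_frame_min_com_distance
#' @param cutoff Heavy-atom distance cutoff in Angstroms (default 4.5).
#' @return Logical scalar.
#' @export
atomic_contact <- function(frame, resno, chain, partner_chain, cutoff = 4.5) {
  tb <- as_tibble(frame)
  res <- tb[tb$chain == chain & tb$resno == resno & !tb$is_hydrogen, ]
  if (nrow(res) == 0) {
    abort(sprintf("no residue %s on chain '%s'", resno, chain),
          class = "mdcontact_lookup_error")
  }
  p <- tb[tb$chain == partner_chain & !tb$is_hydrogen, ]
  if (nrow(p) == 0) {
    abort(sprintf("chain '%s' has no atoms", partner_chain),
          class = "mdcontact_lookup_error")
  }
  min(dist2_mat(xyz_matrix(res), xyz_matrix(p))) < cutoff^2
}

#' Center-of-mass distance series for every ligand-chain residue
#'
#' For each ligand-chain residue and each frame, the Euclidean distance
#' between its center of mass and the center of mass of the closest
#' partner-chain residue.
#'
#' @param traj An `md_trajectory`.
#' @param ligand_chain,partner_chain Chain IDs.
#' @param heavy_only Exclude hydrogens from COMs? Default `FALSE`.
#' @return Tibble with `frame`, `resno`, `resname`, `residue`, `distance`,
#'   `partner_resno`, `partner_resname`.
#' @export
com_distance_series <- function(traj, ligand_chain, partner_chain,
                                heavy_only = FALSE) {
  ar <- traj_arrays(traj)
  lig <- chain_frame_coms(ar, ligand_chain, heavy_only = heavy_only)
  par <- chain_frame_coms(ar, partner_chain, heavy_only = heavy_only)
  n <- ar$n_frames
  n_par <- length(par$resno)
  out <- lapply(seq_along(lig$resno), function(i) {
    d2 <- (par$x - rep(lig$x[i, ], each = n_par))^2 +
      (par$y - rep(lig$y[i, ], each = n_par))^2 +
      (par$z - rep(lig$z[i, ], each = n_par))^2
    dim(d2) <- c(n_par, n)
    j <- max.col(-t(d2), ties.method = "first")
    tibble(
      frame = seq_len(n),
      resno = lig$resno[i],
      resname = lig$resname[i],
      residue = residue_label(lig$resname[i], lig$resno[i]),
      distance = sqrt(d2[cbind(j, seq_len(n))]),
      partner_resno = par$resno[j],
      partner_resname = par$resname[j]
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$frame, .data$resno)
}

# frame-major coordinate matrices with the constant topology of frame 1;
# downstream statistics are vectorised over frames
traj_arrays <- function(traj) {
  tb <- as_tibble(traj)
  ord <- order(tb$frame)
  tb <- tb[ord, ]
  n <- max(tb$frame)
  s <- nrow(tb) / n
  list(
    meta = tb[seq_len(s), model_cols],
    x = matrix(tb$x, nrow = s), y = matrix(tb$y, nrow = s),
    z = matrix(tb$z, nrow = s),
    n_frames = n
  )
}

# per-chain, per-residue COM coordinates as (n_residues x n_frames) matrices
chain_frame_coms <- function(ar, chain, heavy_only = FALSE) {
  sel <- ar$meta$chain == chain
  if (heavy_only) sel <- sel & !ar$meta$is_hydrogen
  if (!any(sel)) {
    abort(sprintf("chain '%s' has no atoms", chain),
          class = "mdcontact_lookup_error")
  }
  idx <- which(sel)[order(ar$meta$resno[sel])]
  resno <- ar$meta$resno[idx]
  mass <- ar$meta$mass[idx]
  g <- factor(resno, levels = unique(resno))
  msum <- as.vector(rowsum(mass, g))
  wcom <- function(m) rowsum(m[idx, , drop = FALSE] * mass, g) / msum
  first <- !duplicated(resno)
  list(
    resno = resno[first], resname = ar$meta$resname[idx][first],
    x = wcom(ar$x), y = wcom(ar$y), z = wcom(ar$z)
  )
}

# per-frame, per-ligand-residue heavy-atom contact flags
contact_flags <- function(traj, ligand_chain, partner_chain, cutoff) {
  ar <- traj_arrays(traj)
  heavy <- !ar$meta$is_hydrogen
  p_idx <- which(heavy & ar$meta$chain == partner_chain)
  l_sel <- which(heavy & ar$meta$chain == ligand_chain)
  l_sel <- l_sel[order(ar$meta$resno[l_sel])]
  resnos <- unique(ar$meta$resno[l_sel])
  n <- ar$n_frames
  out <- lapply(resnos, function(r) {
    g <- l_sel[ar$meta$resno[l_sel] == r]
    acc <- rep(Inf, n)
    for (a in g) {
      for (b in p_idx) {
        d2 <- (ar$x[a, ] - ar$x[b, ])^2 + (ar$y[a, ] - ar$y[b, ])^2 +
          (ar$z[a, ] - ar$z[b, ])^2
        acc <- pmin(acc, d2)
      }
    }
    tibble(frame = seq_len(n), resno = r, contact = acc < cutoff^2)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$frame, .data$resno)
}

#' Analyse one trajectory replicate
#'
#' Computes, for every ligand-chain residue: the fraction of frames in which
#' it is in atomic contact with the partner chain (persistence), the mean
#' and population standard deviation of its per-frame COM distance to the
#' closest partner residue, and whether it passes the relevance criteria
#' (`persistence_fraction > persistence_threshold`, and in
#' `persistence_and_com` mode also `mean_distance <
#' com_distance_threshold`).
#'
#' @param traj An `md_trajectory` with at least one frame.
#' @param ligand_chain,partner_chain Chain IDs.
#' @param criteria A [contact_criteria()] object.
#' @param heavy_only_com Exclude hydrogens from COM computations? Default
#'   `FALSE`.
#' @return A `replicate_contacts` object: list with `summary` (one row per
#'   ligand residue), `series` (the per-frame distance table), the
#'   `replicate_id`, chain IDs and criteria. `tidy()` returns the summary.
#' @export
analyze_replicate <- function(traj, ligand_chain, partner_chain,
                              criteria = contact_criteria(),
                              heavy_only_com = FALSE) {
  if (!inherits(traj, "md_trajectory") || nrow(traj) == 0) {
    abort("empty trajectory", class = "mdcontact_empty_input")
  }
  chains <- unique(traj$chain)
  if (!all(c(ligand_chain, partner_chain) %in% chains)) {
    abort(sprintf("chains '%s'/'%s' not both present in trajectory",
                  ligand_chain, partner_chain),
          class = "mdcontact_lookup_error")
  }
  series <- com_distance_series(traj, ligand_chain, partner_chain,
                                heavy_only = heavy_only_com)
  flags <- contact_flags(traj, ligand_chain, partner_chain,
                         cutoff = criteria$atomic_contact_cutoff)
  pers <- flags |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(persistence_fraction = mean(.data$contact),
                     .groups = "drop")
  summary <- series |>
    dplyr::group_by(.data$resno, .data$resname, .data$residue) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      mean_distance = mean(.data$distance),
      sd_distance = sd_pop(.data$distance),
      .groups = "drop"
    ) |>
    dplyr::left_join(pers, by = "resno") |>
    dplyr::mutate(
      replicate_id = replicate_id(traj),
      passes_criteria =
        .data$persistence_fraction > criteria$persistence_threshold &
        (criteria$criteria_mode != "persistence_and_com" |
           .data$mean_distance < criteria$com_distance_threshold)
    ) |>
    dplyr::arrange(.data$resno) |>
    dplyr::select("replicate_id", "residue", "resno", "resname", "n_frames",
                  "persistence_fraction", "mean_distance", "sd_distance",
                  "passes_criteria")
  structure(
    list(
      summary = summary,
      series = dplyr::mutate(series, replicate_id = replicate_id(traj)),
      replicate_id = replicate_id(traj),
      ligand_chain = ligand_chain,
      partner_chain = partner_chain,
      criteria = criteria
    ),
    class = "replicate_contacts"
  )
}

#' @export
print.replicate_contacts <- function(x, ...) {
  cat(sprintf(
    "<replicate_contacts '%s'> %d ligand residues over %d frames; %d pass criteria (%s)\n",
    x$replicate_id, nrow(x$summary), max(x$series$frame),
    sum(x$summary$passes_criteria), x$criteria$criteria_mode
  ))
  print(x$summary, ...)
  invisible(x)
}

#' Residues selected by the contact criteria in one replicate
#'
#' @param x A `replicate_contacts` object.
#' @return Character vector of residue labels passing the criteria.
#' @export
selected_residues <- function(x) {
  x$summary$residue[x$summary$passes_criteria]
}

#' Aggregate contact summaries across replicates
#'
#' Pools the per-frame COM distance series of each residue over all
#' replicates in which it occurs, reporting the pooled mean and pooled
#' population standard deviation (`method = "pooled"`, the default), or the
#' mean of per-replicate means with the population SD across those means
#' (`method = "replicate_means"`). Per-replicate pass flags are preserved
#' for the prevalence stage; rows are ordered ascending by mean distance,
#' so the closest residue comes first.
#'
#' @param analyses List of `replicate_contacts` objects (one per replicate).
#' @param method `"pooled"` or `"replicate_means"`.
#' @return Tibble with one row per residue: `residue`, `resno`, `resname`,
#'   `mean_distance`, `sd_distance`, `n_frames`, `n_replicates`, `n_pass`
#'   and list-column `pass_replicates` (IDs of replicates in which the
#'   residue passed).
#' @export
aggregate_replicates <- function(analyses,
                                 method = c("pooled", "replicate_means")) {
  method <- match.arg(method)
  if (inherits(analyses, "replicate_contacts")) analyses <- list(analyses)
  if (length(analyses) == 0) {
    abort("no replicates to aggregate", class = "mdcontact_empty_input")
  }
  series <- dplyr::bind_rows(lapply(analyses, `[[`, "series"))
  summaries <- dplyr::bind_rows(lapply(analyses, `[[`, "summary"))
  flags <- summaries |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_pass = sum(.data$passes_criteria),
      pass_replicates = list(.data$replicate_id[.data$passes_criteria]),
      .groups = "drop"
    )
  if (method == "pooled") {
    agg <- series |>
      dplyr::group_by(.data$residue, .data$resno, .data$resname) |>
      dplyr::summarise(
        mean_distance = mean(.data$distance),
        sd_distance = sd_pop(.data$distance),
        n_frames = dplyr::n(),
        .groups = "drop"
      )
  } else {
    agg <- summaries |>
      dplyr::group_by(.data$residue, .data$resno, .data$resname) |>
      dplyr::summarise(
        mean_distance = mean(.data$mean_distance),
        sd_distance = sd_pop(.data$mean_distance),
        n_frames = sum(.data$n_frames),
        .groups = "drop"
      )
  }
  agg |>
    dplyr::left_join(flags, by = "residue") |>
    dplyr::arrange(.data$mean_distance, .data$resno) |>
    dplyr::select("residue", "resno", "resname", "mean_distance",
                  "sd_distance", "n_frames", "n_replicates", "n_pass",
                  "pass_replicates")
}

#' Order a residue distance table by ascending mean distance
#'
#' Utility for distance tables shaped like the published per-residue
#' mean/SD table: sorts ascending by mean so the closest residue is ranked
#' first.
#'
#' @param distances Data frame with columns `residue`, `mean_distance` and
#'   optionally `sd_distance`.
#' @return The table ordered ascending by `mean_distance`, with a `rank`
#'   column prepended.
#' @examples
#' rank_by_distance(ps2aa1_apn_tables()$residue_distances)
#' @export
rank_by_distance <- function(distances) {
  stopifnot(all(c("residue", "mean_distance") %in% names(distances)))
  as_tibble(distances) |>
    dplyr::arrange(.data$mean_distance) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
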