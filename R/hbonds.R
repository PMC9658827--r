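# Interface detection and hydrogen-bond counting between the two chains of a
# complex, and ensemble ranking by interface hydrogen-bond count.

#' Geometric hydrogen-bond criteria
#'
#' Conventional geometric criteria for a hydrogen bond: donor and acceptor
#' heavy atoms (N/O/S by default) on opposite chains within
#' `max_donor_acceptor_distance`, excluding covalently close pairs. When the
#' structure carries explicit hydrogens the donor must have a bonded
#' hydrogen giving a D-H...A angle of at least `min_dha_angle`.
#'
#' @param max_donor_acceptor_distance Maximum donor--acceptor heavy-atom
#'   distance in Angstroms (default 3.5).
#' @param min_dha_angle Minimum donor-hydrogen-acceptor angle in degrees
#'   (default 120); applied only when explicit hydrogens are present.
#' @param donor_elements,acceptor_elements Element symbols allowed as donor
#'   or acceptor heavy atoms.
#' @param covalent_cutoff Heavy-atom pairs closer than this (Angstroms) are
#'   treated as covalently bonded and never counted (default 1.8).
#' @param use_hydrogens Use explicit hydrogens for the angle check when the
#'   model contains any (default `TRUE`); set `FALSE` to force the
#'   heavy-atom-only definition.
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.5,
                           min_dha_angle = 120,
                           donor_elements = c("N", "O", "S"),
                           acceptor_elements = c("N", "O", "S"),
                           covalent_cutoff = 1.8,
                           use_hydrogens = TRUE) {
  stopifnot(
    max_donor_acceptor_distance > 0,
    min_dha_angle >= 0, min_dha_angle <= 180,
    covalent_cutoff > 0
  )
  structure(
    list(
      max_donor_acceptor_distance = max_donor_acceptor_distance,
      min_dha_angle = min_dha_angle,
      donor_elements = toupper(donor_elements),
      acceptor_elements = toupper(acceptor_elements),
      covalent_cutoff = covalent_cutoff,
      use_hydrogens = isTRUE(use_hydrogens)
    ),
    class = "hbond_criteria"
  )
}

#' Interface residues of a two-chain complex
#'
#' A residue belongs to the interface iff any of its heavy atoms lies within
#' `cutoff` (strictly) of any heavy atom of the other chain. The definition
#' is symmetric: both chains' interface residues are returned.
#'
#' @param model A `complex_model` with exactly two chains.
#' @param cutoff Heavy-atom distance cutoff in Angstroms (default 5).
#' @return Tibble with `chain`, `resno`, `resname`, `residue` (label), one
#'   row per interface residue, ordered by chain then residue number.
#' @export
interface_residues <- function(model, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  ch <- assert_two_chains(model)
  heavy <- as_tibble(model)[!model$is_hydrogen, ]
  a <- heavy[heavy$chain == ch[1], ]
  b <- heavy[heavy$chain == ch[2], ]
  d2 <- dist2_mat(xyz_matrix(a), xyz_matrix(b))
  hit <- d2 < cutoff^2
  sel <- dplyr::bind_rows(
    a[rowSums(hit) > 0, c("chain", "resno", "resname")],
    b[colSums(hit) > 0, c("chain", "resno", "resname")]
  )
  sel |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chain, .data$resno) |>
    dplyr::mutate(residue = residue_label(.data$resname, .data$resno))
}

# hydrogens bonded to a heavy atom: same chain & residue, within 1.2 A
bonded_hydrogens <- function(model, heavy_row) {
  h <- as_tibble(model)[model$is_hydrogen &
                          model$chain == heavy_row$chain &
                          model$resno == heavy_row$resno, ]
  if (nrow(h) == 0) return(h)
  d2 <- dist2_mat(xyz_matrix(heavy_row), xyz_matrix(h))[1, ]
  h[d2 < 1.2^2, ]
}

dha_angle <- function(d_pos, h_pos, a_pos) {
  v1 <- d_pos - h_pos
  v2 <- a_pos - h_pos
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds crossing the chain interface
#'
#' Enumerates donor/acceptor heavy-atom pairs on opposite chains that meet
#' the geometric criteria. Without explicit hydrogens, a bond is any
#' non-covalent donor-element/acceptor-element pair within the distance
#' cutoff; with explicit hydrogens the D-H...A angle gate applies in
#' addition. Each heavy-atom pair is reported at most once.
#'
#' @param model A `complex_model` with exactly two chains.
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble with one row per bond: donor and acceptor atom
#'   descriptors, `distance` (Angstroms) and `angle` (degrees, `NA` in
#'   heavy-atom mode).
#' @export
detect_interface_hbonds <- function(model, criteria = hbond_criteria()) {
  ch <- assert_two_chains(model)
  tb <- as_tibble(model)
  elems <- union(criteria$donor_elements, criteria$acceptor_elements)
  heavy <- tb[!tb$is_hydrogen & tb$element %in% elems, ]
  a <- heavy[heavy$chain == ch[1], ]
  b <- heavy[heavy$chain == ch[2], ]
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_hbond_table())
  d2 <- dist2_mat(xyz_matrix(a), xyz_matrix(b))
  cand <- which(
    d2 <= criteria$max_donor_acceptor_distance^2 &
      d2 >= criteria$covalent_cutoff^2,
    arr.ind = TRUE
  )
  if (nrow(cand) == 0) return(empty_hbond_table())
  h_mode <- criteria$use_hydrogens && any(tb$is_hydrogen)
  bonds <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ra <- a[cand[k, 1], ]
    rb <- b[cand[k, 2], ]
    dist <- sqrt(d2[cand[k, 1], cand[k, 2]])
    hit <- NULL
    for (orient in list(list(d = ra, acc = rb), list(d = rb, acc = ra))) {
      if (!(orient$d$element %in% criteria$donor_elements &&
            orient$acc$element %in% criteria$acceptor_elements)) next
      ang <- NA_real_
      if (h_mode) {
        hs <- bonded_hydrogens(model, orient$d)
        if (nrow(hs) == 0) next
        angs <- vapply(seq_len(nrow(hs)), function(i) {
          dha_angle(
            unlist(orient$d[, c("x", "y", "z")]),
            unlist(hs[i, c("x", "y", "z")]),
            unlist(orient$acc[, c("x", "y", "z")])
          )
        }, numeric(1))
        ang <- max(angs)
        if (ang < criteria$min_dha_angle) next
      }
      hit <- tibble(
        donor_serial = orient$d$serial, donor_name = orient$d$name,
        donor_chain = orient$d$chain, donor_resno = orient$d$resno,
        donor_resname = orient$d$resname,
        acceptor_serial = orient$acc$serial, acceptor_name = orient$acc$name,
        acceptor_chain = orient$acc$chain, acceptor_resno = orient$acc$resno,
        acceptor_resname = orient$acc$resname,
        distance = dist, angle = ang
      )
      break
    }
    bonds[[k]] <- hit
  }
  out <- dplyr::bind_rows(bonds)
  if (nrow(out) == 0) return(empty_hbond_table())
  dplyr::arrange(out, .data$donor_chain, .data$donor_serial,
                 .data$acceptor_serial)
}

empty_hbond_table <- function() {
  tibble(
    donor_serial = integer(), donor_name = character(),
    donor_chain = character(), donor_resno = integer(),
    donor_resname = character(),
    acceptor_serial = integer(), acceptor_name = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_resname = character(),
    distance = double(), angle = double()
  )
}

#' @rdname detect_interface_hbonds
#' @return `count_interface_hbonds()` returns the number of interface
#'   hydrogen bonds as an integer.
#' @export
count_interface_hbonds <- function(model, criteria = hbond_criteria()) {
  nrow(detect_interface_hbonds(model, criteria))
}

#' Rank docking models by interface hydrogen-bond count
#'
#' Orders an ensemble of docked two-chain models by the number of hydrogen
#' bonds crossing the interface, descending; ties preserve input order
#' (stable sort), since no further criterion discriminates equal counts.
#' The data-frame method ranks already-counted `(model_id, hbond_count)`
#' pairs; the list method counts bonds with [detect_interface_hbonds()]
#' first.
#'
#' @param x A list of `complex_model` objects, or a data frame with columns
#'   `model_id` and `hbond_count`.
#' @param criteria An [hbond_criteria()] object (list method).
#' @param top_n Number of top models to keep (default 10).
#' @param ... Passed between methods.
#' @return Tibble with `rank` (1-based, consecutive), `model_id` and
#'   `hbond_count`, at most `top_n` rows.
#' @examples
#' counts <- tibble::tibble(
#'   model_id = c("560", "3413", "105", "819"),
#'   hbond_count = c(9, 9, 9, 8)
#' )
#' rank_models(counts, top_n = 3)
#' @export
rank_models <- function(x, ..., top_n = 10) {
  UseMethod("rank_models")
}

#' @rdname rank_models
#' @export
rank_models.data.frame <- function(x, ..., top_n = 10) {
  stopifnot(top_n >= 1)
  if (nrow(x) == 0) {
    abort("empty ensemble: nothing to rank", class = "mdcontact_empty_input")
  }
  if (!all(c("model_id", "hbond_count") %in% names(x))) {
    abort("expected columns 'model_id' and 'hbond_count'")
  }
  as_tibble(x) |>
    dplyr::arrange(dplyr::desc(.data$hbond_count)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::select("rank", "model_id", "hbond_count") |>
    head(top_n)
}

#' @rdname rank_models
#' @export
rank_models.list <- function(x, criteria = hbond_criteria(), ..., top_n = 10) {
  if (length(x) == 0) {
    abort("empty ensemble: nothing to rank", class = "mdcontact_empty_input")
  }
  ids <- vapply(seq_along(x), function(i) {
    id <- model_id(x[[i]])
    if (is.null(id)) id <- if (!is.null(names(x))) names(x)[i] else as.character(i)
    as.character(id)
  }, character(1))
  counts <- unname(vapply(x, count_interface_hbonds, integer(1),
                          criteria = criteria))
  rank_models(tibble(model_id = ids, hbond_count = counts), top_n = top_n)
}
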