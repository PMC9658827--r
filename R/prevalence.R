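# Replicate prevalence: in how many independent MD replicates did each
# residue satisfy the contact criteria, and is there a uniquely maximal one?

as_selection_sets <- function(selections) {
  if (inherits(selections, "replicate_contacts")) selections <- list(selections)
  if (!is.list(selections)) {
    abort("selections must be a list of residue character vectors or replicate_contacts objects")
  }
  sets <- lapply(selections, function(s) {
    if (inherits(s, "replicate_contacts")) s <- selected_residues(s)
    unique(as.character(s))
  })
  if (length(sets) == 0) return(sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("replicate_", seq_along(sets))
  }
  sets
}

#' Residue prevalence across MD replicates
#'
#' Counts, for every residue selected in at least one replicate, the number
#' of replicates whose selection contains it, and labels tiers:
#' `all_replicates` (count equals the number of replicates), `majority`
#' (more than one but not all) and `single` (exactly one). Records are
#' ordered by count descending, then by pooled mean distance ascending when
#' distances are supplied, then by residue label.
#'
#' @param selections List with one element per replicate: either a character
#'   vector of residue labels or a `replicate_contacts` object (its
#'   criteria-passing residues are used). Element names become replicate
#'   IDs.
#' @param distances Optional data frame with `residue` and `mean_distance`
#'   (e.g. from [aggregate_replicates()]) used for the `pooled_mean_distance`
#'   column and the secondary sort.
#' @return Tibble with `residue`, `count`, `n_replicates`, `tier`,
#'   `pooled_mean_distance` and list-column `replicates` (which replicates
#'   selected the residue).
#' @examples
#' compute_prevalence(list(
#'   rep1 = c("PRO255", "GLY256"),
#'   rep2 = c("ARG76", "GLY256"),
#'   rep3 = c("ARG76", "GLY256", "ASN270")
#' ))
#' @export
compute_prevalence <- function(selections, distances = NULL) {
  sets <- as_selection_sets(selections)
  if (length(sets) == 0) {
    abort("no replicate selections supplied", class = "mdcontact_empty_input")
  }
  n_rep <- length(sets)
  long <- tibble(
    replicate_id = rep(names(sets), lengths(sets)),
    residue = unlist(sets, use.names = FALSE)
  )
  out <- long |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      count = dplyr::n(),
      replicates = list(.data$replicate_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_replicates = n_rep,
      tier = dplyr::case_when(
        .data$count == n_rep ~ "all_replicates",
        .data$count > 1 ~ "majority",
        .default = "single"
      )
    )
  if (!is.null(distances)) {
    stopifnot(all(c("residue", "mean_distance") %in% names(distances)))
    out <- dplyr::left_join(
      out,
      dplyr::distinct(as_tibble(distances)[, c("residue", "mean_distance")]),
      by = "residue"
    ) |>
      dplyr::rename(pooled_mean_distance = "mean_distance")
  } else {
    out$pooled_mean_distance <- NA_real_
  }
  out |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pooled_mean_distance,
                   .data$residue) |>
    dplyr::select("residue", "count", "n_replicates", "tier",
                  "pooled_mean_distance", "replicates")
}

#' Uniquely most-prevalent residue
#'
#' Returns the residue attaining the maximal prevalence count iff it is
#' unique; a tie at the maximum returns `NA` rather than an arbitrary pick.
#'
#' @param records Tibble from [compute_prevalence()].
#' @return Residue label (character scalar) or `NA_character_` on a tie.
#' @export
unique_top_residue <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("empty prevalence records", class = "mdcontact_empty_input")
  }
  top <- records$residue[records$count == max(records$count)]
  if (length(top) == 1) top else NA_character_
}
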