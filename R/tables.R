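#' Write a result table as TSV
#'
#' Tab-separated with a header row. Double-precision columns (distances in
#' Angstroms, fractions) are rendered with a fixed number of decimals
#' (default 2, matching how interface distance tables are conventionally
#' printed); integer and character columns are written as-is. An empty input
#' yields a header-only file.
#'
#' @param rows Data frame of homogeneous records.
#' @param path Output file path.
#' @param digits Decimals used for double columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, digits = 2) {
  rows <- as_tibble(rows)
  out <- rows
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      out[[nm]] <- sprintf(paste0("%.", digits, "f"), col)
      out[[nm]][is.na(col)] <- NA_character_
    } else if (is.list(col)) {
      out[[nm]] <- vapply(col, function(v) paste(v, collapse = ","), "")
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a TSV result table
#'
#' @param path Path to a tab-separated table written by [write_table()].
#' @return A tibble with column types guessed from the data.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published PS2Aa1--APN worked-example tables
#'
#' The study of the parasporin PS2Aa1 bound to the aminopeptidase N (APN)
#' receptor published no structures or trajectories, only its result tables.
#' Those printed tables ship with the package as plain TSV and serve as the
#' worked-example inputs for the ranking, prevalence and distance-sorting
#' stages:
#'
#' * `docking_hbond_counts`: the top-10 docking models with their interface
#'   hydrogen-bond counts, in published order.
#' * `contact_residues`: per MD replicate, the PS2Aa1 residues in contact
#'   with APN for more than 80% of the simulation time.
#' * `residue_distances`: per candidate residue, mean and standard deviation
#'   of the center-of-mass distance to the closest APN residue (Angstroms).
#'
#' @return Named list of three tibbles.
#' @examples
#' tabs <- ps2aa1_apn_tables()
#' tabs$docking_hbond_counts
#' @export
ps2aa1_apn_tables <- function() {
  dir <- system.file("extdata", "ps2aa1_apn", package = "mdcontact",
                     mustWork = TRUE)
  list(
    docking_hbond_counts = read_table_tsv(file.path(dir, "docking_hbond_counts.tsv")),
    contact_residues = read_table_tsv(file.path(dir, "contact_residues.tsv")),
    residue_distances = read_table_tsv(file.path(dir, "residue_distances.tsv"))
  )
}
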