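# broom-style accessors for the package's result objects

#' @rdname analyze_replicate
#' @param x A `replicate_contacts` object.
#' @param ... Unused.
#' @method tidy replicate_contacts
#' @export
tidy.replicate_contacts <- function(x, ...) {
  x$summary
}

#' @rdname analyze_replicate
#' @method glance replicate_contacts
#' @export
glance.replicate_contacts <- function(x, ...) {
  tibble(
    replicate_id = x$replicate_id,
    n_frames = max(x$series$frame),
    n_residues = nrow(x$summary),
    n_pass = sum(x$summary$passes_criteria),
    min_mean_distance = min(x$summary$mean_distance),
    criteria_mode = x$criteria$criteria_mode
  )
}

#' @rdname run_pipeline
#' @param x A `contact_run` object.
#' @param ... Unused.
#' @return `tidy()` returns the prevalence table joined with the pooled
#'   distances; `glance()` a one-row run summary.
#' @method tidy contact_run
#' @export
tidy.contact_run <- function(x, ...) {
  x$prevalence
}

#' @rdname run_pipeline
#' @method glance contact_run
#' @export
glance.contact_run <- function(x, ...) {
  tibble(
    n_models = if (is.null(x$ranking)) 0L else nrow(x$ranking),
    top_model_id = x$top_model_id,
    top_hbond_count = if (is.null(x$ranking)) NA_integer_ else x$ranking$hbond_count[1],
    n_replicates = length(x$replicates),
    n_residues = nrow(x$prevalence),
    top_residue = x$top_residue,
    top_residue_mean_distance = if (nrow(x$distances) > 0 && !is.na(x$top_residue)) {
      d <- x$distances$mean_distance[x$distances$residue == x$top_residue]
      if (length(d) == 1) d else NA_real_
    } else {
      NA_real_
    }
  )
}
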