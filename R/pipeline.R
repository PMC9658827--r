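# End-to-end orchestration: rank a docking ensemble, analyse trajectory
# replicates, aggregate distances, compute prevalence, and report.

#' Pipeline configuration
#'
#' @param trajectories Trajectory replicates: a named list whose elements
#'   are `md_trajectory` objects or paths to multi-model PDB files (names
#'   become replicate IDs).
#' @param ligand_chain,partner_chain Chain IDs (must differ).
#' @param ensemble Optional docking ensemble: a directory of PDB files, a
#'   named list of `complex_model` objects, or a data frame of
#'   already-counted `(model_id, hbond_count)` pairs.
#' @param hbond An [hbond_criteria()] object.
#' @param contact A [contact_criteria()] object.
#' @param top_n Models kept in the ranking (default 10).
#' @param aggregate_method `"pooled"` or `"replicate_means"`; see
#'   [aggregate_replicates()].
#' @param output_dir Optional directory; when given, all result tables are
#'   written there as TSV.
#' @param seed Integer seed recorded in the provenance block (the analysis
#'   itself is deterministic).
#' @param verbose Log stage progress to stderr? Default `FALSE`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trajectories, ligand_chain, partner_chain,
                            ensemble = NULL,
                            hbond = hbond_criteria(),
                            contact = contact_criteria(),
                            top_n = 10,
                            aggregate_method = "pooled",
                            output_dir = NULL,
                            seed = 1,
                            verbose = FALSE) {
  if (identical(ligand_chain, partner_chain)) {
    abort("ligand_chain and partner_chain must differ")
  }
  if (length(trajectories) == 0) {
    abort("at least one trajectory replicate is required",
          class = "mdcontact_empty_input")
  }
  structure(
    list(trajectories = trajectories, ligand_chain = ligand_chain,
         partner_chain = partner_chain, ensemble = ensemble,
         hbond = hbond, contact = contact, top_n = top_n,
         aggregate_method = aggregate_method, output_dir = output_dir,
         seed = seed, verbose = verbose),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, file, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed%s: %s", stage,
                  if (is.null(file)) "" else sprintf(" on '%s'", file),
                  conditionMessage(e)),
          class = "mdcontact_stage_error", parent = e)
  })
}

log_stage <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[mdcontact] ", sprintf(...))
}

resolve_ensemble <- function(config) {
  ens <- config$ensemble
  if (is.null(ens)) return(NULL)
  if (is.data.frame(ens)) {
    return(rank_models(ens, top_n = config$top_n))
  }
  if (is.character(ens) && length(ens) == 1 && dir.exists(ens)) {
    paths <- sort(list.files(ens, pattern = "\\.pdb$", full.names = TRUE))
    if (length(paths) == 0) {
      abort(sprintf("no PDB files in ensemble directory '%s'", ens),
            class = "mdcontact_empty_input")
    }
    ens <- lapply(paths, read_pdb)
  }
  rank_models(ens, criteria = config$hbond, top_n = config$top_n)
}

resolve_trajectory <- function(x, id) {
  if (inherits(x, "md_trajectory")) return(x)
  read_trajectory(x, replicate_id = id)
}

#' Run the full interface-contact pipeline
#'
#' Executes the whole procedure on one configuration: rank the docking
#' ensemble by interface hydrogen-bond count (when an ensemble is given),
#' analyse every trajectory replicate for contact persistence and COM
#' distances, aggregate distances across replicates, compute residue
#' prevalence, and identify the uniquely most-prevalent residue. All stage
#' outputs are returned in one report and, when `output_dir` is set,
#' written as TSV tables (`ranking.tsv`, `contacts_<replicate>.tsv`,
#' `distances.tsv`, `prevalence.tsv`, plus a `run_info.txt` provenance
#' block -- the only file carrying a timestamp, so repeated runs produce
#' byte-identical tables).
#'
#' @param config A [pipeline_config()].
#' @return A `contact_run` report: list with `ranking`, `top_model_id`,
#'   `replicates` (list of `replicate_contacts`), `selections`,
#'   `distances`, `prevalence`, `top_residue`, `config` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage(config, "ranking ensemble")
  ranking <- with_stage("ranking", NULL, resolve_ensemble(config))
  top_model_id <- if (!is.null(ranking)) ranking$model_id[1] else NA_character_

  ids <- names(config$trajectories)
  if (is.null(ids)) ids <- paste0("replicate_", seq_along(config$trajectories))
  replicates <- lapply(seq_along(config$trajectories), function(i) {
    src <- config$trajectories[[i]]
    label <- if (is.character(src)) src else ids[i]
    log_stage(config, "analysing replicate %s", ids[i])
    with_stage("trajectory-analysis", label, {
      traj <- resolve_trajectory(src, ids[i])
      analyze_replicate(traj, config$ligand_chain, config$partner_chain,
                        criteria = config$contact)
    })
  })
  names(replicates) <- ids

  log_stage(config, "aggregating %d replicates", length(replicates))
  distances <- with_stage("aggregation", NULL,
    aggregate_replicates(replicates, method = config$aggregate_method))
  selections <- lapply(replicates, selected_residues)
  prevalence <- with_stage("prevalence", NULL,
    compute_prevalence(selections, distances = distances))
  top_residue <- if (nrow(prevalence) > 0) {
    unique_top_residue(prevalence)
  } else {
    NA_character_
  }

  # report consistency: every prevalence residue must come from a selection
  stopifnot(all(prevalence$residue %in% unlist(selections)))

  report <- structure(
    list(
      ranking = ranking, top_model_id = top_model_id,
      replicates = replicates, selections = selections,
      distances = distances, prevalence = prevalence,
      top_residue = top_residue, config = config,
      provenance = list(
        package_version = as.character(packageVersion("mdcontact")),
        r_version = R.version.string,
        seed = config$seed,
        replicate_ids = ids,
        criteria_mode = config$contact$criteria_mode,
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "contact_run"
  )
  if (!is.null(config$output_dir)) write_run_tables(report, config$output_dir)
  report
}

write_run_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$ranking)) {
    write_table(report$ranking, file.path(dir, "ranking.tsv"))
  }
  for (id in names(report$replicates)) {
    write_table(report$replicates[[id]]$summary,
                file.path(dir, sprintf("contacts_%s.tsv", id)))
  }
  write_table(report$distances, file.path(dir, "distances.tsv"))
  write_table(report$prevalence, file.path(dir, "prevalence.tsv"))
  prov <- report$provenance
  writeLines(
    c(sprintf("package_version\t%s", prov$package_version),
      sprintf("r_version\t%s", prov$r_version),
      sprintf("seed\t%s", prov$seed),
      sprintf("replicates\t%s", paste(prov$replicate_ids, collapse = ",")),
      sprintf("criteria_mode\t%s", prov$criteria_mode),
      sprintf("top_model\t%s", report$top_model_id),
      sprintf("top_residue\t%s", report$top_residue),
      sprintf("timestamp\t%s", prov$timestamp)),
    file.path(dir, "run_info.txt")
  )
  invisible(dir)
}

#' @export
print.contact_run <- function(x, ...) {
  cat("<contact_run>\n")
  if (!is.null(x$ranking)) {
    cat(sprintf("  ensemble: %d models ranked, top model '%s'\n",
                nrow(x$ranking), x$top_model_id))
  }
  cat(sprintf("  replicates analysed: %d\n", length(x$replicates)))
  cat(sprintf("  residues selected in >=1 replicate: %d\n",
              nrow(x$prevalence)))
  cat(sprintf("  uniquely most-prevalent residue: %s\n",
              ifelse(is.na(x$top_residue), "none (tie)", x$top_residue)))
  invisible(x)
}
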