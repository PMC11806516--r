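# Plan configuration files, results serialization and the run manifest.

plan_keys <- c("scenario", "n_train", "n_test", "days_grid",
               "total_measurements", "preparations", "learners",
               "replications", "scale_factor", "mlp", "seed", "verbose")

#' Load an experiment plan from a YAML file
#'
#' The file holds a flat mapping of [experiment_plan()] arguments; only
#' `scenario` is required, everything else falls back to the scenario
#' defaults. Unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return An `me_plan`.
#' @export
load_plan <- function(path) {
  if (!file.exists(path)) abort_mepsim(sprintf("no such plan file: %s", path), "io")
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$scenario)) {
    abort_mepsim("plan file must be a mapping with at least a scenario key",
                 "plan")
  }
  unknown <- setdiff(names(raw), plan_keys)
  if (length(unknown) > 0) {
    abort_mepsim(sprintf("unknown plan key(s): %s",
                         paste(unknown, collapse = ", ")), "plan")
  }
  do.call(experiment_plan, raw)
}

#' Save an experiment plan to a YAML file
#'
#' @param plan an `me_plan`.
#' @param path destination path.
#' @return The path, invisibly.
#' @export
save_plan <- function(plan, path) {
  yaml::write_yaml(unclass(plan), path)
  invisible(path)
}

#' Write long-form results to CSV
#'
#' Deterministic column and row order (the grid order in which the runner
#' produced the records), so identical runs produce byte-identical files.
#'
#' @param results a long-form results tibble.
#' @param path destination path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path CSV path.
#' @return A tibble of records.
#' @export
read_results <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a reproducibility manifest
#'
#' Records the plan, root seed, package and R versions and a timestamp.
#' The plan plus the package version suffice to reproduce a results CSV
#' bit for bit.
#'
#' @param plan an `me_plan`.
#' @param path destination JSON path (or `NULL` to return the list).
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(plan, path = NULL) {
  manifest <- list(
    plan = unclass(plan),
    root_seed = plan$seed,
    package_version = as.character(utils::packageVersion("mepsim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (is.null(path)) return(manifest)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
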