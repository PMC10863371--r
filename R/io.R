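#' Read and write the pipeline's tab-separated tables
#'
#' All tables travel as TSV with a header, fixed column order and `NA` as the
#' missing sentinel; the round trip is lossless. `write_tsv()`/`read_tsv()`
#' are thin wrappers shared by the specific dialects.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv()` returns a data.frame; writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}

trials_columns <- c("subject_id", "intervention", "session_order", "trial",
                    "choice1", "state2", "choice2", "transition", "reward",
                    "missing")

#' @rdname pipeline_io
#' @export
write_trials <- function(x, path) {
  stopifnot(all(trials_columns %in% names(x)))
  write_tsv(x[, trials_columns], path)
}

#' @rdname pipeline_io
#' @export
read_trials <- function(path) {
  x <- read_tsv(path)
  missing_cols <- setdiff(trials_columns, names(x))
  if (length(missing_cols))
    stop("trials file lacks columns: ", paste(missing_cols, collapse = ", "))
  x$missing <- as.logical(x$missing)
  x
}

#' Serialize / load a task configuration as JSON
#'
#' Unknown keys in the JSON are rejected so manifests stay exact.
#'
#' @param config A [task_config()].
#' @param path JSON file path.
#' @return `read_task_config()` returns a [task_config()].
#' @export
write_task_config <- function(config, path) {
  stopifnot(inherits(config, "task_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n_trials", "p_common", "walk_sd", "walk_bounds",
             "reward_magnitude", "init_probs", "rng_seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown task-config key(s): ", paste(unknown, collapse = ", "))
  task_config(n_trials = x$n_trials %||% 201L,
              p_common = x$p_common %||% 0.7,
              walk_sd = x$walk_sd %||% 0.025,
              walk_bounds = x$walk_bounds %||% c(0.25, 0.75),
              reward_magnitude = x$reward_magnitude %||% 20,
              init_probs = x$init_probs,
              rng_seed = x$rng_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated cohort to a directory
#'
#' Emits `trials.tsv`, `true_params.tsv`, `blood.tsv` and `manifest.json`.
#'
#' @param cohort A `cohort_data` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(cohort$trials, file.path(dir, "trials.tsv"))
  write_tsv(cohort$true_params, file.path(dir, "true_params.tsv"))
  write_tsv(cohort$blood, file.path(dir, "blood.tsv"))
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
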