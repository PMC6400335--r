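#' Results serialisation
#'
#' Simulation outputs are stored as JSON documents that carry everything
#' needed to reproduce them: the configuration echo and its hash, the seeds,
#' the per-trial summaries and (optionally) per-cycle trajectories. Tidy CSV
#' exports (one row per trial per metric; one row per cell per trial for
#' sweeps) are provided for downstream plotting.
#'
#' @name results-io
NULL

df_to_rows <- function(df) {
  df <- as.data.frame(df)
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v) if (is.factor(v)) as.character(v) else unname(v))
  })
}

results_document <- function(x, ...) UseMethod("results_document")

#' @export
results_document.ward_trial <- function(x, config = NULL, ...) {
  doc <- list(
    tool = "wardsim",
    tool_version = as.character(utils::packageVersion("wardsim")),
    kind = "trial",
    config_hash = x$config_hash,
    seed = x$seed,
    summary = df_to_rows(x$summary),
    per_complication = df_to_rows(x$per_complication)
  )
  if (!is.null(x$trajectories)) doc$trajectories <- df_to_rows(x$trajectories)
  if (!is.null(config)) doc$config = config_to_list(config)
  doc
}

#' @export
results_document.ward_trials <- function(x, config = NULL, ...) {
  doc <- list(
    tool = "wardsim",
    tool_version = as.character(utils::packageVersion("wardsim")),
    kind = "trials",
    config_hash = x$config_hash,
    seeds = as.list(x$seeds),
    summary = df_to_rows(x$summary),
    per_complication = df_to_rows(x$per_complication),
    aggregate = df_to_rows(x$aggregate)
  )
  if (!is.null(config)) doc$config = config_to_list(config)
  doc
}

#' @export
results_document.ward_sweep <- function(x, config = NULL, ...) {
  doc <- list(
    tool = "wardsim",
    tool_version = as.character(utils::packageVersion("wardsim")),
    kind = paste0("sweep_", attr(x, "kind")),
    rows = df_to_rows(x),
    summary = df_to_rows(attr(x, "summary"))
  )
  cmp <- attr(x, "comparisons")
  if (!is.null(cmp)) doc$comparisons <- df_to_rows(cmp)
  if (!is.null(config)) doc$config = config_to_list(config)
  doc
}

#' @export
results_document.list <- function(x, ...) x # already a parsed document

#' Write results to a JSON document
#'
#' Serialises a `ward_trial`, `ward_trials` or `ward_sweep` (or a document
#' previously read with [read_results()]) with a fixed field order, so
#' write -> read -> write is byte-identical.
#'
#' @param x Result object.
#' @param path Output path.
#' @param config Optional `ward_config` to embed for full reproducibility.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = NULL) {
  doc <- results_document(x, config = config)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a results document
#'
#' @param path Path to a JSON file written by [write_results()].
#' @return The parsed document (named list); tabular fields can be
#'   rectangled with [results_table()].
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Extract a table from a results document
#'
#' @param doc A document from [read_results()].
#' @param field Name of a tabular field (e.g. `"summary"`, `"rows"`).
#' @return A tibble.
#' @export
results_table <- function(doc, field = "summary") {
  rows <- doc[[field]]
  if (is.null(rows)) stop("no field `", field, "` in document", call. = FALSE)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
}

#' Export results as tidy CSV
#'
#' One row per trial per metric for trial batches; one row per cell per
#' trial for sweeps.
#'
#' @param x A `ward_trial`, `ward_trials` or `ward_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  if (inherits(x, "ward_sweep")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    return(invisible(path))
  }
  if (inherits(x, "ward_trial")) {
    summary <- dplyr::mutate(x$summary, trial = 1L, .before = 1)
  } else if (inherits(x, "ward_trials")) {
    summary <- x$summary
  } else {
    stop("cannot export object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(summary, -dplyr::all_of(c("trial", "seed")),
                              names_to = "metric", values_to = "value")
  utils::write.csv(as.data.frame(long), path, row.names = FALSE)
  invisible(path)
}
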