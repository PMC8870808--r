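# File exports shared by the package and the command-line script.

#' Write a ranking or influence table to CSV
#'
#' @param x A ranking tibble (`node`, `score`, `rank`) or an
#'   [influence_table()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Serialize an evaluation or ranking report to JSON
#'
#' For an `lwc_ranking`, includes the per-node table plus the entropy
#' weights; for an `lwc_evaluation`, the summary and curve tibbles plus
#' the resolved SIR configuration; for a [network_summary()] row, the
#' statistics themselves.
#'
#' @param x An `lwc_ranking`, `lwc_evaluation`, or summary tibble.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "lwc_ranking")) {
    list(ranking = tidy(x), weights = attr(x, "weights"))
  } else if (inherits(x, "lwc_evaluation")) {
    list(config = x$config, summary = x$summary, imprecision = x$imprecision,
         jaccard = x$jaccard, ccdf = x$ccdf, influence = as_tibble(x$influence))
  } else {
    as_tibble(x)
  }
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
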