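## Result serialization with a reproducibility metadata block.

#' Write a result table with metadata
#'
#' Writes a data frame as CSV (with `#`-prefixed metadata header lines:
#' package version, seed, config echo) or as JSON (metadata and data as
#' separate members). Floats are written at 12 significant digits;
#' column order is preserved.
#'
#' @param results A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param config Optional named list echoed into the metadata block.
#' @param seed Optional integer seed recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json"),
                          config = NULL, seed = NULL) {
  format <- match.arg(format)
  results <- tibble::as_tibble(results)
  num <- vapply(results, is.double, logical(1))
  printed <- results
  printed[num] <- lapply(printed[num], function(x) signif(x, 12))
  meta <- list(
    package = "repool",
    version = as.character(utils::packageVersion("repool")),
    seed = seed,
    config = config
  )
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                null = "null")), con)
    utils::write.csv(printed, con, row.names = FALSE)
  } else {
    jsonlite::write_json(list(metadata = meta, results = printed), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a CSV written by [write_results()].
#' @return A tibble (metadata lines are skipped).
#' @export
read_results <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
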