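#' Write a result report to CSV or JSON
#'
#' Accepts the package's tabular result objects (posterior summaries, risk
#' reports, trend tables — any data.frame) as well as DIC statistics
#' (`stmmr_dic`). Columns keep a deterministic order; numeric values are
#' rounded to 6 significant digits, so a written report re-reads losslessly.
#'
#' @param report a data.frame-like report or an `stmmr_dic` object.
#' @param path output path.
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  if (!is.character(format) || !format[1L] %in% c("csv", "json"))
    stop("unknown report format: ", format[1L])
  format <- format[1L]
  if (inherits(report, "stmmr_dic"))
    report <- data.frame(dbar = report$dbar, d_at_mean = report$d_at_mean,
                         p_d = report$p_d, dic = report$dic)
  if (!is.data.frame(report)) stop("report must be a data.frame or stmmr_dic")
  df <- as.data.frame(report, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6L)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path path to a report file.
#' @param format "csv" or "json"; default inferred from the file extension.
#' @return a data.frame.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!format %in% c("csv", "json")) stop("unknown report format: ", format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE,
                  check.names = FALSE)
  }
}
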