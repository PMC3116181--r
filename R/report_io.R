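# Report serialization: machine-readable JSON (full numeric precision) and
# human-readable delimited tables, with lossless round-trips.

#' Write a report to disk
#'
#' Serializes validation reports, contribution reports and full analysis
#' reports. JSON output keeps full numeric precision so a round-trip read
#' reproduces every number bit-equal; CSV output renders the same fields
#' as a table for human consumption.
#'
#' @param report A `"validation_report"`, `"contribution_report"` or
#'   `"analysis_report"` object.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  UseMethod("write_report")
}

#' @export
write_report.validation_report <- function(report, path,
                                           format = c("json", "csv")) {
  format <- match.arg(format)
  row <- validation_report_row(report)
  if (format == "json") {
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
  } else {
    utils::write.csv(as.data.frame(row, stringsAsFactors = FALSE), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_report.contribution_report <- function(report, path,
                                             format = c("json", "csv")) {
  format <- match.arg(format)
  if (nrow(report) == 0L)
    stop("refusing to write an empty contribution report", call. = FALSE)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = FALSE,
                         digits = I(17))
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_report.analysis_report <- function(report, path,
                                         format = c("json", "csv")) {
  format <- match.arg(format)
  if (length(report$reports) == 0L)
    stop("refusing to write an empty analysis report", call. = FALSE)
  if (format == "json") {
    body <- list(
      metadata = report$metadata,
      models = lapply(report$reports, validation_report_row),
      errors = report$errors,
      contributions = lapply(report$contributions, as.data.frame),
      summary_table = report$contribution_summary
    )
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", dataframe = "rows")
  } else {
    utils::write.csv(summary(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_report.default <- function(report, path, format = c("json", "csv")) {
  stop("no write_report method for class ",
       paste(class(report), collapse = "/"), call. = FALSE)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report] with `format = "json"`.
#' @return The deserialized list (numbers at full precision).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Stable key names of one model-summary row.
validation_report_row <- function(report) {
  need <- c("activity", "n", "x_set", "a", "r2", "q2cv",
            "perm_r2_intercept", "perm_q2_intercept", "valid")
  if (!all(need %in% names(report)) || is.null(report$x_set))
    stop("validation report is not fully populated", call. = FALSE)
  report[need]
}
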