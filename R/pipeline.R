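# Full-study orchestration: fit and validate every requested
# activity x descriptor-set pair, interpret the valid models, and collect
# everything into one auditable report.

#' Activity by descriptor-set pairs of the original study design
#'
#' The twelve models of the source study: DPPH with all four descriptor
#' sets, FRAP with the combined, AA and gAA sets, hydrogen peroxide with
#' the combined, AA and z sets, and superoxide with the combined and gAA
#' sets. Pairs absent from this design (e.g. FRAP with the z set alone)
#' were presumably invalid models and are not fabricated in replication
#' runs.
#'
#' @return Data frame with columns `activity` and `x_set`.
#' @export
replication_design <- function() {
  data.frame(
    activity = c(rep("dpph", 4L), rep("frap", 3L), rep("h2o2", 3L),
                 rep("superoxide", 2L)),
    x_set = c("all", "AA", "gAA", "z",
              "all", "AA", "gAA",
              "all", "AA", "z",
              "all", "gAA"),
    stringsAsFactors = FALSE
  )
}

#' Run the full composition-activity analysis
#'
#' For every requested activity / descriptor-set pair: assemble the X
#' block, select the number of significant components by cross-validation,
#' fit the PLS model, run the permutation validity test, and — for models
#' passing both intercept limits — compute VIP scores and classify
#' contributors. A failure in one pair (e.g. a missing activity) is
#' recorded and does not stop the remaining pairs.
#'
#' @param dataset An [aa_dataset] with at least one activity attached.
#' @param pairs Data frame with columns `activity` and `x_set`; defaults
#'   to every attached activity crossed with the four descriptor sets.
#' @param config A [validation_config].
#' @return A list of class `"analysis_report"`: `reports` (one
#'   `"validation_report"` per completed pair), `contributions` (one
#'   `"contribution_report"` per valid model, named `activity/x_set`),
#'   `contribution_summary` (from [contribution_table], valid combined-set
#'   models), `errors` (per-pair failure messages) and `metadata`.
#' @export
run_analysis <- function(dataset, pairs = NULL,
                         config = validation_config()) {
  stopifnot(inherits(dataset, "aa_dataset"))
  if (is.null(pairs)) {
    if (length(dataset$activities) == 0L)
      stop("dataset has no activities attached", call. = FALSE)
    pairs <- expand.grid(activity = names(dataset$activities),
                         x_set = c("all", "AA", "gAA", "z"),
                         stringsAsFactors = FALSE)
    pairs <- pairs[order(match(pairs$activity, names(dataset$activities))), ]
  }
  stopifnot(all(c("activity", "x_set") %in% names(pairs)))
  reports <- list()
  contribs <- list()
  errors <- list()
  for (i in seq_len(nrow(pairs))) {
    act <- pairs$activity[i]
    xs <- pairs$x_set[i]
    key <- paste(act, normalize_x_set(xs), sep = "/")
    res <- tryCatch(validate_model(dataset, act, xs, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
      next
    }
    reports[[key]] <- res
    if (isTRUE(res$valid) && !is.null(res$model))
      contribs[[key]] <- contributions(res$model)
  }
  if (length(reports) == 0L && length(errors) > 0L)
    stop("all requested models failed; first error: ",
         errors[[1L]], call. = FALSE)
  # summary table over valid combined-set models, one row per activity
  summ_in <- list()
  for (key in names(contribs)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1L]]
    if (parts[2L] == "all") summ_in[[parts[1L]]] <- contribs[[key]]
  }
  structure(list(reports = reports, contributions = contribs,
                 contribution_summary = contribution_table(summ_in),
                 errors = errors,
                 metadata = list(seed = config$seed,
                                 folds = config$folds,
                                 cv_mode = config$cv_mode,
                                 n_permutations = config$n_permutations,
                                 n_pairs = nrow(pairs),
                                 package_version =
                                   as.character(utils::packageVersion("aapls")))),
            class = "analysis_report")
}

#' Summarize an analysis report as one row per model
#'
#' @param object An `"analysis_report"`.
#' @param ... Unused.
#' @return Data frame with columns `activity`, `n`, `x_set`, `a`, `r2`,
#'   `q2cv`, `perm_r2_intercept`, `perm_q2_intercept`, `valid`.
#' @export
summary.analysis_report <- function(object, ...) {
  rows <- lapply(object$reports, function(r)
    as.data.frame(validation_report_row(r), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("activity", "n", "x_set", "a", "r2", "q2cv",
          "perm_r2_intercept", "perm_q2_intercept", "valid")]
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Composition-activity PLS analysis:", length(x$reports),
      "model(s),", sum(vapply(x$reports, function(r) isTRUE(r$valid), TRUE)),
      "valid\n")
  for (r in x$reports) print(r)
  if (length(x$errors) > 0L) {
    cat("Failed pairs:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}
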