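# Model interpretation: VIP scores and the strong/weak contributor
# classification by VIP threshold and coefficient sign.

#' Variable importance for the projection (VIP)
#'
#' For each descriptor `j`,
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )`
#' with unit-norm weight vectors `w_a` and `SSY_a = c_a^2 t_a't_a` the
#' response sum of squares explained by component `a` on scaled data. The
#' squared VIPs average to one over the descriptors, so 1 marks the
#' "average importance" level.
#'
#' @param model A fitted `"pls1"` model.
#' @return Named non-negative vector, one VIP per descriptor;
#'   `mean(vip^2) == 1`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls1"))
  p <- nrow(model$W)
  ssy <- model$c^2 * colSums(model$T^2)
  w2 <- sweep(model$W^2, 2L, colSums(model$W^2), "/")  # guard: W unit-norm
  v <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  stats::setNames(v, model$columns)
}

#' Classify descriptors as strong/weak/unimportant contributors
#'
#' Applies the conventional VIP thresholds: a descriptor is a strong
#' contributor when `VIP > 1.0`, a weak contributor when
#' `0.5 <= VIP <= 1.0`, and unimportant when `VIP < 0.5` (boundary values
#' fall in the weaker class). The direction of the contribution is the
#' sign of the scaled coefficient; a coefficient of exactly zero gets sign
#' `"none"`.
#'
#' @param vip_values Named vector of VIP scores.
#' @param coefficients Coefficient vector on scaled data, aligned with
#'   `vip_values`.
#' @return A data frame of class `"contribution_report"` with columns
#'   `variable`, `vip`, `coefficient`, `class`
#'   (`strong`/`weak`/`unimportant`) and `sign`
#'   (`positive`/`negative`/`none`).
#' @export
classify_contributors <- function(vip_values, coefficients) {
  if (length(vip_values) != length(coefficients))
    stop("vip_values and coefficients differ in length", call. = FALSE)
  if (!is.null(names(vip_values)) && !is.null(names(coefficients)) &&
      !identical(names(vip_values), names(coefficients)))
    coefficients <- coefficients[names(vip_values)]
  cls <- ifelse(vip_values > 1.0, "strong",
                ifelse(vip_values >= 0.5, "weak", "unimportant"))
  sgn <- ifelse(coefficients > 0, "positive",
                ifelse(coefficients < 0, "negative", "none"))
  vars <- names(vip_values)
  if (is.null(vars)) vars <- paste0("X", seq_along(vip_values))
  out <- data.frame(variable = vars, vip = as.numeric(vip_values),
                    coefficient = as.numeric(coefficients),
                    class = cls, sign = sgn,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("contribution_report", "data.frame")
  out
}

#' Contributor report for a fitted model
#'
#' Convenience wrapper combining [vip] and [coef.pls1] with
#' [classify_contributors].
#'
#' @param model A fitted `"pls1"` model.
#' @return A `"contribution_report"` data frame.
#' @export
contributions <- function(model) {
  classify_contributors(vip(model), stats::coef(model))
}

#' Cross-activity contributor summary
#'
#' Condenses one contribution report per activity into a summary table
#' listing, per activity, the positive and negative contributors: strong
#' contributors first, each class ordered by descending VIP (ties broken
#' by descriptor column order), weak contributors in brackets.
#'
#' @param reports Named list of `"contribution_report"` objects, one per
#'   activity (may be empty).
#' @return A data frame with one row per activity and columns
#'   `activity`, `strong_positive`, `weak_positive`, `strong_negative`,
#'   `weak_negative` (comma-separated variable lists) plus a rendered
#'   `positive` / `negative` pair using the bracket convention.
#' @export
contribution_table <- function(reports) {
  cols <- c("strong_positive", "weak_positive", "strong_negative",
            "weak_negative")
  if (length(reports) == 0L) {
    out <- data.frame(activity = character(),
                      strong_positive = character(),
                      weak_positive = character(),
                      strong_negative = character(),
                      weak_negative = character(),
                      positive = character(), negative = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  pick <- function(rep, cls, sgn) {
    r <- rep[rep$class == cls & rep$sign == sgn, , drop = FALSE]
    r <- r[order(-r$vip), , drop = FALSE]  # stable: ties keep column order
    paste(r$variable, collapse = ", ")
  }
  rows <- lapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    sp <- pick(rep, "strong", "positive"); wp <- pick(rep, "weak", "positive")
    sn <- pick(rep, "strong", "negative"); wn <- pick(rep, "weak", "negative")
    bracket <- function(s, w) {
      w <- if (nzchar(w)) paste0(" (", w, ")") else ""
      paste0(s, w)
    }
    data.frame(activity = nm, strong_positive = sp, weak_positive = wp,
               strong_negative = sn, weak_negative = wn,
               positive = bracket(sp, wp), negative = bracket(sn, wn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
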