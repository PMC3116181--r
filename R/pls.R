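# NIPALS PLS1 regression on autoscaled data. For a single response the
# weight extraction per component is non-iterative: w_a is the normalised
# covariance between the deflated X block and the current y residual, so no
# convergence tolerance is involved (unlike multi-response PLS2).

#' Fit a single-response PLS regression (NIPALS)
#'
#' Extracts `a` latent components from the predictor block by the NIPALS
#' algorithm with X deflation: for each component, the unit-norm weight
#' vector `w` maximises covariance between the X residual and the y
#' residual, scores are `t = X w`, X loadings `p = X't / t't`, the y
#' loading `c = t'y / t't`, and X (and y) are deflated by the rank-one
#' fit `t p'` (and `t c`). Latent-vector signs are fixed so that each
#' weight vector's largest-magnitude element is positive, making
#' coefficients and VIP values reproducible across platforms.
#'
#' @param x Descriptor matrix (samples x variables), raw or pre-scaled.
#' @param y Numeric response vector, raw or pre-scaled.
#' @param a Number of latent components (at least 1, at most `rank(x)`).
#' @param scale If `TRUE` (default) autoscale `x` and `y` internally and
#'   store the parameters for back-transformation; if `FALSE`, `x` and `y`
#'   are taken as already centred and scaled (identity back-transform).
#' @return An object of class `"pls1"`: weights `W` (p x a, unit-norm
#'   columns), X loadings `P`, y loadings `c`, X scores `T` (columns
#'   mutually orthogonal), y scores `U` (the y residual entering each
#'   component), the coefficient vector `b = W (P'W)^-1 c` on scaled data,
#'   cumulative `r2` per component count, and the scaling parameters.
#' @export
fit_pls1 <- function(x, y, a, scale = TRUE) {
  x <- as.matrix(unclass(x))
  y <- as.numeric(y)
  if (length(y) != nrow(x))
    stop("x and y have different numbers of samples", call. = FALSE)
  if (a < 1L) stop("number of components must be at least 1", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (scale) {
    sc <- autoscale(x, y)
    xs <- sc$x; ys <- sc$y; params <- sc$params
  } else {
    xs <- x; ys <- y
    params <- list(x_center = stats::setNames(rep(0, ncol(x)), colnames(x)),
                   x_scale = stats::setNames(rep(1, ncol(x)), colnames(x)),
                   y_center = 0, y_scale = 1)
  }
  if (sum(ys^2) == 0) stop("response has zero variance", call. = FALSE)
  rank_x <- qr(xs)$rank
  if (a > rank_x)
    stop("a = ", a, " exceeds rank(x) = ", rank_x, call. = FALSE)

  n <- nrow(xs); p <- ncol(xs)
  W <- P <- matrix(0, p, a, dimnames = list(colnames(x), NULL))
  Tm <- U <- matrix(0, n, a, dimnames = list(rownames(x), NULL))
  cvec <- numeric(a)
  ss_tot <- sum(ys^2)
  r2 <- numeric(a)
  Xd <- xs; yd <- ys
  for (k in seq_len(a)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12)
      stop("component ", k, " has no remaining covariance with y ",
           "(rank exhausted)", call. = FALSE)
    w <- w / wn
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    tvec <- drop(Xd %*% w)
    tt <- sum(tvec^2)
    pvec <- drop(crossprod(Xd, tvec)) / tt
    cc <- sum(tvec * yd) / tt
    W[, k] <- w; P[, k] <- pvec; cvec[k] <- cc
    Tm[, k] <- tvec; U[, k] <- yd
    Xd <- Xd - tcrossprod(tvec, pvec)
    yd <- yd - tvec * cc
    r2[k] <- 1 - sum(yd^2) / ss_tot
  }
  b <- drop(W %*% solve(crossprod(P, W), cvec))
  names(b) <- colnames(x)
  structure(list(A = a, W = W, P = P, c = cvec, T = Tm, U = U, b = b,
                 r2 = r2, params = params, columns = colnames(x),
                 fitted_scaled = drop(xs %*% b), y_scaled = ys),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS1 model:", length(x$columns), "variables,", x$A,
      sprintf("component(s), R2 = %.3f\n", x$r2[x$A]))
  invisible(x)
}

#' Predict activities for new samples
#'
#' Applies the stored centring/scaling to the new descriptor rows, the
#' latent-space coefficient vector, and the inverse response scaling, so
#' predictions are returned in original activity units.
#'
#' @param object A fitted `"pls1"` model.
#' @param newdata Matrix of descriptors with the training columns (any
#'   order; matched by name).
#' @param ... Unused.
#' @return Numeric vector of predictions in original units.
#' @export
predict.pls1 <- function(object, newdata, ...) {
  newdata <- as.matrix(unclass(newdata))
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$columns))
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           length(object$columns), call. = FALSE)
    colnames(newdata) <- object$columns
  }
  missing <- setdiff(object$columns, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$columns)
  if (length(missing) > 0L || length(extra) > 0L)
    stop("descriptor column mismatch; missing: ",
         paste(missing, collapse = ", "), "; unexpected: ",
         paste(extra, collapse = ", "), call. = FALSE)
  newdata <- newdata[, object$columns, drop = FALSE]
  pr <- object$params
  xs <- sweep(sweep(newdata, 2L, pr$x_center), 2L, pr$x_scale, "/")
  drop(xs %*% object$b) * pr$y_scale + pr$y_center
}

#' Fitted values in original units
#' @param object A fitted `"pls1"` model.
#' @param ... Unused.
#' @export
fitted.pls1 <- function(object, ...) {
  object$fitted_scaled * object$params$y_scale + object$params$y_center
}

#' Regression coefficients on centred and scaled data
#'
#' The per-variable coefficients `b = W (P'W)^-1 c` of the latent model,
#' expressed on autoscaled predictors and response. These are the values
#' shown in coefficient plots: magnitude measures a variable's contribution
#' to explaining the response, sign its direction.
#'
#' @param object A fitted `"pls1"` model.
#' @param ... Unused.
#' @return Named numeric vector, one coefficient per descriptor.
#' @export
coef.pls1 <- function(object, ...) object$b

#' Per-component score pairs for inner-relation (t/u) plots
#'
#' For each latent component, the X score `t` and the y score `u` (the
#' response residual entering that component). A tight linear t/u relation
#' indicates that the latent structure of the descriptors explains the
#' activity well.
#'
#' @param model A fitted `"pls1"` model.
#' @return Data frame with columns `component`, `sample_id`, `t`, `u`.
#' @export
scores_tu <- function(model) {
  stopifnot(inherits(model, "pls1"))
  n <- nrow(model$T)
  ids <- rownames(model$T)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  do.call(rbind, lapply(seq_len(model$A), function(a) {
    data.frame(component = a, sample_id = ids,
               t = model$T[, a], u = model$U[, a], row.names = NULL)
  }))
}

#' Cumulative explained response variance
#'
#' `R2(a) = 1 - SS_res(a) / SS_tot` on the scaled response, for each
#' cumulative component count `a = 1..A`. Non-decreasing in `a`.
#'
#' @param model A fitted `"pls1"` model.
#' @return Numeric vector of length `A`.
#' @export
r2_cumulative <- function(model) {
  stopifnot(inherits(model, "pls1"))
  model$r2
}
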