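# Model validation: cross-validated Q2, significant-component selection,
# and the response-permutation (y-scrambling) validity test.

#' Validation configuration
#'
#' Bundles the tunable validation settings with their defaults: 7
#' round-robin ("venetian blind") cross-validation groups assigned in
#' sample order, 20 response permutations, a per-component Q2 limit of
#' 0.05 for keeping a latent component, and the permutation-intercept
#' validity limits (R2 intercept < 0.4, Q2 intercept < 0.05).
#'
#' @param folds Number of cross-validation exclusion groups (ignored when
#'   `cv_mode = "loo"`).
#' @param cv_mode `"venetian"` (round-robin groups) or `"loo"`
#'   (leave-one-out).
#' @param n_permutations Rounds of response permutation.
#' @param seed Integer seed for the permutation draws.
#' @param q2_component_limit Minimum per-component Q2 for a component to
#'   count as significant.
#' @param r2_intercept_limit Maximum permutation R2 intercept of a valid
#'   model.
#' @param q2_intercept_limit Maximum permutation Q2 intercept of a valid
#'   model.
#' @param q2_type `"cumulative"` (default) or `"component"`: which Q2
#'   statistic the permutation test records.
#' @return A list of class `"validation_config"`.
#' @export
validation_config <- function(folds = 7L, cv_mode = c("venetian", "loo"),
                              n_permutations = 20L, seed = 1L,
                              q2_component_limit = 0.05,
                              r2_intercept_limit = 0.4,
                              q2_intercept_limit = 0.05,
                              q2_type = c("cumulative", "component")) {
  structure(list(folds = as.integer(folds), cv_mode = match.arg(cv_mode),
                 n_permutations = as.integer(n_permutations),
                 seed = seed, q2_component_limit = q2_component_limit,
                 r2_intercept_limit = r2_intercept_limit,
                 q2_intercept_limit = q2_intercept_limit,
                 q2_type = match.arg(q2_type)),
            class = "validation_config")
}

# Round-robin fold assignment in sample order (the "venetian blind"
# scheme); leave-one-out assigns each sample its own group.
cv_assignments <- function(n, folds, cv_mode) {
  if (cv_mode == "loo") return(seq_len(n))
  folds <- as.integer(folds)
  if (folds < 2L || folds > n)
    stop("fold count must be between 2 and the number of samples",
         call. = FALSE)
  ((seq_len(n) - 1L) %% folds) + 1L
}

# Cumulative coefficient vectors b(1), ..., b(A) of a fitted model, one
# column per component count.
coef_per_component <- function(model) {
  p <- nrow(model$W)
  out <- matrix(0, p, model$A, dimnames = list(model$columns, NULL))
  for (a in seq_len(model$A)) {
    Wa <- model$W[, seq_len(a), drop = FALSE]
    Pa <- model$P[, seq_len(a), drop = FALSE]
    out[, a] <- drop(Wa %*% solve(crossprod(Pa, Wa), model$c[seq_len(a)]))
  }
  out
}

#' Cross-validate a PLS model
#'
#' Splits the samples into exclusion groups, refits the model on each
#' training remainder (centring and scaling recomputed on the training
#' part only, so no information leaks from held-out samples), and predicts
#' the held-out responses for every cumulative component count. The
#' predictive residual sum of squares `PRESS_a` is accumulated in
#' full-data scaled-response units and compared against the fitted
#' residual sum of squares of the previous component,
#' `Q2_a = 1 - PRESS_a / SS_(a-1)` with `SS_0` the total (centred) sum of
#' squares; the cumulative statistic uses the product rule
#' `Q2cum_a = 1 - prod_k (PRESS_k / SS_(k-1))`.
#'
#' @param x Descriptor matrix (raw units).
#' @param y Numeric response (raw units), aligned with `x` rows.
#' @param a_max Maximum number of components to evaluate; silently capped
#'   at the feasible rank of every training fold.
#' @param folds Number of exclusion groups.
#' @param cv_mode `"venetian"` or `"loo"`.
#' @return A list of class `"cv_result"`: `press`, `ss` (residual SS per
#'   fitted component count, with `ss[1]` = SS_0), per-component `q2_comp`,
#'   cumulative `q2_cum`, the evaluated `a_max`, and the scheme.
#' @export
cross_validate <- function(x, y, a_max = NULL, folds = 7L,
                           cv_mode = c("venetian", "loo")) {
  cv_mode <- match.arg(cv_mode)
  x <- as.matrix(unclass(x))
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("x and y sizes differ", call. = FALSE)
  assign <- cv_assignments(n, if (cv_mode == "loo") n else folds, cv_mode)
  groups <- sort(unique(assign))
  n_train_min <- min(vapply(groups, function(g) sum(assign != g), 0L))
  if (n_train_min < 3L)
    stop("a fold leaves fewer than 3 training samples", call. = FALSE)
  if (is.null(a_max)) a_max <- min(ncol(x), n_train_min - 1L)
  a_max <- min(a_max, ncol(x), n_train_min - 1L)
  # cap at the rank actually reachable in every training fold
  full_sc <- autoscale(x, y)
  a_max <- min(a_max, qr(full_sc$x)$rank,
               min(vapply(groups, function(g)
                 qr(scale(x[assign != g, , drop = FALSE],
                          scale = FALSE))$rank, 0L)))
  if (a_max < 1L) stop("no usable components (rank 0)", call. = FALSE)

  # fitted residual SS per component count on full-data scaled y
  full_fit <- fit_pls1(full_sc$x, full_sc$y, a_max, scale = FALSE)
  ss_tot <- sum(full_sc$y^2)
  ss <- c(ss_tot, (1 - full_fit$r2) * ss_tot)  # ss[a+1] = SS_a

  press <- numeric(a_max)
  y_sd <- full_sc$params$y_scale
  for (g in groups) {
    test <- assign == g
    fit <- fit_pls1(x[!test, , drop = FALSE], y[!test], a_max, scale = TRUE)
    bb <- coef_per_component(fit)
    pr <- fit$params
    xs <- sweep(sweep(x[test, , drop = FALSE], 2L, pr$x_center), 2L,
                pr$x_scale, "/")
    pred <- xs %*% bb * pr$y_scale + pr$y_center   # n_test x a_max, original units
    resid <- (y[test] - pred) / y_sd               # full-data scaled units
    press <- press + colSums(resid^2)
  }
  q2_comp <- 1 - press / ss[seq_len(a_max)]
  q2_cum <- 1 - cumprod(press / ss[seq_len(a_max)])
  structure(list(press = press, ss = ss, q2_comp = q2_comp, q2_cum = q2_cum,
                 a_max = a_max, folds = length(groups), cv_mode = cv_mode),
            class = "cv_result")
}

#' Select the number of significant latent components
#'
#' The model keeps the largest component count `A` such that every
#' component up to `A` has per-component `Q2 >= q2_limit`. `A = 0` is a
#' legitimate outcome and marks "no valid model": nothing in the data
#' predicts better than the response mean.
#'
#' @inheritParams cross_validate
#' @param q2_limit Per-component significance limit (default 0.05).
#' @return Integer component count (possibly 0).
#' @export
select_components <- function(x, y, a_max = NULL, folds = 7L,
                              cv_mode = c("venetian", "loo"),
                              q2_limit = 0.05) {
  cv <- cross_validate(x, y, a_max = a_max, folds = folds,
                       cv_mode = match.arg(cv_mode))
  fail <- which(cv$q2_comp < q2_limit)
  if (length(fail) == 0L) cv$a_max else fail[1L] - 1L
}

#' Response-permutation (y-scrambling) validity test
#'
#' Refits the model on randomly permuted responses (predictors unaltered)
#' to estimate the chance level of the fit and predictive statistics. For
#' each of `n_perm` permutations the absolute Pearson correlation between
#' the permuted and original response is recorded together with the
#' refitted model's cumulative R2 and cross-validated Q2 (same component
#' count, same cross-validation scheme). A straight line is fitted through
#' the `n_perm + 1` points (the unpermuted model sits at correlation 1)
#' separately for R2 and Q2; the intercepts at correlation zero estimate
#' what the statistics would be for a response unrelated to the
#' descriptors. A model is considered valid when the R2 intercept is
#' below `r2_limit` (default 0.4) and the Q2 intercept below `q2_limit`
#' (default 0.05).
#'
#' @inheritParams cross_validate
#' @param a Number of components of the model under test (>= 1).
#' @param n_perm Number of permutations (>= 2; 20 is conventional).
#' @param seed Integer seed making the permutation draws reproducible.
#' @param r2_limit,q2_limit Validity limits for the two intercepts.
#' @param q2_type `"cumulative"` or `"component"` Q2 statistic.
#' @return A list of class `"perm_result"`: a `points` data frame
#'   (`correlation`, `r2`, `q2`; first row the unpermuted model),
#'   `r2_intercept`, `q2_intercept`, the fitted slopes, and `valid`.
#' @export
permutation_test <- function(x, y, a, n_perm = 20L, seed = 1L,
                             folds = 7L, cv_mode = c("venetian", "loo"),
                             r2_limit = 0.4, q2_limit = 0.05,
                             q2_type = c("cumulative", "component")) {
  cv_mode <- match.arg(cv_mode)
  q2_type <- match.arg(q2_type)
  x <- as.matrix(unclass(x))
  y <- as.numeric(y)
  if (a < 1L) stop("permutation test needs a fitted model with a >= 1",
                   call. = FALSE)
  if (n_perm < 2L) stop("n_perm must be at least 2", call. = FALSE)
  if (stats::sd(y) == 0) stop("response is constant", call. = FALSE)
  n <- length(y)

  stat_pair <- function(yy) {
    fit <- fit_pls1(x, yy, a, scale = TRUE)
    cv <- cross_validate(x, yy, a_max = a, folds = folds, cv_mode = cv_mode)
    aa <- min(a, cv$a_max)
    q2 <- if (q2_type == "cumulative") cv$q2_cum[aa] else cv$q2_comp[aa]
    c(r2 = fit$r2[a], q2 = q2)
  }

  orig <- stat_pair(y)
  if (!is.null(seed)) set.seed(seed)
  cors <- r2s <- q2s <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    repeat {
      idx <- sample.int(n)
      if (!all(idx == seq_len(n))) break
    }
    yp <- y[idx]
    cors[i] <- abs(stats::cor(yp, y))
    st <- stat_pair(yp)
    r2s[i] <- st["r2"]; q2s[i] <- st["q2"]
  }
  points <- data.frame(correlation = c(1, cors), r2 = c(orig["r2"], r2s),
                       q2 = c(orig["q2"], q2s), row.names = NULL)
  line_r2 <- stats::lm.fit(cbind(1, points$correlation), points$r2)$coefficients
  line_q2 <- stats::lm.fit(cbind(1, points$correlation), points$q2)$coefficients
  r2_int <- unname(line_r2[1L]); q2_int <- unname(line_q2[1L])
  structure(list(points = points, n_perm = n_perm, seed = seed,
                 r2_intercept = r2_int, q2_intercept = q2_int,
                 r2_slope = unname(line_r2[2L]), q2_slope = unname(line_q2[2L]),
                 valid = (r2_int < r2_limit) && (q2_int < q2_limit),
                 q2_type = q2_type),
            class = "perm_result")
}

#' Validate one activity / descriptor-set model
#'
#' The full validation workflow for one response and one descriptor set:
#' assemble the X block for the samples on which the activity was
#' measured, select the number of significant components by
#' cross-validation, fit the model, and run the permutation test. The
#' result mirrors one row of a model-summary table: sample count, X set,
#' component count, R2, cumulative Q2, the two permutation intercepts and
#' the validity verdict.
#'
#' @param dataset An [aa_dataset] whose `activities` contain `activity`.
#' @param activity Name of the activity to model.
#' @param x_set Descriptor set token (see [assemble_x]).
#' @param config A [validation_config].
#' @return A list of class `"validation_report"` with fields `n`, `x_set`,
#'   `activity`, `a`, `r2`, `q2cv`, `perm_r2_intercept`,
#'   `perm_q2_intercept`, `valid`.
#' @export
validate_model <- function(dataset, activity, x_set = "all",
                           config = validation_config()) {
  stopifnot(inherits(dataset, "aa_dataset"))
  act <- dataset$activities[[activity]]
  if (is.null(act))
    stop("activity not found: '", activity, "' (available: ",
         paste(names(dataset$activities), collapse = ", "), ")",
         call. = FALSE)
  sub <- subset_samples(dataset, act$sample_id)
  x <- assemble_x(sub, x_set)
  y <- act$value
  a <- select_components(x, y, folds = config$folds,
                         cv_mode = config$cv_mode,
                         q2_limit = config$q2_component_limit)
  rep <- list(activity = activity, n = nrow(x),
              x_set = normalize_x_set(x_set), a = a,
              r2 = NA_real_, q2cv = NA_real_,
              perm_r2_intercept = NA_real_, perm_q2_intercept = NA_real_,
              valid = FALSE)
  if (a >= 1L) {
    fit <- fit_pls1(x, y, a, scale = TRUE)
    cv <- cross_validate(x, y, a_max = a, folds = config$folds,
                         cv_mode = config$cv_mode)
    pt <- permutation_test(x, y, a, n_perm = config$n_permutations,
                           seed = config$seed, folds = config$folds,
                           cv_mode = config$cv_mode,
                           r2_limit = config$r2_intercept_limit,
                           q2_limit = config$q2_intercept_limit,
                           q2_type = config$q2_type)
    rep$r2 <- fit$r2[a]
    rep$q2cv <- cv$q2_cum[min(a, cv$a_max)]
    rep$perm_r2_intercept <- pt$r2_intercept
    rep$perm_q2_intercept <- pt$q2_intercept
    rep$valid <- pt$valid
    rep$model <- fit
    rep$permutation <- pt
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%-12s N=%-3d X=%-8s A=%d  R2=%s  Q2cv=%s  IntR2=%s  IntQ2=%s  %s\n",
              x$activity, x$n, x$x_set, x$a, fmt3(x$r2), fmt3(x$q2cv),
              fmt3(x$perm_r2_intercept), fmt3(x$perm_q2_intercept),
              if (isTRUE(x$valid)) "valid" else "not valid"))
  invisible(x)
}

fmt3 <- function(v) if (is.na(v)) "  NA " else sprintf("%.3f", v)

# Restrict a dataset to a subset of samples (activity tables are trimmed
# to the retained ids).
subset_samples <- function(dataset, ids) {
  stopifnot(inherits(dataset, "aa_dataset"))
  missing <- setdiff(ids, rownames(dataset$composition))
  if (length(missing) > 0L)
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  comp <- composition_matrix(unclass(dataset$composition)[ids, , drop = FALSE],
                             sample_ids = ids, row_sum_action = "none")
  acts <- lapply(dataset$activities, function(a) {
    keep <- a$sample_id %in% ids
    activity_table(a$sample_id[keep], a$value[keep],
                   attr(a, "activity_name"), attr(a, "units"))
  })
  aa_dataset(comp, acts, dataset$zscales, dataset$groups_ref, dataset$notes)
}
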