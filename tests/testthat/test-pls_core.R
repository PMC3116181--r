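# NIPALS PLS1: analytic one-component solution, least-squares equivalence
# at full rank, score orthogonality, prediction consistency.

test_that("one-component weights are the normalised covariance direction", {
  inst <- random_instance(12, 5, seed = 41)
  sc <- autoscale(inst$x, inst$y)
  m <- fit_pls1(sc$x, sc$y, 1, scale = FALSE)
  w_direct <- drop(crossprod(sc$x, sc$y))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  if (w_direct[which.max(abs(w_direct))] < 0) w_direct <- -w_direct
  expect_equal(unname(m$W[, 1]), unname(w_direct), tolerance = 1e-12)
  expect_equal(sum(m$W[, 1]^2), 1, tolerance = 1e-12)
})

test_that("full-rank fits and coefficients match the least-squares oracle", {
  for (seed in 1:8) {
    n <- sample(7:10, 1)
    p <- sample(3:min(8, n - 2), 1)
    inst <- random_instance(n, p, seed = seed * 13)
    sc <- autoscale(inst$x, inst$y)
    m <- fit_pls1(sc$x, sc$y, p, scale = FALSE)
    ols <- lm.fit(sc$x, sc$y)
    expect_lt(max(abs(drop(sc$x %*% m$b) - ols$fitted.values)), 1e-8)
    expect_lt(max(abs(m$b - ols$coefficients)), 1e-8)
  }
})

test_that("a response orthogonal to the descriptors explains nothing", {
  set.seed(5)
  n <- 12; p <- 4
  y <- scale(rnorm(n))[, 1]
  x <- matrix(rnorm(n * p), n, p)
  # residualise each column against y (and centre), leaving ~zero covariance
  x <- apply(x, 2, function(col) {
    r <- residuals(lm.fit(cbind(1, y), col))
    r + rnorm(n, sd = 1e-6)  # keep covariance tiny but nonzero
  })
  colnames(x) <- paste0("V", 1:p)
  sc <- autoscale(x)
  m <- fit_pls1(sc$x, y, 1, scale = FALSE)
  expect_lt(m$r2[1], 1e-8)
})

test_that("rank and degenerate-response guards fire", {
  inst <- random_instance(8, 4, seed = 2)
  expect_error(fit_pls1(inst$x, inst$y, 5), "rank")
  expect_error(fit_pls1(inst$x, rep(2, 8), 1), "zero variance")
  expect_error(fit_pls1(inst$x, inst$y, 0), "at least 1")
})

test_that("prediction is consistent with fitting and back-transformation", {
  inst <- random_instance(14, 6, seed = 99)
  m <- fit_pls1(inst$x, inst$y, 3)
  # training-set predictions reproduce fitted values
  expect_lt(max(abs(predict(m, inst$x) - fitted(m))), 1e-10)
  # a row at the training column means predicts the training response mean
  centre <- matrix(m$params$x_center, 1,
                   dimnames = list(NULL, colnames(inst$x)))
  expect_equal(unname(predict(m, centre)), mean(inst$y), tolerance = 1e-10)
  # column order of new data must not matter
  shuf <- sample(ncol(inst$x))
  expect_equal(predict(m, inst$x[, shuf]), predict(m, inst$x),
               tolerance = 1e-12)
  # mismatched columns are reported
  x2 <- inst$x; colnames(x2)[1] <- "OTHER"
  expect_error(predict(m, x2), "mismatch")
})

test_that("a noiseless linear response is recovered on held-out samples", {
  set.seed(17)
  x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("V", 1:5)))
  beta <- c(2, -1, 0.5, 0, 3)
  y <- drop(x %*% beta)
  train <- 1:20; test <- 21:30
  m <- fit_pls1(x[train, ], y[train], 5)
  expect_lt(max(abs(predict(m, x[test, ]) - y[test])), 1e-6)
})

test_that("coefficients are linear in y and agree with the score route", {
  inst <- random_instance(12, 5, seed = 7)
  m_pos <- fit_pls1(inst$x, inst$y, 3)
  m_neg <- fit_pls1(inst$x, -inst$y, 3)
  expect_equal(m_neg$b, -m_pos$b, tolerance = 1e-10)
  # prediction via coefficients equals prediction via sequential scores
  sc <- autoscale(inst$x, inst$y)
  m <- fit_pls1(sc$x, sc$y, 3, scale = FALSE)
  Xd <- sc$x
  yhat_scores <- rep(0, nrow(Xd))
  for (a in 1:3) {
    t_a <- drop(Xd %*% m$W[, a])
    yhat_scores <- yhat_scores + t_a * m$c[a]
    Xd <- Xd - tcrossprod(t_a, m$P[, a])
  }
  expect_lt(max(abs(drop(sc$x %*% m$b) - yhat_scores)), 1e-10)
})

test_that("scores are orthogonal, weights unit-norm, R2 monotone", {
  for (seed in c(3, 11, 29)) {
    inst <- random_instance(15, 7, seed = seed)
    m <- fit_pls1(inst$x, inst$y, 5)
    g <- crossprod(m$T)
    off <- g - diag(diag(g))
    # normalised off-diagonal inner products
    expect_lt(max(abs(off)) / min(diag(g)), 1e-8)
    expect_equal(unname(colSums(m$W^2)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(diff(m$r2) >= -1e-12))
    expect_true(m$r2[5] >= 0 && m$r2[5] <= 1 + 1e-12)
  }
})

test_that("the fit is invariant under descriptor column reordering", {
  inst <- random_instance(14, 6, seed = 23)
  m1 <- fit_pls1(inst$x, inst$y, 3)
  shuf <- c(4, 1, 6, 2, 5, 3)
  m2 <- fit_pls1(inst$x[, shuf], inst$y, 3)
  expect_lt(max(abs(predict(m2, inst$x) - predict(m1, inst$x))), 1e-8)
  expect_equal(m2$b[colnames(inst$x)], m1$b[colnames(inst$x)],
               tolerance = 1e-8)
})

test_that("t/u score pairs express the inner relation", {
  # noiseless single-latent-factor data: perfect first inner relation
  set.seed(31)
  t_true <- rnorm(20)
  loadp <- rnorm(6)
  x <- outer(t_true, loadp)
  colnames(x) <- paste0("V", 1:6)
  x <- x + matrix(rnorm(120, sd = 1e-8), 20)
  y <- 2 * t_true
  m <- fit_pls1(x, y, 1)
  tu <- scores_tu(m)
  expect_equal(abs(cor(tu$t, tu$u)), 1, tolerance = 1e-8)

  # permuting samples permutes scores identically
  inst <- random_instance(12, 5, seed = 53)
  rownames(inst$x) <- paste0("S", 1:12)
  m1 <- fit_pls1(inst$x, inst$y, 2)
  perm <- sample(12)
  m2 <- fit_pls1(inst$x[perm, ], inst$y[perm], 2)
  expect_equal(m2$T, m1$T[perm, ], tolerance = 1e-10)

  # the first component usually carries the tightest inner relation
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed * 7)
    x <- matrix(rnorm(16 * 8), 16, 8)
    y <- drop(x %*% rnorm(8)) + rnorm(16, sd = 0.5)
    m <- fit_pls1(x, y, 2)
    tu <- scores_tu(m)
    c1 <- abs(cor(tu$t[tu$component == 1], tu$u[tu$component == 1]))
    c2 <- abs(cor(tu$t[tu$component == 2], tu$u[tu$component == 2]))
    if (c1 >= c2) hits <- hits + 1
  }
  expect_gte(hits, 8)  # flag-level property, not a theorem
})
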