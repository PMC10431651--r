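test_that("canonical HRF has the stated shape parameters", {
  for (fs in c(4, 7.8125)) {
    h <- canonical_hrf(fs)
    expect_lte(abs(h$t[which.max(h$kernel)] - 4), 1 / fs)
    expect_equal(h$kernel[1], 0)
    expect_equal(max(h$kernel), 1)
    expect_lt(abs(abs(min(h$kernel)) / max(h$kernel) - 1 / 6), 0.02)
    # undershoot minimum near 16 s, support ends at 32 s
    expect_lt(abs(h$t[which.min(h$kernel)] - 16), 2)
    expect_lt(abs(h$kernel[length(h$kernel)]), 0.02)
  }
})

test_that("design matrices have the advertised columns", {
  par <- default_paradigm()
  hrf <- canonical_hrf(4)
  n <- 4080
  sc <- stats::rnorm(n)
  d <- build_design(par, hrf, 4, n, sc = sc, mode = "trialwise")
  expect_equal(ncol(d$X), 18L)  # 15 task + rest + sc + intercept
  expect_setequal(d$task_cols, sprintf("task_%02d", 1:15))
  # each trial column peaks inside (onset, onset + 62 s)
  for (i in c(1, 8, 15)) {
    pk <- (which.max(d$X[, sprintf("task_%02d", i)]) - 1) / 4
    expect_gt(pk, par$onsets[i])
    expect_lt(pk, par$onsets[i] + 62)
  }
  dp <- build_design(par, hrf, 4, n, sc = sc, mode = "pooled",
                     selected_trials = 1:10)
  expect_setequal(colnames(dp$X),
                  c("task_selected", "task_unselected", "rest", "sc",
                    "intercept"))
  d15 <- build_design(par, hrf, 4, n, mode = "pooled",
                      selected_trials = 1:15)
  expect_false("task_unselected" %in% colnames(d15$X))
  expect_error(build_design(par, hrf, 4, n, mode = "pooled",
                            selected_trials = integer(0)), "non-empty")
  # duplicated regressor -> rank-deficiency error naming the column
  expect_error(build_design(par, hrf, 4, n, sc = cbind(sc, sc),
                            mode = "trialwise"), "collinear")
})

test_that("with identity AR and unit weights the fit is exactly OLS", {
  set.seed(31)
  n <- 400
  X <- cbind(task = stats::rnorm(n), drift = seq_len(n) / n, intercept = 1)
  beta_true <- c(0.5, 1, 2)
  y <- drop(X %*% beta_true) + stats::rnorm(n)
  d <- structure(list(X = X, task_cols = "task", fs = 1, band = NULL,
                      provenance = NULL), class = "nf_design")
  f <- fit_ar_irls(matrix(y, dimnames = list(NULL, "ch")), d,
                   ar_order = 0L, robust = FALSE)
  # closed-form OLS oracle
  beta_ols <- solve(crossprod(X), crossprod(X, y))
  expect_lt(max(abs(f$beta - beta_ols) / abs(beta_ols)), 1e-6)
  se_ols <- sqrt(diag(solve(crossprod(X))) *
                   sum((y - X %*% beta_ols)^2) / (n - 3))
  expect_equal(f$se, as.numeric(se_ols), tolerance = 1e-10)
  # BIC picks order zero on white residuals, so the default path agrees too
  f2 <- fit_ar_irls(matrix(y, dimnames = list(NULL, "ch")), d, robust = FALSE)
  expect_equal(unique(f2$ar_order), 0L)
})

test_that("AR prewhitening removes serial correlation from AR(1) noise", {
  set.seed(32)
  n <- 2000
  X <- cbind(task = stats::rnorm(n), intercept = 1)
  eps <- as.numeric(stats::arima.sim(list(ar = 0.8), n))
  y <- drop(X %*% c(1, 0)) + eps
  d <- structure(list(X = X, task_cols = "task", fs = 1, band = NULL,
                      provenance = NULL), class = "nf_design")
  f <- fit_ar_irls(matrix(y, dimnames = list(NULL, "ch")), d, robust = FALSE)
  p <- unique(f$ar_order)
  expect_gte(p, 1L)
  # rebuild the whitened residuals the same way the fitter does
  r <- y - drop(X %*% f$beta)
  phi <- stats::ar.yw(r, aic = FALSE, order.max = p, demean = TRUE)$ar
  e <- nirsfeed:::ar_whiten(r, phi)
  expect_lt(abs(stats::acf(e, plot = FALSE)$acf[2]), 0.1)
})

test_that("type-I error is near nominal for AR(1) noise (classic path)", {
  set.seed(33)
  n <- 300
  X <- cbind(task = stats::rnorm(n), intercept = 1)
  d <- structure(list(X = X, task_cols = "task", fs = 1, band = NULL,
                      provenance = NULL), class = "nf_design")
  ps <- replicate(200, {
    y <- as.numeric(stats::arima.sim(list(ar = 0.6), n))
    f <- fit_ar_irls(matrix(y, dimnames = list(NULL, "ch")), d,
                     robust = FALSE)
    f$p[f$regressor == "task"]
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("t statistics are invariant to positive rescaling", {
  set.seed(34)
  n <- 300
  X <- cbind(task = stats::rnorm(n), nuis = stats::rnorm(n), intercept = 1)
  y <- drop(X %*% c(1, 0.3, -1)) + stats::rnorm(n)
  mk <- function(X) structure(list(X = X, task_cols = "task", fs = 1,
                                   band = NULL, provenance = NULL),
                              class = "nf_design")
  f1 <- fit_ar_irls(matrix(y, dimnames = list(NULL, "ch")), mk(X))
  X2 <- X %*% diag(c(7, 0.2, 3))
  colnames(X2) <- colnames(X)
  f2 <- fit_ar_irls(matrix(5 * y, dimnames = list(NULL, "ch")), mk(X2))
  expect_equal(f1$t, f2$t, tolerance = 1e-6)
})

test_that("robust reweighting resists gross outliers", {
  set.seed(35)
  n <- 500
  X <- cbind(task = stats::rnorm(n), intercept = 1)
  y <- drop(X %*% c(1, 0)) + stats::rnorm(n, 0, 0.5)
  y[sample(n, 10)] <- 50  # motion-artifact-like spikes
  d <- structure(list(X = X, task_cols = "task", fs = 1, band = NULL,
                      provenance = NULL), class = "nf_design")
  f_rob <- fit_ar_irls(matrix(y, dimnames = list(NULL, "ch")), d,
                       ar_order = 0L, robust = TRUE)
  f_ols <- fit_ar_irls(matrix(y, dimnames = list(NULL, "ch")), d,
                       ar_order = 0L, robust = FALSE)
  b_rob <- f_rob$beta[f_rob$regressor == "task"]
  b_ols <- f_ols$beta[f_ols$regressor == "task"]
  expect_lt(abs(b_rob - 1), abs(b_ols - 1))
  expect_lt(abs(b_rob - 1), 0.1)
})

test_that("ROI activation applies the per-ROI Bonferroni rule", {
  lay <- default_layout()
  nf <- roi_channels(lay, "nf_dlpfc")
  mk <- function(p, beta = rep(1, 4)) {
    out <- tibble::tibble(channel = nf, regressor = "task_selected",
                          beta = beta, se = 1, t = beta, p = p, dof = 100,
                          ar_order = 0L, converged = TRUE)
    class(out) <- c("nf_glm", class(out))
    out
  }
  # 0.04 > 0.05/4: nothing survives
  expect_length(roi_activation(mk(c(0.04, 0.2, 0.3, 0.5)), lay, "nf_dlpfc"), 0)
  # 0.01 < 0.0125: one channel
  expect_equal(roi_activation(mk(c(0.01, 0.2, 0.3, 0.5)), lay, "nf_dlpfc"),
               "S1-D1")
  # negative beta never activates, however small its p
  expect_length(
    roi_activation(mk(rep(1e-6, 4), beta = c(-1, -1, -1, -1)),
                   lay, "nf_dlpfc"), 0)
  # monotone in alpha
  r1 <- roi_activation(mk(c(0.001, 0.01, 0.2, 0.5)), lay, "nf_dlpfc",
                       alpha = 0.05)
  r2 <- roi_activation(mk(c(0.001, 0.01, 0.2, 0.5)), lay, "nf_dlpfc",
                       alpha = 0.01)
  expect_true(all(r2 %in% r1))
  expect_error(roi_activation(mk(rep(0.5, 4)), lay, "scalp"))
})
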