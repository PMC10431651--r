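#' Build a GLM design matrix for the neurofeedback paradigm
#'
#' In `trialwise` mode each of the 15 task blocks gets its own
#' HRF-convolved boxcar column, giving per-trial betas and t-values; in
#' `pooled` mode the selected trials form one task column
#' (`task_selected`) and the unselected trials, if any, one nuisance column
#' (`task_unselected`). Both modes add an HRF-convolved rest-block column,
#' optional short-channel nuisance column(s), and an intercept. The initial
#' 2-minute baseline stays unmodelled (implicit baseline). When `band` is
#' given, the paradigm-derived columns are zero-phase filtered with the same
#' band applied to the data, so filtering does not bias the betas;
#' short-channel columns come from the preprocessed data and are already
#' band-limited.
#'
#' @param paradigm An `nf_paradigm`.
#' @param hrf An `hrf_model` at `fs`.
#' @param fs Analysis sampling rate, Hz.
#' @param n Number of time samples.
#' @param sc Optional short-channel regressor: numeric vector or matrix
#'   with columns per regressor (time in rows).
#' @param mode `"trialwise"` or `"pooled"`.
#' @param selected_trials Trial indices forming the task column in pooled
#'   mode.
#' @param band Optional length-2 band (Hz) used to filter paradigm columns.
#' @param provenance Optional preprocessing provenance of the response the
#'   design will be fit against (list with `fs_in`, `n_in`, `mode`; filled
#'   automatically by [fit_subject_glm()] from `hemo$src`). When present
#'   and the preprocessing was zero-phase, [fit_ar_irls()] uses the
#'   filter-aware covariance.
#' @return An object of class `nf_design`: list with `X` (n x p matrix with
#'   labeled columns), `task_cols`, `condition_number`, `fs`.
#' @export
build_design <- function(paradigm, hrf, fs, n, sc = NULL,
                         mode = c("trialwise", "pooled"),
                         selected_trials = NULL, band = NULL,
                         provenance = NULL) {
  mode <- match.arg(mode)
  cols <- list()
  if (mode == "trialwise") {
    for (i in seq_len(paradigm$n_trials)) {
      cols[[sprintf("task_%02d", i)]] <-
        task_response(paradigm$onsets[i], paradigm$task_s, hrf, fs, n)
    }
  } else {
    if (is.null(selected_trials) || length(selected_trials) == 0) {
      stop("pooled mode needs a non-empty selected_trials")
    }
    if (any(selected_trials < 1 | selected_trials > paradigm$n_trials)) {
      stop("selected_trials must lie in 1..", paradigm$n_trials)
    }
    selected_trials <- sort(unique(selected_trials))
    cols[["task_selected"]] <-
      task_response(paradigm$onsets[selected_trials], paradigm$task_s, hrf, fs, n)
    unsel <- setdiff(seq_len(paradigm$n_trials), selected_trials)
    if (length(unsel)) {
      cols[["task_unselected"]] <-
        task_response(paradigm$onsets[unsel], paradigm$task_s, hrf, fs, n)
    }
  }
  cols[["rest"]] <- task_response(paradigm$onsets + paradigm$task_s,
                                  paradigm$rest_s, hrf, fs, n)
  if (!is.null(band)) {
    for (nm in names(cols)) {
      cols[[nm]] <- bandpass(cols[[nm]], fs = fs, band = band,
                             mode = "zero_phase")
    }
  }
  if (!is.null(sc)) {
    sc <- as.matrix(sc)
    if (nrow(sc) != n) stop("short-channel regressor length must match n")
    colnames(sc) <- if (ncol(sc) == 1) "sc" else paste0("sc", seq_len(ncol(sc)))
    for (j in seq_len(ncol(sc))) cols[[colnames(sc)[j]]] <- sc[, j]
  }
  cols[["intercept"]] <- rep(1, n)
  X <- do.call(cbind, cols)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  structure(
    list(X = X, task_cols = grep("^task", colnames(X), value = TRUE),
         condition_number = sv[1] / sv[length(sv)], fs = fs, band = band,
         provenance = provenance),
    class = "nf_design"
  )
}

# BIC-selected AR order from one Yule-Walker pass: the PACF gives the
# innovation-variance recursion v_p = v_{p-1} (1 - pacf_p^2)
select_ar_order <- function(r, p_max) {
  n <- length(r)
  p_max <- min(p_max, n - 2L)
  if (p_max < 1L) return(0L)
  pa <- stats::ar.yw(r, aic = FALSE, order.max = p_max, demean = TRUE)
  k <- drop(pa$partialacf)
  v <- cumprod(c(mean((r - mean(r))^2), 1 - k^2))
  bic <- n * log(pmax(v, .Machine$double.xmin)) + (0:p_max) * log(n)
  which.min(bic) - 1L
}

# prewhiten a series by an AR filter: e_t = x_t - sum phi_k x_{t-k}, t > p
ar_whiten <- function(x, phi) {
  p <- length(phi)
  if (p == 0) return(x)
  emb <- stats::embed(x, p + 1L)
  emb[, 1] - drop(emb[, -1, drop = FALSE] %*% phi)
}

tukey_weights <- function(r, c_tune = 4.685) {
  s <- stats::mad(r, center = 0)
  if (s <= 0) return(rep(1, length(r)))
  u <- r / (c_tune * s)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  w
}

fit_ar_irls_one <- function(y, X, ar_order = NULL, p_max = 16L,
                            robust = TRUE, c_tune = 4.685, tol = 1e-6,
                            max_iter = 50L, op = NULL) {
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("more regressors than samples")
  beta <- qr.coef(qr(X), y)
  converged <- FALSE
  p_used <- 0L
  w <- rep(1, n)
  Xw <- X
  yw <- y
  for (it in seq_len(max_iter)) {
    r_raw <- y - drop(X %*% beta)
    # AR prewhitening is degenerate for data band-limited by a known filter
    # (the filter-aware covariance handles serial correlation exactly), so
    # the AR step runs only when no operator provenance is available.
    p_used <- if (!is.null(op)) 0L
              else if (is.null(ar_order)) select_ar_order(r_raw, p_max)
              else as.integer(ar_order)
    if (p_used > 0L) {
      phi <- stats::ar.yw(r_raw, aic = FALSE, order.max = p_used,
                          demean = TRUE)$ar
      yw <- ar_whiten(y, phi)
      Xw <- apply(X, 2, ar_whiten, phi = phi)
    } else {
      yw <- y
      Xw <- X
    }
    rw <- yw - drop(Xw %*% beta)
    w <- if (robust) tukey_weights(rw, c_tune) else rep(1, length(rw))
    sw <- sqrt(w)
    fit <- stats::lm.fit(Xw * sw, yw * sw)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  nw <- length(yw)
  rw <- yw - drop(Xw %*% beta)
  if (!is.null(op)) {
    inf <- filter_aware_covariance(y, X, w, op)
    se <- inf$se
    dof <- inf$dof
  } else {
    dof <- nw - k
    XtWX <- crossprod(Xw * sqrt(w))
    XtWXinv <- solve(XtWX)
    if (robust) {
      # Huber-type robust covariance: psi and psi' of the bisquare
      s <- stats::mad(rw, center = 0)
      if (s <= 0) s <- sqrt(sum(rw^2) / dof)
      u <- rw / (c_tune * s)
      psi <- ifelse(abs(u) < 1, rw * (1 - u^2)^2, 0)
      dpsi <- ifelse(abs(u) < 1, (1 - u^2) * (1 - 5 * u^2), 0)
      num <- sum(psi^2) / dof
      den <- (mean(dpsi))^2
      XtXinv <- solve(crossprod(Xw))
      cov_beta <- (num / den) * XtXinv
    } else {
      sigma2 <- sum(w * rw^2) / dof
      cov_beta <- sigma2 * XtWXinv
    }
    se <- sqrt(diag(cov_beta))
  }
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), dof)
  list(beta = beta, se = se, t = tval, p = pval, dof = dof,
       ar_order = p_used, converged = converged, n_iter = it,
       weights = w)
}

# Filter-aware covariance of the (weighted) least-squares estimator.
#
# The response was produced by a known linear preprocessing operator L
# (zero-phase band-pass at the device rate followed by polyphase
# resampling). Modelling the input-rate noise as white with unknown scale
# sigma^2, the estimator beta_j = u_j' y has
#   Var(beta_j) = sigma^2 ||L' u_j||^2,   u_j = W X (X'WX)^{-1} e_j,
# computed with the exact operator adjoint. sigma^2 is matched from the
# OLS residual sum of squares, E[r'r] = sigma^2 tr((I-P) L L'), and the t
# reference uses a Satterthwaite effective dof for that quadratic form.
filter_aware_covariance <- function(y, X, w, op) {
  k <- ncol(X)
  A <- solve(crossprod(X))
  fit <- stats::lm.fit(X, y)
  r <- fit$residuals
  G <- chol(A)                       # A = G'G
  XG <- X %*% t(G)
  adj_xg <- lapply(seq_len(k), function(j) op$adj(XG[, j]))
  tau <- op$tr_LLt - sum(vapply(adj_xg, function(v) sum(v^2), 0))
  tau <- max(tau, .Machine$double.eps)
  sigma2 <- sum(r^2) / tau
  # Satterthwaite dof of r'r: tr((R M)^2) ~ tr(M^2) - 2 tr(P M^2), M = L L'
  tr_pm2 <- sum(vapply(adj_xg, function(v) sum(op$fwd(v)^2), 0))
  tr_rm2 <- max(op$tr_LLt2 - 2 * tr_pm2, .Machine$double.eps)
  dof <- max(tau^2 / tr_rm2, 2)
  Aw <- solve(crossprod(X * sqrt(w)))
  se <- vapply(seq_len(k), function(j) {
    u <- w * drop(X %*% Aw[, j])
    sqrt(sigma2 * sum(op$adj(u)^2))
  }, 0)
  list(se = se, dof = dof, sigma2 = sigma2)
}

#' Fit a robust autoregressive GLM per channel
#'
#' Per-channel iterative scheme: (1) (weighted) least-squares fit, (2) AR
#' model of the residuals with BIC-selected order up to `p_max` (Yule-Walker),
#' (3) prewhitening of response and design by the AR filter, (4) Tukey
#' bisquare reweighting of the whitened residuals; repeated until the betas
#' move less than `tol` or `max_iter` is reached (non-convergence is flagged,
#' the last iterate returned). Prewhitening corrects the serial correlation
#' of band-limited hemodynamic noise; the bisquare weights guard against
#' outlying samples such as motion artifacts. Inference uses a Huber-type
#' robust covariance with `dof = n_effective - rank(X)` (prewhitening drops
#' the first `p` samples).
#'
#' @param Y Response: a `hemo_ts` (its HbO2 matrix is used) or a numeric
#'   matrix `[time, channel]`.
#' @param X An `nf_design`, or one design per channel (named list of
#'   `nf_design`, e.g. with channel-specific short-channel regressors).
#' @param ar_order Fixed AR order, or `NULL` (default) for BIC selection in
#'   `0..p_max`.
#' @param p_max Maximum AR order; the default 16 is 4 s of lags at the 4 Hz
#'   analysis rate.
#' @param robust Apply bisquare reweighting (`TRUE`); `FALSE` gives the
#'   pure (prewhitened) least-squares fit.
#' @param c_tune Bisquare tuning constant (4.685, 95% Gaussian efficiency).
#' @param tol Convergence tolerance on `max |delta beta|`.
#' @param max_iter Maximum iterations.
#' @return A tibble of class `nf_glm` with one row per channel x regressor:
#'   `channel`, `regressor`, `beta`, `se`, `t`, `p`, `dof`, `ar_order`,
#'   `converged`.
#' @export
fit_ar_irls <- function(Y, X, ar_order = NULL, p_max = 16L, robust = TRUE,
                        c_tune = 4.685, tol = 1e-6, max_iter = 50L) {
  if (inherits(Y, "hemo_ts")) Y <- t(Y$hbo)
  Y <- as.matrix(Y)
  chans <- colnames(Y)
  if (is.null(chans)) chans <- paste0("ch", seq_len(ncol(Y)))
  per_channel <- is.list(X) && !inherits(X, "nf_design")
  if (per_channel && !all(chans %in% names(X))) {
    stop("per-channel design list must be named by channel")
  }
  rows <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    d <- if (per_channel) X[[chans[j]]] else X
    stopifnot(inherits(d, "nf_design"))
    if (nrow(d$X) != nrow(Y)) stop("design and response must share time frame")
    op <- NULL
    if (!is.null(d$provenance) && identical(d$provenance$mode, "zero_phase") &&
        !is.null(d$band)) {
      op <- preproc_operator(d$provenance$fs_in, d$provenance$n_in, d$band,
                             fs_out = d$fs)
    }
    f <- fit_ar_irls_one(Y[, j], d$X, ar_order = ar_order, p_max = p_max,
                         robust = robust, c_tune = c_tune, tol = tol,
                         max_iter = max_iter, op = op)
    rows[[j]] <- tibble::tibble(
      channel = chans[j], regressor = colnames(d$X),
      beta = unname(f$beta), se = unname(f$se), t = unname(f$t),
      p = unname(f$p), dof = f$dof, ar_order = f$ar_order,
      converged = f$converged
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nf_glm", class(out))
  out
}

#' Activated channels within a region of interest
#'
#' A channel is activated when its task beta is positive and its two-sided
#' p-value passes the Bonferroni-corrected threshold `alpha / m`, with `m`
#' the ROI's channel count -- the correction is applied separately per ROI
#' (m = 4 for `nf_dlpfc`, 12 for `other_frontal`, 1 for `motor`).
#'
#' @param result An `nf_glm` tibble from [fit_ar_irls()].
#' @param layout A `nirs_layout`.
#' @param roi `"nf_dlpfc"`, `"other_frontal"` or `"motor"`.
#' @param alpha Family-wise level (0.05).
#' @param task_label Regressor tested (default `"task_selected"`).
#' @return Character vector of activated channel names (possibly empty).
#' @export
roi_activation <- function(result, layout, roi, alpha = 0.05,
                           task_label = "task_selected") {
  roi <- match.arg(roi, c("nf_dlpfc", "other_frontal", "motor"))
  members <- roi_channels(layout, roi)
  m <- length(members)
  sub <- result[result$regressor == task_label &
                  result$channel %in% members, ]
  if (!nrow(sub)) return(character(0))
  sub$channel[sub$beta > 0 & sub$p < alpha / m]
}
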