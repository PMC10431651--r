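test_that("trial ranking sorts by mean NF-channel t with stable ties", {
  # ordering example: trial 3 carries the best score
  m <- matrix(c(2, 1, 3, rep(0, 12)), 15, 4)
  rk <- rank_trials(m)
  expect_equal(rk$order[1], 3L)
  expect_equal(selected_trials(rk, 15), 1:15)
  # ties broken by the lower trial index
  m2 <- matrix(0, 15, 4)
  m2[c(4, 9), ] <- 5
  expect_equal(rank_trials(m2)$order[1:2], c(4L, 9L))
  # brute-force oracle on random tables
  for (seed in 1:3) {
    set.seed(seed)
    tab <- matrix(stats::rnorm(60), 15, 4)
    rk <- rank_trials(tab)
    scores <- apply(tab, 1, mean)
    oracle <- order(-scores, seq_len(15))
    expect_equal(rk$order, oracle)
    expect_equal(selected_trials(rk, 5), sort(oracle[1:5]))
  }
  expect_error(rank_trials(matrix(c(NA, stats::rnorm(59)), 15, 4)), "missing")
})

test_that("best-k selections are nested", {
  set.seed(11)
  rk <- rank_trials(matrix(stats::rnorm(60), 15, 4))
  s5 <- selected_trials(rk, 5)
  s10 <- selected_trials(rk, 10)
  s15 <- selected_trials(rk, 15)
  expect_true(all(s5 %in% s10))
  expect_true(all(s10 %in% s15))
  expect_length(s15, 15)
})

test_that("concordance reproduces the printed set decompositions", {
  # band 0.01-0.09 Hz, 10 best trials: 18 vs 13 responders, 10 shared
  a <- 1:18
  b <- c(1:10, 19:21)
  cc <- concordance(a, b, 30)
  expect_equal(cc$n_both, 10)
  expect_equal(cc$n_fp, 8)
  expect_equal(cc$n_fn, 3)
  expect_equal(cc$n_neither, 9)
  # band 0.01-0.2 Hz: 25 vs 21 responders, 18 shared
  a2 <- 1:25
  b2 <- c(1:18, 26:28)
  cc2 <- concordance(a2, b2, 30)
  expect_equal(cc2$n_fp, 7)
  expect_equal(cc2$n_fn, 3)
  # identical sets
  cc3 <- concordance(1:5, 1:5, 30)
  expect_equal(cc3$n_fp, 0)
  expect_equal(cc3$n_fn, 0)
  expect_error(concordance(1:31, 1:5, 30), "subset")
})

test_that("concordance counts satisfy the marginal identities", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    a <- sample(n, sample(0:n, 1))
    b <- sample(n, sample(0:n, 1))
    cc <- concordance(a, b, n)
    expect_equal(cc$n_both + cc$n_fp + cc$n_fn + cc$n_neither, n)
    expect_equal(cc$n_both + cc$n_fp, length(unique(a)))
    expect_equal(cc$n_both + cc$n_fn, length(unique(b)))
  }
})

test_that("block averages are baseline-corrected epoch means", {
  lay <- default_layout()
  par <- default_paradigm()
  # constant series -> all-zero block average
  hemo_c <- hemo_ts(matrix(3, 25, 4080, dimnames = list(lay$channels$name, NULL)),
                    matrix(-1, 25, 4080, dimnames = list(lay$channels$name, NULL)),
                    fs = 4, layout = lay, paradigm = par)
  ba0 <- block_average(hemo_c)
  expect_lt(max(abs(ba0$hbo_mean)), 1e-12)
  expect_equal(unique(ba0$n_trials), 15L)
  expect_equal(sum(ba0$channel == "S1-D1"), 260L)  # 65 s at 4 Hz
  # noiseless responder: epoch peaks after onset; HbR = -ratio x HbO2
  s <- noiseless_subject()
  hemo <- preprocess_recording(s$recording, band = c(0.01, 0.09),
                               channels = "S1-D1")
  ba <- block_average(hemo)
  pk <- ba$time_s[which.max(ba$hbo_mean)]
  expect_gt(pk, 0)
  expect_equal(ba$hbr_mean, -0.25 * ba$hbo_mean, tolerance = 1e-6)
  expect_error(block_average(hemo, window = c(-5, 120)), "exceeds")
})

test_that("2x2 chi-square matches the Pearson formula", {
  # control feeling vs activation: 9/15 responders vs 4/15
  res <- chi_square_2x2(matrix(c(9, 4, 6, 11), 2))
  expect_equal(round(res$p, 3), 0.065)
  # hand-evaluated Pearson oracle
  pearson <- function(tab) {
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    sum((tab - e)^2 / e)
  }
  expect_equal(res$statistic, pearson(matrix(c(9, 4, 6, 11), 2)),
               tolerance = 1e-12)
  # identical proportions
  res2 <- chi_square_2x2(matrix(5, 2, 2))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  # perfect separation
  expect_equal(chi_square_2x2(matrix(c(20, 0, 0, 20), 2))$statistic, 40)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("cohort report aggregates outcomes and labels", {
  out <- tibble::tibble(
    subject = 1:30,
    n_active_nf = c(rep(0, 17), rep(1, 6), rep(2, 4), rep(3, 2), rep(4, 1)),
    responder = n_active_nf >= 1,
    control_feeling = rep(c("control", "no_control"), each = 15)
  )
  out$responder[1:30] <- c(rep(FALSE, 17), rep(TRUE, 13))
  # make the control-feeling split 9/15 vs 4/15
  out$control_feeling <- c(rep("no_control", 11), rep("control", 6),
                           rep("control", 9), rep("no_control", 4))
  rep_ <- cohort_report(out)
  expect_equal(sum(rep_$histogram$proportion), 1)
  expect_equal(rep_$responder_prop, 13 / 30)
  expect_equal(round(rep_$by_control$p, 3), 0.065)
})

test_that("k = 15 pooled equals the all-trials single-regressor fit", {
  hemo <- responder_hemo()
  nf <- nf_channels()
  bk <- best_k_activation(hemo, k = 15, sc_on = TRUE, channels = nf,
                          rois = "nf_dlpfc")
  direct <- fit_subject_glm(hemo, channels = nf, mode = "pooled",
                            selected_trials = 1:15, sc = "matched")
  expect_equal(bk$fit$beta, direct$beta)
  expect_equal(bk$fit$p, direct$p)
  expect_equal(bk$selected, 1:15)
})

test_that("a default responder activates NF channels from the 10 best trials", {
  hemo <- responder_hemo()
  bk <- best_k_activation(hemo, k = 10, sc_on = TRUE, channels = nf_channels(),
                          rois = "nf_dlpfc")
  expect_gte(length(bk$activated$nf_dlpfc), 1)
  expect_true(bk$responder)
  expect_length(bk$selected, 10)
})
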