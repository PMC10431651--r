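#' Per-subject GLM with optional source-matched short-channel regression
#'
#' Convenience wrapper around [build_design()] and [fit_ar_irls()]: builds
#' one design per analyzed long channel (they differ only in the
#' short-channel nuisance column, which is the HbO2 series of the short
#' channel sharing the long channel's source) and fits the robust AR GLM.
#' Paradigm-derived regressors are filtered with the band recorded in
#' `hemo$band` so they match the data processing.
#'
#' @param hemo A `hemo_ts` from [preprocess_recording()] containing the
#'   analyzed long channels (and, when `sc = "matched"`, their matched
#'   short channels).
#' @param channels Long channels to fit (default: all long channels present
#'   in `hemo`).
#' @param mode,selected_trials Passed to [build_design()].
#' @param sc `"matched"` (default) adds the source-matched short channel as
#'   nuisance regressor; `"none"` omits short-channel correction.
#' @param ... Passed to [fit_ar_irls()].
#' @return An `nf_glm` tibble.
#' @export
fit_subject_glm <- function(hemo, channels = NULL,
                            mode = c("pooled", "trialwise"),
                            selected_trials = NULL,
                            sc = c("matched", "none"), ...) {
  mode <- match.arg(mode)
  sc <- match.arg(sc)
  stopifnot(inherits(hemo, "hemo_ts"))
  present <- rownames(hemo$hbo)
  layout <- hemo$layout
  if (is.null(channels)) {
    long_all <- layout$channels$name[layout$channels$kind == "long"]
    channels <- intersect(present, long_all)
  }
  if (!all(channels %in% present)) {
    stop("channels missing from hemo: ",
         paste(setdiff(channels, present), collapse = ", "))
  }
  if (mode == "pooled" && is.null(selected_trials)) {
    selected_trials <- seq_len(hemo$paradigm$n_trials)
  }
  n <- ncol(hemo$hbo)
  hrf <- canonical_hrf(hemo$fs)
  Y <- t(hemo$hbo[channels, , drop = FALSE])
  if (sc == "none") {
    d <- build_design(hemo$paradigm, hrf, hemo$fs, n, sc = NULL, mode = mode,
                      selected_trials = selected_trials, band = hemo$band,
                      provenance = hemo$src)
    return(fit_ar_irls(Y, d, ...))
  }
  short_of <- matched_short_channel(layout, channels)
  missing_sc <- setdiff(unique(short_of), present)
  if (length(missing_sc)) {
    stop("matched short channel(s) missing from hemo: ",
         paste(missing_sc, collapse = ", "))
  }
  designs <- lapply(channels, function(ch) {
    build_design(hemo$paradigm, hrf, hemo$fs, n,
                 sc = hemo$hbo[short_of[[ch]], ], mode = mode,
                 selected_trials = selected_trials, band = hemo$band,
                 provenance = hemo$src)
  })
  names(designs) <- channels
  fit_ar_irls(Y, designs, ...)
}

#' Rank trials by their mean t-value over the NF channels
#'
#' Per-trial score = mean of the four NF-channel t-values for that trial's
#' task regressor; trials are sorted by descending score with ties broken by
#' the lower trial index. The best-k selections are nested:
#' selected(5) is contained in selected(10) is contained in selected(15).
#'
#' @param trial_t Numeric matrix `[n_trials, n_channels]` of t-values
#'   (typically 15 x 4), or an `nf_glm` from a trialwise fit of the NF
#'   channels (its `task_XX` rows are used).
#' @return An object of class `trial_ranking`: list with `scores`
#'   (per trial), `order` (trial indices, best first) and `n_trials`.
#' @export
rank_trials <- function(trial_t) {
  if (inherits(trial_t, "nf_glm")) {
    rows <- trial_t[grepl("^task_[0-9]+$", trial_t$regressor), ]
    trials <- as.integer(sub("task_", "", rows$regressor))
    chans <- unique(rows$channel)
    m <- matrix(NA_real_, max(trials), length(chans),
                dimnames = list(NULL, chans))
    m[cbind(trials, match(rows$channel, chans))] <- rows$t
    trial_t <- m
  }
  trial_t <- as.matrix(trial_t)
  if (anyNA(trial_t)) stop("missing t-values in trial table")
  scores <- rowMeans(trial_t)
  ord <- order(-scores, seq_along(scores))
  structure(
    list(scores = scores, order = ord, n_trials = length(scores)),
    class = "trial_ranking"
  )
}

#' Best-k selected trials of a ranking
#'
#' @param ranking A `trial_ranking`.
#' @param k Number of best trials.
#' @return Sorted integer vector of the selected trial indices.
#' @export
selected_trials <- function(ranking, k) {
  stopifnot(inherits(ranking, "trial_ranking"), k >= 1, k <= ranking$n_trials)
  sort(ranking$order[seq_len(k)])
}

#' Activation analysis restricted to the k best trials
#'
#' Pipeline behind the per-subject activation counts: a trialwise GLM on the
#' four NF channels yields per-trial t-values, trials are ranked by their
#' mean NF-channel t, and a pooled GLM is refit with the k best trials as
#' the task regressor of interest (the unselected trials stay in the model
#' as a nuisance column rather than being dropped). Activated channels are
#' then counted per ROI at the Bonferroni-corrected threshold. `k = 15`
#' degenerates to a single all-trials task regressor and skips the ranking
#' step.
#'
#' @param hemo A `hemo_ts` containing the channels to analyze and their
#'   matched short channels.
#' @param k Number of best trials: 5, 10 or 15.
#' @param sc_on Include the source-matched short-channel regressor.
#' @param channels Long channels to analyze (default: all present).
#' @param rois ROIs to report (default all three).
#' @param alpha Family-wise level per ROI.
#' @param ... Passed to [fit_ar_irls()].
#' @return List with `activated` (named list of activated channel names per
#'   ROI), `responder` (>= 1 activated NF channel), `selected` (trial
#'   indices used), `ranking` (`trial_ranking` or `NULL` for k = 15), and
#'   `fit` (the pooled `nf_glm`).
#' @export
best_k_activation <- function(hemo, k = 10, sc_on = TRUE, channels = NULL,
                              rois = c("nf_dlpfc", "other_frontal", "motor"),
                              alpha = 0.05, ...) {
  stopifnot(k %in% c(5L, 10L, 15L))
  sc <- if (sc_on) "matched" else "none"
  ranking <- NULL
  if (k == hemo$paradigm$n_trials) {
    sel <- seq_len(hemo$paradigm$n_trials)
  } else {
    nf <- intersect(rownames(hemo$hbo), roi_channels(hemo$layout, "nf_dlpfc"))
    tw <- fit_subject_glm(hemo, channels = nf, mode = "trialwise", sc = sc, ...)
    ranking <- rank_trials(tw)
    sel <- selected_trials(ranking, k)
  }
  fit <- fit_subject_glm(hemo, channels = channels, mode = "pooled",
                         selected_trials = sel, sc = sc, ...)
  activated <- lapply(rois, function(r) {
    roi_activation(fit, hemo$layout, r, alpha = alpha,
                   task_label = "task_selected")
  })
  names(activated) <- rois
  responder <- "nf_dlpfc" %in% rois && length(activated$nf_dlpfc) >= 1
  list(activated = activated, responder = responder, selected = sel,
       ranking = ranking, fit = fit)
}

#' Concordance of responder calls with and without short-channel correction
#'
#' Exact set arithmetic between the responders detected without
#' short-channel regression (A) and with it (B): `n_both = |A and B|`,
#' `n_fp = |A minus B|` (superficial false positives unmasked by the
#' correction), `n_fn = |B minus A|` (activations revealed only after the
#' correction), `n_neither` the remainder of the cohort.
#'
#' @param responders_no_sc,responders_sc Vectors of subject identifiers.
#' @param cohort Vector of all subject identifiers, or a single integer
#'   cohort size (subjects then assumed to be `1:n`).
#' @return An object of class `nf_concordance`: list with the four counts
#'   and `n`.
#' @export
concordance <- function(responders_no_sc, responders_sc, cohort) {
  if (length(cohort) == 1L && is.numeric(cohort)) cohort <- seq_len(cohort)
  a <- unique(responders_no_sc)
  b <- unique(responders_sc)
  if (!all(a %in% cohort) || !all(b %in% cohort)) {
    stop("responder sets must be subsets of the cohort")
  }
  out <- list(
    n_both = length(intersect(a, b)),
    n_fp = length(setdiff(a, b)),
    n_fn = length(setdiff(b, a)),
    n_neither = length(cohort) - length(union(a, b)),
    n = length(cohort)
  )
  structure(out, class = "nf_concordance")
}

#' @export
print.nf_concordance <- function(x, ...) {
  cat(sprintf(
    "<nf_concordance> n=%d: both %d, no-SC only (FP) %d, SC only (FN) %d, neither %d\n",
    x$n, x$n_both, x$n_fp, x$n_fn, x$n_neither
  ))
  invisible(x)
}

#' Block average of the hemodynamic response around task onsets
#'
#' Extracts an epoch around every task onset, subtracts the mean of the 5 s
#' preceding the onset (per epoch and channel), and averages across the 15
#' trials.
#'
#' @param hemo A `hemo_ts`.
#' @param window Length-2 epoch window relative to onset, s (default
#'   `c(-5, 60)`; the right edge is exclusive).
#' @return A tibble with `channel`, `time_s` (relative to onset),
#'   `hbo_mean`, `hbo_sd`, `hbr_mean`, `hbr_sd`, `n_trials`.
#' @export
block_average <- function(hemo, window = c(-5, 60)) {
  stopifnot(inherits(hemo, "hemo_ts"), length(window) == 2L,
            window[1] < 0, window[2] > 0)
  fs <- hemo$fs
  n <- ncol(hemo$hbo)
  onsets <- hemo$paradigm$onsets
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  base_rel <- rel[rel < 0 & rel >= round(-5 * fs)]
  idx <- outer(round(onsets * fs), rel, `+`) + 1L  # trials x epoch samples
  if (any(idx < 1L) || any(idx > n)) {
    stop("epoch window exceeds the recording")
  }
  bidx <- outer(round(onsets * fs), base_rel, `+`) + 1L
  epoch_stats <- function(mat) {
    ep <- matrix(mat[idx], nrow = length(onsets))
    base <- rowMeans(matrix(mat[bidx], nrow = length(onsets)))
    ep <- ep - base
    list(mean = colMeans(ep), sd = apply(ep, 2, stats::sd))
  }
  rows <- lapply(rownames(hemo$hbo), function(ch) {
    so <- epoch_stats(hemo$hbo[ch, ])
    sr <- epoch_stats(hemo$hbr[ch, ])
    tibble::tibble(
      channel = ch, time_s = rel / fs,
      hbo_mean = so$mean, hbo_sd = so$sd,
      hbr_mean = sr$mean, hbr_sd = sr$sd,
      n_trials = length(onsets)
    )
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Pearson's chi-square without continuity correction (df = 1, two-sided),
#' the test used for the group comparisons of responder proportions.
#'
#' @param table 2x2 matrix of nonnegative integer counts with no zero
#'   marginal.
#' @return List with `statistic`, `p` and `df = 1`.
#' @examples
#' # responders among participants reporting control (9/15) vs not (4/15)
#' chi_square_2x2(matrix(c(9, 4, 6, 11), 2))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ct$statistic), p = unname(ct$p.value), df = 1L)
}

#' Cohort-level summary of subject outcomes
#'
#' Aggregates per-subject outcomes into the group-level views: the
#' distribution of activated NF-channel counts (0..4), the responder
#' proportion, and -- when behavioral labels are present -- responder
#' cross-tabulations by control feeling (with the chi-square comparison)
#' and by gender.
#'
#' @param outcomes A tibble with one row per subject (and condition), with
#'   columns `subject`, `n_active_nf` (0..4) and `responder`, plus optional
#'   `control_feeling` ("control"/"no_control") and `gender`.
#' @return List with `histogram` (count and proportion per number of
#'   activated channels), `responder_prop`, and, if labels are present,
#'   `by_control` (2x2 table plus chi-square statistic and p).
#' @export
cohort_report <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1,
            all(c("subject", "n_active_nf", "responder") %in% names(outcomes)))
  counts <- table(factor(outcomes$n_active_nf, levels = 0:4))
  hist <- tibble::tibble(
    n_active_nf = 0:4,
    n_subjects = as.integer(counts),
    proportion = as.integer(counts) / nrow(outcomes)
  )
  out <- list(
    histogram = hist,
    responder_prop = mean(outcomes$responder),
    n = nrow(outcomes)
  )
  if ("control_feeling" %in% names(outcomes) &&
      !anyNA(outcomes$control_feeling)) {
    tab <- table(
      feeling = factor(outcomes$control_feeling,
                       levels = c("control", "no_control")),
      responder = factor(outcomes$responder, levels = c(TRUE, FALSE))
    )
    out$by_control <- c(list(table = tab), chi_square_2x2(unclass(tab)))
  }
  if ("gender" %in% names(outcomes) && !anyNA(outcomes$gender)) {
    out$by_gender <- table(outcomes$gender, outcomes$responder)
  }
  out
}
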