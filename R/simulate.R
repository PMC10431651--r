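#' Configuration of the synthetic fNIRS generator
#'
#' Collects every free parameter of the forward model. The generator
#' emulates what a continuous-wave device records during the neurofeedback
#' session: an HRF-convolved neural activation on selected long channels, a
#' superficial (scalp) hemodynamic process shared between long and short
#' channels, oscillatory physiological confounds in their standard bands
#' (Mayer waves 0.09--0.1 Hz, respiration 0.2--0.5 Hz, cardiac 1--1.3 Hz),
#' an optional linear drift, and white measurement noise in the
#' optical-density domain.
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   recordings.
#' @param neural_amplitude Peak neural HbO2 response per active trial, uM.
#' @param hbr_ratio HbR response is `-hbr_ratio` times the HbO2 response.
#' @param active_channels Long channels carrying neural activation
#'   (default: the 4 NF channels).
#' @param active_trials Trials (1..n_trials) in which activation occurs.
#' @param scalp_coupling Gain of the scalp component on long channels
#'   (scalar or one value per long channel); short channels receive gain 1.
#' @param scalp_sd Standard deviation of the slow scalp process, uM.
#' @param scalp_task_amplitude Peak of a task-locked ingredient added to the
#'   scalp process, uM; nonzero only in the superficial-false-positive
#'   scenario.
#' @param mayer_freq,breathing_freq,cardiac_freq Oscillation frequencies,
#'   Hz; must lie in [0.09, 0.1], [0.2, 0.5] and [1, 1.3] respectively.
#' @param mayer_amp,breathing_amp,cardiac_amp Oscillation amplitudes, uM
#'   equivalent; each is jittered per subject by a log-normal factor.
#' @param amp_jitter_sdlog Log-sd of the per-subject amplitude jitter.
#' @param drift_slope Linear drift on long channels, uM/s.
#' @param noise_sd Gaussian measurement noise sd, optical-density units.
#' @param dpf Differential pathlength factor of the forward model.
#' @param baseline_intensity Baseline light intensity, arbitrary units.
#' @param fs Device sampling rate, Hz.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       neural_amplitude = 0.5,
                       hbr_ratio = 0.25,
                       active_channels = NULL,
                       active_trials = 1:15,
                       scalp_coupling = 1.0,
                       scalp_sd = 0.5,
                       scalp_task_amplitude = 0,
                       mayer_freq = 0.095,
                       breathing_freq = 0.3,
                       cardiac_freq = 1.1,
                       mayer_amp = 0.2,
                       breathing_amp = 0.1,
                       cardiac_amp = 0.1,
                       amp_jitter_sdlog = 0.2,
                       drift_slope = 0,
                       noise_sd = 0.002,
                       dpf = 6.0,
                       baseline_intensity = 1000,
                       fs = 7.8125) {
  cfg <- list(
    seed = as.integer(seed), neural_amplitude = neural_amplitude,
    hbr_ratio = hbr_ratio, active_channels = active_channels,
    active_trials = as.integer(active_trials),
    scalp_coupling = scalp_coupling, scalp_sd = scalp_sd,
    scalp_task_amplitude = scalp_task_amplitude,
    mayer_freq = mayer_freq, breathing_freq = breathing_freq,
    cardiac_freq = cardiac_freq, mayer_amp = mayer_amp,
    breathing_amp = breathing_amp, cardiac_amp = cardiac_amp,
    amp_jitter_sdlog = amp_jitter_sdlog, drift_slope = drift_slope,
    noise_sd = noise_sd, dpf = dpf,
    baseline_intensity = baseline_intensity, fs = fs
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  in_band <- function(x, lo, hi, what) {
    if (x < lo || x > hi) {
      stop(what, " = ", x, " Hz outside its physiological band [", lo, ", ",
           hi, "]")
    }
  }
  in_band(cfg$mayer_freq, 0.09, 0.1, "mayer_freq")
  in_band(cfg$breathing_freq, 0.2, 0.5, "breathing_freq")
  in_band(cfg$cardiac_freq, 1, 1.3, "cardiac_freq")
  stopifnot(all(cfg$scalp_coupling >= 0), cfg$noise_sd >= 0,
            cfg$baseline_intensity > 0, cfg$fs > 0, cfg$scalp_sd >= 0,
            cfg$neural_amplitude >= 0, cfg$hbr_ratio >= 0)
  invisible(cfg)
}

#' Noiseless neural ground truth of a simulated subject
#'
#' The neural HbO2 series is `neural_amplitude` times the HRF-convolved
#' boxcar over the active trials (unit single-trial peak), placed on the
#' active channels only; HbR is `-hbr_ratio` times HbO2. Deterministic given
#' the configuration.
#'
#' @param config A `sim_config`.
#' @param layout A `nirs_layout`.
#' @param paradigm An `nf_paradigm`.
#' @param hrf An `hrf_model` at `config$fs` (built if missing).
#' @param n Number of samples (defaults to the paradigm length at
#'   `config$fs`).
#' @return An object of class `sim_truth`: `neural_hbo`, `neural_hbr`
#'   (matrices `[channel, time]` over all layout channels), `scalp` (filled
#'   by [simulate_subject()]; `NULL` here), `active_trials` (logical per
#'   trial) and `active_channels`.
#' @export
hemodynamic_truth <- function(config, layout = default_layout(),
                              paradigm = default_paradigm(), hrf = NULL,
                              n = NULL) {
  validate_sim_config(config)
  if (any(config$active_trials < 1 | config$active_trials > paradigm$n_trials)) {
    stop("active_trials must lie in 1..", paradigm$n_trials)
  }
  fs <- config$fs
  if (is.null(hrf)) hrf <- canonical_hrf(fs)
  if (is.null(n)) n <- ceiling(paradigm$total_s * fs)
  ch <- layout$channels$name
  active <- config$active_channels
  if (is.null(active)) active <- roi_channels(layout, "nf_dlpfc")
  bad <- setdiff(active, ch[layout$channels$kind == "long"])
  if (length(bad)) stop("active_channels must be long channels: ",
                        paste(bad, collapse = ", "))
  neural <- matrix(0, length(ch), n, dimnames = list(ch, NULL))
  if (config$neural_amplitude > 0 && length(config$active_trials)) {
    resp <- config$neural_amplitude *
      task_response(paradigm$onsets[config$active_trials], paradigm$task_s,
                    hrf, fs, n)
    neural[active, ] <- matrix(resp, length(active), n, byrow = TRUE)
  }
  structure(
    list(
      neural_hbo = neural,
      neural_hbr = -config$hbr_ratio * neural,
      scalp = NULL,
      active_trials = seq_len(paradigm$n_trials) %in% config$active_trials &
        config$neural_amplitude > 0,
      active_channels = if (config$neural_amplitude > 0) active else character(0),
      fs = fs
    ),
    class = "sim_truth"
  )
}

# zero-phase low-pass used to shape the slow scalp process (< 0.05 Hz)
slow_lowpass <- function(x, fs, cutoff = 0.05) {
  bt <- signal::butter(3, cutoff / (fs / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * fs / cutoff))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[n - seq_len(pad)])
  fwd <- as.numeric(signal::filter(bt$b, bt$a, xp))
  bwd <- rev(as.numeric(signal::filter(bt$b, bt$a, rev(fwd))))
  bwd[pad + seq_len(n)]
}

#' Simulate one subject's raw recording with known ground truth
#'
#' Generates hemoglobin concentration series per channel -- neural
#' activation on the active long channels, a shared scalp process (slow
#' smoothed random walk plus Mayer/respiratory/cardiac sinusoids with
#' per-subject random phase and log-normal amplitude jitter) with gain
#' `scalp_coupling` on long channels, and linear drift -- maps them through
#' the forward Beer-Lambert model to optical density, adds Gaussian OD
#' noise, and exponentiates to strictly positive intensities around
#' `baseline_intensity`. Short channels carry the scalp process only. The
#' scalp process also moves HbR, scaled by `-hbr_ratio`. Identical seeds
#' give bit-identical output.
#'
#' @param config A `sim_config`.
#' @param layout A `nirs_layout`.
#' @param paradigm An `nf_paradigm`.
#' @return List with `recording` (a `nirs_recording`) and `truth`
#'   (a `sim_truth` whose `scalp` field holds the generated scalp series).
#' @export
simulate_subject <- function(config, layout = default_layout(),
                             paradigm = default_paradigm()) {
  validate_sim_config(config)
  fs <- config$fs
  n <- ceiling(paradigm$total_s * fs)
  t <- (seq_len(n) - 1) / fs
  hrf <- canonical_hrf(fs)
  truth <- hemodynamic_truth(config, layout, paradigm, hrf, n)

  set.seed(config$seed)
  # slow scalp process: random walk smoothed below 0.05 Hz, scaled to scalp_sd
  slow <- slow_lowpass(cumsum(stats::rnorm(n)), fs)
  s <- stats::sd(slow)
  slow <- if (s > 0) slow / s * config$scalp_sd else slow * 0
  osc <- numeric(n)
  for (comp in list(c(config$mayer_freq, config$mayer_amp),
                    c(config$breathing_freq, config$breathing_amp),
                    c(config$cardiac_freq, config$cardiac_amp))) {
    phase <- stats::runif(1, 0, 2 * pi)
    jit <- stats::rlnorm(1, 0, config$amp_jitter_sdlog)
    osc <- osc + comp[2] * jit * sin(2 * pi * comp[1] * t + phase)
  }
  scalp <- slow + osc
  if (config$scalp_task_amplitude != 0) {
    scalp <- scalp + config$scalp_task_amplitude *
      task_response(paradigm$onsets, paradigm$task_s, hrf, fs, n)
  }
  truth$scalp <- scalp

  ch <- layout$channels
  is_long <- ch$kind == "long"
  coupling <- rep(0, nrow(ch))
  coupling[is_long] <- config$scalp_coupling  # recycles a scalar
  coupling[!is_long] <- 1
  drift <- config$drift_slope * t

  hbo <- truth$neural_hbo
  hbr <- truth$neural_hbr
  for (i in seq_len(nrow(ch))) {
    superf <- coupling[i] * scalp + if (is_long[i]) drift else 0
    hbo[i, ] <- hbo[i, ] + superf
    hbr[i, ] <- hbr[i, ] - config$hbr_ratio * superf
  }

  constants <- mbll_constants(layout, dpf = config$dpf)
  od <- forward_mbll(
    hemo_ts(hbo, hbr, fs = fs, layout = layout, paradigm = paradigm),
    constants
  )
  odn <- od$od
  if (config$noise_sd > 0) {
    odn <- odn + array(stats::rnorm(length(odn), 0, config$noise_sd), dim(odn))
  }
  if (!all(is.finite(odn))) stop("non-finite optical density generated")
  intens <- config$baseline_intensity * 10^(-odn)
  if (!all(is.finite(intens)) || any(intens <= 0)) {
    stop("non-finite or non-positive intensity generated")
  }
  rec <- nirs_recording(intens, layout, paradigm, fs = fs,
                        meta = list(seed = config$seed))
  list(recording = rec, truth = truth)
}

#' Simulate a cohort under a named scenario
#'
#' Scenarios: `"responder"` places neural activation on the 4 NF channels;
#' `"scalp_false_positive"` has zero neural amplitude but gives the scalp
#' process a task-locked ingredient, so superficial signal mimics
#' activation on every channel it couples into; `"null"` has zero neural
#' amplitude and task-independent scalp physiology. Per-subject seeds and
#' per-subject oscillation frequencies (drawn uniformly inside their
#' physiological bands) are derived deterministically from
#' `base_config$seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param scenario `"responder"`, `"scalp_false_positive"` or `"null"`.
#' @param base_config A `sim_config` used as template.
#' @param layout,paradigm Montage and paradigm.
#' @return List of per-subject lists `(recording, truth)`, with the subject
#'   configuration attached as attribute `config`.
#' @export
simulate_cohort <- function(n_subjects, scenario = c("responder",
                                                     "scalp_false_positive",
                                                     "null"),
                            base_config = sim_config(),
                            layout = default_layout(),
                            paradigm = default_paradigm()) {
  scenario <- match.arg(scenario)
  stopifnot(n_subjects >= 1)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- unclass(base_config)
    cfg$seed <- (base_config$seed + 7919L * i) %% .Machine$integer.max
    set.seed(cfg$seed + 1L)
    cfg$mayer_freq <- stats::runif(1, 0.09, 0.1)
    cfg$breathing_freq <- stats::runif(1, 0.2, 0.5)
    cfg$cardiac_freq <- stats::runif(1, 1, 1.3)
    if (scenario == "responder") {
      cfg$active_channels <- roi_channels(layout, "nf_dlpfc")
      cfg$scalp_task_amplitude <- 0
    } else if (scenario == "scalp_false_positive") {
      # the superficial mimic is as strong as the activation it mimics:
      # an uncorrected analysis cannot tell the two scenarios apart
      cfg$scalp_task_amplitude <- base_config$neural_amplitude
      cfg$neural_amplitude <- 0
    } else {
      cfg$neural_amplitude <- 0
      cfg$scalp_task_amplitude <- 0
    }
    cfg <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
    out[[i]] <- simulate_subject(cfg, layout, paradigm)
    attr(out[[i]], "config") <- cfg
  }
  out
}
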