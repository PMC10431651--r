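# Shared fixtures, computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

nf_channels <- function() roi_channels(default_layout(), "nf_dlpfc")

nf_with_shorts <- function() {
  nf <- nf_channels()
  c(nf, unique(matched_short_channel(default_layout(), nf)))
}

# default responder subject (all trials active, default noise)
responder_subject <- function() {
  fixture("responder_subject", function() simulate_subject(sim_config(seed = 401L)))
}

responder_hemo <- function() {
  fixture("responder_hemo", function() {
    preprocess_recording(responder_subject()$recording, band = c(0.01, 0.09),
                         channels = nf_with_shorts())
  })
}

# noiseless responder for exact proportionality checks
noiseless_subject <- function() {
  fixture("noiseless_subject", function() {
    simulate_subject(sim_config(seed = 402L, noise_sd = 0, scalp_sd = 0,
                                mayer_amp = 0, breathing_amp = 0,
                                cardiac_amp = 0))
  })
}

# short recording for I/O round trips (30 s session)
tiny_recording <- function() {
  fixture("tiny_recording", function() {
    lay <- default_layout()
    par <- default_paradigm(baseline_s = 10, n_trials = 2L, task_s = 5,
                            rest_s = 5)
    n <- ceiling(par$total_s * 7.8125)
    set.seed(77)
    arr <- array(1000 * exp(stats::rnorm(25 * 2 * n, 0, 0.01)),
                 dim = c(25, 2, n))
    nirs_recording(arr, lay, par, fs = 7.8125, meta = list(id = "tiny"))
  })
}

# Independent batch implementation of the online chain: one vectorized pass
# per channel (shared causal-filter primitive, everything else computed
# differently from the streaming state machine).
batch_online_oracle <- function(rec, band = c(0.01, 0.2)) {
  lay <- rec$layout
  nf <- roi_channels(lay, "nf_dlpfc")
  cons <- mbll_constants(lay)
  fs <- rec$fs
  co <- signal::butter(3, band / (fs / 2), "pass")
  w <- round(2 * fs)
  Einv <- solve(cons$extinction)
  mam <- sapply(nf, function(ch) {
    I <- rec$intensities[ch, , ]
    od <- -log10(I / I[, 1])
    hbo <- (Einv %*% (od / (cons$distance_cm[ch] * cons$dpf)))[1, ]
    y <- iir_filter(as.numeric(co$b), as.numeric(co$a), hbo)$y
    full <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 1))
    head_means <- sapply(seq_len(w - 1), function(t) mean(y[seq_len(t)]))
    c(head_means, full[w:length(y)])
  })
  g <- rowMeans(mam)
  wb <- round(5 * fs)
  onset_samp <- round(rec$paradigm$onsets * fs)
  base <- numeric(length(g))
  cur <- 0
  for (t in seq_along(g)) {
    if ((t - 1) %in% onset_samp) cur <- mean(g[(t - wb):(t - 1)])
    base[t] <- cur
  }
  g - base
}
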