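#' Initialize the streaming neurofeedback state
#'
#' The online chain mirrors what the acquisition software computes in real
#' time, sample by sample at the device rate: per NF channel, raw
#' intensities are converted to optical density against the first received
#' sample, mapped to HbO2 by the Beer-Lambert inversion, passed through a
#' causal order-3 Butterworth band-pass (0.01--0.2 Hz) and a 2 s moving
#' average; the four NF channels are averaged and the mean of the 5 s
#' preceding each task onset is subtracted as that trial's baseline. No
#' short-channel correction is applied online by default (`sc_online =
#' TRUE` enables source-matched short-channel subtraction as an extension).
#'
#' @param layout A `nirs_layout`.
#' @param paradigm An `nf_paradigm`.
#' @param fs Device sampling rate, Hz.
#' @param band Online band-pass edges, Hz.
#' @param v0 Gauge compression scale, uM (see [gauge_map()]).
#' @param ma_window Moving-average window, s.
#' @param baseline_window Pre-task baseline window, s.
#' @param sc_online Subtract the source-matched short channel online.
#' @param constants An `mbll_constants` (defaults from `layout`).
#' @return An opaque state list for [nf_stream_step()].
#' @export
nf_stream_init <- function(layout = default_layout(),
                           paradigm = default_paradigm(),
                           fs = 7.8125, band = c(0.01, 0.2), v0 = 1,
                           ma_window = 2, baseline_window = 5,
                           sc_online = FALSE, constants = NULL) {
  validate_layout(layout)
  if (is.null(constants)) constants <- mbll_constants(layout)
  nf <- roi_channels(layout, "nf_dlpfc")
  channels <- nf
  sc_of <- NULL
  if (sc_online) {
    sc_of <- matched_short_channel(layout, nf)
    channels <- c(nf, unique(unname(sc_of)))
  }
  co <- butter_coeffs(band, fs)
  nstate <- max(length(co$b), length(co$a)) - 1L
  nch <- length(channels)
  w <- round(ma_window * fs)
  wb <- round(baseline_window * fs)
  Einv <- solve(constants$extinction)
  pathlen <- outer(constants$distance_cm[channels], constants$dpf)  # ch x wl
  list(
    layout = layout, paradigm = paradigm, fs = fs, band = band, v0 = v0,
    channels = channels, nf = nf, sc_of = sc_of,
    b = co$b / co$a[1], a = co$a / co$a[1],
    z = matrix(0, nstate, nch),
    i_ref = NULL,
    ma_buf = matrix(NA_real_, w, nch), ma_pos = 0L, ma_count = 0L,
    base_buf = rep(NA_real_, wb), base_pos = 0L, base_count = 0L,
    baseline = 0, trial = 0L,
    onset_samples = round(paradigm$onsets * fs),
    Einv = Einv, pathlen = pathlen,
    counter = 0L, last_t = -Inf
  )
}

#' Advance the streaming neurofeedback chain by new samples
#'
#' @param state State from [nf_stream_init()] (or a previous step).
#' @param intensities New raw samples for the state's channels: an array
#'   `[n_new, channel, wavelength]`, or a `[channel, wavelength]` matrix for
#'   a single sample. Channel order must match `state$channels`.
#' @param timestamps Optional per-sample times (s); must be strictly
#'   increasing across calls, otherwise an out-of-order error is raised.
#' @return List with `state` (updated) and `samples`: a tibble with `t`
#'   (s), `v` (feedback value, uM), `height` (gauge height in (0, 1)),
#'   `phase` and `displayed` (TRUE only during task blocks).
#' @export
nf_stream_step <- function(state, intensities, timestamps = NULL) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, c(1L, dim(intensities)))
  }
  stopifnot(length(dim(intensities)) == 3L,
            dim(intensities)[2] == length(state$channels),
            dim(intensities)[3] == 2L)
  n_new <- dim(intensities)[1]
  if (!is.null(timestamps)) {
    stopifnot(length(timestamps) == n_new)
    if (any(diff(c(state$last_t, timestamps)) <= 0)) {
      stop("out-of-order timestamp in stream")
    }
    state$last_t <- timestamps[n_new]
  }
  nch <- length(state$channels)
  nf_idx <- match(state$nf, state$channels)
  w <- nrow(state$ma_buf)
  wb <- length(state$base_buf)
  nstate <- nrow(state$z)
  bs <- state$b[2:(nstate + 1)]
  as_ <- state$a[2:(nstate + 1)]
  out_t <- numeric(n_new)
  out_v <- numeric(n_new)
  phase_all <- character(n_new)

  for (s in seq_len(n_new)) {
    I <- matrix(intensities[s, , ], nch, 2)
    if (any(!is.finite(I)) || any(I <= 0)) stop("non-positive intensity sample")
    if (is.null(state$i_ref)) state$i_ref <- I
    od <- -log10(I / state$i_ref)
    # MBLL inversion per channel; pathlen recycles over wavelength columns
    conc <- state$Einv %*% t(od / state$pathlen)
    hbo <- conc[1, ]
    # one causal filter step (direct form II transposed), all channels at once
    y <- state$b[1] * hbo + state$z[1, ]
    znext <- outer(bs, hbo) - outer(as_, y)
    if (nstate > 1) {
      znext[seq_len(nstate - 1), ] <- znext[seq_len(nstate - 1), ] +
        state$z[2:nstate, , drop = FALSE]
    }
    state$z <- znext
    # 2-s moving average (mean of available samples until the window fills)
    state$ma_pos <- state$ma_pos %% w + 1L
    state$ma_buf[state$ma_pos, ] <- y
    state$ma_count <- min(state$ma_count + 1L, w)
    ma <- colSums(state$ma_buf, na.rm = TRUE) / state$ma_count
    sig <- ma[nf_idx]
    if (!is.null(state$sc_of)) {
      sig <- sig - ma[match(state$sc_of[state$nf], state$channels)]
    }
    g <- mean(sig)
    # baseline: mean of the 5 s preceding each task onset, frozen at onset
    if (state$trial < length(state$onset_samples) &&
        state$counter == state$onset_samples[state$trial + 1L]) {
      state$trial <- state$trial + 1L
      state$baseline <- if (state$base_count > 0) {
        sum(state$base_buf, na.rm = TRUE) / state$base_count
      } else 0
    }
    state$base_pos <- state$base_pos %% wb + 1L
    state$base_buf[state$base_pos] <- g
    state$base_count <- min(state$base_count + 1L, wb)

    out_t[s] <- state$counter / state$fs
    out_v[s] <- g - state$baseline
    state$counter <- state$counter + 1L
  }
  phase_all <- paradigm_phase(state$paradigm, out_t)
  samples <- tibble::tibble(
    t = out_t, v = out_v,
    height = gauge_map(out_v, state$v0),
    phase = phase_all,
    displayed = phase_all == "task"
  )
  list(state = state, samples = samples)
}

#' Replay a recording through the streaming neurofeedback chain
#'
#' Feeds a full recording through [nf_stream_step()], optionally in chunks;
#' chunking never changes the output (the filter state is carried across
#' calls).
#'
#' @param rec A `nirs_recording`.
#' @param chunk Samples per step call (default: whole recording at once).
#' @param ... Passed to [nf_stream_init()].
#' @return The per-sample feedback tibble (see [nf_stream_step()]).
#' @export
online_replay <- function(rec, chunk = NULL, ...) {
  stopifnot(inherits(rec, "nirs_recording"))
  st <- nf_stream_init(rec$layout, rec$paradigm, fs = rec$fs, ...)
  x <- aperm(rec$intensities[st$channels, , , drop = FALSE], c(3, 1, 2))
  n <- dim(x)[1]
  if (is.null(chunk)) chunk <- n
  out <- vector("list", ceiling(n / chunk))
  i0 <- 1L
  k <- 1L
  while (i0 <= n) {
    i1 <- min(n, i0 + chunk - 1L)
    step <- nf_stream_step(st, x[i0:i1, , , drop = FALSE])
    st <- step$state
    out[[k]] <- step$samples
    i0 <- i1 + 1L
    k <- k + 1L
  }
  do.call(rbind, out)
}

#' Map a feedback value to gauge height
#'
#' Smooth, bounded, strictly monotone compression
#' `height = 0.5 + 0.5 tanh(v / v0)`: zero concentration change shows the
#' gauge at half height, positive changes fill the top half, negative
#' changes the bottom half, and the ends saturate smoothly so the display
#' never pins.
#'
#' @param v Feedback value(s), uM.
#' @param v0 Compression scale, uM (> 0); the session calibration constant.
#' @return Gauge height(s) in (0, 1).
#' @examples
#' gauge_map(0)        # 0.5
#' gauge_map(c(-2, 2)) # symmetric about 0.5
#' @export
gauge_map <- function(v, v0 = 1) {
  stopifnot(v0 > 0)
  0.5 + 0.5 * tanh(v / v0)
}
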