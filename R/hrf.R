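#' Canonical hemodynamic response function
#'
#' Difference-of-gammas kernel with the canonical continuous-wave NIRS
#' parameterization: positive lobe peaking at `peak_time` (4 s), undershoot
#' peaking at `undershoot_time` (16 s), support truncated at `duration`
#' (32 s), and undershoot-to-peak amplitude ratio `ratio` (1/6). Both gamma
#' densities use unit rate (dispersion is free in this parameterization);
#' the undershoot weight is solved numerically so the realized min/max
#' amplitude ratio equals `ratio` exactly, and the kernel is normalized to
#' unit peak.
#'
#' @param fs Sampling rate of the kernel in Hz.
#' @param peak_time Positive-lobe peak time, s.
#' @param undershoot_time Undershoot peak time, s.
#' @param duration Kernel support, s.
#' @param ratio Undershoot/peak amplitude ratio.
#' @return An object of class `hrf_model`: list with `kernel` (sampled at
#'   `fs`, unit peak), `t` (sample times), `fs` and the four parameters.
#' @examples
#' h <- canonical_hrf(4)
#' h$t[which.max(h$kernel)]  # 4 s
#' @export
canonical_hrf <- function(fs, peak_time = 4, undershoot_time = 16,
                          duration = 32, ratio = 1 / 6) {
  stopifnot(fs > 0, peak_time > 0, undershoot_time > peak_time, ratio >= 0)
  t <- seq(0, duration, by = 1 / fs)
  # unit-rate gammas with modes at the two peak times: mode = shape - 1
  g1 <- stats::dgamma(t, shape = peak_time + 1, rate = 1)
  g2 <- stats::dgamma(t, shape = undershoot_time + 1, rate = 1)
  ratio_of <- function(cc) {
    k <- g1 - cc * g2
    abs(min(k)) / max(k)
  }
  cc <- if (ratio == 0) 0 else {
    stats::uniroot(function(cc) ratio_of(cc) - ratio,
                   interval = c(1e-6, 10), tol = 1e-12)$root
  }
  kernel <- g1 - cc * g2
  kernel <- kernel / max(kernel)
  structure(
    list(kernel = kernel, t = t, fs = fs, peak_time = peak_time,
         undershoot_time = undershoot_time, duration = duration,
         ratio = ratio),
    class = "hrf_model"
  )
}

#' Expected hemodynamic response to task blocks
#'
#' Convolves per-trial task boxcars with the canonical HRF and normalizes so
#' one isolated trial's response peaks at 1. A series scaled by an amplitude
#' `a` therefore peaks at `a` uM per (isolated) trial, and a GLM whose task
#' regressor is built by the same function recovers `a` as its beta.
#'
#' @param onsets Block onset times, s.
#' @param dur Block duration, s.
#' @param hrf An `hrf_model` sampled at `fs`.
#' @param fs Sampling rate, Hz.
#' @param n Output length in samples.
#' @return Numeric vector of length `n`, unit single-trial peak.
#' @export
task_response <- function(onsets, dur, hrf, fs, n) {
  stopifnot(inherits(hrf, "hrf_model"), abs(hrf$fs - fs) < 1e-9)
  box <- numeric(n)
  for (on in onsets) {
    i0 <- floor(on * fs) + 1L
    i1 <- min(n, ceiling((on + dur) * fs))
    if (i0 > n) next
    box[i0:i1] <- 1
  }
  k <- hrf$kernel / fs
  r <- stats::convolve(box, rev(k), type = "open")[seq_len(n)]
  # unit-peak normalization from one isolated block
  nb <- min(n, ceiling((dur + hrf$duration + 2) * fs))
  box1 <- numeric(nb)
  box1[seq_len(min(nb, ceiling(dur * fs)))] <- 1
  peak1 <- max(stats::convolve(box1, rev(k), type = "open")[seq_len(nb)])
  r / peak1
}
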