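#' Offline preprocessing: intensities to band-limited hemoglobin series
#'
#' The fixed offline chain: raw intensities are converted to optical
#' density, band-pass filtered (order-3 Butterworth, zero-phase by default)
#' under one of the two study bands, resampled to the 4 Hz analysis rate by
#' polyphase interpolation, and converted to hemoglobin concentration
#' changes by the modified Beer-Lambert law. The Beer-Lambert map is linear,
#' so it commutes with the filtering; applying it last matches the
#' analysis-chain ordering.
#'
#' @param rec A `nirs_recording`.
#' @param band Length-2 band edges in Hz: `c(0.01, 0.09)` (default) or
#'   `c(0.01, 0.2)`.
#' @param channels Optional subset of channel names to process (all by
#'   default); processing only the channels a fit needs saves time.
#' @param constants An `mbll_constants`; defaults to
#'   `mbll_constants(rec$layout)`.
#' @param mode Filtering mode passed to [bandpass()]: `"zero_phase"`
#'   (offline default) or `"causal"`.
#' @param fs_out Analysis rate in Hz (4).
#' @return A `hemo_ts` at `fs_out` with the processed channels as rows.
#' @examples
#' \donttest{
#' sub <- simulate_subject(sim_config(seed = 1))
#' hemo <- preprocess_recording(sub$recording, band = c(0.01, 0.09))
#' }
#' @export
preprocess_recording <- function(rec, band = c(0.01, 0.09), channels = NULL,
                                 constants = NULL, mode = "zero_phase",
                                 fs_out = 4) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (is.null(constants)) constants <- mbll_constants(rec$layout)
  od <- intensity_to_od(rec)
  all_ch <- dimnames(od$od)[[1]]
  if (is.null(channels)) channels <- all_ch
  miss <- setdiff(channels, all_ch)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))

  nt <- dim(od$od)[3]
  # filter and resample in the OD domain, per channel x wavelength
  sel <- od$od[channels, , , drop = FALSE]
  nch <- length(channels)
  flat <- matrix(aperm(sel, c(3, 1, 2)), nrow = nt)  # time x (channel*wavelength)
  filt <- bandpass(flat, fs = rec$fs, band = band, mode = mode)
  res <- resample_4hz(filt, fs_in = rec$fs, fs_out = fs_out)
  nt2 <- nrow(res)
  od2 <- aperm(array(res, dim = c(nt2, nch, 2)), c(2, 3, 1))
  dimnames(od2) <- list(channels, dimnames(sel)[[2]], NULL)
  od_obj <- structure(
    list(od = od2, fs = fs_out, layout = rec$layout, paradigm = rec$paradigm,
         reference = od$reference),
    class = "optical_density"
  )
  hemo <- mbll(od_obj, constants = constants, band = band)
  hemo$src <- list(fs_in = rec$fs, n_in = nt, band = band, mode = mode,
                   fs_out = fs_out)
  hemo
}
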