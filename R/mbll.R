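#' Extinction coefficients and pathlength constants for the modified
#' Beer-Lambert law
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at 760 and
#' 850 nm from the Cope (1991) compilation as distributed with the HOMER
#' analysis suite (values in cm^-1 per mole/L, stored here in
#' uM^-1 cm^-1). The differential pathlength factor (DPF) rescales the
#' geometric source-detector separation to the true mean photon path; 6.0 is
#' a common continuous-wave adult-head default and affects concentration
#' scale only, not t-statistics.
#'
#' @param layout A `nirs_layout`; per-channel distances are taken from it.
#' @param dpf Differential pathlength factor, recycled to both wavelengths.
#' @return An object of class `mbll_constants`: list with `extinction`
#'   (2x2 matrix, rows = wavelengths 760/850 nm, cols = HbO2/HbR, in
#'   uM^-1 cm^-1), `dpf` (length 2) and `distance_cm` (named per channel).
#' @export
mbll_constants <- function(layout, dpf = 6.0) {
  if (length(dpf) == 1L) dpf <- rep(dpf, 2L)
  stopifnot(length(dpf) == 2L, all(dpf > 0))
  # Cope (1991) tabulation: cm^-1/(mole/L) -> uM^-1 cm^-1 (x 1e-6)
  ext <- matrix(
    c(1486.6, 3843.7,   # 760 nm: HbO2, HbR
      2526.4, 1798.6),  # 850 nm: HbO2, HbR
    nrow = 2, byrow = TRUE,
    dimnames = list(c("760", "850"), c("HbO2", "HbR"))
  ) * 1e-6
  if (kappa(ext, exact = TRUE) >= 1e4) stop("extinction matrix is ill-conditioned")
  structure(
    list(
      extinction = ext,
      dpf = dpf,
      distance_cm = stats::setNames(layout$channels$distance_mm / 10,
                                    layout$channels$name)
    ),
    class = "mbll_constants"
  )
}

#' Convert raw intensities to optical density
#'
#' OD(t) = -log10(I(t) / Ibar) per channel and wavelength, with Ibar the
#' mean intensity over the whole recording (so OD has zero log-mean
#' reference; any constant offset is removed downstream by the band-pass
#' filter).
#'
#' @param rec A `nirs_recording`.
#' @return An object of class `optical_density`: list with `od` (array
#'   `[channel, wavelength, time]`), `fs`, `layout`, `paradigm` and
#'   `reference` ("whole-recording mean intensity").
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  ii <- rec$intensities
  if (any(ii <= 0)) stop("intensities must be strictly positive")
  ibar <- apply(ii, c(1, 2), mean)
  od <- -log10(ii / as.vector(ibar))  # ibar recycles over the time dimension
  structure(
    list(od = od, fs = rec$fs, layout = rec$layout, paradigm = rec$paradigm,
         reference = "whole-recording mean intensity"),
    class = "optical_density"
  )
}

#' Modified Beer-Lambert law: optical density to hemoglobin concentrations
#'
#' Per channel, solves the 2x2 linear system
#' `dOD_lambda = (eps_HbO2,lambda * dHbO2 + eps_HbR,lambda * dHbR) * d * DPF_lambda`
#' for (dHbO2, dHbR) at every time point. Distances in cm and extinction
#' coefficients in uM^-1 cm^-1 give concentrations in uM.
#'
#' @param od An `optical_density` object (any sampling rate).
#' @param constants An `mbll_constants`; defaults to `mbll_constants(layout)`.
#' @param band Optional length-2 filter band (Hz) recorded as provenance.
#' @return A `hemo_ts` object: list with `hbo`, `hbr` (matrices
#'   `[channel, time]`, uM), `fs`, `layout`, `paradigm`, `band`.
#' @export
mbll <- function(od, constants = NULL, band = NULL) {
  stopifnot(inherits(od, "optical_density"))
  if (is.null(constants)) constants <- mbll_constants(od$layout)
  E <- constants$extinction
  if (abs(det(E)) < .Machine$double.eps * 100) stop("singular extinction matrix")
  Einv <- solve(E)
  nch <- dim(od$od)[1]
  nt <- dim(od$od)[3]
  ch_names <- dimnames(od$od)[[1]]
  d <- constants$distance_cm[ch_names]
  if (anyNA(d)) stop("missing source-detector distance for some channels")
  hbo <- matrix(0, nch, nt, dimnames = list(ch_names, NULL))
  hbr <- hbo
  for (i in seq_len(nch)) {
    # divide each wavelength row by its effective pathlength d * DPF
    odn <- od$od[i, , ] / (d[i] * constants$dpf)
    conc <- Einv %*% odn
    hbo[i, ] <- conc[1, ]
    hbr[i, ] <- conc[2, ]
  }
  hemo_ts(hbo, hbr, fs = od$fs, layout = od$layout, paradigm = od$paradigm,
          band = band)
}

#' Forward modified Beer-Lambert map: concentrations to optical density
#'
#' Exact linear inverse of [mbll()]; used by the simulator to map generated
#' hemoglobin concentrations into the optical-density domain.
#'
#' @param hemo A `hemo_ts`.
#' @param constants An `mbll_constants`.
#' @return An `optical_density` object at `hemo$fs`.
#' @export
forward_mbll <- function(hemo, constants = NULL) {
  stopifnot(inherits(hemo, "hemo_ts"))
  if (is.null(constants)) constants <- mbll_constants(hemo$layout)
  E <- constants$extinction
  ch_names <- rownames(hemo$hbo)
  d <- constants$distance_cm[ch_names]
  nch <- nrow(hemo$hbo)
  nt <- ncol(hemo$hbo)
  od <- array(0, dim = c(nch, 2, nt),
              dimnames = list(ch_names, rownames(E), NULL))
  for (i in seq_len(nch)) {
    conc <- rbind(hemo$hbo[i, ], hemo$hbr[i, ])
    od[i, , ] <- (E %*% conc) * (d[i] * constants$dpf)
  }
  structure(
    list(od = od, fs = hemo$fs, layout = hemo$layout, paradigm = hemo$paradigm,
         reference = "forward model (zero baseline)"),
    class = "optical_density"
  )
}

#' Hemoglobin concentration time-series container
#'
#' @param hbo,hbr Matrices `[channel, time]` of concentration changes (uM).
#' @param fs Sampling rate in Hz.
#' @param layout A `nirs_layout`.
#' @param paradigm An `nf_paradigm`.
#' @param band Optional length-2 band-pass provenance (Hz).
#' @return An object of class `hemo_ts`.
#' @export
hemo_ts <- function(hbo, hbr, fs, layout, paradigm, band = NULL) {
  stopifnot(is.matrix(hbo), is.matrix(hbr), all(dim(hbo) == dim(hbr)), fs > 0)
  structure(
    list(hbo = hbo, hbr = hbr, fs = fs, layout = layout, paradigm = paradigm,
         band = band),
    class = "hemo_ts"
  )
}

#' @export
print.hemo_ts <- function(x, ...) {
  cat(sprintf(
    "<hemo_ts> %d channels x %d samples @ %g Hz%s\n",
    nrow(x$hbo), ncol(x$hbo), x$fs,
    if (is.null(x$band)) "" else sprintf(", band %g-%g Hz", x$band[1], x$band[2])
  ))
  invisible(x)
}
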