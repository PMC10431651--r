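#' Write a recording in the plain-text CSV dialect
#'
#' The package's interchange format is a pair of text files sharing a path
#' prefix: `<path>_intensities.csv` holds one column per channel and
#' wavelength (header `S1-D1@760`, samples in rows, full double precision)
#' and `<path>_meta.json` holds the layout (channel table, sources,
#' detectors, wavelengths), sampling rate, paradigm and free-form metadata.
#' The SNIRF container is the community standard for continuous-wave fNIRS
#' but is HDF5-based; requesting it raises an informative error pointing to
#' the CSV dialect.
#'
#' @param rec A `nirs_recording`.
#' @param path Path prefix (no extension).
#' @param format `"csv"` or `"snirf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf") {
    stop("the SNIRF container is HDF5-based and needs an HDF5 backend; ",
         "use format = \"csv\"")
  }
  stopifnot(inherits(rec, "nirs_recording"))
  d <- dim(rec$intensities)
  wl <- rec$layout$wavelengths
  cols <- matrix(aperm(rec$intensities, c(3, 1, 2)), nrow = d[3])
  colnames(cols) <- as.vector(outer(rec$layout$channels$name, wl,
                                    function(ch, w) paste0(ch, "@", w)))
  txt <- apply(cols, 2, function(x) sprintf("%.17g", x))
  utils::write.csv(txt, paste0(path, "_intensities.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(
    format = "nirsfeed-csv-v1",
    fs = rec$fs,
    wavelengths = wl,
    sources = rec$layout$sources,
    detectors = rec$layout$detectors,
    channels = as.data.frame(rec$layout$channels),
    paradigm = rec$paradigm[c("baseline_s", "n_trials", "task_s", "rest_s")],
    meta = rec$meta
  )
  jsonlite::write_json(meta, paste0(path, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from the CSV dialect
#'
#' Inverse of [write_recording()]: the write/read round trip preserves
#' intensities to better than 1e-12 relative and layout, sampling rate and
#' paradigm exactly. Missing sidecar fields raise a format error naming the
#' field; non-positive intensities raise a validation error.
#'
#' @param path Path prefix used when writing.
#' @param format `"csv"` or `"snirf"`.
#' @return A `nirs_recording`.
#' @export
read_recording <- function(path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf") {
    stop("the SNIRF container is HDF5-based and needs an HDF5 backend; ",
         "use format = \"csv\"")
  }
  fcsv <- paste0(path, "_intensities.csv")
  fjson <- paste0(path, "_meta.json")
  if (!file.exists(fcsv)) stop("missing intensity file: ", fcsv)
  if (!file.exists(fjson)) stop("missing sidecar file: ", fjson)
  meta <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  for (field in c("fs", "wavelengths", "sources", "detectors", "channels",
                  "paradigm")) {
    if (is.null(meta[[field]])) {
      stop("malformed sidecar: missing field '", field, "'")
    }
  }
  for (field in c("baseline_s", "n_trials", "task_s", "rest_s")) {
    if (is.null(meta$paradigm[[field]])) {
      stop("malformed sidecar: missing field 'paradigm$", field, "'")
    }
  }
  layout <- structure(
    list(
      channels = tibble::as_tibble(meta$channels),
      sources = meta$sources,
      detectors = meta$detectors,
      wavelengths = as.numeric(meta$wavelengths)
    ),
    class = "nirs_layout"
  )
  validate_layout(layout)
  paradigm <- default_paradigm(
    baseline_s = meta$paradigm$baseline_s,
    n_trials = meta$paradigm$n_trials,
    task_s = meta$paradigm$task_s,
    rest_s = meta$paradigm$rest_s
  )
  tab <- utils::read.csv(fcsv, check.names = FALSE)
  expected <- as.vector(outer(layout$channels$name, layout$wavelengths,
                              function(ch, w) paste0(ch, "@", w)))
  if (!identical(colnames(tab), expected)) {
    stop("malformed intensity file: column names do not match the layout")
  }
  arr <- aperm(array(as.matrix(tab),
                     dim = c(nrow(tab), nrow(layout$channels), 2)),
               c(2, 3, 1))
  extra <- meta$meta
  if (is.null(extra)) extra <- list()
  nirs_recording(arr, layout, paradigm, fs = meta$fs, meta = extra)
}
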