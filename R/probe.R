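#' Probe layout for the DL-PFC neurofeedback montage
#'
#' Constructs the continuous-wave montage used throughout the package:
#' 8 LED sources and 8 avalanche-photodiode detectors at 760/850 nm.
#' Detectors D1--D7 form 17 long channels (16 frontal, of which 4 cover the
#' bilateral dorsolateral prefrontal cortex and are used for feedback, plus
#' 1 motor control channel); detector D8 collects an 8 mm short channel from
#' every source, measuring scalp/superficial hemodynamics only.
#'
#' @details
#' Channel identity is the ordered pair (source, detector); the row order of
#' `$channels` is the declaration order used for every channel-indexed array
#' in the package. ROIs are `nf_dlpfc` (4 channels: S1-D1, S1-D2, S7-D5,
#' S7-D7), `other_frontal` (12 channels), `motor` (1 channel) and `scalp`
#' (the 8 short channels). Long-channel source-detector separation defaults
#' to 30 mm (the montage specifies a 30--42 mm range but not per-channel
#' values); short channels are 8 mm.
#'
#' @return An object of class `nirs_layout`: a list with `channels`
#'   (a tibble with columns `source`, `detector`, `name`, `kind`,
#'   `distance_mm`, `roi`), `sources`, `detectors` and `wavelengths`
#'   (c(760, 850) nm).
#' @examples
#' lay <- default_layout()
#' table(lay$channels$roi)
#' @export
default_layout <- function() {
  frontal <- c(
    "S1-D1", "S1-D2",            # left DL-PFC feedback pair
    "S7-D5", "S7-D7",            # right DL-PFC feedback pair
    "S2-D1", "S2-D2", "S2-D3", "S3-D2", "S3-D3", "S4-D3",
    "S4-D4", "S5-D3", "S5-D4", "S6-D4", "S6-D5", "S8-D7"
  )
  motor <- "S8-D6"
  long_names <- c(frontal, motor)
  roi <- c(rep("nf_dlpfc", 4L), rep("other_frontal", 12L), "motor")
  short_names <- paste0("S", 1:8, "-D8")

  parse_sd <- function(nm) {
    m <- regmatches(nm, regexec("^S([0-9]+)-D([0-9]+)$", nm))[[1]]
    as.integer(m[2:3])
  }
  all_names <- c(long_names, short_names)
  sd <- t(vapply(all_names, parse_sd, integer(2)))
  channels <- tibble::tibble(
    source = paste0("S", sd[, 1]),
    detector = paste0("D", sd[, 2]),
    name = all_names,
    kind = c(rep("long", length(long_names)), rep("short", 8L)),
    distance_mm = c(rep(30, length(long_names)), rep(8, 8L)),
    roi = c(roi, rep("scalp", 8L))
  )
  structure(
    list(
      channels = channels,
      sources = paste0("S", 1:8),
      detectors = paste0("D", 1:8),
      wavelengths = c(760, 850)
    ),
    class = "nirs_layout"
  )
}

#' @export
print.nirs_layout <- function(x, ...) {
  n_long <- sum(x$channels$kind == "long")
  n_short <- sum(x$channels$kind == "short")
  cat(sprintf(
    "<nirs_layout> %d sources, %d detectors, %d channels (%d long + %d short), wavelengths %s nm\n",
    length(x$sources), length(x$detectors), nrow(x$channels),
    n_long, n_short, paste(x$wavelengths, collapse = "/")
  ))
  print(table(x$channels$roi))
  invisible(x)
}

#' Validate a probe layout
#'
#' Checks the montage invariants: 17 long channels (16 frontal + 1 motor),
#' 8 short channels all on detector D8 (one per source), long separations in
#' 30--42 mm, short separation 8 mm, and the 4-channel `nf_dlpfc` feedback
#' ROI.
#'
#' @param layout A `nirs_layout`.
#' @return `layout`, invisibly; stops on violation.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "nirs_layout"))
  ch <- layout$channels
  long <- ch[ch$kind == "long", ]
  short <- ch[ch$kind == "short", ]
  if (nrow(long) != 17L) stop("layout must have exactly 17 long channels")
  if (nrow(short) != 8L) stop("layout must have exactly 8 short channels")
  if (!all(short$detector == "D8")) stop("all short channels must use detector D8")
  if (!setequal(short$source, layout$sources)) {
    stop("every source must have exactly one short channel")
  }
  if (!all(long$distance_mm >= 30 & long$distance_mm <= 42)) {
    stop("long-channel separation must lie in [30, 42] mm")
  }
  if (!all(short$distance_mm == 8)) stop("short-channel separation must be 8 mm")
  nf <- ch$name[ch$roi == "nf_dlpfc"]
  if (!setequal(nf, c("S1-D1", "S1-D2", "S7-D5", "S7-D7"))) {
    stop("nf_dlpfc ROI must be {S1-D1, S1-D2, S7-D5, S7-D7}")
  }
  if (sum(ch$roi == "other_frontal") != 12L) stop("other_frontal ROI must have 12 channels")
  if (sum(ch$roi == "motor") != 1L) stop("motor ROI must have 1 channel")
  if (length(layout$wavelengths) != 2L) stop("layout needs exactly two wavelengths")
  invisible(layout)
}

#' Channel names of a region of interest
#'
#' @param layout A `nirs_layout`.
#' @param roi One of `"nf_dlpfc"`, `"other_frontal"`, `"motor"`, `"scalp"`.
#' @return Character vector of channel names in declaration order.
#' @export
roi_channels <- function(layout, roi) {
  roi <- match.arg(roi, c("nf_dlpfc", "other_frontal", "motor", "scalp"))
  layout$channels$name[layout$channels$roi == roi]
}

#' Source-matched short channel for each long channel
#'
#' The short-channel nuisance regressor used for a long channel is the short
#' channel that shares the long channel's source (all short channels sit on
#' detector D8).
#'
#' @param layout A `nirs_layout`.
#' @param channels Long-channel names; defaults to all long channels.
#' @return Named character vector mapping long-channel name to its
#'   source-matched short-channel name.
#' @export
matched_short_channel <- function(layout, channels = NULL) {
  ch <- layout$channels
  if (is.null(channels)) channels <- ch$name[ch$kind == "long"]
  src <- ch$source[match(channels, ch$name)]
  if (anyNA(src)) stop("unknown channel name(s): ",
                       paste(channels[is.na(src)], collapse = ", "))
  stats::setNames(paste0(src, "-D8"), channels)
}

#' Task paradigm of the neurofeedback session
#'
#' A 2-minute initial rest (baseline) followed by `n_trials` repetitions of
#' a 30 s neurofeedback task block and a 30 s rest block; the default session
#' lasts 1020 s.
#'
#' @param baseline_s Initial rest duration in seconds.
#' @param n_trials Number of task/rest repetitions.
#' @param task_s Task block duration in seconds.
#' @param rest_s Rest block duration in seconds.
#' @return An object of class `nf_paradigm` with fields `baseline_s`,
#'   `n_trials`, `task_s`, `rest_s`, `onsets` (task onset times, seconds) and
#'   `total_s`.
#' @examples
#' p <- default_paradigm()
#' p$onsets[c(1, 15)]  # 120 and 960 s
#' @export
default_paradigm <- function(baseline_s = 120, n_trials = 15L,
                             task_s = 30, rest_s = 30) {
  stopifnot(baseline_s >= 0, n_trials >= 1, task_s > 0, rest_s >= 0)
  onsets <- baseline_s + (seq_len(n_trials) - 1) * (task_s + rest_s)
  structure(
    list(
      baseline_s = baseline_s, n_trials = as.integer(n_trials),
      task_s = task_s, rest_s = rest_s,
      onsets = onsets,
      total_s = baseline_s + n_trials * (task_s + rest_s)
    ),
    class = "nf_paradigm"
  )
}

#' @export
print.nf_paradigm <- function(x, ...) {
  cat(sprintf(
    "<nf_paradigm> %gs baseline + %d x (%gs task + %gs rest) = %gs\n",
    x$baseline_s, x$n_trials, x$task_s, x$rest_s, x$total_s
  ))
  invisible(x)
}

#' Trial phase at given times
#'
#' @param paradigm An `nf_paradigm`.
#' @param t Times in seconds from recording start.
#' @return Character vector: `"baseline"`, `"task"` or `"rest"`.
#' @export
paradigm_phase <- function(paradigm, t) {
  phase <- rep("baseline", length(t))
  cycle <- paradigm$task_s + paradigm$rest_s
  after <- t >= paradigm$baseline_s &
    t < paradigm$baseline_s + paradigm$n_trials * cycle
  within <- (t[after] - paradigm$baseline_s) %% cycle
  phase[after] <- ifelse(within < paradigm$task_s, "task", "rest")
  phase[t >= paradigm$baseline_s + paradigm$n_trials * cycle] <- "rest"
  phase
}

#' Raw fNIRS recording container
#'
#' Bundles per-channel, per-wavelength raw light intensities with the layout
#' and paradigm they were acquired under. Intensities must be strictly
#' positive (their logarithm is taken when converting to optical density).
#'
#' @param intensities Numeric array `[channel, wavelength, time]` with
#'   dimnames: channel names matching `layout$channels$name` and wavelength
#'   names matching `layout$wavelengths`.
#' @param layout A `nirs_layout`.
#' @param paradigm An `nf_paradigm`.
#' @param fs Sampling rate in Hz (device default 7.8125 Hz).
#' @param meta Optional free-form named list.
#' @return An object of class `nirs_recording`.
#' @export
nirs_recording <- function(intensities, layout, paradigm, fs = 7.8125,
                           meta = list()) {
  validate_layout(layout)
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L, fs > 0)
  if (dim(intensities)[1] != nrow(layout$channels) ||
      dim(intensities)[2] != 2L) {
    stop("intensities must be [n_channels x 2 wavelengths x time]")
  }
  if (!all(is.finite(intensities)) || any(intensities <= 0)) {
    stop("intensities must be finite and strictly positive")
  }
  if (dim(intensities)[3] < floor(paradigm$total_s * fs)) {
    stop("recording shorter than the paradigm (",
         dim(intensities)[3], " samples < ",
         floor(paradigm$total_s * fs), ")")
  }
  dimnames(intensities) <- list(
    channel = layout$channels$name,
    wavelength = as.character(layout$wavelengths),
    NULL
  )
  structure(
    list(intensities = intensities, layout = layout, paradigm = paradigm,
         fs = fs, meta = meta),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<nirs_recording> %d channels x %d wavelengths x %d samples @ %g Hz (%.1f s)\n",
    d[1], d[2], d[3], x$fs, d[3] / x$fs
  ))
  invisible(x)
}
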