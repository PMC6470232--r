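#' Hemodynamic recording container
#'
#' Holds per-channel oxyhemoglobin (`hbo`) and deoxyhemoglobin (`hhb`)
#' concentration-change series (micromol/L, relative to an arbitrary
#' baseline), the sampling rate, named condition segments and free-form
#' metadata.
#'
#' @param hbo,hhb Numeric matrices, samples x channels, with column names
#'   equal to the channel ids.
#' @param sampling_rate Sampling rate, Hz.
#' @param segments Tibble with columns `condition`, `start`, `end` giving
#'   1-based inclusive sample ranges. Defaults to a single segment named
#'   `"all"` spanning the record. Segments must be disjoint and in bounds.
#' @param meta Named list (e.g. `subject`, `group`).
#'
#' @return An object of class `hemo_recording`.
#' @export
hemo_recording <- function(hbo, hhb, sampling_rate,
                           segments = NULL, meta = list()) {
  hbo <- as.matrix(hbo); hhb <- as.matrix(hhb)
  if (!identical(dim(hbo), dim(hhb))) {
    stop("hbo and hhb must have identical dimensions")
  }
  if (is.null(colnames(hbo))) {
    colnames(hbo) <- colnames(hhb) <- sprintf("CH%02d", seq_len(ncol(hbo)))
  }
  if (!identical(colnames(hbo), colnames(hhb))) {
    stop("hbo and hhb channel names differ")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0")
  }
  n <- nrow(hbo)
  if (is.null(segments)) {
    segments <- tibble::tibble(condition = "all", start = 1L, end = n)
  }
  segments <- tibble::as_tibble(segments)
  .check_segments(segments, n)
  structure(list(hbo = hbo, hhb = hhb, sampling_rate = sampling_rate,
                 channels = colnames(hbo), segments = segments, meta = meta),
            class = "hemo_recording")
}

.check_segments <- function(segments, n) {
  stopifnot(all(c("condition", "start", "end") %in% names(segments)))
  if (nrow(segments) == 0) return(invisible(TRUE))
  if (any(segments$start < 1) || any(segments$end > n) ||
      any(segments$start > segments$end)) {
    stop("segments out of bounds")
  }
  o <- order(segments$start)
  s <- segments[o, ]
  if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
    stop("segments overlap")
  }
  invisible(TRUE)
}

#' Optical recording container
#'
#' Per-channel optical-density change series at two or more wavelengths,
#' prior to conversion into hemoglobin concentration changes.
#'
#' @param od Named list, one samples x channels matrix per wavelength; names
#'   are the wavelengths in nm (e.g. `"740"`).
#' @param sampling_rate Sampling rate, Hz.
#' @param segments,meta As in [hemo_recording()].
#' @return An object of class `optical_recording`.
#' @export
optical_recording <- function(od, sampling_rate, segments = NULL,
                              meta = list()) {
  stopifnot(is.list(od), length(od) >= 2)
  wl <- suppressWarnings(as.numeric(names(od)))
  if (anyNA(wl)) stop("names of od must be numeric wavelengths (nm)")
  od <- lapply(od, as.matrix)
  dims <- vapply(od, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all wavelength matrices must share one shape")
  }
  if (is.null(colnames(od[[1]]))) {
    for (i in seq_along(od)) {
      colnames(od[[i]]) <- sprintf("CH%02d", seq_len(ncol(od[[i]])))
    }
  }
  n <- nrow(od[[1]])
  if (is.null(segments)) {
    segments <- tibble::tibble(condition = "all", start = 1L, end = n)
  }
  segments <- tibble::as_tibble(segments)
  .check_segments(segments, n)
  structure(list(od = od, wavelengths = wl, sampling_rate = sampling_rate,
                 channels = colnames(od[[1]]), segments = segments,
                 meta = meta),
            class = "optical_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat("<hemo_recording> ", ncol(x$hbo), " channels x ", nrow(x$hbo),
      " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  cat("segments:", paste(x$segments$condition, collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a recording
#'
#' @param x A `hemo_recording`.
#' @param ... Unused.
#' @return Tibble with columns `time` (s), `channel`, `chromophore`
#'   (`"hbo"`/`"hhb"`), `value` (micromol/L).
#' @method as_tibble hemo_recording
#' @export
as_tibble.hemo_recording <- function(x, ...) {
  n <- nrow(x$hbo)
  tt <- (seq_len(n) - 1) / x$sampling_rate
  long <- function(m, chrom) {
    tibble::tibble(
      time = rep(tt, times = ncol(m)),
      channel = rep(colnames(m), each = n),
      chromophore = chrom,
      value = as.vector(m)
    )
  }
  dplyr::bind_rows(long(x$hbo, "hbo"), long(x$hhb, "hhb"))
}

#' Extract one condition segment of a recording
#'
#' @param rec A `hemo_recording`.
#' @param condition Segment name present in `rec$segments`.
#' @return A `hemo_recording` restricted to that segment (with a single
#'   segment spanning it).
#' @export
segment_recording <- function(rec, condition) {
  stopifnot(inherits(rec, "hemo_recording"))
  row <- rec$segments[rec$segments$condition == condition, ]
  if (nrow(row) != 1) stop("no unique segment named '", condition, "'")
  idx <- row$start:row$end
  hemo_recording(rec$hbo[idx, , drop = FALSE], rec$hhb[idx, , drop = FALSE],
                 rec$sampling_rate,
                 segments = tibble::tibble(condition = condition, start = 1L,
                                           end = length(idx)),
                 meta = rec$meta)
}

#' Restrict a recording to a subset of channels
#'
#' @param rec A `hemo_recording`.
#' @param channels Channel ids to keep.
#' @return A `hemo_recording` with only those channels.
#' @export
select_channels <- function(rec, channels) {
  stopifnot(inherits(rec, "hemo_recording"),
            all(channels %in% rec$channels))
  hemo_recording(rec$hbo[, channels, drop = FALSE],
                 rec$hhb[, channels, drop = FALSE],
                 rec$sampling_rate, segments = rec$segments,
                 meta = rec$meta)
}
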