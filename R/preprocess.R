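#' Preprocessing configuration
#'
#' Bundles every tunable of the cleaning chain. Defaults follow the
#' measurement protocol the package targets: 3-s moving average, moving-SD
#' motion-artifact detection with cubic-spline repair, and a 6th-order
#' Butterworth band-pass of 0.021-2 Hz applied forward-backward
#' (zero-phase).
#'
#' @param moving_average_window Moving-average window, s.
#' @param artifact_sd_window Moving-SD window for artifact detection, s.
#' @param artifact_threshold Detection threshold: a sample is flagged when
#'   its windowed SD exceeds `mean(movSD) + artifact_threshold * sd(movSD)`.
#' @param band Band-pass edges, Hz.
#' @param filter_order Butterworth design order (magnitude order doubles
#'   under zero-phase filtering).
#' @param dpf Differential pathlength factor (scalar or one value per
#'   wavelength, named by wavelength).
#' @param extinction Extinction-coefficient table: tibble with columns
#'   `wavelength` (nm), `hbo`, `hhb` (1/(mM cm)).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(moving_average_window = 3,
                              artifact_sd_window = 1,
                              artifact_threshold = 3,
                              band = c(0.021, 2),
                              filter_order = 6,
                              dpf = 6.0,
                              extinction = default_extinction()) {
  stopifnot(moving_average_window > 0, artifact_sd_window > 0,
            artifact_threshold > 0, length(band) == 2,
            band[1] > 0, band[2] > band[1], filter_order >= 1)
  structure(list(moving_average_window = moving_average_window,
                 artifact_sd_window = artifact_sd_window,
                 artifact_threshold = artifact_threshold,
                 band = band, filter_order = filter_order, dpf = dpf,
                 extinction = tibble::as_tibble(extinction)),
            class = "preprocess_config")
}

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the three
#' instrument wavelengths, in 1/(mM cm), compiled from the standard
#' tabulated in-vitro spectra. Override via
#' [preprocess_config()]`$extinction` for other instruments.
#'
#' @return Tibble with columns `wavelength`, `hbo`, `hhb`.
#' @export
default_extinction <- function() {
  tibble::tibble(
    wavelength = c(740, 808, 840),
    hbo = c(0.446, 0.856, 1.022),
    hhb = c(1.116, 0.718, 0.692)
  )
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Applies the modified Beer-Lambert law assuming constant scattering:
#' \deqn{\Delta OD(\lambda) = d \cdot DPF(\lambda) \,
#'   (\varepsilon_{HbO_2}(\lambda)\Delta[HbO_2] +
#'    \varepsilon_{HHb}(\lambda)\Delta[HHb])}
#' and solves for the two concentration changes per channel and sample in
#' least squares over the available wavelengths (exactly determined for
#' two wavelengths, overdetermined for three). The map is linear in
#' \eqn{\Delta OD}.
#'
#' @param optical An [optical_recording()] of optical-density changes.
#' @param cfg A [preprocess_config()] (pathlength factor + extinction).
#' @param montage Montage supplying the source-detector separation per
#'   channel (mm).
#' @return A [hemo_recording()] in micromol/L.
#' @export
mbll_convert <- function(optical, cfg = preprocess_config(),
                         montage = default_montage()) {
  stopifnot(inherits(optical, "optical_recording"))
  wl <- optical$wavelengths
  ext <- cfg$extinction
  miss <- setdiff(wl, ext$wavelength)
  if (length(miss) > 0) {
    stop("wavelength(s) missing from extinction table: ",
         paste(miss, collapse = ", "))
  }
  dpf <- cfg$dpf
  if (length(dpf) == 1) {
    dpf <- stats::setNames(rep(dpf, length(wl)), wl)
  } else {
    if (is.null(names(dpf)) || !all(as.character(wl) %in% names(dpf))) {
      stop("dpf must be scalar or named by wavelength")
    }
    dpf <- dpf[as.character(wl)]
  }
  eps <- as.matrix(ext[match(wl, ext$wavelength), c("hbo", "hhb")])
  if (abs(det(crossprod(eps))) < 1e-12) {
    stop("singular extinction system for the given wavelengths")
  }
  chans <- optical$channels
  d_cm <- montage$channels$sd_mm[match(chans, montage$channels$channel)] / 10
  if (anyNA(d_cm)) stop("channel(s) absent from montage")
  n <- nrow(optical$od[[1]])
  hbo <- matrix(NA_real_, n, length(chans), dimnames = list(NULL, chans))
  hhb <- hbo
  for (ci in seq_along(chans)) {
    A <- d_cm[ci] * dpf * eps                     # n_wl x 2
    od <- vapply(optical$od, function(m) m[, ci], numeric(n)) # n x n_wl
    dc <- t(qr.solve(A, t(od))) * 1000            # mM -> micromol/L
    hbo[, ci] <- dc[, 1]; hhb[, ci] <- dc[, 2]
  }
  hemo_recording(hbo, hhb, optical$sampling_rate,
                 segments = optical$segments, meta = optical$meta)
}

# centered moving mean with shrinking edge windows, O(n) via cumsum
.roll_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.roll_sd <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  m <- hi - lo + 1L
  mu <- (cs[hi + 1L] - cs[lo]) / m
  v <- (cs2[hi + 1L] - cs2[lo]) / m - mu^2
  v <- pmax(v, 0) * m / pmax(m - 1L, 1L) # unbiased, guard m = 1
  sqrt(v)
}

#' Centered moving-average smoothing
#'
#' The window spans `round(window_s * sampling_rate)` samples, forced odd
#' upward so the window is symmetric (3 s at 10 Hz gives 31 samples);
#' edges use shrinking windows, so the length is preserved.
#'
#' @param series Numeric vector.
#' @param window_s Window length, s.
#' @param sampling_rate Hz.
#' @return Smoothed series of equal length.
#' @export
moving_average <- function(series, window_s, sampling_rate) {
  if (length(series) == 0) stop("empty series")
  w <- max(1L, round(window_s * sampling_rate))
  if (w %% 2L == 0L) w <- w + 1L
  .roll_mean(series, w)
}

#' Moving-SD motion-artifact detection and cubic-spline repair
#'
#' Samples whose windowed SD exceeds `mean + threshold * SD` of the
#' windowed-SD series are masked (each run padded by one sample on both
#' sides) and replaced by a cubic spline fitted to the flanking clean
#' samples, giving a repaired series continuous at the segment joins.
#'
#' @param series Numeric vector.
#' @param cfg A [preprocess_config()].
#' @param sampling_rate Hz.
#' @param flank Clean samples used on each side of a masked run for the
#'   spline fit (default 10).
#' @return List with `series` (repaired) and `mask` (logical vector of
#'   repaired samples).
#' @export
remove_motion_artifacts <- function(series, cfg = preprocess_config(),
                                    sampling_rate, flank = 10L) {
  n <- length(series)
  w <- max(3L, round(cfg$artifact_sd_window * sampling_rate))
  if (w %% 2L == 0L) w <- w + 1L
  if (n <= w) stop("series shorter than the artifact SD window")
  msd <- .roll_sd(series, w)
  thr <- mean(msd) + cfg$artifact_threshold * stats::sd(msd)
  mask <- msd > thr
  # pad each flagged run by one sample
  mask <- mask | c(mask[-1], FALSE) | c(FALSE, mask[-n])
  if (mean(mask) > 0.5) stop("artifact fraction too high")
  if (!any(mask)) return(list(series = series, mask = mask))
  out <- series
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    left <- if (a > 1L) seq.int(max(1L, a - flank), a - 1L) else integer(0)
    right <- if (b < n) seq.int(b + 1L, min(n, b + flank)) else integer(0)
    anchors <- c(left[!mask[left]], right[!mask[right]])
    if (length(anchors) >= 2L) {
      out[a:b] <- stats::spline(anchors, series[anchors], xout = a:b,
                                method = "natural")$y
    } else if (length(anchors) == 1L) {
      out[a:b] <- series[anchors]
    } else {
      out[a:b] <- mean(series[!mask])
    }
  }
  list(series = out, mask = mask)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the configured order and applies it
#' forward-backward (zero-phase, so phase relations between channels are
#' untouched; the magnitude response is squared). The series is demeaned
#' and reflection-padded before filtering to suppress edge transients of
#' the very-low-frequency pole pair; length is preserved.
#'
#' @param series Numeric vector.
#' @param cfg A [preprocess_config()].
#' @param sampling_rate Hz; must exceed twice the upper band edge.
#' @return Filtered series.
#' @export
bandpass_filter <- function(series, cfg = preprocess_config(),
                            sampling_rate) {
  ny <- sampling_rate / 2
  if (cfg$band[2] >= ny) stop("upper band edge at or above Nyquist")
  n <- length(series)
  mu <- mean(series)
  x <- series - mu
  p <- min(n - 1L, round(3 * sampling_rate / cfg$band[1]))
  xp <- c(2 * x[1] - rev(x[seq_len(p) + 1L]),
          x,
          2 * x[n] - rev(x[n - seq_len(p)]))
  bf <- signal::butter(cfg$filter_order, cfg$band / ny, type = "pass")
  y <- signal::filtfilt(bf, xp)
  y[(p + 1L):(p + n)]
}

#' Full preprocessing chain for a recording
#'
#' Per channel and chromophore: moving average, moving-SD artifact repair,
#' zero-phase Butterworth band-pass. Deterministic; permuting channels
#' permutes the output identically.
#'
#' @param rec A [hemo_recording()].
#' @param cfg A [preprocess_config()].
#' @return List with `recording` (cleaned) and `artifact_mask` (named list
#'   `hbo`, `hhb` of logical matrices).
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "hemo_recording"))
  fs <- rec$sampling_rate
  clean <- function(m) {
    mask <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
    for (ci in seq_len(ncol(m))) {
      x <- moving_average(m[, ci], cfg$moving_average_window, fs)
      rep_ <- remove_motion_artifacts(x, cfg, fs)
      mask[, ci] <- rep_$mask
      m[, ci] <- bandpass_filter(rep_$series, cfg, fs)
    }
    list(m = m, mask = mask)
  }
  h <- clean(rec$hbo); d <- clean(rec$hhb)
  out <- rec; out$hbo <- h$m; out$hhb <- d$m
  list(recording = out, artifact_mask = list(hbo = h$mask, hhb = d$mask))
}
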