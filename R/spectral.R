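#' The four physiological frequency intervals
#'
#' Interval I (0.6-2 Hz) captures cardiac activity, II (0.145-0.6 Hz)
#' respiration, III (0.052-0.145 Hz) myogenic and IV (0.021-0.052 Hz)
#' neurogenic vasomotion. The intervals are contiguous and together span
#' the preprocessing pass-band.
#'
#' @return Tibble with columns `band`, `low`, `high` (Hz).
#' @export
band_set <- function() {
  tibble::tibble(
    band = c("I", "II", "III", "IV"),
    low = c(0.6, 0.145, 0.052, 0.021),
    high = c(2, 0.6, 0.145, 0.052)
  )
}

#' Logarithmic frequency grid
#'
#' @param low,high Grid limits, Hz.
#' @param voices Frequencies per octave (default 16).
#' @return Increasing numeric vector of frequencies including both limits.
#' @export
default_freq_grid <- function(low = 0.021, high = 2, voices = 16) {
  n <- ceiling(log2(high / low) * voices)
  f <- low * 2^(seq(0, n) / voices)
  f[f <= high * (1 + 1e-12)]
}

# Fourier transform of the (analytic) Morlet mother wavelet at angular
# frequency omega, scale s, with L2 normalisation: psi_hat(w) =
# sqrt(2 pi) pi^(-1/4) exp(-(w - omega0)^2 / 2) on w > 0.
.morlet_ft <- function(omega, s, omega0) {
  out <- numeric(length(omega))
  pos <- omega > 0
  out[pos] <- sqrt(2 * pi) * pi^(-0.25) * sqrt(s) *
    exp(-(s * omega[pos] - omega0)^2 / 2)
  out
}

#' Morlet continuous wavelet transform
#'
#' Complex wavelet coefficients of a real series on a frequency grid,
#' computed by frequency-domain convolution with the analytic Morlet
#' wavelet \eqn{\psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2}}; the scale
#' for frequency f is \eqn{s = \omega_0 / (2\pi f)}. A cone-of-influence
#' mask marks coefficients within \eqn{\sqrt{2}\,s} (the Gaussian
#' e-folding time) of either record edge, where edge effects dominate.
#'
#' @param series Numeric vector.
#' @param sampling_rate Hz.
#' @param freq_grid Frequencies, Hz, all inside (0, Nyquist); default
#'   [default_freq_grid()] clipped to the Nyquist limit.
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return An object of class `wavelet_spectrum`: list with `coef`
#'   (complex, frequencies x times), `frequencies`, `scales`, `times`,
#'   `coi` (logical, TRUE where valid), `sampling_rate`, `omega0`.
#' @export
morlet_cwt <- function(series, sampling_rate, freq_grid = NULL, omega0 = 6) {
  n <- length(series)
  if (n < 4) stop("series too short")
  ny <- sampling_rate / 2
  if (is.null(freq_grid)) {
    freq_grid <- default_freq_grid(high = min(2, 0.95 * ny))
  }
  if (any(freq_grid <= 0) || any(freq_grid >= ny)) {
    stop("freq_grid must lie strictly inside (0, Nyquist)")
  }
  freq_grid <- sort(freq_grid)
  x <- series - mean(series)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L
  omega <- 2 * pi * ifelse(k <= n / 2, k, k - n) * sampling_rate / n
  scales <- omega0 / (2 * pi * freq_grid)
  coef <- matrix(0i, length(freq_grid), n)
  for (fi in seq_along(freq_grid)) {
    W <- .morlet_ft(omega, scales[fi], omega0)
    coef[fi, ] <- stats::fft(X * W, inverse = TRUE) / n
  }
  tt <- k / sampling_rate
  efold <- sqrt(2) * scales
  coi <- outer(efold, tt, function(e, t) t >= e & t <= (n - 1) / sampling_rate - e)
  structure(list(coef = coef, frequencies = freq_grid, scales = scales,
                 times = tt, coi = coi, sampling_rate = sampling_rate,
                 omega0 = omega0),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat("<wavelet_spectrum> ", length(x$frequencies), " frequencies (",
      signif(min(x$frequencies), 3), "-", signif(max(x$frequencies), 3),
      " Hz) x ", length(x$times), " samples\n", sep = "")
  invisible(x)
}

# phase unwrapping along a vector
.unwrap <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Instantaneous phase at one grid frequency
#'
#' Four-quadrant angle of the complex coefficient row at frequency `f`
#' (the quadrant-correct extension of `arctan(b/a)`), unwrapped over time.
#' Samples whose coefficient magnitude is numerically zero have no defined
#' phase and are flagged.
#'
#' @param spec A [morlet_cwt()] spectrum.
#' @param f Frequency on the grid (matched to the nearest grid point;
#'   must be within half a grid step).
#' @return Numeric vector of unwrapped phase (rad) with attribute
#'   `undefined`, a logical vector marking zero-magnitude samples.
#' @export
instantaneous_phase <- function(spec, f) {
  stopifnot(inherits(spec, "wavelet_spectrum"))
  fi <- which.min(abs(log(spec$frequencies) - log(f)))
  if (abs(spec$frequencies[fi] / f - 1) > 0.05) {
    stop("f is not on the spectrum's frequency grid")
  }
  g <- spec$coef[fi, ]
  undef <- Mod(g) < 1e-300
  ph <- .unwrap(Arg(g))
  attr(ph, "undefined") <- undef
  ph
}

#' Band-limited instantaneous phase
#'
#' One phase series per frequency interval: the complex coefficients of
#' all in-band grid frequencies are averaged at each time with
#' amplitude weights, and the four-quadrant angle of the average is
#' unwrapped over time. The mean in-band amplitude is reported, with a
#' low-confidence flag when the band holds only a small share of total
#' spectral amplitude (energy concentrated elsewhere).
#'
#' @param spec A [morlet_cwt()] spectrum.
#' @param band Band label from [band_set()] or a numeric `c(low, high)`.
#' @param bands Band table used to resolve labels.
#' @return An object of class `phase_series`: list with `phase`
#'   (unwrapped, rad), `times`, `sampling_rate`, `band`, `valid`
#'   (cone-of-influence mask for the band's lowest frequency),
#'   `mean_amplitude`, `low_confidence`.
#' @export
band_phase <- function(spec, band, bands = band_set()) {
  stopifnot(inherits(spec, "wavelet_spectrum"))
  if (is.character(band)) {
    row <- bands[bands$band == band, ]
    if (nrow(row) != 1) stop("unknown band label: ", band)
    lo <- row$low; hi <- row$high; lab <- band
  } else {
    lo <- band[1]; hi <- band[2]; lab <- paste0(lo, "-", hi, "Hz")
  }
  sel <- spec$frequencies >= lo & spec$frequencies <= hi
  if (!any(sel)) stop("no grid frequencies inside the band")
  g <- spec$coef[sel, , drop = FALSE]
  a <- Mod(g)
  wsum <- colSums(a)
  avg <- colSums(a * g) / pmax(wsum, 1e-300)
  ph <- .unwrap(Arg(avg))
  valid <- apply(spec$coi[sel, , drop = FALSE], 2, all)
  mean_amp <- mean(a)
  share <- sum(a) / sum(Mod(spec$coef))
  structure(list(phase = ph, times = spec$times,
                 sampling_rate = spec$sampling_rate, band = lab,
                 valid = valid, mean_amplitude = mean_amp,
                 low_confidence = share < 0.05),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat("<phase_series> band ", x$band, ", ", length(x$phase), " samples @ ",
      x$sampling_rate, " Hz", if (x$low_confidence) " (low confidence)",
      "\n", sep = "")
  invisible(x)
}

# Fast band-phase extraction with optional time decimation, used by the
# connectivity pipeline. Computes the in-band Morlet coefficients from one
# FFT of the series and inverts only a folded (decimated) spectrum, so the
# cost is independent of the decimation factor's inverse. Agrees with
# band_phase(morlet_cwt(x, ...), band) at the retained time points away
# from the record edges.
.band_phase_fast <- function(x, sampling_rate, lo, hi, voices = 16,
                             omega0 = 6, stride = 1L) {
  n <- length(x)
  stride <- as.integer(max(1L, stride))
  L <- .nice_fft_length(as.integer(ceiling(n / stride)))
  n2 <- L * stride
  xp <- c(x - mean(x), numeric(n2 - n))
  X <- stats::fft(xp)
  fgrid <- default_freq_grid(lo, hi, voices)
  scales <- omega0 / (2 * pi * fgrid)
  coefs <- matrix(0i, length(fgrid), L)
  for (fi in seq_along(fgrid)) {
    s <- scales[fi]
    # positive-frequency bins where the wavelet window is non-negligible
    f_c <- fgrid[fi]
    kmin <- max(1L, floor(n2 * max(0, f_c * (1 - 8 / omega0)) /
                            sampling_rate))
    kmax <- min(n2 %/% 2L,
                ceiling(n2 * f_c * (1 + 8 / omega0) / sampling_rate))
    kk <- kmin:kmax
    W <- sqrt(2 * pi) * pi^(-0.25) * sqrt(s) *
      exp(-(s * 2 * pi * kk * sampling_rate / n2 - omega0)^2 / 2)
    Yf <- complex(L)
    idx <- (kk %% L) + 1L
    if (!anyDuplicated(idx)) {
      Yf[idx] <- X[kk + 1L] * W
    } else {
      for (u in seq_along(kk)) { # fold the windowed spectrum to length L
        Yf[idx[u]] <- Yf[idx[u]] + X[kk[u] + 1L] * W[u]
      }
    }
    coefs[fi, ] <- stats::fft(Yf, inverse = TRUE) / n2
  }
  a <- Mod(coefs)
  avg <- colSums(a * coefs) / pmax(colSums(a), 1e-300)
  tt <- (seq_len(L) - 1L) * stride / sampling_rate
  efold <- sqrt(2) * max(scales)
  keep_to <- (n - 1) / sampling_rate # original record end, not the padding
  valid <- tt >= efold & tt <= keep_to - efold
  list(phase = .unwrap(Arg(avg)), times = tt,
       sampling_rate = sampling_rate / stride, valid = valid,
       mean_amplitude = mean(a))
}

# decimation factor keeping >= 12 samples per cycle of the band's upper
# edge (midpoint evaluation keeps the finite-difference error second order)
.band_stride <- function(sampling_rate, hi) {
  max(1L, as.integer(floor(sampling_rate / (12 * hi))))
}

# smallest 5-smooth integer >= n, for fast FFTs
.nice_fft_length <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}
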