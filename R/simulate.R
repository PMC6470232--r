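#' Simulate coupled stochastic phase oscillators
#'
#' Integrates the coupled phase-oscillator model
#' \deqn{\dot\varphi_i = \omega_i + q_i(\varphi_i, \varphi_j) + \xi_i(t)}
#' by the Euler-Maruyama scheme. Each coupling term is a Fourier component
#' \eqn{A\,\mathrm{trig}(k_t \varphi_{target} + k_s \varphi_{source})}
#' added to the target's phase velocity; \eqn{\xi_i} is Gaussian white
#' noise of intensity \eqn{D_i} (rad^2/s), discretised as
#' \eqn{\sqrt{2 D_i / h}\, N(0,1)} per internal step of length \eqn{h}.
#'
#' The internal step is `1 / (substeps * sampling_rate)` with `substeps =
#' max(1, ceiling(20 * max(frequency) / sampling_rate))`, i.e. at least 20
#' internal steps per cycle of the fastest oscillator; the trajectory is
#' then decimated to `sampling_rate`. Returned phases are unwrapped
#' (integration never wraps).
#'
#' @param oscillators Tibble with columns `id`, `frequency` (Hz, > 0) and
#'   `noise` (noise intensity D, rad^2/s, >= 0).
#' @param couplings Tibble with columns `target`, `source` (oscillator
#'   ids), `k_target`, `k_source` (integer wavenumbers), `trig` (`"sin"` or
#'   `"cos"`) and `amplitude` (rad/s); or `NULL` for uncoupled oscillators.
#'   The convenience form `coupling_sin_diff(target, source, a)` builds the
#'   classic `a * sin(phi_source - phi_target)` term.
#' @param duration Length of the simulated record, s.
#' @param sampling_rate Output sampling rate, Hz.
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @param initial_phase Numeric vector of starting phases (rad), recycled;
#'   default 0.
#'
#' @return Matrix (samples x oscillators, column names = ids) of unwrapped
#'   phases in radians, first row = initial phases, `duration *
#'   sampling_rate + 1` rows.
#' @export
#' @examples
#' osc <- tibble::tibble(id = c("a", "b"), frequency = 0.1, noise = 0)
#' ph <- simulate_coupled_phases(osc, coupling_sin_diff("a", "b", 0.5),
#'                               duration = 120, sampling_rate = 10, seed = 1)
simulate_coupled_phases <- function(oscillators, couplings = NULL,
                                    duration, sampling_rate, seed = NULL,
                                    initial_phase = 0) {
  oscillators <- tibble::as_tibble(oscillators)
  stopifnot(all(c("id", "frequency", "noise") %in% names(oscillators)))
  if (any(oscillators$frequency <= 0)) stop("frequencies must be > 0")
  if (any(oscillators$noise < 0)) stop("noise intensities must be >= 0")
  if (duration <= 0 || sampling_rate <= 0) {
    stop("duration and sampling_rate must be > 0")
  }
  m <- nrow(oscillators)
  ids <- oscillators$id
  if (!is.null(seed)) set.seed(seed)

  substeps <- max(1L, ceiling(20 * max(oscillators$frequency) / sampling_rate))
  h <- 1 / (substeps * sampling_rate)
  n_out <- round(duration * sampling_rate)
  w <- 2 * pi * oscillators$frequency
  sig <- sqrt(2 * oscillators$noise / h) * h # per-step noise sd, rad

  has_cpl <- !is.null(couplings) && nrow(tibble::as_tibble(couplings)) > 0
  phi0 <- rep_len(initial_phase, m)
  n_tot <- n_out * substeps
  keep <- seq(substeps, n_tot, by = substeps)
  out <- matrix(NA_real_, n_out + 1L, m, dimnames = list(NULL, ids))
  out[1L, ] <- phi0

  if (!has_cpl) {
    # Without coupling the Euler-Maruyama update is a plain drift +
    # Gaussian-increment recursion, so the whole path vectorises.
    inc <- matrix(stats::rnorm(n_tot * m), n_tot, m)
    inc <- sweep(inc, 2L, sig, "*")
    inc <- sweep(inc, 2L, w * h, "+")
    path <- apply(inc, 2L, cumsum)
    if (n_tot == 1L) path <- matrix(path, 1L, m)
    out[-1L, ] <- sweep(path[keep, , drop = FALSE], 2L, phi0, "+")
    return(out)
  }

  couplings <- tibble::as_tibble(couplings)
  stopifnot(all(c("target", "source", "k_target", "k_source", "trig",
                  "amplitude") %in% names(couplings)))
  ti <- match(couplings$target, ids)
  si <- match(couplings$source, ids)
  if (anyNA(ti) || anyNA(si)) stop("coupling references unknown oscillator id")
  s_sin <- as.numeric(couplings$trig == "sin")
  kt <- couplings$k_target; ks <- couplings$k_source
  amp <- couplings$amplitude
  noise_mat <- if (any(sig > 0)) {
    sweep(matrix(stats::rnorm(n_tot * m), n_tot, m), 2L, sig, "*")
  } else NULL

  phi <- phi0
  drive <- numeric(m)
  row_i <- 0L
  for (k in seq_len(n_tot)) {
    arg <- kt * phi[ti] + ks * phi[si]
    q <- amp * (s_sin * sin(arg) + (1 - s_sin) * cos(arg))
    agg <- rowsum(q, ti)
    drive[] <- 0
    drive[as.integer(rownames(agg))] <- agg
    phi <- phi + (w + drive) * h
    if (!is.null(noise_mat)) phi <- phi + noise_mat[k, ]
    if (k %% substeps == 0L) {
      row_i <- row_i + 1L
      out[row_i + 1L, ] <- phi
    }
  }
  out
}

#' @rdname simulate_coupled_phases
#' @param target,source Oscillator ids.
#' @param amplitude Coupling amplitude, rad/s.
#' @export
coupling_sin_diff <- function(target, source, amplitude) {
  tibble::tibble(target = target, source = source,
                 k_target = -1L, k_source = 1L, trig = "sin",
                 amplitude = amplitude)
}

#' Compose band phases into an fNIRS-like hemodynamic recording
#'
#' Builds oxyhemoglobin traces as a sum of band oscillations
#' \eqn{\sum_b A_b \cos\varphi_b(t)} plus a linear baseline drift and white
#' measurement noise; the deoxyhemoglobin trace is optionally an
#' anti-phase scaled copy with independent noise (the usual reciprocal
#' HbO2/HHb pattern of functional activation).
#'
#' @param band_phases Named list, one entry per band label, each a samples
#'   x channels matrix of unwrapped phases (all sharing one shape and the
#'   same channel columns).
#' @param band_amplitudes Named numeric vector of oscillation amplitudes
#'   (micromol/L) for the same band labels.
#' @param sampling_rate Hz.
#' @param bands A [band_set()]; each band's mean phase slope must lie
#'   inside its declared frequency interval or the band is rejected.
#' @param drift Total linear drift over the record, micromol/L (default 0).
#' @param noise_sd Measurement noise SD, micromol/L.
#' @param antiphase_hhb If `TRUE` (default), HHb = `-hhb_scale` x the
#'   oscillatory part (plus its own noise); otherwise HHb is noise only.
#' @param hhb_scale Scale of the anti-phase HHb copy (default 0.3).
#' @param seed Integer seed.
#' @param segments,meta Passed to [hemo_recording()].
#' @return A [hemo_recording()].
#' @export
phases_to_hemo <- function(band_phases, band_amplitudes, sampling_rate,
                           bands = band_set(), drift = 0, noise_sd = 0,
                           antiphase_hhb = TRUE, hhb_scale = 0.3,
                           seed = NULL, segments = NULL, meta = list()) {
  stopifnot(is.list(band_phases), length(band_phases) >= 1)
  labs <- names(band_phases)
  if (is.null(labs) || !all(labs %in% names(band_amplitudes))) {
    stop("band_phases and band_amplitudes must share band labels")
  }
  dims <- lapply(band_phases, dim)
  if (length(unique(dims)) != 1) stop("band phase matrices must share one shape")
  n <- dims[[1]][1]
  for (b in labs) {
    if (!b %in% bands$band) next
    lo <- bands$low[bands$band == b]; hi <- bands$high[bands$band == b]
    slope <- colMeans(diff(band_phases[[b]])) * sampling_rate / (2 * pi)
    # 10%-of-bandwidth margin: phase noise and coupling shift realised
    # slopes slightly; only gross band mis-assignment is rejected
    marg <- 0.1 * (hi - lo)
    if (any(slope < lo - marg | slope > hi + marg)) {
      stop("band '", b, "' contains an oscillator outside [", lo, ", ", hi,
           "] Hz (observed ", paste(signif(range(slope), 3), collapse = "-"),
           " Hz)")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  osc <- Reduce(`+`, Map(function(ph, b) band_amplitudes[[b]] * cos(ph),
                         band_phases, labs))
  dr <- drift * (seq_len(n) - 1) / max(1, n - 1)
  hbo <- osc + dr +
    matrix(stats::rnorm(length(osc), sd = noise_sd), nrow = n)
  hhb <- (if (antiphase_hhb) -hhb_scale * (osc + dr) else 0 * osc) +
    matrix(stats::rnorm(length(osc), sd = noise_sd * hhb_scale), nrow = n)
  colnames(hbo) <- colnames(hhb) <- colnames(band_phases[[1]])
  hemo_recording(hbo, hhb, sampling_rate, segments = segments, meta = meta)
}

#' Inject spike/step motion artifacts with a known ground-truth mask
#'
#' Adds short high-amplitude transients (half spikes, half steps that decay
#' back over the event) at Poisson-random instants to every channel of both
#' chromophores, and returns the exact set of corrupted samples.
#'
#' @param rec A [hemo_recording()].
#' @param rate Events per minute per channel (>= 0).
#' @param amplitude Event amplitude in multiples of each channel's SD.
#' @param width_s Event width, s (default 0.5).
#' @param seed Integer seed.
#' @return List with `recording` (corrupted copy) and `mask` (logical
#'   samples x channels matrix of injected samples, shared by both
#'   chromophores).
#' @export
inject_motion_artifacts <- function(rec, rate, amplitude = 8, width_s = 0.5,
                                    seed = NULL) {
  stopifnot(inherits(rec, "hemo_recording"), rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(rec$hbo); fs <- rec$sampling_rate
  mask <- matrix(FALSE, n, ncol(rec$hbo), dimnames = dimnames(rec$hbo))
  if (rate == 0) return(list(recording = rec, mask = mask))
  hbo <- rec$hbo; hhb <- rec$hhb
  w <- max(2L, round(width_s * fs))
  lam <- rate * (n / fs) / 60
  for (ch in seq_len(ncol(hbo))) {
    k <- stats::rpois(1, lam)
    if (k == 0) next
    starts <- sort(sample.int(max(1L, n - w), k, replace = TRUE))
    s_hbo <- stats::sd(hbo[, ch]); s_hbo <- if (s_hbo > 0) s_hbo else 1
    s_hhb <- stats::sd(hhb[, ch]); s_hhb <- if (s_hhb > 0) s_hhb else 1
    for (st in starts) {
      idx <- st:(st + w - 1L)
      shape <- if (stats::runif(1) < 0.5) {
        exp(-((seq_len(w) - w / 2)^2) / (w / 4)^2) # spike
      } else {
        seq(1, 0, length.out = w) # step decaying back
      }
      a <- amplitude * sample(c(-1, 1), 1)
      hbo[idx, ch] <- hbo[idx, ch] + a * s_hbo * shape
      hhb[idx, ch] <- hhb[idx, ch] + a * s_hhb * shape
      mask[idx, ch] <- TRUE
    }
  }
  out <- rec; out$hbo <- hbo; out$hhb <- hhb
  list(recording = out, mask = mask)
}
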