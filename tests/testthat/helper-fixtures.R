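# Shared fixtures, all generated in code.

# single-channel recording holding a pure tone per band
tone_recording <- function(freqs = c(I = 1.1, II = 0.25, III = 0.1,
                                     IV = 0.033),
                           duration = 600, fs = 10, amp = 1) {
  tt <- seq(0, duration, by = 1 / fs)
  x <- rowSums(sapply(freqs, function(f) amp * cos(2 * pi * f * tt)))
  hemo_recording(matrix(x, dimnames = list(NULL, "CH01")),
                 matrix(-0.3 * x, dimnames = list(NULL, "CH01")), fs)
}

# two-channel recording from a simulated oscillator pair in one band
pair_recording <- function(a = 0.4, f = c(0.1, 0.1), noise = 0.05,
                           duration = 600, fs = 10, seed = 1,
                           meas_sd = 0.05) {
  osc <- tibble::tibble(id = c("t", "s"), frequency = f, noise = noise)
  cpl <- if (a > 0) coupling_sin_diff("t", "s", a) else NULL
  ph <- simulate_coupled_phases(osc, cpl, duration, fs, seed = seed)
  set.seed(seed + 10000)
  n <- nrow(ph)
  x <- 0.1 * cos(ph) + matrix(rnorm(2 * n, sd = meas_sd), n)
  colnames(x) <- c("CH01", "CH02")
  list(rec = hemo_recording(x, -0.3 * x, fs), phases = ph)
}

# tiny two-region montage (4 channels) for aggregation tests
toy_montage <- function() {
  optodes <- tibble::tibble(
    optode = c("S01", "S02", "D01", "D02", "D03", "D04"),
    type = c("source", "source", rep("detector", 4)),
    x = c(0, 100, 30, -30, 130, 70),
    y = 0
  )
  channels <- tibble::tibble(
    channel = sprintf("CH%02d", 1:4),
    source = c("S01", "S01", "S02", "S02"),
    detector = c("D01", "D02", "D03", "D04"),
    region = c("LMC", "LMC", "LPFC", "LPFC"),
    hemisphere = "L"
  )
  montage(optodes, channels)
}

# fabricated channel-level EC results for aggregation tests
fake_channel_results <- function(montage, sigma, significant = TRUE,
                                 band = "IV", condition = "all",
                                 chromophore = "hbo") {
  ch <- montage$channels$channel
  pairs <- tidyr::expand_grid(source = ch, target = ch) |>
    dplyr::filter(source != target)
  n <- nrow(pairs)
  tibble::tibble(
    condition = condition, chromophore = chromophore, band = band,
    source = pairs$source, target = pairs$target,
    sigma = rep_len(sigma, n),
    surrogate_mean = 0, surrogate_sd = 0, threshold = 0,
    significant = rep_len(significant, n)
  )
}
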