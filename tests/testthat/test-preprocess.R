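test_that("MBLL conversion is linear and matches a hand-solved system", {
  m <- default_montage()
  ext <- tibble::tibble(wavelength = c(700, 850),
                        hbo = c(0.4, 1.0), hhb = c(1.1, 0.7))
  cfg <- preprocess_config(extinction = ext)
  dc_true <- cbind(hbo = c(0.001, -0.002, 0.0005),
                   hhb = c(-0.0003, 0.001, 0)) # mM
  d <- 3; dpf <- 6
  E <- as.matrix(ext[, c("hbo", "hhb")])
  od <- dc_true %*% t(E) * d * dpf
  opt <- optical_recording(
    list(`700` = matrix(od[, 1], dimnames = list(NULL, "CH01")),
         `850` = matrix(od[, 2], dimnames = list(NULL, "CH01"))), 10)
  hemo <- mbll_convert(opt, cfg, m)
  # hand-solved 2x2 inverse applied to dOD/(d*DPF), in micromol/L
  oracle <- t(solve(E) %*% t(od / (d * dpf))) * 1000
  expect_equal(unname(hemo$hbo[, 1]), oracle[, 1], tolerance = 1e-10)
  expect_equal(unname(hemo$hhb[, 1]), oracle[, 2], tolerance = 1e-10)
  # zero optical density -> zero concentration; doubling doubles
  opt0 <- optical_recording(list(`700` = matrix(0, 3, 1),
                                 `850` = matrix(0, 3, 1)), 10)
  expect_true(all(mbll_convert(opt0, cfg, m)$hbo == 0))
  opt2 <- optical_recording(
    list(`700` = matrix(2 * od[, 1], dimnames = list(NULL, "CH01")),
         `850` = matrix(2 * od[, 2], dimnames = list(NULL, "CH01"))), 10)
  expect_equal(mbll_convert(opt2, cfg, m)$hbo, 2 * hemo$hbo,
               tolerance = 1e-10)
})

test_that("MBLL three-wavelength forward model round-trips", {
  m <- default_montage()
  cfg <- preprocess_config()
  set.seed(4)
  dc <- cbind(rnorm(50, sd = 1e-3), rnorm(50, sd = 1e-3)) # mM
  E <- as.matrix(cfg$extinction[, c("hbo", "hhb")])
  od <- dc %*% t(E) * 3 * cfg$dpf
  opt <- optical_recording(
    stats::setNames(lapply(1:3, function(i)
      matrix(od[, i], dimnames = list(NULL, "CH01"))),
      cfg$extinction$wavelength), 10)
  hemo <- mbll_convert(opt, cfg, m)
  expect_equal(unname(hemo$hbo[, 1]), dc[, 1] * 1000, tolerance = 1e-8)
  expect_equal(unname(hemo$hhb[, 1]), dc[, 2] * 1000, tolerance = 1e-8)
  # wavelength absent from the table errors
  names(opt$od)[1] <- "999"; opt$wavelengths[1] <- 999
  expect_error(mbll_convert(opt, cfg, m), "extinction")
})

test_that("moving average has the documented window and edge behaviour", {
  expect_equal(moving_average(rep(3.5, 50), 3, 10), rep(3.5, 50))
  # 3 s at 10 Hz: 30 forced odd upward -> 31 samples; a unit impulse in a
  # long zero series becomes a plateau of 1/31 over 31 samples
  x <- c(rep(0, 100), 1, rep(0, 100))
  y <- moving_average(x, 3, 10)
  expect_equal(sum(y > 0), 31)
  expect_equal(max(y), 1 / 31, tolerance = 1e-12)
  expect_equal(length(y), length(x))
  expect_error(moving_average(numeric(0), 3, 10), "empty")
})

test_that("moving-SD artifact removal repairs spikes and reports masks", {
  cfg <- preprocess_config()
  tt <- seq(0, 300, by = 0.1)
  clean <- sin(2 * pi * 0.05 * tt)
  out <- remove_motion_artifacts(clean, cfg, 10)
  expect_equal(out$series, clean)
  expect_false(any(out$mask))
  # injected spikes from the generator: mask recovered, repair bounded
  rec <- hemo_recording(matrix(clean, dimnames = list(NULL, "CH01")),
                        matrix(clean, dimnames = list(NULL, "CH01")), 10)
  inj <- inject_motion_artifacts(rec, rate = 2, amplitude = 10, seed = 9)
  rep_ <- remove_motion_artifacts(inj$recording$hbo[, 1], cfg, 10)
  truth <- inj$mask[, 1]
  expect_gte(sum(rep_$mask & truth) / sum(truth), 0.9)
  z <- (rep_$series - mean(rep_$series)) / sd(clean)
  expect_lt(max(abs(z)), 4)
  # unusable channel: mostly artifact
  set.seed(1)
  wild <- rnorm(500, sd = rep(c(1, 50), each = 50))
  cfg2 <- preprocess_config(artifact_threshold = 0.01)
  expect_error(remove_motion_artifacts(wild, cfg2, 10), "artifact fraction")
})

test_that("zero-phase Butterworth band-pass has the designed response", {
  cfg <- preprocess_config()
  fs <- 10
  tt <- seq(0, 600, by = 1 / fs)
  # DC blocked
  y0 <- bandpass_filter(rep(5, length(tt)), cfg, fs)
  expect_lt(max(abs(y0)), 1e-3 * 5)
  # in-band tone passed within 5%
  x1 <- sin(2 * pi * 0.1 * tt)
  y1 <- bandpass_filter(x1, cfg, fs)
  amp1 <- 2 * Mod(mean(y1 * exp(-2i * pi * 0.1 * tt)))
  expect_lt(abs(amp1 - 1), 0.05)
  # out-of-band tone attenuated by >= 20 dB
  x2 <- sin(2 * pi * 4.9 * tt)
  y2 <- bandpass_filter(x2, cfg, fs)
  amp2 <- 2 * Mod(mean(y2 * exp(-2i * pi * 4.9 * tt)))
  expect_lt(20 * log10(amp2 / 1), -20)
  expect_error(bandpass_filter(x1, preprocess_config(band = c(0.021, 6)),
                               fs), "Nyquist")
})

test_that("preprocessing chain is deterministic and channel-equivariant", {
  set.seed(11)
  n <- 1200
  hbo <- matrix(rnorm(3 * n, sd = 0.1), n, 3,
                dimnames = list(NULL, c("CH01", "CH02", "CH03")))
  rec <- hemo_recording(hbo, -0.3 * hbo, 10)
  out1 <- preprocess_recording(rec)
  out2 <- preprocess_recording(rec)
  expect_identical(out1$recording$hbo, out2$recording$hbo)
  perm <- c("CH03", "CH01", "CH02")
  outp <- preprocess_recording(select_channels(rec, perm))
  expect_equal(outp$recording$hbo, out1$recording$hbo[, perm])
})
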