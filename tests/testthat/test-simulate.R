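test_that("uncoupled noise-free oscillators advance linearly", {
  osc <- tibble::tibble(id = c("a", "b"), frequency = 0.1, noise = 0)
  ph <- simulate_coupled_phases(osc, NULL, 100, 10, seed = 1)
  expect_equal(dim(ph), c(1001, 2))
  slopes <- diff(ph) * 10
  expect_lt(max(abs(slopes - 2 * pi * 0.1)), 1e-9)
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  osc <- tibble::tibble(id = c("a", "b"), frequency = c(0.1, 0.12),
                        noise = 0.05)
  cpl <- coupling_sin_diff("a", "b", 0.3)
  p1 <- simulate_coupled_phases(osc, cpl, 60, 10, seed = 7)
  p2 <- simulate_coupled_phases(osc, cpl, 60, 10, seed = 7)
  expect_identical(p1, p2)
})

test_that("sine-difference coupling phase-locks a noise-free pair", {
  # oracle: independent fine-step RK-free integration of the same ODE
  fine <- function(h, a, w, tmax, d0) {
    p <- c(0, d0); k <- 0
    while (k * h < tmax) {
      p[1] <- p[1] + h * (w + a * sin(p[2] - p[1]))
      p[2] <- p[2] + h * w
      k <- k + 1
    }
    p[2] - p[1]
  }
  d_or <- fine(1e-3, 0.5, 2 * pi * 0.1, 200, 2)
  osc <- tibble::tibble(id = c("a", "b"), frequency = 0.1, noise = 0)
  ph <- simulate_coupled_phases(osc, coupling_sin_diff("a", "b", 0.5),
                                200, 10, seed = 1,
                                initial_phase = c(0, 2))
  d_pkg <- ph[nrow(ph), 2] - ph[nrow(ph), 1]
  expect_lt(abs(d_pkg - d_or), 0.02)
  # locked: difference constant over the tail
  tail_d <- tail(ph[, 2] - ph[, 1], 100)
  expect_lt(diff(range(tail_d)), 1e-6)
})

test_that("integrator converges: halving the step moves phases < 1% cycle", {
  osc <- tibble::tibble(id = c("a", "b"), frequency = c(0.9, 1.1),
                        noise = 0)
  cpl <- coupling_sin_diff("a", "b", 0.4)
  p1 <- simulate_coupled_phases(osc, cpl, 60, 10, seed = 1)
  p2 <- simulate_coupled_phases(osc, cpl, 60, 20, seed = 1)
  expect_lt(max(abs(p1[61, ] - p2[121, ])), 0.01 * 2 * pi)
})

test_that("phase-locking order parameter grows with coupling/noise ratio", {
  op <- function(a) {
    osc <- tibble::tibble(id = c("a", "b"), frequency = 0.1, noise = 0.05)
    ph <- simulate_coupled_phases(osc, coupling_sin_diff("a", "b", a),
                                  600, 10, seed = 3)
    Mod(mean(exp(1i * (ph[, 1] - ph[, 2]))))
  }
  r <- vapply(c(0.05, 0.3, 1.5), op, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("phases_to_hemo builds the expected hemodynamics", {
  tt <- seq(0, 300, by = 0.1)
  ph <- matrix(2 * pi * 0.1 * tt, dimnames = list(NULL, "CH01"))
  # zero amplitude, zero noise -> constant baseline
  r0 <- phases_to_hemo(list(III = ph), c(III = 0), 10)
  expect_true(all(r0$hbo == 0))
  # interval-III tone dominates the periodogram inside 0.052-0.145 Hz
  r1 <- phases_to_hemo(list(III = ph), c(III = 1), 10)
  sp <- stats::spec.pgram(r1$hbo[, 1], plot = FALSE, taper = 0)
  fpk <- sp$freq[which.max(sp$spec)] * 10
  expect_gt(fpk, 0.052); expect_lt(fpk, 0.145)
  # anti-phase HHb is perfectly anticorrelated without noise
  expect_equal(cor(r1$hbo[, 1], r1$hhb[, 1]), -1)
  # frequency outside the declared band is rejected
  expect_error(phases_to_hemo(list(IV = ph), c(IV = 1), 10), "band 'IV'")
})

test_that("motion-artifact injection has exact bookkeeping", {
  rec <- tone_recording(duration = 600)
  out0 <- inject_motion_artifacts(rec, rate = 0, seed = 1)
  expect_identical(out0$recording$hbo, rec$hbo)
  expect_false(any(out0$mask))
  out <- inject_motion_artifacts(rec, rate = 6, seed = 2)
  # ~60 expected events of >= 2 samples; realised count within a wide
  # Poisson 99% band
  n_events <- sum(diff(c(FALSE, out$mask[, 1])) == 1)
  expect_gt(n_events, qpois(0.005, 60))
  expect_lt(n_events, qpois(0.995, 60))
  expect_true(any(out$recording$hbo != rec$hbo))
  out2 <- inject_motion_artifacts(rec, rate = 6, seed = 2)
  expect_identical(out$mask, out2$mask)
})

test_that("generate_study produces the declared design and truth table", {
  spec <- study_spec(n_per_group = 2, duration_s = 120, artifact_rate = 0,
                     seed = 5)
  st <- generate_study(spec)
  expect_equal(nrow(st$recordings), 2 * 3 * 3)
  expect_equal(sort(unique(st$recordings$group)),
               sort(c("control", "R-H", "L-H")))
  # truth reflects exactly the spec's coupling table
  tr <- st$truth
  expect_true(all(tr$group %in% c("R-H", "L-H")))
  expect_equal(sort(unique(tr$amplitude)), c(0.1, 0.4))
  expect_equal(unique(tr$source_region[tr$group == "R-H"]), "RMC")
  expect_equal(unique(tr$target_region[tr$group == "R-H"]), "RPFC")
  rec <- st$recordings$recording[[1]]
  expect_equal(nrow(rec$hbo), 1201)
  expect_equal(ncol(rec$hbo), 24)
})
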