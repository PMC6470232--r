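test_that("base-function sets have the canonical member counts", {
  b2 <- build_base_functions(2)
  expect_equal(nrow(b2$members), 25) # 1 + 12 classes x {sin, cos}
  b1 <- build_base_functions(1)
  expect_equal(nrow(b1$members), 9) # 1 + 4 classes x 2
  expect_error(build_base_functions(0), "K")
  # lattice oracle: half the non-origin points of [-K,K]^2, twice, plus 1
  for (K in 1:3) {
    n_lattice <- (2 * K + 1)^2 - 1
    expect_equal(nrow(build_base_functions(K)$members), n_lattice + 1)
  }
  # evaluation at (0, 0): constant and cosines 1, sines 0
  v <- eval_base_functions(b2, 0, 0)
  expect_equal(unname(v[1, b2$members$type == "const"]), 1)
  expect_true(all(v[1, b2$members$type == "cos"] == 1))
  expect_true(all(v[1, b2$members$type == "sin"] == 0))
})

test_that("flat-prior fixed-noise inference equals ordinary least squares", {
  set.seed(3)
  n <- 3000
  p1 <- cumsum(rnorm(n, 0.06, 0.01))
  p2 <- cumsum(rnorm(n, 0.05, 0.01))
  ydot <- cbind(diff(p1), diff(p2)) * 10
  m1 <- (p1[-1] + p1[-n]) / 2
  m2 <- (p2[-1] + p2[-n]) / 2
  for (K in 1:2) {
    base <- build_base_functions(K)
    fit <- infer_phase_dynamics(p1, p2, 10, base = base, noise_cov = 1e-10)
    B <- eval_base_functions(base, m1, m2)
    ols <- solve(crossprod(B), crossprod(B, ydot))
    expect_lt(max(abs(fit$coefficients[, , 1] - ols)) / max(abs(ols)),
              1e-6)
  }
})

test_that("noise-free constant-frequency phases give only a constant term", {
  w <- 2 * pi * 0.1
  tt <- seq(0, 600, by = 0.1)
  fit <- infer_phase_dynamics(w * tt, w * 1.13 * tt, 10)
  co <- fit$coefficients[, , 1]
  expect_equal(unname(co["const", 1]), w, tolerance = 1e-3 * w)
  expect_lt(max(abs(co[rownames(co) != "const", 1])), 1e-3 * w)
  expect_true(all(fit$windows$converged))
})

test_that("coupling strength is the Euclidean norm of source-dependent terms", {
  base <- build_base_functions(2)
  M <- nrow(base$members)
  mk_model <- function(fill) {
    co <- array(0, c(M, 2, 1), dimnames = list(base$members$term,
                                               c("eq1", "eq2"), NULL))
    co[, , 1] <- fill
    structure(list(coefficients = co, noise = array(diag(2), c(2, 2, 1)),
                   windows = tibble::tibble(window = 1, converged = TRUE),
                   base = base, h = 0.1), class = "coupling_model")
  }
  dep2 <- base$members$k2 != 0 # members that feel phi2
  fill <- matrix(0, M, 2)
  expect_equal(coupling_strength(mk_model(fill), "phi2", "phi1"), 0)
  fill[which(dep2)[1], 1] <- -7
  expect_equal(coupling_strength(mk_model(fill), "phi2", "phi1"), 7)
  fill[which(dep2)[2], 1] <- 4
  fill[which(dep2)[1], 1] <- 3
  expect_equal(coupling_strength(mk_model(fill), "phi2", "phi1"), 5)
})

test_that("direction index has the documented algebra", {
  expect_equal(direction_index(0.3, 0.3), 0)
  expect_equal(direction_index(0.3, 0), 1)
  expect_equal(direction_index(0.1, 0.3), -direction_index(0.3, 0.1))
  expect_warning(d <- direction_index(0, 0), "undefined")
  expect_true(is.na(d))
  expect_error(direction_index(-1, 0))
})

test_that("simulated unidirectional coupling is recovered with direction", {
  osc <- tibble::tibble(id = c("t", "s"), frequency = 0.1, noise = 0.05)
  cpl <- coupling_sin_diff("t", "s", 0.4)
  base <- build_base_functions(1)
  sel <- which(base$members$type == "sin" & base$members$k1 == 1 &
                 base$members$k2 == -1)
  res <- t(sapply(1:6, function(s) {
    ph <- simulate_coupled_phases(osc, cpl, 600, 10, seed = s)
    fit <- infer_phase_dynamics(ph[, 1], ph[, 2], 10, base = base)
    c(ct = fit$coefficients[sel, 1, 1],
      s21 = coupling_strength(fit, "phi2", "phi1"),
      s12 = coupling_strength(fit, "phi1", "phi2"))
  }))
  # the planted member is sin(phi_s - phi_t) = -sin(phi_t - phi_s)
  expect_lt(abs(mean(-res[, "ct"]) / 0.4 - 1), 0.2)
  expect_true(all(res[, "s21"] > res[, "s12"]))
})

test_that("recovered strength is monotone in the true coupling", {
  osc <- tibble::tibble(id = c("t", "s"), frequency = 0.1, noise = 0.05)
  base <- build_base_functions(1)
  sig <- vapply(c(0.1, 0.3, 0.6), function(a) {
    mean(vapply(1:4, function(s) {
      ph <- simulate_coupled_phases(osc, coupling_sin_diff("t", "s", a),
                                    600, 10, seed = 40 + s)
      coupling_strength(infer_phase_dynamics(ph[, 1], ph[, 2], 10,
                                             base = base),
                        "phi2", "phi1")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("inference is reproducible and guards its preconditions", {
  set.seed(8)
  p1 <- cumsum(rnorm(500, 0.06, 0.02))
  p2 <- cumsum(rnorm(500, 0.05, 0.02))
  f1 <- infer_phase_dynamics(p1, p2, 10)
  f2 <- infer_phase_dynamics(p1, p2, 10)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_error(infer_phase_dynamics(p1[1:100], p2[1:100], 10), "10 x")
  # constant phases make every trig member constant: degenerate design
  expect_error(infer_phase_dynamics(rep(1, 500), rep(2, 500), 10),
               "degenerate")
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(9)
  p1 <- cumsum(rnorm(600, 0.06, 0.02))
  p2 <- cumsum(rnorm(600, 0.05, 0.02))
  fit <- infer_phase_dynamics(p1, p2, 10)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 25)
  expect_setequal(unique(td$equation), c("phi1", "phi2"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_members, 25)
  expect_true(gl$converged)
})
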