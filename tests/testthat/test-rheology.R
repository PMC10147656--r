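# Generalized Stokes-Einstein pipeline: compliance, complex moduli,
# plateau modulus, trap calibration, NPAF and directional viscometry,
# near-wall drag predictions.

test_that("MSD-to-compliance applies the stated prefactors", {
  ctx <- water_ctx()
  m <- structure(list(tau = c(1, 2), values = c(1e-15, 1e-15),
                      n_pairs = c(10L, 10L), dimension = 3L,
                      context = ctx, dt = 1),
                 class = "msd_curve")
  J <- msd_to_compliance(m)
  expect_equal(J$J[1L], pi * 3e-6 * 1e-15 / kBT(ctx), tolerance = 1e-12)
  expect_equal(J$J[1L], 2.2896, tolerance = 1e-4)

  # d = 3 dimension correction coincides with the literal convention
  Jc <- msd_to_compliance(m, "dimension_corrected")
  expect_equal(Jc$J, J$J)

  m$values <- c(0, 0)
  expect_equal(max(msd_to_compliance(m)$J), 0)
})

test_that("the compliance Fourier transform matches closed-form modulus oracles", {
  G0 <- 5; eta <- 0.01
  elapsed <- system.time({
    mod_kv <- compliance_to_modulus(kv_compliance(G0, eta))
    mod_n <- compliance_to_modulus(newtonian_compliance(eta))
  })[["elapsed"]]
  expect_lt(elapsed, 1)

  mid <- mod_kv$omega >= 10 & mod_kv$omega <= 1e4
  expect_lt(max(abs(mod_kv$G_prime[mid] - G0) / G0), 0.05)
  expect_lt(max(abs(mod_kv$G_doubleprime[mid] - eta * mod_kv$omega[mid]) /
                  (eta * mod_kv$omega[mid])), 0.05)

  midn <- mod_n$omega >= 10 & mod_n$omega <= 1e4
  expect_lt(max(abs(mod_n$G_doubleprime[midn] - eta * mod_n$omega[midn]) /
                  (eta * mod_n$omega[midn])), 0.05)
  expect_lt(max(abs(mod_n$G_prime[midn])),
            0.05 * min(eta * mod_n$omega[midn]))

  # plateau ordering: elastic dominates at low frequency for the gel
  low <- mod_kv$omega <= 10
  expect_true(all(mod_kv$G_prime[low] > mod_kv$G_doubleprime[low]))

  expect_warning(compliance_to_modulus(kv_compliance(G0, eta),
                                       omega = c(1e-9, 1, 10)),
                 "trimmed")
})

test_that("plateau modulus follows the variance formula in both conventions", {
  ctx <- water_ctx()
  pm <- plateau_modulus(1e-15, ctx, dimension = 2L)
  expect_equal(pm$G0_prime, 0.4368, tolerance = 1e-3)
  pm2 <- plateau_modulus(2e-15, ctx, dimension = 2L)
  expect_equal(pm2$G0_prime, pm$G0_prime / 2)

  expect_error(plateau_modulus(-1, ctx), "positive")
  expect_error(plateau_modulus(0, ctx), "positive")
})

test_that("gel simulation round-trips the injected plateau modulus", {
  ctx <- water_ctx()
  G0 <- 5
  tr <- simulate_gel_bead(ctx, gel_params(G0, 0.01), 1 / 5000, 150000L,
                          seed = 101)
  v <- plateau_variance(tr)
  est <- plateau_modulus(v, ctx, "dimension_corrected")
  expect_equal(est$G0_prime, G0, tolerance = 0.15)
})

test_that("low-frequency G' from the full pipeline agrees with the variance route", {
  ctx <- water_ctx()
  tr <- simulate_gel_bead(ctx, gel_params(5, 0.01), 1 / 5000, 150000L,
                          seed = 103)
  m <- compute_msd(tr)
  J <- msd_to_compliance(m, "dimension_corrected", terminal = "plateau")
  mod <- compliance_to_modulus(J)
  g_low <- mod$G_prime[which.min(mod$omega)]
  direct <- plateau_modulus(plateau_variance(tr), ctx,
                            "dimension_corrected")$G0_prime
  expect_equal(g_low, direct, tolerance = 0.2)
})

test_that("proportional plateau change behaves as a relative difference", {
  expect_identical(delta_plateau(2, 1), 1)
  expect_identical(delta_plateau(0.5, 1), -0.5)
  expect_identical(delta_plateau(3.7, 3.7), 0)
})

test_that("equipartition recovers the instrument trap stiffnesses within 5%", {
  ctx <- water_ctx()
  for (kappa in c(3.2e-7, 6.7e-8)) {
    tr <- simulate_trapped_bead(ctx, trap_params(kappa), 1 / 300, 300000L,
                                seed = 107, axes = "x")
    expect_equal(trap_stiffness_equipartition(tr, "x"), kappa,
                 tolerance = 0.05)
  }
  tr <- simulate_trapped_bead(ctx, trap_params(3.2e-7), 1 / 300, 20000L,
                              seed = 109, axes = "x")
  half <- tr
  half$positions <- tr$positions / sqrt(2)  # doubled variance -> halved kappa
  expect_equal(trap_stiffness_equipartition(half, "x"),
               2 * trap_stiffness_equipartition(tr, "x"), tolerance = 1e-9)
})

test_that("the NPAF e^-1 intercept reads exact and simulated relative viscosities", {
  ctx <- water_ctx()
  kappa <- 3.2e-7
  # analytic NPAF exp(-tau*/2): eta_r = 2 exactly
  tau <- seq(0, 5, by = 0.05) * 6 * pi * ctx$radius_a *
    ctx$solvent_viscosity_eta_s / kappa
  ts <- kappa * tau / (6 * pi * ctx$radius_a * ctx$solvent_viscosity_eta_s)
  np <- structure(list(tau = tau, values = exp(-ts / 2), tau_star = NULL),
                  class = "npaf_curve")
  vr <- relative_viscosity_npaf(np, kappa, ctx)
  expect_equal(vr$eta_relative, 2, tolerance = 1e-9)

  # simulated water: unit relative viscosity
  tr <- simulate_trapped_bead(ctx, trap_params(kappa), 1 / 300, 100000L,
                              seed = 113, axes = "x")
  khat <- trap_stiffness_equipartition(tr, "x")
  npx <- compute_npaf(tr, "x", max_lag = 1, method = "fft")
  expect_equal(relative_viscosity_npaf(npx, khat, ctx)$eta_relative, 1,
               tolerance = 0.1)

  # doubled viscosity: eta_r = 2 within 10%
  tr2 <- simulate_trapped_bead(ctx, trap_params(kappa), 1 / 300, 100000L,
                               seed = 115, axes = "x",
                               eta = 2 * ctx$solvent_viscosity_eta_s)
  khat2 <- trap_stiffness_equipartition(tr2, "x")
  np2 <- compute_npaf(tr2, "x", max_lag = 2, method = "fft")
  expect_equal(relative_viscosity_npaf(np2, khat2, ctx)$eta_relative, 2,
               tolerance = 0.1)

  short <- compute_npaf(tr, "x", max_lag = 0.01)
  expect_error(relative_viscosity_npaf(short, khat, ctx), "longer")
})

test_that("directional viscometry recovers water and agrees with the NPAF route", {
  ctx <- water_ctx()
  trap <- trap_params(3.2e-7, 3.2e-7, 6.7e-8)
  tr <- simulate_trapped_bead(ctx, trap, 1 / 1000, 400000L, seed = 119)
  det <- detrend(tr)$trajectory
  dv <- mean(c(directional_viscosity(tr, pi / 2, 0)$eta_relative,
               directional_viscosity(tr, pi / 2, pi / 2)$eta_relative))
  expect_equal(dv, 1, tolerance = 0.1)

  # the two viscometry routes agree on the same Newtonian trajectory
  eta_npaf <- mean(vapply(c("x", "y"), function(ax) {
    khat <- trap_stiffness_equipartition(det, ax)
    np <- compute_npaf(det, ax, max_lag = 1, method = "fft")
    relative_viscosity_npaf(np, khat, ctx)$eta_relative
  }, numeric(1L)))
  expect_equal(dv, eta_npaf, tolerance = 0.1)

  # the x direction is the scalar early-lag pipeline on x, exactly
  dvx <- directional_viscosity(tr, pi / 2, 0)
  mx <- directional_msd(tr, pi / 2, 0, lag_scheme = "all",
                        max_lag_fraction = dvx$window_lags / length(tr$t))
  D_manual <- sum(mx$tau * mx$values) / sum(mx$tau^2) / 2
  expect_equal(dvx$D, D_manual, tolerance = 1e-6)

  expect_error(directional_viscosity(tr, pi / 2, 0,
                                     window_fraction = 1e-4), "window")
})

test_that("near-wall drag predictions evaluate the documented series", {
  ctx <- water_ctx()
  expect_equal(faxen_prediction(ctx, Inf, "parallel"), 1)
  expect_equal(faxen_prediction(ctx, Inf, "perpendicular"), 1)

  # a/h = 0.5: parallel factor from the truncated series
  s <- 0.5
  par_expected <- 1 / (1 - 9 / 16 * s + s^3 / 8 - 45 / 256 * s^4 - s^5 / 16)
  expect_equal(faxen_prediction(ctx, 6e-6, "parallel"), par_expected,
               tolerance = 1e-12)
  expect_equal(par_expected, 1.386, tolerance = 1e-3)

  hs <- 3e-6 / seq(0.05, 0.9, by = 0.05)
  par <- vapply(hs, faxen_prediction, numeric(1L), ctx = ctx,
                mode = "parallel")
  perp <- vapply(hs, faxen_prediction, numeric(1L), ctx = ctx,
                 mode = "perpendicular")
  expect_true(all(diff(par) > 0))   # factor grows toward the wall
  expect_true(all(diff(perp) > 0))
  expect_true(all(perp > par))

  expect_error(faxen_prediction(ctx, 2e-6), "exceed")
})

test_that("injected (kappa, eta) pairs are recovered across seeds", {
  ctx <- water_ctx()
  kappa <- 3.2e-7
  for (s in 1:5) {
    tr <- simulate_trapped_bead(ctx, trap_params(kappa), 1 / 300, 60000L,
                                seed = 200 + s, axes = "x")
    expect_equal(trap_stiffness_equipartition(tr, "x"), kappa,
                 tolerance = 0.1)
    np <- compute_npaf(tr, "x", max_lag = 1, method = "fft")
    expect_equal(relative_viscosity_npaf(
      np, trap_stiffness_equipartition(tr, "x"), ctx)$eta_relative, 1,
      tolerance = 0.15)
  }
})
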