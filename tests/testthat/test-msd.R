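# MSD, directional MSD, NPAF, plateau variance and the stretched
# bi-exponential smoothing fit.

test_that("MSD of free diffusion is Fickian and of a constant series is zero", {
  ctx <- water_ctx()
  D <- diffusion_coefficient(ctx)
  tr <- simulate_free_diffusion(ctx, 0.01, 30000L, seed = 61)
  m <- compute_msd(tr, "x", lag_scheme = "all", max_lag_fraction = 3e-4)
  slope <- sum(m$tau * m$values) / sum(m$tau^2)
  expect_equal(slope / 2, D, tolerance = 0.1)
  expect_true(all(m$values >= 0))
  expect_true(all(diff(m$tau) > 0))

  const <- make_traj(cbind(x = rep(1e-7, 200L)))
  expect_equal(max(compute_msd(const)$values), 0)

  expect_error(compute_msd(tr, "z"), "absent")
})

test_that("trapped-bead MSD matches the OU closed form on the log lag grid", {
  ctx <- water_ctx()
  kappa <- 3.2e-7
  tr <- simulate_trapped_bead(ctx, trap_params(kappa), 1 / 300, 150000L,
                              seed = 67, axes = "x")
  m <- compute_msd(tr, "x")
  v <- kBT(ctx) / kappa
  tau_c <- stokes_drag(ctx) / kappa
  oracle <- 2 * v * (1 - exp(-m$tau / tau_c))
  expect_lt(max(abs(m$values - oracle) / oracle), 0.1)
})

test_that("directional MSD reduces to per-axis MSD and sees isotropy", {
  ctx <- water_ctx()
  tr <- simulate_free_diffusion(ctx, 0.01, 20000L, n_axes = 3L, seed = 71)
  mx <- compute_msd(tr, "x")
  md <- directional_msd(tr, pi / 2, 0)   # unit vector = +x
  expect_identical(md$values, mx$values)

  # isotropy: slope agrees across a 26-direction grid
  dirs <- expand.grid(theta = c(pi / 6, pi / 3, pi / 2, 2 * pi / 3),
                      phi = seq(0, 2 * pi, length.out = 7L)[-7L])
  slopes <- vapply(seq_len(nrow(dirs)), function(i) {
    m <- directional_msd(tr, dirs$theta[i], dirs$phi[i],
                         lag_scheme = "all", max_lag_fraction = 5e-4)
    sum(m$tau * m$values) / sum(m$tau^2)
  }, numeric(1L))
  expect_lt((max(slopes) - min(slopes)) / mean(slopes), 0.35)
  expect_lt(stats::sd(slopes) / mean(slopes), 0.1)
})

test_that("near-wall anisotropy shows up in directional MSD slopes", {
  ctx <- water_ctx()
  tr <- simulate_near_wall(ctx, trap_params(3.2e-7, 3.2e-7, 3.2e-7),
                           wall_model(4.5e-6), 1 / 1000, 60000L, seed = 73)
  slope_of <- function(theta, phi) {
    m <- directional_msd(tr, theta, phi, lag_scheme = "all",
                         max_lag_fraction = 2e-4)
    sum(m$tau * m$values) / sum(m$tau^2)
  }
  expect_lt(slope_of(0, 0), slope_of(pi / 2, 0))  # perpendicular slower
})

test_that("stretched bi-exponential fit recovers identifiable parameters", {
  # rising, saturating MSD: negative A1 against a quasi-constant A2 term
  true <- list(A1 = -4e-17, A2 = 5e-17, B1 = 1, B2 = 1,
               tau1 = 0.05, tau2 = 1e9)
  tau <- 10^seq(-3, 1, by = 1 / 16)
  y <- true$A1 * exp(-(tau / true$tau1)^true$B1) +
    true$A2 * exp(-(tau / true$tau2)^true$B2)
  set.seed(77)
  noisy <- y * (1 + 0.01 * stats::rnorm(length(y)))
  m <- structure(list(tau = tau, values = noisy,
                      n_pairs = round(1e5 / seq_along(tau)),
                      dimension = 1L, context = water_ctx(), dt = 1e-3),
                 class = "msd_curve")
  fit <- fit_stretched_biexponential(m)
  cf <- coef(fit)
  expect_equal(unname(cf["A1"]), true$A1, tolerance = 0.1)
  expect_equal(unname(cf["A2"]), true$A2, tolerance = 0.1)
  expect_equal(unname(cf["tau1"]), true$tau1, tolerance = 0.1)
  expect_equal(unname(cf["B1"]), true$B1, tolerance = 0.1)
  expect_lt(max(abs(predict(fit) - y) / y), 0.05)
})

test_that("nested single-exponential data yield a unit stretching exponent", {
  tau <- 10^seq(-3, 1, by = 1 / 16)
  y <- 5e-17 * exp(-tau / 0.05)
  m <- structure(list(tau = tau, values = y,
                      n_pairs = round(1e5 / seq_along(tau)),
                      dimension = 1L, context = water_ctx(), dt = 1e-3),
                 class = "msd_curve")
  fit <- fit_stretched_biexponential(m, init = list(A1 = 5e-17, A2 = 0,
                                                    tau1 = 0.1))
  expect_equal(unname(coef(fit)["B1"]), 1, tolerance = 0.05)
})

test_that("the smoothed fit reproduces the OU closed form within 2%", {
  ctx <- water_ctx()
  kappa <- 3.2e-7
  v <- kBT(ctx) / kappa
  tau_c <- stokes_drag(ctx) / kappa
  tau <- 10^seq(log10(1 / 300), 1, by = 1 / 16)
  y <- 2 * v * (1 - exp(-tau / tau_c))
  m <- structure(list(tau = tau, values = y,
                      n_pairs = round(3e5 / seq_along(tau)),
                      dimension = 1L, context = ctx, dt = 1 / 300),
                 class = "msd_curve")
  fit <- fit_stretched_biexponential(m)
  expect_lt(max(abs(predict(fit) - y) / y), 0.02)
})

test_that("the NPAF is normalized, decays as the OU oracle and vanishes for white noise", {
  ctx <- water_ctx()
  kappa <- 3.2e-7
  tau_c <- stokes_drag(ctx) / kappa
  tr <- simulate_trapped_bead(ctx, trap_params(kappa), 1 / 300, 150000L,
                              seed = 83, axes = "x")
  np <- compute_npaf(tr, "x", max_lag = 3 * tau_c)
  expect_identical(np$values[1L], 1)
  oracle <- exp(-np$tau / tau_c)
  expect_lt(max(abs(np$values - oracle)[oracle > 0.1]), 0.05)
  expect_true(all(np$values <= 1 + 1e-9))

  set.seed(87)
  white <- make_traj(cbind(x = stats::rnorm(20000L, 0, 1e-8)))
  npw <- compute_npaf(white, "x", max_lag_fraction = 0.01)
  expect_lt(max(abs(npw$values[-1L])), 0.05)

  const <- make_traj(cbind(x = rep(1e-7, 200L)))
  expect_error(compute_npaf(const, "x"), "zero variance")
})

test_that("FFT and direct NPAF estimators agree to numerical precision", {
  ctx <- water_ctx()
  tr <- simulate_trapped_bead(ctx, trap_params(3.2e-7), 1 / 300, 20000L,
                              seed = 89, axes = "x")
  a <- compute_npaf(tr, "x", max_lag_fraction = 0.01, method = "direct")
  b <- compute_npaf(tr, "x", max_lag_fraction = 0.01, method = "fft")
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("plateau variance is additive across axes and scales quadratically", {
  set.seed(91)
  pos <- cbind(x = stats::rnorm(5000L, 0, 1e-8),
               y = stats::rnorm(5000L, 0, 2e-8))
  tr <- make_traj(pos)
  vx <- as.numeric(plateau_variance(tr, "x"))
  vy <- as.numeric(plateau_variance(tr, "y"))
  both <- plateau_variance(tr)
  expect_equal(as.numeric(both), vx + vy)
  expect_identical(attr(both, "dimension"), 2L)

  dbl <- make_traj(2 * pos)
  expect_equal(as.numeric(plateau_variance(dbl)), 4 * (vx + vy))

  short <- make_traj(pos[1:50, , drop = FALSE])
  expect_warning(plateau_variance(short), "fewer than 100")
})
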