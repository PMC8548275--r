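# Steady-state two-phase model: trivial cases, qualitative flux geometry,
# exact discrete identities, convergence, a dense brute-force oracle, and
# parameter fitting.

test_that("zero uptake gives the zero solution", {
  p <- model_params(10, 1, 6e5, rhoV = 5e4,
                    grid = seq(0, 1, length.out = 41))
  sol <- solve_steady_state(rep(0, 41), p)
  expect_within(sol$Qr, 0, 1e-10)
  expect_within(sol$Qc, 0, 1e-10)
  expect_within(sol$Pc, 0, 1e-10)
  expect_within(sol$Pr, 0, 1e-10)
})

test_that("the default uptake yields the reported flux geometry", {
  w <- default_world()
  sol <- w$truth$profile
  # Qr rises, peaks, falls: exactly one interior maximum, non-negative
  d <- diff(sol$Qr)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  expect_true(all(sol$Qr > -1e-9))
  # J changes sign exactly at the Qr peak (same-solution identity)
  expect_equal(j_zero_x(sol), qr_peak_x(sol), tolerance = 1e-12)
  # J positive distally, negative proximally
  expect_gt(mean(sol$J[sol$x < 0.4]), 0)
  expect_lt(mean(sol$J[sol$x > 0.8]), 0)
  # the pressure difference inverts near (within 0.075 of) the uptake zero;
  # in this closure the small offset falls on the distal side (see the
  # methods vignette)
  sol$D <- sol$Pc - sol$Pr
  expect_within(zero_crossing_x(sol, "D"), w$cfg$transition_x, 0.075)
})

test_that("discrete conservation holds to near machine precision", {
  w <- default_world()
  sol <- w$truth$profile
  res <- attr(sol, "residuals")
  scale <- max(abs(sol$Qr))
  expect_lt(res["rachis"] / scale, 1e-8)
  expect_lt(res["total"] / scale, 1e-8)
})

test_that("grid refinement converges at second order", {
  cfg <- synthetic_config()
  S <- function(x) uptake_profile(cfg, x)
  rho <- function(x) cfg$cells_per_gonad * mean_volume(cfg, x)
  qr_at <- function(n) {
    g <- seq(0, 1, length.out = n)
    sol <- solve_steady_state(S(g), model_params(10, 1, 6e5, rho(g), g))
    approx(sol$x, sol$Qr, xout = c(0.3, 0.5, 0.7))$y
  }
  ref <- qr_at(1601)
  e1 <- max(abs(qr_at(101) - ref))
  e2 <- max(abs(qr_at(201) - ref))
  # halving h reduces the error by ~4; allow slack for the boundary cells
  expect_gt(e1 / e2, 3)
})

test_that("solution matches a dense brute-force assembly on a 10-point grid", {
  # independent re-assembly of the same staggered discretization, written
  # directly from the balance statements
  n <- 10
  g <- seq(0, 1, length.out = n)
  h <- g[2] - g[1]
  alpha <- 3; kap <- 0.7; gam <- 1e4
  rho <- 2e4 + 1e4 * g
  Sv <- sin(pi * g / 0.6) * (g <= 0.6) * 100 - 50 * (g > 0.6)
  params <- model_params(alpha, kap, gam, rho, g)
  sol <- solve_steady_state(Sv, params)

  beta_f <- (rho[-1] + rho[-n]) / 2 / gam
  w <- rep(h, n); w[c(1, n)] <- h / 2
  A <- matrix(0, 2 * n, 2 * n); b <- numeric(2 * n)
  # build by perturbation (finite differencing the linear forms)
  rowfun <- function(u) {
    out <- numeric(2 * n)
    for (i in 1:n) {
      J <- alpha * (u[i] - u[n + i])
      qrp <- if (i < n) -kap * (u[n + i + 1] - u[n + i]) / h else 0
      qrm <- if (i > 1) -kap * (u[n + i] - u[n + i - 1]) / h else 0
      out[i] <- qrp - qrm - w[i] * J
    }
    for (i in 1:(n - 1)) {
      J <- alpha * (u[i] - u[n + i])
      qcp <- -beta_f[i] * (u[i + 1] - u[i]) / h
      qcm <- if (i > 1) -beta_f[i - 1] * (u[i] - u[i - 1]) / h else 0
      out[n + i] <- qcp - qcm + w[i] * J
    }
    out[2 * n] <- u[2 * n]
    out
  }
  for (j in 1:(2 * n)) {
    e <- numeric(2 * n); e[j] <- 1
    A[, j] <- rowfun(e)
  }
  b[(n + 1):(2 * n - 1)] <- w[1:(n - 1)] * Sv[1:(n - 1)]
  u <- solve(A, b)
  expect_equal(sol$Pc, u[1:n], tolerance = 1e-9)
  expect_equal(sol$Pr, u[(n + 1):(2 * n)], tolerance = 1e-9)
})

test_that("singular parameters raise a parameter error", {
  expect_error(model_params(0, 1, 1, 1e4), "alpha")
  expect_error(model_params(1, -1, 1, 1e4), "kappa_r")
  expect_error(model_params(1, 1, 1, c(1, -2, 3)), "rhoV")
})

test_that("fit recovers self-generated parameters and flags degeneracy", {
  w <- default_world()
  truth <- w$truth$params
  obs <- w$truth$profile[, c("x", "Qr")]
  init <- model_params(truth$alpha * 2.5, truth$kappa_r / 3, truth$gamma_c,
                       truth$rhoV, truth$grid)
  fit <- fit_parameters(obs, w$truth$profile$S, init, n_starts = 6, seed = 3)
  expect_lt(abs(log(fit$alpha / truth$alpha)), log(1.1))
  expect_lt(abs(log(fit$kappa_r / truth$kappa_r)), log(1.1))
  expect_lt(abs(log(fit$gamma_c / truth$gamma_c)), log(1.1))
  expect_lt(attr(fit, "residual"), 1e-6 * max(abs(obs$Qr)))
  # zero observation with zero uptake: any parameters fit; flagged
  g <- truth$grid
  fit0 <- fit_parameters(axial_profile(g, Qr = rep(0, length(g))),
                         rep(0, length(g)), truth, n_starts = 2, seed = 1)
  expect_true(attr(fit0, "degenerate"))
})

test_that("predict_J reproduces the sign structure and integral constraint", {
  w <- default_world()
  params <- w$truth$params
  # S == 0 -> J == 0
  p0 <- predict_J(params, rep(0, length(params$grid)))
  expect_within(p0$J, 0, 1e-10)
  # default S: single sign change, positive distal, negative proximal
  pj <- predict_J(params, uptake_profile(w$cfg, params$grid))
  sgn <- sign(pj$J[abs(pj$J) > 1e-9])
  expect_equal(sum(diff(sgn) != 0), 1)
  # integral of J vanishes (Qr closed at both ends)
  expect_lt(abs(trapz(pj$x, pj$J)) / max(abs(pj$Qr)), 0.02)
  # re-use on a different grid (apoptosis-deficient re-analysis path)
  g2 <- seq(0.16, 1, length.out = 85)
  pj2 <- predict_J(params, uptake_profile(w$cfg, g2), grid = g2)
  expect_equal(nrow(pj2), 85)
  expect_gt(mean(pj2$J[pj2$x < 0.4]), 0)
})
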