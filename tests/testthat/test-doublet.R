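# Doublet (two-balloon) model: the three-term equation, effective
# potential, linear stability, trajectories, fixed points, bifurcation.

base_params <- function(S = 2, Pc_minus_Pr = 3, Tension = 40,
                        alpha0 = 0.5, A_c = 100, R = 10, p = 2 / 3)
  doublet_params(S = S, A_c = A_c, alpha0 = alpha0,
                 Pc_minus_Pr = Pc_minus_Pr, Tension = Tension, R = R, p = p)

test_that("lambda_basal has the stated symmetry, endpoints and slope", {
  expect_equal(lambda_basal(0), 0)
  expect_equal(lambda_basal(1), 1)
  expect_equal(lambda_basal(-1), -1)
  nu <- seq(-0.9, 0.9, 0.1)
  expect_equal(lambda_basal(nu), -lambda_basal(-nu))
  # slope p at the origin, for several exponents
  for (p in c(2 / 3, 0.5, 1)) {
    num <- (lambda_basal(1e-6, p) - lambda_basal(-1e-6, p)) / 2e-6
    expect_equal(num, p, tolerance = 1e-6)
  }
})

test_that("delta_P is the linear two-balloon law", {
  p <- base_params(Tension = 1, R = 10)
  expect_equal(delta_P(0, p), 0)
  expect_equal(delta_P(0.5, p), 0.05)
  nu <- seq(-1, 1, 0.25)
  expect_equal(delta_P(nu, p), -delta_P(-nu, p))
})

test_that("dnu_dt is the printed three-term sum with the stated signs", {
  # symmetric state is always a fixed point
  for (i in 1:5)
    expect_equal(dnu_dt(0, base_params(S = i, Pc_minus_Pr = i - 3,
                                       Tension = 10 * i)), 0)
  # only the destabilizing tension term survives: positive at nu = 0.1
  p_t <- base_params(S = 0, Pc_minus_Pr = 0, Tension = 40)
  expect_gt(dnu_dt(0.1, p_t), 0)
  # term-by-term oracle at nu = 0.1
  nu <- 0.1
  expect_equal(dnu_dt(nu, p_t),
               p_t$alpha0 * (p_t$Tension * nu / p_t$R) / (8 * p_t$A_c) *
                 (1 + 6 * nu^2 + nu^4))
  # strong uptake with no tension is restoring: sign(dnu/dt) = -sign(nu)
  p_s <- base_params(S = 50, Pc_minus_Pr = 0, Tension = 0)
  for (nu in c(-0.8, -0.3, 0.3, 0.8))
    expect_equal(sign(dnu_dt(nu, p_s)), -sign(nu))
  # oddness in nu (trajectory symmetry follows)
  p_g <- base_params()
  nu <- seq(-1, 1, 0.05)
  expect_equal(dnu_dt(nu, p_g), -dnu_dt(-nu, p_g), tolerance = 1e-12)
  expect_error(dnu_dt(1.2, p_g), "exceed")
})

test_that("effective potential is even, reconstructs the flow, and sorts regimes", {
  p_stab <- base_params(S = 50, Pc_minus_Pr = 3)
  W_s <- effective_potential(p_stab)
  expect_equal(W_s$nu[which.min(W_s$W)], 0)
  expect_equal(W_s$W, rev(W_s$W), tolerance = 1e-7)
  expect_equal(max(abs(W_s$W_norm)), 1)

  p_un <- base_params(S = 0, Pc_minus_Pr = -3)
  W_u <- effective_potential(p_un)
  expect_equal(abs(W_u$nu[which.min(W_u$W)]), 1)     # minima at +-1
  i0 <- which(W_u$nu == 0)
  expect_gt(W_u$W[i0], min(W_u$W))                   # nu = 0 is a maximum
  expect_true(all(W_u$W[i0] >= W_u$W - 1e-12))
  # -dW/dnu reconstructs dnu/dt to 1e-6 (central differences)
  grid <- seq(-0.95, 0.95, length.out = 381)
  W <- effective_potential(base_params(), grid)
  h <- grid[2] - grid[1]
  dW <- (W$W[-(1:2)] - W$W[1:(length(grid) - 2)]) / (2 * h)
  inner <- grid[-c(1, length(grid))]
  expect_within(-dW - dnu_dt(inner, base_params()), 0, 1e-6 + h^2)
})

test_that("analytic growth rate matches the numerical derivative", {
  set.seed(13)
  for (i in 1:10) {
    p <- base_params(S = runif(1, -5, 20), Pc_minus_Pr = runif(1, -10, 10),
                     Tension = runif(1, 0, 100), alpha0 = runif(1, 0.1, 2))
    num <- (dnu_dt(1e-5, p) - dnu_dt(-1e-5, p)) / 2e-5
    expect_equal(linear_growth_rate(p), num,
                 tolerance = 1e-8 * max(1, abs(num)) + 1e-10)
  }
  # stabilizing terms only -> sigma < 0; tension only -> sigma > 0
  expect_lt(linear_growth_rate(base_params(S = 5, Pc_minus_Pr = 3,
                                           Tension = 0)), 0)
  expect_gt(linear_growth_rate(base_params(S = 0, Pc_minus_Pr = 0,
                                           Tension = 40)), 0)
})

test_that("trajectories respect fixed points, absorption and symmetry", {
  p_un <- base_params(S = 0, Pc_minus_Pr = -3)
  # exact fixed point stays
  tr0 <- integrate_doublet(0, p_un, c(0, 100))
  expect_equal(max(abs(tr0$nu)), 0)
  # tiny perturbations coarsen to the matching boundary
  up <- integrate_doublet(1e-3, p_un, c(0, 1e4))
  dn <- integrate_doublet(-1e-3, p_un, c(0, 1e4))
  expect_true(attr(up, "coarsened")); expect_equal(attr(up, "end_state"), 1)
  expect_true(attr(dn, "coarsened")); expect_equal(attr(dn, "end_state"), -1)
  # symmetry nu(t; nu0) = -nu(t; -nu0)
  expect_equal(up$nu, -dn$nu, tolerance = 1e-6)
  # stable regime: monotone decay to 0 (Lyapunov property of W)
  p_st <- base_params(S = 50, Pc_minus_Pr = 3)
  tr_s <- integrate_doublet(0.2, p_st, c(0, 1e4))
  expect_false(attr(tr_s, "coarsened"))
  expect_lt(abs(attr(tr_s, "end_state")), 1e-6)
  expect_true(all(diff(tr_s$nu) <= 1e-6))
})

test_that("bracketing fixed points match a brute-force fine scan", {
  set.seed(99)
  for (i in 1:20) {
    p <- base_params(S = runif(1, -2, 8), Pc_minus_Pr = runif(1, -6, 6),
                     Tension = runif(1, 0, 80), alpha0 = runif(1, 0.1, 1.5))
    fp <- doublet_fixed_points(p)
    interior <- fp$nu[!fp$boundary]
    # oracle: sign changes on a 1e-4 grid
    g <- seq(-1 + 1e-4, 1 - 1e-4, by = 1e-4)
    f <- dnu_dt(g, p)
    sc <- which(f[-length(f)] * f[-1] < 0)
    oracle <- (g[sc] + g[sc + 1]) / 2
    oracle <- c(oracle, g[f == 0])
    expect_equal(length(interior), length(oracle))
    if (length(oracle))
      expect_within(sort(interior), sort(oracle), 1e-3)
  }
})

test_that("the bifurcation along the gonad matches the linear stability", {
  w <- default_world()
  sol <- w$truth$profile
  tmpl <- default_doublet_template(sol, w$cfg)
  bif <- bifurcation_along_gonad(sol, tmpl, stations = seq(1, 101, by = 2))
  # distal: single stable interior point at nu = 0
  distal <- bif$branches[bif$branches$x == 0.2, ]
  expect_true(any(distal$nu == 0 & distal$stable & !distal$boundary))
  expect_equal(sum(!distal$boundary), 1)
  # proximal: nu = 0 unstable, boundaries absorb
  prox <- bif$branches[bif$branches$x == 0.9, ]
  expect_false(prox$stable[prox$nu == 0])
  expect_true(all(c(-1, 1) %in% prox$nu[prox$stable]))
  # bifurcation point agrees with the sigma zero crossing
  sig <- bif$sigma
  sgn_flip <- sig$x[which(sig$sigma[-nrow(sig)] < 0 & sig$sigma[-1] >= 0)[1]]
  expect_within(bif$x_bifurcation, sgn_flip, 0.05)
  # and lies in the transition neighbourhood of the planted world
  expect_within(bif$x_bifurcation, w$cfg$transition_x, 0.1)
})
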