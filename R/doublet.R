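# Two-balloon (doublet) instability model: dynamics of the relative volume
# difference nu = (V2 - V1)/(V1 + V2) of two pressure-coupled germ cells
# sharing a rachis. Three contributions drive d(nu)/dt: material uptake
# proportional to basal surface area (stabilizing for S > 0), the mean
# cell-rachis pressure difference (stabilizing when Pc > Pr), and the
# Laplace-like pressure difference between the two cells (~ T nu / R,
# destabilizing: the larger cell has the lower pressure and inflates).

#' Doublet model parameters
#'
#' @param S material uptake shared by the doublet (fl/min).
#' @param A_c combined cross-sectional area of the two cells (um^2).
#' @param alpha0 hydraulic conductivity of the rachis bridges
#'   (fl/min per pressure unit).
#' @param Pc_minus_Pr mean cell-rachis pressure difference (pressure units).
#' @param Tension effective cortical tension T (pressure x um).
#' @param R gonad radius (um).
#' @param p basal-area exponent: area ~ V^p (default 2/3, sphere-like).
#' @return a `doublet_params` list.
#' @export
doublet_params <- function(S, A_c, alpha0, Pc_minus_Pr, Tension, R,
                           p = 2 / 3) {
  check_number(A_c, "A_c", lower = 0, strict_lower = TRUE)
  check_number(alpha0, "alpha0", lower = 0)
  check_number(R, "R", lower = 0, strict_lower = TRUE)
  structure(list(S = S, A_c = A_c, alpha0 = alpha0,
                 Pc_minus_Pr = Pc_minus_Pr, Tension = Tension, R = R, p = p),
            class = "doublet_params")
}

#' Relative basal-area difference of the doublet
#'
#' lambda(nu) = ((1+nu)^p - (1-nu)^p) / ((1+nu)^p + (1-nu)^p), the relative
#' difference in basal surface area when area scales as volume^p.
#'
#' @param nu relative volume difference in \[-1, 1\] (vectorized).
#' @param p area exponent (default 2/3).
#' @return lambda in \[-1, 1\]; odd in nu, slope p at nu = 0.
#' @export
lambda_basal <- function(nu, p = 2 / 3) {
  a <- (1 + nu)^p
  b <- (1 - nu)^p
  (a - b) / (a + b)
}

#' Pressure difference between the two cells
#'
#' Linearized two-balloon law Delta P = T nu / R: the larger cell (nu > 0
#' means cell 2 larger, Delta P = P1 - P2 > 0) has the lower pressure.
#'
#' @param nu relative volume difference.
#' @param params [doublet_params].
#' @return pressure difference (pressure units).
#' @export
delta_P <- function(nu, params) params$Tension * nu / params$R

#' Rate of change of the relative volume difference
#'
#' The three-term doublet equation:
#' d(nu)/dt = -S/Ac (lambda(nu) + nu)
#'            - alpha0 (Pc - Pr)/(2 Ac) nu (1 - nu)(1 + nu)
#'            + alpha0 DeltaP(nu)/(8 Ac) (1 + 6 nu^2 + nu^4).
#'
#' @param nu relative volume difference in \[-1, 1\] (vectorized).
#' @param params [doublet_params].
#' @return d(nu)/dt in 1/min.
#' @export
dnu_dt <- function(nu, params) {
  if (any(abs(nu) > 1 + 1e-12))
    stop("|nu| must not exceed 1", call. = FALSE)
  nu <- pmin(pmax(nu, -1), 1)
  with(params,
       -S / A_c * (lambda_basal(nu, p) + nu) -
         alpha0 * Pc_minus_Pr / (2 * A_c) * nu * (1 - nu) * (1 + nu) +
         alpha0 * delta_P(nu, params) / (8 * A_c) *
           (1 + 6 * nu^2 + nu^4))
}

#' Effective potential of the doublet dynamics
#'
#' W(nu) = -int_0^nu d(nu')/dt d(nu'), so that d(nu)/dt = -dW/d(nu). Minima
#' of W are stable volume configurations: a single minimum at nu = 0 in the
#' stabilized regime, two minima at nu = +/-1 (complete asymmetry) in the
#' destabilized regime. Integration is adaptive per grid interval. The
#' `W_norm` column is the shape-normalized potential
#' (W - W(0)) / max|W - W(0)| used for plotting (W(0) = 0 by construction,
#' so this only rescales).
#'
#' @param params [doublet_params].
#' @param nu_grid grid over \[-1, 1\] (default 201 points).
#' @return data frame with `nu`, `W`, `W_norm`.
#' @export
effective_potential <- function(params,
                                nu_grid = seq(-1, 1, length.out = 201)) {
  f <- function(nu) dnu_dt(nu, params)
  n <- length(nu_grid)
  i0 <- which.min(abs(nu_grid))
  inc <- numeric(n)
  for (i in seq_len(n - 1))
    inc[i + 1] <- integrate(f, nu_grid[i], nu_grid[i + 1],
                            rel.tol = 1e-9, abs.tol = 1e-12)$value
  Wcum <- cumsum(inc)
  W <- -(Wcum - Wcum[i0])
  # anchor exactly at nu = 0 if it is not a grid point
  if (abs(nu_grid[i0]) > 1e-12)
    W <- W - (-integrate(f, nu_grid[i0], 0, rel.tol = 1e-9)$value)
  scale <- max(abs(W))
  data.frame(nu = nu_grid, W = W,
             W_norm = if (scale > 0) W / scale else W)
}

#' Linear growth rate of the symmetric state
#'
#' Analytic derivative of the doublet equation at nu = 0:
#' sigma = (alpha0 T / (8 R) - S (1 + p) - alpha0 (Pc - Pr) / 2) / A_c.
#' sigma < 0: the symmetric state is stable (homogeneous growth);
#' sigma > 0: unstable (volume differences amplify).
#'
#' @param params [doublet_params].
#' @return growth rate sigma in 1/min.
#' @export
linear_growth_rate <- function(params) {
  with(params,
       (alpha0 * Tension / (8 * R) - S * (1 + p) -
          alpha0 * Pc_minus_Pr / 2) / A_c)
}

#' Integrate the doublet dynamics
#'
#' Adaptive Cash-Karp Runge-Kutta integration of d(nu)/dt with absorbing
#' boundaries at nu = +/-1: when the trajectory reaches a boundary (the
#' small cell has lost its cytoplasm) integration stops and the outcome is
#' flagged `coarsened`.
#'
#' @param nu0 initial relative volume difference in \[-1, 1\].
#' @param params [doublet_params].
#' @param t_span c(t0, t1) in minutes.
#' @param dt_init initial step (min).
#' @param tol local error tolerance.
#' @param max_steps safety cap.
#' @return data frame with columns `t`, `nu`; attributes `coarsened`
#'   (logical) and `end_state`.
#' @export
integrate_doublet <- function(nu0, params, t_span, dt_init = 0.1,
                              tol = 1e-8, max_steps = 1e5) {
  check_number(nu0, "nu0", lower = -1, upper = 1)
  f <- function(nu) dnu_dt(pmin(pmax(nu, -1), 1), params)
  t <- t_span[1]; nu <- nu0; h <- dt_init
  ts <- t; nus <- nu
  coarsened <- abs(nu0) >= 1
  # Cash-Karp embedded RK4(5) tableau
  a <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(3 / 10, -9 / 10, 6 / 5),
            c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
            c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592,
              253 / 4096))
  b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)
  steps <- 0
  while (t < t_span[2] && !coarsened && steps < max_steps) {
    steps <- steps + 1
    h <- min(h, t_span[2] - t)
    k <- numeric(6)
    k[1] <- f(nu)
    for (i in 1:5) k[i + 1] <- f(nu + h * sum(a[[i]] * k[1:i]))
    nu5 <- nu + h * sum(b5 * k)
    nu4 <- nu + h * sum(b4 * k)
    err <- abs(nu5 - nu4)
    if (err <= tol || h <= 1e-10) {
      t <- t + h
      nu <- nu5
      if (nu >= 1 || nu <= -1) {
        nu <- sign(nu)
        coarsened <- TRUE
      }
      ts <- c(ts, t); nus <- c(nus, nu)
      if (err > 0) h <- h * min(2, 0.9 * (tol / err)^0.2)
      else h <- h * 2
    } else {
      h <- h * max(0.1, 0.9 * (tol / err)^0.25)
    }
  }
  out <- data.frame(t = ts, nu = nus)
  attr(out, "coarsened") <- coarsened
  attr(out, "end_state") <- nus[length(nus)]
  out
}

#' Seeded initial perturbation of the symmetric state
#' @param seed integer seed.
#' @param sd perturbation scale (default 1e-3).
#' @return a small nu0.
#' @export
perturb_nu0 <- function(seed = 1L, sd = 1e-3) {
  with_preserved_seed(derive_seed(seed, "perturb"), rnorm(1, 0, sd))
}

#' Fixed points and stability of the doublet at given parameters
#'
#' Interior fixed points are located by a sign-change scan of d(nu)/dt on a
#' fine grid followed by bisection (uniroot); stability from the sign of the
#' numerical derivative. The absorbing boundaries nu = +/-1 are classified
#' as stable end states when the flow points into them.
#'
#' @param params [doublet_params].
#' @param dnu scan resolution (default 1e-3).
#' @return data frame with `nu`, `stable` (logical), `boundary` (logical).
#' @export
doublet_fixed_points <- function(params, dnu = 1e-3) {
  grid <- seq(-1, 1, by = dnu)
  fv <- dnu_dt(grid, params)
  roots <- c()
  for (i in seq_len(length(grid) - 1)) {
    if (is.na(fv[i]) || is.na(fv[i + 1])) next
    if (fv[i] == 0 && grid[i] > -1 + dnu / 2) roots <- c(roots, grid[i])
    else if (fv[i] * fv[i + 1] < 0)
      roots <- c(roots, stats::uniroot(function(z) dnu_dt(z, params),
                                       c(grid[i], grid[i + 1]),
                                       tol = 1e-12)$root)
  }
  roots <- unique(round(roots, 9))
  eps <- 1e-6
  out <- data.frame(nu = numeric(), stable = logical(), boundary = logical())
  for (r in roots) {
    d <- (dnu_dt(min(r + eps, 1), params) -
            dnu_dt(max(r - eps, -1), params)) / (2 * eps)
    out <- rbind(out, data.frame(nu = r, stable = d < 0, boundary = FALSE))
  }
  # absorbing boundaries
  if (dnu_dt(1 - eps, params) > 0)
    out <- rbind(out, data.frame(nu = 1, stable = TRUE, boundary = TRUE))
  if (dnu_dt(-1 + eps, params) < 0)
    out <- rbind(out, data.frame(nu = -1, stable = TRUE, boundary = TRUE))
  out[order(out$nu), ]
}

#' Bifurcation diagram of the doublet along the gonad
#'
#' For each axial station of a hydraulic model solution, the local uptake
#' S(x) (scaled to the doublet's share) and pressure difference Pc - Pr are
#' inserted into the doublet equation; all fixed points in \[-1, 1\] are
#' located and classified. The symmetric state loses stability where the
#' linear growth rate sigma(x) crosses zero, which is also returned.
#'
#' @param model_solution a `model_solution` from [solve_steady_state()].
#' @param params_template [doublet_params] providing A_c, alpha0, T, R, p;
#'   its `S` and `Pc_minus_Pr` are overwritten per station.
#' @param cell_length_frac fraction of gonad length occupied by one doublet,
#'   used to convert the per-unit-length uptake S(x) to the doublet's share
#'   (default 2/40: two cells of about one bin each).
#' @param stations optional subset of grid indices.
#' @return list with `branches` (data frame x, nu, stable, boundary),
#'   `sigma` (data frame x, sigma), `x_bifurcation` (first sigma zero
#'   crossing, NA if none).
#' @export
bifurcation_along_gonad <- function(model_solution, params_template,
                                    cell_length_frac = 0.05,
                                    stations = NULL) {
  x <- model_solution$x
  idx <- stations %||% seq_along(x)
  branches <- list()
  sig <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    p <- params_template
    p$S <- model_solution$S[i] * cell_length_frac
    p$Pc_minus_Pr <- model_solution$Pc[i] - model_solution$Pr[i]
    fp <- doublet_fixed_points(p)
    if (nrow(fp) > 0) fp$x <- x[i]
    branches[[k]] <- fp
    sig[k] <- linear_growth_rate(p)
  }
  sig_df <- data.frame(x = x[idx], sigma = sig)
  xb <- NA_real_
  s <- which(sig_df$sigma[-nrow(sig_df)] < 0 & sig_df$sigma[-1] >= 0)
  if (length(s) > 0) {
    i <- s[1]
    xb <- sig_df$x[i] + (sig_df$x[i + 1] - sig_df$x[i]) *
      (-sig_df$sigma[i]) / (sig_df$sigma[i + 1] - sig_df$sigma[i])
  }
  list(branches = do.call(rbind, branches), sigma = sig_df,
       x_bifurcation = xb)
}
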