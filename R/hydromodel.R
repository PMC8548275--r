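# Steady-state 1D two-phase hydraulic model of the gonad.
#
# Two interpenetrating phases along the fractional axis x in [0,1]: the
# rachis (shared cytoplasmic channel) carrying flux Qr, and the germ-cell
# phase carrying flux Qc. Volume is exchanged through rachis bridges at rate
# J per unit length, driven by the pressure difference between the phases,
# and taken up from the surrounding tissue at rate S per unit length:
#
#   dQr/dx = J,            J  = alpha (Pc - Pr)
#   dQc/dx = S - J
#   Qr = -kappa_r dPr/dx           (Poiseuille-like rachis conductance)
#   Qc = -(rhoV/gamma_c) dPc/dx    (Darcy-like crawling cell phase)
#
# Boundary conditions: Qr(0) = Qc(0) = 0 (closed distal tip), Qr(1) = 0
# (rachis flux vanishes at the turn), pressure gauge Pr(1) = 0. This is the
# minimal closure reproducing the qualitative flux/pressure geometry; see the
# methods vignette for its status and the gauge freedom of the parameters.

#' Hydraulic model parameters
#'
#' @param alpha effective hydraulic conductivity of rachis bridges
#'   (flux per pressure per unit fractional length), > 0.
#' @param kappa_r rachis conductance (flux per pressure gradient), > 0.
#' @param gamma_c germ-cell-phase friction (pressure gradient per velocity,
#'   in the model's per-unit-rhoV form), > 0.
#' @param rhoV cell volume per unit fractional length: a single number, a
#'   vector on `grid`, or a function of x.
#' @param grid axial grid, a numeric vector in \[0, 1\] (uniform).
#' @return an object of class `model_params`.
#' @export
model_params <- function(alpha, kappa_r, gamma_c, rhoV,
                         grid = seq(0, 1, length.out = 101)) {
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_number(kappa_r, "kappa_r", lower = 0, strict_lower = TRUE)
  check_number(gamma_c, "gamma_c", lower = 0, strict_lower = TRUE)
  if (!is_uniform_grid(grid)) stop("`grid` must be uniform", call. = FALSE)
  rv <- if (is.function(rhoV)) rhoV(grid) else
    if (length(rhoV) == 1L) rep(rhoV, length(grid)) else rhoV
  if (length(rv) != length(grid) || any(!is.finite(rv)) || any(rv <= 0))
    stop("`rhoV` must be positive and defined on the grid", call. = FALSE)
  structure(list(alpha = alpha, kappa_r = kappa_r, gamma_c = gamma_c,
                 rhoV = rv, grid = grid),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "hydraulic model parameters: alpha = %.4g, kappa_r = %.4g, gamma_c = %.4g (grid n = %d)\n",
    x$alpha, x$kappa_r, x$gamma_c, length(x$grid)))
  invisible(x)
}

#' Solve the steady-state two-phase model
#'
#' Discretizes the coupled flux balances with a conservative staggered
#' (finite-volume) scheme: pressures live on the nodes, fluxes on the faces,
#' so the discrete conservation identities hold to machine precision. The
#' resulting linear system in (Pc, Pr) is solved directly.
#'
#' @param S uptake profile: numeric vector on `params$grid`, a function of x,
#'   or an [axial_profile] data frame with columns `x` and `S` (fl/min per
#'   unit fractional length).
#' @param params a [model_params] object.
#' @return a `model_solution`: an [axial_profile] data frame with columns
#'   `x, Qr, Qc, J, S, Pc, Pr` plus attributes `faces` (face-centred fluxes),
#'   `params`, and `residuals` (discrete conservation residuals).
#' @examples
#' p <- model_params(10, 0.25, 1.5e5, rhoV = 5e4)
#' sol <- solve_steady_state(function(x) sin(pi * x / 0.65) *
#'                             (x <= 0.65) * 1600, p)
#' @export
solve_steady_state <- function(S, params) {
  stopifnot(inherits(params, "model_params"))
  x <- params$grid
  n <- length(x)
  h <- x[2] - x[1]
  Sv <- eval_on_grid(S, x, "S")

  alpha <- params$alpha
  kap <- params$kappa_r
  beta <- params$rhoV / params$gamma_c      # cell-phase conductance, nodal
  beta_f <- (beta[-1] + beta[-n]) / 2       # on interior faces

  w <- rep(h, n); w[c(1, n)] <- h / 2       # control-volume widths

  # Unknowns: u = (Pc_1..Pc_n, Pr_1..Pr_n)
  A <- matrix(0, 2 * n, 2 * n)
  b <- numeric(2 * n)
  iPc <- function(i) i
  iPr <- function(i) n + i

  # Face fluxes as linear forms: Qr_{i+1/2} = -kap (Pr_{i+1}-Pr_i)/h,
  # boundary faces 1/2 and n+1/2 are zero for Qr; Qc_{1/2} = 0.
  for (i in 1:n) {
    # rachis balance: Qr_{i+1/2} - Qr_{i-1/2} - w_i alpha (Pc_i - Pr_i) = 0
    r <- i
    if (i < n) { # face i+1/2
      A[r, iPr(i + 1)] <- A[r, iPr(i + 1)] - kap / h
      A[r, iPr(i)] <- A[r, iPr(i)] + kap / h
    }
    if (i > 1) { # minus face i-1/2
      A[r, iPr(i)] <- A[r, iPr(i)] + kap / h
      A[r, iPr(i - 1)] <- A[r, iPr(i - 1)] - kap / h
    }
    A[r, iPc(i)] <- A[r, iPc(i)] - w[i] * alpha
    A[r, iPr(i)] <- A[r, iPr(i)] + w[i] * alpha
  }
  for (i in 1:(n - 1)) {
    # cell balance: Qc_{i+1/2} - Qc_{i-1/2} + w_i alpha (Pc_i-Pr_i) = w_i S_i
    r <- n + i
    A[r, iPc(i + 1)] <- A[r, iPc(i + 1)] - beta_f[i] / h
    A[r, iPc(i)] <- A[r, iPc(i)] + beta_f[i] / h
    if (i > 1) {
      A[r, iPc(i)] <- A[r, iPc(i)] + beta_f[i - 1] / h
      A[r, iPc(i - 1)] <- A[r, iPc(i - 1)] - beta_f[i - 1] / h
    }
    A[r, iPc(i)] <- A[r, iPc(i)] + w[i] * alpha
    A[r, iPr(i)] <- A[r, iPr(i)] - w[i] * alpha
    b[r] <- w[i] * Sv[i]
  }
  A[2 * n, iPr(n)] <- 1                     # pressure gauge Pr(1) = 0

  u <- tryCatch(solve(A, b), error = function(e)
    abort_stage("hydromodel", paste("singular system:", conditionMessage(e))))
  Pc <- u[1:n]
  Pr <- u[(n + 1):(2 * n)]
  J <- alpha * (Pc - Pr)

  # face fluxes (exactly conservative)
  Qr_f <- c(0, -kap * diff(Pr) / h, 0)          # n+1 faces incl. boundaries
  Qc_f <- c(0, -beta_f * diff(Pc) / h, NA)      # outflow face from balance
  Qc_f[n + 1] <- Qc_f[n] + w[n] * (Sv[n] - J[n])

  prof <- axial_profile(x,
                        Qr = (Qr_f[-1] + Qr_f[-(n + 1)]) / 2,
                        Qc = (Qc_f[-1] + Qc_f[-(n + 1)]) / 2,
                        J = J, S = Sv, Pc = Pc, Pr = Pr)
  res_r <- diff(Qr_f) - w * J
  res_t <- diff(Qr_f) + diff(Qc_f) - w * Sv
  structure(prof,
            faces = list(x = c(x[1], (x[-1] + x[-n]) / 2, x[n]),
                         Qr = Qr_f, Qc = Qc_f),
            params = params,
            residuals = c(rachis = sum(abs(res_r)), total = sum(abs(res_t))),
            class = c("model_solution", class(prof)))
}

# Accept a vector, a function, or a profile data frame for a gridded field.
eval_on_grid <- function(f, x, name) {
  if (is.function(f)) return(f(x))
  if (is.data.frame(f)) {
    if (!all(c("x", name) %in% names(f)))
      stop(sprintf("profile must have columns `x` and `%s`", name),
           call. = FALSE)
    return(approx(f$x, f[[name]], xout = x, rule = 2)$y)
  }
  if (length(f) == length(x)) return(as.numeric(f))
  stop(sprintf("`%s` must be a function, a profile, or a vector on the grid",
               name), call. = FALSE)
}

#' Position where the rachis flux peaks (and J crosses zero)
#'
#' Both locations are read from the same solution: on each cell the face-flux
#' reconstruction has derivative J, so the interpolated maximum of Qr and the
#' linear zero crossing of J coincide by construction. They are exposed as two
#' functions so calling code can assert the identity.
#' @param sol a `model_solution`.
#' @return position in \[0, 1\], or NA if there is no interior sign change.
#' @export
j_zero_x <- function(sol) {
  x <- sol$x; J <- sol$J
  s <- which(J[-length(J)] > 0 & J[-1] <= 0)
  if (length(s) == 0) return(NA_real_)
  i <- s[1]
  x[i] + (x[i + 1] - x[i]) * J[i] / (J[i] - J[i + 1])
}

#' @rdname j_zero_x
#' @export
qr_peak_x <- function(sol) {
  x <- sol$x; J <- sol$J
  n <- length(x)
  # reconstruct Qr with J linear between nodes: piecewise quadratic whose
  # derivative is exactly the interpolated J
  qrec <- cumtrapz(x, J) + sol$Qr[1]
  best_x <- x[which.max(qrec)]
  best_q <- max(qrec)
  for (i in 1:(n - 1)) {
    if (J[i] > 0 && J[i + 1] <= 0 && J[i] != J[i + 1]) {
      xs <- x[i] + (x[i + 1] - x[i]) * J[i] / (J[i] - J[i + 1])
      qs <- qrec[i] + (xs - x[i]) * J[i] / 2
      if (qs > best_q) { best_q <- qs; best_x <- xs }
    }
  }
  best_x
}

#' Fit hydraulic parameters to an observed rachis flux profile
#'
#' Least-squares fit of the model's Qr(x) to an observed profile, given the
#' uptake profile S(x), over (alpha, kappa_r, gamma_c) in log space with
#' multiple seeded starts. The parameter triple carries an exact scale
#' invariance ((alpha, kappa_r, 1/gamma_c) -> c (alpha, kappa_r, 1/gamma_c)
#' with pressures rescaled by 1/c leaves all fluxes unchanged), so after
#' optimization the result is gauge-fixed by rescaling along that direction
#' until gamma_c equals its initial value.
#'
#' @param observed_Qr [axial_profile] (or data frame) with columns `x`, `Qr`.
#' @param S uptake profile (vector on the grid, function, or profile).
#' @param init a [model_params] object used as centre of the multi-start and
#'   as the gauge reference.
#' @param n_starts number of log-uniform random starts (default 12).
#' @param spread half-width of the log10-uniform start box (default 1).
#' @param seed integer seed for the start draw.
#' @return a [model_params] with attributes `residual` (root-mean-square
#'   misfit), `degenerate` (flag: observed flux indistinguishable from zero)
#'   and `convergence`.
#' @export
fit_parameters <- function(observed_Qr, S, init, n_starts = 12, spread = 1,
                           seed = 1L) {
  stopifnot(inherits(init, "model_params"))
  x <- init$grid
  qr_obs <- eval_on_grid(observed_Qr, x, "Qr")
  Sv <- eval_on_grid(S, x, "S")
  scale_q <- max(abs(qr_obs))

  obj <- function(th) {
    p <- model_params(exp(th[1]), exp(th[2]), exp(th[3]), init$rhoV, x)
    sol <- tryCatch(solve_steady_state(Sv, p), error = function(e) NULL)
    if (is.null(sol)) return(1e10)
    sqrt(mean((sol$Qr - qr_obs)^2))
  }

  th0 <- log(c(init$alpha, init$kappa_r, init$gamma_c))
  starts <- with_preserved_seed(derive_seed(seed, "fit_starts"), {
    m <- matrix(runif(3 * n_starts, -spread, spread) * log(10), ncol = 3)
    sweep(m, 2, th0, `+`)
  })
  starts <- rbind(th0, starts)

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    o <- optim(starts[k, ], obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value >= 1e10)
    abort_stage("fit", sprintf("no start converged; best residual %g",
                               best$value))

  th <- best$par
  # gauge fix: move along the invariant direction so gamma_c == init$gamma_c
  c_gauge <- exp(th[3]) / init$gamma_c
  out <- model_params(exp(th[1]) * c_gauge, exp(th[2]) * c_gauge,
                      init$gamma_c, init$rhoV, x)
  attr(out, "residual") <- best$value
  attr(out, "degenerate") <- (scale_q < 1e-12) && (best$value < 1e-12)
  attr(out, "convergence") <- best$convergence
  out
}

#' Predict the germ-cell-to-rachis current from fitted parameters
#'
#' Re-solves the steady-state model for a given uptake profile and returns
#' the solution profile; `grid` allows re-using parameters fitted on one
#' grid for a dataset defined on another (e.g. re-analysis of an
#' apoptosis-deficient condition with control-fit parameters).
#'
#' @param params [model_params].
#' @param S uptake profile.
#' @param grid optional new grid; `params$rhoV` is interpolated onto it.
#' @return a `model_solution` (see [solve_steady_state()]).
#' @export
predict_J <- function(params, S, grid = NULL) {
  if (!is.null(grid)) {
    rv <- approx(params$grid, params$rhoV, xout = grid, rule = 2)$y
    params <- model_params(params$alpha, params$kappa_r, params$gamma_c,
                           rv, grid)
  }
  solve_steady_state(S, params)
}
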