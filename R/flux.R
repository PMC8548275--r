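# Flux estimation along the gonad: rachis flux from velocity fields, cell
# volume flux from cell tables, and the flux-balance derivatives J and S.
# All fluxes are in fl/min (1 fl = 1 um^3); x is the fraction of gonad
# length.

#' Gridded axial profile container
#'
#' A data frame with a common axial grid `x` (fractions of gonad length) and
#' any of the fields `Qr`, `Qc` (fl/min), `J`, `S` (fl/min per unit
#' fractional length), `Pc`, `Pr` (pressure, arbitrary gauge-fixed units).
#'
#' @param x axial grid in \[0, 1\], increasing.
#' @param ... named numeric columns of `length(x)`.
#' @return data frame of class `axial_profile`.
#' @export
axial_profile <- function(x, ...) {
  cols <- list(...)
  if (any(!is.finite(x)) || is.unsorted(x, strictly = TRUE) ||
      x[1] < 0 || x[length(x)] > 1)
    stop("`x` must be strictly increasing within [0, 1]", call. = FALSE)
  for (nm in names(cols))
    if (length(cols[[nm]]) != length(x))
      stop(sprintf("column `%s` does not match the grid length", nm),
           call. = FALSE)
  structure(data.frame(x = x, cols), class = c("axial_profile", "data.frame"))
}

#' Convert a volumetric flux from um^3/s to fl/min
#'
#' 1 fl = 1 um^3, so the conversion is a factor of 60 in time only.
#' @param q flux in um^3 per second.
#' @return flux in fl per minute.
#' @export
um3_s_to_fl_min <- function(q) q * 60

#' @rdname um3_s_to_fl_min
#' @param qf flux in fl per minute.
#' @export
fl_min_to_um3_s <- function(qf) qf / 60

#' Rachis volume flux from a velocity field
#'
#' Assumes axisymmetry of the flow about the centreline: the mid-plane
#' transverse velocity profile v(r) (component along the local centreline
#' tangent, both sides of the centreline pooled) is integrated as
#' Qr = int_0^a v(r) 2 pi r dr by trapezoidal quadrature, per axial station.
#'
#' @param field a `velocity_field` (see [generate_velocity_field()] or
#'   [piv_displacement()]): velocities in um/s on a regular grid with a mask
#'   and a centreline.
#' @param lumen_radius rachis lumen radius a(x) in um: scalar, function of
#'   fractional x, or vector on the field's axial stations.
#' @param gonad_length_um physical length mapped to x = 1; defaults to the
#'   axial extent of the field.
#' @param grid optional output grid (fractions); default the field's axial
#'   stations rescaled.
#' @return an [axial_profile] with column `Qr` (fl/min).
#' @export
flux_from_field <- function(field, lumen_radius, gonad_length_um = NULL,
                            grid = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  xs <- field$x_um
  ys <- field$y_um
  L <- gonad_length_um %||% max(xs)
  if (is.null(field$centreline) || nrow(field$centreline) < 2)
    abort_stage("flux", "centreline missing or shorter than the field")
  cl_y <- approx(field$centreline$x_um, field$centreline$y_um, xout = xs,
                 rule = 2)$y
  # local tangent of the centreline
  ty <- savitzky_golay(cl_y, dx = xs[2] - xs[1],
                       window = min(11, oddify(length(xs))), order = 1)$deriv
  xfrac <- xs / L
  a_vec <- if (is.function(lumen_radius)) lumen_radius(xfrac)
           else if (length(lumen_radius) == 1L) rep(lumen_radius, length(xs))
           else lumen_radius
  if (length(a_vec) != length(xs) || any(a_vec <= 0))
    abort_stage("flux", "lumen radius must be positive on every station")

  Qr <- numeric(length(xs))
  for (j in seq_along(xs)) {
    tvec <- c(1, ty[j]) / sqrt(1 + ty[j]^2)
    inmask <- which(field$mask[, j] & abs(ys - cl_y[j]) <= a_vec[j])
    if (length(inmask) < 3) { Qr[j] <- NA_real_; next }
    r <- abs(ys[inmask] - cl_y[j])
    vpar <- field$vx[inmask, j] * tvec[1] + field$vy[inmask, j] * tvec[2]
    # pool the two sides: average v at equal radii, then integrate
    ord <- order(r)
    r <- r[ord]; vpar <- vpar[ord]
    rr <- unique(r)
    vv <- vapply(rr, function(ri) mean(vpar[r == ri]), 0)
    if (rr[1] > 0) { rr <- c(0, rr); vv <- c(vv[1], vv) }
    if (rr[length(rr)] < a_vec[j]) {
      # extend to the wall by linear extrapolation of the last two samples
      k <- length(rr)
      v_a <- if (k >= 2)
        vv[k] + (vv[k] - vv[k - 1]) / (rr[k] - rr[k - 1]) * (a_vec[j] - rr[k])
      else vv[k]
      rr <- c(rr, a_vec[j]); vv <- c(vv, v_a)
    }
    Qr[j] <- um3_s_to_fl_min(2 * pi * trapz(rr, vv * rr))
  }
  prof <- axial_profile(pmin(pmax(xfrac, 0), 1), Qr = Qr)
  if (!is.null(grid))
    prof <- axial_profile(grid, Qr = approx(prof$x, prof$Qr, xout = grid,
                                            rule = 2)$y)
  prof
}

oddify <- function(n) if (n %% 2 == 0) n - 1 else n

#' Cell volume flux from a cell table and a cell velocity profile
#'
#' Qc(x) = rhoV(x) v_c(x) / L, where rhoV(x) is the cell volume per unit
#' fractional length (binned from the table and averaged per gonad arm,
#' lightly smoothed), v_c the cell speed in um/min, and L the gonad length
#' in um.
#'
#' @param cells a cell table (data frame with `gonad_id`, `x`, `volume_fl`).
#' @param v_c cell velocity profile in um/min: scalar, function of x, or
#'   vector on `grid`.
#' @param gonad_length_um gonad length L in um.
#' @param grid output grid (default 101 points).
#' @param smooth_window Savitzky-Golay window for the density estimate
#'   (odd; default about a fifth of the grid).
#' @return an [axial_profile] with columns `Qc` (fl/min) and `rhoV`
#'   (fl per unit fractional length, per gonad arm).
#' @export
cell_volume_flux <- function(cells, v_c, gonad_length_um,
                             grid = seq(0, 1, length.out = 101),
                             smooth_window = NULL) {
  n <- length(grid)
  h <- grid[2] - grid[1]
  edges <- c(grid - h / 2, grid[n] + h / 2)
  idx <- findInterval(pmin(pmax(cells$x, 0), 1 - 1e-12), edges,
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > n] <- n
  vol <- vapply(1:n, function(i) sum(cells$volume_fl[idx == i]), 0)
  n_gonads <- length(unique(cells$gonad_id))
  widths <- rep(h, n); widths[c(1, n)] <- h / 2 # edge bins only cover half a cell
  rhoV <- vol / widths / n_gonads
  sw <- smooth_window %||% oddify(max(5, round(n / 5)))
  rhoV_s <- pmax(savitzky_golay(rhoV, dx = h, window = sw)$smooth, 0)
  vc <- if (is.function(v_c)) v_c(grid)
        else if (length(v_c) == 1L) rep(v_c, n) else v_c
  axial_profile(grid, Qc = rhoV_s * vc / gonad_length_um, rhoV = rhoV_s)
}

#' Infer the germ-cell-to-rachis current J from a rachis flux profile
#'
#' Estimates J = dQr/dx by Savitzky-Golay differentiation (order 2, window
#' about a tenth of the grid by default). The returned smoothed flux column
#' `Qr_smooth` is the exact cumulative-trapezoid antiderivative of `J`
#' anchored at the smoothed distal value, so `cumtrapz(x, J) + Qr_smooth[1]`
#' reproduces `Qr_smooth` to machine precision. If per-gonad replicate
#' profiles are supplied, a bootstrap band over gonads is attached.
#'
#' @param profile [axial_profile] with columns `x`, `Qr`.
#' @param window,order Savitzky-Golay parameters.
#' @param replicates optional matrix (grid x gonads) of per-gonad Qr
#'   profiles for bootstrap uncertainty.
#' @param n_boot bootstrap draws (default 200).
#' @param seed seed for the bootstrap resampling.
#' @return the profile with columns `J`, `Qr_smooth` (and `J_lo`, `J_hi`
#'   95 percent bootstrap bands when replicates are given). The proximal-most
#'   5 percent of stations is flagged in the `low_confidence` column
#'   (centreline estimation is unreliable near the turn).
#' @export
infer_J <- function(profile, window = NULL, order = 2, replicates = NULL,
                    n_boot = 200, seed = 1L) {
  x <- profile$x
  if (is.null(profile$Qr)) stop("profile lacks `Qr`", call. = FALSE)
  sg <- savitzky_golay(profile$Qr, dx = x[2] - x[1], window = window,
                       order = order)
  profile$J <- sg$deriv
  profile$Qr_smooth <- cumtrapz(x, sg$deriv) + sg$smooth[1]
  profile$low_confidence <- x > 0.95
  if (!is.null(replicates)) {
    bands <- boot_band(x, replicates, window, order, n_boot, seed)
    profile$J_lo <- bands$lo
    profile$J_hi <- bands$hi
  }
  profile
}

#' Infer the material uptake S from rachis and cell flux profiles
#'
#' S = d(Qc + Qr)/dx with the same smoothing contract as [infer_J()].
#'
#' @inheritParams infer_J
#' @param profile [axial_profile] with columns `x`, `Qr`, `Qc`.
#' @return the profile with columns `S` and `Qtot_smooth` (and `S_lo`,
#'   `S_hi` when replicates of Qc+Qr are given).
#' @export
infer_S <- function(profile, window = NULL, order = 2, replicates = NULL,
                    n_boot = 200, seed = 1L) {
  x <- profile$x
  if (is.null(profile$Qr) || is.null(profile$Qc))
    stop("profile lacks `Qr` or `Qc`", call. = FALSE)
  tot <- profile$Qr + profile$Qc
  sg <- savitzky_golay(tot, dx = x[2] - x[1], window = window, order = order)
  profile$S <- sg$deriv
  profile$Qtot_smooth <- cumtrapz(x, sg$deriv) + sg$smooth[1]
  profile$low_confidence <- x > 0.95
  if (!is.null(replicates)) {
    bands <- boot_band(x, replicates, window, order, n_boot, seed)
    profile$S_lo <- bands$lo
    profile$S_hi <- bands$hi
  }
  profile
}

# bootstrap 95% band of the SG derivative over gonad replicates
boot_band <- function(x, replicates, window, order, n_boot, seed) {
  ng <- ncol(replicates)
  dx <- x[2] - x[1]
  draws <- with_preserved_seed(derive_seed(seed, "boot_band"), {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(ng, ng, replace = TRUE)
      m <- rowMeans(replicates[, pick, drop = FALSE])
      savitzky_golay(m, dx = dx, window = window, order = order)$deriv
    }, numeric(length(x)))
  })
  list(lo = apply(draws, 1, quantile, 0.025),
       hi = apply(draws, 1, quantile, 0.975))
}

#' First zero crossing (positive to negative) of a profile column
#'
#' Linear interpolation between grid points; used to locate where the
#' inferred uptake S or current J changes sign.
#' @param profile [axial_profile].
#' @param column column name (default `"S"`).
#' @return position in \[0, 1\] or NA.
#' @export
zero_crossing_x <- function(profile, column = "S") {
  y <- profile[[column]]
  x <- profile$x
  s <- which(y[-length(y)] > 0 & y[-1] <= 0)
  if (length(s) == 0) return(NA_real_)
  i <- s[1]
  x[i] + (x[i + 1] - x[i]) * y[i] / (y[i] - y[i + 1])
}
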