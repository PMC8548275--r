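# Seeded synthetic-data generator.
#
# The generator states a self-consistent "world": an uptake profile S(x)
# changing sign exactly once at the transition position x*, a steady-state
# solution of the two-phase hydraulic model providing the bookkeeping truth
# for Qr, Qc, J and the pressures, per-cell volume tables whose distribution
# is unimodal distally and increasingly bimodal proximally to x*, mid-plane
# Poiseuille velocity fields matching the truth Qr, apoptosis/mitosis event
# streams, and speckle image pairs advected by a known flow. Every draw is
# seeded; fixed seed implies bit-identical outputs.

#' Configuration of the synthetic gonad
#'
#' Defaults state the conditions reported for the adult hermaphrodite
#' germline: ~100 fl cells at the distal tip growing collectively to
#' ~150 fl, a volume-distribution transition at 65 percent of gonad length
#' beyond which cell volumes span ~65 to ~1,200 fl, physiological apoptosis
#' at 4-6 percent per hour restricted to 70-90 percent length, and 18 gonad
#' arms of roughly 290 scored cells each (~5,300 cells total).
#'
#' @param seed integer seed; every generator draw derives its stream from it.
#' @param n_gonads number of gonad arms.
#' @param cells_per_gonad cells scored per arm.
#' @param axis_grid number of axial bins used by default downstream.
#' @param transition_x planted transition position x* in (0, 1).
#' @param distal_mean_start,distal_mean_end mean volume (fl) at x = 0 and at
#'   x = x* (collective growth 100 -> 150 fl).
#' @param proximal_small,proximal_large limits (fl) that the small and large
#'   mixture modes approach at x = 1; also the envelope of generated volumes.
#' @param volume_cv within-mode coefficient of variation of volumes.
#' @param gonad_effect_cv between-gonad multiplicative volume variability.
#' @param mix_weight_start,mix_weight_end weight of the small mode just
#'   proximal to x* and at x = 1 (declines as small cells are removed by
#'   apoptosis; held at `mix_weight_start` when `apoptosis = FALSE`).
#' @param apoptosis logical; FALSE emulates an apoptosis-deficient
#'   (caspase-inhibited) germline in which small cells persist.
#' @param gonad_radius_um gonad tube radius R (um).
#' @param rachis_radius_um rachis lumen radius a (um), scalar or function of
#'   fractional x; must stay below `gonad_radius_um`.
#' @param gonad_length_um gonad arm length L (um).
#' @param uptake_pos,uptake_neg amplitudes (fl/min per unit fractional
#'   length) of the positive distal and negative proximal lobes of S(x).
#' @param model_grid_n axial grid resolution of the hydraulic truth.
#' @param alpha,kappa_r,gamma_c hydraulic parameters of the truth model (see
#'   [model_params()]).
#' @param noise_sd_velocity additive Gaussian velocity noise (um/s).
#' @param apoptosis_rate_per_h apoptosis probability per cell-hour inside
#'   `apoptosis_zone` (4-6 percent per hour is realistic).
#' @param apoptosis_zone fractional interval of apoptotic events.
#' @param mitosis_rate_per_h,mitosis_zone same for mitotic events (distal
#'   mitotic zone).
#' @param field_dx_um velocity-field grid spacing (um).
#' @param frame_interval_s time between image frames (s).
#' @param pixel_size_um image pixel size (um); 16 px then correspond to
#'   about 1.7 um, matching a typical confocal PIV setup.
#' @param psf_sigma_px Gaussian blur applied to speckle textures (px).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_gonads = 18L,
                             cells_per_gonad = 292L,
                             axis_grid = 40L,
                             transition_x = 0.65,
                             distal_mean_start = 100,
                             distal_mean_end = 150,
                             proximal_small = 65,
                             proximal_large = 1200,
                             volume_cv = 0.15,
                             gonad_effect_cv = 0.03,
                             mix_weight_start = 0.5,
                             mix_weight_end = 0.4,
                             apoptosis = TRUE,
                             gonad_radius_um = 10,
                             rachis_radius_um = 4,
                             gonad_length_um = 350,
                             uptake_pos = 1600,
                             uptake_neg = 2000,
                             model_grid_n = 101L,
                             alpha = 10,
                             kappa_r = 1,
                             gamma_c = 6e5,
                             noise_sd_velocity = 0.05,
                             apoptosis_rate_per_h = 0.05,
                             apoptosis_zone = c(0.7, 0.9),
                             mitosis_rate_per_h = 0.04,
                             mitosis_zone = c(0, 0.25),
                             field_dx_um = 0.25,
                             frame_interval_s = 10,
                             pixel_size_um = 1.695 / 16,
                             psf_sigma_px = 1) {
  cfg <- list(seed = as.integer(seed), n_gonads = as.integer(n_gonads),
              cells_per_gonad = as.integer(cells_per_gonad),
              axis_grid = as.integer(axis_grid), transition_x = transition_x,
              distal_mean_start = distal_mean_start,
              distal_mean_end = distal_mean_end,
              proximal_small = proximal_small,
              proximal_large = proximal_large,
              volume_cv = volume_cv, gonad_effect_cv = gonad_effect_cv,
              mix_weight_start = mix_weight_start,
              mix_weight_end = mix_weight_end, apoptosis = isTRUE(apoptosis),
              gonad_radius_um = gonad_radius_um,
              rachis_radius_um = rachis_radius_um,
              gonad_length_um = gonad_length_um,
              uptake_pos = uptake_pos, uptake_neg = uptake_neg,
              model_grid_n = as.integer(model_grid_n),
              alpha = alpha, kappa_r = kappa_r, gamma_c = gamma_c,
              noise_sd_velocity = noise_sd_velocity,
              apoptosis_rate_per_h = apoptosis_rate_per_h,
              apoptosis_zone = apoptosis_zone,
              mitosis_rate_per_h = mitosis_rate_per_h,
              mitosis_zone = mitosis_zone,
              field_dx_um = field_dx_um, frame_interval_s = frame_interval_s,
              pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px)
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  if (cfg$n_gonads < 1 || cfg$cells_per_gonad < 1)
    stop("configuration error: cell and gonad counts must be positive",
         call. = FALSE)
  check_number(cfg$transition_x, "transition_x", 0, 1, strict_lower = TRUE)
  if (cfg$transition_x >= 1 && cfg$transition_x != 1)
    stop("configuration error: transition_x must lie in (0, 1]", call. = FALSE)
  for (nm in c("distal_mean_start", "distal_mean_end", "proximal_small",
               "proximal_large"))
    if (cfg[[nm]] <= 0)
      stop(sprintf("configuration error: `%s` must be a positive volume", nm),
           call. = FALSE)
  if (cfg$volume_cv < 0)
    stop("configuration error: volume_cv must be >= 0", call. = FALSE)
  a_max <- if (is.function(cfg$rachis_radius_um))
    max(cfg$rachis_radius_um(seq(0, 1, 0.01))) else cfg$rachis_radius_um
  if (any(a_max <= 0))
    stop("geometry error: rachis radius must be positive", call. = FALSE)
  if (any(a_max >= cfg$gonad_radius_um))
    stop("geometry error: rachis radius must be below the gonad radius",
         call. = FALSE)
  if (cfg$apoptosis_rate_per_h < 0 || cfg$apoptosis_rate_per_h > 1 ||
      cfg$mitosis_rate_per_h < 0 || cfg$mitosis_rate_per_h > 1)
    stop("configuration error: event rates must lie in [0, 1] per hour",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic gonad config: %d gonads x %d cells, x* = %.2f, seed = %d\n",
    x$n_gonads, x$cells_per_gonad, x$transition_x, x$seed))
  invisible(x)
}

#' Material uptake profile of the synthetic world
#'
#' A smooth positive lobe on \[0, x*\] and a negative lobe on \[x*, 1\]
#' (both half-sine), changing sign exactly once at x*. The integral is not
#' constrained to zero: its positive remainder is the volume exported at the
#' proximal boundary by maturing cells.
#'
#' @param config a [synthetic_config].
#' @param x positions (fractions of gonad length).
#' @return uptake S(x) in fl/min per unit fractional length.
#' @export
uptake_profile <- function(config, x) {
  xs <- config$transition_x
  ifelse(x <= xs,
         config$uptake_pos * sin(pi * pmin(pmax(x, 0), xs) / xs),
         -config$uptake_neg * sin(pi * (x - xs) / (1 - xs)))
}

# Mixture description of the volume distribution at position x:
# a single lognormal mode distally, two modes separating linearly beyond x*.
volume_mixture <- function(config, x) {
  xs <- config$transition_x
  mu_d <- config$distal_mean_start +
    (config$distal_mean_end - config$distal_mean_start) * pmin(x / xs, 1)
  s <- pmax((x - xs) / max(1 - xs, 1e-12), 0)
  w <- ifelse(x < xs, 1,
              if (config$apoptosis)
                config$mix_weight_start +
                  (config$mix_weight_end - config$mix_weight_start) * s
              else config$mix_weight_start)
  list(w_small = w,
       mu_small = ifelse(x < xs, mu_d,
                         mu_d + (config$proximal_small - mu_d) * s),
       mu_large = ifelse(x < xs, mu_d,
                         mu_d + (config$proximal_large - mu_d) * s))
}

#' Expected (mean) cell volume along the axis
#' @param config a [synthetic_config].
#' @param x positions.
#' @return mean volume in fl.
#' @export
mean_volume <- function(config, x) {
  m <- volume_mixture(config, x)
  m$w_small * m$mu_small + (1 - m$w_small) * m$mu_large
}

# lognormal draw with mean mu and cv, truncated to the configured envelope
# by inverse-cdf truncation (continuous; no boundary atoms)
rlnorm_trunc <- function(n, mu, cv, lo, hi) {
  if (cv == 0) return(pmin(pmax(mu, lo), hi))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mu) - sdlog^2 / 2
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  u <- runif(n, plo, phi)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate a per-cell volume table
#'
#' Cells are placed uniformly along the axis of each gonad arm. Distal to
#' the transition, volumes are lognormal about the collective growth curve
#' (SD proportional to the mean); proximal to it they follow a two-component
#' mixture whose modes separate linearly towards the configured extremes,
#' the small mode losing weight with x when apoptosis is active. A small
#' per-gonad multiplicative effect makes bootstrap-over-gonads meaningful.
#' All volumes are truncated to the configured envelope.
#'
#' @param config a [synthetic_config].
#' @return a data frame of class `cell_table` with columns `gonad_id`, `x`,
#'   `volume_fl`, `alive`.
#' @export
generate_cell_table <- function(config) {
  validate_config(config)
  with_preserved_seed(derive_seed(config$seed, "cells"), {
    rows <- lapply(seq_len(config$n_gonads), function(g) {
      x <- sort(runif(config$cells_per_gonad))
      gf <- if (config$gonad_effect_cv > 0)
        rlnorm(1, -config$gonad_effect_cv^2 / 2, config$gonad_effect_cv) else 1
      m <- volume_mixture(config, x)
      small <- rbinom(length(x), 1, m$w_small) == 1
      mu <- ifelse(small, m$mu_small, m$mu_large) * gf
      v <- rlnorm_trunc(length(x), mu, config$volume_cv,
                        config$proximal_small, config$proximal_large)
      data.frame(gonad_id = sprintf("g%02d", g), x = x, volume_fl = v,
                 alive = TRUE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cell_table", "data.frame")
    out
  })
}

#' Hydraulic truth of the synthetic world
#'
#' Solves the steady-state two-phase model for the configured uptake profile
#' with the cell volume density implied by the expected volume curve, giving
#' the generator's bookkeeping truth for Qr, Qc, J, Pc, Pr and the cell
#' velocity profile v_c consistent with Qc.
#'
#' @param config a [synthetic_config].
#' @return list with `profile` (a `model_solution`), `params`
#'   ([model_params]) and `v_c_um_min` (cell speed on the grid, um/min).
#' @export
generate_truth <- function(config) {
  validate_config(config)
  grid <- seq(0, 1, length.out = config$model_grid_n)
  rhoV <- config$cells_per_gonad * mean_volume(config, grid)
  params <- model_params(config$alpha, config$kappa_r, config$gamma_c,
                         rhoV, grid)
  sol <- solve_steady_state(uptake_profile(config, grid), params)
  v_c <- sol$Qc * config$gonad_length_um / rhoV
  list(profile = sol, params = params, v_c_um_min = v_c)
}

#' Generate a mid-plane velocity field with a prescribed rachis flux
#'
#' Builds a straight-tube mid-plane section: at each axial station the
#' along-axis velocity follows a Poiseuille (parabolic) profile across the
#' lumen whose axisymmetric integral equals the target flux (centreline
#' speed 2 Qr / (pi a^2)); transverse velocity is zero. Gaussian noise of
#' `config$noise_sd_velocity` is added to both components inside the mask.
#'
#' @param config a [synthetic_config].
#' @param target_Qr target rachis flux (fl/min): an [axial_profile] with
#'   columns `x`, `Qr`, a function of x, or a vector on the field stations.
#' @return a `velocity_field`: list with `x_um`, `y_um`, `vx`, `vy` (um/s),
#'   `mask`, `centreline`, `pixel_size_um` (grid spacing), `a_um`.
#' @export
generate_velocity_field <- function(config, target_Qr) {
  validate_config(config)
  dx <- config$field_dx_um
  L <- config$gonad_length_um
  R <- config$gonad_radius_um
  xs <- seq(dx / 2, L - dx / 2, by = dx)
  ys <- seq(0, 2 * R, by = dx)
  xfrac <- xs / L
  a_vec <- if (is.function(config$rachis_radius_um))
    config$rachis_radius_um(xfrac) else rep(config$rachis_radius_um,
                                            length(xs))
  if (any(a_vec <= 0)) abort_stage("synthetic", "negative lumen radius")
  qr <- if (is.data.frame(target_Qr))
    approx(target_Qr$x, target_Qr$Qr, xout = xfrac, rule = 2)$y
  else if (is.function(target_Qr)) target_Qr(xfrac)
  else if (length(target_Qr) == length(xs)) as.numeric(target_Qr)
  else stop("`target_Qr` must be a profile, function, or per-station vector",
            call. = FALSE)

  yc <- R
  vmax <- 2 * fl_min_to_um3_s(qr) / (pi * a_vec^2)   # um/s at the centreline
  r2 <- outer(ys - yc, rep(1, length(xs)))^2
  a2 <- outer(rep(1, length(ys)), a_vec^2)
  mask <- r2 <= a2
  vx <- ifelse(mask, outer(rep(1, length(ys)), vmax) * (1 - r2 / a2), 0)
  vy <- matrix(0, length(ys), length(xs))
  if (config$noise_sd_velocity > 0) {
    noise <- with_preserved_seed(derive_seed(config$seed, "velocity"), {
      list(nx = matrix(rnorm(length(vx), 0, config$noise_sd_velocity),
                       nrow(vx)),
           ny = matrix(rnorm(length(vx), 0, config$noise_sd_velocity),
                       nrow(vx)))
    })
    vx <- vx + ifelse(mask, noise$nx, 0)
    vy <- vy + ifelse(mask, noise$ny, 0)
  }
  structure(list(x_um = xs, y_um = ys, vx = vx, vy = vy, mask = mask,
                 centreline = data.frame(x_um = xs,
                                         y_um = rep(yc, length(xs))),
                 pixel_size_um = dx, a_um = a_vec),
            class = "velocity_field")
}

#' Generate an advected speckle image pair from a velocity field
#'
#' Frame A is a blurred uniform-random speckle texture; frame B is frame A
#' advected by the field over one frame interval (backward warp, bilinear
#' interpolation). Outside the mask the texture is static. Fails if the
#' maximal displacement exceeds half the PIV template (the estimate would
#' alias).
#'
#' @param field a `velocity_field` (velocities in um/s).
#' @param config a [synthetic_config] (pixel size, frame interval, PSF).
#' @param template_px PIV template size used for the aliasing check.
#' @return list with matrices `frame_a`, `frame_b` (rows = y) and the pixel
#'   displacement fields `dx_px`, `dy_px`.
#' @export
generate_image_pair <- function(field, config, template_px = 16) {
  stopifnot(inherits(field, "velocity_field"))
  px <- config$pixel_size_um
  dt <- config$frame_interval_s
  xs <- seq(min(field$x_um) - field$pixel_size_um / 2 + px / 2,
            max(field$x_um) + field$pixel_size_um / 2, by = px)
  ys <- seq(min(field$y_um), max(field$y_um), by = px)
  bi <- function(m) bilinear_grid(field$x_um, field$y_um, m, xs, ys)
  vx <- bi(field$vx); vy <- bi(field$vy)
  maskn <- bi(field$mask * 1) > 0.5
  dxp <- vx * dt / px
  dyp <- vy * dt / px
  if (max(abs(c(dxp, dyp))) > template_px / 2)
    abort_stage("synthetic",
                sprintf("aliasing: displacement %.1f px exceeds half the %d px template",
                        max(abs(c(dxp, dyp))), template_px))
  frame_a <- with_preserved_seed(derive_seed(config$seed, "speckle"), {
    gauss_blur(matrix(runif(length(ys) * length(xs)), length(ys)),
               config$psf_sigma_px)
  })
  # backward warp: frame_b(p) = frame_a(p - d(p)) inside the mask
  nyx <- dim(frame_a)
  jj <- matrix(rep(seq_len(nyx[2]), each = nyx[1]), nyx[1])
  ii <- matrix(rep(seq_len(nyx[1]), nyx[2]), nyx[1])
  src_x <- jj - ifelse(maskn, dxp, 0)
  src_y <- ii - ifelse(maskn, dyp, 0)
  frame_b <- bilinear_sample(frame_a, src_x, src_y)
  list(frame_a = frame_a, frame_b = frame_b, dx_px = ifelse(maskn, dxp, 0),
       dy_px = ifelse(maskn, dyp, 0), mask = maskn,
       pixel_size_um = px, frame_interval_s = dt)
}

# resample matrix m defined on (x0, y0) onto the grid (x1, y1), clamped
bilinear_grid <- function(x0, y0, m, x1, y1) {
  jx <- approx(x0, seq_along(x0), xout = pmin(pmax(x1, min(x0)), max(x0)))$y
  iy <- approx(y0, seq_along(y0), xout = pmin(pmax(y1, min(y0)), max(y0)))$y
  bilinear_sample(m, outer(rep(1, length(iy)), jx), outer(iy, rep(1, length(jx))))
}

# sample matrix m at fractional (col = x, row = y) positions, clamped;
# x and y share a common shape, which the result takes
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  dims <- dim(x) %||% c(length(x), 1)
  x <- pmin(pmax(as.vector(x), 1), nc); y <- pmin(pmax(as.vector(y), 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  idx <- function(i, j) m[cbind(i, j)]
  v <- idx(y0, x0) * (1 - fx) * (1 - fy) + idx(y0, x0 + 1) * fx * (1 - fy) +
    idx(y0 + 1, x0) * (1 - fx) * fy + idx(y0 + 1, x0 + 1) * fx * fy
  matrix(v, dims[1], dims[2])
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

#' Generate apoptosis and mitosis event streams
#'
#' Events are drawn from a Poisson process with intensity rate(x) per
#' cell-hour, with cells spread uniformly along the axis; apoptotic events
#' are restricted to the configured apoptosis zone, mitotic events to the
#' mitotic zone. Event positions follow the within-zone intensity, times are
#' uniform over the observation window.
#'
#' @param config a [synthetic_config].
#' @param duration_h observation time in hours.
#' @param n_cells number of cells at risk (default all configured cells).
#' @return data frame of class `event_stream` with columns `x`, `t_h`,
#'   `type` (`"apoptosis"` or `"mitosis"`).
#' @export
generate_events <- function(config, duration_h,
                            n_cells = config$n_gonads * config$cells_per_gonad) {
  validate_config(config)
  check_number(duration_h, "duration_h", lower = 0)
  with_preserved_seed(derive_seed(config$seed, "events"), {
    one <- function(rate, zone, type) {
      zone_len <- diff(zone)
      lambda <- rate * zone_len * n_cells * duration_h
      k <- rpois(1, lambda)
      if (k == 0)
        return(data.frame(x = numeric(), t_h = numeric(),
                          type = character()))
      data.frame(x = runif(k, zone[1], zone[2]),
                 t_h = sort(runif(k, 0, duration_h)), type = type)
    }
    out <- rbind(one(config$apoptosis_rate_per_h * config$apoptosis,
                     config$apoptosis_zone, "apoptosis"),
                 one(config$mitosis_rate_per_h, config$mitosis_zone,
                     "mitosis"))
    class(out) <- c("event_stream", "data.frame")
    out
  })
}

#' Generate the complete synthetic dataset
#'
#' Convenience wrapper bundling the truth profiles, cell table, velocity
#' field and event stream for one configuration.
#'
#' @param config a [synthetic_config].
#' @param duration_h event observation window (default 10 h).
#' @param with_field generate the velocity field (slightly costly; default
#'   TRUE).
#' @return list with `config`, `truth`, `cells`, `field`, `events`.
#' @export
generate_dataset <- function(config = synthetic_config(), duration_h = 10,
                             with_field = TRUE) {
  truth <- generate_truth(config)
  list(config = config,
       truth = truth,
       cells = generate_cell_table(config),
       field = if (with_field)
         generate_velocity_field(config, truth$profile[, c("x", "Qr")]),
       events = generate_events(config, duration_h))
}
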