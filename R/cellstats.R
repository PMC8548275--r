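# Closed-form and small statistical computations: cumulative apoptosis
# probabilities, event-rate profiles with exact Poisson intervals, treated
# vs control outcome proportions, interface curvature from a sagitta, and
# z-stack volume integration.

#' Cumulative cell-death percentage from an hourly apoptosis rate
#'
#' With a per-hour apoptosis probability p_a, survival over `hours` is
#' (1 - p_a)^hours, so the expected cumulative death is
#' 100 (1 - (1 - p_a)^hours) percent. At 4-6 percent per hour this gives
#' 11.5-17 percent of cells commencing apoptosis within 3 h.
#'
#' @param p_a apoptosis probability per hour, in \[0, 1\] (vectorized).
#' @param hours duration in hours.
#' @return cumulative death in percent.
#' @examples
#' cumulative_death_percent(0.04, 3)  # 11.53
#' cumulative_death_percent(0.06, 3)  # 16.94
#' @export
cumulative_death_percent <- function(p_a, hours) {
  if (any(p_a < 0 | p_a > 1)) stop("p_a must lie in [0, 1]", call. = FALSE)
  check_number(hours, "hours", lower = 0)
  100 * (1 - (1 - p_a)^hours)
}

#' Event rates along the axis with exact Poisson intervals
#'
#' Bins an event stream by position and divides by the cell-hours of
#' exposure per bin; 95 percent confidence bounds use the exact
#' Poisson-gamma relation (lower qchisq(.025, 2k)/2, upper
#' qchisq(.975, 2k+2)/2, scaled by exposure), so zero counts get the
#' classical upper bound 3.69 / exposure.
#'
#' @param events event stream (columns `x`, `t_h`, `type`).
#' @param exposure_cell_hours total cell-hours: a scalar (split uniformly
#'   over bins) or per-bin vector.
#' @param bins number of equal-width position bins.
#' @param type event type to tabulate (default `"apoptosis"`).
#' @return data frame of class `rate_profile` with `x_center`, `events`,
#'   `exposure`, `rate` (per cell-hour), `rate_lo`, `rate_hi`.
#' @export
rates_from_events <- function(events, exposure_cell_hours, bins = 20,
                              type = "apoptosis") {
  ev <- events[events$type == type, , drop = FALSE]
  edges <- seq(0, 1, length.out = bins + 1)
  idx <- findInterval(ev$x, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > bins] <- bins
  k <- tabulate(idx, nbins = bins)
  expo <- if (length(exposure_cell_hours) == 1)
    rep(exposure_cell_hours / bins, bins) else exposure_cell_hours
  if (length(expo) != bins || any(expo <= 0))
    stop("exposure must be positive (scalar or per-bin)", call. = FALSE)
  lo <- ifelse(k == 0, 0, qchisq(0.025, 2 * k) / 2) / expo
  hi <- qchisq(0.975, 2 * k + 2) / 2 / expo
  structure(data.frame(x_center = (edges[-1] + edges[-(bins + 1)]) / 2,
                       events = k, exposure = expo, rate = k / expo,
                       rate_lo = lo, rate_hi = hi),
            class = c("rate_profile", "data.frame"))
}

#' Treated vs control outcome proportions with Fisher's exact test
#'
#' Percentages are rounded to one decimal (reporting convention); the
#' p-value is the two-sided Fisher exact test of the 2x2 table. The choice
#' of test is this package's (counts are small); see the methods vignette.
#'
#' @param k_treated,n_treated successes and totals in the treated group.
#' @param k_control,n_control same for the control group.
#' @return list with `percent_treated`, `percent_control`, `p_value`.
#' @examples
#' outcome_proportions(10, 19, 3, 21)  # 52.6 vs 14.3 percent
#' @export
outcome_proportions <- function(k_treated, n_treated, k_control, n_control) {
  for (v in c(k_treated, n_treated, k_control, n_control))
    check_number(v, "count", lower = 0)
  if (k_treated > n_treated || k_control > n_control)
    stop("successes cannot exceed totals", call. = FALSE)
  tab <- matrix(c(k_treated, n_treated - k_treated,
                  k_control, n_control - k_control), 2, byrow = TRUE)
  list(percent_treated = round(100 * k_treated / n_treated, 1),
       percent_control = round(100 * k_control / n_control, 1),
       p_value = fisher.test(tab)$p.value)
}

#' Circular-arc curvature from chord and sagitta
#'
#' A smooth arc with chord L and maximal deflection (sagitta) h has radius
#' R = ((L/2)^2 + h^2) / (2h) and curvature 1/R. A 10 um interface deflected
#' by 0.5 um corresponds to about 0.04 per um.
#'
#' @param chord_um chord length L (um).
#' @param sagitta_um maximal deflection h (um).
#' @return curvature in 1/um (0 for a flat interface).
#' @export
sagitta_curvature <- function(chord_um, sagitta_um) {
  check_number(chord_um, "chord_um", lower = 0, strict_lower = TRUE)
  check_number(sagitta_um, "sagitta_um", lower = 0)
  if (sagitta_um == 0) return(0)
  2 * sagitta_um / ((chord_um / 2)^2 + sagitta_um^2)
}

#' Cell volume from per-plane areas of a z stack
#'
#' Riemann integration of measured cross-sectional areas over the z spacing:
#' V = sum(area_i) dz, with 1 um^3 = 1 fl.
#'
#' @param areas_um2 areas per z plane (um^2).
#' @param dz_um plane spacing (um).
#' @return volume in fl; 0 with a warning for an empty stack.
#' @export
volume_from_z_areas <- function(areas_um2, dz_um) {
  check_number(dz_um, "dz_um", lower = 0, strict_lower = TRUE)
  if (length(areas_um2) == 0) {
    warning("empty z stack; returning 0 fl")
    return(0)
  }
  if (any(areas_um2 < 0)) stop("areas must be non-negative", call. = FALSE)
  sum(areas_um2) * dz_um
}
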