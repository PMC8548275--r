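# Synthetic-data generator: determinism, stated distributions, velocity
# fields, image pairs, event streams, and the generator's bookkeeping.

test_that("generator is deterministic and respects the volume envelope", {
  cfg <- synthetic_config(seed = 5)
  a <- generate_cell_table(cfg)
  b <- generate_cell_table(cfg)
  expect_identical(a, b)
  expect_true(all(a$volume_fl >= cfg$proximal_small - 1e-9))
  expect_true(all(a$volume_fl <= cfg$proximal_large + 1e-9))
  expect_true(all(a$x >= 0 & a$x <= 1))
  expect_equal(nrow(a), cfg$n_gonads * cfg$cells_per_gonad)
  # different seed, different draw
  expect_false(identical(a$volume_fl,
                         generate_cell_table(synthetic_config(seed = 6))$volume_fl))
})

test_that("distal volumes start near 100 fl and follow the mean curve when noise-free", {
  w <- default_world()
  bs <- bin_volumes(w$cells, 40)
  expect_within(bs$mean_V[1], 100, 5)
  expect_within(bs$mean_V[26], 150, 8)       # collective growth to ~150 fl
  expect_true(all(diff(bs$mean_V[1:26]) > -5)) # rising distal mean curve
  # zero noise, no transition: volumes exactly on the mean curve
  cfg0 <- synthetic_config(volume_cv = 0, gonad_effect_cv = 0,
                           transition_x = 1, n_gonads = 2)
  t0 <- generate_cell_table(cfg0)
  expect_equal(t0$volume_fl, mean_volume(cfg0, t0$x), tolerance = 1e-12)
})

test_that("per-bin dip p-values separate the two regimes across seeds", {
  # Monte-Carlo over 20 seeds: proximal bins (x > x* + 0.1) significant,
  # distal bins (x < x* - 0.1) not, in >= 90% of seeds
  ok_prox <- ok_dist <- logical(20)
  for (s in 1:20) {
    cfg <- synthetic_config(seed = 200 + s)
    bs <- bin_volumes(generate_cell_table(cfg), 40, bimodality = "dip")
    prox <- bs$dip_p[bs$x_center > cfg$transition_x + 0.1]
    dist <- bs$dip_p[bs$x_center < cfg$transition_x - 0.1]
    ok_prox[s] <- mean(prox < 0.05) >= 0.9
    ok_dist[s] <- mean(dist > 0.05) >= 0.9
  }
  expect_gte(mean(ok_prox), 0.9)
  expect_gte(mean(ok_dist), 0.9)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(cells_per_gonad = 0), "positive")
  expect_error(synthetic_config(proximal_small = -5), "positive volume")
  expect_error(synthetic_config(rachis_radius_um = 12), "below the gonad")
  expect_error(synthetic_config(apoptosis_rate_per_h = 1.5), "rates")
  expect_error(synthetic_config(transition_x = 0), "transition_x")
  # S changes sign exactly once, at x*
  cfg <- synthetic_config()
  x <- seq(0.001, 0.999, length.out = 500)
  s <- uptake_profile(cfg, x)
  flips <- sum(diff(sign(s[s != 0])) != 0)
  expect_equal(flips, 1)
  expect_lt(abs(uptake_profile(cfg, cfg$transition_x)), 1e-9)
})

test_that("velocity field matches the target flux and noise model", {
  cfg <- synthetic_config(noise_sd_velocity = 0, field_dx_um = 0.25)
  # zero flux -> zero velocities
  f0 <- generate_velocity_field(cfg, function(x) rep(0, length(x)))
  expect_equal(max(abs(f0$vx)), 0)
  # uniform radius, constant flux: centreline speed 2 Q / (pi a^2)
  Q0 <- 300 # fl/min
  f1 <- generate_velocity_field(cfg, function(x) rep(Q0, length(x)))
  v_ctr <- f1$vx[which.min(abs(f1$y_um - cfg$gonad_radius_um)), ]
  expect_within(v_ctr, 2 * (Q0 / 60) / (pi * cfg$rachis_radius_um^2), 1e-9)
  # round trip through flux_from_field within 1% at zero noise
  w <- default_world()
  f2 <- generate_velocity_field(cfg, w$truth$profile[, c("x", "Qr")])
  qr <- flux_from_field(f2, cfg$rachis_radius_um, cfg$gonad_length_um,
                        grid = w$truth$params$grid)
  rel <- sqrt(mean((qr$Qr - w$truth$profile$Qr)^2)) /
    max(abs(w$truth$profile$Qr))
  expect_lt(rel, 0.05)
  # noise is added inside the mask only
  cfgn <- synthetic_config(noise_sd_velocity = 0.05)
  fn <- generate_velocity_field(cfgn, function(x) rep(0, length(x)))
  expect_gt(sd(fn$vx[fn$mask]), 0.04)
  expect_equal(max(abs(fn$vx[!fn$mask])), 0)
})

test_that("image pairs advect the speckle texture as prescribed", {
  cfg <- synthetic_config(pixel_size_um = 0.25, frame_interval_s = 2.5,
                          seed = 3)
  # zero field -> identical frames
  p0 <- generate_image_pair(band_field(0, 0), cfg)
  expect_identical(p0$frame_a, p0$frame_b)
  # uniform 2 px axial shift recovered by PIV within 0.2 px
  pair <- generate_image_pair(band_field(0.2, 0), cfg)
  pp <- piv_params(16, frame_interval_s = 2.5, pixel_size_um = 0.25)
  v <- piv_displacement(pair$frame_a, pair$frame_b, pp, mask = pair$mask)
  expect_within(v$u_px[v$mask], 2, 0.2)
  # rotated geometry: transverse flow gives transverse displacement
  pt <- generate_image_pair(band_field(0, 0.2), cfg)
  vt <- piv_displacement(pt$frame_a, pt$frame_b, pp, mask = pt$mask)
  expect_within(vt$v_px[vt$mask], 2, 0.2)
  expect_within(vt$u_px[vt$mask], 0, 0.2)
  # excessive displacement errors out (aliasing guard)
  cfg_fast <- synthetic_config(pixel_size_um = 0.25, frame_interval_s = 20)
  expect_error(generate_image_pair(band_field(0.2, 0), cfg_fast), "aliasing")
})

test_that("event streams follow the configured rates and zones", {
  cfg0 <- synthetic_config(apoptosis_rate_per_h = 0, mitosis_rate_per_h = 0)
  expect_equal(nrow(generate_events(cfg0, 10)), 0)
  # Poisson moments: 100 cells, p_a = 0.05/h over the whole axis, 10 h
  cfg1 <- synthetic_config(apoptosis_rate_per_h = 0.05,
                           apoptosis_zone = c(0, 1), mitosis_rate_per_h = 0,
                           seed = 8)
  k <- vapply(1:30, function(s) {
    cfg1$seed <- 300L + s
    nrow(generate_events(cfg1, 10, n_cells = 100))
  }, 0L)
  expect_within(mean(k), 50, 3 * sqrt(50) / sqrt(30) * 3)
  expect_true(all(abs(k - 50) <= 4 * sqrt(50)))
  # default zone restriction
  ev <- generate_events(synthetic_config(seed = 4), 10)
  ap <- ev[ev$type == "apoptosis", ]
  expect_true(all(ap$x >= 0.7 & ap$x <= 0.9))
  expect_gt(nrow(ap), 0)
  # apoptosis off (caspase-deficient emulation) -> no apoptotic events
  ev2 <- generate_events(synthetic_config(seed = 4, apoptosis = FALSE), 10)
  expect_equal(sum(ev2$type == "apoptosis"), 0)
})

test_that("generator bookkeeping conserves volume", {
  w <- default_world()
  sol <- w$truth$profile
  n <- nrow(sol)
  # total uptake equals the net export at the boundaries
  lhs <- trapz(sol$x, sol$S)
  rhs <- (sol$Qc[n] + sol$Qr[n]) - (sol$Qc[1] + sol$Qr[1])
  expect_within(rhs / lhs, 1, 0.02)
  # distal boundary closed
  f <- attr(sol, "faces")
  expect_equal(f$Qr[1], 0)
  expect_equal(f$Qc[1], 0)
  expect_equal(f$Qr[n + 1], 0)
})
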