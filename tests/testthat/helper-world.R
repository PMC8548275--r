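# Shared fixtures, built once per test run.

.world <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.world$default)) {
    cfg <- synthetic_config(seed = 42)
    truth <- generate_truth(cfg)
    .world$default <- list(cfg = cfg, truth = truth,
                           cells = generate_cell_table(cfg))
  }
  .world$default
}

# small band-geometry velocity field for PIV tests (straight horizontal tube)
band_field <- function(vx_val = 0.2, vy_val = 0, nx = 50, half_width = 6) {
  xs <- seq(0.5, nx - 0.5, 1)
  ys <- seq(0, 20, 1)
  mask <- outer(abs(ys - 10) <= half_width, rep(TRUE, length(xs)), "&")
  structure(list(x_um = xs, y_um = ys,
                 vx = matrix(vx_val, length(ys), length(xs)) * mask,
                 vy = matrix(vy_val, length(ys), length(xs)) * mask,
                 mask = mask,
                 centreline = data.frame(x_um = xs, y_um = 10),
                 pixel_size_um = 1, a_um = rep(half_width, length(xs))),
            class = "velocity_field")
}

expect_within <- function(x, target, tol) {
  expect_true(all(abs(x - target) <= tol + 1e-9),
              label = sprintf("|%s - %s| <= %s", paste(round(x, 4),
                                                       collapse = ","),
                              target, tol))
}
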