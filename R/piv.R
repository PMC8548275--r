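# Particle image velocimetry front end around the ZNCC C++ kernel.

#' PIV parameters
#'
#' @param template_px square template side (default 16 px, ~1.7 um at the
#'   default pixel size).
#' @param overlap_px template overlap (default half the template).
#' @param search_px maximal integer displacement searched (default 7 px).
#' @param frame_interval_s time between frames (s).
#' @param pixel_size_um pixel size (um).
#' @param min_corr minimal accepted correlation peak (default 0.5).
#' @return a `piv_params` list.
#' @export
piv_params <- function(template_px = 16, overlap_px = template_px / 2,
                       search_px = 7, frame_interval_s = 10,
                       pixel_size_um = 1.695 / 16, min_corr = 0.5) {
  stopifnot(template_px >= 4, overlap_px < template_px, search_px >= 1)
  structure(list(template_px = as.integer(template_px),
                 overlap_px = as.integer(overlap_px),
                 search_px = as.integer(search_px),
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um, min_corr = min_corr),
            class = "piv_params")
}

#' Displacement field between two frames by template matching
#'
#' Zero-normalized cross-correlation over integer shifts with 3-point
#' parabolic sub-pixel refinement, per template window fully inside the
#' mask. Windows with a correlation peak below `min_corr` (or peaking on the
#' search border) are invalid and filled by the nearest valid estimate; the
#' number of filled windows is recorded in the `n_filled` attribute.
#'
#' @param frame_a,frame_b numeric matrices (rows = y) or paths to grayscale
#'   TIFF files.
#' @param params a [piv_params].
#' @param mask optional logical matrix, TRUE inside the rachis lumen
#'   (default: everywhere).
#' @return a `velocity_field` on the template grid: `x_um`, `y_um`, `vx`,
#'   `vy` (um/s), `u_px`, `v_px` (displacements), `peak`, `valid`, `mask`,
#'   `centreline`, `pixel_size_um` (grid spacing in um).
#' @export
piv_displacement <- function(frame_a, frame_b, params = piv_params(),
                             mask = NULL) {
  if (is.character(frame_a)) frame_a <- read_tiff(frame_a)
  if (is.character(frame_b)) frame_b <- read_tiff(frame_b)
  if (!all(dim(frame_a) == dim(frame_b)))
    abort_stage("piv", "frames differ in shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(frame_a), ncol(frame_a))
  step <- params$template_px - params$overlap_px
  res <- .piv_cpp(frame_a, frame_b, mask, params$template_px, step,
                  params$search_px, params$min_corr)
  if (length(res$cx) == 0 || length(res$cy) == 0)
    abort_stage("piv", "frame too small for the template and search window")
  # a window belongs to the lumen if its centre pixel is inside the mask
  ci <- round(res$cy) + 1L
  cj <- round(res$cx) + 1L
  inlumen <- outer(seq_along(res$cy), seq_along(res$cx),
                   Vectorize(function(i, j) mask[ci[i], cj[j]]))
  if (!any(res$valid & inlumen))
    abort_stage("piv", "signal quality: no valid correlation window")
  filled <- fill_nearest(res$u, res$v, res$valid & inlumen)
  filled$u[!inlumen] <- NA_real_
  filled$v[!inlumen] <- NA_real_
  px <- params$pixel_size_um
  scale <- px / params$frame_interval_s
  xs <- as.numeric(res$cx) * px
  ys <- as.numeric(res$cy) * px
  # centreline of the masked region per column of the template grid
  cl <- vapply(seq_along(xs), function(j) {
    rows <- which(inlumen[, j])
    if (length(rows) == 0) NA_real_ else mean(ys[rows])
  }, 0)
  keep <- is.finite(cl)
  structure(list(x_um = xs, y_um = ys,
                 vx = filled$u * scale, vy = filled$v * scale,
                 u_px = filled$u, v_px = filled$v,
                 peak = res$peak, valid = res$valid,
                 mask = inlumen & is.finite(filled$u),
                 centreline = data.frame(x_um = xs[keep], y_um = cl[keep]),
                 pixel_size_um = step * px),
            n_filled = sum(!res$valid & inlumen),
            class = "velocity_field")
}

# replace invalid entries by the nearest valid one (grid distance);
# windows that never overlapped the mask (u == NA and valid == FALSE due to
# mask) stay NA only if nothing valid exists in the field
fill_nearest <- function(u, v, valid) {
  if (all(valid)) return(list(u = u, v = v))
  iv <- which(valid, arr.ind = TRUE)
  bad <- which(!valid, arr.ind = TRUE)
  for (k in seq_len(nrow(bad))) {
    d2 <- (iv[, 1] - bad[k, 1])^2 + (iv[, 2] - bad[k, 2])^2
    j <- which.min(d2)
    u[bad[k, 1], bad[k, 2]] <- u[iv[j, 1], iv[j, 2]]
    v[bad[k, 1], bad[k, 2]] <- v[iv[j, 1], iv[j, 2]]
  }
  list(u = u, v = v)
}
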