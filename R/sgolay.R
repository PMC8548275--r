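#' Savitzky-Golay smoothing and differentiation
#'
#' Least-squares local polynomial smoothing on a uniform grid, returning both
#' the smoothed signal and its first derivative. Interior points use the
#' central window; within half a window of either edge the polynomial fitted
#' to the first (last) full window is evaluated at the off-centre offsets, so
#' no samples are lost.
#'
#' @param y numeric signal sampled on a uniform grid.
#' @param dx grid spacing (default 1); the derivative is per unit of `dx`.
#' @param window odd window length; default an odd number close to one tenth
#'   of `length(y)`, but at least `order + 2` and at most `length(y)`.
#' @param order polynomial order (default 2).
#' @return list with `smooth` and `deriv`, both of length `length(y)`.
#' @examples
#' x <- seq(0, 1, length.out = 101)
#' sg <- savitzky_golay(x^2, dx = x[2] - x[1], window = 11)
#' max(abs(sg$deriv - 2 * x))  # exact for a quadratic, order 2
#' @export
savitzky_golay <- function(y, dx = 1, window = NULL, order = 2) {
  n <- length(y)
  if (is.null(window)) {
    window <- max(order + 2, round(n / 10))
    if (window %% 2 == 0) window <- window + 1
  }
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  if (window %% 2 == 0) window <- window - 1
  if (window < order + 2)
    stop("`window` must be at least order + 2", call. = FALSE)
  if (n < window) stop("signal shorter than the smoothing window", call. = FALSE)
  h <- (window - 1L) %/% 2L
  offs <- -h:h
  A <- outer(offs, 0:order, `^`)
  # H maps window samples to polynomial coefficients (in offset units)
  H <- solve(crossprod(A), t(A))

  smooth <- numeric(n)
  deriv <- numeric(n)
  # interior: evaluate at offset 0 -> coefficient rows 1 (value) and 2 (slope)
  for (i in seq(h + 1, n - h)) {
    cf <- H %*% y[(i - h):(i + h)]
    smooth[i] <- cf[1]
    deriv[i] <- cf[2]
  }
  # edges: evaluate the first/last full-window polynomial off-centre
  cf0 <- H %*% y[1:window]
  cf1 <- H %*% y[(n - window + 1):n]
  pow <- function(t, k) if (k == 0) rep(1, length(t)) else t^k
  for (i in 1:h) {
    t0 <- i - (h + 1)              # offset of point i in the first window
    t1 <- (n - window + h + 1 - n) + (i) # offset of point n-h+i in last window
    smooth[i] <- sum(cf0 * vapply(0:order, function(k) pow(t0, k), 0))
    deriv[i] <- sum(cf0[-1] * vapply(1:order, function(k) k * pow(t0, k - 1), 0))
    tn <- i                         # offsets 1..h right of the last centre
    j <- n - h + i
    smooth[j] <- sum(cf1 * vapply(0:order, function(k) pow(tn, k), 0))
    deriv[j] <- sum(cf1[-1] * vapply(1:order, function(k) k * pow(tn, k - 1), 0))
  }
  list(smooth = smooth, deriv = deriv / dx)
}
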