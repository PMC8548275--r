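# Locating the homogeneous -> heterogeneous growth transition from per-cell
# volume tables: per-bin summary statistics, the slope-break detector on the
# SD-vs-mean relation, and bimodality scans (dip test, Gaussian mixture BIC).

#' Bin cell volumes along the gonad axis
#'
#' Pools all gonads into `n_bins` equal-width bins of fractional position and
#' reports per-bin occupancy, mean and sample SD (n - 1 denominator) of cell
#' volume. Optionally computes per-bin bimodality statistics.
#'
#' @param cells cell table (columns `gonad_id`, `x`, `volume_fl`).
#' @param n_bins number of equal-width bins (>= 4; default 40).
#' @param min_count minimum bin occupancy (default 5); an emptier bin is an
#'   error naming the bin.
#' @param bimodality one of `"none"`, `"dip"`, `"gmm"`, `"both"`: fill the
#'   `dip_p` / `delta_bic` columns (bins with fewer than 20 cells get NA).
#' @return data frame of class `bin_stats` with columns `x_center`, `n`,
#'   `mean_V`, `sd_V`, `dip_p`, `delta_bic`.
#' @export
bin_volumes <- function(cells, n_bins = 40, min_count = 5,
                        bimodality = c("none", "dip", "gmm", "both")) {
  bimodality <- match.arg(bimodality)
  if (n_bins < 4) stop("`n_bins` must be at least 4", call. = FALSE)
  if (any(cells$volume_fl <= 0) || any(cells$x < 0 | cells$x > 1))
    stop("cell table violates its invariants (volume > 0, x in [0, 1])",
         call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(cells$x, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > n_bins] <- n_bins
  out <- data.frame(x_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    n = 0L, mean_V = NA_real_, sd_V = NA_real_,
                    dip_p = NA_real_, delta_bic = NA_real_)
  for (b in seq_len(n_bins)) {
    v <- cells$volume_fl[idx == b]
    if (length(v) == 0)
      abort_stage("volumetrics", sprintf("bin %d of %d is empty", b, n_bins))
    if (length(v) < min_count)
      abort_stage("volumetrics",
                  sprintf("bin %d of %d holds %d cells (< %d)", b, n_bins,
                          length(v), min_count))
    out$n[b] <- length(v)
    out$mean_V[b] <- mean(v)
    out$sd_V[b] <- if (length(v) > 1) sd(v) else 0
    if (bimodality %in% c("dip", "both") && length(v) >= 20)
      out$dip_p[b] <- dip_test(v)$p_value
    if (bimodality %in% c("gmm", "both") && length(v) >= 20)
      out$delta_bic[b] <- gmm_bimodality(v)
  }
  class(out) <- c("bin_stats", "data.frame")
  out
}

#' Transition position from the slope break of SD versus mean volume
#'
#' Distally the per-bin SD of cell volume is proportional to the mean
#' (homogeneous growth); beyond the transition the SD rises much faster as
#' the distribution splits. The detector fits a continuous two-segment
#' piecewise-linear model of `sd_V` against `mean_V` (bins ordered by x,
#' hinge at a candidate bin's mean), choosing the breakpoint bin by
#' exhaustive search over bins 3 .. n-2, and reports the x of that bin. A
#' bootstrap over gonads (resample gonad ids, re-bin, refit) gives the
#' confidence interval, floored at one bin width.
#'
#' @param stats a `bin_stats` data frame (>= 8 bins).
#' @param cells optional cell table enabling the bootstrap CI.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed seed for the bootstrap.
#' @param improvement_threshold minimal relative residual improvement of the
#'   two-segment over the single-line fit; below it the fit is flagged
#'   degenerate (default 0.25).
#' @return object of class `transition_result`: list with `x_star`,
#'   `ci_low`, `ci_high`, `method = "slope_break"`, `slopes` (distal,
#'   proximal), `degenerate`, `stats`.
#' @export
detect_transition_slope <- function(stats, cells = NULL, n_boot = 200,
                                    seed = 1L, improvement_threshold = 0.25) {
  nb <- nrow(stats)
  if (nb < 8) abort_stage("volumetrics", "need at least 8 bins")
  fit <- slope_break_fit(stats$mean_V, stats$sd_V, stats$n,
                         improvement_threshold)
  bin_w <- stats$x_center[2] - stats$x_center[1]
  # the hinge bin is the last bin of the distal regime; the transition sits
  # at its proximal edge (centre reporting would bias distally by half a bin)
  x_star <- stats$x_center[fit$k] + bin_w / 2

  ci <- c(x_star - bin_w / 2, x_star + bin_w / 2)
  if (!is.null(cells) && !fit$degenerate) {
    # bootstrap over gonads via per-gonad sufficient statistics (count, sum,
    # sum of squares per bin): resampling and refitting is then O(gonads x
    # bins) per replicate
    ss <- bin_suffstats(cells, nb)
    boots <- with_preserved_seed(derive_seed(seed, "slope_boot"), {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample.int(dim(ss)[1], dim(ss)[1], replace = TRUE)
        n_b <- c(colSums(ss[pick, , 1, drop = FALSE]))
        s_b <- c(colSums(ss[pick, , 2, drop = FALSE]))
        q_b <- c(colSums(ss[pick, , 3, drop = FALSE]))
        if (any(n_b < 2)) return(NA_real_)
        mv <- s_b / n_b
        sv <- sqrt(pmax(q_b - n_b * mv^2, 0) / (n_b - 1))
        stats$x_center[slope_break_fit(mv, sv, n_b)$k] + bin_w / 2
      }, 0)
    })
    boots <- boots[is.finite(boots)]
    if (length(boots) >= max(20, n_boot / 2))
      ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  # CI floor: never narrower than one bin width
  if (diff(ci) < bin_w) {
    mid <- mean(ci)
    ci <- c(mid - bin_w / 2, mid + bin_w / 2)
  }
  ci[1] <- min(ci[1], x_star); ci[2] <- max(ci[2], x_star)
  transition_result(if (fit$degenerate) NA_real_ else x_star, ci[1], ci[2],
                    "slope_break", slopes = fit$slopes,
                    degenerate = fit$degenerate, stats = stats)
}

# Exhaustive continuous two-segment fit; returns breakpoint bin index k,
# slopes, and a degeneracy flag. Weighted least squares: the sampling
# variance of a sample SD is about sd^2 / (2 (n - 1)), so proximal bins
# (large, noisy SDs) would otherwise drown the distal corner.
slope_break_fit <- function(mv, sv, n = NULL, improvement_threshold = 0.25) {
  nb <- length(mv)
  if (is.null(n)) n <- rep(30, nb)
  sfloor <- max(sv, 1e-300) * 1e-3
  wt <- sqrt(2 * pmax(n - 1, 1)) / pmax(sv, sfloor)
  fit_w <- function(X) {
    f <- suppressWarnings(stats::lsfit(X * wt, sv * wt, intercept = FALSE))
    cf <- f$coefficients
    cf[is.na(cf)] <- 0
    list(rss = sum(f$residuals^2), coef = cf)
  }
  rss1 <- fit_w(cbind(1, mv))$rss
  best <- list(k = NA_integer_, rss = Inf, coef = NULL)
  for (k in 3:(nb - 2)) {
    hx <- mv - mv[k]
    f <- fit_w(cbind(1, hx, pmax(hx, 0)))
    if (f$rss < best$rss) best <- list(k = k, rss = f$rss, coef = f$coef)
  }
  mu_w <- sum(wt^2 * sv) / sum(wt^2)
  scale2 <- sum((wt * (sv - mu_w))^2)
  degenerate <- (rss1 <= 1e-12 * max(scale2, 1e-300)) ||
    ((rss1 - best$rss) / rss1 < improvement_threshold)
  list(k = best$k, rss = best$rss, rss_single = rss1,
       slopes = c(distal = unname(best$coef[2]),
                  proximal = unname(best$coef[2] + best$coef[3])),
       degenerate = degenerate)
}

transition_result <- function(x_star, ci_low, ci_high, method,
                              slopes = c(distal = NA_real_,
                                         proximal = NA_real_),
                              degenerate = FALSE, stats = NULL) {
  structure(list(x_star = x_star, ci_low = ci_low, ci_high = ci_high,
                 method = method, slopes = slopes, degenerate = degenerate,
                 stats = stats),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  if (is.na(x$x_star)) {
    cat(sprintf("transition (%s): none detected%s\n", x$method,
                if (x$degenerate) " (degenerate fit)" else ""))
  } else {
    cat(sprintf("transition (%s): x* = %.3f  [%.3f, %.3f]\n", x$method,
                x$x_star, x$ci_low, x$ci_high))
    if (all(is.finite(x$slopes)))
      cat(sprintf("  sd-vs-mean slopes: distal %.3f, proximal %.3f\n",
                  x$slopes[1], x$slopes[2]))
  }
  invisible(x)
}

#' Dip-test bimodality probability for a set of volumes
#'
#' Thin wrapper around [dip_test()] returning the p-value of the unimodality
#' null (small p: bimodal). Requires at least 20 values.
#' @param values numeric volumes.
#' @param n_boot bootstrap null draws.
#' @return p-value.
#' @export
dip_bimodality <- function(values, n_boot = 1000) {
  dip_test(values, n_boot = n_boot)$p_value
}

#' Gaussian-mixture evidence for bimodality (BIC difference)
#'
#' Fits 1- and 2-component Gaussian mixtures to log-volumes by EM
#' (deterministic quantile-based initialization) and returns
#' BIC(1) - BIC(2); positive values favour bimodality. Degenerate fits
#' (vanishing spread) return the pure penalty difference, which is <= 0.
#'
#' @param values numeric volumes (>= 20).
#' @return delta BIC (dimensionless).
#' @export
gmm_bimodality <- function(values) {
  v <- log(values[is.finite(values) & values > 0])
  n <- length(v)
  if (n < 20) stop("gmm_bimodality needs at least 20 values", call. = FALSE)
  s_all <- sd(v)
  if (!is.finite(s_all) || s_all < 1e-10) return(-3 * log(n))
  ll1 <- sum(dnorm(v, mean(v), sd_mle(v), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  em <- gmm2_em(v)
  if (is.null(em)) return(-3 * log(n))
  bic2 <- -2 * em$loglik + 5 * log(n)
  bic1 - bic2
}

sd_mle <- function(v) sqrt(mean((v - mean(v))^2))

gmm2_em <- function(v, max_iter = 300, tol = 1e-9) {
  n <- length(v)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  if (q[2] - q[1] < 1e-12) return(NULL)
  mu <- q
  sg <- rep(max(sd_mle(v) / 2, 1e-8), 2)
  w <- c(0.5, 0.5)
  floor_sd <- max(1e-6 * sd_mle(v), 1e-12)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(v, mu[1], sg[1])
    d2 <- w[2] * dnorm(v, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    r <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    w <- c(n1, n2) / n
    mu <- c(sum(r * v) / n1, sum((1 - r) * v) / n2)
    sg <- c(sqrt(sum(r * (v - mu[1])^2) / n1),
            sqrt(sum((1 - r) * (v - mu[2])^2) / n2))
    sg <- pmax(sg, floor_sd)
  }
  list(loglik = ll, w = w, mu = mu, sigma = sg)
}

#' Transition position from per-bin bimodality
#'
#' Scans bins from distal to proximal and reports the first bin at which the
#' chosen criterion indicates bimodality (dip p < `alpha`, or delta BIC > 0)
#' and keeps doing so for all more-proximal bins, tolerating one isolated
#' non-indicating bin. Bootstrap over gonads gives the CI (floored at one
#' bin width).
#'
#' @param cells cell table.
#' @param method `"dip"` or `"gmm"`.
#' @param n_bins number of bins (default 40).
#' @param alpha dip significance level (default 0.05).
#' @param n_boot bootstrap replicates for the CI (default 100).
#' @param seed bootstrap seed.
#' @return a `transition_result` (with `x_star = NA` and a `no_transition`
#'   flag in `degenerate` when no bin qualifies).
#' @export
detect_transition_bimodality <- function(cells, method = c("dip", "gmm"),
                                         n_bins = 40, alpha = 0.05,
                                         n_boot = 100, seed = 1L) {
  method <- match.arg(method)
  # the transition is reported at the edge between the last non-indicating
  # and the first persistently indicating bin (the change happened in
  # between; using the flagged bin's centre would bias proximally by half a
  # bin)
  scan_once <- function(tbl, min_count) {
    bs <- bin_volumes(tbl, n_bins = n_bins, min_count = min_count,
                      bimodality = method)
    flag <- if (method == "dip") bs$dip_p < alpha else bs$delta_bic > 0
    flag[is.na(flag)] <- FALSE
    k <- first_persistent(flag)
    list(stats = bs, k = k,
         x = if (is.na(k)) NA_real_ else bs$x_center[k] - 0.5 / n_bins)
  }
  main <- scan_once(cells, min_count = 5)
  bin_w <- 1 / n_bins
  if (is.na(main$k))
    return(transition_result(NA_real_, NA_real_, NA_real_, method,
                             degenerate = TRUE, stats = main$stats))
  ci <- c(main$x - bin_w / 2, main$x + bin_w / 2)
  ids <- unique(cells$gonad_id)
  if (n_boot > 0 && length(ids) > 1) {
    boots <- with_preserved_seed(derive_seed(seed, "bimod_boot"), {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(ids, length(ids), replace = TRUE)
        res <- lapply(seq_along(pick), function(i) {
          d <- cells[cells$gonad_id == pick[i], ]
          d$gonad_id <- sprintf("b%03d", i)
          d
        })
        out <- tryCatch(scan_once(do.call(rbind, res), min_count = 1)$x,
                        error = function(e) NA_real_)
        out
      }, 0)
    })
    boots <- boots[is.finite(boots)]
    if (length(boots) >= max(20, n_boot / 2))
      ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  if (diff(ci) < bin_w) {
    mid <- mean(ci)
    ci <- c(mid - bin_w / 2, mid + bin_w / 2)
  }
  ci[1] <- min(ci[1], main$x); ci[2] <- max(ci[2], main$x)
  transition_result(main$x, ci[1], ci[2], method, stats = main$stats)
}

# per-gonad, per-bin sufficient statistics: array [gonad, bin, (n, sum, sumsq)]
bin_suffstats <- function(cells, n_bins) {
  ids <- unique(cells$gonad_id)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(cells$x, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > n_bins] <- n_bins
  g <- match(cells$gonad_id, ids)
  out <- array(0, c(length(ids), n_bins, 3))
  for (r in seq_len(nrow(cells))) {
    out[g[r], idx[r], 1] <- out[g[r], idx[r], 1] + 1
    out[g[r], idx[r], 2] <- out[g[r], idx[r], 2] + cells$volume_fl[r]
    out[g[r], idx[r], 3] <- out[g[r], idx[r], 3] + cells$volume_fl[r]^2
  }
  out
}

# first index b such that flag[b] is TRUE and flag[b..n] holds with at most
# one FALSE
first_persistent <- function(flag) {
  n <- length(flag)
  for (b in seq_len(n)) {
    if (!flag[b]) next
    if (sum(!flag[b:n]) <= 1) return(b)
  }
  NA_integer_
}
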