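#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

#' Trapezoidal integral
#' @param x,y numeric vectors of equal length, `x` sorted increasing.
#' @return scalar integral of `y dx`.
#' @export
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Cumulative trapezoidal integral, same length as input, starting at 0.
#' @param x,y numeric vectors of equal length, `x` sorted increasing.
#' @export
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# Evaluate the change of RNG state in a local, restorable scope so that
# helper draws (e.g. a cached bootstrap null) do not disturb the caller's
# random stream.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable 32-bit sub-seed derived from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  u <- as.numeric(seed) %% 2147480009
  for (ch in utf8ToInt(as.character(stream)))
    u <- (u * 31 + ch) %% 2147480009
  as.integer(u)
}

# MD5 of an R object's JSON rendering (provenance hash for configs).
config_hash <- function(obj) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10, force = TRUE), f)
  unname(tools::md5sum(f))
}

is_uniform_grid <- function(x, tol = 1e-8) {
  d <- diff(x)
  length(d) > 0 && all(abs(d - d[1]) <= tol * max(abs(d[1]), 1e-300))
}
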