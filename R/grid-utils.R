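# Numerical helpers for grid-represented densities. All integrals are
# trapezoidal, with partial end cells handled by linear interpolation of the
# density so that interval masses are O(h^2) accurate, not O(h).

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoidal integral, same length as x, starting at 0.
trapz_cum <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Linear interpolation of a grid density; zero outside the grid.
interp_density <- function(grid, density, at) {
  out <- numeric(length(at))
  inside <- at >= grid[1] & at <= grid[length(grid)]
  if (any(inside)) {
    out[inside] <- stats::approx(grid, density, xout = at[inside])$y
  }
  out
}

# Mass of the density over [a, b], clipped to the grid support. Interior
# cells by trapezoid; the two partial end cells use interpolated densities.
grid_mass <- function(grid, density, a, b) {
  if (b <= a) return(0)
  lo <- max(a, grid[1])
  hi <- min(b, grid[length(grid)])
  if (hi <= lo) return(0)
  cdf <- trapz_cum(grid, density)
  mass_to <- function(q) {
    i <- findInterval(q, grid)
    if (i >= length(grid)) return(cdf[length(grid)])
    d_q <- density[i] + (density[i + 1] - density[i]) *
      (q - grid[i]) / (grid[i + 1] - grid[i])
    cdf[i] + (q - grid[i]) * (density[i] + d_q) / 2
  }
  mass_to(hi) - mass_to(lo)
}

# Seed handling: run code under a given RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible 31-bit seed for one simulation replicate
#'
#' Deterministic polynomial string hash (Horner scheme, base 31, modulo
#' 2^31 - 1) of the base seed and the cell coordinates, so that any single
#' replicate of the Monte-Carlo study can be regenerated in isolation and
#' results do not depend on the order in which cells are executed. All
#' arithmetic stays below 2^53, so the hash is exact in double precision.
#'
#' @param base_seed integer seed of the whole study.
#' @param setting_name character, name of the effect setting.
#' @param n per-group sample size.
#' @param epsilon noise standard deviation.
#' @param prior_label character, label of the Cauchy prior.
#' @param k replicate number (1-based).
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, setting_name, n, epsilon, prior_label, k) {
  key <- paste(base_seed, setting_name, n, format(epsilon), prior_label, k,
               sep = "|")
  h <- 7
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
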