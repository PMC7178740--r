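#' Significance rules for the index panel
#'
#' Decision thresholds applied to each index by [decide_significance()]:
#' `BF10 >= bf_threshold`; Welch and MAP-based p-values `< alpha`; e-value
#' against H0 `> ev_threshold`; posterior "completely outside" the ROPE
#' `[rope_low, rope_high]` operationalized as inside-mass
#' `<= outside_tolerance` (an exact grid density of a Cauchy-tailed
#' posterior never has literally zero ROPE mass; the default 2.5e-4 is less
#' than one draw in 4000 of a draw-based rule); the probability of
#' direction counts as 1 (or 0) when the minority-side mass is
#' `<= outside_tolerance`.
#'
#' @param bf_threshold Bayes factor cutoff (default 3, moderate evidence).
#' @param alpha significance level for the p-values (default 0.05).
#' @param ev_threshold e-value cutoff (default 0.95).
#' @param rope_low,rope_high ROPE bounds on the delta scale (default
#'   `c(-0.1, 0.1)`, half of a small effect).
#' @param outside_tolerance numeric in `[0, 1]`, see above.
#' @return a list of class `significance_rules`.
#' @export
significance_rules <- function(bf_threshold = 3, alpha = 0.05,
                               ev_threshold = 0.95,
                               rope_low = -0.1, rope_high = 0.1,
                               outside_tolerance = 2.5e-4) {
  stopifnot(rope_low < 0, rope_high > 0, bf_threshold > 0,
            alpha > 0, alpha < 1, ev_threshold > 0, ev_threshold < 1,
            outside_tolerance >= 0, outside_tolerance <= 1)
  structure(list(bf_threshold = bf_threshold, alpha = alpha,
                 ev_threshold = ev_threshold,
                 rope_low = rope_low, rope_high = rope_high,
                 outside_tolerance = outside_tolerance),
            class = "significance_rules")
}

#' Highest posterior density interval of a grid posterior
#'
#' Waterline construction: the density threshold is bisected until the
#' super-level set captures the requested mass; for the unimodal posteriors
#' of the JZS model that set is a single interval, whose endpoints are
#' located by linear interpolation of the density across the waterline.
#'
#' @param post a [delta_posterior()] (or any object with `grid`/`density`).
#' @param level coverage in (0, 1), e.g. 0.95.
#' @return numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(post, level = 0.95) {
  stopifnot(level > 0, level < 1)
  g <- post$grid; d <- post$density
  cdf <- trapz_cum(g, d)
  total <- cdf[length(cdf)]
  # mass of [a, b] from the precomputed CDF with interpolated partial cells
  mass_to <- function(q) {
    i <- findInterval(q, g)
    if (i >= length(g)) return(total)
    d_q <- d[i] + (d[i + 1] - d[i]) * (q - g[i]) / (g[i + 1] - g[i])
    cdf[i] + (q - g[i]) * (d[i] + d_q) / 2
  }
  endpoints <- function(c0) {
    above <- d > c0
    k <- which(above)
    if (!length(k)) return(NULL)
    i1 <- k[1]; i2 <- k[length(k)]
    if (i2 - i1 + 1L != length(k))
      stop("non-interval HPD: posterior is multimodal")
    lo <- if (i1 == 1) g[1] else
      g[i1 - 1] + (g[i1] - g[i1 - 1]) * (c0 - d[i1 - 1]) / (d[i1] - d[i1 - 1])
    hi <- if (i2 == length(g)) g[length(g)] else
      g[i2] + (g[i2 + 1] - g[i2]) * (d[i2] - c0) / (d[i2] - d[i2 + 1])
    c(lo, hi)
  }
  lo_c <- 0; hi_c <- max(d)
  for (i in 1:50) {
    mid <- (lo_c + hi_c) / 2
    ep <- endpoints(mid)
    mass <- if (is.null(ep)) 0 else (mass_to(ep[2]) - mass_to(ep[1])) / total
    if (mass >= level) lo_c <- mid else hi_c <- mid
  }
  endpoints(lo_c)
}

#' Proportion of the 95% HPD interval's mass inside the ROPE
#'
#' The mass of the intersection of the `level` HPD interval with the ROPE,
#' divided by `level` — the convention of draw-based ROPE tooling, where
#' the denominator is the nominal HPD coverage. Set
#' `denominator = "captured"` to divide by the mass the HPD interval
#' actually captured instead.
#'
#' @param post a [delta_posterior()].
#' @param rules a [significance_rules()].
#' @param level HPD coverage (default 0.95).
#' @param denominator `"nominal"` (divide by `level`) or `"captured"`.
#' @return fraction in `[0, 1]`.
#' @export
rope_fraction_95 <- function(post, rules = significance_rules(),
                             level = 0.95,
                             denominator = c("nominal", "captured")) {
  denominator <- match.arg(denominator)
  hpd <- hpd_interval(post, level)
  inter <- grid_mass(post$grid, post$density,
                     max(hpd[1], rules$rope_low), min(hpd[2], rules$rope_high))
  den <- if (denominator == "nominal") level
         else grid_mass(post$grid, post$density, hpd[1], hpd[2])
  min(1, inter / den)
}

#' Posterior mass inside the ROPE (full-posterior version)
#'
#' @param post a [delta_posterior()].
#' @param rules a [significance_rules()].
#' @return fraction in `[0, 1]`.
#' @export
rope_fraction_full <- function(post, rules = significance_rules()) {
  min(1, grid_mass(post$grid, post$density, rules$rope_low, rules$rope_high))
}

#' Probability of direction
#'
#' The posterior mass sharing the sign of the posterior median: with
#' `q = P(delta > 0 | x)`, returns `max(q, 1 - q)`, so the index lives in
#' `[0.5, 1]`.
#'
#' @param post a [delta_posterior()].
#' @return numeric in `[0.5, 1]`.
#' @export
probability_of_direction <- function(post) {
  total <- trapz(post$grid, post$density)
  q <- grid_mass(post$grid, post$density, 0, post$grid[length(post$grid)]) / total
  max(q, 1 - q)
}

#' MAP-based p-value
#'
#' Ratio of the posterior density at the null value `delta = 0` to the
#' density at the maximum a posteriori value. The MAP is located by grid
#' argmax refined with three-point quadratic interpolation; the density at
#' zero by linear interpolation.
#'
#' @param post a [delta_posterior()].
#' @return numeric in (0, 1].
#' @export
map_based_p_value <- function(post) {
  g <- post$grid; d <- post$density
  i <- which.max(d)
  d_map <- d[i]
  if (i > 1 && i < length(g)) {
    # quadratic through the three points around the argmax
    denom <- d[i - 1] - 2 * d[i] + d[i + 1]
    if (denom < 0) {
      s <- 0.5 * (d[i - 1] - d[i + 1]) / denom
      d_map <- d[i] - 0.25 * (d[i - 1] - d[i + 1]) * s
    }
  }
  d0 <- interp_density(g, d, 0)
  min(1, d0 / d_map)
}

#' FBST e-value against the point null
#'
#' Full Bayesian Significance Test for `H0: delta = 0`. The surprise
#' function is `s(delta) = p(delta | x) / r(delta)` with reference density
#' `r` either flat (`r ∝ 1`, so the surprise is the posterior itself) or
#' the Cauchy prior stored in the posterior. With `s* = s(0)`, the e-value
#' against H0, `ev_bar`, is the posterior mass of the tangential set
#' `{delta : s(delta) > s*}`, integrated on the grid with the set's
#' boundary crossings located by linear interpolation; `ev = 1 - ev_bar`
#' supports H0.
#'
#' @param post a [delta_posterior()].
#' @param reference `"flat"` or `"cauchy"`.
#' @return list of class `evalue_result`: `ev_bar`, `ev`, `s_star`,
#'   `reference`.
#' @export
fbst_evalue <- function(post, reference = c("flat", "cauchy")) {
  reference <- match.arg(reference)
  g <- post$grid; d <- post$density
  s <- if (reference == "flat") d else d / stats::dcauchy(g, 0, post$prior$r)
  s0 <- if (reference == "flat") interp_density(g, d, 0) else {
    interp_density(g, d, 0) / stats::dcauchy(0, 0, post$prior$r)
  }
  if (!is.finite(s0)) stop("surprise at the null value is not finite")
  total <- trapz(g, d)
  # mass of {s > s0}: trapezoid over full interior cells plus linearly
  # interpolated partial cells at each boundary crossing of s - s0
  excess <- s - s0
  n <- length(g)
  il <- excess[-n] > 0; ir <- excess[-1] > 0
  h <- g[-1] - g[-n]; dl <- d[-n]; dr <- d[-1]
  both <- il & ir
  mass <- sum(h[both] * (dl[both] + dr[both])) / 2
  cr <- which(il != ir)
  if (length(cr)) {
    frac <- excess[cr] / (excess[cr] - excess[cr + 1])  # crossing position
    dc <- dl[cr] + frac * (dr[cr] - dl[cr])
    enter <- il[cr]  # TRUE: cell starts inside, crossing exits the set
    mass <- mass +
      sum((frac * h[cr] * (dl[cr] + dc) / 2)[enter]) +
      sum(((1 - frac) * h[cr] * (dc + dr[cr]) / 2)[!enter])
  }
  ev_bar <- min(1, max(0, mass / total))
  structure(list(ev_bar = ev_bar, ev = 1 - ev_bar, s_star = s0,
                 reference = reference),
            class = "evalue_result")
}

#' Compute the full index panel for one dataset pair
#'
#' Runs the sufficiency reduction, the JZS Bayes factor, the grid posterior
#' and all six posterior indices plus the Welch reference p-value, and
#' returns them as one flat record.
#'
#' @param x,y numeric vectors of group observations.
#' @param prior a [prior_spec()].
#' @param rules a [significance_rules()].
#' @param n_grid_points grid size passed to [delta_posterior()].
#' @return one-row [tibble::tibble()] of class `index_panel` with columns
#'   `bf10`, `rope95`, `rope_full`, `pd`, `p_map`, `ev_bar_flat`,
#'   `ev_bar_cauchy`, `p_welch`.
#' @examples
#' index_panel(rnorm(15), rnorm(15, 1), prior_spec("wide"))
#' @export
index_panel <- function(x, y, prior = prior_spec("wide"),
                        rules = significance_rules(),
                        n_grid_points = 4001L) {
  ts <- pooled_t(x, y)
  post <- delta_posterior(ts, prior, n_grid_points)
  panel_from_posterior(post, rules, p_welch = welch_p_value(x, y))
}

# Panel from an already-built posterior; used by the simulation engine so
# the posterior is constructed exactly once per replicate.
panel_from_posterior <- function(post, rules, p_welch) {
  out <- tibble::tibble(
    bf10 = jzs_bf10(post$t_summary, post$prior),
    rope95 = rope_fraction_95(post, rules),
    rope_full = rope_fraction_full(post, rules),
    pd = probability_of_direction(post),
    p_map = map_based_p_value(post),
    ev_bar_flat = fbst_evalue(post, "flat")$ev_bar,
    ev_bar_cauchy = fbst_evalue(post, "cauchy")$ev_bar,
    p_welch = p_welch
  )
  class(out) <- c("index_panel", class(out))
  out
}

#' Significance decision for every index of a panel
#'
#' Applies the [significance_rules()] thresholds: `bf10 >=` threshold
#' (non-strict); both ROPE rules call significance when the inside mass is
#' at most `outside_tolerance`; PD when the minority-side mass is at most
#' `outside_tolerance`; MAP-based and Welch p-values strictly below
#' `alpha`; each e-value strictly above `ev_threshold`.
#'
#' @param panel an [index_panel()].
#' @param rules a [significance_rules()].
#' @return named logical vector over the eight indices.
#' @export
decide_significance <- function(panel, rules = significance_rules()) {
  c(bf10 = panel$bf10 >= rules$bf_threshold,
    rope95 = panel$rope95 <= rules$outside_tolerance,
    rope_full = panel$rope_full <= rules$outside_tolerance,
    pd = (1 - panel$pd) <= rules$outside_tolerance,
    p_map = panel$p_map < rules$alpha,
    ev_bar_flat = panel$ev_bar_flat > rules$ev_threshold,
    ev_bar_cauchy = panel$ev_bar_cauchy > rules$ev_threshold,
    p_welch = panel$p_welch < rules$alpha)
}

index_names <- function() {
  c("bf10", "rope95", "rope_full", "pd", "p_map",
    "ev_bar_flat", "ev_bar_cauchy", "p_welch")
}
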