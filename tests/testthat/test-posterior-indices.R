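test_that("HPD interval matches normal quantiles and is symmetric", {
  post <- gaussian_grid_posterior(0, 1)
  hpd <- hpd_interval(post, 0.95)
  expect_equal(hpd[1], -1.959964, tolerance = 0.01)
  expect_equal(hpd[2], 1.959964, tolerance = 0.01)
  expect_lt(abs(hpd[1] + hpd[2]), 1e-6)
  # intervals are nested and widen towards the support as level -> 1
  mid <- hpd_interval(post, 0.999)
  wide <- hpd_interval(post, 1 - 1e-12)
  expect_lt(mid[1], hpd[1]); expect_gt(mid[2], hpd[2])
  expect_lt(wide[1], -6.5); expect_gt(wide[2], 6.5)
  expect_gte(wide[1], post$grid[1]); expect_lte(wide[2], post$grid[length(post$grid)])
  # multimodal density is refused
  g <- seq(-6, 6, length.out = 4001)
  bimodal <- grid_posterior(g, dnorm(g, -3, 0.3) + dnorm(g, 3, 0.3))
  expect_error(hpd_interval(bimodal, 0.5), "multimodal")
})

test_that("ROPE fractions agree with Gaussian closed forms", {
  rules <- significance_rules()
  # posterior well inside the ROPE
  tight <- gaussian_grid_posterior(0, 0.01)
  expect_equal(rope_fraction_full(tight, rules), 1, tolerance = 1e-6)
  expect_equal(rope_fraction_95(tight, rules), 1, tolerance = 1e-3)
  # HPD disjoint from the ROPE
  far <- gaussian_grid_posterior(10, 0.1)
  expect_equal(rope_fraction_95(far, rules), 0)
  expect_lt(rope_fraction_full(far, rules), 1e-12)
  # N(0, 0.05): full-ROPE mass over [-0.1, 0.1] is 2*Phi(2) - 1
  mid <- gaussian_grid_posterior(0, 0.05)
  expect_equal(rope_fraction_full(mid, rules), 2 * pnorm(2) - 1,
               tolerance = 1e-3)
  # 95% HPD of N(0, 0.05) is within [-0.1, 0.1] except the 1.96-2 sliver;
  # closed form: mass(HPD intersect ROPE) / 0.95 = 0.95 / 0.95 = 1 only if
  # HPD inside ROPE; here HPD = +/-0.098 entirely inside -> fraction 1
  expect_equal(rope_fraction_95(mid, rules), 1, tolerance = 1e-3)
  # denominator convention toggle
  expect_equal(rope_fraction_95(mid, rules, denominator = "captured"), 1,
               tolerance = 1e-3)
})

test_that("probability of direction matches Gaussian closed forms", {
  expect_equal(probability_of_direction(gaussian_grid_posterior(0, 1)), 0.5,
               tolerance = 1e-6)
  expect_equal(probability_of_direction(gaussian_grid_posterior(1, 0.5)),
               pnorm(2), tolerance = 1e-3)
  expect_equal(probability_of_direction(gaussian_grid_posterior(-1, 0.5)),
               pnorm(2), tolerance = 1e-3)
  # all mass on one side
  expect_equal(probability_of_direction(gaussian_grid_posterior(-50, 1)), 1)
})

test_that("MAP-based p-value matches Gaussian closed forms", {
  expect_equal(map_based_p_value(gaussian_grid_posterior(0, 0.5)), 1,
               tolerance = 1e-6)
  expect_equal(map_based_p_value(gaussian_grid_posterior(1, 0.5)), exp(-2),
               tolerance = 1e-3)
  # definitional bound: in (0, 1]
  for (m in c(-3, -0.4, 0.2, 5)) {
    p <- map_based_p_value(gaussian_grid_posterior(m, 0.7))
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("FBST e-value matches Gaussian closed forms and its identities", {
  # MAP exactly at 0: empty tangential set
  ev0 <- fbst_evalue(gaussian_grid_posterior(0, 0.5), "flat")
  expect_equal(ev0$ev_bar, 0, tolerance = 1e-6)
  expect_equal(ev0$ev, 1, tolerance = 1e-6)
  # N(1, 0.5): tangential set (0, 2), mass 2*Phi(2) - 1
  ev1 <- fbst_evalue(gaussian_grid_posterior(1, 0.5), "flat")
  expect_equal(ev1$ev_bar, 2 * pnorm(2) - 1, tolerance = 1e-3)
  # ev + ev_bar = 1 exactly, for both references
  post <- delta_posterior(pooled_t(rnorm(8), rnorm(8, 1)), prior_spec("wide"))
  for (ref in c("flat", "cauchy")) {
    ev <- fbst_evalue(post, ref)
    expect_identical(ev$ev + ev$ev_bar, 1)
  }
})

test_that("flat-reference e-value is invariant to rescaling the density", {
  g <- seq(-5, 7, length.out = 4001)
  d <- dnorm(g, 1.2, 0.8)
  a <- fbst_evalue(grid_posterior(g, d), "flat")$ev_bar
  b <- fbst_evalue(grid_posterior(g, 17.3 * d), "flat")$ev_bar
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("indices are stable under grid refinement", {
  ts <- pooled_t(c(-0.2, 0.1, 0.3, -0.1), c(1.1, 0.9, 1.4, 1.0))
  p1 <- delta_posterior(ts, prior_spec("wide"), 4001L)
  p2 <- delta_posterior(ts, prior_spec("wide"), 8001L)
  expect_lt(abs(map_based_p_value(p1) - map_based_p_value(p2)), 1e-4)
  expect_lt(abs(probability_of_direction(p1) - probability_of_direction(p2)),
            1e-4)
})

test_that("shifting a fixed-shape posterior away from 0 orders the indices", {
  rules <- significance_rules()
  shifts <- seq(0, 3, by = 0.5)
  posts <- lapply(shifts, gaussian_grid_posterior, sd = 0.5)
  rope <- vapply(posts, rope_fraction_full, numeric(1), rules = rules)
  pmap <- vapply(posts, map_based_p_value, numeric(1))
  pd <- vapply(posts, probability_of_direction, numeric(1))
  evb <- vapply(posts, function(p) fbst_evalue(p, "flat")$ev_bar, numeric(1))
  expect_true(all(diff(rope) <= 1e-12))
  expect_true(all(diff(pmap) <= 1e-12))
  expect_true(all(diff(pd) >= -1e-12))
  expect_true(all(diff(evb) >= -1e-12))
})

test_that("significance decisions implement the stated thresholds", {
  rules <- significance_rules()
  panel <- tibble::tibble(
    bf10 = 3, rope95 = 0.001, rope_full = 1e-4, pd = 0.99,
    p_map = 0.05, ev_bar_flat = 0.95, ev_bar_cauchy = 0.951,
    p_welch = 0.049)
  dec <- decide_significance(panel, rules)
  expect_true(dec[["bf10"]])        # >= 3 is significant (non-strict)
  expect_false(dec[["rope95"]])     # 0.001 > tolerance 2.5e-4
  expect_true(dec[["rope_full"]])   # 1e-4 <= tolerance
  expect_false(dec[["pd"]])         # PD = 0.99 is not PD = 1
  expect_false(dec[["p_map"]])      # strict <
  expect_false(dec[["ev_bar_flat"]])   # strict >
  expect_true(dec[["ev_bar_cauchy"]])
  expect_true(dec[["p_welch"]])
  # PD at exactly 1 - tolerance counts as directional
  panel$pd <- 1 - rules$outside_tolerance
  expect_true(decide_significance(panel, rules)[["pd"]])
})

test_that("full-ROPE significance implies 95%-ROPE significance", {
  rules <- significance_rules()
  set.seed(11)
  cases <- c(lapply(runif(10, -4, 4), gaussian_grid_posterior,
                    sd = runif(1, 0.05, 1)),
             lapply(1:5, function(i) {
               ts <- pooled_t(rnorm(10), rnorm(10, runif(1, 0, 2)))
               delta_posterior(ts, prior_spec("wide"))
             }))
  for (post in cases) {
    panel <- tibble::tibble(
      bf10 = 1, rope95 = rope_fraction_95(post, rules),
      rope_full = rope_fraction_full(post, rules),
      pd = probability_of_direction(post),
      p_map = map_based_p_value(post),
      ev_bar_flat = 0, ev_bar_cauchy = 0, p_welch = 1)
    dec <- decide_significance(panel, rules)
    if (dec[["rope_full"]]) expect_true(dec[["rope95"]])
  }
})

test_that("significance_rules validates its fields", {
  expect_error(significance_rules(rope_low = 0.1))
  expect_error(significance_rules(alpha = 0))
  expect_error(significance_rules(outside_tolerance = 2))
})
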