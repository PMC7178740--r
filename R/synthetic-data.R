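#' Two-group Gaussian effect setting
#'
#' A data-generating process for a two-group comparison: group 1 is
#' `N(mu1, sigma1^2)`, group 2 is `N(mu2, sigma2^2)` (the second parameter
#' of each normal is a standard deviation). The true standardized effect is
#' computed by [true_effect_size()].
#'
#' @param name short identifier of the setting.
#' @param mu1,sigma1 mean and SD of group 1.
#' @param mu2,sigma2 mean and SD of group 2.
#' @return list of class `effect_setting`, including `delta_true`.
#' @export
effect_setting <- function(name, mu1, sigma1, mu2, sigma2) {
  stopifnot(sigma1 > 0, sigma2 > 0)
  s <- structure(list(name = name, mu1 = mu1, sigma1 = sigma1,
                      mu2 = mu2, sigma2 = sigma2),
                 class = "effect_setting")
  s$delta_true <- true_effect_size(s)
  s
}

#' True standardized effect size of a setting
#'
#' `delta = (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2)` — the mean
#' difference standardized by the root-mean-square of the two group SDs
#' (Cohen's d for heteroscedastic groups).
#'
#' @param setting an [effect_setting()].
#' @return numeric scalar.
#' @examples
#' true_effect_size(effect_setting("small", 2.89, 1.84, 3.5, 1.56))
#' @export
true_effect_size <- function(setting) {
  (setting$mu1 - setting$mu2) /
    sqrt((setting$sigma1^2 + setting$sigma2^2) / 2)
}

#' The four built-in simulation settings
#'
#' The study conditions of the Monte-Carlo comparison: `null` draws both
#' groups from the standard normal (delta = 0); `small` compares
#' `N(2.89, 1.84)` with `N(3.5, 1.56)` (delta ~ -0.357); `medium` compares
#' `N(254.08, 2.36)` with `N(255.84, 3.04)` (delta ~ -0.646); `large`
#' compares `N(15.01, 3.4)` with `N(19.91, 5.8)` (delta ~ -1.03). Group 1
#' always has the smaller mean, so all true effects are negative.
#'
#' @return named list of four [effect_setting()] objects.
#' @export
builtin_settings <- function() {
  list(
    null   = effect_setting("null",   0,      1,    0,      1),
    small  = effect_setting("small",  2.89,   1.84, 3.5,    1.56),
    medium = effect_setting("medium", 254.08, 2.36, 255.84, 3.04),
    large  = effect_setting("large",  15.01,  3.4,  19.91,  5.8)
  )
}

#' @export
print.effect_setting <- function(x, ...) {
  cat(sprintf("%s: N(%g, %g^2) vs N(%g, %g^2), delta = %.4f\n",
              x$name, x$mu1, x$sigma1, x$mu2, x$sigma2, x$delta_true))
  invisible(x)
}

#' Generate one two-group dataset from a setting
#'
#' Draws `n` observations per group from the setting's normals and, if
#' `epsilon > 0`, adds independent `N(0, epsilon^2)` measurement noise to
#' every observation (`epsilon` is a standard deviation). Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param setting an [effect_setting()].
#' @param n per-group sample size (>= 2).
#' @param epsilon noise SD (>= 0).
#' @param seed integer seed.
#' @return list with numeric vectors `x` (group 1) and `y` (group 2).
#' @export
generate_pair <- function(setting, n, epsilon = 0, seed) {
  stopifnot(inherits(setting, "effect_setting"), n >= 2, epsilon >= 0)
  with_seed(seed, {
    x <- stats::rnorm(n, setting$mu1, setting$sigma1)
    y <- stats::rnorm(n, setting$mu2, setting$sigma2)
    if (epsilon > 0) {
      x <- x + stats::rnorm(n, 0, epsilon)
      y <- y + stats::rnorm(n, 0, epsilon)
    }
    list(x = x, y = y)
  })
}
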