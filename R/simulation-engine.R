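#' Configuration of the Monte-Carlo study
#'
#' The full study crosses every effect setting with a grid of per-group
#' sample sizes at zero noise and, separately, with a grid of noise SDs at
#' fixed `n = 30`, under each Cauchy prior. Defaults are the study
#' conditions: `n` from 10 to 100 in steps of 10, `epsilon` from 0.5 to 5
#' in steps of 0.5, priors medium/wide/ultrawide, 10000 replicates per
#' cell.
#'
#' @param settings list of [effect_setting()]s.
#' @param n_grid integer vector of per-group sample sizes.
#' @param epsilon_grid numeric vector of noise SDs (run at `n = noise_n`).
#' @param noise_n per-group sample size of the noise arm.
#' @param priors list of [prior_spec()]s.
#' @param reps replicates per cell.
#' @param base_seed integer seed of the study.
#' @param rules a [significance_rules()].
#' @param n_grid_points posterior grid size per replicate (default 2001 for
#'   the simulation arm; single-dataset analyses default to 4001).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(settings = builtin_settings(),
                              n_grid = seq(10L, 100L, by = 10L),
                              epsilon_grid = seq(0.5, 5, by = 0.5),
                              noise_n = 30L,
                              priors = list(prior_spec("medium"),
                                            prior_spec("wide"),
                                            prior_spec("ultrawide")),
                              reps = 10000L,
                              base_seed = 1L,
                              rules = significance_rules(),
                              n_grid_points = 2001L) {
  stopifnot(reps >= 1, length(n_grid) >= 1 || length(epsilon_grid) >= 1)
  structure(list(settings = settings, n_grid = as.integer(n_grid),
                 epsilon_grid = epsilon_grid, noise_n = as.integer(noise_n),
                 priors = priors, reps = as.integer(reps),
                 base_seed = as.integer(base_seed), rules = rules,
                 n_grid_points = as.integer(n_grid_points)),
            class = "simulation_config")
}

#' Run one Monte-Carlo cell
#'
#' Simulates `reps` dataset pairs from one (setting, n, epsilon, prior)
#' cell, computes the full index panel and the significance decision for
#' every replicate, and aggregates the proportion of significant calls per
#' index with its binomial Monte-Carlo standard error. Replicate `k` uses
#' the seed [derive_seed()]`(base_seed, ...)`, so every replicate is
#' reproducible in isolation and cell order is irrelevant. A replicate
#' whose computation fails is redrawn once with an offset seed; failures
#' are counted and must stay below 0.1% of `reps`.
#'
#' @param setting an [effect_setting()].
#' @param n per-group sample size.
#' @param epsilon noise SD.
#' @param prior a [prior_spec()].
#' @param reps number of replicates.
#' @param base_seed integer study seed.
#' @param rules a [significance_rules()].
#' @param n_grid_points posterior grid size.
#' @param keep_panels if `TRUE`, return the per-replicate panels too.
#' @return list with elements `rates` (tibble: setting, n, epsilon, prior,
#'   index, proportion_significant, reps, mc_se, failures) and `panels`
#'   (tibble or `NULL`).
#' @export
run_cell <- function(setting, n, epsilon, prior, reps, base_seed,
                     rules = significance_rules(), n_grid_points = 2001L,
                     keep_panels = FALSE) {
  hits <- stats::setNames(numeric(length(index_names())), index_names())
  panels <- if (keep_panels) vector("list", reps) else NULL
  failures <- 0L
  for (k in seq_len(reps)) {
    seed_k <- derive_seed(base_seed, setting$name, n, epsilon, prior$label, k)
    panel <- tryCatch(
      one_replicate(setting, n, epsilon, prior, seed_k, rules, n_grid_points),
      error = function(e) e
    )
    if (inherits(panel, "error")) {
      failures <- failures + 1L
      message(sprintf("replicate %d (seed %d) failed: %s; redrawing",
                      k, seed_k, conditionMessage(panel)))
      seed_f <- derive_seed(base_seed, setting$name, n, epsilon,
                            prior$label, k + 1000000L)
      panel <- one_replicate(setting, n, epsilon, prior, seed_f, rules,
                             n_grid_points)
    }
    hits <- hits + decide_significance(panel, rules)
    if (keep_panels) panels[[k]] <- panel
  }
  if (failures > 0.001 * reps)
    stop("numerical failure budget exceeded: ", failures, " of ", reps)
  p <- hits / reps
  rates <- tibble::tibble(
    setting = setting$name, n = as.integer(n), epsilon = epsilon,
    prior = prior$label, index = index_names(),
    proportion_significant = unname(p), reps = as.integer(reps),
    mc_se = unname(sqrt(p * (1 - p) / reps)), failures = failures
  )
  list(rates = rates,
       panels = if (keep_panels) dplyr::bind_rows(panels) else NULL)
}

one_replicate <- function(setting, n, epsilon, prior, seed, rules,
                          n_grid_points) {
  pair <- generate_pair(setting, n, epsilon, seed)
  ts <- pooled_t(pair$x, pair$y)
  post <- delta_posterior(ts, prior, n_grid_points)
  panel_from_posterior(post, rules, p_welch = welch_p_value(pair$x, pair$y))
}

#' Run the full Monte-Carlo grid
#'
#' Concatenates [run_cell()] over every (setting, n, prior) cell of the
#' sample-size arm (`epsilon = 0`) and every (setting, epsilon, prior) cell
#' of the noise arm (at `n = noise_n`). Cell results depend only on the
#' per-replicate seeds, never on execution order.
#'
#' @param config a [simulation_config()].
#' @param progress emit one progress line per cell to standard error.
#' @return a `RateTable` tibble (one row per setting/n/epsilon/prior/index).
#' @export
run_grid <- function(config, progress = interactive()) {
  cells <- grid_cells(config)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s <- config$settings[[cells$setting[i]]]
    pr <- config$priors[[cells$prior_idx[i]]]
    t0 <- Sys.time()
    out[[i]] <- run_cell(s, cells$n[i], cells$epsilon[i], pr, config$reps,
                         config$base_seed, config$rules,
                         config$n_grid_points)$rates
    if (progress)
      message(sprintf("cell %d/%d (%s, n=%d, eps=%.1f, %s): %.1fs, %d failures",
                      i, nrow(cells), s$name, cells$n[i], cells$epsilon[i],
                      pr$label, as.numeric(Sys.time() - t0, units = "secs"),
                      out[[i]]$failures[1]))
  }
  dplyr::bind_rows(out)
}

grid_cells <- function(config) {
  setts <- names(config$settings)
  pr <- seq_along(config$priors)
  a <- expand.grid(setting = setts, n = config$n_grid, epsilon = 0,
                   prior_idx = pr, stringsAsFactors = FALSE)
  b <- if (length(config$epsilon_grid))
    expand.grid(setting = setts, n = config$noise_n,
                epsilon = config$epsilon_grid, prior_idx = pr,
                stringsAsFactors = FALSE)
  else NULL
  rbind(a, b)
}

#' Pivot a rate table into an index-by-n (or index-by-epsilon) report
#'
#' For each effect setting, spreads the proportions into a matrix-style
#' tibble with one row per index and one column per sample size (or noise
#' level, for the noise arm), mirroring the layout of a type-I
#' error/sensitivity table.
#'
#' @param rates a tibble from [run_grid()] or [run_cell()].
#' @param arm `"n"` (sample-size arm) or `"epsilon"` (noise arm).
#' @return named list of tibbles, one per setting.
#' @export
summarize_rates <- function(rates, arm = c("n", "epsilon")) {
  arm <- match.arg(arm)
  sub <- if (arm == "n") rates[rates$epsilon == 0, ]
         else rates[rates$epsilon > 0, ]
  split_by <- split(sub, sub$setting)
  lapply(split_by, function(d) {
    d$index <- factor(d$index, levels = index_names())
    d <- d[order(d$index, d[[arm]]), c("index", arm, "proportion_significant")]
    tidyr::pivot_wider(
      d,
      names_from = dplyr::all_of(arm),
      values_from = "proportion_significant",
      names_prefix = paste0(arm, "=")
    )
  })
}
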