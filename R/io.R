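#' Read a two-group dataset from a long-format delimited file
#'
#' Expects one numeric value column and one two-level group column. The
#' group whose level appears first in the file becomes group 1 (the `x`
#' vector); the mapping is attached as the `"groups"` attribute so users
#' can flip the sign convention of the effect size if needed. The delimiter
#' is inferred from the file extension (`.tsv` -> tab, otherwise comma).
#'
#' @param path file path.
#' @param value_col name of the numeric value column (default `"value"`).
#' @param group_col name of the group column (default `"group"`).
#' @return list with vectors `x`, `y` and attribute `groups` (character
#'   vector of length 2: group-1 level, group-2 level).
#' @export
read_two_group_csv <- function(path, value_col = "value",
                               group_col = "group") {
  if (!file.exists(path)) stop("file not found: ", path)
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE))
    readr::read_tsv else readr::read_csv
  d <- reader(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(value_col, group_col))
    if (!col %in% names(d)) stop("column '", col, "' not found in ", path)
  vals <- d[[value_col]]
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(as.numeric(vals))))[1]
    stop("non-numeric value in column '", value_col, "' at data row ", bad)
  }
  grp <- as.character(d[[group_col]])
  levels <- unique(grp)
  if (length(levels) != 2)
    stop("group column must have exactly 2 levels, found ",
         length(levels), ": ", paste(levels, collapse = ", "))
  x <- vals[grp == levels[1]]
  y <- vals[grp == levels[2]]
  for (i in 1:2) {
    g <- list(x, y)[[i]]
    if (length(g) < 2)
      stop("group ", levels[i], " has fewer than 2 observations")
  }
  structure(list(x = x, y = y), groups = levels)
}

#' Write a two-group dataset as long-format CSV
#'
#' Inverse of [read_two_group_csv()]: group 1 rows first, so a round trip
#' preserves the group-order convention.
#'
#' @param pair list with vectors `x` and `y`.
#' @param path output path.
#' @param groups character vector of the two group labels.
#' @export
write_two_group_csv <- function(pair, path, groups = c("g1", "g2")) {
  d <- tibble::tibble(
    value = c(pair$x, pair$y),
    group = rep(groups, c(length(pair$x), length(pair$y)))
  )
  readr::write_csv(d, path)
  invisible(path)
}

#' Write a rate table (and its reproducibility manifest) to CSV
#'
#' Columns are written in a fixed order at full floating precision. Unless
#' `manifest = NULL`, a YAML manifest recording the configuration snapshot,
#' package version, base seed and per-cell failure counts is written next
#' to the CSV (same path with extension `.manifest.yaml`); re-running the
#' study with the manifest's configuration reproduces the table exactly.
#'
#' @param rates tibble from [run_grid()]/[run_cell()].
#' @param path output CSV path.
#' @param manifest list from [run_manifest()], or `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path, manifest = NULL) {
  cols <- c("setting", "n", "epsilon", "prior", "index",
            "proportion_significant", "reps", "mc_se", "failures")
  cols <- cols[cols %in% names(rates)]
  readr::write_csv(rates[, cols], path)
  if (!is.null(manifest))
    yaml::write_yaml(manifest, sub("\\.csv$", ".manifest.yaml", path))
  invisible(path)
}

#' Write per-replicate index panels to CSV
#'
#' @param panels tibble of [index_panel()] rows.
#' @param path output CSV path.
#' @export
write_panel <- function(panels, path) {
  readr::write_csv(panels, path)
  invisible(path)
}

#' Reproducibility manifest for a simulation run
#'
#' Snapshot of everything needed to regenerate a rate table: configuration
#' fields, package version, base seed, timestamp and the per-cell failure
#' counts observed.
#'
#' @param config a [simulation_config()].
#' @param rates the resulting rate table.
#' @return a list, serializable with [yaml::write_yaml()].
#' @export
run_manifest <- function(config, rates) {
  fail <- unique(rates[, c("setting", "n", "epsilon", "prior", "failures")])
  list(
    package = "btindices",
    version = as.character(utils::packageVersion("btindices")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    base_seed = config$base_seed,
    reps = config$reps,
    n_grid_points = config$n_grid_points,
    n_grid = config$n_grid,
    epsilon_grid = config$epsilon_grid,
    noise_n = config$noise_n,
    priors = vapply(config$priors, function(p) p$label, character(1)),
    settings = lapply(config$settings, function(s)
      list(name = s$name, mu1 = s$mu1, sigma1 = s$sigma1,
           mu2 = s$mu2, sigma2 = s$sigma2, delta_true = s$delta_true)),
    rules = unclass(config$rules),
    failures = apply(fail, 1, function(r) paste(r, collapse = "/"))
  )
}
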