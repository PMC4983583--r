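#' Configure a full pipeline run
#'
#' Either a synthetic scenario ([scenario_config()]) or the three input
#' paths must be supplied, never both.
#'
#' @param scenario Optional [scenario_config()] to simulate inputs.
#' @param leaf_path,census_path,meta_path Optional input CSV paths.
#' @param layers Canopy layers to analyse (each independently); `NULL` =
#'   every layer present in the data.
#' @param nperm Permutations for null models (>= 99).
#' @param alpha Significance level.
#' @param seed Master seed for every stochastic stage.
#' @param outlier_threshold Tree-level LMA variance threshold (g^2 m^-4).
#' @param env_var Plot-metadata column used as the gradient covariate.
#' @param exclude_plots Plots excluded from the gradient regression (still
#'   analysed everywhere else).
#' @param save_null_distributions Keep full null matrices in the result.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, leaf_path = NULL, census_path = NULL,
                       meta_path = NULL, layers = NULL, nperm = 999,
                       alpha = 0.05, seed = 1L, outlier_threshold = 2000,
                       env_var = "elevation", exclude_plots = NULL,
                       save_null_distributions = FALSE) {
  from_files <- !is.null(leaf_path)
  if (is.null(scenario) == !from_files) {
    abort("Supply exactly one of `scenario` or the input paths.")
  }
  if (from_files && (is.null(census_path) || is.null(meta_path))) {
    abort("File input needs `leaf_path`, `census_path` and `meta_path`.")
  }
  if (nperm < 99) abort("nperm must be at least 99.")
  structure(list(scenario = scenario, leaf_path = leaf_path,
                 census_path = census_path, meta_path = meta_path,
                 layers = layers, nperm = as.integer(nperm), alpha = alpha,
                 seed = as.integer(seed),
                 outlier_threshold = outlier_threshold, env_var = env_var,
                 exclude_plots = exclude_plots,
                 save_null_distributions = save_null_distributions),
            class = "run_config")
}

#' Run the full community-assembly pipeline
#'
#' Orchestrates every stage in order: simulate (or read) the input tables,
#' ingest leaves to tree-level traits, community-weighted means and gradient
#' regressions, T-statistics with permutation nulls and SES per canopy
#' layer, nested variance components, the turnover/intraspecific
#' decomposition of CWM variance, and Sorensen/Mantel beta-diversity. Every
#' stochastic stage is seeded from `cfg$seed`, so two runs of the same
#' configuration are identical; the result carries a hash of the
#' configuration for provenance.
#'
#' @param cfg A [run_config()].
#' @return Object of class `assembly_report`: a list with elements `cwm`,
#'   `regressions`, `tstats` (per layer), `nested` (per layer), `turnover`
#'   (per layer), `sorensen`, `env_dist`, `mantel`, `ingest_log`, `plots`,
#'   `config_hash`, `seed`. Use [write_report()] to serialise it.
#' @examples
#' cfg <- run_config(scenario_config(n_plots = 4, pool_size = 15,
#'                                   layers = "sun", seed = 5),
#'                   nperm = 99)
#' rep <- run_pipeline(cfg)
#' rep$regressions
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$scenario)) {
    sim <- simulate_region(cfg$scenario)
    leaves <- sim$leaves; census <- sim$census; meta <- sim$plots
  } else {
    leaves <- read_leaf_table(cfg$leaf_path)
    census <- read_census(cfg$census_path)
    meta <- read_plot_meta(cfg$meta_path)
  }
  check_columns(meta, cfg$env_var, "plot metadata")

  ing <- ingest_leaves(leaves, threshold = cfg$outlier_threshold)
  layers <- cfg$layers %||% sort(unique(ing$trees$layer))

  cwm <- community_weighted_mean(ing$populations, census) |>
    left_join(ing$plots |>
                select("plot_id", "layer", unweighted_mean = "lma",
                       unweighted_sd = "lma_sd"),
              by = c("plot_id", "layer")) |>
    filter(.data$layer %in% layers)

  regressions <- map(layers, function(ly) {
    df <- cwm |>
      filter(.data$layer == ly) |>
      left_join(meta, by = "plot_id") |>
      rename(.env_value = !!rlang::sym(cfg$env_var))
    gradient_regression(df, cwm, .env_value, exclude = cfg$exclude_plots) |>
      mutate(layer = ly, response = "cwm", covariate = cfg$env_var,
             .before = 1)
  }) |> bind_rows()

  ts <- setNames(map(seq_along(layers), function(i) {
    tstats(ing$trees |> filter(.data$layer == layers[i]),
           nperm = cfg$nperm, seed = cfg$seed + (i - 1L) * 100L,
           alpha = cfg$alpha, keep_nulls = cfg$save_null_distributions)
  }), layers)

  nested <- setNames(map(layers, function(ly) {
    dat <- ing$leaves |> filter(.data$layer == ly)
    hier <- intersect(c("plot_id", "family", "genus", "species", "tree_id"),
                      names(dat))
    nested_variance_components(dat, hierarchy = hier)
  }), layers)

  turnover <- setNames(map(layers, function(ly) {
    leps_decomposition(ing$populations |> filter(.data$layer == ly), census)
  }), layers)

  sor <- sorensen_matrix(census)
  envd <- env_distance(meta, cfg$env_var)
  mant <- mantel_test(sor, envd, nperm = cfg$nperm, seed = cfg$seed)

  structure(list(
    cwm = cwm, regressions = regressions, tstats = ts, nested = nested,
    turnover = turnover, sorensen = sor, env_dist = envd, mantel = mant,
    plots = meta,
    ingest_log = list(removed_leaves = ing$removed_leaves,
                      flagged_trees = ing$flagged_trees),
    layers = layers,
    config_hash = rlang::hash(cfg), seed = cfg$seed, nperm = cfg$nperm,
    alpha = cfg$alpha
  ), class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("<assembly_report> seed", x$seed, " hash", x$config_hash, "\n")
  cat("layers:", paste(x$layers, collapse = ", "),
      " plots:", nrow(x$plots), "\n\n")
  cat("CWM ~ gradient:\n"); print(x$regressions)
  cat("\nT-statistics (transect level):\n")
  for (ly in x$layers) {
    cat(" layer", ly, "\n")
    print(glance(x$tstats[[ly]]))
  }
  cat("\nCWM variance decomposition:\n")
  for (ly in x$layers) {
    cat(" layer", ly, "\n"); print(tidy(x$turnover[[ly]]))
  }
  cat("\nMantel (Sorensen vs gradient): r =", round(x$mantel$r, 3),
      " p =", x$mantel$p_value, "\n")
  invisible(x)
}

#' Serialise a pipeline report
#'
#' Writes the per-stage tables as CSVs, the distance matrices as labelled
#' square CSVs, and a machine-readable `summary.json`; every artifact is
#' stamped with the configuration hash and master seed.
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "assembly_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    mutate(df, config_hash = report$config_hash, seed = report$seed)
  }
  readr::write_csv(stamp(report$cwm), file.path(dir, "cwm.csv"))
  readr::write_csv(stamp(report$regressions),
                   file.path(dir, "cwm_regressions.csv"))
  per_plot <- map(report$layers,
                  function(ly) tidy(report$tstats[[ly]]) |>
                    mutate(layer = ly, .before = 1)) |> bind_rows()
  readr::write_csv(stamp(per_plot), file.path(dir, "tstats_per_plot.csv"))
  agg <- map(report$layers,
             function(ly) glance(report$tstats[[ly]]) |>
               mutate(layer = ly, .before = 1)) |> bind_rows()
  readr::write_csv(stamp(agg), file.path(dir, "tstats_transect.csv"))
  nested <- map(report$layers,
                function(ly) tidy(report$nested[[ly]]) |>
                  mutate(layer = ly, .before = 1)) |> bind_rows()
  readr::write_csv(stamp(nested), file.path(dir, "variance_components.csv"))
  turn <- map(report$layers,
              function(ly) as_tibble(report$turnover[[ly]]) |>
                mutate(layer = ly, .before = 1)) |> bind_rows()
  readr::write_csv(stamp(turn), file.path(dir, "cwm_decomposition.csv"))
  write_distance_matrix(report$sorensen, file.path(dir, "sorensen.csv"))
  write_distance_matrix(report$env_dist, file.path(dir, "env_distance.csv"))
  summary <- list(
    config_hash = report$config_hash, seed = report$seed,
    nperm = report$nperm, alpha = report$alpha, layers = report$layers,
    regressions = report$regressions,
    tstats_transect = agg, cwm_decomposition = turn,
    mantel = report$mantel,
    n_removed_leaves = nrow(report$ingest_log$removed_leaves),
    flagged_trees = report$ingest_log$flagged_trees
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

utils::globalVariables(c("cwm", ".env_value"))
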