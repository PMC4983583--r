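#' Parameterise a synthetic trait gradient
#'
#' Bundles every knob of the synthetic-community generator into a validated
#' configuration object. The defaults describe a tropical elevation transect:
#' ten 1-ha plots spanning roughly 200--3500 m, a regional pool of 60 woody
#' species with Gaussian niches along the gradient (so composition turns over
#' strongly between distant plots), and a hierarchical log-normal trait model
#' for leaf mass per area (LMA) with variance stacked at the site, species,
#' population, tree and leaf levels.
#'
#' The trait model is Gaussian on the natural-log scale. A species' trait
#' optimum is `trait_grand_mean + beta_env * opt_s + N(0, sigma_species^2)`,
#' where `opt_s` is its niche position on the gradient. Within a plot, the
#' population mean of an admitted species is pulled toward the plot's trait
#' optimum by the environmental-filter multiplier `gamma_external` (1 = no
#' filtering; values toward 0 squeeze admitted species means together), and
#' the population- and tree-level standard deviations are scaled by the
#' internal-filter multiplier `gamma_internal` (1 = no filtering; values
#' toward 0 make conspecific individuals more similar than random assembly
#' would). Both multipliers may be scalar or per-plot vectors.
#'
#' @param n_plots Number of plots (communities); at least 2.
#' @param env Per-plot gradient value (e.g. elevation in m). Length
#'   `n_plots`; defaults to an even spread over 200--3500 m.
#' @param pool_size Number of species in the regional pool; at least 2.
#' @param niche_width Niche breadth in gradient units; smaller values mean
#'   faster species turnover along the gradient.
#' @param trait_grand_mean Grand mean of log-LMA (log g m^-2).
#' @param sigma_site,sigma_species,sigma_pop,sigma_tree,sigma_leaf Standard
#'   deviations of the site, species, population (species-by-plot), tree and
#'   leaf levels, on the log scale. All must be non-negative.
#' @param beta_env Slope of the species trait optimum against the gradient
#'   (log-LMA per gradient unit).
#' @param gamma_internal,gamma_external Filter multipliers in (0, 1]; scalar
#'   or one value per plot. See Details.
#' @param abundance_shape Log-normal standard deviation of the stochastic
#'   basal-area weights.
#' @param trees_per_species,leaves_per_tree Integer range (length-2 vector)
#'   of trees sampled per species and leaves per tree; default 3--5 each.
#' @param basal_area_target Fraction of plot basal area the sampled dominant
#'   species must reach (default 0.80).
#' @param layers Canopy layers to generate; `"sun"`, or `c("sun", "shade")`.
#' @param shade_offset Additive log-scale offset applied to shade leaves
#'   (negative: shade leaves have lower LMA).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#'
#' @return An object of class `scenario_config` (a named list).
#' @seealso [simulate_region()]
#' @examples
#' cfg <- scenario_config(n_plots = 4, pool_size = 20, seed = 1)
#' cfg$env
#' @export
scenario_config <- function(n_plots = 10,
                            env = NULL,
                            pool_size = 60,
                            niche_width = 400,
                            trait_grand_mean = log(120),
                            sigma_site = 0.10,
                            sigma_species = 0.35,
                            sigma_pop = 0.15,
                            sigma_tree = 0.12,
                            sigma_leaf = 0.10,
                            beta_env = 3e-4,
                            gamma_internal = 1,
                            gamma_external = 1,
                            abundance_shape = 1,
                            trees_per_species = c(3L, 5L),
                            leaves_per_tree = c(3L, 5L),
                            basal_area_target = 0.80,
                            layers = c("sun", "shade"),
                            shade_offset = -0.25,
                            seed = 1L) {
  if (is.null(env)) env <- seq(200, 3500, length.out = n_plots)
  cfg <- list(
    n_plots = as.integer(n_plots), env = as.numeric(env),
    pool_size = as.integer(pool_size), niche_width = niche_width,
    trait_grand_mean = trait_grand_mean,
    sigma_site = sigma_site, sigma_species = sigma_species,
    sigma_pop = sigma_pop, sigma_tree = sigma_tree, sigma_leaf = sigma_leaf,
    beta_env = beta_env,
    gamma_internal = rep_len(gamma_internal, n_plots),
    gamma_external = rep_len(gamma_external, n_plots),
    abundance_shape = abundance_shape,
    trees_per_species = as.integer(trees_per_species),
    leaves_per_tree = as.integer(leaves_per_tree),
    basal_area_target = basal_area_target,
    layers = match.arg(layers, c("sun", "shade"), several.ok = TRUE),
    shade_offset = shade_offset,
    seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$n_plots >= 2, cfg$pool_size >= 2)
  if (length(cfg$env) != cfg$n_plots) {
    abort("`env` must have one value per plot.")
  }
  sigmas <- c(cfg$sigma_site, cfg$sigma_species, cfg$sigma_pop,
              cfg$sigma_tree, cfg$sigma_leaf)
  if (any(sigmas < 0)) abort("All sigma_* values must be >= 0.")
  if (any(cfg$gamma_internal <= 0 | cfg$gamma_internal > 1) ||
      any(cfg$gamma_external <= 0 | cfg$gamma_external > 1)) {
    abort("gamma_internal and gamma_external must lie in (0, 1].")
  }
  if (cfg$basal_area_target <= 0 || cfg$basal_area_target > 1) {
    abort("basal_area_target must lie in (0, 1].")
  }
  if (cfg$niche_width <= 0) abort("niche_width must be > 0.")
  rng <- function(x) length(x) == 2L && all(x >= 1) && x[1] <= x[2]
  if (!rng(cfg$trees_per_species) || !rng(cfg$leaves_per_tree)) {
    abort("trees_per_species and leaves_per_tree must be increasing length-2 integer ranges.")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  plots:", x$n_plots, " gradient:", min(x$env), "-", max(x$env), "\n")
  cat("  pool:", x$pool_size, "species, niche width", x$niche_width, "\n")
  cat("  sigmas (site/species/pop/tree/leaf):",
      paste(c(x$sigma_site, x$sigma_species, x$sigma_pop, x$sigma_tree,
              x$sigma_leaf), collapse = "/"), "\n")
  cat("  gamma_internal:", paste(unique(x$gamma_internal), collapse = ","),
      " gamma_external:", paste(unique(x$gamma_external), collapse = ","), "\n")
  cat("  layers:", paste(x$layers, collapse = "+"), " seed:", x$seed, "\n")
  invisible(x)
}
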