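# Geometry used to split a leaf's target LMA into lamina/petiole masses and
# areas. Recorded in the ground truth so the petiole correction is testable.
leaf_geometry <- function() {
  list(
    petiole_area_frac = 0.05,   # petiole share of whole-leaf fresh area
    petiole_mass_frac = 0.08,   # petiole share of whole-leaf dry mass
    petiole_fresh_dry = 3.0,    # fresh:dry mass ratio of the petiole
    lamina_area_meanlog = log(0.005),  # m^2, typical tropical leaf
    lamina_area_sdlog = 0.4
  )
}

#' Simulate a regional species pool and sampled plot communities
#'
#' Generates leaf-level measurements, a full plot census, and plot metadata
#' for a synthetic environmental gradient with known variance structure and
#' filter strengths, emulating a basal-area-targeted field campaign: within
#' each plot, species are sampled in decreasing order of basal area until the
#' configured coverage target (default 80%) is reached, then 3--5 trees per
#' species and 3--5 leaves per tree (per canopy layer) are measured.
#'
#' All randomness flows from `config$seed`, so a fixed configuration yields
#' bit-identical tables on every run.
#'
#' @param config A [scenario_config()].
#' @return A list of class `region_sim` with elements
#'   \describe{
#'     \item{leaves}{Leaf-measurement tibble (one row per leaf) with lamina
#'       and petiole dry masses, petiole fresh mass, and fresh areas.}
#'     \item{census}{Plot-by-species basal area (m^2 ha^-1) for every species
#'       present, sampled or not, with a `sampled` flag.}
#'     \item{plots}{Plot metadata: gradient value (`elevation`), leaf area
#'       index proxy and vegetation label.}
#'     \item{truth}{Ground truth: the config, species pool with true optima
#'       and means, per-plot site effects and filter strengths, population
#'       and tree-level true values, and the leaf-geometry constants.}
#'   }
#' @examples
#' sim <- simulate_region(scenario_config(n_plots = 3, pool_size = 15, seed = 7))
#' dplyr::count(sim$leaves, plot_id)
#' @export
simulate_region <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  set.seed(config$seed)
  geom <- leaf_geometry()

  plot_ids <- sprintf("P%02d", seq_len(config$n_plots))
  wd <- nchar(as.character(config$pool_size))
  sp_ids <- sprintf("sp%0*d", max(wd, 2L), seq_len(config$pool_size))

  # species pool: niche optimum along the gradient, padded at both ends so
  # edge plots are not pool-starved (pad capped at half the gradient span so
  # very broad niches cannot extrapolate trait optima far off-gradient);
  # genus/family labels nested by construction
  pad <- min(config$niche_width, (max(config$env) - min(config$env)) / 2)
  lo <- min(config$env) - pad
  hi <- max(config$env) + pad
  n_gen <- max(1L, ceiling(config$pool_size / 3))
  genus <- sprintf("g%02d", rep(seq_len(n_gen), each = 3)[seq_len(config$pool_size)])
  family <- sprintf("f%02d", (as.integer(factor(genus)) + 1L) %/% 2L)
  # species trait mean: grand mean + gradient trend at the species' niche
  # position + a species-level deviation
  pool <- tibble(
    species = sp_ids, genus = genus, family = family,
    opt = runif(config$pool_size, lo, hi)
  )
  pool$mu <- config$trait_grand_mean + config$beta_env * pool$opt +
    rnorm(config$pool_size, 0, config$sigma_species)

  plots <- tibble(
    plot_id = plot_ids,
    elevation = config$env,
    site_effect = rnorm(config$n_plots, 0, config$sigma_site),
    plot_optimum = config$trait_grand_mean + config$beta_env * config$env,
    gamma_internal = config$gamma_internal,
    gamma_external = config$gamma_external
  )

  census <- vector("list", config$n_plots)
  pops <- vector("list", config$n_plots)
  leaves <- vector("list", config$n_plots)
  trees_truth <- vector("list", config$n_plots)

  for (k in seq_len(config$n_plots)) {
    pk <- plots[k, ]
    w <- exp(-(pk$elevation - pool$opt)^2 / (2 * config$niche_width^2)) *
      rlnorm(config$pool_size, 0, config$abundance_shape)
    rel <- w / sum(w)
    present <- rel > 1e-6
    if (!any(present)) {
      abort(paste0("Plot ", pk$plot_id,
                   ": no species has positive basal-area weight; ",
                   "basal_area_target is unreachable."))
    }
    ba <- 30 * rel[present] / sum(rel[present])  # scale to 30 m^2 ha^-1
    cen <- tibble(plot_id = pk$plot_id,
                  species = pool$species[present],
                  basal_area = ba) |>
      arrange(desc(.data$basal_area))
    n_keep <- which(cumsum(cen$basal_area) / sum(cen$basal_area) >=
                      config$basal_area_target)[1]
    cen$sampled <- seq_len(nrow(cen)) <= n_keep
    census[[k]] <- cen

    sampled <- cen$species[cen$sampled]
    mu_s <- pool$mu[match(sampled, pool$species)]
    # environmental filter: admitted species means shrink toward the plot
    # trait optimum; internal filter: within-population spread scales down
    pop_mean <- pk$plot_optimum + pk$gamma_external * (mu_s - pk$plot_optimum) +
      pk$site_effect +
      rnorm(length(sampled), 0, config$sigma_pop * pk$gamma_internal)
    pops[[k]] <- tibble(plot_id = pk$plot_id, species = sampled,
                        pop_mean = pop_mean)

    n_trees <- sample_range(config$trees_per_species, length(sampled))
    tr <- tibble(
      plot_id = pk$plot_id,
      species = rep(sampled, n_trees),
      tree_no = unlist(lapply(n_trees, seq_len), use.names = FALSE),
      tree_value = rep(pop_mean, n_trees) +
        rnorm(sum(n_trees), 0, config$sigma_tree * pk$gamma_internal)
    ) |>
      mutate(tree_id = paste0(.data$plot_id, "-", .data$species, "-t",
                              .data$tree_no))
    trees_truth[[k]] <- tr

    n_tl <- nrow(tr) * length(config$layers)
    lf <- tr[rep(seq_len(nrow(tr)), each = length(config$layers)), ] |>
      mutate(layer = rep(config$layers, nrow(tr)))
    n_leaves <- sample_range(config$leaves_per_tree, n_tl)
    lf <- lf[rep(seq_len(n_tl), n_leaves), ] |>
      mutate(leaf_no = unlist(lapply(n_leaves, seq_len), use.names = FALSE))
    log_lma <- lf$tree_value +
      ifelse(lf$layer == "shade", config$shade_offset, 0) +
      rnorm(nrow(lf), 0, config$sigma_leaf)
    lma <- exp(log_lma)
    area <- rlnorm(nrow(lf), geom$lamina_area_meanlog, geom$lamina_area_sdlog)
    dry <- lma * area
    leaves[[k]] <- tibble(
      plot_id = lf$plot_id,
      tree_id = lf$tree_id,
      species = lf$species,
      genus = pool$genus[match(lf$species, pool$species)],
      family = pool$family[match(lf$species, pool$species)],
      leaf_id = paste0(lf$tree_id, "-", substr(lf$layer, 1, 2), lf$leaf_no),
      layer = lf$layer,
      lamina_dry_mass = (1 - geom$petiole_mass_frac) * dry,
      petiole_dry_mass = geom$petiole_mass_frac * dry,
      petiole_fresh_mass = geom$petiole_fresh_dry * geom$petiole_mass_frac * dry,
      lamina_fresh_area = (1 - geom$petiole_area_frac) * area,
      petiole_fresh_area = geom$petiole_area_frac * area
    )
  }

  plots_out <- plots |>
    mutate(
      # LAI proxy declines along the gradient with mild noise; vegetation label
      lai = pmax(0.5, 6 - 1.2e-3 * .data$elevation + rnorm(config$n_plots, 0, 0.3)),
      vegetation = cut(.data$elevation,
                       breaks = c(-Inf, 800, 1500, 3000, Inf),
                       labels = c("lowland forest", "submontane forest",
                                  "cloud forest", "treeline forest")) |>
        as.character()
    ) |>
    select("plot_id", "elevation", "lai", "vegetation")

  structure(list(
    leaves = bind_rows(leaves),
    census = bind_rows(census),
    plots = plots_out,
    truth = list(config = config, geometry = geom, species = pool,
                 plots = plots, populations = bind_rows(pops),
                 trees = bind_rows(trees_truth))
  ), class = "region_sim")
}

sample_range <- function(rng, n) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, replace = TRUE)
}

#' @export
print.region_sim <- function(x, ...) {
  cat("<region_sim>", nrow(x$plots), "plots,",
      length(unique(x$census$species)), "species present,",
      nrow(x$leaves), "leaves\n")
  invisible(x)
}

#' Inject measurement artifacts into a leaf table
#'
#' Emulates two field artifacts: petiole dry masses recorded as zero (a
#' balance with limited precision) and single aberrant leaves whose dry mass
#' pushes the tree's LMA variance over the outlier threshold. Used to
#' exercise [correct_petiole_mass()] and [filter_outlier_leaves()] against a
#' known manifest.
#'
#' @param leaves Leaf-measurement tibble (as from [simulate_region()]).
#' @param zero_petiole_rate Fraction of leaves whose petiole dry mass is set
#'   to zero.
#' @param outlier_rate Fraction of trees that receive one aberrant leaf.
#' @param outlier_scale Multiplier applied to the aberrant leaf's dry masses.
#' @param seed Integer seed.
#' @return The modified leaf tibble, with the injected artifacts recorded in
#'   an `artifact_manifest` attribute (retrieve with [artifact_manifest()]).
#' @export
inject_artifacts <- function(leaves, zero_petiole_rate = 0, outlier_rate = 0,
                             outlier_scale = 3, seed = 1L) {
  stopifnot(zero_petiole_rate >= 0, zero_petiole_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1)
  set.seed(seed)
  out <- leaves
  manifest <- list()

  n_zero <- round(zero_petiole_rate * nrow(out))
  if (n_zero > 0) {
    idx <- sample(nrow(out), n_zero)
    out$petiole_dry_mass[idx] <- 0
    manifest$zero_petiole <- tibble(type = "zero_petiole",
                                    plot_id = out$plot_id[idx],
                                    tree_id = out$tree_id[idx],
                                    leaf_id = out$leaf_id[idx])
  }

  trees <- unique(out$tree_id)
  n_out <- round(outlier_rate * length(trees))
  if (n_out > 0) {
    hit <- sample(trees, n_out)
    idx <- map_dbl(hit, function(tr) {
      rows <- which(out$tree_id == tr)
      rows[sample.int(length(rows), 1)]
    })
    out$lamina_dry_mass[idx] <- out$lamina_dry_mass[idx] * outlier_scale
    out$petiole_dry_mass[idx] <- out$petiole_dry_mass[idx] * outlier_scale
    manifest$outlier <- tibble(type = "outlier",
                               plot_id = out$plot_id[idx],
                               tree_id = out$tree_id[idx],
                               leaf_id = out$leaf_id[idx])
  }

  attr(out, "artifact_manifest") <- bind_rows(manifest)
  out
}

#' Retrieve the artifact manifest attached by [inject_artifacts()]
#' @param x A leaf tibble returned by [inject_artifacts()].
#' @return A tibble of injected artifacts (type, plot, tree, leaf), or an
#'   empty tibble when none were injected.
#' @export
artifact_manifest <- function(x) {
  attr(x, "artifact_manifest") %||%
    tibble(type = character(), plot_id = character(),
           tree_id = character(), leaf_id = character())
}
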