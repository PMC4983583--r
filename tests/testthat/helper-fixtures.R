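# Small programmatic fixtures shared across test files.

# Random tree-level trait table: n_plots communities, each with its own
# species drawn from a shared pool, populations of varying size.
rand_trait_table <- function(n_plots = 3, n_species = 4, max_trees = 4,
                             seed = 1) {
  set.seed(seed)
  purrr::map(seq_len(n_plots), function(p) {
    sp <- sample(letters[1:8], n_species)
    n_tr <- sample(2:max_trees, n_species, replace = TRUE)
    tibble::tibble(
      plot_id = sprintf("P%02d", p),
      species = rep(sp, n_tr),
      tree_id = paste0("P", p, "-", rep(sp, n_tr), "-",
                       unlist(lapply(n_tr, seq_len))),
      log_lma = stats::rnorm(sum(n_tr), mean = 4.8 + 0.3 * p, sd = 0.3)
    )
  }) |> dplyr::bind_rows()
}

# Balanced two-level data (groups + residual) with known generative sigmas.
balanced_two_level <- function(g = 10, n = 10, sigma_b = 2, sigma_w = 1,
                               seed = 1) {
  set.seed(seed)
  tibble::tibble(
    group = rep(sprintf("g%02d", seq_len(g)), each = n),
    log_lma = rep(stats::rnorm(g, 0, sigma_b), each = n) +
      stats::rnorm(g * n, 0, sigma_w)
  )
}

# Balanced three-level data: a sites, b groups per site, n obs per group.
balanced_three_level <- function(a = 5, b = 4, n = 6, s_a = 1.5, s_b = 0.8,
                                 s_w = 0.5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    site = rep(sprintf("s%02d", seq_len(a)), each = b * n),
    group = rep(sprintf("g%02d", seq_len(a * b)), each = n),
    log_lma = rep(stats::rnorm(a, 0, s_a), each = b * n) +
      rep(stats::rnorm(a * b, 0, s_b), each = n) +
      stats::rnorm(a * b * n, 0, s_w)
  )
}

# A leaf row with sane defaults, overridable per test.
leaf_row <- function(...) {
  defaults <- list(plot_id = "P01", tree_id = "t1", species = "sp1",
                   leaf_id = "l1", layer = "sun",
                   lamina_dry_mass = 0.5, petiole_dry_mass = 0.1,
                   petiole_fresh_mass = 0.3, lamina_fresh_area = 0.005,
                   petiole_fresh_area = 0.001)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

# Independent one-way ANOVA decomposition: within-group SS fraction of a
# community, via lm/anova (the brute-force oracle for T_ip.ic).
anova_within_fraction <- function(x, group) {
  fit <- stats::lm(x ~ factor(group))
  an <- stats::anova(fit)
  ss_between <- an[["Sum Sq"]][1]
  ss_total <- sum((x - mean(x))^2)
  1 - ss_between / ss_total
}

# Scenario with all trait structure at the individual (tree) level: no
# species, population or site differences, so individuals are exchangeable
# within communities and across the region (random-assembly conditions).
neutral_scenario <- function(seed, n_plots = 6) {
  scenario_config(n_plots = n_plots, pool_size = 12, niche_width = 1e6,
                  beta_env = 0, sigma_site = 0, sigma_species = 0,
                  sigma_pop = 0, sigma_tree = 0.2, sigma_leaf = 0.1,
                  trees_per_species = c(3L, 3L), leaves_per_tree = c(3L, 3L),
                  layers = "sun", seed = seed)
}
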