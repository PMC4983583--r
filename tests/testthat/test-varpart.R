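test_that("the moments oracle solves known balanced decompositions", {
  # independent check against aov mean squares on a two-level design
  d <- balanced_two_level(g = 8, n = 6, sigma_b = 2, sigma_w = 1, seed = 4)
  mo <- moments_oracle(d, hierarchy = "group")
  an <- stats::anova(stats::lm(log_lma ~ group, data = d))
  ms_b <- an[["Mean Sq"]][1]; ms_w <- an[["Mean Sq"]][2]
  expect_equal(mo$variance[mo$level == "residual"], ms_w, tolerance = 1e-12)
  expect_equal(mo$variance[mo$level == "group"], (ms_b - ms_w) / 6,
               tolerance = 1e-12)
  expect_equal(sum(mo$proportion), 1, tolerance = 1e-12)

  # all equal values -> all components zero
  flat <- dplyr::mutate(d, log_lma = 2)
  expect_true(all(moments_oracle(flat, hierarchy = "group")$variance == 0))

  # unbalanced input is refused
  expect_error(moments_oracle(d[-1, ], hierarchy = "group"), "balanced")
})

test_that("REML components equal the moments estimator on balanced data", {
  d2 <- balanced_two_level(g = 10, n = 10, sigma_b = 2, sigma_w = 1, seed = 1)
  reml <- nested_variance_components(d2, hierarchy = "group")
  mom <- moments_oracle(d2, hierarchy = "group")
  expect_equal(reml$variance, mom$variance, tolerance = 1e-6)

  d3 <- balanced_three_level(seed = 2)
  reml3 <- nested_variance_components(d3, hierarchy = c("site", "group"))
  mom3 <- moments_oracle(d3, hierarchy = c("site", "group"))
  expect_equal(reml3$variance, mom3$variance, tolerance = 1e-6)
  expect_equal(sum(reml3$proportion), 1, tolerance = 1e-9)
})

test_that("a level with no spread collapses to a near-zero component", {
  d <- balanced_three_level(s_a = 0, s_b = 1, s_w = 0.5, seed = 9)
  reml <- nested_variance_components(d, hierarchy = c("site", "group"))
  tot <- sum(reml$variance)
  expect_lt(reml$variance[reml$level == "site"] / tot, 0.05)
})

test_that("taxonomically inconsistent labels are rejected with offenders", {
  d <- tibble::tibble(
    plot_id = "P1", family = c("f1", "f2"), genus = "g1",
    species = c("s1", "s2"), tree_id = c("t1", "t2"),
    log_lma = c(1, 2))
  expect_error(nested_variance_components(d), "g1")
})

test_that("generator variance structure is recovered from leaf data", {
  cfg <- scenario_config(n_plots = 12, pool_size = 15, niche_width = 1e6,
                         beta_env = 0, abundance_shape = 0,
                         basal_area_target = 1,
                         sigma_site = 0.12, sigma_species = 0.30,
                         sigma_pop = 0.10, sigma_tree = 0.15,
                         sigma_leaf = 0.10,
                         trees_per_species = c(4L, 4L),
                         leaves_per_tree = c(4L, 4L),
                         layers = "sun", seed = 31)
  lv <- compute_leaf_lma(simulate_region(cfg)$leaves) |>
    dplyr::mutate(log_lma = log(lma))
  reml <- nested_variance_components(
    lv, hierarchy = c("plot_id", "species", "tree_id"))
  est <- setNames(reml$variance, reml$level)
  # species-within-plot mixes the species and population levels
  expect_equal(unname(est["plot_id"]), 0.12^2, tolerance = 0.6)
  expect_equal(unname(est["species"]), 0.30^2 + 0.10^2, tolerance = 0.35)
  expect_equal(unname(est["tree_id"]), 0.15^2, tolerance = 0.25)
  expect_equal(unname(est["residual"]), 0.10^2, tolerance = 0.15)
})

test_that("CWM variance decomposition is exact on a hand-computed fixture", {
  pops <- tibble::tibble(
    plot_id = rep(c("A", "B"), each = 2),
    species = rep(c("s1", "s2"), 2),
    lma = c(100, 200, 120, 260))
  cen <- tibble::tibble(
    plot_id = rep(c("A", "B"), each = 2),
    species = rep(c("s1", "s2"), 2),
    basal_area = c(3, 1, 1, 3))
  ld <- leps_decomposition(pops, cen)
  # fixed means: s1 110, s2 230
  # specific CWMs: A (300+200)/4 = 125, B (120+780)/4 = 225
  # fixed CWMs:    A (330+230)/4 = 140, B (110+690)/4 = 200
  # intra:         A -15, B 25
  expect_equal(ld$ss_specific, var(c(125, 225)))
  expect_equal(ld$ss_fixed, var(c(140, 200)))
  expect_equal(ld$ss_intra, var(c(-15, 25)))
  expect_equal(ld$cov, ld$ss_specific - ld$ss_fixed - ld$ss_intra)
  expect_equal(ld$turnover_share + ld$intra_share + ld$cov_share, 1,
               tolerance = 1e-12)
})

test_that("decomposition boundary cases behave as documented", {
  # species means identical everywhere -> all variation is turnover
  pops <- tibble::tibble(
    plot_id = rep(c("A", "B", "C"), each = 2),
    species = rep(c("s1", "s2"), 3),
    lma = rep(c(100, 220), 3))
  set.seed(2)
  cen <- dplyr::mutate(pops, basal_area = runif(6, 0.5, 3), lma = NULL)
  ld <- leps_decomposition(pops, cen)
  expect_equal(ld$ss_intra, 0)
  expect_equal(ld$cov, 0)
  expect_equal(ld$turnover_share, 1)
  # a single plot has no across-plot variance
  expect_error(leps_decomposition(dplyr::filter(pops, plot_id == "A"),
                                  dplyr::filter(cen, plot_id == "A")),
               "2 plots")
  # census species without trait data are excluded with a warning
  cen_extra <- dplyr::bind_rows(cen, tibble::tibble(plot_id = "A",
                                                    species = "ghost",
                                                    basal_area = 1))
  expect_warning(leps_decomposition(pops, cen_extra), "ghost")
})

test_that("decomposition identity holds to machine precision on random data", {
  for (s in 1:10) {
    set.seed(s)
    n_sp <- 6
    pops <- tidyr::expand_grid(plot_id = paste0("P", 1:5),
                               species = paste0("s", 1:n_sp)) |>
      dplyr::slice_sample(prop = 0.8) |>
      dplyr::mutate(lma = runif(dplyr::n(), 30, 300))
    cen <- dplyr::mutate(pops, basal_area = runif(dplyr::n(), 0.1, 4),
                         lma = NULL)
    ld <- leps_decomposition(pops, cen)
    expect_equal(ld$ss_fixed + ld$ss_intra + ld$cov, ld$ss_specific,
                 tolerance = 1e-12)
  }
})
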