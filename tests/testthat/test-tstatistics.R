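two_species_plot <- function() {
  tibble::tibble(plot_id = "A",
                 species = rep(c("a", "b"), each = 2),
                 tree_id = paste0("t", 1:4),
                 log_lma = c(10, 12, 20, 22))
}

test_that("variance components match hand-computed sums of squares", {
  vc <- variance_components(two_species_plot())
  # community mean 16; deviations -6,-4,4,6; population means 11 and 21
  expect_equal(vc$ss_community, 104)
  expect_equal(vc$ss_within_pop, 4)
  expect_equal(vc$n_c, 4L)
  expect_equal(vc$ss_region, 104)
  expect_equal(vc$var_pop_means_community, var(c(11, 21)))
  expect_equal(t_ip_ic(vc), 4 / 104)
})

test_that("within-group SS never exceeds the community SS", {
  for (s in 1:10) {
    vc <- variance_components(rand_trait_table(seed = s))
    expect_true(all(vc$ss_within_pop <= vc$ss_community + 1e-12))
    expect_true(all(vc$ss_within_pop >= 0))
    r <- t_ip_ic(vc)
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("degenerate communities hit the documented boundary values", {
  # single species: the population IS the community
  one_sp <- tibble::tibble(plot_id = "A", species = "a",
                           tree_id = paste0("t", 1:3),
                           log_lma = c(1, 2, 4))
  vc1 <- variance_components(one_sp)
  expect_equal(vc1$ss_within_pop, vc1$ss_community)
  expect_equal(t_ip_ic(vc1), 1)
  # region = one community
  expect_equal(t_ic_ir(vc1), 1)
  # zero within-population spread
  no_within <- tibble::tibble(plot_id = "A",
                              species = rep(c("a", "b"), each = 2),
                              tree_id = paste0("t", 1:4),
                              log_lma = c(5, 5, 9, 9))
  expect_equal(t_ip_ic(variance_components(no_within)), 0)
  # all individuals identical
  flat <- dplyr::mutate(no_within, log_lma = 3)
  expect_error(t_ip_ic(variance_components(flat)), "identical")
  # equal population means in one plot, heterogeneous elsewhere
  two_plots <- dplyr::bind_rows(
    no_within,
    dplyr::mutate(no_within, plot_id = "B", log_lma = c(4, 4, 4, 4),
                  tree_id = paste0("u", 1:4)))
  vc2 <- variance_components(two_plots)
  expect_equal(t_pc_pr(vc2)[vc2$plot_id == "B"], 0)
})

test_that("T-statistics are invariant to shifting and scaling traits", {
  tr <- rand_trait_table(seed = 11)
  vc <- variance_components(tr)
  shifted <- variance_components(dplyr::mutate(tr, log_lma = log_lma + 5))
  scaled <- variance_components(dplyr::mutate(tr, log_lma = log_lma * 3))
  for (f in list(t_ip_ic, t_ic_ir, t_pc_pr)) {
    expect_equal(f(shifted), f(vc), tolerance = 1e-12)
    expect_equal(f(scaled), f(vc), tolerance = 1e-12)
  }
})

test_that("T_ip.ic agrees with a brute-force one-way ANOVA decomposition", {
  for (s in 1:15) {
    tr <- rand_trait_table(n_plots = 1, n_species = sample(2:5, 1), seed = s)
    stopifnot(nrow(tr) <= 20)
    vc <- variance_components(tr)
    oracle <- anova_within_fraction(tr$log_lma, tr$species)
    expect_equal(t_ip_ic(vc), oracle, tolerance = 1e-12)
  }
})

test_that("null distributions are deterministic and use the right scheme", {
  tr <- rand_trait_table(seed = 2)
  for (stat in c("t_ip_ic", "t_ic_ir", "t_pc_pr")) {
    n1 <- null_distribution(tr, stat, nperm = 99, seed = 7)
    n2 <- null_distribution(tr, stat, nperm = 99, seed = 7)
    expect_identical(n1, n2)
    expect_false(identical(n1, null_distribution(tr, stat, nperm = 99,
                                                 seed = 8)))
  }
  # the within-community shuffle preserves the community pool, so the
  # unpermuted formula reproduces the observed statistic exactly
  vc <- variance_components(tr)
  obs <- t_ip_ic(vc)
  for (p in vc$plot_id) {
    sub <- dplyr::filter(tr, plot_id == p)
    pop <- factor(paste(sub$plot_id, sub$species))
    gs <- rowsum(matrix(sub$log_lma), pop)
    ssw <- sum(sub$log_lma^2) - sum(gs^2 / as.vector(table(pop)))
    ssc <- sum((sub$log_lma - mean(sub$log_lma))^2)
    expect_equal(ssw / ssc, obs[vc$plot_id == p], tolerance = 1e-12)
  }
  # t_ip_ic nulls stay in [0, 1]
  n <- null_distribution(tr, "t_ip_ic", nperm = 199, seed = 1)
  expect_true(all(n >= 0 & n <= 1))
  expect_error(null_distribution(tr, "t_ip_ic", nperm = 10), "99")
})

test_that("standardized effect sizes behave at their fixed points", {
  null <- 1:100
  expect_equal(ses(mean(null), null)$ses, 0)
  expect_equal(ses(50.5, null)$ses, 0)
  low <- ses(0, null)
  expect_true(low$significant)
  expect_lt(low$ses, low$ci_low)
  inside <- ses(60, null)
  expect_false(inside$significant)
  expect_error(ses(1, rep(2, 50)), "zero spread")
})

test_that("transect aggregation pools SES over plots", {
  per_plot <- tibble::tibble(plot_id = c("A", "B"), ses = c(-1, 1),
                             null_mean = 0, null_sd = 1)
  nulls <- matrix(rnorm(2 * 200, 0, 1), 2, 200,
                  dimnames = list(c("A", "B"), NULL))
  agg <- aggregate_ses(per_plot, nulls)
  expect_equal(agg$mean_ses, 0)
  expect_equal(agg$sd_ses, sqrt(2))
  expect_false(agg$significant)
  expect_error(aggregate_ses(per_plot[1, ], nulls[1, , drop = FALSE]),
               "2 plots")
})

test_that("the tstats wrapper is reproducible and tidies correctly", {
  tr <- rand_trait_table(n_plots = 4, seed = 13)
  ts1 <- tstats(tr, nperm = 99, seed = 3)
  ts2 <- tstats(tr, nperm = 99, seed = 3)
  expect_equal(tidy(ts1), tidy(ts2))
  td <- tidy(ts1)
  expect_setequal(unique(td$statistic), c("t_ip_ic", "t_ic_ir", "t_pc_pr"))
  expect_equal(nrow(td), 12)          # 4 plots x 3 statistics
  expect_equal(td$ses, (td$observed - td$null_mean) / td$null_sd)
  expect_equal(td$significant, td$ses < td$ci_low | td$ses > td$ci_high)
  gl <- glance(ts1)
  expect_equal(nrow(gl), 3)
  expect_s3_class(autoplot(ts1), "ggplot")
  expect_error(tstats(dplyr::mutate(tr, layer = rep(c("sun", "shade"),
                                                    length.out = nrow(tr))),
                      nperm = 99), "layers")
})
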