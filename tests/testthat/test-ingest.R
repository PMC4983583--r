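test_that("whole-leaf LMA arithmetic includes lamina and petiole", {
  # 0.6 g over 0.006 m^2
  expect_equal(compute_leaf_lma(leaf_row())$lma, 100)
  # 0.36 g over 0.0048 m^2
  expect_equal(compute_leaf_lma(leaf_row(
    lamina_dry_mass = 0.3, petiole_dry_mass = 0.06,
    lamina_fresh_area = 0.004, petiole_fresh_area = 0.0008
  ))$lma, 75)
  # petiole-free leaf reduces to lamina-only LMA
  expect_equal(compute_leaf_lma(leaf_row(
    petiole_dry_mass = 0, petiole_fresh_area = 0
  ))$lma, 0.5 / 0.005)
  expect_error(compute_leaf_lma(leaf_row(
    lamina_fresh_area = 0, petiole_fresh_area = 0
  )), "l1")
  expect_error(compute_leaf_lma(dplyr::select(leaf_row(), -lamina_dry_mass)),
               "lamina_dry_mass")
})

test_that("LMA scales with mass, not with units applied to both sides", {
  lv <- leaf_row()
  doubled <- dplyr::mutate(lv, lamina_dry_mass = lamina_dry_mass * 2,
                           petiole_dry_mass = petiole_dry_mass * 2)
  expect_equal(compute_leaf_lma(doubled)$lma, 2 * compute_leaf_lma(lv)$lma)
  both <- dplyr::mutate(lv, dplyr::across(c(lamina_dry_mass, petiole_dry_mass,
                                            lamina_fresh_area,
                                            petiole_fresh_area), ~ .x * 3))
  expect_equal(compute_leaf_lma(both)$lma, compute_leaf_lma(lv)$lma)
})

test_that("zero petiole masses are corrected by the plot ratio of sums", {
  lv <- dplyr::bind_rows(
    leaf_row(leaf_id = "a", petiole_fresh_mass = 0.3, petiole_dry_mass = 0.1),
    leaf_row(leaf_id = "b", petiole_fresh_mass = 0.5, petiole_dry_mass = 0.1),
    leaf_row(leaf_id = "c", petiole_fresh_mass = 0.02, petiole_dry_mass = 0)
  )
  out <- correct_petiole_mass(lv)
  # R_plot = (0.3 + 0.5) / (0.1 + 0.1) = 4; corrected dry = 0.02 / 4
  expect_equal(out$petiole_dry_mass[out$leaf_id == "c"], 0.005)
  expect_true(out$petiole_corrected[out$leaf_id == "c"])
  # nonzero masses are untouched
  expect_equal(out$petiole_dry_mass[out$leaf_id %in% c("a", "b")],
               c(0.1, 0.1))
  expect_false(any(out$petiole_corrected[out$leaf_id %in% c("a", "b")]))
})

test_that("plots without any valid petiole pair warn and keep zeros", {
  lv <- dplyr::bind_rows(
    leaf_row(leaf_id = "a", petiole_dry_mass = 0, petiole_fresh_mass = 0.02),
    leaf_row(leaf_id = "b", petiole_dry_mass = 0, petiole_fresh_mass = 0.03)
  )
  expect_warning(out <- correct_petiole_mass(lv), "P01")
  expect_true(all(out$petiole_dry_mass == 0))
  expect_false(any(out$petiole_corrected))
})

test_that("the outlier filter removes the single variance-driving leaf", {
  lv <- tibble::tibble(tree_id = "t1", layer = "sun",
                       leaf_id = paste0("l", 1:5),
                       lma = c(100, 102, 98, 101, 250))
  expect_gt(var(lv$lma), 2000)  # 4487.2
  res <- filter_outlier_leaves(lv)
  expect_equal(res$removed$lma, 250)
  expect_equal(var(res$kept$lma), 35 / 12)  # 2.9167 after removal
  expect_length(res$flagged, 0)

  quiet <- filter_outlier_leaves(dplyr::filter(lv, lma < 200))
  expect_equal(nrow(quiet$removed), 0)
  ties <- filter_outlier_leaves(tibble::tibble(tree_id = "t", layer = "sun",
                                               leaf_id = c("x", "y"),
                                               lma = c(100, 100)))
  expect_equal(nrow(ties$removed), 0)
})

test_that("at most one leaf is removed per tree and variance never rises", {
  set.seed(7)
  lv <- tibble::tibble(
    tree_id = rep(sprintf("t%02d", 1:30), each = 5),
    layer = "sun",
    leaf_id = paste0("l", 1:150),
    lma = rnorm(150, 150, 40)^2 / 150  # heavy right tail
  )
  res <- filter_outlier_leaves(lv)
  expect_true(all(table(res$removed$tree_id) <= 1))
  pre <- tapply(lv$lma, lv$tree_id, var)
  post <- tapply(res$kept$lma, res$kept$tree_id, var)
  expect_true(all(post <= pre[names(post)] + 1e-12))
  expect_warning(
    filter_outlier_leaves(tibble::tibble(tree_id = "solo", layer = "sun",
                                         leaf_id = "l", lma = 100)),
    "< 2 leaves")
})

test_that("aggregation runs on tree values and keeps layers separate", {
  lv <- dplyr::bind_rows(
    leaf_row(tree_id = "t1", leaf_id = "l1"),
    leaf_row(tree_id = "t1", leaf_id = "l2"),
    leaf_row(tree_id = "t1", leaf_id = "l3", layer = "shade"),
    leaf_row(tree_id = "t2", leaf_id = "l4")
  ) |> compute_leaf_lma()
  lv$lma <- c(90, 110, 80, 130)
  agg <- aggregate_to_trees(lv)
  t1_sun <- dplyr::filter(agg$trees, tree_id == "t1", layer == "sun")
  expect_equal(t1_sun$lma, 100)          # mean of its sun leaves only
  expect_equal(t1_sun$log_lma, log(100)) # log of the tree mean
  expect_equal(nrow(dplyr::filter(agg$trees, tree_id == "t1")), 2)
  # population mean is the mean of tree values, not of pooled leaves:
  # trees (100, 130) -> 115, while pooled sun leaves would give 110
  pop_sun <- dplyr::filter(agg$populations, layer == "sun")
  expect_equal(pop_sun$lma, 115)
  expect_false(isTRUE(all.equal(pop_sun$lma, mean(c(90, 110, 130)))))
  plot_sun <- dplyr::filter(agg$plots, layer == "sun")
  expect_equal(plot_sun$lma, 115)
})

test_that("species means aggregate trees {100,120,140} to 120", {
  trees <- tibble::tibble(plot_id = "P01", species = "sp1",
                          tree_id = c("t1", "t2", "t3"), layer = "sun",
                          lma = c(100, 120, 140)) |>
    tidyr::uncount(3, .id = "leaf") |>
    dplyr::mutate(leaf_id = paste0(tree_id, "-", leaf))
  agg <- aggregate_to_trees(trees)
  expect_equal(agg$populations$lma, 120)
})
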