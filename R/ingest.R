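#' Whole-leaf LMA from lamina and petiole measurements
#'
#' Computes leaf mass per area on a whole-leaf basis: total dry mass (lamina +
#' petiole) divided by total fresh projected area (lamina + petiole), in
#' g m^-2. For compound leaves the rachis is measured with the petiole, so no
#' separate handling is needed.
#'
#' @param leaves Leaf-measurement tibble with columns `lamina_dry_mass`,
#'   `petiole_dry_mass`, `lamina_fresh_area`, `petiole_fresh_area` (and
#'   `leaf_id` for error reporting).
#' @return The input tibble with an added `lma` column (g m^-2).
#' @examples
#' compute_leaf_lma(tibble::tibble(
#'   leaf_id = "l1", lamina_dry_mass = 0.5, petiole_dry_mass = 0.1,
#'   lamina_fresh_area = 0.005, petiole_fresh_area = 0.001
#' ))$lma  # 100
#' @export
compute_leaf_lma <- function(leaves) {
  req <- c("lamina_dry_mass", "petiole_dry_mass",
           "lamina_fresh_area", "petiole_fresh_area")
  check_columns(leaves, req, "leaf table")
  area <- leaves$lamina_fresh_area + leaves$petiole_fresh_area
  if (any(area <= 0)) {
    bad <- if ("leaf_id" %in% names(leaves)) {
      paste(head(leaves$leaf_id[area <= 0], 5), collapse = ", ")
    } else {
      paste(head(which(area <= 0), 5), collapse = ", ")
    }
    abort(paste0("Zero total fresh area for leaf/leaves: ", bad))
  }
  leaves |>
    mutate(lma = (.data$lamina_dry_mass + .data$petiole_dry_mass) / area)
}

#' Correct zero petiole dry masses by the plot-level fresh:dry ratio
#'
#' Petioles too light for the field balance are recorded with zero dry mass.
#' Their dry mass is reconstructed as `petiole_fresh_mass / R_plot`, where
#' `R_plot` is the plot-level ratio of summed petiole fresh mass to summed
#' petiole dry mass over that plot's leaves that have both measurements. The
#' ratio of sums is used rather than a mean of per-leaf ratios: it is robust
#' to tiny denominators.
#'
#' @param leaves Leaf-measurement tibble with `plot_id`, `petiole_dry_mass`
#'   and `petiole_fresh_mass`.
#' @return The tibble with corrected `petiole_dry_mass` and a logical
#'   `petiole_corrected` column. Plots without any valid fresh/dry pair keep
#'   their zeros (flagged `FALSE`) with a warning.
#' @export
correct_petiole_mass <- function(leaves) {
  check_columns(leaves, c("plot_id", "petiole_dry_mass", "petiole_fresh_mass"),
                "leaf table")
  ratios <- leaves |>
    filter(.data$petiole_dry_mass > 0, .data$petiole_fresh_mass > 0) |>
    group_by(.data$plot_id) |>
    summarise(r_plot = sum(.data$petiole_fresh_mass) /
                sum(.data$petiole_dry_mass), .groups = "drop")
  out <- leaves |>
    left_join(ratios, by = "plot_id") |>
    mutate(
      needs_fix = .data$petiole_dry_mass == 0 & .data$petiole_fresh_mass > 0,
      petiole_corrected = .data$needs_fix & !is.na(.data$r_plot),
      petiole_dry_mass = ifelse(.data$petiole_corrected,
                                .data$petiole_fresh_mass / .data$r_plot,
                                .data$petiole_dry_mass)
    )
  orphaned <- out |> filter(.data$needs_fix, is.na(.data$r_plot))
  if (nrow(orphaned) > 0) {
    warn(paste0("No valid petiole fresh/dry pair in plot(s) ",
                paste(unique(orphaned$plot_id), collapse = ", "),
                "; ", nrow(orphaned), " zero petiole mass(es) left uncorrected."))
  }
  out |> select(-"needs_fix", -"r_plot")
}

#' Remove single outlier leaves that inflate a tree's LMA variance
#'
#' Trees whose leaf-level LMA sample variance exceeds `threshold`
#' (2000 g^2 m^-4 by default) most often contain a single mis-measured leaf.
#' For each such tree (within a canopy layer), the one leaf whose removal
#' minimises the remaining variance is dropped; at most one leaf is ever
#' removed per tree. Trees still above the threshold after removal are
#' flagged, not dropped.
#'
#' @param leaves Leaf tibble with `tree_id`, `lma` and (optionally) `layer`.
#' @param threshold Variance threshold in g^2 m^-4.
#' @return A list with `kept` and `removed` leaf tibbles and `flagged`, a
#'   character vector of tree ids whose variance remains above the threshold.
#' @examples
#' lv <- tibble::tibble(tree_id = "t1", layer = "sun",
#'                      leaf_id = paste0("l", 1:5),
#'                      lma = c(100, 102, 98, 101, 250))
#' filter_outlier_leaves(lv)$removed$lma  # 250
#' @export
filter_outlier_leaves <- function(leaves, threshold = 2000) {
  check_columns(leaves, c("tree_id", "lma"), "leaf table")
  if (!"layer" %in% names(leaves)) leaves$layer <- "sun"
  grp <- paste(leaves$tree_id, leaves$layer, sep = "\r")
  drop_idx <- integer()
  flagged <- character()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    x <- leaves$lma[idx]
    if (length(x) < 2) {
      warn(paste0("Tree ", leaves$tree_id[idx[1]],
                  " has < 2 leaves; outlier check skipped."))
      next
    }
    if (var(x) <= threshold) next
    # drop the single leaf whose removal minimises the remaining variance
    rem_var <- vapply(seq_along(x), function(i) var(x[-i]), numeric(1))
    worst <- which.min(rem_var)
    drop_idx <- c(drop_idx, idx[worst])
    if (rem_var[worst] > threshold) flagged <- c(flagged, leaves$tree_id[idx[1]])
  }
  list(
    kept = if (length(drop_idx)) leaves[-drop_idx, ] else leaves,
    removed = leaves[drop_idx, ],
    flagged = unique(flagged)
  )
}

#' Aggregate leaf LMA to tree, population and plot level
#'
#' Each tree's LMA (per canopy layer) is the mean of its leaves' whole-leaf
#' LMA values; species-by-plot (population) and plot means are computed from
#' tree values, never from pooled leaves, so unbalanced leaf counts cannot
#' bias the higher levels. Sun and shade layers are kept separate at every
#' level. Log-LMA (natural log) is carried alongside for the variance
#' analyses.
#'
#' @param leaves Leaf tibble with `plot_id`, `species`, `tree_id`, `layer`
#'   and `lma` (see [compute_leaf_lma()]).
#' @return A list of tibbles: `trees` (one row per tree x layer, with `lma`,
#'   `log_lma`, `n_leaves`), `populations` (species x plot x layer means of
#'   tree values) and `plots` (plot x layer means of tree values).
#' @export
aggregate_to_trees <- function(leaves) {
  check_columns(leaves, c("plot_id", "species", "tree_id", "layer", "lma"),
                "leaf table")
  trees <- leaves |>
    group_by(.data$plot_id, .data$species, .data$tree_id, .data$layer) |>
    summarise(lma = mean(.data$lma), n_leaves = n(), .groups = "drop") |>
    mutate(log_lma = log(.data$lma))
  populations <- trees |>
    group_by(.data$plot_id, .data$species, .data$layer) |>
    summarise(lma = mean(.data$lma), log_lma = mean(.data$log_lma),
              n_trees = n(), .groups = "drop")
  plot_means <- trees |>
    group_by(.data$plot_id, .data$layer) |>
    summarise(lma = mean(.data$lma), lma_sd = sd(.data$lma),
              n_trees = n(), .groups = "drop")
  list(trees = trees, populations = populations, plots = plot_means)
}

#' Full ingest: leaf table to tree-level trait table
#'
#' Convenience wrapper chaining [compute_leaf_lma()], [correct_petiole_mass()],
#' [filter_outlier_leaves()] and [aggregate_to_trees()] in the order the
#' corrections are defined: petiole masses are corrected before LMA is
#' computed, and outliers filtered before aggregation. Rows with an
#' `exclude` flag column set to `TRUE` (e.g. folded-leaf scans) are dropped
#' first.
#'
#' @inheritParams correct_petiole_mass
#' @param threshold Outlier variance threshold (g^2 m^-4), default 2000.
#' @return As [aggregate_to_trees()], plus `removed_leaves` and
#'   `flagged_trees` describing the outlier filter's actions.
#' @export
ingest_leaves <- function(leaves, threshold = 2000) {
  if ("exclude" %in% names(leaves)) {
    leaves <- leaves |> filter(!.data$exclude)
  }
  filtered <- leaves |>
    correct_petiole_mass() |>
    compute_leaf_lma() |>
    filter_outlier_leaves(threshold = threshold)
  out <- aggregate_to_trees(filtered$kept)
  out$leaves <- filtered$kept |> mutate(log_lma = log(.data$lma))
  out$removed_leaves <- filtered$removed
  out$flagged_trees <- filtered$flagged
  out
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("Missing required column(s) in ", what, ": ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
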