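leaf_table_columns <- c("plot_id", "tree_id", "species", "leaf_id", "layer",
                        "lamina_dry_mass", "petiole_dry_mass",
                        "petiole_fresh_mass", "lamina_fresh_area",
                        "petiole_fresh_area")

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  if (file.size(path) == 0) abort(paste0(what, " file is empty: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort(paste0(what, " file has no rows: ", path))
  check_columns(df, required, what)
  inform(paste0("Read ", nrow(df), " rows from ", basename(path), "."))
  df
}

#' Read the pipeline's input tables
#'
#' Strictly validated CSV readers for the three input tables: leaf
#' measurements (one row per leaf; masses in g, areas in m^2), plot census
#' (plot x species basal area) and plot metadata (gradient covariates).
#' Missing required columns raise an itemised error before any computation.
#' Duplicate `(plot_id, species)` census rows are summed with a warning.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble.
#' @export
read_leaf_table <- function(path) {
  read_checked_csv(path, leaf_table_columns, "leaf table")
}

#' @rdname read_leaf_table
#' @export
read_census <- function(path) {
  df <- read_checked_csv(path, c("plot_id", "species", "basal_area"), "census")
  dup <- df |> count(.data$plot_id, .data$species) |> filter(.data$n > 1)
  if (nrow(dup)) {
    warn(paste0(nrow(dup), " duplicate (plot, species) census rows summed."))
    df <- df |>
      group_by(.data$plot_id, .data$species) |>
      summarise(basal_area = sum(.data$basal_area),
                across(any_of("sampled"), any), .groups = "drop")
  }
  df
}

#' @rdname read_leaf_table
#' @export
read_plot_meta <- function(path) {
  read_checked_csv(path, "plot_id", "plot metadata")
}

#' Write a simulated region to disk
#'
#' Writes `leaf_measurements.csv`, `census.csv` and `plots.csv` plus the
#' ground truth as `ground_truth.json`, so a simulation can round-trip
#' through the file-based interface.
#'
#' @param sim A [simulate_region()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "region_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$leaves, file.path(dir, "leaf_measurements.csv"))
  readr::write_csv(sim$census, file.path(dir, "census.csv"))
  readr::write_csv(sim$plots, file.path(dir, "plots.csv"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
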