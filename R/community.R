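#' Community-weighted mean and variance of a trait
#'
#' For each plot (and canopy layer), computes the basal-area-weighted mean
#' of species trait values, `CWM_k = sum_i mu_i f_i`, where `mu_i` is the
#' species mean (from tree-level values) and `f_i` its relative abundance
#' (proportion of plot basal area). Because only dominant species are
#' sampled, the summed sampled abundance differs between plots; to correct
#' this sampling bias the CWM is normalised by the summed sampled abundance,
#' i.e. `CWM_k = sum(mu_i f_i) / sum(f_i)`. The community-weighted variance
#' uses the same normalised weights. The summed sampled relative abundance
#' is reported as `coverage`.
#'
#' @param species_means Tibble of species mean traits per plot, with columns
#'   `plot_id`, `species`, `lma` and optionally `layer` (e.g. the
#'   `populations` element of [aggregate_to_trees()]).
#' @param census Tibble with `plot_id`, `species`, `basal_area`. Species
#'   without trait data contribute to the plot total (hence to `coverage`)
#'   but not to the CWM.
#' @return A tibble with one row per plot x layer: `cwm` (g m^-2), `cwv`
#'   (g^2 m^-4), `coverage`, `n_species`.
#' @examples
#' sm <- tibble::tibble(plot_id = "A", species = c("s1", "s2"),
#'                      lma = c(100, 200))
#' cen <- tibble::tibble(plot_id = "A", species = c("s1", "s2", "s3"),
#'                       basal_area = c(3, 3, 4))
#' community_weighted_mean(sm, cen)  # cwm 150, coverage 0.6
#' @export
community_weighted_mean <- function(species_means, census) {
  check_columns(species_means, c("plot_id", "species", "lma"), "species means")
  check_columns(census, c("plot_id", "species", "basal_area"), "census")
  if (!"layer" %in% names(species_means)) species_means$layer <- "sun"
  totals <- census |>
    group_by(.data$plot_id) |>
    summarise(total_ba = sum(.data$basal_area), .groups = "drop")
  joined <- species_means |>
    inner_join(census, by = c("plot_id", "species")) |>
    inner_join(totals, by = "plot_id") |>
    mutate(f = .data$basal_area / .data$total_ba)
  out <- joined |>
    group_by(.data$plot_id, .data$layer) |>
    summarise(
      cwm = sum(.data$lma * .data$f) / sum(.data$f),
      cwv = sum(.data$f * (.data$lma - sum(.data$lma * .data$f) /
                             sum(.data$f))^2) / sum(.data$f),
      coverage = sum(.data$f),
      n_species = n(),
      .groups = "drop"
    )
  bad <- setdiff(unique(species_means$plot_id), unique(joined$plot_id))
  if (length(bad)) {
    abort(paste0("Plot(s) with zero summed abundance over sampled species: ",
                 paste(bad, collapse = ", ")))
  }
  out
}

#' Ordinary least-squares regression of a plot statistic on a gradient
#'
#' Regresses a per-plot statistic (e.g. community-weighted mean LMA) on an
#' environmental covariate (e.g. elevation), optionally excluding named
#' plots, and reports the slope, intercept, r-squared and the two-sided
#' p-value of the slope.
#'
#' @param data Tibble with one row per plot.
#' @param response,covariate Unquoted column names.
#' @param exclude Optional character vector of `plot_id` values to drop
#'   before fitting.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`, `excluded`.
#' @export
gradient_regression <- function(data, response, covariate, exclude = NULL) {
  if (!is.null(exclude)) {
    check_columns(data, "plot_id", "regression input")
    data <- data |> filter(!.data$plot_id %in% exclude)
  }
  y <- pull(data, {{ response }})
  x <- pull(data, {{ covariate }})
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 plots after exclusion.")
  if (var(x) == 0) abort("Covariate has zero variance.")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (var(y) == 0) 0 else sm$r.squared,
    p_value = if (var(y) == 0) 1 else unname(sm$coefficients[2, 4]),
    n = length(x),
    excluded = paste(exclude %||% character(), collapse = ",")
  )
}

#' Plot community-weighted mean against the environmental gradient
#'
#' @param cwm Tibble from [community_weighted_mean()].
#' @param meta Plot metadata with `plot_id` and the gradient column.
#' @param covariate Unquoted gradient column name (default `elevation`).
#' @return A ggplot object: one panel per layer, OLS fit overlaid.
#' @export
plot_cwm_gradient <- function(cwm, meta, covariate = elevation) {
  df <- cwm |> left_join(meta, by = "plot_id")
  ggplot2::ggplot(df, ggplot2::aes({{ covariate }}, .data$cwm)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(y = expression(CWM ~ LMA ~ (g ~ m^-2))) +
    ggplot2::theme_bw()
}

utils::globalVariables("elevation")
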