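#' Nested random-effects variance components of log-LMA
#'
#' Decomposes trait variance across a fully nested hierarchy (default:
#' plot / family / genus / species / tree, with the leaf as residual) by
#' fitting an intercept-only linear mixed model with nested random effects
#' by restricted maximum likelihood and extracting the variance components.
#' Negative estimates are truncated at zero before proportions are formed.
#'
#' @param data Tibble with one row per observation (leaf), the value column,
#'   and one column per hierarchy level.
#' @param hierarchy Character vector of column names, outermost level first.
#' @param value Unquoted value column; default `log_lma`.
#' @return Object of class `nested_components`: tibble with `level`
#'   (hierarchy levels then `"residual"`), `variance` and `proportion`.
#' @examples
#' sim <- simulate_region(scenario_config(n_plots = 3, pool_size = 15,
#'                                        layers = "sun", seed = 3))
#' lv <- compute_leaf_lma(sim$leaves)
#' nested_variance_components(dplyr::mutate(lv, log_lma = log(lma)))
#' @export
nested_variance_components <- function(data,
                                       hierarchy = c("plot_id", "family",
                                                     "genus", "species",
                                                     "tree_id"),
                                       value = log_lma) {
  check_columns(data, hierarchy, "hierarchy data")
  check_nesting(data, hierarchy)
  df <- data.frame(.y = pull(data, {{ value }}),
                   lapply(data[hierarchy], as.factor))
  form <- as.formula(paste("~ 1 |", paste(hierarchy, collapse = "/")))
  fit <- nlme::lme(.y ~ 1, random = form, data = df,
                   na.action = stats::na.omit,
                   control = nlme::lmeControl(maxIter = 500, msMaxIter = 500,
                                              tolerance = 1e-8, opt = "optim"))
  vc <- ape::varcomp(fit, scale = FALSE)
  v <- pmax(as.numeric(vc), 0)
  lev <- names(vc)
  lev[lev == "Within"] <- "residual"
  new_nested_components(tibble(level = lev, variance = v,
                               proportion = v / sum(v)))
}

new_nested_components <- function(df) {
  structure(df, class = c("nested_components", class(df)))
}

# Taxonomic labels must be consistently nested (a genus cannot sit under two
# families). Plot and tree levels are nested by interaction in the model, so
# reuse of e.g. a family across plots is expected and allowed.
check_nesting <- function(data, hierarchy) {
  tax <- intersect(hierarchy, c("family", "genus", "species"))
  if (length(tax) < 2) return(invisible(data))
  for (i in seq_along(tax)[-1]) {
    parents <- data |>
      distinct(across(all_of(c(tax[i - 1], tax[i])))) |>
      count(across(all_of(tax[i])), name = ".n_parents") |>
      filter(.data$.n_parents > 1)
    if (nrow(parents)) {
      abort(paste0("Non-nested labels: ", tax[i], " value(s) ",
                   paste(head(pull(parents, tax[i]), 5), collapse = ", "),
                   " occur under more than one ", tax[i - 1], "."))
    }
  }
  invisible(data)
}

#' Method-of-moments variance components for balanced nested designs
#'
#' Closed-form expected-mean-squares solution for a perfectly balanced
#' nested ANOVA; the independent check for
#' [nested_variance_components()] (on balanced data REML and the moments
#' estimator coincide when all estimates are interior).
#'
#' For levels `1..q` (outermost first) with residual level `q+1`, the mean
#' square at level `i` has expectation `sigma^2_{q+1} + sum_{j>=i, j<=q}
#' n_j+ * sigma^2_j`, where `n_j+` is the number of observations per level-`j`
#' unit; solving from the bottom up gives the components (truncated at zero).
#'
#' @inheritParams nested_variance_components
#' @return A `nested_components` tibble, as [nested_variance_components()].
#' @export
moments_oracle <- function(data,
                           hierarchy = c("plot_id", "family", "genus",
                                         "species", "tree_id"),
                           value = log_lma) {
  check_columns(data, hierarchy, "hierarchy data")
  y <- pull(data, {{ value }})
  n <- length(y)
  q <- length(hierarchy)
  # unit labels at each level (full nested path so labels are unique)
  paths <- lapply(seq_len(q), function(i) {
    interaction(data[hierarchy[seq_len(i)]], drop = TRUE)
  })
  counts <- lapply(paths, function(f) as.vector(table(f)))
  if (any(vapply(counts, function(ct) length(unique(ct)) > 1, logical(1))) ||
      length(unique(counts[[1]])) > 1) {
    abort("moments_oracle requires a perfectly balanced design.")
  }
  k <- vapply(paths, nlevels, integer(1))        # units per level
  m <- n / k                                     # observations per unit
  # sums of squares between units at each level, within their parent
  grand <- mean(y)
  level_means <- lapply(paths, function(f) tapply(y, f, mean)[f])
  ss <- numeric(q + 1)
  df_lev <- numeric(q + 1)
  parent_means <- rep(grand, n)
  for (i in seq_len(q)) {
    ss[i] <- sum((level_means[[i]] - parent_means)^2)
    df_lev[i] <- k[i] - (if (i == 1) 1 else k[i - 1])
    parent_means <- level_means[[i]]
  }
  ss[q + 1] <- sum((y - parent_means)^2)
  df_lev[q + 1] <- n - k[q]
  ms <- ss / df_lev
  # solve EMS from the bottom up: MS_i = sigma2_resid + sum_{j=i..q} m_j sigma2_j
  sigma2 <- numeric(q + 1)
  sigma2[q + 1] <- ms[q + 1]
  for (i in rev(seq_len(q))) {
    inner <- if (i < q) sum(m[(i + 1):q] * sigma2[(i + 1):q]) else 0
    sigma2[i] <- (ms[i] - sigma2[q + 1] - inner) / m[i]
  }
  v <- pmax(sigma2, 0)
  new_nested_components(tibble(level = c(hierarchy, "residual"),
                               variance = v, proportion = v / sum(v)))
}

#' @export
print.nested_components <- function(x, ...) {
  cat("Nested variance components:\n")
  NextMethod()
}

#' @method tidy nested_components
#' @export
tidy.nested_components <- function(x, ...) as_tibble(x)

#' Variance-component bar chart
#' @param object A `nested_components` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nested_components
#' @export
autoplot.nested_components <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(level = factor(.data$level, levels = rev(.data$level)))
  ggplot2::ggplot(df, ggplot2::aes(.data$proportion, .data$level)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "proportion of variance", y = NULL) +
    ggplot2::theme_bw()
}

#' Decompose across-plot CWM variance into turnover, intraspecific and
#' covariance parts
#'
#' The community-weighted mean of each plot is computed twice: with
#' plot-specific species means (`specific`) and with region-wide fixed
#' species means (`fixed`), using the same normalised basal-area weights.
#' The across-plot variance of the specific CWM then splits exactly into a
#' species-turnover part (variance of the fixed CWM), an intraspecific part
#' (variance of `specific - fixed`), and a covariance remainder:
#' `ss_specific = ss_fixed + ss_intra + cov`, with `cov` defined as the
#' residual so the identity holds to machine precision. Computed on the raw
#' trait scale (it decomposes the CWM itself).
#'
#' @param populations Plot-specific species means: tibble with `plot_id`,
#'   `species`, `lma` and optionally `layer` (single layer only).
#' @param census Tibble with `plot_id`, `species`, `basal_area`.
#' @return Object of class `turnover_decomposition`: one-row tibble with
#'   the three sums of squares, the covariance, and their proportions of
#'   `ss_specific` (`turnover_share`, `intra_share`, `cov_share`).
#' @export
leps_decomposition <- function(populations, census) {
  check_columns(populations, c("plot_id", "species", "lma"), "populations")
  check_columns(census, c("plot_id", "species", "basal_area"), "census")
  if ("layer" %in% names(populations) &&
      length(unique(populations$layer)) > 1) {
    abort("Multiple canopy layers present; decompose layers separately.")
  }
  if (length(unique(populations$plot_id)) < 2) {
    abort("Need at least 2 plots; across-plot variance undefined.")
  }
  fixed_means <- populations |>
    group_by(.data$species) |>
    summarise(mu_fixed = mean(.data$lma), .groups = "drop")
  joined <- census |>
    inner_join(populations |> select("plot_id", "species", "lma"),
               by = c("plot_id", "species")) |>
    left_join(fixed_means, by = "species")
  lost <- census |>
    anti_join(populations, by = c("plot_id", "species")) |>
    distinct(.data$species)
  if (nrow(lost)) {
    warn(paste0(nrow(lost), " census species without trait data excluded ",
                "from CWM weights (e.g. ",
                paste(head(lost$species, 3), collapse = ", "), ")."))
  }
  per_plot <- joined |>
    group_by(.data$plot_id) |>
    summarise(
      specific = sum(.data$basal_area * .data$lma) / sum(.data$basal_area),
      fixed = sum(.data$basal_area * .data$mu_fixed) / sum(.data$basal_area),
      .groups = "drop"
    ) |>
    mutate(intra = .data$specific - .data$fixed)
  ss_specific <- var(per_plot$specific)
  ss_fixed <- var(per_plot$fixed)
  ss_intra <- var(per_plot$intra)
  cv <- ss_specific - ss_fixed - ss_intra
  out <- tibble(
    ss_specific = ss_specific, ss_fixed = ss_fixed, ss_intra = ss_intra,
    cov = cv,
    turnover_share = ss_fixed / ss_specific,
    intra_share = ss_intra / ss_specific,
    cov_share = cv / ss_specific
  )
  structure(out, class = c("turnover_decomposition", class(out)),
            per_plot = per_plot)
}

#' @method tidy turnover_decomposition
#' @export
tidy.turnover_decomposition <- function(x, ...) {
  tibble(component = c("turnover", "intraspecific", "covariance"),
         ss = c(x$ss_fixed, x$ss_intra, x$cov),
         share = c(x$turnover_share, x$intra_share, x$cov_share))
}

#' Stacked-bar chart of the CWM variance decomposition
#' @param object A `turnover_decomposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot turnover_decomposition
#' @export
autoplot.turnover_decomposition <- function(object, ...) {
  df <- tidy(object) |>
    mutate(component = factor(.data$component,
                              levels = c("covariance", "intraspecific",
                                         "turnover")))
  ggplot2::ggplot(df, ggplot2::aes("CWM variance", .data$share,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_grey(start = 0.8, end = 0.2) +
    ggplot2::labs(x = NULL, y = "share of across-plot CWM variance") +
    ggplot2::theme_bw()
}
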