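#' Sums of squares and variance components for T-statistic ratios
#'
#' For each community (plot) in a tree-level trait table, computes the
#' building blocks of the trait variance ratios: the within-population sum
#' of squares (a population is the set of sampled individuals of one species
#' within one plot), the total within-community sum of squares, the regional
#' sum of squares over all individuals, and the variances of population
#' means within the community and across the region. All quantities are on
#' the scale of the supplied value column (log-LMA throughout the package,
#' to avoid mean--variance scaling effects).
#'
#' Populations with a single individual contribute zero to the
#' within-population sum of squares.
#'
#' @param traits Tree-level trait tibble with `plot_id`, `species` and the
#'   value column; a single canopy layer (filter first if needed).
#' @param value Unquoted value column; default `log_lma`.
#' @return One row per plot: `ss_within_pop`, `ss_community`, `n_c`,
#'   `ss_region`, `n_r`, `var_pop_means_community`, `var_pop_means_region`.
#' @export
variance_components <- function(traits, value = log_lma) {
  check_columns(traits, c("plot_id", "species"), "trait table")
  if ("layer" %in% names(traits) && length(unique(traits$layer)) > 1) {
    abort("Multiple canopy layers present; analyse layers separately.")
  }
  x <- pull(traits, {{ value }})
  n_r <- length(x)
  if (n_r < 2) abort("Need at least 2 individuals in the region.")
  ss_region <- sum((x - mean(x))^2)
  df <- traits |> mutate(.x = x)
  pop_means <- df |>
    group_by(.data$plot_id, .data$species) |>
    summarise(m = mean(.data$.x), .groups = "drop")
  vpr <- var(pop_means$m)
  out <- df |>
    group_by(.data$plot_id, .data$species) |>
    mutate(.pm = mean(.data$.x)) |>
    group_by(.data$plot_id) |>
    summarise(
      ss_within_pop = sum((.data$.x - .data$.pm)^2),
      ss_community = sum((.data$.x - mean(.data$.x))^2),
      n_c = n(),
      .groups = "drop"
    ) |>
    mutate(ss_region = ss_region, n_r = n_r)
  vpc <- pop_means |>
    group_by(.data$plot_id) |>
    summarise(var_pop_means_community = var(.data$m), .groups = "drop")
  out <- out |>
    left_join(vpc, by = "plot_id") |>
    mutate(var_pop_means_region = vpr)
  small <- out |> filter(.data$n_c < 2)
  if (nrow(small)) {
    abort(paste0("Plot(s) with fewer than 2 individuals: ",
                 paste(small$plot_id, collapse = ", ")))
  }
  out
}

#' Observed T-statistic variance ratios
#'
#' * `t_ip_ic`: within-population over total within-community variation
#'   (shared denominator cancels, so the ratio is the bounded sum-of-squares
#'   fraction in \[0, 1\]); low values indicate internal filtering (niche
#'   packing) acting on individuals.
#' * `t_ic_ir`: within-community variance over regional-pool variance at the
#'   individual level; low values indicate external (environmental)
#'   filtering acting on individuals.
#' * `t_pc_pr`: variance of population means within the community over the
#'   variance of population means across the region; external filtering at
#'   the species level.
#'
#' @param vc Output of [variance_components()].
#' @return Numeric vector, one ratio per plot (in `vc` row order).
#' @examples
#' tr <- tibble::tibble(plot_id = "A", species = rep(c("a", "b"), each = 2),
#'                      log_lma = c(10, 12, 20, 22))
#' t_ip_ic(variance_components(tr))  # 4 / 104
#' @export
t_ip_ic <- function(vc) {
  if (any(vc$ss_community == 0)) {
    abort(paste0("All individuals identical in plot(s) ",
                 paste(vc$plot_id[vc$ss_community == 0], collapse = ", "),
                 "; T_ip.ic undefined."))
  }
  vc$ss_within_pop / vc$ss_community
}

#' @rdname t_ip_ic
#' @export
t_ic_ir <- function(vc) {
  if (any(vc$ss_region == 0)) abort("Regional pool has zero variance; T_ic.ir undefined.")
  (vc$ss_community / (vc$n_c - 1)) / (vc$ss_region / (vc$n_r - 1))
}

#' @rdname t_ip_ic
#' @export
t_pc_pr <- function(vc) {
  if (any(is.na(vc$var_pop_means_region)) || any(vc$var_pop_means_region == 0)) {
    abort("Degenerate regional pool of population means; T_pc.pr undefined.")
  }
  vc$var_pop_means_community / vc$var_pop_means_region
}

t_stat_names <- c("t_ip_ic", "t_ic_ir", "t_pc_pr")

#' Permutation null distributions for the T-statistics
#'
#' One scheme per statistic, each randomising exactly the structure the
#' statistic measures while holding everything else fixed:
#' \describe{
#'   \item{t_ip_ic}{individual values are shuffled among the individuals of
#'     each community, destroying population structure but preserving the
#'     community trait pool;}
#'   \item{t_ic_ir}{each community is rebuilt by drawing its `n_c`
#'     individual values without replacement from the regional pool of
#'     individuals;}
#'   \item{t_pc_pr}{population-mean values are shuffled across all
#'     populations in the region, preserving each community's number of
#'     populations.}
#' }
#' Each permutation recomputes the statistic for every community. Tied or
#' duplicated values permute as ordinary values.
#'
#' @inheritParams variance_components
#' @param statistic One of `"t_ip_ic"`, `"t_ic_ir"`, `"t_pc_pr"`.
#' @param nperm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return Numeric matrix, plots x permutations, with plot ids as row names.
#' @export
null_distribution <- function(traits, statistic, nperm = 999, seed = 1L,
                              value = log_lma) {
  statistic <- match.arg(statistic, t_stat_names)
  if (nperm < 99) abort("nperm must be at least 99.")
  set.seed(seed)
  x <- pull(traits, {{ value }})
  plot <- as.character(traits$plot_id)
  plot_ids <- unique(plot)
  nulls <- matrix(NA_real_, length(plot_ids), nperm,
                  dimnames = list(plot_ids, NULL))

  if (statistic == "t_ip_ic") {
    for (p in plot_ids) {
      idx <- which(plot == p)
      xp <- x[idx]
      pop <- factor(paste(plot[idx], traits$species[idx]))
      n_g <- as.vector(table(pop))
      ssc <- sum((xp - mean(xp))^2)
      if (ssc == 0) abort(paste0("Plot ", p, ": zero community variance."))
      X <- vapply(seq_len(nperm), function(j) sample(xp), numeric(length(xp)))
      gs <- rowsum(X, pop)
      nulls[p, ] <- (colSums(X^2) - colSums(gs^2 / n_g)) / ssc
    }
  } else if (statistic == "t_ic_ir") {
    n_r <- length(x)
    var_r <- sum((x - mean(x))^2) / (n_r - 1)
    if (var_r == 0) abort("Regional pool has zero variance.")
    for (p in plot_ids) {
      n_c <- sum(plot == p)
      if (n_c > n_r) abort(paste0("Plot ", p, " larger than the regional pool."))
      X <- vapply(seq_len(nperm),
                  function(j) x[sample.int(n_r, n_c)], numeric(n_c))
      v <- (colSums(X^2) - colSums(X)^2 / n_c) / (n_c - 1)
      nulls[p, ] <- v / var_r
    }
  } else {
    pm <- traits |>
      mutate(.x = x) |>
      group_by(.data$plot_id, .data$species) |>
      summarise(m = mean(.data$.x), .groups = "drop")
    m <- pm$m
    pplot <- as.character(pm$plot_id)
    v_all <- var(m)
    if (is.na(v_all) || v_all == 0) abort("Degenerate regional pool of population means.")
    M <- vapply(seq_len(nperm), function(j) sample(m), numeric(length(m)))
    s1 <- rowsum(M, pplot)
    s2 <- rowsum(M^2, pplot)
    k <- as.vector(table(pplot)[rownames(s1)])
    vmat <- (s2 - s1^2 / k) / (k - 1)
    nulls[rownames(s1), ] <- vmat / v_all
  }
  nulls
}

#' Standardized effect size against a permutation null
#'
#' `ses = (observed - mean(null)) / sd(null)`. The null confidence interval
#' is reported on the SES scale: the `alpha/2` and `1 - alpha/2` quantiles
#' of the SES-transformed null values. An observed SES outside this box is
#' flagged significant; the lower the SES, the stronger the filter.
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Numeric vector of null statistic values.
#' @param alpha Two-sided significance level (default 0.05).
#' @return One-row tibble: `observed`, `ses`, `null_mean`, `null_sd`,
#'   `ci_low`, `ci_high` (SES scale), `significant`.
#' @export
ses <- function(observed, null_values, alpha = 0.05) {
  mu <- mean(null_values)
  s <- sd(null_values)
  if (!is.finite(s) || s == 0) abort("Degenerate null: zero spread.")
  z <- (null_values - mu) / s
  ci <- quantile(z, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  obs_z <- (observed - mu) / s
  tibble(observed = observed, ses = obs_z, null_mean = mu, null_sd = s,
         ci_low = ci[1], ci_high = ci[2],
         significant = obs_z < ci[1] | obs_z > ci[2])
}

#' T-statistics with permutation nulls for every community
#'
#' Computes the three observed trait variance ratios for each plot, builds
#' their permutation null distributions (one scheme per statistic, see
#' [null_distribution()]), and summarises each as a standardized effect
#' size with a null confidence box, plus transect-level aggregates (the
#' mean SES over plots compared against the null distribution of the mean).
#'
#' Permutation seeds are split deterministically from `seed`: statistic
#' number `i` (in the order `t_ip_ic`, `t_ic_ir`, `t_pc_pr`) uses
#' `seed * 10 + i`.
#'
#' @inheritParams variance_components
#' @param nperm Number of permutations per statistic (default 999, >= 99).
#' @param seed Master seed.
#' @param alpha Two-sided significance level.
#' @param keep_nulls Keep the full null matrices in the result (default
#'   `TRUE`; set `FALSE` to save memory).
#' @return Object of class `tstats`; see [tidy.tstats()] and
#'   [glance.tstats()].
#' @examples
#' sim <- simulate_region(scenario_config(n_plots = 4, pool_size = 15,
#'                                        layers = "sun", seed = 2))
#' traits <- ingest_leaves(sim$leaves)$trees
#' ts <- tstats(traits, nperm = 99, seed = 1)
#' tidy(ts)
#' @export
tstats <- function(traits, value = log_lma, nperm = 999, seed = 1L,
                   alpha = 0.05, keep_nulls = TRUE) {
  if (nperm < 99) abort("nperm must be at least 99.")
  vc <- variance_components(traits, {{ value }})
  observed <- list(t_ip_ic = t_ip_ic(vc), t_ic_ir = t_ic_ir(vc),
                   t_pc_pr = t_pc_pr(vc))
  per_plot <- list()
  agg <- list()
  nulls <- list()
  for (i in seq_along(t_stat_names)) {
    stat <- t_stat_names[i]
    nl <- null_distribution(traits, stat, nperm = nperm,
                            seed = seed * 10L + i, value = {{ value }})
    nl <- nl[vc$plot_id, , drop = FALSE]
    obs <- observed[[stat]]
    # a community with a single population (or an otherwise degenerate null)
    # has no defined ratio/null for some statistics: report NA, do not fail
    null_sd <- apply(nl, 1, function(z) if (all(is.finite(z))) sd(z) else NA_real_)
    valid <- !is.na(obs) & is.finite(null_sd) & null_sd > 0
    rows <- map(seq_along(obs), function(k) {
      if (valid[k]) {
        ses(obs[k], nl[k, ], alpha)
      } else {
        tibble(observed = obs[k], ses = NA_real_, null_mean = NA_real_,
               null_sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               significant = NA)
      }
    })
    if (any(!valid)) {
      warn(paste0("Plot(s) ", paste(vc$plot_id[!valid], collapse = ", "),
                  ": ", stat, " undefined (degenerate community or null); ",
                  "reported as NA."))
    }
    per_plot[[stat]] <- bind_rows(rows) |>
      mutate(plot_id = vc$plot_id, statistic = stat, .before = 1)
    agg[[stat]] <- (if (sum(valid) >= 2) {
      aggregate_ses(per_plot[[stat]][valid, ], nl[valid, , drop = FALSE],
                    alpha)
    } else {
      tibble(mean_ses = NA_real_, sd_ses = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, significant = NA, n_plots = sum(valid))
    }) |>
      mutate(statistic = stat, .before = 1)
    if (keep_nulls) nulls[[stat]] <- nl
  }
  structure(list(
    per_plot = bind_rows(per_plot) |>
      mutate(nperm = nperm, seed = seed, alpha = alpha),
    aggregate = bind_rows(agg),
    nulls = nulls,
    nperm = nperm, seed = seed, alpha = alpha
  ), class = "tstats")
}

#' Transect-level aggregation of standardized effect sizes
#'
#' Averages per-plot SES values for one statistic and compares the mean
#' against its own null distribution: for each permutation, the SES of every
#' plot's null value is computed and averaged over plots; the confidence box
#' is the quantile interval of those permutation means.
#'
#' @param per_plot Per-plot SES tibble for one statistic (columns `ses`,
#'   `null_mean`, `null_sd`, in the row order of `null_matrix`).
#' @param null_matrix Plots x permutations null matrix for the statistic.
#' @param alpha Two-sided significance level.
#' @return One-row tibble: `mean_ses`, `sd_ses`, `ci_low`, `ci_high`,
#'   `significant`, `n_plots`.
#' @export
aggregate_ses <- function(per_plot, null_matrix, alpha = 0.05) {
  if (nrow(per_plot) < 2) abort("Need at least 2 plots to aggregate.")
  z <- (null_matrix - per_plot$null_mean) / per_plot$null_sd
  null_mean_ses <- colMeans(z)
  ci <- quantile(null_mean_ses, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  m <- mean(per_plot$ses)
  tibble(mean_ses = m, sd_ses = sd(per_plot$ses),
         ci_low = ci[1], ci_high = ci[2],
         significant = m < ci[1] | m > ci[2],
         n_plots = nrow(per_plot))
}

#' @export
print.tstats <- function(x, ...) {
  cat("<tstats>", length(unique(x$per_plot$plot_id)), "plots,",
      x$nperm, "permutations, alpha =", x$alpha, "\n\n")
  print(x$aggregate)
  invisible(x)
}

#' Tidy per-plot T-statistic results
#'
#' @param x A [tstats()] object.
#' @param ... Unused.
#' @return Tibble with one row per plot x statistic: observed ratio, SES,
#'   null confidence box and significance flag.
#' @method tidy tstats
#' @export
tidy.tstats <- function(x, ...) x$per_plot

#' Transect-level summary of a T-statistics fit
#'
#' @param x A [tstats()] object.
#' @param ... Unused.
#' @return Tibble with one row per statistic: mean and SD of per-plot SES,
#'   pooled null confidence box and significance of the mean.
#' @method glance tstats
#' @export
glance.tstats <- function(x, ...) x$aggregate

#' SES-by-plot plot for a T-statistics fit
#'
#' Per-plot standardized effect sizes for the three variance ratios with
#' their null confidence boxes; points outside the ribbon indicate
#' significant departure from random assembly (low = filtering).
#'
#' @param object A [tstats()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tstats
#' @export
autoplot.tstats <- function(object, ...) {
  df <- object$per_plot
  ggplot2::ggplot(df, ggplot2::aes(.data$plot_id, .data$ses)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.4, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~statistic, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "standardized effect size") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

utils::globalVariables(c("log_lma", ".x", ".pm"))
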