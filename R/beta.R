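#' Pairwise Sorensen dissimilarity between plots
#'
#' Incidence-based Sorensen index from a plot-by-species census:
#' `beta_sor(j, k) = (b + c) / (2a + b + c)`, with `a` the number of shared
#' species and `b`, `c` the numbers unique to each plot. A species is
#' present where its basal area is positive.
#'
#' @param census Tibble with `plot_id`, `species`, `basal_area`.
#' @return Symmetric numeric matrix with zero diagonal, plot ids as
#'   dimnames, entries in \[0, 1\].
#' @examples
#' cen <- tibble::tibble(plot_id = rep(c("A", "B"), each = 2),
#'                       species = c("x", "y", "y", "z"), basal_area = 1)
#' sorensen_matrix(cen)  # A-B dissimilarity 0.5
#' @export
sorensen_matrix <- function(census) {
  check_columns(census, c("plot_id", "species", "basal_area"), "census")
  pres <- census |>
    filter(.data$basal_area > 0) |>
    distinct(.data$plot_id, .data$species)
  plots <- unique(census$plot_id)
  empty <- setdiff(plots, unique(pres$plot_id))
  if (length(empty)) {
    abort(paste0("Plot(s) with zero species present: ",
                 paste(empty, collapse = ", ")))
  }
  inc <- table(pres$plot_id, pres$species) > 0
  inc <- inc[plots, , drop = FALSE]
  shared <- inc %*% t(inc)                  # a
  rich <- diag(shared)
  tot <- outer(rich, rich, "+")             # 2a + b + c
  d <- (tot - 2 * shared) / tot             # (b + c) / (2a + b + c)
  diag(d) <- 0
  dimnames(d) <- list(plots, plots)
  d
}

#' Pairwise distance in an environmental covariate
#'
#' Absolute differences `|v_j - v_k|` of a named plot covariate.
#'
#' @param meta Plot metadata tibble with `plot_id` and the covariate.
#' @param variable Column name (string) of the covariate.
#' @return Symmetric numeric matrix with plot ids as dimnames.
#' @export
env_distance <- function(meta, variable = "elevation") {
  check_columns(meta, c("plot_id", variable), "plot metadata")
  v <- meta[[variable]]
  if (anyNA(v)) {
    abort(paste0("Missing `", variable, "` for plot(s): ",
                 paste(meta$plot_id[is.na(v)], collapse = ", ")))
  }
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(meta$plot_id, meta$plot_id)
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' joint row/column permutations of the second matrix. The p-value is
#' one-sided for positive association (the standard choice for a Mantel
#' test): `p = (1 + #\{permuted r >= observed r\}) / (nperm + 1)`.
#'
#' @param d1,d2 Symmetric distance matrices with matching plot labels.
#' @param nperm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return One-row tibble: `r`, `p_value`, `nperm`.
#' @export
mantel_test <- function(d1, d2, nperm = 999, seed = 1L) {
  if (nperm < 99) abort("nperm must be at least 99.")
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2))) {
      abort("Distance matrices have non-matching plot labels.")
    }
    d2 <- d2[rownames(d1), rownames(d1)]
  } else if (!all(dim(d1) == dim(d2))) {
    abort("Distance matrices have different dimensions.")
  }
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  if (sd(v1) == 0 || sd(d2[lower]) == 0) {
    abort("Constant lower triangle; Mantel correlation undefined.")
  }
  r_obs <- stats::cor(v1, d2[lower])
  set.seed(seed)
  n <- nrow(d1)
  r_perm <- vapply(seq_len(nperm), function(j) {
    o <- sample.int(n)
    stats::cor(v1, d2[o, o][lower])
  }, numeric(1))
  tibble(r = r_obs,
         p_value = (1 + sum(r_perm >= r_obs)) / (nperm + 1),
         nperm = nperm)
}

#' Write a labelled square distance matrix as CSV
#'
#' @param d Distance matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- as.data.frame(d)
  df <- cbind(plot_id = rownames(d), df)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}
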