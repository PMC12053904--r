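#' Center and scale a feature table to per-feature z-scores
#'
#' Each feature column is centered by its mean and scaled by its sample
#' standard deviation (n - 1 denominator). Constant columns cannot be scaled
#' and become all-zero, with a warning listing them.
#'
#' @param table A `feature_table` with at least two samples.
#' @return A tibble `sample_id` + z-score columns, with attributes `center`,
#'   `scale` (named numeric vectors) and `constant_features` (character).
#' @export
center_scale <- function(table) {
  m <- ft_matrix(table)
  if (nrow(m) < 2) msg_stop("too-few-samples", "center_scale needs >= 2 samples")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  const <- colnames(m)[s == 0]
  if (length(const)) {
    msg_warn("constant-features", "constant features set to zero: " %+% comma(const))
  }
  s_safe <- ifelse(s == 0, 1, s)
  z <- sweep(sweep(m, 2, mu, "-"), 2, s_safe, "/")
  z[, const] <- 0
  fk <- attr(table, "feature_kind")
  if (is.null(fk) || is.na(fk)) fk <- "genus"
  out <- ft_from_matrix(z, feature_kind = fk, value_kind = "scaled")
  attr(out, "center") <- mu
  attr(out, "scale") <- s
  attr(out, "constant_features") <- const
  out
}

#' Principal component analysis of a scaled table
#'
#' Eigendecomposition of the covariance of the z-scored table; identical to
#' a principal-coordinates analysis of Euclidean distances between the same
#' rows. The sign of each component is fixed so that its largest-magnitude
#' loading is positive, which makes PC1 time series reproducible.
#'
#' @param z A scaled table from [center_scale()] (or any tibble with a
#'   `sample_id` column and centered numeric columns).
#' @param n_components Number of components to keep (default all).
#' @return An object of class `pca_ord` with elements `scores` (tibble),
#'   `loadings` (tibble), `variance_explained` (numeric fractions), `sdev`.
#'   Use [tidy()] / [glance()] to extract tables.
#' @export
pca_ordination <- function(z, n_components = NULL) {
  m <- ft_matrix(z)
  if (nrow(m) < 2) msg_stop("too-few-samples", "pca needs >= 2 samples")
  kmax <- min(nrow(m) - 1, ncol(m))
  k <- min(n_components %||% kmax, kmax)
  # columns are already centered; prcomp would re-center, which is a no-op
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  tot_var <- sum(apply(m, 2, stats::var))
  ve <- pc$sdev^2 / tot_var
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  structure(list(
    scores = tibble(sample_id = rownames(m)) %>%
      dplyr::bind_cols(as_tibble(sco)),
    loadings = tibble(feature = colnames(m)) %>%
      dplyr::bind_cols(as_tibble(rot)),
    variance_explained = ve[seq_len(k)],
    sdev = pc$sdev[seq_len(k)]
  ), class = "pca_ord")
}

#' @export
print.pca_ord <- function(x, ...) {
  cat("PCA ordination:", nrow(x$scores), "samples,",
      length(x$variance_explained), "components\n")
  cat("variance explained:",
      paste0(round(100 * x$variance_explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_ordination
#' @param x A `pca_ord` object.
#' @param matrix Which table to return: `"scores"`, `"loadings"`, or
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.pca_ord <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble(component = seq_along(x$sdev),
                         eigenvalue = x$sdev^2,
                         variance_explained = x$variance_explained)
  )
}

#' Permutational multivariate ANOVA (one factor)
#'
#' Partitions the total sum of squared distances among and within groups and
#' tests the pseudo-F statistic by permuting group labels. The p-value uses
#' the (1 + count) / (n_permutations + 1) estimator, so its smallest
#' attainable value is exactly 1 / (n_permutations + 1). With
#' `n_permutations = "exhaustive"` every distinct label ordering is
#' enumerated (small n only) and the p-value is the exact permutation
#' p-value.
#'
#' @param dist A `dist` object or symmetric matrix of distances with zero
#'   diagonal.
#' @param groups Group labels, one per observation (>= 2 groups).
#' @param n_permutations Number of random label permutations (default 999),
#'   or `"exhaustive"`.
#' @param seed Integer seed for the permutations (ignored for exhaustive).
#' @return An object of class `permanova_fit` with `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations`, `seed`, `df`, and the SS partition.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0)) {
    msg_stop("bad-dist", "distance matrix must be symmetric with zero diagonal")
  }
  g <- as.factor(groups)
  n <- nrow(d)
  if (length(g) != n) msg_stop("bad-groups", "one label per observation required")
  if (nlevels(g) < 2) msg_stop("bad-groups", "need >= 2 groups")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  if (ss_total == 0) msg_stop("no-variation", "all points identical")
  df_b <- nlevels(g) - 1L
  df_w <- n - nlevels(g)
  ss_w_of <- function(gg) {
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(gg == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ss_w
  }
  f_of <- function(gg) {
    ss_w <- ss_w_of(gg)
    ((ss_total - ss_w) / df_b) / (ss_w / df_w)
  }
  f_obs <- f_of(g)
  if (identical(n_permutations, "exhaustive")) {
    if (n > 9) msg_stop("too-big", "exhaustive enumeration limited to n <= 9")
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(p) f_of(g[p]), numeric(1))
    p_val <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    f_perm <- vapply(seq_len(n_permutations), function(b) f_of(sample(g)),
                     numeric(1))
    p_val <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  ss_within <- ss_w_of(g)
  structure(list(
    pseudo_F = f_obs, R2 = (ss_total - ss_within) / ss_total,
    p_value = p_val, n_permutations = n_perm, seed = seed,
    df = c(between = df_b, within = df_w),
    ss = c(total = ss_total, between = ss_total - ss_within,
           within = ss_within)
  ), class = "permanova_fit")
}

# All n! index permutations (identity included); recursion, small n only.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (p in sub) {
    for (i in seq_len(n)) {
      out[[k]] <- append(p, n, after = i - 1L)
      k <- k + 1L
    }
  }
  out
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' @rdname permanova
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble(term = c("between", "within", "total"),
         df = c(x$df[["between"]], x$df[["within"]], sum(x$df)),
         SS = c(x$ss[["between"]], x$ss[["within"]], x$ss[["total"]]),
         pseudo_F = c(x$pseudo_F, NA, NA),
         R2 = c(x$R2, NA, NA),
         p_value = c(x$p_value, NA, NA))
}

#' @rdname permanova
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
         n_permutations = x$n_permutations)
}

#' Nearest-neighbor (temporally adjacent) Euclidean dissimilarity
#'
#' For each sample after the first in chronological order, the Euclidean
#' distance to the immediately preceding sample — a direct readout of rapid
#' community turnover between consecutive sampling points.
#'
#' @param z A scaled table from [center_scale()].
#' @param metadata Sample metadata.
#' @param tie_break Optional character vector of sample ids giving a total
#'   order, required when collection dates are duplicated.
#' @return A tibble `sample_id`, `date`, `nn_dist`, date-ordered; the first
#'   sample has `nn_dist = NA`.
#' @export
nn_dissimilarity <- function(z, metadata, tie_break = NULL) {
  md <- align_metadata(z, metadata)
  if (anyDuplicated(md$date)) {
    if (is.null(tie_break)) {
      msg_stop("duplicate-dates",
               "duplicate collection dates; supply tie_break order")
    }
    ord <- order(md$date, match(md$sample_id, tie_break))
  } else {
    ord <- order(md$date)
  }
  m <- ft_matrix(z)[ord, , drop = FALSE]
  dd <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  tibble(sample_id = md$sample_id[ord], date = md$date[ord],
         nn_dist = c(NA_real_, unname(dd)))
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise distance; merge heights are non-decreasing.
#'
#' @param dist A `dist` object or symmetric distance matrix (>= 2 items).
#' @return A `stats::hclust` object.
#' @seealso [linkage_table()] for the merge list as a tibble.
#' @export
hclust_complete <- function(dist) {
  d <- as.dist(dist)
  if (attr(d, "Size") < 2) msg_stop("too-few-samples", "clustering needs >= 2 items")
  hclust(d, method = "complete")
}

#' @rdname hclust_complete
#' @param hc An `hclust` object.
#' @return `linkage_table()`: a tibble `step`, `member_1`, `member_2`,
#'   `height`; negative members are singleton indices, positive members
#'   earlier merge steps.
#' @export
linkage_table <- function(hc) {
  tibble(step = seq_len(nrow(hc$merge)),
         member_1 = hc$merge[, 1], member_2 = hc$merge[, 2],
         height = hc$height)
}
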