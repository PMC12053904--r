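# Small in-code fixtures shared across test files.

# A feature table from a plain matrix (rows samples, cols features).
ft_of <- function(m, feature_kind = "genus", value_kind = "rpkm",
                  sample_ids = NULL, feature_ids = NULL) {
  if (is.null(rownames(m))) {
    rownames(m) <- sample_ids %||% sprintf("s%02d", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) {
    colnames(m) <- feature_ids %||% sprintf("f%02d", seq_len(ncol(m)))
  }
  df <- tibble::tibble(sample_id = rownames(m))
  df <- dplyr::bind_cols(df, tibble::as_tibble(m, .name_repair = "minimal"))
  feature_table(df, feature_kind = feature_kind, value_kind = value_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Metadata for n monthly samples starting at a given year, baseline
# throughout unless post_from is given.
md_monthly <- function(n, start_year = 2011, post_from = NULL,
                       stage_baseline = "pre", stage_post = "post") {
  months <- (seq_len(n) - 1) %% 12 + 1
  years <- start_year + (seq_len(n) - 1) %/% 12
  dates <- as.Date(sprintf("%d-%02d-15", years, months))
  period <- if (is.null(post_from)) rep("baseline", n) else
    ifelse(dates >= as.Date(post_from), "post", "baseline")
  sample_metadata(tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)), date = dates,
    stage = ifelse(period == "baseline", stage_baseline, stage_post),
    period = period
  ))
}

# Log10-transform a positive feature table (lognormal simulations become
# exactly Gaussian, so the additive year+month model is correctly specified).
log10_ft <- function(table) {
  m <- log10(ft_matrix(table))
  df <- tibble::tibble(sample_id = rownames(m))
  df <- dplyr::bind_cols(df, tibble::as_tibble(m, .name_repair = "minimal"))
  feature_table(df, feature_kind = attr(table, "feature_kind"),
                value_kind = "scaled")
}

# all permutations of seq_len(n), independent recursive construction
gtools_style_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in gtools_style_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# Independent IndVal.g oracle: explicit loops over stages and combinations.
oracle_indval <- function(m, stages, combos) {
  levs <- sort(unique(stages))
  best <- 0
  for (combo in combos) {
    mu_all <- 0; mu_in <- 0
    for (lev in levs) {
      mu <- mean(m[stages == lev])
      mu_all <- mu_all + mu
      if (lev %in% combo) mu_in <- mu_in + mu
    }
    a <- mu_in / mu_all
    in_idx <- stages %in% combo
    b <- sum(m[in_idx] > 0) / sum(in_idx)
    s <- sqrt(a * b)
    if (is.finite(s) && s > best) best <- s
  }
  best
}

# Independent one-way PERMANOVA pseudo-F, written as plain loops over the
# distance matrix (oracle; no shared code with the implementation).
oracle_pseudo_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  g <- as.character(groups)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      acc <- 0
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b) acc <- acc + d[idx[a], idx[b]]^2
      }
      ss_w <- ss_w + acc / length(idx)
    }
  }
  k <- length(unique(g))
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}
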