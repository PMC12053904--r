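#' Indicator value analysis with a permutation null
#'
#' For each feature and each allowed combination of temporal stages, the
#' group-size-corrected indicator value: specificity
#' `A = sum of per-stage mean abundances inside the combination / sum over
#' all stages` and fidelity `B = fraction of the combination's samples where
#' the feature is present (abundance > 0)`; the statistic is `sqrt(A * B)`.
#' Each feature is assigned the combination maximizing the statistic, and
#' significance comes from permuting stage labels: the p-value counts
#' permutations whose best-combination statistic matches or exceeds the
#' observed one, with the (1 + count)/(n + 1) estimator.
#'
#' @param table A `feature_table` (typically KO-level RPKM).
#' @param metadata Sample metadata supplying the `stage` column, or a vector
#'   of stage labels aligned to the table's samples.
#' @param post_stages Optional set of stages forming the post-disturbance
#'   period; their union is added to the allowed combinations (the minimal
#'   set supporting single-post-stage and all-post-stages selection).
#' @param all_combinations If `TRUE`, every non-empty proper subset of the
#'   stages is allowed instead.
#' @param n_permutations Random label permutations (default 999) or
#'   `"exhaustive"` (small n).
#' @param seed Integer seed for the permutations.
#' @return An `indval_result` tibble: `feature`, `best_combination` (stage
#'   labels joined with `"+"`), `A`, `B`, `stat`, `p`, `absent`;
#'   attributes `stages`, `n_permutations`, `seed`.
#' @export
indval <- function(table, metadata, post_stages = NULL,
                   all_combinations = FALSE, n_permutations = 999,
                   seed = NULL) {
  m <- ft_matrix(table)
  if (is.data.frame(metadata)) {
    md <- align_metadata(table, metadata)
    stages <- md$stage
  } else {
    stages <- as.character(metadata)
    if (length(stages) != nrow(m)) {
      msg_stop("bad-groups", "one stage label per sample required")
    }
  }
  g <- factor(stages)
  if (nlevels(g) < 2) msg_stop("bad-groups", "need >= 2 stages")
  if (any(table(g) < 2)) msg_stop("bad-groups", "each stage needs >= 2 samples")

  combos <- indval_combos(levels(g), post_stages, all_combinations)
  pres <- (m > 0) * 1
  n_g <- as.vector(table(g))

  stat_all <- function(gg) {
    mu <- rowsum(m, gg, reorder = TRUE) / as.vector(table(gg))
    pc <- rowsum(pres, gg, reorder = TRUE)
    tot <- colSums(mu)
    best <- rep(0, ncol(m))
    best_i <- rep(1L, ncol(m))
    for (ci in seq_along(combos)) {
      idx <- combos[[ci]]
      a <- colSums(mu[idx, , drop = FALSE]) / tot
      b <- colSums(pc[idx, , drop = FALSE]) / sum(as.vector(table(gg))[idx])
      s <- sqrt(pmax(a, 0) * b)
      s[!is.finite(s)] <- 0
      upd <- s > best
      best[upd] <- s[upd]
      best_i[upd] <- ci
    }
    list(stat = best, combo = best_i)
  }

  obs <- stat_all(g)
  if (identical(n_permutations, "exhaustive")) {
    if (nrow(m) > 9) msg_stop("too-big", "exhaustive enumeration limited to n <= 9")
    perms <- all_permutations(nrow(m))
    ge <- rep(0L, ncol(m))
    for (p in perms) {
      ge <- ge + (stat_all(g[p])$stat >= obs$stat - 1e-12)
    }
    p_val <- ge / length(perms)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    ge <- rep(0L, ncol(m))
    for (b in seq_len(n_permutations)) {
      ge <- ge + (stat_all(sample(g))$stat >= obs$stat - 1e-12)
    }
    p_val <- (1 + ge) / (n_permutations + 1)
    n_perm <- n_permutations
  }

  absent <- colSums(m) == 0
  combo_label <- vapply(combos, function(i) paste(levels(g)[i], collapse = "+"), "")
  # recompute A and B of the chosen combination for reporting
  mu <- rowsum(m, g, reorder = TRUE) / n_g
  pc <- rowsum(pres, g, reorder = TRUE)
  tot <- colSums(mu)
  a_best <- b_best <- numeric(ncol(m))
  for (ci in seq_along(combos)) {
    sel <- obs$combo == ci
    if (!any(sel)) next
    idx <- combos[[ci]]
    a_best[sel] <- (colSums(mu[idx, , drop = FALSE]) / tot)[sel]
    b_best[sel] <- (colSums(pc[idx, , drop = FALSE]) / sum(n_g[idx]))[sel]
  }
  out <- tibble(
    feature = colnames(m),
    best_combination = combo_label[obs$combo],
    A = unname(ifelse(absent, 0, a_best)),
    B = unname(ifelse(absent, 0, b_best)),
    stat = unname(ifelse(absent, 0, obs$stat)),
    p = unname(ifelse(absent, 1, p_val)),
    absent = unname(absent)
  )
  structure(out, class = c("indval_result", class(out)),
            stages = levels(g), n_permutations = n_perm, seed = seed)
}

indval_combos <- function(stages, post_stages, all_combinations) {
  k <- length(stages)
  if (all_combinations) {
    combos <- unlist(lapply(seq_len(k - 1), function(sz) {
      utils::combn(k, sz, simplify = FALSE)
    }), recursive = FALSE)
    return(combos)
  }
  combos <- as.list(seq_len(k))
  if (!is.null(post_stages)) {
    bad <- setdiff(post_stages, stages)
    if (length(bad)) msg_stop("bad-stages", "unknown post stages: " %+% comma(bad))
    idx <- sort(match(unique(post_stages), stages))
    if (length(idx) > 1 && length(idx) < k) combos <- c(combos, list(idx))
  }
  combos
}

#' Select features associated with post-disturbance stages
#'
#' The selection rule applied to indicator results: significant features
#' whose best combination is a single post-disturbance stage, and significant
#' features whose best combination is exactly the union of all
#' post-disturbance stages.
#'
#' @param results An [indval()] result.
#' @param post_stages Character vector of the post-disturbance stages; must
#'   be a subset of the stages the results were computed over.
#' @param alpha Significance level (default 0.05, raw p-values).
#' @param adjust `"none"` (default) or `"BH"` to select on
#'   Benjamini-Hochberg adjusted p-values.
#' @return The results tibble with a `selected_list` column:
#'   `"single_post"`, `"all_post"`, or `"none"`.
#' @export
select_stage_associated <- function(results, post_stages, alpha = 0.05,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stages <- attr(results, "stages")
  bad <- setdiff(post_stages, stages)
  if (length(bad)) {
    msg_stop("bad-stages", "post stages not among observed stages: " %+% comma(bad))
  }
  p_sel <- if (adjust == "BH") p.adjust(results$p, "BH") else results$p
  all_post <- paste(stages[sort(match(unique(post_stages), stages))],
                    collapse = "+")
  sig <- p_sel < alpha
  out <- as_tibble(results)
  out$selected_list <- dplyr::case_when(
    sig & out$best_combination %in% post_stages ~ "single_post",
    sig & out$best_combination == all_post ~ "all_post",
    TRUE ~ "none"
  )
  out
}
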