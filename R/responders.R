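#' Responder and susceptible taxon panels
#'
#' A panel is a curated table of taxa with a role: `"responder"` for taxa
#' reported to bloom after oil exposure (hydrocarbon degraders and
#' opportunists) and `"susceptible"` for taxa that decline (picocyanobacteria
#' and SAR11). Panels are data, not code: any two-column TSV
#' (`feature_id`, `role`) loads. The packaged default panel lists the
#' responder and susceptible genera of the Orange County oil-spill study's
#' main text.
#'
#' @param path Path to a panel TSV.
#' @return A tibble `feature_id`, `role`.
#' @export
read_responder_panel <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("feature_id", "role") %in% names(x))) {
    msg_stop("bad-panel", "panel needs columns feature_id, role")
  }
  bad <- setdiff(unique(x$role), c("susceptible", "responder"))
  if (length(bad)) msg_stop("bad-panel", "unknown roles: " %+% comma(bad))
  if (anyDuplicated(x$feature_id)) {
    msg_stop("bad-panel", "duplicate panel features: " %+%
               comma(x$feature_id[duplicated(x$feature_id)]))
  }
  x[, c("feature_id", "role")]
}

#' @rdname read_responder_panel
#' @export
default_responder_panel <- function() {
  read_responder_panel(system.file("extdata", "responder_panel.tsv",
                                   package = "spillwatch", mustWork = TRUE))
}

panel_features <- function(relabund, panel, role) {
  ids <- panel$feature_id[panel$role %in% role]
  present <- intersect(ids, feature_ids(relabund))
  missing <- setdiff(ids, present)
  if (length(missing)) {
    msg_warn("missing-panel-features",
             "panel features absent from table (counted 0): " %+% comma(missing))
  }
  present
}

#' Summed relative abundance of a panel
#'
#' Per sample, the total relative abundance of the panel's features — the
#' overall trajectory of, e.g., potential oil-responding genera. Panel
#' features missing from the table warn and contribute zero.
#'
#' @param relabund A relative-abundance `feature_table`
#'   (see [relative_abundance()]).
#' @param panel A panel tibble (`feature_id`, `role`).
#' @param role Which role(s) to sum (default `"responder"`).
#' @return A tibble `sample_id`, `total` with `total` in `[0, 1]`.
#' @export
panel_total <- function(relabund, panel, role = "responder") {
  present <- panel_features(relabund, panel, role)
  m <- ft_matrix(relabund)
  tot <- if (length(present)) rowSums(m[, present, drop = FALSE]) else
    rep(0, nrow(m))
  tibble(sample_id = relabund$sample_id, total = unname(tot))
}

#' Panel-internal composition, rescaled to 100%
#'
#' Restricts the table to the panel's features and rescales each sample to
#' sum to 100, exposing internal shifts within the panel independent of its
#' overall abundance. Samples where the panel total is zero are flagged and
#' returned as `NA`.
#'
#' @inheritParams panel_total
#' @return A tibble `sample_id` + one percentage column per panel feature,
#'   plus a logical `panel_missing` column for zero-total samples.
#' @export
panel_rescale <- function(relabund, panel, role = "responder") {
  present <- panel_features(relabund, panel, role)
  if (!length(present)) msg_stop("empty-panel", "no panel features present in table")
  m <- ft_matrix(relabund)[, present, drop = FALSE]
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    msg_warn("zero-panel-total", "zero panel total in samples: " %+%
               comma(relabund$sample_id[zero]))
  }
  scaled <- 100 * m / ifelse(tot == 0, NA_real_, tot)
  out <- tibble(sample_id = relabund$sample_id) %>%
    dplyr::bind_cols(as_tibble(scaled))
  out$panel_missing <- zero
  out
}

#' Mean-center a rescaled panel
#'
#' Subtracts each feature's mean scaled abundance from every observation, so
#' values are percentage-point deviations from that feature's average share
#' of the panel.
#'
#' @param scaled_panel Output of [panel_rescale()].
#' @return The same shape with each feature series mean-centered.
#' @export
panel_center <- function(scaled_panel) {
  feats <- setdiff(names(scaled_panel), c("sample_id", "panel_missing"))
  out <- scaled_panel
  for (f in feats) {
    out[[f]] <- out[[f]] - mean(out[[f]], na.rm = TRUE)
  }
  out
}

#' Pearson correlation screen between two feature sets
#'
#' All pairwise Pearson correlations between a set of susceptible taxa and a
#' set of responder taxa, two-sided t tests on `df = n - 2`, with
#' Benjamini-Hochberg adjustment across every pair in the screen. Pairs
#' involving a zero-variance series are flagged undefined and excluded from
#' the adjustment.
#'
#' @param relabund A relative-abundance `feature_table`.
#' @param set_a,set_b Character vectors of feature ids (e.g. susceptible vs
#'   responder genera); must be present in the table.
#' @param adjust Multiple-testing adjustment (default `"BH"`; any
#'   [stats::p.adjust()] method).
#' @return A tibble `feature_a`, `feature_b`, `n`, `df`, `r`, `p`, `p_adj`,
#'   `status`.
#' @export
pearson_screen <- function(relabund, set_a, set_b, adjust = "BH") {
  feats <- feature_ids(relabund)
  miss <- setdiff(c(set_a, set_b), feats)
  if (length(miss)) msg_stop("missing-features", "features not in table: " %+% comma(miss))
  m <- ft_matrix(relabund)
  grid <- tidyr::expand_grid(feature_a = set_a, feature_b = set_b)
  out <- purrr::pmap_dfr(grid, function(feature_a, feature_b) {
    a <- m[, feature_a]; b <- m[, feature_b]
    ok <- complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 3) {
      return(tibble(feature_a, feature_b, n, df = NA_integer_, r = NA_real_,
                    p = NA_real_, status = "too-few"))
    }
    if (sd(a) == 0 || sd(b) == 0) {
      return(tibble(feature_a, feature_b, n, df = NA_integer_, r = NA_real_,
                    p = NA_real_, status = "undefined"))
    }
    ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
    tibble(feature_a, feature_b, n, df = as.integer(ct$parameter),
           r = unname(ct$estimate), p = ct$p.value, status = "ok")
  })
  out$p_adj <- p.adjust(out$p, method = adjust)
  out[, c("feature_a", "feature_b", "n", "df", "r", "p", "p_adj", "status")]
}
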