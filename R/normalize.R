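#' RPKM normalization of a count table
#'
#' Converts raw counts to reads per kilobase per million:
#' `rpkm = count / (length_kb * library_size / 1e6)`, correcting feature
#' abundances for feature length and sequencing depth.
#'
#' @param counts A data frame with a `sample_id` first column and one integer
#'   count column per feature, or a `feature_table`.
#' @param feature_lengths Named numeric vector (or two-column data frame
#'   `feature_id`, `length_bp`) of feature lengths in base pairs; all > 0.
#' @param library_sizes Named numeric vector (or two-column data frame
#'   `sample_id`, `total_reads`) of total reads per sample; all > 0.
#' @param feature_kind Passed to [feature_table()].
#' @return A `feature_table` with `value_kind = "rpkm"`.
#' @examples
#' counts <- tibble::tibble(sample_id = "s1", gA = 10L)
#' rpkm_normalize(counts, c(gA = 1000), c(s1 = 1e6)) # gA = 10
#' @export
rpkm_normalize <- function(counts, feature_lengths, library_sizes,
                           feature_kind = "genus") {
  if (is.data.frame(feature_lengths)) {
    feature_lengths <- setNames(feature_lengths[[2]], feature_lengths[[1]])
  }
  if (is.data.frame(library_sizes)) {
    library_sizes <- setNames(library_sizes[[2]], library_sizes[[1]])
  }
  tbl <- as_tibble(counts)
  m <- ft_matrix(tbl)
  if (any(m < 0)) msg_stop("bad-counts", "negative counts")
  feats <- colnames(m)
  miss <- setdiff(feats, names(feature_lengths))
  if (length(miss)) msg_stop("bad-lengths", "no length for features: " %+% comma(miss))
  len <- feature_lengths[feats]
  bad <- feats[!is.finite(len) | len <= 0]
  if (length(bad)) msg_stop("bad-lengths", "non-positive length for: " %+% comma(bad))
  miss <- setdiff(rownames(m), names(library_sizes))
  if (length(miss)) msg_stop("bad-libsize", "no library size for samples: " %+% comma(miss))
  lib <- library_sizes[rownames(m)]
  bad <- rownames(m)[!is.finite(lib) | lib <= 0]
  if (length(bad)) msg_stop("bad-libsize", "non-positive library size for: " %+% comma(bad))
  out <- sweep(m, 2, len / 1e3, "/")
  out <- sweep(out, 1, lib / 1e6, "/")
  ft_from_matrix(out, feature_kind = feature_kind, value_kind = "rpkm")
}

#' Aggregate features through a child-to-parent map
#'
#' Sums child feature columns into parent features, e.g. genus to family or
#' KEGG Ortholog to KEGG module. For one-to-many maps a child contributes its
#' full value to every parent it maps to, so each parent aggregate is
#' self-contained; one-to-one maps conserve per-sample totals exactly.
#'
#' @param table A `feature_table`.
#' @param map A feature map (tibble `child_id`, `parent_id`; see
#'   [feature_map()]).
#' @param target_kind `feature_kind` of the aggregated table.
#' @param strict If `TRUE` (default), unmapped features are an error; if
#'   `FALSE` they are dropped with a warning.
#' @return A `feature_table` at the parent level, parents in first-appearance
#'   order of the map.
#' @export
aggregate_features <- function(table, map, target_kind = "family", strict = TRUE) {
  map <- feature_map(map)
  m <- ft_matrix(table)
  feats <- colnames(m)
  unmapped <- setdiff(feats, map$child_id)
  if (length(unmapped)) {
    if (strict) {
      msg_stop("unmapped-features", "unmapped features: " %+% comma(unmapped))
    }
    msg_warn("unmapped-features", "dropping unmapped features: " %+% comma(unmapped))
  }
  map <- map[map$child_id %in% feats, , drop = FALSE]
  parents <- unique(map$parent_id)
  out <- matrix(0, nrow(m), length(parents),
                dimnames = list(rownames(m), parents))
  for (p in parents) {
    kids <- map$child_id[map$parent_id == p]
    out[, p] <- rowSums(m[, kids, drop = FALSE])
  }
  ft_from_matrix(out, feature_kind = target_kind, value_kind = value_kind(table))
}

#' Drop unassigned or multi-assigned features
#'
#' Removes features such as reads unclassified at the genus level or reads
#' with multiple KO assignments, preserving the order of the survivors.
#'
#' @param table A `feature_table`.
#' @param unassigned_labels Character vector of feature ids to drop (possibly
#'   empty; labels absent from the table are ignored).
#' @return The table without the listed features. Dropping every feature
#'   yields a zero-feature table with a warning.
#' @export
drop_unassigned <- function(table, unassigned_labels) {
  keep <- setdiff(feature_ids(table), unassigned_labels)
  if (!length(keep)) {
    msg_warn("empty-table", "all features dropped; returning 0-feature table")
  }
  out <- table[, c("sample_id", keep), drop = FALSE]
  feature_table(out, feature_kind = feature_kind(table),
                value_kind = value_kind(table))
}

#' Per-sample relative abundance
#'
#' Rescales each sample row to sum to 1.
#'
#' @param table A `feature_table` with positive per-sample totals.
#' @return A `feature_table` with `value_kind = "relative"`.
#' @export
relative_abundance <- function(table) {
  m <- ft_matrix(table)
  tot <- rowSums(m)
  bad <- rownames(m)[tot <= 0]
  if (length(bad)) msg_stop("zero-sample", "all-zero sample rows: " %+% comma(bad))
  ft_from_matrix(m / tot, feature_kind = feature_kind(table),
                 value_kind = "relative")
}

#' Top-k most abundant features
#'
#' Ranks features by mean relative abundance across samples (the table is
#' converted to relative abundance internally if it is not already),
#' descending, ties broken lexicographically by feature id.
#'
#' @param table A `feature_table`.
#' @param k Number of features to return; capped at the number of features.
#' @return Character vector of feature ids, most abundant first.
#' @export
top_k_features <- function(table, k = 25) {
  stopifnot(k >= 1)
  if (!identical(value_kind(table), "relative")) {
    table <- relative_abundance(table)
  }
  m <- ft_matrix(table)
  mu <- colMeans(m)
  ord <- order(-mu, colnames(m), method = "radix")
  head(colnames(m)[ord], min(k, ncol(m)))
}
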