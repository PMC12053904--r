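#' Alpha-diversity metrics
#'
#' Shannon entropy (natural log, in nats), richness (count of features above
#' a detection threshold), and Pielou's evenness `J = H / ln(S)`. Pielou is
#' undefined (`NA`) when fewer than two features are detected.
#'
#' @param abundances Nonnegative numeric vector of abundances (RPKM or
#'   relative; Shannon is scale invariant).
#' @param detection_threshold Abundances strictly greater than this count as
#'   detected (default 0: any nonzero RPKM is presence).
#' @return `shannon()` and `pielou()` a single double; `richness()` an
#'   integer count.
#' @examples
#' shannon(rep(1, 4)) # log(4)
#' pielou(c(0.25, 0.25, 0.25, 0.25)) # 1
#' @export
shannon <- function(abundances) {
  x <- check_abund(abundances)
  if (all(x == 0)) msg_stop("zero-sample", "all-zero abundance vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

check_abund <- function(x) {
  if (!is.numeric(x)) msg_stop("bad-abund", "abundances must be numeric")
  if (any(!is.finite(x)) || any(x < 0)) {
    msg_stop("bad-abund", "abundances must be finite and nonnegative")
  }
  x
}

#' @rdname shannon
#' @export
richness <- function(abundances, detection_threshold = 0) {
  x <- check_abund(abundances)
  sum(x > detection_threshold)
}

#' @rdname shannon
#' @export
pielou <- function(abundances, detection_threshold = 0) {
  s <- richness(abundances, detection_threshold)
  if (s <= 1) return(NA_real_)
  shannon(abundances) / log(s)
}

#' Per-sample diversity time series
#'
#' Computes Shannon, richness, and Pielou for every sample of a feature
#' table, ordered by collection date. Samples whose metrics cannot be
#' computed (all-zero rows) are kept as flagged `NA` rows rather than
#' dropped.
#'
#' @param table A `feature_table` (genus- or KO-level, unassigned features
#'   already removed).
#' @param metadata Sample metadata (see [sample_metadata()]).
#' @param detection_threshold Passed to [richness()].
#' @return A tibble `sample_id`, `date`, `shannon`, `richness`, `pielou`,
#'   `ok`, date-ordered.
#' @seealso [diversity_correlations()] for Pearson correlations between the
#'   metrics.
#' @export
diversity_series <- function(table, metadata, detection_threshold = 0) {
  md <- align_metadata(table, metadata)
  m <- ft_matrix(table)
  prof <- purrr::map(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    if (all(x == 0)) {
      tibble(shannon = NA_real_, richness = NA_integer_,
             pielou = NA_real_, ok = FALSE)
    } else {
      tibble(shannon = shannon(x),
             richness = as.integer(richness(x, detection_threshold)),
             pielou = pielou(x, detection_threshold), ok = TRUE)
    }
  })
  out <- dplyr::bind_cols(tibble(sample_id = md$sample_id, date = md$date),
                          dplyr::bind_rows(prof))
  dplyr::arrange(out, .data$date, .data$sample_id)
}

#' Pearson correlations between alpha-diversity metrics
#'
#' Correlates each pair of metrics across samples (pairwise-complete), with
#' a two-sided t test on `df = n - 2`. Pairs with zero variance in either
#' metric are reported as undefined.
#'
#' @param profiles Output of [diversity_series()].
#' @return A tibble `metric_a`, `metric_b`, `n`, `df`, `r`, `p`.
#' @export
diversity_correlations <- function(profiles) {
  metrics <- c("shannon", "richness", "pielou")
  pairs <- utils::combn(metrics, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- as.numeric(profiles[[pr[1]]])
    b <- as.numeric(profiles[[pr[2]]])
    ok <- complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 3 || sd(a) == 0 || sd(b) == 0) {
      return(tibble(metric_a = pr[1], metric_b = pr[2], n = n,
                    df = NA_integer_, r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
    tibble(metric_a = pr[1], metric_b = pr[2], n = n,
           df = as.integer(ct$parameter), r = unname(ct$estimate),
           p = ct$p.value)
  })
}
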