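#' Fit additive seasonal baselines to every feature
#'
#' For each feature, ordinary least squares of the centered/scaled abundance
#' on categorical year plus categorical month (no interaction, sum-to-zero
#' effect coding). The residuals represent natural fluctuation around the
#' interannual + seasonal expectation and are the raw material of the
#' anomaly detector. All features share one design matrix, so the whole
#' table is fit in a single QR decomposition.
#'
#' With `fit_scope = "all"` (default) every sample, baseline and
#' post-disturbance alike, enters the regression. With
#' `fit_scope = "baseline_only"` only baseline-period samples are fit;
#' post-period residuals are observed minus predicted, and post samples from
#' years unseen in the baseline get a zero year effect (reported with a
#' message).
#'
#' @param z A scaled table from [center_scale()] (z-scores; any tibble with
#'   `sample_id` plus numeric columns works).
#' @param metadata Sample metadata with `year`, `month`, `period`.
#' @param fit_scope `"all"` or `"baseline_only"`.
#' @return An object of class `baseline_fit`: residuals for every sample,
#'   per-feature intercept and year/month effects (sum-to-zero), residual
#'   sums of squares of the full and both reduced models, and the metadata.
#'   Methods: [tidy()] (effects), [glance()] (per-feature fit summary),
#'   [augment()] (long residuals), [type2_anova()].
#' @export
fit_seasonal_baseline <- function(z, metadata,
                                  fit_scope = c("all", "baseline_only")) {
  fit_scope <- match.arg(fit_scope)
  md <- align_metadata(z, metadata)
  y_all <- ft_matrix(z)
  fit_rows <- if (fit_scope == "all") seq_len(nrow(y_all)) else which(md$period == "baseline")
  if (!length(fit_rows)) msg_stop("bad-scope", "no baseline samples to fit")
  year_f <- factor(md$year[fit_rows])
  month_f <- factor(md$month[fit_rows])
  if (nlevels(year_f) < 2) msg_stop("single-level", "need >= 2 year levels in fit scope")
  if (nlevels(month_f) < 2) msg_stop("single-level", "need >= 2 month levels in fit scope")

  mats <- design_matrices(year_f, month_f)
  y_fit <- y_all[fit_rows, , drop = FALSE]
  qr_full <- qr(mats$full)
  if (qr_full$rank < ncol(mats$full)) {
    aliased <- colnames(mats$full)[qr_full$pivot[(qr_full$rank + 1):ncol(mats$full)]]
    msg_stop("rank-deficient", "aliased design columns: " %+% comma(aliased))
  }
  beta <- qr.coef(qr_full, y_fit)
  fitted_fit <- mats$full %*% beta
  resid_fit <- y_fit - fitted_fit
  rss_full <- colSums(resid_fit^2)
  rss_year_only <- rss_reduced(mats$year_only, y_fit)
  rss_month_only <- rss_reduced(mats$month_only, y_fit)

  # expand sum-to-zero coefficients to full per-level effects
  ylev <- levels(year_f); mlev <- levels(month_f)
  iy <- seq_len(nlevels(year_f) - 1) + 1
  im <- seq_len(nlevels(month_f) - 1) + 1 + length(iy)
  year_eff <- rbind(beta[iy, , drop = FALSE],
                    -colSums(beta[iy, , drop = FALSE]))
  rownames(year_eff) <- ylev
  month_eff <- rbind(beta[im, , drop = FALSE],
                     -colSums(beta[im, , drop = FALSE]))
  rownames(month_eff) <- mlev

  residuals <- matrix(NA_real_, nrow(y_all), ncol(y_all),
                      dimnames = dimnames(y_all))
  residuals[fit_rows, ] <- resid_fit
  if (length(fit_rows) < nrow(y_all)) {
    out_rows <- setdiff(seq_len(nrow(y_all)), fit_rows)
    unseen <- setdiff(unique(as.character(md$year[out_rows])), ylev)
    if (length(unseen)) {
      msg_info("unseen-year", "zero year effect used for unseen years: " %+%
                 comma(unseen))
    }
    for (i in out_rows) {
      yr <- as.character(md$year[i]); mo <- as.character(md$month[i])
      ye <- if (yr %in% ylev) year_eff[yr, ] else 0
      me <- if (mo %in% mlev) month_eff[mo, ] else 0
      residuals[i, ] <- y_all[i, ] - (beta[1, ] + ye + me)
    }
  }

  fk <- attr(z, "feature_kind")
  if (is.null(fk) || is.na(fk)) fk <- "family"
  structure(list(
    residuals = ft_from_matrix(residuals, feature_kind = fk,
                               value_kind = "scaled"),
    intercept = beta[1, ],
    year_effects = year_eff, month_effects = month_eff,
    rss = list(full = rss_full, year_only = rss_year_only,
               month_only = rss_month_only),
    df = list(year = nlevels(year_f) - 1L, month = nlevels(month_f) - 1L,
              residual = length(fit_rows) - ncol(mats$full)),
    metadata = md, fit_scope = fit_scope, fit_rows = fit_rows,
    features = colnames(y_all)
  ), class = "baseline_fit")
}

design_matrices <- function(year_f, month_f) {
  df <- data.frame(year = year_f, month = month_f)
  ctr <- list(year = "contr.sum", month = "contr.sum")
  list(
    full = stats::model.matrix(~ year + month, df, contrasts.arg = ctr),
    year_only = stats::model.matrix(~ year, df, contrasts.arg = ctr["year"]),
    month_only = stats::model.matrix(~ month, df, contrasts.arg = ctr["month"])
  )
}

rss_reduced <- function(x, y) {
  q <- qr(x)
  colSums(qr.resid(q, y)^2)
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("Seasonal baseline fit:", length(x$features), "features,",
      length(x$fit_rows), "samples in fit (scope:", x$fit_scope, ")\n")
  invisible(x)
}

#' @rdname fit_seasonal_baseline
#' @param x,object A `baseline_fit`.
#' @param ... Unused.
#' @export
tidy.baseline_fit <- function(x, ...) {
  eff <- function(mat, term) {
    as_tibble(mat, rownames = "level") %>%
      tidyr::pivot_longer(-"level", names_to = "feature", values_to = "estimate") %>%
      mutate(term = term)
  }
  dplyr::bind_rows(
    tibble(term = "intercept", level = NA_character_,
           feature = names(x$intercept), estimate = unname(x$intercept)),
    eff(x$year_effects, "year"),
    eff(x$month_effects, "month")
  )[, c("feature", "term", "level", "estimate")]
}

#' @rdname fit_seasonal_baseline
#' @export
glance.baseline_fit <- function(x, ...) {
  tibble(feature = x$features,
         rss = unname(x$rss$full),
         df_residual = x$df$residual,
         n_fit = length(x$fit_rows),
         fit_scope = x$fit_scope)
}

#' @rdname fit_seasonal_baseline
#' @export
augment.baseline_fit <- function(x, ...) {
  residuals_long(x)
}

residuals_long <- function(fit) {
  as_tibble(fit$residuals) %>%
    tidyr::pivot_longer(-"sample_id", names_to = "feature",
                        values_to = "residual") %>%
    left_join(fit$metadata[, c("sample_id", "date", "year", "month", "period")],
              by = "sample_id")
}

#' Type II ANOVA partition of interannual and monthly variability
#'
#' Marginal (Type II) sums of squares for the additive year + month model:
#' each factor's SS is the drop in residual sum of squares when it is added
#' to the model already containing the other factor. On balanced designs
#' this equals sequential SS in either order; on the unbalanced sampling of
#' a field time series it does not depend on term order.
#'
#' @param fit A [fit_seasonal_baseline()] object.
#' @return A tibble with one row per feature and term (`year`, `month`,
#'   `residual`): `SS`, `df`, `F`, `p`.
#' @export
type2_anova <- function(fit) {
  stopifnot(inherits(fit, "baseline_fit"))
  ss_year <- fit$rss$month_only - fit$rss$full
  ss_month <- fit$rss$year_only - fit$rss$full
  ms_res <- fit$rss$full / fit$df$residual
  f_year <- (ss_year / fit$df$year) / ms_res
  f_month <- (ss_month / fit$df$month) / ms_res
  dplyr::bind_rows(
    tibble(feature = fit$features, term = "year", SS = unname(ss_year),
           df = fit$df$year, F = unname(f_year),
           p = pf(unname(f_year), fit$df$year, fit$df$residual, lower.tail = FALSE)),
    tibble(feature = fit$features, term = "month", SS = unname(ss_month),
           df = fit$df$month, F = unname(f_month),
           p = pf(unname(f_month), fit$df$month, fit$df$residual, lower.tail = FALSE)),
    tibble(feature = fit$features, term = "residual", SS = unname(fit$rss$full),
           df = fit$df$residual, F = NA_real_, p = NA_real_)
  ) %>% arrange(.data$feature)
}

#' Baseline residual interval
#'
#' The envelope of natural fluctuation: per feature, the empirical 2.5% and
#' 97.5% quantiles (type-7 interpolation; `level` configurable) of the
#' baseline-period residuals. Residuals whose signed value exceeds
#' `exclusion_threshold` are removed first — extreme baseline excursions are
#' not allowed to widen the envelope.
#'
#' @param fit A `baseline_fit`, or a long residual table (columns `feature`,
#'   `sample_id`, `residual`) such as [module_median_residuals()] output.
#' @param metadata Required only for the data-frame method.
#' @param level Interval coverage (default 0.95).
#' @param exclusion_threshold Signed residual cutoff (default 4); baseline
#'   residuals greater than this are excluded. `Inf` disables exclusion.
#' @param interval_kind `"empirical"` (order-statistic quantiles, default)
#'   or `"normal"` (mean +/- z * sd of retained residuals).
#' @param ... Passed between methods.
#' @return A tibble `feature`, `lower`, `upper`, `level`, `n_baseline`,
#'   `n_excluded`.
#' @export
baseline_interval <- function(fit, ...) UseMethod("baseline_interval")

#' @rdname baseline_interval
#' @export
baseline_interval.baseline_fit <- function(fit, level = 0.95,
                                           exclusion_threshold = 4,
                                           interval_kind = c("empirical", "normal"),
                                           ...) {
  baseline_interval(residuals_long(fit), metadata = fit$metadata,
                    level = level, exclusion_threshold = exclusion_threshold,
                    interval_kind = interval_kind)
}

#' @rdname baseline_interval
#' @export
baseline_interval.data.frame <- function(fit, metadata, level = 0.95,
                                         exclusion_threshold = 4,
                                         interval_kind = c("empirical", "normal"),
                                         ...) {
  interval_kind <- match.arg(interval_kind)
  md <- sample_metadata(metadata)
  base_ids <- md$sample_id[md$period == "baseline"]
  rl <- fit[fit$sample_id %in% base_ids & is.finite(fit$residual), ]
  alpha <- (1 - level) / 2
  out <- rl %>%
    group_by(.data$feature) %>%
    summarise(
      n_excluded = sum(.data$residual > exclusion_threshold),
      n_baseline = sum(.data$residual <= exclusion_threshold),
      lower = interval_bound(.data$residual[.data$residual <= exclusion_threshold],
                             alpha, interval_kind),
      upper = interval_bound(.data$residual[.data$residual <= exclusion_threshold],
                             1 - alpha, interval_kind),
      .groups = "drop"
    ) %>%
    mutate(level = level)
  if (any(out$n_baseline < 2)) {
    msg_stop("too-few-residuals", "fewer than 2 retained baseline residuals for: " %+%
               comma(out$feature[out$n_baseline < 2]))
  }
  if (any(out$n_baseline < 20)) {
    msg_warn("interval-unstable", "fewer than 20 retained baseline residuals for: " %+%
               comma(out$feature[out$n_baseline < 20]))
  }
  out[, c("feature", "lower", "upper", "level", "n_baseline", "n_excluded")]
}

interval_bound <- function(r, prob, kind) {
  if (length(r) < 2) return(NA_real_)
  if (kind == "empirical") {
    unname(quantile(r, prob, type = 7, names = FALSE))
  } else {
    mean(r) + qnorm(prob) * sd(r)
  }
}

#' Flag anomalous residuals against the baseline interval
#'
#' A residual strictly below the lower bound flags `low`, strictly above the
#' upper bound flags `high`; values on a bound are `normal` ("outside" is
#' read strictly).
#'
#' @param fit A `baseline_fit` or long residual table (see
#'   [baseline_interval()]).
#' @param interval Output of [baseline_interval()].
#' @param query_sample_ids Samples to flag; default: all post-period samples.
#' @param metadata Required only when `fit` is a data frame.
#' @return An `anomaly_report` tibble: `feature`, `sample_id`, `date`,
#'   `residual`, `lower`, `upper`, `flag`.
#' @export
flag_anomalies <- function(fit, interval, query_sample_ids = NULL,
                           metadata = NULL) {
  if (inherits(fit, "baseline_fit")) {
    metadata <- fit$metadata
    rl <- residuals_long(fit)
  } else {
    metadata <- sample_metadata(metadata)
    rl <- as_tibble(fit)
    if (!"date" %in% names(rl)) {
      rl <- left_join(rl, metadata[, c("sample_id", "date")], by = "sample_id")
    }
  }
  if (is.null(query_sample_ids)) {
    query_sample_ids <- metadata$sample_id[metadata$period == "post"]
  }
  miss <- setdiff(query_sample_ids, rl$sample_id)
  if (length(miss)) {
    msg_stop("missing-query", "query samples missing from fit: " %+% comma(miss))
  }
  out <- rl[rl$sample_id %in% query_sample_ids, ] %>%
    left_join(interval[, c("feature", "lower", "upper")], by = "feature") %>%
    mutate(flag = dplyr::case_when(
      .data$residual < .data$lower ~ "low",
      .data$residual > .data$upper ~ "high",
      TRUE ~ "normal"
    ))
  out <- out[, c("feature", "sample_id", "date", "residual", "lower", "upper", "flag")]
  class(out) <- c("anomaly_report", class(out))
  out
}

#' Median residual per KEGG module and sampling date
#'
#' Collapses KO-level residuals to their member-wise median within each
#' KEGG module for every sample (even membership counts use the mean of the
#' central pair). The result feeds [baseline_interval()] and
#' [flag_anomalies()] at the module level.
#'
#' @param ko_fit A `baseline_fit` over KO-level features.
#' @param map KO-to-module feature map (`child_id`, `parent_id`).
#' @return A tibble `feature` (module id), `sample_id`, `date`, `residual`.
#' @export
module_median_residuals <- function(ko_fit, map) {
  stopifnot(inherits(ko_fit, "baseline_fit"))
  map <- feature_map(map)
  empty <- setdiff(unique(map$parent_id),
                   unique(map$parent_id[map$child_id %in% ko_fit$features]))
  if (length(empty)) {
    msg_stop("empty-module", "modules with no member KO present: " %+% comma(empty))
  }
  rl <- residuals_long(ko_fit)
  dplyr::inner_join(rl, rename(map, feature = "child_id", module = "parent_id"),
                    by = "feature", relationship = "many-to-many") %>%
    group_by(.data$module, .data$sample_id, .data$date) %>%
    summarise(residual = median(.data$residual), .groups = "drop") %>%
    rename(feature = "module") %>%
    arrange(.data$feature, .data$date)
}

#' Monthly panels of baseline residual densities with post-period points
#'
#' Groups residuals by calendar month: for each month with at least one
#' post-period sample, the baseline residuals (the density input, after the
#' signed exclusion threshold) together with the flagged post-period
#' residuals — the tabular form of a ridgeline figure. Months with no
#' post-period samples are omitted with a message; months with post samples
#' but no baseline residuals are omitted with a warning.
#'
#' @param fit A `baseline_fit`.
#' @param report An [flag_anomalies()] report for the post-period samples.
#' @param exclusion_threshold Signed cutoff applied to baseline residuals
#'   (default 4), matching [baseline_interval()].
#' @return A tibble `month`, `period`, `feature`, `sample_id`, `date`,
#'   `residual`, `flag` (`NA` for baseline rows).
#' @export
monthly_anomaly_panel <- function(fit, report, exclusion_threshold = 4) {
  stopifnot(inherits(fit, "baseline_fit"))
  md <- fit$metadata
  base <- residuals_long(fit) %>%
    filter(.data$period == "baseline", .data$residual <= exclusion_threshold) %>%
    mutate(flag = NA_character_) %>%
    select("month", period = "period", "feature", "sample_id", "date",
           "residual", "flag")
  post <- as_tibble(report) %>%
    left_join(md[, c("sample_id", "month")], by = "sample_id") %>%
    mutate(period = "post") %>%
    select("month", "period", "feature", "sample_id", "date", "residual", "flag")
  post_months <- sort(unique(post$month))
  skipped <- setdiff(sort(unique(base$month)), post_months)
  if (length(skipped)) {
    msg_info("no-post-samples", "months omitted (no post-period samples): " %+%
               comma(skipped))
  }
  no_base <- setdiff(post_months, unique(base$month))
  if (length(no_base)) {
    msg_warn("no-baseline-residuals", "months omitted (no baseline residuals): " %+%
               comma(no_base))
    post_months <- setdiff(post_months, no_base)
  }
  bind_rows(base, post) %>%
    filter(.data$month %in% post_months) %>%
    arrange(.data$month, .data$period, .data$feature, .data$date)
}
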