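# Build a z table from known sum-to-zero year/month effects plus noise.
make_design <- function(n_years = 4, spm = 1, noise_sd = 0, seed = 1,
                        n_feat = 3, drop = 0) {
  set.seed(seed)
  md <- md_monthly(n_years * 12 * spm)
  if (drop > 0) md <- md[-sample(nrow(md), drop), ]
  ylev <- sort(unique(md$year)); mlev <- sort(unique(md$month))
  ye <- matrix(rnorm(length(ylev) * n_feat), length(ylev), n_feat)
  ye <- sweep(ye, 2, colMeans(ye))
  me <- matrix(rnorm(length(mlev) * n_feat), length(mlev), n_feat)
  me <- sweep(me, 2, colMeans(me))
  mu <- matrix(rnorm(n_feat), nrow(md), n_feat, byrow = TRUE)
  z <- mu + ye[match(md$year, ylev), ] + me[match(md$month, mlev), ] +
    matrix(rnorm(nrow(md) * n_feat, 0, noise_sd), nrow(md), n_feat)
  rownames(z) <- md$sample_id
  list(z = ft_of(z, value_kind = "scaled"), md = md,
       year_effects = ye, month_effects = me, intercept = mu[1, ])
}

test_that("noiseless data recovers year and month effects exactly", {
  d <- make_design(noise_sd = 0, seed = 71)
  fit <- fit_seasonal_baseline(d$z, d$md)
  expect_equal(unname(fit$year_effects), unname(d$year_effects), tolerance = 1e-9)
  expect_equal(unname(fit$month_effects), unname(d$month_effects), tolerance = 1e-9)
  expect_equal(unname(fit$intercept), unname(d$intercept), tolerance = 1e-9)
  expect_equal(max(abs(ft_matrix(fit$residuals))), 0, tolerance = 1e-9)
})

test_that("fit matches per-feature lm with sum-to-zero contrasts", {
  d <- make_design(noise_sd = 0.7, seed = 72, drop = 9)
  fit <- fit_seasonal_baseline(d$z, d$md)
  zm <- ft_matrix(d$z)
  df <- data.frame(year = factor(d$md$year), month = factor(d$md$month))
  for (j in 1:3) {
    lmfit <- lm(zm[, j] ~ year + month, data = df,
                contrasts = list(year = "contr.sum", month = "contr.sum"))
    expect_equal(unname(ft_matrix(fit$residuals)[, j]),
                 unname(residuals(lmfit)), tolerance = 1e-9)
  }
  # sum-to-zero constraints hold
  expect_equal(unname(colSums(fit$year_effects)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(colSums(fit$month_effects)), rep(0, 3), tolerance = 1e-9)
  # residuals orthogonal to every factor-level indicator
  res <- ft_matrix(fit$residuals)
  for (y in unique(d$md$year)) {
    expect_equal(unname(colSums(res[d$md$year == y, , drop = FALSE])),
                 rep(0, 3), tolerance = 1e-8)
  }
  for (m in unique(d$md$month)) {
    expect_equal(unname(colSums(res[d$md$month == m, , drop = FALSE])),
                 rep(0, 3), tolerance = 1e-8)
  }
  # SS_residual equals the sum of squared residuals
  expect_equal(unname(fit$rss$full), unname(colSums(res^2)), tolerance = 1e-8)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- make_design(n_years = 1)
  expect_error(fit_seasonal_baseline(d$z, d$md), "2 year levels")
  # perfect aliasing: each year observed in exactly one month
  md <- sample_metadata(tibble::tibble(
    sample_id = sprintf("s%02d", 1:8),
    date = as.Date(c("2011-01-05", "2011-01-20", "2011-01-25", "2011-01-28",
                     "2012-02-05", "2012-02-20", "2012-02-25", "2012-02-28")),
    stage = "pre", period = "baseline"
  ))
  z <- ft_of(matrix(rnorm(16), 8, 2), value_kind = "scaled")
  expect_error(fit_seasonal_baseline(z, md), "aliased")
})

test_that("Type II SS equal brute-force reduced-model refits", {
  d <- make_design(n_years = 3, spm = 1, noise_sd = 1, seed = 73, drop = 7)
  fit <- fit_seasonal_baseline(d$z, d$md)
  a2 <- type2_anova(fit)
  zm <- ft_matrix(d$z)
  df <- data.frame(year = factor(d$md$year), month = factor(d$md$month))
  for (j in 1:3) {
    f <- colnames(zm)[j]
    rss_full <- sum(residuals(lm(zm[, j] ~ year + month, df))^2)
    rss_y <- sum(residuals(lm(zm[, j] ~ year, df))^2)
    rss_m <- sum(residuals(lm(zm[, j] ~ month, df))^2)
    expect_equal(a2$SS[a2$feature == f & a2$term == "year"],
                 rss_m - rss_full, tolerance = 1e-8)
    expect_equal(a2$SS[a2$feature == f & a2$term == "month"],
                 rss_y - rss_full, tolerance = 1e-8)
  }
})

test_that("Type II equals sequential SS in both orders on balanced designs", {
  d <- make_design(n_years = 3, spm = 2, noise_sd = 1, seed = 74)
  fit <- fit_seasonal_baseline(d$z, d$md)
  a2 <- type2_anova(fit)
  zm <- ft_matrix(d$z)
  df <- data.frame(year = factor(d$md$year), month = factor(d$md$month))
  for (j in 1:2) {
    f <- colnames(zm)[j]
    s1 <- anova(lm(zm[, j] ~ year + month, df))
    s2 <- anova(lm(zm[, j] ~ month + year, df))
    expect_equal(a2$SS[a2$feature == f & a2$term == "year"],
                 s1["year", "Sum Sq"], tolerance = 1e-8)
    expect_equal(a2$SS[a2$feature == f & a2$term == "year"],
                 s2["year", "Sum Sq"], tolerance = 1e-8)
    expect_equal(a2$SS[a2$feature == f & a2$term == "month"],
                 s1["month", "Sum Sq"], tolerance = 1e-8)
    expect_equal(a2$SS[a2$feature == f & a2$term == "month"],
                 s2["month", "Sum Sq"], tolerance = 1e-8)
  }
  # balanced: SS partition has vanishing cross-terms
  for (j in 1:2) {
    f <- colnames(zm)[j]
    tot <- sum((zm[, j] - mean(zm[, j]))^2)
    parts <- sum(a2$SS[a2$feature == f])
    expect_equal(parts, tot, tolerance = 1e-8)
  }
})

test_that("Type II F and p agree with car::Anova", {
  skip_if_not_installed("car")
  d <- make_design(n_years = 3, spm = 1, noise_sd = 1, seed = 75, drop = 5)
  fit <- fit_seasonal_baseline(d$z, d$md)
  a2 <- type2_anova(fit)
  zm <- ft_matrix(d$z)
  df <- data.frame(year = factor(d$md$year), month = factor(d$md$month))
  ca <- car::Anova(lm(zm[, 1] ~ year + month, df), type = 2)
  f <- colnames(zm)[1]
  expect_equal(a2$F[a2$feature == f & a2$term == "year"], ca["year", "F value"],
               tolerance = 1e-8)
  expect_equal(a2$p[a2$feature == f & a2$term == "month"], ca["month", "Pr(>F)"],
               tolerance = 1e-8)
})

test_that("baseline_interval retains, excludes, and interpolates correctly", {
  set.seed(76)
  md <- md_monthly(100)
  r <- matrix(sample(1:100), 100, 1, dimnames = list(md$sample_id, "fA"))
  z <- ft_of(r, value_kind = "scaled")
  rl <- tibble::tibble(feature = "fA", sample_id = md$sample_id,
                       residual = r[, 1])
  int <- baseline_interval(rl, metadata = md, exclusion_threshold = Inf)
  expect_equal(int$lower, unname(quantile(1:100, 0.025, type = 7)))
  expect_equal(int$upper, unname(quantile(1:100, 0.975, type = 7)))
  expect_identical(int$n_excluded, 0L)

  # one residual of 5 with threshold 4 is excluded
  rl2 <- tibble::tibble(feature = "fA",
                        sample_id = md$sample_id[1:30],
                        residual = c(5, rnorm(29)))
  int2 <- baseline_interval(rl2, metadata = md)
  expect_identical(int2$n_excluded, 1L)
  expect_identical(int2$n_baseline, 29L)

  # symmetric residuals give symmetric bounds
  sym <- c(seq(-2, 2, length.out = 41))
  rl3 <- tibble::tibble(feature = "fA", sample_id = md$sample_id[1:41],
                        residual = sym)
  int3 <- baseline_interval(rl3, metadata = md, exclusion_threshold = Inf)
  expect_equal(int3$lower, -int3$upper, tolerance = 1e-9)

  # too few residuals error; < 20 warns
  rl4 <- tibble::tibble(feature = "fA", sample_id = md$sample_id[1],
                        residual = 1)
  expect_error(suppressWarnings(baseline_interval(rl4, metadata = md)),
               "fewer than 2")
  rl5 <- tibble::tibble(feature = "fA", sample_id = md$sample_id[1:5],
                        residual = rnorm(5))
  expect_warning(baseline_interval(rl5, metadata = md), "unstable")
})

test_that("normal-theory interval option uses mean +/- z * sd", {
  set.seed(77)
  md <- md_monthly(60)
  rl <- tibble::tibble(feature = "fA", sample_id = md$sample_id,
                       residual = rnorm(60))
  int <- baseline_interval(rl, metadata = md, interval_kind = "normal",
                           exclusion_threshold = Inf)
  expect_equal(int$lower, mean(rl$residual) - qnorm(0.975) * sd(rl$residual))
  expect_equal(int$upper, mean(rl$residual) + qnorm(0.975) * sd(rl$residual))
})

test_that("flag_anomalies uses strict inequality at the bounds", {
  md <- md_monthly(30, post_from = "2013-01-01")
  post_id <- md$sample_id[md$period == "post"][1]
  rl <- tibble::tibble(
    feature = rep("fA", 30), sample_id = md$sample_id,
    residual = c(seq(-1, 1, length.out = 24), 1, -1.0001, 1.0001, 0, 0.5, -0.2)
  )
  int <- tibble::tibble(feature = "fA", lower = -1, upper = 1,
                        level = 0.95, n_baseline = 24L, n_excluded = 0L)
  post_ids <- md$sample_id[25:30]
  rep <- flag_anomalies(rl, int, query_sample_ids = post_ids, metadata = md)
  flags <- setNames(rep$flag, rep$sample_id)
  expect_identical(unname(flags[md$sample_id[25]]), "normal") # exactly at bound
  expect_identical(unname(flags[md$sample_id[26]]), "low")
  expect_identical(unname(flags[md$sample_id[27]]), "high")
  expect_identical(unname(flags[md$sample_id[28]]), "normal")
  expect_error(flag_anomalies(rl, int, query_sample_ids = "nope", metadata = md),
               "missing")
})

test_that("module medians collapse KO residuals per module and date", {
  d <- make_design(n_years = 3, spm = 1, noise_sd = 0.5, seed = 78)
  fit <- fit_seasonal_baseline(d$z, d$md)
  map <- tibble::tibble(child_id = c("f01", "f02", "f03"),
                        parent_id = c("M1", "M2", "M2"))
  mm <- module_median_residuals(fit, map)
  res <- ft_matrix(fit$residuals)
  # single-KO module equals that KO's residual
  m1 <- mm[mm$feature == "M1", ]
  expect_equal(m1$residual[match(rownames(res), m1$sample_id)],
               unname(res[, "f01"]))
  # brute-force per-group median for the 2-KO module
  m2 <- mm[mm$feature == "M2", ]
  want <- apply(res[, c("f02", "f03")], 1, median)
  expect_equal(m2$residual[match(rownames(res), m2$sample_id)], unname(want))
  # odd-count median robustness
  expect_equal(median(c(-1, 0, 5)), 0)
  # empty module errors
  bad <- tibble::tibble(child_id = c("f01", "zzz"), parent_id = c("M1", "M9"))
  expect_error(module_median_residuals(fit, bad), "M9")
})

test_that("monthly panels group baseline densities with flagged post points", {
  set.seed(79)
  n <- 11 * 12
  md <- md_monthly(n, post_from = "2021-01-01")
  # post samples only in Jan..Dec of 2021; restrict post to one October-ish set
  keep <- md$period == "baseline" | md$month %in% c(10, 11)
  md <- md[keep, ]
  z <- ft_of(matrix(rnorm(nrow(md) * 2), nrow(md), 2,
                    dimnames = list(md$sample_id, NULL)),
             value_kind = "scaled")
  fit <- fit_seasonal_baseline(z, md)
  int <- baseline_interval(fit)
  rep <- flag_anomalies(fit, int)
  expect_message(pan <- monthly_anomaly_panel(fit, rep), "omitted")
  # post rows appear only in their own month's panel
  expect_identical(sort(unique(pan$month[pan$period == "post"])), c(10L, 11L))
  oct_post <- pan[pan$period == "post" & pan$month == 10, ]
  expect_true(all(format(oct_post$date, "%m") == "10"))
  # counts per panel equal a brute-force tally
  rl <- augment(fit)
  for (mo in c(10, 11)) {
    want_base <- sum(rl$period == "baseline" & rl$month == mo & rl$residual <= 4)
    expect_identical(sum(pan$month == mo & pan$period == "baseline"),
                     as.integer(want_base))
  }
})

test_that("baseline_only fit predicts post samples and flags unseen years", {
  d <- make_design(n_years = 4, spm = 1, noise_sd = 0.3, seed = 80)
  md <- d$md
  md$period[md$year == max(md$year)] <- "post"
  fit_all <- fit_seasonal_baseline(d$z, md, fit_scope = "all")
  fit_base <- fit_seasonal_baseline(d$z, md, fit_scope = "baseline_only")
  expect_identical(length(fit_base$fit_rows), sum(md$period == "baseline"))
  # post residuals exist (computed from predictions, not NA)
  post_res <- ft_matrix(fit_base$residuals)[md$period == "post", ]
  expect_true(all(is.finite(post_res)))
  # unseen year handled with zero year effect and a message
  md2 <- md
  expect_message(fit_seasonal_baseline(d$z, md2, fit_scope = "baseline_only"),
                 "unseen")
})
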