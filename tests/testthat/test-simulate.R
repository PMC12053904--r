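test_that("degenerate config (no noise, no effects) yields identical samples", {
  cfg <- sim_config(seed = 5, n_years = 2, samples_per_month = 1, n_taxa = 6,
                    n_kos = 4, year_effect_sd = 0, month_effect_sd = 0,
                    noise_sd = 0)
  sim <- simulate_taxa(cfg)
  m <- ft_matrix(sim$table)
  expect_equal(max(apply(m, 2, function(x) diff(range(x)))), 0)
})

test_that("the generator is bit-reproducible from its seed", {
  cfg <- sim_config(seed = 11, n_years = 2, samples_per_month = 2, n_taxa = 8,
                    n_kos = 6)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(ft_matrix(s1$taxa), ft_matrix(s2$taxa))
  expect_identical(ft_matrix(s1$kos), ft_matrix(s2$kos))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth$year_effects, s2$truth$year_effects)
})

test_that("per-month log-means recover the realized month effects", {
  cfg <- sim_config(seed = 12, n_years = 10, samples_per_month = 4,
                    n_taxa = 40, n_kos = 2, month_effect_sd = 0.3,
                    year_effect_sd = 0, noise_sd = 0.2,
                    post_start = "2099-01-01")
  sim <- simulate_taxa(cfg)
  lg <- log10(ft_matrix(sim$table))
  md <- sim$metadata
  n_month <- 10 * 4 # samples per calendar month over the series
  tol <- 3 * cfg$noise_sd / sqrt(n_month)
  hit <- 0; total <- 0
  for (tx in colnames(lg)) {
    base <- sim$truth$base$base_log10[sim$truth$base$taxon == tx]
    for (mo in 1:12) {
      est <- mean(lg[md$month == mo, tx]) - base
      want <- sim$truth$month_effects[as.character(mo), tx]
      total <- total + 1
      if (abs(est - want) <= tol) hit <- hit + 1
    }
  }
  expect_gte(hit / total, 0.95)
})

test_that("disturbance windows apply lagged, role-signed log effects", {
  win <- list(start = "2012-10-01", end = "2012-10-28", lag_days = 7,
              role = "susceptible", effect = 1)
  cfg <- sim_config(seed = 13, n_years = 2, samples_per_month = 2, n_taxa = 20,
                    n_kos = 2, role_fractions = c(susceptible = 0.3, responder = 0.2),
                    disturbances = list(win), post_start = "2012-01-01")
  sim <- simulate_taxa(cfg)
  tr <- sim$truth
  sus <- tr$roles$taxon[tr$roles$role == "susceptible"]
  # effects recorded only for susceptible taxa inside the lagged window
  expect_setequal(unique(tr$disturbance$taxon), sus)
  dates <- sim$metadata$date[match(unique(tr$disturbance$sample_id),
                                   sim$metadata$sample_id)]
  expect_true(all(dates >= as.Date("2012-10-08") & dates <= as.Date("2012-11-04")))
  expect_true(all(tr$disturbance$effect == -1))
  # stage labels mark lagged-window post samples as disturbed
  md <- sim$metadata
  expect_setequal(md$sample_id[md$stage == "disturbed"],
                  unique(tr$disturbance$sample_id))
  # window outside the span is rejected before sampling
  expect_error(sim_config(seed = 1, n_years = 2, disturbances = list(
    list(start = "2020-01-01", end = "2020-02-01", role = "responder", effect = 1)
  )), "outside")
})

test_that("KO tables are sparse nonnegative mixtures of taxa", {
  cfg <- sim_config(seed = 14, n_years = 2, samples_per_month = 1, n_taxa = 10,
                    n_kos = 15, ko_taxa_per_ko = 3, ko_noise_sd = 0)
  sim <- simulate_taxa(cfg)
  ko <- simulate_kos(sim$table, sim$truth, cfg)
  x <- ft_matrix(sim$table)
  # zero KO noise: the table is exactly the loading product
  expect_equal(ft_matrix(ko$table), x %*% t(ko$loadings), tolerance = 1e-10)
  expect_true(all(rowSums(ko$loadings > 0) == 3))

  # one KO loading entirely on one taxon is proportional to it
  cfg1 <- sim_config(seed = 15, n_years = 2, samples_per_month = 1, n_taxa = 5,
                     n_kos = 3, ko_taxa_per_ko = 1, ko_noise_sd = 0)
  sim1 <- simulate_taxa(cfg1)
  ko1 <- simulate_kos(sim1$table, sim1$truth, cfg1)
  w <- ko1$loadings
  for (i in 1:3) {
    tx <- colnames(w)[w[i, ] > 0]
    expect_equal(ft_matrix(ko1$table)[, i],
                 unname(w[i, tx] * ft_matrix(sim1$table)[, tx]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # matmul oracle with noise off, random loadings: brute-force loops
  got <- ft_matrix(ko$table)
  want <- matrix(0, nrow(x), nrow(ko$loadings))
  for (s in seq_len(nrow(x))) for (k in seq_len(nrow(ko$loadings))) {
    want[s, k] <- sum(ko$loadings[k, ] * x[s, ])
  }
  expect_equal(unname(got), want, tolerance = 1e-10)
})

test_that("null_dataset zeroes disturbances but keeps the same draw", {
  win <- list(start = "2012-10-01", end = "2012-10-28", role = "responder",
              effect = 2)
  cfg <- sim_config(seed = 16, n_years = 2, samples_per_month = 2, n_taxa = 12,
                    n_kos = 2, disturbances = list(win),
                    post_start = "2012-01-01")
  null <- null_dataset(cfg)
  expect_identical(nrow(null$truth$disturbance), 0L)
  cfg0 <- cfg
  cfg0$disturbances[[1]]$effect <- 0
  ref <- simulate_taxa(cfg0)
  expect_identical(ft_matrix(null$table), ft_matrix(ref$table))
  # disturbed samples differ from null exactly by the window effect
  sim <- simulate_taxa(cfg)
  res <- sim$truth$roles$taxon[sim$truth$roles$role == "responder"]
  hit <- unique(sim$truth$disturbance$sample_id)
  delta <- log10(ft_matrix(sim$table)[hit, res, drop = FALSE]) -
    log10(ft_matrix(null$table)[hit, res, drop = FALSE])
  expect_equal(unname(delta), matrix(2, length(hit), length(res)),
               tolerance = 1e-9)
})

test_that("raising the injected effect never decreases window residual size", {
  mad_in_window <- function(effect) {
    win <- list(start = "2020-06-01", end = "2020-06-28", role = "susceptible",
                effect = effect)
    cfg <- sim_config(seed = 17, n_years = 10, samples_per_month = 2,
                      n_taxa = 20, n_kos = 2, disturbances = list(win),
                      post_start = "2020-01-01")
    sim <- simulate_taxa(cfg)
    z <- center_scale(log10_ft(sim$table))
    fit <- fit_seasonal_baseline(z, sim$metadata)
    rl <- augment(fit)
    sus <- sim$truth$roles$taxon[sim$truth$roles$role == "susceptible"]
    md <- sim$metadata
    hit <- md$sample_id[md$date >= as.Date("2020-06-08") &
                          md$date <= as.Date("2020-07-05")]
    mean(abs(rl$residual[rl$feature %in% sus & rl$sample_id %in% hit]))
  }
  vals <- vapply(c(0, 0.3, 0.8), mad_in_window, numeric(1))
  expect_true(all(diff(vals) > 0))
})
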