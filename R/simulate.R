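#' Configuration for the synthetic community time-series generator
#'
#' Defines a multi-year, seasonally structured lognormal community: each
#' taxon's log10 abundance is a base level plus an i.i.d. Gaussian year
#' effect, an i.i.d. Gaussian month effect, an optional pulse-disturbance
#' term, and Gaussian noise — the additive year + month structure the
#' baseline detector assumes, with known ground truth. Disturbance windows
#' apply a multiplicative (log-scale) effect to taxa of a targeted role,
#' shifted by a configurable lag: negative for `susceptible` taxa
#' (suppression), positive for `responder` taxa (opportunist bloom).
#'
#' Defaults emulate the study design: ten baseline years plus one
#' post-disturbance year (2011 start) sampled twice a month, with seasonal
#' variability (`month_effect_sd = 0.3`) larger than interannual variability
#' (`year_effect_sd = 0.15`) and measurement/ecological noise
#' `noise_sd = 0.2`, all on the log10 scale, and a one-week disturbance lag.
#'
#' @param seed Integer seed; every draw of the generator is reproducible
#'   from it.
#' @param n_years Number of simulated years (default 11: the final year is
#'   the post period).
#' @param start_year First calendar year (default 2011).
#' @param samples_per_month Evenly spaced sampling dates per month
#'   (default 2).
#' @param n_taxa,n_kos Number of taxa and KEGG Orthologs.
#' @param base_log_range Range of per-taxon base log10 abundance.
#' @param year_effect_sd,month_effect_sd,noise_sd Log10-scale standard
#'   deviations of the interannual effects, seasonal effects, and noise.
#' @param disturbances List of windows, each
#'   `list(start =, end =, lag_days = 7, role = "susceptible"|"responder",
#'   effect = )` with `effect` a nonnegative log10 magnitude; the sign is
#'   applied by role.
#' @param role_fractions Named fractions of taxa assigned the `susceptible`
#'   and `responder` roles (rest are `neutral`); must sum to <= 1.
#' @param ko_taxa_per_ko Number of taxa each KO loads on.
#' @param ko_noise_sd Log10-scale sd of the KO-level multiplicative noise.
#' @param post_start Date splitting baseline from post period (default:
#'   January 1 of the final simulated year).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_years = 11, start_year = 2011,
                       samples_per_month = 2, n_taxa = 100, n_kos = 300,
                       base_log_range = c(-1, 2),
                       year_effect_sd = 0.15, month_effect_sd = 0.3,
                       noise_sd = 0.2, disturbances = list(),
                       role_fractions = c(susceptible = 0.1, responder = 0.1),
                       ko_taxa_per_ko = 3, ko_noise_sd = 0.05,
                       post_start = NULL) {
  stopifnot(n_years >= 1, samples_per_month >= 1, n_taxa >= 1, n_kos >= 1)
  if (year_effect_sd < 0 || month_effect_sd < 0 || noise_sd < 0 || ko_noise_sd < 0) {
    msg_stop("bad-config", "effect/noise sds must be >= 0")
  }
  if (sum(role_fractions) > 1 + 1e-12) {
    msg_stop("bad-config", "role fractions must sum to <= 1")
  }
  span_start <- as.Date(sprintf("%d-01-01", start_year))
  span_end <- as.Date(sprintf("%d-12-31", start_year + n_years - 1))
  disturbances <- lapply(disturbances, function(w) {
    w$start <- as.Date(w$start); w$end <- as.Date(w$end)
    w$lag_days <- w$lag_days %||% 7
    w$effect <- w$effect %||% 0
    if (is.na(w$start) || is.na(w$end) || w$end < w$start) {
      msg_stop("bad-config", "disturbance window has invalid dates")
    }
    if (w$start < span_start || w$end > span_end) {
      msg_stop("bad-config", "disturbance window outside simulated span")
    }
    if (!w$role %in% c("susceptible", "responder")) {
      msg_stop("bad-config", "disturbance role must be susceptible or responder")
    }
    if (!is.finite(w$effect) || w$effect < 0 || w$lag_days < 0) {
      msg_stop("bad-config", "disturbance effect and lag must be nonnegative")
    }
    w
  })
  if (is.null(post_start)) {
    post_start <- as.Date(sprintf("%d-01-01", start_year + n_years - 1))
  }
  structure(list(
    seed = as.integer(seed), n_years = n_years, start_year = start_year,
    samples_per_month = samples_per_month, n_taxa = n_taxa, n_kos = n_kos,
    base_log_range = base_log_range, year_effect_sd = year_effect_sd,
    month_effect_sd = month_effect_sd, noise_sd = noise_sd,
    disturbances = disturbances, role_fractions = role_fractions,
    ko_taxa_per_ko = ko_taxa_per_ko, ko_noise_sd = ko_noise_sd,
    post_start = as.Date(post_start)
  ), class = "sim_config")
}

#' Simulate the taxon table of a seasonal community time series
#'
#' @param config A [sim_config()].
#' @return A list: `table` (RPKM-like `feature_table`, genus kind),
#'   `metadata` (see [sample_metadata()]; `period` is set by `post_start`,
#'   and `stage` is `"pre"` in the baseline period and `"disturbed"` /
#'   `"post"` in the post period depending on lagged window membership),
#'   and `truth` (a `sim_truth` list of roles, realized effects, and the
#'   per-sample disturbance terms actually applied).
#' @export
simulate_taxa <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    years <- config$start_year + seq_len(config$n_years) - 1
    spm <- config$samples_per_month
    grid <- tidyr::expand_grid(year = years, month = 1:12, k = seq_len(spm))
    day <- floor((grid$k - 0.5) / spm * 28) + 1
    dates <- as.Date(sprintf("%d-%02d-%02d", grid$year, grid$month, day))
    ord <- order(dates)
    dates <- dates[ord]
    n <- length(dates)
    sample_id <- sprintf("S%04d", seq_len(n))

    taxa <- sprintf("T%03d", seq_len(config$n_taxa))
    n_sus <- round(config$role_fractions[["susceptible"]] * config$n_taxa)
    n_res <- round(config$role_fractions[["responder"]] * config$n_taxa)
    roles <- sample(c(rep("susceptible", n_sus), rep("responder", n_res),
                      rep("neutral", config$n_taxa - n_sus - n_res)))

    base <- runif(config$n_taxa, config$base_log_range[1], config$base_log_range[2])
    year_eff <- matrix(rnorm(config$n_years * config$n_taxa, 0, config$year_effect_sd),
                       config$n_years, config$n_taxa,
                       dimnames = list(years, taxa))
    month_eff <- matrix(rnorm(12 * config$n_taxa, 0, config$month_effect_sd),
                        12, config$n_taxa, dimnames = list(1:12, taxa))
    noise <- matrix(rnorm(n * config$n_taxa, 0, config$noise_sd),
                    n, config$n_taxa)

    dist_term <- matrix(0, n, config$n_taxa, dimnames = list(sample_id, taxa))
    in_any_window <- rep(FALSE, n)
    for (w in config$disturbances) {
      active <- dates >= (w$start + w$lag_days) & dates <= (w$end + w$lag_days)
      in_any_window <- in_any_window | active
      sign <- if (w$role == "susceptible") -1 else 1
      hit <- roles == w$role
      dist_term[active, hit] <- dist_term[active, hit] + sign * w$effect
    }

    yi <- match(as.integer(format(dates, "%Y")), years)
    mi <- as.integer(format(dates, "%m"))
    log10val <- matrix(base, n, config$n_taxa, byrow = TRUE) +
      year_eff[yi, , drop = FALSE] + month_eff[mi, , drop = FALSE] +
      dist_term + noise
    values <- 10^log10val
    dimnames(values) <- list(sample_id, taxa)

    period <- ifelse(dates >= config$post_start, "post", "baseline")
    stage <- ifelse(period == "baseline", "pre",
                    ifelse(in_any_window, "disturbed", "post"))
    metadata <- sample_metadata(tibble(
      sample_id = sample_id, date = dates, stage = stage, period = period
    ))

    dist_long <- as_tibble(dist_term) %>%
      mutate(sample_id = sample_id) %>%
      tidyr::pivot_longer(-"sample_id", names_to = "taxon",
                          values_to = "effect") %>%
      filter(.data$effect != 0)

    truth <- structure(list(
      roles = tibble(taxon = taxa, role = roles),
      base = tibble(taxon = taxa, base_log10 = base),
      year_effects = year_eff, month_effects = month_eff,
      disturbance = dist_long,
      config = config
    ), class = "sim_truth")

    list(table = ft_from_matrix(values, "genus", "rpkm"),
         metadata = metadata, truth = truth)
  })
}

#' Simulate a KO table linked to simulated taxa
#'
#' Each KEGG Ortholog is a sparse nonnegative weighted sum of taxon
#' abundances with multiplicative lognormal noise, so KO-level anomalies
#' inherit the taxa's disturbances through the loading matrix.
#'
#' @param taxa_table The taxon `feature_table` from [simulate_taxa()].
#' @param truth The matching `sim_truth`.
#' @param config The same [sim_config()].
#' @return A list: `table` (KO-level `feature_table`) and `loadings`
#'   (n_kos x n_taxa matrix, also what `truth$ko_loadings` should hold).
#' @export
simulate_kos <- function(taxa_table, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  x <- ft_matrix(taxa_table)
  withr::with_seed(config$seed + 1L, {
    kos <- sprintf("K%05d", seq_len(config$n_kos))
    w <- matrix(0, config$n_kos, ncol(x), dimnames = list(kos, colnames(x)))
    k <- min(config$ko_taxa_per_ko, ncol(x))
    for (i in seq_len(config$n_kos)) {
      j <- sample(ncol(x), k)
      w[i, j] <- runif(k, 0.5, 1.5)
    }
    if (any(rowSums(w) == 0)) msg_stop("bad-loadings", "all-zero KO loading row")
    ko_vals <- x %*% t(w)
    noise <- matrix(10^rnorm(length(ko_vals), 0, config$ko_noise_sd),
                    nrow(ko_vals), ncol(ko_vals))
    list(table = ft_from_matrix(ko_vals * noise, "ko", "rpkm"),
         loadings = w)
  })
}

#' Simulate taxa and linked KOs in one call
#'
#' @param config A [sim_config()].
#' @return A list `taxa`, `kos` (both `feature_table`s), `metadata`, `truth`
#'   (with `ko_loadings` attached).
#' @export
simulate_community <- function(config) {
  sim <- simulate_taxa(config)
  ko <- simulate_kos(sim$table, sim$truth, config)
  sim$truth$ko_loadings <- ko$loadings
  list(taxa = sim$table, kos = ko$table, metadata = sim$metadata,
       truth = sim$truth)
}

#' Null dataset: the same community with all disturbance effects zeroed
#'
#' Convenience wrapper for calibration suites: identical to
#' [simulate_taxa()] under the same seed except that every disturbance
#' window's effect is set to zero, so `truth$disturbance` is empty.
#'
#' @param config A [sim_config()].
#' @return As [simulate_taxa()].
#' @export
null_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$disturbances <- lapply(config$disturbances, function(w) {
    w$effect <- 0
    w
  })
  simulate_taxa(config)
}
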