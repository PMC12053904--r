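#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates the stages end to end: data (simulated or loaded from TSV
#' inputs), centering/scaling and structure (PCA, PERMANOVA,
#' nearest-neighbor dissimilarity, complete-linkage clustering), alpha
#' diversity, responder panels, the seasonal-baseline anomaly detector, and
#' indicator analysis. Every stage writes its tabular outputs under
#' `outdir` and the run ends with a JSON manifest recording the config,
#' seeds, package version, and per-file row counts. Re-running with the same
#' config and seed reproduces every output bit-identically.
#'
#' The config is a YAML file (or equivalent list) with exactly one of a
#' `simulation` section (arguments to [sim_config()]) or an `inputs` section
#' (paths: `taxa_table`, `ko_table`, `metadata`, `ko_module_map`, optionally
#' `genus_family_map`, `panel`), an optional `stages` vector (default all of
#' `diversity`, `structure`, `responders`, `anomaly`, `indicators`; the
#' anomaly stage consumes the scaled matrices computed by the structure
#' stage and fails fast without it), and an optional `params` section
#' (`level`, `exclusion_threshold`, `fit_scope`, `interval_kind`,
#' `n_permutations`, `alpha`, `top_k`, `seed`).
#'
#' @param config Path to a YAML config or a list with the same structure.
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the config's seed.
#' @param stages Optional character vector overriding the config's stages.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, outdir, seed = NULL, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    msg_stop("bad-config", "config needs exactly one of 'simulation' or 'inputs'")
  }
  params <- config$params %||% list()
  p <- list(
    level = params$level %||% 0.95,
    exclusion_threshold = params$exclusion_threshold %||% 4,
    fit_scope = params$fit_scope %||% "all",
    interval_kind = params$interval_kind %||% "empirical",
    n_permutations = params$n_permutations %||% 999,
    alpha = params$alpha %||% 0.05,
    top_k = params$top_k %||% 25,
    seed = as.integer(seed %||% params$seed %||% config$simulation$seed %||% 1L)
  )
  stages <- stages %||% config$stages %||%
    c("diversity", "structure", "responders", "anomaly", "indicators")
  bad <- setdiff(stages, c("diversity", "structure", "responders",
                           "anomaly", "indicators"))
  if (length(bad)) msg_stop("bad-config", "unknown stages: " %+% comma(bad))
  if ("anomaly" %in% stages && !"structure" %in% stages) {
    msg_stop("stage-dependency",
             "anomaly stage requires the structure stage (scaled matrices)")
  }
  if (has_inputs) {
    need <- c("taxa_table", "ko_table", "metadata", "ko_module_map")
    for (f in intersect(need, names(config$inputs))) {
      if (!file.exists(config$inputs[[f]])) {
        msg_stop("missing-file", "input file not found: " %+% config$inputs[[f]])
      }
    }
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) msg_stop("bad-config", "missing inputs: " %+% comma(miss))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, params = p, stages = stages,
                   package_version = as.character(utils::packageVersion("spillwatch")),
                   outputs = list())
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    if (is.data.frame(x)) {
      readr::write_tsv(as_tibble(x), path, progress = FALSE)
      manifest$outputs[[name]] <<- list(rows = nrow(x))
    } else {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      manifest$outputs[[name]] <<- list(rows = length(x))
    }
  }

  # ---- data stage ------------------------------------------------------
  if (has_sim) {
    sc <- do.call(sim_config, c(config$simulation,
                                if (!is.null(seed)) list(seed = seed)))
    sim <- simulate_community(sc)
    taxa <- sim$taxa; kos <- sim$kos; metadata <- sim$metadata
    panel <- sim$truth$roles %>%
      filter(.data$role != "neutral") %>%
      rename(feature_id = "taxon")
    # synthetic sequential KO -> module map, ~10 KOs per module
    ko_ids <- feature_ids(kos)
    ko_map <- tibble(child_id = ko_ids,
                     parent_id = sprintf("M%04d", (seq_along(ko_ids) - 1) %/% 10 + 1))
    emit(tibble(taxon = sim$truth$roles$taxon, role = sim$truth$roles$role),
         "truth_roles.tsv")
    emit(sim$truth$disturbance, "truth_disturbance.tsv")
  } else {
    taxa <- read_feature_table(config$inputs$taxa_table, "genus")
    kos <- read_feature_table(config$inputs$ko_table, "ko")
    metadata <- read_sample_metadata(config$inputs$metadata)
    ko_map <- read_feature_map(config$inputs$ko_module_map)
    panel <- if (!is.null(config$inputs$panel)) {
      read_responder_panel(config$inputs$panel)
    } else {
      default_responder_panel()
    }
  }
  emit(as_tibble(taxa), "taxa_table.tsv")
  emit(as_tibble(kos), "ko_table.tsv")
  emit(metadata, "metadata.tsv")

  taxa_rel <- relative_abundance(taxa)
  emit(tibble(rank = seq_along(top_k_features(taxa_rel, p$top_k)),
              feature = top_k_features(taxa_rel, p$top_k)),
       "top_features.tsv")

  # ---- diversity -------------------------------------------------------
  if ("diversity" %in% stages) {
    div_t <- diversity_series(taxa, metadata)
    div_k <- diversity_series(kos, metadata)
    emit(div_t, "diversity_taxa.tsv")
    emit(div_k, "diversity_kos.tsv")
    emit(diversity_correlations(div_t), "diversity_correlations_taxa.tsv")
    emit(diversity_correlations(div_k), "diversity_correlations_kos.tsv")
  }

  # ---- structure -------------------------------------------------------
  if ("structure" %in% stages) {
    z_taxa <- center_scale(taxa)
    z_kos <- center_scale(kos)
    pca_t <- pca_ordination(z_taxa, n_components = 2)
    sc_t <- tidy(pca_t, "scores") %>%
      left_join(metadata[, c("sample_id", "date")], by = "sample_id")
    emit(sc_t, "pc_scores_taxa.tsv")
    emit(nn_dissimilarity(z_taxa, metadata), "nn_dissimilarity_taxa.tsv")
    perm <- permanova(dist(ft_matrix(z_taxa)), align_metadata(z_taxa, metadata)$stage,
                      n_permutations = p$n_permutations, seed = p$seed)
    emit(list(pseudo_F = perm$pseudo_F, R2 = perm$R2, p_value = perm$p_value,
              n_permutations = perm$n_permutations, seed = p$seed),
         "permanova_taxa.json")
    hc <- hclust_complete(dist(ft_matrix(z_kos)))
    emit(linkage_table(hc), "linkage_kos.tsv")
  }

  # ---- responders ------------------------------------------------------
  if ("responders" %in% stages) {
    tot <- panel_total(taxa_rel, panel, role = "responder")
    emit(tot, "panel_totals.tsv")
    resc <- panel_rescale(taxa_rel, panel, role = "responder")
    emit(resc, "panel_scaled.tsv")
    emit(panel_center(resc), "panel_centered.tsv")
    sus <- intersect(panel$feature_id[panel$role == "susceptible"],
                     feature_ids(taxa_rel))
    res <- intersect(panel$feature_id[panel$role == "responder"],
                     feature_ids(taxa_rel))
    if (length(sus) && length(res)) {
      emit(pearson_screen(taxa_rel, sus, res), "panel_correlations.tsv")
    }
  }

  # ---- anomaly ---------------------------------------------------------
  if ("anomaly" %in% stages) {
    fit_t <- fit_seasonal_baseline(z_taxa, metadata, fit_scope = p$fit_scope)
    emit(type2_anova(fit_t), "anova_taxa.tsv")
    int_t <- baseline_interval(fit_t, level = p$level,
                               exclusion_threshold = p$exclusion_threshold,
                               interval_kind = p$interval_kind)
    emit(int_t, "baseline_interval_taxa.tsv")
    rep_t <- flag_anomalies(fit_t, int_t)
    emit(rep_t, "anomaly_report_taxa.tsv")
    emit(monthly_anomaly_panel(fit_t, rep_t,
                               exclusion_threshold = p$exclusion_threshold),
         "monthly_panel_taxa.tsv")

    fit_k <- fit_seasonal_baseline(z_kos, metadata, fit_scope = p$fit_scope)
    mod_res <- module_median_residuals(fit_k, ko_map)
    emit(mod_res, "module_median_residuals.tsv")
    int_m <- baseline_interval(mod_res, metadata = metadata, level = p$level,
                               exclusion_threshold = p$exclusion_threshold,
                               interval_kind = p$interval_kind)
    emit(int_m, "baseline_interval_modules.tsv")
    emit(flag_anomalies(mod_res, int_m, metadata = metadata),
         "anomaly_report_modules.tsv")
  }

  # ---- indicators ------------------------------------------------------
  if ("indicators" %in% stages) {
    post_stages <- unique(metadata$stage[metadata$period == "post"])
    iv <- indval(kos, metadata, post_stages = post_stages,
                 n_permutations = p$n_permutations, seed = p$seed + 1L)
    if (length(post_stages) >= 1) {
      iv <- select_stage_associated(iv, post_stages = post_stages,
                                    alpha = p$alpha)
    }
    emit(as_tibble(iv), "indicators_kos.tsv")
  }

  manifest_path <- file.path(outdir, "manifest.json")
  manifest$config <- rapply(manifest$config, function(x)
    if (inherits(x, "Date")) as.character(x) else x, how = "replace")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
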