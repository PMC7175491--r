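#' Default pipeline configuration
#'
#' Thresholds follow the study conventions throughout: detection p 0.01,
#' FDR q 0.05, |delta beta| gates 0.20 (sites) and 0.15 (regions).  The
#' default demo cohort is a simulated adenoma-progression design (20 normal,
#' 18 LGA, 22 HGA, 20 carcinoma) carrying strong coordinated hyper effects
#' (including the marker gene's promoter island) and deliberately weak hypo
#' effects, so the hyper site-set model is constructed to be the stronger
#' discriminator.  Any override is echoed into the run report.
#'
#' @param ... named overrides of the defaults (nested lists are merged).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    cohort = list(
      n_probes = 6000, n_genes = 120,
      n_normal = 20, n_lga = 18, n_hga = 22, n_cancer = 20,
      frac_sex = 0.05, frac_snp = 0.02, sample_sd = 0.05
    ),
    effects = list(
      n_hyper_sites = 150, n_hypo_sites = 300,
      delta_hyper = c(LGA = 0.30, HGA = 0.35, cancer = 0.40),
      delta_hypo = c(LGA = -0.08, HGA = -0.09, cancer = -0.10),
      monotone = TRUE,
      marker_genes = "GENE_001",
      purity_range = c(0.7, 1)
    ),
    thresholds = list(
      q = 0.05, dms_delta = 0.20, dmr_delta = 0.15, detection_p = 0.01
    ),
    learner = list(
      name = "random_forest", scheme = "cv_k_fold", folds = 5,
      params = list(ntree = 500)
    ),
    bootstrap = list(n_replicates = 2000),
    seed = 1,
    out_dir = NULL
  )
  overrides <- list(...)
  merge_config(defaults, overrides)
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[nm] <- list(overrides[[nm]])  # preserves explicit NULLs
    }
  }
  base
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (slot in c("delta_hyper", "delta_hypo")) {
    if (!is.null(raw$effects[[slot]])) {
      v <- unlist(raw$effects[[slot]])
      if (is.null(names(v))) names(v) <- c("LGA", "HGA", "cancer")
      raw$effects[[slot]] <- v
    }
  }
  if (!is.null(raw$effects$purity_range)) {
    raw$effects$purity_range <- unname(unlist(raw$effects$purity_range))
  }
  for (slot in intersect(c("n_probes", "n_genes", "n_normal", "n_lga",
                           "n_hga", "n_cancer"), names(raw$cohort))) {
    raw$cohort[[slot]] <- as.numeric(raw$cohort[[slot]])
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config_yaml
#' @param config a `pipeline_config`.
#' @export
write_config_yaml <- function(config, path) {
  # named atomic vectors become maps so stage names survive the round trip
  to_yaml <- function(x) {
    if (is.list(x)) {
      lapply(x, to_yaml)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(to_yaml(config), path)
  invisible(path)
}

#' Run the full simulate -> preprocess -> differential -> biomarker ->
#' classifier pipeline
#'
#' Stages: simulate a cohort with known truth; QC-filter probes; call DMS
#' (LGA vs normal) and DMR (promoter scheme) with direction tallies; score
#' the marker gene's promoter-island mBV over disease vs normal with cutoff
#' optimization and ROC; bootstrap-compare the hyper vs hypo site-set mBV
#' models; and evaluate a classifier on both site sets.  The hyper/hypo
#' comparison sets are taken from the called DMS table when both directions
#' are represented, otherwise from the simulation truth (the demo's weak
#' hypo effects sit below the DMS delta gate by construction).
#'
#' All randomness derives from `config$seed`; rerunning with the same config
#' reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list with per-stage summaries; written to
#'   `config$out_dir` as JSON (plus TSV stage outputs) when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(is.list(config))
  seed <- config$seed
  co <- config$cohort
  eff <- config$effects

  spec <- effect_spec(
    n_hyper_sites = eff$n_hyper_sites, n_hypo_sites = eff$n_hypo_sites,
    delta_hyper = eff$delta_hyper, delta_hypo = eff$delta_hypo,
    monotone = eff$monotone, marker_genes = eff$marker_genes,
    purity_range = eff$purity_range, seed = seed
  )
  sim <- simulate_cohort(
    n_probes = co$n_probes, n_genes = co$n_genes,
    n_normal = co$n_normal, n_lga = co$n_lga, n_hga = co$n_hga,
    n_cancer = co$n_cancer, spec = spec,
    sample_sd = co$sample_sd, frac_sex = co$frac_sex, frac_snp = co$frac_snp,
    seed = seed
  )

  filt <- filter_probes(sim$betas, sim$manifest,
                        p_threshold = config$thresholds$detection_p)
  betas <- filt$betas
  groups <- sim$groups

  # DMS: LGA vs normal (the earliest lesion contrast)
  sel <- groups %in% c("normal", "LGA")
  dms <- call_dms(betas[, sel, drop = FALSE], groups[sel], reference = "normal",
                  delta_threshold = config$thresholds$dms_delta)
  dms_tally <- direction_tally(dms)

  agg <- aggregate_regions(betas, sim$manifest, scheme = "promoter")
  dmr <- call_dmr(agg$values[, sel, drop = FALSE], groups[sel],
                  reference = "normal",
                  delta_threshold = config$thresholds$dmr_delta)
  dmr_tally <- direction_tally(dmr)

  labels <- ifelse(groups == "normal", "normal", "disease")
  marker <- eff$marker_genes[1]
  marker_set <- promoter_island_set(sim$manifest, marker)
  marker_scores <- mbv(betas, marker_set, labels)
  marker_cut <- optimal_cutoff(marker_scores, "hyper")
  marker_roc <- roc(marker_scores, "hyper")

  # Hyper vs hypo site-set models: from called DMS when both directions are
  # flagged, else from the known simulation truth.
  flagged <- dms[dms$is_dms, , drop = FALSE]
  if (any(flagged$direction == "hyper") && any(flagged$direction == "hypo")) {
    set_source <- "dms"
    hyper_ids <- flagged$unit_id[flagged$direction == "hyper"]
    hypo_ids <- flagged$unit_id[flagged$direction == "hypo"]
  } else {
    set_source <- "truth"
    hyper_ids <- intersect(unique(sim$truth$probe_id[sim$truth$true_delta > 0]),
                           rownames(betas))
    hypo_ids <- intersect(unique(sim$truth$probe_id[sim$truth$true_delta < 0]),
                          rownames(betas))
  }
  comparison <- NULL
  ml <- NULL
  if (length(hyper_ids) && length(hypo_ids)) {
    hyper_set <- site_set("hyper_sites", hyper_ids, "hyper")
    hypo_set <- site_set("hypo_sites", hypo_ids, "hypo")
    comparison <- bootstrap_auc_compare(
      mbv(betas, hyper_set, labels), mbv(betas, hypo_set, labels),
      polarity_a = "hyper", polarity_b = "hypo",
      n_replicates = config$bootstrap$n_replicates, seed = seed + 1L
    )
    ml <- compare_site_set_models(
      betas, labels, hyper_set, hypo_set,
      learner = config$learner$name, scheme = config$learner$scheme,
      params = config$learner$params, folds = config$learner$folds,
      seed = seed + 2L
    )
  }

  report <- list(
    package_version = as.character(utils::packageVersion("adenometh")),
    config = config,
    filter = unclass(filt$report)[c("n_input_probes", "n_removed_sex",
                                    "n_removed_detection", "n_removed_snp",
                                    "n_retained")],
    dms = list(n_tested = nrow(dms), tally = dms_tally),
    dmr = list(n_tested = nrow(dmr), tally = dmr_tally),
    marker = list(
      gene = marker,
      n_sites = length(marker_set$probe_ids),
      cutoff = marker_cut$cutoff,
      n_errors = marker_cut$n_errors,
      error_rate = marker_cut$error_rate,
      confusion = as.list(marker_cut$confusion),
      auc = marker_roc$auc
    ),
    comparison = if (!is.null(comparison)) list(
      set_source = set_source,
      n_hyper_sites = length(hyper_ids),
      n_hypo_sites = length(hypo_ids),
      auc_hyper = comparison$observed_auc_a,
      auc_hypo = comparison$observed_auc_b,
      auc_diff = comparison$auc_diff,
      p_value = comparison$p_value,
      n_replicates = comparison$n_replicates
    ),
    classifier = if (!is.null(ml)) list(
      learner = config$learner$name,
      scheme = config$learner$scheme,
      hyper = list(confusion = as.list(ml$eval_a$confusion),
                   sensitivity = ml$eval_a$sensitivity,
                   specificity = ml$eval_a$specificity),
      hypo = list(confusion = as.list(ml$eval_b$confusion),
                  sensitivity = ml$eval_b$sensitivity,
                  specificity = ml$eval_b$specificity)
    ),
    seeds = list(master = seed, bootstrap = seed + 1L, classifier = seed + 2L)
  )
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_beta_tsv(betas, file.path(config$out_dir, "betas_filtered.tsv"))
    write_manifest_csv(sim$manifest, file.path(config$out_dir, "manifest.csv"))
    write_sample_sheet(sim$sample_sheet, file.path(config$out_dir, "samples.csv"))
    utils::write.table(sim$truth, file.path(config$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_diff_tsv(dms, file.path(config$out_dir, "dms.tsv"))
    write_diff_tsv(dmr, file.path(config$out_dir, "dmr.tsv"))
    write_report_json(strip_config_null(report),
                      file.path(config$out_dir, "report.json"))
  }
  report
}

# jsonlite drops NULL out_dir cleanly; keep helper for explicit NULL slots.
strip_config_null <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.null, logical(1))]
    lapply(x, strip_config_null)
  } else {
    x
  }
}

#' @export
print.run_report <- function(x, ...) {
  cat("adenometh pipeline report\n")
  cat(sprintf("  probes retained after QC: %d / %d\n",
              x$filter$n_retained, x$filter$n_input_probes))
  cat(sprintf("  DMS (LGA vs normal): %d flagged (%s%% hyper / %s%% hypo)\n",
              x$dms$tally$n_flagged, x$dms$tally$pct_hyper, x$dms$tally$pct_hypo))
  cat(sprintf("  DMR (promoter): %d flagged\n", x$dmr$tally$n_flagged))
  cat(sprintf("  marker %s promoter mBV: AUC %.3f, cutoff %.3f, error rate %.2f%%\n",
              x$marker$gene, x$marker$auc, x$marker$cutoff, x$marker$error_rate))
  if (!is.null(x$comparison)) {
    cat(sprintf("  hyper vs hypo mBV AUC: %.3f vs %.3f (bootstrap p = %.4g, sets: %s)\n",
                x$comparison$auc_hyper, x$comparison$auc_hypo,
                x$comparison$p_value, x$comparison$set_source))
  }
  if (!is.null(x$classifier)) {
    cat(sprintf("  %s (%s): hyper sens/spec %.3f/%.3f, hypo %.3f/%.3f\n",
                x$classifier$learner, x$classifier$scheme,
                x$classifier$hyper$sensitivity, x$classifier$hyper$specificity,
                x$classifier$hypo$sensitivity, x$classifier$hypo$specificity))
  }
  invisible(x)
}
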