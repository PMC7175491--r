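#' Generate a synthetic 450K-style probe manifest
#'
#' Builds a probe annotation table that mimics the structure of an Illumina
#' 450K manifest: probes grouped into gene models along autosomes (every gene
#' receives at least one probe in each promoter category -- TSS200, TSS1500,
#' 5'UTR and 1stExon -- plus gene-body and 3'UTR probes), a requested fraction
#' of sex-chromosome probes, a requested fraction of SNP-flagged probes, and
#' intergenic filler probes.  Positions are 1-based and strictly increasing
#' within each chromosome.
#'
#' @param n_probes total number of probes; must be at least `8 * n_genes`
#'   plus the requested sex-chromosome probes.
#' @param n_genes number of gene models to lay down.
#' @param frac_sex fraction of probes placed on chrX/chrY, in `[0, 1)`.
#' @param frac_snp fraction of probes flagged as SNP-overlapping, in `[0, 1)`.
#' @param seed integer seed; the manifest is a pure function of the arguments.
#' @return a data.frame with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   `region_category`, `island_relation`, `snp_flagged`.
#' @examples
#' m <- generate_manifest(1000, 50, frac_sex = 0.05, frac_snp = 0.02, seed = 1)
#' table(m$region_category)
#' @export
generate_manifest <- function(n_probes, n_genes, frac_sex = 0.05,
                              frac_snp = 0.02, seed = 1) {
  stopifnot(n_probes >= 1, n_genes >= 1,
            frac_sex >= 0, frac_sex < 1, frac_snp >= 0, frac_snp < 1)
  if (n_probes < 8 * n_genes) {
    stop(sprintf(
      "n_probes = %d is too small: %d genes need at least %d probes (8 per gene)",
      n_probes, n_genes, 8 * n_genes), call. = FALSE)
  }
  n_sex <- round(frac_sex * n_probes)
  n_gene_probes <- 8L * n_genes
  n_intergenic <- n_probes - n_gene_probes - n_sex
  if (n_intergenic < 0) {
    stop("n_probes cannot accommodate the requested gene structure plus sex-chromosome fraction",
         call. = FALSE)
  }

  with_seed(seed, {
    # One 8-probe block per gene: promoter quartet, two Body, 3'UTR, one extra
    # Body probe.  TSS200/5'UTR/1stExon sit in the CpG island, TSS1500 on the
    # shore, body/3'UTR in shelf or open sea.
    gene_names <- sprintf("GENE_%03d", seq_len(n_genes))
    per_gene_cat <- c("TSS1500", "TSS200", "5'UTR", "1stExon",
                      "Body", "Body", "Body", "3'UTR")
    per_gene_isl <- c("shore", "island", "island", "island",
                      "shelf", "open_sea", "open_sea", "open_sea")
    gene <- rep(gene_names, each = 8L)
    category <- rep(per_gene_cat, times = n_genes)
    island <- rep(per_gene_isl, times = n_genes)

    if (n_intergenic > 0) {
      gene <- c(gene, rep("", n_intergenic))
      category <- c(category, rep("intergenic", n_intergenic))
      island <- c(island, sample(ISLAND_RELATIONS, n_intergenic,
                                 replace = TRUE, prob = c(0.15, 0.15, 0.1, 0.6)))
    }

    # Chromosomes assigned gene-blockwise so each gene sits on one chromosome.
    gene_block <- c(rep(seq_len(n_genes), each = 8L),
                    if (n_intergenic > 0) n_genes + seq_len(n_intergenic))
    block_chrom <- paste0("chr", ((gene_block - 1L) %% 22L) + 1L)

    chrom <- c(block_chrom,
               if (n_sex > 0) sample(SEX_CHROMS, n_sex, replace = TRUE))
    gene <- c(gene, rep("", n_sex))
    category <- c(category, rep("intergenic", n_sex))
    island <- c(island, if (n_sex > 0) sample(ISLAND_RELATIONS, n_sex,
                                              replace = TRUE))

    n_total <- length(chrom)
    # Strictly increasing positions within chromosome: cumulative jumps.
    pos <- integer(n_total)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- cumsum(sample(50:2000, length(idx), replace = TRUE))
    }

    # SNP flags: only on non-promoter probes so promoter site-set extraction
    # stays exercised after QC; counts within +/-1 of frac_snp * n_probes.
    snp_flagged <- rep(FALSE, n_total)
    n_snp <- round(frac_snp * n_probes)
    eligible_snp <- which(!(category %in% PROMOTER_CATEGORIES))
    if (n_snp > length(eligible_snp)) {
      stop("frac_snp too large for the number of non-promoter probes", call. = FALSE)
    }
    if (n_snp > 0) snp_flagged[sample(eligible_snp, n_snp)] <- TRUE

    manifest <- data.frame(
      probe_id = sprintf("cg%08d", seq_len(n_total)),
      chrom = chrom,
      pos = pos,
      gene = gene,
      region_category = category,
      island_relation = island,
      snp_flagged = snp_flagged,
      stringsAsFactors = FALSE
    )
    manifest <- manifest[order(match(manifest$chrom, c(paste0("chr", 1:22), SEX_CHROMS)),
                               manifest$pos), , drop = FALSE]
    rownames(manifest) <- NULL
    manifest
  })
}

#' Draw baseline beta values from a bimodal mixture
#'
#' Each probe receives a baseline methylation level drawn from a two-component
#' beta mixture (an unmethylated mode and a methylated mode, reproducing the
#' bimodal marginal density typical of 450K arrays).  Per-sample values are a
#' mean-preserving beta perturbation of the probe baseline, plus a small
#' per-sample global offset emulating array- and tissue-level variation.
#'
#' @param manifest probe manifest from [generate_manifest()].
#' @param n_samples number of samples to draw.
#' @param mixture list with elements `low_mode`, `high_mode` (modes of the two
#'   components, in (0,1), low < high), `weight` (probability of the low mode),
#'   `concentration` (beta concentration of per-probe baselines around each
#'   mode) and `noise_precision` (precision of the per-sample perturbation).
#' @param sample_sd standard deviation of the per-sample global offset on the
#'   beta scale (0 disables it).
#' @param seed integer seed.
#' @return numeric matrix, probes x samples, rownames = probe ids, colnames
#'   `S001`, `S002`, ...
#' @export
generate_baseline_betas <- function(manifest, n_samples,
                                    mixture = list(low_mode = 0.1,
                                                   high_mode = 0.85,
                                                   weight = 0.5),
                                    sample_sd = 0.05,
                                    seed = 1) {
  assert_manifest(manifest)
  stopifnot(n_samples >= 1)
  # concentration 30 keeps the two component humps sharp and well separated,
  # as in typical whole-array beta densities
  mix <- utils::modifyList(
    list(low_mode = 0.1, high_mode = 0.85, weight = 0.5,
         concentration = 30, noise_precision = 100),
    mixture)
  if (!(mix$low_mode > 0 && mix$low_mode < 1 && mix$high_mode > 0 &&
        mix$high_mode < 1)) {
    stop("mixture modes must lie in (0, 1)", call. = FALSE)
  }
  if (mix$low_mode >= mix$high_mode) {
    stop("degenerate mixture: low_mode must be strictly below high_mode", call. = FALSE)
  }
  stopifnot(mix$weight >= 0, mix$weight <= 1, sample_sd >= 0)

  n_probes <- nrow(manifest)
  with_seed(seed, {
    # Component membership is island-aware: CpG-island probes are mostly
    # unmethylated, open-sea probes mostly methylated.  The shift acts on the
    # log-odds of the mixing weight so weight = 0 or 1 stays degenerate.
    shift <- c(island = 2, shore = 0.5, shelf = -0.5, open_sea = -1)
    p_low <- stats::plogis(stats::qlogis(mix$weight) +
                             shift[manifest$island_relation])
    p_low[is.na(p_low)] <- mix$weight
    low <- stats::runif(n_probes) < p_low
    mode <- ifelse(low, mix$low_mode, mix$high_mode)
    k <- mix$concentration
    baseline <- stats::rbeta(n_probes, 1 + k * mode, 1 + k * (1 - mode))
    s <- mix$noise_precision
    vals <- stats::rbeta(n_probes * n_samples,
                         rep(baseline, n_samples) * s,
                         (1 - rep(baseline, n_samples)) * s)
    betas <- matrix(vals, nrow = n_probes, ncol = n_samples)
    if (sample_sd > 0) {
      offset <- stats::rnorm(n_samples, 0, sample_sd)
      betas <- sweep(betas, 2, offset, `+`)
    }
    betas <- clamp01(betas)
    dimnames(betas) <- list(manifest$probe_id, sprintf("S%03d", seq_len(n_samples)))
    attr(betas, "baseline") <- stats::setNames(baseline, manifest$probe_id)
    betas
  })
}

#' Construct an effect specification for the cohort simulator
#'
#' Describes which probes are perturbed in diseased stages and by how much.
#' Effects are additive shifts on the beta scale with clamping to `[0, 1]`;
#' when `monotone` is `TRUE` the stage-wise deltas must be nondecreasing in
#' magnitude along normal -> LGA -> HGA -> cancer, so changes arising in
#' low-grade adenoma are maintained or amplified later in progression.
#' `purity_range` attenuates every effect in a diseased sample by a
#' sample-specific factor drawn uniformly from that range, emulating tissue
#' purity / cellular heterogeneity; `c(1, 1)` disables attenuation.
#'
#' @param n_hyper_sites,n_hypo_sites numbers of hyper-/hypo-methylated probes.
#' @param delta_hyper,delta_hypo named numeric vectors of beta-scale shifts for
#'   stages `LGA`, `HGA`, `cancer` (hyper positive, hypo negative).
#' @param monotone enforce stage-wise monotone magnitude of the deltas.
#' @param marker_genes genes whose promoter-island probes all receive the
#'   hyper effect jointly (a coordinated promoter marker).
#' @param purity_range length-2 range for per-disease-sample attenuation.
#' @param seed integer seed used when selecting affected probes.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(n_hyper_sites = 100,
                        n_hypo_sites = 200,
                        delta_hyper = c(LGA = 0.15, HGA = 0.25, cancer = 0.30),
                        delta_hypo = c(LGA = -0.15, HGA = -0.25, cancer = -0.30),
                        monotone = TRUE,
                        marker_genes = character(),
                        purity_range = c(0.7, 1),
                        seed = 1) {
  stages <- c("LGA", "HGA", "cancer")
  stopifnot(n_hyper_sites >= 0, n_hypo_sites >= 0,
            all(stages %in% names(delta_hyper)),
            all(stages %in% names(delta_hypo)),
            length(purity_range) == 2, purity_range[1] <= purity_range[2],
            purity_range[1] > 0, purity_range[2] <= 1)
  delta_hyper <- delta_hyper[stages]
  delta_hypo <- delta_hypo[stages]
  if (any(delta_hyper < 0) || any(delta_hypo > 0)) {
    stop("delta_hyper must be >= 0 and delta_hypo <= 0", call. = FALSE)
  }
  if (monotone) {
    if (is.unsorted(delta_hyper)) {
      stop("monotone spec requires delta_hyper(LGA) <= delta_hyper(HGA) <= delta_hyper(cancer)",
           call. = FALSE)
    }
    if (is.unsorted(rev(delta_hypo))) {
      stop("monotone spec requires delta_hypo increasingly negative along progression",
           call. = FALSE)
    }
  }
  structure(list(n_hyper_sites = n_hyper_sites, n_hypo_sites = n_hypo_sites,
                 delta_hyper = delta_hyper, delta_hypo = delta_hypo,
                 monotone = monotone, marker_genes = marker_genes,
                 purity_range = purity_range, seed = seed),
            class = "effect_spec")
}

#' Inject stage-wise methylation effects into a baseline cohort
#'
#' Shifts the selected hyper-/hypo-methylated probes in diseased samples by
#' the stage delta (attenuated by the sample's purity factor) with clamping to
#' `[0, 1]`.  Normal samples are untouched.  Hyper sites are drawn from
#' low-baseline autosomal non-SNP probes and hypo sites from high-baseline
#' ones, so injected truth survives QC filtering and respects the usual
#' island-promoter-gain / open-sea-loss biology.  Marker genes' promoter
#' island probes all receive the hyper effect jointly.
#'
#' @param betas baseline beta matrix from [generate_baseline_betas()].
#' @param manifest matching probe manifest.
#' @param groups character vector of stage labels per sample (subset of
#'   `normal`, `LGA`, `HGA`, `cancer`), parallel to `colnames(betas)`.
#' @param spec an [effect_spec()].
#' @return list with elements `betas` (shifted matrix) and `truth`
#'   (data.frame `probe_id`, `stage`, `true_delta`, `is_marker_promoter`, one
#'   row per affected probe x diseased stage present in `groups`).
#' @export
inject_effects <- function(betas, manifest, groups, spec) {
  assert_beta_matrix(betas)
  assert_manifest(manifest)
  stopifnot(inherits(spec, "effect_spec"),
            length(groups) == ncol(betas))
  if (!all(groups %in% STAGES)) {
    stop("groups must be drawn from {normal, LGA, HGA, cancer}", call. = FALSE)
  }
  missing_marker <- setdiff(spec$marker_genes, manifest$gene)
  if (length(missing_marker)) {
    stop(sprintf("marker gene(s) absent from manifest: %s",
                 paste(missing_marker, collapse = ", ")), call. = FALSE)
  }

  ann <- manifest[match(rownames(betas), manifest$probe_id), , drop = FALSE]
  eligible <- !(ann$chrom %in% SEX_CHROMS) & !ann$snp_flagged &
    !is.na(ann$probe_id)
  base_mean <- rowMeans(betas, na.rm = TRUE)

  marker_idx <- which(eligible & ann$gene %in% spec$marker_genes &
                        ann$region_category %in% PROMOTER_CATEGORIES &
                        ann$island_relation == "island")
  if (length(spec$marker_genes) && !length(marker_idx)) {
    stop("marker genes have no promoter-island probes in the manifest", call. = FALSE)
  }

  with_seed(spec$seed, {
    pick <- function(pool, n) {
      if (n > length(pool)) {
        stop(sprintf("requested %d affected sites but only %d eligible probes",
                     n, length(pool)), call. = FALSE)
      }
      if (n == 0) integer() else sample(pool, n)
    }
    low_pool <- setdiff(which(eligible & base_mean < 0.5), marker_idx)
    high_pool <- setdiff(which(eligible & base_mean >= 0.5), marker_idx)
    n_extra_hyper <- max(0L, spec$n_hyper_sites - length(marker_idx))
    hyper_idx <- c(marker_idx, pick(low_pool, n_extra_hyper))
    hypo_idx <- pick(high_pool, spec$n_hypo_sites)

    stages_present <- intersect(c("LGA", "HGA", "cancer"), unique(groups))
    purity <- rep(1, ncol(betas))
    diseased <- groups != "normal"
    purity[diseased] <- stats::runif(sum(diseased),
                                     spec$purity_range[1], spec$purity_range[2])

    out <- betas
    for (st in stages_present) {
      cols <- which(groups == st)
      if (length(hyper_idx)) {
        shift <- outer(rep(spec$delta_hyper[[st]], length(hyper_idx)),
                       purity[cols])
        out[hyper_idx, cols] <- clamp01(out[hyper_idx, cols, drop = FALSE] + shift)
      }
      if (length(hypo_idx)) {
        shift <- outer(rep(spec$delta_hypo[[st]], length(hypo_idx)),
                       purity[cols])
        out[hypo_idx, cols] <- clamp01(out[hypo_idx, cols, drop = FALSE] + shift)
      }
    }

    truth <- rbind(
      if (length(hyper_idx)) expand_truth(rownames(betas)[hyper_idx],
                                          stages_present, spec$delta_hyper,
                                          rownames(betas)[hyper_idx] %in%
                                            rownames(betas)[marker_idx]),
      if (length(hypo_idx)) expand_truth(rownames(betas)[hypo_idx],
                                         stages_present, spec$delta_hypo, FALSE)
    )
    if (is.null(truth)) {
      truth <- data.frame(probe_id = character(), stage = character(),
                          true_delta = numeric(), is_marker_promoter = logical(),
                          stringsAsFactors = FALSE)
    }
    list(betas = out, truth = truth)
  })
}

expand_truth <- function(ids, stages, deltas, is_marker) {
  do.call(rbind, lapply(stages, function(st) {
    data.frame(probe_id = ids, stage = st, true_delta = unname(deltas[[st]]),
               is_marker_promoter = is_marker, stringsAsFactors = FALSE)
  }))
}

#' Convert beta values to synthetic two-channel intensities
#'
#' Inverse model of the beta computation: each beta value is split into a
#' methylated/unmethylated intensity pair summing to `total_intensity`
#' (`M = beta * T`, `U = (1 - beta) * T`), optionally with Gaussian intensity
#' noise, and a `fail_frac` fraction of entries is assigned a failing
#' detection p-value (> 0.01).  Recomputing beta values from the noiseless
#' output reproduces the input up to the `+100` offset of the beta formula,
#' an error that shrinks as `total_intensity` grows.
#'
#' @param betas beta matrix.
#' @param total_intensity per-entry M + U total; must exceed the formula
#'   offset (100) by a wide margin.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param fail_frac fraction of probe x sample entries flagged as failed
#'   detection.
#' @param seed integer seed.
#' @return data.frame in long format: `probe_id`, `sample_id`, `M`, `U`,
#'   `detection_p`.
#' @export
betas_to_intensities <- function(betas, total_intensity = 10000,
                                 noise_sd = 0, fail_frac = 0, seed = 1) {
  assert_beta_matrix(betas)
  if (total_intensity <= 0) stop("total_intensity must be positive", call. = FALSE)
  if (total_intensity <= 100) {
    stop("total_intensity must exceed the beta-formula offset (100)", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, fail_frac >= 0, fail_frac < 1)
  n <- length(betas)
  with_seed(seed, {
    M <- as.vector(betas) * total_intensity
    U <- (1 - as.vector(betas)) * total_intensity
    if (noise_sd > 0) {
      M <- M + stats::rnorm(n, 0, noise_sd)
      U <- U + stats::rnorm(n, 0, noise_sd)
    }
    failed <- stats::runif(n) < fail_frac
    detection_p <- ifelse(failed, stats::runif(n, 0.01, 1), stats::runif(n) * 1e-4)
    data.frame(
      probe_id = rep(rownames(betas), times = ncol(betas)),
      sample_id = rep(colnames(betas), each = nrow(betas)),
      M = M, U = U, detection_p = detection_p,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete 450K-style cohort with known truth
#'
#' Convenience wrapper chaining [generate_manifest()],
#' [generate_baseline_betas()] and [inject_effects()].  Default arm sizes
#' mirror a normal/LGA/HGA adenoma-progression study design (20/18/22) with
#' an optional carcinoma arm.
#'
#' @param n_probes,n_genes manifest size.
#' @param n_normal,n_lga,n_hga,n_cancer per-stage sample counts.
#' @param spec an [effect_spec()].
#' @param mixture,sample_sd passed to [generate_baseline_betas()].
#' @param frac_sex,frac_snp passed to [generate_manifest()].
#' @param seed master seed; sub-seeds for each generator stage derive from it.
#' @return list with `manifest`, `betas`, `groups`, `sample_sheet`, `truth`.
#' @export
simulate_cohort <- function(n_probes = 5000, n_genes = 100,
                            n_normal = 20, n_lga = 18, n_hga = 22, n_cancer = 0,
                            spec = effect_spec(),
                            mixture = list(), sample_sd = 0.05,
                            frac_sex = 0.05, frac_snp = 0.02,
                            seed = 1) {
  n_samples <- n_normal + n_lga + n_hga + n_cancer
  stopifnot(n_samples >= 2)
  manifest <- generate_manifest(n_probes, n_genes, frac_sex, frac_snp,
                                seed = seed)
  betas <- generate_baseline_betas(manifest, n_samples, mixture = mixture,
                                   sample_sd = sample_sd, seed = seed + 1000L)
  groups <- rep(c("normal", "LGA", "HGA", "cancer"),
                c(n_normal, n_lga, n_hga, n_cancer))
  spec$seed <- spec$seed + seed
  inj <- inject_effects(betas, manifest, groups, spec)
  sheet <- data.frame(sample_id = colnames(betas), group = groups,
                      stringsAsFactors = FALSE)
  list(manifest = manifest, betas = inj$betas, groups = groups,
       sample_sheet = sheet, truth = inj$truth)
}
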