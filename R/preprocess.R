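#' Compute beta values from two-channel intensities
#'
#' The methylation fraction at a CpG is the ratio of the methylated signal to
#' the total signal plus a stabilising offset:
#' `beta = max(M, 0) / (max(M, 0) + max(U, 0) + 100)`.
#' Negative intensities (possible after background subtraction) are clamped
#' to zero before the ratio; the offset keeps the ratio defined and strictly
#' below 1 for low-intensity probes.
#'
#' @param M,U methylated / unmethylated signal intensities (vectorised;
#'   recycled to a common length).
#' @return beta values in `[0, 1)`.
#' @examples
#' compute_beta(100, 0)   # 0.5
#' compute_beta(-50, 900) # 0
#' @export
compute_beta <- function(M, U) {
  if (any(!is.finite(M)) || any(!is.finite(U))) {
    stop("compute_beta: intensities must be finite", call. = FALSE)
  }
  Mc <- pmax(M, 0)
  Uc <- pmax(U, 0)
  Mc / (Mc + Uc + 100)
}

#' Assemble a beta matrix from a long-format intensity cohort
#'
#' @param intensities data.frame with columns `probe_id`, `sample_id`, `M`,
#'   `U`, `detection_p` (one row per probe x sample).
#' @return list with `betas` (probes x samples matrix) and `detection_p`
#'   (matching matrix of detection p-values).
#' @export
intensities_to_beta <- function(intensities) {
  required <- c("probe_id", "sample_id", "M", "U", "detection_p")
  stopifnot(is.data.frame(intensities), all(required %in% names(intensities)))
  probes <- unique(intensities$probe_id)
  samples <- unique(intensities$sample_id)
  beta <- matrix(NA_real_, length(probes), length(samples),
                 dimnames = list(probes, samples))
  det <- beta
  i <- cbind(match(intensities$probe_id, probes),
             match(intensities$sample_id, samples))
  beta[i] <- compute_beta(intensities$M, intensities$U)
  det[i] <- intensities$detection_p
  list(betas = beta, detection_p = det)
}

#' Probe quality-control filtering
#'
#' Removes probes on sex chromosomes, probes failing detection p-value
#' testing, and SNP-flagged probes.  Each removed probe is attributed to the
#' first rule that removes it, in the order sex -> detection -> SNP, so the
#' filter report counts always reconcile with the input.  Probes without an
#' annotation row are retained (filters act on positive evidence) and listed
#' in the report.
#'
#' @param betas beta matrix (probes x samples).
#' @param annot probe annotation with the manifest columns.
#' @param detection matrix of detection p-values matching `betas` (may be
#'   `NULL` to skip the detection rule).
#' @param p_threshold detection p-value threshold (default 0.01).
#' @param fail_rule `"any_sample"` removes a probe failing in at least one
#'   sample; `"fraction"` removes it only when the failing fraction exceeds
#'   `fail_fraction` (the remaining failures are left to imputation).
#' @param fail_fraction failing-sample fraction for `fail_rule = "fraction"`.
#' @param keep_sex retain sex-chromosome probes (off by default).
#' @return list with `betas` (filtered matrix) and `report` (class
#'   `filter_report`): counts per rule, per-rule probe id lists, and ids of
#'   unannotated probes.
#' @export
filter_probes <- function(betas, annot, detection = NULL,
                          p_threshold = 0.01,
                          fail_rule = c("any_sample", "fraction"),
                          fail_fraction = 0.1,
                          keep_sex = FALSE) {
  assert_beta_matrix(betas)
  assert_manifest(annot, "annot")
  fail_rule <- match.arg(fail_rule)
  probes <- rownames(betas)
  ann <- annot[match(probes, annot$probe_id), , drop = FALSE]
  unannotated <- probes[is.na(ann$probe_id)]
  if (length(unannotated)) {
    warning(sprintf("%d probe(s) lack annotation and are retained unfiltered",
                    length(unannotated)), call. = FALSE)
  }

  is_sex <- !keep_sex & !is.na(ann$chrom) & ann$chrom %in% SEX_CHROMS
  if (is.null(detection)) {
    fails <- rep(FALSE, length(probes))
  } else {
    stopifnot(identical(dim(detection), dim(betas)))
    fail_mat <- detection > p_threshold
    fail_mat[is.na(fail_mat)] <- FALSE
    fails <- if (fail_rule == "any_sample") {
      rowSums(fail_mat) > 0
    } else {
      rowMeans(fail_mat) > fail_fraction
    }
  }
  is_snp <- !is.na(ann$snp_flagged) & ann$snp_flagged

  removed_sex <- is_sex
  removed_det <- !removed_sex & fails
  removed_snp <- !removed_sex & !removed_det & is_snp
  keep <- !(removed_sex | removed_det | removed_snp)

  report <- structure(list(
    n_input_probes = length(probes),
    n_removed_sex = sum(removed_sex),
    n_removed_detection = sum(removed_det),
    n_removed_snp = sum(removed_snp),
    n_retained = sum(keep),
    removed_sex = probes[removed_sex],
    removed_detection = probes[removed_det],
    removed_snp = probes[removed_snp],
    unannotated = unannotated,
    p_threshold = p_threshold,
    fail_rule = fail_rule
  ), class = "filter_report")
  list(betas = betas[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe QC filter report\n")
  cat(sprintf("  input probes:      %d\n", x$n_input_probes))
  cat(sprintf("  removed sex-chrom: %d\n", x$n_removed_sex))
  cat(sprintf("  removed detection: %d (p > %g, rule: %s)\n",
              x$n_removed_detection, x$p_threshold, x$fail_rule))
  cat(sprintf("  removed SNP:       %d\n", x$n_removed_snp))
  cat(sprintf("  retained:          %d\n", x$n_retained))
  if (length(x$unannotated)) {
    cat(sprintf("  unannotated (retained): %d\n", length(x$unannotated)))
  }
  invisible(x)
}

#' Impute failed entries from nearest genomic neighbours
#'
#' Each failed probe x sample entry is replaced by the mean of the nearest
#' non-failed probes flanking it on the same chromosome, in the same sample
#' (both flanks where available, the single flank at chromosome ends).  If a
#' chromosome has no non-failed entry for a sample, its failed entries stay
#' missing and a warning is raised.  Non-failed entries are never modified.
#'
#' @param betas beta matrix.
#' @param failed_mask logical matrix matching `betas`; `TRUE` marks entries
#'   to impute.
#' @param annot probe annotation providing `chrom` and `pos`.
#' @return the beta matrix with failed entries imputed.
#' @export
impute_failed <- function(betas, failed_mask, annot) {
  assert_beta_matrix(betas)
  stopifnot(is.logical(failed_mask), identical(dim(failed_mask), dim(betas)))
  assert_manifest(annot, "annot")
  if (!any(failed_mask)) return(betas)
  ann <- annot[match(rownames(betas), annot$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) {
    stop("impute_failed: all probes must be annotated with chrom/pos", call. = FALSE)
  }
  out <- betas
  stranded <- FALSE
  for (ch in unique(ann$chrom)) {
    rows <- which(ann$chrom == ch)
    rows <- rows[order(ann$pos[rows])]
    for (s in seq_len(ncol(betas))) {
      bad <- failed_mask[rows, s]
      if (!any(bad)) next
      good <- which(!bad)
      if (!length(good)) {
        out[rows, s] <- NA_real_
        stranded <- TRUE
        next
      }
      gv <- betas[rows[good], s]
      for (j in which(bad)) {
        left <- good[good < j]
        right <- good[good > j]
        lv <- if (length(left)) gv[length(left)] else NA_real_
        rv <- if (length(right)) gv[length(left) + 1L] else NA_real_
        out[rows[j], s] <- mean(c(lv, rv), na.rm = TRUE)
      }
    }
  }
  if (stranded) {
    warning("some chromosome x sample slices had all entries failed; left missing",
            call. = FALSE)
  }
  out
}

#' Cohort-level methylation summary
#'
#' Per-group global mean beta, a pooled density estimate of all values per
#' group, and the count of probes whose group-mean beta lies in the
#' highly-methylated band `[0.7, 0.9]` (the right-hand mode of the bimodal
#' distribution, which shrinks with progressive genome-wide hypomethylation).
#'
#' @param betas beta matrix.
#' @param groups group label per sample.
#' @param band numeric length-2, the group-mean band to count (default
#'   `c(0.7, 0.9)`).
#' @return list with `group_means`, `band_counts` (probes with group-mean in
#'   the band, per group), and `densities` (one `stats::density` per group).
#' @export
cohort_beta_summary <- function(betas, groups, band = c(0.7, 0.9)) {
  assert_beta_matrix(betas)
  stopifnot(length(groups) == ncol(betas))
  tab <- table(groups)
  if (!length(tab) || any(tab < 1)) {
    stop("every group must contain at least one sample", call. = FALSE)
  }
  gs <- names(tab)
  group_means <- vapply(gs, function(g) {
    mean(betas[, groups == g, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  band_counts <- vapply(gs, function(g) {
    pm <- rowMeans(betas[, groups == g, drop = FALSE], na.rm = TRUE)
    sum(pm >= band[1] & pm <= band[2], na.rm = TRUE)
  }, numeric(1))
  densities <- lapply(stats::setNames(gs, gs), function(g) {
    stats::density(as.vector(betas[, groups == g, drop = FALSE]),
                   na.rm = TRUE, from = 0, to = 1)
  })
  list(group_means = group_means, band_counts = band_counts,
       densities = densities, band = band)
}
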