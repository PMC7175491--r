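#' Define a site set
#'
#' A named set of probes with an expected direction of disease shift
#' (polarity), the unit scored by the mean-beta-value biomarker.
#'
#' @param name set label.
#' @param probe_ids member probe ids (nonempty).
#' @param polarity `"hyper"` (disease shifts beta up) or `"hypo"` (down).
#' @return object of class `site_set`.
#' @export
site_set <- function(name, probe_ids, polarity = c("hyper", "hypo")) {
  polarity <- match.arg(polarity)
  probe_ids <- unique(as.character(probe_ids))
  if (!length(probe_ids)) stop("site set must be nonempty", call. = FALSE)
  structure(list(name = name, probe_ids = probe_ids, polarity = polarity),
            class = "site_set")
}

#' Extract a gene's promoter(-island) site set
#'
#' Probes of the gene annotated to the promoter categories TSS200, TSS1500,
#' 5'UTR or 1stExon, optionally intersected with CpG-island membership.
#'
#' @param annot probe annotation.
#' @param gene gene symbol (must be present in the annotation).
#' @param require_island keep only probes with `island_relation == "island"`.
#' @param polarity expected disease direction of the marker (default hyper,
#'   the usual promoter-island gain).
#' @return a [site_set()].
#' @export
promoter_island_set <- function(annot, gene, require_island = TRUE,
                                polarity = "hyper") {
  assert_manifest(annot, "annot")
  if (!gene %in% annot$gene) {
    stop(sprintf("gene '%s' not present in annotation", gene), call. = FALSE)
  }
  sel <- annot$gene == gene & annot$region_category %in% PROMOTER_CATEGORIES
  if (require_island) sel <- sel & annot$island_relation == "island"
  ids <- annot$probe_id[sel]
  if (!length(ids)) {
    stop(sprintf(
      "gene '%s' has no promoter probes%s",
      gene, if (require_island) " within a CpG island" else ""), call. = FALSE)
  }
  site_set(paste0(gene, if (require_island) "_promoter_island" else "_promoter"),
           ids, polarity)
}

#' Mean beta value (mBV) over a site set
#'
#' Per-sample unweighted mean of the member-probe betas, skipping missing
#' values.  Samples with every member missing are dropped with a warning.
#'
#' @param betas beta matrix.
#' @param set a [site_set()].
#' @param labels optional per-sample class labels (`disease` / `normal`),
#'   parallel to `colnames(betas)`; carried into the score vector.
#' @return data.frame `sample_id`, `mbv`, and `label` when supplied.
#' @export
mbv <- function(betas, set, labels = NULL) {
  assert_beta_matrix(betas)
  stopifnot(inherits(set, "site_set"))
  missing_ids <- setdiff(set$probe_ids, rownames(betas))
  if (length(missing_ids) == length(set$probe_ids)) {
    stop("no member probes of the site set are present in the beta matrix",
         call. = FALSE)
  }
  if (length(missing_ids)) {
    warning(sprintf("%d member probe(s) absent from the beta matrix; skipped",
                    length(missing_ids)), call. = FALSE)
  }
  sub <- betas[intersect(set$probe_ids, rownames(betas)), , drop = FALSE]
  scores <- colMeans(sub, na.rm = TRUE)
  out <- data.frame(sample_id = colnames(betas), mbv = unname(scores),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(betas))
    out$label <- as.character(labels)
  }
  drop <- is.nan(out$mbv)
  if (any(drop)) {
    warning(sprintf("%d sample(s) with all member betas missing dropped",
                    sum(drop)), call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  out
}

check_scores <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("mbv", "label") %in% names(scores)))
  if (!all(scores$label %in% c("disease", "normal"))) {
    stop("score labels must be 'disease' or 'normal'", call. = FALSE)
  }
  if (!all(c("disease", "normal") %in% scores$label)) {
    stop("both classes must be present", call. = FALSE)
  }
  scores
}

classify_counts <- function(scores, cutoff, polarity) {
  pred_disease <- if (polarity == "hyper") scores$mbv >= cutoff else scores$mbv <= cutoff
  is_disease <- scores$label == "disease"
  c(TP = sum(pred_disease & is_disease),
    FN = sum(!pred_disease & is_disease),
    FP = sum(pred_disease & !is_disease),
    TN = sum(!pred_disease & !is_disease))
}

#' Minimal-error cutoff for an mBV score
#'
#' Scans candidate thresholds (midpoints of adjacent sorted unique scores,
#' plus one below the minimum and one above the maximum -- a grid that attains
#' the optimum over all real thresholds) and returns the cutoff minimising the
#' misclassification count.  Disease is called when the score is `>= cutoff`
#' (hyper polarity) or `<= cutoff` (hypo).  Ties are broken toward the
#' smallest threshold.
#'
#' @param scores data.frame with `mbv` and `label` columns (labels `disease`
#'   / `normal`).
#' @param polarity `"hyper"` or `"hypo"`.
#' @return list (`cutoff_result`): `cutoff`, `n_errors`, `error_rate`
#'   (percent, 2 decimals), `confusion` (TP/FN/FP/TN), `degenerate`.
#' @export
optimal_cutoff <- function(scores, polarity = c("hyper", "hypo")) {
  polarity <- match.arg(polarity)
  scores <- check_scores(scores)
  u <- sort(unique(scores$mbv))
  degenerate <- length(u) == 1L
  candidates <- if (degenerate) {
    c(u - 0.5, u + 0.5)
  } else {
    c(u[1] - 0.5, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 0.5)
  }
  errs <- vapply(candidates, function(cut) {
    cc <- classify_counts(scores, cut, polarity)
    cc[["FN"]] + cc[["FP"]]
  }, numeric(1))
  best <- which.min(errs)  # which.min takes the first (smallest) on ties
  cutoff <- candidates[best]
  confusion <- classify_counts(scores, cutoff, polarity)
  n <- nrow(scores)
  structure(list(
    cutoff = cutoff,
    n_errors = unname(errs[best]),
    error_rate = round(100 * errs[best] / n, 2),
    confusion = confusion,
    degenerate = degenerate
  ), class = "cutoff_result")
}

#' ROC curve and AUC for an mBV score
#'
#' Curve over all score thresholds; AUC by the trapezoidal rule, which for
#' this construction equals the pairwise concordance probability (ties
#' counted one half).  For hypo polarity scores are negated internally so
#' higher always indicates disease.
#'
#' @param scores data.frame with `mbv` and `label`.
#' @param polarity `"hyper"` or `"hypo"`.
#' @return list (`roc_curve`): `points` (data.frame `fpr`, `tpr` from (0,0)
#'   to (1,1)) and `auc`.
#' @export
roc <- function(scores, polarity = c("hyper", "hypo")) {
  polarity <- match.arg(polarity)
  scores <- check_scores(scores)
  s <- if (polarity == "hyper") scores$mbv else -scores$mbv
  y <- scores$label == "disease"
  n_pos <- sum(y)
  n_neg <- sum(!y)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  y <- y[ord]
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Confusion counts with disease as the positive class, plus
#' `sensitivity = TP / (TP + FN)` and `specificity = TN / (TN + FP)`,
#' rounded to 3 decimals for reporting.
#'
#' @param scores data.frame with `mbv` and `label`, or `NULL` when
#'   `confusion` is given directly.
#' @param cutoff threshold applied with the polarity rule of
#'   [optimal_cutoff()].
#' @param polarity `"hyper"` or `"hypo"`.
#' @param confusion optional named vector `TP`, `FN`, `FP`, `TN` to compute
#'   metrics from pre-tabulated counts.
#' @return list with `confusion`, `sensitivity`, `specificity`.
#' @export
sens_spec_at <- function(scores = NULL, cutoff = NULL,
                         polarity = c("hyper", "hypo"), confusion = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(confusion)) {
    scores <- check_scores(scores)
    stopifnot(is.numeric(cutoff))
    confusion <- classify_counts(scores, cutoff, polarity)
  }
  stopifnot(all(c("TP", "FN", "FP", "TN") %in% names(confusion)))
  if (confusion[["TP"]] + confusion[["FN"]] == 0 ||
      confusion[["TN"]] + confusion[["FP"]] == 0) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  list(
    confusion = confusion,
    sensitivity = round(confusion[["TP"]] / (confusion[["TP"]] + confusion[["FN"]]), 3),
    specificity = round(confusion[["TN"]] / (confusion[["TN"]] + confusion[["FP"]]), 3)
  )
}

#' Bootstrap comparison of two paired mBV models
#'
#' Both score vectors must cover the same samples (paired by `sample_id`).
#' Each replicate resamples sample ids with replacement, stratified by class,
#' recomputes both AUCs on the replicate and records their difference
#' (A minus B).  The two-sided p-value is `2 * min(frac <= 0, frac >= 0)`
#' with +1 smoothing in numerator and denominator, capped at 1.
#'
#' @param scores_a,scores_b data.frames with `sample_id`, `mbv`, `label`.
#' @param polarity_a,polarity_b polarities of the two models.
#' @param n_replicates bootstrap replicates (default 2000).
#' @param seed integer seed; results are deterministic for a fixed seed.
#' @return list (`bootstrap_comparison`): `observed_auc_a`,
#'   `observed_auc_b`, `auc_diff`, `replicate_diffs`, `p_value`,
#'   `n_replicates`, `seed`.
#' @export
bootstrap_auc_compare <- function(scores_a, scores_b,
                                  polarity_a = "hyper", polarity_b = "hypo",
                                  n_replicates = 2000, seed = 1) {
  scores_a <- check_scores(scores_a)
  scores_b <- check_scores(scores_b)
  stopifnot("sample_id" %in% names(scores_a), "sample_id" %in% names(scores_b))
  scores_b <- scores_b[match(scores_a$sample_id, scores_b$sample_id), , drop = FALSE]
  if (anyNA(scores_b$sample_id) ||
      !identical(scores_a$label, scores_b$label)) {
    stop("score vectors must be paired over the same samples and labels",
         call. = FALSE)
  }
  auc_a <- roc(scores_a, polarity_a)$auc
  auc_b <- roc(scores_b, polarity_b)$auc
  idx_d <- which(scores_a$label == "disease")
  idx_n <- which(scores_a$label == "normal")
  diffs <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      take <- c(sample(idx_d, length(idx_d), replace = TRUE),
                sample(idx_n, length(idx_n), replace = TRUE))
      ra <- roc(scores_a[take, , drop = FALSE], polarity_a)$auc
      rb <- roc(scores_b[take, , drop = FALSE], polarity_b)$auc
      ra - rb
    }, numeric(1))
  })
  p <- 2 * min((1 + sum(diffs <= 0)) / (n_replicates + 1),
               (1 + sum(diffs >= 0)) / (n_replicates + 1))
  structure(list(
    observed_auc_a = auc_a, observed_auc_b = auc_b,
    auc_diff = auc_a - auc_b,
    replicate_diffs = diffs,
    p_value = min(1, p),
    n_replicates = n_replicates,
    seed = seed
  ), class = "bootstrap_comparison")
}
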