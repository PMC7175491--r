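#' Two-sided Wilcoxon rank-sum test
#'
#' Exact two-sided Mann-Whitney p-value (via the exact null distribution of
#' the U statistic) when the combined sample size is at most 12 and there are
#' no ties; otherwise a normal approximation with midranks, tie-corrected
#' variance and continuity correction.  Returns `p = 1` when every value is
#' identical across both groups.
#'
#' @param a,b numeric vectors of beta values for the two groups (nonempty).
#' @return two-sided p-value in `(0, 1]`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # 0.1, exact
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) {
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("both groups must be nonempty", call. = FALSE)
  }
  x <- c(a, b)
  n_a <- length(a)
  n_b <- length(b)
  has_ties <- anyDuplicated(x) > 0
  if (!has_ties && n_a + n_b <= 12) {
    # exact path: U = number of (a_i, b_j) pairs with a_i > b_j
    r <- rank(x)
    U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
    lo <- stats::pwilcox(U, n_a, n_b)
    hi <- 1 - stats::pwilcox(U - 1, n_a, n_b)
    return(min(1, 2 * min(lo, hi)))
  }
  r <- rank(x)
  W <- sum(r[seq_len(n_a)])
  N <- n_a + n_b
  mu <- n_a * (N + 1) / 2
  ties <- table(x)
  sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; order-preserving with
#' the input vector.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, parallel to the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

diff_test <- function(values, groups, reference, delta_threshold, unit = "site") {
  stopifnot(is.matrix(values))
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) != 2) {
    stop("exactly two group labels are required", call. = FALSE)
  }
  if (!reference %in% levels) {
    stop(sprintf("reference group '%s' not present", reference), call. = FALSE)
  }
  contrast <- setdiff(levels, reference)
  idx_a <- which(groups == reference)
  idx_b <- which(groups == contrast)
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  delta <- rowMeans(values[, idx_b, drop = FALSE], na.rm = TRUE) -
    rowMeans(values[, idx_a, drop = FALSE], na.rm = TRUE)
  p <- vapply(seq_len(nrow(values)), function(i) {
    rank_sum_test(values[i, idx_a], values[i, idx_b])
  }, numeric(1))
  q <- bh_fdr(p)
  flag <- q < 0.05 & abs(delta) > delta_threshold
  out <- data.frame(
    unit_id = rownames(values),
    delta_beta = unname(delta),
    p_value = unname(p),
    q_value = unname(q),
    direction = ifelse(delta > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )
  if (unit == "site") out$is_dms <- unname(flag) else out$is_dmr <- unname(flag)
  attr(out, "contrast") <- c(reference = reference, contrast = contrast)
  attr(out, "delta_threshold") <- delta_threshold
  out
}

#' Call differentially methylated sites (DMS)
#'
#' Per-probe two-sided rank-sum test of the contrast group against the
#' reference, BH-FDR adjustment across all tested probes, and the DMS rule:
#' `q < 0.05` and `|delta beta| > 0.20`, where delta beta is the difference
#' of group mean beta values (contrast minus reference).  Direction is
#' `hyper` for positive delta, `hypo` for negative.
#'
#' @param betas beta matrix (QC-filtered).
#' @param groups two-group label per sample.
#' @param reference label of the reference group (e.g. `"normal"`).
#' @param delta_threshold absolute delta-beta gate (default 0.20).
#' @param q_threshold FDR gate (default 0.05; fixed in the flag rule).
#' @return a DiffTable data.frame: `unit_id`, `delta_beta`, `p_value`,
#'   `q_value`, `direction`, `is_dms`.
#' @export
call_dms <- function(betas, groups, reference, delta_threshold = 0.20) {
  assert_beta_matrix(betas)
  stopifnot(length(groups) == ncol(betas))
  diff_test(betas, groups, reference, delta_threshold, unit = "site")
}

#' Aggregate probes into gene-region units
#'
#' Region value = unweighted mean of member-probe betas per sample.  Under
#' the `gene_category` scheme a unit is one (gene, region category) pair;
#' under the `promoter` scheme all promoter-category probes of a gene
#' (TSS200, TSS1500, 5'UTR, 1stExon) form a single unit.  Regions with one
#' member probe are flagged as singletons.
#'
#' @param betas beta matrix.
#' @param annot probe annotation.
#' @param scheme `"gene_category"` or `"promoter"`.
#' @return list with `values` (regions x samples matrix) and `regions`
#'   (data.frame `region_id`, `gene`, `category`, `n_probes`, `singleton`,
#'   plus a `members` list-column of probe ids).
#' @export
aggregate_regions <- function(betas, annot, scheme = c("gene_category", "promoter")) {
  assert_beta_matrix(betas)
  assert_manifest(annot, "annot")
  scheme <- match.arg(scheme)
  ann <- annot[match(rownames(betas), annot$probe_id), , drop = FALSE]
  in_gene <- !is.na(ann$gene) & ann$gene != "" &
    ann$region_category %in% setdiff(REGION_CATEGORIES, "intergenic")
  if (scheme == "promoter") {
    in_gene <- in_gene & ann$region_category %in% PROMOTER_CATEGORIES
    key <- ifelse(in_gene, paste0(ann$gene, "|promoter"), NA)
    cat_of <- function(k) "promoter"
  } else {
    key <- ifelse(in_gene, paste0(ann$gene, "|", ann$region_category), NA)
    cat_of <- function(k) sub("^.*\\|", "", k)
  }
  keys <- sort(unique(key[!is.na(key)]))
  if (!length(keys)) {
    return(list(values = matrix(numeric(), 0, ncol(betas),
                                dimnames = list(NULL, colnames(betas))),
                regions = data.frame(region_id = character(), gene = character(),
                                     category = character(), n_probes = integer(),
                                     singleton = logical())))
  }
  members <- split(rownames(betas)[!is.na(key)], key[!is.na(key)])
  members <- members[keys]
  values <- t(vapply(members, function(ids) {
    colMeans(betas[ids, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(betas))))
  rownames(values) <- keys
  regions <- data.frame(
    region_id = keys,
    gene = sub("\\|.*$", "", keys),
    category = vapply(keys, cat_of, character(1)),
    n_probes = lengths(members),
    singleton = lengths(members) == 1L,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  regions$members <- unname(members)
  list(values = values, regions = regions)
}

#' Call differentially methylated regions (DMR)
#'
#' Same rank-sum + BH-FDR machinery as [call_dms()], applied to region mean
#' values with the region rule `q < 0.05` and `|delta beta| > 0.15`.
#'
#' @param region_values regions x samples matrix from [aggregate_regions()].
#' @param groups,reference as in [call_dms()].
#' @param delta_threshold absolute delta-beta gate (default 0.15).
#' @return a DiffTable data.frame with `is_dmr`.
#' @export
call_dmr <- function(region_values, groups, reference, delta_threshold = 0.15) {
  stopifnot(is.matrix(region_values), length(groups) == ncol(region_values))
  diff_test(region_values, groups, reference, delta_threshold, unit = "region")
}

#' Tally hyper- vs hypo-methylated flagged units
#'
#' Counts and percentages (one decimal) of hyper- and hypo-directed units
#' among those flagged as DMS/DMR in a DiffTable.
#'
#' @param table a DiffTable from [call_dms()] or [call_dmr()].
#' @return list with `n_flagged`, `n_hyper`, `n_hypo`, `pct_hyper`,
#'   `pct_hypo` (percentages rounded to one decimal; `NA` when nothing is
#'   flagged).
#' @export
direction_tally <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  flag_col <- intersect(c("is_dms", "is_dmr"), names(table))
  if (!length(flag_col)) stop("table has no is_dms/is_dmr flag column", call. = FALSE)
  flagged <- table[table[[flag_col[1]]], , drop = FALSE]
  n <- nrow(flagged)
  n_hyper <- sum(flagged$direction == "hyper")
  n_hypo <- sum(flagged$direction == "hypo")
  list(
    n_flagged = n,
    n_hyper = n_hyper,
    n_hypo = n_hypo,
    pct_hyper = if (n > 0) round(100 * n_hyper / n, 1) else NA_real_,
    pct_hypo = if (n > 0) round(100 * n_hypo / n, 1) else NA_real_
  )
}
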