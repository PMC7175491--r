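# Independent oracles used to validate the analytic implementations.

# Exact two-sided rank-sum p by full enumeration of group labelings:
# extremity measured by |U - E[U]| under the permutation null.
enum_rank_sum_p <- function(a, b) {
  x <- c(a, b)
  n_a <- length(a)
  N <- length(x)
  r <- rank(x)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  mu <- n_a * (N - n_a) / 2
  obs <- abs(u_of(seq_len(n_a)) - mu)
  labelings <- utils::combn(N, n_a)
  extreme <- apply(labelings, 2, function(idx) abs(u_of(idx) - mu) >= obs - 1e-12)
  mean(extreme)
}

# AUC as the pairwise concordance statistic (ties count one half).
concordance_auc <- function(disease, normal) {
  tot <- 0
  for (d in disease) for (n in normal) {
    tot <- tot + if (d > n) 1 else if (d == n) 0.5 else 0
  }
  tot / (length(disease) * length(normal))
}

# Brute-force minimal misclassification count over a dense threshold grid.
brute_force_min_errors <- function(scores, labels, polarity) {
  u <- sort(unique(scores))
  grid <- sort(unique(c(u - 1e-6, u, u + 1e-6,
                        (u[-length(u)] + u[-1]) / 2, min(u) - 1, max(u) + 1)))
  errs <- vapply(grid, function(cut) {
    pred <- if (polarity == "hyper") scores >= cut else scores <= cut
    sum(pred & labels == "normal") + sum(!pred & labels == "disease")
  }, numeric(1))
  min(errs)
}

# Tiny hand-buildable manifest for filter/impute/region fixtures.
tiny_manifest <- function() {
  data.frame(
    probe_id = sprintf("p%02d", 1:10),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2",
              "chrX", "chrY", "chrY", "chr3"),
    pos = c(100L, 200L, 300L, 400L, 150L, 250L, 100L, 100L, 200L, 500L),
    gene = c("GA", "GA", "GA", "GA", "GB", "GB", "", "", "", ""),
    region_category = c("TSS200", "TSS1500", "1stExon", "Body",
                        "TSS200", "5'UTR", "intergenic", "intergenic",
                        "intergenic", "intergenic"),
    island_relation = c("island", "shore", "island", "open_sea",
                        "island", "island", "open_sea", "open_sea",
                        "open_sea", "shore"),
    snp_flagged = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

tiny_betas <- function(values = NULL, n_samples = 4) {
  m <- tiny_manifest()
  set.seed(99)
  b <- matrix(round(runif(nrow(m) * n_samples, 0.05, 0.95), 3),
              nrow(m), n_samples,
              dimnames = list(m$probe_id, sprintf("S%03d", seq_len(n_samples))))
  if (!is.null(values)) b[] <- values
  b
}

score_frame <- function(disease, normal) {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(length(disease) + length(normal))),
    mbv = c(disease, normal),
    label = rep(c("disease", "normal"), c(length(disease), length(normal))),
    stringsAsFactors = FALSE
  )
}
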