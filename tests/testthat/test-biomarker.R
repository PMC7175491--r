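test_that("mbv is the unweighted mean over present member betas", {
  b <- matrix(c(0.2, 0.4, 0.6,
                0.2, NA, 0.6), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("S1", "S2")))
  set <- site_set("s", c("p1", "p2", "p3"), "hyper")
  sc <- mbv(b, set)
  expect_equal(sc$mbv, c(0.4, 0.4))  # NA skipped in S2
  # singleton set equals the probe's beta exactly (S2 is NA and dropped)
  single <- site_set("one", "p2", "hyper")
  expect_warning(sc1 <- mbv(b, single), "dropped")
  expect_equal(sc1$mbv[1], 0.4)
  # all members missing for a sample: dropped with warning
  b2 <- b
  b2[, 2] <- NA
  expect_warning(sc2 <- mbv(b2, set), "dropped")
  expect_equal(sc2$sample_id, "S1")
  expect_error(mbv(b, site_set("x", "absent", "hyper")), "no member probes")
})

test_that("mbv recovers injected effect sizes on synthetic cohorts", {
  m <- generate_manifest(1200, 40, seed = 50)
  b <- generate_baseline_betas(m, 40, sample_sd = 0, seed = 51)
  groups <- rep(c("normal", "cancer"), each = 20)
  spec <- effect_spec(n_hyper_sites = 200, n_hypo_sites = 0,
                      delta_hyper = c(LGA = 0.35, HGA = 0.35, cancer = 0.35),
                      delta_hypo = c(LGA = 0, HGA = 0, cancer = 0),
                      purity_range = c(1, 1), seed = 52)
  inj <- inject_effects(b, m, groups, spec)
  hyper <- site_set("hyper", unique(inj$truth$probe_id), "hyper")
  sc <- mbv(inj$betas, hyper, ifelse(groups == "normal", "normal", "disease"))
  diff <- mean(sc$mbv[sc$label == "disease"]) - mean(sc$mbv[sc$label == "normal"])
  expect_lt(abs(diff - 0.35), 0.05)
})

test_that("promoter_island_set applies the category and island rules", {
  annot <- data.frame(
    probe_id = c("q1", "q2", "q3", "q4"),
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    gene = "G1",
    region_category = c("TSS200", "Body", "TSS1500", "Body"),
    island_relation = c("island", "island", "shore", "open_sea"),
    snp_flagged = FALSE, stringsAsFactors = FALSE
  )
  strict <- promoter_island_set(annot, "G1", require_island = TRUE)
  expect_equal(strict$probe_ids, "q1")
  loose <- promoter_island_set(annot, "G1", require_island = FALSE)
  expect_setequal(loose$probe_ids, c("q1", "q3"))
  expect_error(promoter_island_set(annot, "NOPE"), "not present")
  annot2 <- annot
  annot2$island_relation <- "open_sea"
  expect_error(promoter_island_set(annot2, "G1"), "island")
})

test_that("optimal_cutoff matches the exhaustive scan on the worked example", {
  sc <- score_frame(disease = c(0.8, 0.6, 0.3), normal = c(0.2, 0.4))
  res <- optimal_cutoff(sc, "hyper")
  expect_equal(res$n_errors, 1)
  expect_equal(res$cutoff, 0.25)  # tie with 0.5 broken toward the smaller
  expect_equal(res$error_rate, 20)
  # perfectly separated groups
  sep <- score_frame(disease = c(0.9, 0.8), normal = c(0.1, 0.2))
  expect_equal(optimal_cutoff(sep, "hyper")$n_errors, 0)
  # degenerate single score
  degen <- score_frame(disease = 0.5, normal = 0.5)
  expect_true(optimal_cutoff(degen, "hyper")$degenerate)
})

test_that("optimal_cutoff equals the brute-force threshold scan", {
  set.seed(12)
  for (i in 1:20) {
    n_d <- sample(3:25, 1)
    n_n <- sample(3:25, 1)
    sc <- score_frame(disease = round(runif(n_d), 2),
                      normal = round(runif(n_n), 2))
    for (pol in c("hyper", "hypo")) {
      res <- optimal_cutoff(sc, pol)
      expect_equal(res$n_errors,
                   brute_force_min_errors(sc$mbv, sc$label, pol),
                   info = sprintf("case %d polarity %s", i, pol))
    }
  }
})

test_that("polarity duality: flipping polarity on 1 - s preserves error counts", {
  set.seed(13)
  for (i in 1:10) {
    sc <- score_frame(disease = runif(10), normal = runif(8))
    flipped <- sc
    flipped$mbv <- 1 - sc$mbv
    a <- optimal_cutoff(sc, "hyper")
    b <- optimal_cutoff(flipped, "hypo")
    # error counts are invariant; the attained confusion may differ when
    # several thresholds tie (tie-breaking runs toward the smallest cutoff)
    expect_equal(a$n_errors, b$n_errors)
    expect_equal(a$error_rate, b$error_rate)
  }
})

test_that("roc reproduces hand-counted AUCs and the tie rule", {
  expect_equal(roc(score_frame(c(0.9, 0.8), c(0.1, 0.2)), "hyper")$auc, 1)
  expect_equal(roc(score_frame(c(0.9, 0.4, 0.7), c(0.5, 0.3)), "hyper")$auc, 5 / 6)
  expect_equal(roc(score_frame(c(0.3, 0.5), c(0.3, 0.5)), "hyper")$auc, 0.5)
  # curve anchored at (0,0) and (1,1), monotone in both coordinates
  r <- roc(score_frame(runif(10), runif(10)), "hyper")
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_error(roc(data.frame(mbv = 1, label = "disease"), "hyper"),
               "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance on random fixtures", {
  set.seed(14)
  for (i in 1:20) {
    n_d <- sample(3:25, 1)
    n_n <- sample(3:25, 1)
    d <- round(runif(n_d), 1)  # rounding forces ties
    n <- round(runif(n_n), 1)
    sc <- score_frame(d, n)
    expect_equal(roc(sc, "hyper")$auc, concordance_auc(d, n),
                 tolerance = 1e-12)
    expect_equal(roc(sc, "hypo")$auc, concordance_auc(-d, -n),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(15)
  sc <- score_frame(runif(15), runif(12))
  base_auc <- roc(sc, "hyper")$auc
  for (f in list(function(x) x^3, function(x) exp(2 * x), function(x) 5 * x - 1)) {
    tr <- sc
    tr$mbv <- f(sc$mbv)
    expect_equal(roc(tr, "hyper")$auc, base_auc)
  }
})

test_that("roc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  for (i in 1:5) {
    sc <- score_frame(round(runif(20), 1), round(runif(15), 1))
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = sc$label, predictor = sc$mbv,
      levels = c("normal", "disease"), direction = "<")))
    expect_equal(roc(sc, "hyper")$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("sens_spec_at recomputes published-style confusion metrics", {
  r <- sens_spec_at(confusion = c(TP = 532, FN = 23, FP = 39, TN = 239))
  expect_equal(r$sensitivity, 0.959)
  expect_equal(r$specificity, 0.860)
  r2 <- sens_spec_at(confusion = c(TP = 406, FN = 149, FP = 83, TN = 195))
  expect_equal(r2$sensitivity, 0.732)
  expect_equal(r2$specificity, 0.701)
  r3 <- sens_spec_at(confusion = c(TP = 10, FN = 0, FP = 0, TN = 10))
  expect_equal(r3$sensitivity, 1)
  expect_equal(r3$specificity, 1)
  expect_error(sens_spec_at(confusion = c(TP = 0, FN = 0, FP = 1, TN = 1)),
               "nonempty")
  # from scores + cutoff
  sc <- score_frame(c(0.8, 0.6, 0.3), c(0.2, 0.4))
  r4 <- sens_spec_at(sc, cutoff = 0.25, polarity = "hyper")
  expect_equal(unname(r4$confusion[c("TP", "FN", "FP", "TN")]), c(3, 0, 1, 1))
})

test_that("bootstrap_auc_compare is deterministic and handles identity", {
  sc <- score_frame(runif(20, 0.5, 1), runif(15, 0, 0.5))
  same <- bootstrap_auc_compare(sc, sc, "hyper", "hyper",
                                n_replicates = 200, seed = 3)
  expect_true(all(same$replicate_diffs == 0))
  expect_gt(same$p_value, 0.9)
  expect_lte(same$p_value, 1)
  again <- bootstrap_auc_compare(sc, sc, "hyper", "hyper",
                                 n_replicates = 200, seed = 3)
  expect_identical(same$p_value, again$p_value)
  expect_identical(same$replicate_diffs, again$replicate_diffs)
  # unpaired inputs are rejected
  sc2 <- sc
  sc2$sample_id <- paste0("X", sc2$sample_id)
  expect_error(bootstrap_auc_compare(sc, sc2), "paired")
})

test_that("a strong hyper set beats a weak hypo set in bootstrap comparison", {
  m <- generate_manifest(2000, 60, seed = 60)
  b <- generate_baseline_betas(m, 200, seed = 61)
  groups <- rep(c("normal", "cancer"), each = 100)
  spec <- effect_spec(n_hyper_sites = 200, n_hypo_sites = 200,
                      delta_hyper = c(LGA = 0.3, HGA = 0.3, cancer = 0.3),
                      delta_hypo = c(LGA = -0.1, HGA = -0.1, cancer = -0.1),
                      seed = 62)
  inj <- inject_effects(b, m, groups, spec)
  labels <- ifelse(groups == "normal", "normal", "disease")
  hyper <- site_set("hyper", unique(inj$truth$probe_id[inj$truth$true_delta > 0]), "hyper")
  hypo <- site_set("hypo", unique(inj$truth$probe_id[inj$truth$true_delta < 0]), "hypo")
  cmp <- bootstrap_auc_compare(mbv(inj$betas, hyper, labels),
                               mbv(inj$betas, hypo, labels),
                               "hyper", "hypo", n_replicates = 1000, seed = 63)
  expect_gt(cmp$observed_auc_a, cmp$observed_auc_b)
  expect_lt(cmp$p_value, 0.01)
})

test_that("bootstrap p-values under a symmetric null are not anti-conservative", {
  set.seed(17)
  pvals <- replicate(30, {
    n <- 24
    base <- score_frame(runif(12), runif(12))
    noise_a <- base
    noise_b <- base
    noise_b$mbv <- base$mbv + rnorm(n, 0, 0.05)  # same signal, same labels
    bootstrap_auc_compare(noise_a, noise_b, "hyper", "hyper",
                          n_replicates = 99, seed = sample.int(1e6, 1))$p_value
  })
  # super-uniform at coarse tolerance: small p-values are not over-produced
  expect_lt(mean(pvals <= 0.1), 0.25)
})
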