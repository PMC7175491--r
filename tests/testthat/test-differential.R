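test_that("rank_sum_test matches hand-derived exact cases", {
  # a below b entirely: 2 of the 20 labelings are as extreme
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3)), 0.1)
  # identical multisets give the maximal p
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rank_sum_test(rep(0.5, 4), rep(0.5, 5)), 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("exact rank-sum path equals full enumeration on all small fixtures", {
  set.seed(42)
  cases <- list(
    list(n_a = 2, n_b = 3), list(n_a = 3, n_b = 3), list(n_a = 4, n_b = 4),
    list(n_a = 2, n_b = 8), list(n_a = 5, n_b = 5), list(n_a = 4, n_b = 6)
  )
  for (cs in cases) {
    for (rep_i in 1:5) {
      x <- sample(seq_len(100), cs$n_a + cs$n_b)  # distinct -> no ties
      a <- x[seq_len(cs$n_a)]
      b <- x[-seq_len(cs$n_a)]
      expect_equal(rank_sum_test(a, b), enum_rank_sum_p(a, b),
                   tolerance = 1e-12,
                   info = sprintf("n_a=%d n_b=%d rep=%d", cs$n_a, cs$n_b, rep_i))
    }
  }
})

test_that("the normal approximation tracks exact enumeration", {
  # 6 vs 7 distinct values: just above the exact-path size, so the
  # implementation routes through the tie-corrected normal approximation
  # while C(13, 6) = 1716 labelings remain enumerable as the oracle.
  set.seed(8)
  errs <- replicate(20, {
    x <- sample(seq_len(200), 13)
    a <- x[1:6]
    b <- x[7:13]
    # the approximation also matches the reference implementation of the
    # same tie-corrected continuity-corrected formula exactly
    expect_equal(rank_sum_test(a, b),
                 suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-9)
    abs(rank_sum_test(a, b) - enum_rank_sum_p(a, b))
  })
  expect_lt(max(errs), 0.02)
  expect_lt(mean(errs), 0.01)
})

test_that("rank_sum_test agrees with wilcox.test on tied large samples", {
  set.seed(9)
  for (i in 1:10) {
    a <- round(runif(15), 1)
    b <- round(runif(18), 1)
    ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE)$p.value)
    expect_equal(rank_sum_test(a, b), ref, tolerance = 1e-9)
  }
})

test_that("bh_fdr performs the step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_fdr(0.5), 0.5)
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  q <- bh_fdr(p)
  perm <- sample(length(p))
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(q >= p - 1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_dms applies the q < 0.05 and |delta| > 0.20 rule", {
  # build a matrix with controlled effects: 12 vs 12 samples
  set.seed(10)
  n <- 24
  groups <- rep(c("normal", "LGA"), each = 12)
  strong <- 0.4 + c(rnorm(12, 0, 0.01), rnorm(12, 0.25, 0.01))  # clear DMS
  borderline <- 0.4 + c(rnorm(12, 0, 0.01), rnorm(12, 0.18, 0.01))  # fails gate
  flat <- rep(0.5, n) + rnorm(n, 0, 0.01)
  b <- rbind(strong = strong, borderline = borderline, flat = flat)
  colnames(b) <- sprintf("S%03d", 1:n)
  b <- pmin(pmax(b, 0), 1)
  tab <- call_dms(b, groups, reference = "normal")
  expect_true(tab[tab$unit_id == "strong", "is_dms"])
  expect_equal(tab[tab$unit_id == "strong", "direction"], "hyper")
  expect_false(tab[tab$unit_id == "borderline", "is_dms"])
  expect_lt(tab[tab$unit_id == "borderline", "q_value"], 0.05)  # fails only the gate
  expect_false(tab[tab$unit_id == "flat", "is_dms"])
  expect_error(call_dms(b, rep(c("normal", "LGA"), c(1, 23)), "normal"),
               "at least 2")
})

test_that("swapping group labels negates delta and swaps direction", {
  m <- generate_manifest(400, 20, seed = 40)
  b <- generate_baseline_betas(m, 12, seed = 41)
  groups <- rep(c("normal", "LGA"), each = 6)
  t1 <- call_dms(b, groups, reference = "normal")
  t2 <- call_dms(b, groups, reference = "LGA")
  expect_equal(t2$delta_beta, -t1$delta_beta)
  expect_equal(t2$p_value, t1$p_value)
  expect_equal(t2$q_value, t1$q_value)
  nonzero <- abs(t1$delta_beta) > 1e-12
  expect_true(all(t1$direction[nonzero] != t2$direction[nonzero]))
})

test_that("the DMS rule is stricter than the DMR rule at equal q", {
  m <- generate_manifest(600, 25, seed = 42)
  b <- generate_baseline_betas(m, 20, seed = 43)
  groups <- rep(c("normal", "HGA"), each = 10)
  spec <- effect_spec(n_hyper_sites = 40, n_hypo_sites = 40,
                      delta_hyper = c(LGA = 0.18, HGA = 0.22, cancer = 0.25),
                      delta_hypo = c(LGA = -0.18, HGA = -0.22, cancer = -0.25),
                      seed = 44)
  inj <- inject_effects(b, m, groups, spec)
  site_02 <- call_dms(inj$betas, groups, "normal", delta_threshold = 0.20)
  site_015 <- call_dms(inj$betas, groups, "normal", delta_threshold = 0.15)
  expect_true(all(site_02$unit_id[site_02$is_dms] %in%
                    site_015$unit_id[site_015$is_dms]))
  expect_gte(sum(site_015$is_dms), sum(site_02$is_dms))
})

test_that("aggregate_regions averages member probes per scheme", {
  m <- tiny_manifest()
  b <- tiny_betas()
  b["p01", 1] <- 0.2  # GA TSS200
  b["p02", 1] <- 0.4  # GA TSS1500
  b["p03", 1] <- 0.6  # GA 1stExon
  b["p04", 1] <- 0.9  # GA Body
  agg_p <- aggregate_regions(b, m, scheme = "promoter")
  expect_equal(agg_p$values["GA|promoter", 1], mean(c(0.2, 0.4, 0.6)))
  # Body probes are excluded from the promoter scheme
  expect_false(any(vapply(agg_p$regions$members, function(x) "p04" %in% x,
                          logical(1))))
  agg_g <- aggregate_regions(b, m, scheme = "gene_category")
  expect_equal(agg_g$values["GA|TSS200", 1], 0.2)
  expect_equal(agg_g$values["GA|Body", 1], 0.9)
  expect_true(agg_g$regions$singleton[agg_g$regions$region_id == "GA|Body"])
  # constant members yield the constant
  b2 <- tiny_betas(values = 0.7)
  agg2 <- aggregate_regions(b2, m, scheme = "promoter")
  expect_true(all(agg2$values == 0.7))
})

test_that("call_dmr flags regions at the 0.15 gate", {
  set.seed(11)
  groups <- rep(c("normal", "LGA"), each = 10)
  vals <- rbind(
    hypo_dmr = 0.5 + c(rnorm(10, 0, 0.01), rnorm(10, -0.16, 0.01)),
    not_dmr = 0.5 + c(rnorm(10, 0, 0.005), rnorm(10, -0.10, 0.005)),
    null_reg = 0.5 + rnorm(20, 0, 0.01)
  )
  colnames(vals) <- sprintf("S%03d", 1:20)
  tab <- call_dmr(vals, groups, reference = "normal")
  expect_true(tab[tab$unit_id == "hypo_dmr", "is_dmr"])
  expect_equal(tab[tab$unit_id == "hypo_dmr", "direction"], "hypo")
  # tiny p but |delta| below 0.15 is not a DMR
  expect_lt(tab[tab$unit_id == "not_dmr", "q_value"], 0.05)
  expect_false(tab[tab$unit_id == "not_dmr", "is_dmr"])
})

test_that("three-way pairwise DMR calls recover the injected overlap structure", {
  m <- generate_manifest(1600, 60, seed = 45)
  b <- generate_baseline_betas(m, 36, seed = 46)
  groups <- rep(c("normal", "LGA", "HGA"), each = 12)
  # marker genes give coordinated promoter effects visible at region level
  spec <- effect_spec(n_hyper_sites = 0, n_hypo_sites = 0,
                      delta_hyper = c(LGA = 0.25, HGA = 0.35, cancer = 0.4),
                      delta_hypo = c(LGA = 0, HGA = 0, cancer = 0),
                      marker_genes = c("GENE_001", "GENE_002", "GENE_003"),
                      seed = 47)
  inj <- inject_effects(b, m, groups, spec)
  agg <- aggregate_regions(inj$betas, m, scheme = "promoter")
  sel_ln <- groups %in% c("normal", "LGA")
  sel_hn <- groups %in% c("normal", "HGA")
  dmr_ln <- call_dmr(agg$values[, sel_ln], groups[sel_ln], "normal")
  dmr_hn <- call_dmr(agg$values[, sel_hn], groups[sel_hn], "normal")
  marker_regions <- paste0(c("GENE_001", "GENE_002", "GENE_003"), "|promoter")
  genes_ln <- dmr_ln$unit_id[dmr_ln$is_dmr]
  genes_hn <- dmr_hn$unit_id[dmr_hn$is_dmr]
  # effects present in LGA are maintained in HGA: LGA DMRs nest in HGA DMRs
  expect_true(all(marker_regions %in% genes_hn))
  expect_true(all(genes_ln %in% genes_hn))
})

test_that("direction_tally reproduces printed-count arithmetic", {
  mk <- function(n_hypo, n_hyper) {
    data.frame(unit_id = sprintf("r%04d", seq_len(n_hypo + n_hyper)),
               delta_beta = c(rep(-0.3, n_hypo), rep(0.3, n_hyper)),
               p_value = 0.001, q_value = 0.01,
               direction = rep(c("hypo", "hyper"), c(n_hypo, n_hyper)),
               is_dmr = TRUE, stringsAsFactors = FALSE)
  }
  expect_equal(direction_tally(mk(314, 126))$pct_hypo, 71.4)
  expect_equal(direction_tally(mk(4213, 2592))$pct_hypo, 61.9)
  expect_equal(direction_tally(mk(208, 660))$pct_hyper, 76.0)
  expect_equal(direction_tally(mk(0, 10))$pct_hypo, 0)
  none <- mk(1, 1)
  none$is_dmr <- FALSE
  expect_true(is.na(direction_tally(none)$pct_hypo))
})
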