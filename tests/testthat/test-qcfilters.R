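make_sites <- function(...) {
  tibble::tibble(...)
}

test_that("site filter applies the strict QUAL/QD thresholds and drops indels", {
  sites <- make_sites(
    chrom = "chr1", pos = 1:6 * 10L,
    ref = c("A", "A", "A", "A", "A", "A"),
    alt = c("T", "T", "AT", "T", "T", "T,G"),
    qual = c(29, 50, 50, 50, 31, 50),
    qd = c(10, 5.0, 10, NA, 6, 10)
  )
  out <- site_filter(sites)
  expect_equal(out$reason,
               c("low_qual", "low_qd", "indel", "missing_qd", NA, "multiallelic"))
  expect_equal(out$keep, is.na(out$reason))
  # boundary: QUAL exactly 30 fails the strict inequality
  expect_false(site_filter(make_sites(chrom = "c", pos = 1L, ref = "A", alt = "T",
                                      qual = 30, qd = 10))$keep)
})

test_that("genotype depth masking keeps depth >= 12 and preserves DP", {
  g <- matrix(c(1L, 1L, 1L), nrow = 3)
  calls <- calls_from_matrix(g, dp = 30)
  calls$dp <- c(11L, 12L, 0L)
  out <- genotype_depth_mask(calls)
  expect_equal(is.na(out$gt), c(TRUE, FALSE, TRUE))
  expect_equal(out$dp, calls$dp)
  strict <- genotype_depth_mask(calls, filter_config(gt_depth_strict = TRUE))
  expect_true(all(is.na(strict$gt)))
  all0 <- calls; all0$dp <- 0L
  expect_true(all(is.na(genotype_depth_mask(all0)$gt)))
})

test_that("the exact heterozygote-excess p-value matches full enumeration", {
  expect_equal(het_excess_pvalue(7, 0, 0), 1.0)
  expect_equal(het_excess_pvalue(1, 8, 1), hwe_tail_oracle(1, 8, 1),
               tolerance = 1e-12)
  expect_equal(het_excess_pvalue(5, 10, 5), hwe_tail_oracle(5, 10, 5),
               tolerance = 1e-12)
  # symmetry in the homozygote labels
  expect_equal(het_excess_pvalue(3, 6, 9), het_excess_pvalue(9, 6, 3))
  expect_error(het_excess_pvalue(-1, 2, 3), ">= 0")
  expect_error(het_excess_pvalue(0, 0, 0), "nonzero")
})

test_that("the Bonferroni heterozygote-excess filter removes only clear excess", {
  # near-HWE genotype proportions: nothing removed
  hwe_col <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  g <- vapply(1:40, function(i) sample(hwe_col), integer(20))
  out <- het_excess_filter(calls_from_matrix(g))
  expect_false(any(out$pvalues$removed))
  expect_equal(nrow(out$removed), 0L)

  # one all-heterozygous site in a family of 100 is removed
  g2 <- cbind(matrix(rep(hwe_col, 99), ncol = 99), rep(1L, 20))
  out2 <- het_excess_filter(calls_from_matrix(g2))
  hot <- out2$pvalues[out2$pvalues$n_het == 20, ]
  expect_true(hot$removed)
  # Bonferroni monotonicity: the same p would survive a family of 1e9
  expect_gt(hot$p * 1e9, 0.01)
})

test_that("failing amplicons drag their remaining variants out", {
  reg <- tibble::tibble(region = "r", chrom = "chr1", start = 0L, end = 1000L)
  amp <- tibble::tibble(amplicon_id = c("a1", "a2"), chrom = "chr1",
                        start = c(0L, 400L), end = c(500L, 900L), pool = c(1L, 2L))
  panel <- ampli_panel(reg, amp)
  # 10 variants on a1 (one in the a1/a2 overlap), 4 on a2 only
  pos <- c(seq(10L, 390L, by = 42L)[1:9], 450L, seq(510L, 810L, by = 100L))
  g <- matrix(1L, nrow = 4, ncol = length(pos))
  calls <- calls_from_matrix(g, pos = pos)

  # 1 of 10 removed (10%): below the 15% threshold, no extra removals
  one <- variant_id("chr1", pos[1])
  res1 <- amplicon_fail_filter(calls, one, panel)
  expect_equal(res1$extra_removed_ids, character(0))

  # 2 of 10 removed (20%): the remaining 8 on a1 go too
  two <- variant_id("chr1", pos[1:2])
  res2 <- amplicon_fail_filter(calls, two, panel)
  expect_setequal(res2$extra_removed_ids, variant_id("chr1", pos[3:10]))
  # the overlap variant sits on both amplicons and is removed because a1 fails
  expect_true(variant_id("chr1", 450L) %in% res2$extra_removed_ids)
  expect_false(any(variant_id("chr1", pos[11:14]) %in% res2$extra_removed_ids))
})

test_that("missingness filter uses a strict 'more than' boundary", {
  g <- rbind(rep(0L, 3), rep(1L, 3), rep(NA_integer_, 3), rep(NA_integer_, 3))
  g[3:4, 1] <- 0L          # locus 1: 0% missing
  g[4, 2] <- 0L            # locus 2: 25% missing
  # locus 3: 50% missing -> kept ("more than 50%")
  calls <- calls_from_matrix(g)
  kept <- missingness_filter(calls, 0.5)
  expect_setequal(unique(kept$pos), unique(calls$pos))
  g2 <- rbind(matrix(0L, 49, 1), matrix(NA_integer_, 51, 1))
  expect_equal(nrow(missingness_filter(calls_from_matrix(g2), 0.5)), 0L)
})

test_that("novel variants need absence from the known set, MAF and carriers", {
  g <- cbind(c(0L, 0L, 1L, 1L, rep(0L, 21)),   # MAF 0.04, 2 carriers
             c(rep(0L, 24), 1L),               # 1 carrier only
             c(0L, 1L, 1L, 2L, rep(0L, 21)))   # MAF 0.08, 3 carriers
  calls <- calls_from_matrix(g)
  known <- variant_keys(site_table(calls))[1]
  out <- classify_novel(calls, known)
  out <- out[order(out$pos), ]
  expect_equal(out$known, c(TRUE, FALSE, FALSE))
  expect_equal(out$novel, c(FALSE, FALSE, TRUE))
})

test_that("binomial depth probabilities are exact and monotone", {
  expect_equal(binomial_min_reads_prob(12, 2), 1 - 13 / 4096)
  expect_equal(binomial_min_reads_prob(1, 2), 0)
  expect_equal(binomial_min_reads_prob(4, 2), 0.6875)
  p <- binomial_min_reads_prob(0:60, 2)
  expect_true(all(diff(p) >= 0))
  expect_error(binomial_min_reads_prob(10, -1), "min_reads")
})

test_that("coverage summaries compute threshold percentages over bases", {
  u <- coverage_summary(rep(12, 50))
  expect_equal(u$pct_at_12x, 100)
  expect_equal(u$pct_at_20x, 0)
  toy <- coverage_summary(c(rep(0, 5), rep(30, 5)))
  expect_equal(toy$pct_zero, 50)
  expect_equal(toy$pct_at_30x, 50)
  expect_equal(toy$mean_coverage, 15)
  expect_equal(coverage_summary(rep(10, 4), reads_on_target = 500,
                                reads_off_target = 0)$pct_on_target, 100)
  # interval weighting
  tr <- tibble::tibble(depth = c(0, 20), length = c(30, 10))
  w <- coverage_summary(tr)
  expect_equal(w$pct_zero, 75)
  expect_equal(w$mean_coverage, 5)
  expect_error(coverage_summary(numeric(0)), "[Ee]mpty")
})

test_that("the cascade conserves variants and reapplication is a no-op", {
  sim <- paralog_sim()
  fr <- filter_variants(sim$calls, sim$panel)
  # conservation at every stage
  expect_equal(nrow(fr$fate), length(unique(variant_id(sim$calls$chrom, sim$calls$pos))))
  expect_equal(anyDuplicated(fr$fate$variant_id), 0L)
  sc <- fr$stage_counts
  expect_equal(sc$n_in - sc$n_dropped, sc$n_out)
  expect_equal(sum(fr$fate$fate == "dropped"),
               sum(sc$n_dropped))
  expect_equal(sum(fr$fate$fate == "kept"), dplyr::n_distinct(
    variant_id(fr$calls$chrom, fr$calls$pos)))

  # idempotence of the deterministic stages
  masked <- genotype_depth_mask(fr$calls)
  expect_identical(masked, genotype_depth_mask(masked))
  missed <- missingness_filter(fr$calls, 0.5)
  expect_identical(missed, missingness_filter(missed, 0.5))
  sf1 <- site_filter(fr$calls)
  expect_true(all(sf1$keep))
})
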