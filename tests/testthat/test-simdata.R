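test_that("Balding-Nichols frequencies have the right moments", {
  # degenerate limit: F = 0 returns the ancestral frequencies unchanged
  p <- c(0.1, 0.5, 0.9)
  f0 <- simulate_population_frequencies(p, 0, 5, seed = 1)
  expect_equal(f0, matrix(rep(p, each = 5), nrow = 5))

  set.seed(11)
  draws <- simulate_population_frequencies(rep(0.5, 1e5), 0.27, 1)
  expect_lt(abs(mean(draws) - 0.5), 0.01)
  expect_lt(abs(var(as.vector(draws)) - 0.27 * 0.25), 0.005)

  a <- simulate_population_frequencies(p, 0.3, 4, seed = 9)
  b <- simulate_population_frequencies(p, 0.3, 4, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_population_frequencies(p, 1, 2), "fst")
  expect_error(simulate_population_frequencies(c(0, 0.5), 0.2, 2), "\\(0, 1\\)")
})

test_that("accession genotypes follow HWE with inbreeding", {
  expect_true(all(simulate_accession_genotypes(rep(1, 50), 10, seed = 1) == 2L))
  expect_true(all(simulate_accession_genotypes(rep(0.5, 100), 100, fis = 1,
                                               seed = 2) != 1L))
  set.seed(3)
  g <- simulate_accession_genotypes(rep(0.5, 1000), 100, fis = 0)
  expect_lt(abs(mean(g == 1L) - 0.5), 0.01)
  # fis = 0.5 halves the heterozygote fraction
  g2 <- simulate_accession_genotypes(rep(0.5, 1000), 100, fis = 0.5, seed = 4)
  expect_lt(abs(mean(g2 == 1L) - 0.25), 0.01)
  expect_error(simulate_accession_genotypes(0.5, 5, fis = 1.5), "fis")
})

test_that("inbreds are homozygous and F1 crosses are Mendelian", {
  inb <- make_inbred(runif(500), seed = 5)
  expect_true(all(inb %in% c(0L, 2L)))
  expect_equal(cross_f1(c(2L, 2L), c(0L, 2L)), c(1L, 2L))
  expect_equal(cross_f1(rep(0L, 4), rep(0L, 4)), rep(0L, 4))
  set.seed(6)
  p1 <- rep(0L, 1000)
  opp <- sample.int(1000, 400)
  p2 <- p1; p2[opp] <- 2L
  f1 <- cross_f1(p1, p2)
  expect_equal(which(f1 == 1L), sort(opp))
  expect_warning(cross_f1(c(1L, 0L), c(0L, 0L), seed = 7), "[Hh]eterozygous")
  expect_error(cross_f1(0L, c(0L, 2L)), "locus set")
})

test_that("the sequencing layer honours its degenerate limits", {
  panel <- small_panel()
  # total dropout: everything missing at depth zero
  sim <- simulate_study(small_config(dropout_prob = 1, seed = 2), panel = panel)
  expect_true(all(is.na(sim$calls$gt)))
  expect_true(all(sim$calls$dp == 0L))

  # noiseless: every non-missing call equals the truth
  sim0 <- simulate_study(small_config(base_error = 0, dropout_prob = 0, seed = 3),
                         panel = panel)
  g <- gt_matrix(sim0$calls)
  truth <- sim0$truth$genotypes[rownames(g),
                               paste(sim0$loci$chrom, sim0$loci$pos, sep = ":")]
  ok <- !is.na(g)
  expect_true(all(g[ok] == truth[, colnames(g)][ok]))
  # missing only where read support is insufficient
  expect_true(all(sim0$calls$dp[is.na(sim0$calls$gt)] < 2L))
})

test_that("simulation is seed-deterministic", {
  a <- simulate_study(small_config(seed = 9))
  b <- simulate_study(small_config(seed = 9))
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
  c <- simulate_study(small_config(seed = 10))
  expect_false(identical(a$calls$gt, c$calls$gt))
})

test_that("simulated depths match the configured mean", {
  sim <- simulate_study(small_config(dropout_prob = 0, seed = 4))
  dp <- sim$calls$dp
  se <- sd(dp) / sqrt(length(dp))
  expect_lt(abs(mean(dp) - 105), 3 * se)
})

test_that("paralog contamination is confined to carrier cells and forces hets", {
  sim <- paralog_sim()
  cont <- sim$truth$contaminated
  carriers <- sim$truth$paralog_lineages
  expect_false("P1" %in% carriers)
  # containment: contaminated cells only on paralog amplicons x carrier samples
  on_paralog <- sim$loci$amplicon_id %in% sim$truth$paralog_amplicons
  expect_true(all(!cont[, !on_paralog]))
  expect_true(all(!cont[setdiff(rownames(cont), carriers), ]))

  # a contaminated homozygous-reference inbred reads as a heterozygote
  g <- gt_matrix(sim$calls)
  p2_cont <- cont["P2", ] & sim$truth$genotypes["P2", ] == 0L
  called <- g["P2", colnames(cont)[p2_cont]]
  called <- called[!is.na(called)]
  expect_true(all(called == 1L))
})
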