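trio_calls <- function(p1, p2, f1) {
  g <- rbind(P1 = p1, P2 = p2, F1 = f1)
  calls_from_matrix(g)
}

test_that("trio metrics reproduce a hand-enumerated truth table", {
  # 10 sites: parents opposite-homozygous at 6; F1 het at 5 of those,
  # plus 3 spurious hets elsewhere
  p1 <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L, 2L)
  p2 <- c(2L, 2L, 2L, 2L, 2L, 2L, 0L, 0L, 2L, 2L)
  f1 <- c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 0L)
  tm <- trio_het_metrics(trio_calls(p1, p2, f1), "P1", "P2", "F1")
  expect_equal(tm$n_parents_opposite, 6L)
  expect_equal(tm$n_f1_het_calls, 8L)
  expect_equal(tm$sensitivity, 5 / 6)
  expect_equal(tm$precision, 5 / 8)

  # perfect F1: heterozygous exactly where parents are opposite homozygotes
  perfect <- trio_het_metrics(trio_calls(p1, p2, ifelse(p1 != p2, 1L, p1)),
                              "P1", "P2", "F1")
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
})

test_that("undefined trio metrics are signalled as NA, not 0 or 1", {
  same <- trio_het_metrics(trio_calls(rep(0L, 5), rep(0L, 5), rep(0L, 5)),
                           "P1", "P2", "F1")
  expect_true(is.na(same$sensitivity))
  expect_true(is.na(same$precision))
  expect_error(trio_het_metrics(trio_calls(0L, 0L, 0L), "P1", "P1", "F1"),
               "distinct")
  expect_error(trio_het_metrics(trio_calls(0L, 0L, 0L), "P1", "P2", "nope"),
               "absent")
})

test_that("parent-heterozygous sites leave sensitivity but hit precision", {
  # site 1: true informative het; site 2: parent called het, F1 het
  p1 <- c(0L, 0L); p2 <- c(2L, 1L); f1 <- c(1L, 1L)
  tm <- trio_het_metrics(trio_calls(p1, p2, f1), "P1", "P2", "F1")
  expect_equal(tm$n_parents_opposite, 1L)
  expect_equal(tm$sensitivity, 1)
  expect_equal(tm$precision, 1 / 2)
})

test_that("interval restriction is half-open", {
  v <- tibble::tibble(chrom = "chr1", pos = c(5L, 10L, 15L, 20L, 25L))
  iv <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L)
  expect_equal(restrict_to_intervals(v, iv)$pos, c(10L, 15L))
  expect_equal(nrow(restrict_to_intervals(v, iv[0, ])), 0L)
  all_iv <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(restrict_to_intervals(v, all_iv), v)
})

test_that("three-way concordance counts partition the union", {
  ident <- venn3(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(ident$n[ident$region == "ABC"], 5L)
  expect_equal(sum(ident$n), 5L)

  disj <- venn3("a", "b", "c")
  expect_equal(sort(disj$n), c(0L, 0L, 0L, 0L, 1L, 1L, 1L))

  ex <- venn3(c("k1", "k2"), c("k2", "k3"), "k3")
  lk <- setNames(ex$n, ex$region)
  expect_equal(unname(lk[c("A", "AB", "BC")]), c(1L, 1L, 1L))
  expect_equal(sum(lk), 3L)

  # property: regions are a partition of the union; pairwise intersections
  # are recoverable by summing regions
  set.seed(1)
  for (i in 1:10) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    c <- sample(letters, sample(0:15, 1))
    vv <- setNames(venn3(a, b, c)$n, venn3(a, b, c)$region)
    expect_equal(sum(vv), length(union(union(a, b), c)))
    expect_equal(unname(vv["AB"] + vv["ABC"]), length(intersect(a, b)))
    expect_equal(unname(vv["BC"] + vv["ABC"]), length(intersect(b, c)))
  }
})

test_that("SNP density rounds base pairs per SNP", {
  expect_equal(snp_density(1605, 72197), 45L)
  expect_equal(snp_density(7, 7), 1L)
  expect_equal(snp_density(100, 4500), 45L)
  expect_error(snp_density(0, 100), "undefined")
})

test_that("false F1 hets co-occur with heterozygous calls in the carrier parent", {
  sim <- paralog_sim()
  masked <- genotype_depth_mask(sim$calls)
  g <- gt_matrix(masked)
  inf <- !is.na(g["P1", ]) & !is.na(g["P2", ]) & !is.na(g["P1xP2", ])
  opp <- inf & ((g["P1", ] == 0L & g["P2", ] == 2L) |
                  (g["P1", ] == 2L & g["P2", ] == 0L))
  false_het <- inf & g["P1xP2", ] == 1L & !opp
  expect_gt(sum(false_het), 0)
  # the non-reference parent is itself scored heterozygous at these sites
  expect_true(all(g["P2", false_het] == 1L))
})
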