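pops_for <- function(g, pop) tibble::tibble(sample = rownames(g), population = pop)

test_that("diversity statistics hit their closed-form values", {
  # two populations fixed for alternate alleles: maximal differentiation
  g <- matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1)
  rownames(g) <- paste0("s", 1:20)
  st <- pop_basic_stats(calls_from_matrix(g), pops_for(g, rep(c("A", "B"), each = 10)))
  expect_equal(st$overall$hs, 0)
  expect_equal(st$overall$ht, 0.5)
  expect_equal(st$overall$fst_nei, 1)
  expect_equal(st$overall$fst_wc, 1)

  # one population, everyone heterozygous: Ho 1, unbiased Hs 1/2, Fis -1
  g2 <- matrix(rep(1L, 10), ncol = 1, dimnames = list(paste0("s", 1:10), NULL))
  expect_warning(
    st2 <- pop_basic_stats(calls_from_matrix(g2), pops_for(g2, rep("A", 10))),
    "Single population")
  expect_equal(st2$overall$ho, 1)
  expect_equal(st2$overall$hs, 0.5)
  expect_equal(st2$overall$fis, -1)
  expect_true(is.na(st2$overall$fst_wc))

  # monomorphic everywhere: zero diversity, Fst undefined
  g3 <- matrix(0L, nrow = 8, ncol = 3, dimnames = list(paste0("s", 1:8), NULL))
  st3 <- pop_basic_stats(calls_from_matrix(g3), pops_for(g3, rep(c("A", "B"), each = 4)))
  expect_equal(st3$overall$ht, 0)
  expect_true(is.na(st3$overall$fst_wc))
  expect_true(is.na(st3$overall$fst_nei))
})

test_that("Hs never exceeds Ht and theta matches the loop oracle", {
  set.seed(21)
  for (rep in 1:5) {
    # differentiated populations with missing data: per-locus frequencies
    # drawn per population, genotypes binomial, ~10% missing
    S <- 24L; L <- 30L
    pop <- rep(c("A", "B", "C"), each = 8)
    g <- vapply(seq_len(L), function(l) {
      p <- rbeta(3, 0.4, 0.4)
      gt <- rbinom(S, 2L, p[match(pop, c("A", "B", "C"))])
      gt[runif(S) < 0.1] <- NA
      as.integer(gt)
    }, integer(S))
    rownames(g) <- paste0("s", 1:S)
    st <- pop_basic_stats(calls_from_matrix(g), pops_for(g, pop))
    # hierarchy holds for the across-locus means (per-locus unbiased
    # estimates carry sampling noise of either sign)
    expect_lte(st$overall$hs, st$overall$ht + 1e-12)
    expect_equal(st$overall$fst_wc, wc_theta_oracle(g, pop), tolerance = 1e-12)
  }
})

test_that("tidy and glance expose per-locus and overall views", {
  sim <- clean_noiseless_sim()
  land <- sim$sample_sheet[sim$sample_sheet$class == "landrace", ]
  calls <- sim$calls[sim$calls$sample %in% land$sample, ]
  st <- pop_basic_stats(missingness_filter(calls, 0.5), land)
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(nrow(glance(st)), 1L)
  expect_equal(glance(st)$n_populations, 19L)
  # estimator hierarchy on realistic data
  expect_lte(glance(st)$hs, glance(st)$ht + 1e-12)
})

test_that("IBS distances equal the brute-force loop and obey its identities", {
  expect_equal(unname(ibs_distance_matrix(calls_from_matrix(
    rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L))))["a", "b"]), 0)
  expect_equal(unname(ibs_distance_matrix(calls_from_matrix(
    rbind(a = c(0L, 0L), b = c(2L, 2L))))["a", "b"]), 1)
  expect_equal(unname(ibs_distance_matrix(calls_from_matrix(
    rbind(a = 0L, b = 1L)))["a", "b"]), 0.5)

  set.seed(31)
  for (rep in 1:3) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 8 * 20, replace = TRUE),
                nrow = 8, dimnames = list(paste0("s", 1:8), NULL))
    d <- suppressWarnings(ibs_distance_matrix(calls_from_matrix(g)))
    expect_equal(unclass(d)[seq_len(64)], ibs_brute(g)[seq_len(64)])
    expect_true(isSymmetric(unname(unclass(d)[1:8, 1:8])))
  }
})

test_that("classical MDS recovers exact Euclidean configurations", {
  # equilateral triangle: all pairwise coordinate distances equal the input
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  m3 <- classical_mds(d3, k = 2)
  coords <- as.matrix(m3$points[, -1])
  expect_equal(as.numeric(dist(coords)), rep(1, 3), tolerance = 1e-8)

  # planted 2-D configuration recovered to numerical precision
  set.seed(41)
  xy <- matrix(rnorm(24), ncol = 2, dimnames = list(paste0("p", 1:12), NULL))
  d <- as.matrix(dist(xy))
  m <- classical_mds(d, k = 2)
  rec <- as.matrix(dist(as.matrix(m$points[, -1])))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)

  # duplicated sample lands on identical coordinates
  xy2 <- rbind(xy, dup = xy[1, ])
  md <- classical_mds(as.matrix(dist(xy2)), k = 2)
  pts <- as.matrix(md$points[, -1])
  expect_equal(pts[13, ], pts[1, ], tolerance = 1e-8)

  # deterministic sign convention
  m_again <- classical_mds(d, k = 2)
  expect_identical(m$points, m_again$points)
  # collinear points: only one positive eigenvalue, output reduced
  line <- as.matrix(dist(cbind(c(0, 1, 2, 3), 0)))
  expect_warning(mline <- classical_mds(line, k = 2), "eigenvalue")
  expect_equal(ncol(mline$points) - 1L, 1L)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("an F1 projects between its parents on the first MDS axis", {
  sim <- clean_noiseless_sim()
  d <- ibs_distance_matrix(sim$calls)
  m <- classical_mds(d, k = 2)
  x <- setNames(m$points$MDS1, m$points$sample)
  expect_gte(x[["P1xP2"]], min(x[["P1"]], x[["P2"]]))
  expect_lte(x[["P1xP2"]], max(x[["P1"]], x[["P2"]]))
  # the trio alone is exactly collinear: the F1 is the midpoint
  trio <- sim$calls[sim$calls$sample %in% c("P1", "P2", "P1xP2"), ]
  dt <- ibs_distance_matrix(trio)
  expect_equal(dt["P1", "P1xP2"] + dt["P1xP2", "P2"], dt["P1", "P2"])
})
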