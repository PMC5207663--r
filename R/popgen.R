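#' Population-genetic summary statistics
#'
#' Per-locus and overall observed heterozygosity (Ho), within-population
#' gene diversity (Hs), total gene diversity (Ht), Fis, and two Fst
#' estimators: Weir–Cockerham theta (variance components, the default
#' headline estimator) and Nei's (Ht - Hs)/Ht from the unbiased
#' (Nei–Chesser) diversities. Both are reported because "total gene
#' diversity" is Nei's Ht while theta is the standard differentiation
#' estimator for unequal samples.
#'
#' Per-locus values use small-sample corrections with the harmonic mean of
#' the per-population sample sizes. Overall Ho/Hs/Ht are across-locus means
#' (monomorphic loci contribute 0 diversity); overall theta is the ratio of
#' summed variance components and overall Nei Fst the ratio of mean
#' diversities, both over loci polymorphic in the pooled sample.
#'
#' @param calls A variant table of biallelic SNPs (missingness-filtered for
#'   headline use).
#' @param pops Either a tibble with `sample` and `population` columns or a
#'   named character vector sample -> population. Every sample in `calls`
#'   must be assigned.
#' @return An object of class `popgen_stats` with `per_locus` and `overall`
#'   tibbles; see also [tidy()] and [glance()] methods.
#' @export
pop_basic_stats <- function(calls, pops) {
  if (is.data.frame(pops)) {
    pops <- setNames(pops$population, pops$sample)
  }
  samples <- unique(calls$sample)
  unassigned <- setdiff(samples, names(pops))
  if (length(unassigned)) {
    abort(paste0("Samples without population assignment: ",
                 paste(head(unassigned, 5), collapse = ", ")))
  }
  g <- gt_matrix(calls)
  pop_of <- pops[rownames(g)]
  pop_levels <- unique(pop_of)
  single_pop <- length(pop_levels) < 2

  L <- ncol(g)
  per <- vector("list", L)
  for (l in seq_len(L)) {
    gl <- g[, l]
    ok <- !is.na(gl)
    if (!any(ok)) next
    tab <- tibble(pop = pop_of[ok], gt = gl[ok]) |>
      group_by(.data$pop) |>
      summarise(n = n(), p = mean(.data$gt) / 2, ho = mean(.data$gt == 1L),
                .groups = "drop")
    r <- nrow(tab)
    n_i <- tab$n; p_i <- tab$p; ho_i <- tab$ho
    m_ho <- mean(ho_i)
    msp2 <- mean(p_i^2 + (1 - p_i)^2)
    nharm <- r / sum(1 / n_i)
    hs <- if (nharm > 1) nharm / (nharm - 1) * (1 - msp2 - m_ho / (2 * nharm)) else NA_real_
    pbar_u <- mean(p_i)
    ht <- if (!is.na(hs)) {
      1 - (pbar_u^2 + (1 - pbar_u)^2) + hs / (nharm * r) - m_ho / (2 * nharm * r)
    } else NA_real_
    fis <- if (!is.na(hs) && hs > 0) 1 - m_ho / hs else NA_real_
    fst_nei <- if (!is.na(ht) && ht > 0) (ht - hs) / ht else NA_real_

    # Weir & Cockerham variance components (biallelic, unequal sizes)
    wc <- c(a = NA_real_, b = NA_real_, c = NA_real_)
    if (r >= 2) {
      nbar <- mean(n_i)
      nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
      pbar_w <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar_w)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * ho_i) / (r * nbar)
      if (nbar > 1 && nc > 0) {
        a <- nbar / nc *
          (s2 - (pbar_w * (1 - pbar_w) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
        b <- nbar / (nbar - 1) *
          (pbar_w * (1 - pbar_w) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        wc <- c(a = a, b = b, c = cc)
      }
    }
    # pooled polymorphism over all non-missing calls
    p_all <- mean(gl[ok]) / 2
    per[[l]] <- tibble(
      variant_id = colnames(g)[l],
      n_pops = r, n_total = sum(n_i),
      ho = m_ho, hs = hs, ht = ht, fis = fis, fst_nei = fst_nei,
      wc_a = wc["a"], wc_b = wc["b"], wc_c = wc["c"],
      polymorphic = p_all > 0 & p_all < 1
    )
  }
  per_locus <- bind_rows(per)
  if (nrow(per_locus) == 0) abort("No informative loci: every call is missing.")

  poly <- per_locus$polymorphic & !is.na(per_locus$hs)
  denom <- per_locus$wc_a + per_locus$wc_b + per_locus$wc_c
  theta_ok <- poly & !is.na(denom)
  fst_wc <- if (!single_pop && any(theta_ok) && sum(denom[theta_ok]) > 0) {
    sum(per_locus$wc_a[theta_ok]) / sum(denom[theta_ok])
  } else NA_real_
  m_hs <- mean(per_locus$hs, na.rm = TRUE)
  m_ht <- mean(per_locus$ht, na.rm = TRUE)
  m_ho <- mean(per_locus$ho, na.rm = TRUE)
  fst_nei <- if (!single_pop && any(poly)) {
    hs_p <- mean(per_locus$hs[poly]); ht_p <- mean(per_locus$ht[poly])
    if (ht_p > 0) (ht_p - hs_p) / ht_p else NA_real_
  } else NA_real_
  if (single_pop) {
    warn("Single population: Fst is undefined and reported as NA.")
  }
  overall <- tibble(
    n_loci = nrow(per_locus), n_polymorphic = sum(poly),
    n_populations = length(pop_levels),
    ho = m_ho, hs = m_hs, ht = m_ht,
    fis = if (m_hs > 0) 1 - m_ho / m_hs else NA_real_,
    fst_wc = fst_wc, fst_nei = fst_nei
  )
  structure(list(per_locus = per_locus, overall = overall), class = "popgen_stats")
}

#' @method print popgen_stats
#' @export
print.popgen_stats <- function(x, ...) {
  o <- x$overall
  cat("<popgen_stats> ", o$n_loci, " loci, ", o$n_populations, " populations\n",
      sep = "")
  cat(sprintf("  Ho = %.3f  Hs = %.3f  Ht = %.3f  Fis = %.3f\n",
              o$ho, o$hs, o$ht, o$fis))
  cat(sprintf("  Fst (Weir-Cockerham theta) = %.3f; Fst (Nei) = %.3f\n",
              o$fst_wc, o$fst_nei))
  invisible(x)
}

#' @describeIn pop_basic_stats Per-locus statistics as a tibble.
#' @param x A `popgen_stats` object.
#' @param ... Unused.
#' @export
tidy.popgen_stats <- function(x, ...) x$per_locus

#' @describeIn pop_basic_stats One-row tibble of the overall estimates.
#' @export
glance.popgen_stats <- function(x, ...) x$overall

#' Identity-by-state distance matrix
#'
#' For dosage genotypes the number of shared alleles at a locus is
#' 2 - |g_i - g_j|, so the allele-sharing distance contribution is
#' |g_i - g_j| / 2. Pairwise distances average over the loci where both
#' samples are called (pairwise-complete); the per-pair shared-locus count
#' is attached as attribute `n_shared`. A pair with no shared non-missing
#' locus gets `NA` with a warning.
#'
#' @param calls A variant table.
#' @return Symmetric numeric matrix with zero diagonal and sample dimnames.
#' @export
ibs_distance_matrix <- function(calls) {
  g <- gt_matrix(calls)
  if (nrow(g) < 2) abort("Need at least two samples.")
  S <- nrow(g)
  d <- matrix(0, S, S, dimnames = list(rownames(g), rownames(g)))
  nsh <- matrix(ncol(g), S, S, dimnames = dimnames(d))
  for (i in seq_len(S - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):S) {
      both <- !is.na(gi) & !is.na(g[j, ])
      nsh[i, j] <- nsh[j, i] <- sum(both)
      d[i, j] <- d[j, i] <- if (any(both)) {
        mean(abs(gi[both] - g[j, both])) / 2
      } else NA_real_
    }
  }
  if (anyNA(d)) warn("Some sample pairs share no non-missing locus; distances are NA.")
  attr(d, "n_shared") <- nsh
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers -d^2/2 and takes the top-k spectral coordinates
#' (delegated to `stats::cmdscale`), then applies a deterministic sign
#' convention: on each axis the largest-magnitude loading is positive. If
#' fewer than `k` positive eigenvalues exist the output is reduced with a
#' warning.
#'
#' @param d Symmetric distance matrix (or `dist`) with zero diagonal.
#' @param k Number of dimensions (default 2).
#' @return An object of class `mds_result`: `points` tibble (`sample`,
#'   `MDS1`, ...), `eig` eigenvalues.
#' @export
classical_mds <- function(d, k = 2L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("`d` must be symmetric.")
  if (any(abs(diag(d)) > 1e-12)) abort("`d` must have a zero diagonal.")
  if (k < 1) abort("`k` must be >= 1.")
  k_eff <- min(k, nrow(d) - 1L)
  fit <- suppressWarnings(cmdscale(d, k = k_eff, eig = TRUE))
  pts <- fit$points
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-10)
  if (n_pos < k) {
    pts <- pts[, seq_len(min(n_pos, ncol(pts))), drop = FALSE]
    warn(sprintf("Only %d positive eigenvalue(s) available; returning %d dimension(s).",
                 n_pos, ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  structure(list(
    points = as_tibble(pts, rownames = "sample"),
    eig = fit$eig
  ), class = "mds_result")
}

#' @method print mds_result
#' @export
print.mds_result <- function(x, ...) {
  cat("<mds_result> ", nrow(x$points), " samples, ",
      ncol(x$points) - 1L, " dimensions\n", sep = "")
  print(head(x$points))
  invisible(x)
}

#' @describeIn classical_mds Coordinates as a tibble.
#' @param x An `mds_result`.
#' @param ... Unused.
#' @export
tidy.mds_result <- function(x, ...) x$points

#' Write per-locus stats, distance matrix or MDS coordinates
#'
#' @param stats A `popgen_stats`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_popgen_stats <- function(stats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(stats$per_locus, file.path(dir, "per_locus_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(stats$overall), file.path(dir, "overall_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
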