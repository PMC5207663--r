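# Independent oracles used to freeze expected values.

# Exact heterozygote-excess tail by enumeration: multinomial weights
# choose(n, h) * choose(n - h, n_minor_hom) * 2^h over all parity-consistent
# heterozygote counts, normalized, then summed over the upper tail.
hwe_tail_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het
  n_b <- 2 * n_hom_alt + n_het
  nm <- min(n_a, n_b)
  if (nm == 0) return(1.0)
  hs <- seq(nm %% 2, nm, by = 2)
  w <- vapply(hs, function(h) {
    n1 <- (nm - h) / 2
    n2 <- n - h - n1
    if (n1 < 0 || n2 < 0) return(0)
    choose(n, h) * choose(n - h, n1) * 2^h
  }, numeric(1))
  sum(w[hs >= n_het]) / sum(w)
}

# Brute-force identity-by-state distances: per-pair, per-locus loop.
ibs_brute <- function(g) {
  S <- nrow(g)
  d <- matrix(0, S, S, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i == j) next
      num <- 0; cnt <- 0
      for (l in seq_len(ncol(g))) {
        if (!is.na(g[i, l]) && !is.na(g[j, l])) {
          shared <- 2 - abs(g[i, l] - g[j, l])
          num <- num + (1 - shared / 2)
          cnt <- cnt + 1
        }
      }
      d[i, j] <- if (cnt > 0) num / cnt else NA_real_
    }
  }
  d
}

# Weir & Cockerham (1984) theta by scalar loops over populations and loci.
wc_theta_oracle <- function(g, pop) {
  sum_a <- 0; sum_abc <- 0
  for (l in seq_len(ncol(g))) {
    gl <- g[, l]
    ok <- !is.na(gl)
    if (!any(ok)) next
    pops <- unique(pop[ok])
    r <- length(pops)
    if (r < 2) next
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      sel <- ok & pop == pops[k]
      n_i[k] <- sum(sel)
      p_i[k] <- mean(gl[sel]) / 2
      h_i[k] <- mean(gl[sel] == 1)
    }
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (mean(gl[ok]) / 2 > 0 && mean(gl[ok]) / 2 < 1) {
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  sum_a / sum_abc
}

# Brute-force amplicon containment: linear scan over every amplicon.
assign_brute <- function(chrom, pos, panel) {
  amp <- panel$amplicons
  hit <- amp$chrom == chrom & amp$start <= pos & pos < amp$end
  sort(amp$amplicon_id[hit])
}
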