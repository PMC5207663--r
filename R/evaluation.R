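#' Trio-based heterozygote sensitivity and precision
#'
#' F1 hybrids of fully homozygous inbred parents are heterozygous with
#' certainty wherever the parents carry opposite alleles, which makes a
#' parent-parent-F1 trio a truth standard for heterozygote calling.
#'
#' A site is *informative* when all three trio members have non-missing
#' calls. Sensitivity is the fraction of informative sites with
#' opposite-homozygous parents (true heterozygotes) at which the F1 is
#' called heterozygous; sites where either parent is itself called
#' heterozygous are excluded from the sensitivity denominator (a
#' heterozygous inbred call is itself suspect) but F1 heterozygote calls at
#' such sites still count against precision. Precision (positive predictive
#' value) is the fraction of F1 heterozygote calls at informative sites
#' whose parents are opposite homozygotes.
#'
#' @param calls A variant table containing the three samples.
#' @param parent1,parent2,f1 Sample ids of the trio.
#' @return One-row tibble: `parent1`, `parent2`, `f1`,
#'   `n_informative_sites`, `n_parents_opposite`, `n_true_het_called_het`,
#'   `n_f1_het_calls`, `n_f1_het_with_polymorphic_parents`, `sensitivity`,
#'   `precision`. A zero denominator yields `NA` for the affected metric
#'   (undefined, not 0 or 1).
#' @export
trio_het_metrics <- function(calls, parent1, parent2, f1) {
  ids <- c(parent1, parent2, f1)
  if (length(unique(ids)) != 3) abort("Trio sample ids must be distinct.")
  missing_ids <- setdiff(ids, unique(calls$sample))
  if (length(missing_ids)) {
    abort(paste0("Samples absent from the call table: ",
                 paste(missing_ids, collapse = ", ")))
  }
  wide <- calls |>
    filter(.data$sample %in% ids) |>
    mutate(.id = variant_id(.data$chrom, .data$pos)) |>
    select(".id", "sample", "gt") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "gt")
  g1 <- wide[[parent1]]; g2 <- wide[[parent2]]; gf <- wide[[f1]]
  informative <- !is.na(g1) & !is.na(g2) & !is.na(gf)
  opposite <- informative &
    ((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L))
  f1_het <- informative & gf == 1L
  n_opp <- sum(opposite)
  n_f1_het <- sum(f1_het)
  n_tp_sens <- sum(opposite & gf == 1L)
  n_tp_prec <- sum(f1_het & opposite)
  tibble(
    parent1 = parent1, parent2 = parent2, f1 = f1,
    n_informative_sites = sum(informative),
    n_parents_opposite = n_opp,
    n_true_het_called_het = n_tp_sens,
    n_f1_het_calls = n_f1_het,
    n_f1_het_with_polymorphic_parents = n_tp_prec,
    sensitivity = if (n_opp > 0) n_tp_sens / n_opp else NA_real_,
    precision = if (n_f1_het > 0) n_tp_prec / n_f1_het else NA_real_
  )
}

#' Trio metrics for every F1 in a sample sheet
#'
#' @param calls A variant table.
#' @param sample_sheet Tibble with columns `sample`, `class`, `parent1`,
#'   `parent2`; rows with class `"f1"` define the trios.
#' @return Tibble, one row per trio (see [trio_het_metrics()]).
#' @export
trio_het_metrics_all <- function(calls, sample_sheet) {
  f1s <- filter(sample_sheet, .data$class == "f1")
  if (nrow(f1s) == 0) abort("Sample sheet contains no F1 rows.")
  purrr::pmap_dfr(list(f1s$parent1, f1s$parent2, f1s$sample),
                  function(p1, p2, f1) trio_het_metrics(calls, p1, p2, f1))
}

#' Restrict variants to designed intervals
#'
#' Keeps variants whose position falls inside any of the half-open
#' intervals; a position equal to an interval end is outside. Row order is
#' preserved.
#'
#' @param variants Tibble with `chrom` and `pos` columns (site table or
#'   variant table).
#' @param intervals Tibble with `chrom`, `start`, `end` columns.
#' @return The subset of `variants` inside the intervals.
#' @export
restrict_to_intervals <- function(variants, intervals) {
  hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (variants$chrom == intervals$chrom[i] &
                    variants$pos >= intervals$start[i] &
                    variants$pos < intervals$end[i])
  }
  variants[hit, ]
}

#' Three-way variant-set concordance
#'
#' Partitions the union of three canonical key sets into the seven mutually
#' exclusive regions of a three-set Venn diagram — the standard comparison
#' of two caller outputs against a reference SNP panel.
#'
#' @param set_a,set_b,set_c Character vectors of variant keys (duplicates
#'   collapse).
#' @param names Labels for the three sets.
#' @return Tibble with `region` (e.g. `"A"`, `"AB"`, `"ABC"` using the
#'   given labels) and `n`; the counts sum to the union size.
#' @export
venn3 <- function(set_a, set_b, set_c, names = c("A", "B", "C")) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  lab <- function(av, bv, cv) paste0(if (av) names[1] else "",
                                     if (bv) names[2] else "",
                                     if (cv) names[3] else "")
  combos <- tibble(
    region = c(lab(TRUE, FALSE, FALSE), lab(FALSE, TRUE, FALSE),
               lab(FALSE, FALSE, TRUE), lab(TRUE, TRUE, FALSE),
               lab(TRUE, FALSE, TRUE), lab(FALSE, TRUE, TRUE),
               lab(TRUE, TRUE, TRUE)),
    n = c(sum(in_a & !in_b & !in_c), sum(!in_a & in_b & !in_c),
          sum(!in_a & !in_b & in_c), sum(in_a & in_b & !in_c),
          sum(in_a & !in_b & in_c), sum(!in_a & in_b & in_c),
          sum(in_a & in_b & in_c))
  )
  combos
}

#' SNP density as base pairs per SNP
#'
#' @param n_snps Number of SNPs found in the target space.
#' @param target_bp Size of the (covered) target space in bp.
#' @return Rounded integer bp-per-SNP.
#' @examples
#' snp_density(1605, 72197) # 45
#' @export
snp_density <- function(n_snps, target_bp) {
  if (any(n_snps <= 0)) abort("`n_snps` must be > 0 (density undefined).")
  as.integer(round(target_bp / n_snps))
}
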