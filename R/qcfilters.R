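#' Filter thresholds for the variant QC cascade
#'
#' Defaults are the published working point for amplicon-panel calls:
#' site quality strictly above 30, quality-by-depth strictly above 5,
#' per-genotype depth of at least 12 (a depth at which each homologous
#' chromosome is sequenced twice or more with probability ~99.7%, see
#' [binomial_min_reads_prob()]), family-wise alpha 0.01 (Bonferroni) for the
#' heterozygote-excess exact test, amplicon failure above a 15% removed
#' fraction, novel-variant criteria of 2% minor-allele frequency in at least
#' two carriers, and a 50% missingness cap before population-genetic
#' analysis.
#'
#' @param qual_min Site QUAL threshold (keep iff QUAL > qual_min).
#' @param qd_min Quality-by-depth threshold (keep iff QD > qd_min).
#' @param gt_depth_min Per-genotype depth threshold.
#' @param gt_depth_strict If FALSE (default) genotypes with depth >=
#'   `gt_depth_min` are retained; if TRUE the inequality is strict
#'   (depth > `gt_depth_min`).
#' @param het_excess_alpha Family-wise alpha for the Bonferroni-corrected
#'   heterozygote-excess filter.
#' @param amplicon_fail_fraction An amplicon fails when the fraction of its
#'   variants removed by the heterozygote-excess filter exceeds this.
#' @param novel_maf_min,novel_min_carriers Novel-variant criteria.
#' @param popgen_max_missing Drop variants with missing-call fraction above
#'   this before population-genetic analysis.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qual_min = 30, qd_min = 5,
                          gt_depth_min = 12L, gt_depth_strict = FALSE,
                          het_excess_alpha = 0.01,
                          amplicon_fail_fraction = 0.15,
                          novel_maf_min = 0.02, novel_min_carriers = 2L,
                          popgen_max_missing = 0.50) {
  cfg <- as.list(environment())
  if (het_excess_alpha <= 0 || het_excess_alpha > 1) abort("`het_excess_alpha` must be in (0, 1].")
  if (amplicon_fail_fraction < 0 || amplicon_fail_fraction > 1) abort("`amplicon_fail_fraction` must be in [0, 1].")
  if (qual_min < 0 || qd_min < 0 || gt_depth_min < 0) abort("Thresholds must be non-negative.")
  if (popgen_max_missing < 0 || popgen_max_missing > 1) abort("`popgen_max_missing` must be in [0, 1].")
  structure(cfg, class = "filter_config")
}

#' Site-level filter: indels, multi-allelic records, QUAL and QD
#'
#' Keeps biallelic SNPs with QUAL strictly above `qual_min` and QD strictly
#' above `qd_min`. Indels are always dropped (they are the dominant
#' semiconductor-sequencing error mode), multi-allelic records are dropped
#' with their own reason code, and sites lacking QD are dropped as
#' `missing_qd` (conservative).
#'
#' @param sites Per-site tibble with `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `qd` (a full variant table also works; it is reduced to sites).
#' @param cfg A [filter_config()].
#' @return Tibble of sites with `keep` (logical) and `reason` (`NA` when
#'   kept; otherwise `indel`, `multiallelic`, `low_qual`, `missing_qd` or
#'   `low_qd`).
#' @export
site_filter <- function(sites, cfg = filter_config()) {
  sites <- distinct(as_tibble(sites), .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$qual, .data$qd)
  snp <- is_snp(sites$ref, sites$alt)
  multi <- is_multiallelic(sites$alt)
  reason <- rep(NA_character_, nrow(sites))
  reason[!snp & !multi] <- "indel"
  reason[multi] <- ifelse(snp[multi], "multiallelic", "indel")[seq_len(sum(multi))]
  todo <- is.na(reason)
  reason[todo & sites$qual <= cfg$qual_min] <- "low_qual"
  todo <- is.na(reason)
  reason[todo & is.na(sites$qd)] <- "missing_qd"
  todo <- is.na(reason)
  reason[todo & sites$qd <= cfg$qd_min] <- "low_qd"
  mutate(sites, keep = is.na(reason), reason = reason)
}

#' Mask genotype calls below the depth threshold
#'
#' Calls whose per-genotype depth falls below the threshold are set to
#' missing; the depth field is preserved. By default depth >= `gt_depth_min`
#' is retained; strict mode requires depth > `gt_depth_min`.
#'
#' @param calls A variant table.
#' @param cfg A [filter_config()].
#' @return The variant table with sub-threshold `gt` set to `NA`.
#' @export
genotype_depth_mask <- function(calls, cfg = filter_config()) {
  low <- if (cfg$gt_depth_strict) calls$dp <= cfg$gt_depth_min else calls$dp < cfg$gt_depth_min
  mutate(calls, gt = if_else(is.na(low) | low, NA_integer_, .data$gt))
}

#' Exact one-sided p-value for heterozygote excess
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' under Hardy–Weinberg equilibrium follows the exact distribution
#' P(h | n, nA) = n! / (nAA! h! naa!) * 2^h * nA! na! / (2n)!, over the
#' heterozygote counts h sharing the parity of the minor-allele count nA.
#' The upper tail P(h' >= h_obs) is returned: small values indicate more
#' heterozygotes than random union of the sampled alleles can explain —
#' the signature of paralog co-amplification. Monomorphic sites return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectors recycle).
#' @return Numeric vector of one-sided p-values.
#' @examples
#' het_excess_pvalue(1, 8, 1)
#' @export
het_excess_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  nn <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  n_hom_ref <- rep_len(n_hom_ref, nn)
  n_het <- rep_len(n_het, nn)
  n_hom_alt <- rep_len(n_hom_alt, nn)
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) abort("Genotype counts must be >= 0.")
  vapply(seq_len(nn), function(i) {
    n <- n_hom_ref[i] + n_het[i] + n_hom_alt[i]
    if (n == 0) abort("At least one genotype count must be nonzero.")
    n_a <- 2 * n_hom_ref[i] + n_het[i]
    n_b <- 2 * n_hom_alt[i] + n_het[i]
    nA <- min(n_a, n_b)                   # minor allele copies
    if (nA == 0) return(1.0)
    hs <- seq(n_het[i], nA, by = 2)       # parity-consistent upper tail
    hs <- hs[(nA - hs) %% 2 == 0 & (nA - hs) / 2 + hs <= n]
    if (!length(hs)) return(1.0)
    logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
      lfactorial(n - hs - (nA - hs) / 2) + hs * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    min(sum(exp(logp)), 1.0)
  }, numeric(1))
}

#' Heterozygote-excess filter with Bonferroni correction
#'
#' Computes the exact heterozygote-excess p-value at every site from its
#' non-missing genotype calls and removes sites whose Bonferroni-corrected
#' p-value (p times the number of sites tested) falls below the family-wise
#' alpha. Only excess is tested; a heterozygote deficit never removes a
#' site.
#'
#' @param calls A variant table of biallelic SNPs (post depth masking).
#' @param cfg A [filter_config()].
#' @return List with `kept` and `removed` variant tables and `pvalues`, a
#'   per-site tibble (`variant_id`, genotype counts, `p`, `p_bonferroni`,
#'   `removed`).
#' @export
het_excess_filter <- function(calls, cfg = filter_config()) {
  sites <- site_table(calls)
  if (nrow(sites) == 0) {
    return(list(kept = calls, removed = calls[0, ],
                pvalues = tibble(variant_id = character(), p = numeric(),
                                 p_bonferroni = numeric(), removed = logical())))
  }
  m <- nrow(sites)
  ntot <- sites$n_hom_ref + sites$n_het + sites$n_hom_alt
  p <- rep(1.0, m)                        # fully missing sites: nothing to test
  if (any(ntot > 0)) {
    p[ntot > 0] <- het_excess_pvalue(sites$n_hom_ref[ntot > 0],
                                     sites$n_het[ntot > 0],
                                     sites$n_hom_alt[ntot > 0])
  }
  pv <- tibble(
    variant_id = variant_id(sites$chrom, sites$pos),
    n_hom_ref = sites$n_hom_ref, n_het = sites$n_het, n_hom_alt = sites$n_hom_alt,
    p = p, p_bonferroni = pmin(p * m, 1), removed = p * m < cfg$het_excess_alpha
  )
  ids <- variant_id(calls$chrom, calls$pos)
  removed_ids <- pv$variant_id[pv$removed]
  list(kept = calls[!ids %in% removed_ids, ],
       removed = calls[ids %in% removed_ids, ],
       pvalues = pv)
}

#' Amplicon-level filter after the heterozygote-excess stage
#'
#' False heterozygotes from paralog co-amplification cluster on the affected
#' amplicons. An amplicon fails when the fraction of its variants removed by
#' the heterozygote-excess filter exceeds `amplicon_fail_fraction`; every
#' variant on any failing amplicon (union semantics for variants covered by
#' two tiled amplicons) is then removed.
#'
#' @param calls Variant table of the sites that entered the
#'   heterozygote-excess stage (kept and removed alike).
#' @param removed_ids `chrom:pos` keys removed by [het_excess_filter()].
#' @param panel An [ampli_panel()] with amplicons.
#' @param cfg A [filter_config()].
#' @return List: `extra_removed_ids` (keys newly removed by this filter) and
#'   `amplicon_stats` (per-amplicon variant counts, removed fraction, fail
#'   flag).
#' @export
amplicon_fail_filter <- function(calls, removed_ids, panel, cfg = filter_config()) {
  sites <- distinct(calls, .data$chrom, .data$pos)
  ids <- variant_id(sites$chrom, sites$pos)
  hits <- assign_to_amplicons(sites$chrom, sites$pos, panel)
  map <- tibble(variant_id = rep(ids, lengths(hits)),
                amplicon_id = unlist(hits) %||% character(0))
  stats <- map |>
    group_by(.data$amplicon_id) |>
    summarise(n_variants = n(),
              n_removed_het = sum(.data$variant_id %in% removed_ids),
              .groups = "drop") |>
    mutate(fraction_removed = .data$n_removed_het / .data$n_variants,
           fails = .data$fraction_removed > cfg$amplicon_fail_fraction)
  failing <- stats$amplicon_id[stats$fails]
  on_failing <- unique(map$variant_id[map$amplicon_id %in% failing])
  list(extra_removed_ids = setdiff(on_failing, removed_ids),
       amplicon_stats = stats)
}

#' Drop variants with excessive missing calls
#'
#' @param calls A variant table.
#' @param max_missing Maximum tolerated missing-call fraction; variants
#'   strictly above it are dropped (exactly at the boundary is kept).
#' @return The filtered variant table.
#' @export
missingness_filter <- function(calls, max_missing = 0.50) {
  keep <- calls |>
    group_by(.data$chrom, .data$pos) |>
    summarise(miss = mean(is.na(.data$gt)), .groups = "drop") |>
    filter(.data$miss <= max_missing)
  semi_join(calls, keep, by = c("chrom", "pos"))
}

#' Flag novel variants
#'
#' A variant is novel when it is absent from the known-variant key set, its
#' minor-allele frequency (over non-missing calls) is at least
#' `novel_maf_min`, and the minor allele is carried by at least
#' `novel_min_carriers` distinct samples.
#'
#' @param calls A variant table.
#' @param known Character vector of known-variant keys (see
#'   [variant_keys()]).
#' @param cfg A [filter_config()].
#' @param by Key dialect passed to [variant_keys()].
#' @return Per-site tibble with `key`, `maf`, `n_carriers`, `known`,
#'   `novel`.
#' @export
classify_novel <- function(calls, known, cfg = filter_config(),
                           by = c("site_allele", "position")) {
  by <- match.arg(by)
  per_site <- calls |>
    filter(!is.na(.data$gt)) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(
      p_alt = mean(.data$gt) / 2,
      n_carriers_alt = sum(.data$gt > 0),
      n_carriers_ref = sum(.data$gt < 2),
      .groups = "drop"
    ) |>
    mutate(
      maf = pmin(.data$p_alt, 1 - .data$p_alt),
      n_carriers = if_else(.data$p_alt <= 0.5, .data$n_carriers_alt,
                           .data$n_carriers_ref)
    )
  per_site$key <- vapply(seq_len(nrow(per_site)), function(i) {
    variant_keys(per_site[i, ], by = by)
  }, character(1))
  per_site |>
    mutate(known = .data$key %in% known,
           novel = !.data$known & .data$maf >= cfg$novel_maf_min &
             .data$n_carriers >= cfg$novel_min_carriers) |>
    select("key", "chrom", "pos", "ref", "alt", "maf", "n_carriers",
           "known", "novel")
}

#' Probability of sequencing an allele at least k times
#'
#' For a heterozygous genotype sequenced to a given depth, the number of
#' reads from one homologous chromosome is Binomial(depth, 1/2). This
#' returns P(X >= min_reads) — e.g. at depth 12 there is a 99.7% chance of
#' sequencing either homolog at least twice, the justification for the
#' genotype depth threshold of 12.
#'
#' @param depth Read depth (vectorized).
#' @param min_reads Required read support.
#' @param allele_prob Per-read probability of the allele (1/2 for a
#'   heterozygote).
#' @return Numeric vector of probabilities.
#' @examples
#' binomial_min_reads_prob(12, 2) # 0.99683...
#' @export
binomial_min_reads_prob <- function(depth, min_reads = 2L, allele_prob = 0.5) {
  if (any(min_reads < 0)) abort("`min_reads` must be >= 0.")
  if (any(depth < 0)) abort("`depth` must be >= 0.")
  pbinom(min_reads - 1, depth, allele_prob, lower.tail = FALSE)
}

#' Coverage summary over the covered design space
#'
#' Computes the standard targeted-sequencing coverage table: mean coverage,
#' the percentage of covered bases at or above each depth threshold, the
#' percentage with zero coverage, and (when read assignments are given) the
#' percentage of reads on target.
#'
#' @param depth_track Either a numeric vector of per-base depths or a tibble
#'   with a `depth` column and a `length` (or `end` - `start`) weight column
#'   giving how many bases each row represents.
#' @param reads_on_target,reads_off_target Optional read counts.
#' @param thresholds Depth thresholds for the "percent of bases at >= kX"
#'   columns.
#' @return One-row tibble: `mean_coverage`, `pct_zero`, `pct_at_<k>x`
#'   columns, and `pct_on_target` (NA when read counts are absent).
#' @export
coverage_summary <- function(depth_track, reads_on_target = NULL,
                             reads_off_target = NULL,
                             thresholds = c(2, 10, 12, 20, 30)) {
  if (is.data.frame(depth_track)) {
    depth <- depth_track$depth
    w <- if ("length" %in% names(depth_track)) {
      depth_track$length
    } else if (all(c("start", "end") %in% names(depth_track))) {
      depth_track$end - depth_track$start
    } else {
      rep(1, length(depth))
    }
  } else {
    depth <- depth_track
    w <- rep(1, length(depth))
  }
  if (length(depth) == 0) abort("Empty depth track.")
  reads_on_target <- reads_on_target %||% attr(depth_track, "reads_on_target")
  reads_off_target <- reads_off_target %||% attr(depth_track, "reads_off_target")
  tot <- sum(w)
  out <- tibble(
    mean_coverage = sum(depth * w) / tot,
    pct_zero = 100 * sum(w[depth == 0]) / tot
  )
  for (k in thresholds) {
    out[[paste0("pct_at_", k, "x")]] <- 100 * sum(w[depth >= k]) / tot
  }
  out$pct_on_target <- if (!is.null(reads_on_target) && !is.null(reads_off_target)) {
    100 * reads_on_target / (reads_on_target + reads_off_target)
  } else {
    NA_real_
  }
  out
}

#' Run the full variant QC cascade
#'
#' Applies the filters in their fixed order: indel / multi-allelic / site
#' QUAL-QD -> genotype depth mask -> heterozygote-excess exact test with
#' Bonferroni correction -> amplicon-level filter -> (optionally) the
#' missingness filter used before population-genetic analysis. Every input
#' variant appears exactly once in the per-variant fate table.
#'
#' @param calls A variant table.
#' @param panel Optional [ampli_panel()]; without it the amplicon-level
#'   stage is skipped.
#' @param cfg A [filter_config()].
#' @param missingness Apply the missingness stage (default FALSE; it is a
#'   population-genetics pre-filter, not part of the call-set definition).
#' @return An object of class `filter_report`: `calls` (the surviving
#'   variant table, depth-masked), `fate` (per-variant tibble: variant_id,
#'   fate kept/dropped, stage, reason), `stage_counts`, `het_pvalues`,
#'   `amplicon_stats`, `config`.
#' @export
filter_variants <- function(calls, panel = NULL, cfg = filter_config(),
                            missingness = FALSE) {
  calls <- variant_table(calls)
  all_ids <- unique(variant_id(calls$chrom, calls$pos))
  fate <- tibble(variant_id = all_ids, fate = "kept",
                 stage = NA_character_, reason = NA_character_)
  mark <- function(fate, ids, stage, reason) {
    hit <- fate$variant_id %in% ids & fate$fate == "kept"
    fate$fate[hit] <- "dropped"
    fate$stage[hit] <- stage
    fate$reason[hit] <- reason
    fate
  }
  counts <- list()
  note <- function(stage, n_in, n_drop) {
    tibble(stage = stage, n_in = n_in, n_dropped = n_drop, n_out = n_in - n_drop)
  }

  # stage 1: site-level (indel, multiallelic, QUAL, QD)
  sf <- site_filter(calls, cfg)
  sf$variant_id <- variant_id(sf$chrom, sf$pos)
  for (rsn in unique(stats::na.omit(sf$reason))) {
    fate <- mark(fate, sf$variant_id[!sf$keep & sf$reason == rsn], "site", rsn)
  }
  counts$site <- note("site", length(all_ids), sum(!sf$keep))
  keep_ids <- sf$variant_id[sf$keep]
  cur <- calls[variant_id(calls$chrom, calls$pos) %in% keep_ids, ]

  # stage 2: genotype depth mask (cell-level; drops no variants)
  cur <- genotype_depth_mask(cur, cfg)
  counts$depth_mask <- note("depth_mask", length(keep_ids), 0L)

  # stage 3: heterozygote-excess exact test, Bonferroni over sites tested
  het <- het_excess_filter(cur, cfg)
  removed_het <- het$pvalues$variant_id[het$pvalues$removed]
  fate <- mark(fate, removed_het, "het_excess", "excess_heterozygosity")
  counts$het_excess <- note("het_excess", length(keep_ids), length(removed_het))

  # stage 4: amplicon-level filter over the same site family
  extra <- character(0)
  amp_stats <- NULL
  if (!is.null(panel) && !is.null(panel$amplicons)) {
    af <- amplicon_fail_filter(cur, removed_het, panel, cfg)
    extra <- af$extra_removed_ids
    amp_stats <- af$amplicon_stats
    fate <- mark(fate, extra, "amplicon", "failing_amplicon")
  }
  counts$amplicon <- note("amplicon", counts$het_excess$n_out, length(extra))
  cur_ids <- setdiff(keep_ids, c(removed_het, extra))
  cur <- cur[variant_id(cur$chrom, cur$pos) %in% cur_ids, ]

  # stage 5 (popgen-only): missingness
  if (missingness) {
    kept <- missingness_filter(cur, cfg$popgen_max_missing)
    dropped_miss <- setdiff(unique(variant_id(cur$chrom, cur$pos)),
                            unique(variant_id(kept$chrom, kept$pos)))
    fate <- mark(fate, dropped_miss, "missingness", "high_missingness")
    counts$missingness <- note("missingness", length(cur_ids), length(dropped_miss))
    cur <- kept
  }

  structure(list(calls = cur, fate = fate,
                 stage_counts = bind_rows(counts),
                 het_pvalues = het$pvalues,
                 amplicon_stats = amp_stats,
                 config = cfg),
            class = "filter_report")
}

#' @method print filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", sum(x$fate$fate == "kept"), "/", nrow(x$fate),
      " variants kept\n", sep = "")
  print(x$stage_counts)
  invisible(x)
}

#' Write a filter report
#'
#' @param report A `filter_report`.
#' @param path_tsv Per-variant fate table destination (TSV).
#' @param path_json Optional JSON summary destination.
#' @return `report`, invisibly.
#' @export
write_filter_report <- function(report, path_tsv, path_json = NULL) {
  utils::write.table(report$fate, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(stage_counts = report$stage_counts,
           n_kept = sum(report$fate$fate == "kept"),
           n_dropped = sum(report$fate$fate == "dropped")),
      path_json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}
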