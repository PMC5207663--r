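---
title: "Amplicon-panel QC, trio accuracy and population genetics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon-panel QC, trio accuracy and population genetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliqc)
library(dplyr)
```

`ampliqc` analyses variant calls from highly multiplexed PCR panels
(amplicon target enrichment followed by high-depth sequencing) in diverse,
outcrossing plant germplasm. This vignette documents the models and
estimators it implements, the design choices behind the defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions used throughout.

## Coordinates and data model

All genomic intervals are half-open with 0-based starts (the BED
convention), so an interval's length is `end - start` and a position `p`
lies inside `[start, end)` iff `start <= p < end`. This is the only
convention under which a design-coverage table whose start/end columns must
reproduce its "total targeted bases" column is self-consistent, and it
makes region, amplicon and variant arithmetic uniform. Variant positions
are stored 0-based internally; the VCF reader and writer shift by one at
the boundary. Whether a given panel's published coordinates are 0- or
1-based against the reference assembly is generally not recoverable from
the table itself — only the length convention is — so `read_bed()` takes an
explicit `one_based` flag and otherwise takes input as-is.

Calls live in a long tibble, one row per (site, sample): site fields
(`chrom`, `pos`, `ref`, `alt`, `qual`, `qd`) and call fields (`sample`,
`gt` as alt-allele dosage 0/1/2/NA, `dp`). Dosage coding is sufficient
because the QC cascade reduces the data to biallelic SNPs before any
genotype-based analysis; multi-allelic records are dropped with their own
reason code rather than decomposed, the simplest rule that preserves an
audit trail.

## The QC cascade

Filters run in a fixed, logged order; each variant appears exactly once in
the fate table with the first reason that removed it:

1. **indel / multi-allelic** — only biallelic SNPs proceed. Indels are the
   dominant error mode of semiconductor sequencing (homopolymer over- and
   under-calls), so they are removed unconditionally.
2. **site quality** — keep iff `QUAL > 30` and `QD > 5`, strict
   inequalities. A site with no QD annotation is dropped as `missing_qd`
   (conservative: QD is the evidence the threshold is about).
3. **genotype depth mask** — calls with `DP < 12` become missing; the depth
   value itself is preserved. The threshold's rationale is binomial: at
   depth 12, the probability that each homologous chromosome of a
   heterozygote is sequenced at least twice is
   `binomial_min_reads_prob(12, 2)` = 0.9968 ≈ 99.7%. Published
   descriptions of this working point waver between "depth of 12" and
   "greater than 12"; the package defaults to `DP >= 12` (the binomial
   argument is phrased for 12 itself) with a strict mode available.
4. **heterozygote excess** — for each site, the exact one-sided p-value of
   the observed heterozygote count under Hardy–Weinberg equilibrium,
   conditional on the allele counts:
   P(h | n, n_A) = n! / (n_AA! h! n_aa!) · 2^h · n_A! n_a! / (2n)!,
   summed over all h' ≥ h with the parity of n_A. Sites with
   p · m < 0.01 are removed, where m is the number of sites entering this
   stage (the Bonferroni family is the tested family, not the pre-filter
   input). Only excess is tested: a heterozygote *deficit* is expected
   under inbreeding and is never filtered. The implementation sums the
   direct formula in log space; the test suite checks it against an
   independent enumeration oracle for every genotype configuration with
   n ≤ 20 at 1e-12.
5. **amplicon-level filter** — paralog co-amplification affects whole
   amplicons, not single sites, so an amplicon fails when more than 15% of
   its variants were removed by stage 4, and then *all* its variants are
   removed. A variant lying in the overlap of two tiled amplicons is
   removed if *any* covering amplicon fails (union semantics,
   conservative).
6. **missingness** (population-genetics pre-filter only) — variants with
   more than 50% missing calls are dropped; exactly 50% is kept. This
   stage defines the marker set for diversity estimation, not the call-set
   itself, so `filter_variants()` applies it only on request and
   `run_pipeline()` applies it before the popgen stage.

Stages 1–3 and 6 are idempotent. Stage 4 is idempotent only up to its
Bonferroni denominator: re-running it on its own output shrinks m and can
tip borderline sites, which is why the cascade runs it exactly once.

## Trio heterozygote metrics

An F1 of two fully homozygous inbreds is heterozygous precisely where its
parents carry opposite alleles, giving internal truth for heterozygote
calling. A site is *informative* when all three trio members are called.
Sensitivity is estimated over informative sites whose parents are called
opposite homozygotes; sites where either parent is itself called
heterozygous are excluded from that denominator, because a heterozygous
call in an inbred is itself suspect (it is the signature of paralog
co-amplification) — but an F1 heterozygote call at such a site still counts
against precision, since false positives concentrate exactly there.
Precision is the fraction of F1 heterozygote calls (at informative sites)
whose parents are opposite homozygotes. Empty denominators yield `NA`,
never 0 or 1. Whether sites with missing parent calls belong in the
precision denominator is a genuinely open convention; excluding them (the
informative-site rule) is the package's documented choice.

## Population-genetic estimators

Per biallelic locus, with r populations, sample sizes n_i, alt-allele
frequencies p_i and observed heterozygosities Ho_i (ñ = harmonic mean of
n_i):

* Nei–Chesser unbiased within-population diversity
  Hs = ñ/(ñ−1) · (1 − mean(p_i² + q_i²) − Ho/(2ñ)), total diversity
  Ht = 1 − (p̄² + q̄²) + Hs/(ñr) − Ho/(2ñr) with unweighted p̄, and
  F_IS = 1 − Ho/Hs.
* Weir–Cockerham variance components a (among populations), b (among
  individuals within populations) and c (within individuals), with
  θ = a/(a+b+c); across loci θ is the ratio of summed components, the
  standard combination (a mean of per-locus ratios would be badly behaved
  at weakly informative loci).

Both F_ST flavours are reported side by side — θ as the default headline
estimator and Nei's (Ht−Hs)/Ht because "total gene diversity" is Nei's Ht —
since field reports rarely say which one a number is. Overall Ho/Hs/Ht are
across-locus means with monomorphic loci contributing zero diversity;
F_ST ratios are taken over loci polymorphic in the pooled sample. The
per-locus unbiased estimates are noisy in both directions, so Hs ≤ Ht is
guaranteed only for the across-locus means on differentiated data, which is
what the tests assert. A single population makes F_ST undefined (`NA` with
a warning), not zero.

Identity-by-state distances use d(i,j) = mean over pairwise-complete loci
of (1 − shared_alleles/2) = mean |g_i − g_j| / 2, with the per-pair
shared-locus count attached; a pair with no shared locus is `NA`, signalled
by a warning. Classical (Torgerson) MDS — double-centering of −d²/2
followed by the spectral decomposition, delegated to `stats::cmdscale` —
returns the top-k coordinates (default k = 2, the usual relationship plot)
under a deterministic sign convention: on each axis the largest-magnitude
loading is positive, so repeated runs and platforms agree. If fewer than k
positive eigenvalues exist, the output is reduced with a warning.

## The synthetic-data generator

`simulate_study()` emulates the validation design of an amplicon-panel
study of outcrossing landraces: 19 accessions × 5 plants, three inbred
lines (the first reference-like, i.e. hom-ref everywhere), and two F1
hybrids sharing the reference line as one parent. Defaults are the study
conditions the acceptance checks run under, chosen once:

* **Structure** — ancestral frequencies uniform on (0.05, 0.95);
  population frequencies Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F) with
  F = 0.27, so E(freq) = p and Var = F·p(1−p); within-accession genotypes
  at HWE with f = 0.02 (heterozygote probability 2p(1−p)(1−f)) — strong
  differentiation and near-panmixia within accessions, as reported for
  maize landraces.
* **Depth** — negative binomial with mean 105 (the panel's observed
  per-genotype coverage) and dispersion 0.3, a realistic overdispersion
  for multiplexed PCR; amplicon length bias is deliberately absent, since
  read counts per amplicon show little relationship with amplicon length
  in such panels.
* **Dropout** — each (sample, amplicon) pair drops out with probability
  0.15, reflecting the ~17% per-sample zero-coverage fraction typical of
  these designs (priming-site variation, presence/absence variation).
* **Errors** — per-read allele flips at 0.003, of which a third hit the
  specific alternate allele. With the read-support calling rule
  (heterozygote iff each allele has ≥ 2 reads; majority homozygote
  otherwise; missing below depth 2, and a 1/1 depth-2 tie is ambiguous
  hence missing), this yields a ~0.1% false-het rate per homozygous cell
  at 105×. The calling rule mirrors the binomial depth argument above; the
  upstream callers themselves are out of scope.
* **QUAL/QD** — Normal(60, 18) and Normal(12, 4.25) truncated at zero, so
  ~5% of sites fall below each site-filter threshold and the cascade is
  actually exercised.
* **Paralog co-amplification** — chosen amplicons carry a co-amplifying
  paralog modelled as a duplication absent from the reference line: every
  other sample is a carrier (`paralog_lineages = "auto"`). At each site of
  those amplicons the paralog diverges with probability 0.5 (panels do not
  report this fraction; it is a free parameter, not an empirical claim),
  and a contaminated cell's reads are a 50/50 mixture of target and
  paralog alleles — the minimal mechanism that forces heterozygous calls
  clustered by amplicon and lineage, reproducing the artifact the
  excess-het and amplicon filters exist for.
* **Panel** — 20 regions around 4.3 kb tiled by 83–339 bp amplicons in two
  pools with a 17% tiling-gap rate, giving design coverage in the
  mid-80% range like real relaxed-specificity designs.

All randomness flows from one root seed through named substreams
(panel, loci, frequencies, genotypes, dropout, depths, reads, QUAL/QD), so
identical configurations give byte-identical VCF output and individual
stages are independently reproducible.

**What the generator does not emulate:** read sequences and base-quality
strings (no FASTQ), flow-space homopolymer errors, alignment and mapping
ambiguity, caller-specific genotype likelihoods, linkage between nearby
loci (sites are drawn independently), allele-frequency ascertainment from
reference-based primer design, and structural variation beyond whole-
amplicon dropout. Tests passing on synthetic data therefore validate the
*statistics and filters* under a known generative model — they do not
certify caller accuracy on real reads, and the published headline accuracy
values of any particular study depend on its reads and callers and are not
reproduced here.

## Problem sizes and tolerances

The test suite and the acceptance script run the full study geometry
(19 × 5 landraces + controls, 960 loci) for parameter recovery — five
independent seeds, each required to land within ±0.05 of the simulated
F_ST = 0.27 and F_IS = 0.02 — and reduced geometries (4 accessions,
120 loci) for unit tests, a scale at which every behaviour is already
expressed. Exact-test agreement with enumeration is required at 1e-12 over
all genotype configurations with n ≤ 20; MDS must reproduce planted
Euclidean geometry at 1e-8. The paralog scenario places the paralog on the
two amplicons carrying the most variants, which makes the artifact's
clustering visible to the 15% amplicon rule at the default divergence; its
acceptance check asserts the qualitative contract — precision strictly
improves, sensitivity unchanged — rather than a tuned magnitude, because
borderline contaminated sites can legitimately survive a Bonferroni-
corrected exact test.

## Known limitations

* The Bonferroni family for the excess-het test is per filtered call set;
  analyses that pool call sets from several callers should decide whether
  the family spans callers (it is not specified by convention).
* `classify_novel()` keys on (chrom, pos, ref, alt-set) by default;
  position-only matching is available but blurs multi-allelic sites.
* IBS distances use pairwise-complete loci, so with pathological
  missingness patterns the distance matrix need not be Euclidean; classical
  MDS then truncates negative eigenvalues (reported in `eig`).
* The generator draws loci independently; any analysis sensitive to LD
  decay needs a different simulator.
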