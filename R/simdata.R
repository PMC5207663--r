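#' Configuration for the synthetic amplicon-panel study
#'
#' The generator emulates a targeted-resequencing validation panel: a set of
#' outcrossing landrace accessions with strong differentiation among them,
#' a few fully homozygous inbred lines (the first doubling as the reference
#' line, i.e. carrying no alternate alleles), their F1 hybrids as
#' heterozygote truth controls, and the artifact modes of multiplexed PCR
#' enrichment — per-(sample, amplicon) dropout and paralog co-amplification
#' that forces clustered false-heterozygote calls in the lineages carrying
#' the paralog.
#'
#' Defaults are the study conditions the package is tested under:
#' 19 accessions x 5 plants, 960 loci, differentiation `fst = 0.27`,
#' within-accession inbreeding `fis = 0.02`, mean genotype depth 105 with
#' negative-binomial overdispersion 0.3, 15% amplicon dropout, 20%
#' off-target reads, and QUAL/QD samplers calibrated so roughly 5% of sites
#' fall below the QUAL 30 and QD 5 thresholds.
#'
#' @param n_populations,n_plants_per_population Landrace structure.
#' @param inbreds Character ids of inbred lines; the first is the
#'   reference-like line (all hom-ref) when `reference_inbred` is TRUE.
#' @param f1_crosses List of length-2 character vectors of parent ids.
#' @param n_loci Number of segregating sites to place on the panel.
#' @param fst Differentiation parameter F of the Balding–Nichols model,
#'   in [0, 1).
#' @param fis Within-population inbreeding coefficient in [-1, 1].
#' @param ancestral_freq_sampler Function n -> ancestral allele frequencies.
#' @param mean_depth,depth_dispersion Negative-binomial depth model
#'   (variance = mu + dispersion * mu^2).
#' @param dropout_prob Per-(sample, amplicon) probability of total dropout.
#' @param base_error Per-read allele-flip probability.
#' @param off_target_rate Fraction of a sample's reads mapping off target.
#' @param paralog_amplicons Amplicon ids carrying a co-amplifying paralog
#'   (NULL for a clean simulation).
#' @param paralog_lineages Sample ids whose DNA carries the paralog; `"auto"`
#'   selects every sample except the reference inbred (the paralog is
#'   modelled as a duplication absent from the reference line).
#' @param paralog_divergence Probability that the paralog differs from the
#'   target at a given site on a paralog amplicon.
#' @param qual_sampler,qd_sampler Functions n -> site QUAL / QD values.
#' @param reference_inbred Force the first inbred to be all hom-ref.
#' @param seed Root seed; every stage derives a named substream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 19L,
                       n_plants_per_population = 5L,
                       inbreds = c("P1", "P2", "P3"),
                       f1_crosses = list(c("P1", "P2"), c("P1", "P3")),
                       n_loci = 960L,
                       fst = 0.27,
                       fis = 0.02,
                       ancestral_freq_sampler = function(n) runif(n, 0.05, 0.95),
                       mean_depth = 105,
                       depth_dispersion = 0.3,
                       dropout_prob = 0.15,
                       base_error = 0.003,
                       off_target_rate = 0.20,
                       paralog_amplicons = NULL,
                       paralog_lineages = "auto",
                       paralog_divergence = 0.5,
                       qual_sampler = function(n) pmax(rnorm(n, 60, 18), 0.1),
                       qd_sampler = function(n) pmax(rnorm(n, 12, 4.25), 0.1),
                       reference_inbred = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(fst = fst, dropout_prob = dropout_prob, base_error = base_error,
             off_target_rate = off_target_rate,
             paralog_divergence = paralog_divergence)
  if (any(probs < 0 | probs > 1)) abort("All rate parameters must lie in [0, 1].")
  if (fst >= 1) abort("`fst` must be in [0, 1).")
  if (fis < -1 || fis > 1) abort("`fis` must lie in [-1, 1].")
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  structure(cfg, class = "sim_config")
}

# Named RNG substream: each simulation stage reseeds from the root seed and
# a stage label, so stages are reproducible independently of one another.
substream_seed <- function(seed, name) {
  u <- utf8ToInt(name)
  (as.integer(seed) + sum(u * seq_along(u)) * 131L) %% .Machine$integer.max
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, name))
  force(code)
}

#' Simulate a synthetic amplicon panel
#'
#' Builds a panel in the image of a multiplexed PCR design: regions of a few
#' kb tiled by short amplicons (~263 bp, range 83–339) split into two primer
#' pools, with tiling gaps so the design covers only part of each region.
#'
#' @param n_regions Number of target regions.
#' @param mean_region_bp Mean region length (bp).
#' @param amplicon_bp_range Min/max amplicon length (bp).
#' @param gap_prob Probability that a tiling step leaves a gap (uncovered
#'   design space), emulating primers that could not be placed.
#' @param seed Integer seed.
#' @return An [ampli_panel()] whose regions carry design-coverage columns.
#' @export
simulate_panel <- function(n_regions = 20L, mean_region_bp = 4300,
                           amplicon_bp_range = c(83L, 339L),
                           gap_prob = 0.17, seed = 1L) {
  with_substream(seed, "panel", {
    regions <- vector("list", n_regions)
    amplicons <- vector("list", n_regions)
    aid <- 0L
    for (r in seq_len(n_regions)) {
      chrom <- paste0("chr", 1L + (r - 1L) %% 10L)
      len <- max(600L, as.integer(round(rnorm(1, mean_region_bp, mean_region_bp / 4))))
      start <- as.integer(sample.int(2e8, 1L))
      end <- start + len
      covered <- integer(0)
      cur <- start
      amps <- list()
      while (cur < end - amplicon_bp_range[1]) {
        alen <- as.integer(round(runif(1, amplicon_bp_range[1], amplicon_bp_range[2])))
        if (runif(1) < gap_prob) { # primer placement failed: skip ahead
          cur <- cur + alen
          next
        }
        aid <- aid + 1L
        a_end <- min(cur + alen, end)
        amps[[length(amps) + 1L]] <- tibble(
          amplicon_id = sprintf("AMP%04d", aid), chrom = chrom,
          start = cur, end = a_end, pool = 1L + aid %% 2L
        )
        covered <- c(covered, a_end - cur)
        # small overlap between consecutive amplicons, as tiled designs have
        cur <- a_end - as.integer(round(runif(1, 0, 30)))
        if (cur >= a_end) cur <- a_end
      }
      amps <- bind_rows(amps)
      cov_bp <- if (nrow(amps)) {
        # union of amplicon intervals clipped to the region
        o <- amps[order(amps$start), ]
        tot <- 0L; hi <- start
        for (i in seq_len(nrow(o))) {
          s <- max(o$start[i], hi); e <- min(o$end[i], end)
          if (e > s) { tot <- tot + (e - s); hi <- e }
        }
        tot
      } else 0L
      regions[[r]] <- tibble(
        region = sprintf("REG%02d", r), chrom = chrom, start = start, end = end,
        n_amplicons = nrow(amps), targeted_bases = len, covered_bases = cov_bp,
        fraction_covered = round(cov_bp / len, 3)
      )
      amplicons[[r]] <- amps
    }
    ampli_panel(bind_rows(regions), bind_rows(amplicons))
  })
}

#' Balding–Nichols population allele frequencies
#'
#' Draws population-specific frequencies around ancestral frequencies `p`
#' from Beta(p(1-F)/F, (1-p)(1-F)/F), so that E(freq) = p and
#' Var(freq) = F p (1-p) — the expected differentiation among populations
#' is F. `F = 0` returns `p` unchanged for every population.
#'
#' @param p Ancestral allele frequency vector (values strictly in (0,1)).
#' @param fst Differentiation parameter F in [0, 1).
#' @param n_populations Number of populations.
#' @param seed Optional seed (set by the caller's substream otherwise).
#' @return Matrix n_populations x length(p) of frequencies.
#' @export
simulate_population_frequencies <- function(p, fst, n_populations, seed = NULL) {
  if (fst < 0 || fst >= 1) abort("`fst` must lie in [0, 1).")
  if (any(p <= 0 | p >= 1)) abort("Ancestral frequencies must lie in (0, 1).")
  if (!is.null(seed)) set.seed(seed)
  L <- length(p)
  if (fst == 0) {
    return(matrix(rep(p, each = n_populations), nrow = n_populations))
  }
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  matrix(rbeta(n_populations * L, rep(a, each = n_populations),
               rep(b, each = n_populations)),
         nrow = n_populations)
}

#' Genotypes for one outcrossing accession
#'
#' Draws plant genotypes given the accession's allele frequencies with
#' within-accession inbreeding `fis`: heterozygote probability
#' 2p(1-p)(1-fis), homozygote probabilities p^2 + fis p(1-p) and the
#' symmetric term.
#'
#' @param freqs Allele frequency vector over loci (values in [0, 1]).
#' @param n_plants Number of plants to draw.
#' @param fis Inbreeding coefficient in [-1, 1].
#' @param seed Optional seed.
#' @return Integer matrix n_plants x loci of alt dosages.
#' @export
simulate_accession_genotypes <- function(freqs, n_plants, fis = 0, seed = NULL) {
  if (fis < -1 || fis > 1) abort("`fis` must lie in [-1, 1].")
  if (any(freqs < 0 | freqs > 1)) abort("Frequencies must lie in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  p <- rep(freqs, each = n_plants)
  p_het <- pmax(2 * p * (1 - p) * (1 - fis), 0)
  p_homalt <- p^2 + fis * p * (1 - p)
  u <- runif(n_plants * L)
  g <- ifelse(u < p_homalt, 2L, ifelse(u < p_homalt + p_het, 1L, 0L))
  matrix(as.integer(g), nrow = n_plants)
}

#' Fully homozygous inbred line
#'
#' One allele is drawn per locus from the given frequencies and doubled.
#'
#' @param freqs Allele frequency vector.
#' @param seed Optional seed.
#' @return Integer dosage vector (0 or 2 at every locus).
#' @export
make_inbred <- function(freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  2L * rbinom(length(freqs), 1L, freqs)
}

#' Cross two parents into an F1
#'
#' The F1 receives one allele from each parent per locus. With fully
#' homozygous parents the cross is deterministic: opposite homozygotes give
#' a heterozygous F1 with certainty. A heterozygous "inbred" parent triggers
#' a warning and a random gamete.
#'
#' @param parent1,parent2 Integer dosage vectors over the same loci.
#' @param seed Optional seed (only consumed if a parent is heterozygous).
#' @return Integer dosage vector for the F1.
#' @export
cross_f1 <- function(parent1, parent2, seed = NULL) {
  if (length(parent1) != length(parent2)) abort("Parents must share a locus set.")
  if (any(parent1 == 1L) || any(parent2 == 1L)) {
    warn("Heterozygous parent passed to cross_f1(); drawing random gametes at heterozygous loci.")
  }
  if (!is.null(seed)) set.seed(seed)
  gamete <- function(g) {
    out <- as.integer(g >= 1L)           # 0 -> 0, 2 -> 1
    het <- which(g == 1L)
    if (length(het)) out[het] <- rbinom(length(het), 1L, 0.5)
    out
  }
  gamete(parent1) + gamete(parent2)
}

#' Simulate a full panel study with known truth
#'
#' Runs the whole generative model: panel (unless supplied), locus placement
#' on amplicons, Balding–Nichols population frequencies, landrace / inbred /
#' F1 genotypes, and the sequencing layer ([simulate_calls()]).
#'
#' @param config A [sim_config()].
#' @param panel Optional [ampli_panel()]; simulated from the config seed
#'   otherwise.
#' @return A list of class `ampli_sim`: `panel`, `loci`, `truth` (genotype
#'   matrix, population frequencies, dropout mask, contaminated cells),
#'   `calls` (variant table), `depth` (per sample x amplicon track),
#'   `sample_sheet`, `config`.
#' @export
simulate_study <- function(config = sim_config(), panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  if (is.null(panel)) panel <- simulate_panel(seed = seed)
  amp <- panel$amplicons
  if (is.null(amp) || nrow(amp) == 0) abort("Panel has no amplicons to place loci on.")

  # --- loci placed uniformly over the amplicon-covered space -------------
  loci <- with_substream(seed, "loci", {
    w <- amp$end - amp$start
    idx <- sample.int(nrow(amp), config$n_loci, replace = TRUE, prob = w)
    pos <- amp$start[idx] + floor(runif(config$n_loci) * w[idx])
    l <- tibble(chrom = amp$chrom[idx], pos = as.integer(pos),
                amplicon_id = amp$amplicon_id[idx])
    l <- distinct(l, .data$chrom, .data$pos, .keep_all = TRUE)
    while (nrow(l) < config$n_loci) {      # top up collisions
      k <- config$n_loci - nrow(l)
      idx <- sample.int(nrow(amp), k, replace = TRUE, prob = w)
      pos <- amp$start[idx] + floor(runif(k) * w[idx])
      l <- distinct(bind_rows(l, tibble(chrom = amp$chrom[idx],
                                        pos = as.integer(pos),
                                        amplicon_id = amp$amplicon_id[idx])),
                    .data$chrom, .data$pos, .keep_all = TRUE)
    }
    l <- arrange(l, .data$chrom, .data$pos)
    bases <- c("A", "C", "G", "T")
    l$ref <- sample(bases, nrow(l), replace = TRUE)
    l$alt <- vapply(l$ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    l
  })

  # --- population frequencies and genotypes ------------------------------
  p_anc <- with_substream(seed, "ancestral", config$ancestral_freq_sampler(config$n_loci))
  p_anc <- pmin(pmax(p_anc, 1e-6), 1 - 1e-6)
  pop_freqs <- with_substream(seed, "frequencies",
    simulate_population_frequencies(p_anc, config$fst, config$n_populations))
  pop_ids <- sprintf("A%02d", seq_len(config$n_populations))
  rownames(pop_freqs) <- pop_ids

  geno <- list(); sheet <- list()
  with_substream(seed, "genotypes", {
    for (i in seq_len(config$n_populations)) {
      g <- simulate_accession_genotypes(pop_freqs[i, ], config$n_plants_per_population,
                                        config$fis)
      ids <- sprintf("%s_p%d", pop_ids[i], seq_len(config$n_plants_per_population))
      rownames(g) <- ids
      geno[[length(geno) + 1L]] <- g
      sheet[[length(sheet) + 1L]] <- tibble(sample = ids, population = pop_ids[i],
                                             class = "landrace",
                                             parent1 = NA_character_, parent2 = NA_character_)
    }
    inb <- matrix(0L, nrow = length(config$inbreds), ncol = config$n_loci,
                  dimnames = list(config$inbreds, NULL))
    for (j in seq_along(config$inbreds)) {
      inb[j, ] <- if (j == 1L && config$reference_inbred) {
        rep(0L, config$n_loci)
      } else {
        make_inbred(p_anc)
      }
    }
    geno[[length(geno) + 1L]] <- inb
    sheet[[length(sheet) + 1L]] <- tibble(sample = config$inbreds,
                                           population = config$inbreds,
                                           class = "inbred",
                                           parent1 = NA_character_, parent2 = NA_character_)
    if (length(config$f1_crosses)) {
      f1 <- t(vapply(config$f1_crosses, function(pr) {
        cross_f1(inb[pr[1], ], inb[pr[2], ])
      }, integer(config$n_loci)))
      f1_ids <- vapply(config$f1_crosses, function(pr) paste(pr, collapse = "x"),
                       character(1))
      rownames(f1) <- f1_ids
      geno[[length(geno) + 1L]] <- f1
      sheet[[length(sheet) + 1L]] <- tibble(sample = f1_ids, population = f1_ids,
                                             class = "f1",
                                             parent1 = vapply(config$f1_crosses, `[`, "", 1L),
                                             parent2 = vapply(config$f1_crosses, `[`, "", 2L))
    }
  })
  genotypes <- do.call(rbind, geno)
  sample_sheet <- bind_rows(sheet)

  # --- paralog scenario ---------------------------------------------------
  # "auto": the paralog is a duplication absent from the reference line
  # (presence/absence variation), so every sample except the reference
  # inbred co-amplifies it and shows clustered heterozygous calls at
  # divergent sites — the cohort-wide signature the excess-het filter keys on.
  paralog_lineages <- config$paralog_lineages
  if (!is.null(config$paralog_amplicons) && identical(paralog_lineages, "auto")) {
    ref_line <- if (config$reference_inbred) config$inbreds[1] else character(0)
    paralog_lineages <- setdiff(sample_sheet$sample, ref_line)
  }
  if (identical(paralog_lineages, "auto")) paralog_lineages <- character(0)

  truth <- list(
    genotypes = genotypes,
    loci = loci,
    population_freqs = pop_freqs,
    sample_sheet = sample_sheet,
    paralog_amplicons = config$paralog_amplicons %||% character(0),
    paralog_lineages = paralog_lineages
  )
  class(truth) <- "truth_set"

  sim <- simulate_calls(truth, panel, config)
  structure(list(panel = panel, loci = loci, truth = sim$truth, calls = sim$calls,
                 depth = sim$depth, sample_sheet = sample_sheet, config = config),
            class = "ampli_sim")
}

#' Sequencing layer: depths, read errors, dropout, paralog contamination
#'
#' Turns true genotypes into a called variant table. Per (sample, locus)
#' cell, depth is negative-binomial (zero under amplicon dropout), alt read
#' counts are binomial given the genotype with `base_error` flips, and the
#' genotype is re-called from read support: heterozygote when each allele
#' has >= 2 supporting reads, majority homozygote otherwise, missing below
#' depth 2 (a 1/1 depth-2 tie is ambiguous and is set missing). Cells on
#' paralog amplicons in paralog-carrying lineages read as a 50/50 mixture of
#' target and paralog DNA at divergent sites, which forces heterozygous
#' calls there. Site QUAL and QD come from the configured samplers.
#'
#' @param truth A `truth_set` (see [simulate_study()]).
#' @param panel The [ampli_panel()] the loci live on.
#' @param config A [sim_config()].
#' @return List: `calls` (variant table), `depth` (per sample x amplicon
#'   tibble with on/off-target read counts as attributes), `truth` (the
#'   input truth augmented with `dropout_mask` and `contaminated` matrices).
#' @export
simulate_calls <- function(truth, panel, config) {
  loci <- truth$loci
  g <- truth$genotypes
  S <- nrow(g); L <- ncol(g)
  stopifnot(L == nrow(loci))
  amp <- panel$amplicons
  if (!all(loci$amplicon_id %in% amp$amplicon_id)) {
    abort("Some loci are not placed on panel amplicons.")
  }
  samples <- rownames(g)
  seed <- config$seed

  # depth per (sample, amplicon): the track used for coverage summaries;
  # per-cell genotype depths are drawn from the same model independently
  amp_ids <- amp$amplicon_id
  A <- length(amp_ids)
  size <- 1 / config$depth_dispersion
  dropout <- with_substream(seed, "dropout",
    matrix(runif(S * A) < config$dropout_prob, nrow = S,
           dimnames = list(samples, amp_ids)))
  depth_track <- with_substream(seed, "amplicon-depth", {
    d <- matrix(rnbinom(S * A, mu = config$mean_depth, size = size), nrow = S,
                dimnames = list(samples, amp_ids))
    d[dropout] <- 0L
    d
  })

  amp_of_locus <- match(loci$amplicon_id, amp_ids)
  cell_drop <- dropout[, amp_of_locus, drop = FALSE]
  dp <- with_substream(seed, "depths", {
    d <- matrix(rnbinom(S * L, mu = config$mean_depth, size = size), nrow = S)
    d[cell_drop] <- 0L
    d
  })

  # paralog contamination: divergent sites on paralog amplicons, carrier samples
  divergent <- with_substream(seed, "paralog",
    loci$amplicon_id %in% truth$paralog_amplicons &
      runif(L) < config$paralog_divergence)
  carrier <- samples %in% truth$paralog_lineages
  contaminated <- outer(carrier, divergent, `&`)

  calls_gt <- with_substream(seed, "reads", {
    # only a third of base-call errors hit the specific alternate allele
    e_alt <- config$base_error / 3
    q <- matrix(c(e_alt, 0.5, 1 - e_alt)[g + 1L], nrow = S)
    # 50/50 target/paralog mixture; the paralog carries the alt allele
    q[contaminated] <- 0.5 * q[contaminated] + 0.5 * (1 - config$base_error)
    nalt <- matrix(rbinom(S * L, as.vector(dp), as.vector(q)), nrow = S)
    nref <- dp - nalt
    called <- matrix(NA_integer_, S, L)
    het <- nalt >= 2L & nref >= 2L
    called[het] <- 1L
    hom_alt <- !het & dp >= 2L & nalt > nref
    hom_ref <- !het & dp >= 2L & nref > nalt
    called[hom_alt] <- 2L
    called[hom_ref] <- 0L
    called
  })

  qual <- with_substream(seed, "qual", config$qual_sampler(L))
  qd <- with_substream(seed, "qd", config$qd_sampler(L))

  calls <- tibble(
    chrom = rep(loci$chrom, each = S),
    pos = rep(loci$pos, each = S),
    ref = rep(loci$ref, each = S),
    alt = rep(loci$alt, each = S),
    qual = rep(round(qual, 2), each = S),
    qd = rep(round(qd, 2), each = S),
    sample = rep(samples, times = L),
    gt = as.integer(calls_gt),
    dp = as.integer(dp)
  )
  calls <- variant_table(arrange(calls, .data$chrom, .data$pos, .data$sample))

  depth_tbl <- tibble(
    sample = rep(samples, times = A),
    amplicon_id = rep(amp_ids, each = S),
    length = rep(amp$end - amp$start, each = S),
    depth = as.integer(depth_track)
  )
  reads_on <- round(sum(as.numeric(depth_track) *
                          rep(amp$end - amp$start, each = S)) / 200)
  reads_off <- round(reads_on * config$off_target_rate / (1 - config$off_target_rate))
  attr(depth_tbl, "reads_on_target") <- reads_on
  attr(depth_tbl, "reads_off_target") <- reads_off

  truth$dropout_mask <- cell_drop
  truth$contaminated <- contaminated
  dimnames(truth$contaminated) <- list(samples, variant_id(loci$chrom, loci$pos))
  dimnames(truth$dropout_mask) <- dimnames(truth$contaminated)
  colnames(truth$genotypes) <- variant_id(loci$chrom, loci$pos)

  list(calls = calls, depth = depth_tbl, truth = truth)
}

#' @method print ampli_sim
#' @export
print.ampli_sim <- function(x, ...) {
  cat("<ampli_sim> ", nrow(x$sample_sheet), " samples x ", nrow(x$loci),
      " loci (seed ", x$config$seed, ")\n", sep = "")
  cat("  classes: ", paste(names(table(x$sample_sheet$class)),
                           table(x$sample_sheet$class),
                           sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write simulation artifacts to disk
#'
#' Emits the study as standard files: VCF of calls, BED of loci and
#' amplicons, TSV sample sheet and truth tables.
#'
#' @param sim An `ampli_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_variant_vcf(sim$calls, file.path(dir, "calls.vcf"))
  utils::write.table(sim$loci[c("chrom", "pos")] |>
                       mutate(end = .data$pos + 1L),
                     file.path(dir, "loci.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$panel$amplicons[c("chrom", "start", "end", "amplicon_id")],
                     file.path(dir, "amplicons.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$sample_sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tg <- as_tibble(sim$truth$genotypes, rownames = "sample")
  utils::write.table(tg, file.path(dir, "truth_genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
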