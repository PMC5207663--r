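# Build a long-format variant table from a dosage matrix (samples x loci).
calls_from_matrix <- function(g, chrom = "chr1", pos = NULL, qual = 50, qd = 10,
                              dp = 30, ref = "A", alt = "T") {
  S <- nrow(g); L <- ncol(g)
  if (is.null(pos)) pos <- seq_len(L) * 10L
  samples <- if (is.null(rownames(g))) paste0("S", seq_len(S)) else rownames(g)
  variant_table(tibble::tibble(
    chrom = rep(chrom, S * L),
    pos = rep(as.integer(pos), each = S),
    ref = rep(rep_len(ref, L), each = S),
    alt = rep(rep_len(alt, L), each = S),
    qual = rep(rep_len(qual, L), each = S),
    qd = rep(rep_len(qd, L), each = S),
    sample = rep(samples, times = L),
    gt = as.integer(g),
    dp = rep_len(as.integer(dp), S * L)
  ))
}

# A small, quick study configuration for unit tests (full scale is reserved
# for the acceptance checks).
small_config <- function(...) {
  sim_config(n_populations = 4L, n_plants_per_population = 5L, n_loci = 120L,
             ...)
}

small_panel <- function(seed = 1L) {
  simulate_panel(n_regions = 6L, mean_region_bp = 2000, seed = seed)
}

# Expensive simulations shared between test files, built once per run.
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- fn()
  .sim_cache[[key]]
}

clean_noiseless_sim <- function() {
  cached("clean", function() {
    simulate_study(sim_config(base_error = 0, dropout_prob = 0, seed = 1))
  })
}

paralog_sim <- function() {
  cached("paralog", function() {
    panel <- simulate_panel(seed = 1)
    base <- simulate_study(sim_config(base_error = 0, seed = 1), panel = panel)
    top2 <- names(sort(table(base$loci$amplicon_id), decreasing = TRUE))[1:2]
    simulate_study(sim_config(base_error = 0, paralog_amplicons = top2, seed = 1),
                   panel = panel)
  })
}

pooled_precision <- function(tm) {
  sum(tm$n_f1_het_with_polymorphic_parents) / sum(tm$n_f1_het_calls)
}
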