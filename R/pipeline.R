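#' Assemble a pipeline run configuration
#'
#' One flat configuration object drives [run_pipeline()]. Exactly one of
#' `vcf` (a path or a variant table) and `sim` (a [sim_config()]) must be
#' given: the pipeline either analyses an existing call set or generates a
#' synthetic study with known truth.
#'
#' @param vcf Path to a VCF, or a variant table tibble, or NULL.
#' @param sim A [sim_config()], or NULL.
#' @param panel An [ampli_panel()], a path to a region TSV (read with
#'   [read_panel_regions()]), or NULL (simulation supplies its own panel).
#' @param sample_sheet Tibble (or TSV path) with `sample`, `population`,
#'   `class`, `parent1`, `parent2`; taken from the simulation when NULL.
#' @param known_variants Character vector of known-variant keys, or a VCF
#'   path to derive them from, or NULL.
#' @param filter A [filter_config()].
#' @param run_trio,run_popgen,run_mds Stage toggles.
#' @param mds_k MDS dimensions.
#' @param out_dir Output directory (NULL: return the report only).
#' @param seed Root seed; overrides `sim$seed` when a simulation is run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, sim = NULL, panel = NULL,
                       sample_sheet = NULL, known_variants = NULL,
                       filter = filter_config(),
                       run_trio = TRUE, run_popgen = TRUE, run_mds = TRUE,
                       mds_k = 2L, out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a run configuration
#'
#' Violations are returned, not raised, so a caller can report all of them
#' at once.
#'
#' @param config A [run_config()].
#' @return Tibble with `field` and `problem` columns; zero rows when valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, problem) tibble(field = field, problem = problem)
  n_inputs <- (!is.null(config$vcf)) + (!is.null(config$sim))
  if (n_inputs != 1) {
    v[[length(v) + 1]] <- bad("vcf/sim", "exactly one of `vcf` and `sim` must be provided")
  }
  for (f in c("vcf", "panel", "sample_sheet")) {
    x <- config[[f]]
    if (is.character(x) && length(x) == 1 && !file.exists(x)) {
      v[[length(v) + 1]] <- bad(f, paste0("file does not exist: ", x))
    }
  }
  fc <- config$filter
  if (!inherits(fc, "filter_config")) {
    chk <- tryCatch(do.call(filter_config, fc), error = function(e) conditionMessage(e))
    if (is.character(chk)) v[[length(v) + 1]] <- bad("filter", chk)
  }
  if (!is.null(config$sim) && !inherits(config$sim, "sim_config")) {
    v[[length(v) + 1]] <- bad("sim", "`sim` must be a sim_config object")
  }
  sheet <- config$sample_sheet
  if (is.data.frame(sheet) && all(c("sample", "class", "parent1", "parent2") %in% names(sheet))) {
    f1s <- sheet[sheet$class == "f1", ]
    missing_parents <- setdiff(stats::na.omit(c(f1s$parent1, f1s$parent2)), sheet$sample)
    if (length(missing_parents)) {
      v[[length(v) + 1]] <- bad("sample_sheet",
                                paste0("F1 parents absent from sheet: ",
                                       paste(missing_parents, collapse = ", ")))
    }
  }
  if (length(v)) bind_rows(v) else tibble(field = character(), problem = character())
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> panel summary -> QC filter cascade -> trio
#' heterozygote metrics (before and after the excess-heterozygosity and
#' amplicon filters) -> novel-variant classification -> population-genetic
#' statistics and MDS. Stages run in the fixed cascade order; a stage
#' failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report` with elements `panel_summary`,
#'   `filter` (a `filter_report`), `coverage`, `trio` (before/after
#'   tibbles), `novel`, `popgen`, `mds`, `provenance` and, for simulated
#'   input, `sim`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  viol <- validate_config(config)
  if (nrow(viol)) {
    abort(paste0("Invalid configuration:\n",
                 paste0("- ", viol$field, ": ", viol$problem, collapse = "\n")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  report <- list()

  # --- input --------------------------------------------------------------
  sim <- NULL
  if (!is.null(config$sim)) {
    sc <- config$sim
    sc$seed <- config$seed %||% sc$seed
    panel <- if (inherits(config$panel, "ampli_panel")) config$panel else NULL
    sim <- stage("simulate", simulate_study(sc, panel = panel))
    calls <- sim$calls
    panel <- sim$panel
    sheet <- sim$sample_sheet
    report$sim <- sim
  } else {
    calls <- stage("load", {
      if (is.character(config$vcf)) read_variant_vcf(config$vcf) else variant_table(config$vcf)
    })
    panel <- config$panel
    if (is.character(panel)) panel <- ampli_panel(read_panel_regions(panel))
    sheet <- config$sample_sheet
    if (is.character(sheet)) sheet <- as_tibble(read.delim(sheet))
  }

  # --- panel summary -------------------------------------------------------
  if (!is.null(panel)) {
    report$panel_summary <- stage("panel-summary", panel_summary(panel))
  }
  if (!is.null(sim)) {
    report$coverage <- stage("coverage", coverage_summary(sim$depth))
  }

  # --- QC cascade ----------------------------------------------------------
  report$filter <- stage("filter",
    filter_variants(calls, panel = panel, cfg = config$filter))
  filtered <- report$filter$calls

  # --- trio evaluation -----------------------------------------------------
  if (isTRUE(config$run_trio) && !is.null(sheet) && any(sheet$class == "f1")) {
    report$trio <- stage("trio-eval", {
      before <- trio_het_metrics_all(
        genotype_depth_mask(calls, config$filter), sheet)
      after <- trio_het_metrics_all(filtered, sheet)
      list(before_het_filters = before, after_het_filters = after)
    })
  }

  # --- novel variants ------------------------------------------------------
  if (!is.null(config$known_variants)) {
    known <- config$known_variants
    if (is.character(known) && length(known) == 1 && file.exists(known)) {
      known <- variant_keys(site_table(read_variant_vcf(known)))
    }
    report$novel <- stage("novel", classify_novel(filtered, known, config$filter))
  }

  # --- population genetics -------------------------------------------------
  if (isTRUE(config$run_popgen) && !is.null(sheet)) {
    report$popgen <- stage("popgen", {
      pg_calls <- missingness_filter(filtered, config$filter$popgen_max_missing)
      pop_basic_stats(pg_calls, sheet)
    })
    if (isTRUE(config$run_mds)) {
      report$mds <- stage("mds", {
        pg_calls <- missingness_filter(filtered, config$filter$popgen_max_missing)
        classical_mds(ibs_distance_matrix(pg_calls), k = config$mds_k)
      })
    }
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  report$provenance <- list(
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ampliqc"))
  )
  report <- structure(report, class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> (config ", substr(x$provenance$config_hash, 1, 8), ", seed ",
      x$provenance$seed %||% NA, ")\n", sep = "")
  if (!is.null(x$panel_summary)) {
    cat(sprintf("  panel: %d regions, %d / %d bp covered (%.1f%%)\n",
                x$panel_summary$n_regions, x$panel_summary$total_covered_bp,
                x$panel_summary$total_targeted_bp,
                100 * x$panel_summary$overall_fraction))
  }
  if (!is.null(x$filter)) {
    cat("  filter: ", sum(x$filter$fate$fate == "kept"), "/", nrow(x$filter$fate),
        " variants kept\n", sep = "")
  }
  if (!is.null(x$trio)) {
    a <- x$trio$after_het_filters
    cat(sprintf("  trio (post-filter): sensitivity %s, precision %s\n",
                paste(round(a$sensitivity, 3), collapse = "/"),
                paste(round(a$precision, 3), collapse = "/")))
  }
  if (!is.null(x$popgen)) {
    o <- x$popgen$overall
    cat(sprintf("  popgen: Ht %.3f, Fst(WC) %.3f, Fis %.3f\n", o$ht, o$fst_wc, o$fis))
  }
  invisible(x)
}

#' Write all pipeline artifacts
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$panel_summary)) {
    jsonlite::write_json(as.list(report$panel_summary),
                         file.path(dir, "panel_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$filter)) {
    write_filter_report(report$filter, file.path(dir, "filter_fate.tsv"),
                        file.path(dir, "filter_summary.json"))
    write_variant_vcf(report$filter$calls, file.path(dir, "filtered.vcf"))
  }
  if (!is.null(report$trio)) {
    utils::write.table(bind_rows(before = report$trio$before_het_filters,
                                 after = report$trio$after_het_filters,
                                 .id = "when"),
                       file.path(dir, "trio_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$novel)) {
    utils::write.table(report$novel, file.path(dir, "novel_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$popgen)) write_popgen_stats(report$popgen, dir)
  if (!is.null(report$mds)) {
    utils::write.table(report$mds$points, file.path(dir, "mds_coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
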