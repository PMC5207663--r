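#' Length of a half-open genomic interval
#'
#' All intervals in this package follow the BED convention: 0-based start,
#' exclusive end, so that length equals `end - start`. This is the only
#' convention under which published amplicon-panel coverage tables are
#' self-consistent (start/end columns versus "total targeted bases").
#'
#' @param start,end Integer coordinate vectors, `end >= start` elementwise.
#' @return Integer vector of interval lengths in base pairs.
#' @examples
#' interval_length(90221947, 90224841) # 2894
#' @export
interval_length <- function(start, end) {
  if (length(start) != length(end)) {
    abort("`start` and `end` must have the same length.")
  }
  if (any(end < start)) {
    abort("Invalid interval: `end` must be >= `start`.")
  }
  as.integer(end - start)
}

#' Fraction of a target region covered by the amplicon design
#'
#' @param covered,targeted Integer base counts; `targeted` must be positive
#'   and `0 <= covered <= targeted`.
#' @param digits If non-NULL, round (half-to-even, as in base R) to this many
#'   decimals for tabular display. Default `NULL` returns the full fraction.
#' @return Numeric vector of coverage fractions.
#' @examples
#' region_coverage_fraction(4520, 5007, digits = 3) # 0.903
#' @export
region_coverage_fraction <- function(covered, targeted, digits = NULL) {
  if (any(targeted <= 0)) {
    abort("Degenerate region: `targeted` must be > 0.")
  }
  if (any(covered < 0 | covered > targeted)) {
    abort("`covered` must lie in [0, targeted].")
  }
  frac <- covered / targeted
  if (!is.null(digits)) frac <- round(frac, digits)
  frac
}

#' Assemble an amplicon panel
#'
#' A panel bundles the target regions (the intervals the design was asked to
#' cover) with the amplicons that tile them. Regions with duplicated names
#' are allowed (one gene may be split into several design intervals) and are
#' keyed internally by (region, start).
#'
#' @param regions Tibble with columns `region`, `chrom`, `start`, `end` and
#'   optionally `targeted_bases`, `covered_bases`, `fraction_covered`,
#'   `n_amplicons`. Missing `targeted_bases` is filled from the interval
#'   length.
#' @param amplicons Optional tibble with columns `amplicon_id`, `chrom`,
#'   `start`, `end`, `pool` (1 or 2).
#' @param max_amplicon_length Plausibility bound on amplicon length (bp).
#' @return An object of class `ampli_panel`.
#' @export
ampli_panel <- function(regions, amplicons = NULL, max_amplicon_length = 1000L) {
  regions <- as_tibble(regions)
  req <- c("region", "chrom", "start", "end")
  if (!all(req %in% names(regions))) {
    abort(paste0("`regions` must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(regions) == 0) abort("Empty panel: no regions.")
  len <- interval_length(regions$start, regions$end)
  if (!"targeted_bases" %in% names(regions)) regions$targeted_bases <- len
  if (any(regions$targeted_bases != len)) {
    abort("`targeted_bases` inconsistent with end - start.")
  }
  if (!"covered_bases" %in% names(regions)) regions$covered_bases <- len
  if (any(regions$covered_bases < 0 | regions$covered_bases > regions$targeted_bases)) {
    abort("`covered_bases` must lie in [0, targeted_bases].")
  }
  if (anyDuplicated(regions[c("region", "start")])) {
    abort("Region keys (region, start) must be unique.")
  }
  if (!is.null(amplicons)) {
    amplicons <- as_tibble(amplicons)
    reqa <- c("amplicon_id", "chrom", "start", "end", "pool")
    if (!all(reqa %in% names(amplicons))) {
      abort(paste0("`amplicons` must have columns: ", paste(reqa, collapse = ", ")))
    }
    alen <- interval_length(amplicons$start, amplicons$end)
    if (any(alen > max_amplicon_length)) {
      abort("Amplicon longer than `max_amplicon_length`.")
    }
    if (!all(amplicons$pool %in% c(1L, 2L))) abort("`pool` must be 1 or 2.")
    if (anyDuplicated(amplicons$amplicon_id)) abort("Amplicon ids must be unique.")
  }
  structure(list(regions = regions, amplicons = amplicons), class = "ampli_panel")
}

#' @method print ampli_panel
#' @export
print.ampli_panel <- function(x, ...) {
  s <- panel_summary(x)
  cat("<ampli_panel> ", s$n_regions, " regions, ",
      if (is.null(x$amplicons)) 0L else nrow(x$amplicons), " amplicons\n", sep = "")
  cat("  targeted: ", s$total_targeted_bp, " bp; covered by design: ",
      s$total_covered_bp, " bp (", round(100 * s$overall_fraction, 1), "%)\n", sep = "")
  invisible(x)
}

#' Read a panel region table
#'
#' Reads the packaged tab-separated mirror of a design-coverage table
#' (columns: region, chrom, start, end, n_amplicons, targeted_bases,
#' covered_bases, fraction_covered), or any TSV with at least the first four.
#'
#' @param path Path to the TSV. Defaults to the packaged 20-region maize
#'   photoperiod-candidate panel.
#' @return A tibble of regions.
#' @export
read_panel_regions <- function(path = system.file("extdata", "panel_regions.tsv",
                                                  package = "ampliqc")) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a BED interval file
#'
#' @param path Path to a 3+ column BED file (chrom, start, end, name...).
#' @param one_based If TRUE the file uses 1-based inclusive coordinates and
#'   starts are shifted down by one on input.
#' @return Tibble with columns chrom, start, end and (if present) name.
#' @export
read_bed <- function(path, one_based = FALSE) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name"
  if (one_based) bed$start <- bed$start - 1L
  as_tibble(bed[, 1:min(4, ncol(bed))])
}

#' Panel-wide design-coverage summary
#'
#' Column sums and means over the region table: how much of the requested
#' target space the amplicon design actually covers.
#'
#' @param panel An `ampli_panel`, or a region tibble as accepted by
#'   [ampli_panel()].
#' @return One-row tibble: `n_regions`, `total_targeted_bp`,
#'   `total_covered_bp`, `overall_fraction`, `mean_targeted_bp`,
#'   `mean_covered_bp`.
#' @examples
#' panel_summary(read_panel_regions())
#' @export
panel_summary <- function(panel) {
  regions <- if (inherits(panel, "ampli_panel")) panel$regions else ampli_panel(panel)$regions
  tibble(
    n_regions = nrow(regions),
    total_targeted_bp = sum(regions$targeted_bases),
    total_covered_bp = sum(regions$covered_bases),
    overall_fraction = sum(regions$covered_bases) / sum(regions$targeted_bases),
    mean_targeted_bp = sum(regions$targeted_bases) / nrow(regions),
    mean_covered_bp = sum(regions$covered_bases) / nrow(regions)
  )
}

#' Amplicons containing a position
#'
#' Returns the ids of every amplicon whose half-open interval contains the
#' query position (`start <= pos < end`), sorted by id. Positions falling in
#' the overlap of two tiled amplicons map to both.
#'
#' @param chrom,pos Query position (vectors recycle to common length).
#' @param panel An `ampli_panel` with amplicons.
#' @return A list (one element per query) of character vectors of amplicon
#'   ids; empty vector where no amplicon contains the position.
#' @export
assign_to_amplicons <- function(chrom, pos, panel) {
  amp <- panel$amplicons
  if (is.null(amp)) abort("Panel has no amplicons.")
  nq <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, nq)
  pos <- rep_len(pos, nq)
  q <- tibble(.q = seq_len(nq), chrom = chrom, pos = pos)
  hits <- inner_join(q, amp, by = "chrom", relationship = "many-to-many")
  hits <- filter(hits, .data$start <= .data$pos, .data$pos < .data$end)
  hits <- arrange(hits, .data$.q, .data$amplicon_id)
  out <- rep(list(character(0)), nq)
  if (nrow(hits)) {
    sp <- split(hits$amplicon_id, hits$.q)
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Serialize a panel summary
#'
#' @param panel An `ampli_panel` or region tibble.
#' @param path Output path; format by extension (`.json` or `.tsv`).
#' @return The summary tibble, invisibly.
#' @export
write_panel_summary <- function(panel, path) {
  s <- panel_summary(panel)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(s), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(s)
}
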