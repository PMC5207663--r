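#' Long-format variant call table
#'
#' The central container of the package is an ordinary tibble in long format,
#' one row per (site, sample) call, with the columns
#'
#' * `chrom`, `pos` — site location; `pos` is 0-based so that interval
#'   membership uses the same half-open convention as the panel (BED) files.
#'   VCF readers/writers convert to and from 1-based positions.
#' * `ref`, `alt` — alleles; `alt` may hold several comma-separated alleles
#'   for multi-allelic records (which the QC cascade drops).
#' * `qual`, `qd` — site quality (QUAL) and quality-by-depth (INFO:QD);
#'   `qd` may be `NA` where the caller did not emit it.
#' * `sample` — sample id.
#' * `gt` — alt-allele dosage: 0 (hom ref), 1 (het), 2 (hom alt), `NA`
#'   (missing). Only meaningful for biallelic records.
#' * `dp` — per-genotype read depth (FORMAT:DP).
#'
#' `variant_table()` validates a tibble against this contract.
#'
#' @param calls A data frame with the columns above.
#' @return The validated tibble (invisibly classed as written).
#' @export
variant_table <- function(calls) {
  calls <- as_tibble(calls)
  req <- c("chrom", "pos", "ref", "alt", "qual", "sample", "gt", "dp")
  miss <- setdiff(req, names(calls))
  if (length(miss)) {
    abort(paste0("variant table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"qd" %in% names(calls)) calls$qd <- NA_real_
  if (any(calls$dp < 0, na.rm = TRUE)) abort("`dp` must be >= 0.")
  if (any(!calls$gt %in% c(0L, 1L, 2L, NA))) abort("`gt` must be 0, 1, 2 or NA.")
  if (any(stats::na.omit(calls$qual) < 0)) abort("`qual` must be >= 0.")
  calls
}

#' Per-site view of a variant table
#'
#' @param calls A variant table (see [variant_table()]).
#' @return Tibble with one row per site: chrom, pos, ref, alt, qual, qd,
#'   plus genotype counts over non-missing calls (`n_hom_ref`, `n_het`,
#'   `n_hom_alt`, `n_missing`, `n_samples`).
#' @export
site_table <- function(calls) {
  calls |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$qual, .data$qd) |>
    summarise(
      n_hom_ref = sum(.data$gt == 0L, na.rm = TRUE),
      n_het = sum(.data$gt == 1L, na.rm = TRUE),
      n_hom_alt = sum(.data$gt == 2L, na.rm = TRUE),
      n_missing = sum(is.na(.data$gt)),
      n_samples = n(),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$pos)
}

#' Genotype dosage matrix
#'
#' @param calls A variant table.
#' @return Integer matrix, samples x sites, of alt dosages with `NA` for
#'   missing; column names are `chrom:pos` keys.
#' @export
gt_matrix <- function(calls) {
  calls <- mutate(calls, .id = variant_id(.data$chrom, .data$pos))
  wide <- tidyr::pivot_wider(
    select(calls, ".id", "sample", "gt"),
    names_from = ".id", values_from = "gt"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- wide$sample
  m
}

#' Is a record a single-nucleotide variant?
#'
#' A site is a SNP iff the ref allele and every alt allele have length 1.
#' @param ref,alt Character vectors (alt possibly comma-separated).
#' @return Logical vector.
#' @export
is_snp <- function(ref, alt) {
  one <- function(a) all(nchar(strsplit(a, ",", fixed = TRUE)[[1]]) == 1L)
  nchar(ref) == 1L & vapply(alt, one, logical(1), USE.NAMES = FALSE)
}

is_multiallelic <- function(alt) grepl(",", alt, fixed = TRUE)

#' Read a VCF into a variant table
#'
#' Uses `vcfR` to parse, then flattens GT (as alt dosage) and DP per sample,
#' QUAL and INFO:QD per site. Positions are shifted to the package's 0-based
#' convention.
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @return A variant table tibble.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  dosage <- function(g) {
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_integer_)
      sum(a != "0")
    }, integer(1))
  }
  samples <- colnames(gt_raw)
  n_site <- nrow(fix)
  out <- tibble(
    chrom = rep(fix$CHROM, times = length(samples)),
    pos = rep(as.integer(fix$POS) - 1L, times = length(samples)),
    ref = rep(fix$REF, times = length(samples)),
    alt = rep(fix$ALT, times = length(samples)),
    qual = rep(suppressWarnings(as.numeric(fix$QUAL)), times = length(samples)),
    qd = rep(qd, times = length(samples)),
    sample = rep(samples, each = n_site),
    gt = as.integer(dosage(as.vector(gt_raw))),
    dp = as.integer(as.vector(dp))
  )
  variant_table(out)
}

#' Write a variant table as VCF 4.2
#'
#' Emits the dialect the rest of the package consumes: QUAL and INFO:QD per
#' site, GT:DP per sample, biallelic dosage genotypes. Positions are written
#' 1-based.
#'
#' @param calls A variant table.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  sites <- site_table(calls)
  samples <- sort(unique(calls$sample))
  gt_chr <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- mutate(calls,
    .id = variant_id(.data$chrom, .data$pos),
    .cell = paste0(if_else(is.na(.data$gt), "./.", gt_chr[as.character(.data$gt)]),
                   ":", if_else(is.na(.data$dp), ".", as.character(.data$dp)))
  )
  wide <- tidyr::pivot_wider(select(calls, ".id", "sample", ".cell"),
                             names_from = "sample", values_from = ".cell")
  wide <- wide[match(variant_id(sites$chrom, sites$pos), wide$.id), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ampliqc",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  info <- if_else(is.na(sites$qd), ".", paste0("QD=", format(sites$qd, trim = TRUE)))
  body <- paste(sites$chrom, sites$pos + 1L, ".", sites$ref, sites$alt,
                format(sites$qual, trim = TRUE), "PASS", info, "GT:DP",
                sep = "\t")
  cell_cols <- as.matrix(wide[, samples, drop = FALSE])
  body <- paste(body, apply(cell_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Canonical variant keys
#'
#' Builds the matching keys used for variant-set comparison: either
#' site+allele keys (`chrom:pos:ref>alt`, alt alleles sorted) or plain
#' position keys (`chrom:pos`).
#'
#' @param sites A tibble with `chrom`, `pos`, and (for allele keys) `ref`,
#'   `alt` columns; a full variant table also works.
#' @param by `"site_allele"` (default) or `"position"`.
#' @return Character vector of unique keys (duplicates collapse).
#' @export
variant_keys <- function(sites, by = c("site_allele", "position")) {
  by <- match.arg(by)
  sites <- distinct(as_tibble(sites),
                    dplyr::pick(dplyr::any_of(c("chrom", "pos", "ref", "alt"))))
  if (by == "position") {
    return(unique(variant_id(sites$chrom, sites$pos)))
  }
  alt_sorted <- vapply(strsplit(sites$alt, ",", fixed = TRUE),
                       function(a) paste(sort(a), collapse = ","), character(1))
  unique(paste0(variant_id(sites$chrom, sites$pos), ":", sites$ref, ">", alt_sorted))
}
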