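#' Write a haplotype panel to a VCFv4.2 file
#'
#' Phased GT records, one biallelic SNV per site; internal 0-based positions
#' become 1-based VCF POS. Alleles are written as REF=A, ALT=C placeholders
#' (the panel is binary).
#'
#' @param panel a phased `pp_panel`
#' @param path output path (.vcf, plain text)
#' @param chrom chromosome name to write
#' @return `path`, invisibly
#' @export
write_vcf <- function(panel, path, chrom = "1") {
  if (!isTRUE(panel$phased))
    stop_pp("cannot write haplotypes from an unphased panel", "pyrenpop_phase_error")
  n <- length(panel$sample_ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       as.integer(panel$sequence_length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t")),
             con)
  if (length(panel$positions)) {
    h1 <- panel$haplotypes[seq(1, 2 * n, 2), , drop = FALSE]
    h2 <- panel$haplotypes[seq(2, 2 * n, 2), , drop = FALSE]
    gts <- matrix(paste0(h1, "|", h2), n)  # samples x sites
    rec <- paste(chrom, as.integer(panel$positions) + 1L, ".", "A", "C", ".",
                 ".", ".", "GT",
                 apply(gts, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a VCF into a haplotype panel
#'
#' Only biallelic SNV records are used; others are skipped and the skip
#' count is reported in attribute `"n_skipped"` (and a message). Phased GT
#' is required unless `unphased_ok = TRUE`, in which case a dosage-only
#' object of class `pp_dosage` is returned; half-calls ("./1") and missing
#' genotypes become NA dosages.
#'
#' @param path VCF path (vcfR handles plain or gzipped)
#' @param region_map optional data.frame `sample_id`, `region`, `x_km`,
#'   `y_km` (see [read_sample_map()]); NULL gives region "NA" everywhere
#' @param unphased_ok allow unphased genotypes (dosage-only result)
#' @return a `pp_panel` (phased) or `pp_dosage` (unphased mode)
#' @export
read_vcf <- function(path, region_map = NULL, unphased_ok = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  # treat records with missing ALT as non-usable too
  n_skipped <- sum(!bi)
  if (n_skipped > 0) {
    message(sprintf("read_vcf: skipped %d non-biallelic record(s)", n_skipped))
    v <- v[bi, ]
  }
  fix <- vcfR::getFIX(v)
  pos <- as.numeric(fix[, "POS"]) - 1
  gt <- vcfR::extract.gt(v, element = "GT")  # sites x samples
  ids <- colnames(gt)
  n <- length(ids)
  labels <- rep(NA_character_, n)
  coords <- NULL
  if (!is.null(region_map)) {
    i <- match(ids, region_map$sample_id)
    if (anyNA(i)) stop_pp("sample(s) in VCF missing from region map",
                          "pyrenpop_validation_error")
    labels <- region_map$region[i]
    coords <- as.matrix(region_map[i, c("x_km", "y_km")])
  }
  phased <- !any(grepl("/", gt, fixed = TRUE), na.rm = TRUE)
  if (!phased && !unphased_ok)
    stop_pp("VCF contains unphased genotypes; pass unphased_ok=TRUE for dosage-only reading",
            "pyrenpop_phase_error")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  if (phased && !unphased_ok) {
    if (any(is.na(gt)) || any(a1 == ".") || any(a2 == "."))
      stop_pp("missing genotypes cannot be read as haplotypes",
              "pyrenpop_phase_error")
    h <- matrix(0L, 2 * n, length(pos))
    h[seq(1, 2 * n, 2), ] <- t(matrix(as.integer(a1), nrow(gt)))
    h[seq(2, 2 * n, 2), ] <- t(matrix(as.integer(a2), nrow(gt)))
    out <- new_panel(h, pos, ids, labels, coords)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  d1 <- suppressWarnings(as.integer(a1))
  d2 <- suppressWarnings(as.integer(a2))
  dos <- t(matrix(d1 + d2, nrow(gt)))  # NA wherever either allele missing
  rownames(dos) <- ids
  out <- structure(list(dosages = dos, positions = pos, sample_ids = ids,
                        region_labels = labels, coords = coords,
                        phased = FALSE),
                   class = "pp_dosage")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a sample-to-region map
#'
#' TSV with header `sample_id  region  x_km  y_km`.
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_sample_map <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "x_km", "y_km")
  if (!all(need %in% names(m)))
    stop_pp("sample map needs columns sample_id, region, x_km, y_km",
            "pyrenpop_validation_error")
  m
}

#' Write the sample map of a panel as TSV
#' @param panel a `pp_panel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sample_map <- function(panel, path) {
  m <- data.frame(sample_id = panel$sample_ids, region = panel$region_labels,
                  x_km = panel$coords[, 1], y_km = panel$coords[, 2])
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
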