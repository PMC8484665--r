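#' Construct a phased haplotype panel
#'
#' The universal genotype container: a 2N x L binary haplotype matrix with
#' strictly increasing 0-based bp positions, one pair of rows per diploid
#' sample, a region label and a planar (km) coordinate per sample.
#'
#' @param haplotypes integer matrix (2N x L) of 0/1 alleles; rows 2i-1, 2i
#'   are the two haplotypes of sample i
#' @param positions numeric vector of strictly increasing 0-based positions
#' @param sample_ids character vector of N sample names
#' @param region_labels character vector of N region labels
#' @param coords N x 2 numeric matrix of planar km coordinates (or NULL)
#' @param sequence_length total sequence length in bp
#' @param phased logical; FALSE marks a dosage-only panel (haplotype rows
#'   are then undefined and `dosages` must be supplied instead)
#' @return object of class `pp_panel`
#' @export
new_panel <- function(haplotypes, positions, sample_ids, region_labels,
                      coords = NULL, sequence_length = NULL, phased = TRUE) {
  n <- length(sample_ids)
  if (nrow(haplotypes) != 2L * n)
    stop_pp("need exactly 2 haplotype rows per sample", "pyrenpop_validation_error")
  if (ncol(haplotypes) != length(positions))
    stop_pp("positions length must match haplotype columns", "pyrenpop_validation_error")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop_pp("positions must be strictly increasing", "pyrenpop_validation_error")
  if (length(haplotypes) && !all(haplotypes %in% c(0L, 1L)))
    stop_pp("haplotype alleles must be 0/1", "pyrenpop_validation_error")
  if (length(region_labels) != n)
    stop_pp("one region label per sample required", "pyrenpop_validation_error")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2)
      stop_pp("coords must be N x 2", "pyrenpop_validation_error")
  }
  structure(list(
    haplotypes = haplotypes, positions = as.numeric(positions),
    sample_ids = as.character(sample_ids),
    region_labels = as.character(region_labels), coords = coords,
    sequence_length = sequence_length %||%
      (if (length(positions)) max(positions) + 1 else 0),
    phased = phased
  ), class = "pp_panel")
}

#' @export
print.pp_panel <- function(x, ...) {
  cat(sprintf("pp_panel: %d samples, %d sites, %s, %.3g bp\n",
              length(x$sample_ids), length(x$positions),
              if (x$phased) "phased" else "unphased", x$sequence_length))
  cat("regions:", paste(sprintf("%s=%d", names(table(x$region_labels)),
                                table(x$region_labels)), collapse = " "), "\n")
  invisible(x)
}

#' Diploid dosage matrix of a panel
#'
#' @param panel a `pp_panel`
#' @return N x L integer matrix of alternate-allele dosages in \{0,1,2\}
#' @export
panel_dosages <- function(panel) {
  h <- panel$haplotypes
  n <- length(panel$sample_ids)
  d <- h[seq(1, 2 * n, by = 2), , drop = FALSE] +
       h[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(d) <- panel$sample_ids
  d
}

#' Subset a panel to a set of samples
#' @param panel a `pp_panel`
#' @param idx integer or logical index over samples
#' @param drop_monomorphic drop sites monomorphic within the subset
#' @return a `pp_panel`
#' @export
panel_subset <- function(panel, idx, drop_monomorphic = FALSE) {
  idx <- seq_along(panel$sample_ids)[idx]
  hrows <- as.vector(rbind(2 * idx - 1, 2 * idx))
  h <- panel$haplotypes[hrows, , drop = FALSE]
  pos <- panel$positions
  if (drop_monomorphic && ncol(h)) {
    cs <- colSums(h)
    keep <- cs > 0 & cs < nrow(h)
    h <- h[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  new_panel(h, pos, panel$sample_ids[idx], panel$region_labels[idx],
            panel$coords[idx, , drop = FALSE], panel$sequence_length,
            panel$phased)
}

#' Per-sample coordinates from a region coordinate table
#' @param region_labels character vector of region labels
#' @param coords_table data.frame with `region`, `x_km`, `y_km`
#' @return N x 2 matrix
#' @export
coords_for <- function(region_labels, coords_table = region_coords()) {
  i <- match(region_labels, coords_table$region)
  if (anyNA(i)) stop_pp("region label without coordinates", "pyrenpop_validation_error")
  as.matrix(coords_table[i, c("x_km", "y_km")])
}
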