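#' Summary-statistic vector of a five-region panel
#'
#' Deterministic, fixed-ordering summary set for ABC: per-region normalized
#' folded SFS, per-region mean heterozygosity, the 10 pairwise Hudson FST
#' values, per-region mean HR in 3 coarse distance bins (0-50 kb, 50-200 kb,
#' 200-500 kb; sites thinned deterministically to at most `max_hr_sites`),
#' and per-region mean total RoH under scaled-down detection parameters
#' suited to Mb-scale panels. Undefined entries (monomorphic regions,
#' undefined FST) are encoded as 0 and listed in attribute `"flags"`.
#'
#' @param panel a `pp_panel` containing all five regions
#' @param max_hr_sites cap on sites entering the HR computation per region
#' @param roh_p RoH detection parameters for the RoH summaries
#' @return named numeric vector (fixed length and order given the region
#'   sample counts)
#' @export
summarize_panel <- function(panel, max_hr_sites = 200,
                            roh_p = roh_params(window_snvs = 25,
                                               max_het_per_window = 1,
                                               min_length_bp = 2e5,
                                               min_snvs = 25,
                                               max_gap_bp = 1e5)) {
  regs <- the_regions
  if (!all(regs %in% panel$region_labels))
    stop_pp("panel must contain all five regions", "pyrenpop_validation_error")
  d <- panel_dosages(panel)
  flags <- character(0)
  out <- numeric(0)
  # folded SFS per region
  for (r in regs) {
    ix <- which(panel$region_labels == r)
    nr <- length(ix)
    dr <- d[ix, , drop = FALSE]
    ac <- colSums(dr)
    seg <- ac > 0 & ac < 2 * nr
    sfs <- numeric(nr)
    if (any(seg)) {
      fc <- pmin(ac[seg], 2 * nr - ac[seg])
      tt <- tabulate(fc, nbins = nr)
      sfs <- tt / sum(tt)
    } else flags <- c(flags, paste0("sfs_", r, ":monomorphic"))
    out <- c(out, setNames(sfs, paste0("sfs_", r, "_", seq_len(nr))))
  }
  # mean heterozygosity per region
  for (r in regs) {
    ix <- which(panel$region_labels == r)
    h <- if (ncol(d)) mean(d[ix, , drop = FALSE] == 1) else 0
    out <- c(out, setNames(h, paste0("het_", r)))
  }
  # pairwise Hudson FST (relative differentiation)
  prs <- combn(regs, 2)
  for (pi in seq_len(ncol(prs))) {
    r1 <- prs[1, pi]; r2 <- prs[2, pi]
    f <- if (ncol(d)) hudson_fst(d[panel$region_labels == r1, , drop = FALSE],
                                 d[panel$region_labels == r2, , drop = FALSE])
         else NA_real_
    if (is.na(f)) { f <- 0; flags <- c(flags, paste0("fst_", r1, "_", r2, ":undefined")) }
    out <- c(out, setNames(f, paste0("fst_", r1, "_", r2)))
  }
  # pairwise dxy per bp (absolute divergence; tracks deep coalescence)
  L <- max(panel$sequence_length, 1)
  for (pi in seq_len(ncol(prs))) {
    r1 <- prs[1, pi]; r2 <- prs[2, pi]
    v <- 0
    if (ncol(d)) {
      p1 <- colMeans(d[panel$region_labels == r1, , drop = FALSE]) / 2
      p2 <- colMeans(d[panel$region_labels == r2, , drop = FALSE]) / 2
      v <- sum(p1 * (1 - p2) + p2 * (1 - p1)) / L
    }
    out <- c(out, setNames(v, paste0("dxy_", r1, "_", r2)))
  }
  # mean HR in 3 coarse bins per region
  edges <- c(0, 5e4, 2e5, 5e5)
  for (r in regs) {
    ix <- which(panel$region_labels == r)
    dr <- d[ix, , drop = FALSE]
    v <- c(0, 0, 0)
    if (ncol(dr) >= 2) {
      maf <- site_maf(dr)
      keep <- which(maf >= 0.05)
      if (length(keep) > max_hr_sites)
        keep <- keep[round(seq(1, length(keep), length.out = max_hr_sites))]
      if (length(keep) >= 2) {
        curve <- ld_decay(dr[, keep, drop = FALSE],
                          positions = panel$positions[keep],
                          config = ld_config(bin_edges = edges, min_maf = 0.05))
        v <- ifelse(is.na(curve$mean_hr), 0, curve$mean_hr)
        if (anyNA(curve$mean_hr))
          flags <- c(flags, paste0("hr_", r, ":empty_bin"))
      } else flags <- c(flags, paste0("hr_", r, ":too_few_sites"))
    } else flags <- c(flags, paste0("hr_", r, ":too_few_sites"))
    out <- c(out, setNames(v, paste0("hr_", r, "_bin", 1:3)))
  }
  # mean total RoH per region
  roh <- if (ncol(d) >= 2) detect_roh(panel, params = roh_p) else
    detect_roh(matrix(0L, 1, 2), positions = c(0, 1), params = roh_p)
  tot <- roh_totals(roh, panel$sample_ids)
  for (r in regs) {
    ix <- which(panel$region_labels == r)
    out <- c(out, setNames(mean(tot[ix]), paste0("roh_", r)))
  }
  attr(out, "flags") <- flags
  out
}
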