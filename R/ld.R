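#' HR linkage-disequilibrium statistic between two sites
#'
#' Phase-free composite LD: the squared Pearson correlation of the diploid
#' dosage vectors at the two sites (signed r available via `signed`).
#'
#' @param dosages_a,dosages_b dosage vectors in \{0, 1, 2, NA\} over the
#'   same individuals
#' @param signed return the signed correlation r instead of r^2
#' @return scalar in [0, 1] (or [-1, 1] if `signed`)
#' @export
hr_statistic <- function(dosages_a, dosages_b, signed = FALSE) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 5)
    stop_pp("need >= 5 individuals with non-missing dosages at both sites",
            "pyrenpop_validation_error")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop_pp(sprintf("undefined LD: monomorphic site (%s)",
                    if (stats::var(a) == 0) "first" else "second"),
            "pyrenpop_ld_error")
  r <- cor(a, b)
  if (signed) r else r^2
}

site_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' LD-decay configuration
#'
#' @param maf_tolerance maximum |MAF_a - MAF_b| for a pair to enter the
#'   average (frequency matching)
#' @param bin_edges increasing bp distance-bin edges
#' @param min_maf minimum per-site MAF
#' @param max_distance maximum pair distance (bp)
#' @return list of class `pp_ld_config`
#' @export
ld_config <- function(maf_tolerance = 0.05,
                      bin_edges = seq(0, 5e5, by = 1e4),
                      min_maf = 0.05, max_distance = max(bin_edges)) {
  if (maf_tolerance <= 0) stop_pp("maf_tolerance must be > 0",
                                  "pyrenpop_validation_error")
  if (any(diff(bin_edges) <= 0)) stop_pp("bin edges must be increasing",
                                         "pyrenpop_validation_error")
  structure(list(maf_tolerance = maf_tolerance, bin_edges = bin_edges,
                 min_maf = min_maf, max_distance = max_distance),
            class = "pp_ld_config")
}

#' LD decay curve via the HR statistic with MAF matching
#'
#' Enumerates intra-chromosome site pairs within `max_distance`, drops pairs
#' whose per-site MAF is below `min_maf` or whose MAF difference is not
#' below `maf_tolerance`, and averages HR within distance bins. Empty bins
#' report count 0 and mean NA (never 0).
#'
#' @param x a `pp_panel`, `pp_dosage`, or dosage matrix (samples x sites,
#'   with `positions` attribute or supplied separately)
#' @param positions site positions (bp), if `x` is a plain matrix
#' @param region restrict to samples with this region label (NULL = all)
#' @param config an [ld_config()]
#' @param return_pairs also return the per-pair records
#' @return list of class `pp_ld_curve`: `mid` (bin midpoints), `mean_hr`,
#'   `n_pairs`, and optionally `pairs` (data.frame dist, hr, bin)
#' @export
ld_decay <- function(x, positions = NULL, region = NULL,
                     config = ld_config(), return_pairs = FALSE) {
  if (inherits(x, "pp_panel")) {
    d <- panel_dosages(x); positions <- x$positions
    labels <- x$region_labels
  } else if (inherits(x, "pp_dosage")) {
    d <- x$dosages; positions <- x$positions; labels <- x$region_labels
  } else {
    d <- as.matrix(x)
    if (is.null(positions)) stop_pp("positions required for a plain matrix",
                                    "pyrenpop_validation_error")
    labels <- rep(NA_character_, nrow(d))
  }
  if (!is.null(region)) d <- d[labels == region, , drop = FALSE]
  if (nrow(d) < 5)
    stop_pp("LD decay needs >= 5 individuals", "pyrenpop_validation_error")
  maf <- site_maf(d)
  keep <- which(maf >= config$min_maf & maf > 0)
  d <- d[, keep, drop = FALSE]
  pos <- positions[keep]
  maf <- maf[keep]
  edges <- config$bin_edges
  nb <- length(edges) - 1
  sums <- numeric(nb); counts <- integer(nb)
  recs <- if (return_pairs) list() else NULL
  S <- length(pos)
  if (S >= 2) {
    block <- 512L
    for (i0 in seq(1, S, by = block)) {
      i1 <- min(i0 + block - 1L, S)
      jmax <- findInterval(pos[i0:i1] + config$max_distance, pos)
      jend <- max(jmax)
      if (jend <= i0) next
      cc <- suppressWarnings(cor(d[, i0:jend, drop = FALSE]))^2
      for (ii in seq(i0, i1)) {
        hi <- jmax[ii - i0 + 1L]
        if (hi <= ii) next
        js <- (ii + 1L):hi
        js <- js[abs(maf[js] - maf[ii]) < config$maf_tolerance]
        if (!length(js)) next
        hr <- cc[ii - i0 + 1L, js - i0 + 1L]
        ok <- is.finite(hr)
        if (!any(ok)) next
        js <- js[ok]; hr <- hr[ok]
        dist <- pos[js] - pos[ii]
        bin <- findInterval(dist, edges, rightmost.closed = TRUE)
        inb <- bin >= 1 & bin <= nb
        if (!any(inb)) next
        bs <- rowsum(hr[inb], bin[inb])
        bc <- rowsum(rep(1L, sum(inb)), bin[inb])
        idx <- as.integer(rownames(bs))
        sums[idx] <- sums[idx] + bs[, 1]
        counts[idx] <- counts[idx] + bc[, 1]
        if (return_pairs)
          recs[[length(recs) + 1]] <- data.frame(dist = dist[inb],
                                                 hr = hr[inb],
                                                 bin = bin[inb])
      }
    }
  }
  out <- structure(list(mid = (edges[-1] + edges[-length(edges)]) / 2,
                        mean_hr = ifelse(counts > 0, sums / pmax(counts, 1), NA),
                        n_pairs = counts), class = "pp_ld_curve")
  if (return_pairs)
    out$pairs <- if (length(recs)) do.call(rbind, recs) else
      data.frame(dist = numeric(0), hr = numeric(0), bin = integer(0))
  out
}
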