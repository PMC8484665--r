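#' Runs-of-homozygosity detection parameters
#'
#' Sliding-window scan defaults: 50-SNV windows with at most 1 heterozygote,
#' segments of >= 1 Mb, >= 50 SNVs, and inter-SNV gaps <= 100 kb.
#'
#' @param window_snvs SNVs per sliding window
#' @param max_het_per_window heterozygote calls tolerated per window
#' @param min_length_bp minimum segment length
#' @param min_snvs minimum SNVs per segment
#' @param max_gap_bp maximum gap between consecutive SNVs inside a segment
#' @return list of class `pp_roh_params`
#' @export
roh_params <- function(window_snvs = 50, max_het_per_window = 1,
                       min_length_bp = 1e6, min_snvs = 50, max_gap_bp = 1e5) {
  structure(list(window_snvs = window_snvs,
                 max_het_per_window = max_het_per_window,
                 min_length_bp = min_length_bp, min_snvs = min_snvs,
                 max_gap_bp = max_gap_bp), class = "pp_roh_params")
}

roh_one_sample <- function(dos, positions, params) {
  ok <- !is.na(dos)
  dos <- dos[ok]; pos <- positions[ok]
  L <- length(dos)
  w <- min(params$window_snvs, L)
  if (L < 1) return(NULL)
  het <- as.integer(dos == 1)
  # window het counts; site flagged if any covering window is near-homozygous
  cs <- c(0, cumsum(het))
  nwin <- L - w + 1
  if (nwin < 1) return(NULL)
  wins_ok <- (cs[(w + 1):(L + 1)] - cs[1:nwin]) <= params$max_het_per_window
  flag <- logical(L)
  # window j covers sites j..j+w-1; flag site i if any j in [i-w+1, i] passes
  ok_idx <- which(wins_ok)
  for (j in ok_idx) flag[j:(j + w - 1)] <- TRUE
  if (!any(flag)) return(NULL)
  # maximal runs of flagged sites, broken at long gaps
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- list()
  for (ri in which(runs$values)) {
    idx <- starts[ri]:ends[ri]
    # split at gaps > max_gap_bp
    gaps <- diff(pos[idx])
    cut <- c(0, which(gaps > params$max_gap_bp), length(idx))
    for (ci in seq_len(length(cut) - 1)) {
      sub <- idx[(cut[ci] + 1):cut[ci + 1]]
      n_snv <- length(sub)
      len <- pos[sub[n_snv]] - pos[sub[1]] + 1
      if (n_snv >= params$min_snvs && len >= params$min_length_bp)
        segs[[length(segs) + 1]] <- data.frame(
          start = pos[sub[1]], end = pos[sub[n_snv]] + 1, n_snvs = n_snv,
          n_het = sum(dos[sub] == 1))
    }
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan: a site is flagged when at least one window of
#' `window_snvs` consecutive SNVs covering it contains at most
#' `max_het_per_window` heterozygous calls; maximal runs of flagged sites
#' (broken at gaps > `max_gap_bp`) that satisfy the length and SNV-count
#' constraints become segments. Coordinates are 0-based half-open.
#'
#' @param x a `pp_panel`, `pp_dosage`, or dosage matrix (samples x sites)
#' @param positions site positions, for a plain matrix
#' @param params a [roh_params()]
#' @return data.frame of class `pp_roh`: `sample_id`, `start`, `end`,
#'   `length`, `n_snvs`, `n_het` (zero rows when none found)
#' @export
detect_roh <- function(x, positions = NULL, params = roh_params()) {
  if (inherits(x, "pp_panel")) { d <- panel_dosages(x); positions <- x$positions }
  else if (inherits(x, "pp_dosage")) { d <- x$dosages; positions <- x$positions }
  else {
    d <- as.matrix(x)
    if (is.null(positions)) stop_pp("positions required", "pyrenpop_validation_error")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop_pp("positions must be sorted strictly increasing",
            "pyrenpop_validation_error")
  ids <- rownames(d) %||% paste0("S", seq_len(nrow(d)))
  out <- lapply(seq_len(nrow(d)), function(i) {
    s <- roh_one_sample(d[i, ], positions, params)
    if (is.null(s)) return(NULL)
    cbind(data.frame(sample_id = ids[i]), s)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), start = numeric(0), end = numeric(0),
               n_snvs = integer(0), n_het = integer(0))
  res$length <- res$end - res$start
  class(res) <- c("pp_roh", "data.frame")
  res
}

#' Per-sample total RoH length
#' @param roh a `pp_roh` (from [detect_roh()])
#' @param sample_ids all sample ids (so samples with no segment report 0)
#' @return named numeric vector of total bp in RoH per sample
#' @export
roh_totals <- function(roh, sample_ids) {
  tot <- setNames(numeric(length(sample_ids)), sample_ids)
  if (nrow(roh)) {
    agg <- tapply(roh$length, roh$sample_id, sum)
    tot[names(agg)] <- agg
  }
  tot
}

#' Kruskal-Wallis comparison of per-sample RoH totals across regions
#'
#' @param totals numeric vector of per-sample totals
#' @param regions region label per sample
#' @return list `H` (rank statistic, tie-corrected), `p_value`, `df`
#' @export
roh_region_test <- function(totals, regions) {
  tab <- table(regions)
  if (length(tab) < 2) stop_pp("need >= 2 regions", "pyrenpop_validation_error")
  if (any(tab < 2)) stop_pp(sprintf("region(s) with < 2 samples: %s",
                                    paste(names(tab)[tab < 2], collapse = ", ")),
                            "pyrenpop_validation_error")
  if (stats::var(totals) == 0)  # complete ties: no rank information
    return(list(H = 0, p_value = 1, df = length(tab) - 1))
  kt <- kruskal.test(totals, factor(regions))
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}
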