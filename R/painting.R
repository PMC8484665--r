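site_spans <- function(positions) {
  L <- length(positions)
  if (L == 1) return(1)
  d <- diff(positions)
  c(d[1] / 2, (d[-(L - 1)] + d[-1]) / 2, d[L - 1] / 2)
}

paint_pass <- function(panel, switch_rate, miscopy_rate) {
  # one all-vs-all painting sweep; returns coancestry accumulation plus the
  # EM sufficient statistics (expected switches per inter-site step, loglik)
  pos <- panel$positions
  L <- length(pos)
  if (L < 2) stop_pp("painting needs at least 2 sites", "pyrenpop_validation_error")
  n <- length(panel$sample_ids)
  if (n < 3) stop_pp("painting needs at least 3 individuals",
                     "pyrenpop_validation_error")
  H <- t(panel$haplotypes)          # L x 2n
  w <- site_spans(pos)
  q <- 1 - exp(-switch_rate * diff(pos))
  hap_ind <- rep(seq_len(n), each = 2)
  lengths <- matrix(0, n, n)
  exp_sw <- numeric(L - 1)
  loglik <- 0
  n_rec <- 0L
  for (r in seq_len(2 * n)) {
    ind <- hap_ind[r]
    donors <- which(hap_ind != ind)
    res <- ls_paint_hap(H[, donors, drop = FALSE], H[, r], q, w, miscopy_rate)
    # collapse donor haplotypes to donor individuals
    agg <- rowsum(res$copied, group = hap_ind[donors])
    lengths[as.integer(rownames(agg)), ind] <-
      lengths[as.integer(rownames(agg)), ind] + agg[, 1]
    exp_sw <- exp_sw + res$exp_switch
    loglik <- loglik + res$loglik
    n_rec <- n_rec + 1L
  }
  list(lengths = lengths, exp_switch = exp_sw, loglik = loglik,
       n_rec = n_rec, total_span = sum(w))
}

#' Paint a phased panel into a coancestry matrix
#'
#' Each recipient haplotype is painted against all other individuals'
#' haplotypes under the Li-Stephens copying model (forward-backward
#' posterior; switch probability 1 - exp(-switch_rate * bp gap), emission
#' miscopy rate). Posterior copying mass times inter-site span is
#' accumulated per donor; donor haplotypes collapse to donor individuals
#' and the recipient's two haplotypes are summed, giving entry (j, i) =
#' expected bp that individual i copies from donor j.
#'
#' @param panel a phased `pp_panel` with >= 3 individuals
#' @param switch_rate per-bp copying switch rate; `NULL` estimates it first
#'   with [estimate_switch_rate()]
#' @param miscopy_rate emission error rate
#' @return a [new_coancestry()] object; attribute `"loglik"` holds the total
#'   copying log-likelihood, `"switch_rate"` the rate used
#' @export
paint_panel <- function(panel, switch_rate = NULL, miscopy_rate = 0.01) {
  if (!isTRUE(panel$phased))
    stop_pp("painting requires phased haplotypes; use dosage-based analyses for unphased data",
            "pyrenpop_phase_error")
  if (is.null(switch_rate))
    switch_rate <- estimate_switch_rate(panel, n_em_iters = 3,
                                        miscopy_rate = miscopy_rate)$switch_rate
  pass <- paint_pass(panel, switch_rate, miscopy_rate)
  cm <- new_coancestry(pass$lengths, panel$sample_ids)
  attr(cm, "loglik") <- pass$loglik
  attr(cm, "switch_rate") <- switch_rate
  cm
}

#' Estimate the copying switch rate by EM
#'
#' Alternates painting sweeps (E-step: expected switch counts per inter-site
#' step) with an exact one-dimensional M-step maximizing the expected
#' complete-data log-likelihood of the exponential switch model
#' q = 1 - exp(-r * gap). The observed log-likelihood trace is recorded and
#' is non-decreasing. The rate starts at the lower bound, so panels whose
#' haplotypes never force a copying switch (e.g. identical haplotypes, a
#' flat likelihood) report the floor rather than an arbitrary value; where
#' the data demand switches the exact M-step jumps to the matching rate in
#' the first iteration.
#'
#' @param panel a phased `pp_panel`
#' @param n_em_iters number of EM iterations (>= 1)
#' @param init initial rate per bp (default: the lower bound)
#' @param miscopy_rate emission error rate
#' @param bounds search interval for the rate
#' @return list `switch_rate`, `loglik_trace`
#' @export
estimate_switch_rate <- function(panel, n_em_iters = 5, init = NULL,
                                 miscopy_rate = 0.01,
                                 bounds = c(1e-12, 1e-2)) {
  if (n_em_iters < 1) stop_pp("n_em_iters must be >= 1", "pyrenpop_validation_error")
  if (length(panel$positions) < 2)
    stop_pp("switch-rate estimation needs >= 2 sites (degenerate panel)",
            "pyrenpop_validation_error")
  gaps <- diff(panel$positions)
  r <- init %||% bounds[1]
  trace <- numeric(n_em_iters)
  for (it in seq_len(n_em_iters)) {
    pass <- paint_pass(panel, r, miscopy_rate)
    trace[it] <- pass$loglik
    S <- pass$exp_switch               # expected switches per step, all recipients
    N <- pass$n_rec
    obj <- function(logr) {
      rr <- exp(logr)
      qq <- -expm1(-rr * gaps)
      qq <- pmax(qq, 1e-300)
      sum(S * log(qq) - (N - S) * rr * gaps)
    }
    r <- exp(optimize(obj, log(bounds), maximum = TRUE, tol = 1e-10)$maximum)
  }
  list(switch_rate = r, loglik_trace = trace)
}

#' Cluster a coancestry matrix
#'
#' Average-linkage agglomerative clustering on a dissimilarity derived from
#' the row-normalized, symmetrized coancestry: copying fractions span
#' orders of magnitude, so the dissimilarity is the negative log copying
#' fraction, d_ij = -log(similarity_ij). Flat clusterings for k = 2..k_max
#' are scored by mean silhouette width and the best k is chosen. A
#' deterministic surrogate for the fineSTRUCTURE coancestry-clustering
#' step.
#'
#' @param coancestry a `pp_coancestry`
#' @param k_max maximum number of flat clusters (< N)
#' @return list of class `pp_clust`: `tree` (hclust), `clusters` (matrix of
#'   memberships, one column per k), `silhouette` (mean width per k),
#'   `best_k`, `membership` (at best_k), `max_silhouette`
#' @export
cluster_coancestry <- function(coancestry, k_max = 5) {
  n <- length(coancestry$sample_ids)
  if (k_max >= n) stop_pp("k_max must be < number of samples",
                          "pyrenpop_validation_error")
  s <- (coancestry$lengths + t(coancestry$lengths)) / 2
  diag(s) <- 0
  rs <- rowSums(s)
  rs[rs == 0] <- 1
  sim <- s / rs
  sim <- (sim + t(sim)) / 2
  eps <- if (any(sim > 0)) min(sim[sim > 0]) / 2 else 1
  dm <- -log(sim + eps)  # positive: row-normalized similarities are < 1
  diag(dm) <- 0
  dimnames(dm) <- list(coancestry$sample_ids, coancestry$sample_ids)
  d <- stats::as.dist(dm)
  tree <- hclust(d, method = "average")
  ks <- 2:k_max
  clusters <- sapply(ks, function(k) cutree(tree, k))
  colnames(clusters) <- ks
  sil <- vapply(seq_along(ks), function(i) {
    cl <- clusters[, i]
    if (length(unique(cl)) < 2) return(NA_real_)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  best <- ks[which.max(sil)]
  structure(list(tree = tree, clusters = clusters,
                 silhouette = setNames(sil, ks), best_k = best,
                 membership = clusters[, as.character(best)],
                 max_silhouette = max(sil, na.rm = TRUE)),
            class = "pp_clust")
}
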