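#' 1-IBS distance matrix from diploid dosages
#'
#' d(i, j) = mean over pairwise-complete sites of |g_i - g_j| / 2, the
#' complement of the identity-by-state similarity between two diploid
#' genotypes.
#'
#' @param genotypes N x L dosage matrix in \{0, 1, 2, NA\}
#' @return list of class `pp_dist`: `values` (symmetric N x N in [0, 1],
#'   zero diagonal), `sample_ids`
#' @export
ibs_distance <- function(genotypes) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  if (n < 2 || ncol(g) < 1)
    stop_pp("need >= 2 samples and >= 1 site", "pyrenpop_validation_error")
  ids <- rownames(g) %||% paste0("S", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (!anyNA(g)) {
    d <- as.matrix(dist(g, method = "manhattan")) / (2 * ncol(g))
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok))
        stop_pp(sprintf("samples %s and %s share no non-missing sites",
                        ids[i], ids[j]), "pyrenpop_validation_error")
      d[i, j] <- d[j, i] <- mean(abs(g[i, ok] - g[j, ok])) / 2
    }
  }
  structure(list(values = d, sample_ids = ids), class = "pp_dist")
}

#' Classical (metric) multidimensional scaling
#'
#' Eigendecomposition of the double-centered squared-distance matrix;
#' coordinates are scaled by the square root of the nonnegative eigenvalues.
#' Axes with non-positive eigenvalues are dropped with a warning, truncating
#' `k` if needed.
#'
#' @param dist a `pp_dist` or symmetric distance matrix
#' @param k number of requested dimensions
#' @return list of class `pp_mds`: `coordinates` (N x k'), `eigenvalues`
#'   (descending, all returned), `sample_ids`
#' @export
classical_mds <- function(dist, k = 2) {
  if (k < 1) stop_pp("k must be >= 1", "pyrenpop_validation_error")
  m <- if (inherits(dist, "pp_dist")) dist$values else as.matrix(dist)
  n <- nrow(m)
  if (k > n - 1) stop_pp("k must be <= N - 1", "pyrenpop_validation_error")
  fit <- suppressWarnings(cmdscale(m, k = n - 1, eig = TRUE))
  ev <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (k > npos) {
    warning(sprintf("only %d positive eigenvalue axes; k truncated from %d",
                    npos, k))
    k <- npos
  }
  if (any(fit$eig < -sqrt(.Machine$double.eps) * max(abs(fit$eig))))
    warning("negative eigenvalues dropped (distances not fully Euclidean)")
  coords <- fit$points[, seq_len(k), drop = FALSE]
  ids <- rownames(m) %||% paste0("S", seq_len(n))
  rownames(coords) <- ids
  structure(list(coordinates = coords, eigenvalues = ev, sample_ids = ids),
            class = "pp_mds")
}

#' Symmetric Procrustes correlation with permutation test
#'
#' Both configurations are centered and scaled to unit sum of squares; the
#' correlation is sqrt(1 - residual SS) after the optimal rotation, and the
#' p-value is (1 + #\{permuted >= observed\}) / (n_perm + 1) over random row
#' permutations of `Y` (vegan's PROTEST).
#'
#' @param X N x k reference configuration (e.g. MDS coordinates)
#' @param Y N x k configuration to rotate (e.g. geographic coordinates)
#' @param n_perm number of permutations
#' @return list `correlation`, `p_value`, `n_perm`
#' @export
procrustes_test <- function(X, Y, n_perm = 999) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_perm < 1) stop_pp("n_perm must be >= 1", "pyrenpop_validation_error")
  if (nrow(X) != nrow(Y))
    stop_pp("configurations must have the same number of rows",
            "pyrenpop_validation_error")
  if (nrow(X) < 3) stop_pp("need at least 3 rows", "pyrenpop_validation_error")
  pt <- vegan::protest(X, Y, permutations = n_perm)
  list(correlation = unname(pt$t0), p_value = unname(pt$signif),
       n_perm = n_perm)
}
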