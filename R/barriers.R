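#' Construct a barrier-model fit object
#'
#' The spatial coancestry model: normalized coancestry between individuals
#' i, j is beta0 + beta1 * exp(-lambda * d_ij), where d_ij is an anisotropic
#' Mahalanobis distance with a per-group metric
#' M_g = s_g * R(theta_g)' diag(1, rho_g^2) R(theta_g); pairs in different
#' groups use the averaged metric (M_g + M_h) / 2 plus an additive barrier
#' b_gh. The first group's scale is fixed to 1 so that barriers are in km.
#'
#' @param partition named integer vector: region -> group index
#' @param groups list (one per group) of `theta` (radians, [0, pi)),
#'   `rho` (>= 1), `s` (> 0)
#' @param barrier symmetric k x k matrix of nonnegative barriers, zero diag
#' @param beta0,beta1,lambda decay parameters (beta1 >= 0, lambda > 0)
#' @param fit_score residual sum of squares of the fit
#' @param p_value permutation p-value (NA until tested)
#' @return object of class `pp_barrier_fit`
#' @export
new_barrier_fit <- function(partition, groups, barrier, beta0, beta1, lambda,
                            fit_score = NA_real_, p_value = NA_real_) {
  structure(list(partition = partition, groups = groups, barrier = barrier,
                 beta0 = beta0, beta1 = beta1, lambda = lambda,
                 fit_score = fit_score, p_value = p_value),
            class = "pp_barrier_fit")
}

group_metric <- function(theta, rho, s) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
  s * (t(R) %*% diag(c(1, rho^2)) %*% R)
}

#' Effective (anisotropic + barrier) distance between two individuals
#'
#' @param coord_i,coord_j length-2 planar coordinates (km)
#' @param group_i,group_j group indices of the two individuals
#' @param fit a `pp_barrier_fit`
#' @return nonnegative scalar distance
#' @export
effective_distance <- function(coord_i, coord_j, group_i, group_j, fit) {
  Mi <- with(fit$groups[[group_i]], group_metric(theta, rho, s))
  Mj <- with(fit$groups[[group_j]], group_metric(theta, rho, s))
  M <- (Mi + Mj) / 2
  dx <- as.numeric(coord_i) - as.numeric(coord_j)
  d <- sqrt(drop(t(dx) %*% M %*% dx))
  if (group_i != group_j) d <- d + fit$barrier[group_i, group_j]
  d
}

#' All-pairs effective distances (matrix form of [effective_distance()])
#' @param coords N x 2 coordinates
#' @param grp integer group index per individual
#' @param fit a `pp_barrier_fit`
#' @return N x N symmetric distance matrix
#' @export
pairwise_effective_distance <- function(coords, grp, fit) {
  a <- t(vapply(fit$groups, function(g) {
    M <- group_metric(g$theta, g$rho, g$s)
    c(M[1, 1], M[1, 2], M[2, 2])
  }, numeric(3)))
  a11 <- outer(a[grp, 1], a[grp, 1], "+") / 2
  a12 <- outer(a[grp, 2], a[grp, 2], "+") / 2
  a22 <- outer(a[grp, 3], a[grp, 3], "+") / 2
  dx <- outer(coords[, 1], coords[, 1], "-")
  dy <- outer(coords[, 2], coords[, 2], "-")
  d <- sqrt(pmax(a11 * dx^2 + 2 * a12 * dx * dy + a22 * dy^2, 0))
  d + fit$barrier[cbind(grp[row(d)], grp[col(d)])]
}

#' Model-predicted coancestry surface
#' @param fit a `pp_barrier_fit`
#' @param coords N x 2 coordinates
#' @param grp group index per individual
#' @return N x N matrix beta0 + beta1 * exp(-lambda * d)
#' @export
predict_barrier_model <- function(fit, coords, grp) {
  fit$beta0 + fit$beta1 * exp(-fit$lambda * pairwise_effective_distance(coords, grp, fit))
}

# --- internal parameterization -------------------------------------------
# par layout (barrier model, k groups):
#   theta_1..theta_k, u_1..u_k (rho = 1 + u^2), v_2..v_k (s = exp(v)),
#   w (lambda = exp(w)), z_gh for g<h (b = z^2)
# no-barrier model: theta, u, w (single shared metric, b = 0)

unpack_par <- function(par, k, barrier) {
  if (!barrier) {
    groups <- list(list(theta = par[1] %% pi, rho = 1 + par[2]^2, s = 1))
    return(list(groups = groups, lambda = exp(par[3]),
                barrier = matrix(0, 1, 1)))
  }
  theta <- par[seq_len(k)] %% pi
  u <- par[k + seq_len(k)]
  v <- if (k > 1) par[2 * k + seq_len(k - 1)] else numeric(0)
  w <- par[3 * k]
  z <- par[3 * k + seq_len(k * (k - 1) / 2)]
  groups <- lapply(seq_len(k), function(g)
    list(theta = theta[g], rho = 1 + u[g]^2,
         s = if (g == 1) 1 else exp(v[g - 1])))
  B <- matrix(0, k, k)
  B[upper.tri(B)] <- z^2
  B <- B + t(B)
  list(groups = groups, lambda = exp(w), barrier = B)
}

n_par <- function(k, barrier) {
  if (!barrier) 3L else as.integer(3 * k + k * (k - 1) / 2)
}

profile_betas <- function(cvec, t) {
  vt <- stats::var(t)
  b1 <- if (vt < 1e-14) 0 else stats::cov(cvec, t) / vt
  if (b1 < 0) b1 <- 0
  b0 <- mean(cvec) - b1 * mean(t)
  rss <- sum((cvec - b0 - b1 * t)^2)
  list(beta0 = b0, beta1 = b1, rss = rss)
}

barrier_objective <- function(cvec, dx, dy, gi, gj, k, barrier) {
  cross <- gi != gj
  function(par) {
    up <- unpack_par(par, k, barrier)
    a <- t(vapply(up$groups, function(g) {
      M <- group_metric(g$theta, g$rho, g$s)
      c(M[1, 1], M[1, 2], M[2, 2])
    }, numeric(3)))
    g1 <- if (barrier) gi else rep(1L, length(gi))
    g2 <- if (barrier) gj else rep(1L, length(gj))
    a11 <- (a[g1, 1] + a[g2, 1]) / 2
    a12 <- (a[g1, 2] + a[g2, 2]) / 2
    a22 <- (a[g1, 3] + a[g2, 3]) / 2
    d <- sqrt(pmax(a11 * dx^2 + 2 * a12 * dx * dy + a22 * dy^2, 0))
    if (barrier) d <- d + up$barrier[cbind(gi, gj)]
    t_ <- exp(-up$lambda * d)
    if (any(!is.finite(t_))) return(1e12)
    profile_betas(cvec, t_)$rss
  }
}

fit_pairs <- function(cvec, dx, dy, gi, gj, k, barrier, n_starts, seed,
                      extra_starts = list(), maxit = 2000, reltol = 1e-10) {
  obj <- barrier_objective(cvec, dx, dy, gi, gj, k, barrier)
  np <- n_par(k, barrier)
  dbar <- mean(sqrt(dx^2 + dy^2))
  if (!is.finite(dbar) || dbar <= 0) dbar <- 1
  set.seed(seed)
  iso <- numeric(np)  # isotropic start: theta=0, rho=1, s=1, b=0
  iso[if (barrier) 3 * k else 3] <- log(1 / dbar)
  starts <- c(list(iso), extra_starts)
  for (i in seq_len(n_starts)) {
    st <- numeric(np)
    if (barrier) {
      st[seq_len(k)] <- runif(k, 0, pi)
      st[k + seq_len(k)] <- runif(k, 0, 1.2)
      if (k > 1) st[2 * k + seq_len(k - 1)] <- rnorm(k - 1, 0, 0.5)
      st[3 * k] <- log(1 / dbar) + runif(1, -1.5, 1.5)
      st[3 * k + seq_len(k * (k - 1) / 2)] <- runif(k * (k - 1) / 2, 0,
                                                    sqrt(dbar))
    } else {
      st <- c(runif(1, 0, pi), runif(1, 0, 1.2),
              log(1 / dbar) + runif(1, -1.5, 1.5))
    }
    starts[[length(starts) + 1]] <- st
  }
  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    res <- tryCatch(
      optim(st, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop_pp("barrier-model optimizer failed to converge on all starts",
            "pyrenpop_optim_error")
  list(par = best$par, value = best$value, n_conv = n_conv, obj = obj)
}

prepare_pairs <- function(coancestry, coords, grp) {
  cn <- normalize_coancestry(coancestry)
  n <- nrow(cn)
  ij <- which(upper.tri(cn), arr.ind = TRUE)
  list(cvec = cn[ij],
       dx = coords[ij[, 1], 1] - coords[ij[, 2], 1],
       dy = coords[ij[, 1], 2] - coords[ij[, 2], 2],
       gi = pmin(grp[ij[, 1]], grp[ij[, 2]]),
       gj = pmax(grp[ij[, 1]], grp[ij[, 2]]), n = n)
}

#' Fit the anisotropy + barrier model to a coancestry matrix
#'
#' Minimizes the residual sum of squares of
#' c_ij ~ beta0 + beta1 * exp(-lambda * d_ij) over the per-group anisotropy
#' parameters, the inter-group barriers and the decay parameters, where
#' c_ij is the symmetrized, grand-mean-normalized coancestry
#' ([normalize_coancestry()]). beta0/beta1 are profiled out analytically;
#' the remaining parameters are optimized by seeded multi-start Nelder-Mead.
#' With `barrier = FALSE` the nested no-barrier model (single shared
#' isotropy/anisotropy metric, b = 0) is fitted instead. The no-barrier
#' solution is always included as a start of the barrier fit, so the
#' barrier model's score never exceeds the nested model's.
#'
#' @param coancestry a `pp_coancestry`
#' @param coords N x 2 planar coordinates (km) per individual
#' @param regions region label per individual
#' @param partition named vector region -> group index (ignored if
#'   `barrier = FALSE`)
#' @param n_starts random multi-starts
#' @param seed seed for the starts
#' @param barrier fit the barrier model (TRUE) or the nested no-barrier
#'   model (FALSE)
#' @return a `pp_barrier_fit` with `fit_score` (RSS) filled in; attribute
#'   `"n_converged"` counts successful starts
#' @export
fit_barrier_model <- function(coancestry, coords, regions, partition,
                              n_starts = 20, seed = 1L, barrier = TRUE,
                              maxit = 2000, reltol = 1e-10) {
  coords <- as.matrix(coords)
  tab <- table(regions)
  if (any(tab < 2))
    stop_pp("need >= 2 individuals per region", "pyrenpop_validation_error")
  if (barrier) {
    if (!all(regions %in% names(partition)))
      stop_pp("partition must cover all regions", "pyrenpop_validation_error")
    grp <- as.integer(partition[regions])
    k <- max(partition)
  } else {
    grp <- rep(1L, length(regions))
    k <- 1L
    partition <- setNames(rep(1L, length(unique(regions))), unique(regions))
  }
  pp <- prepare_pairs(coancestry, coords, grp)
  extra <- list()
  if (barrier && k > 1) {
    # start from the nested no-barrier solution (guarantees dominance)
    nb <- fit_pairs(pp$cvec, pp$dx, pp$dy, rep(1L, length(pp$gi)),
                    rep(1L, length(pp$gj)), 1L, FALSE,
                    n_starts = max(3, n_starts %/% 3), seed = seed + 1L,
                    maxit = maxit, reltol = reltol)
    st <- numeric(n_par(k, TRUE))
    st[seq_len(k)] <- nb$par[1]
    st[k + seq_len(k)] <- nb$par[2]
    st[3 * k] <- nb$par[3]
    extra <- list(st)
  }
  res <- fit_pairs(pp$cvec, pp$dx, pp$dy, pp$gi, pp$gj, k, barrier,
                   n_starts = n_starts, seed = seed, extra_starts = extra,
                   maxit = maxit, reltol = reltol)
  up <- unpack_par(res$par, k, barrier)
  # recompute profiled betas at the optimum
  a <- t(vapply(up$groups, function(g) {
    M <- group_metric(g$theta, g$rho, g$s); c(M[1, 1], M[1, 2], M[2, 2])
  }, numeric(3)))
  g1 <- if (barrier) pp$gi else rep(1L, length(pp$gi))
  g2 <- if (barrier) pp$gj else rep(1L, length(pp$gj))
  d <- sqrt(pmax((a[g1, 1] + a[g2, 1]) / 2 * pp$dx^2 +
                 (a[g1, 2] + a[g2, 2]) * pp$dx * pp$dy +
                 (a[g1, 3] + a[g2, 3]) / 2 * pp$dy^2, 0))
  if (barrier) d <- d + up$barrier[cbind(pp$gi, pp$gj)]
  pb <- profile_betas(pp$cvec, exp(-up$lambda * d))
  fit <- new_barrier_fit(partition, up$groups, up$barrier,
                         pb$beta0, pb$beta1, up$lambda,
                         fit_score = res$value)
  attr(fit, "n_converged") <- res$n_conv
  fit
}

# all set partitions of `elements` into exactly k nonempty groups
set_partitions_k <- function(elements, k) {
  n <- length(elements)
  out <- list()
  assign <- integer(n)
  recurse <- function(i, used) {
    if (i > n) {
      if (used == k) out[[length(out) + 1]] <<- setNames(assign, elements)
      return(invisible())
    }
    if (n - i + 1 < k - used) return(invisible())  # cannot reach k groups
    for (g in seq_len(min(used + 1, k))) {
      assign[i] <<- g
      recurse(i + 1, max(used, g))
    }
  }
  recurse(1L, 0L)
  out
}

#' Exhaustive partition search for the barrier model
#'
#' Enumerates every set partition of the regions into k nonempty groups
#' (15 for 5 regions with k = 2), fits the barrier model to each, and
#' returns the best fit together with a ranked table of all partitions.
#'
#' @param coancestry a `pp_coancestry`
#' @param coords N x 2 coordinates
#' @param regions region label per individual
#' @param k number of groups (>= 2, <= number of regions)
#' @param n_starts multi-starts per partition fit
#' @param seed seed
#' @return list `best_fit` (`pp_barrier_fit`), `table` (data.frame:
#'   `partition`, `fit_score`, ranked), `fits` (all fits, same order)
#' @export
search_partitions <- function(coancestry, coords, regions, k = 2,
                              n_starts = 8, seed = 1L, maxit = 1000,
                              reltol = 1e-9) {
  regs <- sort(unique(regions))
  if (k < 2) stop_pp("k must be >= 2", "pyrenpop_validation_error")
  if (k > length(regs))
    stop_pp("k exceeds the number of regions", "pyrenpop_validation_error")
  parts <- set_partitions_k(regs, k)
  fits <- lapply(seq_along(parts), function(i)
    fit_barrier_model(coancestry, coords, regions, parts[[i]],
                      n_starts = n_starts, seed = seed + i,
                      maxit = maxit, reltol = reltol))
  scores <- vapply(fits, function(f) f$fit_score, numeric(1))
  lab <- vapply(parts, function(p)
    paste(vapply(seq_len(k), function(g)
      paste0("{", paste(names(p)[p == g], collapse = ","), "}"),
      character(1)), collapse = " | "), character(1))
  o <- order(scores)
  list(best_fit = fits[[o[1]]],
       table = data.frame(partition = lab[o], fit_score = scores[o],
                          stringsAsFactors = FALSE),
       fits = fits[o])
}

#' Permutation test for the barrier model
#'
#' Null distribution: individuals' region labels (and with them their
#' coordinates and group memberships) are permuted jointly; the statistic is
#' the fit-score improvement of the barrier model over the nested
#' no-barrier model. p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param coancestry a `pp_coancestry`
#' @param coords N x 2 coordinates
#' @param regions region label per individual
#' @param best_fit the observed-data `pp_barrier_fit` whose partition is
#'   being tested
#' @param n_perm number of permutations (>= 99)
#' @param seed seed
#' @param n_starts_perm multi-starts per permuted refit
#' @return list `p_value`, `observed`, `null` (vector of null statistics)
#' @export
barrier_permutation_test <- function(coancestry, coords, regions, best_fit,
                                     n_perm = 199, seed = 1L,
                                     n_starts_perm = 3, maxit = 400,
                                     reltol = 1e-8) {
  if (n_perm < 99) stop_pp("n_perm must be >= 99", "pyrenpop_validation_error")
  coords <- as.matrix(coords)
  stat <- function(regs, cds, seed_i) {
    fb <- fit_barrier_model(coancestry, cds, regs, best_fit$partition,
                            n_starts = n_starts_perm, seed = seed_i,
                            maxit = maxit, reltol = reltol)
    f0 <- fit_barrier_model(coancestry, cds, regs, best_fit$partition,
                            n_starts = n_starts_perm, seed = seed_i,
                            barrier = FALSE, maxit = maxit, reltol = reltol)
    f0$fit_score - fb$fit_score
  }
  observed <- stat(regions, coords, seed)
  set.seed(seed)
  perms <- replicate(n_perm, sample(length(regions)))
  null <- vapply(seq_len(n_perm), function(b) {
    p <- perms[, b]
    stat(regions[p], coords[p, , drop = FALSE], seed + b)
  }, numeric(1))
  list(p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       observed = observed, null = null)
}
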