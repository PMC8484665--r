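#' Deterministic test-surface fixtures
#'
#' Generates small synthetic objects with planted, known structure so each
#' downstream analysis can be checked against ground truth:
#' \describe{
#'   \item{planted_roh}{diploid genotypes with homozygous tracts at known
#'     coordinates (params: `n_sites`, `chrom_length`, `tracts` = list of
#'     `c(start, end)` in bp, `het_prob`)}
#'   \item{two_cluster_coancestry}{symmetric coancestry matrix with higher
#'     within-cluster than between-cluster means (params: `n1`, `n2`,
#'     `mu_within`, `mu_between`, `sd`)}
#'   \item{anisotropic_lattice}{lattice of individuals whose coancestry
#'     decays with a known anisotropic metric plus a known inter-group
#'     barrier (params: `nx`, `ny`, `spacing`, `theta`, `rho`, `theta2`,
#'     `rho2`, `s2`, `lambda`, `b`, `beta0`, `beta1`, `noise_sd`)}
#' }
#'
#' @param kind fixture kind
#' @param params named list of kind-specific parameters (defaults filled in)
#' @param seed integer seed
#' @return kind-specific list; see Details
#' @export
make_fixture <- function(kind = c("planted_roh", "two_cluster_coancestry",
                                  "anisotropic_lattice"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
         planted_roh = fixture_planted_roh(params),
         two_cluster_coancestry = fixture_two_cluster(params),
         anisotropic_lattice = fixture_lattice(params))
}

fixture_planted_roh <- function(p) {
  n_sites <- p$n_sites %||% 4000L
  chrom_length <- p$chrom_length %||% 5e6
  tracts <- p$tracts %||% list(c(1e6, 3e6))
  het_prob <- p$het_prob %||% 0.30
  n_samples <- p$n_samples %||% 1L
  for (tr in tracts)
    if (tr[2] <= tr[1])
      stop_pp("non-positive tract length", "pyrenpop_validation_error")
  positions <- sort(sample.int(chrom_length, n_sites)) - 1
  dos <- matrix(sample(c(0L, 1L, 2L), n_samples * n_sites, replace = TRUE,
                       prob = c((1 - het_prob) / 2, het_prob,
                                (1 - het_prob) / 2)),
                n_samples, n_sites)
  in_tract <- rep(FALSE, n_sites)
  for (tr in tracts) in_tract <- in_tract | (positions >= tr[1] & positions < tr[2])
  # planted tracts are fully homozygous in sample 1
  hom <- sample(c(0L, 2L), sum(in_tract), replace = TRUE)
  dos[1, in_tract] <- hom
  list(dosages = dos, positions = positions, tracts = tracts,
       chrom_length = chrom_length,
       sample_ids = paste0("S", seq_len(n_samples)))
}

fixture_two_cluster <- function(p) {
  n1 <- p$n1 %||% 6L; n2 <- p$n2 %||% 6L
  mu_w <- p$mu_within %||% 2; mu_b <- p$mu_between %||% 1
  sdv <- p$sd %||% 0.1
  n <- n1 + n2
  member <- rep(c(1L, 2L), c(n1, n2))
  same <- outer(member, member, "==")
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- ifelse(same[ut], mu_w, mu_b) + rnorm(sum(ut), 0, sdv)
  m <- m + t(m)
  m[m < 0] <- 0
  diag(m) <- NA
  list(coancestry = new_coancestry(m, paste0("S", seq_len(n))),
       membership = member)
}

fixture_lattice <- function(p) {
  nx <- p$nx %||% 6L; ny <- p$ny %||% 5L
  spacing <- p$spacing %||% 10
  theta <- p$theta %||% 0.4; rho <- p$rho %||% 2
  theta2 <- p$theta2 %||% 1.1; rho2 <- p$rho2 %||% 1.5
  s2 <- p$s2 %||% 1
  lambda <- p$lambda %||% 0.05
  b <- p$b %||% 3
  beta0 <- p$beta0 %||% 0.2; beta1 <- p$beta1 %||% 1
  noise_sd <- p$noise_sd %||% 0
  if (b < 0) stop_pp("negative barrier", "pyrenpop_validation_error")
  coords <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * spacing,
                                  y = (seq_len(ny) - 1) * spacing))
  n <- nrow(coords)
  grp <- ifelse(coords[, 1] < (nx / 2) * spacing - 1e-9, 1L, 2L)
  region <- paste0(c("A", "B")[grp], ifelse(coords[, 2] < (ny / 2) * spacing, 1, 2))
  groups <- list(list(theta = theta, rho = rho, s = 1),
                 list(theta = theta2, rho = rho2, s = s2))
  barrier <- matrix(c(0, b, b, 0), 2)
  fit <- new_barrier_fit(
    partition = setNames(c(1L, 1L, 2L, 2L), c("A1", "A2", "B1", "B2")),
    groups = groups, barrier = barrier,
    beta0 = beta0, beta1 = beta1, lambda = lambda)
  d <- pairwise_effective_distance(coords, grp, fit)
  cm <- beta0 + beta1 * exp(-lambda * d)
  if (noise_sd > 0) {
    e <- matrix(0, n, n)
    e[upper.tri(e)] <- rnorm(sum(upper.tri(e)), 0, noise_sd)
    cm <- cm + e + t(e)
    cm[cm < 0] <- 0
  }
  diag(cm) <- NA
  list(coancestry = new_coancestry(cm, paste0("L", seq_len(n))),
       coords = coords, regions = region, groups_of_points = grp,
       truth = fit)
}
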