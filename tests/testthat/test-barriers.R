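iso_fit <- function(b = 0) {
  new_barrier_fit(partition = c(A = 1L, B = 2L),
                  groups = list(list(theta = 0, rho = 1, s = 1),
                                list(theta = 0, rho = 1, s = 1)),
                  barrier = matrix(c(0, b, b, 0), 2),
                  beta0 = 0, beta1 = 1, lambda = 1)
}

test_that("effective distance reduces to hand-computed cases", {
  f <- iso_fit()
  expect_equal(effective_distance(c(0, 0), c(3, 4), 1, 1, f), 5)
  # rho = 2, theta = 0: the y axis is stretched twofold
  f2 <- iso_fit()
  f2$groups[[1]]$rho <- 2
  d_y <- effective_distance(c(0, 0), c(0, 1), 1, 1, f2)
  d_x <- effective_distance(c(0, 0), c(1, 0), 1, 1, f2)
  expect_equal(d_y, 2 * d_x)
  expect_equal(d_x, 1)
  # barrier adds to a cross-group pair even at zero spatial separation
  f5 <- iso_fit(b = 5)
  expect_equal(effective_distance(c(2, 2), c(2, 2), 1, 2, f5), 5)
  # rotation by theta moves the stretched axis
  f3 <- iso_fit(); f3$groups[[1]]$theta <- pi / 2; f3$groups[[1]]$rho <- 2
  expect_equal(effective_distance(c(0, 0), c(1, 0), 1, 1, f3), 2)
})

test_that("pairwise distances agree with the scalar form", {
  fx <- make_fixture("anisotropic_lattice", list(nx = 3, ny = 2), seed = 41)
  D <- pairwise_effective_distance(fx$coords, fx$groups_of_points, fx$truth)
  for (i in c(1, 4)) for (j in c(2, 6)) {
    expect_equal(D[i, j],
                 effective_distance(fx$coords[i, ], fx$coords[j, ],
                                    fx$groups_of_points[i],
                                    fx$groups_of_points[j], fx$truth))
  }
})

test_that("barrier and anisotropy are recovered from a noise-free lattice", {
  fx <- make_fixture("anisotropic_lattice", list(noise_sd = 0), seed = 42)
  part <- setNames(c(1L, 1L, 2L, 2L), c("A1", "A2", "B1", "B2"))
  fit <- fit_barrier_model(fx$coancestry, fx$coords, fx$regions, part,
                           n_starts = 20, seed = 43)
  expect_lt(abs(fit$barrier[1, 2] - 3) / 3, 0.05)
  expect_lt(abs(fit$groups[[1]]$rho - 2) / 2, 0.10)
  expect_lt(abs(fit$groups[[2]]$rho - 1.5) / 1.5, 0.10)
})

test_that("no spurious barrier is fitted when none was planted", {
  fx <- make_fixture("anisotropic_lattice", list(noise_sd = 0, b = 0),
                     seed = 44)
  part <- setNames(c(1L, 1L, 2L, 2L), c("A1", "A2", "B1", "B2"))
  fit <- fit_barrier_model(fx$coancestry, fx$coords, fx$regions, part,
                           n_starts = 12, seed = 45)
  expect_lt(fit$barrier[1, 2], 0.05 * fit$beta1)
})

test_that("a constant coancestry surface is fitted flat without failure", {
  n <- 12
  m <- matrix(1, n, n); diag(m) <- NA
  cm <- new_coancestry(m)
  coords <- cbind(rep(1:4, 3), rep(1:3, each = 4))
  regions <- rep(c("A", "B"), each = 6)
  fit <- fit_barrier_model(cm, coords, regions, c(A = 1L, B = 2L),
                           n_starts = 4, seed = 46)
  expect_lt(fit$fit_score, 1e-10)
  expect_lt(fit$beta1, 1e-4)
})

test_that("the barrier model never scores worse than its nested no-barrier model", {
  for (s in 47:49) {
    fx <- make_fixture("anisotropic_lattice",
                       list(noise_sd = 0.3, b = (s - 47) * 2), seed = s)
    part <- setNames(c(1L, 1L, 2L, 2L), c("A1", "A2", "B1", "B2"))
    fb <- fit_barrier_model(fx$coancestry, fx$coords, fx$regions, part,
                            n_starts = 4, seed = s, maxit = 600)
    f0 <- fit_barrier_model(fx$coancestry, fx$coords, fx$regions, part,
                            n_starts = 4, seed = s, barrier = FALSE,
                            maxit = 600)
    expect_lte(fb$fit_score, f0$fit_score + 1e-9)
  }
})

test_that("the fit score is invariant to sample reordering", {
  fx <- make_fixture("anisotropic_lattice", list(noise_sd = 0.1), seed = 50)
  part <- setNames(c(1L, 1L, 2L, 2L), c("A1", "A2", "B1", "B2"))
  set.seed(2)
  perm <- sample(length(fx$regions))
  cmp <- new_coancestry(fx$coancestry$lengths[perm, perm])
  fa <- fit_barrier_model(fx$coancestry, fx$coords, fx$regions, part,
                          n_starts = 6, seed = 51)
  fb <- fit_barrier_model(cmp, fx$coords[perm, ], fx$regions[perm], part,
                          n_starts = 6, seed = 51)
  expect_equal(fa$fit_score, fb$fit_score, tolerance = 1e-6)
})

test_that("partition enumeration matches Stirling counts", {
  expect_identical(length(pyrenpop:::set_partitions_k(letters[1:5], 2)), 15L)
  expect_identical(length(pyrenpop:::set_partitions_k(letters[1:2], 2)), 1L)
  expect_identical(length(pyrenpop:::set_partitions_k(letters[1:4], 3)), 6L)
})

test_that("partition search finds the planted grouping and validates k", {
  fx <- make_fixture("anisotropic_lattice",
                     list(nx = 4, ny = 4, noise_sd = 0.02), seed = 52)
  sp <- search_partitions(fx$coancestry, fx$coords, fx$regions, k = 2,
                          n_starts = 4, seed = 53)
  best <- sp$best_fit$partition
  expect_identical(best[["A1"]], best[["A2"]])
  expect_identical(best[["B1"]], best[["B2"]])
  expect_false(best[["A1"]] == best[["B1"]])
  expect_identical(nrow(sp$table), 7L)  # partitions of 4 regions into 2
  expect_error(search_partitions(fx$coancestry, fx$coords, fx$regions, k = 5),
               class = "pyrenpop_validation_error")
})

test_that("the permutation test is seeded, bounded and detects a planted barrier", {
  fx <- make_fixture("anisotropic_lattice",
                     list(nx = 4, ny = 4, b = 30, noise_sd = 0.01), seed = 54)
  part <- setNames(c(1L, 1L, 2L, 2L), c("A1", "A2", "B1", "B2"))
  fit <- fit_barrier_model(fx$coancestry, fx$coords, fx$regions, part,
                           n_starts = 4, seed = 55, maxit = 600)
  p1 <- barrier_permutation_test(fx$coancestry, fx$coords, fx$regions, fit,
                                 n_perm = 99, seed = 56, n_starts_perm = 2)
  p2 <- barrier_permutation_test(fx$coancestry, fx$coords, fx$regions, fit,
                                 n_perm = 99, seed = 56, n_starts_perm = 2)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal(p1$p_value, 1 / 100)
  expect_error(barrier_permutation_test(fx$coancestry, fx$coords, fx$regions,
                                        fit, n_perm = 10, seed = 1),
               class = "pyrenpop_validation_error")
})
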