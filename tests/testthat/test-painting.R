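# independent forward-backward oracle: naive O(K^2) implementation with an
# explicit transition matrix, kept deliberately different from the package's
# scaled single-pass recursion
fb_oracle <- function(H, rec, q, w, miscopy) {
  L <- nrow(H); K <- ncol(H)
  em <- function(l) ifelse(H[l, ] == rec[l], 1 - miscopy, miscopy)
  A <- matrix(0, L, K)
  A[1, ] <- em(1) / K
  for (l in 2:L) {
    Tm <- (1 - q[l - 1]) * diag(K) + q[l - 1] / K
    A[l, ] <- em(l) * as.vector(t(Tm) %*% A[l - 1, ])
    A[l, ] <- A[l, ] / sum(A[l, ])  # rescale (oracle compares posteriors)
  }
  B <- matrix(0, L, K)
  B[L, ] <- 1
  for (l in (L - 1):1) {
    Tm <- (1 - q[l]) * diag(K) + q[l] / K
    B[l, ] <- as.vector(Tm %*% (em(l + 1) * B[l + 1, ]))
    B[l, ] <- B[l, ] / sum(B[l, ])
  }
  G <- A * B
  G <- G / rowSums(G)
  colSums(G * w)
}

toy_hap_set <- function(L = 40, K = 3, seed = 1) {
  set.seed(seed)
  H <- matrix(rbinom(L * K, 1, 0.5), L, K)
  pos <- sort(sample.int(L * 500, L)) - 1
  list(H = H, pos = pos)
}

test_that("the painting posterior matches an independent forward-backward oracle", {
  th <- toy_hap_set(L = 40, K = 3, seed = 21)
  rec <- th$H[, 1]; rec[c(5, 17, 30)] <- 1 - rec[c(5, 17, 30)]
  q <- 1 - exp(-2e-4 * diff(th$pos))
  w <- rep(1, 40)
  got <- pyrenpop:::ls_paint_hap(th$H, rec, q, w, 0.05)
  want <- fb_oracle(th$H, rec, q, w, 0.05)
  expect_equal(got$copied, want, tolerance = 1e-8)
})

test_that("a recipient matching one donor copies almost everything from it", {
  th <- toy_hap_set(L = 120, K = 4, seed = 22)
  rec <- th$H[, 2]
  q <- 1 - exp(-1e-5 * diff(th$pos))
  w <- pyrenpop:::site_spans(th$pos)
  got <- pyrenpop:::ls_paint_hap(th$H, rec, q, w, 0.01)
  fr <- got$copied / sum(got$copied)
  expect_gt(fr[2], 0.9)
  # in the zero-switch, zero-miscopy limit the fraction goes to 1
  got0 <- pyrenpop:::ls_paint_hap(th$H, rec, rep(1e-14, 119), w, 1e-9)
  expect_gt(got0$copied[2] / sum(got0$copied), 1 - 1e-6)
})

test_that("identical donors receive identical expected copy lengths", {
  set.seed(23)
  h <- matrix(rbinom(8 * 50, 1, 0.5), 8, 50)
  h[5, ] <- h[3, ]; h[6, ] <- h[4, ]  # individual 3 duplicates individual 2
  pos <- sort(sample.int(30000, 50)) - 1
  panel <- new_panel(h, pos, paste0("S", 1:4), rep("G", 4))
  cm <- paint_panel(panel, switch_rate = 1e-4, miscopy_rate = 0.05)
  expect_lt(max(abs(cm$lengths[2, c(1, 4)] - cm$lengths[3, c(1, 4)])), 1e-9)
})

test_that("painting conserves posterior mass per recipient", {
  panel <- toy_panel(n = 5, L = 80, seed = 24)
  cm <- paint_panel(panel, switch_rate = 1e-4)
  total <- sum(pyrenpop:::site_spans(panel$positions))
  expect_equal(unname(colSums(cm$lengths, na.rm = TRUE)),
               rep(2 * total, 5), tolerance = 1e-6)
})

test_that("painting refuses unphased input", {
  panel <- toy_panel(n = 4, L = 30, seed = 25)
  panel$phased <- FALSE
  expect_error(paint_panel(panel, 1e-4), class = "pyrenpop_phase_error")
})

test_that("EM switch-rate estimation has a non-decreasing likelihood trace", {
  panel <- toy_panel(n = 5, L = 100, seed = 26)
  est <- estimate_switch_rate(panel, n_em_iters = 5, init = 1e-5)
  expect_true(all(diff(est$loglik_trace) > -1e-6))
  expect_error(estimate_switch_rate(toy_panel(n = 4, L = 1), n_em_iters = 2),
               class = "pyrenpop_validation_error")
})

test_that("mutually identical haplotypes drive the switch rate to its floor", {
  set.seed(27)
  h <- matrix(rbinom(60, 1, 0.5), 8, 60, byrow = TRUE)  # every row identical
  pos <- sort(sample.int(40000, 60)) - 1
  panel <- new_panel(h, pos, paste0("S", 1:4), rep("G", 4))
  est <- estimate_switch_rate(panel, n_em_iters = 4,
                              bounds = c(1e-12, 1e-2))
  expect_lt(est$switch_rate, 1e-9)
})

test_that("higher recombination yields higher estimated switch rates", {
  cfg_lo <- model_config(sequence_length = 2e5, recombination_rate = 1e-9,
                         mutation_rate = 5e-8)
  cfg_hi <- model_config(sequence_length = 2e5, recombination_rate = 5e-8,
                         mutation_rate = 5e-8)
  lo <- simulate_single_pop(1000, 5, cfg_lo, n_reps = 6, seed = 31)
  hi <- simulate_single_pop(1000, 5, cfg_hi, n_reps = 6, seed = 31)
  r_lo <- vapply(lo, function(p)
    estimate_switch_rate(p, n_em_iters = 3)$switch_rate, numeric(1))
  r_hi <- vapply(hi, function(p)
    estimate_switch_rate(p, n_em_iters = 3)$switch_rate, numeric(1))
  expect_gt(mean(r_hi), mean(r_lo))
})
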