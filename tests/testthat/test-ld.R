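test_that("HR equals brute-force Pearson r^2 from raw sums", {
  set.seed(61)
  for (i in 1:20) {
    a <- sample(0:2, 50, replace = TRUE)
    b <- sample(0:2, 50, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    n <- 50
    num <- n * sum(a * b) - sum(a) * sum(b)
    den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
    expect_equal(hr_statistic(a, b), (num / den)^2, tolerance = 1e-12)
  }
})

test_that("HR is 1 for identical and perfectly anti-correlated dosages", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(hr_statistic(a, a), 1)
  expect_equal(hr_statistic(a, rev(a)), 1)  # r = -1, r^2 = 1
})

test_that("HR is invariant to allele-label flips at either site", {
  set.seed(62)
  for (i in 1:10) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(hr_statistic(a, b), hr_statistic(2 - a, b), tolerance = 1e-12)
    expect_equal(hr_statistic(a, b), hr_statistic(a, 2 - b), tolerance = 1e-12)
  }
})

test_that("HR rejects monomorphic sites and tiny samples", {
  expect_error(hr_statistic(rep(1, 10), sample(0:2, 10, replace = TRUE)),
               class = "pyrenpop_ld_error")
  expect_error(hr_statistic(c(0, 1, 2), c(2, 1, 0)),
               class = "pyrenpop_validation_error")
})

test_that("MAF matching includes |dMAF| < 0.05 and excludes the rest", {
  # 50 diploids; three sites with MAF 0.30, 0.34, 0.36
  set.seed(63)
  mk <- function(n_alt) {
    v <- c(rep(1, n_alt), rep(0, 100 - n_alt))[sample(100)]
    v[seq(1, 99, 2)] + v[seq(2, 100, 2)]
  }
  d <- cbind(mk(30), mk(34), mk(36))
  pos <- c(0, 1000, 2000)
  cfg <- ld_config(bin_edges = c(0, 5000), min_maf = 0.05)
  curve <- ld_decay(d, positions = pos, config = cfg, return_pairs = TRUE)
  # pairs (1,2): dMAF 0.04 kept; (1,3): 0.06 dropped; (2,3): 0.02 kept
  expect_identical(curve$n_pairs, 2L)
  expect_identical(nrow(curve$pairs), 2L)
  expect_setequal(curve$pairs$dist, c(1000, 1000))
})

test_that("empty bins report count 0 and NA mean, and bin means are consistent", {
  panel <- toy_panel(n = 8, L = 60, seed = 64, span_bp = 3e5)
  cfg <- ld_config(bin_edges = seq(0, 4e5, 5e4), min_maf = 0.01,
                   maf_tolerance = 0.5)
  curve <- ld_decay(panel, config = cfg, return_pairs = TRUE)
  empty <- curve$n_pairs == 0
  expect_true(all(is.na(curve$mean_hr[empty])))
  # recompute bin means from emitted per-pair records: exact agreement
  for (b in which(!empty)) {
    expect_equal(curve$mean_hr[b],
                 mean(curve$pairs$hr[curve$pairs$bin == b]))
    expect_identical(curve$n_pairs[b], sum(curve$pairs$bin == b))
  }
})

test_that("LD decay requires at least five individuals", {
  panel <- toy_panel(n = 4, L = 30, seed = 65)
  expect_error(ld_decay(panel), class = "pyrenpop_validation_error")
})
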