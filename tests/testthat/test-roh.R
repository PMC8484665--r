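test_that("a planted 2 Mb homozygous tract is recovered almost entirely", {
  fx <- make_fixture("planted_roh",
                     list(n_sites = 6000, tracts = list(c(1e6, 3e6))),
                     seed = 71)
  roh <- detect_roh(fx$dosages, positions = fx$positions)
  expect_gte(nrow(roh), 1)
  ov <- pmin(roh$end, 3e6) - pmax(roh$start, 1e6)
  expect_gt(max(ov) / 2e6, 0.95)
})

test_that("all-heterozygous and all-homozygous chromosomes are edge cases", {
  set.seed(70)
  pos <- sort(sample.int(5e6, 4000)) - 1
  expect_identical(nrow(detect_roh(matrix(1L, 1, 4000), positions = pos)), 0L)
  hom <- matrix(sample(c(0L, 2L), 4000, replace = TRUE), 1)
  roh <- detect_roh(hom, positions = pos)
  expect_identical(nrow(roh), 1L)
  expect_equal(roh$start, pos[1])
  expect_equal(roh$end, pos[4000] + 1)
})

test_that("unsorted positions are rejected", {
  expect_error(detect_roh(matrix(0L, 1, 3), positions = c(10, 5, 20)),
               class = "pyrenpop_validation_error")
})

test_that("segments are split at long marker gaps", {
  # two dense homozygous blocks separated by a 500 kb marker desert
  pos <- c(seq(0, 1.5e6, by = 1000), seq(2e6, 3.5e6, by = 1000))
  d <- matrix(0L, 1, length(pos))
  roh <- detect_roh(d, positions = pos,
                    params = roh_params(max_gap_bp = 1e5))
  expect_identical(nrow(roh), 2L)
})

test_that("Kruskal-Wallis on RoH totals matches a hand-ranked oracle", {
  totals <- c(10, 11, 12, 100, 110, 120)
  regions <- rep(c("A", "B"), each = 3)
  res <- roh_region_test(totals, regions)
  # ranks 1..6, no ties: H = 12/(n(n+1)) * sum R_g^2/n_g - 3(n+1)
  H_hand <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(res$H, H_hand, tolerance = 1e-12)
  expect_equal(res$H, 3.857142857142854, tolerance = 1e-9)
})

test_that("identical totals give H = 0 and p = 1", {
  res <- roh_region_test(rep(5e6, 8), rep(c("A", "B"), 4))
  expect_identical(res$H, 0)
  expect_identical(res$p_value, 1)
})

test_that("the test demands two samples per region and two regions", {
  expect_error(roh_region_test(c(1, 2, 3), c("A", "A", "B")),
               class = "pyrenpop_validation_error")
  expect_error(roh_region_test(c(1, 2), c("A", "A")),
               class = "pyrenpop_validation_error")
})

test_that("p-values are calibrated when labels carry no information", {
  set.seed(72)
  totals <- rnorm(20)
  ps <- replicate(300, {
    roh_region_test(totals, sample(rep(c("A", "B", "C", "D"), 5)))$p_value
  })
  # chi-square approximation: roughly uniform p under the null
  expect_gt(mean(ps > 0.05), 0.85)
  expect_lt(mean(ps > 0.05), 1)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 1e-4)
})
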