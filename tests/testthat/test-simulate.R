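test_that("zero mutation rate yields a panel with no variant sites", {
  p <- median_params_old_split()
  panel <- simulate_dataset(p, model_config(mutation_rate = 0,
                                            sequence_length = 2e5, seed = 1))
  expect_identical(length(panel$positions), 0L)
  expect_identical(ncol(panel$haplotypes), 0L)
})

test_that("identical seeds give bit-identical panels", {
  p <- median_params_old_split(m = 1e-3)
  cfg <- model_config(sequence_length = 3e5, seed = 17)
  a <- simulate_dataset(p, cfg)
  b <- simulate_dataset(p, cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$positions, b$positions)
  c <- simulate_dataset(p, model_config(sequence_length = 3e5, seed = 18))
  expect_false(identical(a$positions, c$positions))
})

test_that("single-population reduction matches Watterson's expectation", {
  # theta = 4 * (Ne/2) * mu * L; E[S] = theta * sum_{i=1}^{n-1} 1/i
  ne_hap <- 1000; n_dip <- 5; L <- 5e5; mu <- 1.25e-8
  cfg <- model_config(sequence_length = L, mutation_rate = mu)
  panels <- simulate_single_pop(ne_hap, n_dip, cfg, n_reps = 60, seed = 9)
  S <- vapply(panels, function(p) length(p$positions), numeric(1))
  theta <- 4 * (ne_hap / 2) * mu * L
  expected <- theta * sum(1 / seq_len(2 * n_dip - 1))
  expect_lt(abs(mean(S) / expected - 1), 0.10)
})

test_that("an older root split gives higher FST between the two pools", {
  base <- median_params_old_split()
  young <- base; young$t_GRUBP <- 2500; young$t_GR <- 870; young$t_UPB <- 870
  cfg <- model_config(sequence_length = 3e5)
  fst_pool <- function(panel) {
    gr <- panel$region_labels %in% c("G", "R")
    d <- panel_dosages(panel)
    hudson_fst(d[gr, , drop = FALSE], d[!gr, , drop = FALSE])
  }
  n_rep <- 12
  old_f <- vapply(simulate_batch(rep(list(base), n_rep), cfg, seed = 21),
                  fst_pool, numeric(1))
  new_f <- vapply(simulate_batch(rep(list(young), n_rep), cfg, seed = 22),
                  fst_pool, numeric(1))
  expect_gt(mean(old_f), mean(new_f))
})

test_that("time-ordering violations are rejected before simulation", {
  p <- median_params_old_split()
  p$t_UPB <- p$t_GRUBP + 500
  expect_error(simulate_dataset(unclass(p), model_config()),
               class = "pyrenpop_validation_error")
})

test_that("panel invariants hold on simulated output", {
  p <- median_params_old_split(m = 5e-3)
  panel <- simulate_dataset(p, model_config(sequence_length = 3e5, seed = 4))
  expect_true(all(diff(panel$positions) > 0))
  expect_true(all(panel$haplotypes %in% c(0L, 1L)))
  expect_identical(nrow(panel$haplotypes), 2L * length(panel$sample_ids))
  cs <- colSums(panel$haplotypes)
  expect_true(all(cs > 0 & cs < nrow(panel$haplotypes)))  # segregating only
  expect_identical(sort(unique(panel$region_labels)),
                   sort(c("G", "R", "U", "P", "B")))
})
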