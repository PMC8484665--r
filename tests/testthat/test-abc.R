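test_that("half-range mode matches the brute-force oracle on small sets", {
  expect_equal(half_range_mode(c(0, 0, 0, 1)), 0)
  set.seed(91)
  for (i in 1:100) {
    v <- round(runif(sample(3:10, 1), 0, 10), 2)
    expect_equal(half_range_mode(v), hrm_oracle(v))
  }
})

test_that("the 89% HDI of a large uniform sample has width 0.89", {
  set.seed(92)
  v <- runif(1e5)
  h <- hdi_interval(v, 0.89)
  expect_lt(abs((h[2] - h[1]) - 0.89), 0.01)
})

test_that("posterior summaries are coherent and guard small samples", {
  set.seed(93)
  v <- c(rep(1:3, 4))
  s <- posterior_summaries(v)
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_lte(s$ci_low, s$median); expect_gte(s$ci_high, s$median)
  expect_lte(s$hdi_low, s$hdi_high)
  expect_error(posterior_summaries(1:3), class = "pyrenpop_validation_error")
  # HDI and CI both contain the median on asymmetric samples
  w <- rexp(500)
  sw <- posterior_summaries(w)
  expect_true(sw$hdi_low <= sw$median && sw$median <= sw$hdi_high)
})

test_that("abc_reject with accept_fraction 1 returns the prior draws", {
  set.seed(94)
  P <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  S <- P + rnorm(200, 0, 0.1)
  post <- abc_reject(S[1, ], P, S, accept_fraction = 1)
  expect_identical(nrow(post$params), 50L)
  expect_equal(sort(post$params[, "a"]), sort(P[, "a"]))
})

test_that("abc_reject recovers a simulation from its own summary", {
  set.seed(95)
  P <- matrix(rnorm(400), 100, 4)
  S <- P + rnorm(400, 0, 0.05)
  post <- abc_reject(S[37, ], P, S, accept_fraction = 1 / 100)
  expect_identical(post$indices, 37L)
  expect_error(abc_reject(S[1, ], P, S, accept_fraction = 1e-4),
               class = "pyrenpop_validation_error")
})

test_that("the summary regressor learns, is seeded, and drops constants", {
  set.seed(96)
  X <- matrix(rnorm(300 * 6), 300, 6)
  X <- cbind(X, 1)  # constant column
  Y <- cbind(y1 = X[, 1] + 0.5 * X[, 2]^2 + rnorm(300, 0, 0.1),
             y2 = X[, 3] + rnorm(300, 0, 0.1))
  expect_warning(reg <- train_summary_regressor(X, Y, epochs = 150, seed = 5),
                 "constant")
  expect_true(all(diff(reg$loss_trace) <= 1e-12))
  pr <- predict(reg, X)
  expect_gt(cor(pr[, "y1"], Y[, "y1"]), 0.8)
  reg2 <- suppressWarnings(train_summary_regressor(X, Y, epochs = 150, seed = 5))
  expect_identical(reg$loss_trace, reg2$loss_trace)
  expect_identical(predict(reg2, X), pr)
  expect_error(train_summary_regressor(X[1:50, ], Y[1:50, ]),
               class = "pyrenpop_validation_error")
})

test_that("panel summaries are deterministic with a fixed, documented layout", {
  bank <- get_abc_bank()
  panel_params <- sample_priors(seed = derive_seeds(7, 1, stream = 10L))
  panel <- simulate_dataset(panel_params,
                            model_config(sequence_length = 1e6, seed = 501))
  a <- summarize_panel(panel)
  b <- summarize_panel(panel)
  expect_identical(a, b)
  sfs <- a[grep("^sfs_G_", names(a))]
  expect_equal(sum(sfs), 1, tolerance = 1e-12)
  expect_identical(length(a), ncol(bank$S))
  expect_true(all(startsWith(
    names(a)[c(1, 30, 35, 45, 55, 70)],
    c("sfs_", "het_", "fst_", "dxy_", "hr_", "roh_"))))
})

test_that("a monomorphic panel is summarized with explicit flags", {
  h <- matrix(0L, 2 * 29, 0)
  panel <- new_panel(h, numeric(0), paste0("S", 1:29), study_labels(),
                     sequence_length = 1e6)
  s <- summarize_panel(panel)
  expect_true(all(s[grep("^sfs_", names(s))] == 0))
  expect_true(all(s[grep("^fst_", names(s))] == 0))
  expect_gt(length(attr(s, "flags")), 0)
})

test_that("the learned mapping is informative for the root population size", {
  bank <- get_abc_bank()
  pr <- predict(bank$reg, bank$S[bank$itrain, ])
  expect_gt(cor(pr[, "Ne_GRUBP"], bank$pmat[bank$itrain, "Ne_GRUBP"]), 0.3)
})

test_that("posterior medians beat the prior median for the root size", {
  bank <- get_abc_bank()
  prior_med <- (15000 + 40000) / 2
  wins <- 0
  for (i in bank$iobs) {
    post <- suppressWarnings(
      abc_reject(bank$S[i, ], bank$pmat[bank$iref, ],
                 bank$S[bank$iref, ], bank$reg, accept_fraction = 0.05))
    truth <- bank$pmat[i, "Ne_GRUBP"]
    wins <- wins +
      (abs(median(post$params[, "Ne_GRUBP"]) - truth) < abs(prior_med - truth))
  }
  expect_gte(wins / length(bank$iobs), 0.7)
})

test_that("simulation-based calibration: rank statistics are uniform", {
  bank <- get_abc_bank()
  set.seed(17)
  obs_idx <- sample(bank$iref, 50)
  ranks <- vapply(obs_idx, function(i) {
    ref <- setdiff(bank$iref, i)
    post <- suppressWarnings(
      abc_reject(bank$S[i, ], bank$pmat[ref, ], bank$S[ref, ], bank$reg,
                 accept_fraction = 0.05))
    v <- post$params[, "t_GRUBP"]
    # jittered rank of the truth within its own posterior sample
    (sum(v < bank$pmat[i, "t_GRUBP"]) + runif(1)) / (length(v) + 1)
  }, numeric(1))
  cs <- suppressWarnings(
    stats::chisq.test(table(cut(ranks, breaks = seq(0, 1, 0.1)))))
  expect_gt(cs$p.value, 0.01)
})

test_that("the end-to-end pipeline emits the posterior-summary report", {
  bank <- get_abc_bank()
  obs <- bank$S[1010, ]
  sims <- list(params = bank$pmat[1:700, ], summaries = bank$S[1:700, ],
               n_train = 500)
  rep_ <- suppressWarnings(
    run_abc_pipeline(obs, accept_fraction = 0.1, seed = 2, sims = sims))
  expect_identical(dim(rep_$table), c(11L, 9L))  # parameter + 8 report columns
  expect_identical(names(rep_$table),
                   c("parameter", "prior", "mean", "median",
                     "half_range_mode", "ci_2.5", "ci_97.5",
                     "hdi_low", "hdi_high"))
  expect_identical(rep_$table$parameter, model_param_names())
  # marginal posterior locations stay inside the resolved prior bounds
  pr <- default_priors()
  for (i in 1:11) {
    lo <- pr$low[i]
    hi <- suppressWarnings(as.numeric(pr$high[i]))
    if (is.na(hi)) hi <- 14500
    expect_gte(rep_$table$mean[i], lo); expect_lte(rep_$table$mean[i], hi)
    expect_gte(rep_$table$median[i], lo); expect_lte(rep_$table$median[i], hi)
  }
})
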