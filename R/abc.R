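#' ABC rejection step
#'
#' Observed and simulated summaries are mapped through the learned regressor
#' (if supplied), each dimension is standardized by its simulation mean/SD
#' (zero-SD dimensions dropped with a warning), and the simulations with the
#' lowest `accept_fraction` quantile of Euclidean distances to the observed
#' point are accepted.
#'
#' @param observed observed summary vector
#' @param sim_params n x q matrix of simulated parameter draws
#' @param sim_summaries n x p matrix of their summaries
#' @param mapping optional `pp_regressor` (NULL = raw-summary rejection)
#' @param accept_fraction fraction of simulations to accept, in (0, 1]
#' @return list of class `pp_posterior`: `params` (accepted draws),
#'   `distances`, `tolerance`, `indices`
#' @export
abc_reject <- function(observed, sim_params, sim_summaries, mapping = NULL,
                       accept_fraction = 0.05) {
  sim_params <- as.matrix(sim_params)
  sim_summaries <- as.matrix(sim_summaries)
  n <- nrow(sim_summaries)
  if (n < 1) stop_pp("no simulations supplied", "pyrenpop_validation_error")
  if (accept_fraction <= 0 || accept_fraction > 1)
    stop_pp("accept_fraction must be in (0, 1]", "pyrenpop_validation_error")
  if (!is.null(mapping)) {
    S <- predict(mapping, sim_summaries)
    o <- predict(mapping, matrix(observed, 1))
  } else {
    S <- sim_summaries
    o <- matrix(observed, 1)
  }
  mu <- colMeans(S); s <- apply(S, 2, sd)
  keep <- s > 0
  if (any(!keep)) warning(sprintf("dropping %d zero-variance dimension(s)",
                                  sum(!keep)))
  Z <- sweep(sweep(S[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  zo <- (o[, keep, drop = FALSE] - mu[keep]) / s[keep]
  dist2 <- colSums((t(Z) - as.numeric(zo))^2)
  n_acc <- floor(accept_fraction * n)
  if (n_acc < 1)
    stop_pp("accept_fraction yields zero accepted simulations",
            "pyrenpop_validation_error")
  idx <- order(dist2)[seq_len(n_acc)]
  structure(list(params = sim_params[idx, , drop = FALSE],
                 distances = sqrt(dist2[idx]),
                 tolerance = sqrt(max(dist2[idx])), indices = idx),
            class = "pp_posterior")
}

#' Half-range mode of a sample
#'
#' Iterative modal-interval halving: repeatedly keep the half-range window
#' (leftmost on ties) containing the most points, until at most two points
#' (or a zero range) remain; return their mean.
#'
#' @param values numeric vector
#' @return scalar mode estimate
#' @export
half_range_mode <- function(values) {
  v <- sort(values)
  while (length(v) > 2) {
    rng <- v[length(v)] - v[1]
    if (rng == 0) return(v[1])
    w <- rng / 2
    cnt <- findInterval(v + w, v) - seq_along(v) + 1
    i <- which.max(cnt)  # leftmost maximal window
    v <- v[v >= v[i] & v <= v[i] + w]
  }
  mean(v)
}

#' Shortest contiguous highest-density interval
#'
#' The shortest interval between order statistics containing
#' `ceiling(prob * n)` of the sample values.
#'
#' @param values numeric vector
#' @param prob probability mass (default 0.89)
#' @return c(low, high)
#' @export
hdi_interval <- function(values, prob = 0.89) {
  v <- sort(values)
  n <- length(v)
  m <- ceiling(prob * n)
  if (m >= n) return(c(v[1], v[n]))
  width <- v[(m):n] - v[1:(n - m + 1)]
  i <- which.min(width)
  c(v[i], v[i + m - 1])
}

#' Posterior summaries of one parameter
#'
#' Mean, median, half-range mode, 95% credible interval (empirical 2.5/97.5
#' quantiles, linear interpolation) and 89% highest-density interval.
#'
#' @param samples numeric vector of accepted parameter values (>= 10)
#' @return list of class `pp_summary`: `mean`, `median`, `half_range_mode`,
#'   `ci_low`, `ci_high`, `hdi_low`, `hdi_high`
#' @export
posterior_summaries <- function(samples) {
  if (length(samples) < 10)
    stop_pp("need >= 10 accepted values", "pyrenpop_validation_error")
  q <- quantile(samples, c(0.025, 0.975), names = FALSE, type = 7)
  h <- hdi_interval(samples, 0.89)
  structure(list(mean = mean(samples), median = median(samples),
                 half_range_mode = half_range_mode(samples),
                 ci_low = q[1], ci_high = q[2],
                 hdi_low = h[1], hdi_high = h[2]),
            class = "pp_summary")
}

prior_label <- function(priors) {
  setNames(sprintf("U (%s, %s)", format(priors$low, trim = TRUE),
                   priors$high), priors$name)
}

#' Run the full ABC inference pipeline
#'
#' End-to-end orchestration: draw parameters from the priors, simulate
#' training and reference sets, summarize all panels, train the summary
#' regressor on the training set, reject against the reference set, and
#' summarize the marginal posteriors of the 11 demographic parameters in a
#' report with the columns prior, mean, median, half-range mode, CI 2.5%,
#' CI 97.5%, low HDI, high HDI.
#'
#' @param observed an observed `pp_panel` (or a summary vector)
#' @param n_train training simulations for the regressor
#' @param n_abc reference simulations for rejection
#' @param accept_fraction rejection acceptance fraction
#' @param sim_config `pp_config` used for every simulation
#' @param priors prior table
#' @param use_net train and use the learned summary regressor (FALSE = raw
#'   summary rejection)
#' @param seed master seed
#' @param sims optional pre-computed list(params=, summaries=) reference
#'   bank to reuse across calls (then only the rejection is redone)
#' @return list of class `pp_abc_report`: `table` (11 x 8 data.frame),
#'   `posterior` (`pp_posterior`), `regressor`, `bank` (reusable
#'   simulations)
#' @export
run_abc_pipeline <- function(observed, n_train = 2000, n_abc = 1000,
                             accept_fraction = 0.05,
                             sim_config = model_config(sequence_length = 1e6),
                             priors = default_priors(), use_net = TRUE,
                             seed = 1L, sims = NULL) {
  obs_sum <- if (inherits(observed, "pp_panel")) summarize_panel(observed)
             else observed
  if (is.null(sims)) {
    n_tot <- n_train + n_abc
    seeds <- derive_seeds(seed, n_tot, stream = 10L)
    params <- lapply(seeds, function(s) sample_priors(priors, seed = s))
    panels <- simulate_batch(params, sim_config, seed = seed)
    summaries <- t(vapply(panels, summarize_panel,
                          numeric(length(obs_sum))))
    pmat <- t(vapply(params, function(p)
      unlist(p[model_param_names()]), numeric(11)))
    colnames(pmat) <- model_param_names()
    sims <- list(params = pmat, summaries = summaries,
                 n_train = n_train)
  }
  n_train <- sims$n_train
  itr <- seq_len(n_train)
  iab <- seq(n_train + 1, nrow(sims$params))
  reg <- NULL
  if (use_net)
    reg <- train_summary_regressor(sims$summaries[itr, , drop = FALSE],
                                   sims$params[itr, , drop = FALSE],
                                   seed = derive_seeds(seed, 1, stream = 11L))
  post <- abc_reject(obs_sum, sims$params[iab, , drop = FALSE],
                     sims$summaries[iab, , drop = FALSE],
                     mapping = reg, accept_fraction = accept_fraction)
  labs <- prior_label(priors)
  rows <- lapply(model_param_names(), function(pn) {
    s <- posterior_summaries(post$params[, pn])
    data.frame(parameter = pn, prior = unname(labs[pn]), mean = s$mean,
               median = s$median, half_range_mode = s$half_range_mode,
               ci_2.5 = s$ci_low, ci_97.5 = s$ci_high,
               hdi_low = s$hdi_low, hdi_high = s$hdi_high,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, posterior = post, regressor = reg,
                 bank = sims), class = "pp_abc_report")
}
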