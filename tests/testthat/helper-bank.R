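# one shared ABC simulation bank, built lazily and reused by every test
# file in the session (520 reference + 500 training + 20 pseudo-observed
# datasets at 1 Mb keeps the whole suite tractable on one CPU)

.bank_env <- new.env(parent = emptyenv())

get_abc_bank <- function() {
  if (!is.null(.bank_env$bank)) return(.bank_env$bank)
  n_tot <- 1020L
  seeds <- derive_seeds(7, n_tot, stream = 10L)
  params <- lapply(seeds, function(s) sample_priors(seed = s))
  panels <- simulate_batch(params, model_config(sequence_length = 1e6),
                           seed = 7)
  s1 <- summarize_panel(panels[[1]])
  S <- t(vapply(panels, summarize_panel, numeric(length(s1))))
  pmat <- t(vapply(params, function(p) unlist(p[model_param_names()]),
                   numeric(11)))
  colnames(pmat) <- model_param_names()
  reg <- suppressWarnings(
    train_summary_regressor(S[1:500, ], pmat[1:500, ], seed = 3))
  .bank_env$bank <- list(S = S, pmat = pmat, reg = reg,
                         itrain = 1:500, iref = 501:1000, iobs = 1001:1020)
  .bank_env$bank
}
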