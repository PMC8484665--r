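# small deterministic in-memory panels (no simulator involved)

toy_panel <- function(n = 5, L = 60, seed = 1, labels = NULL,
                      span_bp = L * 1000) {
  set.seed(seed)
  h <- matrix(rbinom(2 * n * L, 1, 0.4), 2 * n, L)
  pos <- sort(sample.int(span_bp, L)) - 1
  new_panel(h, pos, paste0("S", seq_len(n)),
            labels %||% rep("G", n), sequence_length = span_bp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# posterior-median parameter vector of the demographic model with an old root split and no
# migration: the clearest structured condition of the five-population model
median_params_old_split <- function(m = 0) {
  validate_params(list(
    Ne_GRUBP = 27079, Ne_GR = 1586, Ne_UPB = 1248, Ne_G = 840, Ne_R = 1679,
    Ne_U = 320, Ne_P = 719, Ne_B = 7766,
    t_GRUBP = 14500, t_GR = 870, t_UPB = 870, m = m))
}

study_labels <- function() rep(c("G", "R", "U", "P", "B"), c(6, 6, 6, 6, 5))
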