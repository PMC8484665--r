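# brute-force half-range mode oracle: literal recursion on the definition,
# independent of the package's findInterval-based implementation
hrm_oracle <- function(v) {
  v <- sort(v)
  if (length(v) <= 2) return(mean(v))
  rng <- v[length(v)] - v[1]
  if (rng == 0) return(v[1])
  w <- rng / 2
  best_i <- NULL; best_n <- -1
  for (i in seq_along(v)) {
    n_in <- sum(v >= v[i] & v <= v[i] + w)
    if (n_in > best_n) { best_n <- n_in; best_i <- i }
  }
  hrm_oracle(v[v >= v[best_i] & v <= v[best_i] + w])
}
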