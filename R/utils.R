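#' @useDynLib pyrenpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale cor cutree dist hclust kruskal.test median
#'   optim optimize quantile runif sd setNames rbinom rnorm
#' @importFrom utils head read.table write.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pp <- function(msg, class) {
  stop(structure(class = c(class, "pyrenpop_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Derive a stream of child seeds from one master seed
#'
#' Deterministic splitting of a single user-facing seed into independent
#' sub-seeds for batched simulations; all results stay < 2^31.
#'
#' @param seed master integer seed
#' @param n number of child seeds
#' @param stream small integer distinguishing independent consumers
#' @return integer vector of length `n`
#' @export
derive_seeds <- function(seed, n, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  # Lehmer-style integer hash folded into [1, 2^31 - 2]. The base is
  # reduced first so every product stays below 2^53 and the arithmetic is
  # exact in doubles even for chained (already-derived) seeds.
  base <- as.double(seed) %% 2147483647
  x <- (base * 16807 + stream * 1664525 + seq_len(n) * 22695477) %% 2147483647
  as.integer(x %% 2147483645 + 1)
}

the_regions <- c("G", "R", "U", "P", "B")

#' Schematic west-east coordinates of the five valley regions
#'
#' A planar (km) 5-point configuration spanning ~140 km on the west-east
#' axis, ordered Pallars (west) to Garrotxa (east). Schematic plumbing
#' constants, not cartography; replace with a sample-map TSV for real data.
#'
#' @return data.frame with columns `region`, `x_km`, `y_km`
#' @export
region_coords <- function() {
  data.frame(
    region = c("P", "U", "B", "R", "G"),
    x_km   = c(0,  38,  78, 108, 140),
    y_km   = c(8,   0,   6,  14,  10),
    stringsAsFactors = FALSE
  )
}
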