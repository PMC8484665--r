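#' Default prior specification for the five-population demographic model
#'
#' Uniform priors on the eight effective sizes (in chromosomes, i.e. haploid
#' counts) and the three split times (years before present) of the
#' five-population model, plus a log-uniform prior on the symmetric
#' migration rate between the five terminal populations. The split times of
#' the two internal clusters are bounded above by the drawn root split time
#' (`high = "t_GRUBP"`), so their marginal priors are not uniform.
#'
#' @return data.frame with columns `name`, `low`, `high` (numeric or the name
#'   of another parameter), `log` (logical: sample on log10 scale)
#' @export
default_priors <- function() {
  data.frame(
    name = c("Ne_GRUBP", "Ne_GR", "Ne_UPB", "Ne_G", "Ne_R", "Ne_U", "Ne_P",
             "Ne_B", "t_GRUBP", "t_GR", "t_UPB", "m"),
    low  = c(15000, 1000, 1000, 500, 500, 200, 500, 500, 2320, 870, 870, 1e-5),
    high = c("40000", "5000", "5000", "2500", "2500", "2000", "2500", "10000",
             "14500", "t_GRUBP", "t_GRUBP", "1e-2"),
    log  = c(rep(FALSE, 11), TRUE),
    stringsAsFactors = FALSE
  )
}

#' Names of the 11 demographic model parameters (migration excluded)
#' @return character vector
#' @export
model_param_names <- function() {
  c("Ne_GRUBP", "Ne_GR", "Ne_UPB", "Ne_G", "Ne_R", "Ne_U", "Ne_P", "Ne_B",
    "t_GRUBP", "t_GR", "t_UPB")
}

resolve_bounds <- function(priors, draws) {
  # returns numeric high bounds given already-drawn values
  high <- suppressWarnings(as.numeric(priors$high))
  for (i in which(is.na(high))) {
    ref <- priors$high[i]
    if (!ref %in% names(draws)) {
      stop_pp(sprintf("prior '%s': symbolic upper bound '%s' not resolvable",
                      priors$name[i], ref), "pyrenpop_config_error")
    }
    high[i] <- draws[[ref]]
  }
  high
}

#' Draw one parameter vector from the priors
#'
#' Samples each parameter from its uniform (or log10-uniform) prior.
#' Symbolic upper bounds ("t_GRUBP") are resolved against parameters drawn
#' earlier in the table; a reference to a not-yet-drawn or unknown parameter
#' is a configuration error.
#'
#' @param priors prior table as in [default_priors()]
#' @param seed integer seed (optional; uses the current RNG state if NULL)
#' @return named list of class `pp_params` with all prior parameters
#' @export
sample_priors <- function(priors = default_priors(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- list()
  for (i in seq_len(nrow(priors))) {
    nm <- priors$name[i]
    lo <- priors$low[i]
    hi <- suppressWarnings(as.numeric(priors$high[i]))
    if (is.na(hi)) {
      ref <- priors$high[i]
      if (!ref %in% names(draws))
        stop_pp(sprintf("prior '%s': symbolic upper bound '%s' not resolvable",
                        nm, ref), "pyrenpop_config_error")
      hi <- draws[[ref]]
    }
    if (lo > hi)
      stop_pp(sprintf("prior '%s': low %g > high %g after resolution", nm, lo, hi),
              "pyrenpop_config_error")
    lg <- isTRUE(priors$log[i])
    draws[[nm]] <- if (lg) 10^runif(1, log10(lo), log10(hi)) else runif(1, lo, hi)
  }
  validate_params(draws)
  structure(draws, class = "pp_params")
}

#' Draw many parameter vectors from the priors (vectorized)
#'
#' Matrix equivalent of repeated [sample_priors()] calls: one row per draw.
#' Symbolic upper bounds are resolved row-wise against the already-drawn
#' columns, so `t_GR` and `t_UPB` are uniform on (low, drawn `t_GRUBP`).
#'
#' @param priors prior table as in [default_priors()]
#' @param n number of draws
#' @param seed integer seed
#' @return n x (number of parameters) numeric matrix
#' @export
sample_priors_n <- function(priors = default_priors(), n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n, nrow(priors),
                dimnames = list(NULL, priors$name))
  for (i in seq_len(nrow(priors))) {
    nm <- priors$name[i]
    lo <- priors$low[i]
    hi <- suppressWarnings(as.numeric(priors$high[i]))
    hi <- if (is.na(hi)) {
      ref <- priors$high[i]
      if (!ref %in% colnames(out)[seq_len(i - 1)])
        stop_pp(sprintf("prior '%s': symbolic upper bound '%s' not resolvable",
                        nm, ref), "pyrenpop_config_error")
      out[, priors$high[i]]
    } else rep(hi, n)
    if (any(lo > hi))
      stop_pp(sprintf("prior '%s': low > high after resolution", nm),
              "pyrenpop_config_error")
    out[, i] <- if (isTRUE(priors$log[i]))
      10^runif(n, log10(lo), log10(hi))
    else runif(n, lo, hi)
  }
  out
}

#' Validate a demographic parameter vector
#'
#' Checks positivity of all effective sizes, the time ordering
#' 0 < t_GR <= t_GRUBP and 0 < t_UPB <= t_GRUBP, and m >= 0.
#'
#' @param params named list or vector with the 11 model parameters (+ `m`)
#' @return the parameters, invisibly, as class `pp_params`
#' @export
validate_params <- function(params) {
  p <- as.list(params)
  need <- model_param_names()
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop_pp(paste("missing parameters:", paste(miss, collapse = ", ")),
            "pyrenpop_validation_error")
  sizes <- unlist(p[grep("^Ne_", need, value = TRUE)])
  if (any(sizes <= 0))
    stop_pp("all effective sizes must be > 0", "pyrenpop_validation_error")
  if (p$t_GR <= 0 || p$t_UPB <= 0 || p$t_GRUBP <= 0)
    stop_pp("all split times must be > 0", "pyrenpop_validation_error")
  if (p$t_GR > p$t_GRUBP || p$t_UPB > p$t_GRUBP)
    stop_pp("time ordering violated: need t_GR <= t_GRUBP and t_UPB <= t_GRUBP",
            "pyrenpop_validation_error")
  if (!is.null(p$m) && p$m < 0)
    stop_pp("migration rate m must be >= 0", "pyrenpop_validation_error")
  invisible(structure(p, class = "pp_params"))
}

#' Convert between years and generations
#'
#' @param x numeric vector of times
#' @param generation_time years per generation (default 29)
#' @param direction `"years_to_generations"` (rounds to nearest generation)
#'   or `"generations_to_years"`
#' @return converted numeric vector
#' @export
convert_times <- function(x, generation_time = 29,
                          direction = c("years_to_generations",
                                        "generations_to_years")) {
  direction <- match.arg(direction)
  if (generation_time <= 0) stop_pp("generation_time must be > 0",
                                    "pyrenpop_validation_error")
  if (any(x < 0)) stop_pp("negative times not allowed", "pyrenpop_validation_error")
  if (direction == "years_to_generations") round(x / generation_time)
  else x * generation_time
}
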