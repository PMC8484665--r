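#' Hudson's FST estimator between two sample sets
#'
#' Ratio-of-averages Hudson estimator from sample allele frequencies:
#' numerator (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1), denominator
#' p1(1-p2) + p2(1-p1), summed over sites before dividing.
#'
#' @param dos1,dos2 dosage matrices (samples x sites) of the two groups over
#'   the same sites
#' @return scalar FST (NA if the denominator is zero, i.e. no variation)
#' @export
hudson_fst <- function(dos1, dos2) {
  n1 <- 2 * nrow(dos1); n2 <- 2 * nrow(dos2)
  if (n1 < 4 || n2 < 4)
    stop_pp("need >= 2 diploids per group", "pyrenpop_validation_error")
  p1 <- colMeans(dos1) / 2
  p2 <- colMeans(dos2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  if (!any(keep)) return(NA_real_)
  sum(num[keep]) / sum(den[keep])
}
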