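#' Heterozygosity ratio of one sample
#'
#' HetR = #heterozygous SNVs / #homozygous-alternate SNVs, missing dosages
#' excluded. A zero denominator gives a defined-failure result (`defined =
#' FALSE`, `HetR = NA`), never a crash or a silent 0.
#'
#' @param dosages dosage vector in \{0, 1, 2, NA\}
#' @return list `n_het`, `n_hom_alt`, `HetR`, `defined`
#' @export
het_ratio <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n_het <- sum(d == 1)
  n_hom <- sum(d == 2)
  if (n_hom == 0)
    list(n_het = n_het, n_hom_alt = 0L, HetR = NA_real_, defined = FALSE)
  else
    list(n_het = n_het, n_hom_alt = n_hom, HetR = n_het / n_hom,
         defined = TRUE)
}

#' Resampling-normalized heterozygosity ratio (nHetR)
#'
#' Per replicate, `subsample_size` samples are drawn without replacement
#' from every region; sites are restricted to those polymorphic within the
#' pooled drawn set; each drawn sample's HetR is computed on those sites.
#' nHetR of a sample is the mean of its HetR over the replicates in which it
#' was drawn. This normalizes HetR across cohorts of different size by
#' fixing the ascertainment depth.
#'
#' @param x a `pp_panel`, `pp_dosage`, or dosage matrix with complete data
#' @param regions region label per sample (taken from the panel if absent)
#' @param subsample_size samples drawn per region per replicate (default 5)
#' @param n_reps number of resampling replicates (default 5000)
#' @param seed integer seed
#' @return data.frame `sample_id`, `region`, `HetR` (full-data, full-site
#'   ascertainment), `nHetR`, `n_drawn` (replicates the sample entered)
#' @export
normalized_het_ratio <- function(x, regions = NULL, subsample_size = 5,
                                 n_reps = 5000, seed = 1L) {
  if (inherits(x, "pp_panel")) { d <- panel_dosages(x); regions <- x$region_labels }
  else if (inherits(x, "pp_dosage")) { d <- x$dosages; regions <- x$region_labels }
  else d <- as.matrix(x)
  if (is.null(regions)) stop_pp("regions required", "pyrenpop_validation_error")
  n <- nrow(d)
  tab <- table(regions)
  small <- names(tab)[tab < subsample_size]
  if (length(small))
    stop_pp(sprintf("region(s) smaller than subsample_size=%d: %s",
                    subsample_size, paste(small, collapse = ", ")),
            "pyrenpop_validation_error")
  ids <- rownames(d) %||% paste0("S", seq_len(n))
  het <- d == 1L
  hom <- d == 2L
  by_region <- split(seq_len(n), regions)
  set.seed(seed)
  sums <- setNames(numeric(n), ids)
  drawn_n <- setNames(integer(n), ids)
  for (rep_i in seq_len(n_reps)) {
    drawn <- unlist(lapply(by_region, function(ix)
      ix[sample.int(length(ix), subsample_size)]), use.names = FALSE)
    cs <- colSums(d[drawn, , drop = FALSE])
    poly <- cs > 0 & cs < 2 * length(drawn)
    nh <- as.vector(het[drawn, , drop = FALSE] %*% poly)
    nm <- as.vector(hom[drawn, , drop = FALSE] %*% poly)
    ratio <- ifelse(nm > 0, nh / nm, NA_real_)
    sums[drawn] <- sums[drawn] + ifelse(is.na(ratio), 0, ratio)
    drawn_n[drawn] <- drawn_n[drawn] + as.integer(!is.na(ratio))
  }
  full <- vapply(seq_len(n), function(i) het_ratio(d[i, ])$HetR, numeric(1))
  data.frame(sample_id = ids, region = regions, HetR = full,
             nHetR = ifelse(drawn_n > 0, sums / pmax(drawn_n, 1), NA_real_),
             n_drawn = drawn_n, stringsAsFactors = FALSE)
}
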