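#' Construct a coancestry matrix object
#'
#' Entry (j, i) is the expected genome length (bp) that recipient i copies
#' from donor j under the haplotype-copying model. The diagonal
#' (self-copying) is undefined and stored as NA.
#'
#' @param lengths square numeric matrix, nonnegative off-diagonal, NA diagonal
#' @param sample_ids character vector
#' @return object of class `pp_coancestry`
#' @export
new_coancestry <- function(lengths, sample_ids = rownames(lengths)) {
  lengths <- as.matrix(lengths)
  if (nrow(lengths) != ncol(lengths))
    stop_pp("coancestry matrix must be square", "pyrenpop_validation_error")
  diag(lengths) <- NA_real_
  off <- lengths[row(lengths) != col(lengths)]
  if (any(!is.finite(off)))
    stop_pp("non-finite coancestry entries", "pyrenpop_validation_error")
  if (any(off < 0))
    stop_pp("coancestry entries must be nonnegative", "pyrenpop_validation_error")
  sample_ids <- sample_ids %||% paste0("S", seq_len(nrow(lengths)))
  dimnames(lengths) <- list(sample_ids, sample_ids)
  structure(list(lengths = lengths, sample_ids = as.character(sample_ids)),
            class = "pp_coancestry")
}

#' Symmetrized, grand-mean-normalized coancestry
#'
#' (C + t(C))/2 divided by the mean off-diagonal entry; removes the painted
#' genome-length scale before spatial model fitting.
#'
#' @param coancestry a `pp_coancestry`
#' @return numeric matrix with NA diagonal, mean off-diagonal 1
#' @export
normalize_coancestry <- function(coancestry) {
  cm <- coancestry$lengths
  s <- (cm + t(cm)) / 2
  mu <- mean(s[row(s) != col(s)])
  if (mu <= 0) stop_pp("degenerate (all-zero) coancestry matrix",
                       "pyrenpop_validation_error")
  s / mu
}

#' Write / read a coancestry matrix as TSV with ID header row and column
#' @param coancestry a `pp_coancestry`
#' @param path file path
#' @return `path` (write) or a `pp_coancestry` (read)
#' @export
write_coancestry <- function(coancestry, path) {
  write.table(coancestry$lengths, path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' @rdname write_coancestry
#' @export
read_coancestry <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  new_coancestry(m, rownames(m))
}
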