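#' Contact map container
#'
#' A symmetric, nonnegative dense matrix of interaction scores over the global
#' bins of a [genome_layout], plus a flag recording whether iterative
#' correction has been applied.
#'
#' @param matrix An `n_bins x n_bins` numeric matrix, symmetric, nonnegative.
#' @param layout The `genome_layout` the bins refer to.
#' @param normalized Logical; `TRUE` after [ice_normalize()].
#' @return A `contact_map` object (list with `matrix`, `layout`, `normalized`,
#'   `total`).
#' @export
contact_map <- function(matrix, layout, normalized = FALSE) {
  stopifnot(inherits(layout, "genome_layout"))
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("contact matrix must be square")
  if (nrow(m) != layout$n_bins) {
    stop("matrix dimension (", nrow(m), ") does not match layout n_bins (",
         layout$n_bins, ")")
  }
  if (any(m < 0)) stop("contact matrix has negative entries")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("contact matrix is not symmetric")
  }
  structure(list(matrix = m, layout = layout,
                 normalized = isTRUE(normalized), total = sum(m)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map: ", nrow(x$matrix), "x", ncol(x$matrix),
      if (x$normalized) " (normalized)" else " (raw)",
      ", total score ", format(x$total), "\n", sep = "")
  invisible(x)
}
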