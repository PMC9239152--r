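#' Filter contact records
#'
#' Simplified validity filter for ligation products: records whose two sides
#' carry the same restriction-fragment id are classed as self/non-ligation
#' products and removed; records without fragment ids pass through. The full
#' orientation/fragment-distance classification used on real libraries is an
#' upstream concern and intentionally out of scope.
#'
#' @param records A `data.frame` with columns `replicon1`, `pos1`, `replicon2`,
#'   `pos2` and optionally `frag1`, `frag2`.
#' @return A list with `records` (the retained rows) and `counts`, a named
#'   vector `c(valid =, same_fragment =)`.
#' @export
filter_pairs <- function(records) {
  stopifnot(is.data.frame(records))
  if (all(c("frag1", "frag2") %in% names(records)) && nrow(records) > 0) {
    same <- !is.na(records$frag1) & !is.na(records$frag2) &
      records$frag1 == records$frag2
  } else {
    same <- rep(FALSE, nrow(records))
  }
  list(records = records[!same, , drop = FALSE],
       counts = c(valid = sum(!same), same_fragment = sum(same)))
}

#' Bin contact records into a raw contact map
#'
#' Each record adds 1 to `m[i, j]` and 1 to `m[j, i]` (so 2 to the diagonal
#' when both sides fall in the same bin); the map total is twice the record
#' count. Coordinates on the first replicon are rearranged (see
#' [rearrange_ch1()]) before binning when the layout carries a non-zero offset.
#'
#' @param records A `data.frame` of contact records (see [filter_pairs()]).
#' @param layout A `genome_layout`.
#' @return A raw `contact_map`.
#' @export
bin_contacts <- function(records, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- layout$n_bins
  m <- matrix(0, n, n)
  if (nrow(records) > 0) {
    first <- layout$replicons$name[1L]
    fix <- function(rep, pos) {
      if (layout$ch1_start_offset > 0) {
        is1 <- rep == first
        pos[is1] <- rearrange_ch1(pos[is1], layout)
      }
      pos
    }
    b1 <- coord_to_global_bin(records$replicon1,
                              fix(records$replicon1, records$pos1), layout)
    b2 <- coord_to_global_bin(records$replicon2,
                              fix(records$replicon2, records$pos2), layout)
    lin <- c(b1 + (b2 - 1) * n, b2 + (b1 - 1) * n)
    m <- matrix(tabulate(lin, nbins = n * n), n, n)
  }
  contact_map(m, layout, normalized = FALSE)
}

#' Iterative correction (matrix balancing) of a contact map
#'
#' Repeats the per-sweep update
#' `m_ij <- m_ij * T / (R_i * C_j)` -- where `T` is the current matrix total
#' and `R_i`, `C_j` the current row/column marginals (equal, by symmetry) --
#' until the maximum relative deviation of the bin marginals from their mean is
#' below `tol`. The converged matrix is then divided by the common row sum so
#' every unmasked row and column sums to 1. Bins with zero marginal in the
#' input (unmappable bins) are masked: excluded from the error criterion and
#' left at zero.
#'
#' The update is applied Jacobi-style (marginals recomputed once per sweep,
#' not per entry), is exactly scale-invariant (`ice_normalize(c*M)` equals
#' `ice_normalize(M)`), and preserves symmetry.
#'
#' @param map A raw (or already normalized) `contact_map`.
#' @param tol Convergence tolerance on the relative marginal error
#'   (default `1e-5`).
#' @param max_iter Maximum sweeps (default 1000); non-convergence raises a
#'   warning and flags the result via `attr(, "converged")`.
#' @return A normalized `contact_map` with attributes `converged`,
#'   `iterations`, and `mask` (logical vector, `TRUE` for masked bins).
#' @export
#' @examples
#' lay <- build_layout(replicon_spec("r", 20000, "linear"),
#'                     bin_size = 10000, ch1_start_offset = 0)
#' ice_normalize(contact_map(matrix(c(4, 2, 2, 1), 2), lay))$matrix
ice_normalize <- function(map, tol = 1e-5, max_iter = 1000L) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$matrix
  if (sum(m) <= 0) stop("cannot normalize a map with zero total")
  marg <- rowSums(m)
  keep <- marg > 0
  sub <- m[keep, keep, drop = FALSE]
  n <- nrow(sub)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    R <- rowSums(sub)
    tot <- sum(R)
    target <- tot / n
    if (max(abs(R - target)) / target < tol) {
      converged <- TRUE
      break
    }
    sub <- sub * (tot / outer(R, R))
    iters <- it
  }
  if (!converged) {
    warning("iterative correction did not converge within ", max_iter,
            " sweeps; partial result flagged")
  }
  sub <- sub / mean(rowSums(sub))
  out <- matrix(0, nrow(m), ncol(m))
  out[keep, keep] <- sub
  res <- contact_map(out, map$layout, normalized = TRUE)
  attr(res, "converged") <- converged
  attr(res, "iterations") <- iters
  attr(res, "mask") <- !keep
  res
}
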