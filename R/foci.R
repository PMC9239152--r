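#' Per-cell focus table
#'
#' Container for single-cell fluorescence focus data: a `cells` table (one row
#' per cell: id, two pole points, length and width in pixels) and a `foci`
#' table (one row per focus: cell id, channel, pixel coordinates). Cells with
#' no foci are legitimate and appear only in `cells`.
#'
#' @param cells `data.frame` with columns `cell_id`, `pole_ax`, `pole_ay`,
#'   `pole_bx`, `pole_by`, `length_px`, `width_px`.
#' @param foci `data.frame` with columns `cell_id`, `channel`, `x`, `y`.
#' @return A `foci_table`.
#' @export
foci_table <- function(cells, foci) {
  stopifnot(all(c("cell_id", "pole_ax", "pole_ay", "pole_bx", "pole_by",
                  "length_px", "width_px") %in% names(cells)),
            all(c("cell_id", "channel", "x", "y") %in% names(foci)))
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids")
  same_pole <- cells$pole_ax == cells$pole_bx & cells$pole_ay == cells$pole_by
  if (any(same_pole)) stop("cell poles must be distinct")
  orphan <- setdiff(foci$cell_id, cells$cell_id)
  if (length(orphan)) stop("foci reference unknown cells: ",
                           paste(utils::head(orphan), collapse = ", "))
  structure(list(cells = cells, foci = foci), class = "foci_table")
}

#' @export
print.foci_table <- function(x, ...) {
  cat("foci_table:", nrow(x$cells), "cells,", nrow(x$foci), "foci (",
      paste(names(table(x$foci$channel)), table(x$foci$channel),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Fraction of green foci colocalized with a red focus
#'
#' A green focus counts as colocalized when at least one red focus in the same
#' cell lies at Euclidean distance strictly below `threshold` pixels ("fewer
#' than 6 pixels", the diameter of a typical focus). The denominator is the
#' number of green foci; cells without green foci contribute nothing.
#'
#' @param ft A `foci_table`.
#' @param threshold Distance threshold in pixels (default 6; strict `<`).
#' @param channels `c(reference, partner)` channel names.
#' @return Fraction in `[0, 1]` (`NA` if there are no reference foci).
#' @export
colocalization_fraction <- function(ft, threshold = 6,
                                    channels = c("green", "red")) {
  stopifnot(inherits(ft, "foci_table"), threshold > 0)
  if (nrow(ft$cells) == 0) stop("empty cell list")
  g <- ft$foci[ft$foci$channel == channels[1], , drop = FALSE]
  r <- ft$foci[ft$foci$channel == channels[2], , drop = FALSE]
  if (nrow(g) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(g)), function(k) {
    rr <- r[r$cell_id == g$cell_id[k], , drop = FALSE]
    if (nrow(rr) == 0) return(FALSE)
    any(sqrt((rr$x - g$x[k])^2 + (rr$y - g$y[k])^2) < threshold)
  }, logical(1))
  mean(hit)
}

#' Distance from a focus to the nearest cell pole
#'
#' @param cell One row of a `foci_table`'s `cells` table.
#' @param focus Numeric `c(x, y)` in pixels.
#' @return Distance in pixels.
#' @export
distance_to_nearest_pole <- function(cell, focus) {
  da <- sqrt((focus[1] - cell$pole_ax)^2 + (focus[2] - cell$pole_ay)^2)
  db <- sqrt((focus[1] - cell$pole_bx)^2 + (focus[2] - cell$pole_by)^2)
  min(da, db)
}

#' Pole distances for every focus of a table
#'
#' @param ft A `foci_table`.
#' @return The `foci` table with an extra `pole_distance` column.
#' @export
pole_distances <- function(ft) {
  stopifnot(inherits(ft, "foci_table"))
  idx <- match(ft$foci$cell_id, ft$cells$cell_id)
  da <- sqrt((ft$foci$x - ft$cells$pole_ax[idx])^2 +
               (ft$foci$y - ft$cells$pole_ay[idx])^2)
  db <- sqrt((ft$foci$x - ft$cells$pole_bx[idx])^2 +
               (ft$foci$y - ft$cells$pole_by[idx])^2)
  out <- ft$foci
  out$pole_distance <- pmin(da, db)
  out
}

#' Joint focus-count summary
#'
#' Cross-tabulates cells by their per-channel focus counts, as percentages of
#' all cells, with marginal means and the per-channel zero-focus fractions
#' (the readout behind "more than 40% of cells with no foci" phenotypes).
#'
#' @param ft A `foci_table`.
#' @param channels `c(first, second)` channel names (rows, columns).
#' @return A list: `table` (percent matrix, rows = first-channel counts),
#'   `mean` (named mean foci per cell per channel), `frac_zero` (named
#'   zero-focus cell fractions), `n_cells`.
#' @export
focus_count_matrix <- function(ft, channels = c("green", "red")) {
  stopifnot(inherits(ft, "foci_table"))
  n_cells <- nrow(ft$cells)
  count_of <- function(ch) {
    f <- ft$foci[ft$foci$channel == ch, , drop = FALSE]
    tab <- table(factor(f$cell_id, levels = ft$cells$cell_id))
    as.integer(tab)
  }
  n1 <- count_of(channels[1])
  n2 <- count_of(channels[2])
  lev1 <- 0:max(0, n1)
  lev2 <- 0:max(0, n2)
  tab <- table(factor(n1, levels = lev1), factor(n2, levels = lev2))
  pct <- 100 * tab / n_cells
  dimnames(pct) <- stats::setNames(dimnames(pct), channels)
  list(table = as.matrix(pct),
       mean = stats::setNames(c(mean(n1), mean(n2)), channels),
       frac_zero = stats::setNames(c(mean(n1 == 0), mean(n2 == 0)), channels),
       n_cells = n_cells)
}

#' Read / write a focus table TSV
#'
#' One focus per line with the owning cell's geometry repeated:
#' `cell_id`, `pole_ax`, `pole_ay`, `pole_bx`, `pole_by`, `length_px`,
#' `width_px`, `channel`, `focus_x`, `focus_y`. Cells without foci are written
#' with channel `none` and empty coordinates.
#'
#' @param path File path.
#' @return `read_foci` returns a `foci_table`; `write_foci` returns `path`
#'   invisibly.
#' @export
read_foci <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("cell_id", "pole_ax", "pole_ay", "pole_bx", "pole_by",
            "length_px", "width_px", "channel", "focus_x", "focus_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("foci TSV is missing columns: ",
                         paste(miss, collapse = ", "))
  cells <- unique(df[, c("cell_id", "pole_ax", "pole_ay", "pole_bx",
                         "pole_by", "length_px", "width_px")])
  has <- df$channel != "none" & !is.na(df$focus_x)
  foci <- data.frame(cell_id = df$cell_id[has], channel = df$channel[has],
                     x = df$focus_x[has], y = df$focus_y[has])
  foci_table(cells, foci)
}

#' @rdname read_foci
#' @param ft A `foci_table`.
#' @export
write_foci <- function(ft, path) {
  stopifnot(inherits(ft, "foci_table"))
  idx <- match(ft$foci$cell_id, ft$cells$cell_id)
  with_foci <- cbind(ft$cells[idx, , drop = FALSE],
                     data.frame(channel = ft$foci$channel,
                                focus_x = ft$foci$x, focus_y = ft$foci$y))
  lonely <- !(ft$cells$cell_id %in% ft$foci$cell_id)
  if (any(lonely)) {
    with_foci <- rbind(with_foci,
                       cbind(ft$cells[lonely, , drop = FALSE],
                             data.frame(channel = "none", focus_x = NA_real_,
                                        focus_y = NA_real_)))
  }
  with_foci <- with_foci[order(with_foci$cell_id), , drop = FALSE]
  utils::write.table(with_foci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
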