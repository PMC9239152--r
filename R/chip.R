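#' Per-base-pair coverage track
#'
#' Nonnegative read counts per base pair for one sample, stored as a named
#' list of numeric vectors (one per replicon).
#'
#' @param values Named list of per-bp numeric vectors.
#' @param total_reads Library size; defaults to the sum of the counts.
#' @param sample Sample label.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(values, total_reads = NULL, sample = "") {
  stopifnot(is.list(values), length(values) >= 1L,
            !is.null(names(values)), all(nzchar(names(values))))
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(v < 0), logical(1)))) {
    stop("coverage counts must be nonnegative")
  }
  tot <- sum(vapply(values, sum, numeric(1)))
  if (is.null(total_reads)) total_reads <- tot
  structure(list(values = values, total_reads = total_reads, sample = sample),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track '", x$sample, "': ",
      paste0(names(x$values), " (", vapply(x$values, length, integer(1)),
             " bp)", collapse = ", "),
      "; total reads ", format(x$total_reads), "\n", sep = "")
  invisible(x)
}

#' ChIP/input enrichment track
#'
#' Per base pair: `(chip_bp / chip_total) / (input_bp / input_total)`.
#' Positions with zero input coverage are masked (`NA`) unless a pseudocount
#' is supplied.
#'
#' @param chip,input `coverage_track`s over the same replicons.
#' @param pseudocount Added to both per-bp counts before the ratio (default 0,
#'   i.e. mask zero-input positions; useful for sparse real libraries).
#' @return An `enrichment_track`: named list of per-bp ratio vectors with `NA`
#'   at masked positions.
#' @export
enrichment <- function(chip, input, pseudocount = 0) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (!identical(names(chip$values), names(input$values)) ||
      !identical(lengths(chip$values), lengths(input$values))) {
    stop("chip and input tracks are on different layouts")
  }
  if (chip$total_reads <= 0 || input$total_reads <= 0) {
    stop("zero-total track")
  }
  vals <- mapply(function(c_v, i_v) {
    c_v <- c_v + pseudocount
    i_v <- i_v + pseudocount
    r <- (c_v / chip$total_reads) / (i_v / input$total_reads)
    r[i_v == 0] <- NA_real_
    r
  }, chip$values, input$values, SIMPLIFY = FALSE)
  structure(list(values = vals), class = "enrichment_track")
}

#' Bin an enrichment track
#'
#' Mean of unmasked per-bp values per bin (1-kb bins for whole-genome display,
#' 100-bp bins for high-resolution views); a final partial bin is kept; a bin
#' with every position masked yields `NA`.
#'
#' @param track An `enrichment_track`.
#' @param bin_size Bin width in base pairs.
#' @return A `data.frame` with columns `replicon`, `start`, `end`, `value`
#'   (1-based inclusive coordinates).
#' @export
bin_track <- function(track, bin_size = 1000) {
  stopifnot(inherits(track, "enrichment_track"), bin_size >= 1)
  out <- lapply(names(track$values), function(rn) {
    v <- track$values[[rn]]
    L <- length(v)
    nb <- ceiling(L / bin_size)
    grp <- rep(seq_len(nb), each = bin_size, length.out = L)
    means <- tapply(v, grp, function(z) {
      z <- z[!is.na(z)]
      if (length(z)) mean(z) else NA_real_
    })
    data.frame(replicon = rn,
               start = (seq_len(nb) - 1) * bin_size + 1,
               end = pmin(seq_len(nb) * bin_size, L),
               value = as.numeric(means))
  })
  do.call(rbind, out)
}

#' Above-baseline peak score in a window
#'
#' `sum(max(value - baseline, 0))` over the unmasked base pairs of the window.
#' Linear in peak height above the baseline and additive over disjoint
#' windows, which makes ratios of peak scores a depletion/occupancy readout.
#'
#' @param track An `enrichment_track`.
#' @param window `list(replicon =, start =, end =)` (1-based inclusive), e.g.
#'   the parS2 cluster +- 5 kb.
#' @param baseline Enrichment baseline (default 1.0).
#' @return Numeric score.
#' @export
peak_score <- function(track, window, baseline = 1.0) {
  stopifnot(inherits(track, "enrichment_track"),
            all(c("replicon", "start", "end") %in% names(window)))
  v <- track$values[[window$replicon]]
  if (is.null(v)) stop("unknown replicon: ", window$replicon)
  if (window$start < 1 || window$end > length(v) ||
      window$start > window$end) {
    stop("window out of range")
  }
  w <- v[window$start:window$end]
  w <- w[!is.na(w)]
  if (!length(w)) stop("window is empty or fully masked")
  sum(pmax(w - baseline, 0))
}

#' Enrichment percentage relative to a reference condition
#'
#' `100 * sample_score / reference_score`, the convention used to report,
#' e.g., a binding peak "reduced to 35.9%" of its reference level.
#'
#' @param sample_score,reference_score Peak scores (see [peak_score()]).
#' @return Percentage.
#' @export
relative_enrichment <- function(sample_score, reference_score) {
  if (reference_score <= 0) stop("reference score must be positive")
  100 * sample_score / reference_score
}
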