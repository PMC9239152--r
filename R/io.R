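header_comment <- function(key, value) paste0("# ", key, ": ", value)

layout_signature <- function(layout) {
  paste(sprintf("%s:%s:%s", layout$replicons$name,
                format(layout$replicons$length, scientific = FALSE,
                       trim = TRUE),
                layout$replicons$topology),
        collapse = ",")
}

#' Write / read a dense contact matrix
#'
#' Whitespace-separated dense matrix text with `#`-prefixed header comments
#' recording the layout signature, bin size, rearrangement offset,
#' normalization state and provenance; a round-trip preserves values to full
#' precision.
#'
#' @param map A `contact_map`.
#' @param path File path.
#' @param provenance Optional named character vector of extra header fields
#'   (e.g. seed, tool version).
#' @return `write_matrix` returns `path` invisibly; `read_matrix` a
#'   `contact_map`.
#' @export
write_matrix <- function(map, path, provenance = NULL) {
  stopifnot(inherits(map, "contact_map"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(header_comment("multihic", as.character(utils::packageVersion("multihic"))),
           header_comment("layout", layout_signature(map$layout)),
           header_comment("bin_size",
                          format(map$layout$bin_size, scientific = FALSE)),
           header_comment("ch1_start_offset",
                          format(map$layout$ch1_start_offset,
                                 scientific = FALSE)),
           header_comment("normalized", map$normalized))
  if (!is.null(provenance)) {
    hdr <- c(hdr, mapply(header_comment, names(provenance), provenance))
  }
  writeLines(hdr, con)
  utils::write.table(format(map$matrix, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# *([^:]+): *(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 character(1))
  stats::setNames(vals, keys)
}

layout_from_header <- function(h) {
  parts <- strsplit(strsplit(h[["layout"]], ",", fixed = TRUE)[[1]],
                    ":", fixed = TRUE)
  reps <- do.call(rbind, lapply(parts, function(p) {
    replicon_spec(p[1], as.numeric(p[2]), p[3])
  }))
  off <- if (!is.na(h["ch1_start_offset"])) as.numeric(h[["ch1_start_offset"]])
  else 0
  build_layout(reps, bin_size = as.numeric(h[["bin_size"]]),
               ch1_start_offset = off)
}

#' @rdname write_matrix
#' @param layout Optional `genome_layout`; if `NULL` it is reconstructed from
#'   the file header (origin positions are not serialized in matrix headers,
#'   so pass a layout when downstream code needs them).
#' @export
read_matrix <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  h <- read_header(lines)
  if (is.null(layout)) {
    if (is.na(h["layout"]) || is.na(h["bin_size"])) {
      stop("matrix header lacks a layout; pass one explicitly")
    }
    layout <- layout_from_header(h)
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) != layout$n_bins) {
    stop("expected ", layout$n_bins, " matrix rows, found ", length(body))
  }
  rows <- strsplit(trimws(body), "[ \t]+")
  bad <- which(lengths(rows) != layout$n_bins)
  if (length(bad)) {
    stop("malformed matrix row ", bad[1], ": expected ", layout$n_bins,
         " values, found ", length(rows[[bad[1]]]))
  }
  m <- matrix(as.numeric(unlist(rows)), nrow = layout$n_bins, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric entries in matrix body")
  contact_map(m, layout,
              normalized = isTRUE(as.logical(h["normalized"])))
}

#' Write / read a bedGraph coverage track
#'
#' Standard 4-column bedGraph (chrom, start, end, value), 0-based half-open on
#' disk as the format requires, converted to the package's 1-based inclusive
#' convention at this boundary. Zero runs are written so the round-trip is the
#' identity. Parsing is delegated to `rtracklayer`.
#'
#' @param track A `coverage_track`.
#' @param path File path.
#' @return `write_bedgraph` returns `path` invisibly; `read_bedgraph` a
#'   `coverage_track`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  grs <- lapply(names(track$values), function(rn) {
    r <- rle(track$values[[rn]])
    ends <- cumsum(r$lengths)
    GenomicRanges::GRanges(rn,
                           IRanges::IRanges(start = ends - r$lengths + 1,
                                            end = ends),
                           score = r$values)
  })
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @param layout A `genome_layout` naming the expected replicons and lengths.
#' @param sample Sample label for the returned track.
#' @export
read_bedgraph <- function(path, layout, sample = "") {
  stopifnot(inherits(layout, "genome_layout"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(chroms), layout$replicons$name)
  if (length(bad)) stop("unknown replicon(s) in bedGraph: ",
                        paste(bad, collapse = ", "))
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(self)) stop("overlapping intervals in bedGraph: ", path)
  vals <- lapply(seq_len(nrow(layout$replicons)), function(k) {
    L <- layout$replicons$length[k]
    v <- numeric(L)
    sel <- chroms == layout$replicons$name[k]
    if (any(sel)) {
      g <- gr[sel]
      st <- GenomicRanges::start(g)  # already 1-based after import
      en <- GenomicRanges::end(g)
      if (any(en > L)) stop("interval beyond replicon end in ", path)
      for (j in seq_along(g)) v[st[j]:en[j]] <- g$score[j]
    }
    v
  })
  names(vals) <- layout$replicons$name
  coverage_track(vals, sample = sample)
}

#' Write / read contact-record pair TSV
#'
#' Tab-separated `replicon1 pos1 replicon2 pos2 [frag1 frag2]` with a header
#' line; `#` comment lines carry provenance.
#'
#' @param records A contact-record `data.frame`.
#' @param path File path.
#' @param provenance Optional named character vector written as header
#'   comments.
#' @return `write_pairs` returns `path` invisibly; `read_pairs` a
#'   `data.frame`.
#' @export
write_pairs <- function(records, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(mapply(header_comment, names(provenance), provenance), con)
  }
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("replicon1", "pos1", "replicon2", "pos2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pair TSV is missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
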