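#' Replicon specification
#'
#' One replicon of a multipartite genome: a name, a length in base pairs, a
#' topology, and (optionally) the position of its replication origin on the
#' native reference.
#'
#' @param name Replicon label, e.g. `"Ch1"`.
#' @param length Replicon length in base pairs (> 0).
#' @param topology `"circular"` or `"linear"`.
#' @param origin_pos Optional replication-origin position in base pairs on the
#'   native reference, in `[1, length]`. Used by the synthetic-map generator
#'   and by origin-neighborhood helpers; `NA` if unknown.
#' @return A one-row `data.frame` with columns `name`, `length`, `topology`,
#'   `origin_pos`.
#' @export
#' @examples
#' replicon_spec("pTi", 216000, "circular", 105000)
replicon_spec <- function(name, length, topology = c("circular", "linear"),
                          origin_pos = NA_real_) {
  topology <- match.arg(topology)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(length) || length <= 0) {
    stop("replicon length must be a positive number of base pairs")
  }
  if (!is.na(origin_pos) && (origin_pos < 1 || origin_pos > length)) {
    stop("origin_pos must lie in [1, length]")
  }
  data.frame(name = name, length = as.numeric(length), topology = topology,
             origin_pos = as.numeric(origin_pos), stringsAsFactors = FALSE)
}

#' Build a genome layout
#'
#' Defines the global coordinate system shared by every other module: replicons
#' in a fixed order, a bin size, contiguous 1-based global bin ranges covering
#' each replicon (`ceiling(length / bin_size)` bins each, the last bin possibly
#' partial), and the rearrangement offset applied to the first replicon so that
#' its origin region can be displayed at the center of the contact map.
#'
#' Coordinates and bins are 1-based throughout; bin `b` of a replicon covers
#' base pairs `(b-1)*bin_size + 1` through `min(b*bin_size, length)`.
#'
#' @param replicons A `data.frame` of replicon specs (rows as returned by
#'   [replicon_spec()]), in display order.
#' @param bin_size Bin width in base pairs (default 10,000).
#' @param ch1_start_offset Base pairs by which the first replicon's reference
#'   is rotated before binning (default 1,400,000), so that the rearranged
#'   reference starts at `offset + 1` of the native one. Requires the first
#'   replicon to be circular when non-zero.
#' @return A `genome_layout` object: list with `replicons`, `bin_size`,
#'   `ch1_start_offset`, per-replicon `bin_start`/`bin_end` (global, inclusive)
#'   and `n_bins`.
#' @export
#' @examples
#' layout <- agrobacterium_c58_layout()
#' layout$n_bins  # 570
build_layout <- function(replicons, bin_size = 10000,
                         ch1_start_offset = 1400000) {
  if (is.null(replicons) || nrow(replicons) == 0L) {
    stop("at least one replicon is required")
  }
  stopifnot(all(c("name", "length", "topology") %in% names(replicons)))
  if (!is.numeric(bin_size) || bin_size <= 0) stop("bin_size must be positive")
  if (any(replicons$length <= 0)) stop("replicon lengths must be positive")
  if (anyDuplicated(replicons$name)) stop("replicon names must be unique")
  if (ch1_start_offset < 0) stop("ch1_start_offset must be >= 0")
  if (ch1_start_offset > 0 && replicons$topology[1L] != "circular") {
    stop("a non-zero start offset requires the first replicon to be circular")
  }
  if (!"origin_pos" %in% names(replicons)) replicons$origin_pos <- NA_real_
  nb <- ceiling(replicons$length / bin_size)
  bin_end <- cumsum(nb)
  bin_start <- bin_end - nb + 1
  structure(
    list(replicons = replicons,
         bin_size = as.numeric(bin_size),
         ch1_start_offset = as.numeric(ch1_start_offset),
         bin_start = stats::setNames(bin_start, replicons$name),
         bin_end = stats::setNames(bin_end, replicons$name),
         n_bins = sum(nb)),
    class = "genome_layout")
}

#' Default Agrobacterium tumefaciens C58 layout
#'
#' The four-replicon C58 genome at 10-kb bins: Ch1 (2,841 kb, circular),
#' Ch2 (2,076 kb, linear), pAt (542 kb) and pTi (216 kb), yielding global bins
#' Ch1 1-285, Ch2 286-493, pAt 494-548, pTi 549-570. The rearrangement offset
#' of 1,400 kb places the Ch1 origin region at the center of the rearranged
#' chromosome.
#'
#' Origin positions: ori1 is stored at 2,825,000 so that its rearranged
#' position (1,425,000, bin 143) sits at the midpoint of the standard ori1
#' quantification window (bins 122-163); ori2 at Ch2:975,000 is the midpoint
#' of the ori2 window (bins 363-402). The plasmid origins are synthetic
#' mid-replicon stand-ins (no published coordinate is used here); they matter
#' only to the synthetic-map generator.
#'
#' @param bin_size Bin width in base pairs.
#' @param ch1_start_offset Rotation offset of Ch1 in base pairs.
#' @return A `genome_layout`.
#' @export
agrobacterium_c58_layout <- function(bin_size = 10000,
                                     ch1_start_offset = 1400000) {
  reps <- rbind(
    replicon_spec("Ch1", 2841000, "circular", 2825000),
    replicon_spec("Ch2", 2076000, "linear", 975000),
    replicon_spec("pAt", 542000, "circular", 275000),
    replicon_spec("pTi", 216000, "circular", 105000))
  build_layout(reps, bin_size = bin_size, ch1_start_offset = ch1_start_offset)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$replicons), "replicon(s),",
      x$n_bins, "bins of", x$bin_size, "bp\n")
  df <- x$replicons
  df$bins <- paste0(x$bin_start, "-", x$bin_end)
  print(df, row.names = FALSE)
  if (x$ch1_start_offset > 0) {
    cat("rearrangement:", df$name[1L], "reference starts at",
        x$ch1_start_offset, "bp\n")
  }
  invisible(x)
}

replicon_index <- function(layout, replicon) {
  i <- match(replicon, layout$replicons$name)
  if (anyNA(i)) {
    stop("unknown replicon(s): ",
         paste(unique(replicon[is.na(i)]), collapse = ", "))
  }
  i
}

#' Rearrange a Ch1 coordinate
#'
#' Maps a native coordinate on the first (circular) replicon onto the rotated
#' reference that starts at `ch1_start_offset`: position `offset + 1` of the
#' native reference becomes position 1. Identity when the offset is 0. Applied
#' only to the first replicon's coordinates; it is a bijection on
#' `[1, length]`.
#'
#' @param pos Native coordinate(s) in base pairs, in `[1, Ch1 length]`.
#' @param layout A `genome_layout`.
#' @return Rearranged coordinate(s), 1-based.
#' @export
#' @examples
#' rearrange_ch1(1400001, agrobacterium_c58_layout())  # 1
rearrange_ch1 <- function(pos, layout) {
  len <- layout$replicons$length[1L]
  if (any(pos < 1 | pos > len)) stop("position out of range for ",
                                     layout$replicons$name[1L])
  ((pos - 1 - layout$ch1_start_offset) %% len) + 1
}

# inverse of rearrange_ch1 (rearranged -> native); internal
unrearrange_ch1 <- function(pos, layout) {
  len <- layout$replicons$length[1L]
  if (any(pos < 1 | pos > len)) stop("position out of range")
  ((pos - 1 + layout$ch1_start_offset) %% len) + 1
}

#' Map a (replicon, position) to a global bin index
#'
#' Positions on the first replicon are expected to be already rearranged (see
#' [rearrange_ch1()]); this function performs pure binning.
#'
#' @param replicon Replicon name(s).
#' @param pos Coordinate(s) in base pairs, 1-based, within the replicon.
#' @param layout A `genome_layout`.
#' @return Global 1-based bin index (integer vector).
#' @export
coord_to_global_bin <- function(replicon, pos, layout) {
  i <- replicon_index(layout, replicon)
  len <- layout$replicons$length[i]
  if (any(pos < 1 | pos > len)) stop("position out of range")
  as.integer(layout$bin_start[i] + floor((pos - 1) / layout$bin_size))
}

#' Origin bins of a layout
#'
#' Global bin of each replicon's origin, with the first replicon's origin
#' passed through the rearrangement first. `NA` where `origin_pos` is unset.
#'
#' @param layout A `genome_layout`.
#' @return Named integer vector of global bins.
#' @export
origin_bins <- function(layout) {
  reps <- layout$replicons
  out <- rep(NA_integer_, nrow(reps))
  names(out) <- reps$name
  for (k in seq_len(nrow(reps))) {
    p <- reps$origin_pos[k]
    if (is.na(p)) next
    if (k == 1L) p <- rearrange_ch1(p, layout)
    out[k] <- coord_to_global_bin(reps$name[k], p, layout)
  }
  out
}

#' Read / write a genome layout config
#'
#' The config is a small key/value file in Debian-control (DCF) format: a first
#' record with the global keys `bin_size` and `ch1_start_offset`, then one
#' record per replicon with `name`, `length`, `topology` and optional `origin`.
#' A bundled default encoding the C58 genome ships as
#' `system.file("extdata", "layout_c58.cfg", package = "multihic")`.
#'
#' @param path File path.
#' @return `read_layout` returns a `genome_layout`; `write_layout` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout config not found: ", path)
  recs <- read.dcf(path)
  if (nrow(recs) < 2L || !"bin_size" %in% colnames(recs)) {
    stop("malformed layout config: need a global record plus >=1 replicon")
  }
  g <- recs[1L, ]
  reps <- do.call(rbind, lapply(seq(2L, nrow(recs)), function(k) {
    r <- recs[k, ]
    if (is.na(r["name"]) || is.na(r["length"]) || is.na(r["topology"])) {
      stop("malformed replicon record ", k - 1L, " in ", path)
    }
    replicon_spec(unname(r["name"]), as.numeric(r["length"]),
                  unname(r["topology"]),
                  if ("origin" %in% names(r) && !is.na(r["origin"]))
                    as.numeric(r["origin"]) else NA_real_)
  }))
  off <- if ("ch1_start_offset" %in% names(g) && !is.na(g["ch1_start_offset"]))
    as.numeric(g["ch1_start_offset"]) else 0
  build_layout(reps, bin_size = as.numeric(g["bin_size"]),
               ch1_start_offset = off)
}

#' @rdname read_layout
#' @param layout A `genome_layout` to serialize.
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("bin_size: ", format(layout$bin_size, scientific = FALSE)),
               paste0("ch1_start_offset: ",
                      format(layout$ch1_start_offset, scientific = FALSE))),
             con)
  for (k in seq_len(nrow(layout$replicons))) {
    r <- layout$replicons[k, ]
    writeLines("", con)
    writeLines(c(paste0("name: ", r$name),
                 paste0("length: ", format(r$length, scientific = FALSE)),
                 paste0("topology: ", r$topology)), con)
    if (!is.na(r$origin_pos)) {
      writeLines(paste0("origin: ", format(r$origin_pos, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}
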