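#' Quantification regions in (bin, bin) space
#'
#' A `quant_region` is a set of bin pairs over which interaction scores are
#' summed, defined either as an axis-aligned rectangle (inclusive bin ranges)
#' or as a union of convex polygons (boundary inclusive) minus an optional
#' excluded rectangle. Conventions: `x` is the column bin, `y` the row bin;
#' for inter-replicon regions `x` indexes the first chromosome and `y` the
#' second, and the region lies off the main diagonal (its mirror image across
#' the diagonal is accounted for by the factor of two in [region_sum()]).
#'
#' @param x_range,y_range Inclusive integer bin ranges `c(min, max)`.
#' @return A `quant_region`.
#' @export
#' @examples
#' region_rectangle(c(122, 163), c(363, 402))  # the standard ori1-ori2 window
region_rectangle <- function(x_range, y_range) {
  stopifnot(length(x_range) == 2L, length(y_range) == 2L,
            x_range[1] <= x_range[2], y_range[1] <= y_range[2],
            x_range[1] >= 1, y_range[1] >= 1)
  structure(list(kind = "rectangle",
                 x_range = as.integer(x_range), y_range = as.integer(y_range)),
            class = "quant_region")
}

#' @rdname region_rectangle
#' @param polygons List of vertex matrices (columns `x`, `y`), one per convex
#'   polygon; vertices in any order (the convex hull is used).
#' @param exclude Optional rectangle `quant_region` whose bin pairs are removed
#'   from the union.
#' @export
region_polygon_union <- function(polygons, exclude = NULL) {
  stopifnot(is.list(polygons), length(polygons) >= 1L)
  polygons <- lapply(polygons, function(v) {
    v <- as.matrix(v)
    stopifnot(ncol(v) == 2L, nrow(v) >= 3L, all(v >= 1))
    v
  })
  if (!is.null(exclude)) stopifnot(inherits(exclude, "quant_region"),
                                   exclude$kind == "rectangle")
  structure(list(kind = "polygon_union", polygons = polygons,
                 exclude = exclude),
            class = "quant_region")
}

# boundary-inclusive point-in-convex-polygon test, vectorized over (px, py)
points_in_convex <- function(px, py, verts) {
  h <- grDevices::chull(verts)
  v <- verts[h, , drop = FALSE]
  k <- nrow(v)
  # signed area to fix orientation
  nx <- c(seq_len(k)[-1], 1L)
  area2 <- sum(v[, 1] * v[nx, 2] - v[nx, 1] * v[, 2])
  s <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, length(px))
  for (e in seq_len(k)) {
    a <- v[e, ]
    b <- v[if (e == k) 1L else e + 1L, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (s * cr >= 0)
  }
  inside
}

#' Enumerate the bin pairs of a region
#'
#' Integer lattice points `(x, y)` inside the region, boundary inclusive;
#' pairs inside more than one polygon of a union are returned once, and pairs
#' of the excluded rectangle are removed.
#'
#' @param region A `quant_region`.
#' @param n_bins Matrix dimension; all vertices must lie in `[1, n_bins]`.
#' @return A two-column integer matrix with columns `x`, `y`.
#' @export
region_membership <- function(region, n_bins) {
  stopifnot(inherits(region, "quant_region"), n_bins >= 1)
  if (region$kind == "rectangle") {
    if (region$x_range[2] > n_bins || region$y_range[2] > n_bins) {
      stop("region extends beyond the matrix (n_bins = ", n_bins, ")")
    }
    g <- expand.grid(x = seq(region$x_range[1], region$x_range[2]),
                     y = seq(region$y_range[1], region$y_range[2]))
    return(cbind(x = as.integer(g$x), y = as.integer(g$y)))
  }
  allv <- do.call(rbind, region$polygons)
  if (max(allv) > n_bins) {
    stop("region vertices extend beyond the matrix (n_bins = ", n_bins, ")")
  }
  xs <- seq(max(1L, min(allv[, 1])), min(n_bins, max(allv[, 1])))
  ys <- seq(max(1L, min(allv[, 2])), min(n_bins, max(allv[, 2])))
  g <- expand.grid(x = xs, y = ys)
  inside <- rep(FALSE, nrow(g))
  for (v in region$polygons) {
    inside <- inside | points_in_convex(g$x, g$y, v)
  }
  if (!is.null(region$exclude)) {
    ex <- region$exclude
    inside <- inside & !(g$x >= ex$x_range[1] & g$x <= ex$x_range[2] &
                           g$y >= ex$y_range[1] & g$y <= ex$y_range[2])
  }
  cbind(x = as.integer(g$x[inside]), y = as.integer(g$y[inside]))
}

#' Sum interaction scores over a region
#'
#' Returns `2 * sum(m[y, x])` over the region's bin pairs; the factor of two
#' counts the mirrored region across the primary diagonal. A region touching
#' the main diagonal triggers a warning because the mirror factor would then
#' double-count diagonal pairs.
#'
#' @param map A `contact_map` (normalized for the standard analysis, but any
#'   map is accepted).
#' @param region A `quant_region`.
#' @return Numeric score.
#' @export
region_sum <- function(map, region) {
  stopifnot(inherits(map, "contact_map"))
  mem <- region_membership(region, nrow(map$matrix))
  if (any(mem[, "x"] == mem[, "y"])) {
    warning("region touches the main diagonal; the mirror factor ",
            "double-counts those pairs")
  }
  2 * sum(map$matrix[cbind(mem[, "y"], mem[, "x"])])
}

#' Standard inter-replicon quantification regions (C58, 10-kb bins)
#'
#' `ori_region()` is the origin-origin rectangle: ori1 bins 122-163 (x) by
#' ori2 bins 363-402 (y). `alignment_region()` is the union of the two
#' chromosome-alignment parallelograms with vertices
#' (13,285),(63,285),(220,492),(270,492) and (13,492),(63,492),(220,285),
#' (270,285), with the origin rectangle removed. Both assume the standard
#' 570-bin C58 layout geometry.
#'
#' @return A `quant_region`.
#' @export
ori_region <- function() region_rectangle(c(122, 163), c(363, 402))

#' @rdname ori_region
#' @export
alignment_region <- function() {
  p1 <- rbind(c(13, 285), c(63, 285), c(220, 492), c(270, 492))
  p2 <- rbind(c(13, 492), c(63, 492), c(220, 285), c(270, 285))
  region_polygon_union(list(p1, p2), exclude = ori_region())
}

#' Origin-origin and chromosome-alignment interaction scores
#'
#' `ori_interaction_score()` sums the map over the origin rectangle (times
#' two, see [region_sum()]); `alignment_score()` sums over the alignment
#' parallelogram union minus the origin rectangle. Whether the overlap of the
#' two parallelograms should be counted once (default, a true union) or twice
#' is ambiguous in principle; `double_count_overlap = TRUE` switches to the
#' latter reading.
#'
#' @param map A `contact_map` on a layout with enough bins (>= 402 for the
#'   origin rectangle, >= 492 for the alignment region).
#' @return Numeric score.
#' @export
ori_interaction_score <- function(map) {
  if (nrow(map$matrix) < 402) {
    stop("layout too small for the standard ori region (needs >= 402 bins)")
  }
  region_sum(map, ori_region())
}

#' @rdname ori_interaction_score
#' @param double_count_overlap Count the central overlap of the two
#'   parallelograms twice instead of once.
#' @export
alignment_score <- function(map, double_count_overlap = FALSE) {
  if (nrow(map$matrix) < 492) {
    stop("layout too small for the alignment region (needs >= 492 bins)")
  }
  reg <- alignment_region()
  if (!double_count_overlap) return(region_sum(map, reg))
  sum(vapply(reg$polygons, function(v) {
    region_sum(map, region_polygon_union(list(v), exclude = reg$exclude))
  }, numeric(1)))
}

#' Interaction percentage relative to wild type after background subtraction
#'
#' Rescales a sample score so the background score maps to 0% and the
#' wild-type score to 100%:
#' `100 * (S_sample - S_bg) / (S_wt - S_bg)`. Values below 0% ("below
#' background levels") or above 100% are representable.
#'
#' @param s_sample,s_wt,s_bg Region scores for the sample, wild-type reference,
#'   and background strains.
#' @return Percentage (numeric).
#' @export
relative_interaction <- function(s_sample, s_wt, s_bg) {
  if (isTRUE(all(s_wt == s_bg))) {
    stop("wild-type and background scores are equal; the percentage scale ",
         "is undefined")
  }
  100 * (s_sample - s_bg) / (s_wt - s_bg)
}

#' Read region definitions from a TSV
#'
#' Tab-separated with columns `name`, `kind` (`rectangle` or
#' `polygon_union`), `definition`, `exclude`. For rectangles the definition is
#' `x_min:x_max,y_min:y_max`; for polygon unions it is polygons separated by
#' `|`, each a list of `x,y` vertices separated by `;`. `exclude` names a
#' rectangle region defined earlier in the file (or is empty). The standard
#' C58 regions ship as
#' `system.file("extdata", "regions_c58.tsv", package = "multihic")`.
#'
#' @param path File path.
#' @return Named list of `quant_region` objects.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", fill = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("name", "kind", "definition") %in% names(df)))
  out <- list()
  for (k in seq_len(nrow(df))) {
    kind <- df$kind[k]
    def <- df$definition[k]
    if (kind == "rectangle") {
      parts <- strsplit(def, ",", fixed = TRUE)[[1]]
      xr <- as.integer(strsplit(parts[1], ":", fixed = TRUE)[[1]])
      yr <- as.integer(strsplit(parts[2], ":", fixed = TRUE)[[1]])
      out[[df$name[k]]] <- region_rectangle(xr, yr)
    } else if (kind == "polygon_union") {
      polys <- lapply(strsplit(def, "|", fixed = TRUE)[[1]], function(p) {
        do.call(rbind, lapply(strsplit(p, ";", fixed = TRUE)[[1]], function(v) {
          as.integer(strsplit(v, ",", fixed = TRUE)[[1]])
        }))
      })
      ex <- NULL
      if ("exclude" %in% names(df) && !is.na(df$exclude[k]) &&
          nzchar(df$exclude[k])) {
        ex <- out[[df$exclude[k]]]
        if (is.null(ex)) stop("exclude region '", df$exclude[k],
                              "' not defined earlier in ", path)
      }
      out[[df$name[k]]] <- region_polygon_union(polys, exclude = ex)
    } else {
      stop("unknown region kind: ", kind)
    }
  }
  out
}
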