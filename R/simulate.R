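# run code under a local, seeded RNG state without disturbing the caller's
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic contact-map model parameters
#'
#' The generator's expected map is a sum of additive features over a constant
#' background: an intra-replicon power-law distance decay, interarm
#' anti-diagonals on the two chromosomes, pairwise origin-origin clustering
#' blocks, and an X-shaped inter-chromosomal alignment band. Each feature acts
#' only inside its designated region, so region sums respond linearly to the
#' corresponding strength.
#'
#' @param decay_exponent Power-law exponent of the intra-replicon decay
#'   (`|i-j|^-decay_exponent`, circular distance on circular replicons;
#'   diagonal entries capped at 1).
#' @param interarm_strength Added to intra-chromosomal pairs symmetric about
#'   the origin (the interarm anti-diagonal), on the first two replicons.
#' @param ori_cluster_strength Added to every inter-replicon block of origin
#'   neighborhoods (`+- ori_halfwidth` bins around each origin bin).
#' @param alignment_strength Added to chromosome-1 x chromosome-2 pairs whose
#'   distances from their origins match in absolute value within
#'   `alignment_halfwidth` bins (both signs, producing the X shape).
#' @param background Constant added to every entry.
#' @param noise_pairs If positive, the returned map is a multinomial sample of
#'   this many contact pairs from the expected map (0 returns the expected map
#'   itself).
#' @param seed Integer seed (or `NULL`).
#' @param interarm_halfwidth,ori_halfwidth,alignment_halfwidth Band/block
#'   half-widths in bins.
#' @return A `map_model_params` list.
#' @export
map_model_params <- function(decay_exponent = 1, interarm_strength = 0.2,
                             ori_cluster_strength = 0.2,
                             alignment_strength = 0.025,
                             background = 0.005, noise_pairs = 0, seed = NULL,
                             interarm_halfwidth = 2, ori_halfwidth = 20,
                             alignment_halfwidth = 25) {
  p <- list(decay_exponent = decay_exponent,
            interarm_strength = interarm_strength,
            ori_cluster_strength = ori_cluster_strength,
            alignment_strength = alignment_strength,
            background = background, noise_pairs = noise_pairs, seed = seed,
            interarm_halfwidth = interarm_halfwidth,
            ori_halfwidth = ori_halfwidth,
            alignment_halfwidth = alignment_halfwidth)
  num <- p[setdiff(names(p), "seed")]
  if (any(unlist(num) < 0)) stop("model parameters must be nonnegative")
  structure(p, class = "map_model_params")
}

origin_neighborhood <- function(layout, k, halfwidth) {
  ob <- origin_bins(layout)[k]
  if (is.na(ob)) return(integer(0))
  lo <- max(layout$bin_start[k], ob - halfwidth)
  hi <- min(layout$bin_end[k], ob + halfwidth)
  seq(lo, hi)
}

#' Simulate a synthetic contact map
#'
#' Builds the expected map described in [map_model_params()]; when
#' `noise_pairs > 0` it instead returns a seeded multinomial sample of that
#' many contact pairs (each pair incrementing `m[i,j]` and `m[j,i]`, matching
#' the [bin_contacts()] convention, so the sampled total is `2 * noise_pairs`).
#'
#' @param layout A `genome_layout` with origin positions set.
#' @param params A `map_model_params`.
#' @return A raw `contact_map`.
#' @export
#' @examples
#' m <- simulate_contact_map(agrobacterium_c58_layout(), map_model_params())
simulate_contact_map <- function(layout, params = map_model_params()) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "map_model_params"))
  n <- layout$n_bins
  m <- matrix(params$background, n, n)

  reps <- layout$replicons
  for (k in seq_len(nrow(reps))) {
    idx <- seq(layout$bin_start[k], layout$bin_end[k])
    nb <- length(idx)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    if (reps$topology[k] == "circular") d <- pmin(d, nb - d)
    dec <- ifelse(d == 0, 1, d^(-params$decay_exponent))
    m[idx, idx] <- m[idx, idx] + dec
  }

  # interarm anti-diagonals on the two chromosomes (first two replicons)
  obins <- origin_bins(layout)
  if (params$interarm_strength > 0) {
    for (k in seq_len(min(2L, nrow(reps)))) {
      if (is.na(obins[k])) next
      idx <- seq(layout$bin_start[k], layout$bin_end[k])
      s <- outer(idx, idx, "+")
      band <- abs(s - 2 * obins[k]) <= params$interarm_halfwidth &
        outer(idx, idx, "!=")
      m[idx, idx] <- m[idx, idx] + params$interarm_strength * band
    }
  }

  # pairwise origin-cluster blocks between distinct replicons
  if (params$ori_cluster_strength > 0 && nrow(reps) >= 2L) {
    nb_list <- lapply(seq_len(nrow(reps)), origin_neighborhood,
                      layout = layout, halfwidth = params$ori_halfwidth)
    for (a in seq_len(nrow(reps) - 1L)) {
      for (b in seq(a + 1L, nrow(reps))) {
        ia <- nb_list[[a]]; ib <- nb_list[[b]]
        if (!length(ia) || !length(ib)) next
        m[ia, ib] <- m[ia, ib] + params$ori_cluster_strength
        m[ib, ia] <- m[ib, ia] + params$ori_cluster_strength
      }
    }
  }

  # X-shaped Ch1-Ch2 alignment band
  if (params$alignment_strength > 0 && nrow(reps) >= 2L &&
      !is.na(obins[1L]) && !is.na(obins[2L])) {
    i1 <- seq(layout$bin_start[1L], layout$bin_end[1L])
    i2 <- seq(layout$bin_start[2L], layout$bin_end[2L])
    d1 <- i1 - obins[1L]
    d2 <- i2 - obins[2L]
    band <- (abs(outer(d1, d2, "-")) <= params$alignment_halfwidth) |
      (abs(outer(d1, d2, "+")) <= params$alignment_halfwidth)
    m[i1, i2] <- m[i1, i2] + params$alignment_strength * band
    m[i2, i1] <- m[i2, i1] + params$alignment_strength * t(band)
  }

  if (params$noise_pairs > 0) {
    m <- with_seed_(params$seed, {
      counts <- stats::rmultinom(1, size = params$noise_pairs,
                                 prob = as.vector(m) / sum(m))
      cm <- matrix(as.numeric(counts), n, n)
      cm + t(cm)
    })
  }
  contact_map(m, layout, normalized = FALSE)
}

#' Simulate contact records from a map
#'
#' Draws `n_pairs` contact records whose implied bin pairs follow the map's
#' probabilities, with coordinates uniform within bins. Coordinates on the
#' first (rearranged) replicon are reported on the native reference, so that
#' [bin_contacts()] round-trips them onto the sampled bins.
#'
#' @param map A nonnegative `contact_map` with positive total.
#' @param n_pairs Number of records.
#' @param seed Integer seed (or `NULL`).
#' @return A `data.frame` with columns `replicon1`, `pos1`, `replicon2`, `pos2`.
#' @export
simulate_contact_records <- function(map, n_pairs, seed = NULL) {
  stopifnot(inherits(map, "contact_map"), n_pairs >= 0)
  if (map$total <= 0) stop("cannot sample records from a zero-total map")
  layout <- map$layout
  n <- nrow(map$matrix)
  if (n_pairs == 0) {
    return(data.frame(replicon1 = character(0), pos1 = numeric(0),
                      replicon2 = character(0), pos2 = numeric(0)))
  }
  with_seed_(seed, {
    counts <- stats::rmultinom(1, size = n_pairs,
                               prob = as.vector(map$matrix) / map$total)
    cells <- which(counts > 0)
    b1 <- rep(((cells - 1) %% n) + 1, counts[cells])
    b2 <- rep(((cells - 1) %/% n) + 1, counts[cells])
    side <- function(b) {
      ri <- findInterval(b, layout$bin_start)
      name <- layout$replicons$name[ri]
      local_bin <- b - layout$bin_start[ri] + 1
      lo <- (local_bin - 1) * layout$bin_size + 1
      hi <- pmin(local_bin * layout$bin_size, layout$replicons$length[ri])
      pos <- floor(stats::runif(length(b), lo, hi + 1))
      if (layout$ch1_start_offset > 0) {
        is1 <- ri == 1L
        pos[is1] <- unrearrange_ch1(pos[is1], layout)
      }
      list(replicon = name, pos = pos)
    }
    s1 <- side(b1)
    s2 <- side(b2)
    ord <- sample.int(length(b1))  # shuffle so records are not sorted by bin
    data.frame(replicon1 = s1$replicon[ord], pos1 = s1$pos[ord],
               replicon2 = s2$replicon[ord], pos2 = s2$pos[ord],
               stringsAsFactors = FALSE)
  })
}

#' Synthetic ChIP/input model parameters
#'
#' @param peak_sites `data.frame` with columns `replicon`, `position`,
#'   `height` (enrichment over background at the summit) and `width`
#'   (Gaussian sd, bp). Default: ParB-type peaks of height 20 and sd 1,500 bp
#'   at the parS1 and parS2 clusters of the C58 layout.
#' @param background_rate Expected reads per base pair in the input (default
#'   20, deep coverage typical of a small bacterial genome).
#' @param library_sizes Optional `c(chip, input)` total read counts; when set,
#'   the expected per-bp rates are rescaled so each library's expected total
#'   matches. `NULL` leaves the rates as stated.
#' @param seed Integer seed (or `NULL`).
#' @return A `chip_model_params` list.
#' @export
chip_model_params <- function(peak_sites = NULL, background_rate = 20,
                              library_sizes = NULL, seed = NULL) {
  if (is.null(peak_sites)) {
    peak_sites <- data.frame(
      replicon = c("Ch1", "Ch2"), position = c(2825000, 975000),
      height = c(20, 20), width = c(1500, 1500), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("replicon", "position", "height", "width")
                %in% names(peak_sites)),
            all(peak_sites$height >= 0), all(peak_sites$width > 0),
            background_rate > 0)
  structure(list(peak_sites = peak_sites, background_rate = background_rate,
                 library_sizes = library_sizes, seed = seed),
            class = "chip_model_params")
}

#' Simulate ChIP and input coverage tracks
#'
#' The input track is Poisson with a flat per-bp rate; the ChIP track
#' multiplies that rate by `1 + sum of Gaussian peak profiles`, so `height` is
#' the expected ChIP/input enrichment above 1 at the summit. Both tracks are
#' nonnegative integer per-bp counts.
#'
#' @param layout A `genome_layout`.
#' @param params A `chip_model_params`.
#' @return A list with `chip` and `input`, both `coverage_track`s.
#' @export
simulate_chip_tracks <- function(layout, params = chip_model_params()) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "chip_model_params"))
  reps <- layout$replicons
  bad <- setdiff(params$peak_sites$replicon, reps$name)
  if (length(bad)) stop("peak site on unknown replicon: ",
                        paste(bad, collapse = ", "))
  lam_input <- lapply(reps$length, function(L) rep(params$background_rate, L))
  names(lam_input) <- reps$name
  lam_chip <- lam_input
  for (k in seq_len(nrow(params$peak_sites))) {
    p <- params$peak_sites[k, ]
    L <- reps$length[match(p$replicon, reps$name)]
    lo <- max(1, floor(p$position - 6 * p$width))
    hi <- min(L, ceiling(p$position + 6 * p$width))
    x <- seq(lo, hi)
    g <- p$height * exp(-((x - p$position)^2) / (2 * p$width^2))
    lam_chip[[p$replicon]][x] <-
      lam_chip[[p$replicon]][x] + params$background_rate * g
  }
  if (!is.null(params$library_sizes)) {
    lam_chip <- lapply(lam_chip, function(v)
      v * params$library_sizes[1] / sum(unlist(lam_chip)))
    lam_input <- lapply(lam_input, function(v)
      v * params$library_sizes[2] / sum(unlist(lam_input)))
  }
  with_seed_(params$seed, {
    draw <- function(lam, label) {
      vals <- lapply(lam, function(v) stats::rpois(length(v), v))
      coverage_track(vals, sample = label)
    }
    list(chip = draw(lam_chip, "chip"), input = draw(lam_input, "input"))
  })
}

#' Synthetic focus-table model parameters
#'
#' The stated world: rod-shaped cells 45 x 14 px with poles at the cell tips;
#' per-cell focus counts drawn from `count_dist`, the red channel mirroring
#' the green count (origin copies pair up); green (primary-channel)
#' foci placed at the poles with Gaussian scatter `polar_sigma_px`; each
#' green focus acquires, with probability `coloc_prob`, a red partner within
#' `coloc_jitter_px` (uniform in a disk), while unpaired red foci fall
#' uniformly in the cell (mislocalized origins).
#'
#' @param n_cells Number of cells.
#' @param coloc_prob Probability that a green focus has a colocalized red
#'   partner (default 0.97, a wild-type-like value).
#' @param coloc_jitter_px Maximum displacement of a colocalized partner, px.
#' @param polar_sigma_px Polar scatter sd, px.
#' @param count_dist Named probability vector over per-cell focus counts,
#'   names "0","1","2",... Default `c("1" = 0.6, "2" = 0.4)`.
#' @param cell_length_px,cell_width_px Cell dimensions, px.
#' @param seed Integer seed (or `NULL`).
#' @return A `foci_model_params` list.
#' @export
foci_model_params <- function(n_cells = 1000, coloc_prob = 0.97,
                              coloc_jitter_px = 2, polar_sigma_px = 3,
                              count_dist = c("1" = 0.6, "2" = 0.4),
                              cell_length_px = 45, cell_width_px = 14,
                              seed = NULL) {
  stopifnot(n_cells >= 1, coloc_prob >= 0, coloc_prob <= 1,
            coloc_jitter_px >= 0, polar_sigma_px >= 0,
            abs(sum(count_dist) - 1) < 1e-9, all(count_dist >= 0),
            cell_length_px > 0, cell_width_px > 0)
  structure(list(n_cells = n_cells, coloc_prob = coloc_prob,
                 coloc_jitter_px = coloc_jitter_px,
                 polar_sigma_px = polar_sigma_px, count_dist = count_dist,
                 cell_length_px = cell_length_px,
                 cell_width_px = cell_width_px, seed = seed),
            class = "foci_model_params")
}

#' Simulate a per-cell focus table
#'
#' @param params A `foci_model_params`.
#' @return A `foci_table` (see [foci_table()]).
#' @export
simulate_foci <- function(params = foci_model_params()) {
  stopifnot(inherits(params, "foci_model_params"))
  L <- params$cell_length_px
  W <- params$cell_width_px
  counts <- as.integer(names(params$count_dist))
  with_seed_(params$seed, {
    cells <- data.frame(
      cell_id = seq_len(params$n_cells),
      pole_ax = 0, pole_ay = 0, pole_bx = L, pole_by = 0,
      length_px = L, width_px = W)
    rows <- vector("list", params$n_cells)
    clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
    polar_point <- function(k) {
      # k-th focus: first two alternate poles, later ones pick at random
      pole <- if (k == 1L) 0 else if (k == 2L) L else sample(c(0, L), 1)
      dx <- abs(stats::rnorm(1, 0, params$polar_sigma_px))
      x <- if (pole == 0) pole + dx else pole - dx
      c(clamp(x, 0, L), clamp(stats::rnorm(1, 0, params$polar_sigma_px),
                              -W / 2, W / 2))
    }
    uniform_point <- function() c(stats::runif(1, 0, L),
                                  stats::runif(1, -W / 2, W / 2))
    disk_jitter <- function(p, r) {
      if (r == 0) return(p)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- r * sqrt(stats::runif(1))
      p + rad * c(cos(ang), sin(ang))
    }
    draw_count <- function() {
      counts[sample.int(length(counts), 1, prob = params$count_dist)]
    }
    for (c_i in seq_len(params$n_cells)) {
      ng <- draw_count()
      nr <- ng  # red channel mirrors the green count (paired origins)
      greens <- if (ng > 0) lapply(seq_len(ng), polar_point) else list()
      reds <- list()
      for (k in seq_len(nr)) {
        reds[[k]] <- if (stats::runif(1) < params$coloc_prob) {
          disk_jitter(greens[[k]], params$coloc_jitter_px)
        } else {
          uniform_point()
        }
      }
      pts <- c(greens, reds)
      if (length(pts)) {
        rows[[c_i]] <- data.frame(
          cell_id = c_i,
          channel = c(rep("green", ng), rep("red", nr)),
          x = vapply(pts, `[`, numeric(1), 1),
          y = vapply(pts, `[`, numeric(1), 2))
      }
    }
    foci <- do.call(rbind, rows)
    if (is.null(foci)) {
      foci <- data.frame(cell_id = integer(0), channel = character(0),
                         x = numeric(0), y = numeric(0))
    }
    foci_table(cells, foci)
  })
}
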