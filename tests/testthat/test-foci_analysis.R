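cell_row <- function(id = 1, L = 40, W = 10) {
  data.frame(cell_id = id, pole_ax = 0, pole_ay = 0, pole_bx = L, pole_by = 0,
             length_px = L, width_px = W)
}

pair_table <- function(dist) {
  foci_table(cell_row(),
             data.frame(cell_id = 1, channel = c("green", "red"),
                        x = c(10, 10 + dist), y = c(0, 0)))
}

test_that("colocalization uses a strict distance threshold", {
  expect_equal(colocalization_fraction(pair_table(0)), 1.0)
  expect_equal(colocalization_fraction(pair_table(6.0)), 0.0)  # exactly 6 px
  expect_equal(colocalization_fraction(pair_table(5.999)), 1.0)
  expect_equal(colocalization_fraction(pair_table(2), threshold = 1), 0.0)

  # partners must be in the same cell
  two_cells <- foci_table(
    rbind(cell_row(1), cell_row(2)),
    data.frame(cell_id = c(1, 2), channel = c("green", "red"),
               x = c(10, 10), y = c(0, 0)))
  expect_equal(colocalization_fraction(two_cells), 0.0)

  expect_error(colocalization_fraction(
    foci_table(cell_row()[0, ],
               data.frame(cell_id = integer(0), channel = character(0),
                          x = numeric(0), y = numeric(0)))),
    "empty cell list")
})

test_that("colocalization is monotone in the threshold", {
  ft <- simulate_foci(foci_model_params(n_cells = 200, coloc_prob = 0.5,
                                        seed = 14))
  fr <- vapply(c(0.5, 2, 6, 20, 1000), colocalization_fraction, numeric(1),
               ft = ft)
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[5], 1.0)  # every cell here has both colors or no greens
})

test_that("distance_to_nearest_pole matches hand geometry", {
  cell <- cell_row(L = 40)
  expect_equal(distance_to_nearest_pole(cell, c(0, 0)), 0)
  expect_equal(distance_to_nearest_pole(cell, c(20, 0)), 20)  # midpoint
  expect_equal(distance_to_nearest_pole(cell, c(3, 4)), 5)  # 3-4-5 triangle
  expect_equal(distance_to_nearest_pole(cell, c(37, -4)), 5)

  # symmetric under swapping pole labels, bounded by pole-to-pole distance
  swapped <- cell
  swapped[, c("pole_ax", "pole_ay", "pole_bx", "pole_by")] <-
    cell[, c("pole_bx", "pole_by", "pole_ax", "pole_ay")]
  for (f in list(c(5, 2), c(33, -1))) {
    expect_equal(distance_to_nearest_pole(cell, f),
                 distance_to_nearest_pole(swapped, f))
    expect_lte(distance_to_nearest_pole(cell, f), 40)
  }
})

test_that("pole_distances annotates every focus", {
  ft <- simulate_foci(foci_model_params(n_cells = 50, seed = 15))
  pd <- pole_distances(ft)
  expect_equal(nrow(pd), nrow(ft$foci))
  expect_true(all(pd$pole_distance >= 0))
  expect_true(all(pd$pole_distance <= 45))
  # polar placement: most green foci sit near a pole
  expect_gt(mean(pd$pole_distance[pd$channel == "green"] < 10), 0.9)
})

test_that("focus_count_matrix tabulates joint counts as percentages", {
  all11 <- foci_table(
    rbind(cell_row(1), cell_row(2)),
    data.frame(cell_id = c(1, 1, 2, 2),
               channel = c("green", "red", "green", "red"),
               x = 1:4, y = 0))
  s <- focus_count_matrix(all11)
  expect_equal(s$table["1", "1"], 100)
  expect_equal(sum(s$table), 100)

  ten <- do.call(rbind, lapply(1:10, cell_row))
  foci <- data.frame(cell_id = c(1:10, 1:6), channel = c(rep("green", 10),
                                                         rep("red", 6)),
                     x = 1, y = 0)
  s2 <- focus_count_matrix(foci_table(ten, foci))
  expect_equal(unname(s2$frac_zero[["red"]]), 0.40)
  expect_equal(unname(s2$mean[["green"]]), 1)
  expect_equal(sum(s2$table), 100)

  empty <- focus_count_matrix(foci_table(
    ten, data.frame(cell_id = integer(0), channel = character(0),
                    x = numeric(0), y = numeric(0))))
  expect_equal(empty$table["0", "0"], 100)
})

test_that("foci tables validate and round-trip through TSV", {
  expect_error(foci_table(data.frame(cell_id = 1, pole_ax = 0, pole_ay = 0,
                                     pole_bx = 0, pole_by = 0, length_px = 1,
                                     width_px = 1),
                          data.frame(cell_id = 1, channel = "green",
                                     x = 0, y = 0)),
               "poles must be distinct")
  ft <- simulate_foci(foci_model_params(
    n_cells = 30, count_dist = c("0" = 0.3, "1" = 0.7), seed = 16))
  tmp <- tempfile(fileext = ".tsv")
  write_foci(ft, tmp)
  back <- read_foci(tmp)
  expect_equal(nrow(back$cells), nrow(ft$cells))
  o1 <- ft$foci[order(ft$foci$cell_id, ft$foci$channel, ft$foci$x), ]
  o2 <- back$foci[order(back$foci$cell_id, back$foci$channel, back$foci$x), ]
  expect_equal(o1$x, o2$x, tolerance = 1e-9)
  expect_equal(o1$channel, o2$channel)
})
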