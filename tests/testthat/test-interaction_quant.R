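test_that("region_membership matches lattice enumeration oracles", {
  ori <- region_membership(ori_region(), 570)
  expect_equal(nrow(ori), 42 * 40)  # 1,680 pairs
  expect_identical(member_key(ori), member_key(oracle_ori_members()))

  # one parallelogram alone: 208 rows x 51 x-values
  p1 <- region_polygon_union(list(rbind(c(13, 285), c(63, 285),
                                        c(220, 492), c(270, 492))))
  expect_equal(nrow(region_membership(p1, 570)), 208 * 51)

  aln <- region_membership(alignment_region(), 570)
  expect_identical(member_key(aln), member_key(oracle_alignment_members()))

  degenerate <- region_rectangle(c(5, 5), c(9, 9))
  expect_equal(region_membership(degenerate, 570),
               cbind(x = 5L, y = 9L))

  expect_error(region_membership(ori_region(), 300), "beyond the matrix")
})

test_that("vertex order does not matter for polygon regions", {
  shuffled <- region_polygon_union(list(rbind(c(270, 492), c(13, 285),
                                              c(220, 492), c(63, 285))))
  ordered <- region_polygon_union(list(rbind(c(13, 285), c(63, 285),
                                             c(220, 492), c(270, 492))))
  expect_identical(member_key(region_membership(shuffled, 570)),
                   member_key(region_membership(ordered, 570)))
})

test_that("region_sum doubles the lattice mass and flags the diagonal", {
  ones <- ones_map(570)
  expect_equal(region_sum(ones, ori_region()), 3360)
  expect_equal(region_sum(ones, alignment_region()),
               2 * nrow(oracle_alignment_members()))
  zero <- contact_map(matrix(0, 570, 570), ones$layout)
  expect_equal(region_sum(zero, alignment_region()), 0)
  expect_warning(region_sum(ones, region_rectangle(c(1, 5), c(1, 5))),
                 "diagonal")
})

test_that("ori_interaction_score responds exactly to added ori mass", {
  p0 <- map_model_params(ori_cluster_strength = 0)
  p1 <- map_model_params(ori_cluster_strength = 0.7)
  m0 <- simulate_contact_map(c58, p0)
  m1 <- simulate_contact_map(c58, p1)
  mem <- region_membership(ori_region(), 570)
  added <- sum((m1$matrix - m0$matrix)[cbind(mem[, "y"], mem[, "x"])])
  expect_gt(added, 0)
  expect_equal(ori_interaction_score(m1) - ori_interaction_score(m0),
               2 * added)
  expect_equal(ori_interaction_score(ones_map(570)), 3360)

  small <- contact_map(matrix(1, 10, 10), tiny_layout(100000))
  expect_error(ori_interaction_score(small), "too small")
  expect_error(alignment_score(small), "too small")
})

test_that("alignment_score sees added alignment mass, overlap switch works", {
  m0 <- simulate_contact_map(c58, map_model_params(alignment_strength = 0))
  m1 <- simulate_contact_map(c58, map_model_params(alignment_strength = 0.2))
  expect_gt(alignment_score(m1), alignment_score(m0))

  ones <- ones_map(570)
  once <- alignment_score(ones)
  twice <- alignment_score(ones, double_count_overlap = TRUE)
  # the two parallelograms overlap in the middle of the X, so double counting
  # must add exactly the overlap mass
  reg <- alignment_region()
  n1 <- nrow(region_membership(
    region_polygon_union(reg$polygons[1], exclude = reg$exclude), 570))
  n2 <- nrow(region_membership(
    region_polygon_union(reg$polygons[2], exclude = reg$exclude), 570))
  expect_equal(twice, 2 * (n1 + n2))
  expect_gt(twice, once)
})

test_that("relative_interaction realizes the 100%/0% convention", {
  expect_identical(relative_interaction(8.5, 8.5, 2.5), 100)
  expect_identical(relative_interaction(2.5, 8.5, 2.5), 0)
  expect_equal(relative_interaction(2.5 + 0.4 * 6, 8.5, 2.5), 40)
  expect_equal(relative_interaction(1.0, 8.5, 2.5), -25)  # below background
  expect_error(relative_interaction(1, 3, 3), "undefined")
})

test_that("equal added background leaves percentages unchanged", {
  mk <- function(f, extra_bg) {
    p <- map_model_params(background = 0.005 + extra_bg)
    p$alignment_strength <- p$alignment_strength * f
    alignment_score(simulate_contact_map(c58, p))
  }
  for (bg in c(0, 0.05)) {
    pct <- relative_interaction(mk(0.4, bg), mk(1, bg), mk(0, bg))
    expect_equal(pct, 40, tolerance = 1e-9)
  }
})

test_that("bundled region definitions match the built-in constructors", {
  regs <- read_regions(system.file("extdata", "regions_c58.tsv",
                                   package = "multihic"))
  expect_identical(member_key(region_membership(regs$ori1_ori2, 570)),
                   member_key(region_membership(ori_region(), 570)))
  expect_identical(
    member_key(region_membership(regs$ch1_ch2_alignment, 570)),
    member_key(region_membership(alignment_region(), 570)))
})
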