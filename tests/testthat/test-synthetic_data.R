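test_that("feature strengths act additively and only in their regions", {
  base <- map_model_params(interarm_strength = 0, ori_cluster_strength = 0,
                           alignment_strength = 0)
  m0 <- simulate_contact_map(c58, base)$matrix
  # strengths 0: inter-replicon blocks are pure background
  ch1 <- 1:285
  ch2 <- 286:493
  expect_true(all(m0[ch1, ch2] == base$background))
  expect_true(all(diag(m0) == base$background + 1))

  withA <- base
  withA$alignment_strength <- 0.4
  mA <- simulate_contact_map(c58, withA)$matrix
  delta <- mA - m0
  expect_true(all(delta >= 0))
  expect_true(all(delta[ch1, ch1] == 0))  # nothing added intra-Ch1
  added <- delta[ch1, ch2]
  expect_setequal(unique(as.vector(added)), c(0, 0.4))
  expect_identical(delta, t(delta))
})

test_that("alignment fraction is recovered exactly on noiseless maps", {
  mk <- function(f) {
    p <- map_model_params()
    p$alignment_strength <- p$alignment_strength * f
    simulate_contact_map(c58, p)
  }
  s_wt <- alignment_score(mk(1))
  s_bg <- alignment_score(mk(0))
  for (f in c(0.25, 0.8)) {
    expect_equal(relative_interaction(alignment_score(mk(f)), s_wt, s_bg),
                 100 * f, tolerance = 1e-9)
  }
})

test_that("sampled maps are seeded, reproducible, and unbiased", {
  p <- map_model_params(noise_pairs = 20000, seed = 99)
  a <- simulate_contact_map(c58, p)
  b <- simulate_contact_map(c58, p)
  expect_identical(a$matrix, b$matrix)
  expect_equal(a$total, 2 * 20000)
  p2 <- p
  p2$seed <- 100
  expect_false(identical(a$matrix, simulate_contact_map(c58, p2)$matrix))

  # averaging seeded samples converges to the expected map (region readout)
  expected <- simulate_contact_map(c58, map_model_params())
  target <- alignment_score(expected) / expected$total
  est <- function(n_pairs, seed) {
    m <- simulate_contact_map(c58, map_model_params(noise_pairs = n_pairs,
                                                    seed = seed))
    alignment_score(m) / m$total
  }
  err_small <- abs(est(2e4, 1) - target)
  err_big <- abs(est(8e5, 2) - target)
  expect_lt(err_big, err_small)
  expect_lt(err_big / target, 0.02)
})

test_that("simulate_contact_records round-trips through bin_contacts", {
  lay <- c58
  expected <- simulate_contact_map(lay, map_model_params())
  expect_equal(nrow(simulate_contact_records(expected, 0)), 0)

  recs <- simulate_contact_records(expected, 50000, seed = 3)
  expect_identical(recs, simulate_contact_records(expected, 50000, seed = 3))
  expect_true(all(recs$pos1 >= 1 & recs$pos2 >= 1))
  lens <- lay$replicons$length[match(recs$replicon1, lay$replicons$name)]
  expect_true(all(recs$pos1 <= lens))

  # binned record frequencies approach the map distribution as n grows
  dev <- function(n, seed) {
    r <- simulate_contact_records(expected, n, seed = seed)
    m <- bin_contacts(r, lay)
    max(abs(m$matrix / m$total - expected$matrix / expected$total))
  }
  d1 <- dev(10000, 4)
  d2 <- dev(160000, 5)
  expect_lt(d2, d1)  # multinomial concentration

  zero <- contact_map(matrix(0, 2, 2), tiny_layout(20000))
  expect_error(simulate_contact_records(zero, 10), "zero-total")
})

test_that("ChIP track simulation is seeded and peaks scale linearly", {
  lay <- tiny_layout(100000)
  flat <- chip_model_params(
    peak_sites = data.frame(replicon = "chr", position = 1, height = 0,
                            width = 1),
    background_rate = 100, seed = 21)
  tr <- simulate_chip_tracks(lay, flat)
  expect_identical(tr$chip$values,
                   simulate_chip_tracks(lay, flat)$chip$values)
  enr <- enrichment(tr$chip, tr$input)
  binned <- bin_track(enr, 1000)
  expect_equal(mean(binned$value), 1, tolerance = 0.02)

  peak_at <- function(h, seed) {
    p <- chip_model_params(
      peak_sites = data.frame(replicon = "chr", position = 50000, height = h,
                              width = 300),
      background_rate = 100, seed = seed)
    tr <- simulate_chip_tracks(lay, p)
    peak_score(enrichment(tr$chip, tr$input),
               list(replicon = "chr", start = 48000, end = 52000))
  }
  s1 <- peak_at(5, 31)
  s2 <- peak_at(10, 32)
  expect_equal(s2 / s1, 2, tolerance = 0.1)
})

test_that("focus simulation matches its stated world", {
  perfect <- simulate_foci(foci_model_params(n_cells = 100, coloc_prob = 1,
                                             coloc_jitter_px = 0, seed = 8))
  expect_equal(colocalization_fraction(perfect, threshold = 1e-3), 1.0)

  none <- simulate_foci(foci_model_params(n_cells = 400, coloc_prob = 0,
                                          seed = 9))
  expect_lt(colocalization_fraction(none), 0.2)  # chance level only

  lost <- simulate_foci(foci_model_params(
    n_cells = 1000, count_dist = c("0" = 0.4, "1" = 0.6), seed = 10))
  zf <- focus_count_matrix(lost)$frac_zero
  expect_equal(unname(zf[["green"]]), 0.4, tolerance = 0.05)

  expect_identical(
    simulate_foci(foci_model_params(n_cells = 50, seed = 12))$foci,
    simulate_foci(foci_model_params(n_cells = 50, seed = 12))$foci)
})
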