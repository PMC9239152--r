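check_row <- function(check, value, expected, tol) {
  data.frame(check = check, value = value, expected = expected, tol = tol,
             pass = is.finite(value) & abs(value - expected) <= tol,
             stringsAsFactors = FALSE)
}

#' End-to-end synthetic reproduction workflow
#'
#' Generates a wild-type-like / background / mutant triple of synthetic
#' contact maps plus ChIP and focus demos, runs the full analysis
#' (simulate, balance, quantify), and reports a table of property checks:
#' the 100%/0% identities of the relative-interaction scale, recovery of
#' alignment fractions across a grid, ChIP depletion recovery, and focus
#' colocalization recovery. All randomness derives from `seed`.
#'
#' Noiseless expected maps make fraction recovery exact; with
#' `n_pairs > 0` the maps are multinomial samples and recovery is checked to
#' the stochastic tolerance (+-5 percentage points at 5e5 pairs).
#'
#' @param seed Integer master seed.
#' @param fractions Alignment-strength fractions for the recovery grid.
#' @param n_pairs Contact pairs per sampled map (0 = noiseless expected maps).
#' @param n_cells Cells in the focus demo.
#' @param chip_depletion Depletion factor applied to the parS2 peak in the
#'   ChIP demo.
#' @param chip Run the ChIP demo (full-genome per-bp simulation; a few
#'   seconds)?
#' @param out_dir Optional directory; when set, the maps, report and demo
#'   tables are written there.
#' @param quiet Suppress progress messages.
#' @return A `data.frame` report with one row per check (`check`, `value`,
#'   `expected`, `tol`, `pass`).
#' @export
reproduce_synthetic <- function(seed = 1, fractions = c(0.15, 0.35, 0.6),
                                n_pairs = 0, n_cells = 1000,
                                chip_depletion = 0.36, chip = TRUE,
                                out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  layout <- agrobacterium_c58_layout()
  base <- map_model_params()
  mk <- function(frac, s) {
    p <- base
    p$alignment_strength <- base$alignment_strength * frac
    p$noise_pairs <- n_pairs
    p$seed <- s
    simulate_contact_map(layout, p)
  }
  say("simulating contact maps (", if (n_pairs > 0) paste0(n_pairs, " pairs")
      else "noiseless", ") ...")
  wt <- mk(1, seed + 101L)
  bg <- mk(0, seed + 102L)
  tol_rec <- if (n_pairs > 0) 5 else 1e-9
  s_wt <- alignment_score(wt)
  s_bg <- alignment_score(bg)
  report <- rbind(
    check_row("relative_interaction(wt, wt, bg) == 100%",
              relative_interaction(s_wt, s_wt, s_bg), 100, 1e-12),
    check_row("relative_interaction(bg, wt, bg) == 0%",
              relative_interaction(s_bg, s_wt, s_bg), 0, 1e-12))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    s_f <- alignment_score(mk(f, seed + 200L + i))
    report <- rbind(report, check_row(
      sprintf("alignment fraction %.2f recovered", f),
      relative_interaction(s_f, s_wt, s_bg), 100 * f, tol_rec))
  }

  say("balancing the wild-type map ...")
  wt_n <- ice_normalize(if (n_pairs > 0) wt else {
    p <- base; p$noise_pairs <- 5e5; p$seed <- seed + 103L
    simulate_contact_map(layout, p)
  })
  rs <- rowSums(wt_n$matrix)
  rs <- rs[!attr(wt_n, "mask")]
  report <- rbind(report, check_row(
    "balanced map: max row-sum deviation below 1e-5",
    max(abs(rs - 1)), 0, 1e-5))

  if (chip) {
    say("simulating ChIP/input tracks ...")
    ref_par <- chip_model_params(seed = seed + 301L)
    dep_sites <- ref_par$peak_sites
    dep_sites$height[dep_sites$replicon == "Ch2"] <-
      dep_sites$height[dep_sites$replicon == "Ch2"] * chip_depletion
    dep_par <- chip_model_params(peak_sites = dep_sites, seed = seed + 302L)
    win <- list(replicon = "Ch2", start = 975000 - 5000, end = 975000 + 5000)
    tr_ref <- simulate_chip_tracks(layout, ref_par)
    tr_dep <- simulate_chip_tracks(layout, dep_par)
    rel <- relative_enrichment(
      peak_score(enrichment(tr_dep$chip, tr_dep$input), win),
      peak_score(enrichment(tr_ref$chip, tr_ref$input), win))
    report <- rbind(report, check_row(
      sprintf("ChIP depletion %.2f recovered at parS2 +-5 kb",
              chip_depletion),
      rel, 100 * chip_depletion, 3))
  }

  say("simulating focus tables ...")
  ft <- simulate_foci(foci_model_params(n_cells = n_cells, coloc_prob = 0.9,
                                        seed = seed + 401L))
  # tolerance: chance-colocalization margin + 3 sigma binomial at the
  # expected number of green foci (mean 1.4 per cell under the default counts)
  coloc_tol <- 0.015 + 3 * sqrt(0.9 * 0.1 / (1.4 * n_cells))
  report <- rbind(report, check_row(
    "colocalization fraction 0.90 recovered",
    colocalization_fraction(ft), 0.9, coloc_tol))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- c(seed = as.character(seed))
    write_matrix(wt, file.path(out_dir, "wt_map.txt"), provenance = prov)
    write_matrix(bg, file.path(out_dir, "bg_map.txt"), provenance = prov)
    write_foci(ft, file.path(out_dir, "foci.tsv"))
    utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  say("done: ", sum(report$pass), "/", nrow(report), " checks passed")
  report
}
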