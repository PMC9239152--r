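# Independent oracles and tiny fixtures, deliberately coded along different
# paths than the package implementation.

# classic alternating row/column normalization to a doubly stochastic matrix
# (Sinkhorn iteration); independent of the per-sweep update in ice_normalize
ipf_oracle <- function(M, tol = 1e-10, max_iter = 10000) {
  for (i in seq_len(max_iter)) {
    M <- M / rowSums(M)
    M <- t(t(M) / colSums(M))
    if (max(abs(rowSums(M) - 1)) < tol && max(abs(colSums(M) - 1)) < tol) {
      break
    }
  }
  (M + t(M)) / 2
}

# lattice enumeration of the standard quantification regions straight from
# half-plane inequalities (derived by hand from the printed vertices), not
# from the package's generic polygon code
oracle_ori_members <- function() {
  g <- expand.grid(x = 122:163, y = 363:402)
  cbind(x = g$x, y = g$y)
}

oracle_alignment_members <- function(n = 570, drop_ori = TRUE) {
  g <- expand.grid(x = 1:n, y = 1:n)
  p1 <- g$y >= 285 & g$y <= 492 & (g$y - g$x) >= 222 & (g$y - g$x) <= 272
  p2 <- g$y >= 285 & g$y <= 492 & (g$x + g$y) >= 505 & (g$x + g$y) <= 555
  keep <- p1 | p2
  if (drop_ori) {
    keep <- keep & !(g$x >= 122 & g$x <= 163 & g$y >= 363 & g$y <= 402)
  }
  cbind(x = g$x[keep], y = g$y[keep])
}

member_key <- function(mem) sort(mem[, "x"] * 10000 + mem[, "y"])

# small single-replicon layout (no rearrangement)
tiny_layout <- function(len = 100000, bin_size = 10000,
                        topology = "linear", origin = NA_real_) {
  build_layout(replicon_spec("chr", len, topology, origin),
               bin_size = bin_size, ch1_start_offset = 0)
}

random_symmetric <- function(n, min = 0.1, max = 2) {
  A <- matrix(stats::runif(n * n, min, max), n, n)
  A + t(A)
}

# contact_map of all ones on an n-bin synthetic layout
ones_map <- function(n) {
  lay <- build_layout(replicon_spec("chr", n * 1000, "linear"),
                      bin_size = 1000, ch1_start_offset = 0)
  contact_map(matrix(1, n, n), lay)
}

c58 <- agrobacterium_c58_layout()
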