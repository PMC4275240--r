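# shared fixtures, all generated in code

# cache for results shared between acceptance blocks (power runs feed the
# pooled FDR check)
.acc_cache <- new.env(parent = emptyenv())

toy_map <- function() {
  genetic_map(c("m1", "m2", "m3"), c("chr1", "chr1", "chr2"), c(0, 12.5, 3))
}

# block-correlated expression: `blocks` clusters of `per_block` traits with
# within-block correlation `rho` (latent-factor construction), independent
# between blocks
planted_expression <- function(blocks = 4L, per_block = 15L, rho = 0.4,
                               n_lines = 211L, n_rep = 1L, sd = 1) {
  n_obs <- n_lines * n_rep
  vals <- matrix(0, blocks * per_block, n_obs)
  for (b in seq_len(blocks)) {
    f <- rnorm(n_obs)
    rows <- (b - 1L) * per_block + seq_len(per_block)
    for (r in rows) {
      vals[r, ] <- sd * (sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_obs))
    }
  }
  rownames(vals) <- sprintf("T%03d", seq_len(nrow(vals)))
  trait_matrix(vals, rep(sprintf("L%03d", seq_len(n_lines)), each = n_rep),
               rep(seq_len(n_rep), times = n_lines))
}

planted_labels <- function(blocks = 4L, per_block = 15L) {
  stats::setNames(rep(seq_len(blocks), each = per_block),
                  sprintf("T%03d", seq_len(blocks * per_block)))
}

# balanced two-locus design: every genotype class replicated `reps` times
balanced_codes <- function(reps = 2L) {
  g <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  list(xa = rep(g$a, each = reps), xb = rep(g$b, each = reps))
}

# a dense 493-marker map on 5 chromosomes organised as 47 framework regions
# (synthetic stand-in for an Arabidopsis-scale RIL map, which is an external
# resource): greedy 10-cM selection recovers exactly the 47 region heads
synthetic_dense_map_493 <- function() {
  regions_per_chr <- c(10L, 10L, 9L, 9L, 9L)           # 47 regions
  sizes <- rep(10L, 47L)
  sizes[seq_len(23L)] <- 11L                           # 23*11 + 24*10 = 493
  marker <- character(0); chrom <- character(0); pos <- numeric(0)
  reg <- 0L
  for (c in seq_along(regions_per_chr)) {
    for (r in seq_len(regions_per_chr[c])) {
      reg <- reg + 1L
      k <- seq_len(sizes[reg])
      marker <- c(marker, sprintf("C%dR%dM%d", c, r, k))
      chrom <- c(chrom, rep(sprintf("chr%d", c), sizes[reg]))
      pos <- c(pos, (r - 1L) * 10 + (k - 1L) * 0.8)
    }
  }
  genetic_map(marker, chrom, pos)
}

# small simulation configuration for fast structural tests
small_sim_config <- function(...) {
  sim_config(n_lines = 80L, n_sim = 2L, seed = 42L, ...)
}
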