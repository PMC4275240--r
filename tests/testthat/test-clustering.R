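test_that("correlation matrix matches the direct formula and validates input", {
  set.seed(1)
  vals <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expr <- trait_matrix(vals, paste0("L", 1:4))
  cc <- correlation_matrix(expr)
  # brute-force covariance / sd oracle
  for (i in 1:3) for (j in 1:3) {
    xi <- vals[i, ]; xj <- vals[j, ]
    oracle <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(cc[i, j], oracle)
  }
  # duplicated trait -> 1, negated trait -> -1
  vals2 <- rbind(vals, d = vals["a", ], e = -vals["a", ])
  cc2 <- correlation_matrix(trait_matrix(vals2, paste0("L", 1:4)))
  expect_equal(cc2["a", "d"], 1)
  expect_equal(cc2["a", "e"], -1)

  vals3 <- rbind(vals, flat = rep(1, 4))
  expect_error(correlation_matrix(trait_matrix(vals3, paste0("L", 1:4))),
               "flat")
})

test_that("adjacency is the soft-thresholded absolute correlation", {
  cc <- matrix(c(1, 0.5, -0.8, 0.5, 1, 0, -0.8, 0, 1), 3, 3)
  expect_equal(adjacency(cc, beta = 2)[1, 2], 0.25)
  expect_equal(adjacency(cc, beta = 2)[1, 3], 0.64)
  expect_equal(adjacency(matrix(1, 2, 2), beta = 9)[1, 2], 1)
  expect_error(adjacency(cc, beta = 0.5), "beta")
  # monotone in |cor| at fixed beta
  a <- adjacency(cc, beta = 6)
  expect_true(a[1, 3] > a[1, 2])
})

test_that("TOM dissimilarity equals the brute-force triple loop", {
  tom_brute <- function(a) {
    n <- nrow(a)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      d[i, j] <- 1 - (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    d
  }
  # two-trait edge cases
  a2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(tom_dissimilarity(a2)[1, 2], 0)
  a0 <- diag(2)
  expect_equal(tom_dissimilarity(a0)[1, 2], 1)

  set.seed(9)
  for (n in c(4L, 10L)) {
    cc <- stats::cor(matrix(rnorm(n * 20), 20, n))
    a <- adjacency(cc, beta = 3)
    d <- tom_dissimilarity(a)
    expect_equal(d, tom_brute(a), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(isSymmetric(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(diag(d), rep(0, n))
  }
})

test_that("planted partitions are recovered by module detection", {
  skip_if_not_installed("mclust")
  # strong two-block structure: exact recovery
  set.seed(13)
  expr2 <- planted_expression(blocks = 2L, per_block = 15L, rho = 0.9,
                              n_lines = 60L)
  d2 <- tom_dissimilarity(adjacency(correlation_matrix(expr2)))
  cs2 <- detect_modules(d2)
  expect_equal(sort(unname(cs2$sizes)), c(15L, 15L))
  expect_equal(mclust::adjustedRandIndex(cs2$labels, planted_labels(2L, 15L)), 1)

  # the simulation design: 4 clusters x 15 traits at correlation 0.4, n = 211
  set.seed(17)
  expr4 <- planted_expression(blocks = 4L, per_block = 15L, rho = 0.4,
                              n_lines = 211L)
  d4 <- tom_dissimilarity(adjacency(correlation_matrix(expr4)))
  cs4 <- detect_modules(d4)
  ari <- mclust::adjustedRandIndex(cs4$labels, planted_labels(4L, 15L))
  expect_gte(ari, 0.9)

  # structureless data must not reproduce a planted partition
  set.seed(19)
  noise <- planted_expression(blocks = 1L, per_block = 30L, rho = 0,
                              n_lines = 211L)
  dn <- tom_dissimilarity(adjacency(correlation_matrix(noise)))
  csn <- detect_modules(dn)
  fake <- stats::setNames(rep(1:2, each = 15L), rownames(noise$values))
  expect_lt(abs(mclust::adjustedRandIndex(csn$labels, fake)), 0.3)

  # fewer traits than the minimum size: one module
  tiny <- planted_expression(blocks = 1L, per_block = 4L, rho = 0.5,
                             n_lines = 30L)
  dt <- tom_dissimilarity(adjacency(correlation_matrix(tiny)))
  cst <- detect_modules(dt, min_module_size = 5)
  expect_equal(unname(cst$labels), rep(1L, 4L))
})

test_that("meta-traits are first principal components with the sign convention", {
  # identical traits: variance explained 1, meta-trait tracks the profile
  set.seed(23)
  prof <- rnorm(40)
  vals <- rbind(t1 = prof, t2 = prof, t3 = prof)
  expr <- trait_matrix(vals, sprintf("L%02d", 1:40))
  cs <- cluster_set(stats::setNames(c(1L, 1L, 1L), rownames(vals)))
  mt <- compute_meta_traits(expr, cs)
  expect_equal(unname(mt$var_explained), 1)
  expect_equal(abs(cor(mt$values[1, ], prof)), 1)
  expect_gt(cor(mt$values[1, ], prof), 0)        # sign anchored to module mean
  expect_equal(mean(mt$values[1, ]), 0)          # centred over samples

  # two traits: variance explained is (1 + |rho|) / 2 from the 2x2 eigenvalues
  x <- rnorm(60); y <- 0.6 * x + rnorm(60, 0, 0.8)
  expr2 <- trait_matrix(rbind(a = x, b = y), sprintf("L%02d", 1:60))
  cs2 <- cluster_set(stats::setNames(c(1L, 1L), c("a", "b")))
  mt2 <- compute_meta_traits(expr2, cs2)
  rho <- cor(x, y)
  expect_equal(unname(mt2$var_explained), (1 + abs(rho)) / 2)

  # flipping all trait signs flips the meta-trait
  expr2f <- trait_matrix(rbind(a = -x, b = -y), sprintf("L%02d", 1:60))
  mt2f <- compute_meta_traits(expr2f, cs2)
  expect_equal(mt2f$values[1, ], -mt2$values[1, ], tolerance = 1e-10)

  # invariant (up to the sign convention) under trait reordering
  expr2r <- trait_matrix(rbind(b = y, a = x), sprintf("L%02d", 1:60))
  mt2r <- compute_meta_traits(expr2r, cs2)
  expect_equal(mt2r$values[1, ], mt2$values[1, ], tolerance = 1e-10)

  # a module with fewer than 2 traits is an error
  cs_bad <- cluster_set(stats::setNames(c(1L, 2L), c("a", "b")))
  expect_error(compute_meta_traits(expr2, cs_bad), "fewer than 2")
})
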