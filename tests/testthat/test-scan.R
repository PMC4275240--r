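test_that("framework selection follows the greedy spacing rule", {
  # markers exactly 10 cM apart: all selected
  m10 <- genetic_map(sprintf("m%d", 1:10), rep("c1", 10), seq(0, 90, by = 10))
  plan10 <- select_framework_markers(m10, 10)
  expect_equal(plan10$framework, sprintf("m%d", 1:10))

  # 0,3,6,9,12 at spacing 10 -> {0, 12}
  m5 <- genetic_map(sprintf("m%d", 1:5), rep("c1", 5), c(0, 3, 6, 9, 12))
  plan5 <- select_framework_markers(m5, 10)
  expect_equal(plan5$framework, c("m1", "m5"))
  # regions partition the chromosome; midpoint ties go to the earlier marker
  expect_equal(sort(unlist(plan5$regions, use.names = FALSE)), sprintf("m%d", 1:5))
  expect_equal(unname(plan5$region["m3"]), "m1")   # 6 cM: nearer m1 (tie at 6/6)
})

test_that("BH step-up equals the exhaustive subset oracle on small families", {
  # oracle: largest subset whose maximum p-value passes |S| * q / m
  bh_oracle <- function(p, q) {
    m <- length(p)
    best <- integer(0)
    for (size in seq_len(m)) {
      idx <- order(p)[seq_len(size)]
      if (max(p[idx]) <= size * q / m) best <- idx
    }
    sort(best)
  }
  expect_equal(sort(bh_select(c(0.001, 0.02, 0.8), 0.05)), c(1L, 2L))
  expect_equal(bh_select(rep(1, 5), 0.1), integer(0))
  expect_equal(sort(bh_select(rep(0, 5), 0.1)), 1:5)
  expect_equal(bh_select(numeric(0), 0.1), integer(0))

  set.seed(61)
  for (i in 1:25) {
    m <- sample(2:12, 1)
    p <- round(runif(m), 3)              # rounding creates ties
    q <- runif(1, 0.01, 0.3)
    expect_equal(sort(bh_select(p, q)), bh_oracle(p, q))
  }
})

test_that("within-family level and full-tree bound follow the tree calibration", {
  expect_equal(full_tree_level(0.1, 1.015), 0.1 / (2 * 1.015))
  expect_equal(full_tree_level(0.1, 1.015), 0.04926, tolerance = 1e-4)
  expect_equal(full_tree_level(0.3, 1), 0.15)
  expect_gt(full_tree_level(0.1, 1.0), full_tree_level(0.1, 1.44))
  expect_error(full_tree_level(0, 1.2), "in \\(0, 1\\)")
  expect_error(full_tree_level(0.1, 0.5), "delta")

  expect_equal(fdr_bound(0.05, 1, 1), 0.10)
  expect_lt(fdr_bound(0.05, 1, 0.6), fdr_bound(0.05, 1, 1))
})

test_that("level-2 families pair the two parental regions and exclude the parent", {
  map <- synthetic_ril_map()                       # regions of 6 markers
  plan <- select_framework_markers(map, 10)
  rejected <- data.frame(trait = "M1", markerA = "C1R1M1", markerB = "C2R2M1",
                         stringsAsFactors = FALSE)
  fams <- level2_families(rejected, plan)
  expect_length(fams, 1L)
  expect_equal(nrow(fams[[1]]$pairs), 6L * 6L - 1L)   # 35
  # all pairs come from the two regions
  expect_true(all(fams[[1]]$pairs[, 1] %in% plan$regions[["C1R1M1"]]))
  expect_true(all(fams[[1]]$pairs[, 2] %in% plan$regions[["C2R2M1"]]))

  # singleton regions give an empty family
  m1 <- genetic_map(c("a", "b"), c("c1", "c2"), c(0, 0))
  p1 <- select_framework_markers(m1, 10)
  f1 <- level2_families(data.frame(trait = "t", markerA = "a", markerB = "b"),
                        p1)
  expect_equal(nrow(f1[[1]]$pairs), 0L)

  # no rejections, no families (the whole subtree disappears)
  expect_length(level2_families(NULL, plan), 0L)
  expect_length(level2_families(rejected[0, ], plan), 0L)
})

test_that("level-1 scan enumerates trait x framework-pair combinations", {
  set.seed(67)
  map <- synthetic_ril_map(n_chr = 1L, regions_per_chr = 3L)
  geno <- simulate_ril_genotypes(map, 40L)
  expr <- planted_expression(blocks = 1L, per_block = 2L, rho = 0,
                             n_lines = 40L)
  plan <- select_framework_markers(map, 10)
  l1 <- level1_scan(expr, geno, plan)
  expect_equal(nrow(l1$nodes), 2L * choose(3L, 2L))
  expect_true(all(l1$nodes$p >= 0 & l1$nodes$p <= 1))
})

test_that("level-1 p-values are uniform on null data", {
  set.seed(71)
  map <- synthetic_ril_map()
  geno <- simulate_ril_genotypes(map, 211L)
  expr <- planted_expression(blocks = 1L, per_block = 10L, rho = 0,
                             n_lines = 211L)
  plan <- select_framework_markers(map, 10)
  l1 <- level1_scan(expr, geno, plan)
  # keep only inter-chromosomal pairs: independent loci, independent traits
  chr <- stats::setNames(map$chromosome, map$marker)
  inter <- chr[l1$nodes$markerA] != chr[l1$nodes$markerB]
  ks <- stats::ks.test(l1$nodes$p[inter], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted epistatic pair drives hierarchical discoveries; noise does not", {
  set.seed(73)
  cfg <- sim_config(n_lines = 150L, epi_coef = -0.6, n_main_effects = 2L)
  map <- synthetic_ril_map()
  geno <- simulate_ril_genotypes(map, cfg$n_lines)
  sim <- simulate_traits(geno, map, cfg)
  meta <- compute_meta_traits(sim$expression, cluster_set(sim$clusters))
  report <- run_hierarchical(meta, geno, map, q = 0.2)

  # the implanted framework pair of cluster 1 is discovered for meta-trait M1
  pair1 <- sim$pairs[[1]]
  d1 <- report$discoveries[report$discoveries$level == 1L &
                             report$discoveries$trait == "M1", ]
  hit <- (d1$markerA == pair1[1] & d1$markerB == pair1[2]) |
         (d1$markerA == pair1[2] & d1$markerB == pair1[1])
  expect_true(any(hit))
  # and most of its secondary family follows at level 2
  d2 <- report$discoveries[report$discoveries$level == 2L &
                             report$discoveries$trait == "M1", ]
  expect_gte(nrow(d2), 18L)                        # > half of the 35 children

  # report totals are conserved
  expect_equal(report$counts$n_discoveries,
               report$counts$n_level1_rejected + report$counts$n_level2_rejected)
  expect_equal(nrow(report$discoveries), report$counts$n_discoveries)
  # every rejection passed its family's BH threshold
  l1r <- report$level1[report$level1$rejected, ]
  m1 <- nrow(report$level1)
  expect_true(all(l1r$p <= nrow(l1r) * report$q_star / m1 + 1e-12))

  # pure noise: (almost) nothing is discovered
  set.seed(79)
  noise <- planted_expression(blocks = 4L, per_block = 2L, rho = 0,
                              n_lines = 150L)
  rep0 <- run_hierarchical(noise, geno, map, q = 0.1)
  expect_lte(rep0$counts$n_discoveries, 2L)
})

test_that("delta estimation is deterministic and bounded", {
  set.seed(83)
  map <- synthetic_ril_map(n_chr = 2L, regions_per_chr = 3L)
  geno <- simulate_ril_genotypes(map, 100L)
  expr <- planted_expression(blocks = 1L, per_block = 4L, rho = 0.3,
                             n_lines = 100L)
  est1 <- estimate_delta(expr, geno, map, q = 0.4, reps = 60L, seed = 5L)
  est2 <- estimate_delta(expr, geno, map, q = 0.4, reps = 60L, seed = 5L)
  expect_identical(est1$delta, est2$delta)
  expect_gte(est1$delta, 1)
  expect_lte(est1$delta, 1.44)
  expect_gte(est1$se, 0)
})

test_that("test-count accounting matches hand arithmetic", {
  tc <- hierarchical_test_counts(6, 10, 3, 2, 4)
  expect_equal(tc$marker_pairs, 15)
  expect_equal(tc$direct_tests, 150)
  expect_equal(tc$level1_tests, 6)
  expect_equal(tc$total_hierarchical, 10)
  expect_equal(tc$fold_reduction, 15)
})
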