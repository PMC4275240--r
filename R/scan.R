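#' Select sparse framework markers and their regions
#'
#' Greedy per chromosome: the first marker is selected; thereafter the first
#' marker at least `spacing_cM` beyond the last selected one. Every marker is
#' assigned to the region of its nearest framework marker on the same
#' chromosome (cM distance, ties to the earlier framework marker), so the
#' regions partition each chromosome's markers.
#'
#' @param map a [genetic_map].
#' @param spacing_cM target spacing between framework markers.
#' @return An object of class `framework_plan`: list with `framework`
#'   (character vector of framework marker ids), `region` (named character
#'   vector mapping every marker to its framework marker), `regions` (list of
#'   member markers per framework marker), `map`, `spacing_cM`.
#' @export
select_framework_markers <- function(map, spacing_cM = 10) {
  stopifnot(inherits(map, "genetic_map"))
  framework <- character(0)
  region <- stats::setNames(character(nrow(map)), map$marker)
  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    sel <- 1L
    last <- sub$position_cM[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$position_cM[i] - last >= spacing_cM) {
        sel <- c(sel, i)
        last <- sub$position_cM[i]
      }
    }
    fw <- sub$marker[sel]
    framework <- c(framework, fw)
    # nearest framework marker; ties -> the earlier (lower-position) one
    dmat <- abs(outer(sub$position_cM, sub$position_cM[sel], "-"))
    nearest <- apply(dmat, 1L, which.min)   # which.min is first-tie -> earlier
    region[sub$marker] <- fw[nearest]
  }
  regions <- split(names(region), region)[unique(framework)]
  structure(list(framework = framework, region = region, regions = regions,
                 map = map, spacing_cM = spacing_cM),
            class = "framework_plan")
}

#' @export
print.framework_plan <- function(x, ...) {
  cat(sprintf("framework_plan: %d framework markers (%d marker pairs), %d markers total\n",
              length(x$framework), choose(length(x$framework), 2L),
              length(x$region)))
  invisible(x)
}

#' Benjamini-Hochberg linear step-up selection
#'
#' Sorts the p-values ascending (stable), finds the largest `k` with
#' `p_(k) <= k * q / m`, and rejects those `k` hypotheses.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q_level BH level.
#' @return Integer indices (into `pvalues`) of the rejected hypotheses;
#'   empty for an empty family.
#' @export
bh_select <- function(pvalues, q_level) {
  m <- length(pvalues)
  if (m == 0L) return(integer(0))
  o <- order(pvalues)                 # stable for ties
  ps <- pvalues[o]
  ok <- which(ps <= seq_len(m) * q_level / m)
  if (!length(ok)) return(integer(0))
  o[seq_len(max(ok))]
}

#' Within-family BH level for a two-level tree
#'
#' The full-tree FDR of the two-level hierarchical procedure is bounded by
#' `2 * delta * pi * q*`; to control it at `q` the within-family level is
#' `q* = q / (2 * delta)`.
#'
#' @param q target full-tree FDR in (0, 1).
#' @param delta family-specific multiplicative factor (>= 1; universal upper
#'   bound 1.44).
#' @return The within-family BH level `q*`.
#' @export
full_tree_level <- function(q, delta) {
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (delta < 1) stop("delta must be >= 1")
  q / (2 * delta)
}

#' Full-tree FDR bound of a two-level hierarchical scan
#'
#' @param q_star within-family BH level.
#' @param delta family-specific multiplicative factor.
#' @param pi_hat weighted proportion of true nulls (1 is conservative).
#' @return The bound `2 * delta * pi_hat * q_star`.
#' @export
fdr_bound <- function(q_star, delta, pi_hat = 1) {
  2 * delta * pi_hat * q_star
}

# observation-level genotype rows for the samples of a trait matrix
expand_genotypes <- function(geno, samples) {
  idx <- match(samples$line, rownames(geno))
  if (anyNA(idx)) {
    stop("samples reference lines missing from the genotype matrix: ",
         paste(unique(samples$line[is.na(idx)]), collapse = ", "))
  }
  geno[idx, , drop = FALSE]
}

# scan a set of marker pairs (2-column matrix of marker ids) against all
# traits in `values` (traits x observations); gobs is the observation-level
# genotype matrix. Returns a data.frame of nodes plus a skip log.
scan_pairs <- function(values, gobs, pairs, min_n = 5L, alias_cor = 0.99,
                       traits = rownames(values)) {
  used <- unique(c(pairs))
  # statistical (frequency-centered) codes per marker, NA preserved; for
  # pairs with missing genotypes the codes are recomputed on complete cases
  codes <- matrix(NA_real_, nrow(gobs), length(used),
                  dimnames = list(NULL, used))
  has_na <- logical(length(used)); names(has_na) <- used
  for (mk in used) {
    g <- gobs[, mk]
    isna <- is.na(g)
    has_na[mk] <- any(isna)
    x <- numeric(length(g)); x[isna] <- NA_real_
    x[!isna] <- ifelse(g[!isna] == "P2", 1, -1)
    if (!has_na[mk] && length(unique(x)) == 2L) x <- recode_statistical(x)
    codes[, mk] <- x
  }
  tY <- t(values[traits, , drop = FALSE])   # observations x traits
  np <- nrow(pairs); nt <- length(traits)
  p <- iAB <- h2ab <- h2tot <- matrix(NA_real_, nt, np)
  skip_reason <- character(np)
  for (i in seq_len(np)) {
    ma <- pairs[i, 1L]; mb <- pairs[i, 2L]
    xa <- codes[, ma]; xb <- codes[, mb]
    if (has_na[ma] || has_na[mb]) {
      kept <- !(is.na(xa) | is.na(xb))
      if (sum(kept) < min_n) { skip_reason[i] <- "too few usable samples"; next }
      fit <- noia_fit_batch(tY[kept, , drop = FALSE], xa[kept], xb[kept],
                            alias_cor = alias_cor, recode = TRUE)
    } else {
      fit <- noia_fit_batch(tY, xa, xb, alias_cor = alias_cor)
    }
    if (!is.null(fit$error)) { skip_reason[i] <- fit$error; next }
    p[, i] <- fit$p
    iAB[, i] <- fit$coef[4L, ]
    h2ab[, i] <- fit$h2[3L, ]
    h2tot[, i] <- fit$h2_total
  }
  ok <- skip_reason == ""
  nodes <- data.frame(trait = rep(traits, times = sum(ok)),
                      markerA = rep(pairs[ok, 1L], each = nt),
                      markerB = rep(pairs[ok, 2L], each = nt),
                      p = as.vector(p[, ok]), iAB = as.vector(iAB[, ok]),
                      h2_AB = as.vector(h2ab[, ok]),
                      h2_total = as.vector(h2tot[, ok]),
                      stringsAsFactors = FALSE)
  skipped <- if (any(!ok)) {
    data.frame(markerA = pairs[!ok, 1L], markerB = pairs[!ok, 2L],
               reason = skip_reason[!ok], stringsAsFactors = FALSE)
  } else NULL
  list(nodes = nodes, skipped = skipped)
}

#' Level-1 scan over framework marker pairs
#'
#' Fits the two-locus NOIA model for every combination of trait (usually a
#' meta-trait) and pair of framework markers, recording the epistasis
#' p-value. Aliased or otherwise unfittable pairs are skipped and logged.
#'
#' @param traits a [trait_matrix] (meta-traits or single traits).
#' @param geno genotype matrix (lines x markers, `"P1"`/`"P2"`/`NA`).
#' @param plan a `framework_plan`.
#' @param min_n minimum usable samples per fit.
#' @param alias_cor aliasing guard on between-locus correlation.
#' @return A list with `nodes` (data.frame: trait, markerA, markerB, p, iAB,
#'   h2_AB, h2_total) and `skipped`.
#' @export
level1_scan <- function(traits, geno, plan, min_n = 5L, alias_cor = 0.99) {
  stopifnot(inherits(traits, "trait_matrix"), inherits(plan, "framework_plan"))
  gobs <- expand_genotypes(geno, traits$samples)
  fw <- plan$framework
  if (length(fw) < 2L) stop("need at least two framework markers")
  pairs <- t(utils::combn(fw, 2L))
  scan_pairs(traits$values, gobs, pairs, min_n = min_n, alias_cor = alias_cor)
}

#' Level-2 families under rejected level-1 nodes
#'
#' For each rejected level-1 node (trait, framework pair `(f1, f2)`), the
#' family is all pairs `(u, v)` with `u` in region(f1) and `v` in region(f2),
#' excluding the parent pair itself.
#'
#' @param rejected data.frame of rejected level-1 nodes (columns `trait`,
#'   `markerA`, `markerB`).
#' @param plan a `framework_plan`.
#' @return A list of families; each a list with `trait`, `parentA`,
#'   `parentB`, and `pairs` (2-column matrix of marker ids, possibly empty).
#' @export
level2_families <- function(rejected, plan) {
  if (is.null(rejected) || nrow(rejected) == 0L) return(list())
  out <- vector("list", nrow(rejected))
  for (i in seq_len(nrow(rejected))) {
    f1 <- rejected$markerA[i]; f2 <- rejected$markerB[i]
    r1 <- plan$regions[[f1]]; r2 <- plan$regions[[f2]]
    pairs <- as.matrix(expand.grid(r1, r2, KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE))
    drop <- (pairs[, 1L] == f1 & pairs[, 2L] == f2) |
            (pairs[, 1L] == f2 & pairs[, 2L] == f1)
    pairs <- pairs[!drop, , drop = FALSE]
    out[[i]] <- list(trait = rejected$trait[i], parentA = f1, parentB = f2,
                     pairs = pairs)
  }
  out
}

#' Run the two-step hierarchical epistasis scan
#'
#' Framework selection, level-1 scan of all (trait, framework-pair)
#' combinations tested as one BH family at `q* = q / (2 delta)`, then for
#' each rejection a level-2 family of dense secondary-marker pairs within the
#' two regions, each family again tested by BH at `q*`. The report carries
#' all nodes, the rejections at both levels, and the full-tree FDR bound.
#'
#' @param traits a [trait_matrix] (meta-traits or single traits).
#' @param geno genotype matrix (lines x markers).
#' @param map a [genetic_map].
#' @param q target full-tree FDR level.
#' @param spacing_cM framework marker spacing.
#' @param delta_mode `"fixed"` uses the universal bound 1.44; `"supplied"`
#'   uses `delta`; `"estimated"` calls [estimate_delta()] with `n_perm`
#'   permutations.
#' @param delta multiplicative factor when `delta_mode = "supplied"`.
#' @param pi_hat proportion of true nulls used in the reported bound
#'   (1 = conservative).
#' @param q_star optional explicit within-family BH level; overrides the
#'   full-tree calibration `q / (2 delta)` (used e.g. when the testing level
#'   itself, rather than a full-tree target, is the study condition). The
#'   reported bound is always `2 * delta * pi_hat * q_star`.
#' @param n_perm,seed controls for `delta_mode = "estimated"`.
#' @param min_n,alias_cor fit guards, see [level1_scan()].
#' @return An object of class `scan_report`; see [write_scan_report()].
#' @export
run_hierarchical <- function(traits, geno, map, q = 0.1, spacing_cM = 10,
                             delta_mode = c("fixed", "supplied", "estimated"),
                             delta = 1.44, pi_hat = 1, n_perm = 200L,
                             seed = NULL, min_n = 5L, alias_cor = 0.99,
                             q_star = NULL) {
  delta_mode <- match.arg(delta_mode)
  plan <- select_framework_markers(map, spacing_cM)
  delta_used <- switch(delta_mode,
    fixed = 1.44,
    supplied = delta,
    estimated = estimate_delta(traits, geno, map, q = q,
                               spacing_cM = spacing_cM, reps = n_perm,
                               seed = seed)$delta)
  if (is.null(q_star)) {
    q_star <- full_tree_level(q, delta_used)
  } else {
    stopifnot(q_star > 0, q_star < 1)
  }

  l1 <- level1_scan(traits, geno, plan, min_n = min_n, alias_cor = alias_cor)
  nodes1 <- l1$nodes
  nodes1$rejected <- FALSE
  if (nrow(nodes1)) {
    rej <- bh_select(nodes1$p, q_star)
    nodes1$rejected[rej] <- TRUE
  }
  rejected1 <- nodes1[nodes1$rejected, , drop = FALSE]

  gobs <- expand_genotypes(geno, traits$samples)
  fams <- level2_families(rejected1, plan)
  nodes2 <- NULL
  skipped2 <- NULL
  for (j in seq_along(fams)) {
    fam <- fams[[j]]
    if (nrow(fam$pairs) == 0L) next
    sc <- scan_pairs(traits$values, gobs, fam$pairs, min_n = min_n,
                     alias_cor = alias_cor, traits = fam$trait)
    if (!is.null(sc$skipped)) {
      sc$skipped$family <- j
      skipped2 <- rbind(skipped2, sc$skipped)
    }
    fn <- sc$nodes
    if (is.null(fn) || nrow(fn) == 0L) next
    fn$family <- j
    fn$parentA <- fam$parentA
    fn$parentB <- fam$parentB
    fn$rejected <- FALSE
    rej <- bh_select(fn$p, q_star)
    fn$rejected[rej] <- TRUE
    nodes2 <- rbind(nodes2, fn)
  }

  disc1 <- if (nrow(rejected1)) cbind(level = 1L, rejected1[, c("trait", "markerA",
              "markerB", "p", "iAB", "h2_AB", "h2_total")]) else NULL
  disc2 <- if (!is.null(nodes2) && any(nodes2$rejected)) {
    cbind(level = 2L, nodes2[nodes2$rejected, c("trait", "markerA", "markerB",
                                                "p", "iAB", "h2_AB", "h2_total")])
  } else NULL
  discoveries <- rbind(disc1, disc2)
  if (is.null(discoveries)) {
    discoveries <- data.frame(level = integer(0), trait = character(0),
                              markerA = character(0), markerB = character(0),
                              p = numeric(0), iAB = numeric(0),
                              h2_AB = numeric(0), h2_total = numeric(0))
  }
  rownames(discoveries) <- NULL
  n_l2 <- if (is.null(nodes2)) 0L else nrow(nodes2)
  counts <- list(n_level1 = nrow(nodes1),
                 n_level1_rejected = sum(nodes1$rejected),
                 n_level2 = n_l2,
                 n_level2_rejected = if (is.null(nodes2)) 0L else sum(nodes2$rejected),
                 n_families = 1L + length(fams),
                 n_tests = nrow(nodes1) + n_l2,
                 n_discoveries = nrow(discoveries))
  structure(list(q = q, q_star = q_star, delta = delta_used,
                 delta_mode = delta_mode, pi_hat = pi_hat,
                 bound = fdr_bound(q_star, delta_used, pi_hat),
                 plan = plan, level1 = nodes1, level2 = nodes2,
                 discoveries = discoveries, counts = counts,
                 skipped = list(level1 = l1$skipped, level2 = skipped2)),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf(paste0("scan_report: q = %.3g, q* = %.4g, delta = %.3f, ",
                     "FDR bound = %.3g\n"), x$q, x$q_star, x$delta, x$bound))
  cat(sprintf("  level 1: %d tests, %d rejected; level 2: %d tests in %d families, %d rejected\n",
              x$counts$n_level1, x$counts$n_level1_rejected, x$counts$n_level2,
              x$counts$n_families - 1L, x$counts$n_level2_rejected))
  cat(sprintf("  total discoveries: %d\n", x$counts$n_discoveries))
  invisible(x)
}

#' Estimate the hierarchical FDR factor by full-null permutation
#'
#' Repeatedly permutes the line labels of the genotypes relative to the
#' traits (a full-null resample preserving both marginal structures), runs
#' the two-level procedure, and records the realized family factor
#' `(R + M) / (R + 1)` per tree, where `R` is the total number of
#' discoveries and `M` the number of families tested. The estimate is the
#' mean over trees with at least one discovery, clamped into `[1, 1.44]`
#' (the universal bound).
#'
#' @param traits a [trait_matrix].
#' @param geno genotype matrix.
#' @param map a [genetic_map].
#' @param q full-tree FDR level used in the permuted runs.
#' @param spacing_cM framework spacing.
#' @param reps number of permutations (>= 100 recommended).
#' @param seed integer seed.
#' @return List with `delta`, `se`, `n_used` (trees with >= 1 discovery),
#'   `reps`.
#' @export
estimate_delta <- function(traits, geno, map, q = 0.1, spacing_cM = 10,
                           reps = 200L, seed = 1L) {
  if (reps < 10L) stop("reps too small for estimation")
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(0)
  n_lines <- nrow(geno)
  for (r in seq_len(reps)) {
    perm <- sample.int(n_lines)
    gperm <- geno[perm, , drop = FALSE]
    rownames(gperm) <- rownames(geno)
    rep_r <- run_hierarchical(traits, gperm, map, q = q,
                              spacing_cM = spacing_cM,
                              delta_mode = "fixed")
    R <- rep_r$counts$n_discoveries
    M <- rep_r$counts$n_families
    if (R >= 1L) vals <- c(vals, (R + M) / (R + 1))
  }
  if (!length(vals)) stop("all permutation runs were degenerate (no discoveries)")
  est <- min(max(mean(vals), 1), 1.44)
  list(delta = est, se = stats::sd(vals) / sqrt(length(vals)),
       n_used = length(vals), reps = reps)
}

#' Test-count accounting for the hierarchical search
#'
#' Book-keeping of how many epistasis tests the two-stage design performs
#' versus direct all-pairs testing of single traits: `choose(n_markers, 2) *
#' n_traits` direct tests, `choose(n_framework, 2) * n_meta` level-1 tests,
#' plus the realized level-2 tests, and the resulting fold reduction.
#'
#' @param n_markers number of dense markers.
#' @param n_traits number of single traits.
#' @param n_framework number of framework markers.
#' @param n_meta number of meta-traits.
#' @param n_level2_tests realized number of level-2 tests.
#' @return List with `marker_pairs`, `direct_tests`, `framework_pairs`,
#'   `level1_tests`, `total_hierarchical`, `fold_reduction` (floored).
#' @export
hierarchical_test_counts <- function(n_markers, n_traits, n_framework,
                                     n_meta, n_level2_tests = 0) {
  marker_pairs <- choose(n_markers, 2)
  framework_pairs <- choose(n_framework, 2)
  level1 <- framework_pairs * n_meta
  total <- level1 + n_level2_tests
  list(marker_pairs = marker_pairs,
       direct_tests = marker_pairs * n_traits,
       framework_pairs = framework_pairs,
       level1_tests = level1,
       total_hierarchical = total,
       fold_reduction = floor(marker_pairs * n_traits / total))
}
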