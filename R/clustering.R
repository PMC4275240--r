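#' Trait-trait Pearson correlation matrix
#'
#' @param expr a [trait_matrix] with at least 3 samples.
#' @return Symmetric correlation matrix (traits x traits) with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  stopifnot(inherits(expr, "trait_matrix"))
  if (ncol(expr$values) < 3L) stop("need at least 3 samples for correlations")
  sds <- apply(expr$values, 1L, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    bad <- rownames(expr$values)[sds < .Machine$double.eps^0.5]
    stop("zero-variance trait(s): ", paste(bad, collapse = ", "))
  }
  cc <- stats::cor(t(expr$values))
  diag(cc) <- 1
  cc
}

#' Soft-thresholded (unsigned) network adjacency
#'
#' `a_ij = |cor_ij|^beta`. The unsigned network with the canonical default
#' `beta = 6` is used; `beta` must be >= 1.
#'
#' @param cor correlation matrix.
#' @param beta soft-thresholding power.
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
adjacency <- function(cor, beta = 6) {
  if (beta < 1) stop("beta must be >= 1")
  a <- abs(cor)^beta
  diag(a) <- 1
  a
}

#' Topological overlap dissimilarity
#'
#' Computes the topological overlap matrix
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity `k_i = sum_{u != i} a_iu`,
#' and returns the dissimilarity `1 - TOM` with zero diagonal.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return Dissimilarity matrix in `[0, 1]`, symmetric, zero diagonal.
#' @export
tom_dissimilarity <- function(adj) {
  a <- as.matrix(adj)
  n <- nrow(a)
  # with unit diagonal, (A %*% A)_ij = l_ij + a_ii a_ij + a_ij a_jj = l_ij + 2 a_ij
  l <- a %*% a - 2 * a
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  d <- 1 - tom
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Detect co-expression modules by top-down branch cutting
#'
#' Average-linkage hierarchical clustering of a dissimilarity matrix followed
#' by a top-down cut: a static cut at a height quantile gives the initial
#' coarse clusters; each cluster whose dendrogram root shows a clear,
#' well-separated two-way split (see `split_z`) is split recursively;
#' clusters smaller than
#' `min_module_size` are merged into the module with the nearest average
#' dissimilarity, or left unassigned (label 0) when no sufficiently large
#' module exists.
#'
#' @param dissim square dissimilarity matrix (e.g. from
#'   [tom_dissimilarity()]).
#' @param min_module_size minimum module size.
#' @param cut_height_quantile quantile of merge heights for the static cut.
#' @param split_z minimum separation, in standard-error units, between the
#'   mean between-branch and mean within-branch dissimilarity for a two-way
#'   split of a cluster to be accepted.
#' @return An object of class `cluster_set`: list with `labels` (named
#'   integer vector, 0 = unassigned, module labels contiguous and ordered by
#'   decreasing size), `sizes`, and `members`.
#' @export
detect_modules <- function(dissim, min_module_size = 5,
                           cut_height_quantile = 0.99, split_z = 3) {
  d <- as.matrix(dissim)
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n <= min_module_size) {
    labels <- stats::setNames(rep(1L, n), ids)
    return(new_cluster_set(labels))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cut_h <- stats::quantile(hc$height, cut_height_quantile, names = FALSE)
  labs0 <- stats::cutree(hc, h = cut_h)

  # split a cluster when its dendrogram root separates two sub-branches of
  # substantial size whose between-branch dissimilarity stands clear of the
  # within-branch dissimilarity (a sub-cluster structure); recurse into the
  # accepted branches. Homogeneous clusters show unbalanced root splits and
  # no separation, and are left intact.
  split_recursive <- function(members) {
    n_m <- length(members)
    floor_size <- min(min_module_size, max(3L, n_m %/% 3L))
    if (n_m < 2L * floor_size) return(list(members))
    sub <- d[members, members, drop = FALSE]
    shc <- stats::hclust(stats::as.dist(sub), method = "average")
    ct <- stats::cutree(shc, k = 2L)
    b1 <- members[ct == 1L]; b2 <- members[ct == 2L]
    if (length(b1) < floor_size || length(b2) < floor_size) {
      return(list(members))
    }
    m1 <- sub[ct == 1L, ct == 1L]; m2 <- sub[ct == 2L, ct == 2L]
    w <- c(m1[upper.tri(m1)], m2[upper.tri(m2)])
    spread <- stats::sd(w)
    if (!is.finite(spread) || spread <= .Machine$double.eps^0.5) {
      return(list(members))
    }
    between <- mean(d[b1, b2, drop = FALSE])
    within <- max(mean(m1[upper.tri(m1)]), mean(m2[upper.tri(m2)]))
    n_b <- length(b1) * length(b2)
    n_w <- max(1L, min(choose(length(b1), 2L), choose(length(b2), 2L)))
    se <- spread * sqrt(1 / n_b + 1 / n_w)
    if ((between - within) / se < split_z) return(list(members))
    c(split_recursive(b1), split_recursive(b2))
  }

  clusters <- list()
  for (lab in unique(labs0)) {
    clusters <- c(clusters, split_recursive(ids[labs0 == lab]))
  }

  big <- clusters[vapply(clusters, length, 1L) >= min_module_size]
  small <- clusters[vapply(clusters, length, 1L) < min_module_size]
  labels <- stats::setNames(rep(0L, n), ids)
  if (length(big) == 0L) {
    return(new_cluster_set(labels))
  }
  for (j in seq_along(big)) labels[big[[j]]] <- j
  # merge undersized clusters into the nearest large module (average dissim)
  for (cl in small) {
    avg <- vapply(big, function(m) mean(d[cl, m, drop = FALSE]), numeric(1))
    labels[cl] <- which.min(avg)
  }
  new_cluster_set(labels)
}

new_cluster_set <- function(labels) {
  # relabel contiguously, ordered by decreasing size (0 stays 0)
  tab <- table(labels[labels > 0L])
  ord <- names(sort(tab, decreasing = TRUE))
  relab <- stats::setNames(seq_along(ord), ord)
  out <- labels
  out[labels > 0L] <- relab[as.character(labels[labels > 0L])]
  out <- stats::setNames(as.integer(out), names(labels))
  members <- split(names(out)[out > 0L], out[out > 0L])
  structure(list(labels = out,
                 sizes = vapply(members, length, 1L),
                 members = members),
            class = "cluster_set")
}

#' Build a cluster_set from known labels
#'
#' Convenience constructor when module membership is known (e.g. simulated
#' ground truth): labels are made contiguous and sizes computed.
#'
#' @param labels integer vector of module labels (0 = unassigned), named by
#'   trait id.
#' @return A `cluster_set`.
#' @export
cluster_set <- function(labels) {
  if (is.null(names(labels))) stop("labels must be named by trait id")
  new_cluster_set(labels)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d modules, %d traits assigned, %d unassigned\n",
              length(x$sizes), sum(x$sizes), sum(x$labels == 0L)))
  invisible(x)
}

#' Write module assignments as two-column TSV
#' @param clusters a `cluster_set`.
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cluster_set <- function(clusters, path, sep = "\t") {
  df <- data.frame(trait = names(clusters$labels),
                   module = as.integer(clusters$labels))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Meta-traits: first principal component per module
#'
#' Traits in each module are standardized (zero mean, unit sd over samples)
#' and the module's meta-trait is the first principal component score vector
#' over samples. The sign is fixed so the meta-trait correlates positively
#' with the module's mean standardized expression. Variance explained is the
#' leading eigenvalue over the trace of the module correlation matrix.
#'
#' @param expr a [trait_matrix].
#' @param clusters a `cluster_set` over the traits of `expr`; every module
#'   must have at least 2 member traits.
#' @return A [trait_matrix] of class `c("meta_traits", "trait_matrix")`:
#'   `values` holds one row per module (`M1`, `M2`, ...), with an extra
#'   element `var_explained`.
#' @export
compute_meta_traits <- function(expr, clusters) {
  stopifnot(inherits(expr, "trait_matrix"), inherits(clusters, "cluster_set"))
  mods <- clusters$members
  if (length(mods) == 0L) stop("no modules to summarise")
  bad <- names(mods)[vapply(mods, length, 1L) < 2L]
  if (length(bad)) stop("modules with fewer than 2 traits: ",
                        paste(bad, collapse = ", "))
  n_samp <- ncol(expr$values)
  scores <- matrix(0, length(mods), n_samp,
                   dimnames = list(paste0("M", names(mods)), NULL))
  ve <- numeric(length(mods))
  for (j in seq_along(mods)) {
    members <- mods[[j]]
    sub <- expr$values[members, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds < .Machine$double.eps^0.5)) {
      stop("zero-variance trait in module ", names(mods)[j])
    }
    z <- scale(t(sub))                       # samples x traits, standardized
    sv <- svd(z, nu = 1L, nv = 0L)
    s <- sv$u[, 1L] * sv$d[1L]
    m <- rowMeans(z)
    if (stats::sd(m) > 0 && stats::cor(s, m) < 0) s <- -s
    scores[j, ] <- s
    ve[j] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  out <- trait_matrix(scores, expr$samples$line, expr$samples$replicate)
  out$var_explained <- stats::setNames(ve, rownames(scores))
  class(out) <- c("meta_traits", "trait_matrix")
  out
}
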