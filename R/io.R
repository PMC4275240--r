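#' Construct and validate a genetic map
#'
#' A genetic map is a table of markers with their chromosome and position in
#' centiMorgans. Markers are sorted by (chromosome, position); positions must
#' be strictly increasing within a chromosome and marker ids unique.
#'
#' @param marker character vector of marker ids.
#' @param chromosome character (or coercible) vector of chromosome labels.
#' @param position_cM numeric vector of non-negative map positions (cM).
#' @return A `data.frame` of class `genetic_map` with columns `marker`,
#'   `chromosome`, `position_cM`, sorted by chromosome then position.
#' @export
genetic_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  if (length(marker) == 0L) stop("genetic map is empty")
  if (anyDuplicated(marker)) {
    dup <- unique(marker[duplicated(marker)])
    stop("duplicate marker ids in map: ", paste(dup, collapse = ", "))
  }
  if (anyNA(position_cM) || any(position_cM < 0)) {
    stop("marker positions must be non-negative cM values")
  }
  map <- data.frame(marker = marker, chromosome = chromosome,
                    position_cM = position_cM, stringsAsFactors = FALSE)
  map <- map[order(map$chromosome, map$position_cM), , drop = FALSE]
  rownames(map) <- NULL
  for (chr in unique(map$chromosome)) {
    pos <- map$position_cM[map$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("marker positions not strictly increasing on chromosome ", chr)
    }
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Read a genetic map from delimited text
#'
#' Expects a header row with columns `marker`, `chromosome`, `position_cM`
#' (in that order; names are not required to match).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return A validated [genetic_map].
#' @export
read_genetic_map <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3L) stop("genetic map file needs 3 columns (marker, chromosome, cM)")
  genetic_map(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Write a genetic map to delimited text
#' @param map a [genetic_map].
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path, sep = "\t") {
  utils::write.table(as.data.frame(map), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read RIL genotypes from delimited text
#'
#' The file is a lines-by-markers table: first column line id, remaining
#' columns one per marker with the two parental allele codes. RIL populations
#' are homozygous, so only two allele states (plus missing) are permitted;
#' any other code is an error. Alleles are stored canonically as
#' `"P1"`/`"P2"` and columns are aligned to the map's marker order.
#'
#' @param path file path.
#' @param map a [genetic_map]; every genotype column must be a mapped marker.
#' @param allele_codes length-2 character vector `c(P1 = ..., P2 = ...)`
#'   giving the file's codes for the two parental alleles.
#' @param missing_codes codes treated as missing genotypes.
#' @param sep field separator.
#' @return Character matrix (lines x markers) with entries `"P1"`, `"P2"` or
#'   `NA`, rownames = line ids, columns in map order.
#' @export
read_genotypes <- function(path, map, allele_codes = c(P1 = "A", P2 = "B"),
                           missing_codes = c("NA", "-", ""), sep = "\t") {
  stopifnot(inherits(map, "genetic_map"))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  lines <- tab[[1L]]
  if (anyDuplicated(lines)) stop("duplicate line ids in genotype file")
  g <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(g) <- lines
  unknown <- setdiff(colnames(g), map$marker)
  if (length(unknown)) {
    stop("genotype markers absent from map: ", paste(unknown, collapse = ", "))
  }
  g[g %in% missing_codes] <- NA_character_
  bad <- !(g %in% c(allele_codes, NA))
  if (any(bad)) {
    stop("allele codes outside the two-parent RIL alphabet: ",
         paste(unique(g[bad]), collapse = ", "),
         " (heterozygote or unknown codes are not allowed)")
  }
  out <- matrix(NA_character_, nrow(g), ncol(g),
                dimnames = list(rownames(g), colnames(g)))
  out[g == allele_codes[["P1"]]] <- "P1"
  out[g == allele_codes[["P2"]]] <- "P2"
  # align to map order (markers present in the file)
  keep <- map$marker[map$marker %in% colnames(out)]
  out[, keep, drop = FALSE]
}

#' Write RIL genotypes to delimited text
#'
#' Inverse of [read_genotypes()]: canonical `"P1"`/`"P2"` entries are written
#' with the supplied allele codes.
#'
#' @inheritParams read_genotypes
#' @param geno character matrix as returned by [read_genotypes()].
#' @param path file path.
#' @param missing_code code written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, allele_codes = c(P1 = "A", P2 = "B"),
                            missing_code = "NA", sep = "\t") {
  out <- geno
  out[geno == "P1"] <- allele_codes[["P1"]]
  out[geno == "P2"] <- allele_codes[["P2"]]
  out[is.na(geno)] <- missing_code
  df <- data.frame(line = rownames(geno), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a trait matrix over (line, replicate) samples
#'
#' Container shared by raw expression data and meta-traits: a numeric
#' traits-by-samples matrix plus the sample annotation (line id and replicate
#' index).
#'
#' @param values numeric matrix, traits in rows, samples in columns.
#' @param line character vector of line ids, one per sample column.
#' @param replicate integer vector of replicate indices (>= 1), one per column.
#' @return An object of class `trait_matrix`: a list with elements `values`
#'   and `samples` (a data.frame with columns `line`, `replicate`).
#' @export
trait_matrix <- function(values, line, replicate = rep(1L, length(line))) {
  values <- as.matrix(values)
  line <- as.character(line)
  replicate <- as.integer(replicate)
  if (ncol(values) != length(line) || length(line) != length(replicate)) {
    stop("sample annotation length does not match the number of columns")
  }
  if (any(replicate < 1L)) stop("replicate indices must be >= 1")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("T%03d", seq_len(nrow(values)))
  }
  colnames(values) <- paste(line, replicate, sep = "_")
  structure(list(values = values,
                 samples = data.frame(line = line, replicate = replicate,
                                      stringsAsFactors = FALSE)),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d traits x %d samples (%d lines, up to %d replicates)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$line)),
              max(x$samples$replicate)))
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Traits in rows, samples in columns. The sample header encodes line and
#' replicate as `<line><sep><k>` (e.g. `L001_2`); a header without a trailing
#' integer field is taken as replicate 1.
#'
#' @param path file path.
#' @param sep field separator.
#' @param sample_sep separator between line id and replicate index in the
#'   sample headers.
#' @param lines optional character vector of known line ids; sample headers
#'   referencing other lines raise an error.
#' @return A [trait_matrix].
#' @export
read_expression <- function(path, sep = "\t", sample_sep = "_", lines = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(tab)
  storage.mode(values) <- "double"
  parsed <- parse_sample_names(colnames(values), sample_sep)
  if (!is.null(lines)) {
    unknown <- setdiff(parsed$line, lines)
    if (length(unknown)) {
      stop("expression samples reference unknown lines: ",
           paste(unknown, collapse = ", "))
    }
  }
  trait_matrix(values, parsed$line, parsed$replicate)
}

parse_sample_names <- function(nms, sample_sep = "_") {
  parts <- strsplit(nms, sample_sep, fixed = TRUE)
  line <- character(length(nms))
  repl <- integer(length(nms))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    last <- p[length(p)]
    if (length(p) > 1L && grepl("^[0-9]+$", last)) {
      line[i] <- paste(p[-length(p)], collapse = sample_sep)
      repl[i] <- as.integer(last)
    } else {
      line[i] <- nms[i]
      repl[i] <- 1L
    }
  }
  list(line = line, replicate = repl)
}

#' Write an expression (or meta-trait) matrix to delimited text
#' @param expr a [trait_matrix].
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  df <- data.frame(trait = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-component univariate normal mixture by EM
#'
#' Plain EM for a two-component Gaussian mixture, used to separate expressed
#' from unexpressed traits by their mean intensity. Initialised by k-means
#' (reproducible under `set.seed()` by the caller); the log-likelihood trace
#' is recorded and is non-decreasing.
#'
#' @param x numeric vector.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param max_iter maximum number of EM iterations; non-convergence is an
#'   error carrying the last iterate in the condition's `fit` field.
#' @return A list of class `mixture_fit`: component means `mu` (ascending),
#'   sds `sigma`, mixing proportions `lambda`, per-point `posterior` matrix
#'   (each row sums to 1), `loglik` trace, `degenerate`
#'   flag (set when the data cannot support two components).
#' @export
normal_mixture_em <- function(x, tol = 1e-8, max_iter = 2000L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("too few observations for a two-component mixture")
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    # all values (essentially) identical: no second component supported
    post <- cbind(rep(0, n), rep(1, n))
    return(structure(list(mu = c(x[1], x[1]), sigma = c(0, 0),
                          lambda = c(0, 1), posterior = post,
                          loglik = numeric(0), degenerate = TRUE,
                          iterations = 0L),
                     class = "mixture_fit"))
  }
  km <- stats::kmeans(x, centers = 2L, nstart = 5L)
  ord <- order(km$centers)
  z <- match(km$cluster, ord)            # 1 = lower-mean component
  mu <- as.numeric(km$centers[ord])
  sigma <- vapply(1:2, function(k) {
    s <- stats::sd(x[z == k])
    if (!is.finite(s) || s < 1e-6 * stats::sd(x)) 1e-6 * stats::sd(x) else s
  }, numeric(1))
  lambda <- as.numeric(table(factor(z, levels = 1:2))) / n
  lambda <- pmax(lambda, 1e-6); lambda <- lambda / sum(lambda)
  sigma_floor <- 1e-8 * stats::sd(x)
  loglik <- numeric(0)
  post <- NULL
  for (it in seq_len(max_iter)) {
    d1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    post <- cbind(d1 / tot, d2 / tot)
    converged <- length(loglik) > 0 && (ll - loglik[length(loglik)]) < tol
    loglik <- c(loglik, ll)
    if (converged) {
      fit <- structure(list(mu = mu, sigma = sigma, lambda = lambda,
                            posterior = post, loglik = loglik,
                            degenerate = FALSE, iterations = it),
                       class = "mixture_fit")
      return(fit)
    }
    # M-step
    w <- colSums(post)
    lambda <- w / n
    mu <- c(sum(post[, 1] * x) / w[1], sum(post[, 2] * x) / w[2])
    sigma <- c(sqrt(sum(post[, 1] * (x - mu[1])^2) / w[1]),
               sqrt(sum(post[, 2] * (x - mu[2])^2) / w[2]))
    sigma <- pmax(sigma, sigma_floor)
    if (mu[1] > mu[2]) {   # keep component 1 the low-mean one
      mu <- rev(mu); sigma <- rev(sigma); lambda <- rev(lambda)
    }
  }
  last <- structure(list(mu = mu, sigma = sigma, lambda = lambda,
                         posterior = post, loglik = loglik,
                         degenerate = FALSE, iterations = max_iter),
                    class = "mixture_fit")
  cond <- simpleError(sprintf("EM did not converge within %d iterations", max_iter))
  cond$fit <- last
  stop(cond)
}

#' Filter unexpressed traits with a two-component mixture model
#'
#' Fits a two-component univariate normal mixture to the per-trait mean
#' intensity and removes traits assigned to the lower ("unexpressed")
#' component with posterior probability > 0.5. With a degenerate fit (all
#' trait means essentially identical) nothing is removed.
#'
#' @param expr a [trait_matrix] of normalized expression values.
#' @param fit optional existing `mixture_fit` (from a previous call) used to
#'   classify traits instead of refitting; filtering an already-filtered
#'   matrix with its own fit removes nothing.
#' @param tol,max_iter EM controls, see [normal_mixture_em()].
#' @param seed optional integer seed for the k-means initialisation.
#' @return A list with elements `expression` (the retained [trait_matrix]),
#'   `fit` (the `mixture_fit`), and `removed` (ids of filtered traits).
#' @export
filter_expressed_traits <- function(expr, fit = NULL, tol = 1e-8,
                                    max_iter = 2000L, seed = NULL) {
  stopifnot(inherits(expr, "trait_matrix"))
  means <- rowMeans(expr$values)
  if (is.null(fit)) {
    if (!is.null(seed)) set.seed(seed)
    fit <- normal_mixture_em(means, tol = tol, max_iter = max_iter)
  }
  if (isTRUE(fit$degenerate)) {
    removed <- character(0)
  } else {
    # posterior of the lower-mean component for each trait mean, under `fit`
    d1 <- fit$lambda[1] * stats::dnorm(means, fit$mu[1], max(fit$sigma[1], 1e-12))
    d2 <- fit$lambda[2] * stats::dnorm(means, fit$mu[2], max(fit$sigma[2], 1e-12))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    removed <- rownames(expr$values)[d1 / tot > 0.5]
  }
  keep <- setdiff(rownames(expr$values), removed)
  out <- trait_matrix(expr$values[keep, , drop = FALSE],
                      expr$samples$line, expr$samples$replicate)
  list(expression = out, fit = fit, removed = removed)
}
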