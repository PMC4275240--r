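#' Orthogonal single-locus coding for RIL genotypes
#'
#' With only two homozygous genotype classes, the statistical (frequency
#' centered) coding assigns `code(P1) = -2 p2` and `code(P2) = 2 p1`, where
#' `p1`, `p2` are the allele frequencies observed in the fitted sample. The
#' codes have zero mean over the sample and span `code(P2) - code(P1) = 2`,
#' so with balanced frequencies they reduce to the familiar -1/+1 contrast.
#'
#' @param g character vector of genotypes (`"P1"`/`"P2"`, `NA` allowed;
#'   missing values are ignored for the frequencies).
#' @return A list of class `locus_coding`: `p1`, `p2`, `code_P1`, `code_P2`.
#' @export
locus_coding <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop("no observed genotypes")
  if (!all(g %in% c("P1", "P2"))) stop("genotypes must be 'P1' or 'P2'")
  p2 <- mean(g == "P2")
  p1 <- 1 - p2
  if (p1 == 0 || p2 == 0) {
    stop("monomorphic marker: no additive contrast can be estimated")
  }
  structure(list(p1 = p1, p2 = p2, code_P1 = -2 * p2, code_P2 = 2 * p1),
            class = "locus_coding")
}

#' Numeric genotype codes for one locus
#'
#' @param g character genotype vector (`"P1"`/`"P2"`/`NA`).
#' @param coding optional [locus_coding()]; computed from `g` if missing.
#' @return Numeric vector of codes (NA preserved).
#' @export
encode_locus <- function(g, coding = NULL) {
  if (is.null(coding)) coding <- locus_coding(g)
  out <- rep(NA_real_, length(g))
  out[g == "P1"] <- coding$code_P1
  out[g == "P2"] <- coding$code_P2
  out
}

# frequency-centered codes from a +/-1 functional coding, computed within the
# supplied (complete-case) sample; x in {-1, +1}
recode_statistical <- function(x) {
  p2 <- mean(x > 0)
  ifelse(x > 0, 2 * (1 - p2), -2 * p2)
}

#' Two-locus NOIA design matrix
#'
#' Columns `(1, x_A, x_B, x_A x_B)`: intercept (reference point), the two
#' additive contrasts and their product, the epistasis regressor. This is the
#' row-wise evaluation of the Kronecker-product construction of the two
#' single-locus design matrices. Samples with a missing genotype at either
#' locus are dropped.
#'
#' @param codes_A,codes_B numeric code vectors for the two loci (same sample
#'   order; `NA` for missing genotypes).
#' @param min_n minimum number of usable samples.
#' @return Numeric matrix `n x 4` with columns `R`, `aA`, `aB`, `iAB` and an
#'   attribute `kept` (logical vector of retained samples).
#' @export
build_design <- function(codes_A, codes_B, min_n = 5L) {
  stopifnot(length(codes_A) == length(codes_B))
  kept <- !(is.na(codes_A) | is.na(codes_B))
  if (sum(kept) < min_n) {
    stop("fewer than ", min_n, " samples with genotypes at both loci")
  }
  xa <- codes_A[kept]; xb <- codes_B[kept]
  X <- cbind(R = 1, aA = xa, aB = xb, iAB = xa * xb)
  attr(X, "kept") <- kept
  X
}

#' Fit the two-locus NOIA model by least squares
#'
#' Ordinary least squares fit of
#' `y = R + a_A x_A + a_B x_B + i_AB x_A x_B + e`, with replicates entering
#' as independent observations sharing a design row. The epistasis test is
#' the two-sided t-test on `i_AB`. Per-effect heritability is the sequential
#' model sum of squares of the effect's column over the total sum of squares;
#' with frequency-centered codes and independent loci the columns are
#' orthogonal, the decomposition is exact and sums to the model R-squared.
#' Under linkage disequilibrium between the loci the sequential decomposition
#' is reported with a warning.
#'
#' @param y numeric response (expression) vector, one value per design row.
#' @param design matrix from [build_design()].
#' @param alias_cor absolute correlation between the two additive columns
#'   above which the pair is declared aliased (inestimable epistasis).
#' @param ld_warn absolute between-locus correlation above which the LD
#'   warning is raised.
#' @return A list of class `noia_fit`: `coefficients` (R, aA, aB, iAB), `se`,
#'   `t`, `p` (per coefficient), `p_epistasis`, `h2` (per effect), `h2_total`,
#'   `r_squared`, `sigma2`, `df`, `n`.
#' @export
fit_noia <- function(y, design, alias_cor = 0.99, ld_warn = 0.1) {
  y <- as.numeric(y)
  if (nrow(design) != length(y)) stop("response length does not match design")
  if (stats::sd(y) < .Machine$double.eps^0.5) {
    stop("zero variance in the response")
  }
  r_ab <- stats::cor(design[, "aA"], design[, "aB"])
  if (!is.finite(r_ab) || abs(r_ab) > alias_cor) {
    stop("aliased pair: loci are (near-)perfectly linked, epistasis inestimable")
  }
  if (abs(r_ab) > ld_warn) {
    warning(sprintf(paste0("between-locus correlation %.2f: design columns are",
                           " not orthogonal; heritabilities are sequential",
                           " sums of squares"), r_ab))
  }
  fit <- noia_fit_batch(matrix(y, ncol = 1L), design[, "aA"], design[, "aB"],
                        alias_cor = alias_cor)
  if (!is.null(fit$error)) stop(fit$error)
  structure(list(coefficients = stats::setNames(fit$coef[, 1L],
                                                c("R", "aA", "aB", "iAB")),
                 se = stats::setNames(fit$se[, 1L], c("R", "aA", "aB", "iAB")),
                 t = stats::setNames(fit$t[, 1L], c("R", "aA", "aB", "iAB")),
                 p = stats::setNames(fit$p_all[, 1L], c("R", "aA", "aB", "iAB")),
                 p_epistasis = unname(fit$p[1L]),
                 h2 = stats::setNames(fit$h2[, 1L], c("A", "B", "AB")),
                 h2_total = fit$h2_total[1L],
                 r_squared = fit$h2_total[1L],
                 sigma2 = fit$sigma2[1L],
                 df = fit$df, n = fit$n),
            class = "noia_fit")
}

#' @export
print.noia_fit <- function(x, ...) {
  cat("two-locus NOIA fit (n =", x$n, ")\n")
  print(round(rbind(estimate = x$coefficients, se = x$se, p = x$p), 5))
  cat(sprintf("epistasis p = %.3g; h2: A %.3f, B %.3f, AB %.3f (total %.3f)\n",
              x$p_epistasis, x$h2["A"], x$h2["B"], x$h2["AB"], x$h2_total))
  invisible(x)
}

#' Epistasis p-value of a NOIA fit
#' @param fit a `noia_fit`.
#' @return The two-sided p-value for the interaction coefficient.
#' @export
epistasis_pvalue <- function(fit) {
  stopifnot(inherits(fit, "noia_fit"))
  fit$p_epistasis
}

# Batched NOIA fit: one marker pair, many traits.
#
# Y: n x T response matrix (complete rows only), xa/xb: +/-1 or statistical
# codes of length n. Codes are re-centered to the statistical coding within
# this sample when `recode = TRUE` (used when rows were dropped for
# missingness). Returns per-trait interaction p-values, coefficients,
# sequential-SS heritabilities, or an `error` string when the pair is
# monomorphic / aliased / rank deficient.
noia_fit_batch <- function(Y, xa, xb, alias_cor = 0.99, recode = FALSE) {
  n <- nrow(Y)
  if (recode) {
    if (length(unique(xa)) < 2L || length(unique(xb)) < 2L) {
      return(list(error = "monomorphic marker in fitted sample"))
    }
    xa <- recode_statistical(sign(xa))
    xb <- recode_statistical(sign(xb))
  }
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    return(list(error = "monomorphic marker in fitted sample"))
  }
  r_ab <- stats::cor(xa, xb)
  if (!is.finite(r_ab) || abs(r_ab) > alias_cor) {
    return(list(error = "aliased pair"))
  }
  X <- cbind(1, xa, xb, xa * xb)
  qx <- qr(X)
  if (qx$rank < 4L) return(list(error = "rank-deficient design"))
  eff <- qr.qty(qx, Y)                      # n x T; rows 1:4 = effects
  coef <- qr.coef(qx, Y)                    # 4 x T
  rss <- colSums(eff[-(1:4), , drop = FALSE]^2)
  df <- n - 4L
  sigma2 <- rss / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  if (!identical(qx$pivot, 1:4)) {
    ord <- order(qx$pivot)
    xtx_inv <- xtx_inv[ord, ord]
  }
  se <- sqrt(outer(diag(xtx_inv), sigma2))  # 4 x T
  tval <- coef / se
  p_all <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  # sequential sums of squares for columns 2..4; SS_total about the mean
  ss_seq <- eff[2:4, , drop = FALSE]^2
  ybar <- colMeans(Y)
  ss_tot <- colSums(Y^2) - n * ybar^2
  ss_tot[ss_tot <= 0] <- NA_real_
  h2 <- sweep(ss_seq, 2L, ss_tot, "/")
  list(coef = coef, se = se, t = tval, p = p_all[4L, ], p_all = p_all,
       h2 = h2, h2_total = colSums(ss_seq) / ss_tot,
       sigma2 = sigma2, df = df, n = n, cor_ab = r_ab, error = NULL)
}
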