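#' Single-variant genotypic association test
#'
#' Likelihood-ratio test of disease status on genotype class. The genotypic
#' logistic model with indicator coding of the observed genotype classes is
#' saturated, so its likelihood-ratio statistic against the intercept-only
#' model equals the G-statistic of the status x genotype-class contingency
#' table (with the `0 * log 0 = 0` convention); the test has 2 df when all
#' three genotype classes (aa, Aa, AA) are observed in the analyzed sample
#' and 1 df when minor-allele homozygotes are absent.
#'
#' @param genotype_column Integer vector of minor-allele counts (0/1/2).
#' @param status 0/1 disease status vector.
#' @return A list with `df`, `statistic` (LR chi-square) and `p_value`.
#' @export
genotypic_test <- function(genotype_column, status) {
  if (length(unique(genotype_column)) < 2L)
    stop("genotype column is monomorphic; test undefined", call. = FALSE)
  if (length(unique(status)) < 2L)
    stop("status has a single class; test undefined", call. = FALSE)
  res <- svt_pvalues(matrix(as.integer(genotype_column), ncol = 1),
                     as.integer(status))
  list(df = res$df[1], statistic = res$stat[1], p_value = res$p[1])
}

# Vectorized genotypic G-test for all columns of X against one or many
# status assignments. `case_mat` is an n x B 0/1 matrix whose columns are
# case indicators (the first column is typically the observed status).
# Returns per-variant df and, per column of case_mat, the statistic and
# p-value matrices (p x B). Untestable variants (one genotype class) get
# p = 1, stat = 0, df = 0.
svt_pvalues_multi <- function(X, case_mat) {
  n <- nrow(X)
  I1 <- (X == 1L) * 1
  I2 <- (X == 2L) * 1
  t1 <- colSums(I1)
  t2 <- colSums(I2)
  t0 <- n - t1 - t2
  ncase <- colSums(case_mat)
  a1 <- crossprod(I1, case_mat)
  a2 <- crossprod(I2, case_mat)
  a0 <- matrix(ncase, nrow = ncol(X), ncol = length(ncase), byrow = TRUE) -
    a1 - a2
  b0 <- t0 - a0
  b1 <- t1 - a1
  b2 <- t2 - a2
  fc <- matrix(ncase / n, nrow = ncol(X), ncol = length(ncase), byrow = TRUE)
  xlogx <- function(o, e) {
    out <- o * log(o / e)
    out[o == 0] <- 0
    out
  }
  G <- 2 * (xlogx(a0, t0 * fc) + xlogx(a1, t1 * fc) + xlogx(a2, t2 * fc) +
              xlogx(b0, t0 * (1 - fc)) + xlogx(b1, t1 * (1 - fc)) +
              xlogx(b2, t2 * (1 - fc)))
  df <- (t0 > 0) + (t1 > 0) + (t2 > 0) - 1L
  p <- matrix(stats::pchisq(G, df, lower.tail = FALSE), nrow(G), ncol(G))
  p[df == 0L, ] <- 1
  G[df == 0L, ] <- 0
  list(df = df, stat = G, p = p)
}

svt_pvalues <- function(X, status) {
  res <- svt_pvalues_multi(X, matrix(as.numeric(status), ncol = 1))
  list(df = res$df, stat = res$stat[, 1], p = res$p[, 1])
}

#' Per-variant p-values and the min-p family statistic
#'
#' Applies the genotypic test to every column of the genotype matrix;
#' untestable (single-genotype-class) columns are assigned p = 1.
#'
#' @param genotype_matrix n x p minor-allele-count matrix.
#' @param status 0/1 disease status vector.
#' @return List with `p_values` (length p) and `min_p`.
#' @export
min_p_statistic <- function(genotype_matrix, status) {
  if (length(unique(status)) < 2L)
    stop("status has a single class; tests undefined", call. = FALSE)
  p <- svt_pvalues(genotype_matrix, as.integer(status))$p
  list(p_values = as.numeric(p), min_p = min(p))
}
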