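#' Prefilter genes on a zero-floored working copy of the counts
#'
#' Counts below `min_per_sample` are floored to zero on a working copy; a
#' gene is retained when it has at least `min(group_sizes)` samples at or
#' above `min_per_sample` and a working total of at least `min_total`.
#' Downstream analysis then uses the ORIGINAL counts of the retained genes —
#' the flooring exists only to decide membership, so isolated shallow
#' counts cannot rescue a gene.
#'
#' @param counts A [count_matrix()] or plain matrix.
#' @param min_per_sample Per-sample floor and support threshold.
#' @param min_total Minimum working-copy total per gene.
#' @param group_sizes Integer vector of design cell sizes; the smallest is
#'   the required support.
#' @return Character vector of retained gene ids.
#' @export
prefilter_genes <- function(counts, min_per_sample = 10, min_total = 320,
                            group_sizes) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (nrow(y) == 0 || ncol(y) == 0) stop("empty count matrix")
  w <- y
  w[w < min_per_sample] <- 0
  support <- rowSums(w >= min_per_sample)
  keep <- support >= min(group_sizes) & rowSums(w) >= min_total
  rownames(y)[keep]
}

#' TMM normalization factors (trimmed mean of M-values)
#'
#' Computes composition-correction factors from pairwise log-ratios against
#' a reference sample. The reference is the sample whose upper-quartile /
#' library-size ratio is closest to the mean of that statistic. For each
#' sample, per-gene log-ratios M and average abundances A are formed against
#' the reference over genes expressed in both; the stated fractions of
#' extreme M and A values are trimmed; the factor is 2 to the
#' inverse-variance-weighted mean of the surviving M values. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts A [count_matrix()] or matrix (genes x samples).
#' @param trim_M Fraction of M values trimmed from each tail.
#' @param trim_A Fraction of A values trimmed from each tail.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(y) < 2) stop("TMM needs at least two samples")
  lib <- colSums(y)
  if (any(lib == 0)) stop("sample with zero library size")
  uq <- apply(y, 2, function(col) quantile(col, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  yr <- y[, ref]
  nr <- lib[ref]
  f <- vapply(seq_len(ncol(y)), function(i) {
    if (i == ref) return(1)
    yi <- y[, i]; ni <- lib[i]
    ok <- yi > 0 & yr > 0
    if (!any(ok)) return(1)
    m <- log2((yi[ok] / ni) / (yr[ok] / nr))
    a <- 0.5 * log2((yi[ok] / ni) * (yr[ok] / nr))
    v <- (ni - yi[ok]) / (ni * yi[ok]) + (nr - yr[ok]) / (nr * yr[ok])
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(m) >= loM & rank(m) <= hiM & rank(a) >= loA & rank(a) <= hiA
    if (!any(keep)) return(1)
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  f
}

#' Log counts per million on effective library sizes
#'
#' `logCPM = log2((y + prior) / (N_eff + 1) * 1e6)` where `N_eff` is the
#' TMM-scaled library size. The half-count prior keeps zeros finite.
#'
#' @param counts [count_matrix()] or matrix.
#' @param effective_sizes Positive effective library sizes per sample
#'   (defaults to raw library sizes).
#' @param prior Prior count added to each observation.
#' @return Matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, effective_sizes = NULL, prior = 0.5) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (is.null(effective_sizes)) effective_sizes <- colSums(y)
  if (any(effective_sizes <= 0)) stop("effective library sizes must be positive")
  t(log2(t(y + prior) / (effective_sizes + 1) * 1e6))
}

#' Per-observation precision weights from the mean-variance trend
#'
#' RNA-seq log-CPM values are heteroskedastic: low-abundance genes are
#' noisier. A per-gene linear fit on `design` yields residual standard
#' deviations; their square roots are smoothed against mean log-CPM with
#' lowess, and each observation's weight is the predicted trend value at
#' its fitted log-CPM, raised to the power -4 (so the weight approximates
#' the inverse of the trend variance).
#'
#' @param logcpm Matrix genes x samples.
#' @param design Full-rank design matrix, samples x coefficients.
#' @param span Lowess span.
#' @return Matrix of strictly positive weights, same shape as `logcpm`.
#' @export
mean_variance_weights <- function(logcpm, design, span = 0.5) {
  n <- ncol(logcpm); p <- qr(design)$rank
  if (p < ncol(design)) stop("design is not full rank")
  if (n - ncol(design) < 1) stop("fewer than 1 residual degree of freedom")
  qr_d <- qr(design)
  fit_coef <- t(qr.coef(qr_d, t(logcpm)))
  fitted <- fit_coef %*% t(design)
  res <- logcpm - fitted
  s <- sqrt(rowSums(res^2) / (n - ncol(design)))
  amean <- rowMeans(logcpm)
  lo <- lowess(amean, sqrt(s), f = span)
  pred <- if (length(unique(lo$x)) < 2) {
    rep(mean(lo$y), length(fitted))
  } else {
    approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2, ties = mean)$y
  }
  w <- matrix(pmax(pred, 1e-6)^(-4), nrow(logcpm), n,
              dimnames = dimnames(logcpm))
  w
}
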