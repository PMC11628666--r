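#' Cell-means design matrix for karyotype x stage-group
#'
#' One indicator column per (karyotype, stage group) cell, named e.g.
#' `AA.EARLY`. Both tissues use the same parameterisation; the liver
#' contrasts simply average the two development cells of each karyotype.
#'
#' @param meta Metadata data frame with `karyotype` and `stage_group`.
#' @return Indicator matrix, samples x cells.
#' @export
design_cell_means <- function(meta) {
  k <- check_karyotypes(meta$karyotype)
  cell <- factor(paste(k, meta$stage_group, sep = "."),
                 levels = as.vector(outer(KARYOTYPES, STAGE_GROUPS, paste, sep = ".")))
  x <- stats::model.matrix(~ 0 + cell)
  colnames(x) <- levels(cell)
  rownames(x) <- meta$sample_id
  x[, colSums(x) > 0, drop = FALSE]
}

#' Karyotype contrast matrix for a tissue
#'
#' Testis: the three pairwise karyotype comparisons within each development
#' group (EARLY, LATE), six contrasts. Liver: development has no effect, so
#' each karyotype's two cells are averaged (equal weights) and the three
#' pairwise comparisons are formed, three contrasts. Every contrast's
#' coefficients sum to zero.
#'
#' @param tissue `"testis"` or `"liver"`.
#' @param cells Cell names (defaults to all six karyotype x group cells).
#' @return Matrix cells x contrasts.
#' @export
build_contrasts <- function(tissue,
                            cells = as.vector(outer(KARYOTYPES, STAGE_GROUPS,
                                                    paste, sep = "."))) {
  if (!tissue %in% TISSUES) stop("unknown tissue: ", tissue)
  pairs <- list(c("AA", "AB"), c("AA", "BB"), c("AB", "BB"))
  cons <- list()
  if (tissue == "testis") {
    for (grp in STAGE_GROUPS) {
      for (p in pairs) {
        v <- setNames(numeric(length(cells)), cells)
        v[paste0(p[1], ".", grp)] <- 1
        v[paste0(p[2], ".", grp)] <- -1
        cons[[paste0(p[1], "-", p[2], ".", grp)]] <- v
      }
    }
  } else {
    for (p in pairs) {
      v <- setNames(numeric(length(cells)), cells)
      v[paste0(p[1], ".", STAGE_GROUPS)] <- 0.5
      v[paste0(p[2], ".", STAGE_GROUPS)] <- -0.5
      cons[[paste0(p[1], "-", p[2])]] <- v
    }
  }
  do.call(cbind, cons)
}

#' Invert the trigamma function (Newton iteration)
#' @noRd
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes squeezing of per-gene variances
#'
#' Method-of-moments fit of the scaled inverse chi-squared prior on the
#' log residual variances: with `e_g = log(s_g^2) - digamma(d_g/2) +
#' log(d_g/2)`, the prior df `d0` solves `trigamma(d0/2) = var(e) -
#' mean(trigamma(d_g/2))` and the prior variance is recovered from
#' `mean(e)`. Posterior variances are the df-weighted average of prior and
#' observed.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @param d0 Optional prior-df override: `0` disables moderation, `Inf`
#'   squeezes completely.
#' @return List `d0`, `s02`, `s2_post`.
#' @export
squeeze_var <- function(s2, df, d0 = NULL) {
  df <- rep_len(df, length(s2))
  ok <- s2 > 0 & df > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  if (is.null(d0)) {
    evar <- var(e) - mean(trigamma(df[ok] / 2))
    d0 <- if (is.na(evar) || evar <= 0) Inf else 2 * trigamma_inverse(evar)
  }
  s02 <- if (is.infinite(d0)) {
    exp(emean)
  } else if (d0 == 0) {
    exp(emean)  # reported but unused: posterior equals observed
  } else {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Moderated per-gene contrast tests (weighted least squares + eBayes)
#'
#' Fits each gene by weighted least squares on the cell-means design,
#' forms the requested contrasts of cell means, squeezes the residual
#' variances toward a common prior with [squeeze_var()], and returns
#' moderated t-statistics on `d0 + d_g` degrees of freedom with two-sided
#' p-values.
#'
#' @param logcpm Matrix genes x samples.
#' @param weights Positive per-observation weights, same shape.
#' @param design Full-rank design matrix, samples x cells.
#' @param contrasts Matrix cells x contrasts (see [build_contrasts()]).
#' @param d0 Optional prior-df override passed to [squeeze_var()].
#' @return Data frame of class `de_result`: `gene`, `contrast`, `logFC`,
#'   `t`, `df_total`, `p`; attributes `d0`, `s02`, `s2`, `df_residual`.
#' @export
fit_moderated <- function(logcpm, weights, design, contrasts, d0 = NULL) {
  if (any(weights <= 0)) stop("weights must be strictly positive")
  if (qr(design)$rank < ncol(design)) stop("design is not full rank")
  ng <- nrow(logcpm); n <- ncol(logcpm); p <- ncol(design)
  df_res <- n - p
  if (df_res < 1) stop("zero residual degrees of freedom")
  cn <- colnames(contrasts)
  beta <- matrix(NA_real_, ng, length(cn), dimnames = list(rownames(logcpm), cn))
  s2 <- numeric(ng)
  vc <- matrix(NA_real_, ng, length(cn))
  for (g in seq_len(ng)) {
    w <- weights[g, ]
    sw <- sqrt(w)
    xw <- design * sw
    yw <- logcpm[g, ] * sw
    fit <- .lm.fit(xw, yw)
    coefs <- fit$coefficients
    xtxinv <- chol2inv(chol(crossprod(xw)))
    s2[g] <- sum(fit$residuals^2) / df_res
    beta[g, ] <- drop(t(contrasts) %*% coefs)
    vc[g, ] <- diag(t(contrasts) %*% xtxinv %*% contrasts)
  }
  sq <- squeeze_var(s2, df_res, d0 = d0)
  s2_use <- if (sq$d0 == 0) s2 else sq$s2_post
  tstat <- beta / sqrt(s2_use * vc)
  df_total <- if (is.infinite(sq$d0)) Inf else sq$d0 + df_res
  pval <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(
    gene = rep(rownames(logcpm), times = length(cn)),
    contrast = rep(cn, each = ng),
    logFC = as.vector(beta),
    t = as.vector(tstat),
    df_total = df_total,
    p = as.vector(pval),
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- sq$d0
  attr(out, "s02") <- sq$s02
  attr(out, "s2") <- s2
  attr(out, "df_residual") <- df_res
  class(out) <- c("de_result", class(out))
  out
}

#' Global significance decisions across the whole gene x contrast matrix
#'
#' Benjamini-Hochberg adjustment applied to the pooled vector of all gene x
#' contrast p-values (one cutoff for the whole matrix, so contrasts with
#' many strong effects share their budget with weaker ones), then an
#' up/down/ns decision per cell by the sign of the fold change.
#'
#' @param de A `de_result` from [fit_moderated()].
#' @param alpha Significance cutoff on the adjusted p-value.
#' @return The input with columns `adj_p` and `decision` added; attribute
#'   `de_genes` lists genes significant in at least one contrast.
#' @export
global_decide <- function(de, alpha = 0.05) {
  if (anyNA(de$p)) stop("p-values present for all gene x contrast cells required")
  de$adj_p <- p.adjust(de$p, method = "BH")
  de$decision <- ifelse(de$adj_p < alpha, ifelse(de$logFC > 0, "up", "down"), "ns")
  attr(de, "alpha") <- alpha
  attr(de, "de_genes") <- sort(unique(de$gene[de$decision != "ns"]))
  de
}

#' Cluster differentially expressed genes by expression profile
#'
#' Rows are standardised to Z-scores across samples (each gene centred and
#' scaled on its own mean and SD), then hierarchically clustered with
#' Euclidean distance and Ward linkage, and the tree is cut at `k`
#' clusters. Deterministic for fixed input.
#'
#' @param logcpm Matrix restricted to the DE genes.
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cluster_de_genes <- function(logcpm, k = 10) {
  if (k > nrow(logcpm)) stop("k exceeds the number of genes")
  z <- t(scale(t(logcpm)))
  z[is.nan(z)] <- 0  # constant rows carry no profile
  hc <- hclust(dist(z), method = "ward.D2")
  cutree(hc, k = k)
}
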