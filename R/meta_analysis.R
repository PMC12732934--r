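#' Fisher's combined probability test
#'
#' `X = -2 * sum(log p_i)` referred to a chi-square with `2k` degrees of
#' freedom. Zero p-values are clipped to the smallest positive double.
#'
#' @param p_values Numeric vector of per-cohort p-values in (0, 1].
#' @return list(statistic, df, p).
#' @export
fisher_combine <- function(p_values) {
  stopifnot(length(p_values) >= 1, all(p_values > 0 | p_values == 0),
            all(p_values <= 1))
  p <- pmax(p_values, .Machine$double.xmin)
  x <- -2 * sum(log(p))
  k <- length(p)
  list(statistic = x, df = 2 * k,
       p = stats::pchisq(x, df = 2 * k, lower.tail = FALSE))
}

#' Signed sample-size-weighted Stouffer Z
#'
#' Converts each cohort's two-sided p to a signed normal quantile
#' `Z_i = sign_i * qnorm(1 - p_i / 2)` and combines with weights
#' `w_i = sqrt(n_i)`: `Z = sum(w_i Z_i) / sqrt(sum(w_i^2))`; two-sided p
#' from the standard normal. Invariant to rescaling all weights.
#'
#' @param p_values Two-sided p-values per cohort, in (0, 1].
#' @param signs Effect direction per cohort (-1 / +1).
#' @param n_sizes Cohort sample sizes (>= 2).
#' @return list(z, p).
#' @export
stouffer_signed <- function(p_values, signs, n_sizes) {
  k <- length(p_values)
  if (length(signs) != k || length(n_sizes) != k)
    stop("p_values, signs and n_sizes must have equal length")
  stopifnot(all(p_values > 0), all(p_values <= 1),
            all(signs %in% c(-1, 1)), all(n_sizes >= 2))
  zi <- signs * stats::qnorm(1 - p_values / 2)
  w <- sqrt(n_sizes)
  z <- sum(w * zi) / sqrt(sum(w^2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-cohort meta-analysis of per-gene onset evidence
#'
#' Combines two DGE tables by Fisher's method and the signed
#' sample-size-weighted Stouffer Z (direction = the onset slope sign in each
#' cohort), BH-adjusts each statistic across genes, and flags sign
#' concordance.
#'
#' @param tab1,tab2 DGE tables (columns `gene`, `slope`, `p`) on a shared
#'   gene universe; only shared genes are combined.
#' @param n1,n2 Cohort sample sizes.
#' @return data.frame (gene, slope1, slope2, fisher_stat, fisher_p,
#'   fisher_fdr, stouffer_z, stouffer_p, stouffer_fdr, concordant).
#' @export
meta_analyze <- function(tab1, tab2, n1, n2) {
  shared <- intersect(tab1$gene, tab2$gene)
  if (!length(shared)) stop("no shared genes between cohorts")
  i1 <- match(shared, tab1$gene)
  i2 <- match(shared, tab2$gene)
  p1 <- pmax(tab1$p[i1], .Machine$double.xmin)
  p2 <- pmax(tab2$p[i2], .Machine$double.xmin)
  s1 <- ifelse(tab1$slope[i1] >= 0, 1, -1)
  s2 <- ifelse(tab2$slope[i2] >= 0, 1, -1)
  x <- -2 * (log(p1) + log(p2))
  fisher_p <- stats::pchisq(x, df = 4, lower.tail = FALSE)
  w <- sqrt(c(n1, n2))
  z <- (w[1L] * s1 * stats::qnorm(1 - p1 / 2) +
        w[2L] * s2 * stats::qnorm(1 - p2 / 2)) / sqrt(sum(w^2))
  stouffer_p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene = shared, slope1 = tab1$slope[i1], slope2 = tab2$slope[i2],
             fisher_stat = x, fisher_p = fisher_p,
             fisher_fdr = bh_adjust(fisher_p),
             stouffer_z = z, stouffer_p = stouffer_p,
             stouffer_fdr = bh_adjust(stouffer_p),
             concordant = s1 == s2, stringsAsFactors = FALSE)
}

#' High-confidence replicated gene set
#'
#' Genes with Fisher FDR and Stouffer FDR both below the threshold and a
#' concordant direction of effect in both cohorts, sorted by |Stouffer Z|.
#'
#' @param meta Output of [meta_analyze()].
#' @param fdr_threshold Default 0.05.
#' @return Character vector of gene ids.
#' @export
high_confidence_set <- function(meta, fdr_threshold = 0.05) {
  sel <- meta$fisher_fdr < fdr_threshold &
    meta$stouffer_fdr < fdr_threshold & meta$concordant
  genes <- meta$gene[sel]
  genes[order(-abs(meta$stouffer_z[sel]))]
}
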