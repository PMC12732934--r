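#' Per-gene weighted least-squares fits
#'
#' Fits the same design to every gene by (weighted) least squares,
#' `beta = (X'WX)^-1 X'Wy` with per-gene weight rows, and records residual
#' variance, residual degrees of freedom, unscaled coefficient standard
#' deviations and the unscaled onset/interaction covariance needed for
#' diagnosis-specific slope contrasts.
#'
#' @param expr [elist()] (optionally with precision weights) or matrix of
#'   log2 expression, genes x samples.
#' @param design Full-rank design matrix (samples x terms, with intercept).
#' @return A `gene_fit` list: `coefficients`, `stdev_unscaled` (genes x
#'   terms), `sigma2`, `df_residual`, `cov_onset_inter` (if the interaction
#'   term is present), and the design.
#' @export
fit_gene_models <- function(expr, design) {
  el <- as_elist(expr)
  Y <- el$E
  W <- el$weights
  X <- as.matrix(design)
  n <- ncol(Y)
  p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (n <= p) stop("need more samples than design columns")
  onset_col <- match("onset", colnames(X))
  inter_col <- grep("^onset:", colnames(X))
  inter_col <- if (length(inter_col)) inter_col[1L] else NA_integer_

  G <- nrow(Y)
  coefs <- matrix(NA_real_, G, p, dimnames = list(rownames(Y), colnames(X)))
  su <- coefs
  sigma2 <- numeric(G)
  cov13 <- if (!is.na(inter_col)) numeric(G) else NULL

  if (is.null(W)) {
    fit <- stats::lm.fit(X, t(Y))
    coefs[] <- t(fit$coefficients)
    sigma2 <- colSums(fit$residuals^2) / (n - p)
    xtxinv <- chol2inv(chol(crossprod(X)))
    su[] <- rep(sqrt(diag(xtxinv)), each = G)
    if (!is.null(cov13))
      cov13[] <- xtxinv[onset_col, inter_col]
  } else {
    for (g in seq_len(G)) {
      fg <- stats::lm.wfit(X, Y[g, ], W[g, ])
      coefs[g, ] <- fg$coefficients
      sigma2[g] <- sum(W[g, ] * fg$residuals^2) / (n - p)
      xtxinv <- chol2inv(chol(crossprod(sqrt(W[g, ]) * X)))
      su[g, ] <- sqrt(diag(xtxinv))
      if (!is.null(cov13)) cov13[g] <- xtxinv[onset_col, inter_col]
    }
  }
  structure(list(coefficients = coefs, stdev_unscaled = su, sigma2 = sigma2,
                 df_residual = n - p, cov_onset_inter = cov13,
                 design = X), class = "gene_fit")
}

# Newton solver for trigamma(x) = y (y > 0), as used for the
# method-of-moments fit of the residual-variance prior
trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  x <- 0.5 + 1 / y
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif) / x) < 1e-8) break
  }
  x
}

# Empirical-Bayes variance moderation: fit a scaled inverse-chi-square prior
# (d0, s0^2) to the gene residual variances by method of moments on log s^2
squeeze_variances <- function(sigma2, df) {
  ok <- sigma2 > 0
  e <- log(sigma2[ok])
  emean <- mean(e)
  evar <- stats::var(e)
  target <- evar - trigamma(df / 2)
  if (!is.finite(target) || target <= 0) {
    # no excess spread beyond chi-square sampling noise: the prior is a
    # point mass and its scale is the plain mean of the sample variances
    d0 <- Inf
    s02 <- mean(sigma2[ok])
    post <- rep(s02, length(sigma2))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s02 <- exp(emean - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * sigma2) / (d0 + df)
  }
  list(df_prior = d0, var_prior = s02, var_post = post)
}

# Degrees of freedom for moderated tests: residual df plus the prior df,
# capped at the pooled residual df across genes (shrinkage cannot add more
# information than the data pool contains)
moderated_df <- function(fit) {
  sq <- squeeze_variances(fit$sigma2, fit$df_residual)
  min(fit$df_residual + sq$df_prior,
      fit$df_residual * length(fit$sigma2))
}

dge_table <- function(genes, slope, t, df, model) {
  p <- 2 * stats::pt(-abs(t), df = df)
  out <- data.frame(gene = genes, slope = slope, t = t, p = p,
                    fdr = bh_adjust(p), direction = sign(slope),
                    model = model, stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Moderated t-tests for one coefficient
#'
#' Shrinks per-gene residual variances toward a common prior
#' (`s2_tilde = (d0*s0^2 + dg*s2) / (d0 + dg)`, prior estimated by method of
#' moments on `log s2` across genes) and tests the named coefficient with a
#' t-statistic on `d0 + dg` degrees of freedom, BH-adjusted across genes.
#'
#' @param fit A `gene_fit`.
#' @param coefficient Design column to test (default `"onset"`).
#' @param moderate Apply variance moderation (default `TRUE`); `FALSE` gives
#'   the ordinary per-gene t-statistic.
#' @param model Label stored in the output table.
#' @return data.frame (gene, slope, t, p, fdr, direction, model), ordered by
#'   p-value.
#' @export
moderate_and_test <- function(fit, coefficient = "onset", moderate = TRUE,
                              model = coefficient) {
  stopifnot(inherits(fit, "gene_fit"))
  if (!coefficient %in% colnames(fit$coefficients))
    stop("coefficient '", coefficient, "' is not in the design")
  if (nrow(fit$coefficients) < 10L)
    stop("variance moderation needs >= 10 genes")
  b <- fit$coefficients[, coefficient]
  su <- fit$stdev_unscaled[, coefficient]
  if (moderate) {
    sq <- squeeze_variances(fit$sigma2, fit$df_residual)
    s2 <- sq$var_post
    df <- moderated_df(fit)
  } else {
    s2 <- fit$sigma2
    df <- fit$df_residual
  }
  dge_table(rownames(fit$coefficients), b, b / (sqrt(s2) * su), df, model)
}

#' Interaction and diagnosis-specific onset slopes
#'
#' From an interaction-design fit, returns (a) the diagnosis-by-onset
#' interaction test and (b) the BD-specific slope `beta_onset +
#' beta_interaction` with covariance-propagated standard error, each
#' BH-adjusted separately, plus up/down counts at the given FDR cutoff.
#'
#' @param fit A `gene_fit` produced under the interaction design.
#' @param moderate Apply variance moderation (default `TRUE`).
#' @param fdr_threshold Cutoff for the up/down counts (default 0.05).
#' @return list(interaction, bd_slope, n_significant, n_up, n_down).
#' @export
interaction_slopes <- function(fit, moderate = TRUE, fdr_threshold = 0.05) {
  stopifnot(inherits(fit, "gene_fit"))
  inter <- grep("^onset:", colnames(fit$coefficients), value = TRUE)
  if (!length(inter))
    stop("fit has no onset x diagnosis interaction column")
  inter <- inter[1L]
  if (moderate) {
    sq <- squeeze_variances(fit$sigma2, fit$df_residual)
    s2 <- sq$var_post
    df <- moderated_df(fit)
  } else {
    s2 <- fit$sigma2
    df <- fit$df_residual
  }
  genes <- rownames(fit$coefficients)
  b1 <- fit$coefficients[, "onset"]
  b3 <- fit$coefficients[, inter]
  su1 <- fit$stdev_unscaled[, "onset"]
  su3 <- fit$stdev_unscaled[, inter]
  tab_inter <- dge_table(genes, b3, b3 / (sqrt(s2) * su3), df, "interaction")
  su_bd <- sqrt(su1^2 + su3^2 + 2 * fit$cov_onset_inter)
  bd <- b1 + b3
  tab_bd <- dge_table(genes, bd, bd / (sqrt(s2) * su_bd), df, "bd_slope")
  sig <- tab_inter$fdr < fdr_threshold
  list(interaction = tab_inter, bd_slope = tab_bd,
       n_significant = sum(sig),
       n_up = sum(sig & tab_inter$slope > 0),
       n_down = sum(sig & tab_inter$slope < 0))
}

#' Sex-stratified onset fit
#'
#' Subsets the samples to one sex, drops the sex term from the primary
#' design, refits, and tests the onset coefficient.
#'
#' @param expr [elist()] or matrix over all samples.
#' @param metadata Metadata aligned with the expression columns.
#' @param stratum `"F"`, `"M"`, or `"all"` (no subsetting; still drops the
#'   sex term only when a single sex is present).
#' @param moderate Apply variance moderation.
#' @return DGETable labelled `female`/`male`/`all`.
#' @export
stratified_fit <- function(expr, metadata, stratum = c("F", "M", "all"),
                           moderate = TRUE) {
  stratum <- match.arg(stratum)
  el <- as_elist(expr)
  keep <- if (stratum == "all") rep(TRUE, nrow(metadata))
          else metadata$sex == stratum
  meta <- metadata[keep, , drop = FALSE]
  include_sex <- length(unique(meta$sex)) > 1L
  # design size check before building (sex column may drop)
  sub <- elist(el$E[, keep, drop = FALSE],
               if (is.null(el$weights)) NULL else el$weights[, keep, drop = FALSE])
  design <- build_design(meta, "primary", include_sex = include_sex)
  if (nrow(design) < ncol(design) + 2L)
    stop("stratum '", stratum, "' has ", nrow(design),
         " samples; need at least ", ncol(design) + 2L)
  fit <- fit_gene_models(sub, design)
  label <- c(F = "female", M = "male", all = "all")[[stratum]]
  moderate_and_test(fit, "onset", moderate = moderate, model = label)
}
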