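#' Expression container with optional precision weights
#'
#' A lightweight list (`E` = gene x sample log2-CPM matrix, `weights` =
#' optional positive matrix of the same shape), in the style of weighted
#' expression containers used throughout differential-expression tooling.
#'
#' @param E Numeric gene x sample matrix.
#' @param weights Optional positive matrix, same dimensions as `E`.
#' @return An object of class `elist`.
#' @export
elist <- function(E, weights = NULL) {
  stopifnot(is.matrix(E), all(is.finite(E)))
  if (!is.null(weights))
    stopifnot(identical(dim(weights), dim(E)), all(weights > 0),
              all(is.finite(weights)))
  structure(list(E = E, weights = weights), class = "elist")
}

as_elist <- function(x) {
  if (inherits(x, "elist")) return(x)
  elist(as.matrix(x))
}

#' Build a design matrix for the onset models
#'
#' Primary design: intercept + age of onset (years) + diagnosis (BD = 1,
#' SCZ reference) + age at death + sex + race + PMI + pH + RIN. The
#' interaction design adds the onset x diagnosis term. Sex-stratified fits
#' drop the sex column (`include_sex = FALSE`).
#'
#' @param metadata Sample metadata with columns `onset`, `diagnosis`, `sex`,
#'   `race`, `age_death`, `pmi`, `ph`, `rin`.
#' @param design `"primary"` or `"interaction"`.
#' @param include_sex Include the sex term (drop when stratifying by sex).
#' @param bd_reference If `TRUE`, code SCZ = 1 instead (reference switch).
#' @return Numeric design matrix with an `(Intercept)` column; errors if not
#'   full column rank.
#' @export
build_design <- function(metadata, design = c("primary", "interaction"),
                         include_sex = TRUE, bd_reference = FALSE) {
  design <- match.arg(design)
  levels <- if (bd_reference) c("BD", "SCZ") else c("SCZ", "BD")
  df <- data.frame(
    onset = metadata$onset,
    diagnosis = factor(metadata$diagnosis, levels = levels),
    age_death = metadata$age_death,
    sex = factor(metadata$sex, levels = c("F", "M")),
    race = factor(metadata$race, levels = c("nonwhite", "white")),
    pmi = metadata$pmi, ph = metadata$ph, rin = metadata$rin
  )
  terms <- c("onset", "diagnosis",
             if (design == "interaction") "onset:diagnosis",
             "age_death", if (include_sex) "sex", "race", "pmi", "ph", "rin")
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, df)
  rownames(X) <- metadata$sample_id
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; check covariates for collinearity")
  X
}

#' Counts per million
#'
#' `cpm_gi = counts_gi / libsize_i * 1e6`; with `log = TRUE`,
#' `log2((counts_gi + prior) / (libsize_i + 2 * prior) * 1e6)`.
#'
#' @param counts Non-negative integer gene x sample matrix.
#' @param log Return log2-CPM?
#' @param prior Pseudo-count for the log transform (default 0.5).
#' @return Numeric matrix of (log-)CPM values.
#' @export
compute_cpm <- function(counts, log = FALSE, prior = 0.5) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  if (log) {
    log2(sweep(counts + prior, 2, lib + 2 * prior, `/`) * 1e6)
  } else {
    sweep(counts, 2, lib, `/`) * 1e6
  }
}

#' Filter lowly expressed genes
#'
#' Keeps gene `g` iff `CPM_gi > cpm_threshold` in at least
#' `sample_fraction` of samples. Defaults: CPM > 1 in at least 50% of
#' samples. Idempotent on its own output.
#'
#' @param counts Count matrix.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param sample_fraction Minimum fraction of samples above the cutoff.
#' @return The filtered count matrix, with attributes `n_kept` and
#'   `n_dropped`.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  sample_fraction = 0.5) {
  stopifnot(sample_fraction > 0, sample_fraction <= 1)
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm > cpm_threshold) >= sample_fraction * ncol(counts)
  if (!any(keep)) stop("all genes removed by the expression filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Exclude low-RIN samples and duplicate donors
#'
#' Drops samples with RIN below `rin_min` (default 6) and, when a donor id
#' column is present, all but the first sample of each duplicated donor.
#'
#' @param counts Count matrix (columns = samples).
#' @param metadata Metadata aligned to columns, with an `rin` column and an
#'   optional donor id column.
#' @param rin_min Minimum RIN retained (default 6).
#' @param donor_col Name of the donor id column, if any.
#' @return list(counts, metadata, n_excluded_rin, n_excluded_duplicates).
#' @export
exclude_samples <- function(counts, metadata, rin_min = 6,
                            donor_col = "donor") {
  stopifnot(identical(colnames(counts), metadata$sample_id))
  if (anyNA(metadata$rin))
    stop("missing RIN for sample(s): ",
         paste(metadata$sample_id[is.na(metadata$rin)], collapse = ", "))
  keep <- metadata$rin >= rin_min
  n_rin <- sum(!keep)
  n_dup <- 0L
  if (donor_col %in% names(metadata)) {
    first <- !duplicated(metadata[[donor_col]])
    n_dup <- sum(keep & !first)
    keep <- keep & first
  }
  list(counts = counts[, keep, drop = FALSE],
       metadata = metadata[keep, , drop = FALSE],
       n_excluded_rin = n_rin, n_excluded_duplicates = n_dup)
}

# empirical-Bayes posterior for one gene-batch cell (location-scale model);
# standard iterative solution for the conditional posterior means
eb_cell <- function(z, gamma_hat, delta2_hat, gamma_bar, tau2, a_prior,
                    b_prior, tol = 1e-4, maxit = 100L) {
  nb <- length(z)
  g_new <- gamma_hat
  d_new <- delta2_hat
  for (it in seq_len(maxit)) {
    g_old <- g_new
    d_old <- d_new
    g_new <- (nb * tau2 * gamma_hat + d_new * gamma_bar) / (nb * tau2 + d_new)
    d_new <- (b_prior + 0.5 * sum((z - g_new)^2)) / (nb / 2 + a_prior - 1)
    if (abs(g_new - g_old) + abs(d_new - d_old) < tol * (1 + abs(d_old)))
      break
  }
  c(g_new, d_new)
}

#' Empirical-Bayes location-scale batch adjustment on log-CPM
#'
#' Per-gene standardization under a protected design, per-batch mean and
#' variance parameters shrunk toward their across-gene priors (normal prior
#' on the batch means, inverse-gamma on the batch variances, moment-matched),
#' then back-transformation with the batch terms removed. Effects of the
#' protected biological covariates are estimated jointly with the batch
#' terms and restored untouched.
#'
#' @param expr An [elist()] or gene x sample matrix of log2-CPM values.
#' @param batch Per-sample batch labels (>= 2 batches, each with >= 2
#'   samples, unless a single batch: identity with a warning).
#' @param protect Protected design matrix (with intercept) whose fitted
#'   effects must survive correction; `NULL` protects only the intercept.
#' @param shrink Use empirical-Bayes shrinkage (default). `FALSE` reduces to
#'   plain per-batch centering/scaling of the standardized data.
#' @return Object of the same type with batch-adjusted `E`.
#' @export
correct_batch <- function(expr, batch, protect = NULL, shrink = TRUE) {
  el <- as_elist(expr)
  Y <- el$E
  batch <- factor(batch)
  if (nlevels(batch) < 2L) {
    warning("single batch: nothing to correct")
    return(if (inherits(expr, "elist")) el else Y)
  }
  if (any(table(batch) < 2L))
    stop("every batch needs >= 2 samples")
  B <- stats::model.matrix(~ 0 + batch)
  C <- if (is.null(protect)) NULL else {
    P <- as.matrix(protect)
    P[, colnames(P) != "(Intercept)", drop = FALSE]
  }
  X <- cbind(B, C)
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with a protected covariate (rank deficiency)")
  n <- ncol(Y)
  nb <- as.integer(table(batch))
  fit <- stats::lm.fit(X, t(Y))
  beta <- fit$coefficients                      # (batch + cov) x genes
  gamma_ls <- beta[seq_len(ncol(B)), , drop = FALSE]
  alpha <- as.numeric(crossprod(gamma_ls, nb / n))   # grand mean per gene
  cov_part <- if (is.null(C)) 0 else
    t(C %*% beta[-seq_len(ncol(B)), , drop = FALSE])
  res <- t(fit$residuals)
  sigma <- sqrt(rowSums(res^2) / n)
  sigma[sigma == 0] <- 1
  Z <- (Y - alpha - cov_part) / sigma

  Zadj <- Z
  for (b in levels(batch)) {
    idx <- which(batch == b)
    Zb <- Z[, idx, drop = FALSE]
    gamma_hat <- rowMeans(Zb)
    delta2_hat <- apply(Zb, 1L, stats::var)
    delta2_hat[delta2_hat == 0] <- 1e-8
    if (shrink) {
      gamma_bar <- mean(gamma_hat)
      tau2 <- stats::var(gamma_hat)
      m <- mean(delta2_hat)
      s2 <- stats::var(delta2_hat)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      post <- t(vapply(seq_len(nrow(Z)), function(g)
        eb_cell(Zb[g, ], gamma_hat[g], delta2_hat[g], gamma_bar, tau2,
                a_prior, b_prior), numeric(2)))
      gamma_star <- post[, 1L]
      delta2_star <- post[, 2L]
    } else {
      gamma_star <- gamma_hat
      delta2_star <- delta2_hat
    }
    Zadj[, idx] <- (Zb - gamma_star) / sqrt(delta2_star)
  }
  Yadj <- Zadj * sigma + alpha + cov_part
  if (inherits(expr, "elist")) elist(Yadj, el$weights) else Yadj
}

#' PCA batch diagnostics
#'
#' Gene-centered PCA of the samples with a per-component batch-separation
#' statistic (the between-batch share of each component's variance).
#'
#' @param expr [elist()] or matrix of log2 expression.
#' @param batch Per-sample batch labels.
#' @param k Number of components (default 3).
#' @return list(scores = sample x k matrix, var_explained, batch_r2,
#'   pc12, pc23 = score tables for plotting).
#' @export
pca_batch_check <- function(expr, batch, k = 3L) {
  E <- as_elist(expr)$E
  stopifnot(k < min(dim(E)))
  if (all(apply(E, 1L, stats::var) == 0)) stop("constant expression matrix")
  pc <- stats::prcomp(t(E), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  batch <- factor(batch)
  batch_r2 <- apply(scores, 2L, function(s) {
    fit <- stats::lm(s ~ batch)
    1 - sum(stats::residuals(fit)^2) / sum((s - mean(s))^2)
  })
  list(scores = scores, var_explained = ve, batch_r2 = batch_r2,
       pc12 = data.frame(sample_id = rownames(scores), batch = batch,
                         PC1 = scores[, 1L], PC2 = scores[, 2L]),
       pc23 = data.frame(sample_id = rownames(scores), batch = batch,
                         PC2 = scores[, 2L],
                         PC3 = if (k >= 3L) scores[, 3L] else NA_real_))
}

#' Log-CPM with mean-variance precision weights
#'
#' Computes log2-CPM, fits the design per gene, smooths the square-root
#' residual standard deviation against average log2 count with locally
#' weighted regression, predicts each observation's standard deviation at
#' its fitted log-count, and assigns weight = predicted SD^-4.
#'
#' @param counts Count matrix.
#' @param design Design matrix (full rank, with intercept).
#' @param span Smoother span (default 0.5).
#' @param prior Pseudo-count (default 0.5).
#' @return An [elist()] with `E` (log2-CPM) and positive `weights`.
#' @export
voom_weights <- function(counts, design, span = 0.5, prior = 0.5) {
  validate_counts(counts)
  if (nrow(counts) < 10L)
    stop("need >= 10 genes to fit the mean-variance trend; enlarge the fixture")
  stopifnot(nrow(design) == ncol(counts))
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  if (ncol(counts) < ncol(design) + 2L)
    stop("too few samples for the design")
  lib <- colSums(counts)
  y <- compute_cpm(counts, log = TRUE, prior = prior)
  fit <- stats::lm.fit(design, t(y))
  dfres <- ncol(counts) - ncol(design)
  sigma <- sqrt(colSums(fit$residuals^2) / dfres)
  # average log2 count scale
  sx <- rowMeans(y) + mean(log2(lib + 2 * prior)) - log2(1e6)
  sy <- sqrt(sigma)
  lo <- stats::lowess(sx, sy, f = span)
  predict_sd <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_cpm <- t(design %*% fit$coefficients)
  fitted_count <- sweep(fitted_cpm, 2, log2(lib + 2 * prior) - log2(1e6), `+`)
  w <- predict_sd(fitted_count)^-4
  w <- matrix(pmin(pmax(w, 1e-10), 1e10), nrow = nrow(y), dimnames = dimnames(y))
  elist(y, w)
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing each non-intercept column on all
#' other non-intercept columns (with intercept). Exact collinearity is
#' reported as `Inf` rather than an error.
#'
#' @param design Design matrix (with or without intercept column).
#' @return data.frame (term, vif) sorted by decreasing VIF.
#' @export
compute_vif <- function(design) {
  X <- as.matrix(design)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2L) stop("need >= 2 non-intercept columns")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Xo <- cbind(1, X[, -j, drop = FALSE])
    r <- stats::lm.fit(Xo, yj)$residuals
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(r^2) / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out <- data.frame(term = colnames(X), vif = vif, stringsAsFactors = FALSE)
  out[order(-out$vif), , drop = FALSE]
}
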