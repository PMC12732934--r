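test_that("per-gene fits match the normal-equation oracle, weighted and not", {
  X <- make_toy_design(n = 30)
  E <- make_toy_expr(G = 12, X, n_signal = 3)
  fit <- fit_gene_models(elist(E), X)
  for (g in 1:5)
    expect_equal(unname(fit$coefficients[g, ]), oracle_wls(X, E[g, ]),
                 tolerance = 1e-8)
  set.seed(9)
  W <- matrix(runif(length(E), 0.2, 3), nrow(E))
  fitw <- fit_gene_models(elist(E, W), X)
  for (g in 1:5)
    expect_equal(unname(fitw$coefficients[g, ]), oracle_wls(X, E[g, ], W[g, ]),
                 tolerance = 1e-8)
  # unscaled SE and residual variance against lm() for one gene
  lmf <- lm(E[3, ] ~ 0 + X)
  expect_equal(unname(fit$sigma2[3]), summary(lmf)$sigma^2, tolerance = 1e-10)
  expect_equal(unname(fit$stdev_unscaled[3, ] * sqrt(fit$sigma2[3])),
               unname(summary(lmf)$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
})

test_that("a noise-free planted slope is recovered to machine precision", {
  X <- make_toy_design(n = 20)
  E <- matrix(0.1, 10, 20, dimnames = list(sprintf("g%02d", 1:10), NULL)) *
    matrix(X[, "onset"], 10, 20, byrow = TRUE)
  E <- E + seq_len(10) # gene-specific intercepts
  fit <- fit_gene_models(elist(E), X)
  expect_equal(unname(fit$coefficients[, "onset"]), rep(0.1, 10),
               tolerance = 1e-12)
})

test_that("trigamma_inverse inverts trigamma over the useful range", {
  for (x in c(0.01, 0.1, 1, 5, 50)) {
    expect_equal(onsetomics:::trigamma_inverse(trigamma(x)), x,
                 tolerance = 1e-8)
  }
})

test_that("variance moderation shrinks toward the prior with correct limits", {
  set.seed(13)
  df <- 20L
  s2 <- exp(rnorm(200, log(1), 0.8))
  sq <- onsetomics:::squeeze_variances(s2, df)
  expect_true(sq$df_prior > 0)
  # posterior variances lie between each gene's value and the prior
  between <- (sq$var_post >= pmin(s2, sq$var_prior) - 1e-12) &
    (sq$var_post <= pmax(s2, sq$var_prior) + 1e-12)
  expect_true(all(between))
  # exact formula
  expect_equal(sq$var_post,
               (sq$df_prior * sq$var_prior + df * s2) / (sq$df_prior + df),
               tolerance = 1e-10)
  # identical variances: no excess spread, infinite prior df, full shrinkage
  # to the mean sample variance
  sq0 <- onsetomics:::squeeze_variances(rep(2, 50), df)
  expect_identical(sq0$df_prior, Inf)
  expect_equal(sq0$var_post, rep(2, 50))
  expect_equal(sq0$var_post, rep(sq0$var_prior, 50))
})

test_that("moderated tests agree with limma::eBayes", {
  X <- make_toy_design(n = 36, seed = 17)
  E <- make_toy_expr(G = 150, X, effect = 0.6, n_signal = 25, seed = 18)
  fit <- fit_gene_models(elist(E), X)
  tab <- moderate_and_test(fit, "onset")
  lf <- limma::eBayes(limma::lmFit(E, X))
  idx <- match(tab$gene, rownames(E))
  expect_equal(tab$t, unname(lf$t[idx, "onset"]), tolerance = 1e-6)
  expect_equal(tab$p, unname(lf$p.value[idx, "onset"]), tolerance = 1e-6)
  expect_equal(tab$slope, unname(lf$coefficients[idx, "onset"]),
               tolerance = 1e-10)
  # moderate = FALSE gives the ordinary t-test
  plain <- moderate_and_test(fit, "onset", moderate = FALSE)
  g <- plain$gene[1]
  lmf <- summary(lm(E[g, ] ~ 0 + X))$coefficients
  expect_equal(plain$t[1], unname(lmf["Xonset", "t value"]), tolerance = 1e-8)
  # output table is sorted by p with valid FDR
  expect_true(!is.unsorted(tab$p))
  expect_true(all(tab$fdr >= tab$p - 1e-15))
})

test_that("null genes are calibrated: uniform p-values, no FDR calls", {
  set.seed(19)
  X <- make_toy_design(n = 50, seed = 23)
  E <- make_toy_expr(G = 400, X, n_signal = 0, seed = 24)
  tab <- moderate_and_test(fit_gene_models(elist(E), X), "onset")
  expect_gt(stats::ks.test(tab$p, "punif")$p.value, 0.01)
  expect_lt(mean(tab$fdr < 0.05), 0.01)
})

test_that("interaction slopes use the covariance-propagated contrast SE", {
  co <- small_cohort()
  meta <- co$metadata
  set.seed(29)
  E <- matrix(rnorm(40 * nrow(meta)), 40,
              dimnames = list(sprintf("g%03d", 1:40), meta$sample_id))
  X <- build_design(meta, "interaction")
  fit <- fit_gene_models(elist(E), X)
  res <- interaction_slopes(fit, moderate = FALSE)
  # oracle via lm + vcov for a few genes
  onset <- X[, "onset"]
  bd <- X[, "diagnosisBD"]
  for (g in c(1, 7, 25)) {
    lmf <- lm(E[g, ] ~ 0 + X)
    v <- vcov(lmf)
    cn <- colnames(X)
    b <- coef(lmf)
    names(b) <- cn
    rownames(v) <- colnames(v) <- cn
    # interaction test
    ti <- b["onset:diagnosisBD"] / sqrt(v["onset:diagnosisBD",
                                          "onset:diagnosisBD"])
    row <- res$interaction[res$interaction$gene == sprintf("g%03d", g), ]
    expect_equal(row$t, unname(ti), tolerance = 1e-8)
    # BD slope = onset + interaction, with the covariance term
    bbd <- b["onset"] + b["onset:diagnosisBD"]
    sbd <- sqrt(v["onset", "onset"] +
                  v["onset:diagnosisBD", "onset:diagnosisBD"] +
                  2 * v["onset", "onset:diagnosisBD"])
    rowb <- res$bd_slope[res$bd_slope$gene == sprintf("g%03d", g), ]
    expect_equal(rowb$slope, unname(bbd), tolerance = 1e-10)
    expect_equal(rowb$t, unname(bbd / sbd), tolerance = 1e-8)
  }
})

test_that("planted BD-specific slopes surface in the interaction test", {
  co <- small_cohort()
  ex <- exclude_samples(co$counts, co$metadata)
  cts <- filter_low_expression(ex$counts)
  meta <- ex$metadata
  des <- build_design(meta, "primary")
  vw <- voom_weights(cts, des)
  corrected <- correct_batch(vw$E, meta$batch, protect = des)
  expr <- elist(corrected, vw$weights)
  res <- interaction_slopes(fit_gene_models(expr,
                                            build_design(meta, "interaction")))
  inter_genes <- co$plan$interaction_genes
  # at n = 120 the interaction test is underpowered gene-by-gene; require
  # strong enrichment of planted genes in the top of the ranking rather
  # than a majority
  top <- head(res$interaction$gene, 30)
  expect_gt(mean(top %in% inter_genes), 0.25)
  expect_lt(ora_hypergeometric(top, intersect(inter_genes,
                                              res$interaction$gene),
                               res$interaction$gene)$p, 1e-4)
  # planted direction is negative
  sl <- res$interaction$slope[res$interaction$gene %in% inter_genes]
  expect_gt(mean(sl < 0), 0.8)
  # BD slope for interaction genes is near the planted value, SCZ-only slope
  # (primary onset coefficient) near zero
  bd <- res$bd_slope[match(inter_genes, res$bd_slope$gene), ]
  expect_lt(abs(mean(bd$slope) + 0.05), 0.02)
})

test_that("sex-stratified fits isolate the female-specific effect", {
  co <- small_cohort()
  ex <- exclude_samples(co$counts, co$metadata)
  cts <- filter_low_expression(ex$counts)
  meta <- ex$metadata
  des <- build_design(meta, "primary")
  vw <- voom_weights(cts, des)
  expr <- elist(correct_batch(vw$E, meta$batch, protect = des), vw$weights)
  fem <- stratified_fit(expr, meta, "F")
  mal <- stratified_fit(expr, meta, "M")
  sex_genes <- intersect(co$plan$sex_specific_genes, fem$gene)
  pf <- fem$p[match(sex_genes, fem$gene)]
  pm <- mal$p[match(sex_genes, mal$gene)]
  # evidence concentrates in the female stratum
  expect_lt(median(pf), 0.05)
  expect_gt(median(pm), 0.1)
  expect_gt(mean(pm > pf), 0.7)
  # the sex term is dropped within a stratum
  expect_identical(fem$model[1], "female")
})
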