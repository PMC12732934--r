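test_that("compute_cpm matches hand-computed values and sums to 1e6", {
  cts <- matrix(c(10, 90, 40, 160), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- compute_cpm(cts)
  expect_equal(cpm, matrix(c(1e5, 9e5, 2e5, 8e5), 2, 2,
                           dimnames = dimnames(cts)))
  expect_equal(colSums(cpm), c(s1 = 1e6, s2 = 1e6))
  # log version with pseudo-count, hand-computed
  lg <- compute_cpm(cts, log = TRUE, prior = 0.5)
  expect_equal(lg[1, 1], log2((10 + 0.5) / (100 + 1) * 1e6))
  expect_equal(lg[2, 2], log2((160 + 0.5) / (200 + 1) * 1e6))
})

test_that("expression filter keeps exactly the genes passing the rule", {
  # 4 samples; gene passes if CPM > 1 in >= 2 of them
  cts <- rbind(g_hi = c(100, 100, 100, 100),
               g_half = c(100, 100, 0, 0),
               g_low = c(100, 0, 0, 0),
               g_zero = c(0, 0, 0, 0),
               g_fill = c(1e6, 1e6, 1e6, 1e6))
  colnames(cts) <- paste0("s", 1:4)
  kept <- filter_low_expression(cts, cpm_threshold = 1, sample_fraction = 0.5)
  expect_identical(rownames(kept), c("g_hi", "g_half", "g_fill"))
  expect_identical(attr(kept, "n_kept"), 3L)
  expect_identical(attr(kept, "n_dropped"), 2L)
  # idempotent
  again <- filter_low_expression(kept)
  expect_equal(unclass(again)[, ], unclass(kept)[, ])
  # an impossible threshold removes everything (library sizes stay valid)
  expect_error(filter_low_expression(cts, cpm_threshold = 2e6),
               "all genes removed")
  # all-zero columns are a data error, reported as such
  expect_error(compute_cpm(cts["g_zero", , drop = FALSE]), "library size")
})

test_that("sample exclusion drops low-RIN samples and duplicate donors", {
  co <- small_cohort()
  meta <- co$metadata
  meta$donor <- meta$sample_id
  meta$donor[31:40] <- meta$donor[21:30] # 10 injected duplicate donors
  low <- meta$rin < 6
  ex <- exclude_samples(co$counts, meta)
  expect_identical(ex$n_excluded_rin, sum(low))
  expect_identical(ex$n_excluded_duplicates, sum(!low[31:40]))
  expect_identical(colnames(ex$counts), ex$metadata$sample_id)
  expect_true(all(ex$metadata$rin >= 6))
  expect_identical(anyDuplicated(ex$metadata$donor), 0L)
  # without a donor column only the RIN rule applies
  ex2 <- exclude_samples(co$counts, co$metadata)
  expect_identical(ex2$n_excluded_duplicates, 0L)
  # missing RIN is an error, not a silent drop
  meta_na <- co$metadata
  meta_na$rin[5] <- NA
  expect_error(exclude_samples(co$counts, meta_na), "missing RIN")
})

test_that("build_design encodes reference levels and both model forms", {
  co <- small_cohort()
  d <- build_design(co$metadata, "primary")
  expect_true(all(c("(Intercept)", "onset", "diagnosisBD", "age_death",
                    "sexM", "racewhite", "pmi", "ph", "rin") %in% colnames(d)))
  # SCZ is the reference: the BD indicator is 1 exactly for BD samples
  expect_equal(unname(d[, "diagnosisBD"]),
               as.numeric(co$metadata$diagnosis == "BD"))
  di <- build_design(co$metadata, "interaction")
  expect_true("onset:diagnosisBD" %in% colnames(di))
  expect_equal(unname(di[, "onset:diagnosisBD"]),
               unname(di[, "onset"] * di[, "diagnosisBD"]))
  expect_identical(qr(di)$rank, ncol(di))
})

test_that("batch correction removes a planted additive batch offset", {
  set.seed(41)
  n <- 60
  G <- 50
  batch <- rep(c("b1", "b2", "b3"), each = n / 3)
  E <- matrix(rnorm(G * n, mean = 8), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:n)))
  shift <- matrix(rnorm(G, sd = 1), G, n) * (rep(c(0, 1, 2), each = n / 3))[col(E)]
  Eb <- E + shift
  corrected <- correct_batch(Eb, batch)
  # between-batch mean differences collapse
  bm <- sapply(unique(batch), function(b) rowMeans(corrected[, batch == b]))
  expect_lt(max(abs(bm[, 1] - bm[, 2])), 0.35)
  expect_lt(mean(abs(bm[, 1] - bm[, 3])), 0.1)
  # PCA diagnostic agrees
  pre <- pca_batch_check(Eb, batch)
  post <- pca_batch_check(corrected, batch)
  expect_gt(pre$batch_r2[1], 0.5)
  expect_lt(post$batch_r2[1], 0.1)
})

test_that("shrink = FALSE reduces to exact per-batch centering/scaling", {
  set.seed(43)
  G <- 30
  n <- 24
  batch <- rep(c("b1", "b2"), each = 12)
  E <- matrix(rnorm(G * n, 5), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:n)))
  out <- correct_batch(E, batch, shrink = FALSE)
  # oracle: standardize per gene, center/scale per batch, back-transform
  alpha <- rowMeans(E)
  gm <- cbind(rowMeans(E[, 1:12]), rowMeans(E[, 13:24]))
  res <- E - gm[, c(rep(1, 12), rep(2, 12))]
  # pooled (ML) sigma from the batch-mean model
  sigma <- sqrt(rowSums(res^2) / n)
  Z <- (E - alpha) / sigma
  Zc <- Z
  for (b in 1:2) {
    idx <- if (b == 1) 1:12 else 13:24
    mu <- rowMeans(Z[, idx])
    sdv <- apply(Z[, idx], 1, sd)
    Zc[, idx] <- (Z[, idx] - mu) / sdv
  }
  oracle <- Zc * sigma + alpha
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("batch correction matches sva::ComBat on realistic data", {
  co <- small_cohort()
  cts <- filter_low_expression(co$counts)
  des <- build_design(co$metadata, "primary")
  E <- compute_cpm(cts, log = TRUE)
  ours <- correct_batch(E, co$metadata$batch, protect = des)
  theirs <- suppressMessages(sva::ComBat(E, batch = co$metadata$batch,
                                         mod = des))
  expect_gt(stats::cor(as.vector(ours), as.vector(theirs)), 0.9999)
  expect_lt(sqrt(mean((ours - theirs)^2)), 0.05)
})

test_that("batch correction protects planted biology and rejects confounding", {
  set.seed(47)
  n <- 60
  G <- 40
  onset <- rnorm(n, 22, 8)
  batch <- rep(c("b1", "b2"), each = 30)
  E <- matrix(rnorm(G * n, 6), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:n)))
  E[1:10, ] <- E[1:10, ] - 0.05 * matrix(onset, 10, n, byrow = TRUE)
  Eb <- E + matrix(rnorm(G), G, n) * (batch == "b2")[col(E)]
  protect <- cbind(`(Intercept)` = 1, onset = onset)
  corrected <- correct_batch(Eb, batch, protect = protect)
  slopes <- apply(corrected[1:10, ], 1, function(y) coef(lm(y ~ onset))[2])
  # planted slope survives: close on average and nowhere wiped out
  expect_lt(abs(mean(slopes) + 0.05), 0.02)
  expect_lt(max(abs(slopes + 0.05)), 0.06)
  # batch == covariate is unidentifiable and must error
  expect_error(correct_batch(Eb, batch,
                             protect = cbind(`(Intercept)` = 1,
                                             grp = as.numeric(batch == "b2"))),
               "confounded")
  # single batch: identity with a warning
  expect_warning(ident <- correct_batch(Eb, rep("b1", n)), "single batch")
  expect_identical(ident, Eb)
})

test_that("voom weights match limma::voom and track the mean-variance trend", {
  co <- small_cohort()
  cts <- filter_low_expression(co$counts)
  des <- build_design(co$metadata, "primary")
  ours <- voom_weights(cts, des)
  theirs <- limma::voom(cts, des)
  expect_equal(ours$E, theirs$E, tolerance = 1e-12)
  expect_equal(log(ours$weights), log(unclass(theirs$weights)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(ours$weights > 0))
  # weights must not change the point estimates' invariance: doubling all
  # weights leaves the weighted fit unchanged
  fit1 <- fit_gene_models(elist(ours$E, ours$weights), des)
  fit2 <- fit_gene_models(elist(ours$E, 2 * ours$weights), des)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
})

test_that("voom guards reject unusable inputs", {
  co <- small_cohort()
  des <- build_design(co$metadata, "primary")
  expect_error(voom_weights(co$counts[1:5, ], des), ">= 10 genes")
  bad <- cbind(des, dup = des[, "onset"])
  expect_error(voom_weights(co$counts, bad), "rank deficient")
})

test_that("VIF matches the closed form and flags collinearity", {
  # two predictors with known correlation r: VIF = 1 / (1 - r^2)
  set.seed(53)
  n <- 5000
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  r <- cor(x, y)
  v <- compute_vif(cbind(`(Intercept)` = 1, x = x, y = y))
  expect_equal(v$vif[1], 1 / (1 - r^2), tolerance = 1e-8)
  expect_equal(v$vif, sort(v$vif, decreasing = TRUE))
  # exact collinearity is Inf, not an error
  v2 <- compute_vif(cbind(`(Intercept)` = 1, x = x, x2 = 2 * x, y = y))
  expect_true(any(is.infinite(v2$vif)))
  # orthogonal design: all VIFs 1
  v3 <- compute_vif(cbind(a = rep(c(1, -1), 4), b = rep(c(1, 1, -1, -1), 2)))
  expect_equal(v3$vif, c(1, 1))
})
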