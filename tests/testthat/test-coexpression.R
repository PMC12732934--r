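test_that("signed adjacency maps correlations as documented", {
  # build genes with exact correlations: g2 = -g1, g3 = g1
  x <- c(1, 2, 3, 4, 5, 7)
  E <- rbind(g1 = x, g2 = -x, g3 = 2 * x + 1)
  a <- adjacency_matrix(E, power = 6, signed = TRUE)
  expect_equal(unname(a["g1", "g2"]), 0)            # r = -1 -> 0
  expect_equal(unname(a["g1", "g3"]), 1)            # r = +1 -> 1
  expect_equal(unname(diag(a)), c(0, 0, 0))
  au <- adjacency_matrix(E, power = 6, signed = FALSE)
  expect_equal(unname(au["g1", "g2"]), 1)           # |r| = 1
  # r = 0 -> (1/2)^power
  E2 <- rbind(g1 = c(1, 1, -1, -1), g2 = c(1, -1, 1, -1))
  a2 <- adjacency_matrix(E2, power = 6)
  expect_equal(unname(a2["g1", "g2"]), 0.5^6)
})

test_that("topological overlap matches the direct formula oracle", {
  set.seed(79)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    r <- stats::cor(matrix(rnorm(n * 20), 20, n))
    a <- ((1 + r) / 2)^4
    diag(a) <- 0
    tom <- topological_overlap(a)
    expect_equal(tom, oracle_tom_direct(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
  # all-ones off-diagonal adjacency: complete overlap, TOM exactly 1
  a1 <- matrix(1, 3, 3)
  diag(a1) <- 0
  expect_equal(topological_overlap(a1), matrix(1, 3, 3), ignore_attr = TRUE)
  # zero adjacency: zero off-diagonal overlap
  a0 <- matrix(0, 4, 4)
  expect_equal(unname(topological_overlap(a0)), diag(4))
  expect_error(topological_overlap(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("soft-threshold selection returns the smallest adequate power", {
  co <- small_cohort()
  E <- compute_cpm(co$counts[1:200, ], log = TRUE)
  st <- pick_soft_threshold(E, candidate_powers = 1:20)
  expect_true(st$power %in% 1:20)
  # mean connectivity decreases monotonically with power
  expect_true(all(diff(st$fit$mean_connectivity) < 0))
  # smallest power at target: no earlier power passes
  earlier <- st$fit$r2[st$fit$power < st$power]
  if (length(earlier)) expect_true(all(earlier < 0.80))
  expect_error(pick_soft_threshold(E[1:20, ]), ">= 50 genes")
})

test_that("two planted blocks are detected as two clean modules", {
  set.seed(83)
  n <- 60
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  E <- rbind(
    t(sapply(1:40, function(i) 3 * z1 + rnorm(n))),
    t(sapply(1:40, function(i) 3 * z2 + rnorm(n))),
    matrix(rnorm(40 * n), 40, n)
  )
  rownames(E) <- sprintf("g%03d", 1:120)
  cfg <- network_config(power = 6, min_module_size = 30)
  net <- build_network(E, cfg)
  truth <- rep(c("block1", "block2", "null"), each = 40)
  lab <- net$labels
  # each planted block lands in a single non-grey module
  expect_identical(length(unique(lab[1:40])), 1L)
  expect_identical(length(unique(lab[41:80])), 1L)
  expect_false(unique(lab[1:40]) == "grey")
  expect_false(unique(lab[41:80]) == "grey")
  expect_false(unique(lab[1:40]) == unique(lab[41:80]))
  # block recovery: ARI on the planted genes is perfect
  expect_equal(adjusted_rand_index(truth[1:80], lab[1:80]), 1)
  # eigengene of block 1 tracks its latent factor
  eg <- net$eigengenes[, unique(lab[1:40])]
  expect_gt(abs(cor(eg, z1)), 0.95)
  # gene-order invariance of the partition
  perm <- sample(120)
  net2 <- build_network(E[perm, ], cfg)
  expect_equal(adjusted_rand_index(net2$labels[rownames(E)], lab), 1)
})

test_that("small clusters fall into grey and module sizes are ordered", {
  set.seed(89)
  E <- matrix(rnorm(20 * 30), 20, dimnames = list(sprintf("g%02d", 1:20), NULL))
  a <- adjacency_matrix(E, 6)
  expect_warning(
    mods <- detect_modules(1 - topological_overlap(a),
                           network_config(power = 6, min_module_size = 30)),
    "grey")
  expect_true(all(mods$labels == "grey"))
  expect_identical(length(mods$sizes), 0L)
})

test_that("module eigengene equals the first PC and is sign-aligned", {
  set.seed(97)
  n <- 25
  z <- rnorm(n)
  E <- t(sapply(1:6, function(i) 2 * z + rnorm(n, sd = 0.3)))
  rownames(E) <- paste0("g", 1:6)
  colnames(E) <- paste0("s", 1:n)
  me <- module_eigengene(E, rownames(E))
  # oracle: first right singular vector of the row-standardized matrix
  zstd <- t(scale(t(E)))
  sv <- svd(zstd)
  ve_oracle <- sv$d[1]^2 / sum(sv$d^2)
  expect_equal(me$var_explained, ve_oracle, tolerance = 1e-12)
  expect_equal(abs(unname(me$eigengene)), abs(sv$v[, 1]), tolerance = 1e-10)
  # sign alignment: positively loaded module correlates positively
  expect_gt(mean(cor(t(zstd), me$eigengene)), 0)
  expect_equal(sum(me$eigengene^2), 1, tolerance = 1e-12)
  # near-perfect module: variance explained close to 1
  expect_gt(me$var_explained, 0.9)
  expect_error(module_eigengene(E, "g1"), ">= 2")
})

test_that("modules with near-identical eigengenes merge; distinct ones do not", {
  set.seed(101)
  n <- 50
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  E <- rbind(
    t(sapply(1:35, function(i) 3 * z1 + rnorm(n, sd = 0.5))),
    t(sapply(1:35, function(i) 3 * z1 + rnorm(n, sd = 0.5))), # same factor
    t(sapply(1:35, function(i) 3 * z2 + rnorm(n, sd = 0.5)))  # different
  )
  rownames(E) <- sprintf("g%03d", 1:105)
  labels <- setNames(rep(c("m1", "m2", "m3"), each = 35), rownames(E))
  mods <- structure(list(labels = labels,
                         sizes = onsetomics:::module_sizes(labels),
                         dendrogram = NULL, cut_height = NA_real_),
                    class = "module_set")
  merged <- merge_modules(mods, E, merge_height = 0.25)
  lab <- merged$labels
  expect_identical(unique(lab[1:35]), unique(lab[36:70]))   # merged
  expect_false(unique(lab[1:35]) == unique(lab[71:105]))    # kept apart
  expect_identical(ncol(merged$eigengenes), 2L)
})

test_that("module-trait correlation matches cor.test and handles degenerate traits", {
  set.seed(103)
  n <- 40
  z <- rnorm(n)
  E <- t(sapply(1:30, function(i) 2 * z + rnorm(n, sd = 0.5)))
  rownames(E) <- sprintf("g%02d", 1:30)
  colnames(E) <- sprintf("s%02d", 1:n)
  labels <- setNames(rep("turquoise", 30), rownames(E))
  mods <- structure(list(labels = labels,
                         sizes = onsetomics:::module_sizes(labels),
                         dendrogram = NULL, cut_height = NA_real_),
                    class = "module_set")
  mods <- merge_modules(mods, E, merge_height = 0.25)
  meta <- data.frame(onset = 5 * z + rnorm(n), sex = rep(c("F", "M"), n / 2),
                     flat = rep(1, n))
  tt <- module_trait_correlation(mods, meta, c("onset", "sex", "flat"))
  row <- tt[tt$trait == "onset", ]
  ct <- cor.test(mods$eigengenes[, 1], meta$onset)
  expect_equal(row$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  # zero-variance trait gives NA rather than an error
  expect_true(is.na(tt$r[tt$trait == "flat"]))
})
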