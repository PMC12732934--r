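# Brute-force oracle implementations used by the unit and acceptance tests.
# Each one recomputes a package quantity by the most direct formula
# available, independent of the package's own code path.

# weighted least squares by explicit normal equations
oracle_wls <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  W <- diag(w, nrow = length(w))
  as.numeric(solve(t(X) %*% W %*% X) %*% t(X) %*% W %*% y)
}

# exhaustive GSEA running sum: walk the whole ranking step by step and
# return the positive and negative extreme deviations
oracle_es_bounds <- function(r_sorted, set, exponent = 1) {
  inset <- names(r_sorted) %in% set
  N <- length(r_sorted)
  NH <- sum(inset)
  w <- abs(r_sorted)^exponent * inset
  W <- sum(w)
  if (W == 0) {
    w <- as.numeric(inset)
    W <- NH
  }
  steps <- ifelse(inset, w / W, -1 / (N - NH))
  walk <- cumsum(steps)
  list(hi = max(c(0, walk)), lo = min(c(0, walk)))
}

oracle_es_walk <- function(r_sorted, set, exponent = 1) {
  b <- oracle_es_bounds(r_sorted, set, exponent)
  if (b$hi >= -b$lo) b$hi else b$lo
}

# compare a package ES against the walk oracle; when the positive and
# negative extremes tie to within floating-point noise the sign is a
# convention, so only the magnitude is checked
expect_es_matches_oracle <- function(es, r_sorted, set, exponent = 1,
                                     tol = 1e-12) {
  b <- oracle_es_bounds(r_sorted, set, exponent)
  if (abs(b$hi + b$lo) < 1e-9) {
    testthat::expect_equal(abs(es), b$hi, tolerance = tol)
  } else {
    testthat::expect_equal(es, if (b$hi >= -b$lo) b$hi else b$lo,
                           tolerance = tol)
  }
}

# AUC by exhaustive pairwise concordance (ties count 1/2)
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# topological overlap by the direct elementwise formula
oracle_tom_direct <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        tom[i, j] <- 1
        next
      }
      l <- sum(a[i, ] * a[, j])
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# small deterministic design + expression fixture for model tests
make_toy_design <- function(n = 40, seed = 7) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1,
             onset = as.numeric(scale(rnorm(n))),
             grp = rbinom(n, 1, 0.5))
  X
}

make_toy_expr <- function(G = 60, X, effect = 0.8, n_signal = 10, seed = 8) {
  set.seed(seed)
  n <- nrow(X)
  E <- matrix(rnorm(G * n), G, n,
              dimnames = list(sprintf("g%04d", seq_len(G)),
                              sprintf("s%03d", seq_len(n))))
  if (n_signal > 0)
    E[seq_len(n_signal), ] <- E[seq_len(n_signal), ] +
      outer(rep(effect, n_signal), X[, "onset"])
  E
}

# small synthetic cohort shared by several test files (cached per session)
.small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.small_cohort_cache$co)) {
    spec <- cohort_spec(n_samples = 120L, n_genes = 600L, seed = 42L)
    .small_cohort_cache$co <- simulate_cohort(spec, effect_plan(600L))
  }
  .small_cohort_cache$co
}
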