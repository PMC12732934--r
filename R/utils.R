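#' Derive a stage-specific seed from a global seed
#'
#' All stochastic stages draw their seed deterministically from one global
#' seed so that a single integer reproduces a whole run. Seeds stay within
#' the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  # cheap string hash folded into [0, 2^31 - 2]
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 1009 + h * 7919) %% 2147483563L) + 1L
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, with ties counted 1/2.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Adjusted Rand index; 1 for identical partitions, ~0 for random.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin named wrapper so that every module adjusts p-values the same way.
#'
#' @param p Numeric p-values.
#' @return BH-adjusted p-values (FDR).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# internal: run an expression under a local RNG seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Demographic table of the reference postmortem cohort
#'
#' Printed demographic margins of the 369-sample dorsolateral prefrontal
#' cortex cohort (male/female/overall counts and covariate moments) that the
#' synthetic generator emulates. Used for demographic arithmetic and as the
#' default targets of [cohort_spec()].
#'
#' @return A list with diagnosis counts by sex and covariate summaries.
#' @export
cmc_table1 <- function() {
  list(
    n = c(male = 191L, female = 178L, overall = 369L),
    bd = c(male = 43L, female = 63L, overall = 106L),
    scz = c(male = 148L, female = 115L, overall = 263L),
    onset = list(mean = 22.1, sd = 8.2, median = 21.0, min = 7.0, max = 48.0),
    age_death = list(mean = 45.9, sd = 14.9, min = 17.0, max = 83.4),
    rin = list(mean = 7.7, sd = 0.8, min = 5.1, max = 9.4),
    pmi = list(mean = 37.4, sd = 25.6, min = 5.5, max = 168.0),
    ph = list(mean = 6.4, sd = 0.4, min = 5.7, max = 7.0),
    white = c(male = 142L, female = 137L, overall = 279L)
  )
}
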