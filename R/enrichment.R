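#' Build a ranked gene list
#'
#' Sorts scores (typically moderated t-values) in decreasing order; ties are
#' broken by gene id lexicographic order so the ranking is reproducible.
#'
#' @param scores Named numeric vector (names = gene ids, unique).
#' @return Named numeric vector sorted decreasing.
#' @export
ranked_list <- function(scores) {
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)),
            all(is.finite(scores)))
  scores[order(-scores, names(scores))]
}

# signed maximum deviation of the GSEA running sum, from sorted hit
# positions and their weights; also returns the extreme position for the
# leading edge
running_es <- function(positions, w, N) {
  k <- length(positions)
  o <- order(positions)
  positions <- positions[o]
  w <- w[o]
  W <- sum(w)
  if (W == 0) {
    w <- rep(1, k)
    W <- k
  }
  miss <- 1 / (N - k)
  j <- seq_len(k)
  after <- cumsum(w) / W - (positions - j) * miss
  # value just before hit j: previous peak minus the intervening misses
  before <- c(0, after[-k]) - (positions - c(0, positions[-k]) - 1) * miss
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) {
    list(es = hi, peak = positions[which.max(after)], sign = 1)
  } else {
    list(es = lo, peak = positions[which.min(before)], sign = -1)
  }
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment: hit increments
#' `|r|^exponent` normalized by the set total, miss decrements `1/(N - NH)`;
#' ES is the signed maximum deviation. The null is built by gene-label
#' permutation (random sets of the same size), NES = ES divided by the mean
#' |null ES| of matching sign, and q is an empirical FDR over the pooled
#' signed null NES distributions (BH on nominal p available via
#' `fdr_method = "BH"`).
#'
#' @param ranked Named score vector (will be sorted via [ranked_list()]).
#' @param sets Named list of gene-id vectors (GMT-style).
#' @param n_perm Number of permutations (warning below 100).
#' @param weight_exponent Weighting exponent on |score| (default 1).
#' @param seed Integer seed for the permutation null.
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranked universe (defaults 10 and 500).
#' @param fdr_method `"empirical"` (signed null pools) or `"BH"`.
#' @return data.frame (set, size, es, nes, p, q, leading_edge) ordered by p;
#'   sets outside the size bounds or equal to the whole universe are skipped.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, weight_exponent = 1,
                           seed = 1L, min_size = 10L, max_size = 500L,
                           fdr_method = c("empirical", "BH")) {
  fdr_method <- match.arg(fdr_method)
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse permutation null")
  r <- ranked_list(ranked)
  N <- length(r)
  genes <- names(r)
  absw <- abs(r)^weight_exponent

  keep <- list()
  for (s in names(sets)) {
    members <- intersect(sets[[s]], genes)
    if (length(members) < min_size || length(members) > max_size ||
        length(members) >= N) next
    keep[[s]] <- match(members, genes)
  }
  if (!length(keep))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), q = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE))

  obs <- lapply(keep, function(pos) running_es(pos, absw[pos], N))
  sizes <- vapply(keep, length, 0L)

  with_seed(derive_seed(seed, "gsea"), {
    null_by_size <- list()
    for (k in unique(sizes)) {
      null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
        pos <- sample.int(N, k)
        running_es(pos, absw[pos], N)$es
      }, numeric(1))
    }

    res <- data.frame(set = names(keep), size = sizes, stringsAsFactors = FALSE)
    res$es <- vapply(obs, function(o) o$es, 0)
    nes <- numeric(nrow(res))
    pval <- numeric(nrow(res))
    null_nes_pool <- numeric(0)
    for (i in seq_len(nrow(res))) {
      nul <- null_by_size[[as.character(res$size[i])]]
      same <- nul[sign(nul) == sign(res$es[i])]
      denom <- mean(abs(same))
      nes[i] <- if (length(same) && denom > 0) res$es[i] / denom else NA_real_
      pval[i] <- if (length(same))
        (sum(abs(same) >= abs(res$es[i])) + 1) / (length(same) + 1) else 1
    }
    # pooled null NES for the empirical FDR (each null ES normalized by the
    # sign-matched mean of its own size's null)
    for (k in unique(sizes)) {
      nul <- null_by_size[[as.character(k)]]
      mp <- mean(abs(nul[nul >= 0]))
      mn <- mean(abs(nul[nul < 0]))
      nn <- ifelse(nul >= 0, nul / mp, nul / mn)
      null_nes_pool <- c(null_nes_pool, nn[is.finite(nn)])
    }
    res$nes <- nes
    res$p <- pval
    if (fdr_method == "BH") {
      res$q <- bh_adjust(res$p)
    } else {
      res$q <- vapply(seq_len(nrow(res)), function(i) {
        x <- res$nes[i]
        if (!is.finite(x)) return(NA_real_)
        if (x >= 0) {
          nul <- null_nes_pool[null_nes_pool >= 0]
          obs_nes <- res$nes[res$nes >= 0 & is.finite(res$nes)]
          num <- mean(nul >= x)
          den <- mean(obs_nes >= x)
        } else {
          nul <- null_nes_pool[null_nes_pool < 0]
          obs_nes <- res$nes[res$nes < 0 & is.finite(res$nes)]
          num <- mean(nul <= x)
          den <- mean(obs_nes <= x)
        }
        min(1, max(0, num / max(den, .Machine$double.eps)))
      }, numeric(1))
    }
    res$leading_edge <- vapply(seq_len(nrow(res)), function(i) {
      pos <- keep[[i]]
      o <- obs[[i]]
      le <- if (o$sign > 0) pos[pos <= o$peak] else pos[pos >= o$peak]
      paste(genes[sort(le)], collapse = ",")
    }, "")
    res[order(res$p, -abs(res$nes)), , drop = FALSE]
  })
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and a
#' gene set within a universe, with the 2x2 table and odds ratio.
#'
#' @param hits Character vector of hit gene ids (subset of `universe`).
#' @param set Character vector of set members (subset of `universe`).
#' @param universe Character vector of all testable genes.
#' @return list(table = 2x2 matrix, overlap, odds_ratio, p).
#' @export
ora_hypergeometric <- function(hits, set, universe) {
  if (!length(universe)) stop("empty universe")
  stopifnot(all(hits %in% universe), all(set %in% universe))
  hits <- unique(hits)
  set <- unique(set)
  N <- length(unique(universe))
  a <- length(intersect(hits, set))
  b <- length(hits) - a
  c_ <- length(set) - a
  d <- N - a - b - c_
  p <- stats::phyper(a - 1, length(set), N - length(set), length(hits),
                     lower.tail = FALSE)
  or <- (a * d) / max(b * c_, .Machine$double.eps)
  list(table = matrix(c(a, b, c_, d), 2, 2,
                      dimnames = list(c("in_set", "not_set"),
                                      c("hit", "not_hit"))),
       overlap = a, odds_ratio = or, p = p)
}

#' Over-representation across a gene-set collection
#'
#' Runs [ora_hypergeometric()] for every set and adjusts p-values by BH.
#'
#' @param hits Hit gene ids.
#' @param sets Named list of gene sets.
#' @param universe Universe gene ids.
#' @return data.frame (set, size, overlap, odds_ratio, p, fdr) ordered by p.
#' @export
ora_collection <- function(hits, sets, universe) {
  rows <- lapply(names(sets), function(s) {
    set <- intersect(sets[[s]], universe)
    r <- ora_hypergeometric(hits, set, universe)
    data.frame(set = s, size = length(set), overlap = r$overlap,
               odds_ratio = r$odds_ratio, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
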