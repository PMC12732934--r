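#' Relative cell-type proportions from marker genes
#'
#' For each cell type, takes the first principal component across samples of
#' the row-standardized marker submatrix, sign-aligned so the majority of
#' marker loadings are positive, then z-scores the estimates within the
#' dataset. Cell types with fewer than two markers present in the expression
#' matrix are skipped.
#'
#' @param expr [elist()] or matrix (genes x samples).
#' @param markers Named list of marker gene-id vectors per cell type.
#' @return Sample x cell-type matrix of z-scored relative proportions, with
#'   a `skipped` attribute naming any skipped cell types.
#' @export
estimate_rctp <- function(expr, markers) {
  E <- as_elist(expr)$E
  skipped <- character()
  cols <- list()
  for (ct in names(markers)) {
    present <- intersect(markers[[ct]], rownames(E))
    if (length(present) < 2L) {
      skipped <- c(skipped, ct)
      next
    }
    sub <- E[present, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2L) {
      skipped <- c(skipped, ct)
      next
    }
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 1, nv = 1)
    score <- sv$v[, 1L]
    if (mean(sv$u[, 1L] > 0) < 0.5) score <- -score
    cols[[ct]] <- as.numeric(scale(score))
  }
  if (!length(cols)) stop("no cell type had >= 2 usable markers")
  out <- do.call(cbind, cols)
  rownames(out) <- colnames(E)
  attr(out, "skipped") <- skipped
  out
}

#' Fisher's exact overlap test between a hit list and the marker union
#'
#' Two-sided exact test on the 2x2 membership table within the universe.
#'
#' @param dge_hits Gene ids called significant.
#' @param marker_union Union of all marker genes.
#' @param universe All testable gene ids.
#' @return list(table, overlap, odds_ratio, p); an empty hit list yields
#'   `p = 1` with a note attribute.
#' @export
overlap_test <- function(dge_hits, marker_union, universe) {
  stopifnot(all(dge_hits %in% universe), all(marker_union %in% universe))
  if (!length(dge_hits)) {
    out <- list(table = NULL, overlap = 0L, odds_ratio = NA_real_, p = 1)
    attr(out, "note") <- "empty hit list"
    return(out)
  }
  hits <- unique(dge_hits)
  set <- unique(marker_union)
  N <- length(unique(universe))
  a <- length(intersect(hits, set))
  tab <- matrix(c(a, length(hits) - a, length(set) - a,
                  N - length(hits) - length(set) + a), 2, 2,
                dimnames = list(c("marker", "non_marker"),
                                c("hit", "not_hit")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, overlap = a, odds_ratio = unname(ft$estimate),
       p = ft$p.value)
}

#' Correlate module eigengenes with cell-type proportions
#'
#' Pearson correlation between each module eigengene and each rCTP column,
#' BH-adjusted across the table; flags modules likely driven by cellular
#' composition.
#'
#' @param rctp Sample x cell-type matrix from [estimate_rctp()].
#' @param modules A merged `module_set` with eigengenes.
#' @param flag_r Absolute correlation above which a module-cell-type pair is
#'   flagged (default 0.5).
#' @return data.frame (module, cell_type, r, p, fdr, flagged).
#' @export
rctp_module_association <- function(rctp, modules, flag_r = 0.5) {
  stopifnot(inherits(modules, "module_set"), !is.null(modules$eigengenes))
  egs <- modules$eigengenes
  shared <- intersect(rownames(rctp), rownames(egs))
  if (!length(shared)) stop("no shared samples between rCTPs and eigengenes")
  rctp <- rctp[shared, , drop = FALSE]
  egs <- egs[shared, , drop = FALSE]
  n <- length(shared)
  grid <- expand.grid(module = colnames(egs), cell_type = colnames(rctp),
                      stringsAsFactors = FALSE)
  grid$r <- mapply(function(m, ct) stats::cor(egs[, m], rctp[, ct]),
                   grid$module, grid$cell_type)
  tstat <- grid$r * sqrt((n - 2) / (1 - grid$r^2))
  grid$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  grid$fdr <- bh_adjust(grid$p)
  grid$flagged <- abs(grid$r) > flag_r & grid$fdr < 0.05
  grid
}
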