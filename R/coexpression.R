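#' Network configuration
#'
#' @param power Soft power (integer >= 1) or `NULL` to select via
#'   [pick_soft_threshold()].
#' @param signed Signed adjacency `((1 + r) / 2)^power` (default) versus
#'   unsigned `|r|^power`.
#' @param r2_target Scale-free fit target (default 0.80).
#' @param min_module_size Minimum genes per module (default 30).
#' @param merge_height Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param cut_quantile Quantile of the dendrogram merge heights used for the
#'   static tree cut (default 0.99).
#' @return A `network_config` list.
#' @export
network_config <- function(power = NULL, signed = TRUE, r2_target = 0.80,
                           min_module_size = 30L, merge_height = 0.25,
                           cut_quantile = 0.99) {
  stopifnot(is.null(power) || power >= 1,
            r2_target > 0, r2_target <= 1,
            merge_height > 0, merge_height < 1,
            min_module_size >= 2, cut_quantile > 0, cut_quantile <= 1)
  structure(list(power = power, signed = signed, r2_target = r2_target,
                 min_module_size = as.integer(min_module_size),
                 merge_height = merge_height, cut_quantile = cut_quantile),
            class = "network_config")
}

#' Signed (or unsigned) soft-threshold adjacency
#'
#' @param expr [elist()] or matrix (genes x samples).
#' @param power Soft power.
#' @param signed Use the signed transform `((1 + r) / 2)^power`.
#' @return Gene x gene adjacency in `[0, 1]` with zero diagonal.
#' @export
adjacency_matrix <- function(expr, power, signed = TRUE) {
  E <- as_elist(expr)$E
  r <- stats::cor(t(E))
  a <- if (signed) ((1 + r) / 2)^power else abs(r)^power
  diag(a) <- 0
  a
}

scale_free_r2 <- function(k, n_breaks = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  cuts <- cut(k, breaks = n_breaks)
  freq <- tapply(k, cuts, length)
  kmean <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  x <- log10(kmean[ok])
  y <- log10(freq[ok] / sum(freq[ok]))
  if (length(x) < 3L) return(0)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  # signed fit: only a decreasing log-log relationship counts
  sign(-stats::coef(fit)[2L]) * r2
}

#' Choose the soft-thresholding power
#'
#' For each candidate power, builds the (signed) adjacency, computes per-gene
#' connectivity `k_i = sum_j a_ij`, and the signed scale-free fit R^2 from
#' regressing log10 binned connectivity frequency on log10 connectivity.
#' Returns the smallest power reaching `r2_target` (default 0.80); if none
#' does, the power with the best fit, with a warning.
#'
#' @param expr [elist()] or matrix (>= 50 genes).
#' @param candidate_powers Integer powers to scan (default 1:20).
#' @param config A [network_config()].
#' @return list(power, fit = data.frame(power, r2, mean_connectivity)).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20,
                                config = network_config()) {
  E <- as_elist(expr)$E
  if (nrow(E) < 50L) stop("need >= 50 genes to assess scale-free fit")
  r <- stats::cor(t(E))
  base <- if (config$signed) (1 + r) / 2 else abs(r)
  diag(base) <- NA
  fit <- data.frame(power = candidate_powers, r2 = NA_real_,
                    mean_connectivity = NA_real_)
  for (i in seq_along(candidate_powers)) {
    a <- base^candidate_powers[i]
    k <- rowSums(a, na.rm = TRUE)
    fit$r2[i] <- scale_free_r2(k)
    fit$mean_connectivity[i] <- mean(k)
  }
  hit <- which(fit$r2 >= config$r2_target)
  if (length(hit)) {
    power <- fit$power[hit[1L]]
  } else {
    power <- fit$power[which.max(fit$r2)]
    warning("no candidate power reached R^2 >= ", config$r2_target,
            "; returning the best-fit power ", power)
  }
  list(power = power, fit = fit)
}

#' Topological overlap matrix
#'
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; the clustering dissimilarity is `1 - tom`.
#'
#' @param adjacency Symmetric gene x gene matrix in `[0, 1]`, zero diagonal.
#' @return TOM matrix (same dimensions, diagonal 1).
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(a, tol = 1e-10)) stop("adjacency must be symmetric")
  stopifnot(all(a >= 0), all(a <= 1), all(diag(a) == 0))
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by average-linkage clustering
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' static height cut (default: the `cut_quantile` quantile of the merge
#' heights). Clusters smaller than `min_module_size` are assigned to the
#' unassigned `grey` label; remaining modules get size-ordered colour names.
#'
#' @param dissimilarity Square symmetric dissimilarity (usually `1 - TOM`).
#' @param config A [network_config()].
#' @param cut_height Optional explicit cut height overriding the quantile.
#' @return A `module_set` list: `labels` (named per-gene), `sizes`,
#'   `dendrogram` (hclust object); eigengenes are added by
#'   [merge_modules()] / [module_eigengene()].
#' @export
detect_modules <- function(dissimilarity, config = network_config(),
                           cut_height = NULL) {
  d <- as.matrix(dissimilarity)
  if (!isSymmetric(d, tol = 1e-8)) stop("dissimilarity must be symmetric")
  genes <- rownames(d)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(d)))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.null(cut_height))
    cut_height <- stats::quantile(hc$height, config$cut_quantile)
  raw <- stats::cutree(hc, h = cut_height)
  tab <- table(raw)
  big <- names(tab)[tab >= config$min_module_size]
  labels <- rep("grey", length(raw))
  if (length(big)) {
    # size-ordered colour labels, ties broken by cluster id for determinism
    ord <- big[order(-tab[big], as.integer(big))]
    palette <- module_palette(length(ord))
    for (i in seq_along(ord))
      labels[raw == as.integer(ord[i])] <- palette[i]
  } else {
    warning("no cluster reached min_module_size; all genes unassigned (grey)")
  }
  names(labels) <- genes
  structure(list(labels = labels, sizes = module_sizes(labels),
                 dendrogram = hc, cut_height = unname(cut_height)),
            class = "module_set")
}

module_palette <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("module%02d", seq_len(n - length(base))))
}

module_sizes <- function(labels) {
  tab <- table(labels[labels != "grey"])
  sort(tab, decreasing = TRUE)
}

#' Module eigengene
#'
#' First principal component across samples of the gene-standardized module
#' submatrix, sign-aligned so the average gene correlation with the
#' eigengene is positive, scaled to unit norm.
#'
#' @param expr [elist()] or matrix (genes x samples).
#' @param genes Gene ids of one module (>= 2).
#' @return list(eigengene = named sample vector (unit norm),
#'   var_explained).
#' @export
module_eigengene <- function(expr, genes) {
  E <- as_elist(expr)$E
  stopifnot(length(genes) >= 2, all(genes %in% rownames(E)))
  sub <- E[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (all(sds == 0)) stop("constant module submatrix")
  sub <- sub[sds > 0, , drop = FALSE]
  z <- t(scale(t(sub)))
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1L]
  if (mean(stats::cor(t(z), eg)) < 0) eg <- -eg
  names(eg) <- colnames(E)
  list(eigengene = eg, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

compute_eigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  egs <- lapply(mods, function(m)
    module_eigengene(expr, names(labels)[labels == m])$eigengene)
  if (!length(mods)) return(NULL)
  do.call(cbind, stats::setNames(egs, mods))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges module pairs whose eigengene dissimilarity
#' `1 - cor(eigengene_a, eigengene_b)` is below `merge_height` (default
#' 0.25), recomputing eigengenes after each pass until a fixpoint.
#'
#' @param modules A `module_set` from [detect_modules()].
#' @param expr The expression used to build the network.
#' @param merge_height Dissimilarity cutoff (default from the module set's
#'   config, 0.25).
#' @return The merged `module_set`, with `eigengenes` (samples x modules).
#' @export
merge_modules <- function(modules, expr, merge_height = 0.25) {
  stopifnot(inherits(modules, "module_set"))
  labels <- modules$labels
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    egs <- compute_eigengenes(expr, labels)
    dis <- 1 - stats::cor(egs)
    diag(dis) <- Inf
    idx <- which(dis == min(dis), arr.ind = TRUE)[1L, ]
    if (dis[idx[1L], idx[2L]] >= merge_height) break
    a <- colnames(egs)[idx[2L]]
    b <- colnames(egs)[idx[1L]]
    # absorb the smaller module into the larger
    na <- sum(labels == a)
    nb <- sum(labels == b)
    if (na >= nb) labels[labels == b] <- a else labels[labels == a] <- b
  }
  egs <- compute_eigengenes(expr, labels)
  structure(list(labels = labels, sizes = module_sizes(labels),
                 dendrogram = modules$dendrogram,
                 cut_height = modules$cut_height, eigengenes = egs),
            class = "module_set")
}

#' Full signed co-expression network pipeline
#'
#' Soft-threshold selection (unless `config$power` is set), signed
#' adjacency, TOM, static-cut module detection, eigengene merging.
#'
#' @param expr [elist()] or matrix.
#' @param config A [network_config()].
#' @param candidate_powers Powers scanned when `config$power` is `NULL`.
#' @return `module_set` with `power` and `soft_threshold_fit` attached.
#' @export
build_network <- function(expr, config = network_config(),
                          candidate_powers = 1:20) {
  if (is.null(config$power)) {
    st <- pick_soft_threshold(expr, candidate_powers, config)
    power <- st$power
    fit <- st$fit
  } else {
    power <- config$power
    fit <- NULL
  }
  a <- adjacency_matrix(expr, power, config$signed)
  tom <- topological_overlap(a)
  mods <- detect_modules(1 - tom, config)
  mods <- merge_modules(mods, expr, config$merge_height)
  mods$power <- power
  mods$soft_threshold_fit <- fit
  mods
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with each (numeric-coded)
#' trait, p-value via the t transform on `n - 2` degrees of freedom,
#' BH-adjusted across the whole table.
#'
#' @param modules A merged `module_set` with eigengenes.
#' @param metadata Sample metadata aligned with the eigengene rows.
#' @param traits Character vector of metadata columns; non-numeric columns
#'   are coded via `as.numeric(factor(...))`.
#' @return data.frame (module, trait, r, p, fdr).
#' @export
module_trait_correlation <- function(modules, metadata,
                                     traits = c("onset", "sex")) {
  stopifnot(inherits(modules, "module_set"), !is.null(modules$eigengenes))
  egs <- modules$eigengenes
  n <- nrow(egs)
  stopifnot(nrow(metadata) == n)
  rows <- list()
  for (tr in traits) {
    x <- metadata[[tr]]
    if (!is.numeric(x)) x <- as.numeric(factor(x))
    if (stats::sd(x) == 0) {
      rows[[tr]] <- data.frame(module = colnames(egs), trait = tr,
                               r = NA_real_, p = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    r <- as.numeric(stats::cor(egs, x))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    rows[[tr]] <- data.frame(module = colnames(egs), trait = tr, r = r, p = p,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  out
}
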