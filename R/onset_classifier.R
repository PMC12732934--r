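#' Dichotomize age of onset
#'
#' Early onset is defined as onset strictly below the cutoff (default 18
#' years, so 17.9 is early and 18.0 is late). Diagnosis-specific cutoffs
#' (e.g. <21 for BD, <18 for SCZ) are supported for sensitivity analyses.
#'
#' @param onset Numeric onset ages (years); `NA` propagates (callers exclude).
#' @param cutoff Single cutoff in years (default 18).
#' @param diagnosis Optional per-sample diagnosis labels; if given, `cutoff`
#'   must be a named vector with one cutoff per diagnosis level.
#' @return Integer vector: 1 = early onset, 0 = late onset.
#' @export
dichotomize_onset <- function(onset, cutoff = 18, diagnosis = NULL) {
  if (!is.null(diagnosis)) {
    stopifnot(!is.null(names(cutoff)), all(diagnosis %in% names(cutoff)))
    cutoff <- unname(cutoff[diagnosis])
  }
  as.integer(onset < cutoff)
}

# stratified k-fold assignment: per class, shuffle and deal round-robin so
# fold class counts differ by at most one
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Build a repeated stratified nested cross-validation plan
#'
#' Realizes the outer partitions: `outer_folds` stratified folds per repeat,
#' `outer_repeats` repeats under per-repeat seeds derived from `seed`. Inner
#' partitions are drawn later, on each outer-training set only, from the
#' recorded per-fold seeds.
#'
#' @param labels Binary labels (0/1) per sample.
#' @param outer_folds Outer folds (default 5).
#' @param outer_repeats Repeats (default 10).
#' @param inner_folds,inner_repeats Inner CV geometry (defaults 5 and 3).
#' @param seed Integer seed.
#' @return A `cv_plan`: fold assignment matrix (samples x repeats), geometry
#'   and seeds.
#' @export
build_cv_plan <- function(labels, outer_folds = 5L, outer_repeats = 10L,
                          inner_folds = 5L, inner_repeats = 3L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  counts <- table(factor(labels, levels = 0:1))
  if (any(counts < outer_folds))
    stop("each class needs >= ", outer_folds, " samples; have ",
         paste(counts, collapse = "/"))
  assign <- matrix(0L, nrow = length(labels), ncol = outer_repeats)
  for (r in seq_len(outer_repeats)) {
    assign[, r] <- with_seed(derive_seed(seed, paste0("outer", r)),
                             stratified_folds(labels, outer_folds))
  }
  structure(list(assignments = assign, labels = labels,
                 outer_folds = as.integer(outer_folds),
                 outer_repeats = as.integer(outer_repeats),
                 inner_folds = as.integer(inner_folds),
                 inner_repeats = as.integer(inner_repeats),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Default hyperparameter grids
#'
#' Lambda: 30 log-spaced values from the data-driven maximal lambda down to
#' 1e-3 of it (built per tuning set). C: 10 log-spaced values in
#' `[1e-3, 1e3]`; the ridge penalty used is `lambda = 1 / (n * C)`.
#'
#' @param n_lambda,lambda_min_ratio Lambda grid geometry.
#' @param c_grid Ridge-logistic C grid.
#' @return list(n_lambda, lambda_min_ratio, c_grid).
#' @export
tuning_grid <- function(n_lambda = 30L, lambda_min_ratio = 1e-3,
                        c_grid = 10^seq(-3, 3, length.out = 10)) {
  stopifnot(n_lambda >= 1, lambda_min_ratio > 0, all(c_grid > 0))
  list(n_lambda = as.integer(n_lambda), lambda_min_ratio = lambda_min_ratio,
       c_grid = c_grid)
}

lambda_sequence <- function(X, y, grid) {
  xs <- scale(X)
  xs[is.na(xs)] <- 0
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
  lmax <- max(lmax, 1e-6)
  exp(seq(log(lmax), log(lmax * grid$lambda_min_ratio),
          length.out = grid$n_lambda))
}

ridge_lambda <- function(C, n) 1 / (n * C)

#' Inner-loop hyperparameter tuning
#'
#' Executed strictly inside one outer-training set: lambda* minimizes the
#' repeated inner-CV mean squared error of the L1 regression on continuous
#' onset; C* maximizes the inner-CV AUC of the L2-logistic classifier refit
#' on the lambda*-selected features. Feature standardization is performed
#' inside each inner fit on its own training portion.
#'
#' @param X Sample x gene matrix (outer-training samples only).
#' @param onset Continuous onset for the same samples.
#' @param labels Binary early-onset labels for the same samples.
#' @param grid A [tuning_grid()].
#' @param inner_folds,inner_repeats Inner CV geometry.
#' @param seed Integer seed for the inner partitions.
#' @return list(lambda, C, selected, inner_auc, fallback).
#' @export
inner_tune <- function(X, onset, labels, grid = tuning_grid(),
                       inner_folds = 5L, inner_repeats = 3L, seed = 1L) {
  n <- nrow(X)
  lambdas <- lambda_sequence(X, onset, grid)
  mse <- matrix(NA_real_, inner_folds * inner_repeats, length(lambdas))
  row <- 0L
  folds <- with_seed(derive_seed(seed, "inner"), {
    lapply(seq_len(inner_repeats), function(r) stratified_folds(labels, inner_folds))
  })
  for (r in seq_len(inner_repeats)) {
    for (f in seq_len(inner_folds)) {
      row <- row + 1L
      tr <- folds[[r]] != f
      if (sum(tr) < 3L || sum(!tr) < 1L) next
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], onset[tr],
                            lambda = lambdas, standardize = TRUE)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE], s = lambdas)
      mse[row, ] <- colMeans((pred - onset[!tr])^2)
    }
  }
  lambda_star <- lambdas[which.min(colMeans(mse, na.rm = TRUE))]

  sel <- selected_features(X, onset, lambda_star)
  fallback <- FALSE
  if (!length(sel$features)) {
    # fall back to the smallest lambda with at least one selected feature
    path <- glmnet::glmnet(X, onset, lambda = lambdas, standardize = TRUE)
    nz <- path$df
    ok <- which(nz >= 1L)
    if (length(ok)) {
      lambda_star <- lambdas[max(ok)]
      sel <- selected_features(X, onset, lambda_star)
      fallback <- TRUE
    }
  }

  c_grid <- grid$c_grid
  auc <- matrix(NA_real_, inner_folds * inner_repeats, length(c_grid))
  if (length(sel$features) >= 1L) {
    Xs <- X[, sel$features, drop = FALSE]
    # glmnet needs >= 2 columns; pad a single selected feature with zeros
    if (ncol(Xs) == 1L) Xs <- cbind(Xs, `..dup..` = Xs[, 1L] * 0)
    rl <- sort(ridge_lambda(c_grid, n), decreasing = TRUE)
    ord <- order(ridge_lambda(c_grid, n), decreasing = TRUE)
    row <- 0L
    for (r in seq_len(inner_repeats)) {
      for (f in seq_len(inner_folds)) {
        row <- row + 1L
        tr <- folds[[r]] != f
        if (length(unique(labels[tr])) < 2L ||
            length(unique(labels[!tr])) < 2L) next
        fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], labels[tr],
                              family = "binomial", alpha = 0, lambda = rl,
                              standardize = TRUE)
        pred <- stats::predict(fit, Xs[!tr, , drop = FALSE], s = rl,
                               type = "response")
        auc[row, ord] <- apply(pred, 2L, auc_rank, labels = labels[!tr])
      }
    }
  }
  mean_auc <- colMeans(auc, na.rm = TRUE)
  c_star <- if (all(is.nan(mean_auc))) c_grid[1L] else
    c_grid[which.max(mean_auc)]
  list(lambda = lambda_star, C = c_star, selected = sel$features,
       inner_auc = suppressWarnings(max(mean_auc, na.rm = TRUE)),
       fallback = fallback)
}

selected_features <- function(X, onset, lambda) {
  fit <- glmnet::glmnet(X, onset, lambda = lambda, standardize = TRUE)
  cf <- as.matrix(stats::coef(fit))[-1L, 1L]
  list(features = names(cf)[cf != 0], fit = fit)
}

#' Fit the two-stage onset model
#'
#' Stage 1: L1-penalized linear regression of continuous onset on the gene
#' features at `lambda`; features with non-zero coefficients are retained.
#' Stage 2: L2-regularized logistic regression of the binary early-onset
#' label on the retained features (ridge penalty `1 / (n * C)`). With zero
#' retained features the model degenerates to an intercept-only classifier.
#'
#' @param X Sample x gene matrix (training samples only).
#' @param onset Continuous onset (training).
#' @param labels Binary labels (training).
#' @param lambda,C Hyperparameters (both > 0).
#' @return A `two_stage_model`: selected features, stage-2 fit (or the
#'   training prevalence for the degenerate case).
#' @export
fit_two_stage <- function(X, onset, labels, lambda, C) {
  stopifnot(lambda > 0, C > 0)
  sel <- selected_features(X, onset, lambda)$features
  if (!length(sel)) {
    model <- list(selected = character(), intercept_only = TRUE,
                  prevalence = mean(labels), lambda = lambda, C = C)
  } else {
    rl <- ridge_lambda(C, nrow(X))
    # glmnet needs >= 2 columns; duplicate a single selected feature
    Xs <- X[, sel, drop = FALSE]
    if (ncol(Xs) == 1L) Xs <- cbind(Xs, `..dup..` = Xs[, 1L] * 0)
    fit <- glmnet::glmnet(Xs, labels, family = "binomial", alpha = 0,
                          lambda = c(rl * 100, rl), standardize = TRUE)
    model <- list(selected = sel, intercept_only = FALSE, fit = fit,
                  ridge_lambda = rl, lambda = lambda, C = C)
  }
  structure(model, class = "two_stage_model")
}

#' Score and evaluate a fitted two-stage model on held-out samples
#'
#' @param model A `two_stage_model`.
#' @param X_test Sample x gene matrix of test samples (disjoint from
#'   training; the nested-CV driver audits this).
#' @param labels_test Binary labels.
#' @return list(auc, scores, roc = data.frame(fpr, tpr)); `auc` is `NA` when
#'   the test fold has a single class.
#' @export
evaluate_outer <- function(model, X_test, labels_test) {
  scores <- predict_two_stage(model, X_test)
  auc <- auc_rank(scores, labels_test)
  list(auc = auc, scores = scores, labels = labels_test,
       roc = roc_points(scores, labels_test))
}

predict_two_stage <- function(model, X) {
  if (model$intercept_only) return(rep(model$prevalence, nrow(X)))
  Xs <- X[, model$selected, drop = FALSE]
  if (ncol(Xs) == 1L) Xs <- cbind(Xs, `..dup..` = Xs[, 1L] * 0)
  as.numeric(stats::predict(model$fit, Xs, s = model$ridge_lambda,
                            type = "response"))
}

roc_points <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    return(data.frame(fpr = numeric(), tpr = numeric()))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / neg, 0)
  data.frame(fpr = fpr, tpr = tpr)
}

#' Repeated nested cross-validation of the two-stage onset classifier
#'
#' For every repeat and outer fold: tunes lambda and C by repeated inner CV
#' on the outer-training set only, refits the two-stage model on the full
#' outer-training set, and evaluates on the held-out fold. Records the full
#' fold ledger for the leakage audit.
#'
#' @param X Sample x gene expression matrix.
#' @param onset Continuous onset per sample.
#' @param plan A `cv_plan` built on `dichotomize_onset(onset)` labels.
#' @param grid A [tuning_grid()].
#' @return A `cv_report`: `folds` (per-fold data.frame), `mean_auc`,
#'   `stability` (per-gene selection frequency), `roc` (pooled points),
#'   `ledger` (per-fold train/test index sets), `plan`.
#' @export
nested_cv <- function(X, onset, plan, grid = tuning_grid()) {
  stopifnot(inherits(plan, "cv_plan"), nrow(X) == length(onset),
            length(plan$labels) == nrow(X))
  labels <- plan$labels
  folds <- list()
  ledger <- list()
  sel_count <- stats::setNames(numeric(ncol(X)), colnames(X))
  pooled_scores <- numeric()
  pooled_labels <- integer()
  i <- 0L
  for (r in seq_len(plan$outer_repeats)) {
    assign <- plan$assignments[, r]
    for (f in seq_len(plan$outer_folds)) {
      i <- i + 1L
      test <- which(assign == f)
      train <- which(assign != f)
      tune <- inner_tune(X[train, , drop = FALSE], onset[train],
                         labels[train], grid,
                         inner_folds = plan$inner_folds,
                         inner_repeats = plan$inner_repeats,
                         seed = derive_seed(plan$seed,
                                            paste0("tune", r, "_", f)))
      model <- fit_two_stage(X[train, , drop = FALSE], onset[train],
                             labels[train], tune$lambda, tune$C)
      ev <- evaluate_outer(model, X[test, , drop = FALSE], labels[test])
      sel_count[model$selected] <- sel_count[model$selected] + 1
      pooled_scores <- c(pooled_scores, ev$scores)
      pooled_labels <- c(pooled_labels, labels[test])
      folds[[i]] <- data.frame(repeat_ = r, fold = f, auc = ev$auc,
                               lambda = tune$lambda, C = tune$C,
                               n_selected = length(model$selected),
                               fallback = tune$fallback,
                               single_class_test = is.na(ev$auc))
      ledger[[i]] <- list(repeat_ = r, fold = f, train = train, test = test,
                          selected = model$selected)
    }
  }
  folds <- do.call(rbind, folds)
  n_folds <- nrow(folds)
  structure(list(folds = folds,
                 mean_auc = mean(folds$auc, na.rm = TRUE),
                 stability = sort(sel_count / n_folds, decreasing = TRUE),
                 roc = roc_points(pooled_scores, pooled_labels),
                 ledger = ledger, plan = plan),
            class = "cv_report")
}

#' Feature stability across outer folds
#'
#' @param report A `cv_report`.
#' @param top_k Size of the exported top list (default 50).
#' @return list(stability = data.frame(gene, frequency), always = genes
#'   selected in every fold, half = genes selected in >= 50% of folds,
#'   top = the `top_k` most frequently selected genes).
#' @export
feature_stability <- function(report, top_k = 50L) {
  stopifnot(inherits(report, "cv_report"))
  freq <- report$stability
  df <- data.frame(gene = names(freq), frequency = as.numeric(freq),
                   stringsAsFactors = FALSE)
  nonzero <- df[df$frequency > 0, , drop = FALSE]
  list(stability = df,
       always = df$gene[df$frequency >= 1],
       half = df$gene[df$frequency >= 0.5],
       top = utils::head(nonzero$gene, top_k))
}

#' Audit the nested CV for train/test leakage
#'
#' Programmatic check over the recorded fold ledger: within each repeat the
#' outer test folds partition the samples, and no test sample index appears
#' in the training (selection/tuning/standardization) set of its own fold.
#'
#' @param report A `cv_report`.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
audit_leakage <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  n <- length(report$plan$labels)
  for (r in seq_len(report$plan$outer_repeats)) {
    entries <- Filter(function(e) e$repeat_ == r, report$ledger)
    tests <- lapply(entries, `[[`, "test")
    covered <- sort(unlist(tests))
    if (!identical(covered, seq_len(n)))
      stop("repeat ", r, ": outer test folds do not partition the samples")
    for (e in entries) {
      if (length(intersect(e$train, e$test)))
        stop("repeat ", e$repeat_, " fold ", e$fold,
             ": test samples leaked into training")
    }
  }
  invisible(TRUE)
}
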