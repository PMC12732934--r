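#' Default end-to-end run configuration
#'
#' All thresholds of the pipeline in one place: expression filter CPM > 1 in
#' >= 50% of samples, RIN >= 6, GSEA q < 0.25, minimum module size 30,
#' module merge height 0.25, early-onset cutoff 18 years, meta-analysis FDR
#' 0.05. Every stochastic stage derives its seed from the global `seed`.
#'
#' @param seed Global integer seed.
#' @param n_samples,n_genes Synthetic cohort size (defaults 300 x 2000 for a
#'   desk-scale run).
#' @param out_dir Optional output directory for TSV artifacts.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, n_samples = 300L, n_genes = 2000L,
                               out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(enabled = TRUE, n_samples = as.integer(n_samples),
                    n_genes = as.integer(n_genes), onset_slope = -0.05),
    paths = list(counts = NULL, metadata = NULL, pathways = NULL,
                 markers = NULL),
    thresholds = list(cpm = 1, sample_fraction = 0.5, rin_min = 6,
                      dge_fdr = 0.05, gsea_q = 0.25, min_module_size = 30L,
                      merge_height = 0.25, onset_cutoff = 18,
                      meta_fdr = 0.05, r2_target = 0.80),
    stages = list(preprocess = TRUE, dge = TRUE, gsea = TRUE, network = TRUE,
                  bd_network = TRUE, deconv = TRUE, classify = TRUE,
                  meta = TRUE),
    use_weights_in_dge = TRUE,
    gsea = list(n_perm = 200L, min_size = 10L, max_size = 500L),
    cv = list(outer_folds = 5L, outer_repeats = 10L, inner_folds = 5L,
              inner_repeats = 3L),
    second_cohort = list(n_samples = 40L, noise_sd = 1.0, share_frac = 1.0,
                         effect_scale = 1.0)
  )
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  modifyList(cfg, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full onset-transcriptomics pipeline
#'
#' Executes simulate (or load) -> sample exclusion -> expression filtering ->
#' batch correction -> precision weights -> per-gene onset models (primary,
#' sex-stratified, interaction) -> GSEA -> signed co-expression network
#' (full cohort and BD-only) -> cell-type proportion checks -> nested-CV
#' early-onset classifier -> two-cohort meta-analysis, under one global
#' seed. Any stage failure aborts with the stage name; completed stage
#' outputs are preserved in the error's `partial` attribute.
#'
#' @param config Configuration from [default_run_config()] or
#'   [read_run_config()].
#' @return list of stage outputs plus a `manifest` recording seeds,
#'   thresholds, stage status and documented methodological deviations.
#' @export
run_pipeline <- function(config = default_run_config()) {
  out <- list()
  manifest <- list(seed = config$seed, thresholds = config$thresholds,
                   stages = list(),
                   deviations = c(
                     "batch adjustment is an empirical-Bayes location-scale model on log-CPM, not a count-level model",
                     "module detection uses a static dendrogram cut, not hybrid dynamic tree cut",
                     "over-representation analysis is an internal hypergeometric test, not an external web service"
                   ),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  stage <- function(name, enabled, fun) {
    if (!enabled) {
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      err <- simpleError(paste0("stage '", name, "' failed: ",
                                conditionMessage(e)))
      attr(err, "partial") <- out
      stop(err)
    })
    manifest$stages[[name]] <<- "done"
    res
  }

  # --- simulate or load ------------------------------------------------
  out$cohort <- stage("simulate", TRUE, function() {
    if (isTRUE(config$simulate$enabled)) {
      spec <- cohort_spec(n_samples = config$simulate$n_samples,
                          n_genes = config$simulate$n_genes,
                          seed = derive_seed(config$seed, "simulate"))
      plan <- effect_plan(spec$n_genes,
                          onset_slope = config$simulate$onset_slope)
      simulate_cohort(spec, plan)
    } else {
      counts <- read_counts_tsv(config$paths$counts)
      metadata <- read_metadata_tsv(config$paths$metadata)
      structure(list(counts = counts, metadata = metadata, plan = NULL,
                     truth = NULL,
                     marker_sets = if (!is.null(config$paths$markers))
                       read_gmt(config$paths$markers) else NULL,
                     pathway_sets = if (!is.null(config$paths$pathways))
                       read_gmt(config$paths$pathways) else NULL),
                class = "synthetic_cohort")
    }
  })
  cohort <- out$cohort

  # --- preprocess ------------------------------------------------------
  out$preprocess <- stage("preprocess", config$stages$preprocess, function() {
    ex <- exclude_samples(cohort$counts, cohort$metadata,
                          rin_min = config$thresholds$rin_min)
    counts <- filter_low_expression(ex$counts,
                                    cpm_threshold = config$thresholds$cpm,
                                    sample_fraction = config$thresholds$sample_fraction)
    meta <- ex$metadata
    design <- build_design(meta, "primary")
    vw <- voom_weights(counts, design)
    pca_pre <- pca_batch_check(vw$E, meta$batch)
    corrected <- correct_batch(vw$E, meta$batch, protect = design)
    pca_post <- pca_batch_check(corrected, meta$batch)
    expr <- elist(corrected,
                  if (isTRUE(config$use_weights_in_dge)) vw$weights else NULL)
    list(expr = expr, metadata = meta, design = design,
         n_genes_kept = attr(counts, "n_kept"),
         n_genes_dropped = attr(counts, "n_dropped"),
         n_excluded_rin = ex$n_excluded_rin,
         n_excluded_duplicates = ex$n_excluded_duplicates,
         vif = compute_vif(design), pca_pre = pca_pre, pca_post = pca_post)
  })
  pp <- out$preprocess
  expr <- pp$expr
  meta <- pp$metadata

  # --- differential expression ----------------------------------------
  out$dge <- stage("dge", config$stages$dge, function() {
    fit <- fit_gene_models(expr, pp$design)
    primary <- moderate_and_test(fit, "onset", model = "primary")
    female <- stratified_fit(expr, meta, "F")
    male <- stratified_fit(expr, meta, "M")
    ifit <- fit_gene_models(expr, build_design(meta, "interaction"))
    inter <- interaction_slopes(ifit,
                                fdr_threshold = config$thresholds$dge_fdr)
    list(primary = primary, female = female, male = male,
         interaction = inter$interaction, bd_slope = inter$bd_slope,
         n_interaction_significant = inter$n_significant,
         n_interaction_up = inter$n_up, n_interaction_down = inter$n_down)
  })

  # --- enrichment ------------------------------------------------------
  out$gsea <- stage("gsea", config$stages$gsea, function() {
    scores <- stats::setNames(out$dge$primary$t, out$dge$primary$gene)
    res <- gsea_preranked(scores, cohort$pathway_sets,
                          n_perm = config$gsea$n_perm,
                          seed = derive_seed(config$seed, "gsea"),
                          min_size = config$gsea$min_size,
                          max_size = config$gsea$max_size)
    res$significant <- res$q < config$thresholds$gsea_q
    res
  })

  # --- co-expression networks -----------------------------------------
  net_config <- network_config(min_module_size = config$thresholds$min_module_size,
                               merge_height = config$thresholds$merge_height,
                               r2_target = config$thresholds$r2_target)
  out$network <- stage("network", config$stages$network, function() {
    mods <- build_network(expr, net_config)
    traits <- module_trait_correlation(mods, meta, c("onset", "sex"))
    list(modules = mods, traits = traits)
  })
  out$bd_network <- stage("bd_network", config$stages$bd_network, function() {
    bd <- meta$diagnosis == "BD"
    sub <- elist(expr$E[, bd, drop = FALSE])
    mods <- build_network(sub, net_config)
    traits <- module_trait_correlation(mods, meta[bd, , drop = FALSE],
                                       c("onset", "sex"))
    list(modules = mods, traits = traits)
  })

  # --- cell-type proportions ------------------------------------------
  out$deconv <- stage("deconv", config$stages$deconv && !is.null(cohort$marker_sets),
                      function() {
    rctp <- estimate_rctp(expr, cohort$marker_sets)
    hits <- out$dge$primary$gene[out$dge$primary$fdr < config$thresholds$dge_fdr]
    ov <- overlap_test(hits, unique(unlist(cohort$marker_sets)),
                       rownames(expr$E))
    assoc <- if (!is.null(out$network))
      rctp_module_association(rctp, out$network$modules) else NULL
    sens <- rctp_sensitivity(expr, meta, rctp, hits)
    list(rctp = rctp, overlap = ov, module_association = assoc,
         sensitivity = sens)
  })

  # --- classifier ------------------------------------------------------
  out$classifier <- stage("classify", config$stages$classify, function() {
    labels <- dichotomize_onset(meta$onset, config$thresholds$onset_cutoff)
    keep <- !is.na(labels)
    plan <- build_cv_plan(labels[keep],
                          outer_folds = config$cv$outer_folds,
                          outer_repeats = config$cv$outer_repeats,
                          inner_folds = config$cv$inner_folds,
                          inner_repeats = config$cv$inner_repeats,
                          seed = derive_seed(config$seed, "cv"))
    report <- nested_cv(t(expr$E[, keep, drop = FALSE]), meta$onset[keep],
                        plan)
    audit_leakage(report)
    stab <- feature_stability(report)
    top_ora <- if (!is.null(cohort$pathway_sets) && length(stab$top))
      ora_collection(stab$top, cohort$pathway_sets, rownames(expr$E)) else NULL
    list(report = report, stability = stab, top_ora = top_ora)
  })

  # --- meta-analysis ---------------------------------------------------
  out$meta <- stage("meta", config$stages$meta && !is.null(cohort$plan),
                    function() {
    sc <- generate_second_cohort(cohort$plan,
                                 n_samples = config$second_cohort$n_samples,
                                 noise_sd = config$second_cohort$noise_sd,
                                 share_frac = config$second_cohort$share_frac,
                                 effect_scale = config$second_cohort$effect_scale,
                                 seed = derive_seed(config$seed, "cohort2"))
    tab2 <- second_cohort_dge(sc)
    # cohort 1 evidence: BD-specific onset slopes (the replication cohort is
    # all-BD), restricted to genes present in both
    tab1 <- out$dge$bd_slope
    mm <- meta_analyze(tab1, tab2, n1 = ncol(expr$E),
                       n2 = nrow(sc$metadata))
    hc <- high_confidence_set(mm, config$thresholds$meta_fdr)
    list(second_cohort = sc, table = mm, high_confidence = hc)
  })

  out$manifest <- manifest
  if (!is.null(config$out_dir)) out$manifest$files <- write_outputs(out, config$out_dir)
  out
}

#' Per-gene onset model for the array-like second cohort
#'
#' Ordinary least squares of log2 intensity on onset, sex, age at death and
#' PMI (the covariates available for the replication cohort), moderated
#' onset test.
#'
#' @param second A cohort from [generate_second_cohort()].
#' @return DGETable labelled `cohort2`.
#' @export
second_cohort_dge <- function(second) {
  m <- second$metadata
  X <- stats::model.matrix(~ onset + sex + age_death + pmi, m)
  colnames(X)[colnames(X) == "onset"] <- "onset"
  fit <- fit_gene_models(second$exprs, X)
  moderate_and_test(fit, "onset", model = "cohort2")
}

#' Sensitivity of DGE hits to cell-type proportion adjustment
#'
#' Refits the primary design with the rCTP columns appended and reports, for
#' each hit gene, the onset-slope attenuation; genes whose |slope| shrinks
#' by more than `attenuation_frac` are flagged as possibly
#' composition-driven. Reported only, never auto-applied.
#'
#' @param expr [elist()].
#' @param metadata Sample metadata.
#' @param rctp Sample x cell-type matrix from [estimate_rctp()].
#' @param hits Gene ids to check.
#' @param attenuation_frac Flagging threshold on 1 - |adjusted/base| (0.5).
#' @return data.frame (gene, slope_base, slope_adjusted, attenuation,
#'   flagged), or NULL if `hits` is empty.
#' @export
rctp_sensitivity <- function(expr, metadata, rctp, hits,
                             attenuation_frac = 0.5) {
  if (!length(hits)) return(NULL)
  el <- as_elist(expr)
  base_design <- build_design(metadata, "primary")
  adj_design <- cbind(base_design, rctp[metadata$sample_id, , drop = FALSE])
  sub <- elist(el$E[hits, , drop = FALSE],
               if (is.null(el$weights)) NULL else
                 el$weights[hits, , drop = FALSE])
  b0 <- fit_gene_models(sub, base_design)$coefficients[, "onset"]
  b1 <- fit_gene_models(sub, adj_design)$coefficients[, "onset"]
  att <- 1 - abs(b1) / pmax(abs(b0), .Machine$double.eps)
  data.frame(gene = hits, slope_base = b0, slope_adjusted = b1,
             attenuation = att, flagged = att > attenuation_frac,
             row.names = NULL, stringsAsFactors = FALSE)
}

write_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  if (!is.null(out$dge)) {
    for (nm in c("primary", "female", "male", "interaction", "bd_slope")) {
      tab <- out$dge[[nm]]
      tab$neg_log10_fdr <- -log10(pmax(tab$fdr, .Machine$double.xmin))
      put(tab, paste0("dge_", nm, ".tsv"))
    }
  }
  if (!is.null(out$gsea)) put(out$gsea, "gsea.tsv")
  if (!is.null(out$network)) {
    put(data.frame(gene = names(out$network$modules$labels),
                   module = out$network$modules$labels), "modules.tsv")
    put(out$network$traits, "module_traits.tsv")
  }
  if (!is.null(out$deconv)) {
    put(as.data.frame(out$deconv$rctp), "rctp.tsv")
    if (!is.null(out$deconv$sensitivity))
      put(out$deconv$sensitivity, "rctp_sensitivity.tsv")
  }
  if (!is.null(out$classifier)) {
    put(out$classifier$report$folds, "cv_folds.tsv")
    put(out$classifier$stability$stability, "cv_stability.tsv")
    put(out$classifier$report$roc, "cv_roc.tsv")
  }
  if (!is.null(out$meta)) {
    put(out$meta$table, "meta.tsv")
    put(data.frame(gene = out$meta$high_confidence), "meta_high_confidence.tsv")
  }
  data.frame(file = basename(paths), md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}
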