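#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the demographic margins of the 369-sample postmortem
#' DLPFC cohort the pipeline was designed around ([cmc_table1()]): 28.7% BD,
#' 48.2% female, onset 22.1 +/- 8.2 years truncated to [7, 48], age at death
#' 45.9 +/- 14.9, PMI 37.4 +/- 25.6 h, pH 6.4 +/- 0.4, RIN 7.7 +/- 0.8, and
#' three exchangeable batches.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param n_batches Number of batches (>= 1).
#' @param frac_bd Proportion with bipolar disorder (the rest schizophrenia).
#' @param frac_female Proportion female.
#' @param frac_white Proportion of white race (binary coding).
#' @param onset_mean,onset_sd,onset_min,onset_max Age-of-onset distribution
#'   (years, truncated normal).
#' @param death_mean,death_sd Age-at-death normal (years), floored at onset.
#' @param pmi_mean,pmi_sd Postmortem interval normal (hours), clipped > 0.
#' @param ph_mean,ph_sd Brain pH normal.
#' @param rin_mean,rin_sd RNA integrity number normal.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 369L, n_genes = 2000L, n_batches = 3L,
                        frac_bd = 106 / 369, frac_female = 178 / 369,
                        frac_white = 279 / 369,
                        onset_mean = 22.1, onset_sd = 8.2,
                        onset_min = 7, onset_max = 48,
                        death_mean = 45.9, death_sd = 14.9,
                        pmi_mean = 37.4, pmi_sd = 25.6,
                        ph_mean = 6.4, ph_sd = 0.4,
                        rin_mean = 7.7, rin_sd = 0.8,
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               n_batches = as.integer(n_batches), frac_bd = frac_bd,
               frac_female = frac_female, frac_white = frac_white,
               onset_mean = onset_mean, onset_sd = onset_sd,
               onset_min = onset_min, onset_max = onset_max,
               death_mean = death_mean, death_sd = death_sd,
               pmi_mean = pmi_mean, pmi_sd = pmi_sd,
               ph_mean = ph_mean, ph_sd = ph_sd,
               rin_mean = rin_mean, rin_sd = rin_sd,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(
    spec$n_samples >= 1, spec$n_genes >= 1, spec$n_batches >= 1,
    spec$frac_bd > 0, spec$frac_bd < 1,
    spec$frac_female >= 0, spec$frac_female <= 1,
    spec$onset_min < spec$onset_mean, spec$onset_mean < spec$onset_max,
    spec$onset_sd >= 0, spec$death_sd >= 0, spec$pmi_sd >= 0,
    spec$ph_sd >= 0, spec$rin_sd >= 0
  )
  invisible(spec)
}

gene_universe <- function(n_genes) sprintf("g%05d", seq_len(n_genes))

#' Planted effect structure for the synthetic cohort
#'
#' Every gene belongs to exactly one bookkeeping class: a planted
#' co-expression module (the first module also carries the onset effect),
#' sex-specific (female-only onset slope), interaction (BD-only onset
#' slope), or null. Slopes are in log2 expression units per year of onset.
#'
#' @param n_genes Size of the gene universe.
#' @param onset_slope Onset slope (log2/yr) for the onset module; the
#'   default -0.05 means expression drops by 0.05 log2 units per year of
#'   later onset (i.e. higher expression with earlier onset).
#' @param module_sizes Named integer vector of planted module sizes; the
#'   first module carries `onset_slope`, later modules are co-expressed but
#'   onset-null.
#' @param n_sex_specific Genes with a female-only onset slope (`onset_slope`).
#' @param n_interaction Genes with a BD-only onset slope (`onset_slope`);
#'   their SCZ slope is zero so the diagnosis-by-onset interaction equals
#'   `onset_slope`.
#' @param batch_shift Per-batch scale (log2) of gene-specific batch offsets;
#'   each gene draws its own direction, scaled by the batch's value.
#' @param module_factor_sd SD (log2) of the shared latent factor inducing
#'   within-module co-expression beyond the onset effect.
#' @param dispersion_median,dispersion_log_sd Log-normal spread of the
#'   negative-binomial dispersion across genes.
#' @return An `effect_plan` list with disjoint gene-id sets and `null_genes`
#'   holding the remainder.
#' @export
effect_plan <- function(n_genes = 2000L, onset_slope = -0.05,
                        module_sizes = c(onset_module = 40L, coexpr_module = 40L),
                        n_sex_specific = 30L, n_interaction = 30L,
                        batch_shift = c(0.5, 0, 0.5),
                        module_factor_sd = 0.4,
                        dispersion_median = 0.15, dispersion_log_sd = 0.4) {
  stopifnot(is.finite(onset_slope), all(module_sizes >= 0),
            n_sex_specific >= 0, n_interaction >= 0,
            all(is.finite(batch_shift)), module_factor_sd >= 0,
            dispersion_median > 0, dispersion_log_sd >= 0)
  genes <- gene_universe(n_genes)
  need <- sum(module_sizes) + n_sex_specific + n_interaction
  if (need > n_genes)
    stop("effect plan requires ", need, " genes but universe has ", n_genes)
  cursor <- 0L
  take <- function(k) {
    out <- genes[cursor + seq_len(k)]
    cursor <<- cursor + k
    out
  }
  module_genes <- lapply(module_sizes, take)
  names(module_genes) <- names(module_sizes)
  sex_specific <- take(n_sex_specific)
  interaction <- take(n_interaction)
  plan <- list(
    module_genes = module_genes,
    onset_slope = onset_slope,
    sex_specific_genes = sex_specific,
    interaction_genes = interaction,
    null_genes = genes[(cursor + 1L):n_genes],
    batch_shift = batch_shift,
    module_factor_sd = module_factor_sd,
    dispersion_median = dispersion_median,
    dispersion_log_sd = dispersion_log_sd,
    n_genes = as.integer(n_genes)
  )
  planted <- c(unlist(module_genes, use.names = FALSE), sex_specific, interaction)
  stopifnot(!anyDuplicated(planted))
  structure(plan, class = "effect_plan")
}

#' Truth table of an effect plan
#'
#' @param plan An [effect_plan()].
#' @return data.frame with one row per gene: class, module and slopes.
#' @export
truth_table <- function(plan) {
  genes <- gene_universe(plan$n_genes)
  cls <- rep("null", plan$n_genes)
  module <- rep(NA_character_, plan$n_genes)
  slope <- rep(0, plan$n_genes)
  for (m in names(plan$module_genes)) {
    idx <- match(plan$module_genes[[m]], genes)
    cls[idx] <- "module"
    module[idx] <- m
  }
  if (length(plan$module_genes))
    slope[match(plan$module_genes[[1L]], genes)] <- plan$onset_slope
  idx <- match(plan$sex_specific_genes, genes)
  cls[idx] <- "sex_specific"
  idx <- match(plan$interaction_genes, genes)
  cls[idx] <- "interaction"
  data.frame(gene = genes, class = cls, module = module,
             onset_slope = ifelse(cls == "module", slope, 0),
             female_onset_slope = ifelse(cls == "sex_specific",
                                         plan$onset_slope, 0),
             bd_onset_slope = ifelse(cls == "interaction",
                                     plan$onset_slope, 0),
             stringsAsFactors = FALSE)
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate per-sample metadata for a synthetic cohort
#'
#' Draws diagnosis, sex, race, age of onset (truncated normal), age at death
#' (floored at onset + 1 year), PMI, pH and RIN from the spec's margins, and
#' assigns batches round-robin over a random sample order (balanced sizes).
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with one row per sample.
#' @export
generate_metadata <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_samples
  if (n < 4L * spec$n_batches)
    stop("n_samples = ", n, " is below 4 per batch for ", spec$n_batches,
         " batches; strata would be degenerate")
  with_seed(derive_seed(spec$seed, "metadata"), {
    onset <- rtruncnorm1(n, spec$onset_mean, spec$onset_sd,
                         spec$onset_min, spec$onset_max)
    death <- stats::rnorm(n, spec$death_mean, spec$death_sd)
    death <- pmax(death, onset + 1)
    data.frame(
      sample_id = sprintf("s%04d", seq_len(n)),
      diagnosis = ifelse(stats::runif(n) < spec$frac_bd, "BD", "SCZ"),
      sex = ifelse(stats::runif(n) < spec$frac_female, "F", "M"),
      race = ifelse(stats::runif(n) < spec$frac_white, "white", "nonwhite"),
      onset = onset,
      age_death = death,
      pmi = pmax(stats::rnorm(n, spec$pmi_mean, spec$pmi_sd), 1),
      ph = stats::rnorm(n, spec$ph_mean, spec$ph_sd),
      rin = pmax(stats::rnorm(n, spec$rin_mean, spec$rin_sd), 1),
      batch = paste0("b", sample(rep_len(seq_len(spec$n_batches), n))),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate negative-binomial counts with planted effects
#'
#' Counts follow `count_gi ~ NB(mean = 2^(eta_gi) * lib_i / 1e6, size = 1/phi_g)`
#' where the log2 linear predictor `eta` holds the gene baseline (log2 CPM),
#' planted onset / sex-specific / interaction slopes on centred onset,
#' per-module shared latent factors, per-cell-type marker abundance factors,
#' and gene-specific batch offsets. Also attaches synthetic marker sets
#' (4 pseudo-cell-types x 20 markers from null genes) and a GMT-compatible
#' pathway collection containing every planted set plus random null sets.
#'
#' @param metadata Output of [generate_metadata()].
#' @param plan An [effect_plan()] over the same gene universe.
#' @param spec The [cohort_spec()] (supplies `n_genes` and `seed`).
#' @return A `synthetic_cohort` list: `counts` (integer gene x sample
#'   matrix), `metadata`, `plan`, `truth` (data.frame), `marker_sets`,
#'   `pathway_sets`, `cell_abundance` (latent truth for rCTP tests),
#'   `library_sizes`.
#' @export
generate_counts <- function(metadata, plan, spec) {
  stopifnot(inherits(plan, "effect_plan"), plan$n_genes == spec$n_genes)
  n <- nrow(metadata)
  G <- spec$n_genes
  genes <- gene_universe(G)
  batch_idx <- as.integer(factor(metadata$batch))
  if (max(batch_idx) > length(plan$batch_shift))
    stop("plan$batch_shift has fewer entries than batches present")
  with_seed(derive_seed(spec$seed, "counts"), {
    alpha <- stats::rnorm(G, mean = 4, sd = 1.5)          # baseline log2 CPM
    phi <- exp(stats::rnorm(G, log(plan$dispersion_median),
                            plan$dispersion_log_sd))
    libsize <- round(exp(stats::rnorm(n, log(1e6), 0.2)))
    onset_c <- metadata$onset - mean(metadata$onset)
    female <- as.numeric(metadata$sex == "F")
    bd <- as.numeric(metadata$diagnosis == "BD")

    eta <- matrix(alpha, nrow = G, ncol = n)
    # planted slopes (log2 per year)
    if (length(plan$module_genes)) {
      onset_mod <- match(plan$module_genes[[1L]], genes)
      eta[onset_mod, ] <- eta[onset_mod, ] +
        plan$onset_slope * rep(onset_c, each = length(onset_mod))
    }
    if (length(plan$sex_specific_genes)) {
      idx <- match(plan$sex_specific_genes, genes)
      eta[idx, ] <- eta[idx, ] +
        plan$onset_slope * rep(onset_c * female, each = length(idx))
    }
    if (length(plan$interaction_genes)) {
      idx <- match(plan$interaction_genes, genes)
      eta[idx, ] <- eta[idx, ] +
        plan$onset_slope * rep(onset_c * bd, each = length(idx))
    }
    # shared latent factor per module: co-expression beyond the onset slope
    for (m in names(plan$module_genes)) {
      idx <- match(plan$module_genes[[m]], genes)
      z <- stats::rnorm(n)
      eta[idx, ] <- eta[idx, ] +
        plan$module_factor_sd * rep(z, each = length(idx))
    }
    # pseudo-cell-type abundance factors on marker genes (from null genes)
    n_types <- 4L
    markers_per_type <- 20L
    null_pool <- plan$null_genes
    stopifnot(length(null_pool) >= n_types * markers_per_type)
    marker_sets <- list()
    cell_abundance <- matrix(stats::rnorm(n * n_types), nrow = n,
                             dimnames = list(metadata$sample_id,
                                             paste0("celltype", seq_len(n_types))))
    for (k in seq_len(n_types)) {
      mk <- null_pool[(k - 1L) * markers_per_type + seq_len(markers_per_type)]
      marker_sets[[paste0("celltype", k)]] <- mk
      idx <- match(mk, genes)
      eta[idx, ] <- eta[idx, ] + 0.5 * rep(cell_abundance[, k], each = length(idx))
    }
    # gene-specific batch offsets: each batch has its own random gene
    # direction, scaled by that batch's shift magnitude
    u <- matrix(stats::rnorm(G * length(plan$batch_shift)), nrow = G)
    eta <- eta + sweep(u, 2, plan$batch_shift, `*`)[, batch_idx]
    # independent biological noise on top of NB sampling noise
    eta <- eta + matrix(stats::rnorm(G * n, sd = 0.2), nrow = G)

    if (!all(is.finite(eta))) {
      bad <- which(!is.finite(eta), arr.ind = TRUE)[1L, ]
      stop("non-finite linear predictor for gene ", genes[bad[1L]],
           ", sample ", metadata$sample_id[bad[2L]])
    }
    mu <- 2^eta * rep(libsize / 1e6, each = G)
    counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / phi, n)),
                     nrow = G, dimnames = list(genes, metadata$sample_id))

    # pathway collection: planted sets + random null sets
    pathway_sets <- c(
      plan$module_genes,
      list(sex_specific_set = plan$sex_specific_genes,
           interaction_set = plan$interaction_genes)
    )
    marker_free_nulls <- setdiff(null_pool, unlist(marker_sets))
    for (r in seq_len(20L)) {
      pathway_sets[[sprintf("random_set_%02d", r)]] <-
        sample(marker_free_nulls, 30L)
    }

    structure(list(counts = counts, metadata = metadata, plan = plan,
                   truth = truth_table(plan), marker_sets = marker_sets,
                   pathway_sets = pathway_sets,
                   cell_abundance = cell_abundance,
                   gene_params = data.frame(gene = genes,
                                            baseline_log2_cpm = alpha,
                                            dispersion = phi,
                                            stringsAsFactors = FALSE),
                   target_library_sizes = libsize,
                   library_sizes = colSums(counts)),
              class = "synthetic_cohort")
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_metadata()] then [generate_counts()].
#'
#' @param spec A [cohort_spec()].
#' @param plan An [effect_plan()]; defaults to `effect_plan(spec$n_genes)`.
#' @return A `synthetic_cohort`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), plan = effect_plan(spec$n_genes)) {
  generate_counts(generate_metadata(spec), plan, spec)
}

#' Generate an array-like second cohort sharing planted onset effects
#'
#' Emulates a small external microarray validation cohort of bipolar
#' disorder samples: continuous log2 intensities, Gaussian noise, and a
#' configurable subset of the true BD onset effects (the onset module plus
#' the BD-specific interaction genes) reproduced at a scaled magnitude.
#'
#' @param plan An [effect_plan()] (the first cohort's truth).
#' @param n_samples Number of samples; the default 40 mirrors the combined
#'   external validation cohort size.
#' @param noise_sd Residual SD of log2 intensities.
#' @param share_frac Fraction of true-effect genes whose effect is shared.
#' @param effect_scale Multiplier on the shared slopes.
#' @param seed Integer seed.
#' @return A list with `exprs` (gene x sample log2 matrix), `metadata`,
#'   `shared_genes` and `true_slopes` (named per-gene slope vector).
#' @export
generate_second_cohort <- function(plan, n_samples = 40L, noise_sd = 1.0,
                                   share_frac = 1.0, effect_scale = 1.0,
                                   seed = 1L) {
  stopifnot(inherits(plan, "effect_plan"), noise_sd > 0,
            share_frac >= 0, share_frac <= 1)
  if (n_samples < 10L)
    warning("second cohort has n = ", n_samples,
            " (< 10); replication power will be negligible")
  genes <- gene_universe(plan$n_genes)
  with_seed(derive_seed(seed, "second_cohort"), {
    effect_genes <- c(if (length(plan$module_genes)) plan$module_genes[[1L]],
                      plan$interaction_genes)
    shared <- effect_genes[seq_len(floor(share_frac * length(effect_genes)))]
    slopes <- stats::setNames(rep(0, plan$n_genes), genes)
    slopes[shared] <- effect_scale * plan$onset_slope
    onset <- rtruncnorm1(n_samples, 22.1, 8.2, 7, 48)
    meta <- data.frame(
      sample_id = sprintf("a%03d", seq_len(n_samples)),
      diagnosis = "BD",
      sex = ifelse(stats::runif(n_samples) < 0.5, "F", "M"),
      onset = onset,
      age_death = pmax(stats::rnorm(n_samples, 45.9, 14.9), onset + 1),
      pmi = pmax(stats::rnorm(n_samples, 37.4, 25.6), 1),
      stringsAsFactors = FALSE
    )
    baseline <- stats::rnorm(plan$n_genes, 7, 1)
    onset_c <- onset - mean(onset)
    exprs <- baseline + outer(slopes, onset_c) +
      matrix(stats::rnorm(plan$n_genes * n_samples, sd = noise_sd),
             nrow = plan$n_genes)
    dimnames(exprs) <- list(genes, meta$sample_id)
    list(exprs = exprs, metadata = meta, shared_genes = shared,
         true_slopes = slopes)
  })
}
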