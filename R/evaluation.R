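#' Simulation studies: planted-truth evaluation of the screening pipeline
#'
#' These drivers run the pipeline end-to-end on synthetic data with planted
#' ground truth and measure recovery. They power the numbered analysis
#' scripts and the acceptance report.
#'
#' @name nfkbscreen-evaluation
NULL

#' Compound-knockdown pair count after cell-line filtering
#'
#' Builds a metadata table for a library of the given dimensions (every
#' perturbagen profiled in `n_cell_lines` cell lines), applies the coverage
#' filter, and returns the number of compound-KD pairs the feature stage
#' enumerates. At the full screening scale (1680 compounds x 3104 knockdowns
#' surviving the >= 4-cell-line filter) this is 5,214,720.
#'
#' @param n_compounds,n_knockdowns Library dimensions.
#' @param n_cell_lines Cell lines each perturbagen is profiled in.
#' @param min_cell_lines Coverage filter.
#' @return Integer pair count.
#' @export
#' @examples
#' full_scale_pair_count(1680, 3104)
full_scale_pair_count <- function(n_compounds = 1680L, n_knockdowns = 3104L,
                                  n_cell_lines = 4L, min_cell_lines = 4L) {
  meta <- rbind(
    expand.grid(perturbagen_id = sprintf("CPD%04d", seq_len(n_compounds)),
                pert_type = "compound",
                cell_line = sprintf("CL%d", seq_len(n_cell_lines)),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    expand.grid(perturbagen_id = sprintf("G%05d", seq_len(n_knockdowns)),
                pert_type = "knockdown",
                cell_line = sprintf("CL%d", seq_len(n_cell_lines)),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  retained_perturbagens(meta, min_cell_lines)$n_pairs
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical or 0/1 true labels (both classes required).
#' @return AUROC in \[0, 1\]; ties handled by midranks.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  n_pos <- sum(y)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * sum(!y))
}

# standard simulated screen: 30 planted inhibitors among 60 compounds,
# 40-gene KD panel over a module-structured interactome
screen_config <- function(seed, effect_size = 4, noise_sd = 1) {
  targets <- stats::setNames(sprintf("G%04d", 1:30), sprintf("CPD%03d", 1:30))
  signature_sim_config(n_genes = 300, n_compounds = 60, n_knockdowns = 40,
                       n_cell_lines = 4, n_modules = 20,
                       planted_targets = targets, effect_size = effect_size,
                       noise_sd = noise_sd, seed = seed)
}

#' Held-out classifier recovery on a planted synthetic screen
#'
#' Simulates a signature library with planted compound-target pairs, builds
#' connectivity features over a module-structured interactome, trains the
#' random-forest classifier on half the compounds, and scores the held-out
#' half against the planted truth.
#'
#' @param seed Integer master seed.
#' @param effect_size,noise_sd Signal-to-noise of the planted perturbations.
#' @param n_trees Forest size.
#' @return List: `auroc` (held-out), `n_pairs` scored held-out pairs,
#'   `predictions` (scored held-out table joined to the truth).
#' @export
evaluate_classifier_recovery <- function(seed = 1L, effect_size = 4,
                                         noise_sd = 1, n_trees = 500L) {
  cfg <- screen_config(derive_seed(seed, 1), effect_size, noise_sd)
  sim <- simulate_signature_library(cfg)
  ids <- signature_sim_ids(cfg)
  net <- simulate_network(cfg$n_genes, edge_prob = 0.02,
                          pathway_module = split(ids$genes, ids$module),
                          intra_module_prob = 0.8,
                          seed = derive_seed(seed, 2))
  ft <- build_feature_table(sim$library, net,
                            pathway_gene_set("module1", ids$genes[ids$module == 1]),
                            min_cell_lines = 4)

  train_cpds <- sprintf("CPD%03d", c(1:20, 31:50))     # 20 planted + 20 decoys
  test_cpds <- setdiff(ids$compounds, train_cpds)
  gt <- sim$ground_truth
  set.seed(derive_seed(seed, 3))
  labels <- do.call(rbind, lapply(train_cpds, function(cpd) {
    g <- gt[gt$compound_id == cpd, ]
    pos <- g[g$planted, c("compound_id", "kd_gene")]
    neg <- g[!g$planted, c("compound_id", "kd_gene")]
    rbind(if (nrow(pos)) cbind(pos, label = 1),
          cbind(neg[sample(nrow(neg), 4), ], label = 0))
  }))
  names(labels)[names(labels) == "kd_gene"] <- "target_gene"

  model <- train_interaction_classifier(
    ft, labels, classifier_config(n_trees = n_trees, seed = derive_seed(seed, 4)))
  pred <- predict_interaction_probability(
    model, ft[ft$compound_id %in% test_cpds, ])
  scored <- merge(pred, gt, by = c("compound_id", "kd_gene"))
  list(auroc = auroc(scored$probability, scored$planted),
       n_pairs = nrow(scored), predictions = scored)
}

#' Planted-inhibitor recovery by mean pathway-correlation ranking
#'
#' Replicated simulation: in each replicate, 5 planted inhibitors of the
#' pathway module sit among 60 compounds; a replicate succeeds when every
#' planted compound ranks in the top decile of
#' [rank_by_mean_pathway_correlation()].
#'
#' @param n_replicates Number of independent replicates.
#' @param seed Integer master seed.
#' @param effect_size,noise_sd Signal-to-noise of the planted perturbations.
#' @return List: `successes`, `n_replicates`, `top_decile_rate`, and the
#'   per-replicate worst planted rank `worst_rank`.
#' @export
evaluate_ranking_recovery <- function(n_replicates = 20L, seed = 1L,
                                      effect_size = 4, noise_sd = 1) {
  worst <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    pathway_kd <- c("G0001", "G0011")   # the module-1 members of the KD panel
    targets <- stats::setNames(pathway_kd[(0:4 %% 2) + 1], sprintf("CPD%03d", 1:5))
    cfg <- signature_sim_config(n_genes = 200, n_compounds = 60,
                                n_knockdowns = 20, n_cell_lines = 4,
                                n_modules = 10, planted_targets = targets,
                                effect_size = effect_size, noise_sd = noise_sd,
                                seed = derive_seed(seed, r))
    lib <- simulate_signature_library(cfg)$library
    rk <- rank_by_mean_pathway_correlation(lib, pathway_kds = pathway_kd)
    worst[r] <- max(rk$rank[rk$compound_id %in% names(targets)])
  }
  decile <- ceiling(0.1 * 60)
  list(successes = sum(worst <= decile), n_replicates = n_replicates,
       top_decile_rate = mean(worst <= decile), worst_rank = worst)
}

#' Type-I error calibration of the permutation test
#'
#' Simulates null datasets (both groups from the same normal distribution)
#' and measures the rejection rate of the two-tailed Monte-Carlo permutation
#' test at level `alpha`.
#'
#' @param n_sims Number of null datasets.
#' @param n_permutations Permutations per test.
#' @param n_per_group Observations per group.
#' @param alpha Nominal level.
#' @param seed Integer master seed.
#' @return List: `rejection_rate`, `n_sims`, `alpha`, and the binomial
#'   standard error `se` of the rate under the nominal level.
#' @export
evaluate_type_i_error <- function(n_sims = 1000L, n_permutations = 1e4,
                                  n_per_group = 15L, alpha = 0.05, seed = 1L) {
  set.seed(derive_seed(seed, 101))
  x <- matrix(stats::rnorm(n_sims * n_per_group), ncol = n_sims)
  y <- matrix(stats::rnorm(n_sims * n_per_group), ncol = n_sims)
  rej <- vapply(seq_len(n_sims), function(i) {
    permutation_test(x[, i], y[, i], n_permutations = n_permutations,
                     seed = derive_seed(seed, 200L + i))$p_value <= alpha
  }, logical(1))
  list(rejection_rate = mean(rej), n_sims = n_sims, alpha = alpha,
       se = sqrt(alpha * (1 - alpha) / n_sims))
}

#' Monte-Carlo vs exhaustive permutation-test agreement
#'
#' On small two-group datasets (pooled size <= 12) compares the Monte-Carlo
#' p value against the exhaustive enumeration oracle, in units of the
#' binomial standard error of the Monte-Carlo estimate.
#'
#' @param n_datasets Number of random datasets.
#' @param n_permutations Monte-Carlo permutations per dataset.
#' @param seed Integer master seed.
#' @return List: `max_dev_se` (worst |p_mc - p_exact| / SE), `max_abs_dev`,
#'   `n_datasets`.
#' @export
evaluate_mc_vs_exact <- function(n_datasets = 10L, n_permutations = 1e5,
                                 seed = 1L) {
  set.seed(derive_seed(seed, 301))
  dev_se <- abs_dev <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    x <- stats::rnorm(6); y <- stats::rnorm(6) + stats::runif(1, 0, 1.5)
    ex <- exhaustive_permutation_test(x, y)$p_value
    mc <- permutation_test(x, y, n_permutations = n_permutations,
                           seed = derive_seed(seed, 400L + i))$p_value
    se <- sqrt(max(ex * (1 - ex), 1 / n_permutations) / n_permutations)
    abs_dev[i] <- abs(mc - ex)
    dev_se[i] <- abs_dev[i] / se
  }
  list(max_dev_se = max(dev_se), max_abs_dev = max(abs_dev),
       n_datasets = n_datasets)
}

#' Descriptor closed-form check on a noiseless pulse
#'
#' Simulates one noiseless, jitter-free pulse at the generator defaults and
#' compares the measured descriptors against the model's closed forms:
#' Max = 1 + A, t_max = t0 + tau_r, AUC = A e tau_r.
#'
#' @param amplitude,rise_time,stimulus_time,duration Pulse parameters
#'   (defaults: the generator's study conditions, 5-min frames, window
#'   > 10 rise times).
#' @return List: measured `max_fc`, `t_max`, `auc`, plus `auc_expected` and
#'   the signed relative error `auc_rel_error`.
#' @export
evaluate_descriptor_closed_forms <- function(amplitude = 2, rise_time = 30,
                                             stimulus_time = 30,
                                             duration = 360) {
  tr <- simulate_traces(trace_sim_config(
    n_cells = 1, amplitude = amplitude, rise_time = rise_time,
    stimulus_time = stimulus_time, duration = duration, noise_sd = 0,
    amp_jitter_sdlog = 0, tau_jitter_sdlog = 0, baseline_jitter_sdlog = 0,
    seed = 1))
  d <- descriptor_table(tr, stimulus_times = stimulus_time)
  auc <- descriptor_values(d, "TNF", "auc")
  expected <- amplitude * exp(1) * rise_time
  list(max_fc = descriptor_values(d, "TNF", "max_fc"),
       t_max = descriptor_values(d, "TNF", "t_max"),
       auc = auc, auc_expected = expected,
       auc_rel_error = auc / expected - 1)
}

#' Tm recovery on replicated noisy melt curves
#'
#' Simulates sigmoidal melt curves with Gaussian noise at a fraction of the
#' fluorescence amplitude and measures the worst-case absolute Tm error of
#' the Boltzmann-fit estimator across replicates (true Tm varies over the
#' physiological 45-65 degC range).
#'
#' @param n_replicates Number of curves.
#' @param noise_frac Noise SD as a fraction of `f_max - f_min`.
#' @param seed Integer master seed.
#' @param method Tm estimator passed to [estimate_tm()] (fit mode is the
#'   estimator intended for noisy curves).
#' @return List: `max_abs_error_C`, `mean_abs_error_C`, `n_replicates`.
#' @export
evaluate_tm_recovery <- function(n_replicates = 50L, noise_frac = 0.02,
                                 seed = 1L, method = "fit") {
  set.seed(derive_seed(seed, 501))
  tms <- stats::runif(n_replicates, 45, 65)
  errs <- vapply(seq_len(n_replicates), function(i) {
    cfg <- melt_sim_config(tm_true = tms[i], k = 2, f_min = 2000, f_max = 30000,
                           noise_sd = noise_frac * 28000,
                           seed = derive_seed(seed, 600L + i))
    est <- estimate_tm(normalize_melt(simulate_melt_curve(cfg)), method = method)
    as.numeric(est) - tms[i]
  }, numeric(1))
  list(max_abs_error_C = max(abs(errs)), mean_abs_error_C = mean(abs(errs)),
       n_replicates = n_replicates)
}
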