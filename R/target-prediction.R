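FEATURE_COLUMNS <- c("direct_corr", "indirect_corr", "baseline_activity",
                     "max_pathway_de", "mean_pathway_de")

#' Classifier configuration
#'
#' Hyperparameters for the compound-target interaction random forest. The
#' forest size and cell-line aggregation rule are deliberately explicit
#' config knobs.
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Variables tried per split; `NULL` for the randomForest default.
#' @param aggregate How per-cell-line feature rows are reduced to one row per
#'   (compound, KD) pair: `"mean"`, `"median"`, or `"max"`.
#' @param seed Integer seed for training.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_trees = 500L, mtry = NULL,
                              aggregate = c("mean", "median", "max"),
                              seed = 1L) {
  aggregate <- match.arg(aggregate)
  stop_if_not_scalar_number(n_trees, "n_trees", lower = 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 aggregate = aggregate, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Aggregate per-cell-line feature rows to one row per compound-KD pair
#'
#' @param features Feature table from [build_feature_table()].
#' @param method `"mean"`, `"median"`, or `"max"`; applied per feature with
#'   `NA` removal (a pair whose feature is missing in every cell line stays
#'   `NA`).
#' @return Data frame with one row per (compound_id, kd_gene).
#' @export
aggregate_pair_features <- function(features, method = c("mean", "median", "max")) {
  method <- match.arg(method)
  check_feature_schema(features)
  f <- switch(method,
              mean = function(x) mean(x, na.rm = TRUE),
              median = function(x) stats::median(x, na.rm = TRUE),
              max = function(x) max(x, na.rm = TRUE))
  safe_f <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else f(x)
  }
  key <- interaction(features$compound_id, features$kd_gene, drop = TRUE, sep = "\r")
  agg <- lapply(features[FEATURE_COLUMNS],
                function(col) tapply(col, key, safe_f))
  ids <- strsplit(names(agg[[1]]), "\r", fixed = TRUE)
  out <- data.frame(compound_id = vapply(ids, `[`, "", 1L),
                    kd_gene = vapply(ids, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  for (nm in FEATURE_COLUMNS) out[[nm]] <- as.numeric(agg[[nm]])
  out <- out[order(out$compound_id, out$kd_gene), ]
  rownames(out) <- NULL
  out
}

check_feature_schema <- function(features) {
  missing <- setdiff(c("compound_id", "kd_gene", FEATURE_COLUMNS), names(features))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(features)
}

#' Train the compound-target interaction classifier
#'
#' Fits a random forest to the five connectivity features of labeled
#' (compound, target-gene) pairs, to predict whether a compound inhibits a
#' knocked-down protein's interaction network.
#'
#' @param features Feature table from [build_feature_table()] (per cell line;
#'   rows are aggregated per the config before training).
#' @param labels Data frame with columns `compound_id`, `target_gene`, and
#'   logical/0-1 `label`; every labeled pair must have feature rows.
#' @param config A [classifier_config()].
#' @return An `interaction_classifier`: list with the fitted `model`, the
#'   `config`, and the training-feature medians used to fill missing values.
#' @export
train_interaction_classifier <- function(features, labels,
                                         config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  check_feature_schema(features)
  req <- c("compound_id", "target_gene", "label")
  if (!all(req %in% names(labels)))
    stop("`labels` must have columns compound_id, target_gene, label", call. = FALSE)
  y_raw <- as.integer(labels$label)
  if (!all(y_raw %in% c(0L, 1L)))
    stop("`label` must be logical or 0/1", call. = FALSE)
  if (length(unique(y_raw)) < 2L)
    stop("training labels contain a single class; need both positives and negatives",
         call. = FALSE)
  pair_key <- paste(labels$compound_id, labels$target_gene, sep = "\r")
  if (anyDuplicated(pair_key))
    stop("duplicate (compound_id, target_gene) rows in `labels`", call. = FALSE)

  agg <- aggregate_pair_features(features, config$aggregate)
  idx <- match(pair_key, paste(agg$compound_id, agg$kd_gene, sep = "\r"))
  if (anyNA(idx)) {
    orphans <- paste(labels$compound_id[is.na(idx)], labels$target_gene[is.na(idx)],
                     sep = "/")
    stop("labeled pairs without feature rows: ",
         paste(utils::head(orphans, 10L), collapse = ", "),
         if (length(orphans) > 10L) sprintf(" (+%d more)", length(orphans) - 10L),
         call. = FALSE)
  }
  x <- agg[idx, FEATURE_COLUMNS, drop = FALSE]
  na_fill <- vapply(x, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  na_fill[is.na(na_fill)] <- 0
  for (nm in FEATURE_COLUMNS) x[[nm]][is.na(x[[nm]])] <- na_fill[[nm]]

  set.seed(config$seed)
  mtry <- config$mtry %||% max(1L, floor(sqrt(length(FEATURE_COLUMNS))))
  model <- randomForest::randomForest(
    x = x, y = factor(y_raw, levels = c(0L, 1L)),
    ntree = config$n_trees, mtry = mtry)
  structure(list(model = model, config = config,
                 feature_names = FEATURE_COLUMNS, na_fill = na_fill),
            class = "interaction_classifier")
}

#' @export
print.interaction_classifier <- function(x, ...) {
  cat(sprintf("interaction_classifier: random forest, %d trees, aggregation = %s\n",
              x$config$n_trees, x$config$aggregate))
  invisible(x)
}

#' Predict compound-target interaction probabilities
#'
#' @param model An [train_interaction_classifier()] fit.
#' @param features Feature table with the training schema (per cell line;
#'   aggregated per the model's config before scoring).
#' @return Data frame `compound_id`, `kd_gene`, `probability` — one row per
#'   pair, probability in \[0, 1\].
#' @export
predict_interaction_probability <- function(model, features) {
  stopifnot(inherits(model, "interaction_classifier"))
  check_feature_schema(features)
  agg <- aggregate_pair_features(features, model$config$aggregate)
  x <- agg[model$feature_names]
  for (nm in model$feature_names) x[[nm]][is.na(x[[nm]])] <- model$na_fill[[nm]]
  prob <- stats::predict(model$model, newdata = x, type = "prob")[, "1"]
  data.frame(compound_id = agg$compound_id, kd_gene = agg$kd_gene,
             probability = as.numeric(prob), stringsAsFactors = FALSE)
}

#' Top-k predicted targets per compound
#'
#' @param predictions Output of [predict_interaction_probability()].
#' @param k Number of targets to keep per compound (default 100). Ties are
#'   broken by lexicographic gene id for reproducibility.
#' @return Data frame `compound_id`, `kd_gene`, `probability`, `rank`,
#'   `truncated` (TRUE when the compound had fewer than `k` scored genes, so
#'   all were returned).
#' @export
top_predicted_targets <- function(predictions, k = 100L) {
  stopifnot(all(c("compound_id", "kd_gene", "probability") %in% names(predictions)))
  stop_if_not_scalar_number(k, "k", lower = 1)
  parts <- split(predictions, predictions$compound_id)
  out <- lapply(parts, function(p) {
    p <- p[order(-p$probability, p$kd_gene), , drop = FALSE]
    n_keep <- min(nrow(p), k)
    p <- p[seq_len(n_keep), , drop = FALSE]
    p$rank <- seq_len(n_keep)
    p$truncated <- nrow(p) < k
    p
  })
  out <- do.call(rbind, out[sort(names(out))])
  rownames(out) <- NULL
  out
}

#' Hypergeometric enrichment of predicted targets in a pathway
#'
#' Upper-tail hypergeometric probability of observing at least the measured
#' overlap between a compound's predicted target list and a pathway gene
#' set, drawing `|top_targets|` genes from the universe.
#'
#' @param top_targets Character vector of predicted target gene ids (a
#'   subset of `universe`).
#' @param pathway A [pathway_gene_set()] or character vector; must be a
#'   subset of `universe`.
#' @param universe Character vector: all scoreable genes.
#' @return `P(X >= overlap)` from the hypergeometric null.
#' @export
#' @examples
#' pathway_target_enrichment(paste0("g", 1:4), paste0("g", 1:5), paste0("g", 1:10))
pathway_target_enrichment <- function(top_targets, pathway, universe) {
  pathway <- as_pathway_gene_set(pathway)
  top_targets <- unique(top_targets)
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  if (!length(top_targets)) stop("empty target list", call. = FALSE)
  if (length(setdiff(top_targets, universe)))
    stop("top_targets contains genes outside the universe", call. = FALSE)
  if (length(setdiff(pathway$genes, universe)))
    stop(sprintf("pathway '%s' contains genes outside the universe", pathway$name),
         call. = FALSE)
  n_univ <- length(universe)
  n_path <- length(pathway$genes)
  n_draw <- length(top_targets)
  overlap <- length(intersect(top_targets, pathway$genes))
  stats::phyper(overlap - 1L, n_path, n_univ - n_path, n_draw, lower.tail = FALSE)
}

#' Filter compounds by correlation with seed-gene knockdowns
#'
#' Keeps compounds whose mean direct correlation with each seed gene's
#' knockdown signatures (averaged over shared cell lines) reaches `r_min` —
#' the initial screen against knockdowns of the receptor-proximal adaptors.
#'
#' @param library A [signature_library()].
#' @param compounds Compound ids to screen; default all compounds.
#' @param seed_genes Gene ids whose knockdowns anchor the filter; each must
#'   have at least one KD signature in the library.
#' @param r_min Correlation threshold.
#' @param mode `"all"` (every seed gene must pass; default) or `"any"`.
#' @return Character vector of passing compound ids, with the per-seed mean
#'   correlation matrix attached as attribute `"mean_correlations"`
#'   (compounds x seed genes; `NA` when no shared cell line — treated as a
#'   fail).
#' @export
seed_gene_filter <- function(library, compounds = NULL, seed_genes,
                             r_min = 0.3, mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "signature_library"), length(seed_genes) >= 1)
  compounds <- compounds %||% perturbagens(library, "compound")
  kd_ids <- unique(library$meta$perturbagen_id[library$meta$pert_type == "knockdown"])
  missing_seed <- setdiff(seed_genes, kd_ids)
  if (length(missing_seed))
    stop("seed gene(s) without knockdown signatures: ",
         paste(missing_seed, collapse = ", "), call. = FALSE)

  m <- matrix(NA_real_, nrow = length(compounds), ncol = length(seed_genes),
              dimnames = list(compounds, seed_genes))
  for (cl in cell_lines(library)) {
    zc <- signature_matrix(library, cl, "compound")
    zc <- zc[, intersect(colnames(zc), compounds), drop = FALSE]
    zk <- signature_matrix(library, cl, "knockdown")
    zk <- zk[, intersect(colnames(zk), seed_genes), drop = FALSE]
    if (!ncol(zc) || !ncol(zk)) next
    r <- stats::cor(zc, zk)
    for (g in colnames(zk)) {
      cur <- m[colnames(zc), g]
      # running mean across cell lines: accumulate then divide at the end
      m[colnames(zc), g] <- ifelse(is.na(cur), r[, g], cur + r[, g])
    }
  }
  # convert accumulated sums to means over shared cell lines
  n_shared <- matrix(0L, nrow = length(compounds), ncol = length(seed_genes),
                     dimnames = dimnames(m))
  for (cl in cell_lines(library)) {
    cc <- intersect(library$meta$perturbagen_id[library$meta$pert_type == "compound" &
                                                  library$meta$cell_line == cl], compounds)
    gg <- intersect(library$meta$perturbagen_id[library$meta$pert_type == "knockdown" &
                                                  library$meta$cell_line == cl], seed_genes)
    n_shared[cc, gg] <- n_shared[cc, gg] + 1L
  }
  m <- ifelse(n_shared > 0L, m / n_shared, NA_real_)

  pass_mat <- !is.na(m) & m >= r_min
  pass <- if (mode == "all") apply(pass_mat, 1, all) else apply(pass_mat, 1, any)
  out <- compounds[pass]
  attr(out, "mean_correlations") <- m
  out
}

#' Rank candidate compounds by mean pathway-KD correlation
#'
#' For each compound, averages its direct Pearson correlation with every
#' available pathway knockdown signature across shared cell lines, and ranks
#' compounds in descending order (ties broken by lexicographic compound id;
#' compounds with no shared cell line are flagged and placed last).
#'
#' @param library A [signature_library()].
#' @param compounds Compound ids to rank; default all compounds.
#' @param pathway_kds Gene ids of pathway knockdowns; each must have at least
#'   one KD signature.
#' @return Data frame `compound_id`, `mean_pathway_corr`, `n_correlations`,
#'   `no_shared_cell_line`, `rank` — sorted by rank.
#' @export
rank_by_mean_pathway_correlation <- function(library, compounds = NULL, pathway_kds) {
  stopifnot(inherits(library, "signature_library"), length(pathway_kds) >= 1)
  compounds <- compounds %||% perturbagens(library, "compound")
  kd_ids <- unique(library$meta$perturbagen_id[library$meta$pert_type == "knockdown"])
  missing_kd <- setdiff(pathway_kds, kd_ids)
  if (length(missing_kd))
    stop("pathway KD gene(s) without knockdown signatures: ",
         paste(missing_kd, collapse = ", "), call. = FALSE)

  sums <- stats::setNames(numeric(length(compounds)), compounds)
  ns <- stats::setNames(integer(length(compounds)), compounds)
  for (cl in cell_lines(library)) {
    zc <- signature_matrix(library, cl, "compound")
    zc <- zc[, intersect(colnames(zc), compounds), drop = FALSE]
    zk <- signature_matrix(library, cl, "knockdown")
    zk <- zk[, intersect(colnames(zk), pathway_kds), drop = FALSE]
    if (!ncol(zc) || !ncol(zk)) next
    r <- stats::cor(zc, zk)
    sums[colnames(zc)] <- sums[colnames(zc)] + rowSums(r)
    ns[colnames(zc)] <- ns[colnames(zc)] + ncol(zk)
  }
  mean_r <- ifelse(ns > 0L, sums / ns, NA_real_)
  out <- data.frame(compound_id = compounds,
                    mean_pathway_corr = as.numeric(mean_r),
                    n_correlations = as.integer(ns),
                    no_shared_cell_line = ns == 0L,
                    stringsAsFactors = FALSE)
  ord <- order(out$no_shared_cell_line, -ifelse(is.na(out$mean_pathway_corr),
                                                -Inf, out$mean_pathway_corr),
               out$compound_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
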