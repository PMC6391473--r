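#' Pathway gene set
#'
#' @param name Set name (e.g. a pathway identifier).
#' @param genes Character vector of gene ids.
#' @return An object of class `pathway_gene_set`.
#' @export
pathway_gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, is.character(genes))
  structure(list(name = name, genes = unique(genes)), class = "pathway_gene_set")
}

as_pathway_gene_set <- function(x) {
  if (inherits(x, "pathway_gene_set")) return(x)
  if (is.character(x)) return(pathway_gene_set("pathway", x))
  stop("expected a pathway_gene_set or a character vector of gene ids", call. = FALSE)
}

sig_zscores <- function(x) {
  if (inherits(x, "expression_signature")) return(x$zscores)
  if (is.numeric(x)) return(x)
  stop("expected an expression_signature or a numeric vector", call. = FALSE)
}

#' Direct correlation between two signatures
#'
#' Pearson correlation between two differential-expression signatures over
#' the full gene universe — the primary connectivity measure between a
#' compound treatment and a gene knockdown in one cell line.
#'
#' @param sig_a,sig_b `expression_signature` objects or plain numeric vectors
#'   over the same gene universe.
#' @return Pearson r in \[-1, 1\].
#' @export
#' @examples
#' direct_correlation(c(1, 2, 3, 4), c(1, 2, 2, 5))
direct_correlation <- function(sig_a, sig_b) {
  za <- sig_zscores(sig_a); zb <- sig_zscores(sig_b)
  if (length(za) != length(zb))
    stop("signatures have different gene-universe sizes", call. = FALSE)
  if (!is.null(names(za)) && !is.null(names(zb)) && !identical(names(za), names(zb)))
    stop("signatures are indexed by different gene universes", call. = FALSE)
  if (stats::sd(za) == 0 || stats::sd(zb) == 0)
    stop("correlation undefined: zero-variance signature", call. = FALSE)
  stats::cor(za, zb)
}

#' Indirect correlation over network partners
#'
#' The fraction of a knockdown gene's interaction partners whose own
#' knockdown signatures (in the compound's cell line) are highly correlated
#' with the compound signature. Partners without an available knockdown
#' signature in that cell line are excluded from the denominator; if no
#' partner is observable the value is missing (`NA`), never 0.
#'
#' @param compound_sig An `expression_signature` for a compound.
#' @param kd_gene Knockdown gene id.
#' @param network An igraph interaction network with named nodes.
#' @param library The [signature_library()] supplying partner KD signatures.
#' @param r_threshold Correlation cutoff defining "highly correlated"
#'   (default 0.3); must lie in (-1, 1).
#' @return Fraction in \[0, 1\], or `NA_real_` when no partner has a KD
#'   signature in the cell line.
#' @export
indirect_correlation <- function(compound_sig, kd_gene, network, library,
                                 r_threshold = 0.3) {
  stopifnot(inherits(compound_sig, "expression_signature"),
            inherits(library, "signature_library"))
  if (r_threshold <= -1 || r_threshold >= 1)
    stop("`r_threshold` must be in (-1, 1)", call. = FALSE)
  partners <- network_partners(network, kd_gene)
  if (!length(partners)) return(NA_real_)
  kd_meta <- library$meta[library$meta$pert_type == "knockdown" &
                            library$meta$cell_line == compound_sig$cell_line, ]
  avail <- intersect(partners, kd_meta$perturbagen_id)
  if (!length(avail)) return(NA_real_)
  r <- vapply(avail, function(p) {
    direct_correlation(compound_sig, get_signature(library, p, compound_sig$cell_line))
  }, numeric(1))
  sum(r >= r_threshold) / length(avail)
}

#' Baseline activity of a compound signature
#'
#' Overall signature strength: the mean absolute z-score over the gene
#' universe. A transcriptionally inert compound scores near 0.
#'
#' @param compound_sig An `expression_signature` or numeric vector.
#' @return Non-negative scalar.
#' @export
baseline_activity <- function(compound_sig) {
  mean(abs(sig_zscores(compound_sig)))
}

#' Maximum and mean differential expression of pathway genes
#'
#' @param compound_sig An `expression_signature` (named z-scores).
#' @param pathway A [pathway_gene_set()] or character vector of gene ids;
#'   must intersect the signature's gene universe.
#' @return Named numeric vector `c(max_pathway_de, mean_pathway_de)`: max and
#'   mean |z| over the pathway genes present in the universe.
#' @export
pathway_de_features <- function(compound_sig, pathway) {
  pathway <- as_pathway_gene_set(pathway)
  z <- sig_zscores(compound_sig)
  if (is.null(names(z)))
    stop("signature z-scores must be named by gene id", call. = FALSE)
  genes <- intersect(pathway$genes, names(z))
  if (!length(genes))
    stop(sprintf("pathway '%s' shares no genes with the signature's gene universe",
                 pathway$name), call. = FALSE)
  a <- abs(z[genes])
  c(max_pathway_de = max(a), mean_pathway_de = mean(a))
}

#' Perturbagens surviving the cell-line coverage filter
#'
#' Restricts a signature-library metadata table to compounds and knockdowns
#' profiled in at least `min_cell_lines` distinct cell lines — mirroring the
#' requirement that perturbagens be assayed in at least 4 of the most common
#' cell lines.
#'
#' @param meta Data frame with columns `perturbagen_id`, `pert_type`,
#'   `cell_line` (a [signature_library()]'s `$meta`, or metadata alone).
#' @param min_cell_lines Minimum number of distinct cell lines.
#' @return List with character vectors `compounds` and `knockdowns` (sorted)
#'   and `n_pairs = length(compounds) * length(knockdowns)`, the number of
#'   compound-KD pairs the feature stage will enumerate.
#' @export
retained_perturbagens <- function(meta, min_cell_lines = 4L) {
  stopifnot(is.data.frame(meta),
            all(c("perturbagen_id", "pert_type", "cell_line") %in% names(meta)))
  stop_if_not_scalar_number(min_cell_lines, "min_cell_lines", lower = 1)
  counts <- stats::aggregate(cell_line ~ perturbagen_id + pert_type,
                             data = unique(meta[c("perturbagen_id", "pert_type", "cell_line")]),
                             FUN = length)
  keep <- counts[counts$cell_line >= min_cell_lines, ]
  compounds <- sort(keep$perturbagen_id[keep$pert_type == "compound"])
  knockdowns <- sort(keep$perturbagen_id[keep$pert_type == "knockdown"])
  list(compounds = compounds, knockdowns = knockdowns,
       n_pairs = length(compounds) * length(knockdowns))
}

#' Connectivity feature table for all compound-knockdown pairs
#'
#' For every retained compound, retained knockdown, and cell line shared by
#' the two, computes the five connectivity features: direct Pearson
#' correlation, indirect correlation over network partners, baseline
#' activity, and the maximum and mean pathway differential expression of the
#' compound signature.
#'
#' @param library A [signature_library()].
#' @param network An igraph interaction network with named nodes.
#' @param pathway A [pathway_gene_set()] or character vector of pathway genes.
#' @param min_cell_lines Cell-line coverage filter applied to both compounds
#'   and knockdowns (default 4).
#' @param r_threshold "Highly correlated" cutoff for the indirect feature.
#' @return Data frame with columns `compound_id`, `kd_gene`, `cell_line`,
#'   `direct_corr`, `indirect_corr`, `baseline_activity`, `max_pathway_de`,
#'   `mean_pathway_de`; one row per (compound, KD, shared cell line).
#'   `indirect_corr` is `NA` when the KD gene has no observable partner.
#'   Warns and returns an empty table when nothing survives the filter.
#' @export
build_feature_table <- function(library, network, pathway,
                                min_cell_lines = 4L, r_threshold = 0.3) {
  stopifnot(inherits(library, "signature_library"))
  pathway <- as_pathway_gene_set(pathway)
  if (!length(intersect(pathway$genes, library$gene_universe)))
    stop(sprintf("pathway '%s' shares no genes with the library gene universe",
                 pathway$name), call. = FALSE)
  retained <- retained_perturbagens(library$meta, min_cell_lines)
  empty <- data.frame(compound_id = character(0), kd_gene = character(0),
                      cell_line = character(0), direct_corr = numeric(0),
                      indirect_corr = numeric(0), baseline_activity = numeric(0),
                      max_pathway_de = numeric(0), mean_pathway_de = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(retained$compounds) || !length(retained$knockdowns)) {
    warning("no compound-KD pair survives the cell-line coverage filter")
    return(empty)
  }
  path_genes <- intersect(pathway$genes, library$gene_universe)
  partner_sets <- lapply(stats::setNames(retained$knockdowns, retained$knockdowns),
                         function(g) network_partners(network, g))

  rows <- list()
  for (cl in cell_lines(library)) {
    zc <- signature_matrix(library, cl, "compound")
    zc <- zc[, intersect(colnames(zc), retained$compounds), drop = FALSE]
    zk_all <- signature_matrix(library, cl, "knockdown")  # all KDs: partner pool
    zk <- zk_all[, intersect(colnames(zk_all), retained$knockdowns), drop = FALSE]
    if (!ncol(zc) || !ncol(zk)) next

    direct <- stats::cor(zc, zk)                       # compounds x retained KDs
    partner_corr <- stats::cor(zc, zk_all)             # compounds x all KDs in cl
    base_act <- colMeans(abs(zc))
    max_de <- apply(abs(zc[path_genes, , drop = FALSE]), 2, max)
    mean_de <- colMeans(abs(zc[path_genes, , drop = FALSE]))

    indirect <- matrix(NA_real_, nrow = ncol(zc), ncol = ncol(zk),
                       dimnames = list(colnames(zc), colnames(zk)))
    for (g in colnames(zk)) {
      avail <- intersect(partner_sets[[g]], colnames(zk_all))
      if (length(avail))
        indirect[, g] <- rowMeans(partner_corr[, avail, drop = FALSE] >= r_threshold)
    }

    grid <- expand.grid(compound_id = colnames(zc), kd_gene = colnames(zk),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows[[cl]] <- data.frame(
      grid, cell_line = cl,
      direct_corr = direct[cbind(grid$compound_id, grid$kd_gene)],
      indirect_corr = indirect[cbind(grid$compound_id, grid$kd_gene)],
      baseline_activity = base_act[grid$compound_id],
      max_pathway_de = max_de[grid$compound_id],
      mean_pathway_de = mean_de[grid$compound_id],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no compound-KD pair shares a cell line")
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
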