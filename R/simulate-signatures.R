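#' Configuration for the synthetic signature-library generator
#'
#' The generator emulates a landmark-gene perturbation library: z-score
#' signatures for compound treatments and gene knockdowns across several cell
#' lines, with a planted, recoverable compound-target structure. Signatures
#' are low-rank: genes belong to latent modules, each module has one dense
#' loading vector over the whole gene universe, and a perturbation of a gene
#' expresses its module's loading plus i.i.d. Gaussian noise. A compound with
#' planted target t therefore correlates (in expectation) with the knockdown
#' signatures of t and of t's module co-members; decoy compounds are pure
#' noise.
#'
#' Genes are assigned to modules round-robin (gene i belongs to module
#' ((i-1) mod n_modules) + 1), so the assignment is transparent and the
#' knockdown panel (the first `n_knockdowns` genes) covers modules evenly.
#'
#' @param n_genes Signature length; default 978 to mirror the landmark-gene
#'   space.
#' @param n_compounds,n_knockdowns,n_cell_lines Library dimensions; knockdown
#'   signatures exist for the first `n_knockdowns` genes of the universe.
#' @param n_modules Number of latent gene modules.
#' @param planted_targets Named character vector mapping compound ids to
#'   target gene ids (must be knockdown genes); unnamed compounds are decoys.
#'   `NULL` for an all-decoy (null) library.
#' @param effect_size Z-score scale of the planted perturbation signal
#'   (default 3; strong perturbation signatures in landmark z-score space).
#' @param noise_sd Per-gene Gaussian noise SD (default 1, the z-score unit).
#' @param seed Integer seed.
#' @return A `signature_sim_config` list.
#' @export
signature_sim_config <- function(n_genes = 978L, n_compounds = 50L,
                                 n_knockdowns = 40L, n_cell_lines = 4L,
                                 n_modules = 20L, planted_targets = NULL,
                                 effect_size = 3, noise_sd = 1, seed = 1L) {
  for (nm in c("n_genes", "n_compounds", "n_knockdowns", "n_cell_lines", "n_modules"))
    stop_if_not_scalar_number(get(nm), nm, lower = 1)
  stop_if_not_scalar_number(effect_size, "effect_size", lower = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (n_knockdowns > n_genes)
    stop("`n_knockdowns` cannot exceed `n_genes`", call. = FALSE)
  if (!is.null(planted_targets)) {
    if (is.null(names(planted_targets)) || any(names(planted_targets) == ""))
      stop("`planted_targets` must be a named character vector (names = compound ids)",
           call. = FALSE)
    if (anyDuplicated(names(planted_targets)))
      stop("duplicate compound ids in `planted_targets`", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_compounds = as.integer(n_compounds),
         n_knockdowns = as.integer(n_knockdowns),
         n_cell_lines = as.integer(n_cell_lines),
         n_modules = as.integer(n_modules),
         planted_targets = planted_targets,
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "signature_sim_config"
  )
}

#' Gene, compound and cell-line ids used by the signature generator
#' @param config A [signature_sim_config()].
#' @return List with `genes`, `kd_genes`, `compounds`, `cells`, and the
#'   integer `module` assignment of each gene.
#' @export
signature_sim_ids <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  list(genes = genes,
       kd_genes = genes[seq_len(config$n_knockdowns)],
       compounds = sprintf("CPD%03d", seq_len(config$n_compounds)),
       cells = sprintf("CL%d", seq_len(config$n_cell_lines)),
       module = ((seq_len(config$n_genes) - 1L) %% config$n_modules) + 1L)
}

#' Simulate a perturbation signature library with planted targets
#'
#' Builds knockdown and compound z-score signatures per
#' [signature_sim_config()]: KD of gene g gives
#' `effect_size * loading[module(g)] + noise`; a compound with planted target
#' t gives `effect_size * loading[module(t)] + noise`; decoy compounds are
#' `noise` alone. Noise is drawn independently per signature and cell line.
#'
#' @param config A [signature_sim_config()].
#' @return List with `library` (a [signature_library()]) and `ground_truth`,
#'   a data frame over all (compound, kd gene) pairs with logical columns
#'   `planted` (the pair is a planted compound-target association) and
#'   `same_module` (the kd gene shares the latent module of the compound's
#'   target — the guilt-by-association confound).
#' @export
#' @examples
#' cfg <- signature_sim_config(n_genes = 60, n_compounds = 6, n_knockdowns = 10,
#'                             n_cell_lines = 2, n_modules = 5,
#'                             planted_targets = c(CPD001 = "G0003"), seed = 7)
#' sim <- simulate_signature_library(cfg)
#' sim$library
simulate_signature_library <- function(config) {
  stopifnot(inherits(config, "signature_sim_config"))
  ids <- signature_sim_ids(config)
  targets <- config$planted_targets
  if (!is.null(targets)) {
    bad_cpd <- setdiff(names(targets), ids$compounds)
    if (length(bad_cpd))
      stop("planted_targets name unknown compounds: ",
           paste(bad_cpd, collapse = ", "), call. = FALSE)
    bad_gene <- setdiff(targets, ids$kd_genes)
    if (length(bad_gene))
      stop("planted_targets reference genes without knockdowns: ",
           paste(bad_gene, collapse = ", "), call. = FALSE)
  }

  set.seed(config$seed)
  loadings <- matrix(stats::rnorm(config$n_genes * config$n_modules),
                     nrow = config$n_genes, ncol = config$n_modules)

  n_sig_per_cell <- config$n_knockdowns + config$n_compounds
  z <- matrix(0, nrow = config$n_genes, ncol = n_sig_per_cell * config$n_cell_lines)
  rownames(z) <- ids$genes
  pert_id <- character(ncol(z)); pert_type <- character(ncol(z)); cell <- character(ncol(z))

  col <- 0L
  for (cl in ids$cells) {
    for (g in ids$kd_genes) {
      col <- col + 1L
      m <- ids$module[match(g, ids$genes)]
      z[, col] <- config$effect_size * loadings[, m] +
        stats::rnorm(config$n_genes, sd = config$noise_sd)
      pert_id[col] <- g; pert_type[col] <- "knockdown"; cell[col] <- cl
    }
    for (cpd in ids$compounds) {
      col <- col + 1L
      tgt <- if (!is.null(targets)) unname(targets[cpd]) else NA_character_
      if (!is.na(tgt)) {
        m <- ids$module[match(tgt, ids$genes)]
        z[, col] <- config$effect_size * loadings[, m] +
          stats::rnorm(config$n_genes, sd = config$noise_sd)
      } else {
        z[, col] <- stats::rnorm(config$n_genes, sd = config$noise_sd)
      }
      pert_id[col] <- cpd; pert_type[col] <- "compound"; cell[col] <- cl
    }
  }

  lib <- signature_library(z, data.frame(perturbagen_id = pert_id,
                                         pert_type = pert_type,
                                         cell_line = cell,
                                         stringsAsFactors = FALSE))

  gt <- expand.grid(compound_id = ids$compounds, kd_gene = ids$kd_genes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tgt_of <- if (!is.null(targets)) targets[gt$compound_id] else rep(NA_character_, nrow(gt))
  gt$planted <- !is.na(tgt_of) & gt$kd_gene == unname(tgt_of)
  mod_of_kd <- ids$module[match(gt$kd_gene, ids$genes)]
  mod_of_tgt <- ids$module[match(unname(tgt_of), ids$genes)]
  gt$same_module <- !is.na(mod_of_tgt) & mod_of_kd == mod_of_tgt
  list(library = lib, ground_truth = gt)
}

#' Simulate an undirected interaction network with a dense pathway module
#'
#' A planted-partition random graph standing in for a protein-interaction
#' network: node pairs inside `pathway_module` are connected with probability
#' `intra_module_prob`, all other pairs with `edge_prob`. Undirected, simple,
#' no self-loops. `pathway_module` may also be a list of disjoint node sets,
#' in which case every within-set pair is densely wired — useful for graphs
#' whose community structure mirrors the latent gene modules of
#' [simulate_signature_library()].
#'
#' @param n_nodes Number of nodes (ignored when `node_ids` is given).
#' @param edge_prob Background edge probability in \[0,1\].
#' @param pathway_module Character vector of node ids forming the dense
#'   module, or a list of disjoint such vectors.
#' @param intra_module_prob Edge probability within the module.
#' @param seed Integer seed.
#' @param node_ids Optional node id vector; defaults to `G0001..`, matching
#'   [signature_sim_ids()].
#' @return An [igraph::graph] with node names.
#' @export
#' @examples
#' g <- simulate_network(20, 0.05, pathway_module = sprintf("G%04d", 1:5),
#'                       intra_module_prob = 0.9, seed = 3)
#' igraph::ecount(g)
simulate_network <- function(n_nodes, edge_prob, pathway_module = character(),
                             intra_module_prob = edge_prob, seed = 1L,
                             node_ids = NULL) {
  stop_if_not_scalar_number(edge_prob, "edge_prob", 0, 1)
  stop_if_not_scalar_number(intra_module_prob, "intra_module_prob", 0, 1)
  ids <- node_ids %||% sprintf("G%04d", seq_len(n_nodes))
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  modules <- if (is.list(pathway_module)) pathway_module else list(pathway_module)
  all_mod <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_mod))
    stop("pathway modules must be disjoint", call. = FALSE)
  unknown <- setdiff(all_mod, ids)
  if (length(unknown))
    stop("pathway_module nodes not in the network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(ids)
  # module index per node, 0 = background
  mod_id <- integer(n)
  for (m in seq_along(modules)) mod_id[ids %in% modules[[m]]] <- m
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  if (n >= 2) {
    pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
    same_mod <- mod_id[pair_i] > 0L & mod_id[pair_i] == mod_id[pair_j]
    p <- ifelse(same_mod, intra_module_prob, edge_prob)
    keep <- stats::runif(length(p)) < p
    from <- pair_i[keep]; to <- pair_j[keep]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(from))
    g <- igraph::add_edges(g, rbind(ids[from], ids[to]))
  g
}

#' Network partners (interaction neighbors) of a gene
#'
#' @param network An igraph network with named nodes.
#' @param gene Gene id; genes absent from the network have no partners.
#' @return Character vector of partner gene ids (possibly empty).
#' @export
network_partners <- function(network, gene) {
  stopifnot(inherits(network, "igraph"))
  if (!gene %in% igraph::V(network)$name) return(character(0))
  setdiff(igraph::neighbors(network, gene)$name, gene)
}
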