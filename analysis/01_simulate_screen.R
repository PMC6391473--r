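#!/usr/bin/env Rscript
# Stage 1: simulate the perturbation screen.
#
# Generates the synthetic inputs every later stage consumes: a z-score
# signature library (compounds + gene knockdowns across cell lines) with 30
# planted pathway inhibitors among 60 compounds, a module-structured
# interactome, the planted ground truth, and the pathway gene set. Written
# as GCT / TSV under results/sim/.

suppressPackageStartupMessages(library(nfkbscreen))
seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- signature_sim_config(
  n_genes = 300, n_compounds = 60, n_knockdowns = 40, n_cell_lines = 4,
  n_modules = 20,
  planted_targets = setNames(sprintf("G%04d", 1:30), sprintf("CPD%03d", 1:30)),
  effect_size = 4, noise_sd = 1, seed = derive_seed(seed, 1))
sim <- simulate_signature_library(cfg)
ids <- signature_sim_ids(cfg)

net <- simulate_network(cfg$n_genes, edge_prob = 0.02,
                        pathway_module = split(ids$genes, ids$module),
                        intra_module_prob = 0.8, seed = derive_seed(seed, 2))

write_gct(sim$library, file.path(out, "signatures.gct"))
write_edge_list(net, file.path(out, "network.tsv"))
write.table(sim$ground_truth, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(ids$genes[ids$module == 1], file.path(out, "pathway_module1.txt"))

message(sprintf("library: %d genes x %d signatures (%d planted inhibitors)",
                length(sim$library$gene_universe), nrow(sim$library$meta),
                length(cfg$planted_targets)))
message(sprintf("network: %d nodes, %d edges (dense within the %d latent modules)",
                igraph::vcount(net), igraph::ecount(net), cfg$n_modules))
message("wrote ", out, "/{signatures.gct, network.tsv, ground_truth.tsv, pathway_module1.txt}")
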