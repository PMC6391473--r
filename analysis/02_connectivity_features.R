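#!/usr/bin/env Rscript
# Stage 2: connectivity features for every compound-KD pair.
#
# Reads the simulated screen from stage 1 and computes, per (compound,
# knockdown, shared cell line): direct Pearson correlation, indirect
# correlation over interaction partners, baseline activity, and max/mean
# pathway differential expression. Confirms that planted compound-target
# pairs out-correlate the decoys.

suppressPackageStartupMessages(library(nfkbscreen))
sim_dir <- "results/sim"
if (!file.exists(file.path(sim_dir, "signatures.gct")))
  stop("run analysis/01_simulate_screen.R first")

lib <- read_gct(file.path(sim_dir, "signatures.gct"))
net <- read_edge_list(file.path(sim_dir, "network.tsv"))
pathway <- read_gene_list(file.path(sim_dir, "pathway_module1.txt"),
                          name = "pathway_module1")
gt <- read.delim(file.path(sim_dir, "ground_truth.tsv"))

ft <- build_feature_table(lib, net, pathway, min_cell_lines = 4,
                          r_threshold = 0.3)
write.table(ft, "results/features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

m <- merge(ft, gt, by = c("compound_id", "kd_gene"))
message(sprintf("feature rows: %d (%d compounds x %d KDs x shared cell lines)",
                nrow(ft), length(unique(ft$compound_id)),
                length(unique(ft$kd_gene))))
message(sprintf("mean direct correlation, planted pairs: %.3f; decoy pairs: %.3f",
                mean(m$direct_corr[m$planted]), mean(m$direct_corr[!m$planted])))
message(sprintf("mean indirect correlation, planted pairs: %.3f; decoy pairs: %.3f",
                mean(m$indirect_corr[m$planted], na.rm = TRUE),
                mean(m$indirect_corr[!m$planted], na.rm = TRUE)))
message("wrote results/features.tsv")
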