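# Shared fixtures: small seeded simulations and independent oracles.

# A small planted library: compounds CPD001..CPD<k> target knockdown genes
# round-robin; remaining compounds are decoys.
planted_config <- function(n_genes = 200, n_compounds = 20, n_planted = 6,
                           n_knockdowns = 20, n_cell_lines = 3, n_modules = 10,
                           effect_size = 4, noise_sd = 1, seed = 1) {
  kd <- sprintf("G%04d", seq_len(n_knockdowns))
  targets <- stats::setNames(kd[((seq_len(n_planted) - 1) %% n_knockdowns) + 1],
                             sprintf("CPD%03d", seq_len(n_planted)))
  signature_sim_config(n_genes = n_genes, n_compounds = n_compounds,
                       n_knockdowns = n_knockdowns, n_cell_lines = n_cell_lines,
                       n_modules = n_modules, planted_targets = targets,
                       effect_size = effect_size, noise_sd = noise_sd,
                       seed = seed)
}

# Hand-built library from explicit z-score vectors.
# sig_list: list of lists(id, type, cell, z)
manual_library <- function(sig_list, genes) {
  z <- vapply(sig_list, function(s) s$z, numeric(length(genes)))
  rownames(z) <- genes
  meta <- data.frame(
    perturbagen_id = vapply(sig_list, function(s) s$id, ""),
    pert_type = vapply(sig_list, function(s) s$type, ""),
    cell_line = vapply(sig_list, function(s) s$cell, ""),
    stringsAsFactors = FALSE)
  signature_library(z, meta)
}

# Independent brute-force oracle for the indirect correlation: plain loop
# over the partner list using only base R.
oracle_indirect <- function(compound_z, kd_gene, partner_list, lib, cell, r_threshold) {
  partners <- partner_list[[kd_gene]]
  if (is.null(partners) || !length(partners)) return(NA_real_)
  kd_here <- lib$meta$perturbagen_id[lib$meta$pert_type == "knockdown" &
                                       lib$meta$cell_line == cell]
  avail <- partners[partners %in% kd_here]
  if (!length(avail)) return(NA_real_)
  hits <- 0L
  for (p in avail) {
    zp <- lib$zscores[, sig_key(p, cell)]
    if (stats::cor(compound_z, zp) >= r_threshold) hits <- hits + 1L
  }
  hits / length(avail)
}

sig_key <- function(id, cell) paste(id, cell, sep = "::")

# Noiseless single-cell pulse as a long trace table.
pulse_traces <- function(n_cells = 1, amplitude = 2, rise_time = 30,
                         stimulus_time = 30, duration = 360, noise_sd = 0,
                         inhibition_factor = 1, condition = "TNF", seed = 1,
                         jitter = FALSE) {
  simulate_traces(trace_sim_config(
    n_cells = n_cells, amplitude = amplitude, rise_time = rise_time,
    stimulus_time = stimulus_time, duration = duration, noise_sd = noise_sd,
    inhibition_factor = inhibition_factor, condition = condition, seed = seed,
    amp_jitter_sdlog = if (jitter) 0.25 else 0,
    tau_jitter_sdlog = if (jitter) 0.15 else 0,
    baseline_jitter_sdlog = if (jitter) 0.1 else 0))
}
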