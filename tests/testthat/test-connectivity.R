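test_that("direct correlation matches the covariance formula and its symmetries", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 2, 5)
  # independent oracle: explicit covariance / sd computation
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(direct_correlation(a, b), oracle)
  expect_equal(direct_correlation(b, a), oracle)

  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(direct_correlation(x, x), 1.0)
  expect_equal(direct_correlation(x, -x), -1.0)
  # invariant under positive affine transforms, sign flip under negation
  expect_equal(direct_correlation(3 * x + 7, y), direct_correlation(x, y))
  expect_equal(direct_correlation(-x, y), -direct_correlation(x, y))

  expect_error(direct_correlation(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(direct_correlation(rnorm(4), rnorm(5)), "different gene-universe")
  s1 <- expression_signature("a", "compound", "CL1", c(g1 = 1, g2 = 2, g3 = 0))
  s2 <- expression_signature("b", "compound", "CL1", c(g9 = 1, g2 = 2, g3 = 5))
  expect_error(direct_correlation(s1, s2), "different gene universes")
})

test_that("indirect correlation counts highly correlated observable partners", {
  genes <- paste0("g", 1:40)
  set.seed(7)
  x <- rnorm(40)
  y <- rnorm(40); y <- y - x * sum(x * y) / sum(x * x)   # orthogonal to x
  sigs <- list(
    list(id = "cpd", type = "compound", cell = "CL1", z = x),
    list(id = "B", type = "knockdown", cell = "CL1", z = x),              # r = 1
    list(id = "C", type = "knockdown", cell = "CL1", z = y),              # r = 0
    list(id = "D", type = "knockdown", cell = "CL1", z = x + 0.1 * y),    # r ~ 1
    list(id = "E", type = "knockdown", cell = "CL2", z = rnorm(40)))      # wrong cell
  lib <- manual_library(sigs, genes)
  net <- igraph::graph_from_data_frame(
    data.frame(a = "A", b = c("B", "C", "D", "E", "Z")), directed = FALSE)
  cpd <- get_signature(lib, "cpd", "CL1")

  # partners with KD signatures in CL1: B, C, D; two exceed r = 0.5
  expect_equal(indirect_correlation(cpd, "A", net, lib, r_threshold = 0.5), 2 / 3)
  # isolated / absent node: missing value, not zero
  expect_true(is.na(indirect_correlation(cpd, "Z9", net, lib)))
  net_iso <- igraph::make_empty_graph(2, directed = FALSE)
  net_iso <- igraph::set_vertex_attr(net_iso, "name", value = c("A", "B"))
  expect_true(is.na(indirect_correlation(cpd, "A", net_iso, lib)))
  expect_error(indirect_correlation(cpd, "A", net, lib, r_threshold = 1),
               "r_threshold")
})

test_that("indirect correlation equals the brute-force partner loop on random cases", {
  set.seed(42)
  for (case in 1:25) {
    n_genes <- 30
    genes <- sprintf("G%04d", 1:n_genes)
    kd_genes <- genes[1:12]
    cfg <- signature_sim_config(n_genes = n_genes, n_compounds = 2,
                                n_knockdowns = 12, n_cell_lines = 2,
                                n_modules = 4, noise_sd = 1, seed = 100 + case)
    lib <- simulate_signature_library(cfg)$library
    net <- simulate_network(n_genes, edge_prob = 0.25, seed = 200 + case)
    partner_list <- lapply(stats::setNames(kd_genes, kd_genes),
                           function(g) network_partners(net, g))
    thr <- runif(1, -0.3, 0.6)
    g <- sample(kd_genes, 1)
    cl <- sample(c("CL1", "CL2"), 1)
    cpd <- get_signature(lib, "CPD001", cl)
    expect_equal(indirect_correlation(cpd, g, net, lib, thr),
                 oracle_indirect(cpd$zscores, g, partner_list, lib, cl, thr))
  }
})

test_that("indirect correlation is monotonically non-increasing in the threshold", {
  cfg <- planted_config(n_genes = 100, seed = 3)
  lib <- simulate_signature_library(cfg)$library
  net <- simulate_network(100, edge_prob = 0.3, seed = 5)
  cpd <- get_signature(lib, "CPD001", "CL1")
  vals <- vapply(seq(-0.5, 0.9, by = 0.1), function(thr) {
    indirect_correlation(cpd, "G0001", net, lib, thr)
  }, numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("baseline activity and pathway DE features reduce |z| correctly", {
  expect_equal(baseline_activity(rep(0, 10)), 0)
  expect_equal(baseline_activity(c(1, -1, 1, -1)), 1)
  set.seed(2); z <- rnorm(200)
  expect_equal(baseline_activity(z), sum(abs(z)) / length(z))

  sig <- expression_signature("c", "compound", "CL1",
                              c(gA = 2, gB = -3, gC = 1, gD = 9))
  f <- pathway_de_features(sig, c("gA", "gB", "gC"))
  expect_equal(unname(f["max_pathway_de"]), 3)
  expect_equal(unname(f["mean_pathway_de"]), 2)
  # pathway = whole universe makes mean pathway DE coincide with baseline activity
  f_all <- pathway_de_features(sig, c("gA", "gB", "gC", "gD"))
  expect_equal(unname(f_all["mean_pathway_de"]), baseline_activity(sig))
  # brute-force subset oracle on a random signature
  set.seed(3)
  zr <- stats::setNames(rnorm(50), paste0("g", 1:50))
  sigr <- expression_signature("c", "compound", "CL1", zr)
  pw <- sample(names(zr), 10)
  expect_equal(unname(pathway_de_features(sigr, pw)["mean_pathway_de"]),
               mean(abs(zr[pw])))
  expect_error(pathway_de_features(sigr, pathway_gene_set("nfkb", "missing")),
               "nfkb")
})

test_that("feature table enumerates one row per compound, KD and shared cell line", {
  cfg <- signature_sim_config(n_genes = 50, n_compounds = 3, n_knockdowns = 4,
                              n_cell_lines = 2, n_modules = 4, noise_sd = 1,
                              seed = 8)
  lib <- simulate_signature_library(cfg)$library
  net <- simulate_network(50, 0.2, seed = 1)
  ft <- build_feature_table(lib, net, lib$gene_universe[1:10], min_cell_lines = 2)
  expect_equal(nrow(ft), 3 * 4 * 2)
  expect_true(all(ft$direct_corr >= -1 & ft$direct_corr <= 1))
  ind <- ft$indirect_corr[!is.na(ft$indirect_corr)]
  expect_true(all(ind >= 0 & ind <= 1))
  expect_true(all(ft$baseline_activity >= 0))
  expect_true(all(ft$max_pathway_de >= ft$mean_pathway_de))

  # spot-check one row against the single-pair operations
  row <- ft[17, ]
  cpd <- get_signature(lib, row$compound_id, row$cell_line)
  kd <- get_signature(lib, row$kd_gene, row$cell_line)
  expect_equal(row$direct_corr, direct_correlation(cpd, kd))
  expect_equal(row$baseline_activity, baseline_activity(cpd))
  expect_equal(row$indirect_corr,
               indirect_correlation(cpd, row$kd_gene, net, lib, 0.3))

  # raising the coverage threshold above the library's coverage removes all rows
  expect_warning(
    empty <- build_feature_table(lib, net, lib$gene_universe[1:10],
                                 min_cell_lines = 4),
    "no compound-KD pair")
  expect_equal(nrow(empty), 0)
})

test_that("cell-line coverage filtering matches independent set arithmetic", {
  set.seed(99)
  # compound present in fewer cell lines than the cutoff contributes nothing
  genes <- paste0("g", 1:5)
  sigs <- list()
  for (cl in c("A", "B", "C")) {
    sigs[[length(sigs) + 1]] <- list(id = "cpdFull", type = "compound", cell = cl,
                                     z = rnorm(5))
    sigs[[length(sigs) + 1]] <- list(id = "g1", type = "knockdown", cell = cl,
                                     z = rnorm(5))
  }
  sigs[[length(sigs) + 1]] <- list(id = "cpdSparse", type = "compound",
                                   cell = "A", z = rnorm(5))
  lib <- manual_library(sigs, genes)
  ret <- retained_perturbagens(lib$meta, min_cell_lines = 3)
  expect_equal(ret$compounds, "cpdFull")
  expect_equal(ret$knockdowns, "g1")
  expect_equal(ret$n_pairs, 1)
  ft <- build_feature_table(lib, simulate_network(5, 0, node_ids = genes, seed = 1),
                            genes, min_cell_lines = 3)
  expect_false("cpdSparse" %in% ft$compound_id)
  expect_equal(nrow(ft), 3)

  # randomized libraries: row count equals the set-arithmetic oracle
  for (rep in 1:5) {
    cfg <- signature_sim_config(n_genes = 30, n_compounds = 4, n_knockdowns = 5,
                                n_cell_lines = 3, n_modules = 3, seed = 400 + rep)
    lib2 <- simulate_signature_library(cfg)$library
    keep <- sample(nrow(lib2$meta), round(0.7 * nrow(lib2$meta)))
    lib2 <- signature_library(lib2$zscores[, keep, drop = FALSE],
                              lib2$meta[keep, ])
    min_cl <- sample(1:3, 1)
    # oracle: per-perturbagen cell-line counts via table()
    tab <- table(lib2$meta$perturbagen_id, lib2$meta$cell_line) > 0
    ok <- rownames(tab)[rowSums(tab) >= min_cl]
    comp_ok <- intersect(ok, lib2$meta$perturbagen_id[lib2$meta$pert_type == "compound"])
    kd_ok <- intersect(ok, lib2$meta$perturbagen_id[lib2$meta$pert_type == "knockdown"])
    expected_rows <- 0
    for (cpd in comp_ok) for (g in kd_ok) {
      shared <- intersect(lib2$meta$cell_line[lib2$meta$perturbagen_id == cpd],
                          lib2$meta$cell_line[lib2$meta$perturbagen_id == g])
      expected_rows <- expected_rows + length(shared)
    }
    ft2 <- suppressWarnings(
      build_feature_table(lib2, simulate_network(30, 0.2, seed = rep),
                          lib2$gene_universe, min_cell_lines = min_cl))
    expect_equal(nrow(ft2), expected_rows)
  }
})

test_that("planted pairs out-correlate decoy pairs on synthetic libraries", {
  means <- vapply(1:5, function(s) {
    sim <- simulate_signature_library(planted_config(seed = 500 + s))
    lib <- sim$library
    ft <- build_feature_table(lib, simulate_network(200, 0.1, seed = s),
                              lib$gene_universe, min_cell_lines = 3)
    m <- merge(ft, sim$ground_truth, by = c("compound_id", "kd_gene"))
    mean(m$direct_corr[m$planted]) - mean(m$direct_corr[!m$planted])
  }, numeric(1))
  expect_true(all(means > 0.5))
})
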