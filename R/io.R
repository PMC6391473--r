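#' Read and write signature libraries, networks, gene sets and assay tables
#'
#' The pipeline's on-disk formats are deliberately plain text: long-form TSV
#' or GCT 1.2 for signature libraries, 2-column TSV edge lists for networks,
#' GMT or one-gene-per-line files for pathway sets, and CSV for single-cell
#' traces and melt curves.
#'
#' @name nfkbscreen-io
NULL

#' Write / read a signature library as long-form TSV
#'
#' Columns: `perturbagen_id`, `pert_type`, `cell_line`, `gene_id`, `zscore`.
#' The gene universe order is the order of first appearance.
#'
#' @param library A [signature_library()].
#' @param path File path.
#' @return `write_signature_library_tsv` returns `path` invisibly;
#'   `read_signature_library_tsv` returns a [signature_library()].
#' @export
write_signature_library_tsv <- function(library, path) {
  stopifnot(inherits(library, "signature_library"))
  n_genes <- length(library$gene_universe)
  long <- data.frame(
    perturbagen_id = rep(library$meta$perturbagen_id, each = n_genes),
    pert_type = rep(library$meta$pert_type, each = n_genes),
    cell_line = rep(library$meta$cell_line, each = n_genes),
    gene_id = rep(library$gene_universe, times = nrow(library$meta)),
    zscore = as.vector(library$zscores),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_library_tsv
#' @export
read_signature_library_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("perturbagen_id", "pert_type", "cell_line", "gene_id", "zscore")
  if (!all(req %in% names(long)))
    stop("signature TSV needs columns ", paste(req, collapse = ", "), call. = FALSE)
  genes <- unique(long$gene_id)
  key <- sig_key(long$perturbagen_id, long$cell_line)
  keys <- unique(key)
  z <- matrix(NA_real_, nrow = length(genes), ncol = length(keys),
              dimnames = list(genes, keys))
  z[cbind(match(long$gene_id, genes), match(key, keys))] <- long$zscore
  if (anyNA(z))
    stop("signature TSV does not cover the full gene universe for every signature",
         call. = FALSE)
  first <- !duplicated(key)
  meta <- data.frame(perturbagen_id = long$perturbagen_id[first],
                     pert_type = long$pert_type[first],
                     cell_line = long$cell_line[first],
                     stringsAsFactors = FALSE)
  signature_library(z, meta)
}

#' Write / read a signature library as GCT 1.2 text
#'
#' Column ids encode the signature key as
#' `perturbagen_id|pert_type|cell_line`; the Description column carries the
#' gene id again.
#'
#' @param library A [signature_library()].
#' @param path File path.
#' @return `write_gct` returns `path` invisibly; `read_gct` a
#'   [signature_library()].
#' @export
write_gct <- function(library, path) {
  stopifnot(inherits(library, "signature_library"))
  ids <- paste(library$meta$perturbagen_id, library$meta$pert_type,
               library$meta$cell_line, sep = "|")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2",
               paste(length(library$gene_universe), nrow(library$meta), sep = "\t"),
               paste(c("Name", "Description", ids), collapse = "\t")), con)
  body <- cbind(library$gene_universe, library$gene_universe,
                format(library$zscores, trim = TRUE, digits = 15))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gct
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (!identical(header[1], "#1.2"))
    stop("not a GCT 1.2 file (missing '#1.2' header)", call. = FALSE)
  dims <- as.integer(strsplit(header[2], "\t")[[1]])
  tab <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) != dims[1] || ncol(tab) != dims[2] + 2L)
    stop("GCT dimensions disagree with its header", call. = FALSE)
  z <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(z) <- tab$Name
  parts <- strsplit(colnames(z), "|", fixed = TRUE)
  meta <- data.frame(perturbagen_id = vapply(parts, `[`, "", 1L),
                     pert_type = vapply(parts, `[`, "", 2L),
                     cell_line = vapply(parts, `[`, "", 3L),
                     stringsAsFactors = FALSE)
  signature_library(z, meta)
}

#' Write / read an interaction network as a 2-column TSV edge list
#'
#' @param network An igraph network with named nodes.
#' @param path File path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list` an
#'   undirected simple igraph network.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "igraph"))
  el <- igraph::as_edgelist(network)
  utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(el) < 2L) stop("edge list needs two columns", call. = FALSE)
  g <- igraph::graph_from_data_frame(el[, 1:2], directed = FALSE)
  igraph::simplify(g)  # drop self-loops / duplicate edges defensively
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Named list of [pathway_gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line: ", substr(l, 1, 60), call. = FALSE)
    pathway_gene_set(parts[1], parts[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, ""))
}

#' Read a one-gene-per-line pathway file
#'
#' @param path Text file with one gene id per line; blank lines ignored.
#' @param name Set name (default: the file's base name).
#' @return A [pathway_gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  genes <- trimws(readLines(path))
  pathway_gene_set(name %||% sub("\\.[^.]*$", "", basename(path)),
                   genes[nzchar(genes)])
}

#' Write / read single-cell trace tables as CSV
#'
#' Columns: `cell_id`, `condition`, `time_min`, `intensity`.
#'
#' @param traces Long trace data frame (see [simulate_traces()]).
#' @param path File path.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   the long data frame.
#' @export
write_traces_csv <- function(traces, path) {
  req <- c("cell_id", "condition", "time_min", "intensity")
  stopifnot(all(req %in% names(traces)))
  utils::write.csv(traces[req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "condition", "time_min", "intensity")
  if (!all(req %in% names(tr)))
    stop("trace CSV needs columns ", paste(req, collapse = ", "), call. = FALSE)
  tr
}

#' Write / read melt-curve tables as CSV
#'
#' Columns: `temperature_C`, `fluorescence`, `sample_id`, `condition`.
#'
#' @param curves Long melt-curve data frame (see [simulate_melt_curve()]).
#' @param path File path.
#' @return `write_melt_csv` returns `path` invisibly; `read_melt_csv` the
#'   long data frame.
#' @export
write_melt_csv <- function(curves, path) {
  req <- c("temperature_C", "fluorescence", "sample_id", "condition")
  stopifnot(all(req %in% names(curves)))
  utils::write.csv(curves[req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_melt_csv
#' @export
read_melt_csv <- function(path) {
  mc <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("temperature_C", "fluorescence", "sample_id", "condition")
  if (!all(req %in% names(mc)))
    stop("melt CSV needs columns ", paste(req, collapse = ", "), call. = FALSE)
  mc
}
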