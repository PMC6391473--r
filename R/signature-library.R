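#' Signature library: differential-expression z-score signatures
#'
#' A `signature_library` holds one z-score vector per (perturbagen, cell line)
#' over a fixed, ordered gene universe — the container for landmark-style
#' differential-expression signatures of compound treatments and gene
#' knockdowns. Knockdown signatures use the knocked-down gene id as their
#' perturbagen id.
#'
#' @param zscores Numeric matrix, genes in rows (rownames = gene ids),
#'   signatures in columns. All values must be finite.
#' @param meta Data frame with one row per column of `zscores`, columns
#'   `perturbagen_id`, `pert_type` (`"compound"` or `"knockdown"`), and
#'   `cell_line`. (perturbagen_id, cell_line) pairs must be unique.
#' @return An object of class `signature_library` with elements
#'   `gene_universe`, `zscores`, `meta`.
#' @export
#' @examples
#' z <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("G", 1:5), NULL))
#' m <- data.frame(perturbagen_id = c("c1", "c1", "G2", "G2"),
#'                 pert_type = c("compound", "compound", "knockdown", "knockdown"),
#'                 cell_line = c("A", "B", "A", "B"))
#' lib <- signature_library(z, m)
#' cell_lines(lib)
signature_library <- function(zscores, meta) {
  if (!is.matrix(zscores) || !is.numeric(zscores))
    stop("`zscores` must be a numeric matrix (genes x signatures)", call. = FALSE)
  if (is.null(rownames(zscores)))
    stop("`zscores` must have gene ids as rownames", call. = FALSE)
  if (!all(is.finite(zscores)))
    stop("signatures must contain finite values only", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("perturbagen_id", "pert_type", "cell_line")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("`meta` is missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(meta) != ncol(zscores))
    stop("`meta` must have one row per signature column", call. = FALSE)
  if (!all(meta$pert_type %in% c("compound", "knockdown")))
    stop("`pert_type` must be 'compound' or 'knockdown'", call. = FALSE)
  keys <- sig_key(meta$perturbagen_id, meta$cell_line)
  if (anyDuplicated(keys))
    stop("duplicate (perturbagen_id, cell_line) keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  colnames(zscores) <- keys
  structure(
    list(gene_universe = rownames(zscores),
         zscores = zscores,
         meta = meta),
    class = "signature_library"
  )
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("signature_library: %d genes, %d signatures (%d compounds, %d knockdowns) in %d cell line(s)\n",
              length(x$gene_universe), nrow(x$meta),
              length(unique(x$meta$perturbagen_id[x$meta$pert_type == "compound"])),
              length(unique(x$meta$perturbagen_id[x$meta$pert_type == "knockdown"])),
              length(unique(x$meta$cell_line))))
  invisible(x)
}

#' Cell lines represented in a signature library
#' @param library A [signature_library()].
#' @return Character vector of cell-line ids.
#' @export
cell_lines <- function(library) {
  stopifnot(inherits(library, "signature_library"))
  sort(unique(library$meta$cell_line))
}

#' Perturbagen ids of a given type
#' @param library A [signature_library()].
#' @param pert_type `"compound"`, `"knockdown"`, or `NULL` for all.
#' @return Character vector of perturbagen ids.
#' @export
perturbagens <- function(library, pert_type = NULL) {
  stopifnot(inherits(library, "signature_library"))
  meta <- library$meta
  if (!is.null(pert_type)) meta <- meta[meta$pert_type == pert_type, , drop = FALSE]
  sort(unique(meta$perturbagen_id))
}

#' Extract one expression signature
#'
#' @param library A [signature_library()].
#' @param perturbagen_id Perturbagen id (for knockdowns, the gene id).
#' @param cell_line Cell-line id.
#' @return An `expression_signature`: list with `perturbagen_id`, `pert_type`,
#'   `cell_line` and the named numeric `zscores` vector.
#' @export
get_signature <- function(library, perturbagen_id, cell_line) {
  stopifnot(inherits(library, "signature_library"))
  key <- sig_key(perturbagen_id, cell_line)
  idx <- match(key, colnames(library$zscores))
  if (is.na(idx))
    stop(sprintf("no signature for perturbagen '%s' in cell line '%s'",
                 perturbagen_id, cell_line), call. = FALSE)
  expression_signature(perturbagen_id,
                       library$meta$pert_type[idx],
                       cell_line,
                       library$zscores[, idx])
}

#' Construct an expression signature
#'
#' @param perturbagen_id Perturbagen id.
#' @param pert_type `"compound"` or `"knockdown"`.
#' @param cell_line Cell-line id.
#' @param zscores Named numeric vector of finite z-scores (names = gene ids).
#' @return An object of class `expression_signature`.
#' @export
expression_signature <- function(perturbagen_id, pert_type, cell_line, zscores) {
  if (!is.numeric(zscores) || is.null(names(zscores)))
    stop("`zscores` must be a named numeric vector", call. = FALSE)
  if (!all(is.finite(zscores)))
    stop("`zscores` must be finite", call. = FALSE)
  if (!pert_type %in% c("compound", "knockdown"))
    stop("`pert_type` must be 'compound' or 'knockdown'", call. = FALSE)
  structure(
    list(perturbagen_id = perturbagen_id, pert_type = pert_type,
         cell_line = cell_line, zscores = zscores),
    class = "expression_signature"
  )
}

#' @export
print.expression_signature <- function(x, ...) {
  cat(sprintf("expression_signature: %s (%s) in %s, %d genes\n",
              x$perturbagen_id, x$pert_type, x$cell_line, length(x$zscores)))
  invisible(x)
}

#' Z-score matrix for one cell line and perturbagen type
#'
#' @param library A [signature_library()].
#' @param cell_line Cell-line id.
#' @param pert_type `"compound"`, `"knockdown"`, or `NULL` for both.
#' @return Numeric matrix genes x perturbagens; column names are perturbagen
#'   ids. Zero columns if nothing matches.
#' @export
signature_matrix <- function(library, cell_line, pert_type = NULL) {
  stopifnot(inherits(library, "signature_library"))
  keep <- library$meta$cell_line == cell_line
  if (!is.null(pert_type)) keep <- keep & library$meta$pert_type == pert_type
  z <- library$zscores[, keep, drop = FALSE]
  colnames(z) <- library$meta$perturbagen_id[keep]
  z
}
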