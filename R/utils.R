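#' Derive a substream seed from a master seed
#'
#' All generators in the package are seeded. Analysis drivers and the
#' acceptance script derive per-stage seeds from one master seed so that
#' stages can be regenerated independently while the whole run stays
#' reproducible from a single integer.
#'
#' @param master_seed Single integer master seed.
#' @param offset Non-negative integer identifying the substream.
#' @return An integer seed, guaranteed below 2^31.
#' @export
#' @examples
#' derive_seed(1, 3)
derive_seed <- function(master_seed, offset) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  as.integer((abs(as.numeric(master_seed)) %% 2146483L) * 1000 + (offset %% 1000))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared key for (perturbagen, cell line) signature columns
sig_key <- function(perturbagen_id, cell_line) {
  paste(perturbagen_id, cell_line, sep = "::")
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
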