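#' Normalize a thermal-shift melt curve to \[0, 1\]
#'
#' Optionally truncates the curve after its global fluorescence maximum
#' (dye-based melt curves decay once the unfolded protein aggregates), then
#' min-max scales the retained segment so its minimum is exactly 0 and its
#' maximum exactly 1.
#'
#' @param curve Data frame with columns `temperature_C` (strictly
#'   increasing) and `fluorescence` (finite), at least 5 points; extra
#'   columns such as `sample_id` are carried through.
#' @param truncate_at_peak Discard frames after the global maximum before
#'   scaling (default `TRUE`).
#' @return A `normalized_melt_curve`: list with `temperature_C`,
#'   `fluorescence` in \[0,1\], `truncation_temp` (temperature of the
#'   retained maximum when truncation removed points, else `NA`), and
#'   `sample_id`/`condition` when present.
#' @export
normalize_melt <- function(curve, truncate_at_peak = TRUE) {
  if (!all(c("temperature_C", "fluorescence") %in% names(curve)))
    stop("`curve` needs columns temperature_C and fluorescence", call. = FALSE)
  temps <- as.numeric(curve$temperature_C)
  f <- as.numeric(curve$fluorescence)
  if (length(temps) < 5L)
    stop("melt curve needs at least 5 points", call. = FALSE)
  if (any(diff(temps) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (!all(is.finite(f)) || !all(is.finite(temps)))
    stop("melt curve contains non-finite values", call. = FALSE)
  if (diff(range(f)) == 0)
    stop("no melt transition: constant fluorescence", call. = FALSE)
  truncation_temp <- NA_real_
  if (isTRUE(truncate_at_peak)) {
    i_max <- which.max(f)
    if (i_max < length(f)) {
      truncation_temp <- temps[i_max]
      temps <- temps[seq_len(i_max)]
      f <- f[seq_len(i_max)]
    }
  }
  if (length(f) < 5L)
    stop("fewer than 5 points remain after post-peak truncation", call. = FALSE)
  rng <- range(f)
  if (rng[1] == rng[2])
    stop("no melt transition: constant fluorescence", call. = FALSE)
  structure(list(temperature_C = temps,
                 fluorescence = (f - rng[1]) / (rng[2] - rng[1]),
                 truncation_temp = truncation_temp,
                 sample_id = curve$sample_id[1] %||% NA_character_,
                 condition = curve$condition[1] %||% NA_character_),
            class = "normalized_melt_curve")
}

#' @export
print.normalized_melt_curve <- function(x, ...) {
  cat(sprintf("normalized_melt_curve: %s, %d points, %.2f-%.2f degC%s\n",
              x$sample_id, length(x$temperature_C),
              min(x$temperature_C), max(x$temperature_C),
              if (is.na(x$truncation_temp)) ""
              else sprintf(", truncated at %.2f degC", x$truncation_temp)))
  invisible(x)
}

#' Estimate the melting temperature from a normalized melt curve
#'
#' `method = "midpoint"` (default) reads Tm literally as the curve midpoint:
#' the temperature of the first upward crossing of 0.5, linearly
#' interpolated between the bracketing samples. Later crossings set the
#' `multi_crossing` attribute. `method = "fit"` instead fits a Boltzmann
#' sigmoid `f = a + (b - a) / (1 + exp(-(T - Tm)/k))` by nonlinear least
#' squares and reports the fitted Tm — the estimator of choice for noisy
#' curves, where point-wise threshold crossing is biased early by noise.
#'
#' @param curve A [normalize_melt()] result.
#' @param method `"midpoint"` or `"fit"`.
#' @return Tm in degC, with attributes `method` and (midpoint mode)
#'   `multi_crossing`.
#' @export
estimate_tm <- function(curve, method = c("midpoint", "fit")) {
  stopifnot(inherits(curve, "normalized_melt_curve"))
  method <- match.arg(method)
  temps <- curve$temperature_C
  f <- curve$fluorescence
  tm <- if (method == "midpoint") {
    up <- which(f[-length(f)] < 0.5 & f[-1] >= 0.5)
    if (!length(up))
      stop("no upward 0.5 crossing: no melt transition detected", call. = FALSE)
    i <- up[1]
    val <- temps[i] + (0.5 - f[i]) * (temps[i + 1] - temps[i]) / (f[i + 1] - f[i])
    attr(val, "multi_crossing") <- length(up) > 1L
    val
  } else {
    start_tm <- midpoint_start(temps, f)
    fit <- minpack.lm::nlsLM(
      f ~ a + (b - a) / (1 + exp(-(temp - tm) / k)),
      data = list(f = f, temp = temps),
      start = list(a = 0, b = 1, tm = start_tm,
                   k = (max(temps) - min(temps)) / 25),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    val <- unname(stats::coef(fit)[["tm"]])
    if (val < min(temps) || val > max(temps))
      stop("fitted Tm falls outside the analyzed temperature range", call. = FALSE)
    val
  }
  attr(tm, "method") <- method
  tm
}

# crossing of a lightly smoothed curve: robust starting value for the fit
midpoint_start <- function(temps, f) {
  w <- max(3L, 2L * (length(f) %/% 100L) + 1L)
  fs <- as.numeric(stats::filter(f, rep(1 / w, w), sides = 2))
  fs[is.na(fs)] <- f[is.na(fs)]
  up <- which(fs[-length(fs)] < 0.5 & fs[-1] >= 0.5)
  if (length(up)) temps[up[1]] else stats::median(temps)
}

#' Thermal shift between two melting temperatures
#'
#' @param sample,reference Tm estimates in degC ([estimate_tm()] outputs or
#'   plain numbers); the reference is typically the vehicle control.
#' @return `Tm(sample) - Tm(reference)` in degC (positive = stabilized).
#' @export
delta_tm <- function(sample, reference) {
  s <- as.numeric(sample); r <- as.numeric(reference)
  if (length(s) != 1L || length(r) != 1L || !is.finite(s) || !is.finite(r))
    stop("`sample` and `reference` must be single finite Tm values", call. = FALSE)
  s - r
}

#' Tm and thermal-shift table for a set of melt curves
#'
#' Normalizes every sample's curve, estimates its Tm, and reports the shift
#' relative to the mean Tm of the reference condition.
#'
#' @param curves Long data frame with columns `temperature_C`,
#'   `fluorescence`, `sample_id` and `condition` (the format written by
#'   [simulate_melt_curve()]).
#' @param reference_condition Condition whose mean Tm anchors `delta_tm`.
#' @param truncate_at_peak,method Passed to [normalize_melt()] /
#'   [estimate_tm()].
#' @return Data frame `sample_id`, `condition`, `tm`, `delta_tm`, `method`,
#'   sorted by condition then sample.
#' @export
analyze_melt_curves <- function(curves, reference_condition,
                                truncate_at_peak = TRUE,
                                method = c("midpoint", "fit")) {
  method <- match.arg(method)
  req <- c("temperature_C", "fluorescence", "sample_id", "condition")
  if (!all(req %in% names(curves)))
    stop("`curves` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (!reference_condition %in% curves$condition)
    stop(sprintf("reference condition '%s' absent from the curves",
                 reference_condition), call. = FALSE)
  parts <- split(curves, curves$sample_id)
  res <- lapply(parts, function(p) {
    p <- p[order(p$temperature_C), ]
    tm <- estimate_tm(normalize_melt(p, truncate_at_peak), method)
    data.frame(sample_id = p$sample_id[1], condition = p$condition[1],
               tm = as.numeric(tm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ref_tm <- mean(out$tm[out$condition == reference_condition])
  out$delta_tm <- out$tm - ref_tm
  out$method <- method
  out <- out[order(out$condition, out$sample_id), ]
  rownames(out) <- NULL
  out
}
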