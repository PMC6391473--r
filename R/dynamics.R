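#' Single-cell nuclear-fluorescence time course
#'
#' @param cell_id Cell identifier.
#' @param condition Condition label (e.g. `"TNF"`, `"TNF+cpd2_10uM"`).
#' @param times Strictly increasing sampling times, minutes.
#' @param values Nuclear fluorescence (a.u.), same length as `times`,
#'   finite; at least 3 samples with at least one strictly before
#'   `stimulus_time`.
#' @param stimulus_time Stimulus addition time, minutes.
#' @return An object of class `single_cell_trace`.
#' @export
single_cell_trace <- function(cell_id, condition, times, values, stimulus_time) {
  if (length(times) != length(values) || length(times) < 3L)
    stop("`times` and `values` must have equal length >= 3", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(values)) || !all(is.finite(times)))
    stop("trace contains non-finite values", call. = FALSE)
  if (!any(times < stimulus_time))
    stop("trace needs at least one sample strictly before `stimulus_time`",
         call. = FALSE)
  structure(list(cell_id = cell_id, condition = condition,
                 times = as.numeric(times), values = as.numeric(values),
                 stimulus_time = stimulus_time),
            class = "single_cell_trace")
}

#' Fold-change normalization of a single-cell trace
#'
#' Divides a trace by its own pre-stimulus baseline F0, the mean fluorescence
#' over the `baseline_window` minutes preceding the stimulus. Fold change is
#' the per-cell-normalized quantity all downstream descriptors use.
#'
#' @param trace A [single_cell_trace()].
#' @param baseline_window Length of the pre-stimulus window, minutes
#'   (default 30, matching at least 30 min of baseline imaging).
#' @return A `fold_change_trace`: list with `cell_id`, `condition`, `times`,
#'   `fc_values`, `baseline_f0`, `stimulus_time`.
#' @export
compute_fold_change <- function(trace, baseline_window = 30) {
  stopifnot(inherits(trace, "single_cell_trace"))
  stop_if_not_scalar_number(baseline_window, "baseline_window",
                            lower = .Machine$double.eps)
  in_win <- trace$times >= trace$stimulus_time - baseline_window &
    trace$times < trace$stimulus_time
  if (!any(in_win))
    stop("no frames inside the pre-stimulus baseline window", call. = FALSE)
  f0 <- mean(trace$values[in_win])
  if (f0 <= 0)
    stop("non-positive baseline F0; cannot form fold change", call. = FALSE)
  structure(list(cell_id = trace$cell_id, condition = trace$condition,
                 times = trace$times, fc_values = trace$values / f0,
                 baseline_f0 = f0, stimulus_time = trace$stimulus_time),
            class = "fold_change_trace")
}

#' Trajectory descriptors of a fold-change trace
#'
#' Summarizes a nuclear NF-kB fold-change trajectory by five descriptors:
#' \describe{
#'   \item{auc}{trapezoidal integral of (fold change - 1) from the stimulus
#'     to the last frame; a non-responding cell scores 0, and negative
#'     excursions are included.}
#'   \item{max_fc}{maximum fold change on that interval.}
#'   \item{t_max}{time of the maximum (earliest frame on ties), minutes.}
#'   \item{rate_in}{maximal single-interval forward difference of fold
#'     change per minute on \[stimulus, t_max\] (nuclear entry).}
#'   \item{rate_out}{maximal magnitude of negative forward difference per
#'     minute on \[t_max, end\] (nuclear exit); 0 with `decay_observed =
#'     FALSE` when the trace ends at its maximum.}
#' }
#' If the stimulus falls between frames, the fold change at the stimulus is
#' linearly interpolated so the integration interval starts exactly there.
#'
#' @param fc A `fold_change_trace` from [compute_fold_change()].
#' @param smooth Apply a centered 3-frame moving average before
#'   differentiation and peak-finding (default `FALSE`: raw maximal rates).
#' @param epsilon Non-responder threshold: cells with
#'   `max_fc < 1 + epsilon` are flagged (`responder = FALSE`) but retained.
#' @return A one-row data frame: `cell_id`, `condition`, `auc`, `max_fc`,
#'   `t_max`, `rate_in`, `rate_out`, `responder`, `decay_observed`.
#' @export
compute_descriptors <- function(fc, smooth = FALSE, epsilon = 0.05) {
  stopifnot(inherits(fc, "fold_change_trace"))
  t0 <- fc$stimulus_time
  times <- fc$times
  vals <- fc$fc_values
  if (max(times) <= t0)
    stop("trace ends before the stimulus; no response interval", call. = FALSE)
  if (isTRUE(smooth)) {
    vals <- stats::filter(vals, rep(1 / 3, 3), sides = 2)
    vals[1] <- fc$fc_values[1]; vals[length(vals)] <- fc$fc_values[length(vals)]
    vals <- as.numeric(vals)
  }
  keep <- times >= t0
  seg_t <- times[keep]
  seg_v <- vals[keep]
  if (seg_t[1] > t0) {  # interpolate the value at the stimulus itself
    v0 <- stats::approx(times, vals, xout = t0)$y
    seg_t <- c(t0, seg_t)
    seg_v <- c(v0, seg_v)
  }

  auc <- pracma::trapz(seg_t, seg_v - 1)
  i_max <- which.max(seg_v)          # which.max takes the earliest tie
  max_fc <- seg_v[i_max]
  t_max <- seg_t[i_max]

  d <- diff(seg_v) / diff(seg_t)
  rate_in <- if (i_max > 1L) max(0, d[seq_len(i_max - 1L)]) else 0
  decay_observed <- i_max < length(seg_v)
  rate_out <- if (decay_observed) max(0, -d[i_max:(length(seg_v) - 1L)]) else 0

  data.frame(cell_id = fc$cell_id, condition = fc$condition,
             auc = auc, max_fc = max_fc, t_max = t_max,
             rate_in = rate_in, rate_out = rate_out,
             responder = max_fc >= 1 + epsilon,
             decay_observed = decay_observed,
             stringsAsFactors = FALSE)
}

#' Descriptor table for a collection of traces
#'
#' Runs fold-change normalization and descriptor extraction over every cell
#' in a long trace table. Cells violating preconditions (too few frames, no
#' pre-stimulus baseline, non-positive F0, ...) are dropped with a recorded
#' reason, never silently.
#'
#' @param traces Long data frame with columns `cell_id`, `condition`,
#'   `time_min`, `intensity` (the format written by [simulate_traces()]).
#' @param stimulus_times Stimulus time in minutes: a single number for all
#'   conditions or a named vector keyed by condition.
#' @param baseline_window Passed to [compute_fold_change()].
#' @param smooth,epsilon Passed to [compute_descriptors()].
#' @return Long data frame with one row per (cell, descriptor): `cell_id`,
#'   `condition`, `descriptor`, `value`. Attributes: `"exclusions"` (data
#'   frame of dropped cells and reasons) and `"n_cells"` (named per-condition
#'   cell counts, mirroring the trajectory counts reported alongside the
#'   plots). Warns on empty input.
#' @export
descriptor_table <- function(traces, stimulus_times, baseline_window = 30,
                             smooth = FALSE, epsilon = 0.05) {
  req <- c("cell_id", "condition", "time_min", "intensity")
  if (!all(req %in% names(traces)))
    stop("`traces` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  empty <- data.frame(cell_id = character(0), condition = character(0),
                      descriptor = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(traces)) {
    warning("empty trace table")
    attr(empty, "exclusions") <- data.frame(cell_id = character(0),
                                            reason = character(0))
    attr(empty, "n_cells") <- integer(0)
    return(empty)
  }
  get_t0 <- function(cond) {
    if (length(stimulus_times) == 1L && is.null(names(stimulus_times)))
      return(as.numeric(stimulus_times))
    if (!cond %in% names(stimulus_times))
      stop(sprintf("no stimulus time given for condition '%s'", cond), call. = FALSE)
    as.numeric(stimulus_times[[cond]])
  }

  desc_cols <- c("auc", "max_fc", "t_max", "rate_in", "rate_out")
  rows <- list(); excl <- list()
  for (part in split(traces, traces$cell_id)) {
    part <- part[order(part$time_min), ]
    cid <- part$cell_id[1]; cond <- part$condition[1]
    res <- tryCatch({
      tr <- single_cell_trace(cid, cond, part$time_min, part$intensity, get_t0(cond))
      compute_descriptors(compute_fold_change(tr, baseline_window),
                          smooth = smooth, epsilon = epsilon)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[cid]] <- data.frame(cell_id = cid, reason = conditionMessage(res),
                                stringsAsFactors = FALSE)
    } else {
      rows[[cid]] <- data.frame(cell_id = cid, condition = cond,
                                descriptor = desc_cols,
                                value = as.numeric(res[1, desc_cols]),
                                stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(cell_id = character(0), reason = character(0))
  rownames(exclusions) <- NULL
  if (nrow(exclusions))
    message(sprintf("descriptor_table: dropped %d trace(s) failing preconditions",
                    nrow(exclusions)))
  kept <- unique(out[c("cell_id", "condition")])
  attr(out, "exclusions") <- exclusions
  attr(out, "n_cells") <- table(kept$condition)
  out
}

#' Extract one descriptor's values for a condition
#'
#' Convenience accessor for permutation testing: pulls the numeric vector of
#' one descriptor under one condition from a [descriptor_table()].
#'
#' @param descriptors A [descriptor_table()] result.
#' @param condition Condition label.
#' @param descriptor One of `"auc"`, `"max_fc"`, `"t_max"`, `"rate_in"`,
#'   `"rate_out"`.
#' @return Numeric vector (one value per cell).
#' @export
descriptor_values <- function(descriptors, condition, descriptor) {
  stopifnot(all(c("condition", "descriptor", "value") %in% names(descriptors)))
  v <- descriptors$value[descriptors$condition == condition &
                           descriptors$descriptor == descriptor]
  if (!length(v))
    stop(sprintf("no '%s' values for condition '%s'", descriptor, condition),
         call. = FALSE)
  v
}
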