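#' Configuration for the thermal-shift melt-curve generator
#'
#' Emulates a dye-based protein melt curve: a two-state sigmoidal unfolding
#' transition sampled on a dense temperature ramp,
#' \deqn{F(T) = f_{min} + \frac{f_{max} - f_{min}}{1 + e^{-(T - T_m)/k}} + \epsilon.}
#' The default grid is 25-99 degC in 0.05 degC steps, the ramp used by
#' real-time PCR melt programs.
#'
#' @param tm_true True midpoint melting temperature, degC.
#' @param k Transition slope parameter, degC (> 0; smaller = sharper melt).
#' @param temp_start,temp_stop,temp_step Temperature grid, degC.
#' @param f_min,f_max Pre- and post-transition fluorescence plateaus (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param sample_id,condition Labels stamped on the curve.
#' @param seed Integer seed.
#' @return A `melt_sim_config` list.
#' @export
melt_sim_config <- function(tm_true = 50, k = 2, temp_start = 25,
                            temp_stop = 99, temp_step = 0.05,
                            f_min = 2000, f_max = 30000, noise_sd = 0,
                            sample_id = "sample", condition = "vehicle",
                            seed = 1L) {
  stop_if_not_scalar_number(k, "k", lower = .Machine$double.eps)
  stop_if_not_scalar_number(temp_step, "temp_step", lower = .Machine$double.eps)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!(temp_start < tm_true && tm_true < temp_stop))
    stop("`tm_true` must lie strictly inside [temp_start, temp_stop]", call. = FALSE)
  structure(
    list(tm_true = tm_true, k = k, temp_start = temp_start,
         temp_stop = temp_stop, temp_step = temp_step,
         f_min = f_min, f_max = f_max, noise_sd = noise_sd,
         sample_id = sample_id, condition = condition, seed = as.integer(seed)),
    class = "melt_sim_config"
  )
}

#' Simulate one melt curve
#'
#' @param config A [melt_sim_config()].
#' @return Data frame with columns `temperature_C`, `fluorescence`,
#'   `sample_id`, `condition`.
#' @export
#' @examples
#' mc <- simulate_melt_curve(melt_sim_config(tm_true = 52, seed = 4))
#' range(mc$temperature_C)
simulate_melt_curve <- function(config) {
  stopifnot(inherits(config, "melt_sim_config"))
  temps <- seq(config$temp_start, config$temp_stop, by = config$temp_step)
  set.seed(config$seed)
  f <- config$f_min + (config$f_max - config$f_min) /
    (1 + exp(-(temps - config$tm_true) / config$k)) +
    stats::rnorm(length(temps), sd = config$noise_sd)
  data.frame(temperature_C = temps, fluorescence = f,
             sample_id = config$sample_id, condition = config$condition,
             stringsAsFactors = FALSE)
}
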