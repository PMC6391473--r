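make_trace <- function(times, values, t0 = 30, id = "c1", cond = "TNF") {
  single_cell_trace(id, cond, times, values, t0)
}

test_that("fold change self-normalizes and is scale invariant", {
  tms <- seq(0, 120, by = 5)
  tr <- make_trace(tms, rep(80, length(tms)))
  fc <- compute_fold_change(tr)
  expect_equal(fc$fc_values, rep(1, length(tms)))
  expect_equal(fc$baseline_f0, 80)

  set.seed(1)
  vals <- 100 * pulse_fold_change(tms, 30, 2, 20) + rnorm(length(tms))
  f1 <- compute_fold_change(make_trace(tms, vals))
  f2 <- compute_fold_change(make_trace(tms, 2 * vals))
  expect_equal(f1$fc_values, f2$fc_values)

  expect_error(compute_fold_change(make_trace(tms, vals), baseline_window = 1e-9),
               "baseline window")
  expect_error(compute_fold_change(make_trace(tms, vals - 200)),
               "non-positive baseline")
  expect_error(single_cell_trace("c", "x", c(40, 50, 60), c(1, 2, 3), 30),
               "before")
})

test_that("noiseless generator traces reproduce the pulse model pointwise", {
  tr <- pulse_traces(amplitude = 2, rise_time = 20)
  one <- tr[tr$cell_id == tr$cell_id[1], ]
  fc <- compute_fold_change(make_trace(one$time_min, one$intensity))
  expect_equal(fc$fc_values, pulse_fold_change(one$time_min, 30, 2, 20),
               tolerance = 1e-12)
})

test_that("descriptors of a flat trace are null", {
  tms <- seq(0, 200, by = 5)
  d <- compute_descriptors(compute_fold_change(make_trace(tms, rep(50, length(tms)))))
  expect_equal(d$auc, 0)
  expect_equal(d$max_fc, 1)
  expect_equal(d$rate_in, 0)
  expect_equal(d$rate_out, 0)
  expect_false(d$responder)
})

test_that("descriptors match closed forms on a noiseless pulse", {
  # A = 2, tau_r = 30, t0 = 30: peak 1 + A at t0 + tau_r, AUC -> A e tau_r
  tr <- pulse_traces(amplitude = 2, rise_time = 30, duration = 360)
  one <- tr[tr$cell_id == tr$cell_id[1], ]
  d <- compute_descriptors(compute_fold_change(make_trace(one$time_min, one$intensity)))
  expect_equal(d$max_fc, 3.0, tolerance = 1e-12)
  expect_equal(d$t_max, 60)
  expect_equal(d$auc, 2 * exp(1) * 30, tolerance = 0.01)
  expect_true(d$responder)

  # independent trapezoid oracle: explicit interval loop
  fc <- pulse_fold_change(one$time_min, 30, 2, 30)
  keep <- one$time_min >= 30
  tt <- one$time_min[keep]; vv <- fc[keep] - 1
  oracle <- sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
  expect_equal(d$auc, oracle, tolerance = 1e-12)

  # faster rise: tau_r = 10 pulse peaks at 3.0, AUC = 20e within the
  # coarser relative discretization of 5-min frames
  tr10 <- pulse_traces(amplitude = 2, rise_time = 10, duration = 200)
  one10 <- tr10[tr10$cell_id == tr10$cell_id[1], ]
  d10 <- compute_descriptors(compute_fold_change(make_trace(one10$time_min,
                                                            one10$intensity)))
  expect_equal(d10$max_fc, 3.0, tolerance = 1e-12)
  expect_equal(d10$t_max, 40)
  expect_equal(d10$auc, 2 * exp(1) * 10, tolerance = 0.03)
})

test_that("time shifts move t_max only; AUC is additive over a split", {
  tms <- seq(0, 300, by = 5)
  vals <- 100 * pulse_fold_change(tms, 30, 1.5, 25)
  d0 <- compute_descriptors(compute_fold_change(make_trace(tms, vals, t0 = 30)))
  d30 <- compute_descriptors(compute_fold_change(
    make_trace(tms + 30, vals, t0 = 60)))
  expect_equal(d30$t_max, d0$t_max + 30)
  for (col in c("auc", "max_fc", "rate_in", "rate_out"))
    expect_equal(d30[[col]], d0[[col]])

  # splitting the integration interval at interior frames preserves the AUC
  fc <- compute_fold_change(make_trace(tms, vals, t0 = 30))
  seg <- fc$fc_values - 1
  total <- pracma::trapz(tms[tms >= 30], seg[tms >= 30])
  for (cut in c(60, 100, 250)) {
    left <- pracma::trapz(tms[tms >= 30 & tms <= cut], seg[tms >= 30 & tms <= cut])
    right <- pracma::trapz(tms[tms >= cut], seg[tms >= cut])
    expect_equal(left + right, total, tolerance = 1e-12)
  }
})

test_that("rates capture entry and exit; truncated decay is flagged", {
  tms <- seq(0, 100, by = 5)
  vals <- 100 * pulse_fold_change(tms, 30, 2, 20)
  d <- compute_descriptors(compute_fold_change(make_trace(tms, vals)))
  # independent finite-difference oracle
  fc <- vals / 100
  dd <- diff(fc) / diff(tms)
  i_max <- which.max(fc[tms >= 30]) + sum(tms < 30)
  expect_equal(d$rate_in, max(dd[seq(sum(tms < 30) + 1, i_max - 1)]))
  expect_equal(d$rate_out, max(-dd[i_max:(length(fc) - 1)]))
  expect_true(d$decay_observed)

  # trace ending exactly at its maximum: no decay interval
  cut <- tms <= 50
  d2 <- compute_descriptors(compute_fold_change(make_trace(tms[cut], vals[cut])))
  expect_equal(d2$rate_out, 0)
  expect_false(d2$decay_observed)
})

test_that("descriptor table accounts for every cell and logs exclusions", {
  tr <- pulse_traces(n_cells = 10, noise_sd = 0.02, jitter = TRUE, seed = 8)
  # two invalid cells: one too short, one with no pre-stimulus frames
  bad <- rbind(
    data.frame(cell_id = "bad_short", condition = "TNF",
               time_min = c(0, 5), intensity = c(1, 2)),
    data.frame(cell_id = "bad_late", condition = "TNF",
               time_min = seq(40, 100, 5),
               intensity = rep(1, 13)))
  suppressMessages(dt <- descriptor_table(rbind(tr, bad), stimulus_times = 30))
  expect_equal(nrow(dt), 10 * 5)
  excl <- attr(dt, "exclusions")
  expect_setequal(excl$cell_id, c("bad_short", "bad_late"))
  expect_equal(unname(attr(dt, "n_cells")["TNF"]), 10L)

  # single condition: group values equal a per-trace oracle loop
  aucs <- descriptor_values(dt, "TNF", "auc")
  oracle <- vapply(sort(unique(tr$cell_id)), function(cid) {
    one <- tr[tr$cell_id == cid, ]
    compute_descriptors(compute_fold_change(
      make_trace(one$time_min, one$intensity, id = cid)))$auc
  }, numeric(1))
  expect_equal(sort(aucs), sort(unname(oracle)))

  expect_warning(empty <- descriptor_table(tr[0, ], stimulus_times = 30),
                 "empty")
  expect_equal(nrow(empty), 0)
  expect_error(descriptor_values(dt, "TNF", "nope"), "no 'nope' values")
})

test_that("median AUC and Max fall monotonically with increasing inhibition", {
  med <- function(inh, seed, desc) {
    tr <- simulate_traces(trace_sim_config(n_cells = 40, inhibition_factor = inh,
                                           noise_sd = 0.05, seed = seed))
    median(descriptor_values(descriptor_table(tr, stimulus_times = 30),
                             "TNF", desc))
  }
  doses <- c(1.0, 0.6, 0.3, 0.0)   # rising inhibitor concentration
  for (desc in c("auc", "max_fc")) {
    meds <- vapply(seq_along(doses),
                   function(i) med(doses[i], 700 + i, desc), numeric(1))
    expect_true(all(diff(meds) < 0))
  }
})
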