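test_that("pulse controls are half-open boxes with exact totals", {
  sch <- pulse_schedule("SD", slot_length = 5, h_s = 5, h_d = 5,
                        u_S_rate = 8.2, u_D_rate = 46, t_end = 10)
  ctl <- build_pulse_controls(sch)
  expect_equal(ctl$u_S(2.5), 8.2)
  expect_equal(ctl$u_S(5), 0)      # half-open: off at the slot edge
  expect_equal(ctl$u_D(5), 46)
  expect_equal(ctl$u_D(9.999), 46)
  expect_equal(ctl$u_D(10), 0)
  # delivered totals: rate * h * N, and the quadrature of u agrees
  sch2 <- pulse_schedule("SSSDDD", u_S_rate = 8.2, u_D_rate = 46)
  ctl2 <- build_pulse_controls(sch2)
  expect_equal(ctl2$total_S, 123)
  expect_equal(ctl2$total_D, 690)
  mids <- seq(0.0005, 29.9995, by = 0.001)
  expect_equal(sum(ctl2$u_S(mids)) * 0.001, 123, tolerance = 1e-8)
  expect_equal(sum(ctl2$u_D(mids)) * 0.001, 690, tolerance = 1e-8)
  expect_error(pulse_schedule("SXD"), "over \\{S, D\\}")
  expect_error(pulse_schedule("SD", t_start = 5, t_end = 5), "horizon")
})

test_that("schedule enumeration is exhaustive and sorted", {
  expect_identical(enumerate_schedules(1, 0), "S")
  expect_identical(enumerate_schedules(2, 1), c("DSS", "SDS", "SSD"))
  s33 <- enumerate_schedules(3, 3)
  expect_length(s33, 20)
  expect_identical(s33, sort(s33))
  expect_identical(anyDuplicated(s33), 0L)
})

test_that("rate rescaling preserves fixed drug totals", {
  s <- rescale_rate_for_fixed_total(pulse_schedule("SSSDDD"), total_S = 123,
                                    total_D = 690)
  expect_equal(s$u_S_rate, 8.2)
  expect_equal(s$u_D_rate, 46)
  s2 <- rescale_rate_for_fixed_total(
    pulse_schedule("SSSDDD", h_s = 1), total_S = 123)
  expect_equal(s2$u_S_rate, 41)
  # delivered total is invariant in the on-duration
  for (h in c(2, 1, 0.5, 0.1)) {
    sh <- rescale_rate_for_fixed_total(pulse_schedule("SSSDDD", h_s = h),
                                       total_S = 123)
    expect_equal(build_pulse_controls(sh)$total_S, 123)
  }
})

test_that("zero-rate schedules have unit normalized volume", {
  sch <- pulse_schedule("SSSDDD", u_S_rate = 0, u_D_rate = 0)
  res <- simulate_schedule(default_p, sch, default_th,
                           dt_out = fast$dt_out, dt_max = fast$dt_max)
  expect_equal(res$summary$normalized_volume, 1)
})

test_that("contiguous early IFN-beta beats the scattered worst ordering", {
  nv <- function(sq) {
    sch <- pulse_schedule(sq, u_S_rate = 8.2, u_D_rate = 46)
    simulate_schedule(default_p, sch, default_th, control = "no_ifn",
                      dt_out = fast$dt_out,
                      dt_max = fast$dt_max)$summary$normalized_volume
  }
  expect_lt(nv("SSSDDD"), nv("DSDDSS"))
})

test_that("grouped summaries split and average correctly", {
  scan <- schedule_scan(default_p, dt_out = 0.05, dt_max = 0.01)
  g <- grouped_schedule_summary(scan, "first_drug")
  expect_identical(sort(g$n), c(10L, 10L))
  # IFN-beta-first schedules suppress the anti-apoptotic gate keeper more
  expect_lt(g$mean_B[g$group == "IFN_first"],
            g$mean_B[g$group == "DDP_first"])
  g2 <- grouped_schedule_summary(scan, "first_half_weighting")
  expect_lt(g2$mean_B[g2$group == "IFN_first_half"],
            g2$mean_B[g2$group == "IFN_second_half"])
  expect_lt(g2$normalized_volume[g2$group == "IFN_first_half"],
            g2$normalized_volume[g2$group == "IFN_second_half"])
  # a single-schedule group averages to itself
  one <- grouped_schedule_summary(scan[scan$sequence == "SSSDDD", ],
                                  "first_drug")
  expect_equal(one$normalized_volume,
               scan$normalized_volume[scan$sequence == "SSSDDD"])
  expect_error(grouped_schedule_summary(scan[0, ]), "empty")
})

test_that("dose response is monotone non-increasing and deterministic", {
  grid <- c(0, 8, 20, 60, 100)
  dr <- dose_response(default_p, default_th, u_S_grid = grid,
                      dt_out = fast$dt_out, dt_max = fast$dt_max)
  expect_identical(dr$u_S, grid)
  expect_true(all(diff(dr$volume) <= 1e-9))
  dr2 <- dose_response(default_p, default_th, u_S_grid = grid,
                       dt_out = fast$dt_out, dt_max = fast$dt_max)
  expect_identical(dr$volume, dr2$volume)
})

test_that("minimum-rate bisection hits the target and reports doses", {
  md <- min_rate_for_reduction(default_p, "SSSDDD", bracket = c(4, 16),
                               dt_out = fast$dt_out, dt_max = fast$dt_max)
  expect_lte(md$normalized_volume, 0.5)
  expect_equal(md$normalized_volume, 0.5, tolerance = 1e-2)
  expect_equal(md$total_dose, 3 * 5 * md$u_S)
  expect_equal(md$dose_per_slot, 5 * md$u_S)
  # an infeasible bracket is reported with its endpoint values
  expect_error(
    min_rate_for_reduction(default_p, "SSSDDD", bracket = c(0.01, 0.02),
                           dt_out = 0.05, dt_max = 0.01),
    "bracket does not straddle")
})

test_that("resting-time search degenerates correctly at the extremes", {
  r <- max_resting_time(default_p, "SSSDDD", u_S_rate = 8.2,
                        target_fraction = 1,
                        dt_out = fast$dt_out, dt_max = fast$dt_max)
  expect_equal(r$resting_time, 5)
  expect_true(r$feasible)
  # the scattered alternating ordering cannot afford any rest at this rate
  r2 <- max_resting_time(default_p, "DSDSDS", u_S_rate = 8.2,
                         dt_out = fast$dt_out, dt_max = fast$dt_max)
  expect_equal(r2$resting_time, 0)
  expect_false(r2$feasible)
})

test_that("shorter infusions at fixed totals never improve the mean outcome", {
  seqs <- c("SSSDDD", "SDSDSD", "DSDDSS", "DDSSSD")  # representative subset
  mean_nv <- vapply(c(5, 1, 0.1), function(hs) {
    mean(vapply(seqs, function(sq) {
      sch <- rescale_rate_for_fixed_total(
        pulse_schedule(sq, h_s = hs, h_d = 5), total_S = 123, total_D = 690)
      simulate_schedule(default_p, sch, default_th, control = "no_ifn",
                        dt_out = 0.05,
                        dt_max = 0.01)$summary$normalized_volume
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_nv) >= -1e-9))
})
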