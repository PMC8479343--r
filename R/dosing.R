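#' Pulsed injection schedule
#'
#' A schedule is an ordered string over the alphabet {S, D} -- 'S' slots
#' infuse IFN-beta, 'D' slots cisplatin -- with one slot per `slot_length`
#' time units starting at `t_start`. Within its slot a drug is infused for
#' `h_s` (resp. `h_d`) time units from the slot start at constant rate
#' `u_S_rate` (resp. `u_D_rate`), then rests.
#'
#' @param sequence character string over {S, D}, e.g. `"SSSDDD"`.
#' @param slot_length time per sequence position.
#' @param h_s,h_d infusion durations within a slot (0 < h <= slot_length).
#' @param u_S_rate,u_D_rate infusion rates while on (>= 0).
#' @param t_start,t_end simulation horizon.
#' @return A `pulse_schedule` object.
#' @examples
#' pulse_schedule("SSSDDD", u_S_rate = 8.2, u_D_rate = 46)
#' @export
pulse_schedule <- function(sequence, slot_length = 5, h_s = 5, h_d = 5,
                           u_S_rate = 8.2, u_D_rate = 46,
                           t_start = 0, t_end = 30) {
  letters_ <- strsplit(sequence, "")[[1]]
  if (length(letters_) == 0L || !all(letters_ %in% c("S", "D"))) {
    stop("sequence must be a non-empty string over {S, D}", call. = FALSE)
  }
  if (t_end <= t_start) stop("zero-length horizon", call. = FALSE)
  if (h_s <= 0 || h_d <= 0 || h_s > slot_length || h_d > slot_length) {
    stop("infusion durations must satisfy 0 < h <= slot_length", call. = FALSE)
  }
  if (u_S_rate < 0 || u_D_rate < 0) stop("rates must be >= 0", call. = FALSE)
  structure(list(
    sequence = sequence, letters = letters_, slot_length = slot_length,
    h_s = h_s, h_d = h_d, u_S_rate = u_S_rate, u_D_rate = u_D_rate,
    t_start = t_start, t_end = t_end,
    N_S = sum(letters_ == "S"), N_D = sum(letters_ == "D")
  ), class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat("<pulse_schedule> ", x$sequence, " | slot ", x$slot_length,
      ", h_s = ", x$h_s, ", h_d = ", x$h_d,
      ", u_S = ", x$u_S_rate, ", u_D = ", x$u_D_rate,
      ", horizon [", x$t_start, ", ", x$t_end, "]\n", sep = "")
  invisible(x)
}

#' Build the pulse control functions of a schedule
#'
#' Converts a [pulse_schedule()] into the pair of piecewise-constant
#' infusion-rate functions `u_S(t)`, `u_D(t)` (half-open on-intervals
#' `[t_i, t_i + h)` so abutting pulses never overlap), together with the
#' exact breakpoint list used by the integrator.
#'
#' @param schedule a [pulse_schedule()].
#' @return A `stat_controls` list with elements `u_S`, `u_D` (functions),
#'   `breakpoints`, `total_S`, `total_D` (exact delivered doses
#'   `rate * h * N`).
#' @examples
#' ctl <- build_pulse_controls(pulse_schedule("SD", h_s = 5, h_d = 5))
#' ctl$u_S(2.5); ctl$u_S(7)
#' @export
build_pulse_controls <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  sl <- schedule$slot_length
  starts <- schedule$t_start + (seq_along(schedule$letters) - 1L) * sl
  s_starts <- starts[schedule$letters == "S"]
  d_starts <- starts[schedule$letters == "D"]
  pw <- function(st, h, rate) {
    force(st); force(h); force(rate)
    function(t) {
      on <- vapply(t, function(ti) any(ti >= st & ti < st + h), logical(1))
      ifelse(on, rate, 0)
    }
  }
  structure(list(
    u_S = pw(s_starts, schedule$h_s, schedule$u_S_rate),
    u_D = pw(d_starts, schedule$h_d, schedule$u_D_rate),
    breakpoints = sort(unique(c(s_starts, s_starts + schedule$h_s,
                                d_starts, d_starts + schedule$h_d))),
    total_S = schedule$u_S_rate * schedule$h_s * schedule$N_S,
    total_D = schedule$u_D_rate * schedule$h_d * schedule$N_D,
    schedule = schedule
  ), class = "stat_controls")
}

#' Enumerate all drug orderings
#'
#' All distinct sequences containing `N_S` 'S' slots and `N_D` 'D' slots,
#' lexicographically sorted ('D' < 'S').
#'
#' @param N_S,N_D non-negative slot counts.
#' @return Character vector of length `choose(N_S + N_D, N_S)`.
#' @examples
#' enumerate_schedules(2, 1)
#' length(enumerate_schedules(3, 3)) # 20
#' @export
enumerate_schedules <- function(N_S, N_D) {
  if (N_S < 0 || N_D < 0) stop("counts must be >= 0", call. = FALSE)
  n <- N_S + N_D
  if (n == 0L) return(character(0))
  if (N_S == 0L) return(strrep("D", N_D))
  pos <- utils::combn(n, N_S, simplify = FALSE)
  seqs <- vapply(pos, function(ix) {
    s <- rep("D", n)
    s[ix] <- "S"
    paste(s, collapse = "")
  }, character(1))
  sort(seqs)
}

#' Simulate one schedule and normalize the outcome
#'
#' Runs the full model under a pulsed schedule and divides the final tumour
#' volume by that of a control run: either the same schedule with the
#' IFN-beta rate zeroed (`control = "no_ifn"`, keeping the cisplatin pulses;
#' the convention of the minimum-dose experiments) or a fully untreated run
#' (`control = "untreated"`).
#'
#' @param params a [stat_params()] object.
#' @param schedule a [pulse_schedule()].
#' @param thresholds a [stat_thresholds()] object.
#' @param init initial state.
#' @param control which control run normalizes the volume.
#' @param t_eval evaluation time (defaults to the schedule horizon end).
#' @param dt_out,dt_max integrator settings (see [simulate_model()]).
#' @return A `stat_schedule_result` list: `trajectory`, `control_trajectory`,
#'   and a one-row `summary` tibble (sequence, rates, final volumes,
#'   `normalized_volume`, delivered doses, apoptosis on-time).
#' @export
simulate_schedule <- function(params = stat_params(), schedule,
                              thresholds = stat_thresholds(),
                              init = default_initial_state(params, thresholds),
                              control = c("no_ifn", "untreated"),
                              t_eval = NULL, dt_out = 0.01, dt_max = 0.002) {
  control <- match.arg(control)
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (is.null(t_eval)) t_eval <- schedule$t_end
  ctl <- build_pulse_controls(schedule)
  tr <- simulate_model(params, thresholds, init,
                       t_start = schedule$t_start, t_end = schedule$t_end,
                       u_S = ctl, dt_out = dt_out, dt_max = dt_max)
  ref_schedule <- schedule
  ref_schedule$u_S_rate <- 0
  if (control == "untreated") ref_schedule$u_D_rate <- 0
  ref_ctl <- build_pulse_controls(ref_schedule)
  ctr <- simulate_model(params, thresholds, init,
                        t_start = schedule$t_start, t_end = schedule$t_end,
                        u_S = ref_ctl, dt_out = dt_out, dt_max = dt_max)
  T_tr <- volume_at(tr, t_eval)
  T_ct <- volume_at(ctr, t_eval)
  dt <- diff(tr$time)
  on_time <- sum(dt * (tr$indicator[-1] + tr$indicator[-nrow(tr)]) / 2)
  summary <- tibble::tibble(
    sequence = schedule$sequence,
    u_S = schedule$u_S_rate, u_D = schedule$u_D_rate,
    h_s = schedule$h_s, h_d = schedule$h_d,
    t_eval = t_eval,
    T_treated = T_tr, T_control = T_ct,
    normalized_volume = T_tr / T_ct,
    total_dose_S = ctl$total_S, total_dose_D = ctl$total_D,
    apoptosis_time = on_time,
    control = control
  )
  structure(list(trajectory = tr, control_trajectory = ctr,
                 summary = summary),
            class = "stat_schedule_result")
}

volume_at <- function(trajectory, t_eval) {
  stats::approx(trajectory$time, trajectory$T, xout = t_eval)$y
}

#' @export
print.stat_schedule_result <- function(x, ...) {
  cat("<stat_schedule_result>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.stat_schedule_result <- function(x, ...) x$summary

#' Batch-run every ordering of a slot design
#'
#' Simulates all `choose(N_S + N_D, N_S)` orderings at fixed rates and
#' durations and collects per-schedule outcomes, including horizon-averaged
#' intracellular levels (used by the grouped summaries).
#'
#' @inheritParams simulate_schedule
#' @param N_S,N_D slot counts.
#' @param u_S_rate,u_D_rate,slot_length,h_s,h_d,t_end schedule design.
#' @return Tibble, one row per sequence, with normalized volume, doses and
#'   time-averaged `S1, S3, B, X`.
#' @export
schedule_scan <- function(params = stat_params(), N_S = 3, N_D = 3,
                          u_S_rate = 8.2, u_D_rate = 46, slot_length = 5,
                          h_s = 5, h_d = 5, t_end = 30,
                          thresholds = stat_thresholds(),
                          init = default_initial_state(params, thresholds),
                          control = c("no_ifn", "untreated"),
                          dt_out = 0.01, dt_max = 0.002) {
  control <- match.arg(control)
  seqs <- enumerate_schedules(N_S, N_D)
  rows <- lapply(seqs, function(sq) {
    sch <- pulse_schedule(sq, slot_length = slot_length, h_s = h_s, h_d = h_d,
                          u_S_rate = u_S_rate, u_D_rate = u_D_rate,
                          t_start = 0, t_end = t_end)
    res <- simulate_schedule(params, sch, thresholds, init, control,
                             dt_out = dt_out, dt_max = dt_max)
    tr <- res$trajectory
    means <- vapply(c("S1", "S3", "B", "X"),
                    function(v) mean(tr[[v]]), numeric(1))
    dplyr::bind_cols(res$summary,
                     tibble::tibble(mean_S1 = means[["S1"]],
                                    mean_S3 = means[["S3"]],
                                    mean_B = means[["B"]],
                                    mean_X = means[["X"]]))
  })
  dplyr::bind_rows(rows)
}

#' Group-average schedule outcomes
#'
#' Splits the batch results of [schedule_scan()] into two groups -- by which
#' drug is injected first (`grouping = "first_drug"`) or by whether IFN-beta
#' is more frequent in the first half of the sequence
#' (`grouping = "first_half_weighting"`; balanced sequences count as
#' second-half weighted) -- and averages the intracellular levels and the
#' normalized tumour volume within each group.
#'
#' @param results tibble from [schedule_scan()].
#' @param grouping `"first_drug"` or `"first_half_weighting"`.
#' @return Tibble with one row per group.
#' @export
grouped_schedule_summary <- function(results,
                                     grouping = c("first_drug",
                                                  "first_half_weighting")) {
  grouping <- match.arg(grouping)
  if (nrow(results) == 0L) stop("empty results", call. = FALSE)
  if (grouping == "first_drug") {
    grp <- ifelse(substr(results$sequence, 1, 1) == "S",
                  "IFN_first", "DDP_first")
  } else {
    half <- nchar(results$sequence) %/% 2
    n_first <- vapply(seq_len(nrow(results)), function(i) {
      sum(strsplit(substr(results$sequence[i], 1, half[i]), "")[[1]] == "S")
    }, integer(1))
    n_total <- vapply(strsplit(results$sequence, ""),
                      function(s) sum(s == "S"), integer(1))
    grp <- ifelse(n_first * 2 > n_total, "IFN_first_half", "IFN_second_half")
  }
  out <- results |>
    dplyr::mutate(group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(c("mean_S1", "mean_S3", "mean_B", "mean_X",
                                    "normalized_volume")), mean),
      .groups = "drop"
    )
  if (any(out$n == 0L)) stop("empty group", call. = FALSE)
  out
}

#' Dose-response of pulsed IFN-beta monotherapy
#'
#' Simulates repeated short IFN-beta infusions (no cisplatin) at each rate
#' in `u_S_grid` and reports the tumour volume at the evaluation time.
#'
#' @param params,thresholds,init model setup.
#' @param pulse_times pulse onset times.
#' @param h pulse width.
#' @param u_S_grid infusion rates to test.
#' @param t_eval evaluation time.
#' @param t_end simulation end (>= `t_eval`).
#' @param dt_out,dt_max integrator settings.
#' @return Tibble with columns `u_S` and `volume`.
#' @export
dose_response <- function(params = stat_params(),
                          thresholds = stat_thresholds(),
                          init = default_initial_state(params, thresholds),
                          pulse_times = c(1, 3, 5, 7, 9), h = 1,
                          u_S_grid = c(0, 2, 4, 6, 8, 10, 15, 20, 40, 60, 100),
                          t_eval = 25, t_end = 25,
                          dt_out = 0.01, dt_max = 0.002) {
  if (any(u_S_grid < 0)) stop("rates must be non-negative", call. = FALSE)
  vols <- vapply(u_S_grid, function(u) {
    ctl <- structure(list(
      u_S = function(t) ifelse(vapply(t, function(ti)
        any(ti >= pulse_times & ti < pulse_times + h), logical(1)), u, 0),
      u_D = function(t) rep(0, length(t)),
      breakpoints = sort(unique(c(pulse_times, pulse_times + h)))
    ), class = "stat_controls")
    tr <- simulate_model(params, thresholds, init, t_end = t_end,
                         u_S = ctl, dt_out = dt_out, dt_max = dt_max)
    volume_at(tr, t_eval)
  }, numeric(1))
  tibble::tibble(u_S = u_S_grid, volume = vols)
}

#' Minimum IFN-beta rate for a target tumour reduction
#'
#' Bisection on the IFN-beta infusion rate of a schedule until the final
#' normalized tumour volume (relative to the no-IFN-beta control) hits the
#' target fraction, returning the smallest rate achieving at most the
#' target. The bracket is auto-expanded (up to 4 doublings) and must
#' straddle the target; the response is checked to be monotone between the
#' bracket endpoints.
#'
#' @inheritParams simulate_schedule
#' @param sequence schedule string, e.g. `"SSSDDD"`.
#' @param target_fraction target normalized volume in (0, 1).
#' @param u_D_rate,slot_length,h_s,h_d,t_end schedule design.
#' @param bracket initial rate bracket.
#' @param tol bisection tolerance on the rate.
#' @return One-row tibble: `sequence, u_S, normalized_volume,
#'   dose_per_slot` (`h_s * u_S`) and `total_dose` (`N_S * h_s * u_S`).
#' @export
min_rate_for_reduction <- function(params = stat_params(), sequence,
                                   target_fraction = 0.5, u_D_rate = 46,
                                   slot_length = 5, h_s = 5, h_d = 5,
                                   t_end = 30, bracket = c(0.5, 16),
                                   tol = 1e-3,
                                   thresholds = stat_thresholds(),
                                   init = default_initial_state(params, thresholds),
                                   dt_out = 0.01, dt_max = 0.002) {
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must be in (0, 1)", call. = FALSE)
  }
  nv <- function(u) {
    sch <- pulse_schedule(sequence, slot_length, h_s, h_d,
                          u_S_rate = u, u_D_rate = u_D_rate, t_end = t_end)
    simulate_schedule(params, sch, thresholds, init, control = "no_ifn",
                      dt_out = dt_out, dt_max = dt_max)$summary$normalized_volume
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- nv(lo); f_hi <- nv(hi)
  expansions <- 0L
  while (f_hi > target_fraction && expansions < 4L) {
    hi <- hi * 2; f_hi <- nv(hi); expansions <- expansions + 1L
  }
  if (f_lo < target_fraction || f_hi > target_fraction) {
    stop(sprintf(
      "bracket does not straddle the target: f(%g) = %.4f, f(%g) = %.4f",
      lo, f_lo, hi, f_hi), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nv(mid) > target_fraction) lo <- mid else hi <- mid
  }
  u_min <- hi   # smallest tested rate achieving <= target
  N_S <- sum(strsplit(sequence, "")[[1]] == "S")
  tibble::tibble(
    sequence = sequence, u_S = u_min,
    normalized_volume = nv(u_min),
    dose_per_slot = h_s * u_min,
    total_dose = N_S * h_s * u_min
  )
}

#' Maximum IFN-beta resting time at fixed rate
#'
#' Bisection on the per-slot infusion duration `h_s` for the smallest
#' duration that still achieves the target reduction at a fixed infusion
#' rate; the resting time is `slot_length - h_s`. If even continuous
#' infusion (`h_s = slot_length`) misses the target, the resting time is 0
#' with `feasible = FALSE`.
#'
#' @inheritParams min_rate_for_reduction
#' @param u_S_rate fixed IFN-beta rate during the on-intervals.
#' @return One-row tibble: `sequence, u_S, h_s, resting_time,
#'   normalized_volume, feasible`.
#' @export
max_resting_time <- function(params = stat_params(), sequence,
                             u_S_rate = 8.2, target_fraction = 0.5,
                             u_D_rate = 46, slot_length = 5, h_d = 5,
                             t_end = 30, tol = 1e-3,
                             thresholds = stat_thresholds(),
                             init = default_initial_state(params, thresholds),
                             dt_out = 0.01, dt_max = 0.002) {
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  }
  nv <- function(h) {
    sch <- pulse_schedule(sequence, slot_length, h_s = h, h_d = h_d,
                          u_S_rate = u_S_rate, u_D_rate = u_D_rate,
                          t_end = t_end)
    simulate_schedule(params, sch, thresholds, init, control = "no_ifn",
                      dt_out = dt_out, dt_max = dt_max)$summary$normalized_volume
  }
  if (target_fraction == 1) {
    h_min <- tol  # any dosing meets the target; rest the whole slot
    return(tibble::tibble(sequence = sequence, u_S = u_S_rate, h_s = 0,
                          resting_time = slot_length,
                          normalized_volume = 1, feasible = TRUE))
  }
  f_full <- nv(slot_length)
  if (f_full > target_fraction) {
    return(tibble::tibble(sequence = sequence, u_S = u_S_rate,
                          h_s = slot_length, resting_time = 0,
                          normalized_volume = f_full, feasible = FALSE))
  }
  lo <- tol; hi <- slot_length
  if (nv(lo) <= target_fraction) {
    hi <- lo
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (nv(mid) > target_fraction) lo <- mid else hi <- mid
    }
  }
  tibble::tibble(
    sequence = sequence, u_S = u_S_rate, h_s = hi,
    resting_time = slot_length - hi,
    normalized_volume = nv(hi), feasible = TRUE
  )
}

#' Rescale a schedule's rate to deliver a fixed total dose
#'
#' Sets the infusion rate so that `rate * h * N` equals the requested total;
#' used by the duration experiments where total drug amount is held fixed
#' while the per-slot duration varies.
#'
#' @param schedule a [pulse_schedule()].
#' @param total_S,total_D requested totals (NULL leaves a drug unchanged).
#' @return The schedule with updated rates.
#' @examples
#' s <- rescale_rate_for_fixed_total(pulse_schedule("SSSDDD"), total_S = 123)
#' s$u_S_rate # 8.2
#' @export
rescale_rate_for_fixed_total <- function(schedule, total_S = NULL,
                                         total_D = NULL) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (!is.null(total_S)) {
    denom <- schedule$N_S * schedule$h_s
    if (denom <= 0) stop("zero total IFN-beta infusion duration", call. = FALSE)
    schedule$u_S_rate <- total_S / denom
  }
  if (!is.null(total_D)) {
    denom <- schedule$N_D * schedule$h_d
    if (denom <= 0) stop("zero total cisplatin infusion duration", call. = FALSE)
    schedule$u_D_rate <- total_D / denom
  }
  schedule
}
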