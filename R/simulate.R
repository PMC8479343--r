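#' Default initial state
#'
#' The simulation experiments start from the anti-apoptotic (Pt) resting
#' state of an untreated cell: the intracellular variables sit at the stable
#' Pt equilibrium computed at `S = 0` and the baseline JAK2 level
#' `J = Js / muJ`, with no drug on board. The initial tumour volume defaults
#' to 0.1 (0.1% of the carrying capacity), the value consistent with the
#' desired-volume convention used by the optimal-control experiments.
#'
#' @param params a [stat_params()] object.
#' @param thresholds a [stat_thresholds()] object.
#' @param T0_init initial tumour volume (dimensionless).
#' @return Named numeric vector `S1, S3, B, X, T, S, J, D`.
#' @examples
#' default_initial_state()
#' @export
default_initial_state <- function(params = stat_params(),
                                  thresholds = stat_thresholds(),
                                  T0_init = 0.1) {
  J0 <- params$Js / params$muJ
  eq <- find_equilibria(params, S = 0, J = J0, thresholds = thresholds)
  pt <- eq[eq$stable & eq$phase == "Pt", ]
  if (nrow(pt) == 0L) {
    # fall back to the lowest-STAT1 stable state
    pt <- eq[eq$stable, ][which.min(eq$S1[eq$stable]), ]
  }
  c(S1 = pt$S1[1], S3 = pt$S3[1], B = pt$B[1], X = pt$X[1],
    T = T0_init, S = 0, J = J0, D = 0)
}

#' Simulate the eight-state model
#'
#' Integrates STAT1, STAT3, Bcl-2, BAX, tumour volume, IFN-beta, JAK2 and
#' cisplatin forward in time under the given infusion controls, with the
#' apoptosis indicator re-evaluated continuously from (Bcl-2, BAX). The
#' integrator is fixed-step RK4 with sub-steps no longer than `dt_max`;
#' breakpoints of piecewise-constant controls (pulse edges) are placed
#' exactly on grid nodes so each step sees a constant infusion rate.
#'
#' @param params a [stat_params()] object.
#' @param thresholds a [stat_thresholds()] object.
#' @param init named initial state (see [default_initial_state()]).
#' @param t_start,t_end simulation span (`t_end > t_start`).
#' @param u_S,u_D infusion controls: a number (constant rate), a function of
#'   time, or a `stat_controls` pair from [build_pulse_controls()] (then both
#'   are taken from it and `u_D` is ignored).
#' @param dt_out spacing of output/control nodes.
#' @param dt_max maximum RK4 sub-step.
#' @param indicator_mode `"hard"` (discontinuous switch) or `"smooth"`
#'   (steep product-of-sigmoids relaxation).
#' @param smooth_k sigmoid steepness for `indicator_mode = "smooth"`.
#' @return A `stat_trajectory`: a tibble with columns `time`, the 8 states,
#'   `indicator` and `phase`, carrying solver metadata as attributes.
#' @examples
#' tr <- simulate_model(t_end = 5, u_S = 15)
#' tail(tr)
#' @export
simulate_model <- function(params = stat_params(),
                           thresholds = stat_thresholds(),
                           init = default_initial_state(params, thresholds),
                           t_start = 0, t_end = 30,
                           u_S = 0, u_D = 0,
                           dt_out = 0.01, dt_max = 0.002,
                           indicator_mode = c("hard", "smooth"),
                           smooth_k = 100) {
  indicator_mode <- match.arg(indicator_mode)
  if (!is.numeric(t_end) || t_end <= t_start) {
    stop("t_span is degenerate: need t_end > t_start", call. = FALSE)
  }
  y0 <- unlist(init)[state_names]
  if (any(is.na(y0)) || any(y0 < 0)) {
    stop("initial state must be non-negative and name all 8 variables",
         call. = FALSE)
  }
  breaks <- numeric(0)
  if (inherits(u_S, "stat_controls")) {
    breaks <- u_S$breakpoints
    u_D <- u_S$u_D
    u_S <- u_S$u_S
  }
  u_Sf <- as_control_fn(u_S)
  u_Df <- as_control_fn(u_D)
  times <- control_grid(t_start, t_end, dt_out, breaks)
  mid <- (times[-1] + times[-length(times)]) / 2
  uS <- vapply(mid, u_Sf, numeric(1))
  uD <- vapply(mid, u_Df, numeric(1))
  if (any(uS < 0) || any(uD < 0)) {
    stop("controls must be non-negative over the horizon", call. = FALSE)
  }
  states <- sim_rk4_cpp(times, y0, as.double(params), unclass(thresholds),
                        uS, uD, dt_max, indicator_mode == "smooth", smooth_k)
  colnames(states) <- state_names
  out <- tibble::as_tibble(as.data.frame(states))
  out <- tibble::add_column(out, time = times, .before = 1)
  out$indicator <- apoptosis_indicator(out$B, out$X, thresholds)
  out$phase <- classify_phase(out$B, out$X, thresholds)
  attr(out, "params") <- params
  attr(out, "thresholds") <- thresholds
  attr(out, "solver") <- list(method = "rk4", dt_out = dt_out, dt_max = dt_max,
                              indicator_mode = indicator_mode,
                              smooth_k = smooth_k,
                              n_nodes = length(times))
  class(out) <- c("stat_trajectory", class(out))
  out
}

control_grid <- function(t_start, t_end, dt_out, breaks = numeric(0)) {
  base <- seq(t_start, t_end, by = dt_out)
  if (base[length(base)] < t_end) base <- c(base, t_end)
  breaks <- breaks[breaks > t_start & breaks < t_end]
  times <- sort(unique(c(base, breaks)))
  # drop nodes that coincide to numerical precision
  keep <- c(TRUE, diff(times) > 1e-12)
  times[keep]
}

#' @export
print.stat_trajectory <- function(x, ...) {
  meta <- attr(x, "solver")
  cat("<stat_trajectory> ", nrow(x), " time points over [",
      format(x$time[1]), ", ", format(x$time[nrow(x)]), "], ",
      meta$method, " (dt_max = ", format(meta$dt_max), ")\n", sep = "")
  NextMethod()
}

#' Summarize a trajectory
#'
#' @param x a `stat_trajectory`.
#' @param ... unused.
#' @return One-row tibble with the final state, final phase, and the total
#'   time the apoptosis indicator was on (trapezoid of the indicator column).
#' @export
glance.stat_trajectory <- function(x, ...) {
  n <- nrow(x)
  dt <- diff(x$time)
  on_time <- sum(dt * (x$indicator[-1] + x$indicator[-n]) / 2)
  tibble::tibble(
    t_final = x$time[n],
    T_final = x$T[n],
    phase_final = as.character(x$phase[n]),
    apoptosis_time = on_time
  )
}
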