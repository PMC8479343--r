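#' Objective weights of the dosing control problem
#'
#' Running cost `A1 (T - T_bar)^2 + A2 B^2 - A3 X^2 + C1 u_S + C2 u_D +
#' C3 u_S^2 + C4 u_D^2` integrated over `[t_s, t_e]`: the tumour is pushed
#' toward the desired volume while Bcl-2 is minimized and BAX maximized, and
#' drug use is penalized linearly (total amount) and quadratically
#' (convexity).
#'
#' @param A1,A2,A3 state weights (tumour deviation, Bcl-2, BAX), >= 0.
#' @param C1,C2,C3,C4 control cost weights (linear IFN-beta, linear DDP,
#'   quadratic IFN-beta, quadratic DDP), >= 0.
#' @param T_bar desired tumour volume.
#' @param t_s,t_e horizon endpoints.
#' @return A `control_weights` object.
#' @examples
#' strategy_I_weights()
#' strategy_II_weights()
#' @export
control_weights <- function(A1, A2, A3, C1, C2, C3, C4, T_bar,
                            t_s = 0, t_e = 30) {
  w <- c(A1 = A1, A2 = A2, A3 = A3, C1 = C1, C2 = C2, C3 = C3, C4 = C4,
         T_bar = T_bar)
  if (any(!is.finite(w)) || any(w[1:7] < 0)) {
    stop("weights must be finite and A1..A3, C1..C4 non-negative",
         call. = FALSE)
  }
  structure(list(A1 = A1, A2 = A2, A3 = A3, C1 = C1, C2 = C2, C3 = C3,
                 C4 = C4, T_bar = T_bar, t_s = t_s, t_e = t_e),
            class = "control_weights")
}

#' @rdname control_weights
#' @export
strategy_I_weights <- function() {
  control_weights(1, 0, 0, 4e-5, 1e-5, 4e-5, 1e-5, 0)
}

#' @rdname control_weights
#' @export
strategy_II_weights <- function() {
  control_weights(12, 1, 4, 2e-2, 0, 2e-2, 0, 1.7634)
}

weights_vec <- function(w) {
  c(w$A1, w$A2, w$A3, w$C1, w$C2, w$C3, w$C4, w$T_bar)
}

#' Define an optimal dosing problem
#'
#' Bundles the model, the objective weights, box bounds on the two infusion
#' rates, optional support masks restricting when each control may be
#' nonzero (Strategy II optimizes IFN-beta only on its scheduled slots), and
#' optional fixed background controls (e.g. cisplatin pulses held fixed
#' while only IFN-beta is optimized).
#'
#' @param params,thresholds,init model setup.
#' @param weights a [control_weights()] object.
#' @param u_S_max,u_D_max control upper bounds.
#' @param optimize_S,optimize_D whether each control is optimized. A control
#'   that is not optimized follows its `fixed_u_*` function.
#' @param mask_S,mask_D `NULL` (no restriction) or a function of time
#'   returning TRUE where the control may be nonzero.
#' @param fixed_u_S,fixed_u_D background controls for non-optimized drugs
#'   (number or function of time).
#' @param dt grid spacing for the sweep.
#' @param dt_max RK4 sub-step.
#' @param indicator_mode `"smooth"` (default for optimization: the tumour
#'   equation uses a steep product-of-sigmoids indicator, so the
#'   control-to-state map stays differentiable) or `"hard"` (discontinuous
#'   indicator, frozen at its forward-pass values in the adjoint).
#' @param smooth_k sigmoid steepness.
#' @param breakpoints extra time nodes (pulse edges of fixed controls).
#' @return A `control_problem` object.
#' @export
control_problem <- function(params = stat_params(),
                            thresholds = stat_thresholds(),
                            init = default_initial_state(params, thresholds),
                            weights = strategy_I_weights(),
                            u_S_max = 50, u_D_max = 100,
                            optimize_S = TRUE, optimize_D = TRUE,
                            mask_S = NULL, mask_D = NULL,
                            fixed_u_S = 0, fixed_u_D = 0,
                            dt = 0.01, dt_max = 0.002,
                            indicator_mode = c("smooth", "hard"),
                            smooth_k = 100, breakpoints = numeric(0)) {
  indicator_mode <- match.arg(indicator_mode)
  if (u_S_max < 0 || u_D_max < 0) stop("bounds must be >= 0", call. = FALSE)
  if (optimize_S && weights$C3 <= 0) {
    stop("optimizing u_S requires a positive quadratic weight C3",
         call. = FALSE)
  }
  if (optimize_D && weights$C4 <= 0) {
    stop("optimizing u_D requires a positive quadratic weight C4",
         call. = FALSE)
  }
  times <- control_grid(weights$t_s, weights$t_e, dt, breakpoints)
  mid <- (times[-1] + times[-length(times)]) / 2
  msk <- function(mask) {
    if (is.null(mask)) rep(TRUE, length(mid)) else vapply(mid, mask, logical(1))
  }
  structure(list(
    params = params, thresholds = thresholds, init = unlist(init)[state_names],
    weights = weights, u_S_max = u_S_max, u_D_max = u_D_max,
    optimize_S = optimize_S, optimize_D = optimize_D,
    mask_S = msk(mask_S), mask_D = msk(mask_D),
    fixed_u_S = vapply(mid, as_control_fn(fixed_u_S), numeric(1)),
    fixed_u_D = vapply(mid, as_control_fn(fixed_u_D), numeric(1)),
    times = times, mid = mid, dt_max = dt_max,
    indicator_mode = indicator_mode, smooth_k = smooth_k
  ), class = "control_problem")
}

# forward solve on the problem grid; uS/uD are per-interval values
forward_pass <- function(pb, uS, uD) {
  states <- sim_rk4_cpp(pb$times, pb$init, as.double(pb$params),
                        unclass(pb$thresholds), uS, uD, pb$dt_max,
                        pb$indicator_mode == "smooth", pb$smooth_k)
  colnames(states) <- state_names
  states
}

#' Running-cost integral of a trajectory
#'
#' Composite-trapezoid evaluation of the objective integrand on the solution
#' grid, with per-interval (piecewise constant) controls.
#'
#' @param states matrix or data frame of the 8 states at the time nodes.
#' @param times time nodes covering the horizon.
#' @param uS,uD control values on the intervals between nodes.
#' @param weights a [control_weights()] object.
#' @return Scalar cost.
#' @export
objective_value <- function(states, times, uS, uD, weights) {
  w <- weights
  if (times[1] > w$t_s + 1e-9 || times[length(times)] < w$t_e - 1e-9) {
    stop("grid does not cover the horizon", call. = FALSE)
  }
  st <- as.matrix(as.data.frame(states)[, state_names])
  Lstate <- w$A1 * (st[, "T"] - w$T_bar)^2 + w$A2 * st[, "B"]^2 -
    w$A3 * st[, "X"]^2
  dt <- diff(times)
  state_part <- sum(dt * (Lstate[-1] + Lstate[-length(Lstate)]) / 2)
  ctrl_part <- sum(dt * (w$C1 * uS + w$C2 * uD + w$C3 * uS^2 + w$C4 * uD^2))
  state_part + ctrl_part
}

#' Costate derivatives of the dosing Hamiltonian
#'
#' `-dH/dx` for `H = L + lambda . f`, with the apoptosis indicator treated
#' as a frozen exogenous value `I` (its forward-pass value) in hard mode;
#' in smooth mode the sigmoid relaxation and its B/X derivatives are used.
#' Terminal condition is `lambda(t_e) = 0`.
#'
#' @param state named 8-state vector at time t.
#' @param adjoint 8-vector of costates (ordered as the states).
#' @param indicator frozen indicator value at time t (hard mode).
#' @param params,thresholds,weights model and objective.
#' @param indicator_mode,smooth_k see [control_problem()].
#' @return Named 8-vector of costate time derivatives.
#' @export
adjoint_rhs <- function(state, adjoint, indicator, params = stat_params(),
                        thresholds = stat_thresholds(),
                        weights = strategy_I_weights(),
                        indicator_mode = c("hard", "smooth"),
                        smooth_k = 100) {
  indicator_mode <- match.arg(indicator_mode)
  p <- params
  w <- weights
  y <- unlist(state)[state_names]
  lam <- unname(unlist(adjoint))
  S1 <- y[["S1"]]; S3 <- y[["S3"]]; B <- y[["B"]]; X <- y[["X"]]
  T <- y[["T"]]; S <- y[["S"]]; J <- y[["J"]]; D <- y[["D"]]
  d1 <- p$k2^2 + p$alpha * S3^2
  d2 <- p$k4^2 + p$beta * S1^2
  d3 <- p$k6^2 + p$gamma * S1^2
  d4 <- p$k8^2 + p$delta * B^2
  d5 <- p$K + p$lambda_S2 * S
  df1dS3 <- -2 * p$k1 * p$k2^2 * p$alpha * S3 / d1^2
  df2dS1 <- -2 * p$k3 * p$k4^2 * p$beta * S1 / d2^2
  df2dS <- -(p$lambda_k + p$lambda_J * J) * p$lambda_S2 / d5^2
  df2dJ <- p$lambda_J / d5
  df3dS1 <- -2 * p$k5 * p$k6^2 * p$gamma * S1 / d3^2
  df4dB <- -2 * p$k7 * p$k8^2 * p$delta * B / d4^2
  phi <- S1^2 / (p$k10^2 + S1^2)
  dphi <- 2 * S1 * p$k10^2 / (p$k10^2 + S1^2)^2
  logis <- T * (1 - T / p$T0)
  I <- indicator
  df5dB <- 0; df5dX <- 0
  if (indicator_mode == "smooth") {
    Bth <- thresholds[["B_th"]]; Xth <- thresholds[["X_th"]]
    sB <- stats::plogis(smooth_k * (Bth - B))
    sX <- stats::plogis(smooth_k * (X - Xth))
    I <- sB * sX
    dIdB <- -smooth_k * sB * (1 - sB) * sX
    dIdX <- smooth_k * sX * (1 - sX) * sB
    fac <- -p$r * p$k9 * phi * logis - p$muT * T
    df5dB <- fac * dIdB
    df5dX <- fac * dIdX
  }
  df5dS1 <- -p$r * p$k9 * I * dphi * logis
  df5dT <- p$r * (1 - p$k9 * phi * I) * (1 - 2 * T / p$T0) - p$muT * I
  out <- c(
    S1 = -(-lam[1] + lam[2] * df2dS1 + lam[3] * df3dS1 + lam[5] * df5dS1),
    S3 = -(lam[1] * df1dS3 - lam[2] * p$mu3 + lam[3] * p$lambda3),
    B = -(2 * w$A2 * B + lam[4] * df4dB - lam[3] * p$muB + lam[5] * df5dB),
    X = -(-2 * w$A3 * X - lam[4] * p$muX + lam[5] * df5dX),
    T = -(2 * w$A1 * (T - w$T_bar) + lam[5] * df5dT),
    S = -(lam[1] * p$lambda_S1 + lam[2] * df2dS - lam[6] * p$muS),
    J = -(lam[2] * df2dJ + lam[7] * (-p$gammaD * D - p$muJ)),
    D = -(lam[7] * (-p$gammaD * J) - lam[8] * p$muD)
  )
  if (any(!is.finite(out))) stop("non-finite costate derivative", call. = FALSE)
  out
}

#' Pointwise control update from Hamiltonian stationarity
#'
#' For quadratic-plus-linear control costs the interior stationary point of
#' the Hamiltonian is `u_S* = (-C1 - lambda_S) / (2 C3)` (and analogously
#' for cisplatin with `C2`, `C4`, `lambda_D`), clipped to the control box
#' and zeroed off the support mask.
#'
#' @param lambda_S,lambda_D costates of the IFN-beta and cisplatin equations
#'   on the control grid.
#' @param weights a [control_weights()] object.
#' @param u_S_max,u_D_max bounds.
#' @param mask_S,mask_D logical support masks.
#' @return List with vectors `u_S`, `u_D`.
#' @export
control_update <- function(lambda_S, lambda_D, weights,
                           u_S_max = 50, u_D_max = 100,
                           mask_S = TRUE, mask_D = TRUE) {
  w <- weights
  if (w$C3 <= 0 || w$C4 <= 0) {
    # only the controls actually updated need a positive quadratic weight;
    # callers pass through only those, but guard direct misuse
    if (w$C3 <= 0 && w$C4 <= 0) {
      stop("quadratic weights must be positive for the stationarity update",
           call. = FALSE)
    }
  }
  uS <- if (w$C3 > 0) pmin(pmax((-w$C1 - lambda_S) / (2 * w$C3), 0), u_S_max)
        else rep(0, length(lambda_S))
  uD <- if (w$C4 > 0) pmin(pmax((-w$C2 - lambda_D) / (2 * w$C4), 0), u_D_max)
        else rep(0, length(lambda_D))
  list(u_S = uS * as.numeric(mask_S), u_D = uD * as.numeric(mask_D))
}

#' Forward-backward sweep solver
#'
#' Iterates a forward state solve, a backward adjoint solve with zero
#' terminal costate, the pointwise stationarity update of the controls, and
#' a relaxed acceptance `u <- c u_new + (1 - c) u_old`. Convergence is
#' declared when the relative L1 distance between the current controls and
#' their unrelaxed stationarity update falls below `tol` (a fixed-point
#' residual, so a shrinking step cannot fake convergence). With
#' `adapt_relax = TRUE` the relaxation factor is halved whenever the
#' objective increases and grown 10% on success (capped at `relax`), which
#' stabilizes the sweep against the steep indicator nonlinearity of the
#' tumour equation. The algorithm is deterministic: identical inputs give
#' identical iteration logs.
#'
#' @param problem a [control_problem()].
#' @param u_S_init,u_D_init initial control guesses (scalar or vector on the
#'   grid intervals).
#' @param relax initial relaxation factor `c` in (0, 1].
#' @param tol relative L1 fixed-point tolerance on the controls.
#' @param max_iter iteration cap; reaching it returns the last iterate
#'   flagged `converged = FALSE`.
#' @param adapt_relax halve the relaxation on objective increases.
#' @return A `stat_control_solution` list: `solution` tibble (time, states,
#'   controls, costates), `objective`, `iterations` log tibble, `converged`,
#'   `totals` (delivered doses), and the problem.
#' @export
forward_backward_sweep <- function(problem, u_S_init = 0, u_D_init = 0,
                                   relax = 0.5, tol = 1e-3, max_iter = 500,
                                   adapt_relax = TRUE) {
  pb <- problem
  if (relax <= 0 || relax > 1) stop("relax must be in (0, 1]", call. = FALSE)
  m <- length(pb$mid)
  uS <- rep(u_S_init, length.out = m) * as.numeric(pb$mask_S)
  uD <- rep(u_D_init, length.out = m) * as.numeric(pb$mask_D)
  if (!pb$optimize_S) uS <- pb$fixed_u_S
  if (!pb$optimize_D) uD <- pb$fixed_u_D
  wv <- weights_vec(pb$weights)
  log_rows <- vector("list", max_iter)
  converged <- FALSE
  relax0 <- relax
  obj_prev <- Inf
  states <- forward_pass(pb, uS, uD)
  for (it in seq_len(max_iter)) {
    ind <- apoptosis_indicator(states[, "B"], states[, "X"], pb$thresholds)
    lam <- adjoint_rk4_cpp(pb$times, states, as.double(pb$params),
                           unclass(pb$thresholds), wv, as.numeric(ind),
                           pb$dt_max, pb$indicator_mode == "smooth",
                           pb$smooth_k)
    lam_mid_S <- (lam[-1, 6] + lam[-(m + 1), 6]) / 2
    lam_mid_D <- (lam[-1, 8] + lam[-(m + 1), 8]) / 2
    upd <- control_update(lam_mid_S, lam_mid_D, pb$weights,
                          pb$u_S_max, pb$u_D_max, pb$mask_S, pb$mask_D)
    resid_num <- (if (pb$optimize_S) sum(abs(upd$u_S - uS)) else 0) +
      (if (pb$optimize_D) sum(abs(upd$u_D - uD)) else 0)
    resid_den <- (if (pb$optimize_S) sum(abs(uS)) else 0) +
      (if (pb$optimize_D) sum(abs(uD)) else 0)
    resid <- resid_num / max(resid_den, 1e-12)
    if (pb$optimize_S) uS <- relax * upd$u_S + (1 - relax) * uS
    if (pb$optimize_D) uD <- relax * upd$u_D + (1 - relax) * uD
    states <- forward_pass(pb, uS, uD)
    obj <- objective_value(states, pb$times, uS, uD, pb$weights)
    log_rows[[it]] <- tibble::tibble(iteration = it, objective = obj,
                                     control_change = resid, relax = relax)
    if (resid < tol) { converged <- TRUE; break }
    if (adapt_relax) {
      relax <- if (obj > obj_prev + 1e-9) max(relax / 2, 2e-3)
               else min(relax * 1.1, relax0)
    }
    obj_prev <- obj
  }
  iter_log <- dplyr::bind_rows(log_rows[!vapply(log_rows, is.null, logical(1))])
  if (!converged) {
    warning("forward-backward sweep did not converge within max_iter",
            call. = FALSE)
  }
  ind <- apoptosis_indicator(states[, "B"], states[, "X"], pb$thresholds)
  lam <- adjoint_rk4_cpp(pb$times, states, as.double(pb$params),
                         unclass(pb$thresholds), wv, as.numeric(ind),
                         pb$dt_max, pb$indicator_mode == "smooth", pb$smooth_k)
  colnames(lam) <- paste0("lambda_", state_names)
  dt <- diff(pb$times)
  sol <- tibble::as_tibble(as.data.frame(states))
  sol <- tibble::add_column(sol, time = pb$times, .before = 1)
  sol$u_S <- c(uS, uS[m])   # right-pad: controls live on intervals
  sol$u_D <- c(uD, uD[m])
  sol <- dplyr::bind_cols(sol, tibble::as_tibble(as.data.frame(lam)))
  sol$indicator <- ind
  out <- list(
    solution = sol,
    objective = objective_value(states, pb$times, uS, uD, pb$weights),
    iterations = iter_log,
    converged = converged,
    totals = c(S = sum(dt * uS), D = sum(dt * uD)),
    u_S = uS, u_D = uD,
    problem = pb
  )
  class(out) <- "stat_control_solution"
  out
}

#' @export
print.stat_control_solution <- function(x, ...) {
  cat("<stat_control_solution> objective =", format(x$objective),
      "|", nrow(x$iterations), "sweeps",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  delivered totals: IFN-beta =", format(round(x$totals[["S"]], 3)),
      ", DDP =", format(round(x$totals[["D"]], 3)), "\n")
  invisible(x)
}

#' Tidy / summarize a control solution
#'
#' @param x a `stat_control_solution`.
#' @param ... unused.
#' @return `tidy()`: the per-time solution tibble. `glance()`: one row with
#'   objective, convergence, iteration count, delivered totals and final
#'   tumour volume.
#' @export
tidy.stat_control_solution <- function(x, ...) x$solution

#' @rdname tidy.stat_control_solution
#' @export
glance.stat_control_solution <- function(x, ...) {
  n <- nrow(x$solution)
  tibble::tibble(
    objective = x$objective,
    converged = x$converged,
    iterations = nrow(x$iterations),
    total_S = x$totals[["S"]],
    total_D = x$totals[["D"]],
    T_final = x$solution$T[n]
  )
}
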