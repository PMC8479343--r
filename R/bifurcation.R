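#' Equilibria of the intracellular subsystem
#'
#' Finds all steady states of the STAT1-STAT3-Bcl-2-BAX subsystem at fixed
#' IFN-beta (`S`) and JAK2 (`J`) levels, with stability from the analytic
#' Jacobian. Because STAT3, Bcl-2 and BAX each appear only linearly in their
#' own balance equation, every equilibrium is a root of a scalar function of
#' STAT1; the default method brackets its sign changes on a fine grid and
#' polishes each root with `uniroot` (complete for this model structure).
#' `method = "multistart"` instead runs a damped Newton iteration from
#' Latin-hypercube starting points in the search box; it is the slower,
#' structure-agnostic cross-check.
#'
#' @param params a [stat_params()] object.
#' @param S,J non-negative IFN-beta and JAK2 levels.
#' @param thresholds a [stat_thresholds()] object (for phase labels).
#' @param method `"reduction"` (default) or `"multistart"`.
#' @param box upper corner of the positive search box for S1 (and, for the
#'   multi-start method, all four variables).
#' @param n_starts number of Latin-hypercube starts for `"multistart"`.
#' @param tol root tolerance; equilibria closer than 1e-6 are merged.
#' @return Tibble with columns `S1, S3, B, X, stable, marginal,
#'   leading_eig, phase`, ordered by `S1`.
#' @examples
#' find_equilibria(stat_params(), S = 0.4, J = 0)
#' @export
find_equilibria <- function(params = stat_params(), S, J,
                            thresholds = stat_thresholds(),
                            method = c("reduction", "multistart"),
                            box = 20, n_starts = 200, tol = 1e-10) {
  method <- match.arg(method)
  if (S < 0 || J < 0) stop("S and J must be non-negative", call. = FALSE)
  roots <- if (method == "reduction") {
    equilibria_reduction(params, S, J, box, tol)
  } else {
    equilibria_multistart(params, S, J, box, n_starts, tol)
  }
  if (nrow(roots) == 0L) {
    warning("no equilibrium found in the search box", call. = FALSE)
    return(tibble::tibble(S1 = numeric(0), S3 = numeric(0), B = numeric(0),
                          X = numeric(0), stable = logical(0),
                          marginal = logical(0), leading_eig = numeric(0),
                          phase = factor(character(0),
                                         levels = c("Pt", "Pa", "neither"))))
  }
  lead <- vapply(seq_len(nrow(roots)), function(i) {
    Jm <- intracellular_jacobian(roots$S1[i], roots$S3[i], roots$B[i],
                                 roots$X[i], S, J, params)
    max(Re(eigen(Jm, only.values = TRUE)$values))
  }, numeric(1))
  out <- tibble::tibble(
    S1 = roots$S1, S3 = roots$S3, B = roots$B, X = roots$X,
    stable = lead < -1e-8,
    marginal = abs(lead) <= 1e-8,
    leading_eig = lead,
    phase = classify_phase(roots$B, roots$X, thresholds)
  )
  out[order(out$S1), ]
}

# explicit S3, B, X given S1 at equilibrium
equilibrium_slaves <- function(s1, S, J, p) {
  s3 <- ((p$lambda_k + p$lambda_J * J) / (p$K + p$lambda_S2 * S) +
           p$k3 * p$k4^2 / (p$k4^2 + p$beta * s1^2)) / p$mu3
  b <- (p$lambda1 + p$k5 * p$k6^2 / (p$k6^2 + p$gamma * s1^2) +
          p$lambda3 * s3) / p$muB
  x <- (p$lambda2 + p$k7 * p$k8^2 / (p$k8^2 + p$delta * b^2)) / p$muX
  list(S3 = s3, B = b, X = x)
}

equilibria_reduction <- function(p, S, J, box, tol, n_grid = 4001L) {
  f <- function(s1) {
    s3 <- equilibrium_slaves(s1, S, J, p)$S3
    p$lambda_S1 * S + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * s3^2) - s1
  }
  grid <- seq(0, box, length.out = n_grid)
  vals <- f(grid)  # elementwise arithmetic: one vectorized evaluation
  sgn <- vals[-1] * vals[-n_grid]
  idx <- which(sgn < 0)
  s1s <- vapply(idx, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
  }, numeric(1))
  s1s <- c(s1s, grid[vals == 0])
  s1s <- dedup_sorted(sort(s1s))
  sl <- lapply(s1s, equilibrium_slaves, S = S, J = J, p = p)
  tibble::tibble(
    S1 = s1s,
    S3 = vapply(sl, `[[`, numeric(1), "S3"),
    B = vapply(sl, `[[`, numeric(1), "B"),
    X = vapply(sl, `[[`, numeric(1), "X")
  )
}

equilibria_multistart <- function(p, S, J, box, n_starts, tol) {
  F4 <- function(y) unname(intracellular_rhs(y[1], y[2], y[3], y[4], S, J, p))
  starts <- lhs::randomLHS(n_starts, 4) * box
  sols <- matrix(numeric(0), ncol = 4)
  for (i in seq_len(n_starts)) {
    y <- pmax(starts[i, ], 1e-9)
    ok <- FALSE
    for (it in 1:100) {
      Fy <- F4(y)
      if (sqrt(sum(Fy^2)) < 1e-11) { ok <- TRUE; break }
      Jm <- intracellular_jacobian(y[1], y[2], y[3], y[4], S, J, p)
      step <- tryCatch(solve(Jm, -Fy), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {  # damping: halve until the residual decreases
        cand <- pmax(y + lam * step, 0)
        if (sqrt(sum(F4(cand)^2)) < sqrt(sum(Fy^2)) || lam < 1e-4) break
        lam <- lam / 2
      }
      y <- pmax(y + lam * step, 0)
    }
    if (ok && all(y >= 0) && all(y <= box * 1.5)) {
      sols <- rbind(sols, y)
    }
  }
  if (nrow(sols) == 0L) {
    return(tibble::tibble(S1 = numeric(0), S3 = numeric(0),
                          B = numeric(0), X = numeric(0)))
  }
  sols <- sols[order(sols[, 1]), , drop = FALSE]
  keep <- rep(TRUE, nrow(sols))
  for (i in seq_len(nrow(sols))[-1]) {
    prev <- max(which(keep[seq_len(i - 1)]))
    if (sqrt(sum((sols[i, ] - sols[prev, ])^2)) < 1e-6) keep[i] <- FALSE
  }
  sols <- sols[keep, , drop = FALSE]
  tibble::tibble(S1 = sols[, 1], S3 = sols[, 2], B = sols[, 3], X = sols[, 4])
}

dedup_sorted <- function(x, tol = 1e-6) {
  if (length(x) <= 1L) return(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

#' Bifurcation scan over the IFN-beta level
#'
#' Computes all equilibria of the intracellular subsystem on a grid of
#' IFN-beta levels at fixed JAK2, assigns lower/middle/upper branches by
#' STAT1 ordering, and refines the two fold (saddle-node) points -- the
#' edges of the bistability window -- by bisection on the equilibrium count.
#'
#' @inheritParams find_equilibria
#' @param S_grid increasing grid of IFN-beta levels.
#' @param refine_tol bisection tolerance (in S) for the fold points.
#' @return A `stat_bifurcation` tibble with columns `S, branch, S1, S3, B,
#'   X, stable, leading_eig, phase`; attributes `window` (`c(S_m, S_M)` or
#'   `NULL`) and `J`.
#' @examples
#' bd <- scan_bifurcation(stat_params(), S_grid = seq(0, 1, by = 0.05), J = 0)
#' bistability_window(bd)
#' @export
scan_bifurcation <- function(params = stat_params(),
                             S_grid = seq(0, 1, by = 0.005), J = 0,
                             thresholds = stat_thresholds(),
                             refine_tol = 1e-4, box = 20) {
  if (is.unsorted(S_grid, strictly = TRUE)) {
    stop("S_grid must be strictly increasing", call. = FALSE)
  }
  per_S <- lapply(S_grid, function(S) {
    eq <- find_equilibria(params, S = S, J = J, thresholds = thresholds,
                          box = box)
    n <- nrow(eq)
    eq$branch <- if (n == 1L) "lower" else
      c("lower", "middle", "upper")[seq_len(min(n, 3L))]
    eq$S <- S
    eq
  })
  diag <- dplyr::bind_rows(per_S)
  diag <- diag[, c("S", "branch", "S1", "S3", "B", "X", "stable",
                   "leading_eig", "phase")]
  counts <- vapply(per_S, nrow, integer(1))
  window <- NULL
  if (any(counts >= 3L)) {
    i3 <- which(counts >= 3L)
    S_m <- S_grid[min(i3)]
    S_M <- S_grid[max(i3)]
    count_at <- function(S) nrow(find_equilibria(params, S, J,
                                                 thresholds = thresholds,
                                                 box = box))
    if (min(i3) > 1L) {
      S_m <- bisect_count(count_at, S_grid[min(i3) - 1L], S_m, refine_tol,
                          want_upper = TRUE)
    }
    if (max(i3) < length(S_grid)) {
      S_M <- bisect_count(count_at, S_M, S_grid[max(i3) + 1L], refine_tol,
                          want_upper = FALSE)
    }
    window <- c(S_m = S_m, S_M = S_M)
  }
  attr(diag, "window") <- window
  attr(diag, "J") <- J
  attr(diag, "params") <- params
  class(diag) <- c("stat_bifurcation", class(diag))
  diag
}

# bisection on the 1<->3 equilibrium-count transition inside [lo, hi];
# want_upper: TRUE when the 3-count side is the upper end of the interval
bisect_count <- function(count_at, lo, hi, tol, want_upper) {
  for (i in seq_len(ceiling(log2((hi - lo) / tol)) + 1L)) {
    mid <- (lo + hi) / 2
    if ((count_at(mid) >= 3L) == want_upper) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Bistability window of a diagram
#'
#' @param diagram a `stat_bifurcation` from [scan_bifurcation()].
#' @return Numeric `c(S_m, S_M)` where three equilibria coexist, or
#'   `numeric(0)` when the branch is single everywhere.
#' @export
bistability_window <- function(diagram) {
  w <- attr(diagram, "window")
  if (is.null(w)) numeric(0) else w
}

#' Quasi-static hysteresis sweep
#'
#' Ramps the IFN-beta level slowly up (or down) while the intracellular
#' state tracks the local stable branch, and records where the (Bcl-2, BAX)
#' phase switches. The ramp is imposed exactly by driving the IFN-beta
#' equation with the feed-forward input `u_S = dS/dt + muS * S(t)`; JAK2 is
#' pinned at `J` the same way. Switch points converge to the fold points of
#' the equilibrium diagram as the ramp rate goes to zero.
#'
#' @inheritParams find_equilibria
#' @param S_from,S_to ramp endpoints.
#' @param rate ramp speed |dS/dt| (must be slow relative to the intracellular
#'   relaxation times).
#' @param dt_out output spacing (in time).
#' @return Tibble with columns `time, S, S1, S3, B, X, phase` plus attribute
#'   `transitions`: tibble of phase-change locations (`S`, `from`, `to`).
#' @export
hysteresis_sweep <- function(params = stat_params(), J = 0,
                             S_from = 0, S_to = 1, rate = 1e-3,
                             thresholds = stat_thresholds(), dt_out = NULL) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  dir <- sign(S_to - S_from)
  if (dir == 0) stop("S_from and S_to must differ", call. = FALSE)
  t_end <- abs(S_to - S_from) / rate
  if (is.null(dt_out)) dt_out <- t_end / 2000
  S_of <- function(t) S_from + dir * rate * t
  u_S <- function(t) pmax(dir * rate + params$muS * S_of(t), 0)
  # start on the stable branch nearest the requested phase history
  eq0 <- find_equilibria(params, S = S_from, J = J, thresholds = thresholds)
  st0 <- eq0[eq0$stable, ]
  pick <- if (dir > 0) which.min(st0$S1) else which.max(st0$S1)
  init <- c(S1 = st0$S1[pick], S3 = st0$S3[pick], B = st0$B[pick],
            X = st0$X[pick], T = 0.1, S = S_from, J = J, D = 0)
  params_pin <- stat_params(Js = max(params$muJ * J, 1e-12), .base = params)
  tr <- simulate_model(params_pin, thresholds, init, t_start = 0,
                       t_end = t_end, u_S = u_S, u_D = 0,
                       dt_out = dt_out, dt_max = min(0.01, dt_out))
  out <- tibble::tibble(time = tr$time, S = S_of(tr$time),
                        S1 = tr$S1, S3 = tr$S3, B = tr$B, X = tr$X,
                        phase = tr$phase)
  ph <- as.character(out$phase)
  chg <- which(ph[-1] != ph[-length(ph)])
  attr(out, "transitions") <- tibble::tibble(
    S = out$S[chg + 1L], from = ph[chg], to = ph[chg + 1L]
  )
  # flag ramps that are too fast to track the stable branch
  eq_end <- find_equilibria(params, S = S_to, J = J, thresholds = thresholds)
  stb <- eq_end[eq_end$stable, ]
  devs <- sqrt((stb$S1 - out$S1[nrow(out)])^2 + (stb$S3 - out$S3[nrow(out)])^2)
  attr(out, "tracking_ok") <- length(devs) > 0 && min(devs) < 0.05
  out
}

#' Calibrate the IFN-beta source coefficient
#'
#' The IFN-beta-to-STAT1 source coefficient `lambda_S1` is not identifiable
#' from the published dimensionless table; this routine tunes it (holding
#' `lambda_S2` fixed) so that the bistability window of the J = 0 diagram
#' matches a target window, minimizing the larger of the two fold-point
#' deviations by golden-section search.
#'
#' @param params a [stat_params()] object.
#' @param target_window numeric `c(S_m, S_M)` inside the unit interval.
#' @param bracket search interval for `lambda_S1`.
#' @param J JAK2 level of the calibration scan (0 for the published window).
#' @param step scan step in S.
#' @param tol search tolerance in `lambda_S1`.
#' @return List with `lambda_S1`, `achieved_window`, `max_deviation`, and
#'   the calibrated `params`.
#' @examples
#' \donttest{
#' cal <- calibrate_source_coefficients(stat_params())
#' cal$lambda_S1
#' }
#' @export
calibrate_source_coefficients <- function(params = stat_params(),
                                          target_window = c(0.3, 0.53),
                                          bracket = c(0.25, 4), J = 0,
                                          step = 0.005, tol = 1e-3) {
  if (any(target_window < 0) || any(target_window > 1) ||
      diff(target_window) <= 0) {
    stop("target_window must be an increasing interval inside [0, 1]",
         call. = FALSE)
  }
  S_grid <- seq(0, 1, by = step)
  objective <- function(ls1) {
    p <- stat_params(lambda_S1 = ls1, .base = params)
    w <- bistability_window(scan_bifurcation(p, S_grid, J = J))
    if (length(w) == 0) return(Inf)
    max(abs(w - target_window))
  }
  # coarse scan to locate the bistable region of the bracket
  cand <- seq(bracket[1], bracket[2], length.out = 17)
  vals <- vapply(cand, objective, numeric(1))
  if (all(!is.finite(vals))) {
    stop("calibration failure: no lambda_S1 in the bracket yields bistability",
         call. = FALSE)
  }
  i0 <- which.min(vals)
  lo <- cand[max(1, i0 - 1)]
  hi <- cand[min(length(cand), i0 + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- objective(x1); f2 <- objective(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- objective(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- objective(x2)
    }
  }
  best <- (a + b) / 2
  p_best <- stat_params(lambda_S1 = best, .base = params)
  w_best <- bistability_window(scan_bifurcation(p_best, S_grid, J = J))
  list(lambda_S1 = best, achieved_window = w_best,
       max_deviation = if (length(w_best)) max(abs(w_best - target_window)) else Inf,
       params = p_best)
}

#' @export
print.stat_bifurcation <- function(x, ...) {
  w <- attr(x, "window")
  cat("<stat_bifurcation> J =", attr(x, "J"),
      if (is.null(w)) "| monostable over the scanned range"
      else paste0("| bistability window [", signif(w[1], 4), ", ",
                  signif(w[2], 4), "]"), "\n")
  NextMethod()
}

#' Tidy a bifurcation diagram
#'
#' @param x a `stat_bifurcation`.
#' @param ... unused.
#' @return The underlying tibble (one row per equilibrium per S value).
#' @export
tidy.stat_bifurcation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.stat_bifurcation <- function(x, ...) {
  w <- attr(x, "window")
  tibble::tibble(
    J = attr(x, "J"),
    bistable = !is.null(w),
    S_m = if (is.null(w)) NA_real_ else w[[1]],
    S_M = if (is.null(w)) NA_real_ else w[[2]],
    n_S = length(unique(x$S))
  )
}
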