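test_that("the running-cost integral reproduces analytic cases", {
  times <- seq(0, 30, by = 0.1)
  m <- length(times) - 1
  zeros <- matrix(0, length(times), 8,
                  dimnames = list(NULL, statswitch:::state_names))
  w0 <- control_weights(1, 0, 0, 0, 0, 1, 1, 0)
  expect_equal(objective_value(zeros, times, rep(0, m), rep(0, m), w0), 0)
  # constant unit tumour deviation over a 30-unit horizon integrates to 30
  st <- zeros; st[, "T"] <- 1
  expect_equal(objective_value(st, times, rep(0, m), rep(0, m), w0), 30)
  # the BAX term rewards (lowers cost for) high BAX
  stX <- zeros; stX[, "X"] <- 1
  wA3 <- control_weights(0, 0, 2, 0, 0, 1, 1, 0)
  expect_lt(objective_value(stX, times, rep(0, m), rep(0, m), wA3),
            objective_value(stX, times, rep(0, m), rep(0, m), w0))
  expect_error(objective_value(zeros, times[1:10], rep(0, 9), rep(0, 9), w0),
               "horizon")
})

test_that("costate derivatives match finite differences of the Hamiltonian", {
  set.seed(14)
  w <- strategy_II_weights()
  H <- function(y, lam, I, mode) {
    L <- w$A1 * (y[5] - w$T_bar)^2 + w$A2 * y[3]^2 - w$A3 * y[4]^2
    f <- statswitch:::frozen_rhs(y, 3, 2, default_p, default_th,
                                 indicator = if (mode == "hard") I else NULL,
                                 smooth_k = 100)
    L + sum(lam * f)
  }
  for (mode in c("hard", "smooth")) {
    worst <- 0
    for (rep in 1:25) {
      y <- runif(8, 0.05, 3)
      names(y) <- statswitch:::state_names
      lam <- runif(8, -2, 2)
      I <- rbinom(1, 1, 0.5)
      dl <- adjoint_rhs(y, lam, I, default_p, default_th, w,
                        indicator_mode = mode)
      h <- 1e-6
      for (i in 1:8) {
        yp <- y; ym <- y
        yp[i] <- y[i] + h; ym[i] <- y[i] - h
        fd <- -(H(yp, lam, I, mode) - H(ym, lam, I, mode)) / (2 * h)
        worst <- max(worst, abs(fd - dl[i]))
      }
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("zero weights give the trivial homogeneous adjoint", {
  w0 <- control_weights(0, 0, 0, 0, 0, 1, 1, 0)
  y <- c(S1 = 1, S3 = 1, B = 2, X = 0.2, T = 1, S = 0.5, J = 1, D = 0.5)
  expect_equal(unname(adjoint_rhs(y, rep(0, 8), 1, default_p, default_th,
                                  w0)),
               rep(0, 8))
})

test_that("the cisplatin costate decouples from state weights when inert", {
  p0 <- stat_params(gammaD = 0)
  y <- c(S1 = 1, S3 = 1, B = 2, X = 0.2, T = 1, S = 0.5, J = 1, D = 0.5)
  lam <- runif(8, -1, 1)
  dA <- adjoint_rhs(y, lam, 1, p0, default_th,
                    control_weights(5, 3, 2, 0, 0, 1, 1, 0))["D"]
  dB <- adjoint_rhs(y, lam, 1, p0, default_th,
                    control_weights(0, 0, 0, 0, 0, 1, 1, 0))["D"]
  expect_equal(dA, dB)
})

test_that("the stationarity update clips and scales as derived", {
  w <- control_weights(1, 0, 0, 0.5, 0.1, 2, 1, 0)
  # lambda_S = -C1 puts the interior optimum exactly at zero
  upd <- control_update(rep(-0.5, 3), rep(0, 3), w)
  expect_equal(upd$u_S, rep(0, 3))
  # a very negative costate saturates at the bound
  upd2 <- control_update(rep(-1e9, 3), rep(-1e9, 3), w,
                         u_S_max = 50, u_D_max = 100)
  expect_equal(upd2$u_S, rep(50, 3))
  expect_equal(upd2$u_D, rep(100, 3))
  # doubling the quadratic weight halves the interior magnitude
  w2 <- control_weights(1, 0, 0, 0.5, 0.1, 4, 1, 0)
  u1 <- control_update(rep(-10, 1), 0, w)$u_S
  u2 <- control_update(rep(-10, 1), 0, w2)$u_S
  expect_equal(u2, u1 / 2)
  # off-mask controls are forced to zero
  u3 <- control_update(rep(-10, 4), rep(0, 4), w,
                       mask_S = c(TRUE, FALSE, TRUE, FALSE))$u_S
  expect_equal(u3[c(2, 4)], c(0, 0))
})

test_that("with pure control costs the sweep converges to zero dosing", {
  w <- control_weights(0, 0, 0, 1, 1, 1, 1, 0, t_e = 5)
  pb <- control_problem(default_p, default_th, weights = w,
                        dt = 0.1, dt_max = 0.02)
  sol <- forward_backward_sweep(pb, u_S_init = 5, u_D_init = 5)
  expect_true(sol$converged)
  expect_lt(max(sol$u_S), 1e-6)
  expect_lt(max(sol$u_D), 1e-6)
})

test_that("the sweep is deterministic", {
  run_once <- function() {
    run_strategy_II(default_p, default_th, sequence = "SSSDDD",
                    dt = 0.05, dt_max = 0.01, max_iter = 60)
  }
  a <- suppressWarnings(run_once())
  b <- suppressWarnings(run_once())
  expect_identical(a$solution$iterations, b$solution$iterations)
  expect_identical(a$solution$u_S, b$solution$u_S)
})

test_that("the backward C++ integrator matches an R-side adjoint solve", {
  # short horizon, coarse grid: RK4 on adjoint_rhs with frozen indicator
  w <- strategy_II_weights(); w$t_e <- 2
  pb <- control_problem(default_p, default_th, weights = w,
                        optimize_D = FALSE, fixed_u_D = 1,
                        dt = 0.02, dt_max = 0.02,
                        indicator_mode = "hard")
  m <- length(pb$mid)
  uS <- rep(3, m); uD <- rep(1, m)
  states <- statswitch:::forward_pass(pb, uS, uD)
  ind <- apoptosis_indicator(states[, "B"], states[, "X"], default_th)
  lam_cpp <- statswitch:::adjoint_rk4_cpp(
    pb$times, states, as.double(default_p), unclass(default_th),
    statswitch:::weights_vec(w), as.numeric(ind), pb$dt_max, FALSE, 100)
  # reference: plain RK4 in R over the same grid, interpolating states
  lam <- rep(0, 8)
  lam_ref <- matrix(0, m + 1, 8)
  for (i in m:1) {
    h <- pb$times[i + 1] - pb$times[i]
    y0 <- states[i, ]; y1 <- states[i + 1, ]
    ym <- (y0 + y1) / 2
    f <- function(y, l) unname(adjoint_rhs(y, l, ind[i], default_p,
                                           default_th, w))
    k1 <- f(y1, lam)
    k2 <- f(ym, lam - h / 2 * k1)
    k3 <- f(ym, lam - h / 2 * k2)
    k4 <- f(y0, lam - h * k3)
    lam <- lam - h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    lam_ref[i, ] <- lam
  }
  expect_lt(max(abs(lam_cpp - lam_ref)), 1e-6)
})

test_that("whole-horizon optimization beats both reference profiles", {
  res <- suppressMessages(run_strategy_I(default_p, default_th,
                                         dt = fast$dt_out,
                                         dt_max = fast$dt_max))
  cmp <- res$comparison
  obj <- stats::setNames(cmp$objective, cmp$strategy)
  Tf <- stats::setNames(cmp$T_final, cmp$strategy)
  expect_true(res$optimal$converged)
  expect_lt(obj[["optimal"]], obj[["constant"]])
  expect_lt(obj[["optimal"]], obj[["alternating"]])
  expect_lt(Tf[["optimal"]], Tf[["constant"]])
  expect_lt(Tf[["constant"]], Tf[["alternating"]])
  # the two reference profiles deliver identical totals by construction
  expect_equal(cmp$total_S[1], cmp$total_S[2])
  expect_equal(cmp$total_D[1], cmp$total_D[2])
})

test_that("the optimum beats random admissible profiles of equal totals", {
  set.seed(31)
  res <- suppressMessages(run_strategy_I(default_p, default_th,
                                         dt = fast$dt_out,
                                         dt_max = fast$dt_max))
  w <- strategy_I_weights()
  totals <- res$totals
  times <- statswitch:::control_grid(0, 30, fast$dt_out)
  m <- length(times) - 1
  mid <- (times[-1] + times[-length(times)]) / 2
  better <- 0
  for (rep in 1:25) {
    # random piecewise-constant profiles on 10 blocks, scaled to the totals
    blocks <- findInterval(mid, seq(0, 30, length.out = 11),
                           rightmost.closed = TRUE)
    uS <- runif(10)[blocks]; uD <- runif(10)[blocks]
    uS <- uS * totals[["S"]] / (sum(uS) * fast$dt_out)
    uD <- uD * totals[["D"]] / (sum(uD) * fast$dt_out)
    tr <- sim_fast(default_p, default_th, default_ic, t_end = 30,
                   u_S = stats::approxfun(mid, uS, method = "constant",
                                          rule = 2),
                   u_D = stats::approxfun(mid, uD, method = "constant",
                                          rule = 2))
    md <- (tr$time[-1] + tr$time[-nrow(tr)]) / 2
    o <- objective_value(tr[, statswitch:::state_names], tr$time,
                         stats::approx(mid, uS, md, method = "constant",
                                       rule = 2)$y,
                         stats::approx(mid, uD, md, method = "constant",
                                       rule = 2)$y, w)
    if (res$optimal$objective <= o) better <- better + 1
  }
  expect_equal(better, 25)
})

test_that("stationarity holds on interior arcs at convergence", {
  res <- run_strategy_II(default_p, default_th, sequence = "SSSDDD",
                         dt = fast$dt_out, dt_max = fast$dt_max)
  sol <- res$solution
  expect_true(sol$converged)
  w <- strategy_II_weights()
  lamS <- sol$solution$lambda_S
  uS <- sol$solution$u_S
  # dH/du = C1 + 2 C3 u + lambda_S; check nodes strictly inside the bounds
  interior <- uS > 0.05 & uS < 49.95 & sol$solution$time < 15
  dHdu <- w$C1 + 2 * w$C3 * uS + lamS
  expect_lt(stats::median(abs(dHdu[interior])), 0.05)
  # at the lower bound (u = 0 on-mask) the gradient must push down
  lower <- abs(uS) < 1e-9 & sol$solution$time < 15
  if (any(lower)) expect_gt(min(dHdu[lower]), -0.05)
})
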