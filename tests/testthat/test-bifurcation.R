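test_that("equilibrium structure across the IFN-beta range", {
  e0 <- find_equilibria(default_p, S = 0, J = 0)
  expect_identical(nrow(e0), 1L)
  expect_true(e0$stable)
  expect_equal(as.character(e0$phase), "Pt")

  e4 <- find_equilibria(default_p, S = 0.4, J = 0)
  expect_identical(nrow(e4), 3L)
  expect_identical(sum(e4$stable), 2L)
  expect_identical(sum(!e4$stable), 1L)
  # the unstable state is the middle branch by STAT1 ordering
  expect_false(e4$stable[2])

  e1 <- find_equilibria(default_p, S = 1, J = 0)
  expect_identical(nrow(e1), 1L)
  expect_true(e1$stable)
  expect_equal(as.character(e1$phase), "Pa")
})

test_that("multi-start damped Newton agrees with the scalar reduction", {
  set.seed(99)
  for (S in seq(0, 1, by = 0.1)) {
    a <- find_equilibria(default_p, S = S, J = 0)
    b <- find_equilibria(default_p, S = S, J = 0, method = "multistart",
                         n_starts = 150)
    expect_identical(nrow(a), nrow(b))
    expect_lt(max(abs(as.matrix(a[, 1:4]) - as.matrix(b[, 1:4]))), 1e-4)
  }
})

test_that("bistability window at J = 0 brackets both saddle-node folds", {
  bd <- scan_bifurcation(default_p, seq(0, 1, by = 0.005), J = 0)
  w <- bistability_window(bd)
  expect_length(w, 2)
  # frozen values computed with this package's scan (fold refinement 1e-4)
  expect_equal(unname(w), c(0.30426, 0.53004), tolerance = 1e-3)
  # wherever three equilibria coexist exactly one is unstable
  multi <- dplyr::count(tibble::as_tibble(bd), S)
  for (Sv in multi$S[multi$n == 3]) {
    sub <- bd[bd$S == Sv, ]
    expect_identical(sum(!sub$stable), 1L)
    expect_identical(sub$branch[!sub$stable], "middle")
  }
})

test_that("with JAK2 present the response is uniformly anti-apoptotic", {
  bd <- scan_bifurcation(default_p, seq(0, 1, by = 0.01), J = 1)
  expect_length(bistability_window(bd), 0)
  expect_identical(unique(table(bd$S)), 1L)  # single branch everywhere
  expect_true(all(bd$S1 < 1.8))
  expect_true(all(bd$S3 > 1.3))
  expect_true(all(bd$B > 1.44))
  expect_true(all(bd$X < 0.3))
})

test_that("a single-point scan degenerates to plain equilibrium finding", {
  bd <- scan_bifurcation(default_p, S_grid = 0.4, J = 0)
  eq <- find_equilibria(default_p, S = 0.4, J = 0)
  expect_identical(nrow(tibble::as_tibble(bd)), nrow(eq))
  expect_equal(bd$S1, eq$S1)
  expect_length(bistability_window(bd), 2)  # degenerate window at the point
})

test_that("perturbed unstable states flow to a stable equilibrium", {
  S <- 0.4
  eq <- find_equilibria(default_p, S = S, J = 0)
  uns <- eq[!eq$stable, ]
  Jm <- intracellular_jacobian(uns$S1, uns$S3, uns$B, uns$X, S, 0, default_p)
  ev <- eigen(Jm)
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  stable_pts <- as.matrix(eq[eq$stable, c("S1", "S3", "B", "X")])
  # pin S via feed-forward infusion and JAK2 at zero, then relax
  p_pin <- stat_params(Js = 1e-12, .base = default_p)
  for (sgn in c(-1, 1)) {
    y0 <- pmax(unlist(uns[, c("S1", "S3", "B", "X")]) + sgn * 1e-3 * v, 0)
    init <- c(y0, T = 0.1, S = S, J = 0, D = 0)
    names(init) <- statswitch:::state_names
    # escaping a 1e-3 neighbourhood of the saddle takes ~ log(1e3) over the
    # unstable rate (~0.13), so allow a long relaxation horizon
    tr <- sim_fast(p_pin, default_th, init, t_end = 250,
                   u_S = default_p$muS * S)
    final <- unlist(tr[nrow(tr), c("S1", "S3", "B", "X")])
    d <- apply(stable_pts, 1, function(r) sqrt(sum((r - final)^2)))
    expect_lt(min(d), 1e-4)
  }
})

test_that("slow ramps exhibit hysteresis consistent with the fold points", {
  bd <- scan_bifurcation(default_p, seq(0, 1, by = 0.005), J = 0)
  w <- bistability_window(bd)
  up <- hysteresis_sweep(default_p, J = 0, S_from = 0, S_to = 1, rate = 1e-4)
  dn <- hysteresis_sweep(default_p, J = 0, S_from = 1, S_to = 0, rate = 1e-4)
  t_up <- attr(up, "transitions")
  t_dn <- attr(dn, "transitions")
  expect_identical(nrow(t_up[t_up$from == "Pt", ]), 1L)
  expect_equal(t_up$S[t_up$from == "Pt"], w[["S_M"]], tolerance = 0.02)
  expect_equal(min(t_dn$S[t_dn$from == "Pa"]), w[["S_m"]], tolerance = 0.05)
  expect_true(attr(up, "tracking_ok"))
  # a constant path never switches phase
  flat <- hysteresis_sweep(default_p, J = 0, S_from = 0.1, S_to = 0.100001,
                           rate = 1e-5)
  expect_identical(nrow(attr(flat, "transitions")), 0L)
})

test_that("source-coefficient calibration is a fixed point at the defaults", {
  bd <- scan_bifurcation(default_p, seq(0, 1, by = 0.02), J = 0)
  w <- bistability_window(bd)
  cal <- calibrate_source_coefficients(default_p, target_window = unname(w),
                                       bracket = c(0.8, 1.25),
                                       step = 0.02, tol = 0.02)
  expect_equal(cal$lambda_S1, default_p$lambda_S1, tolerance = 0.02)
  expect_lt(cal$max_deviation, 0.02)
})

test_that("calibration fails cleanly when no bistability exists", {
  expect_error(
    calibrate_source_coefficients(default_p, target_window = c(0.3, 0.53),
                                  bracket = c(0.9, 1.1), J = 1,
                                  step = 0.05, tol = 0.05),
    "calibration failure")
})
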