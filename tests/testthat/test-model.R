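test_that("intracellular derivatives match hand-evaluated values", {
  # at the origin with no IFN-beta or JAK2 every Hill term is at its maximum
  expect_equal(
    unname(intracellular_rhs(0, 0, 0, 0, S = 0, J = 0, default_p)),
    c(4.0, 4.2, 1.2, 4.2)
  )
  # unit IFN-beta source with unit coupling coefficients
  p1 <- stat_params(lambda_S1 = 1, lambda_S2 = 1)
  d <- intracellular_rhs(0, 0, 0, 0, S = 1, J = 0, p1)
  expect_equal(unname(d[["S1"]]), 5.0)
  expect_equal(unname(d[["S3"]]), 1 / 6 + 4)
})

test_that("intracellular derivatives vanish at computed equilibria", {
  for (S in c(0, 0.4, 1)) {
    eq <- find_equilibria(default_p, S = S, J = 0)
    for (i in seq_len(nrow(eq))) {
      d <- intracellular_rhs(eq$S1[i], eq$S3[i], eq$B[i], eq$X[i],
                             S = S, J = 0, default_p)
      expect_lt(max(abs(d)), 1e-8)
    }
  }
})

test_that("invalid intracellular inputs are rejected", {
  expect_error(intracellular_rhs(-1, 0, 0, 0, S = 0, J = 0, default_p),
               "non-negative")
  expect_error(intracellular_rhs(NaN, 0, 0, 0, S = 0, J = 0, default_p),
               "finite")
})

test_that("analytic Jacobian matches central differences", {
  set.seed(11)
  for (rep in 1:10) {
    y <- runif(4, 0.05, 4)
    S <- runif(1, 0, 1); J <- runif(1, 0, 1)
    Jan <- intracellular_jacobian(y[1], y[2], y[3], y[4], S, J, default_p)
    h <- 1e-6
    for (j in 1:4) {
      yp <- y; ym <- y
      yp[j] <- y[j] + h; ym[j] <- y[j] - h
      fd <- (intracellular_rhs(yp[1], yp[2], yp[3], yp[4], S, J, default_p) -
             intracellular_rhs(ym[1], ym[2], ym[3], ym[4], S, J, default_p)) /
        (2 * h)
      expect_lt(max(abs(fd - Jan[, j])), 1e-6)
    }
  }
})

test_that("full model derivatives reproduce closed-form balances", {
  st <- c(S1 = 1, S3 = 1, B = 2, X = 0.1, T = 10, S = 0, J = 1, D = 0)
  d <- full_rhs(st, 0, default_p, default_th)
  # JAK2 production balances decay at its baseline level Js / muJ = 1
  expect_equal(unname(d[["J"]]), 0)
  # at carrying capacity with apoptosis off the tumour is stationary
  st2 <- st; st2["T"] <- default_p$T0
  expect_equal(unname(full_rhs(st2, 0, default_p, default_th)[["T"]]), 0)
  # IFN-beta balance under constant infusion
  st3 <- st; st3["S"] <- 15 / default_p$muS
  d3 <- full_rhs(st3, 0, default_p, default_th, u_S = 15)
  expect_equal(unname(d3[["S"]]), 0, tolerance = 1e-12)
  expect_error(full_rhs(st, 0, default_p, default_th, u_S = "high"),
               "control")
})

test_that("apoptosis indicator and phase use strict threshold inequalities", {
  expect_identical(apoptosis_indicator(1.0, 0.5, default_th), 1L)
  expect_identical(apoptosis_indicator(2.0, 0.1, default_th), 0L)
  # boundary points are off / unclassified
  expect_identical(apoptosis_indicator(1.44, 0.3, default_th), 0L)
  expect_equal(as.character(classify_phase(c(1, 2, 1, 1.44),
                                           c(0.5, 0.1, 0.1, 0.3),
                                           default_th)),
               c("Pa", "Pt", "neither", "neither"))
})

test_that("dimensional conversion reproduces the reference scaling", {
  expect_equal(unname(nondimensionalize(c(S1 = 2.43))), 1.0)
  expect_equal(unname(nondimensionalize(c(T = 100))), 1.0)
  set.seed(3)
  q <- stats::setNames(runif(9, 0.1, 100),
                       c("S1", "S3", "B", "X", "T", "S", "J", "D", "t"))
  expect_equal(dimensionalize(nondimensionalize(q)), q)
  expect_error(reference_scales(S1_ref = 0), "> 0")
  expect_error(nondimensionalize(c(bogus = 1)), "unknown")
})

test_that("parameter constructor enforces the published constraints", {
  p <- stat_params()
  expect_equal(p$k1, 4); expect_equal(p$alpha, 1.5)
  expect_equal(p$muB, 1.2); expect_equal(p$muX, 5)
  expect_equal(p$r, 0.12); expect_equal(p$T0, 100)
  expect_equal(p$muS, 4.8); expect_equal(p$Js, 1.3); expect_equal(p$muD, 10)
  expect_equal(p$mu3, 1)  # STAT1 and STAT3 share a half-life
  expect_error(stat_params(k9 = 1.5), "k9")
  expect_error(stat_params(muB = -1), "> 0")
  expect_error(stat_params(bogus = 1), "unknown")
  # lambda_S2 may be zero (no IFN-beta suppression of the STAT3 source)
  expect_silent(stat_params(lambda_S2 = 0))
  expect_equal(unname(unclass(stat_thresholds())),
               c(1.8, 1.3, 1.44, 0.3))
})
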