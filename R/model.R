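#' Right-hand side of the intracellular subsystem
#'
#' Time derivatives of STAT1, STAT3, Bcl-2 and BAX at fixed IFN-beta (`S`)
#' and JAK2 (`J`) levels. STAT1 and STAT3 mutually inhibit each other's
#' autocatalytic (Hill-type) production; STAT1 suppresses Bcl-2, STAT3 drives
#' it, and Bcl-2 gates BAX. All quantities are dimensionless; the STAT1 decay
#' coefficient is 1 by construction of the time scale (STAT1 and STAT3 share
#' the same half-life, carried as `mu3 = 1`).
#'
#' @param s1,s3,b,x current STAT1, STAT3, Bcl-2, BAX concentrations (>= 0).
#' @param S IFN-beta level (>= 0).
#' @param J JAK2 level (>= 0).
#' @param params a [stat_params()] object.
#' @return Named numeric vector `c(S1, S3, B, X)` of time derivatives.
#' @examples
#' intracellular_rhs(0, 0, 0, 0, S = 0, J = 0, stat_params())
#' @export
intracellular_rhs <- function(s1, s3, b, x, S, J, params = stat_params()) {
  v <- c(s1 = s1, s3 = s3, b = b, x = x, S = S, J = J)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("intracellular_rhs: all inputs must be finite and non-negative",
         call. = FALSE)
  }
  p <- params
  dS1 <- p$lambda_S1 * S + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * s3^2) - s1
  dS3 <- (p$lambda_k + p$lambda_J * J) / (p$K + p$lambda_S2 * S) +
    p$k3 * p$k4^2 / (p$k4^2 + p$beta * s1^2) - p$mu3 * s3
  dB <- p$lambda1 + p$k5 * p$k6^2 / (p$k6^2 + p$gamma * s1^2) +
    p$lambda3 * s3 - p$muB * b
  dX <- p$lambda2 + p$k7 * p$k8^2 / (p$k8^2 + p$delta * b^2) - p$muX * x
  c(S1 = dS1, S3 = dS3, B = dB, X = dX)
}

#' Analytic Jacobian of the intracellular subsystem
#'
#' Exact partial derivatives of [intracellular_rhs()] with respect to
#' (S1, S3, B, X); used for equilibrium stability classification and by the
#' damped-Newton multi-start solver.
#'
#' @inheritParams intracellular_rhs
#' @return A 4 x 4 numeric matrix.
#' @export
intracellular_jacobian <- function(s1, s3, b, x, S, J, params = stat_params()) {
  p <- params
  d1 <- p$k2^2 + p$alpha * s3^2
  d2 <- p$k4^2 + p$beta * s1^2
  d3 <- p$k6^2 + p$gamma * s1^2
  d4 <- p$k8^2 + p$delta * b^2
  matrix(c(
    -1, -2 * p$k1 * p$k2^2 * p$alpha * s3 / d1^2, 0, 0,
    -2 * p$k3 * p$k4^2 * p$beta * s1 / d2^2, -p$mu3, 0, 0,
    -2 * p$k5 * p$k6^2 * p$gamma * s1 / d3^2, p$lambda3, -p$muB, 0,
    0, 0, -2 * p$k7 * p$k8^2 * p$delta * b / d4^2, -p$muX
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("S1", "S3", "B", "X"), c("S1", "S3", "B", "X")))
}

#' Apoptosis indicator
#'
#' The binary switch that gates tumour-cell killing: apoptosis is on (1) iff
#' Bcl-2 is strictly below its threshold and BAX strictly above its
#' threshold. Boundary points give 0. Vectorized over `b` and `x`.
#'
#' @param b,x Bcl-2 and BAX concentrations (>= 0).
#' @param thresholds a [stat_thresholds()] object.
#' @return Integer vector of 0/1 values.
#' @examples
#' apoptosis_indicator(1.0, 0.5)
#' apoptosis_indicator(1.44, 0.3) # boundary: off
#' @export
apoptosis_indicator <- function(b, x, thresholds = stat_thresholds()) {
  if (any(!is.finite(b)) || any(!is.finite(x)) || any(b < 0) || any(x < 0)) {
    stop("apoptosis_indicator: b and x must be finite and non-negative",
         call. = FALSE)
  }
  as.integer(b < thresholds[["B_th"]] & x > thresholds[["X_th"]])
}

#' Classify the (Bcl-2, BAX) phase
#'
#' Pa (apoptotic): B below and X above threshold; Pt (anti-apoptotic): B
#' above and X below; anything else (including boundary points) is
#' "neither". Vectorized.
#'
#' @inheritParams apoptosis_indicator
#' @return Factor with levels `Pt`, `Pa`, `neither`.
#' @examples
#' classify_phase(c(1, 2, 1), c(0.5, 0.1, 0.1))
#' @export
classify_phase <- function(b, x, thresholds = stat_thresholds()) {
  Bth <- thresholds[["B_th"]]
  Xth <- thresholds[["X_th"]]
  out <- rep("neither", length(b))
  out[b < Bth & x > Xth] <- "Pa"
  out[b > Bth & x < Xth] <- "Pt"
  factor(out, levels = c("Pt", "Pa", "neither"))
}

#' Right-hand side of the full eight-state model
#'
#' Appends to the intracellular derivatives: logistic tumour growth with
#' STAT1-mediated growth inhibition and apoptotic killing (both gated by the
#' apoptosis indicator), first-order IFN-beta and cisplatin pharmacokinetics
#' with infusion inputs, and JAK2 production/degradation (cisplatin degrades
#' JAK2 at rate `gammaD * D`).
#'
#' @param state named numeric vector or single-row data frame with entries
#'   `S1, S3, B, X, T, S, J, D` (all >= 0).
#' @param t time (passed to the control functions).
#' @param params a [stat_params()] object.
#' @param thresholds a [stat_thresholds()] object.
#' @param u_S,u_D infusion-rate functions of time (or single non-negative
#'   numbers, interpreted as constant rates).
#' @return Named numeric vector of the 8 time derivatives.
#' @examples
#' st <- c(S1 = 1, S3 = 1, B = 2, X = 0.1, T = 10, S = 0, J = 1, D = 0)
#' full_rhs(st, 0, stat_params(), stat_thresholds(), u_S = 0, u_D = 0)
#' @export
full_rhs <- function(state, t, params = stat_params(),
                     thresholds = stat_thresholds(), u_S = 0, u_D = 0) {
  u_S <- as_control_fn(u_S)
  u_D <- as_control_fn(u_D)
  y <- unlist(state)[state_names]
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("full_rhs: state must be finite and non-negative", call. = FALSE)
  }
  us <- u_S(t)
  ud <- u_D(t)
  if (us < 0 || ud < 0) stop("controls must be non-negative", call. = FALSE)
  p <- params
  intra <- intracellular_rhs(y["S1"], y["S3"], y["B"], y["X"],
                             S = y["S"], J = y["J"], params = params)
  I <- apoptosis_indicator(y["B"], y["X"], thresholds)
  phi <- y["S1"]^2 / (p$k10^2 + y["S1"]^2)
  dT <- p$r * (1 - p$k9 * phi * I) * y["T"] * (1 - y["T"] / p$T0) -
    p$muT * y["T"] * I
  dS <- us - p$muS * y["S"]
  dJ <- p$Js - p$gammaD * y["D"] * y["J"] - p$muJ * y["J"]
  dD <- ud - p$muD * y["D"]
  c(intra, T = unname(dT), S = unname(dS), J = unname(dJ), D = unname(dD))
}

# full-model RHS with the indicator supplied externally (frozen) or relaxed
# to the steep-sigmoid form; the Hamiltonian helpers in the tests and the
# adjoint derivation both differentiate THIS map, not the discontinuous one
frozen_rhs <- function(y, u_S, u_D, params, thresholds,
                       indicator = NULL, smooth_k = NULL) {
  p <- params
  y <- unlist(y)[state_names]
  I <- if (!is.null(indicator)) {
    indicator
  } else {
    stats::plogis(smooth_k * (thresholds[["B_th"]] - y[["B"]])) *
      stats::plogis(smooth_k * (y[["X"]] - thresholds[["X_th"]]))
  }
  intra <- intracellular_rhs(y[["S1"]], y[["S3"]], y[["B"]], y[["X"]],
                             S = y[["S"]], J = y[["J"]], params = params)
  phi <- y[["S1"]]^2 / (p$k10^2 + y[["S1"]]^2)
  dT <- p$r * (1 - p$k9 * phi * I) * y[["T"]] * (1 - y[["T"]] / p$T0) -
    p$muT * y[["T"]] * I
  c(intra,
    T = unname(dT),
    S = u_S - p$muS * y[["S"]],
    J = p$Js - p$gammaD * y[["D"]] * y[["J"]] - p$muJ * y[["J"]],
    D = u_D - p$muD * y[["D"]])
}

as_control_fn <- function(u) {
  if (is.function(u)) return(u)
  if (is.numeric(u) && length(u) == 1L && is.finite(u)) {
    force(u)
    return(function(t) rep(u, length(t)))
  }
  stop("control must be a function of time or a single finite number",
       call. = FALSE)
}

#' Convert between dimensional and dimensionless quantities
#'
#' Divides (or multiplies) each named quantity by its reference scale; time
#' maps as `t = mu_S1_dim * t_dim`. The round trip is exact to machine
#' precision.
#'
#' @param q named numeric vector; names from `S1, S3, B, X, T, S, J, D, t`.
#' @param scales a [reference_scales()] object.
#' @return Named numeric vector of the same length.
#' @examples
#' nondimensionalize(c(S1 = 2.43, T = 100))
#' dimensionalize(nondimensionalize(c(B = 25)))
#' @export
nondimensionalize <- function(q, scales = reference_scales()) {
  convert_scales(q, scales, inverse = FALSE)
}

#' @rdname nondimensionalize
#' @export
dimensionalize <- function(q, scales = reference_scales()) {
  convert_scales(q, scales, inverse = TRUE)
}

convert_scales <- function(q, scales, inverse) {
  if (is.null(names(q)) || any(!nzchar(names(q)))) {
    stop("quantities must be named", call. = FALSE)
  }
  known <- c(state_names, "t")
  bad <- setdiff(names(q), known)
  if (length(bad)) {
    stop("unknown quantities: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fac <- vapply(names(q), function(nm) {
    if (nm == "t") scales[["mu_S1_dim"]] else 1 / scales[[nm]]
  }, numeric(1))
  if (inverse) q / fac else q * fac
}
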