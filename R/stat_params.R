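# canonical parameter order shared with src/integrate.cpp -- do not reorder
.param_order <- c(
  "lambda_S1", "k1", "k2", "alpha", "lambda_k", "lambda_J", "K", "lambda_S2",
  "k3", "k4", "beta", "mu3",
  "lambda1", "k5", "k6", "gamma", "lambda3", "muB",
  "lambda2", "k7", "k8", "delta", "muX",
  "r", "k9", "k10", "T0", "muT",
  "muS", "Js", "gammaD", "muJ", "muD"
)

# fields that may be zero; k9 is additionally capped at 1
.nonneg_only <- c("lambda_S2", "gammaD", "k9")

#' Model parameters of the apoptosis-switch system
#'
#' Builds the full dimensionless parameter set of the coupled
#' STAT1-STAT3-Bcl-2-BAX / tumour / drug model. Defaults are the published
#' dimensionless values; the two IFN-beta source coefficients `lambda_S1`
#' (IFN-beta to STAT1) and `lambda_S2` (IFN-beta suppression of the STAT3
#' source) default to 1 and can be refined with
#' [calibrate_source_coefficients()].
#'
#' @param ... named parameter overrides, e.g. `muS = 3.2`. Unknown names are
#'   an error.
#' @param .base optional existing `stat_params` object to start from.
#'
#' @return A `stat_params` object: a named list of scalars with fields
#'   `lambda_S1, k1, k2, alpha` (STAT1 source, autocatalysis, Hill constant,
#'   inhibition by STAT3), `lambda_k, lambda_J, K, lambda_S2` (STAT3 source
#'   terms), `k3, k4, beta, mu3` (STAT3 autocatalysis and decay),
#'   `lambda1, k5, k6, gamma, lambda3, muB` (Bcl-2), `lambda2, k7, k8,
#'   delta, muX` (BAX), `r, k9, k10, T0, muT` (tumour), `muS` (IFN-beta
#'   decay), `Js, gammaD, muJ` (JAK2), `muD` (cisplatin decay).
#' @examples
#' p <- stat_params()
#' p$muS
#' stat_params(muS = 3.2)$muS
#' @export
stat_params <- function(..., .base = NULL) {
  defaults <- list(
    lambda_S1 = 1, k1 = 4, k2 = 1, alpha = 1.5,
    lambda_k = 1, lambda_J = 4, K = 5, lambda_S2 = 1,
    k3 = 4, k4 = 1, beta = 1, mu3 = 1,
    lambda1 = 0.2, k5 = 1, k6 = 1, gamma = 1, lambda3 = 1.2, muB = 1.2,
    lambda2 = 0.2, k7 = 4, k8 = 1, delta = 1, muX = 5,
    r = 0.12, k9 = 1, k10 = 10, T0 = 100, muT = 0.1,
    muS = 4.8, Js = 1.3, gammaD = 1, muJ = 1.3, muD = 10
  )
  p <- if (is.null(.base)) defaults else unclass(.base)
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots))) {
    dots <- dots[[1]]
  }
  if (length(dots)) {
    bad <- setdiff(names(dots), .param_order)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p <- p[.param_order]
  validate_stat_params(p)
  structure(p, class = "stat_params")
}

validate_stat_params <- function(p) {
  for (nm in .param_order) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
    }
    if (nm %in% .nonneg_only) {
      if (v < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
    } else if (v <= 0) {
      stop("parameter '", nm, "' must be > 0", call. = FALSE)
    }
  }
  if (p$k9 > 1) stop("k9 must be <= 1 (growth inhibition is a fraction)", call. = FALSE)
  invisible(p)
}

#' @export
print.stat_params <- function(x, ...) {
  cat("<stat_params> dimensionless apoptosis-switch model parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
as.double.stat_params <- function(x, ...) {
  unlist(unclass(x))[.param_order]
}

#' Tidy a parameter set
#'
#' @param x a `stat_params` object.
#' @param ... unused.
#' @return A tibble with columns `parameter` and `value`.
#' @export
tidy.stat_params <- function(x, ...) {
  tibble::tibble(parameter = .param_order, value = unname(unlist(unclass(x))))
}

#' Phase-classification thresholds
#'
#' Threshold concentrations that define the anti-apoptotic (Pt) and apoptotic
#' (Pa) regions of the Bcl-2/BAX plane. Only `B_th` and `X_th` take part in
#' the apoptosis indicator of the tumour equation; `S1_th` and `S3_th` are
#' descriptive classification levels for STAT1 and STAT3.
#'
#' @param S1_th,S3_th,B_th,X_th positive threshold levels (dimensionless
#'   concentrations).
#' @return A `stat_thresholds` object (named numeric vector of length 4).
#' @examples
#' stat_thresholds()
#' @export
stat_thresholds <- function(S1_th = 1.8, S3_th = 1.3, B_th = 1.44, X_th = 0.3) {
  th <- c(S1_th = S1_th, S3_th = S3_th, B_th = B_th, X_th = X_th)
  if (any(!is.finite(th)) || any(th <= 0)) {
    stop("all thresholds must be finite and > 0", call. = FALSE)
  }
  structure(th, class = "stat_thresholds")
}

#' @export
print.stat_thresholds <- function(x, ...) {
  cat("<stat_thresholds>\n")
  print(unclass(x))
  invisible(x)
}

#' Reference scales for dimensional conversion
#'
#' Concentration / volume scales used by the non-dimensionalization, plus the
#' dimensional STAT1 decay rate that sets the time unit (dimensionless time
#' `t = mu_S1_dim * t_dim`).
#'
#' @param S1_ref,S3_ref STAT1/STAT3 scales (micrograms per ml).
#' @param B_ref Bcl-2 scale (nM).
#' @param X_ref BAX scale (microM).
#' @param S_ref IFN-beta scale (ng per ml).
#' @param J_ref JAK2 scale (nM).
#' @param D_ref cisplatin scale (micrograms per ml).
#' @param T_ref tumour-volume scale (cubic mm).
#' @param mu_S1_dim dimensional STAT1 decay rate (per day); the time scale.
#' @return A `reference_scales` object (named numeric vector).
#' @export
reference_scales <- function(S1_ref = 2.43, S3_ref = 1.38, B_ref = 10,
                             X_ref = 351, S_ref = 10, J_ref = 2.8,
                             D_ref = 10, T_ref = 100, mu_S1_dim = 1) {
  sc <- c(S1 = S1_ref, S3 = S3_ref, B = B_ref, X = X_ref,
          S = S_ref, J = J_ref, D = D_ref, T = T_ref,
          mu_S1_dim = mu_S1_dim)
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    stop("all reference scales must be finite and > 0", call. = FALSE)
  }
  structure(sc, class = "reference_scales")
}

state_names <- c("S1", "S3", "B", "X", "T", "S", "J", "D")
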