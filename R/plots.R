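#' Plot a simulated trajectory
#'
#' Facetted time courses of the eight state variables, with the apoptotic
#' episodes (indicator on) shaded.
#'
#' @param object a `stat_trajectory` from [simulate_model()].
#' @param vars which state columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stat_trajectory <- function(object,
                                     vars = c("S1", "S3", "B", "X", "T",
                                              "S", "J", "D"), ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df[, c("time", vars)], cols = -"time",
                              names_to = "variable", values_to = "level")
  long$variable <- factor(long$variable, levels = vars)
  # contiguous apoptotic episodes as shaded bands
  r <- rle(df$indicator)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  on_runs <- tibble::tibble(xmin = df$time[starts[r$values == 1L]],
                            xmax = df$time[ends[r$values == 1L]])
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$level))
  if (nrow(on_runs)) {
    gg <- gg + ggplot2::geom_rect(
      data = on_runs, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      fill = "grey92")
  }
  gg +
    ggplot2::geom_line(colour = "#2C7FB8") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (dimensionless)", y = "level") +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Equilibrium level of one variable against the IFN-beta level, stable
#' branches drawn solid and unstable dashed; the bistability window, when
#' present, is shaded.
#'
#' @param object a `stat_bifurcation` from [scan_bifurcation()].
#' @param var which state to plot on the y axis.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stat_bifurcation <- function(object, var = "S1", ...) {
  df <- tibble::as_tibble(object)
  df$stability <- ifelse(df$stable, "stable", "unstable")
  w <- attr(object, "window")
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$S, y = .data[[var]],
                                         group = .data$branch,
                                         linetype = .data$stability))
  if (!is.null(w)) {
    gg <- gg + ggplot2::annotate("rect", xmin = w[1], xmax = w[2],
                                 ymin = -Inf, ymax = Inf,
                                 fill = "grey90", alpha = 0.7)
  }
  gg +
    ggplot2::geom_line(colour = "#D95F02") +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = "IFN-beta level S", y = paste0(var, " equilibrium")) +
    ggplot2::theme_minimal()
}

#' Plot an optimal-control solution
#'
#' Control profiles (top) and the tumour trajectory (bottom).
#'
#' @param object a `stat_control_solution`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stat_control_solution <- function(object, ...) {
  sol <- object$solution
  long <- tidyr::pivot_longer(sol[, c("time", "u_S", "u_D", "T")],
                              cols = -"time", names_to = "series",
                              values_to = "value")
  long$panel <- ifelse(long$series == "T", "tumour volume", "infusion rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_step(data = ~dplyr::filter(.x, .data$panel == "infusion rate")) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$panel == "tumour volume")) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (dimensionless)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response curve plot
#'
#' @param dr tibble from [dose_response()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(dr) {
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$u_S, y = .data$volume)) +
    ggplot2::geom_line(colour = "#1B9E77") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IFN-beta infusion rate", y = "tumour volume") +
    ggplot2::theme_minimal()
}
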