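.experiment_names <- c("fig3", "fig4", "fig5", "fig6", "fig7", "fig8",
                       "fig9", "fig10", "fig11", "fig12", "custom")

.config_keys <- c("experiment", "params", "thresholds", "initial_state",
                  "schedule", "weights", "control", "solver", "output",
                  "seed")

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON experiment description, fills defaults for every
#' omitted model parameter and threshold, and validates strictly: unknown
#' top-level keys, unknown parameter names, non-numeric values and `k9 > 1`
#' are all rejected with the offending key named.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return An `experiment_config` list with elements `experiment`, `params`
#'   ([stat_params()]), `thresholds`, `initial_state`, `schedule`,
#'   `weights`, `control`, `solver`, `output`, `seed`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), .config_keys)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_num <- function(block, block_name) {
    for (nm in names(block)) {
      v <- block[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        stop("config key '", block_name, ".", nm,
             "' must be a finite number", call. = FALSE)
      }
    }
    block
  }
  params <- stat_params(check_num(raw$params, "params"))
  th_over <- check_num(raw$thresholds, "thresholds")
  th_def <- list(S1_th = 1.8, S3_th = 1.3, B_th = 1.44, X_th = 0.3)
  th_def[names(th_over)] <- th_over
  thresholds <- do.call(stat_thresholds, th_def)
  experiment <- raw$experiment %||% "custom"
  if (!experiment %in% .experiment_names) {
    stop("unknown experiment '", experiment, "'; valid names: ",
         paste(.experiment_names, collapse = ", "), call. = FALSE)
  }
  structure(list(
    experiment = experiment,
    params = params,
    thresholds = thresholds,
    initial_state = raw$initial_state,
    schedule = raw$schedule,
    weights = raw$weights,
    control = raw$control,
    solver = raw$solver %||% list(dt_out = 0.01, dt_max = 0.002),
    output = raw$output,
    seed = raw$seed
  ), class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  flat <- utils::capture.output(utils::str(config, digits.d = 15))
  format(sum(utf8ToInt(paste(flat, collapse = ""))) %% 1e9, scientific = FALSE)
}

#' Run a packaged experiment
#'
#' Dispatches a validated configuration to the matching analysis
#' (bifurcation scans for the diagram experiments, schedule scans and
#' dose/rest searches for the infusion experiments, sweep solves for the
#' control experiments), writes the tabular results as CSV with a
#' provenance header, and returns the key scalar results.
#'
#' @param config an `experiment_config` from [load_experiment_config()], or
#'   the name of a packaged experiment (`"fig4"`, ...).
#' @param out_dir output directory (created if missing). `NULL` suppresses
#'   file output.
#' @return List with elements `tables` (named list of tibbles) and
#'   `summary` (named list of scalars); written files carry a
#'   `# statswitch <version> config_hash=<hash>` header.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    path <- system.file("extdata", paste0(config, ".yaml"),
                        package = "statswitch")
    if (!nzchar(path)) {
      stop("unknown experiment '", config, "'; valid names: ",
           paste(setdiff(.experiment_names, "custom"), collapse = ", "),
           call. = FALSE)
    }
    config <- load_experiment_config(path)
  }
  stopifnot(inherits(config, "experiment_config"))
  p <- config$params
  th <- config$thresholds
  sv <- config$solver
  res <- switch(config$experiment,
    fig3 = ,
    fig4 = {
      bd <- scan_bifurcation(p, seq(0, 1, by = 0.005), J = 0, thresholds = th)
      w <- bistability_window(bd)
      list(tables = list(diagram = tidy.stat_bifurcation(bd)),
           summary = list(S_m = unname(w[1]), S_M = unname(w[2])))
    },
    fig5 = {
      bd <- scan_bifurcation(p, seq(0, 1, by = 0.005), J = 1, thresholds = th)
      list(tables = list(diagram = tidy.stat_bifurcation(bd)),
           summary = list(bistable = length(bistability_window(bd)) > 0,
                          max_S1 = max(bd$S1), min_S3 = min(bd$S3),
                          min_B = min(bd$B), max_X = max(bd$X)))
    },
    fig6 = {
      dr <- dose_response(p, th, dt_out = sv$dt_out, dt_max = sv$dt_max)
      list(tables = list(dose_response = dr),
           summary = list(control_volume = dr$volume[dr$u_S == 0],
                          volume_at_15 = dr$volume[dr$u_S == 15]))
    },
    fig7 = {
      scan <- schedule_scan(p, thresholds = th,
                            dt_out = sv$dt_out, dt_max = sv$dt_max)
      g1 <- grouped_schedule_summary(scan, "first_drug")
      g2 <- grouped_schedule_summary(scan, "first_half_weighting")
      list(tables = list(schedules = scan, by_first_drug = g1,
                         by_first_half = g2),
           summary = list(
             best = scan$sequence[which.min(scan$normalized_volume)],
             worst = scan$sequence[which.max(scan$normalized_volume)]))
    },
    fig8 = {
      seqs <- config$schedule$sequences %||% c("SSSDDD", "DSDDSS")
      md <- dplyr::bind_rows(lapply(seqs, function(sq)
        min_rate_for_reduction(p, sq, thresholds = th,
                               dt_out = sv$dt_out, dt_max = sv$dt_max)))
      rest <- dplyr::bind_rows(lapply(seqs, function(sq)
        max_resting_time(p, sq, thresholds = th,
                         dt_out = sv$dt_out, dt_max = sv$dt_max)))
      list(tables = list(min_dose = md, resting_time = rest),
           summary = list(min_rate = min(md$u_S), max_rate = max(md$u_S)))
    },
    fig9 = {
      hs_values <- config$schedule$h_s_values %||% c(2, 1, 0.5, 0.1)
      rows <- lapply(hs_values, function(hs) {
        seqs <- enumerate_schedules(3, 3)
        vols <- vapply(seqs, function(sq) {
          sch <- pulse_schedule(sq, 5, h_s = hs, h_d = 5, t_end = 30)
          sch <- rescale_rate_for_fixed_total(sch, total_S = 123,
                                              total_D = 690)
          simulate_schedule(p, sch, th, control = "no_ifn",
                            dt_out = sv$dt_out,
                            dt_max = sv$dt_max)$summary$normalized_volume
        }, numeric(1))
        tibble::tibble(h_s = hs, sequence = seqs, normalized_volume = vols)
      })
      tab <- dplyr::bind_rows(rows)
      means <- tab |> dplyr::group_by(.data$h_s) |>
        dplyr::summarise(mean_volume = mean(.data$normalized_volume),
                         .groups = "drop")
      list(tables = list(duration = tab, means = means),
           summary = as.list(stats::setNames(means$mean_volume,
                                             paste0("mean_h", means$h_s))))
    },
    fig10 = {
      res <- run_strategy_I(p, th, dt = sv$dt_out, dt_max = sv$dt_max)
      list(tables = list(comparison = res$comparison,
                         optimal = tidy.stat_control_solution(res$optimal)),
           summary = as.list(stats::setNames(res$comparison$T_final,
                                             res$comparison$strategy)))
    },
    fig11 = {
      tab <- half_life_experiment(p, thresholds = th,
                                  dt = sv$dt_out, dt_max = sv$dt_max)
      list(tables = list(half_life = tab), summary = list())
    },
    fig12 = {
      seqs <- config$schedule$sequences %||% c("SSSDDD", "DSDDSS")
      rows <- lapply(seqs, function(sq)
        run_strategy_II(p, th, sequence = sq,
                        dt = sv$dt_out, dt_max = sv$dt_max)$summary)
      tab <- dplyr::bind_rows(rows)
      list(tables = list(strategy_II = tab),
           summary = as.list(stats::setNames(tab$accumulated_S,
                                             paste0("accumulated_",
                                                    tab$sequence))))
    },
    custom = stop("custom experiments must be run through the package ",
                  "functions directly", call. = FALSE)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- sprintf("# statswitch %s config_hash=%s experiment=%s",
                   as.character(utils::packageVersion("statswitch")),
                   config_hash(config), config$experiment)
    for (nm in names(res$tables)) {
      f <- file.path(out_dir, paste0(config$experiment, "_", nm, ".csv"))
      writeLines(hdr, f)
      suppressWarnings(utils::write.table(
        res$tables[[nm]], f, append = TRUE, sep = ",", row.names = FALSE,
        qmethod = "double"))
    }
    jsonlite::write_json(
      c(list(.provenance = hdr), res$summary),
      file.path(out_dir, paste0(config$experiment, "_summary.json")),
      auto_unbox = TRUE, digits = NA)
  }
  res
}
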