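## Orchestration: generate -> analyze -> summarize runs from a single
## configuration, with deterministic seeding and machine-readable outputs.

#' Run configuration
#'
#' Describes a complete generate/analyze run.  Defaults use the standard
#' analysis thresholds: 35-water closure criterion, 10/20-A blocker
#' thresholds with 30-ns running medians, 2-A permeation hysteresis.
#'
#' @param scenario scenario name for [scenario_preset()].
#' @param voltages voltages to simulate, mV.
#' @param duration_us duration per replicate, us.
#' @param replicates replicates per voltage (>= 1).
#' @param seed master seed; replicate streams are derived as
#'   `seed + 1000 * voltage_index + replicate_index`.
#' @param dt_ns frame interval for rendering, ns.
#' @param analyses character subset of
#'   `c("permeation", "gating", "blocker")`.
#' @param hydration_threshold closure criterion, waters.
#' @param persistence_us closure persistence window, us.
#' @param d_on,d_off,window_ns blocker detection parameters.
#' @param hysteresis permeation hysteresis band, A.
#' @param with_blocker include the scenario's blocker in the simulation.
#' @return object of class `run_config`.
#' @export
run_config <- function(scenario = "WT", voltages = 310, duration_us = 10,
                       replicates = 1, seed = 1, dt_ns = 2,
                       analyses = c("permeation", "gating"),
                       hydration_threshold = 35, persistence_us = 1,
                       d_on = 10, d_off = 20, window_ns = 30,
                       hysteresis = 2,
                       with_blocker = "blocker" %in% analyses) {
  if (replicates < 1) stop("'replicates' must be >= 1")
  stopifnot(all(analyses %in% c("permeation", "gating", "blocker")))
  structure(list(scenario = scenario, voltages = voltages,
                 duration_us = duration_us, replicates = replicates,
                 seed = seed, dt_ns = dt_ns, analyses = analyses,
                 hydration_threshold = hydration_threshold,
                 persistence_us = persistence_us,
                 d_on = d_on, d_off = d_off, window_ns = window_ns,
                 hysteresis = hysteresis, with_blocker = with_blocker),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys raise an error; all known keys override the
#' [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Execute a full generate/analyze/summarize run
#'
#' For every voltage and replicate, generates a synthetic trajectory from
#' the scenario preset, renders frames, runs the requested analyzers, and
#' aggregates the results.  Rerunning with an identical configuration
#' reproduces all stochastic outputs bit-exact (replicate seeds derive from
#' the master seed and replicate index, never from the clock).  When
#' `out_dir` is given, results are serialized (CSV/JSON) together with the
#' configuration hash, seed and package version; a failing stage is caught,
#' recorded in the error summary, and does not discard completed results.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `per_run` (one entry per voltage x replicate:
#'   current/occupancy/closure/blocker results), `iv` (i-V table when >= 2
#'   voltages), `errors` (per-stage error messages), and `meta`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  per_run <- list()
  errors <- character(0)
  iv_rows <- list()
  for (vi in seq_along(config$voltages)) {
    V <- config$voltages[vi]
    for (ri in seq_len(config$replicates)) {
      run_id <- sprintf("V%g_r%d", V, ri)
      res <- tryCatch({
        sc <- scenario_preset(config$scenario, voltage = V)
        seed_i <- config$seed + 1000L * vi + ri
        sim <- simulate_pore(sc$model, sc$gate,
                             if (config$with_blocker) sc$blocker else NULL,
                             duration = config$duration_us, seed = seed_i)
        include <- c("ions", "coperm_waters",
                     if ("gating" %in% config$analyses)
                       c("gate", "landmarks", "cavity_waters"),
                     if (config$with_blocker) c("spm", "landmarks"))
        tracks <- render_frames(sim, dt_ns = config$dt_ns,
                                include = unique(include),
                                seed = seed_i + 500000L)
        out <- list(run_id = run_id, voltage = V, seed = seed_i)
        if ("permeation" %in% config$analyses) {
          ev <- detect_permeation_events(tracks,
                                         hysteresis = config$hysteresis)
          out$events <- ev
          out$current <- current_and_conductance(ev, config$duration_us, V)
          out$occupancy_SF <- kinetic_occupancy(
            tracks, region = "SF", rule = "intracellular_entry_only")
          wev <- detect_permeation_events(tracks, particle_role = "water",
                                          hysteresis = config$hysteresis)
          out$water_ratio <- tryCatch(
            water_ion_ratio(wev, ev[ev$direction == "outward", ]),
            error = function(e) NULL)
        }
        if ("gating" %in% config$analyses) {
          hyd <- cavity_hydration(tracks)
          out$hydration_mean <- mean(hyd$count)
          out$closure <- detect_closure(
            hyd, threshold = config$hydration_threshold,
            persistence = max(1L, round(config$persistence_us * 1000 /
                                          config$dt_ns)))
          out$gate_distance_mean <-
            mean(gate_diagonal_distance(tracks, "I177")$distance)
        }
        if (config$with_blocker) {
          dser <- blocker_distance_series(
            tracks, blocker_config(config$d_on, config$d_off,
                                   config$window_ns))
          out$binding <- detect_binding(
            dser, blocker_config(config$d_on, config$d_off,
                                 config$window_ns))
        }
        out
      }, error = function(e) {
        errors <<- c(errors, paste0(run_id, ": ", conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        per_run[[run_id]] <- res
        if (!is.null(res$current))
          iv_rows[[run_id]] <- data.frame(voltage = V,
                                          current_pA = res$current$current_pA)
      }
    }
  }
  iv <- if (length(config$voltages) >= 2 && length(iv_rows))
    summarize_iv(do.call(rbind, iv_rows)) else NULL
  meta <- list(package_version = as.character(
                 utils::packageVersion("kirtraj")),
               config = unclass(config), config_hash = .config_hash(config),
               seed = config$seed)
  result <- list(per_run = per_run, iv = iv, errors = errors, meta = meta)
  if (!is.null(out_dir)) .write_report(result, config, out_dir)
  result
}

.write_report <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jd <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  jd(result$meta, "meta.json")
  summaries <- lapply(result$per_run, function(r) {
    list(run_id = r$run_id, voltage = r$voltage, seed = r$seed,
         current_pA = r$current$current_pA,
         conductance_pS = r$current$conductance_pS,
         n_out = r$current$n_out, n_in = r$current$n_in,
         occupancy_SF = r$occupancy_SF$mean,
         water_ratio = r$water_ratio$ratio,
         hydration_mean = r$hydration_mean,
         gate_distance_mean = r$gate_distance_mean,
         closed = if (!is.null(r$closure)) r$closure$closed,
         closure_time = if (!is.null(r$closure)) r$closure$time,
         t_on = if (!is.null(r$binding)) r$binding$t_on)
  })
  jd(summaries, "summary.json")
  ev_all <- data.table::rbindlist(
    lapply(result$per_run, function(r)
      if (!is.null(r$events) && nrow(r$events))
        cbind(run_id = r$run_id, r$events) else NULL),
    use.names = TRUE)
  if (NROW(ev_all))
    utils::write.csv(ev_all, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
  if (!is.null(result$iv))
    utils::write.csv(result$iv, file.path(out_dir, "iv.csv"),
                     row.names = FALSE)
  if (length(result$errors))
    writeLines(result$errors, file.path(out_dir, "errors.txt"))
  invisible(out_dir)
}

#' Current-voltage summary table
#'
#' Aggregates per-replicate currents by voltage into an i-V table (mean and
#' standard error across replicates; no fitting).  Replicates at the same
#' voltage are aggregated (with a note when several input rows duplicate a
#' voltage); at least two distinct voltages are required.
#'
#' @param currents data.frame with columns `voltage` (mV) and `current_pA`
#'   (one row per replicate), or a list of `current_result` objects.
#' @return data.frame with `voltage`, `current_pA`, `se`, `n`.
#' @export
summarize_iv <- function(currents) {
  if (is.list(currents) && !is.data.frame(currents) &&
      all(vapply(currents, inherits, TRUE, "current_result"))) {
    currents <- do.call(rbind, lapply(currents, function(x)
      data.frame(voltage = x$voltage, current_pA = x$current_pA)))
  }
  stopifnot(all(c("voltage", "current_pA") %in% names(currents)))
  vs <- unique(currents$voltage)
  if (length(vs) < 2)
    stop("i-V summary needs at least two distinct voltages")
  if (anyDuplicated(currents$voltage))
    message("aggregating replicate currents at duplicated voltages")
  agg <- do.call(rbind, lapply(sort(vs), function(v) {
    x <- currents$current_pA[currents$voltage == v]
    data.frame(voltage = v, current_pA = mean(x),
               se = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                    else NA_real_,
               n = length(x))
  }))
  rownames(agg) <- NULL
  agg
}
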