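#' Default model-speed grid for sweeps
#'
#' Log-spaced speeds covering the LGN-responsive band with margin on both
#' sides.
#'
#' @param n number of speeds; default 60.
#' @param lo,hi grid bounds in model-speed units; defaults 1e-2 and 1e2.
#' @return strictly increasing numeric vector.
#' @export
default_speed_grid <- function(n = 60L, lo = 1e-2, hi = 1e2) {
  if (lo <= 0 || hi <= lo) stop("need 0 < lo < hi")
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Selectivities and latencies across stimulus speeds
#'
#' Runs \code{\link{measure_run}} at each speed. A speed at which the
#' simulation fails is recorded as a row of missing values rather than
#' aborting the sweep.
#'
#' @param speeds model speeds, strictly increasing; default
#'   \code{\link{default_speed_grid}()}.
#' @param spec,lgn,p stimulus, LGN and circuit parameters.
#' @param ... further arguments passed to \code{\link{measure_run}}
#'   (e.g. \code{dense_dt}, \code{rtol}, \code{threshold}).
#' @return data frame with one row per speed (columns as in
#'   \code{\link{measure_run}}).
#' @export
speed_sweep <- function(speeds = default_speed_grid(),
                        spec = stimulus_spec(), lgn = lgn_params(),
                        p = shunting_params(), ...) {
  if (any(diff(speeds) <= 0)) stop("'speeds' must be strictly increasing")
  rows <- lapply(speeds, function(v) {
    tryCatch(
      suppressWarnings(measure_run(spec, lgn, p, v_model = v, ...)),
      error = function(e) {
        data.frame(v_model = v, v_physical = v * spec$w,
                   s_on = NA_real_, s_dir = NA_real_, s_off = NA_real_,
                   t_on = NA_real_, t_dir = NA_real_, t_off = NA_real_,
                   x_min = NA_real_, x_max = NA_real_,
                   y_min = NA_real_, y_max = NA_real_)
      })
  })
  do.call(rbind, rows)
}

#' Selectivity curves across circuit-parameter choices
#'
#' Repeats a speed sweep with each of the named shunting parameters scaled
#' by each multiplier (defaults: two orders of magnitude around the standard
#' values), to separate circuit-connectivity effects from parameter choice.
#'
#' @param params which parameters to vary; subset of
#'   \code{c("A", "B", "tau")}.
#' @param multipliers scale factors applied to one parameter at a time;
#'   default \code{c(0.1, 1, 10)}.
#' @param speeds model-speed grid; default
#'   \code{\link{default_speed_grid}()}.
#' @param spec,lgn,p baseline stimulus, LGN and circuit parameters.
#' @param ... passed to \code{\link{measure_run}}.
#' @return data frame: columns \code{param}, \code{multiplier}, then the
#'   sweep columns. Multiplier-1 blocks are identical across parameters.
#' @export
parameter_sweep <- function(params = c("A", "B", "tau"),
                            multipliers = c(0.1, 1, 10),
                            speeds = default_speed_grid(),
                            spec = stimulus_spec(), lgn = lgn_params(),
                            p = shunting_params(), ...) {
  params <- match.arg(params, c("A", "B", "tau"), several.ok = TRUE)
  baseline <- NULL
  blocks <- list()
  for (pm in params) {
    for (m in multipliers) {
      if (m == 1) {
        if (is.null(baseline))
          baseline <- speed_sweep(speeds, spec, lgn, p, ...)
        sw <- baseline
      } else {
        p2 <- p
        p2[[pm]] <- p[[pm]] * m
        sw <- speed_sweep(speeds, spec, lgn, p2, ...)
      }
      blocks[[length(blocks) + 1L]] <-
        cbind(data.frame(param = pm, multiplier = m), sw)
    }
  }
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}

#' Single standard run with event summary
#'
#' The canonical demonstration run: patch appears at \code{start_pos} at
#' \code{t = 0}, moves at \code{v_model}, and vanishes after leaving
#' \code{end_pos}. Returns the full trajectory, the accumulator readout,
#' and a summary of stimulus events (appearance, per-position occupancy,
#' input vanishing). With zero drive (e.g. zero contrast) the event table
#' is empty.
#'
#' @param spec,lgn,p stimulus, LGN and circuit parameters.
#' @param ... passed to \code{\link{simulate_circuit}}.
#' @return list with elements \code{trajectory} (a
#'   \code{"bl_trajectory"}), \code{readout} (one-row data frame from
#'   \code{\link{measure_run}}) and \code{events} (data frame with columns
#'   \code{event}, \code{position}, \code{t_start}, \code{t_end}).
#' @export
run_single <- function(spec = stimulus_spec(), lgn = lgn_params(),
                       p = shunting_params(), ...) {
  readout <- suppressWarnings(
    measure_run(spec, lgn, p, v_model = spec$v_model,
                keep_trajectory = TRUE, ...))
  traj <- attr(readout, "trajectory")
  attr(readout, "trajectory") <- NULL

  J <- traj$settings$J
  if (J > 0) {
    step <- if (stimulus_direction(spec) == "r") 1L else -1L
    m <- seq_len(n_occupied(spec)) - 1L
    pos <- spec$start_pos + step * m
    events <- data.frame(
      event = c("motion_onset",
                rep("occupancy", length(pos)),
                "input_vanish"),
      position = c(spec$start_pos, pos, NA_integer_),
      t_start = c(0, m / spec$v_model, n_occupied(spec) / spec$v_model),
      t_end = c(0, (m + 1L) / spec$v_model,
                n_occupied(spec) / spec$v_model)
    )
  } else {
    events <- data.frame(event = character(), position = integer(),
                         t_start = numeric(), t_end = numeric())
  }
  list(trajectory = traj, readout = readout, events = events)
}

#' Write sweep or trajectory results as CSV with a JSON sidecar
#'
#' Deterministic output: re-running with the same inputs reproduces
#' byte-identical files. Missing latencies/RTs serialize as empty fields.
#' The sidecar records the full parameter set and integrator settings so a
#' run can be reproduced from it.
#'
#' @param x a data frame (sweep, RT curve), a \code{"bl_trajectory"}, or the
#'   list returned by \code{\link{run_single}}.
#' @param out_prefix path prefix; files \code{<prefix>.csv} (and
#'   \code{<prefix>_events.csv}, \code{<prefix>_readout.csv} for single
#'   runs) plus \code{<prefix>.json} are written.
#' @param meta named list merged into the sidecar.
#' @return invisibly, the paths written.
#' @export
write_tables <- function(x, out_prefix, meta = list()) {
  paths <- character()
  put_csv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    paths <<- c(paths, path)
  }
  sidecar <- function(extra) {
    path <- paste0(out_prefix, ".json")
    jsonlite::write_json(c(extra, meta), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    paths <<- c(paths, path)
  }
  describe <- function(traj) {
    list(stimulus = unclass(traj$spec), lgn = unclass(traj$lgn),
         model = unclass(traj$params), integrator = traj$settings)
  }
  if (inherits(x, "bl_trajectory")) {
    put_csv(as.data.frame(x), paste0(out_prefix, ".csv"))
    sidecar(describe(x))
  } else if (is.data.frame(x)) {
    put_csv(x, paste0(out_prefix, ".csv"))
    sidecar(list(columns = names(x), rows = nrow(x)))
  } else if (is.list(x) && all(c("trajectory", "readout", "events")
                               %in% names(x))) {
    put_csv(as.data.frame(x$trajectory), paste0(out_prefix, ".csv"))
    put_csv(x$readout, paste0(out_prefix, "_readout.csv"))
    put_csv(x$events, paste0(out_prefix, "_events.csv"))
    sidecar(describe(x$trajectory))
  } else {
    stop("don't know how to write an object of class ",
         paste(class(x), collapse = "/"))
  }
  invisible(paths)
}
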