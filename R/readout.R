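#' Evidence-accumulator specification
#'
#' A lumped accumulator population obeying the shunting equation with time
#' constant \code{C * tau}: excited by the summed rectified activities of its
#' excitatory taps ("correct" evidence) and inhibited by those of its
#' inhibitory taps ("incorrect" evidence). Coupling is one-way - accumulators
#' read the network and never feed back.
#'
#' @param label short name, e.g. \code{"on"}.
#' @param exc,inh data frames with columns \code{layer}, \code{position},
#'   \code{direction} naming the tapped cells. \code{inh} may have zero rows.
#' @return An object of class \code{"accumulator_spec"}.
#' @export
accumulator_spec <- function(label, exc, inh) {
  check_taps <- function(df, what) {
    if (!is.data.frame(df) ||
        !all(c("layer", "position", "direction") %in% names(df)))
      stop(sprintf("'%s' must have columns layer, position, direction", what))
    if (nrow(df) && (!all(df$layer %in% LAYERS) ||
                     !all(df$direction %in% DIRECTIONS)))
      stop(sprintf("unknown layer or direction in '%s' taps", what))
    df
  }
  if (nrow(exc) < 1L) stop("an accumulator needs at least one excitatory tap")
  structure(list(label = as.character(label),
                 exc = check_taps(exc, "exc"), inh = check_taps(inh, "inh")),
            class = "accumulator_spec")
}

taps <- function(layer, position, direction) {
  data.frame(layer = layer, position = as.integer(position),
             direction = direction, stringsAsFactors = FALSE)
}

#' Standard onset / direction / offset accumulators for a stimulus
#'
#' Builds the three readout populations matched to a moving-patch stimulus
#' (direction \code{d}, appearing at \code{start_pos}, stopping at
#' \code{end_pos}):
#' \itemize{
#'   \item \code{on}: + onset cell at the appearance position (direction
#'     \code{d}), - onset cells at every other position (same direction);
#'   \item \code{dir}: + directional cell at \code{end_pos} tuned to
#'     \code{d} (a position crossed during constant motion), - the
#'     opposite-direction cell at the same position;
#'   \item \code{off}: + offset cell one position past \code{end_pos}
#'     (where the patch fails to arrive), - offset cells at every other
#'     position.
#' }
#'
#' @param spec a \code{\link{stimulus_spec}}. The offset accumulator needs a
#'   position beyond \code{end_pos}, so \code{end_pos} cannot be the last
#'   grid position in the direction of motion.
#' @return list of three \code{\link{accumulator_spec}} objects named
#'   \code{on}, \code{dir}, \code{off}.
#' @export
default_accumulators <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  d <- stimulus_direction(spec)
  D <- opposite_direction(d)
  n <- spec$n_positions
  step <- if (d == "r") 1L else -1L
  off_pos <- spec$end_pos + step
  if (off_pos < 1L || off_pos > n)
    stop("offset accumulator needs a grid position one step past 'end_pos'")
  others <- function(pos) setdiff(seq_len(n), pos)
  list(
    on = accumulator_spec(
      "on",
      exc = taps("on", spec$start_pos, d),
      inh = taps("on", others(spec$start_pos), d)),
    dir = accumulator_spec(
      "dir",
      exc = taps("dir", spec$end_pos, d),
      inh = taps("dir", spec$end_pos, D)),
    off = accumulator_spec(
      "off",
      exc = taps("off", off_pos, d),
      inh = taps("off", others(off_pos), d))
  )
}

#' Accumulator dynamics
#'
#' The shunting right-hand side with the accumulator slowdown \code{C}
#' applied to the time constant; drives are sums of rectified tapped
#' activities.
#'
#' @param y accumulator activity.
#' @param exc,inh nonnegative summed drives.
#' @param p a \code{\link{shunting_params}}.
#' @return \code{dy/dt}.
#' @export
accumulator_rhs <- function(y, exc, inh, p) {
  shunting_rhs(y, exc, inh, p, slowdown = p$C)
}

#' Integrate accumulators against a recorded trajectory
#'
#' Post-hoc integration: the rectified tapped activities are interpolated
#' linearly on the trajectory's dense grid and each accumulator ODE is
#' integrated from 0. Agrees with co-integration (accumulators solved
#' together with the network in \code{\link{simulate_circuit}}) to within
#' interpolation error on the dense grid.
#'
#' @param traj a \code{"bl_trajectory"}.
#' @param specs list of \code{\link{accumulator_spec}} objects; defaults to
#'   the trajectory's own.
#' @param p a \code{\link{shunting_params}}; defaults to the trajectory's.
#' @param rtol,atol integrator tolerances.
#' @param method \code{"lsoda"} (default) or \code{"ode45"}.
#' @return matrix with one column per accumulator, sampled at
#'   \code{traj$times}.
#' @export
integrate_accumulators <- function(traj, specs = traj$accumulators,
                                   p = traj$params,
                                   rtol = 1e-8, atol = 1e-10,
                                   method = c("lsoda", "ode45")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "bl_trajectory"))
  if (!length(specs)) stop("no accumulator specs given")
  n <- traj$spec$n_positions
  cols <- function(df) {
    idx <- mapply(cell_index, df$layer, df$position, df$direction,
                  MoreArgs = list(n = n))
    if (!all(idx <= ncol(traj$net)))
      stop("accumulator tap outside the recorded network")
    idx
  }
  out <- matrix(NA_real_, length(traj$times), length(specs),
                dimnames = list(NULL,
                                vapply(specs, `[[`, character(1L), "label")))
  for (k in seq_along(specs)) {
    a <- specs[[k]]
    exc_course <- rowSums(rectify(traj$net[, cols(a$exc), drop = FALSE]))
    inh_course <- if (nrow(a$inh))
      rowSums(rectify(traj$net[, cols(a$inh), drop = FALSE]))
    else rep(0, length(traj$times))
    fe <- stats::approxfun(traj$times, exc_course, rule = 2)
    fi <- stats::approxfun(traj$times, inh_course, rule = 2)
    sol <- deSolve::ode(
      y = 0, times = traj$times,
      func = function(t, y, parms) list(accumulator_rhs(y, fe(t), fi(t), p)),
      parms = NULL, method = method, rtol = rtol, atol = atol)
    out[, k] <- unclass(sol)[, 2L]
  }
  out
}

#' Selectivity of an accumulator time course
#'
#' The peak rectified activity reached over the course: the model's
#' perceptual-evidence measure for the stimulus aspect the accumulator
#' encodes.
#'
#' @param y accumulator activity samples.
#' @return \code{max_t [y(t)]^+}.
#' @export
selectivity <- function(y) {
  if (!length(y)) stop("empty accumulator course")
  max(rectify(y))
}

#' Threshold-crossing latency of an accumulator
#'
#' Time from a stimulus event to the accumulator first reaching
#' \code{threshold}, with the crossing located by linear interpolation
#' between the bracketing samples. Negative latencies (crossing before the
#' event) are legitimate - offset accumulators can fire predictively at low
#' speeds. Returns \code{NA} if the threshold is never reached.
#'
#' @param y accumulator activity samples.
#' @param times sample times (strictly increasing, same length as \code{y}).
#' @param event_time time of the referenced stimulus event.
#' @param threshold activity criterion, > 0; default 0.1.
#' @return latency in simulation-time units, or \code{NA_real_}.
#' @examples
#' response_latency(seq(0, 1, 0.01), seq(0, 10, 0.1), 0, 0.1)  # ramp t/10
#' @export
response_latency <- function(y, times, event_time, threshold = 0.1) {
  if (threshold <= 0) stop("'threshold' must be positive")
  if (length(y) != length(times)) stop("'y' and 'times' lengths differ")
  k <- which(y >= threshold)
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  t_cross <- if (k == 1L) times[1L] else {
    # linear interpolation between the bracketing samples
    times[k - 1L] + (threshold - y[k - 1L]) / (y[k] - y[k - 1L]) *
      (times[k] - times[k - 1L])
  }
  t_cross - event_time
}

#' Run one simulation and read out selectivities and latencies
#'
#' Simulates the circuit at model speed \code{v_model} with the standard
#' accumulators co-integrated, then reports each accumulator's selectivity
#' (peak activity) and neural latency (first crossing of \code{threshold}).
#' Latency reference events: motion onset (\code{t = 0}) for the onset and
#' direction accumulators, input-vanishing time
#' (\code{n_occupied(spec) / v_model}) for the offset accumulator.
#'
#' @param spec a \code{\link{stimulus_spec}}; its \code{v_model} is replaced
#'   by the \code{v_model} argument.
#' @param lgn an \code{\link{lgn_params}}.
#' @param p a \code{\link{shunting_params}}.
#' @param v_model stimulus speed, positions per time unit.
#' @param threshold latency criterion; default 0.1.
#' @param dense_dt,rtol,atol,onset_inh,method passed to
#'   \code{\link{simulate_circuit}}.
#' @param t_end simulation horizon; default as in
#'   \code{\link{simulate_circuit}}. A warning is issued if any accumulator
#'   is still at its running maximum in the final sample.
#' @param keep_trajectory keep the full trajectory in the result? Default
#'   \code{FALSE}.
#' @return one-row data frame: \code{v_model}, \code{v_physical},
#'   \code{s_on}, \code{s_dir}, \code{s_off}, \code{t_on}, \code{t_dir},
#'   \code{t_off}, plus network activity extrema \code{x_min}, \code{x_max}
#'   and accumulator extrema \code{y_min}, \code{y_max} for bound checks.
#'   If \code{keep_trajectory}, the trajectory is attached as attribute
#'   \code{"trajectory"}.
#' @export
measure_run <- function(spec = stimulus_spec(), lgn = lgn_params(),
                        p = shunting_params(), v_model = spec$v_model,
                        threshold = 0.1, dense_dt = 0.01 * p$tau,
                        t_end = NULL, rtol = 1e-8, atol = 1e-10,
                        onset_inh = c("same", "opposite"),
                        method = c("lsoda", "ode45"),
                        keep_trajectory = FALSE) {
  onset_inh <- match.arg(onset_inh)
  method <- match.arg(method)
  spec <- stimulus_spec(v_model = v_model, n_positions = spec$n_positions,
                        start_pos = spec$start_pos, end_pos = spec$end_pos,
                        w = spec$w)
  traj <- simulate_circuit(spec, lgn, p, t_end = t_end, dense_dt = dense_dt,
                           onset_inh = onset_inh, rtol = rtol, atol = atol,
                           method = method)
  t_offset_event <- n_occupied(spec) / spec$v_model
  events <- c(on = 0, dir = 0, off = t_offset_event)

  s <- vapply(colnames(traj$acc),
              function(lb) selectivity(traj$acc[, lb]), numeric(1L))
  lat <- vapply(colnames(traj$acc), function(lb) {
    response_latency(traj$acc[, lb], traj$times, events[[lb]], threshold)
  }, numeric(1L))

  nT <- length(traj$times)
  for (lb in colnames(traj$acc)) {
    if (s[[lb]] > 1e-3 && traj$acc[nT, lb] >= s[[lb]] - 1e-12)
      warning(sprintf(
        "accumulator '%s' still at its maximum at t_end = %g (v_model = %g); consider a longer horizon",
        lb, max(traj$times), v_model))
  }

  res <- data.frame(
    v_model = v_model, v_physical = v_model * spec$w,
    s_on = s[["on"]], s_dir = s[["dir"]], s_off = s[["off"]],
    t_on = lat[["on"]], t_dir = lat[["dir"]], t_off = lat[["off"]],
    x_min = min(traj$net), x_max = max(traj$net),
    y_min = min(traj$acc), y_max = max(traj$acc)
  )
  if (keep_trajectory) attr(res, "trajectory") <- traj
  res
}
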