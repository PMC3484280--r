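## Network layout -----------------------------------------------------------
## Five ODE layers (inh, dir, srf, on, off), each with one cell per
## (position, direction). The undirectional layer is explicit input, not
## state. Flat state ordering is layer-major, then position, then direction
## with l before r: index = dir + 2*(pos-1) + 2*n*(layer-1).

LAYERS <- c("inh", "dir", "srf", "on", "off")
DIRECTIONS <- c("l", "r")

#' Threshold-linear rectification
#'
#' The rectified activity \code{max(x, 0)} represents a cell's firing rate;
#' negative activity is hyperpolarization and transmits nothing.
#'
#' @param x activity value(s).
#' @return elementwise \code{max(x, 0)}.
#' @export
rectify <- function(x) pmax(x, 0)

#' Shunting membrane equation right-hand side
#'
#' The generic cell dynamic: passive decay towards 0 at rate \code{A},
#' excitation gated by the distance to the ceiling \code{alpha}, inhibition
#' gated (gain \code{B}) by the distance to the floor \code{-omega}:
#' \deqn{\tau \dot x = -A x + (\alpha - x) I_{exc} - B(\omega + x) I_{inh}}
#' The \code{slowdown} factor multiplies \code{tau} (it is \code{C} for
#' evidence accumulators, 1 for circuit cells) and rescales time only: the
#' fixed point \code{x* = (alpha I_exc - B omega I_inh) / (A + I_exc + B
#' I_inh)} is unchanged.
#'
#' @param x current activity (vectorized).
#' @param I_exc nonnegative excitatory drive.
#' @param I_inh nonnegative inhibitory drive.
#' @param p a \code{\link{shunting_params}}.
#' @param slowdown time-constant multiplier, default 1.
#' @return \code{dx/dt}.
#' @examples
#' p <- shunting_params()
#' shunting_rhs(0, 1, 0, p)                    # unit drive from rest
#' p$alpha / (p$A + 1)                         # its equilibrium
#' @export
shunting_rhs <- function(x, I_exc, I_inh, p, slowdown = 1) {
  if (any(I_exc < 0) || any(I_inh < 0))
    stop("synaptic drives must be nonnegative")
  (-p$A * x + (p$alpha - x) * I_exc - p$B * (p$omega + x) * I_inh) /
    (slowdown * p$tau)
}

#' Neighboring position ahead of / behind a cell
#'
#' "Ahead" is one step in the cell's preferred direction (\code{i + 1} for a
#' rightward cell, \code{i - 1} for leftward); "behind" is the mirror.
#' Off-grid neighbors are \code{NA}: such taps contribute zero drive.
#'
#' @param i position index.
#' @param d direction, \code{"l"} or \code{"r"}.
#' @param n number of positions.
#' @return integer position or \code{NA_integer_} when off-grid.
#' @export
neighbor_ahead <- function(i, d, n) {
  d <- match.arg(d, DIRECTIONS)
  stopifnot(i >= 1, i <= n)
  j <- if (d == "r") i + 1L else i - 1L
  if (j < 1L || j > n) NA_integer_ else as.integer(j)
}

#' @rdname neighbor_ahead
#' @export
neighbor_behind <- function(i, d, n) {
  d <- match.arg(d, DIRECTIONS)
  stopifnot(i >= 1, i <= n)
  k <- if (d == "r") i - 1L else i + 1L
  if (k < 1L || k > n) NA_integer_ else as.integer(k)
}

opposite_direction <- function(d) c(l = "r", r = "l")[[d]]

#' Flat state index of a cell
#'
#' @param layer one of \code{"inh"}, \code{"dir"}, \code{"srf"}, \code{"on"},
#'   \code{"off"}.
#' @param i position index.
#' @param d direction, \code{"l"} or \code{"r"}.
#' @param n number of positions.
#' @return index into the flat state vector of length \code{10 * n}.
#' @export
cell_index <- function(layer, i, d, n) {
  layer <- match.arg(layer, LAYERS)
  d <- match.arg(d, DIRECTIONS)
  stopifnot(i >= 1, i <= n)
  li <- match(layer, LAYERS)
  di <- match(d, DIRECTIONS)
  as.integer(di + 2L * (i - 1L) + 2L * n * (li - 1L))
}

#' An all-quiescent network state
#'
#' @param n number of positions.
#' @return named list of five 2 x n activity matrices (rows \code{"l"},
#'   \code{"r"}), one per layer, all zero.
#' @export
blank_state <- function(n) {
  m <- matrix(0, 2L, n, dimnames = list(DIRECTIONS, NULL))
  stats::setNames(lapply(LAYERS, function(.) m), LAYERS)
}

state_to_vector <- function(state) {
  unlist(lapply(state, as.vector), use.names = FALSE)
}

vector_to_state <- function(y, n) {
  out <- blank_state(n)
  for (li in seq_along(LAYERS))
    out[[li]][] <- y[(li - 1L) * 2L * n + seq_len(2L * n)]
  out
}

## Per-cell right-hand sides ------------------------------------------------

tap <- function(mat, i, d) {
  if (is.na(i)) 0 else rectify(mat[d, i])
}

#' Single-cell layer dynamics
#'
#' Right-hand sides of the five circuit layers at one cell, written directly
#' from each layer's connectivity. These scalar forms mirror the vectorized
#' network derivative used by \code{\link{simulate_circuit}} and exist for
#' inspection and testing; off-grid taps contribute zero.
#'
#' \itemize{
#'   \item interneuron / directional cell: excited by the undirectional
#'     drive at the own position, inhibited by the rectified interneuron one
#'     position ahead tuned to the opposite direction (nulling inhibition).
#'     A directional cell receives exactly the same taps as its interneuron.
#'   \item short-range filter (SRF): excited by
#'     \code{10 * [dir at own position]^+ * [dir one position behind]^+};
#'     the product vetoes isolated directional transients.
#'   \item onset cell: excited by the SRF one position ahead (same
#'     direction), inhibited by the SRF at its own position - motion that
#'     has already passed through nulls the onset signal.
#'   \item offset cell: excited by the SRF one position behind, inhibited by
#'     the SRF at its own position - continuing motion nulls the offset
#'     signal.
#' }
#'
#' @param state a state list from \code{\link{blank_state}}.
#' @param i position index.
#' @param d direction, \code{"l"} or \code{"r"}.
#' @param drive undirectional input at position \code{i}.
#' @param p a \code{\link{shunting_params}}.
#' @param onset_inh direction of the onset cell's own-position inhibitory SRF
#'   tap: \code{"same"} (default; produces null-sequence cancellation) or
#'   \code{"opposite"}.
#' @return the time derivative of the addressed cell.
#' @export
interneuron_rhs <- function(state, i, d, drive, p) {
  n <- ncol(state$inh)
  j <- neighbor_ahead(i, d, n)
  unname(shunting_rhs(state$inh[d, i], drive,
                      tap(state$inh, j, opposite_direction(d)), p))
}

#' @rdname interneuron_rhs
#' @export
directional_rhs <- function(state, i, d, drive, p) {
  n <- ncol(state$dir)
  j <- neighbor_ahead(i, d, n)
  unname(shunting_rhs(state$dir[d, i], drive,
                      tap(state$inh, j, opposite_direction(d)), p))
}

#' @rdname interneuron_rhs
#' @export
srf_rhs <- function(state, i, d, p) {
  n <- ncol(state$srf)
  k <- neighbor_behind(i, d, n)
  exc <- 10 * rectify(state$dir[d, i]) * tap(state$dir, k, d)
  unname(shunting_rhs(state$srf[d, i], exc, 0, p))
}

#' @rdname interneuron_rhs
#' @export
onset_rhs <- function(state, i, d, p, onset_inh = c("same", "opposite")) {
  onset_inh <- match.arg(onset_inh)
  n <- ncol(state$on)
  j <- neighbor_ahead(i, d, n)
  d_inh <- if (onset_inh == "same") d else opposite_direction(d)
  unname(shunting_rhs(state$on[d, i], tap(state$srf, j, d),
                      rectify(state$srf[d_inh, i]), p))
}

#' @rdname interneuron_rhs
#' @export
offset_rhs <- function(state, i, d, p) {
  n <- ncol(state$off)
  k <- neighbor_behind(i, d, n)
  unname(shunting_rhs(state$off[d, i], tap(state$srf, k, d),
                      rectify(state$srf[d, i]), p))
}

## Vectorized network derivative --------------------------------------------

# Core derivative of the 10n network states (+ optional accumulators),
# written as one shunting expression over the flat state with precomputed
# gather indices (pp comes from build_rhs_parms; pad index holds a 0 so
# off-grid taps contribute nothing). drive: length-n undirectional input.
network_deriv <- function(y, drive, pp) {
  nx <- pp$nx
  net <- y[seq_len(nx)]
  q <- c(net, 0)                 # rectified activities + off-grid pad
  q[q < 0] <- 0

  E <- numeric(nx)
  H <- numeric(nx)
  drive2 <- drive[pp$pos_of_cell]            # per-(position,direction) drive
  E[pp$i_inh] <- drive2
  E[pp$i_dir] <- drive2
  H[pp$i_inh] <- q[pp$idx_null]              # nulling interneuron ahead
  H[pp$i_dir] <- q[pp$idx_null]
  E[pp$i_srf] <- 10 * q[pp$idx_dir_own] * q[pp$idx_dir_behind]
  E[pp$i_on] <- q[pp$idx_srf_ahead]
  H[pp$i_on] <- q[pp$idx_on_inh]
  E[pp$i_off] <- q[pp$idx_srf_behind]
  H[pp$i_off] <- q[pp$idx_srf_own]

  dy <- (-pp$A * net + (pp$alpha - net) * E - pp$B * (pp$omega + net) * H) /
    pp$tau

  if (length(pp$acc)) {
    yacc <- y[nx + seq_along(pp$acc)]
    dacc <- numeric(length(pp$acc))
    for (k in seq_along(pp$acc)) {
      a <- pp$acc[[k]]
      dacc[k] <- (-pp$A * yacc[k] +
                    (pp$alpha - yacc[k]) * sum(q[a$exc_idx]) -
                    pp$B * (pp$omega + yacc[k]) * sum(q[a$inh_idx])) /
        (pp$C * pp$tau)
    }
    dy <- c(dy, dacc)
  }
  dy
}

build_rhs_parms <- function(spec, p, accumulators, onset_inh) {
  n <- spec$n_positions
  nx <- 10L * n
  pad <- nx + 1L
  onset_same <- identical(onset_inh, "same")

  # per-cell source indices in (direction fastest, then position) order
  gather <- function(layer, pos_fun, dir_fun) {
    out <- integer(2L * n)
    for (i in seq_len(n)) for (di in 1:2) {
      d <- DIRECTIONS[di]
      ps <- pos_fun(i, d)
      out[di + 2L * (i - 1L)] <-
        if (is.na(ps)) pad else cell_index(layer, ps, dir_fun(d), n)
    }
    out
  }
  own <- function(i, d) i
  ahead <- function(i, d) neighbor_ahead(i, d, n)
  behind <- function(i, d) neighbor_behind(i, d, n)
  same <- identity

  acc <- lapply(accumulators, function(a) {
    list(
      exc_idx = mapply(cell_index, a$exc$layer, a$exc$position,
                       a$exc$direction, MoreArgs = list(n = n)),
      inh_idx = if (nrow(a$inh))
        mapply(cell_index, a$inh$layer, a$inh$position, a$inh$direction,
               MoreArgs = list(n = n))
      else integer()
    )
  })

  list(
    n = n, nx = nx, A = p$A, B = p$B, alpha = p$alpha, omega = p$omega,
    tau = p$tau, C = p$C, onset_same = onset_same, acc = acc,
    pos_of_cell = rep(seq_len(n), each = 2L),
    i_inh = seq_len(2L * n),
    i_dir = 2L * n + seq_len(2L * n),
    i_srf = 4L * n + seq_len(2L * n),
    i_on = 6L * n + seq_len(2L * n),
    i_off = 8L * n + seq_len(2L * n),
    idx_null = gather("inh", ahead, opposite_direction),
    idx_dir_own = gather("dir", own, same),
    idx_dir_behind = gather("dir", behind, same),
    idx_srf_ahead = gather("srf", ahead, same),
    idx_srf_behind = gather("srf", behind, same),
    idx_srf_own = gather("srf", own, same),
    idx_on_inh = if (onset_same) gather("srf", own, same)
                 else gather("srf", own, opposite_direction)
  )
}

#' Full network right-hand side
#'
#' Assembles the derivatives of all circuit cells (and any co-integrated
#' evidence accumulators) at time \code{t}, evaluating the undirectional
#' drive from the stimulus and LGN front end. Deterministic in
#' \code{(t, y)}; usable directly with \pkg{deSolve}.
#'
#' @param t time.
#' @param y flat state vector of length \code{10 * n_positions} (plus one
#'   entry per accumulator, if any).
#' @param spec a \code{\link{stimulus_spec}}.
#' @param lgn an \code{\link{lgn_params}}.
#' @param p a \code{\link{shunting_params}}.
#' @param accumulators list of \code{\link{accumulator_spec}} objects to
#'   co-integrate; default none.
#' @param onset_inh onset-cell inhibitory tap direction, see
#'   \code{\link{onset_rhs}}.
#' @return derivative vector of the same length as \code{y}.
#' @export
full_rhs <- function(t, y, spec, lgn, p, accumulators = list(),
                     onset_inh = c("same", "opposite")) {
  onset_inh <- match.arg(onset_inh)
  pp <- build_rhs_parms(spec, p, accumulators, onset_inh)
  if (length(y) != 10L * pp$n + length(pp$acc))
    stop(sprintf("state vector has length %d, expected %d",
                 length(y), 10L * pp$n + length(pp$acc)))
  J <- lgn_gain(lgn, spec$v_model * spec$w)
  drive <- vapply(seq_len(pp$n),
                  function(i) J * contrast_indicator(spec, i, t),
                  numeric(1L))
  network_deriv(y, drive, pp)
}

#' Cell counts of the standard network
#'
#' One undirectional input cell per position plus five ODE layers with one
#' cell per (position, direction): \code{11 * n_positions} cells in total
#' (77 for the standard 7-position network).
#'
#' @param spec a \code{\link{stimulus_spec}} (only \code{n_positions} is
#'   used).
#' @return named integer vector of per-layer counts; its sum is the network
#'   size.
#' @export
network_cell_count <- function(spec = stimulus_spec()) {
  n <- spec$n_positions
  c(undirectional = n,
    inh = 2L * n, dir = 2L * n, srf = 2L * n, on = 2L * n, off = 2L * n)
}

## Simulation ----------------------------------------------------------------

#' Simulate the circuit response to a moving contrast patch
#'
#' Integrates the network (and, by default, the evidence accumulators) from
#' an all-zero initial state with an adaptive solver. The undirectional
#' drive is piecewise constant - the patch jumps position every
#' \code{1 / v_model} time units - so the integration is restarted at every
#' switch instant and the solver never steps across a drive discontinuity;
#' within each segment the right-hand side is smooth. The default solver is
#' \code{"lsoda"}, which interpolates dense output between its internal
#' steps; \code{"ode45"} (Dormand-Prince 4(5)) is available and agrees to
#' well within the integration tolerances, at the cost of stepping to every
#' output time.
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @param lgn an \code{\link{lgn_params}}.
#' @param p a \code{\link{shunting_params}}.
#' @param t_end simulation horizon; default
#'   \code{n_occupied(spec) / v_model + C * tau / A}, long enough for the
#'   slow accumulators (time constant \code{C * tau / A}) to peak.
#' @param dense_dt output sampling step; default \code{0.01 * tau}.
#' @param accumulators list of \code{\link{accumulator_spec}} objects to
#'   co-integrate; default \code{\link{default_accumulators}(spec)}. Use
#'   \code{list()} for the bare network.
#' @param onset_inh onset-cell inhibitory tap direction, see
#'   \code{\link{onset_rhs}}.
#' @param rtol,atol integrator relative/absolute tolerances.
#' @param method \code{"lsoda"} (default) or \code{"ode45"}.
#' @return A \code{"bl_trajectory"}: list with \code{times}, matrix
#'   \code{net} (one column per cell, named \code{layer_position_direction}),
#'   matrix \code{acc} (one column per accumulator), matrix \code{drive}
#'   (undirectional input per position), and the inputs that produced it.
#' @examples
#' \donttest{
#' traj <- simulate_circuit(stimulus_spec(), lgn_params(), shunting_params(),
#'                          t_end = 10, dense_dt = 0.05)
#' max(traj$net[, "on_2_r"])
#' }
#' @export
simulate_circuit <- function(spec, lgn, p,
                             t_end = NULL,
                             dense_dt = 0.01 * p$tau,
                             accumulators = default_accumulators(spec),
                             onset_inh = c("same", "opposite"),
                             rtol = 1e-8, atol = 1e-10,
                             method = c("lsoda", "ode45")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "stimulus_spec"), inherits(lgn, "lgn_params"),
            inherits(p, "shunting_params"))
  onset_inh <- match.arg(onset_inh)
  if (is.null(t_end))
    t_end <- n_occupied(spec) / spec$v_model + p$C * p$tau / p$A
  if (t_end <= 0) stop("'t_end' must be positive")

  pp <- build_rhs_parms(spec, p, accumulators, onset_inh)
  n <- pp$n
  nstate <- 10L * n + length(pp$acc)
  J <- lgn_gain(lgn, spec$v_model * spec$w)

  # drive switch instants: the patch advances at m / v, vanishing after the
  # last occupied position
  switches <- seq_len(n_occupied(spec)) / spec$v_model
  switches <- switches[switches < t_end]
  breaks <- c(0, switches, t_end)

  grid <- seq(0, t_end, by = dense_dt)
  times <- sort(unique(c(grid, breaks)))
  # collapse output times closer than integrator resolution
  times <- times[c(TRUE, diff(times) > 1e-12)]
  if (times[length(times)] < t_end) times <- c(times, t_end)

  # evaluate at the segment midpoint: segment interiors lie strictly inside
  # one occupancy interval, so this is immune to floating-point roundoff of
  # floor(t * v) at the switch instants themselves
  drive_in_segment <- function(t0, t1) {
    tm <- (t0 + t1) / 2
    vapply(seq_len(n), function(i) J * contrast_indicator(spec, i, tm),
           numeric(1L))
  }

  rhs_const <- function(t, y, parms) {
    list(network_deriv(y, parms$drive, pp))
  }

  y0 <- numeric(nstate)
  rows <- vector("list", length(breaks) - 1L)
  for (s in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1L]
    tseg <- times[times >= t0 - 1e-12 & times <= t1 + 1e-12]
    tseg[1] <- t0; tseg[length(tseg)] <- t1
    if (length(tseg) < 2L) tseg <- c(t0, t1)
    sol <- deSolve::ode(y = y0, times = tseg, func = rhs_const,
                        parms = list(drive = drive_in_segment(t0, t1)),
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("integration failed in segment starting at t = %g", t0))
    sol <- unclass(sol)
    y0 <- sol[nrow(sol), -1L]
    rows[[s]] <- if (s == 1L) sol else sol[-1L, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  tout <- out[, 1L]
  net <- out[, 1L + seq_len(10L * n), drop = FALSE]
  suffix <- as.vector(outer(DIRECTIONS, seq_len(n),
                            function(d, i) paste0("_", i, "_", d)))
  colnames(net) <- paste0(rep(LAYERS, each = 2L * n), rep(suffix, 5L))
  acc <- NULL
  if (length(pp$acc)) {
    acc <- out[, 1L + 10L * n + seq_along(pp$acc), drop = FALSE]
    colnames(acc) <- vapply(accumulators, `[[`, character(1L), "label")
  }
  drive <- vapply(seq_len(n), function(i) J * contrast_indicator(spec, i, tout),
                  numeric(length(tout)))
  colnames(drive) <- paste0("I_", seq_len(n))

  structure(list(times = tout, net = net, acc = acc, drive = drive,
                 spec = spec, lgn = lgn, params = p,
                 accumulators = accumulators,
                 settings = list(t_end = t_end, dense_dt = dense_dt,
                                 onset_inh = onset_inh, method = method,
                                 rtol = rtol, atol = atol, J = J)),
            class = "bl_trajectory")
}

#' @export
print.bl_trajectory <- function(x, ...) {
  cat(sprintf(
    "Circuit trajectory: %d positions, %d samples over t = [0, %g]\n",
    x$spec$n_positions, length(x$times), max(x$times)))
  cat(sprintf("  v_model = %g (%g deg/s), drive amplitude J = %.4g\n",
              x$spec$v_model, x$spec$v_model * x$spec$w, x$settings$J))
  if (!is.null(x$acc))
    cat("  accumulators:", paste(colnames(x$acc), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x a \code{"bl_trajectory"}.
#' @param row.names,optional unused, for S3 compatibility.
#' @param ... unused.
#' @return data frame with columns \code{t}, \code{layer}, \code{position},
#'   \code{direction}, \code{activity}.
#' @export
as.data.frame.bl_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  cn <- colnames(x$net)
  parts <- strsplit(cn, "_", fixed = TRUE)
  data.frame(
    t = rep(x$times, times = length(cn)),
    layer = rep(vapply(parts, `[[`, character(1L), 1L),
                each = length(x$times)),
    position = rep(as.integer(vapply(parts, `[[`, character(1L), 2L)),
                   each = length(x$times)),
    direction = rep(vapply(parts, `[[`, character(1L), 3L),
                    each = length(x$times)),
    activity = as.vector(x$net)
  )
}
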