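#' Moving contrast indicator
#'
#' Whether the moving patch occupies position \code{i} at time \code{t}.
#' The patch appears at \code{start_pos} at \code{t = 0} and advances one
#' position every \code{1 / v_model} time units, so occupancy intervals are
#' half-open: the value at an exact switch instant belongs to the later
#' interval. Positions outside the \code{start_pos..end_pos} span are always
#' 0, and the indicator is 0 everywhere for
#' \code{t >= n_occupied(spec) / v_model}.
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @param i position index (scalar, 1..n_positions).
#' @param t time, >= 0 (vectorized).
#' @return 0/1 vector the length of \code{t}.
#' @examples
#' spec <- stimulus_spec()
#' contrast_indicator(spec, 2, 0.5)   # patch still at its start position
#' contrast_indicator(spec, 6, c(4.5, 5))
#' @export
contrast_indicator <- function(spec, i, t) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (length(i) != 1L || !is.numeric(i) || i != as.integer(i))
    stop("'i' must be a single integer position index")
  i <- as.integer(i)
  if (i < 1L || i > spec$n_positions)
    stop(sprintf("position index %d outside 1..%d", i, spec$n_positions))
  if (any(t < 0)) stop("'t' must be nonnegative")
  lo <- min(spec$start_pos, spec$end_pos)
  hi <- max(spec$start_pos, spec$end_pos)
  if (i < lo || i > hi) return(rep(0, length(t)))
  step <- if (spec$end_pos >= spec$start_pos) 1L else -1L
  as.numeric(floor(t * spec$v_model) == (i - spec$start_pos) * step)
}

#' Effective high-pass time constant of the LGN front end
#'
#' Contrast shortens the high-pass time constant:
#' \code{tau_S = T_0 / (1 + (contrast / C_half)^2)}.
#'
#' @param p an \code{\link{lgn_params}}.
#' @return time constant in seconds, in \code{(0, T_0]}.
#' @export
tau_s_effective <- function(p) {
  stopifnot(inherits(p, "lgn_params"))
  p$T_0 / (1 + (p$contrast / p$C_half)^2)
}

#' Temporal frequency of a drifting Gabor patch
#'
#' A patch with spatial frequency \code{f_S} cycles/degree drifting at
#' \code{v_physical} deg/s modulates at \code{2 * pi * f_S * v_physical}
#' radians per second.
#'
#' @param p an \code{\link{lgn_params}}.
#' @param v_physical stimulus speed, degrees/second, >= 0 (vectorized).
#' @return temporal frequency in radians/second.
#' @export
temporal_frequency <- function(p, v_physical) {
  stopifnot(inherits(p, "lgn_params"))
  if (any(v_physical < 0)) stop("'v_physical' must be nonnegative")
  2 * pi * p$f_S * v_physical
}

#' Speed-dependent LGN gain
#'
#' Amplitude of the magnocellular-LGN response to the drifting patch: the
#' modulus of a high-pass stage (strength \code{H_S}, time constant
#' \code{tau_S}) cascaded with \code{N_L} low-pass stages (time constant
#' \code{tau_L}), evaluated at the patch's temporal frequency and scaled by
#' \code{F_gain}:
#' \deqn{J_v = F \sqrt{\left(1 - \frac{2H_S - H_S^2}{1 + (\omega\tau_S)^2}
#'   \right) \left(1 + (\omega\tau_L)^2\right)^{-N_L}}}
#' With the default parameters the gain rises from 0 at rest, peaks at 1
#' near 6.8 deg/s, and falls back to 0 at high speed.
#'
#' @param p an \code{\link{lgn_params}}.
#' @param v_physical stimulus speed, degrees/second, >= 0 (vectorized).
#' @return nonnegative gain values.
#' Contrast enters the response only through \code{tau_S} (the front end is
#' strongly contrast-gain-controlled), except that a zero-contrast patch is
#' no stimulus at all and yields zero gain.
#'
#' @examples
#' lgn_gain(lgn_params(), c(0.1, 1, 6.8, 100))
#' @export
lgn_gain <- function(p, v_physical) {
  stopifnot(inherits(p, "lgn_params"))
  if (p$contrast == 0) return(rep(0, length(v_physical)))
  om <- temporal_frequency(p, v_physical)
  tau_S <- tau_s_effective(p)
  hp <- 1 - (2 * p$H_S - p$H_S^2) / (1 + (om * tau_S)^2)
  if (any(hp < 0))
    stop("negative radicand in LGN gain (requires H_S <= 1)")
  lp <- (1 + (om * p$tau_L)^2)^(-p$N_L)
  p$F_gain * sqrt(hp * lp)
}

#' Locate the peak of the LGN gain curve
#'
#' Maximizes \code{\link{lgn_gain}} over speed: a 400-point log-spaced grid
#' over \code{[1e-2, 1e3]} deg/s picks the bracketing interval, then
#' golden-section refinement in log-speed localizes the optimum to 1e-8
#' relative tolerance.
#'
#' @param p an \code{\link{lgn_params}}.
#' @return list with \code{v_peak} (deg/s) and \code{J_max}.
#' @examples
#' peak_lgn_gain(lgn_params())$J_max   # ~1 by construction of F_gain
#' @export
peak_lgn_gain <- function(p) {
  stopifnot(inherits(p, "lgn_params"))
  lv <- seq(log(1e-2), log(1e3), length.out = 400L)
  J <- lgn_gain(p, exp(lv))
  k <- which.max(J)
  lo <- lv[max(1L, k - 1L)]
  hi <- lv[min(length(lv), k + 1L)]
  opt <- stats::optimize(function(x) lgn_gain(p, exp(x)),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  list(v_peak = exp(opt$maximum), J_max = opt$objective)
}

#' Undirectional input drive
#'
#' The drive delivered to the undirectional cell at position \code{i} and
#' time \code{t}: the LGN gain at the stimulus's physical speed
#' (\code{v_model * w} deg/s) wherever the contrast indicator is 1, and 0
#' elsewhere. Constant within each occupancy interval.
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @param p an \code{\link{lgn_params}}.
#' @param i position index (scalar).
#' @param t time, >= 0 (vectorized).
#' @return drive values the length of \code{t}.
#' @export
input_drive <- function(spec, p, i, t) {
  J <- lgn_gain(p, spec$v_model * spec$w)
  J * contrast_indicator(spec, i, t)
}

#' Tabulate the LGN gain over a speed grid
#'
#' @param p an \code{\link{lgn_params}}.
#' @param speeds physical speeds in deg/s; default 200 log-spaced points over
#'   \code{[1e-2, 1e3]}.
#' @return data frame with columns \code{v_physical} and \code{J}.
#' @export
lgn_curve <- function(p, speeds = NULL) {
  if (is.null(speeds))
    speeds <- exp(seq(log(1e-2), log(1e3), length.out = 200L))
  if (any(speeds < 0)) stop("'speeds' must be nonnegative")
  data.frame(v_physical = speeds, J = lgn_gain(p, speeds))
}
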