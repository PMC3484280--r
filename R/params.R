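#' Shunting-equation circuit parameters
#'
#' Constants of the shunting membrane equation shared by all circuit layers:
#' passive decay \code{A}, inhibitory gain \code{B}, time constant \code{tau},
#' excitatory ceiling \code{alpha}, hyperpolarization floor magnitude
#' \code{omega} (activities live in \code{[-omega, alpha]}), and the
#' accumulator slowdown factor \code{C} that stretches the time constant of
#' the evidence-accumulator populations to \code{C * tau}.
#'
#' Defaults are the values used for every simulation reported by the package:
#' \code{A} < 1 so an input produces a substantial rate increase, \code{B} > 1
#' so nulling inhibition can veto excitation, and \code{C = 10} so accumulators
#' integrate over a horizon an order of magnitude longer than circuit cells.
#'
#' @param A passive decay rate (relative to \code{tau}); default 0.1.
#' @param B inhibitory gain; default 10.
#' @param tau time constant, simulation-time units; default 1.
#' @param alpha maximum (depolarized) activity; default 1.
#' @param omega magnitude of the hyperpolarization floor \code{-omega};
#'   default 0.3.
#' @param C slowdown factor for evidence accumulators; default 10.
#' @return An object of class \code{"shunting_params"}.
#' @examples
#' p <- shunting_params()
#' p$B / p$A
#' @export
shunting_params <- function(A = 0.1, B = 10, tau = 1, alpha = 1,
                            omega = 0.3, C = 10) {
  for (nm in c("A", "B", "tau", "alpha", "omega", "C")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  structure(list(A = A, B = B, tau = tau, alpha = alpha,
                 omega = omega, C = C),
            class = "shunting_params")
}

#' @export
print.shunting_params <- function(x, ...) {
  cat("Shunting circuit parameters:\n")
  cat(sprintf("  A = %g, B = %g, tau = %g, alpha = %g, omega = %g, C = %g\n",
              x$A, x$B, x$tau, x$alpha, x$omega, x$C))
  invisible(x)
}

#' Magnocellular-LGN front-end parameters
#'
#' Constants of the temporal-frequency response of magnocellular LGN cells
#' (Benardete-Kaplan form) used to convert stimulus speed into an
#' undirectional drive amplitude: a high-pass stage with strength \code{H_S}
#' and contrast-dependent time constant
#' \code{tau_S = T_0 / (1 + (contrast / C_half)^2)}, followed by a cascade of
#' \code{N_L} low-pass stages with per-stage time constant \code{tau_L}. The
#' stimulus is a Gabor patch of spatial frequency \code{f_S}, so a speed
#' \code{v} (deg/s) maps to temporal frequency \code{2 * pi * f_S * v} rad/s.
#'
#' The default \code{T_0 = 4.496e-2} s is the value consistent with the
#' normalizer \code{F_gain = 2.206}: with it the gain curve peaks at 1.000
#' near 6.8 deg/s (about 15 Hz), in the temporal-frequency range where
#' magnocellular cells respond most strongly.
#'
#' @param F_gain multiplicative normalizer; default 2.206, chosen so the peak
#'   gain over speed equals 1.
#' @param H_S high-pass (surround) strength, in \code{[0, 1]}; default 1.
#' @param tau_L per-stage low-pass time constant, seconds; default 1.68e-3.
#' @param N_L number of low-pass stages (may be fractional); default 25.50.
#' @param T_0 zero-contrast high-pass time constant, seconds; default 4.496e-2.
#' @param C_half semisaturation contrast of the high-pass time constant;
#'   default 0.048.
#' @param f_S stimulus spatial frequency, cycles per degree; default 2.181.
#' @param contrast stimulus contrast (dimensionless); default 0.1.
#' @return An object of class \code{"lgn_params"}.
#' @examples
#' lgn <- lgn_params()
#' tau_s_effective(lgn)
#' @export
lgn_params <- function(F_gain = 2.206, H_S = 1.00, tau_L = 1.68e-3,
                       N_L = 25.50, T_0 = 4.496e-2, C_half = 0.048,
                       f_S = 2.181, contrast = 0.1) {
  for (nm in c("F_gain", "tau_L", "N_L", "T_0", "C_half", "f_S")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  if (!is.numeric(H_S) || length(H_S) != 1L || H_S < 0 || H_S > 1)
    stop("'H_S' must lie in [0, 1]")
  if (!is.numeric(contrast) || length(contrast) != 1L || contrast < 0)
    stop("'contrast' must be nonnegative")
  structure(list(F_gain = F_gain, H_S = H_S, tau_L = tau_L, N_L = N_L,
                 T_0 = T_0, C_half = C_half, f_S = f_S, contrast = contrast),
            class = "lgn_params")
}

#' @export
print.lgn_params <- function(x, ...) {
  cat("LGN front-end parameters:\n")
  cat(sprintf("  F_gain = %g, H_S = %g, tau_L = %g s, N_L = %g\n",
              x$F_gain, x$H_S, x$tau_L, x$N_L))
  cat(sprintf("  T_0 = %g s, C_half = %g, f_S = %g cyc/deg, contrast = %g\n",
              x$T_0, x$C_half, x$f_S, x$contrast))
  cat(sprintf("  (effective tau_S = %g s)\n", tau_s_effective(x)))
  invisible(x)
}

#' Moving-contrast stimulus specification
#'
#' A single patch of contrast that appears at \code{start_pos}, moves at
#' constant model speed \code{v_model} (positions per simulation-time unit)
#' one position at a time towards \code{end_pos}, and vanishes after leaving
#' \code{end_pos}. Positions outside the \code{start_pos..end_pos} span never
#' receive input. \code{start_pos > end_pos} gives leftward motion. The
#' constant \code{w} converts model speed to physical speed:
#' \code{v_physical = v_model * w} deg/s.
#'
#' @param v_model stimulus speed in positions per simulation-time unit;
#'   default 1.
#' @param n_positions number of spatial positions in the network; default 7.
#' @param start_pos position at which the patch appears; default 2.
#' @param end_pos last position the patch occupies; default 6.
#' @param w physical degrees/second per unit model speed; default 10.
#' @return An object of class \code{"stimulus_spec"}.
#' @examples
#' spec <- stimulus_spec(v_model = 0.5)
#' stimulus_direction(spec)
#' @export
stimulus_spec <- function(v_model = 1, n_positions = 7, start_pos = 2,
                          end_pos = 6, w = 10) {
  if (!is.numeric(v_model) || length(v_model) != 1L || v_model <= 0)
    stop("'v_model' must be a single positive number")
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("'w' must be a single positive number")
  n_positions <- as.integer(n_positions)
  start_pos <- as.integer(start_pos)
  end_pos <- as.integer(end_pos)
  if (n_positions < 2L) stop("'n_positions' must be at least 2")
  if (start_pos < 1L || start_pos > n_positions ||
      end_pos < 1L || end_pos > n_positions)
    stop("'start_pos' and 'end_pos' must lie in 1..n_positions")
  structure(list(v_model = v_model, n_positions = n_positions,
                 start_pos = start_pos, end_pos = end_pos, w = w),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "Stimulus: %s motion, positions %d -> %d of %d, v_model = %g (%g deg/s)\n",
    stimulus_direction(x), x$start_pos, x$end_pos, x$n_positions,
    x$v_model, x$v_model * x$w))
  invisible(x)
}

#' Direction of motion implied by a stimulus specification
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @return \code{"r"} for rightward (increasing position), \code{"l"} for
#'   leftward. A stationary patch (\code{start_pos == end_pos}) is reported as
#'   rightward by convention.
#' @export
stimulus_direction <- function(spec) {
  if (spec$end_pos >= spec$start_pos) "r" else "l"
}

#' Number of positions the moving patch visits
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @return integer count \code{abs(end_pos - start_pos) + 1}; the input
#'   vanishes from every position at \code{t = n_occupied(spec) / v_model}.
#' @export
n_occupied <- function(spec) {
  abs(spec$end_pos - spec$start_pos) + 1L
}

#' Reaction-time transform parameters
#'
#' Constants mapping a selectivity value \code{s} (peak evidence-accumulator
#' activity) to a predicted manual reaction time
#' \code{RT = c_scale / s + r_offset} milliseconds, where \code{c_scale}
#' converts selectivity into a decision time and \code{r_offset} is a
#' speed-independent motor component. \code{w} converts between model speed
#' and physical speed as in \code{\link{stimulus_spec}}.
#'
#' @param c_scale decision-time scale, ms; default 100.
#' @param r_offset motor offset, ms; default 175.
#' @param w degrees/second per unit model speed; default 10.
#' @return An object of class \code{"rt_params"}.
#' @export
rt_params <- function(c_scale = 100, r_offset = 175, w = 10) {
  for (nm in c("c_scale", "r_offset", "w")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  structure(list(c_scale = c_scale, r_offset = r_offset, w = w),
            class = "rt_params")
}

#' Empirical power-law reaction-time fit
#'
#' The form \code{RT(v) = c_fit * v^(-beta) + r_fit} used by simple
#' reaction-time studies of motion onset and offset, provided for overlaying
#' on model reaction-time curves. The exponent \code{beta} is typically
#' between 0.5 and 1.
#'
#' @param c_fit scale, ms (at v = 1 deg/s the speed-dependent part equals
#'   \code{c_fit}).
#' @param beta power-law exponent, > 0.
#' @param r_fit additive speed-independent offset, ms.
#' @return An object of class \code{"empirical_fit"}.
#' @export
empirical_fit <- function(c_fit, beta, r_fit) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a single positive number")
  if (!is.numeric(c_fit) || length(c_fit) != 1L || !is.finite(c_fit))
    stop("'c_fit' must be a single finite number")
  if (!is.numeric(r_fit) || length(r_fit) != 1L || !is.finite(r_fit))
    stop("'r_fit' must be a single finite number")
  structure(list(c_fit = c_fit, beta = beta, r_fit = r_fit),
            class = "empirical_fit")
}
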