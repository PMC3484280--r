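#' Model reaction time from selectivity
#'
#' Under a low-noise diffusion account of decision making, mean reaction
#' time is inversely related to the evidence accumulation rate, which the
#' model summarizes by peak accumulator activity (selectivity):
#' \code{RT = c_scale / s + r_offset} ms. Selectivities at or below
#' \code{s_floor} give a missing RT rather than an astronomically large one:
#' at such speeds the directional circuit is silent and other (undirectional)
#' pathways would drive the response.
#'
#' @param s selectivity value(s), >= 0.
#' @param p an \code{\link{rt_params}}.
#' @param s_floor selectivities at or below this are reported as \code{NA};
#'   default 1e-6.
#' @return reaction time(s) in milliseconds.
#' @examples
#' model_reaction_time(c(1, 0.5, 0), rt_params())
#' @export
model_reaction_time <- function(s, p = rt_params(), s_floor = 1e-6) {
  stopifnot(inherits(p, "rt_params"))
  if (any(s < 0, na.rm = TRUE)) stop("selectivity must be nonnegative")
  out <- ifelse(is.na(s) | s <= s_floor, NA_real_,
                p$c_scale / s + p$r_offset)
  as.numeric(out)
}

#' Reaction-time curve from a speed sweep
#'
#' Applies \code{\link{model_reaction_time}} to the onset and offset
#' selectivities of a sweep, giving predicted manual reaction times against
#' physical stimulus speed. Optional \code{\link{empirical_fit}} objects add
#' overlay columns with the power-law form fitted to human data.
#'
#' @param sweep a data frame from \code{\link{speed_sweep}} (columns
#'   \code{v_physical}, \code{s_on}, \code{s_off}).
#' @param p an \code{\link{rt_params}}.
#' @param overlays named list of \code{\link{empirical_fit}} objects; each
#'   adds a column \code{rt_<name>_ms}.
#' @return data frame with columns \code{v_physical_deg_per_s},
#'   \code{rt_on_ms}, \code{rt_off_ms}, plus any overlays.
#' @export
rt_curve <- function(sweep, p = rt_params(), overlays = list()) {
  stopifnot(is.data.frame(sweep),
            all(c("v_physical", "s_on", "s_off") %in% names(sweep)))
  out <- data.frame(
    v_physical_deg_per_s = sweep$v_physical,
    rt_on_ms = model_reaction_time(sweep$s_on, p),
    rt_off_ms = model_reaction_time(sweep$s_off, p)
  )
  for (nm in names(overlays)) {
    fit <- overlays[[nm]]
    out[[paste0("rt_", nm, "_ms")]] <-
      ifelse(out$v_physical_deg_per_s > 0,
             empirical_rt(pmax(out$v_physical_deg_per_s, .Machine$double.eps),
                          fit),
             NA_real_)
  }
  out
}

#' Empirical power-law reaction time
#'
#' The form \code{RT(v) = c_fit * v^(-beta) + r_fit} reported by simple
#' reaction-time studies of motion onset/offset; strictly decreasing in
#' speed.
#'
#' @param v physical speed(s), deg/s, > 0.
#' @param fit an \code{\link{empirical_fit}}.
#' @return reaction time(s) in milliseconds.
#' @export
empirical_rt <- function(v, fit) {
  stopifnot(inherits(fit, "empirical_fit"))
  if (any(v <= 0)) stop("'v' must be positive")
  fit$c_fit * v^(-fit$beta) + fit$r_fit
}
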