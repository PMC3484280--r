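# Shared fixtures: everything is generated in code at test time.

default_p <- shunting_params()
default_lgn <- lgn_params()
default_spec <- stimulus_spec()

# Closed-form fixed point of the shunting equation under frozen drives.
shunting_equilibrium <- function(I_exc, I_inh, p = default_p) {
  (p$alpha * I_exc - p$B * p$omega * I_inh) / (p$A + I_exc + p$B * I_inh)
}

# Integrate one shunting cell under frozen drives (independent of the
# network code path).
frozen_cell <- function(I_exc, I_inh, p = default_p, t_end = 100 * p$tau,
                        slowdown = 1) {
  sol <- deSolve::ode(
    y = 0, times = c(0, t_end),
    func = function(t, y, parms)
      list(shunting_rhs(y, I_exc, I_inh, p, slowdown = slowdown)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  unname(unclass(sol)[2L, 2L])
}

# The full default speed sweep is expensive; compute it once per session and
# share it across test files (test-acceptance.R runs first alphabetically).
.sweep_cache <- new.env(parent = emptyenv())
cached_default_sweep <- function() {
  if (is.null(.sweep_cache$sweep))
    .sweep_cache$sweep <- speed_sweep(default_speed_grid())
  .sweep_cache$sweep
}

# Locate a 0/1 transition of the contrast indicator by bisection.
indicator_transition <- function(spec, i, t_lo, t_hi, iter = 60L) {
  v_lo <- contrast_indicator(spec, i, t_lo)
  for (k in seq_len(iter)) {
    tm <- (t_lo + t_hi) / 2
    if (contrast_indicator(spec, i, tm) == v_lo) t_lo <- tm else t_hi <- tm
  }
  (t_lo + t_hi) / 2
}

# Measure per-position occupancy windows of the moving patch by scanning the
# indicator on a fine grid and refining edges by bisection.
measure_occupancy <- function(spec, dt = 1e-3) {
  horizon <- 2 * n_occupied(spec) / spec$v_model
  tt <- seq(0, horizon, by = dt)
  out <- lapply(seq_len(spec$n_positions), function(i) {
    on <- contrast_indicator(spec, i, tt)
    if (!any(on > 0)) return(NULL)
    k1 <- which(on > 0)[1L]
    k2 <- max(which(on > 0))
    t_on <- if (k1 == 1L) tt[1L] else
      indicator_transition(spec, i, tt[k1 - 1L], tt[k1])
    t_off <- indicator_transition(spec, i, tt[k2], tt[k2 + 1L])
    data.frame(position = i, t_on = t_on, t_off = t_off)
  })
  do.call(rbind, out)
}
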