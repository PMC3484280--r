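#' Default configuration
#'
#' Nested list mirroring the YAML config file layout. Every circuit, LGN,
#' stimulus, readout, reaction-time and sweep constant is a named key with
#' its standard value, so a config file only needs the keys it overrides.
#'
#' @return nested named list with sections \code{model}, \code{lgn},
#'   \code{stimulus}, \code{readout}, \code{rt}, \code{sweep},
#'   \code{integrator}.
#' @export
default_config <- function() {
  list(
    model = list(A = 0.1, B = 10, tau = 1, alpha = 1, omega = 0.3, C = 10),
    lgn = list(F_gain = 2.206, H_S = 1.00, tau_L = 1.68e-3, N_L = 25.50,
               T_0 = 4.496e-2, C_half = 0.048, f_S = 2.181, contrast = 0.1),
    stimulus = list(v_model = 1, n_positions = 7L, start_pos = 2L,
                    end_pos = 6L, w = 10),
    readout = list(threshold = 0.1, dense_dt = 0.01, onset_inh = "same"),
    rt = list(c_scale = 100, r_offset = 175),
    sweep = list(n_speeds = 60L, v_lo = 1e-2, v_hi = 1e2,
                 params = c("A", "B", "tau"), multipliers = c(0.1, 1, 10)),
    integrator = list(rtol = 1e-8, atol = 1e-10)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a configuration file
#'
#' Reads a YAML file with any subset of the sections/keys of
#' \code{\link{default_config}} and merges it over the defaults. Unknown
#' keys are an error (typically typos).
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return a complete config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  check <- function(base, override, where) {
    bad <- setdiff(names(override), names(base))
    if (length(bad))
      stop(sprintf("unknown config key%s at %s: %s",
                   if (length(bad) > 1) "s" else "", where,
                   paste(bad, collapse = ", ")))
    for (nm in names(override))
      if (is.list(override[[nm]]) && is.list(base[[nm]]))
        check(base[[nm]], override[[nm]], paste0(where, nm, "."))
  }
  check(cfg, user, "")
  merge_config(cfg, user)
}

#' Write a configuration file
#'
#' The written file round-trips: feeding it back through
#' \code{\link{read_config}} reproduces the same configuration.
#'
#' @param cfg config list.
#' @param path output YAML path.
#' @return invisibly, \code{path}.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build parameter objects from a configuration
#'
#' @param cfg config list from \code{\link{read_config}}.
#' @return list with \code{spec}, \code{lgn}, \code{p}, \code{rtp},
#'   \code{readout}, \code{sweep}, \code{integrator}.
#' @export
config_objects <- function(cfg) {
  list(
    spec = do.call(stimulus_spec, cfg$stimulus),
    lgn = do.call(lgn_params, cfg$lgn),
    p = do.call(shunting_params, cfg$model),
    rtp = rt_params(c_scale = cfg$rt$c_scale, r_offset = cfg$rt$r_offset,
                    w = cfg$stimulus$w),
    readout = cfg$readout,
    sweep = cfg$sweep,
    integrator = cfg$integrator
  )
}
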