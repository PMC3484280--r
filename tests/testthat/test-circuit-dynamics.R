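test_that("shunting dynamics: derivative values and frozen-input equilibria", {
  p <- default_p

  expect_equal(rectify(c(0.5, -0.3, 0)), c(0.5, 0, 0))

  expect_equal(shunting_rhs(0, 0, 0, p), 0)
  expect_equal(shunting_rhs(0, 1, 0, p), 1)             # unit drive from rest
  expect_error(shunting_rhs(0, -0.1, 0, p), "nonnegative")

  # closed-form fixed points vs long frozen-input integration (independent
  # code path through deSolve on a scalar ODE)
  cases <- rbind(c(1, 0), c(0, 1), c(0.7, 0.2), c(2.5, 0.05))
  for (r in seq_len(nrow(cases))) {
    eq <- shunting_equilibrium(cases[r, 1], cases[r, 2], p)
    expect_equal(frozen_cell(cases[r, 1], cases[r, 2], p), eq,
                 tolerance = 1e-4)
  }
  expect_equal(shunting_equilibrium(1, 0, p), 1 / 1.1, tolerance = 1e-12)
  expect_equal(shunting_equilibrium(0, 1, p), -3 / 10.1, tolerance = 1e-12)

  # slowdown rescales time but not the fixed point
  expect_equal(frozen_cell(1, 0, p, t_end = 100 * p$C * p$tau, slowdown = p$C),
               1 / 1.1, tolerance = 1e-4)
})

test_that("ahead/behind neighbors follow the preferred direction and stop at edges", {
  expect_equal(neighbor_ahead(4, "r", 7), 5L)
  expect_equal(neighbor_behind(4, "r", 7), 3L)
  expect_equal(neighbor_ahead(4, "l", 7), 3L)
  expect_equal(neighbor_behind(4, "l", 7), 5L)
  expect_true(is.na(neighbor_ahead(7, "r", 7)))
  expect_true(is.na(neighbor_ahead(1, "l", 7)))
  expect_true(is.na(neighbor_behind(1, "r", 7)))
  expect_true(is.na(neighbor_behind(7, "l", 7)))
})

test_that("layer connectivity produces the expected single-cell derivatives", {
  p <- default_p
  st <- blank_state(7)

  # quiescent network, no input
  expect_equal(interneuron_rhs(st, 4, "r", 0, p), 0)
  expect_equal(onset_rhs(st, 4, "r", p), 0)
  expect_equal(offset_rhs(st, 4, "r", p), 0)

  # nulling inhibition from the opposite-direction interneuron ahead
  expect_equal(interneuron_rhs(st, 4, "r", 1, p), 1)
  st$inh["l", 5] <- 0.5
  expect_equal(interneuron_rhs(st, 4, "r", 1, p), 1 - 10 * 0.3 * 0.5)
  expect_equal(directional_rhs(st, 4, "r", 1, p),
               interneuron_rhs(st, 4, "r", 1, p))

  # SRF product gating
  st2 <- blank_state(7)
  st2$dir["r", 4] <- 0.5
  expect_equal(srf_rhs(st2, 4, "r", p), 0)      # behind factor still zero
  st2$dir["r", 3] <- 0.5
  expect_equal(srf_rhs(st2, 4, "r", p), 10 * 0.25)
  expect_equal(shunting_equilibrium(10, 0, p), 10 / 10.1, tolerance = 1e-12)

  # onset: preferred sequence excites, null sequence is crushed
  st3 <- blank_state(7)
  st3$srf["r", 5] <- 0.8
  expect_equal(onset_rhs(st3, 4, "r", p), 0.8)
  st3$srf["r", 4] <- 0.8
  expect_equal(onset_rhs(st3, 4, "r", p), 0.8 - 10 * 0.3 * 0.8)
  # the "opposite" inhibitory variant ignores same-direction SRF at i
  expect_equal(onset_rhs(st3, 4, "r", p, onset_inh = "opposite"), 0.8)

  # offset: motion stopping behind excites, continuing motion vetoes
  st4 <- blank_state(7)
  st4$srf["r", 3] <- 0.8
  expect_equal(offset_rhs(st4, 4, "r", p), 0.8)
  st4$srf["r", 4] <- 0.8
  expect_equal(offset_rhs(st4, 4, "r", p), -1.6)

  # off-grid taps contribute nothing
  st5 <- blank_state(7)
  st5$srf["r", 7] <- 0.9
  expect_equal(offset_rhs(st5, 1, "r", p), 0)
  # at the right edge the onset cell keeps its own-position veto but has no
  # source of excitation
  expect_equal(onset_rhs(st5, 7, "r", p), -10 * 0.3 * 0.9)
})

test_that("assembled network derivative matches the per-cell equations", {
  p <- default_p
  spec <- default_spec
  lgn <- default_lgn
  accs <- default_accumulators(spec)
  J <- lgn_gain(lgn, spec$v_model * spec$w)

  expect_equal(full_rhs(20, numeric(73), spec, lgn, p, accs), numeric(73))
  expect_error(full_rhs(0, numeric(10), spec, lgn, p), "length")

  set.seed(7)
  for (t_probe in c(0.5, 2.5, 6.0)) {
    y <- runif(73, -0.3, 1)
    got <- full_rhs(t_probe, y, spec, lgn, p, accs)
    st <- blmotion:::vector_to_state(y[1:70], 7)
    want <- numeric(70)
    for (i in 1:7) for (d in c("l", "r")) {
      drv <- J * contrast_indicator(spec, i, t_probe)
      want[cell_index("inh", i, d, 7)] <- interneuron_rhs(st, i, d, drv, p)
      want[cell_index("dir", i, d, 7)] <- directional_rhs(st, i, d, drv, p)
      want[cell_index("srf", i, d, 7)] <- srf_rhs(st, i, d, p)
      want[cell_index("on", i, d, 7)] <- onset_rhs(st, i, d, p)
      want[cell_index("off", i, d, 7)] <- offset_rhs(st, i, d, p)
    }
    expect_equal(got[1:70], want, tolerance = 1e-14)
    # accumulator rows: shunting with slowdown C on summed rectified taps
    on_taps <- rectify(y[vapply(1:7, cell_index, 1L, layer = "on",
                                d = "r", n = 7)])
    expect_equal(got[71],
                 accumulator_rhs(y[71], on_taps[2], sum(on_taps[-2]), p),
                 tolerance = 1e-14)
  }
})

test_that("derivative points inward on the activity box boundary", {
  p <- default_p
  spec <- default_spec
  # ceiling: any cell at alpha with nonnegative drives cannot rise
  y_top <- rep(p$alpha, 73)
  d_top <- full_rhs(2.5, y_top, spec, default_lgn, p,
                    default_accumulators(spec))
  expect_true(all(d_top <= 0))
  # floor: at -omega the inhibition term vanishes, decay pulls back up
  y_bot <- rep(-p$omega, 73)
  d_bot <- full_rhs(2.5, y_bot, spec, default_lgn, p,
                    default_accumulators(spec))
  expect_true(all(d_bot >= 0))
})

test_that("zero input leaves the network identically quiescent", {
  spec <- default_spec
  lgn0 <- lgn_params(contrast = 0)
  traj <- simulate_circuit(spec, lgn0, default_p, t_end = 8, dense_dt = 0.05)
  expect_equal(max(abs(traj$net)), 0)
  expect_equal(max(abs(traj$acc)), 0)
  expect_equal(max(abs(traj$drive)), 0)
})

test_that("default run reproduces the canonical event sequence", {
  traj <- simulate_circuit(default_spec, default_lgn, default_p)
  tt <- traj$times

  # rightward onset cell at the appearance position activates early ...
  on2 <- traj$net[, "on_2_r"]
  expect_gt(max(on2[tt <= 3]), 0.5)
  # ... the rightward offset cell at position 7 is silent until the patch
  # approaches (preemptive excitation starts once position 6 is occupied at
  # t = 4) and fires hardest after the input vanishes at t = 5
  off7 <- traj$net[, "off_7_r"]
  expect_equal(max(off7[tt <= 4]), 0)
  expect_gt(max(off7[tt > 5]), 2 * max(off7[tt <= 5]))
  expect_gt(max(off7[tt > 5]), 0.5)
  # only rightward motion is signalled at the SRF stage
  lsrf <- traj$net[, grepl("^srf_._l$", colnames(traj$net))]
  rsrf <- traj$net[, grepl("^srf_._r$", colnames(traj$net))]
  expect_lt(max(rectify(lsrf)), 0.05)
  expect_gt(max(rsrf), 0.9)
  # null-direction suppression at the directional stage during motion
  move <- tt > 1 & tt < 5
  expect_lt(max(traj$net[move, grepl("^dir_._l$", colnames(traj$net))]),
            max(traj$net[move, grepl("^dir_._r$", colnames(traj$net))]))
})

test_that("leftward stimulus is the exact mirror of the rightward run", {
  tr <- simulate_circuit(default_spec, default_lgn, default_p,
                         t_end = 25, dense_dt = 0.02, accumulators = list())
  specL <- stimulus_spec(start_pos = 6, end_pos = 2)
  tl <- simulate_circuit(specL, default_lgn, default_p,
                         t_end = 25, dense_dt = 0.02, accumulators = list())
  worst <- 0
  for (lay in c("inh", "dir", "srf", "on", "off"))
    for (i in 1:7) for (d in c("l", "r")) {
      D <- if (d == "l") "r" else "l"
      worst <- max(worst, max(abs(
        tl$net[, paste0(lay, "_", i, "_", d)] -
          tr$net[, paste0(lay, "_", 8 - i, "_", D)])))
    }
  expect_lt(worst, 1e-6)
})

test_that("solution is integrator-independent", {
  base <- simulate_circuit(default_spec, default_lgn, default_p, t_end = 12)
  alt <- simulate_circuit(default_spec, default_lgn, default_p, t_end = 12,
                          method = "ode45")
  tight <- simulate_circuit(default_spec, default_lgn, default_p, t_end = 12,
                            rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(base$net - alt$net)), 1e-5)
  expect_lt(max(abs(base$acc - alt$acc)), 1e-5)
  expect_lt(max(abs(apply(base$net, 2, max) - apply(tight$net, 2, max))),
            1e-5)
})
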