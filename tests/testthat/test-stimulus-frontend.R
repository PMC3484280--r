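test_that("contrast indicator follows the floor/Kronecker occupancy rule", {
  spec <- default_spec  # v_model = 1, patch moves 2 -> 6 on a 7-cell grid

  expect_equal(contrast_indicator(spec, 2, 0.5), 1)
  expect_equal(contrast_indicator(spec, 7, 3.0), 0)  # boundary always silent
  expect_equal(contrast_indicator(spec, 1, 0.0), 0)
  expect_equal(contrast_indicator(spec, 6, 4.5), 1)
  expect_equal(contrast_indicator(spec, 6, 5.0), 0)  # vanished for t >= 5

  # half-open intervals: a switch instant belongs to the later interval
  expect_equal(contrast_indicator(spec, 2, 1.0), 0)
  expect_equal(contrast_indicator(spec, 3, 1.0), 1)

  expect_error(contrast_indicator(spec, 8, 1), "outside")
  expect_error(contrast_indicator(spec, 0, 1), "outside")
  expect_error(contrast_indicator(spec, 2, -0.1), "nonnegative")
})

test_that("exactly one position is occupied while the patch is in flight", {
  for (v in c(0.3, 1, 2.7)) {
    spec <- stimulus_spec(v_model = v)
    tt <- seq(0, 1.5 * n_occupied(spec) / v, length.out = 400)
    occ <- vapply(seq_len(spec$n_positions),
                  function(i) contrast_indicator(spec, i, tt),
                  numeric(length(tt)))
    per_t <- rowSums(occ)
    in_flight <- tt < n_occupied(spec) / v
    expect_true(all(per_t[in_flight] == 1))
    expect_true(all(per_t[!in_flight] == 0))
  }
})

test_that("occupancy of each interior position lasts exactly 1/v", {
  for (v in c(0.5, 1, 4)) {
    occ <- measure_occupancy(stimulus_spec(v_model = v))
    expect_equal(occ$position, 2:6)
    expect_equal(occ$t_off - occ$t_on, rep(1 / v, 5), tolerance = 1e-9)
  }
})

test_that("contrast shortens the high-pass time constant as T_0/(1+(c/C_half)^2)", {
  expect_equal(tau_s_effective(lgn_params(contrast = 0, T_0 = 4.496e-3)),
               4.496e-3)
  # arithmetic on printed front-end constants
  expect_equal(tau_s_effective(lgn_params(T_0 = 4.496e-3)),
               8.419e-4, tolerance = 1e-4)
  expect_lt(tau_s_effective(lgn_params(contrast = 0.9)),
            0.01 * lgn_params()$T_0)
})

test_that("temporal frequency is 2 pi f_S v", {
  lgn <- default_lgn
  expect_equal(temporal_frequency(lgn, 0), 0)
  expect_equal(temporal_frequency(lgn, 1), 2 * pi * 2.181, tolerance = 1e-12)
  expect_equal(temporal_frequency(lgn, 2), 2 * temporal_frequency(lgn, 1))
  expect_error(temporal_frequency(lgn, -1), "nonnegative")
})

test_that("LGN gain is band-pass: zero at rest and at very high speed", {
  lgn <- default_lgn  # H_S = 1 kills the response to a static patch
  expect_equal(lgn_gain(lgn, 0), 0)
  expect_lt(lgn_gain(lgn, 1e4), 1e-12)
  # single interior peak: rises then falls along a log-spaced grid
  v <- exp(seq(log(1e-2), log(1e3), length.out = 120))
  J <- lgn_gain(lgn, v)
  k <- which.max(J)
  expect_true(k > 1 && k < length(v))
  expect_true(all(diff(J[1:k]) > 0))
  expect_true(all(diff(J[k:length(v)]) < 0))
  # F_gain is a pure scale factor
  lgn2 <- lgn_params(F_gain = 2 * lgn$F_gain)
  expect_equal(lgn_gain(lgn2, v), 2 * J, tolerance = 1e-12)
  # H_S > 1 (negative radicand) is rejected at construction
  expect_error(lgn_params(H_S = 1.2), "H_S")
})

test_that("peak LGN gain is the grid+golden-section maximum", {
  pk <- peak_lgn_gain(default_lgn)
  probes <- exp(seq(log(1e-2), log(1e3), length.out = 500))
  expect_true(all(pk$J_max >= lgn_gain(default_lgn, probes)))
  pk2 <- peak_lgn_gain(lgn_params(F_gain = 2 * 2.206))
  expect_equal(pk2$J_max, 2 * pk$J_max, tolerance = 1e-9)
  expect_equal(pk2$v_peak, pk$v_peak, tolerance = 1e-4)
})

test_that("input drive separates into gain times indicator", {
  spec <- default_spec
  lgn <- default_lgn
  J <- lgn_gain(lgn, spec$v_model * spec$w)
  expect_equal(input_drive(spec, lgn, 4, 0.2), 0)
  tt <- seq(2.05, 2.95, by = 0.1)  # patch sits at position 4 throughout
  expect_equal(input_drive(spec, lgn, 4, tt), rep(J, length(tt)))
  # running the patch at the LGN-optimal speed saturates the drive at 1
  pk <- peak_lgn_gain(lgn)
  spec_pk <- stimulus_spec(v_model = pk$v_peak / spec$w)
  expect_equal(input_drive(spec_pk, lgn, 2, 0.01), 1, tolerance = 1e-3)
  # zero-contrast patch: no stimulus, no drive
  lgn0 <- lgn_params(contrast = 0)
  expect_equal(input_drive(spec, lgn0, 4, tt), rep(0, length(tt)))
})

test_that("lgn_curve tabulates the gain over the requested speeds", {
  cv <- lgn_curve(default_lgn, speeds = c(0.5, 5, 50))
  expect_equal(cv$J, lgn_gain(default_lgn, c(0.5, 5, 50)))
  expect_named(cv, c("v_physical", "J"))
})
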