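test_that("parameter validation enforces model invariants", {
  expect_s3_class(forward_model_params(), "forward_model_params")
  expect_error(forward_model_params(top = 0, base = 0))
  expect_error(forward_model_params(base = -0.1))
  expect_error(forward_model_params(ed50 = 0))
  expect_error(forward_model_params(slope = -1))
  expect_error(forward_model_params(w_ipsi = 0.5, w_contra = 0.7))
  expect_error(forward_model_params(g_inhib = -0.1))
  expect_error(forward_model_params(antenna_sep = 0))
})

test_that("logistic response matches hand-evaluated values", {
  p <- forward_model_params(top = 1, base = 0, ed50 = 2.2, slope = 0.5)
  expect_equal(logistic_response(2.2, p), 0.5)
  expect_equal(logistic_response(1, p), 1 / (1 + exp((1 - 2.2) / 0.5)),
               tolerance = 1e-12)
  expect_equal(logistic_response(1, p), 0.9168, tolerance = 1e-4)
  expect_lt(logistic_response(100, p), 1e-10)
  p2 <- forward_model_params(top = 0.8, base = 0.2)
  expect_equal(logistic_response(p2$ed50, p2), 0.5)
  expect_equal(logistic_response(1e6, p2), 0.2)
})

test_that("presets set cell-type specific half-maximal distances", {
  expect_equal(forward_model_preset("orn")$ed50, 2.2)
  expect_equal(forward_model_preset("lpn")$ed50, 2.4)
  expect_equal(forward_model_preset("lvpn")$ed50, 1.5)
  expect_equal(forward_model_preset("orn", ed50 = 3)$ed50, 3)
})

test_that("stimulus scripts interpolate linearly and hold the endpoints", {
  s <- stimulus_script(time = c(0, 2, 4), x = c(10, 2, 2), y = c(0, 0, 0))
  pos <- script_position(s, c(0, 1, 2, 3, 5))
  expect_equal(pos$x, c(10, 6, 2, 2, 2))
  expect_error(stimulus_script(c(0, 0), c(1, 2), c(0, 0)))
  expect_error(stimulus_script(c(0, 1), c(1, Inf), c(0, 0)))
  pres <- script_presentation(0.5, speed = 8.04, hold = 10)
  expect_equal(min(script_position(pres, seq(0, 30, 0.01))$x), 0.5)
})

test_that("noiseless traces settle to the closed-form steady state", {
  p <- forward_model_params(noise_sd = 0, tau_rise = 0.3)
  hold <- 16 * p$tau_rise
  s <- stimulus_script(time = c(0, hold), x = c(p$ed50, p$ed50), y = c(0, 0))
  # stimulus on the midline: distance to an antenna slightly exceeds ed50
  tr <- simulate_orn_trace(p, s, "left", fs = 7.2)
  d <- sqrt(p$ed50^2 + (p$antenna_sep / 2)^2)
  expect_equal(tail(tr$samples, 1), logistic_response(d, p),
               tolerance = 1e-6)
  # far stimulus settles to base
  s_far <- stimulus_script(time = c(0, hold), x = c(50, 50), y = c(0, 0))
  tr_far <- simulate_orn_trace(p, s_far, "left", fs = 7.2)
  expect_equal(tail(tr_far$samples, 1), p$base, tolerance = 1e-6)
})

test_that("trace simulation is deterministic under a fixed seed", {
  p <- forward_model_params(noise_sd = 0.05)
  s <- script_presentation(1)
  a <- simulate_orn_trace(p, s, "left", seed = 7)
  b <- simulate_orn_trace(p, s, "left", seed = 7)
  expect_identical(a$samples, b$samples)
  expect_false(identical(
    simulate_orn_trace(p, s, "left", seed = 7)$samples,
    simulate_orn_trace(p, s, "left", seed = 8)$samples))
})

test_that("simulation rejects invalid inputs", {
  p <- forward_model_params()
  s <- script_presentation(1)
  expect_error(simulate_orn_trace(p, s, "left", fs = 0), "fs")
})

test_that("bilateral PN traces are symmetric for a midline stimulus", {
  p <- forward_model_params(noise_sd = 0)
  s <- stimulus_script(time = c(0, 5), x = c(2, 2), y = c(0, 0))
  pn <- simulate_bilateral_pn(p, s)
  expect_equal(pn$left$samples, pn$right$samples, tolerance = 1e-12)
})

test_that("bilateral circuit reduces to a pure ipsilateral relay", {
  p <- forward_model_params(noise_sd = 0, w_ipsi = 0.8, w_contra = 0,
                            g_inhib = 0)
  s <- stimulus_script(time = c(0, 5), x = c(1, 1), y = c(2, 2))
  pn <- simulate_bilateral_pn(p, s)
  orn <- simulate_orn_trace(p, s, "left")
  expect_equal(pn$left$samples, 0.8 * orn$samples, tolerance = 1e-12)
})

test_that("blocking the contralateral antenna disinhibits the PN", {
  # with g_inhib > w_contra the net contralateral effect is inhibitory, so
  # silencing the contralateral ORN must increase the PN response to a
  # contralateral stimulus
  p <- forward_model_params(noise_sd = 0)
  expect_gt(p$g_inhib, p$w_contra)
  ss <- steady_state_bilateral(p, x = 0.5, y = 1.5, cell_type = "pn")
  orn <- steady_state_bilateral(p, x = 0.5, y = 1.5, cell_type = "orn")
  left_blocked <- p$w_ipsi * orn$left # right antenna silenced
  expect_gt(left_blocked, ss$left)
})

test_that("lattice sessions have the documented shape and symmetry", {
  lat <- build_hex_lattice()
  p0 <- forward_model_params(noise_sd = 0)
  ses <- generate_lattice_session(p0, lat, n_flies = 8, n_trials = 3)
  expect_equal(nrow(ses), 8 * 3 * 16)
  # noiseless trials at a position are identical
  v <- tapply(ses$left, ses$pos, function(x) diff(range(x)))
  expect_true(all(v == 0))
  # mirrored positions swap left and right responses
  pos <- lat$positions
  for (i in seq_len(nrow(pos))) {
    j <- which(abs(pos$x - pos$x[i]) < 1e-9 & abs(pos$y + pos$y[i]) < 1e-9)
    expect_length(j, 1)
    ri <- ses[ses$fly == 1 & ses$trial == 1 & ses$pos == pos$pos[i], ]
    rj <- ses[ses$fly == 1 & ses$trial == 1 & ses$pos == pos$pos[j], ]
    expect_equal(ri$left, rj$right, tolerance = 1e-12)
  }
  expect_error(generate_lattice_session(p0, lat, n_flies = 0))
  # determinism
  p <- forward_model_params()
  expect_identical(generate_lattice_session(p, lat, seed = 3),
                   generate_lattice_session(p, lat, seed = 3))
})

test_that("distance sessions carry the generating tuning", {
  p <- forward_model_params(noise_sd = 0)
  ds <- generate_distance_session(p, n_flies = 2, n_trials = 2)
  expect_equal(nrow(ds), 10 * 2 * 2)
  expect_equal(ds$response, logistic_response(ds$distance, p))
  p2 <- forward_model_params(noise_sd = 0.05)
  expect_identical(generate_distance_session(p2, seed = 5),
                   generate_distance_session(p2, seed = 5))
})
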