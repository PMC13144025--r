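# Dyadic/JSR reaction-diffusion: calibration, buffers, refill, stepping.

test_that("permeability calibration reproduces the single-channel currents", {
  p_ryr <- calibrate_permeability(0.16, 850)
  # hand unit conversion: 0.16 pA / (2 * 96485 C/mol * 850 uM) ~ 9.75e-16 L/s
  expect_equal(p_ryr * 1000, 9.7546e-16, tolerance = 1e-4)
  # exact inverse map, any current
  for (i in c(0.05, 0.16, 1.2)) {
    expect_equal(channel_current(calibrate_permeability(i, 850), 850), i,
                 tolerance = 1e-12)
  }
  # linearity in the current specification
  expect_equal(calibrate_permeability(0.05, 850) / p_ryr, 0.05 / 0.16,
               tolerance = 1e-12)
  expect_error(calibrate_permeability(0, 850), "positive")
  expect_error(calibrate_permeability(0.16, -1), "positive")
})

test_that("channel fluxes follow the gradient with calibrated magnitudes", {
  tp <- default_params()$transport
  expect_equal(flux_ryr(0, 850, 0.1, tp), 0)
  expect_equal(flux_ryr(1, 500, 500, tp), 0)
  expect_lt(flux_ryr(1, 100, 500, tp), 0)  # reverse gradient
  # one open RyR at the calibration gradient delivers the 0.16-pA flow
  j <- flux_ryr(1, 850, 0, tp)
  p <- calibrate_permeability(0.16, 850)
  expect_equal(j, p * 850 / tp$v_ds_L, tolerance = 1e-12)
  # permeability ratio carries through to the fluxes
  expect_equal(flux_ip3r(1, 850, 0.1, tp) / flux_ryr(1, 850, 0.1, tp),
               0.05 / 0.16, tolerance = 1e-12)
})

test_that("buffers relax to equilibrium with the analytic rate", {
  bp <- default_params()$buffers
  cam <- bp$calmodulin
  c0 <- 2
  beq <- cam$b_total * cam$k_off / (cam$k_off + cam$k_on * c0)
  # equilibrium is a fixed point with zero net flux
  st <- buffer_step(list(calmodulin = beq), c0, 0.01,
                    list(calmodulin = cam))
  expect_equal(st$b_free$calmodulin, beq, tolerance = 1e-12)
  expect_equal(st$j_total, 0, tolerance = 1e-12)
  # relaxation at fixed c follows the single-exponential closed form
  b <- cam$b_total  # start fully free
  dt <- 0.002; nsteps <- 2500
  for (s in seq_len(nsteps)) {
    b <- buffer_step(list(calmodulin = b), c0, dt,
                     list(calmodulin = cam))$b_free$calmodulin
  }
  rate <- cam$k_on * c0 + cam$k_off
  b_exact <- beq + (cam$b_total - beq) * exp(-rate * dt * nsteps)
  expect_equal(b, b_exact, tolerance = 1e-3)
  # free + bound partition is preserved (free stays within [0, b_total])
  expect_true(b >= 0 && b <= cam$b_total)
})

test_that("refill flux and its e-folding time match the first-order law", {
  tp <- default_params()$transport
  expect_equal(refill_flux(850, tp), 0)
  expect_equal(refill_flux(0, tp), 106.25)  # 850 / 8
  # with diffusion flat and channels closed, JSR relaxes to 850 uM with
  # an 8-ms e-folding time at beta = 1
  p <- default_params()
  g <- make_checkerboard(0, margin = 3)
  f <- new_field_state(g, p)
  f$c_jsr[] <- 400
  dt <- 2.5e-4; nsteps <- 8 / dt  # run exactly one time constant
  for (s in seq_len(nsteps)) f <- step_fields(f, dt, p, beta = 1)
  expect_equal(f$c_jsr[1, 1], 850 - 450 * exp(-1), tolerance = 1e-3)
})

test_that("the resting state is a fixed point of the field update", {
  p <- default_params()
  g <- make_checkerboard(4, margin = 3)
  f0 <- new_field_state(g, p)
  f <- f0
  dt <- dt_stability(p)$dt_fields * 0.9
  for (s in 1:100) f <- step_fields(f, dt, p)
  expect_equal(f$c_ds, f0$c_ds, tolerance = 1e-9)
  expect_equal(f$c_jsr, f0$c_jsr, tolerance = 1e-9)
})

test_that("the stability guard rejects an explicit-scheme violation", {
  p <- default_params()
  g <- make_checkerboard(4, margin = 3)
  f <- new_field_state(g, p)
  bound <- 0.5 * 0.03^2 / (4 * p$transport$d_myo)
  expect_error(step_fields(f, 2 * bound, p), "stability")
  expect_error(run_trial(make_checkerboard(4),
                         trial_config(duration = 1, dt = 1)),
               "bound")
})

test_that("a point release spreads with mean-squared displacement 4 D t", {
  p <- no_buffer_params()
  g <- make_checkerboard(0, margin = 20)  # 40 x 40 empty grid
  f <- new_field_state(g, p)
  cx <- 20; cy <- 20
  f$c_ds[cx, cy] <- f$c_ds[cx, cy] + 100
  dt <- dt_stability(p)$dt_fields * 0.8
  elapsed <- 0
  for (s in 1:60) { f <- step_fields(f, dt, p, boundary_ds = "noflux",
                                     refill = FALSE); elapsed <- elapsed + dt }
  w <- f$c_ds - p$transport$c_rest
  xs <- (row(w) - cx) * 0.03; ys <- (col(w) - cy) * 0.03
  msd <- sum(w * (xs^2 + ys^2)) / sum(w)
  expect_equal(msd, 4 * p$transport$d_myo * elapsed, tolerance = 0.01)
})

test_that("total Ca2+ is conserved in the closed configuration", {
  # no-flux dyadic boundary, refill off, beta = 1, one channel held open
  p <- frozen_ryr_params()
  p$transport$beta <- 1
  g <- make_checkerboard(9, margin = 6)
  cfg <- trial_config(duration = 50, seed = 1, ip3 = 0,
                      boundary_ds = "noflux", refill = FALSE)
  rec <- run_trial(g, cfg, p)
  expect_true(all(rec$n_open_ryr == 1))   # frozen gating keeps it open
  drift <- abs(rec$ca_total - rec$ca_total[1]) / rec$ca_total[1]
  expect_lt(max(drift), 1e-3)
  # and the release actually moved Ca2+ between compartments
  expect_gt(max(rec$cds_max_uM), 50)
  expect_lt(min(rec$cjsr_min_uM), 849)
})

test_that("compiled and R field updates agree step for step", {
  p <- frozen_ryr_params()
  g <- make_checkerboard(5, margin = 5)
  cfg <- trial_config(duration = 2, seed = 1, ip3 = 0, record_stride = 100)
  rec <- run_trial(g, cfg, p)
  dt <- attr(rec, "dt")
  # R reference loop with the same forced-open channel
  f <- new_field_state(g, p)
  ry <- g$sites[g$sites$kind == "RYR", ]
  ctr <- which.min((ry$ix - mean(ry$ix))^2 + (ry$iy - mean(ry$iy))^2)
  n_open <- matrix(0, g$nx, g$ny)
  n_open[ry$ix[ctr], ry$iy[ctr]] <- 1
  means <- numeric(0)
  nsteps <- ceiling(cfg$duration / dt)
  for (s in 0:(nsteps - 1)) {
    if (s %% 100 == 0) means <- c(means, mean(f$c_ds))
    f <- step_fields(f, dt, p, n_open_ryr = n_open)
  }
  means <- c(means, mean(f$c_ds))
  expect_equal(rec$cds_mean_uM, means, tolerance = 1e-10)
})

test_that("halving dt changes the trajectory by less than one percent", {
  p <- frozen_ryr_params()
  g <- make_checkerboard(9, margin = 6)
  dt0 <- dt_stability(p)$dt
  run <- function(dt, stride) {
    run_trial(g, trial_config(duration = 20, seed = 1, ip3 = 0, dt = dt,
                              record_stride = stride), p)
  }
  r1 <- head(run(dt0, 200L), -1)       # drop the ragged final sample
  r2 <- head(run(dt0 / 2, 400L), -1)
  expect_equal(r1$t_ms, r2$t_ms, tolerance = 1e-9)
  rel <- abs(r1$cds_mean_uM - r2$cds_mean_uM) /
    pmax(r1$cds_mean_uM, 1e-12)
  expect_lt(max(rel), 0.01)
})
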