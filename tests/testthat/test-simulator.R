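test_that("reference programs have the prescribed shapes", {
  # ramp reaches l0 * target at target/rate and caps there
  r <- make_reference("ramp", strain_rate = 0.025, target_strain = 0.6,
                      l0 = 8e-3)
  expect_equal(sample_reference(r, 24), 4.8e-3)
  expect_equal(sample_reference(r, 30), 4.8e-3)
  expect_equal(reference_duration(r), 24)

  # triangle returns to zero at twice the ramp duration
  tr <- make_reference("triangle", strain_rate = 0.025, target_strain = 0.6,
                       l0 = 8e-3)
  expect_equal(sample_reference(tr, 48), 0)
  expect_equal(sample_reference(tr, 24), 4.8e-3)

  # cycles: exactly n_cycles local maxima
  cy <- make_reference("cycles", strain_rate = 0.05, target_strain = 0.2,
                       n_cycles = 6, l0 = 8e-3)
  t <- seq(0, reference_duration(cy), by = 5e-3)
  q <- sample_reference(cy, t)
  n_max <- sum(diff(sign(diff(q))) == -2)
  expect_equal(n_max, 6)

  expect_error(make_reference("ramp", strain_rate = 0), "positive")
})

test_that("zero reference with no bias current leaves the sample at rest", {
  s <- tissue_scale_sample(5)
  ref <- make_reference("hold", target_strain = 0, l0 = s$l0)
  tr <- run_closed_loop(s, ref, duration = 1, seed = 1,
                        ccd = quiet_ccd(),
                        controller = controller_config(I_init = 0,
                                                       I_op_min = 0))
  expect_true(all(tr$data$q_true_m == 0))
  expect_true(all(tr$data$I_A == 0))
})

test_that("a static hold converges to the static force balance", {
  k <- 5
  s <- tissue_scale_sample(k)
  ref <- make_reference("hold", target_strain = 0.05, l0 = s$l0)
  tr <- run_closed_loop(s, ref, duration = 12, seed = 2)
  late <- tail(tr$data, 100)
  q_star <- 0.05 * s$l0
  expect_equal(mean(late$F_E_N), k * q_star, tolerance = 5e-3)
  expect_equal(mean(late$q_true_m), q_star, tolerance = 5e-3)
})

test_that("traces are reproducible under a fixed seed", {
  s <- tissue_scale_sample(5)
  ref <- make_reference("ramp", strain_rate = 0.02, target_strain = 0.05,
                        l0 = s$l0)
  t1 <- run_closed_loop(s, ref, duration = 4, seed = 99)
  t2 <- run_closed_loop(s, ref, duration = 4, seed = 99)
  expect_identical(t1$data, t2$data)
  t3 <- run_closed_loop(s, ref, duration = 4, seed = 100)
  expect_false(identical(t3$data$q_meas_m, t1$data$q_meas_m))
})

test_that("substep refinement has converged", {
  s <- tissue_scale_sample(20)
  ref <- make_reference("ramp", strain_rate = 0.02, target_strain = 0.05,
                        l0 = s$l0)
  t10 <- run_closed_loop(s, ref, duration = 4, seed = 5, ccd = quiet_ccd())
  t20 <- run_closed_loop(s, ref, duration = 4, seed = 5, ccd = quiet_ccd(),
                         n_sub = 20)
  q10 <- tail(t10$data$q_true_m, 1)
  q20 <- tail(t20$data$q_true_m, 1)
  expect_lt(abs(q10 - q20) / abs(q20), 1e-4)
})

test_that("the C++ loop reproduces the R-level sensor and gain contracts", {
  s <- tissue_scale_sample(5)
  ccd <- quiet_ccd()
  ctrl <- controller_config()
  ref <- make_reference("ramp", strain_rate = 0.02, target_strain = 0.04,
                        l0 = s$l0)
  tr <- run_closed_loop(s, ref, duration = 3, seed = 3, ccd = ccd,
                        controller = ctrl)
  d <- tr$data
  s0 <- ccd$n_pixels * ccd$pitch / 2

  # measured positions equal the R channel applied to the true positions
  ch <- measurement_channel(s0 + d$q_true_m, tr$bead$d, ccd)
  expect_equal(d$q_meas_m, ch$measured - s0, tolerance = 1e-12)

  # gain snapshots equal adaptive_update at the recorded operating point
  I_prev <- c(ctrl$I_init, head(d$I_A, -1))
  for (i in seq(10, nrow(d), by = 37)) {
    g <- adaptive_update(max(0, tr$x_start - d$q_meas_m[i]), I_prev[i],
                         q = NA, config = ctrl, cell = tr$cell,
                         params = tr$magnet, bead = tr$bead,
                         k_hat = d$k_hat[i])
    expect_equal(c(d$Kp[i], d$Ki[i], d$Kd[i]), c(g$Kp, g$Ki, g$Kd),
                 tolerance = 1e-12)
  }

  # frozen-time poles of the live gains sit at the specification
  for (i in seq(10, nrow(d), by = 53)) {
    lin <- linearize_plant(max(0, tr$x_start - d$q_meas_m[i]),
                           max(I_prev[i], ctrl$I_op_min),
                           k_hat = d$k_hat[i], c_hat = ctrl$c_hat,
                           cell = tr$cell, params = tr$magnet,
                           bead = tr$bead)
    expect_lt(pole_distance(closed_loop_poles(lin,
      pid_gains(d$Kp[i], d$Ki[i], d$Kd[i]))), 1e-6)
  }
})

test_that("energy audit: a purely elastic cycle dissipates no spring work", {
  s <- tissue_scale_sample(2, zeta = 0)
  ref <- make_reference("triangle", strain_rate = 0.025,
                        target_strain = 0.3, l0 = s$l0)
  tr <- run_closed_loop(s, ref, duration = reference_duration(ref) + 2,
                        seed = 6)
  d <- tr$data
  w <- sum(d$F_spring_N[-1] * diff(d$q_true_m))
  peak_work <- 0.5 * 2 * (0.3 * s$l0)^2
  expect_lt(abs(w) / peak_work, 5e-3)
})

test_that("protocol suite runs the study protocols", {
  expect_identical(run_protocol_suite(tissue_scale_sample(2), list()),
                   list())

  # elastic sample: identical cycle maxima over 4 cycles
  s <- tissue_scale_sample(2, zeta = 0)
  pre <- make_reference("cycles", strain_rate = 0.05, target_strain = 0.3,
                        n_cycles = 4, l0 = s$l0)
  out <- run_protocol_suite(s, list(pre = pre), seed = 3,
                            ccd = quiet_ccd())
  mx <- cycle_maxima(out$pre)
  expect_length(mx, 4)
  expect_lt(max(abs(diff(mx))) / mx[1], 1e-3)

  # Kelvin-Voigt: peak stress increases with strain rate
  kv <- tissue_scale_sample(2, zeta = 0.5)
  rates <- c(0.025, 0.05, 0.1)
  refs <- lapply(rates, function(r)
    make_reference("ramp", strain_rate = r, target_strain = 0.3,
                   l0 = kv$l0))
  names(refs) <- paste0("r", rates)
  traces <- run_protocol_suite(kv, refs, seed = 4)
  peak <- vapply(traces, function(tr)
    max(trace_to_curve(tr)$stress), numeric(1))
  expect_true(all(diff(peak) > 0))
})

test_that("the loop stays bounded across the design envelope at tissue rates", {
  # stability (bounded response), not tracking accuracy: tracking degrades
  # with k * rate as physics dictates, but the loop must never diverge
  cell <- buoyancy_cell()
  for (k in c(0.5, 20)) {
    s <- tissue_scale_sample(k, zeta = 0.5, cell = cell)
    for (rate in c(0.025, 0.05, 0.1)) {
      ref <- make_reference("ramp", strain_rate = rate,
                            target_strain = 0.3, l0 = s$l0)
      tr <- run_closed_loop(s, ref,
                            duration = reference_duration(ref) + 3,
                            seed = 2, cell = cell)
      expect_lt(max(abs(tr$data$q_true_m)), 2 * 0.3 * s$l0)
    }
  }
})

test_that("a rigid sample pins the current at its ceiling with negligible motion", {
  # required force far beyond the actuator's authority: the integral winds
  # to its anti-windup clamp and the command sits at its effective ceiling
  # while the sample barely moves
  s <- virtual_sample(l0 = 3e-3, A = 2.6e-7, k = 2000, c = 1)
  ref <- make_reference("ramp", strain_rate = 0.05, target_strain = 0.1,
                        l0 = s$l0)
  tr <- run_closed_loop(s, ref, duration = 30, seed = 3)
  late <- tail(tr$data, 200)
  expect_gt(mean(late$I_A), 0.6)                  # near the 1 A ceiling
  expect_lt(diff(range(late$I_A)), 0.05)          # pinned, not tracking
  expect_lt(max(tr$data$q_true_m), 0.1 * 0.1 * s$l0)
})
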