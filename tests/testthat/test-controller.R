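test_that("desired polynomial coefficients match the design poles", {
  a <- desired_poly_coeffs(pole_placement_spec())
  # (s + 60)(s^2 + 13 s + 43.25): 6.5^2 + 1 = 43.25, 60 * 43.25 = 2595
  expect_equal(unname(a), c(73, 823.25, 2595))
  expect_error(pole_placement_spec(p1 = 1), "negative real parts")
})

test_that("plant linearization encodes the magnetic destabilization", {
  p <- electromagnet_params()
  b <- bead_spec()
  cell <- buoyancy_cell()

  # zero current: K_I = 0, k_eff = k_hat
  lin0 <- linearize_plant(6e-3, 0, k_hat = 7, cell = cell, params = p,
                          bead = b)
  expect_equal(lin0$K_I, 0)
  expect_equal(lin0$k_eff, 7)

  # K_I * I = 2 F always
  lin <- linearize_plant(6e-3, 0.5, k_hat = 7, cell = cell, params = p,
                         bead = b)
  expect_equal(lin$K_I * 0.5, 2 * lin$F_bar, tolerance = 1e-12)

  # k_eff changes sign where F = k_hat * x0
  k_hat <- 7
  I_flip <- required_current(k_hat * p$x0, 6e-3, p, b)$I
  lo <- linearize_plant(6e-3, I_flip * 0.99, k_hat = k_hat, params = p,
                        bead = b)
  hi <- linearize_plant(6e-3, I_flip * 1.01, k_hat = k_hat, params = p,
                        bead = b)
  expect_gt(lo$k_eff, 0)
  expect_lt(hi$k_eff, 0)
})

test_that("pole placement reproduces the specified closed-loop poles", {
  spec <- pole_placement_spec()

  # unit plant: gains equal the desired coefficients
  unit <- structure(list(m = 1, c_t = 0, k_eff = 0, K_I = 1),
                    class = "plant_linearization")
  g <- place_poles(unit, spec)
  expect_equal(c(g$Kd, g$Kp, g$Ki), c(73, 823.25, 2595))

  # randomized plants: characteristic roots within 1e-9 of the targets
  set.seed(42)
  for (i in 1:50) {
    lin <- structure(list(m = runif(1, 1e-4, 1e-1),
                          c_t = runif(1, 0, 1),
                          k_eff = runif(1, -30, 30),
                          K_I = runif(1, 1e-4, 1)),
                     class = "plant_linearization")
    gains <- place_poles(lin, spec)
    roots <- closed_loop_poles(lin, gains)
    expect_lt(pole_distance(roots), 1e-9)
  }

  expect_error(place_poles(structure(list(m = 1, c_t = 0, k_eff = 0,
                                          K_I = 0),
                                     class = "plant_linearization"), spec),
               "not actuatable")

  # Ki ceiling is enforced
  g2 <- place_poles(unit, spec, Ki_max = 1000)
  expect_equal(g2$Ki, 1000)
})

test_that("adaptive update is stationary at a fixed operating point and
           falls back to bootstrap without actuation", {
  cfg <- controller_config()
  g1 <- adaptive_update(6e-3, 0.3, 4e-4, cfg)
  g2 <- adaptive_update(6e-3, 0.3, 4e-4, cfg)
  expect_identical(g1, g2)

  cfg0 <- controller_config(I_init = 0, I_op_min = 0)
  gb <- adaptive_update(6e-3, 0, 0, cfg0)
  expect_equal(gb$Kp, cfg0$bootstrap$Kp)
  expect_equal(gb$Ki, cfg0$bootstrap$Ki)

  # along a sweep of operating points the frozen-time poles stay put
  for (x in seq(5e-3, 7.9e-3, length.out = 8)) {
    q <- 8e-3 - x
    I <- 0.2
    g <- adaptive_update(x, I, q, cfg)
    F_bar <- coil_force(x, I)
    lin <- linearize_plant(x, I,
                           k_hat = estimate_stiffness(F_bar, q, cfg),
                           c_hat = cfg$c_hat)
    expect_lt(pole_distance(closed_loop_poles(lin, g)), 1e-6)
  }
})

test_that("secant stiffness estimate clamps and guards small stretch", {
  cfg <- controller_config()
  expect_equal(estimate_stiffness(2e-3, 1e-4, cfg), 20)
  expect_equal(estimate_stiffness(2e-3, 1e-6, cfg), 0)    # below q_min
  expect_equal(estimate_stiffness(1, 1e-4, cfg), cfg$k_hat_max)
})

test_that("pid step integrates trapezoidally with anti-windup", {
  dt <- 5e-3
  # zero error, zero state -> zero output
  g0 <- pid_gains(Kp = 100, Ki = 50, Kd = 1)
  st <- controller_state()
  out <- pid_step(1e-4, 1e-4, g0, st, dt)
  expect_equal(out$I, 0)

  # pure integrator: constant error over n steps -> Ki * e * n * dt
  gi <- pid_gains(Kp = 0, Ki = 200, Kd = 0)
  st <- controller_state(prev_meas = 0, prev_error = 1e-4)
  n <- 40; e <- 1e-4
  for (i in 1:n) { out <- pid_step(e, 0, gi, st, dt); st <- out$state }
  expect_equal(st$integral, gi$Ki * e * n * dt, tolerance = 1e-12)

  # saturation at I_max freezes the accumulator
  gsat <- pid_gains(Kp = 1e6, Ki = 100, Kd = 0, I_clamp = 1)
  st <- controller_state(integral = 0.5, prev_meas = 0, prev_error = 1e-2)
  out1 <- pid_step(1e-2, 0, gsat, st, dt, I_max = 1)
  expect_true(out1$saturated)
  expect_equal(out1$I, 1)
  expect_equal(out1$state$integral, 0.5)
  out2 <- pid_step(1e-2, 0, gsat, out1$state, dt, I_max = 1)
  expect_equal(out2$state$integral, 0.5)

  # derivative acts on the measurement, filtered
  gd <- pid_gains(Kp = 0, Ki = 0, Kd = 2)
  st <- controller_state(prev_meas = 0)
  out <- pid_step(0, 1e-4, gd, st, dt, deriv_tau = dt)
  expect_equal(out$state$deriv_f, 0.5 * (-(1e-4) / dt))

  expect_error(pid_step(NaN, 0, g0, controller_state(), dt),
               "controller fault")
})
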