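test_that("stress-strain conversion is the engineering definition", {
  A <- pi * 0.58e-3^2 / 4    # capillary-molded specimen cross-section
  cv <- to_stress_strain(rep(1e-3, 5), seq(0, 3e-3, length.out = 5),
                         A = A, l0 = 3e-3)
  expect_equal(cv$stress, rep(1e-3 / A, 5))
  expect_equal(cv$stress[1], 3785, tolerance = 1e-4)
  expect_equal(max(cv$strain), 1)          # q = l0 -> strain 1

  # zero force -> zero stress; linear in F; scale-invariant in (F, A)
  expect_equal(to_stress_strain(0, 1e-3, A, 3e-3)$stress, 0)
  cv2 <- to_stress_strain(rep(2e-3, 5), seq(0, 3e-3, length.out = 5),
                          A = 2 * A, l0 = 3e-3)
  expect_equal(cv2$stress, cv$stress)
  expect_error(to_stress_strain(1, 1, A = 0, l0 = 1), "positive")
})

test_that("windowed modulus recovers generating slopes", {
  eps <- seq(0, 0.12, by = 5e-4)

  # exact line at the soft elastomer modulus: zero residual
  cv <- stress_strain_curve(eps, 216e3 * eps, A = 1, l0 = 1)
  est <- youngs_modulus(cv, c(0.05, 0.10))
  expect_equal(est$E, 216e3, tolerance = 1e-12)
  expect_lt(est$residual, 1e-6)

  # unbiased under zero-mean noise (200 replicates, 3 standard errors)
  set.seed(21)
  E_hat <- replicate(200, {
    noisy <- stress_strain_curve(eps, 216e3 * eps + rnorm(length(eps), 0, 500),
                                 A = 1, l0 = 1)
    youngs_modulus(noisy, c(0.05, 0.10))$E
  })
  se <- sd(E_hat) / sqrt(200)
  expect_lt(abs(mean(E_hat) - 216e3), 3 * se)

  # high-strain window on a stiffening law: regression slope matches the
  # analytic secant-window slope within 1%
  E0 <- 2e3; B <- 4
  eps2 <- seq(0, 0.7, by = 1e-3)
  cv2 <- stress_strain_curve(eps2, stiffening_stress(eps2, E0, B),
                             A = 1, l0 = 1)
  est2 <- youngs_modulus(cv2, c(0.5, 0.6))
  secant <- (stiffening_stress(0.6, E0, B) -
             stiffening_stress(0.5, E0, B)) / 0.1
  expect_equal(est2$E, secant, tolerance = 0.01)

  expect_error(youngs_modulus(cv, c(0.5, 0.6)), "window error")
})

test_that("hysteresis metrics: identical branches, viscous loop, windows", {
  eps <- seq(0, 0.1, length.out = 400)
  up <- stress_strain_curve(eps, 5e3 * eps, A = 1, l0 = 1)
  dn <- stress_strain_curve(rev(eps), 5e3 * rev(eps), A = 1, l0 = 1)
  hm0 <- hysteresis_metrics(up, dn, windows = list(c(0, 0.1)))
  expect_equal(hm0$loop_area, 0, tolerance = 1e-12)
  expect_equal(hm0$moduli$E_load, hm0$moduli$E_unload)

  # Kelvin-Voigt triangle: loop area = 2 (c l0 / A) rate eps_max within 2%
  c_v <- 0.2; l0 <- 3e-3; A <- 2.642e-7; rate <- 2e-3; emax <- 0.1
  visc <- (c_v * l0 / A) * rate
  load <- stress_strain_curve(eps, 216e3 * eps + visc, A, l0)
  unld <- stress_strain_curve(rev(eps), 216e3 * rev(eps) - visc, A, l0)
  hm <- hysteresis_metrics(load, unld, windows = list(c(0, 0.1)))
  expect_equal(hm$loop_area, 2 * visc * emax, tolerance = 0.02)
  expect_gt(hm$dissipation_ratio, 0)

  expect_error(hysteresis_metrics(up,
    stress_strain_curve(eps + 1, 5e3 * eps, 1, 1)), "overlap")
})

test_that("preconditioning deviations match hand arithmetic", {
  mx <- c(0.50, 0.53, 0.545, 0.55)
  dev <- preconditioning_deviation(mx)
  expect_equal(dev, c(0.06, 0.0283019, 0.0091743), tolerance = 1e-5)
  # first deviation below 5% is from cycle 3 to 4
  expect_equal(preconditioning_converged_after(mx, 0.05), 3L)
  expect_equal(preconditioning_deviation(c(0.5, 0.5, 0.5)), c(0, 0))
  expect_error(preconditioning_deviation(0.5), "at least two")
  expect_error(preconditioning_deviation(c(0, 0.1)), "zero")
})

test_that("strain-rate summary reduces to single fits and orders KV rates", {
  eps <- seq(0, 0.12, by = 5e-4)
  cv <- stress_strain_curve(eps, 100e3 * eps, A = 1, l0 = 1)
  tab <- strain_rate_summary(list(cv), rates = 0.05,
                             windows = list(c(0.05, 0.10)))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$E, youngs_modulus(cv, c(0.05, 0.10))$E)

  # analytic KV at three rates: apparent low-strain modulus grows with rate
  c_eff <- 2e3  # c l0 / A in Pa s
  rates <- c(0.025, 0.05, 0.1)
  curves <- lapply(rates, function(r)
    stress_strain_curve(eps, 50e3 * eps + c_eff * r, A = 1, l0 = 1))
  tab2 <- strain_rate_summary(curves, rates = rates,
                              windows = list(c(0, 0.10)))
  # pure rate offset does not change the slope; elastic rate-independence
  expect_equal(tab2$E, rep(50e3, 3), tolerance = 1e-10)
})

test_that("trace curves use the coil force at the measured state", {
  s <- tissue_scale_sample(5)
  ref <- make_reference("ramp", strain_rate = 0.02, target_strain = 0.05,
                        l0 = s$l0)
  tr <- run_closed_loop(s, ref, duration = 4, seed = 8, ccd = quiet_ccd())
  cv <- trace_to_curve(tr)
  i <- 300
  F_expect <- coil_force(tr$x_start - tr$data$q_meas_m[i],
                         tr$data$I_A[i], tr$magnet, tr$bead)
  expect_equal(cv$stress[i], F_expect / s$A, tolerance = 1e-12)
  expect_equal(cv$strain[i], tr$data$q_meas_m[i] / s$l0, tolerance = 1e-12)
})
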