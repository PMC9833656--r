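test_that("physiological strain is residual plus applied", {
  expect_equal(physiological_strain(0.02, 0.43), 0.45)   # stroma
  expect_equal(physiological_strain(-0.21, 0.43), 0.22)  # epithelium
  expect_equal(physiological_strain(0, 0.37), 0.37)
  expect_error(physiological_strain(-1.2, 0.4), "exceed -1")
  expect_error(physiological_strain(0.1, -0.1), "non-negative")
})

test_that("iso-strain composite modulus is a thickness-weighted mean", {
  l1 <- tissue_layer("a", h = 100, eps_R = 0, E_P = 4e3)
  l2 <- tissue_layer("b", h = 300, eps_R = 0, E_P = 8e3)

  expect_equal(composite_modulus(composite_wall(list(l1))), 4e3)
  expect_equal(composite_modulus(composite_wall(list(l1, l2))),
               (100 * 4e3 + 300 * 8e3) / 400)

  # equal moduli collapse to that modulus
  l3 <- tissue_layer("c", h = 55, eps_R = 0, E_P = 4e3)
  expect_equal(composite_modulus(composite_wall(list(l1, l3))), 4e3)

  # bounded by the layer moduli and permutation invariant
  set.seed(9)
  for (i in 1:20) {
    ls <- lapply(1:4, function(j)
      tissue_layer(paste0("l", j), h = runif(1, 10, 300),
                   eps_R = runif(1, -0.3, 0.3), E_P = runif(1, 1e3, 2e4)))
    E <- composite_modulus(composite_wall(ls))
    Es <- vapply(ls, function(l) l$E_P, numeric(1))
    expect_gte(E, min(Es)); expect_lte(E, max(Es))
    expect_equal(composite_modulus(composite_wall(rev(ls))), E)
  }

  expect_error(composite_modulus(composite_wall(list(
    tissue_layer("x", h = 10, eps_R = 0)))), "no modulus")
})

test_that("the packaged layer table reproduces the wall predictions", {
  tab <- esophagus_layers()
  expect_true(all(c("epithelium", "stroma", "muscle") %in% tab$layer))
  # layer thicknesses are consistent with the intact wall (within 5%)
  h_sum <- sum(tab$h_um[tab$layer %in% c("epithelium_stroma", "muscle")])
  h_wall <- tab$h_um[tab$layer == "esophagus_experimental"]
  expect_lt(abs(h_sum - h_wall) / h_wall, 0.05)

  # two-layer: weighted mean of (83.44, 9.68) and (229.03, 3.26) kPa
  p2 <- predict_wall_modulus("two")
  expect_equal(p2$E_wall_kPa,
               (83.44 * 9.68 + 229.03 * 3.26) / (83.44 + 229.03),
               tolerance = 1e-12)
  expect_lt(abs(p2$E_wall_kPa - p2$reported_kPa), p2$reported_sd_kPa)

  # three-layer prediction sits inside its reported standard deviation and
  # below the two-layer one (splitting the inner layer softens the mean)
  p3 <- predict_wall_modulus("three")
  expect_lt(abs(p3$E_wall_kPa - p3$reported_kPa), p3$reported_sd_kPa)
  expect_lt(p3$E_wall_kPa, p2$E_wall_kPa)
})

test_that("composite curves evaluate layers at residual-shifted strains", {
  law <- function(eps) 5e3 * eps
  l1 <- tissue_layer("a", h = 100, eps_R = 0, E_P = 5e3, law = law)
  l2 <- tissue_layer("b", h = 200, eps_R = 0, E_P = 5e3, law = law)
  eps <- seq(0, 0.5, by = 0.01)

  # identical laws, zero residuals: wall curve equals the layer curve
  cw <- composite_curve(composite_wall(list(l1, l2)), eps)
  expect_equal(cw$stress, law(eps))

  # linear laws: tangent of the composite equals the modulus mixture
  law2 <- function(eps) 12e3 * eps
  l3 <- tissue_layer("c", h = 200, eps_R = -0.1, E_P = 12e3, law = law2)
  cw2 <- composite_curve(composite_wall(list(l1, l3)), eps)
  slope <- diff(cw2$stress) / diff(cw2$strain)
  expect_equal(mean(slope), (100 * 5e3 + 200 * 12e3) / 300,
               tolerance = 1e-10)

  # exponential laws with tangents matched to the layer moduli at their
  # physiological strains: wall tangent at the applied strain agrees with
  # composite_modulus within 1%
  tab <- esophagus_layers()
  eps_S <- tab$eps_S[tab$layer == "esophagus_experimental"]
  rows <- tab[match(c("epithelium", "stroma", "muscle"), tab$layer), ]
  layers <- lapply(seq_len(nrow(rows)), function(i) {
    E_P <- rows$E_P_kPa[i] * 1e3
    eps_P <- rows$eps_P[i]
    E0 <- E_P / 3
    B <- log(3) / eps_P
    tissue_layer(rows$layer[i], h = rows$h_um[i], eps_R = rows$eps_R[i],
                 E_P = E_P,
                 law = function(e) stiffening_stress(e, E0, B))
  })
  wall <- composite_wall(layers, eps_S = eps_S)
  h <- 1e-6
  cwt <- composite_curve(wall, c(eps_S - h, eps_S + h))
  tangent <- diff(cwt$stress) / (2 * h)
  expect_equal(tangent, composite_modulus(wall), tolerance = 0.01)
})
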