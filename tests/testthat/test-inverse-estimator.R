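test_that("residual functions all equal nu on model-consistent strains", {
  g <- ventricle_geometry(2.5, 1.0)
  ld <- loading_state(2000)
  # consistent chain: stresses AND strains at the same (E, nu)
  s <- ellipsoid_stresses_k1(g, ld, 0.6)
  tr <- hooke_strains(s, elastic_moduli(7000, 0.6))
  f <- residual_functions(7000, 0.6, s, tr)
  expect_equal(f$f1, 0.6, tolerance = 1e-12)
  expect_equal(f$f2, 0.6, tolerance = 1e-12)
  expect_equal(f$f3, 0.6, tolerance = 1e-12)

  # property over random truths
  cases <- random_cases(50, seed = 41)
  for (i in seq_len(nrow(cases))) {
    E <- runif(1, 2000, 15000); nu <- cases$nu[i]
    cc <- consistent_case(E, nu, cases$R0[i], cases$T[i], cases$P[i])
    if (is.null(cc)) next
    s <- ellipsoid_stresses_k1(cc$geom, cc$load, nu)
    f <- residual_functions(E, nu, s, cc$strain)
    expect_equal(c(f$f1, f$f2, f$f3), rep(nu, 3), tolerance = 1e-10)
  }
})

test_that("f1 vanishes when E equals sigma_rr over eps_rr", {
  g <- ventricle_geometry(2.5, 1.0)
  s <- ellipsoid_stresses_k1(g, loading_state(2000), 0.4)
  tr <- strain_triplet(-0.2, 0.15, 0.08)
  E0 <- s$sigma_rr / tr$eps_rr
  f <- residual_functions(E0, 0.4, s, tr)
  expect_equal(f$f1, 0, tolerance = 1e-14)
})

test_that("cost is zero with zero gradient at exact consistency, nonnegative elsewhere", {
  g <- ventricle_geometry(2.5, 1.0)
  ld <- loading_state(2000)
  s <- ellipsoid_stresses_k1(g, ld, 0.6)
  tr <- hooke_strains(s, elastic_moduli(7000, 0.6))
  ce <- cost_index(7000, 0.6, s, tr)
  expect_lt(ce$J, 1e-24)
  expect_lt(abs(ce$dJ_dE) * 7000, 1e-10)
  expect_lt(abs(ce$dJ_dnu), 1e-10)

  set.seed(5)
  for (i in 1:100) {
    ce <- cost_index(runif(1, 100, 3e4), runif(1, -0.9, 1.4), s, tr)
    expect_gte(ce$J, 0)
  }
})

test_that("analytic gradient matches central finite differences", {
  g <- ventricle_geometry(2.5, 1.0)
  ld <- loading_state(2000)
  s <- ellipsoid_stresses_k1(g, ld, 0.55)
  tr <- hooke_strains(s, elastic_moduli(6500, 0.55))
  # perturb strains so the cost surface is generic, not at its minimum
  trn <- strain_triplet(tr$eps_rr * 1.07, tr$eps_tt * 0.93, tr$eps_pp * 1.1)
  set.seed(7)
  for (i in 1:200) {
    E <- exp(runif(1, log(500), log(3e4)))
    nu <- runif(1, -0.9, 1.4)
    ce <- cost_index(E, nu, s, trn)
    hE <- E * 1e-6; hN <- 1e-6
    fdE <- (cost_index(E + hE, nu, s, trn)$J -
            cost_index(E - hE, nu, s, trn)$J) / (2 * hE)
    fdN <- (cost_index(E, nu + hN, s, trn)$J -
            cost_index(E, nu - hN, s, trn)$J) / (2 * hN)
    expect_lt(abs(ce$dJ_dE - fdE) / (1 + abs(ce$dJ_dE)), 1e-6)
    expect_lt(abs(ce$dJ_dnu - fdN) / (1 + abs(ce$dJ_dnu)), 1e-6)
  }
})

test_that("forward-inverse round trips recover the generating moduli", {
  g <- ventricle_geometry(2.5, 1.0)
  ld <- loading_state(2000)
  tr <- forward_strains(g, ld, elastic_moduli(7000, 0.6))
  est <- estimate_moduli(g, ld, tr, estimator_config(seed = 1))
  expect_lt(abs(est$moduli$E - 7000) / 7000, 1e-6)
  expect_lt(abs(est$moduli$nu - 0.6) / 0.6, 1e-6)
  expect_lt(est$J_final, 1e-12)
  expect_true(est$converged)
  expect_identical(est$model, "ellipsoid")

  # published older-hypertensive group means as geometry and pressure
  g2 <- ventricle_geometry(R0 = 5.23 / 2, T = 0.91)
  ld2 <- derive_pressure(list(e_over_eprime = 11.39))
  tr2 <- forward_strains(g2, ld2, elastic_moduli(8000, 0.73))
  est2 <- estimate_moduli(g2, ld2, tr2, estimator_config(seed = 2))
  expect_lt(abs(est2$moduli$E - 8000) / 8000, 1e-6)
  expect_lt(abs(est2$moduli$nu - 0.73) / 0.73, 1e-6)
})

test_that("recovered modulus is covariant with pressure scaling", {
  g <- ventricle_geometry(2.4, 0.9)
  ld <- loading_state(1500)
  tr <- forward_strains(g, ld, elastic_moduli(6000, 0.5))
  base <- estimate_moduli(g, ld, tr, estimator_config(seed = 3))
  for (c in c(0.5, 3)) {
    est <- estimate_moduli(g, loading_state(1500 * c), tr,
                           estimator_config(seed = 3))
    expect_lt(abs(est$moduli$E - c * base$moduli$E) / (c * base$moduli$E),
              1e-6)
    expect_lt(abs(est$moduli$nu - base$moduli$nu), 1e-6)
  }
})

test_that("identical seeds give bit-identical estimates", {
  g <- ventricle_geometry(2.5, 1.0)
  ld <- loading_state(1800)
  tr <- strain_triplet(-0.35, 0.21, 0.09)
  a <- estimate_moduli(g, ld, tr, estimator_config(seed = 99))
  b <- estimate_moduli(g, ld, tr, estimator_config(seed = 99))
  expect_identical(a$moduli$E, b$moduli$E)
  expect_identical(a$moduli$nu, b$moduli$nu)
  expect_identical(a$diagnostics, b$diagnostics)
})

test_that("optimizer never loses to a dense grid search on noisy input", {
  g <- ventricle_geometry(2.5, 1.0)
  ld <- loading_state(2000)
  tr <- forward_strains(g, ld, elastic_moduli(7000, 0.6))
  set.seed(13)
  for (i in 1:3) {
    noisy <- strain_triplet(tr$eps_rr + rnorm(1, 0, 0.02),
                            tr$eps_tt + rnorm(1, 0, 0.02),
                            tr$eps_pp + rnorm(1, 0, 0.02))
    est <- estimate_moduli(g, ld, noisy, estimator_config(seed = i))
    grid <- cost_grid_min(g, ld, noisy, estimator_config(seed = i), n = 120L)
    expect_lte(est$J_final, grid$J_min + 1e-15)
  }
})

test_that("estimator rejects unusable inputs", {
  g <- ventricle_geometry(2.5, 1.0, kappa = 1)
  ld <- loading_state(2000)
  expect_error(estimate_moduli(g, ld, strain_triplet(-0.2, 0, 0)),
               "at least two directions")
  g2 <- ventricle_geometry(2.5, 1.0, kappa = 1.2)
  expect_error(estimate_moduli(g2, ld, strain_triplet(-0.2, 0.1, 0.05)),
               "kappa = 1")
})
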