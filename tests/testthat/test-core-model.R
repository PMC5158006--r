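test_that("shell coefficients match their closed forms at key points", {
  co <- shell_coefficients(kappa = 1, nu = 0.3)
  expect_identical(co$n, 9)
  expect_equal(co$C0, 0.65)
  expect_identical(co$C1, 0)

  # at kappa = 1 the exponent is independent of Poisson's ratio
  for (nu in c(0, 0.1, 0.49, 0.73)) {
    co <- shell_coefficients(1, nu)
    expect_identical(co$n, 9)
    expect_identical(co$C1, 0)
    expect_equal(co$C0, (1 + nu) / 2)
  }

  # hand-evaluated non-spherical case
  co2 <- shell_coefficients(kappa = 2, nu = 0)
  expect_equal(co2$n, (4 + 5 * 4) / 4)
  expect_equal(co2$C0, 2 / 3)
  expect_identical(co2$C1, 0)
})

test_that("degenerate shell-coefficient inputs are rejected", {
  expect_error(shell_coefficients(1, 1), "degenerate")
  expect_error(shell_coefficients(0, 0.3), "degenerate")
})

test_that("equatorial-plane stresses reproduce the arithmetic oracle", {
  g <- ventricle_geometry(R0 = 2.5, T = 1.0)
  s <- ellipsoid_stresses_k1(g, loading_state(2000), nu = 0.5)
  # values pinned from a direct transcription of the closed form
  expect_equal(s$A, 175.77904360679639, tolerance = 1e-12)
  expect_equal(s$B, 21.016997139028604, tolerance = 1e-12)
  expect_equal(s$sigma_rr, -528.08406603101412, tolerance = 1e-12)
  expect_equal(s$sigma_tt, 2111.0558037629849, tolerance = 1e-12)
  expect_equal(s$sigma_pp, 1583.2918528222388, tolerance = 1e-12)

  o <- oracle_k1(2.5, 1.0, 2000, 0.5)
  expect_equal(s$sigma_rr, o$srr, tolerance = 1e-14)
  expect_equal(s$sigma_tt, o$stt, tolerance = 1e-14)
  expect_equal(s$sigma_pp, o$spp, tolerance = 1e-14)
})

test_that("radial stress meets the pressure boundary conditions", {
  cases <- random_cases(500, seed = 11)
  for (i in seq_len(nrow(cases))) {
    g <- ventricle_geometry(cases$R0[i], cases$T[i])
    ld <- loading_state(cases$P[i])
    inner <- ellipsoid_stresses(g, ld, cases$nu[i], at_radius = g$R0)
    outer <- ellipsoid_stresses(g, ld, cases$nu[i], at_radius = g$R0 + g$T)
    expect_lt(abs(inner$sigma_rr + ld$P) / ld$P, 1e-10)
    expect_lt(abs(outer$sigma_rr) / ld$P, 1e-10)
  }
  # the boundary conditions hold for non-spherical latitude planes too
  set.seed(12)
  for (i in 1:200) {
    g <- ventricle_geometry(runif(1, 1.5, 3.5), runif(1, 0.4, 1.6),
                            kappa = runif(1, 0.5, 2))
    P <- runif(1, 800, 3000)
    inner <- ellipsoid_stresses(g, loading_state(P), runif(1, -0.5, 0.9),
                                at_radius = g$R0)
    expect_lt(abs(inner$sigma_rr + P) / P, 1e-10)
  }
})

test_that("the general solution reduces to the kappa = 1 closed form", {
  cases <- random_cases(300, seed = 21)
  for (i in seq_len(nrow(cases))) {
    g <- ventricle_geometry(cases$R0[i], cases$T[i])
    ld <- loading_state(cases$P[i])
    gen <- ellipsoid_stresses(g, ld, cases$nu[i])
    k1 <- ellipsoid_stresses_k1(g, ld, cases$nu[i])
    expect_equal(gen$sigma_rr, k1$sigma_rr, tolerance = 1e-12)
    expect_equal(gen$sigma_tt, k1$sigma_tt, tolerance = 1e-12)
    expect_equal(gen$sigma_pp, k1$sigma_pp, tolerance = 1e-12)
  }
})

test_that("in-plane stresses sum to A*B and coincide only at nu = 1", {
  cases <- random_cases(200, seed = 31)
  for (i in seq_len(nrow(cases))) {
    g <- ventricle_geometry(cases$R0[i], cases$T[i])
    s <- ellipsoid_stresses_k1(g, loading_state(cases$P[i]), cases$nu[i])
    expect_equal(s$sigma_tt + s$sigma_pp, s$A * s$B, tolerance = 1e-12)
  }
  g <- ventricle_geometry(2.5, 1.0)
  s1 <- ellipsoid_stresses_k1(g, loading_state(2000), nu = 1)
  expect_equal(s1$sigma_tt, s1$sigma_pp, tolerance = 1e-14)
  s2 <- ellipsoid_stresses_k1(g, loading_state(2000), nu = 0.4)
  expect_gt(abs(s2$sigma_tt - s2$sigma_pp), 1)
})

test_that("stresses scale linearly with pressure at fixed geometry", {
  g <- ventricle_geometry(2.2, 0.8)
  base <- ellipsoid_stresses_k1(g, loading_state(1000), 0.6)
  for (c in c(0.5, 2, 7.3)) {
    s <- ellipsoid_stresses_k1(g, loading_state(1000 * c), 0.6)
    expect_equal(s$sigma_rr, c * base$sigma_rr, tolerance = 1e-13)
    expect_equal(s$sigma_tt, c * base$sigma_tt, tolerance = 1e-13)
    expect_equal(s$sigma_pp, c * base$sigma_pp, tolerance = 1e-13)
  }
})

test_that("Hooke strains match the oracle, vanish unloaded, scale linearly", {
  s0 <- stress_triplet(0, 0, 0, A = 1, B = 0)
  z <- hooke_strains(s0, elastic_moduli(7000, 0.6))
  expect_identical(c(z$eps_rr, z$eps_tt, z$eps_pp), c(0, 0, 0))

  g <- ventricle_geometry(2.5, 1.0)
  s <- ellipsoid_stresses_k1(g, loading_state(2000), nu = 0.5)
  tr <- hooke_strains(s, elastic_moduli(7000, 0.6))
  # pinned: (sigma_rr - 0.6 * A*B) / 7000 with A*B = sigma_tt + sigma_pp
  expect_equal(tr$eps_rr, -0.39209895142602114, tolerance = 1e-12)
  o <- oracle_hooke(s$sigma_rr, s$sigma_tt, s$sigma_pp, 7000, 0.6)
  expect_equal(c(tr$eps_rr, tr$eps_tt, tr$eps_pp), unname(o),
               tolerance = 1e-14)

  # linearity: scaling the stresses scales the strains
  s2 <- stress_triplet(s$sigma_rr * 0.5, s$sigma_tt * 0.5, s$sigma_pp * 0.5)
  tr2 <- hooke_strains(s2, elastic_moduli(7000, 0.6))
  expect_equal(tr2$eps_rr, tr$eps_rr * 0.5, tolerance = 1e-14)
  expect_equal(tr2$eps_tt, tr$eps_tt * 0.5, tolerance = 1e-14)
})

test_that("invalid geometry and radii are rejected with clear errors", {
  expect_error(ventricle_geometry(-1, 1), "R0")
  expect_error(ventricle_geometry(2, 0), "thickness")
  expect_error(ventricle_geometry(2, 1, R_mid = 3.5), "R_mid")
  g <- ventricle_geometry(2.5, 1.0)
  expect_error(ellipsoid_stresses(g, loading_state(2000), 0.3, at_radius = 4),
               "outside the wall")
  expect_error(loading_state(0), "positive")
  expect_error(hooke_strains(stress_triplet(1, 1, 1),
                             structure(list(E = -1, nu = 0.3),
                                       class = "elastic_moduli")),
               "positive")
})
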