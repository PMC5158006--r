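test_that("geometry derivation halves LVIDd and takes the posterior wall", {
  m <- fixture_measurement()
  g <- derive_geometry(m)
  expect_equal(g$R0, 2.615)
  expect_equal(g$T, 0.91)
  expect_equal(g$R_mid, (2 * 2.615 + 0.91) / 2)
  expect_identical(g$kappa, 1)

  m2 <- fixture_measurement(); m2$LVIDd <- 4.92
  expect_equal(derive_geometry(m2)$R0, 2.46)

  m3 <- fixture_measurement(); m3$LVIDs <- m3$LVIDd + 0.1
  expect_error(derive_geometry(m3), "LVIDd must exceed LVIDs")
})

test_that("pressure conversion is the documented affine map", {
  expect_equal(derive_pressure(list(e_over_eprime = 9.06))$P,
               (1.9 + 1.24 * 9.06) / 0.0075, tolerance = 1e-14)
  expect_equal(derive_pressure(list(e_over_eprime = 9.06))$P,
               1751.2533333333333, tolerance = 1e-12)
  # affine: numeric slope and intercept
  p1 <- derive_pressure(list(e_over_eprime = 1))$P
  p2 <- derive_pressure(list(e_over_eprime = 2))$P
  expect_equal(p2 - p1, 1.24 / 0.0075, tolerance = 1e-10)
  expect_equal(2 * p1 - p2, 1.9 / 0.0075, tolerance = 1e-10)
  expect_error(derive_pressure(list(e_over_eprime = -2)), "positive")
  # typical clinical ratios land in the low-kPa filling-pressure range
  for (ee in c(7, 9, 12))
    expect_true(derive_pressure(list(e_over_eprime = ee))$P > 1000 &&
                derive_pressure(list(e_over_eprime = ee))$P < 2500)
})

test_that("strain derivation converts percents once and honors conventions", {
  m <- fixture_measurement()
  tr <- derive_strains(m, "echo")
  expect_equal(tr$eps_rr, (5.23 - 3.08) / 5.23, tolerance = 1e-14)
  expect_equal(tr$eps_tt, -0.1746)
  expect_equal(tr$eps_pp, -0.1764)

  trm <- derive_strains(m, "model")
  expect_equal(trm$eps_rr, -tr$eps_rr)
  expect_equal(trm$eps_tt, 0.1746)
  expect_equal(trm$eps_pp, 0.1764)

  m0 <- fixture_measurement(); m0$LVIDs <- m0$LVIDd - 1e-9
  expect_equal(derive_strains(m0, "echo")$eps_rr, 0, tolerance = 1e-8)
})

test_that("cohort reading validates rows without dropping them", {
  path <- fixture_cohort_csv()
  tbl <- read_cohort(path)
  expect_s3_class(tbl, "cohort_table")
  expect_identical(nrow(tbl), 4L)
  expect_identical(nrow(attr(tbl, "validation")), 0L)

  # an invalid row is kept and reported, counts in = counts out
  df <- fixture_cohort_df()
  df$LVIDs_cm[2] <- df$LVIDd_cm[2] + 1
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  tbl2 <- read_cohort(p2)
  expect_identical(nrow(tbl2), 4L)
  rep <- attr(tbl2, "validation")
  expect_identical(rep$row, 2L)
  expect_match(rep$problem, "LVIDd must exceed LVIDs")
})

test_that("missing columns are named and alternatives are mapped", {
  df <- fixture_cohort_df(); df$LVPWd_cm <- NULL
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_cohort(p), "LVPWd_cm")

  df2 <- fixture_cohort_df()
  names(df2)[names(df2) == "LVIDd_cm"] <- "lv_dim_diastole"
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df2, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "LVIDd_cm")
  tbl <- read_cohort(p2, col_map = list(LVIDd_cm = "lv_dim_diastole"))
  expect_identical(nrow(tbl), 4L)

  # medial/lateral e/e' columns averaged when the mean column is absent
  df3 <- fixture_cohort_df()
  df3$e_over_eprime_medial <- df3$e_over_eprime + 1
  df3$e_over_eprime_lateral <- df3$e_over_eprime - 1
  df3$e_over_eprime <- NULL
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(df3, p3, row.names = FALSE)
  tbl3 <- read_cohort(p3)
  expect_equal(tbl3$e_over_eprime, fixture_cohort_df()$e_over_eprime)
})

test_that("read-write-read is an identity and preserves unknown columns", {
  df <- fixture_cohort_df()
  df$site <- c("A", "A", "B", "B")
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  t1 <- read_cohort(p)
  p2 <- tempfile(fileext = ".csv")
  write_cohort(t1, p2)
  t2 <- read_cohort(p2)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_true("site" %in% names(t2))
})

test_that("cohort estimation appends results and survives bad rows", {
  df <- fixture_cohort_df()
  df$LVPWd_cm[3] <- -1
  res <- estimate_cohort(as_cohort_table(df),
                         estimator_config(seed = 1, sign_convention = "model"))
  expect_identical(nrow(res), 4L)
  expect_true(all(c("E_Pa", "poisson", "J_final", "model", "converged",
                    "note") %in% names(res)))
  expect_false(res$converged[3])
  expect_true(is.na(res$E_Pa[3]))
  expect_match(res$note[3], "LVPWd")
  expect_true(all(is.finite(res$E_Pa[-3])))
})
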