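# Independent oracles and fixture builders shared across the suite.
# The oracles transcribe the closed-form equations directly and stay
# separate from the package's code paths.

# Direct transcription of the equatorial-plane (kappa = 1) stress
# equations; arithmetic oracle for the shell solution.
oracle_k1 <- function(R0, T, P, nu, R = (2 * R0 + T) / 2) {
  A <- P * R0^6 * R^3 / ((R0 + T)^9 - R0^9)
  B <- (5 * R^9 + 4 * (R0 + T)^9) / R^9
  list(A = A, B = B,
       srr = A * (R^9 - (R0 + T)^9) / R^9,
       stt = (2 / (3 + nu)) * A * B,
       spp = ((1 + nu) / (3 + nu)) * A * B)
}

# Hooke's-law oracle.
oracle_hooke <- function(srr, stt, spp, E, nu) {
  c(err = (srr - nu * (stt + spp)) / E,
    ett = (stt - nu * (srr + spp)) / E,
    epp = (spp - nu * (srr + stt)) / E)
}

# Lame plane-strain cylinder oracle.
oracle_lame <- function(a, b, P, r) {
  k <- P * a^2 / (b^2 - a^2)
  c(srr = k * (1 - b^2 / r^2), stt = k * (1 + b^2 / r^2))
}

# Random physiological-scale geometry/loading draws.
random_cases <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(R0 = runif(n, 1.5, 3.5), T = runif(n, 0.4, 1.6),
             P = runif(n, 800, 3000), nu = runif(n, -0.5, 0.9))
}

# Model-consistent forward strains at given truth, with rejection of
# draws the linear model cannot represent (|strain| >= 1).
consistent_case <- function(E, nu, R0, T, P) {
  g <- ventricle_geometry(R0, T)
  ld <- loading_state(P)
  tr <- tryCatch(forward_strains(g, ld, elastic_moduli(E, nu)),
                 error = function(e) NULL)
  if (is.null(tr)) return(NULL)
  list(geom = g, load = ld, strain = tr)
}

# Minimal valid measurement list (older hypertensive group means).
fixture_measurement <- function() {
  list(subject_id = "S1", age = 71, sex = "F", htn = 1L,
       LVIDd = 5.23, LVIDs = 3.08, LVPWd = 0.91, IVSd = 1.03,
       e_over_eprime = 11.39, GLS = -17.64, GCS = -17.46)
}

# Four-row cohort file mirroring the four published strata means.
fixture_cohort_df <- function() {
  data.frame(
    subject_id = c("YN", "ON", "YP", "OP"),
    age = c(50.2, 70.3, 49.4, 71.7),
    sex = c("M", "F", "M", "F"),
    htn = c(0L, 0L, 1L, 1L),
    sbp = c(120.2, 129.7, 143.1, 151.3),
    dbp = c(83.0, 82.7, 85.5, 87.4),
    LVIDd_cm = c(4.92, 5.01, 4.74, 5.23),
    LVIDs_cm = c(2.97, 3.14, 2.58, 3.08),
    LVPWd_cm = c(0.82, 0.88, 0.94, 0.91),
    IVSd_cm = c(0.77, 0.81, 0.95, 1.03),
    e_over_eprime = c(7.22, 9.78, 8.01, 11.39),
    GLS_pct = c(-20.02, -18.00, -18.59, -17.64),
    GCS_pct = c(-20.65, -19.11, -18.86, -17.46),
    stringsAsFactors = FALSE)
}

fixture_cohort_csv <- function(path = tempfile(fileext = ".csv")) {
  utils::write.csv(fixture_cohort_df(), path, row.names = FALSE)
  path
}
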