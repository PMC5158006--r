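#' Ventricle geometry for the thick-walled ellipsoidal shell model
#'
#' Bundles the geometric inputs of the shell stress solution: the
#' endocardial radius of curvature `R0`, the wall thickness `T`, the
#' stress-evaluation radius `R_mid`, and the ellipsoid shape ratio
#' `kappa`. The equatorial latitude plane corresponds to `kappa = 1`,
#' which is the configuration used for clinical estimation; the midwall
#' evaluation radius defaults to `(2 * R0 + T) / 2`.
#'
#' @param R0 Endocardial radius of curvature in cm. Clinically
#'   `LVIDd / 2` (see [derive_geometry()]).
#' @param T Wall thickness in cm. Clinically `LVPWd`.
#' @param R_mid Radius at which stresses are evaluated, in cm. Must lie
#'   strictly inside the wall. Default is the midwall radius
#'   `(2 * R0 + T) / 2`.
#' @param kappa Dimensionless ellipsoid shape ratio; `1` selects the
#'   equatorial latitude plane.
#' @return An object of class `ventricle_geometry`: a list with fields
#'   `R0`, `T`, `R_mid`, `kappa` (all numeric scalars).
#' @examples
#' ventricle_geometry(R0 = 5.23 / 2, T = 0.91)
#' @seealso [ellipsoid_stresses()], [derive_geometry()]
#' @export
ventricle_geometry <- function(R0, T, R_mid = (2 * R0 + T) / 2, kappa = 1) {
  stopifnot(is.numeric(R0), is.numeric(T), is.numeric(R_mid), is.numeric(kappa),
            length(R0) == 1L, length(T) == 1L, length(R_mid) == 1L,
            length(kappa) == 1L)
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be a positive finite radius (cm)")
  if (!is.finite(T) || T <= 0) stop("wall thickness T must be positive (cm)")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  if (!(R_mid > R0 && R_mid < R0 + T))
    stop("R_mid must lie strictly inside the wall: R0 < R_mid < R0 + T")
  structure(list(R0 = R0, T = T, R_mid = R_mid, kappa = kappa),
            class = "ventricle_geometry")
}

#' @export
print.ventricle_geometry <- function(x, ...) {
  cat(sprintf(
    "Ventricle geometry: R0 = %.4g cm, T = %.4g cm, R_mid = %.4g cm, kappa = %.3g\n",
    x$R0, x$T, x$R_mid, x$kappa))
  invisible(x)
}

#' Intraventricular loading state
#'
#' The internal pressure acting on the endocardial surface; the outer
#' surface is traction-free. Optionally records the e/e' ratio the
#' pressure was derived from (see [derive_pressure()]).
#'
#' @param P Internal pressure in Pa.
#' @param e_over_eprime Optional e/e' ratio of provenance (dimensionless).
#' @return An object of class `loading_state` with fields `P` and
#'   `e_over_eprime`.
#' @export
loading_state <- function(P, e_over_eprime = NA_real_) {
  stopifnot(is.numeric(P), length(P) == 1L)
  if (!is.finite(P) || P <= 0) stop("internal pressure P must be positive (Pa)")
  structure(list(P = P, e_over_eprime = as.numeric(e_over_eprime)),
            class = "loading_state")
}

#' @export
print.loading_state <- function(x, ...) {
  cat(sprintf("Loading state: P = %.6g Pa", x$P))
  if (is.finite(x$e_over_eprime))
    cat(sprintf(" (from e/e' = %.3g)", x$e_over_eprime))
  cat("\n")
  invisible(x)
}

#' Elastic moduli of the myocardium
#'
#' @param E Young's modulus in Pa; must be positive.
#' @param nu Poisson's ratio, dimensionless. Normal isotropic materials
#'   have `nu` in (-1, 0.5]; the estimator's feasibility window is wider
#'   (see [estimator_config()]) because clinically reported values reach
#'   above 0.5.
#' @return An object of class `elastic_moduli` with fields `E` and `nu`.
#' @export
elastic_moduli <- function(E, nu) {
  stopifnot(is.numeric(E), is.numeric(nu), length(E) == 1L, length(nu) == 1L)
  if (!is.finite(E) || E <= 0) stop("Young's modulus E must be positive (Pa)")
  if (!is.finite(nu)) stop("Poisson's ratio nu must be finite")
  structure(list(E = E, nu = nu), class = "elastic_moduli")
}

#' @export
print.elastic_moduli <- function(x, ...) {
  cat(sprintf("Elastic moduli: E = %.6g Pa, nu = %.4g\n", x$E, x$nu))
  invisible(x)
}

#' Shell coefficients of the ellipsoidal stress solution
#'
#' Evaluates the exponent `n` and the coefficients `C0`, `C1` that govern
#' the stress field of a pressurized thick-walled ellipsoidal shell at a
#' latitude plane with shape ratio `kappa`:
#' \deqn{n = \frac{4\kappa\nu(1-\kappa) + (1-\nu)(4+5\kappa^2)}{\kappa^2(1-\nu)},
#'   \quad C_0 = \frac{\kappa+\nu}{1+\kappa}, \quad
#'   C_1 = \frac{\nu(1-\kappa)}{1+\kappa\nu}.}
#' At the equatorial plane (`kappa = 1`) these collapse to `n = 9`,
#' `C0 = (1 + nu) / 2`, `C1 = 0` for every Poisson ratio.
#'
#' @param kappa Positive shape ratio.
#' @param nu Poisson's ratio; `nu = 1` makes the `n` denominator vanish
#'   and is rejected.
#' @return An object of class `shell_coefficients`: list with numeric
#'   fields `n`, `C0`, `C1`.
#' @examples
#' shell_coefficients(kappa = 1, nu = 0.3)  # n = 9, C0 = 0.65, C1 = 0
#' @export
shell_coefficients <- function(kappa, nu) {
  stopifnot(is.numeric(kappa), is.numeric(nu), length(kappa) == 1L,
            length(nu) == 1L)
  if (!is.finite(kappa) || kappa == 0)
    stop("degenerate shell coefficients: kappa must be nonzero")
  if (!is.finite(nu) || nu == 1)
    stop("degenerate shell coefficients: nu = 1 makes the exponent denominator vanish")
  if (1 + kappa * nu == 0)
    stop("degenerate shell coefficients: 1 + kappa * nu = 0")
  n  <- (4 * kappa * nu * (1 - kappa) + (1 - nu) * (4 + 5 * kappa^2)) /
        (kappa^2 * (1 - nu))
  C0 <- (kappa + nu) / (1 + kappa)
  C1 <- nu * (1 - kappa) / (1 + kappa * nu)
  structure(list(n = n, C0 = C0, C1 = C1), class = "shell_coefficients")
}

#' @export
print.shell_coefficients <- function(x, ...) {
  cat(sprintf("Shell coefficients: n = %.6g, C0 = %.6g, C1 = %.6g\n",
              x$n, x$C0, x$C1))
  invisible(x)
}

new_stress_triplet <- function(sigma_rr, sigma_tt, sigma_pp, A, B) {
  structure(list(sigma_rr = sigma_rr, sigma_tt = sigma_tt,
                 sigma_pp = sigma_pp, A = A, B = B),
            class = "stress_triplet")
}

#' Construct a stress triplet
#'
#' Radial, circumferential and longitudinal stresses in Pa, with the
#' auxiliary quantities `A` (Pa) and `B` (dimensionless) whose product
#' `A * B` equals `sigma_tt + sigma_pp` for the equatorial-plane shell
#' solution. When `A` and `B` are not supplied they are backfilled so
#' that `A * B = sigma_tt + sigma_pp` (with `B = 1`), which keeps the
#' inverse-problem residuals well defined for externally supplied
#' stresses.
#'
#' @param sigma_rr,sigma_tt,sigma_pp Stresses in Pa (radial,
#'   circumferential, longitudinal).
#' @param A,B Optional auxiliaries of the shell solution.
#' @return An object of class `stress_triplet`.
#' @export
stress_triplet <- function(sigma_rr, sigma_tt, sigma_pp,
                           A = sigma_tt + sigma_pp, B = 1) {
  vals <- c(sigma_rr, sigma_tt, sigma_pp, A, B)
  stopifnot(is.numeric(vals), length(vals) == 5L, all(is.finite(vals)))
  new_stress_triplet(sigma_rr, sigma_tt, sigma_pp, A, B)
}

#' @export
print.stress_triplet <- function(x, ...) {
  cat(sprintf(
    "Stress triplet (Pa): sigma_rr = %.6g, sigma_tt = %.6g, sigma_pp = %.6g\n",
    x$sigma_rr, x$sigma_tt, x$sigma_pp))
  cat(sprintf("  auxiliaries: A = %.6g Pa, B = %.6g\n", x$A, x$B))
  invisible(x)
}

#' Construct a strain triplet
#'
#' Signed dimensionless strain fractions in the radial, circumferential
#' and longitudinal directions. Each strain must lie strictly inside
#' (-1, 1); the linear-elastic small-strain model is meaningless outside
#' that range.
#'
#' @param eps_rr,eps_tt,eps_pp Strain fractions (not percent).
#' @return An object of class `strain_triplet`.
#' @export
strain_triplet <- function(eps_rr, eps_tt, eps_pp) {
  vals <- c(eps_rr, eps_tt, eps_pp)
  stopifnot(is.numeric(vals), length(vals) == 3L)
  if (any(!is.finite(vals)) || any(abs(vals) >= 1))
    stop("strains must be finite fractions strictly inside (-1, 1)")
  structure(list(eps_rr = eps_rr, eps_tt = eps_tt, eps_pp = eps_pp),
            class = "strain_triplet")
}

#' @export
print.strain_triplet <- function(x, ...) {
  cat(sprintf(
    "Strain triplet: eps_rr = %.6g, eps_tt = %.6g, eps_pp = %.6g\n",
    x$eps_rr, x$eps_tt, x$eps_pp))
  invisible(x)
}

#' Stresses in a pressurized thick-walled ellipsoidal shell (general kappa)
#'
#' Evaluates the radial, circumferential and longitudinal stresses at a
#' radius inside the wall for an internally pressurized thick-walled
#' ellipsoidal shell at a latitude plane with shape ratio `kappa`, using
#' the shell coefficients from [shell_coefficients()]. With
#' \eqn{q = ((R_0+T)/r)^n} and
#' \eqn{K = P R_0^{(n+3)/2} r^{(n-3)/2} / ((R_0+T)^n - R_0^n)}:
#' \deqn{\sigma_{rr} = K (1 - q)}
#' \deqn{\sigma_{\theta\theta} = \frac{K}{C_0 + 1/\kappa}
#'   \left[\tfrac{n+1}{2} - C_1 + \left(C_1 + \tfrac{n-1}{2}\right) q\right]}
#' \deqn{\sigma_{\phi\phi} = \frac{K}{C_0 + 1/\kappa}
#'   \left[C_0 \tfrac{n+1}{2} + \tfrac{C_1}{\kappa}
#'   - \left(C_0 \tfrac{1-n}{2} + \tfrac{C_1}{\kappa}\right) q\right]}
#' The solution satisfies the boundary conditions
#' \eqn{\sigma_{rr}(R_0) = -P} and \eqn{\sigma_{rr}(R_0+T) = 0} for every
#' `kappa`, and reduces exactly to the closed equatorial-plane form of
#' [ellipsoid_stresses_k1()] at `kappa = 1`.
#'
#' @param geom A [ventricle_geometry()].
#' @param load A [loading_state()].
#' @param nu Poisson's ratio (enters through the shell coefficients).
#' @param at_radius Evaluation radius in cm; must satisfy
#'   `R0 <= at_radius <= R0 + T`. Defaults to `geom$R_mid`.
#' @return A [stress_triplet()]. The auxiliaries `A`, `B` are populated
#'   so that `A * B = sigma_tt + sigma_pp`.
#' @export
ellipsoid_stresses <- function(geom, load, nu, at_radius = geom$R_mid) {
  stopifnot(inherits(geom, "ventricle_geometry"), inherits(load, "loading_state"),
            is.numeric(nu), length(nu) == 1L, is.numeric(at_radius),
            length(at_radius) == 1L)
  R0 <- geom$R0; T <- geom$T; P <- load$P
  if (at_radius < R0 || at_radius > R0 + T)
    stop(sprintf("at_radius = %g cm lies outside the wall [%g, %g]",
                 at_radius, R0, R0 + T))
  co <- shell_coefficients(geom$kappa, nu)
  n <- co$n; C0 <- co$C0; C1 <- co$C1; kap <- geom$kappa
  r <- at_radius
  q <- ((R0 + T) / r)^n
  K <- P * R0^((n + 3) / 2) * r^((n - 3) / 2) / ((R0 + T)^n - R0^n)
  pref <- K / (C0 + 1 / kap)
  sigma_rr <- K * (1 - q)
  sigma_tt <- pref * ((n + 1) / 2 - C1 + (C1 + (n - 1) / 2) * q)
  sigma_pp <- pref * (C0 * (n + 1) / 2 + C1 / kap -
                      (C0 * (1 - n) / 2 + C1 / kap) * q)
  new_stress_triplet(sigma_rr, sigma_tt, sigma_pp,
                     A = sigma_tt + sigma_pp, B = 1)
}

#' Equatorial-plane (kappa = 1) ellipsoid stresses in closed form
#'
#' The `kappa = 1` specialization of the shell solution, evaluated at the
#' geometry's stress radius `R = geom$R_mid` (midwall by default). With
#' \deqn{A = \frac{P R_0^6 R^3}{(R_0+T)^9 - R_0^9}, \quad
#'   B = \frac{5R^9 + 4(R_0+T)^9}{R^9},}
#' the stresses are
#' \deqn{\sigma_{rr} = A\,\frac{R^9 - (R_0+T)^9}{R^9},\quad
#'   \sigma_{\theta\theta} = \frac{2}{3+\nu} A B,\quad
#'   \sigma_{\phi\phi} = \frac{1+\nu}{3+\nu} A B,}
#' so that \eqn{\sigma_{\theta\theta} + \sigma_{\phi\phi} = A B}
#' identically. The auxiliaries `A` and `B` are carried on the returned
#' triplet because the inverse-problem residuals are written in terms of
#' `A * B`.
#'
#' @inheritParams ellipsoid_stresses
#' @return A [stress_triplet()] with the exact `A` and `B` of the closed
#'   form.
#' @examples
#' g <- ventricle_geometry(R0 = 2.5, T = 1.0)
#' ellipsoid_stresses_k1(g, loading_state(2000), nu = 0.5)
#' @export
ellipsoid_stresses_k1 <- function(geom, load, nu) {
  stopifnot(inherits(geom, "ventricle_geometry"), inherits(load, "loading_state"),
            is.numeric(nu), length(nu) == 1L)
  if (geom$kappa != 1)
    stop("ellipsoid_stresses_k1 requires kappa = 1; use ellipsoid_stresses()")
  R0 <- geom$R0; T <- geom$T; P <- load$P; R <- geom$R_mid
  R9 <- R^9; Ro9 <- (R0 + T)^9; R09 <- R0^9
  A <- P * R0^6 * R^3 / (Ro9 - R09)
  B <- (5 * R9 + 4 * Ro9) / R9
  sigma_rr <- A * (R9 - Ro9) / R9
  sigma_tt <- (2 / (3 + nu)) * A * B
  sigma_pp <- ((1 + nu) / (3 + nu)) * A * B
  new_stress_triplet(sigma_rr, sigma_tt, sigma_pp, A, B)
}

#' Hooke's-law strains from a stress triplet
#'
#' Linear isotropic constitutive map from stresses to strains:
#' \deqn{\varepsilon_{rr} = \frac{1}{E}\left[\sigma_{rr} -
#'   \nu(\sigma_{\theta\theta}+\sigma_{\phi\phi})\right]} and cyclic
#' permutations for the circumferential and longitudinal components.
#' This is the forward map used to generate model-consistent synthetic
#' strains; the inverse estimator recovers `(E, nu)` from its output.
#'
#' @param stress A [stress_triplet()].
#' @param moduli An [elastic_moduli()] (requires `E > 0`).
#' @return A [strain_triplet()] in the model's own sign convention
#'   (radial compression negative under internal pressure).
#' @export
hooke_strains <- function(stress, moduli) {
  stopifnot(inherits(stress, "stress_triplet"), inherits(moduli, "elastic_moduli"))
  E <- moduli$E; nu <- moduli$nu
  if (E <= 0) stop("Young's modulus E must be positive (Pa)")
  s <- stress
  strain_triplet(
    eps_rr = (s$sigma_rr - nu * (s$sigma_tt + s$sigma_pp)) / E,
    eps_tt = (s$sigma_tt - nu * (s$sigma_rr + s$sigma_pp)) / E,
    eps_pp = (s$sigma_pp - nu * (s$sigma_rr + s$sigma_tt)) / E
  )
}

#' Model-consistent forward strains for given moduli
#'
#' Convenience composition of [ellipsoid_stresses_k1()] and
#' [hooke_strains()] at a single Poisson ratio: the stresses are
#' evaluated at `moduli$nu` and fed through Hooke's law at
#' `(moduli$E, moduli$nu)`. Strains produced this way satisfy the
#' inverse-problem residual identity exactly (all three residual
#' functions equal `nu` at the generating moduli), making this the
#' canonical generator for recovery experiments.
#'
#' @param geom A [ventricle_geometry()] with `kappa = 1`.
#' @param load A [loading_state()].
#' @param moduli An [elastic_moduli()].
#' @return A [strain_triplet()] in the model sign convention.
#' @export
forward_strains <- function(geom, load, moduli) {
  stress <- ellipsoid_stresses_k1(geom, load, moduli$nu)
  hooke_strains(stress, moduli)
}
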