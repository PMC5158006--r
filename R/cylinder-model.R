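#' Thick-walled cylinder geometry
#'
#' Geometry of the axisymmetric plane-strain cylinder used as the
#' comparison model: inner radius `a`, outer radius `b`, and the stress
#' evaluation radius `r_mid` (midwall by default, mirroring the
#' ellipsoid's midwall choice). From echo measurements, `a = LVIDd / 2`
#' and `b = a + LVPWd`.
#'
#' @param a Inner radius, cm.
#' @param b Outer radius, cm; `b > a`.
#' @param r_mid Evaluation radius, cm, strictly inside the wall; default
#'   `(a + b) / 2`.
#' @return Object of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(a, b, r_mid = (a + b) / 2) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(r_mid),
            length(a) == 1L, length(b) == 1L, length(r_mid) == 1L)
  if (!is.finite(a) || a <= 0) stop("inner radius a must be positive (cm)")
  if (!is.finite(b) || b <= a) stop("outer radius b must exceed a (cm)")
  if (!(r_mid > a && r_mid < b))
    stop("r_mid must lie strictly inside the wall: a < r_mid < b")
  structure(list(a = a, b = b, r_mid = r_mid), class = "cylinder_geometry")
}

#' @export
print.cylinder_geometry <- function(x, ...) {
  cat(sprintf("Cylinder geometry: a = %.4g cm, b = %.4g cm, r_mid = %.4g cm\n",
              x$a, x$b, x$r_mid))
  invisible(x)
}

#' Lame stresses in a pressurized thick-walled cylinder
#'
#' Classical Lame solution for an internally pressurized thick-walled
#' cylinder with a free outer surface:
#' \deqn{\sigma_{rr}(r) = \frac{P a^2}{b^2 - a^2}\left(1 - \frac{b^2}{r^2}\right),
#'   \quad
#'   \sigma_{\theta\theta}(r) = \frac{P a^2}{b^2 - a^2}\left(1 + \frac{b^2}{r^2}\right).}
#' The axial stress is not evaluated explicitly; under plane strain it is
#' eliminated from the constitutive equations inside
#' [cylinder_estimate()]. The longitudinal slot of the returned triplet
#' is therefore set to zero by convention and the strain normal to the
#' cross-section is identically zero in this model.
#'
#' @param geom A [cylinder_geometry()].
#' @param load A [loading_state()].
#' @param at_radius Evaluation radius in cm (default `geom$r_mid`).
#' @return A [stress_triplet()] with `sigma_pp = 0` (plane-strain
#'   convention, axial stress implicit).
#' @export
cylinder_stresses <- function(geom, load, at_radius = geom$r_mid) {
  stopifnot(inherits(geom, "cylinder_geometry"), inherits(load, "loading_state"))
  a <- geom$a; b <- geom$b; P <- load$P; r <- at_radius
  if (r < a || r > b)
    stop(sprintf("at_radius = %g cm lies outside the wall [%g, %g]", r, a, b))
  k <- P * a^2 / (b^2 - a^2)
  stress_triplet(sigma_rr = k * (1 - b^2 / r^2),
                 sigma_tt = k * (1 + b^2 / r^2),
                 sigma_pp = 0)
}

#' Plane-strain forward strains for the cylinder model
#'
#' The plane-strain constitutive map at the evaluation radius: with
#' `x = (1 - nu^2) / E` and `y = nu (1 + nu) / E`,
#' \deqn{\varepsilon_{rr} = x\,\sigma_{rr} - y\,\sigma_{\theta\theta},\quad
#'   \varepsilon_{\theta\theta} = x\,\sigma_{\theta\theta} - y\,\sigma_{rr},}
#' and the axial strain is identically zero. Used to generate
#' cylinder-consistent strains for exact-recovery checks.
#'
#' @param geom A [cylinder_geometry()].
#' @param load A [loading_state()].
#' @param moduli An [elastic_moduli()].
#' @return A [strain_triplet()] with `eps_pp = 0`.
#' @export
cylinder_strains <- function(geom, load, moduli) {
  s <- cylinder_stresses(geom, load)
  E <- moduli$E; nu <- moduli$nu
  x <- (1 - nu^2) / E
  y <- nu * (1 + nu) / E
  strain_triplet(eps_rr = x * s$sigma_rr - y * s$sigma_tt,
                 eps_tt = x * s$sigma_tt - y * s$sigma_rr,
                 eps_pp = 0)
}

#' Exact elasticity estimate from the cylinder model
#'
#' The plane-strain cylinder yields two linear equations in the
#' compound unknowns `x = (1 - nu^2) / E` and `y = nu (1 + nu) / E`:
#' \deqn{\varepsilon_{rr} = x\,\sigma_{rr} - y\,\sigma_{\theta\theta},\qquad
#'   \varepsilon_{\theta\theta} = x\,\sigma_{\theta\theta} - y\,\sigma_{rr},}
#' solved exactly by 2x2 elimination, after which
#' `nu = y / (x + y)` and `E = (1 - nu^2) / x`. Only the radial and
#' circumferential strains are used; the longitudinal strain has no
#' meaning under plane strain and is ignored.
#'
#' @param geom A [cylinder_geometry()].
#' @param strain A [strain_triplet()] (only `eps_rr`, `eps_tt` used).
#' @param load A [loading_state()].
#' @return An `elastic_estimate` with `model = "cylinder"`,
#'   `J_final = 0` (the solution is exact), and `converged = TRUE`.
#'   Errors on a degenerate system (`|eps_rr sigma_tt - eps_tt sigma_rr|`
#'   numerically zero relative to its terms, which includes the
#'   `eps_rr = eps_tt` boundary where `x = -y`) and on `x + y = 0` or
#'   a nonpositive recovered modulus.
#' @export
cylinder_estimate <- function(geom, strain, load) {
  stopifnot(inherits(geom, "cylinder_geometry"), inherits(strain, "strain_triplet"),
            inherits(load, "loading_state"))
  s <- cylinder_stresses(geom, load)
  srr <- s$sigma_rr; stt <- s$sigma_tt
  err <- strain$eps_rr; ett <- strain$eps_tt
  M <- matrix(c(srr, -stt,
                stt, -srr), nrow = 2, byrow = TRUE)
  det <- srr * (-srr) - (-stt) * stt   # stt^2 - srr^2
  scale <- max(abs(c(srr, stt)))^2
  if (!is.finite(det) || abs(det) <= 1e-12 * scale)
    stop("degenerate cylinder system: stresses do not separate x and y")
  xy <- solve(M, c(err, ett))
  x <- xy[1]; y <- xy[2]
  if (abs(x + y) <= 1e-12 * (abs(x) + abs(y)))
    stop("nonphysical cylinder solution: x + y = 0 (nu undefined)")
  nu <- y / (x + y)
  if (x == 0) stop("nonphysical cylinder solution: x = 0 (E undefined)")
  E <- (1 - nu^2) / x
  if (!is.finite(E) || E <= 0)
    stop("nonphysical cylinder solution: recovered modulus is not positive")
  structure(list(moduli = elastic_moduli(E, nu),
                 J_final = 0,
                 converged = TRUE,
                 grad = c(0, 0),
                 n_stationary_points = 1L,
                 model = "cylinder",
                 diagnostics = data.frame(x = x, y = y)),
            class = "elastic_estimate")
}
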