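#' Estimator configuration
#'
#' Settings for the multi-start minimization of the consistency cost.
#' The feasibility window deliberately exceeds the isotropic-material
#' range of Poisson's ratio (-1, 0.5] because clinically recovered values
#' reach above 0.7; the window is a search box, not a physical claim.
#'
#' @param E_bounds Length-2 numeric, Pa: search window for Young's
#'   modulus, `0 < low < high`. Default `c(1, 5e4)`.
#' @param nu_bounds Length-2 numeric: search window for Poisson's ratio.
#'   Default `c(-0.999, 1.5)`.
#' @param E_starts,nu_starts Multi-start grid: `E_starts` log-spaced
#'   modulus starts crossed with `nu_starts` equispaced ratio starts
#'   (defaults 8 x 6), each jittered reproducibly from `seed`.
#' @param grad_tol Scaled gradient-norm convergence tolerance (default
#'   `1e-10`).
#' @param max_iter Maximum iterations per local search (default 500).
#' @param seed Integer seed driving the start jitter; identical seeds
#'   give bit-identical estimates.
#' @param sign_convention `"echo"` (default) to take cohort strains as
#'   reported by the echo machine (radial positive, GLS/GCS negative), or
#'   `"model"` to flip them into the forward model's own convention
#'   before solving. Applied where strains are derived from measurements
#'   ([derive_strains()], [estimate_cohort()]); [estimate_moduli()]
#'   takes its strain triplet at face value.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(E_bounds = c(1, 5e4),
                             nu_bounds = c(-0.999, 1.5),
                             E_starts = 8L, nu_starts = 6L,
                             grad_tol = 1e-10, max_iter = 500L,
                             seed = 1L,
                             sign_convention = c("echo", "model")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(length(E_bounds) == 2L, length(nu_bounds) == 2L,
            E_bounds[1] > 0, E_bounds[1] < E_bounds[2],
            nu_bounds[1] < nu_bounds[2], E_starts >= 1L, nu_starts >= 1L,
            grad_tol > 0, max_iter >= 1L)
  structure(list(E_bounds = as.numeric(E_bounds),
                 nu_bounds = as.numeric(nu_bounds),
                 E_starts = as.integer(E_starts),
                 nu_starts = as.integer(nu_starts),
                 n_starts = as.integer(E_starts) * as.integer(nu_starts),
                 grad_tol = grad_tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed),
                 sign_convention = sign_convention),
            class = "estimator_config")
}

# Fixed (nu-independent) stress context of the inverse problem:
# sigma_rr and the product A*B at the evaluation radius. Only these,
# never the nu-split circumferential/longitudinal stresses, enter the
# residuals.
stress_context <- function(geom, load) {
  R0 <- geom$R0; T <- geom$T; P <- load$P; R <- geom$R_mid
  R9 <- R^9; Ro9 <- (R0 + T)^9
  A <- P * R0^6 * R^3 / (Ro9 - R0^9)
  B <- (5 * R9 + 4 * Ro9) / R9
  list(srr = A * (R9 - Ro9) / R9, AB = A * B, A = A, B = B)
}

#' Residual functions of the inverse elasticity problem
#'
#' The three consistency equations relating the shell stresses to the
#' measured strains through Hooke's law, each rearranged into a function
#' that equals Poisson's ratio when `(E, nu)` and the strains are
#' mutually consistent:
#' \deqn{f_1 = \frac{\sigma_{rr} - \varepsilon_{rr} E}{AB}, \quad
#'  f_2 = \frac{2AB/(3+\nu) - E\varepsilon_{\theta\theta}}
#'             {\sigma_{rr} + \frac{1+\nu}{3+\nu}AB}, \quad
#'  f_3 = \frac{\frac{1+\nu}{3+\nu}AB - E\varepsilon_{\phi\phi}}
#'             {\sigma_{rr} + \frac{2}{3+\nu}AB}.}
#' On strains produced by [forward_strains()] at moduli `(E*, nu*)`,
#' all three equal `nu*` exactly at `(E*, nu*)`.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson's ratio.
#' @param stress A [stress_triplet()] carrying `sigma_rr` and the
#'   auxiliaries `A`, `B`.
#' @param strain A [strain_triplet()].
#' @return Named list with `f1`, `f2`, `f3` and the two denominators
#'   `D2`, `D3`.
#' @export
residual_functions <- function(E, nu, stress, strain) {
  stopifnot(inherits(stress, "stress_triplet"), inherits(strain, "strain_triplet"))
  AB <- stress$A * stress$B
  srr <- stress$sigma_rr
  if (AB == 0) stop("singular residual: A * B = 0")
  s <- 3 + nu
  D2 <- srr + (1 + nu) / s * AB
  D3 <- srr + 2 / s * AB
  if (D2 == 0) stop("singular residual: denominator sigma_rr + (1+nu)/(3+nu) * A*B = 0")
  if (D3 == 0) stop("singular residual: denominator sigma_rr + 2/(3+nu) * A*B = 0")
  list(f1 = (srr - strain$eps_rr * E) / AB,
       f2 = (2 * AB / s - E * strain$eps_tt) / D2,
       f3 = ((1 + nu) / s * AB - E * strain$eps_pp) / D3,
       D2 = D2, D3 = D3)
}

# Vectorized cost over (E, nu) vectors; srr/AB/strains scalar.
# Singular or non-finite points get a large finite penalty so local
# searches step away from them instead of aborting.
cost_J_vec <- function(E, nu, srr, AB, err, ett, epp) {
  s <- 3 + nu
  D2 <- srr + (1 + nu) / s * AB
  D3 <- srr + 2 / s * AB
  f1 <- (srr - err * E) / AB
  f2 <- (2 * AB / s - E * ett) / D2
  f3 <- ((1 + nu) / s * AB - E * epp) / D3
  J <- 0.5 * ((nu - f1)^2 + (nu - f2)^2 + (nu - f3)^2)
  J[!is.finite(J)] <- 1e12
  J
}

# Scalar cost with analytic gradient, derived from the sum-of-squares
# form (the printed gradient display is not used; it carries a typo).
cost_eval_core <- function(E, nu, srr, AB, err, ett, epp) {
  s <- 3 + nu
  D2 <- srr + (1 + nu) / s * AB
  D3 <- srr + 2 / s * AB
  if (!is.finite(D2) || !is.finite(D3) || D2 == 0 || D3 == 0)
    return(list(J = 1e12, grad = c(0, 0), f = c(NA_real_, NA_real_, NA_real_)))
  N2 <- 2 * AB / s - E * ett
  N3 <- (1 + nu) / s * AB - E * epp
  f1 <- (srr - err * E) / AB
  f2 <- N2 / D2
  f3 <- N3 / D3
  r1 <- nu - f1; r2 <- nu - f2; r3 <- nu - f3
  J <- 0.5 * (r1^2 + r2^2 + r3^2)
  # dE
  df1_dE <- -err / AB
  df2_dE <- -ett / D2
  df3_dE <- -epp / D3
  dJ_dE <- -(r1 * df1_dE + r2 * df2_dE + r3 * df3_dE)
  # dnu: d/dnu [1/s] = -1/s^2 ; d/dnu [(1+nu)/s] = 2/s^2
  dN2 <- -2 * AB / s^2; dD2 <- 2 * AB / s^2
  dN3 <- 2 * AB / s^2;  dD3 <- -2 * AB / s^2
  df2_dnu <- (dN2 * D2 - N2 * dD2) / D2^2
  df3_dnu <- (dN3 * D3 - N3 * dD3) / D3^2
  dJ_dnu <- r1 + r2 * (1 - df2_dnu) + r3 * (1 - df3_dnu)
  list(J = J, grad = c(dJ_dE, dJ_dnu), f = c(f1, f2, f3))
}

#' Consistency cost and analytic gradient
#'
#' The scalar cost
#' \deqn{J(E, \nu) = \tfrac{1}{2}\sum_{i=1}^{3} (\nu - f_i)^2}
#' over the three residual functions of [residual_functions()], together
#' with its analytic gradient with respect to `E` and `nu`. `J` is zero
#' exactly when all three residuals simultaneously equal `nu`, i.e. when
#' the strains are Hooke-consistent with the stresses at `(E, nu)`. The
#' gradient is derived from the sum-of-squares form and is validated
#' against central finite differences in the test suite.
#'
#' @inheritParams residual_functions
#' @return Object of class `cost_evaluation`: list with `J`, `f1`, `f2`,
#'   `f3`, `dJ_dE`, `dJ_dnu`.
#' @export
cost_index <- function(E, nu, stress, strain) {
  stopifnot(inherits(stress, "stress_triplet"), inherits(strain, "strain_triplet"))
  AB <- stress$A * stress$B
  if (AB == 0) stop("singular cost: A * B = 0")
  ce <- cost_eval_core(E, nu, stress$sigma_rr, AB,
                       strain$eps_rr, strain$eps_tt, strain$eps_pp)
  structure(list(J = ce$J, f1 = ce$f[1], f2 = ce$f[2], f3 = ce$f[3],
                 dJ_dE = ce$grad[1], dJ_dnu = ce$grad[2]),
            class = "cost_evaluation")
}

#' @export
print.cost_evaluation <- function(x, ...) {
  cat(sprintf("Cost J = %.6g (f1 = %.4g, f2 = %.4g, f3 = %.4g)\n",
              x$J, x$f1, x$f2, x$f3))
  cat(sprintf("  grad: dJ/dE = %.4g /Pa, dJ/dnu = %.4g\n", x$dJ_dE, x$dJ_dnu))
  invisible(x)
}

# Newton polish on the 2x2 system grad J = 0, Hessian by central
# differences of the analytic gradient. J is quadratic in E at fixed nu,
# so the polish converges in a handful of steps near a minimum.
newton_polish <- function(par, srr, AB, err, ett, epp, bounds, grad_tol,
                          max_iter = 30L) {
  scale <- c(max(abs(par[1]), 1), 1)
  for (i in seq_len(max_iter)) {
    ce <- cost_eval_core(par[1], par[2], srr, AB, err, ett, epp)
    g <- ce$grad
    if (sqrt(sum((g * scale)^2)) < grad_tol) break
    hE <- max(abs(par[1]), 1) * 1e-6
    hN <- 1e-7
    gEp <- cost_eval_core(par[1] + hE, par[2], srr, AB, err, ett, epp)$grad
    gEm <- cost_eval_core(par[1] - hE, par[2], srr, AB, err, ett, epp)$grad
    gNp <- cost_eval_core(par[1], par[2] + hN, srr, AB, err, ett, epp)$grad
    gNm <- cost_eval_core(par[1], par[2] - hN, srr, AB, err, ett, epp)$grad
    H <- cbind((gEp - gEm) / (2 * hE), (gNp - gNm) / (2 * hN))
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    new <- par + step
    # keep inside the search box; stop if the constraint is active
    new[1] <- min(max(new[1], bounds$E[1]), bounds$E[2])
    new[2] <- min(max(new[2], bounds$nu[1]), bounds$nu[2])
    Jnew <- cost_eval_core(new[1], new[2], srr, AB, err, ett, epp)$J
    # halve the step while it increases J (up to a few times)
    k <- 0L
    while (Jnew > ce$J && k < 8L) {
      new <- par + (new - par) / 2
      Jnew <- cost_eval_core(new[1], new[2], srr, AB, err, ett, epp)$J
      k <- k + 1L
    }
    if (Jnew > ce$J || identical(new, par)) break
    par <- new
  }
  par
}

#' Estimate Young's modulus and Poisson's ratio from strains
#'
#' Recovers the elastic moduli of the ventricular wall by minimizing the
#' consistency cost [cost_index()] over `(E, nu)` within the
#' configuration's search box, from a jittered multi-start grid of local
#' searches (L-BFGS-B with the analytic gradient, followed by a Newton
#' polish of the stationarity conditions). The cost typically has more
#' than one stationary point; all distinct ones found are recorded and
#' the feasible point (positive modulus inside the box) with smallest
#' cost is returned, ties broken by smaller `E`.
#'
#' @param geom A [ventricle_geometry()] with `kappa = 1`.
#' @param load A [loading_state()].
#' @param strain A [strain_triplet()], taken at face value (see
#'   `sign_convention` in [estimator_config()] for where conventions are
#'   reconciled).
#' @param config An [estimator_config()].
#' @return Object of class `elastic_estimate`: list with `moduli`
#'   ([elastic_moduli()]), `J_final`, `converged` (scaled gradient norm
#'   below `grad_tol`), `grad` (at the solution),
#'   `n_stationary_points`, `model = "ellipsoid"`, and `diagnostics`
#'   (one row per start: start values, terminal values, cost,
#'   optimizer convergence code).
#' @examples
#' g <- ventricle_geometry(2.5, 1.0)
#' ld <- loading_state(2000)
#' tr <- forward_strains(g, ld, elastic_moduli(7000, 0.6))
#' estimate_moduli(g, ld, tr, estimator_config(seed = 1))
#' @export
estimate_moduli <- function(geom, load, strain, config = estimator_config()) {
  stopifnot(inherits(geom, "ventricle_geometry"), inherits(load, "loading_state"),
            inherits(strain, "strain_triplet"), inherits(config, "estimator_config"))
  if (geom$kappa != 1)
    stop("the inverse estimator operates on the equatorial-plane model (kappa = 1)")
  nz <- sum(abs(c(strain$eps_rr, strain$eps_tt, strain$eps_pp)) > 0)
  if (nz < 2L)
    stop("need nonzero strains in at least two directions to identify (E, nu)")
  ctx <- stress_context(geom, load)
  srr <- ctx$srr; AB <- ctx$AB
  err <- strain$eps_rr; ett <- strain$eps_tt; epp <- strain$eps_pp
  bounds <- list(E = config$E_bounds, nu = config$nu_bounds)

  # reproducible start jitter without disturbing the caller's RNG stream
  starts <- local_seed(config$seed, {
    E0 <- exp(seq(log(bounds$E[1] * 1.0001), log(bounds$E[2] * 0.9999),
                  length.out = config$E_starts))
    n0 <- seq(bounds$nu[1], bounds$nu[2], length.out = config$nu_starts + 2L)
    n0 <- n0[-c(1L, length(n0))]
    gr <- expand.grid(E = E0, nu = n0)
    gr$E <- pmin(pmax(gr$E * exp(stats::runif(nrow(gr), -0.1, 0.1)),
                      bounds$E[1]), bounds$E[2])
    gr$nu <- pmin(pmax(gr$nu + stats::runif(nrow(gr), -0.05, 0.05),
                       bounds$nu[1]), bounds$nu[2])
    gr
  })

  fn <- function(p) cost_eval_core(p[1], p[2], srr, AB, err, ett, epp)$J
  gr <- function(p) cost_eval_core(p[1], p[2], srr, AB, err, ett, epp)$grad

  diag_rows <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$E[i], starts$nu[i])
    fit <- tryCatch(
      stats::optim(p0, fn, gr, method = "L-BFGS-B",
                   lower = c(bounds$E[1], bounds$nu[1]),
                   upper = c(bounds$E[2], bounds$nu[2]),
                   control = list(maxit = config$max_iter, factr = 10,
                                  pgtol = 0,
                                  parscale = c(max(p0[1], 1), 1))),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag_rows[[i]] <- data.frame(E_start = p0[1], nu_start = p0[2],
                                   E = NA_real_, nu = NA_real_, J = Inf,
                                   code = NA_integer_)
      next
    }
    par <- newton_polish(fit$par, srr, AB, err, ett, epp, bounds,
                         config$grad_tol)
    J <- cost_eval_core(par[1], par[2], srr, AB, err, ett, epp)$J
    diag_rows[[i]] <- data.frame(E_start = p0[1], nu_start = p0[2],
                                 E = par[1], nu = par[2], J = J,
                                 code = fit$convergence)
  }
  diagnostics <- do.call(rbind, diag_rows)

  ok <- is.finite(diagnostics$J) & !is.na(diagnostics$E)
  if (!any(ok))
    stop("no feasible solution: every local search failed inside the window")
  cand <- diagnostics[ok, , drop = FALSE]
  cand <- cand[order(cand$J, cand$E), , drop = FALSE]

  # count distinct stationary points (relative clustering tolerance 1e-4)
  dedup <- cand[1, , drop = FALSE]
  if (nrow(cand) > 1L) {
    for (i in 2L:nrow(cand)) {
      dif <- abs(cand$E[i] - dedup$E) / pmax(abs(dedup$E), 1) +
             abs(cand$nu[i] - dedup$nu)
      if (all(dif > 1e-4)) dedup <- rbind(dedup, cand[i, ])
    }
  }

  best <- cand[1, ]
  ce <- cost_eval_core(best$E, best$nu, srr, AB, err, ett, epp)
  scale <- c(max(abs(best$E), 1), 1)
  converged <- sqrt(sum((ce$grad * scale)^2)) < max(config$grad_tol, 1e-6) ||
               ce$J < 1e-18
  if (best$E <= 0)
    stop("no feasible solution: best stationary point has nonpositive modulus")
  structure(list(moduli = elastic_moduli(best$E, best$nu),
                 J_final = best$J,
                 converged = converged,
                 grad = ce$grad,
                 n_stationary_points = nrow(dedup),
                 model = "ellipsoid",
                 diagnostics = diagnostics),
            class = "elastic_estimate")
}

#' @export
print.elastic_estimate <- function(x, ...) {
  cat(sprintf("Elastic estimate (%s model)\n", x$model))
  cat(sprintf("  E  = %.6g Pa\n  nu = %.6g\n", x$moduli$E, x$moduli$nu))
  cat(sprintf("  J_final = %.3g, converged = %s, stationary points = %d\n",
              x$J_final, x$converged, x$n_stationary_points))
  invisible(x)
}

#' Dense grid minimum of the consistency cost
#'
#' Brute-force evaluation of [cost_index()] on an `n x n` grid spanning
#' the configuration's search box (moduli log-spaced, ratios linear).
#' Used as an independent lower-bound oracle for the optimizer: the
#' returned minimized cost of [estimate_moduli()] should never exceed
#' the grid minimum.
#'
#' @inheritParams estimate_moduli
#' @param n Grid points per axis (default 400).
#' @return List with `J_min`, `E`, `nu` at the best grid node.
#' @export
cost_grid_min <- function(geom, load, strain, config = estimator_config(),
                          n = 400L) {
  ctx <- stress_context(geom, load)
  Es <- exp(seq(log(config$E_bounds[1]), log(config$E_bounds[2]),
                length.out = n))
  nus <- seq(config$nu_bounds[1], config$nu_bounds[2], length.out = n)
  gr <- expand.grid(E = Es, nu = nus)
  J <- cost_J_vec(gr$E, gr$nu, ctx$srr, ctx$AB,
                  strain$eps_rr, strain$eps_tt, strain$eps_pp)
  i <- which.min(J)
  list(J_min = J[i], E = gr$E[i], nu = gr$nu[i])
}

# Evaluate an expression under a temporary RNG state seeded from `seed`,
# restoring the caller's stream afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
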