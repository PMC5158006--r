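#' @name echo_cohort_format
#' @title Echo cohort table format
#' @description
#' Cohort tables are delimited (CSV) files with one row per subject and
#' the header
#' `subject_id,age,sex,htn,sbp,dbp,LVIDd_cm,LVIDs_cm,LVPWd_cm,IVSd_cm,e_over_eprime,GLS_pct,GCS_pct`:
#' chamber dimensions and wall thicknesses in cm, the averaged
#' medial-lateral e/e' ratio (dimensionless), and the global
#' longitudinal/circumferential strains in signed percent (negative by
#' echo convention). Unknown extra columns are preserved untouched.
#' If `e_over_eprime` is absent but `e_over_eprime_medial` and
#' `e_over_eprime_lateral` are both present, they are averaged on load.
#' A column-mapping list (canonical name -> actual header) supports
#' alternative headers.
NULL

.echo_required <- c("LVIDd_cm", "LVIDs_cm", "LVPWd_cm", "IVSd_cm",
                    "e_over_eprime", "GLS_pct", "GCS_pct")
.echo_canonical <- c("subject_id", "age", "sex", "htn", "sbp", "dbp",
                     .echo_required)

# Accept a measurement as a list/one-row data.frame keyed by either
# file-style (LVIDd_cm, GLS_pct) or plain (LVIDd, GLS) names.
.m_field <- function(m, name) {
  plain <- sub("_(cm|pct)$", "", name)
  for (key in unique(c(name, plain))) {
    v <- m[[key]]
    if (!is.null(v) && length(v) == 1L) return(as.numeric(v))
  }
  NA_real_
}

#' Validate one echo measurement
#'
#' Checks the physiological invariants of a single subject's
#' measurements: `LVIDd > LVIDs > 0`, positive wall thicknesses, a
#' positive e/e' ratio, and strain percents of magnitude below 100.
#' Every violated invariant is reported, not just the first.
#'
#' @param m A named list or one-row data.frame (plain or file-style
#'   field names, see [echo_cohort_format]).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_measurement <- function(m) {
  lvidd <- .m_field(m, "LVIDd_cm"); lvids <- .m_field(m, "LVIDs_cm")
  lvpwd <- .m_field(m, "LVPWd_cm"); ivsd <- .m_field(m, "IVSd_cm")
  ee <- .m_field(m, "e_over_eprime")
  gls <- .m_field(m, "GLS_pct"); gcs <- .m_field(m, "GCS_pct")
  bad <- character()
  if (!is.finite(lvidd) || lvidd <= 0) bad <- c(bad, "LVIDd must be positive")
  if (!is.finite(lvids) || lvids <= 0) bad <- c(bad, "LVIDs must be positive")
  if (is.finite(lvidd) && is.finite(lvids) && lvidd <= lvids)
    bad <- c(bad, "LVIDd must exceed LVIDs (systolic dimension is smaller)")
  if (!is.finite(lvpwd) || lvpwd <= 0) bad <- c(bad, "LVPWd must be positive")
  if (!is.finite(ivsd) || ivsd <= 0) bad <- c(bad, "IVSd must be positive")
  if (!is.finite(ee) || ee <= 0) bad <- c(bad, "e/e' must be positive")
  if (!is.finite(gls) || abs(gls) >= 100)
    bad <- c(bad, "GLS percent magnitude must be below 100")
  if (!is.finite(gcs) || abs(gcs) >= 100)
    bad <- c(bad, "GCS percent magnitude must be below 100")
  bad
}

#' Ventricle geometry from an echo measurement
#'
#' Definitional conversions: the endocardial radius of curvature is half
#' the end-diastolic internal dimension, `R0 = LVIDd / 2`; the wall
#' thickness is the posterior wall thickness, `T = LVPWd`; the shape
#' ratio is fixed at `kappa = 1` and the evaluation radius at midwall,
#' `(2 R0 + T) / 2`. IVSd is carried in tables for reporting only and
#' never feeds `T`.
#'
#' @inheritParams validate_measurement
#' @return A [ventricle_geometry()].
#' @examples
#' derive_geometry(list(LVIDd = 5.23, LVIDs = 3.08, LVPWd = 0.91,
#'                      IVSd = 1.03, e_over_eprime = 11.39,
#'                      GLS = -17.64, GCS = -17.46))
#' @export
derive_geometry <- function(m) {
  bad <- validate_measurement(m)
  if (length(bad)) stop("invalid measurement: ", paste(bad, collapse = "; "))
  R0 <- .m_field(m, "LVIDd_cm") / 2
  T <- .m_field(m, "LVPWd_cm")
  ventricle_geometry(R0 = R0, T = T)
}

#' Intraventricular pressure from the e/e' ratio
#'
#' Affine surrogate of LV filling pressure from the averaged
#' medial-lateral e/e' ratio, with the mmHg-to-Pa conversion folded in:
#' \deqn{P = \frac{1.9 + 1.24\, (e/e')}{0.0075} \;\mathrm{Pa}.}
#' Slope `1.24 / 0.0075` Pa per unit ratio, intercept `1.9 / 0.0075` Pa.
#'
#' @inheritParams validate_measurement
#' @return A [loading_state()] with the source ratio recorded.
#' @examples
#' derive_pressure(list(e_over_eprime = 9.06))$P  # 1751.253 Pa
#' @export
derive_pressure <- function(m) {
  ee <- .m_field(m, "e_over_eprime")
  if (!is.finite(ee) || ee <= 0) stop("e/e' ratio must be positive")
  loading_state(P = (1.9 + 1.24 * ee) / 0.0075, e_over_eprime = ee)
}

#' Strain triplet from an echo measurement
#'
#' Converts measured deformation into dimensionless strain fractions:
#' the radial strain is the fractional internal-dimension change
#' `(LVIDd - LVIDs) / LVIDd` (positive), and the circumferential and
#' longitudinal strains are `GCS / 100` and `GLS / 100` (negative by
#' echo convention; reference state end-diastole). Percents are divided
#' by 100 exactly once, here at parse time.
#'
#' With `sign_convention = "echo"` the triplet is returned as reported.
#' With `"model"` all three signs are flipped into the forward model's
#' own convention (radial compression negative, in-plane stretches
#' positive), which is the convention under which forward-generated
#' strains are exactly recoverable.
#'
#' @inheritParams validate_measurement
#' @param sign_convention `"echo"` (as reported) or `"model"` (flipped).
#' @return A [strain_triplet()].
#' @export
derive_strains <- function(m, sign_convention = c("echo", "model")) {
  sign_convention <- match.arg(sign_convention)
  bad <- validate_measurement(m)
  if (length(bad)) stop("invalid measurement: ", paste(bad, collapse = "; "))
  eps_rr <- (.m_field(m, "LVIDd_cm") - .m_field(m, "LVIDs_cm")) /
    .m_field(m, "LVIDd_cm")
  eps_tt <- .m_field(m, "GCS_pct") / 100
  eps_pp <- .m_field(m, "GLS_pct") / 100
  s <- if (sign_convention == "model") -1 else 1
  if (any(abs(c(eps_rr, eps_tt, eps_pp)) >= 1))
    stop("derived strain magnitude of 1 or more is outside the model's range")
  strain_triplet(s * eps_rr, s * eps_tt, s * eps_pp)
}

#' Read an echo cohort table
#'
#' Reads a delimited cohort file (see [echo_cohort_format]), applies an
#' optional column mapping, averages separate medial/lateral e/e'
#' columns when the averaged column is absent, and validates every row.
#' Rows are never dropped: per-row validation failures are collected in
#' the `"validation"` attribute (a data.frame with `row`, `subject_id`,
#' `problem`), so counts in equal counts out plus nothing.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named list mapping canonical column names to
#'   the file's actual headers, e.g.
#'   `list(LVIDd_cm = "lv_dimension_diastole")`.
#' @param sep Field separator (default comma).
#' @return A data.frame of class `cohort_table` with canonical columns
#'   first and unknown columns preserved; attribute `"validation"`
#'   holds the row-level report.
#' @export
read_cohort <- function(path, col_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tbl <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      actual <- col_map[[canon]]
      if (actual %in% names(tbl)) names(tbl)[names(tbl) == actual] <- canon
    }
  }
  if (!("e_over_eprime" %in% names(tbl)) &&
      all(c("e_over_eprime_medial", "e_over_eprime_lateral") %in% names(tbl))) {
    tbl$e_over_eprime <-
      (tbl$e_over_eprime_medial + tbl$e_over_eprime_lateral) / 2
  }
  missing <- setdiff(.echo_required, names(tbl))
  if (length(missing))
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  as_cohort_table(tbl)
}

#' Coerce a data.frame to a validated cohort table
#'
#' @param tbl A data.frame with the columns of [echo_cohort_format].
#' @return The table, classed `cohort_table`, canonical columns first,
#'   with the `"validation"` attribute populated.
#' @export
as_cohort_table <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  missing <- setdiff(.echo_required, names(tbl))
  if (length(missing))
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))
  front <- intersect(.echo_canonical, names(tbl))
  tbl <- tbl[, c(front, setdiff(names(tbl), front)), drop = FALSE]
  probs <- lapply(seq_len(nrow(tbl)), function(i) {
    bad <- validate_measurement(as.list(tbl[i, , drop = FALSE]))
    if (length(bad))
      data.frame(row = i,
                 subject_id = as.character(
                   if ("subject_id" %in% names(tbl)) tbl$subject_id[i] else i),
                 problem = bad)
  })
  report <- do.call(rbind, probs)
  if (is.null(report))
    report <- data.frame(row = integer(), subject_id = character(),
                         problem = character())
  attr(tbl, "validation") <- report
  class(tbl) <- c("cohort_table", "data.frame")
  tbl
}

#' Write a cohort or results table
#'
#' Plain CSV writer (no row names, no quoting beyond what the values
#' require); reading the file back with [read_cohort()] reproduces the
#' table.
#'
#' @param tbl A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' Estimate elasticity for every subject of a cohort
#'
#' Runs the inverse estimator (ellipsoid model) or the exact cylinder
#' solve on each row of a cohort table. Per-subject failures
#' (validation or estimation) never abort the run: the offending row is
#' returned with `NA` estimates, `converged = FALSE`, and the error
#' text in `note`.
#'
#' For the ellipsoid, the inputs are `R0 = LVIDd/2`, `T = LVPWd`,
#' midwall evaluation, and pressure from e/e'; for the cylinder,
#' `a = LVIDd/2`, `b = a + LVPWd`. Strains follow
#' `config$sign_convention` (see [derive_strains()]).
#'
#' @param tbl A `cohort_table` (or data.frame with the required
#'   columns).
#' @param config An [estimator_config()].
#' @param model `"ellipsoid"` (default) or `"cylinder"`.
#' @return The input columns with `E_Pa`, `poisson`, `J_final`,
#'   `model`, `converged`, `note` appended.
#' @export
estimate_cohort <- function(tbl, config = estimator_config(),
                            model = c("ellipsoid", "cylinder")) {
  model <- match.arg(model)
  tbl <- as_cohort_table(as.data.frame(tbl))
  n <- nrow(tbl)
  out <- data.frame(E_Pa = rep(NA_real_, n), poisson = NA_real_,
                    J_final = NA_real_, model = model, converged = FALSE,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    m <- as.list(tbl[i, , drop = FALSE])
    res <- tryCatch({
      load <- derive_pressure(m)
      strain <- derive_strains(m, config$sign_convention)
      est <- if (model == "ellipsoid") {
        estimate_moduli(derive_geometry(m), load, strain, config)
      } else {
        a <- .m_field(m, "LVIDd_cm") / 2
        cylinder_estimate(cylinder_geometry(a, a + .m_field(m, "LVPWd_cm")),
                          strain, load)
      }
      list(E = est$moduli$E, nu = est$moduli$nu, J = est$J_final,
           conv = est$converged, note = "")
    }, error = function(e) list(E = NA_real_, nu = NA_real_, J = NA_real_,
                                conv = FALSE, note = conditionMessage(e)))
    out$E_Pa[i] <- res$E; out$poisson[i] <- res$nu
    out$J_final[i] <- res$J; out$converged[i] <- res$conv
    out$note[i] <- res$note
  }
  cbind(as.data.frame(tbl), out)
}
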