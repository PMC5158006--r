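#' Compare a variable across cohort strata
#'
#' Reporting layer for group contrasts: per-stratum mean, SD and n, and
#' an unpaired two-group t test (Welch by default; set
#' `var.equal = TRUE` for the pooled-variance variant) when there are
#' two strata, or a one-way ANOVA F test when there are more. No
#' multiple-testing correction is applied, and that is recorded in the
#' returned object.
#'
#' @param tbl A data.frame (cohort or estimates table).
#' @param variable Name of the numeric column to compare.
#' @param strata Character vector of one or more grouping columns;
#'   multiple columns are crossed (e.g. age group x hypertension gives
#'   four strata).
#' @param var.equal Pooled-variance t test instead of Welch.
#' @return Object of class `group_summary`: list with `summary`
#'   (per-stratum data.frame), `statistic`, `p_value`, `method`,
#'   `adjusted` (always `"none"`).
#' @export
group_compare <- function(tbl, variable, strata, var.equal = FALSE) {
  stopifnot(is.data.frame(tbl), variable %in% names(tbl),
            all(strata %in% names(tbl)))
  y <- tbl[[variable]]
  g <- interaction(tbl[strata], drop = TRUE, sep = ":")
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  counts <- table(g)
  if (nlevels(g) < 2L) stop("need at least two non-empty strata")
  if (any(counts < 2L))
    stop("insufficient n: every stratum needs at least 2 observations, got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  summ <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- y[g == lv]
    data.frame(stratum = lv, n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  if (nlevels(g) == 2L) {
    ht <- stats::t.test(y ~ g, var.equal = var.equal)
    method <- if (var.equal) "pooled t test" else "Welch t test"
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    fit <- stats::aov(y ~ g)
    av <- summary(fit)[[1]]
    method <- "one-way ANOVA"
    stat <- av[["F value"]][1]; p <- av[["Pr(>F)"]][1]
  }
  structure(list(variable = variable, summary = summ, statistic = stat,
                 p_value = p, method = method, adjusted = "none"),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s, p adjustment: %s)\n",
              x$variable, x$method, x$adjusted))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-18s n = %3d  %.4g +/- %.4g\n", x$summary$stratum[i],
                x$summary$n[i], x$summary$mean[i], x$summary$sd[i]))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Age trend of a variable, overall and per stratum
#'
#' Simple least-squares regression of a variable on age with the
#' Pearson correlation: slope, r, R-squared (the squared Pearson r for
#' simple regression) and the correlation p-value, overall and within
#' each level of an optional stratifying column.
#'
#' @param tbl A data.frame with an `age` column.
#' @param variable Numeric column to regress on age.
#' @param by Optional stratifying column name (e.g. `"htn"`).
#' @return Object of class `trend_report`: data.frame with one row per
#'   stratum (plus `"all"`) and columns `stratum`, `n`, `slope`, `r`,
#'   `R2`, `p_value`.
#' @export
age_trend <- function(tbl, variable, by = NULL) {
  stopifnot(is.data.frame(tbl), "age" %in% names(tbl),
            variable %in% names(tbl))
  one <- function(df, label) {
    ok <- is.finite(df[[variable]]) & is.finite(df$age)
    df <- df[ok, , drop = FALSE]
    if (nrow(df) < 3L)
      stop("need at least 3 complete (age, ", variable, ") pairs in stratum ",
           label)
    if (stats::sd(df[[variable]]) == 0 || stats::sd(df$age) == 0)
      stop("degenerate trend in stratum ", label,
           ": constant variable or constant age")
    ct <- stats::cor.test(df$age, df[[variable]], method = "pearson")
    sl <- unname(stats::coef(stats::lm(df[[variable]] ~ df$age))[2])
    data.frame(stratum = label, n = nrow(df), slope = sl,
               r = unname(ct$estimate), R2 = unname(ct$estimate)^2,
               p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- one(tbl, "all")
  if (!is.null(by)) {
    stopifnot(by %in% names(tbl))
    for (lv in unique(tbl[[by]]))
      out <- rbind(out, one(tbl[tbl[[by]] == lv, , drop = FALSE],
                            paste0(by, "=", lv)))
  }
  structure(out, class = c("trend_report", "data.frame"))
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Age trend\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
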