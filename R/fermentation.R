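# Normalisation and statistics for shake-flask fermentation measurements.
#
# Secreted protein is normalised to fungal dry weight (mg/g biomass);
# organic acids to depleted glucose (g/g). Mutants are compared to the
# progenitor control dose by dose with two-sided pooled-variance Student's
# t-tests, without multiple-testing correction (each comparison is reported
# with the number of tests performed, so a reader can adjust if desired).

#' Normalise fermentation titres
#'
#' Adds `protein_mg_per_g_biomass` (protein / dry weight),
#' `citric_g_per_g_glucose` and `oxaloacetate_g_per_g_glucose`
#' (acid / depleted glucose). Zero denominators yield `NA` (undefined, not
#' zero) with a warning.
#'
#' @param records data.frame with the fermentation-table columns (see
#'   [generate_fermentation_table()]).
#' @return The data.frame with the three normalised columns appended.
#' @export
#' @examples
#' normalize_titres(data.frame(strain = "s", dox_ug_ml = 0, replicate = 1,
#'   protein_mg = 50, dry_weight_g = 2, citric_g_l = 4,
#'   oxaloacetate_g_l = 1, glucose_depleted_g_l = 8))
normalize_titres <- function(records) {
  validate_fermentation_table(records)
  ratio <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning(sum(bad), " record(s) with zero denominator for ", what,
              "; normalised value undefined (NA)", call. = FALSE)
    }
    ifelse(bad, NA_real_, num / den)
  }
  records$protein_mg_per_g_biomass <-
    ratio(records$protein_mg, records$dry_weight_g, "protein per biomass")
  records$citric_g_per_g_glucose <-
    ratio(records$citric_g_l, records$glucose_depleted_g_l,
          "citric acid per glucose")
  records$oxaloacetate_g_per_g_glucose <-
    ratio(records$oxaloacetate_g_l, records$glucose_depleted_g_l,
          "oxaloacetate per glucose")
  records
}

#' Pairwise Student's t-test (pooled variance)
#'
#' Two-sided two-sample t-test with pooled variance, comparing a mutant's
#' replicate values against the control's at the same dose. When the pooled
#' variance is zero, equal means give `t = 0, p = 1` by convention and
#' unequal means give `p = 0` (the groups are exactly separated).
#'
#' @param mutant_values,control_values numeric vectors, each of length >= 2.
#' @param alpha significance level for the `significant` flag.
#' @return List with `t_statistic`, `df`, `p_value` and `significant`
#'   (`p < alpha`).
#' @export
#' @examples
#' pairwise_t_test(c(10, 12, 11), c(20, 22, 21))
pairwise_t_test <- function(mutant_values, control_values, alpha = 0.05) {
  check_that(is.numeric(mutant_values) && length(mutant_values) >= 2L &&
               is.numeric(control_values) && length(control_values) >= 2L,
             "each group needs at least 2 values")
  check_that(!anyNA(mutant_values) && !anyNA(control_values),
             "missing values are not allowed")
  check_that(is_scalar_number(alpha) && alpha > 0 && alpha <= 1,
             "`alpha` must lie in (0, 1]")
  n1 <- length(mutant_values); n2 <- length(control_values)
  m1 <- mean(mutant_values); m2 <- mean(control_values)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(mutant_values) +
            (n2 - 1) * stats::var(control_values)) / df
  if (sp2 == 0) {
    if (m1 == m2) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(m1 - m2) * Inf; p <- 0
    }
  } else {
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  list(t_statistic = t_stat, df = df, p_value = p, significant = p < alpha)
}

#' Least-squares polynomial trend fit
#'
#' Fits `y ~ poly(x, degree)` by ordinary least squares and reports the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`. Nested models
#' guarantee that the degree-2 fit never has a smaller R-squared than the
#' linear fit on the same data. Constant `y` (zero total sum of squares)
#' yields `R^2 = 0` by convention.
#'
#' @param x,y numeric vectors of equal length, at least `degree + 2` points,
#'   `x` not all equal.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return List with `degree`, `coefficients` (highest degree first) and
#'   `r_squared`.
#' @export
fit_trend <- function(x, y, degree) {
  check_that(degree %in% c(1L, 2L), "`degree` must be 1 or 2")
  check_that(is.numeric(x) && is.numeric(y) && length(x) == length(y),
             "`x` and `y` must be numeric vectors of equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  check_that(length(x) >= degree + 2L,
             "need at least %d finite points for degree %d", degree + 2L, degree)
  check_that(min(x) < max(x), "`x` must not be constant")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(degree = as.integer(degree),
       coefficients = rev(unname(stats::coef(fit))),
       r_squared = r2)
}

#' Per-strain, per-dose means of normalised titres
#'
#' Averages the normalised protein and acid titres over replicates for each
#' strain x dose cell -- the table behind protein-versus-acid trend plots.
#'
#' @param records fermentation data.frame (normalised columns are added if
#'   absent).
#' @return data.frame with one row per strain x dose: `strain`,
#'   `dox_ug_ml`, `n_replicates`, `protein_mg_per_g_biomass`,
#'   `citric_g_per_g_glucose`, `oxaloacetate_g_per_g_glucose` (means).
#' @export
correlation_table <- function(records) {
  if (!"protein_mg_per_g_biomass" %in% names(records)) {
    records <- normalize_titres(records)
  }
  vars <- c("protein_mg_per_g_biomass", "citric_g_per_g_glucose",
            "oxaloacetate_g_per_g_glucose")
  agg <- stats::aggregate(records[vars],
                          by = records[c("strain", "dox_ug_ml")],
                          FUN = mean)
  cnt <- stats::aggregate(list(n_replicates = records$replicate),
                          by = records[c("strain", "dox_ug_ml")],
                          FUN = length)
  out <- merge(cnt, agg, by = c("strain", "dox_ug_ml"))
  out <- out[order(out$strain, out$dox_ug_ml), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare every mutant to the control, dose by dose
#'
#' Runs [pairwise_t_test()] for each mutant strain against the control at
#' each shared dose, for each normalised variable. No multiple-testing
#' correction is applied; the number of tests is attached as an attribute
#' `n_tests` so downstream users can adjust.
#'
#' @param records fermentation data.frame.
#' @param control control strain label present in `records`.
#' @param alpha significance level.
#' @param variables normalised columns to test.
#' @return data.frame: `strain`, `dox_ug_ml`, `variable`, `t_statistic`,
#'   `df`, `p_value`, `significant`.
#' @export
compare_to_control <- function(records, control, alpha = 0.05,
                               variables = c("protein_mg_per_g_biomass",
                                             "citric_g_per_g_glucose",
                                             "oxaloacetate_g_per_g_glucose")) {
  check_that(control %in% records$strain,
             "control strain `%s` not present in the table", control)
  if (!all(variables %in% names(records))) records <- normalize_titres(records)
  rows <- list()
  for (s in setdiff(unique(records$strain), control)) {
    for (d in intersect(unique(records$dox_ug_ml[records$strain == s]),
                        unique(records$dox_ug_ml[records$strain == control]))) {
      for (v in variables) {
        mut <- records[records$strain == s & records$dox_ug_ml == d, v]
        ctl <- records[records$strain == control & records$dox_ug_ml == d, v]
        if (anyNA(mut) || anyNA(ctl)) next  # undefined normalisations
        tt <- pairwise_t_test(mut, ctl, alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = s, dox_ug_ml = d, variable = v,
          t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
          significant = tt$significant, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(strain = character(), dox_ug_ml = numeric(),
               variable = character(), t_statistic = numeric(),
               df = integer(), p_value = numeric(), significant = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(out$strain, out$dox_ug_ml, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  out
}
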