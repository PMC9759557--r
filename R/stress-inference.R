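#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

check_fit_table <- function(table, parameter = NULL) {
  need <- c("concentration_mM", "day", "replicate")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("fit table lacks columns: ", paste(miss, collapse = ", "))
  if (!is.null(parameter) && !parameter %in% names(table)) {
    stop("unknown parameter column: ", parameter)
  }
  invisible(table)
}

#' One-way ANOVA of a GEV parameter across treatment days
#'
#' Tests, at one NaCl concentration, whether a fitted parameter (typically
#' the shape `xi`) changes with the duration of treatment: one-way ANOVA with
#' day as a factor and replicates as the error term.
#'
#' @param table fit table with columns `concentration_mM`, `day`,
#'   `replicate` and the parameter.
#' @param parameter column to test (default `"xi"`).
#' @param concentration which concentration (mM) to test.
#' @return list with `parameter`, `concentration_mM`, `f_statistic`,
#'   `p_value`, `stars`, `df`.
#' @export
gev_trend_anova <- function(table, parameter = "xi", concentration = 0) {
  check_fit_table(table, parameter)
  sub <- table[table$concentration_mM == concentration, ]
  if (length(unique(sub$day)) < 2) stop("need at least 2 days")
  if (min(table(sub$day)) < 2) stop("need at least 2 replicates per day")
  fit <- stats::aov(stats::reformulate("factor(day)", parameter), data = sub)
  a <- summary(fit)[[1]]
  f <- a[["F value"]][1]
  p <- a[["Pr(>F)"]][1]
  list(parameter = parameter, concentration_mM = concentration,
       f_statistic = f, p_value = p, stars = p_stars(p),
       df = c(a[["Df"]][1], a[["Df"]][2]))
}

#' Spearman correlation of a GEV parameter with NaCl concentration
#'
#' Rank correlation over replicate-level `(concentration, parameter)` pairs
#' at one treatment day, mid-ranking ties.
#'
#' @param table fit table.
#' @param parameter column to correlate (default `"mu"`).
#' @param day treatment day.
#' @return list with `rho`, `p_value`, `n`, `parameter`, `day`.
#' @export
spearman_param_vs_concentration <- function(table, parameter = "mu", day) {
  check_fit_table(table, parameter)
  sub <- table[table$day == day, ]
  if (length(unique(sub$concentration_mM)) < 3) {
    stop("need at least 3 distinct concentrations")
  }
  y <- sub[[parameter]]
  if (stats::sd(y) == 0) stop("constant parameter values: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(sub$concentration_mM, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(sub),
       parameter = parameter, day = day)
}

#' Linear regression of the GEV location on NaCl concentration
#'
#' Ordinary least squares of `mu` (or another response) on concentration at
#' one treatment day, on replicate-level rows, with 95% confidence intervals
#' from the t distribution and a confidence band over the concentration
#' range for plotting.
#'
#' @param table fit table.
#' @param day treatment day.
#' @param response response column (default `"mu"`; `"median"` regresses the
#'   robust median of |s3| instead).
#' @param band_points number of points in the returned confidence band.
#' @return list with `day`, `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `r_squared`, `n` and a `band` data frame
#'   (`concentration_mM`, `fit`, `lwr`, `upr`).
#' @export
regress_location_vs_concentration <- function(table, day, response = "mu",
                                              band_points = 50) {
  check_fit_table(table, response)
  sub <- table[table$day == day, ]
  if (length(unique(sub$concentration_mM)) < 3) {
    stop("need at least 3 distinct concentrations")
  }
  fit <- stats::lm(stats::reformulate("concentration_mM", response), data = sub)
  ci <- stats::confint(fit, level = 0.95)
  grid <- data.frame(concentration_mM = seq(min(sub$concentration_mM),
                                            max(sub$concentration_mM),
                                            length.out = band_points))
  pr <- stats::predict(fit, newdata = grid, interval = "confidence",
                       level = 0.95)
  list(day = day,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = unname(ci[2, ]),
       intercept_ci = unname(ci[1, ]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = nrow(sub),
       band = cbind(grid, as.data.frame(pr)))
}

#' Flag salt-stressed treatment groups from |s3| samples
#'
#' A treatment group is flagged as salt-stressed when its |s3| sample is
#' significantly below the untreated reference: a one-sided Wilcoxon test
#' (`alternative = "less"`) at level `alpha`, plus the requirement that the
#' group median actually lies below the reference median.
#'
#' @param samples named list of |s3| sample vectors, one per concentration;
#'   names are the concentrations in mM.
#' @param reference name of the reference group (default `"0"`).
#' @param alpha significance level.
#' @param method Wilcoxon variant for [compare_distributions()].
#' @return data frame with `concentration`, `p_value`, `median`,
#'   `stressed`.
#' @export
classify_salt_stress <- function(samples, reference = "0", alpha = 0.05,
                                 method = "rank_sum") {
  stopifnot(is.list(samples), !is.null(names(samples)))
  if (!reference %in% names(samples)) {
    stop("reference group \"", reference, "\" not present")
  }
  ref <- samples[[reference]]
  ref_med <- stats::median(ref)
  out <- lapply(names(samples), function(g) {
    x <- samples[[g]]
    if (g == reference) {
      return(data.frame(concentration = g, p_value = 1,
                        median = ref_med, stressed = FALSE))
    }
    cmp <- compare_distributions(x, ref, method = method,
                                 alternative = "less")
    data.frame(concentration = g, p_value = cmp$p_value,
               median = stats::median(x),
               stressed = cmp$p_value < alpha && stats::median(x) < ref_med)
  })
  do.call(rbind, out)
}
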