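# Group-statistics layer: single-pass two-standard-deviation outlier
# removal, one-way fixed-effects ANOVA, Dunnett many-to-one comparisons
# against the reference arm (multcomp's multivariate-t implementation), and
# percent-of-reference report assembly.

#' Single-pass k-standard-deviation outlier removal
#'
#' Within each arm, values lying strictly more than `k` sample standard
#' deviations (n-1 denominator) from the arm mean are removed, with mean and
#' SD computed on the full arm including the candidate. A single pass only:
#' removal is not iterated. Arms with fewer than 3 values, or zero SD, are
#' left untouched.
#'
#' @param data Tibble with at least `arm` and `value` columns.
#' @param k Threshold in standard deviations (default 2).
#' @return `data` without the outlying rows; the removed rows are attached
#'   as attribute `"outliers"`. Errors if any arm drops below 2 values.
#' @export
remove_outliers <- function(data, k = 2) {
  if (!all(c("arm", "value") %in% names(data))) {
    stop_input("data needs `arm` and `value` columns")
  }
  check_number(k, "k", min = 0, strict_min = TRUE)
  flagged <- dplyr::mutate(
    dplyr::group_by(data, .data$arm),
    .out = dplyr::n() >= 3 & sd(.data$value) > 0 &
      abs(.data$value - mean(.data$value)) > k * sd(.data$value)
  )
  flagged <- dplyr::ungroup(flagged)
  kept <- dplyr::select(dplyr::filter(flagged, !.data$.out), -".out")
  removed <- dplyr::select(dplyr::filter(flagged, .data$.out), -".out")
  n_after <- table(factor(kept$arm, levels = unique(data$arm)))
  if (any(n_after < 2)) {
    stop_input(sprintf("outlier removal left arm '%s' with < 2 values",
                       names(n_after)[which(n_after < 2)[1]]))
  }
  if (nrow(removed) > 0) {
    inform(sprintf("remove_outliers: removed %d value(s) beyond %g SD",
                   nrow(removed), k))
  }
  attr(kept, "outliers") <- removed
  kept
}

significance_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits a one-way fixed-effects ANOVA on raw endpoint values and compares
#' every treatment arm against the reference arm with Dunnett's two-sided
#' procedure (single-step multivariate-t adjustment, via
#' [multcomp::glht()]). Significance tiers follow the usual star
#' convention: `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001,
#' `****` p <= 0.0001.
#'
#' @param data Tibble with `arm` and `value` columns (one row per
#'   subject/pair), outliers already removed.
#' @param reference Reference arm label.
#' @return An object of class `dunnett_fit` with the ANOVA table, the
#'   comparison tibble and the underlying fits. Use [tidy()] / [glance()]
#'   to extract tidy summaries.
#' @export
anova_dunnett <- function(data, reference) {
  if (!all(c("arm", "value") %in% names(data))) {
    stop_input("data needs `arm` and `value` columns")
  }
  arms <- unique(data$arm)
  if (length(arms) < 2) stop_input("need >= 2 arms")
  if (!reference %in% arms) {
    stop_config(sprintf("reference arm '%s' absent from data", reference))
  }
  counts <- table(data$arm)
  if (any(counts < 2)) stop_input("every arm needs >= 2 values")
  within_sd <- tapply(data$value, data$arm, sd)
  if (all(within_sd == 0)) {
    stop_input("zero within-group variance: ANOVA F is undefined")
  }
  data$arm <- stats::relevel(factor(data$arm), ref = reference)
  fit <- aov(value ~ arm, data = data)
  an <- anova(fit)
  if (!is.finite(an[["Mean Sq"]][2]) || an[["Mean Sq"]][2] <= 0) {
    stop_input("zero within-group variance: ANOVA F is undefined")
  }
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(arm = "Dunnett"))
  smry <- summary(glht_fit)
  comp <- tibble(
    arm = sub(paste0(" - ", reference, "$"), "", names(smry$test$coefficients)),
    estimate = as.numeric(smry$test$coefficients),
    std_error = as.numeric(smry$test$sigma),
    statistic = as.numeric(smry$test$tstat),
    p_adj = as.numeric(smry$test$pvalues)
  )
  comp$stars <- significance_stars(comp$p_adj)
  structure(
    list(
      anova = an,
      f_statistic = an[["F value"]][1],
      df = c(an[["Df"]][1], an[["Df"]][2]),
      p_value = an[["Pr(>F)"]][1],
      comparisons = comp,
      reference = reference,
      n = nrow(data),
      fit = fit, glht = glht_fit, data = data
    ),
    class = "dunnett_fit"
  )
}

#' @export
print.dunnett_fit <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat(sprintf("Dunnett comparisons vs '%s':\n", x$reference))
  print(as.data.frame(x$comparisons), digits = 4)
  invisible(x)
}

#' Tidy a Dunnett fit
#'
#' @param x A `dunnett_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per comparison against the reference arm with
#'   the mean difference, its standard error, the t statistic and the
#'   Dunnett-adjusted p value. `glance()`: a one-row model summary.
#' @export
tidy.dunnett_fit <- function(x, ...) {
  dplyr::mutate(x$comparisons,
    contrast = paste(.data$arm, "-", x$reference), .before = 1
  )
}

#' @rdname tidy.dunnett_fit
#' @export
glance.dunnett_fit <- function(x, ...) {
  tibble(
    statistic = x$f_statistic, df = x$df[1], df_residual = x$df[2],
    p_value = x$p_value, n = x$n,
    n_comparisons = nrow(x$comparisons), reference = x$reference
  )
}

#' Assemble a study report across endpoints
#'
#' For each endpoint table: removes outliers (2 SD, single pass), normalizes
#' to percent of the reference-arm mean, runs the ANOVA/Dunnett layer on the
#' raw values, and emits one row per arm with raw and normalized means,
#' SEMs, and the Dunnett-adjusted p value (NA for the reference arm, whose
#' normalized mean is 100 by construction). Endpoints with no rows are
#' skipped with a warning.
#'
#' @param endpoints Named list of tibbles, each with `arm` and `value`
#'   columns (plus optional `channel`, analyzed separately).
#' @param reference Reference arm label.
#' @param outlier_sd Outlier threshold in standard deviations.
#' @return A tibble (endpoint, channel, arm, n, mean, sem, pct_mean,
#'   pct_sem, f_statistic, anova_p, dunnett_p, stars) with the per-endpoint
#'   outlier log attached as attribute `"outliers"`.
#' @export
build_report <- function(endpoints, reference, outlier_sd = 2) {
  stopifnot(is.list(endpoints), !is.null(names(endpoints)))
  sem <- function(v) sd(v) / sqrt(length(v))
  rows <- list()
  outlier_log <- list()
  for (nm in names(endpoints)) {
    tbl <- endpoints[[nm]]
    if (is.null(tbl) || nrow(tbl) == 0) {
      warn(sprintf("endpoint '%s' is empty; omitted from report", nm))
      next
    }
    if (!"channel" %in% names(tbl)) tbl$channel <- NA_character_
    for (ch in unique(tbl$channel)) {
      sub <- tbl[if (is.na(ch)) is.na(tbl$channel) else tbl$channel == ch, ]
      clean <- remove_outliers(sub, k = outlier_sd)
      out_rows <- attr(clean, "outliers")
      if (nrow(out_rows) > 0) {
        out_rows$endpoint <- nm
        outlier_log[[length(outlier_log) + 1L]] <- out_rows
      }
      clean <- percent_of_reference(clean, "value", reference)
      fit <- anova_dunnett(clean, reference)
      per_arm <- dplyr::summarise(
        dplyr::group_by(clean, .data$arm),
        n = dplyr::n(), mean = mean(.data$value), sem = sem(.data$value),
        pct_mean = mean(.data$percent), pct_sem = sem(.data$percent),
        .groups = "drop"
      )
      per_arm <- dplyr::left_join(
        per_arm,
        dplyr::select(fit$comparisons, "arm", "p_adj", "stars"),
        by = "arm"
      )
      per_arm <- dplyr::mutate(per_arm,
        endpoint = nm, channel = ch,
        f_statistic = fit$f_statistic, anova_p = fit$p_value,
        .before = 1
      )
      rows[[length(rows) + 1L]] <- dplyr::rename(per_arm, dunnett_p = "p_adj")
    }
  }
  if (length(rows) == 0) stop_input("no endpoint could be analyzed")
  report <- dplyr::bind_rows(rows)
  attr(report, "outliers") <- dplyr::bind_rows(outlier_log)
  report
}
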