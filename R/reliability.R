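#' Subjects-by-measurements ratings table
#'
#' Container for a balanced repeated-measurements design: `n` subjects in
#' rows, `k` repeated measurements (raters, sessions or repeats) in
#' columns, with the study design recorded (`inter_rater`, `test_retest`
#' or `intra_rater`). Listwise completeness is required: no missing cells.
#'
#' @param x Numeric matrix (or data frame) of measurements, subjects in
#'   rows. At least 2 rows and 2 columns, no `NA`.
#' @param design One of `"inter_rater"`, `"test_retest"`, `"intra_rater"`.
#' @param metric_name,units Descriptive labels carried into reports.
#' @return An object of class `ratings_table`.
#' @export
ratings_table <- function(x, design = c("inter_rater", "test_retest", "intra_rater"),
                          metric_name = "", units = "") {
  design <- match.arg(design)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("ratings must be numeric")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 subjects and 2 measurements")
  if (anyNA(m)) stop("ratings table has missing cells; listwise completeness is required")
  structure(list(matrix = m, design = design,
                 metric_name = metric_name, units = units),
            class = "ratings_table")
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf("Ratings table (%s): %d subjects x %d measurements%s\n",
              x$design, nrow(x$matrix), ncol(x$matrix),
              if (nzchar(x$metric_name))
                sprintf(" of %s [%s]", x$metric_name, x$units) else ""))
  invisible(x)
}

as_ratings_matrix <- function(x) {
  if (inherits(x, "ratings_table")) x$matrix
  else {
    m <- as.matrix(x)
    if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L || anyNA(m))
      stop("need a complete numeric matrix with >= 2 rows and >= 2 columns")
    m
  }
}

#' Two-way ANOVA mean squares of a ratings table
#'
#' Decomposes the total sum of squares of an `n x k` ratings table into
#' between-subjects, between-measurements and residual components
#' (`SS_total = SS_subjects + SS_measurements + SS_residual`) with degrees
#' of freedom `n - 1`, `k - 1` and `(n - 1)(k - 1)`. These are the variance
#' components underlying the two-way mixed-effects consistency ICC.
#'
#' @param table A [ratings_table()] or numeric matrix.
#' @return An object of class `anova_components`: mean squares `BMS`
#'   (between subjects), `JMS` (between measurements), `EMS` (residual),
#'   their `df`, and the sums of squares.
#' @export
anova_components <- function(table) {
  m <- as_ratings_matrix(table)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_b <- k * sum((row_means - grand)^2)
  ss_j <- n * sum((col_means - grand)^2)
  ss_t <- sum((m - grand)^2)
  ss_e <- ss_t - ss_b - ss_j
  # guard tiny negative residual from floating-point cancellation
  if (ss_e < 0 && ss_e > -1e-8 * max(ss_t, 1)) ss_e <- 0
  df_b <- n - 1L; df_j <- k - 1L; df_e <- (n - 1L) * (k - 1L)
  structure(list(BMS = ss_b / df_b, JMS = ss_j / df_j, EMS = ss_e / df_e,
                 df = c(subjects = df_b, measurements = df_j, residual = df_e),
                 ss = c(subjects = ss_b, measurements = ss_j,
                        residual = ss_e, total = ss_t),
                 n = n, k = k),
            class = "anova_components")
}

#' @export
print.anova_components <- function(x, ...) {
  cat("Two-way ANOVA components\n")
  df <- data.frame(term = c("subjects", "measurements", "residual"),
                   df = unname(x$df),
                   SS = unname(x$ss[1:3]),
                   MS = c(x$BMS, x$JMS, x$EMS))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Intraclass correlation ICC(3,1) for fixed raters
#'
#' Fits the two-way mixed-effects, single-measure, consistency intraclass
#' correlation: `ICC = (BMS - EMS) / (BMS + (k - 1) EMS)`, where `BMS` and
#' `EMS` are the between-subjects and residual mean squares of the two-way
#' decomposition. Raters (measurements) are fixed effects, so ICC(3,1) is
#' invariant to adding any constant to a measurement column. The
#' `100(1 - alpha)%` confidence interval is the exact F-based interval:
#' with `F = BMS / EMS` on `(n-1, (n-1)(k-1))` degrees of freedom,
#' `FL = F / qf(1 - alpha/2)`, `FU = F * qf'(1 - alpha/2)` (quantile with
#' swapped df), and each bound maps through `(F* - 1) / (F* + k - 1)`.
#' The p-value is from the F test of the subject effect.
#'
#' @param x A [ratings_table()] or numeric matrix (subjects in rows).
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `icc31`: `icc`, `ci` (lower, upper),
#'   `p_value`, `interpretation` (see [interpret_icc()]), `components`
#'   ([anova_components()]), `n`, `k`, `alpha`, and `degenerate` (`TRUE`
#'   when the residual mean square is zero and the interval collapses).
#'   Negative estimates are reported as computed, not truncated.
#' @examples
#' rt <- simulate_ratings(30, 2, subject_sd = 3, error_sd = 1, seed = 42)
#' fit <- icc31(rt)
#' fit
#' confint(fit)
#' @export
icc31 <- function(x, alpha = 0.05) {
  comp <- anova_components(x)
  n <- comp$n; k <- comp$k
  design <- if (inherits(x, "ratings_table")) x$design else NA_character_
  if (comp$EMS == 0 && comp$BMS == 0)
    stop("degenerate table: no subject or residual variance; ICC undefined")
  degenerate <- comp$EMS == 0
  if (degenerate) {
    icc <- 1; ci <- c(1, 1); p <- 0
    warning("residual mean square is zero; ICC = 1 with degenerate CI [1, 1]")
  } else {
    icc <- (comp$BMS - comp$EMS) / (comp$BMS + (k - 1) * comp$EMS)
    f <- comp$BMS / comp$EMS
    df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(icc = icc, ci = ci, p_value = p,
                 interpretation = interpret_icc(icc),
                 components = comp, n = n, k = k, alpha = alpha,
                 design = design, degenerate = degenerate),
            class = "icc31")
}

#' @export
print.icc31 <- function(x, digits = 3, ...) {
  cat(sprintf("ICC(3,1) = %.*f (%d%% CI %.*f to %.*f), p = %s -- %s reliability\n",
              digits, x$icc, round(100 * (1 - x$alpha)),
              digits, x$ci[1], digits, x$ci[2],
              format.pval(x$p_value, digits = 2, eps = 1e-3),
              x$interpretation))
  cat(sprintf("  %d subjects x %d measurements%s\n", x$n, x$k,
              if (!is.na(x$design)) paste0(" (", x$design, ")") else ""))
  if (x$degenerate)
    cat("  note: zero residual variance; interval is degenerate\n")
  invisible(x)
}

#' @export
summary.icc31 <- function(object, ...) {
  print(object, ...)
  cat("\n")
  print(object$components)
  invisible(object)
}

#' @export
confint.icc31 <- function(object, parm, level, ...) {
  out <- matrix(object$ci, 1L, 2L,
                dimnames = list("icc", sprintf("%g %%", c(
                  100 * object$alpha / 2, 100 * (1 - object$alpha / 2)))))
  out
}

#' @export
coef.icc31 <- function(object, ...) c(icc = object$icc)

#' Standard error of measurement
#'
#' Classical SEM accompanying a consistency ICC: `SEM = sd * sqrt(1 - ICC)`.
#'
#' @param sd Non-negative standard deviation of the measurements (after
#'   removal of fixed measurement-column effects; see
#'   [pooled_sd_consistency()]).
#' @param icc ICC estimate, at most 1.
#' @return SEM in the units of `sd`.
#' @export
sem_from_sd <- function(sd, icc) {
  if (any(sd < 0)) stop("sd must be non-negative")
  if (any(icc > 1)) stop("icc cannot exceed 1")
  sd * sqrt(1 - icc)
}

#' Pooled SD for the SEM of a consistency design
#'
#' Standard deviation of the table cells after removing the fixed
#' measurement-column means -- the spread against which the consistency
#' ICC partitions subject and error variance.
#'
#' @param x A [ratings_table()] or numeric matrix.
#' @return Non-negative scalar SD.
#' @export
pooled_sd_consistency <- function(x) {
  m <- as_ratings_matrix(x)
  centred <- sweep(m, 2L, colMeans(m))
  stats::sd(as.vector(centred))
}

#' Smallest detectable change at 95% confidence
#'
#' `SDC95 = 1.96 * sqrt(2) * SEM`: the smallest difference between two
#' measurements that exceeds measurement error with 95% confidence.
#'
#' @param sem Non-negative SEM (any units).
#' @return SDC95 in the same units.
#' @examples
#' sdc95(18.9)   # 52.4 mm2
#' @export
sdc95 <- function(sem) {
  if (any(sem < 0)) stop("sem must be non-negative")
  1.96 * sqrt(2) * sem
}

#' Qualitative interpretation band of an ICC
#'
#' Bands: poor below 0.5, moderate in `[0.5, 0.75)`, good in `[0.75, 0.9]`,
#' excellent strictly above 0.9. Note the closed upper edge of "good": an
#' ICC of exactly 0.9 is good, not excellent.
#'
#' @param icc Numeric vector of ICC estimates (each at most 1).
#' @return Character vector of band labels.
#' @export
interpret_icc <- function(icc) {
  if (any(icc > 1)) stop("icc cannot exceed 1")
  ifelse(icc < 0.5, "poor",
         ifelse(icc < 0.75, "moderate",
                ifelse(icc <= 0.9, "good", "excellent")))
}

#' Mean absolute error
#'
#' Accuracy of test measurements against a reference modality.
#'
#' @param test,reference Equal-length numeric vectors.
#' @return Mean of `|test - reference|`.
#' @examples
#' mae(c(120, 271, 254), c(126, 258, 240))   # 11
#' @export
mae <- function(test, reference) {
  if (length(test) != length(reference)) stop("test and reference lengths differ")
  if (length(test) < 1L) stop("need at least one pair")
  mean(abs(test - reference))
}

#' Reliability report over contact measurements
#'
#' Builds one ratings table per metric (normalized contact area, ML and AP
#' centroid percent position) and compartment from a long table of repeated
#' contact measurements, and reports for each: ICC(3,1) with CI and
#' p-value, SEM and SDC95 in percent and in absolute units, and the
#' qualitative band. Absolute-unit SEMs are derived from the percent SEMs
#' through the cohort-mean plateau scale (maximum axial cross-section for
#' areas, plateau extent along the axis for centroids), so the percent and
#' absolute columns of each row are exact unit conversions of one another,
#' and `sdc = 1.96 * sqrt(2) * sem` holds exactly in both unit systems.
#'
#' @param measurements Data frame with columns `subject`, `measurement`
#'   (repeat index `1..k`), `compartment`, `area_pct`, `centroid_ml_pct`,
#'   `centroid_ap_pct`, `plateau_area_mm2`, `extent_ml_mm`, `extent_ap_mm`
#'   (as produced by [measure_contact()] plus design bookkeeping).
#' @param design Design label: `inter_rater`, `test_retest` or
#'   `intra_rater`.
#' @param alpha Confidence level for ICC intervals.
#' @return A data frame of class `reliability_report`, one row per
#'   metric x compartment: `design`, `compartment`, `metric`, `icc`,
#'   `ci_low`, `ci_high`, `p_value`, `sem_pct`, `sem_abs`, `sdc_pct`,
#'   `sdc_abs`, `abs_units`, `scale_mm`, `interpretation`.
#' @export
reliability_report <- function(measurements,
                               design = c("inter_rater", "test_retest", "intra_rater"),
                               alpha = 0.05) {
  design <- match.arg(design)
  req <- c("subject", "measurement", "compartment", "area_pct",
           "centroid_ml_pct", "centroid_ap_pct", "plateau_area_mm2",
           "extent_ml_mm", "extent_ap_mm")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols))
    stop("measurements lack column(s): ", paste(missing_cols, collapse = ", "))
  counts <- table(measurements$subject, measurements$compartment)
  if (length(unique(as.vector(counts))) != 1L)
    stop("unbalanced design; offending subjects: ",
         paste(rownames(counts)[apply(counts, 1L, function(r)
           any(r != max(counts)))], collapse = ", "))
  metrics <- list(
    area = list(col = "area_pct", scale = "plateau_area_mm2",
                units = "mm2", per_100 = TRUE),
    centroid_x = list(col = "centroid_ml_pct", scale = "extent_ml_mm",
                      units = "mm", per_100 = TRUE),
    centroid_y = list(col = "centroid_ap_pct", scale = "extent_ap_mm",
                      units = "mm", per_100 = TRUE))
  rows <- list()
  for (comp in sort(unique(measurements$compartment))) {
    sub <- measurements[measurements$compartment == comp, ]
    sub <- sub[order(sub$subject, sub$measurement), ]
    for (mn in names(metrics)) {
      spec <- metrics[[mn]]
      wide <- stats::reshape(
        sub[, c("subject", "measurement", spec$col)],
        idvar = "subject", timevar = "measurement", direction = "wide")
      m <- as.matrix(wide[, -1, drop = FALSE])
      rt <- ratings_table(m, design = design, metric_name = mn, units = "%")
      fit <- suppressWarnings(icc31(rt, alpha = alpha))
      sem_pct <- sem_from_sd(pooled_sd_consistency(rt), min(fit$icc, 1))
      scale_mm <- mean(sub[[spec$scale]])
      sem_abs <- sem_pct / 100 * scale_mm
      rows[[length(rows) + 1L]] <- data.frame(
        design = design, compartment = comp, metric = mn,
        icc = fit$icc, ci_low = fit$ci[1], ci_high = fit$ci[2],
        p_value = fit$p_value,
        sem_pct = sem_pct, sem_abs = sem_abs,
        sdc_pct = sdc95(sem_pct), sdc_abs = sdc95(sem_abs),
        abs_units = spec$units, scale_mm = scale_mm,
        interpretation = fit$interpretation)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Reliability report (%s)\n", paste(unique(x$design), collapse = ", ")))
  df <- as.data.frame(x)
  for (cn in c("icc", "ci_low", "ci_high", "sem_pct", "sem_abs",
               "sdc_pct", "sdc_abs", "scale_mm"))
    df[[cn]] <- round(df[[cn]], 3)
  df$p_value <- format.pval(df$p_value, digits = 2, eps = 1e-3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a reliability report to CSV and JSON
#'
#' @param report A [reliability_report()].
#' @param path Output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_reliability_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(as.data.frame(report), paste0(path, ".json"),
                       digits = NA, dataframe = "rows")
  invisible(path)
}
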