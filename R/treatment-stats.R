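#' Mean and standard error of replicate mesocosms
#'
#' @param values numeric vector of replicate measurements (one per
#'   mesocosm); at least two.
#' @return list with `mean`, `se` (sample sd / sqrt(n)) and `n`.
#' @export
#' @examples
#' summarize_replicates(c(1, 2, 3, 4, 5))
summarize_replicates <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L)
    stop("at least two replicate values are required for a standard error",
         call. = FALSE)
  list(mean = mean(values), se = sd(values) / sqrt(n), n = n)
}

#' Two-sample t-test per size class or group
#'
#' Compares replicate measurements (e.g. per-size-class biomass of the five
#' control vs the five high-CO2 mesocosms) with an independent two-sample
#' t-test. Homogeneity of variances is assessed beforehand with Levene's
#' test (Brown-Forsythe, median-centred): if variances are homogeneous at
#' `alpha`, the pooled-variance test is used, otherwise Welch's test.
#' Normality is assessed per arm with Shapiro-Wilk and reported as a
#' diagnostic flag; it does not switch the test to a non-parametric
#' alternative, staying within the t-test framework.
#'
#' @param control,treatment numeric replicate values, >= 2 each.
#' @param alpha significance threshold for both the assumption checks and
#'   the `significant` flag.
#' @param id optional label (size class or group) carried into the result.
#' @return one-row data.frame of class `"class_comparison"`: `id`,
#'   `mean_control`, `se_control`, `mean_treatment`, `se_treatment`,
#'   `t_statistic`, `df`, `p_value`, `significant`, `test_variant`
#'   (`"pooled"` or `"welch"`), `levene_p`, `shapiro_p_min`, `degenerate`.
#' @export
per_class_ttest <- function(control, treatment, alpha = 0.05, id = NA) {
  stopifnot(is.numeric(control), is.numeric(treatment))
  if (length(control) < 2L || length(treatment) < 2L)
    stop("need at least 2 values per arm", call. = FALSE)
  sc <- summarize_replicates(control)
  st <- summarize_replicates(treatment)

  degenerate <- var(control) == 0 && var(treatment) == 0
  if (degenerate) {
    equal <- isTRUE(all.equal(sc$mean, st$mean))
    res <- data.frame(
      id = id, mean_control = sc$mean, se_control = 0,
      mean_treatment = st$mean, se_treatment = 0,
      t_statistic = if (equal) 0 else Inf * sign(sc$mean - st$mean),
      df = sc$n + st$n - 2, p_value = if (equal) 1 else 0,
      significant = !equal, test_variant = "pooled",
      levene_p = NA_real_, shapiro_p_min = NA_real_, degenerate = TRUE,
      stringsAsFactors = FALSE)
    class(res) <- c("class_comparison", "data.frame")
    return(res)
  }

  g <- factor(rep(c("control", "treatment"),
                  c(length(control), length(treatment))))
  vals <- c(control, treatment)
  # leveneTest warns when the spread statistic is itself nearly constant
  # (near-degenerate classes); the decision below is still well defined
  lev <- suppressWarnings(car::leveneTest(vals ~ g, center = median))
  levene_p <- lev[["Pr(>F)"]][1]
  pooled <- is.na(levene_p) || levene_p >= alpha
  tt <- t.test(control, treatment, var.equal = pooled)

  shap <- function(x) {
    if (length(unique(x)) < 3L) return(NA_real_)
    shapiro.test(x)$p.value
  }
  shapiro_min <- suppressWarnings(min(c(shap(control), shap(treatment)),
                                      na.rm = TRUE))
  if (!is.finite(shapiro_min)) shapiro_min <- NA_real_

  res <- data.frame(
    id = id, mean_control = sc$mean, se_control = sc$se,
    mean_treatment = st$mean, se_treatment = st$se,
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value < alpha,
    test_variant = if (pooled) "pooled" else "welch",
    levene_p = levene_p, shapiro_p_min = shapiro_min, degenerate = FALSE,
    stringsAsFactors = FALSE)
  class(res) <- c("class_comparison", "data.frame")
  res
}

#' t-test from published summary statistics
#'
#' Reconstructs an independent two-sample t-test from group means and
#' standard errors, as printed in a results table:
#' `t = (mean1 - mean2) / sqrt(se1^2 + se2^2)`, with `n1 + n2 - 2` degrees
#' of freedom for the pooled rule or Welch-Satterthwaite degrees of freedom
#' computed from the SEs otherwise. With equal group sizes the pooled
#' statistic from summaries equals the pooled statistic from raw data.
#'
#' @param mean1,se1,n1 summary of the first group (SE >= 0, n >= 2).
#' @param mean2,se2,n2 summary of the second group.
#' @param df_rule `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' # copepod total biomass, high CO2 vs control, five mesocosms each:
#' ttest_from_summary(3.68, 0.31, 5, 2.58, 0.40, 5)
ttest_from_summary <- function(mean1, se1, n1, mean2, se2, n2,
                               df_rule = c("pooled", "welch")) {
  df_rule <- match.arg(df_rule)
  stopifnot(se1 >= 0, se2 >= 0, n1 >= 2, n2 >= 2)
  if (se1 == 0 && se2 == 0) {
    if (isTRUE(all.equal(mean1, mean2)))
      stop("both SEs are zero and the means are equal: the test statistic ",
           "is undefined", call. = FALSE)
    return(list(t = Inf * sign(mean1 - mean2), df = n1 + n2 - 2, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(se1^2 + se2^2)
  df <- if (df_rule == "pooled") n1 + n2 - 2 else
    (se1^2 + se2^2)^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Squared Pearson correlation
#'
#' Coefficient of determination of a simple linear association, used e.g.
#' to validate image-derived biomass against independent analytical
#' measurements.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return squared Pearson correlation in \[0, 1\].
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  cor(x, y)^2
}

#' Per-size-class treatment comparison of spectra or biomass tables
#'
#' Runs [per_class_ttest()] for every class (spectrum bin or taxon group)
#' of a long-format table of per-mesocosm values. Classes with fewer than
#' two replicates per arm, or absent from one arm, are skipped with a note.
#' No multiple-testing correction is applied across classes, matching the
#' per-class p < alpha reporting convention of mesocosm studies; the
#' expected number of false positives (`alpha` times the number of classes
#' tested) is attached so that this choice stays transparent.
#'
#' @param values data.frame with columns `mesocosm`, `class` (bin midpoint
#'   or group label) and `value`.
#' @param design data.frame with columns `mesocosm`, `treatment`
#'   (`"control"` / `"high_co2"`).
#' @param alpha per-class significance threshold.
#' @return data.frame of class comparisons (one row per class tested) with
#'   attributes `n_skipped` and `expected_false_positives`.
#' @export
compare_size_classes <- function(values, design, alpha = 0.05) {
  stopifnot(all(c("mesocosm", "class", "value") %in% names(values)),
            all(c("mesocosm", "treatment") %in% names(design)))
  trt <- setNames(design$treatment, design$mesocosm)
  if (!all(values$mesocosm %in% names(trt)))
    stop("mesocosms in 'values' missing from 'design'", call. = FALSE)
  values$treatment <- trt[values$mesocosm]
  out <- list(); skipped <- 0L
  for (cl in unique(values$class)) {
    v <- values[values$class == cl, ]
    ctl <- v$value[v$treatment == "control"]
    hi <- v$value[v$treatment == "high_co2"]
    if (length(ctl) < 2L || length(hi) < 2L) {
      skipped <- skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- per_class_ttest(ctl, hi, alpha, id = cl)
  }
  res <- if (length(out)) do.call(rbind, out) else
    per_class_ttest(c(0, 1), c(0, 1))[0, ]
  attr(res, "n_skipped") <- skipped
  attr(res, "expected_false_positives") <- alpha * nrow(res)
  res
}
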