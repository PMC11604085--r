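#' Normalise marker expression to a high percentile
#'
#' For each marker, pooled across all cells of the table, the `q`-th
#' percentile `P` of the raw intensities is computed (linear
#' interpolation between order statistics) and values are scaled as
#' `min(raw, P) / P`, i.e. clipped to \[0, 1\]. Markers whose percentile
#' is zero are set to 0 with a warning. Normalised values are stored in
#' `norm_<marker>` columns.
#'
#' The operation is idempotent on the normalised columns and invariant to
#' rescaling all raw values of a marker by a positive constant.
#'
#' @param table a `cell_table` with raw intensities.
#' @param q percentile in (0, 100\]; default 99.9.
#' @return The table with `norm_<marker>` columns added/replaced and the
#'   per-marker percentiles in the `"norm_percentiles"` attribute.
#' @export
normalize_expression <- function(table, q = 99.9) {
  stopifnot(q > 0, q <= 100)
  mk <- markers(table)
  if (nrow(table) == 0) {
    for (m in mk) table[[paste0("norm_", m)]] <- numeric()
    return(table)
  }
  P <- setNames(numeric(length(mk)), mk)
  for (m in mk) {
    P[[m]] <- percentile(table[[m]], q)
    if (P[[m]] == 0) {
      warnf("normalize_expression: marker '%s' has zero %gth percentile; normalised to 0", m, q)
      table[[paste0("norm_", m)]] <- rep(0, nrow(table))
    } else {
      table[[paste0("norm_", m)]] <- pmin(table[[m]], P[[m]]) / P[[m]]
    }
  }
  attr(table, "norm_percentiles") <- P
  table
}

# Matrix of normalised values (cells x markers); errors if absent.
norm_matrix <- function(table) {
  mk <- markers(table)
  cols <- paste0("norm_", mk)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stopf("table has no normalised values; run normalize_expression()")
  m <- as.matrix(as.data.frame(table)[cols])
  colnames(m) <- mk
  m
}

#' Mean normalised expression per case
#'
#' Arithmetic mean of a marker's normalised value over all cells of each
#' case (ROIs pooled). Cases present in `table` with zero cells cannot
#' occur (cases are defined by their cells), so the map covers exactly
#' the cases that have cells.
#'
#' @param table a normalised `cell_table`.
#' @param marker marker name.
#' @return Named numeric vector, one entry per case.
#' @export
case_mean_expression <- function(table, marker) {
  if (!marker %in% markers(table)) stopf("unknown marker '%s'", marker)
  col <- paste0("norm_", marker)
  if (!col %in% names(table)) stopf("no normalised values; run normalize_expression()")
  tapply(table[[col]], table$case_id, mean)[unique(table$case_id)]
}

#' Cell densities per square millimetre
#'
#' Counts of cells divided by the summed area of the case's ROIs. The
#' denominator always includes every ROI of the case in `geometry`
#' (including ROIs with no matching cells), so strata with zero cells
#' report density 0.
#'
#' @param table a `cell_table`.
#' @param geometry a `roi_geometry` covering every `roi_id` in the table.
#' @param stratum `"case"` for total density per case,
#'   `"case_population"` or `"case_hierarchy"` to stratify by the
#'   corresponding label column.
#' @return A data frame with columns `case_id`, (optionally `label`), and
#'   `density_per_mm2`.
#' @export
cell_density <- function(table, geometry,
                         stratum = c("case", "case_population", "case_hierarchy")) {
  stratum <- match.arg(stratum)
  unknown <- setdiff(unique(table$roi_id), geometry$roi_id)
  if (length(unknown)) stopf("roi_id without geometry: %s",
                             paste(unknown, collapse = ", "))
  area_by_case <- tapply(geometry$area_mm2, geometry$case_id, sum)
  cases <- names(area_by_case)
  if (stratum == "case") {
    cnt <- table(factor(table$case_id, levels = cases))
    return(data.frame(case_id = cases,
                      density_per_mm2 = as.numeric(cnt) / as.numeric(area_by_case),
                      stringsAsFactors = FALSE))
  }
  lab_col <- if (stratum == "case_population") "population_label" else "hierarchy_label"
  if (!lab_col %in% names(table)) stopf("table has no '%s' column", lab_col)
  labs <- sort(unique(table[[lab_col]]))
  cnt <- table(factor(table$case_id, levels = cases),
               factor(table[[lab_col]], levels = labs))
  out <- expand.grid(case_id = cases, label = labs, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$density_per_mm2 <- as.numeric(cnt[cbind(out$case_id, out$label)]) /
    as.numeric(area_by_case[out$case_id])
  out
}

#' Normality-gated correlation with growth rate
#'
#' Tests both variables for normality (Shapiro-Wilk); when both pass at
#' `alpha`, a two-tailed Pearson correlation is reported, otherwise a
#' two-tailed Spearman correlation. A simple linear regression on the raw
#' pairs is fitted in either case.
#'
#' @param values named numeric vector, one value per case.
#' @param metadata a `case_metadata` data frame supplying
#'   `growth_rate_pct_per_year` per case.
#' @param alpha normality-gate level, default 0.05.
#' @return A `correlation_result` list: `method`, `r`, `p_two_tailed`,
#'   `slope`, `intercept`, `normality_p_x`, `normality_p_y`, `n`.
#' @export
correlate_with_growth <- function(values, metadata, alpha = 0.05) {
  common <- intersect(names(values), metadata$case_id)
  x <- metadata$growth_rate_pct_per_year[match(common, metadata$case_id)]
  y <- as.numeric(values[common])
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("correlate_with_growth needs at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: zero variance")
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  method <- if (px >= alpha && py >= alpha) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided", exact = FALSE))
  fit <- stats::lm(y ~ x)
  structure(list(method = method, r = unname(ct$estimate),
                 p_two_tailed = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 normality_p_x = px, normality_p_y = py, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$method, x$r, x$p_two_tailed, x$n))
  cat(sprintf("linear fit: y = %.4g + %.4g x; normality p (x, y) = %.3g, %.3g\n",
              x$intercept, x$slope, x$normality_p_x, x$normality_p_y))
  invisible(x)
}

#' Normality-gated group comparison
#'
#' Two-sample design: both groups are tested for normality
#' (Shapiro-Wilk); when both pass at `alpha`, a two-tailed unpaired
#' t-test is used, otherwise a two-tailed Mann-Whitney test. Groups with
#' fewer than 3 observations cannot be tested for normality and fall
#' back to Mann-Whitney with a warning. Two-way design: a two-way ANOVA
#' with interaction on the supplied factors.
#'
#' @param values numeric vector of case-level values (two-sample), or a
#'   data frame with columns `value`, `factorA`, `factorB` (two-way).
#' @param group factor/character of group membership (two-sample design).
#' @param design `"two_sample"` or `"two_way"`.
#' @param alpha normality-gate level.
#' @return A `group_comparison_result` list: `test`, `statistic`, `p`,
#'   `group_summaries` (and `anova_table` for the two-way design).
#' @export
compare_groups <- function(values, group = NULL,
                           design = c("two_sample", "two_way"), alpha = 0.05) {
  design <- match.arg(design)
  if (design == "two_sample") {
    stopifnot(length(values) == length(group))
    ok <- is.finite(values)
    values <- values[ok]; group <- as.character(group)[ok]
    gl <- sort(unique(group))
    if (length(gl) != 2) stopf("two_sample design needs exactly 2 groups")
    a <- values[group == gl[1]]; b <- values[group == gl[2]]
    if (!length(a) || !length(b)) stopf("both groups must be non-empty")
    if (length(a) < 3 || length(b) < 3) {
      warnf("group with n < 3: normality untestable, using Mann-Whitney")
      normal <- FALSE; pa <- NA_real_; pb <- NA_real_
    } else {
      pa <- tryCatch(stats::shapiro.test(a)$p.value, error = function(e) 0)
      pb <- tryCatch(stats::shapiro.test(b)$p.value, error = function(e) 0)
      normal <- pa >= alpha && pb >= alpha
    }
    if (normal) {
      tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
      res <- list(test = "t_test", statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                                exact = TRUE))
      res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                  p = wt$p.value)
    }
    res$normality_p <- c(pa, pb)
    res$group_summaries <- data.frame(
      group = gl, n = c(length(a), length(b)),
      mean = c(mean(a), mean(b)), median = c(stats::median(a), stats::median(b)),
      stringsAsFactors = FALSE)
    return(structure(res, class = "group_comparison_result"))
  }
  # two-way ANOVA with interaction
  stopifnot(is.data.frame(values),
            all(c("value", "factorA", "factorB") %in% names(values)))
  d <- values
  d$factorA <- factor(d$factorA); d$factorB <- factor(d$factorB)
  fit <- stats::aov(value ~ factorA * factorB, data = d)
  tab <- summary(fit)[[1]]
  res <- list(test = "anova_2way",
              statistic = tab[["F value"]][1],
              p = tab[["Pr(>F)"]][1],
              anova_table = tab,
              group_summaries = stats::aggregate(value ~ factorA + factorB,
                                                 data = d, FUN = mean))
  structure(res, class = "group_comparison_result")
}

#' @export
print.group_comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p))
  print(x$group_summaries)
  invisible(x)
}
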