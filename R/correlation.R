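#' Pearson correlation with t-distributed significance
#'
#' Sample Pearson r with a two-tailed p-value from the exact
#' t-transform `t = r * sqrt(df / (1 - r^2))` on `df = n - 2` degrees of
#' freedom. With 17 processor-gap sequences this is the `r(15)`
#' reported for model-vs-annotation KPS columns.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, both non-constant.
#' @return List with `r`, `df`, `p_two_tailed`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t), df)
  }
  list(r = r, df = df, p_two_tailed = p)
}

#' Shapiro-Wilk normality test
#'
#' Pearson correlation assumes both samples are drawn from normal
#' distributions; this checks that assumption. Wraps the Royston (1995)
#' algorithm (AS R94), valid for 3 <= n <= 5000.
#'
#' @param x Numeric vector, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (stats::sd(x) == 0) stopf("Shapiro-Wilk undefined for a constant vector")
  if (length(x) < 3L || length(x) > 5000L) stopf("need 3 <= n <= 5000")
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric vectors, `n >= 2`, `x` non-constant.
#' @return List with `slope` and `intercept` minimizing
#'   `sum((y - slope * x - intercept)^2)`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) stopf("need n >= 2 pairs")
  if (stats::sd(x) == 0) stopf("singular fit: x is constant")
  co <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Correlation analysis of one model's KPS against annotation KPS
#'
#' Runs the full per-model analysis on a KPS table: Shapiro-Wilk
#' normality on both columns, Pearson r with df = n - 2 and two-tailed
#' p, the variance explained (100 r^2), and the least-squares line of
#' model KPS on annotation KPS. Because normality is an assumption of
#' the Pearson test, the report refuses to proceed when either
#' Shapiro-Wilk p-value falls below 0.05 unless `force = TRUE`.
#'
#' @param kps_tab Data frame with one row per sequence, the model
#'   column, and an `annotation` column (see [kps_table()],
#'   [table4_kps()]).
#' @param model Name of the model column.
#' @param force Proceed even if a normality test rejects at 0.05.
#' @return A list of class `kps_correlation`: `model`, `n`, `df`, `r`,
#'   `p_two_tailed`, `r_squared_percent`, `slope`, `intercept`,
#'   `shapiro_w_x`, `shapiro_p_x`, `shapiro_w_y`, `shapiro_p_y`
#'   (x = annotation, y = model).
#' @export
correlation_report <- function(kps_tab, model, force = FALSE) {
  if (!model %in% names(kps_tab))
    stopf("no column `%s` in KPS table", model)
  if (!"annotation" %in% names(kps_tab))
    stopf("KPS table has no `annotation` column")
  y <- kps_tab[[model]]
  x <- kps_tab$annotation
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    ids <- if (!is.null(kps_tab$sequence_id)) kps_tab$sequence_id[bad] else which(bad)
    stopf("missing KPS cells for sequences: %s", paste(ids, collapse = ", "))
  }
  swx <- shapiro_wilk(x)
  swy <- shapiro_wilk(y)
  if (!force && (swx$p < 0.05 || swy$p < 0.05))
    stopf(paste("Shapiro-Wilk rejects normality (p = %.3g / %.3g);",
                "Pearson assumptions violated - use force = TRUE to override"),
          swx$p, swy$p)
  pr <- pearson(x, y)
  fit <- linear_fit(x, y)
  structure(list(model = model, n = length(x), df = pr$df, r = pr$r,
                 p_two_tailed = pr$p_two_tailed,
                 r_squared_percent = 100 * pr$r^2,
                 slope = fit$slope, intercept = fit$intercept,
                 shapiro_w_x = swx$W, shapiro_p_x = swx$p,
                 shapiro_w_y = swy$W, shapiro_p_y = swy$p),
            class = "kps_correlation")
}

#' @export
print.kps_correlation <- function(x, ...) {
  cat(sprintf("%s vs annotation KPS: r(%d) = %.2f, p = %.2g, r2 = %.1f%%\n",
              x$model, x$df, x$r, x$p_two_tailed, x$r_squared_percent))
  cat(sprintf("  fit: model = %.3f * annotation + %.2f\n", x$slope, x$intercept))
  cat(sprintf("  Shapiro-Wilk: annotation W = %.2f (p = %.2f), model W = %.2f (p = %.2f)\n",
              x$shapiro_w_x, x$shapiro_p_x, x$shapiro_w_y, x$shapiro_p_y))
  invisible(x)
}

#' Scatter plot of model KPS against annotation KPS with its fit line
#'
#' @param kps_tab KPS table (see [correlation_report()]).
#' @param model Model column name.
#' @return A ggplot object.
#' @export
plot_kps_fit <- function(kps_tab, model) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_kps_fit needs the ggplot2 package")
  fit <- linear_fit(kps_tab$annotation, kps_tab[[model]])
  df <- data.frame(annotation = kps_tab$annotation, model_kps = kps_tab[[model]])
  ggplot2::ggplot(df, ggplot2::aes(x = annotation, y = model_kps)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "Annotation KPS (%)", y = sprintf("%s KPS (%%)", model),
                  title = sprintf("y = %.2fx %+.1f", fit$slope, fit$intercept))
}
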