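# container for the regression / t-test summaries reported throughout

#' Statistical result container
#'
#' Light-weight container for the slope/t/F summaries the analyses report.
#'
#' @param kind one of `"unpaired_t"`, `"paired_t"`, `"ols_slope_t"`,
#'   `"ols_slope_F"`.
#' @param beta effect estimate (slope or mean difference).
#' @param statistic t or F value.
#' @param df degrees of freedom (length 1 for t, length 2 for F).
#' @param p p-value.
#' @param r_squared optional coefficient of determination.
#' @return A `vvs_stat` list.
#' @export
vvs_stat <- function(kind, beta, statistic, df, p, r_squared = NULL) {
  structure(list(kind = kind, beta = beta, statistic = statistic,
                 df = df, p = p, r_squared = r_squared),
            class = "vvs_stat")
}

#' @export
print.vvs_stat <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ",")
  lab <- switch(x$kind,
                unpaired_t = , paired_t = , ols_slope_t = "t",
                ols_slope_F = "F", "stat")
  r2 <- if (!is.null(x$r_squared)) sprintf("R2=%.2f, ", x$r_squared) else ""
  cat(sprintf("<vvs_stat %s> %sbeta=%.3g, %s(%s)=%.3g, p=%.3g\n",
              x$kind, r2, x$beta, lab, dfs, x$statistic, x$p))
  invisible(x)
}

# OLS of y on x with intercept; returns slope stats + R^2.
ols_slope_stat <- function(x, y, kind = c("ols_slope_t", "ols_slope_F")) {
  kind <- match.arg(kind)
  if (stats::sd(x) == 0) vvs_abort("zero-variance predictor in regression")
  fit <- stats::lm(y ~ x)
  sm <- muffle_warning(summary(fit), "essentially perfect fit")
  tval <- sm$coefficients["x", "t value"]
  p <- sm$coefficients["x", "Pr(>|t|)"]
  df2 <- fit$df.residual
  if (kind == "ols_slope_t") {
    vvs_stat(kind, beta = unname(stats::coef(fit)["x"]), statistic = tval,
             df = df2, p = p, r_squared = sm$r.squared)
  } else {
    vvs_stat(kind, beta = unname(stats::coef(fit)["x"]), statistic = tval^2,
             df = c(1, df2), p = p, r_squared = sm$r.squared)
  }
}
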