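#' Estimate the specific growth rate from an OD600 series
#'
#' The specific growth rate mu is the slope of the least-squares fit of
#' `ln(OD600)` against time over an exponential-phase window. If no window is
#' given, the contiguous sub-window of at least `min_points` points with the
#' highest R-squared is chosen (longest, then earliest, among ties), which on
#' a clean exponential selects the whole series. A constant series yields
#' `mu = 0` exactly.
#'
#' @param series A tibble with columns `time_h` and `od600` (> 0).
#' @param window Optional `c(t_min, t_max)` interval (hours) to fit within.
#' @param min_points Minimum points in an automatically chosen window.
#' @return An object of class `evo_growth`: `mu` (per hour), `window`,
#'   `n_points`, `sigma` (residual standard error), `r_squared`, and the
#'   underlying `lm` fit.
#' @export
specific_growth_rate <- function(series, window = NULL, min_points = 4) {
  assert_columns(series, c("time_h", "od600"), "series")
  if (any(series$od600 <= 0)) {
    abort("OD600 values must be positive",
          class = "evotrace_invalid_argument")
  }
  series <- arrange(series, .data$time_h)
  if (!is.null(window)) {
    sub <- filter(series, .data$time_h >= window[1], .data$time_h <= window[2])
    if (nrow(sub) < 3L) {
      abort("need at least 3 points in the fit window",
            class = "evotrace_invalid_argument")
    }
    return(fit_growth(sub))
  }
  n <- nrow(series)
  if (n < min_points) {
    abort(sprintf("need at least %d points", min_points),
          class = "evotrace_invalid_argument")
  }
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      fit <- fit_growth(series[i:j, ])
      better <- is.null(best) ||
        fit$r_squared > best$r_squared + 1e-10 ||
        (abs(fit$r_squared - best$r_squared) <= 1e-10 &&
           fit$n_points > best$n_points)
      if (better) best <- fit
    }
  }
  best
}

fit_growth <- function(sub) {
  y <- log(sub$od600)
  fit <- lm(y ~ sub$time_h)
  mu <- unname(coef(fit)[2])
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-20) 1 else 1 - rss / tss # flat series: perfect fit
  structure(list(mu = mu,
                 window = range(sub$time_h),
                 n_points = nrow(sub),
                 sigma = sqrt(rss / max(fit$df.residual, 1)),
                 r_squared = r2,
                 fit = fit),
            class = "evo_growth")
}

#' @export
print.evo_growth <- function(x, ...) {
  cat(sprintf("<evo_growth> mu = %.4f /h over [%g, %g] h (%d points, R2 = %.4f)\n",
              x$mu, x$window[1], x$window[2], x$n_points, x$r_squared))
  invisible(x)
}

#' Compare group growth rates with one-way ANOVA and Dunnett's test
#'
#' Fits a one-way ANOVA across all groups, then performs Dunnett's
#' many-to-one comparison of every group against the control. Adjusted
#' p-values are computed from the null distribution of the maximum absolute
#' component of the equicorrelated multivariate t, evaluated by seeded
#' Monte-Carlo integration (`n_mc` draws sharing one chi-squared denominator
#' per draw), so arbitrary group counts and unbalanced designs are handled
#' without tables. Significance stars: `*` < 0.05, `**` < 0.01, `***` < 0.001.
#'
#' @param df A tibble with one row per replicate culture.
#' @param rate_col Name of the numeric growth-rate column.
#' @param group_col Name of the group (strain) column.
#' @param control Label of the control group (e.g. the parent strain).
#' @param n_mc Monte-Carlo draws for the null max-|t| distribution.
#' @param seed Integer seed for the Monte-Carlo integration.
#' @return An object of class `evo_dunnett`: `anova` (tibble: F, p, dfs),
#'   `comparisons` (tibble: group, n, mean, sd, estimate vs control, t,
#'   p_unadjusted, p_adjusted, stars), plus `control`, `n_mc`, `seed`.
#' @export
compare_growth_dunnett <- function(df, rate_col = "mu", group_col = "group",
                                   control = "parent", n_mc = 1e5,
                                   seed = 1L) {
  assert_columns(df, c(rate_col, group_col), "df")
  y <- df[[rate_col]]
  g <- as.character(df[[group_col]])
  if (!control %in% g) {
    abort(sprintf("control group '%s' not present", control),
          class = "evotrace_invalid_argument")
  }
  groups <- unique(g)
  if (length(groups) < 2L) {
    abort("need at least 2 groups", class = "evotrace_invalid_argument")
  }
  ns <- table(g)
  if (any(ns < 2L)) {
    abort("every group needs at least 2 replicates",
          class = "evotrace_invalid_argument")
  }

  fit <- aov(y ~ factor(g))
  an <- summary(fit)[[1L]]
  df_err <- an["Residuals", "Df"]
  mse <- an["Residuals", "Mean Sq"]
  if (!is.finite(mse) || mse <= 1e-18 * max(abs(y), 1)^2) {
    abort("zero within-group variance across all groups",
          class = "evotrace_degenerate_variance")
  }
  anova_tbl <- tibble(statistic = an[1L, "F value"],
                      p_value = an[1L, "Pr(>F)"],
                      df_between = an[1L, "Df"], df_within = df_err)

  trt <- setdiff(groups, control)
  n0 <- as.numeric(ns[[control]])
  m0 <- mean(y[g == control])
  comp <- purrr::map_dfr(trt, function(gr) {
    yi <- y[g == gr]
    est <- mean(yi) - m0
    se <- sqrt(mse * (1 / length(yi) + 1 / n0))
    tibble(group = gr, n = length(yi), mean = mean(yi), sd = sd(yi),
           estimate = est, t = est / se)
  })

  lambda <- sqrt((1 / n0) / (1 / comp$n + 1 / n0))
  maxt <- with_seed(seed, dunnett_null_maxt(lambda, df_err, n_mc))
  comp <- comp |>
    mutate(
      p_unadjusted = 2 * pt(abs(.data$t), df_err, lower.tail = FALSE),
      p_adjusted = vapply(abs(.data$t),
                          function(tt) mean(maxt >= tt), numeric(1)),
      p_adjusted = pmax(.data$p_adjusted, .data$p_unadjusted),
      stars = dplyr::case_when(
        .data$p_adjusted < 0.001 ~ "***",
        .data$p_adjusted < 0.01 ~ "**",
        .data$p_adjusted < 0.05 ~ "*",
        TRUE ~ ""
      ))

  structure(list(anova = anova_tbl, comparisons = comp, control = control,
                 control_mean = m0, df_error = df_err, mse = mse,
                 lambda = lambda, n_mc = n_mc, seed = seed),
            class = "evo_dunnett")
}

# Monte-Carlo samples of max_i |T_i| where T is the Dunnett many-to-one
# statistic vector: T_i = Z_i / sqrt(W / df), Z equicorrelated standard
# normal (Z_i = lambda_i Z0 + sqrt(1 - lambda_i^2) E_i), W ~ chi^2_df shared.
dunnett_null_maxt <- function(lambda, df, n_mc) {
  k <- length(lambda)
  z0 <- rnorm(n_mc)
  maxz <- matrix(rnorm(n_mc * k), ncol = k)
  for (i in seq_len(k)) {
    maxz[, i] <- abs(lambda[i] * z0 + sqrt(1 - lambda[i]^2) * maxz[, i])
  }
  denom <- sqrt(rchisq(n_mc, df) / df)
  apply(maxz, 1L, max) / denom
}

#' @export
print.evo_dunnett <- function(x, ...) {
  cat(sprintf("<evo_dunnett> ANOVA F = %.3f (p = %.3g); control = '%s'\n",
              x$anova$statistic, x$anova$p_value, x$control))
  print(select(x$comparisons, "group", "estimate", "t", "p_adjusted", "stars"))
  invisible(x)
}
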