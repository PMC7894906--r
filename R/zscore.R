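# Z-score abnormality baselines: the individual-history statistic (exact
# Student-t reference) and the population-informed variant with a universal
# within-subject variance.

#' Individual-history Z-score
#'
#' Standardises a new observation against the subject's own history:
#' `z = (y_new - mean(history)) / (sd(history) * sqrt(1 + 1/(n+1)))`. The
#' exact null distribution is Student t with `n - 1` degrees of freedom, so
#' the two-sided p-value uses that reference. The `1/(n+1)` term inside the
#' scaling is kept as in the source formulation; set
#' `conventional_factor = TRUE` for the usual prediction-interval factor
#' `sqrt(1 + 1/n)`.
#'
#' @param history Numeric vector of `n >= 2` past values with nonzero
#'   variance.
#' @param new_value The observation to assess.
#' @param conventional_factor Use `sqrt(1 + 1/n)` instead of
#'   `sqrt(1 + 1/(n+1))`.
#' @return A list of class `zscore_result`: `z`, `df`, `p_two_sided`,
#'   `method = "individual"`.
#' @examples
#' zscore_individual(c(1, 2, 3), 4)
#' @export
zscore_individual <- function(history, new_value, conventional_factor = FALSE) {
  history <- as.numeric(history)
  n <- length(history)
  if (n < 2) stop_data("insufficient history")
  s <- sd(history)
  if (s == 0) stop_data("degenerate history")
  fac <- if (conventional_factor) sqrt(1 + 1 / n) else sqrt(1 + 1 / (n + 1))
  z <- (new_value - mean(history)) / (s * fac)
  structure(list(z = z, df = n - 1L,
                 p_two_sided = 2 * pt(-abs(z), df = n - 1),
                 method = "individual"),
            class = "zscore_result")
}

#' Pooled (universal) within-subject variance
#'
#' The standard unbiased pooled estimator
#' `sum_i sum_j (y_ij - ybar_i)^2 / sum_i (n_i - 1)` over subjects with at
#' least two observations.
#'
#' @param table An `obs_table`.
#' @return The pooled within-subject variance (a single positive number).
#' @export
pooled_wsv <- function(table) {
  st <- subject_stats(table)
  keep <- st$n_i >= 2
  if (!any(keep)) stop_data("cannot estimate universal WSV")
  ss_w <- st$s2[keep] - st$s1[keep]^2 / st$n_i[keep]
  sum(ss_w) / sum(st$n_i[keep] - 1)
}

#' Population-informed Z-score with universal within-subject variability
#'
#' Standardises a new observation for one subject using that subject's mean
#' but a single within-subject standard deviation shared by the whole
#' population (estimated by [pooled_wsv()]):
#' `z = (y_new - mean_i) / (sigma_uni * sqrt(1 + 1/(n+1)))`, referred to the
#' standard normal. Loses sensitivity for subjects whose true variability is
#' smaller than the universal value, which motivates the subject-specific
#' variance models in this package.
#'
#' @param table An `obs_table` providing the population (>= 2 subjects with
#'   >= 2 observations each for the variance estimate).
#' @param subject_id Subject whose history centres the score.
#' @param new_value The observation to assess.
#' @return A list of class `zscore_result`: `z`, `p_two_sided`,
#'   `method = "sharpe"`, plus the `sigma_uni` used.
#' @export
zscore_sharpe <- function(table, subject_id, new_value) {
  sel <- table$subject == subject_id
  if (!any(sel)) stop_data("unknown subject")
  s_uni <- sqrt(pooled_wsv(table))
  n <- sum(sel)
  z <- (new_value - mean(table$value[sel])) / (s_uni * sqrt(1 + 1 / (n + 1)))
  structure(list(z = z, df = NA_integer_, p_two_sided = 2 * pnorm(-abs(z)),
                 method = "sharpe", sigma_uni = s_uni),
            class = "zscore_result")
}

#' @export
print.zscore_result <- function(x, ...) {
  cat(sprintf("%s z-score: z = %.4f, p = %.4g%s\n", x$method, x$z,
              x$p_two_sided,
              if (!is.na(x$df)) sprintf(" (t, df = %d)", x$df) else ""))
  invisible(x)
}
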