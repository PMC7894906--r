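# Population-based (static) reference ranges: normal two-sided tolerance
# intervals and the Harris-Boyd stratification check.

#' Two-sided normal tolerance factor
#'
#' Howe's approximation to the factor `k` such that `mean(y) +/- k * sd(y)`
#' contains at least a proportion `p` of a normal population with confidence
#' `confidence`: `k = z_{(1+p)/2} * sqrt(nu * (1 + 1/n) / chisq_{1-conf, nu})`
#' with `nu = n - 1`. Accurate for n >= 10 and converges to the plain normal
#' quantile `z_{(1+p)/2}` as `n -> Inf`.
#'
#' @param n Sample size (>= 2).
#' @param p Population proportion to be covered.
#' @param confidence Confidence level of the coverage guarantee.
#' @return The tolerance factor (a single positive number).
#' @export
tolerance_factor <- function(n, p = 0.95, confidence = 0.95) {
  if (n < 2) stop_usage("tolerance factor needs n >= 2")
  nu <- n - 1
  z <- qnorm((1 + p) / 2)
  z * sqrt(nu * (1 + 1 / n) / qchisq(1 - confidence, nu))
}

#' Normal two-sided tolerance interval
#'
#' Computes `mean(y) +/- k * sd(y)` with `k` from [tolerance_factor()]. The
#' sample is assumed (possibly after log transformation by the caller) to be
#' normal.
#'
#' @param sample Numeric vector of at least 3 finite values.
#' @param p Proportion of the population the interval must cover.
#' @param confidence Confidence level of the coverage guarantee.
#' @return A list of class `tolerance_interval` with elements `lower`,
#'   `upper`, `center`, `sd`, `k`, `p`, `confidence`, `n`.
#' @examples
#' tolerance_interval(rnorm(100), p = 0.95, confidence = 0.95)
#' @export
tolerance_interval <- function(sample, p = 0.95, confidence = 0.95) {
  sample <- as.numeric(sample)
  if (length(sample) < 3) stop_data("insufficient data")
  if (any(!is.finite(sample))) stop_data("invalid value")
  if (p <= 0 || p >= 1 || confidence <= 0 || confidence >= 1) {
    stop_usage("p and confidence must lie in (0, 1)")
  }
  m <- mean(sample)
  s <- sd(sample)
  if (s == 0) stop_data("degenerate sample")
  k <- tolerance_factor(length(sample), p, confidence)
  structure(list(lower = m - k * s, upper = m + k * s, center = m, sd = s,
                 k = k, p = p, confidence = confidence, n = length(sample)),
            class = "tolerance_interval")
}

#' @export
print.tolerance_interval <- function(x, ...) {
  cat(sprintf("(%g%%, %g%%) normal tolerance interval, n = %d\n",
              100 * x$p, 100 * x$confidence, x$n))
  cat(sprintf("  [%.6g, %.6g]  (center %.6g, sd %.6g, k %.4f)\n",
              x$lower, x$upper, x$center, x$sd, x$k))
  invisible(x)
}

#' Static reference band for one subject
#'
#' Leave-one-subject-out static range: the tolerance interval is fitted on
#' observations from all subjects other than `subject_id` (by default pooling
#' every observation; alternatively one mean per subject) and replicated over
#' all of the subject's observation indices.
#'
#' @param table An `obs_table` with at least 2 subjects.
#' @param subject_id Subject the band is for.
#' @param p,confidence Tolerance interval settings.
#' @param per_subject_means If `TRUE`, fit on one summary mean per control
#'   subject instead of pooling all their observations (sensitivity analysis).
#' @return A [reference_band()] with `method = "static"` and constant limits
#'   across the subject's indices.
#' @export
static_band_for_subject <- function(table, subject_id, p = 0.95,
                                    confidence = 0.95,
                                    per_subject_means = FALSE) {
  sel <- table$subject == subject_id
  if (!any(sel)) stop_data("unknown subject")
  if (length(unique(table$subject[!sel])) < 1) stop_data("insufficient data")
  cohort <- if (per_subject_means) {
    as.numeric(tapply(table$value[!sel], table$subject[!sel], mean))
  } else {
    table$value[!sel]
  }
  ti <- tolerance_interval(cohort, p = p, confidence = confidence)
  idx <- table$index[sel]
  reference_band(subject = table$subject[sel], index = idx,
                 observed = table$value[sel],
                 lower = rep(ti$lower, length(idx)),
                 upper = rep(ti$upper, length(idx)),
                 method = "static", alpha_level = 1 - p)
}

#' Harris-Boyd stratification ratio
#'
#' Ratio (larger over smaller) of the between-subject variances of subject
#' means computed within each of two groups. Harris and Boyd's rule suggests
#' stratifying the reference interval (e.g. by sex) when the ratio exceeds
#' 1.5.
#'
#' @param table An `obs_table`.
#' @param group_labels Either `NULL` (use the table's `group` column) or a
#'   named vector mapping subject ids to one of exactly two group labels.
#' @return The variance ratio (>= 1).
#' @export
stratification_ratio <- function(table, group_labels = NULL) {
  if (is.null(group_labels)) {
    if (is.null(table$group)) stop_usage("no group labels supplied")
    grp_by_subject <- tapply(table$group, table$subject,
                             function(g) unique(g)[1])
  } else {
    grp_by_subject <- group_labels[unique(table$subject)]
  }
  subj_means <- tapply(table$value, table$subject, mean)
  grp <- as.character(grp_by_subject[names(subj_means)])
  if (anyNA(grp) || length(unique(grp)) != 2) {
    stop_data("need exactly two groups covering all subjects")
  }
  sizes <- table(grp)
  if (any(sizes < 2)) stop_data("insufficient group data")
  bsv <- tapply(as.numeric(subj_means), grp, var)
  if (any(bsv == 0)) stop_data("degenerate group data")
  max(bsv) / min(bsv)
}

# Two-sided normal tail probability of `observed` under the control cohort's
# fitted N(mean, sd^2); the abnormality score used for the static method's
# ROC curves (thresholding at alpha reproduces a quantile-interval flag).
static_score <- function(center, s, observed) {
  2 * pnorm(-abs(observed - center) / s)
}
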