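# Core data structures: the long-format observation table, prior
# hyperparameters, generating parameters, and the synthetic-data generator.

#' Validate a long-format observation table
#'
#' Canonicalises raw longitudinal records into the observation table used by
#' every other function in the package. Records are sorted by subject and
#' observation index, observation indices are re-assigned so that they form
#' `1..n_i` within each subject (only the original order matters, not the
#' spacing), and values are checked to be finite numbers.
#'
#' @param records A data.frame with columns `subject`, `index`, `value` and
#'   optionally `group` (used for stratification), or a matrix/list coercible
#'   to one. `index` may be any orderable quantity (integer index, timestamp);
#'   it is reduced to within-subject rank order.
#' @return A data.frame of class `obs_table` with columns `subject`
#'   (character), `index` (integer, consecutive from 1 within subject),
#'   `value` (double) and optionally `group`.
#' @examples
#' validate_table(data.frame(subject = "A", index = 1:2, value = c(5, 6)))
#' @export
validate_table <- function(records) {
  if (is.null(records) || NROW(records) == 0L) stop_data("no data")
  records <- as.data.frame(records)
  needed <- c("subject", "index", "value")
  if (!all(needed %in% names(records))) {
    stop_data(sprintf("bad header: need columns %s",
                      paste(needed, collapse = ", ")))
  }
  subject <- as.character(records$subject)
  index <- records$index
  value <- suppressWarnings(as.numeric(records$value))
  if (anyNA(subject) || any(!nzchar(subject))) stop_data("invalid subject id")
  if (anyNA(value) || any(!is.finite(value))) stop_data("invalid value")
  if (anyNA(index)) stop_data("invalid index")
  if (anyDuplicated(paste(subject, index, sep = "\r"))) {
    stop_data("duplicate observation")
  }
  ord <- order(subject, index)
  out <- data.frame(subject = subject[ord],
                    index = NA_integer_,
                    value = value[ord],
                    stringsAsFactors = FALSE)
  out$index <- stats::ave(seq_along(out$value), out$subject,
                          FUN = seq_along)
  if ("group" %in% names(records)) out$group <- as.character(records$group)[ord]
  class(out) <- c("obs_table", "data.frame")
  out
}

#' Prior hyperparameters for the hierarchical model
#'
#' Container for the constants of the weakly informative priors:
#' `mu ~ N(0, nu^2)`, `sigma_i^2 ~ IG(alpha1, beta1)`,
#' `tau^2 ~ IG(alpha2, beta2)`, plus the two-sided miscoverage level
#' `alpha_level` used for reference bands. Defaults follow the
#' vague-prior convention: a large `nu` and a common low value (0.01) for all
#' inverse-gamma shapes and scales.
#'
#' @param nu Prior standard deviation of the grand mean (must be > 0).
#' @param alpha1,beta1 Shape/scale of the IG prior on each within-subject
#'   variance.
#' @param alpha2,beta2 Shape/scale of the IG prior on the between-subject
#'   variance.
#' @param alpha_level Two-sided miscoverage of the reference band, in (0,1).
#' @return A list of class `adaptref_hyper`.
#' @export
hyperparameters <- function(nu = 1000, alpha1 = 0.01, beta1 = 0.01,
                            alpha2 = 0.01, beta2 = 0.01, alpha_level = 0.05) {
  vals <- c(nu = nu, alpha1 = alpha1, beta1 = beta1,
            alpha2 = alpha2, beta2 = beta2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_usage("hyperparameters must all be positive finite numbers")
  }
  if (!is.finite(alpha_level) || alpha_level <= 0 || alpha_level >= 1) {
    stop_usage("alpha_level must lie in (0, 1)")
  }
  structure(list(nu = nu, alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2, alpha_level = alpha_level),
            class = "adaptref_hyper")
}

#' Simulate a hierarchical-normal population
#'
#' Draws subject means `mu_i ~ N(mu, tau2)` and observations
#' `y_ij ~ N(mu_i, sigma_i^2)`. Within-subject variances can be fixed, given
#' per subject, or drawn from an inverse-gamma distribution whose first two
#' moments are set by the ratios `r1 = Var(sigma_i^2)/tau2` and
#' `r2 = E(sigma_i^2)/tau2` (moment matching; `r1 = 0` degenerates to the
#' fixed variance `r2 * tau2`).
#'
#' @param I Number of subjects (>= 1).
#' @param n_per_subject Observations per subject; a scalar or a length-`I`
#'   vector.
#' @param mu Grand mean of subject means.
#' @param tau2 Between-subject variance (> 0).
#' @param sigma2_spec Within-subject variance specification: a single positive
#'   number (shared variance), a length-`I` positive vector, or
#'   `list(r1 =, r2 =)` with `r1 >= 0`, `r2 > 0` interpreted relative to
#'   `tau2` as above.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list with elements `table` (an `obs_table`) and `params` (a list
#'   of class `population_params` with `mu`, `tau2`, `mu_i`, `sigma2` — the
#'   true generating values, named by subject).
#' @export
simulate_population <- function(I, n_per_subject, mu, tau2, sigma2_spec,
                                seed = NULL) {
  if (I < 1) stop_usage("I must be >= 1")
  if (!is.finite(tau2) || tau2 <= 0) stop_data("invalid variance spec")
  n_i <- rep_len(as.integer(n_per_subject), I)
  if (any(n_i < 1)) stop_usage("n_per_subject must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- draw_sigma2(I, tau2, sigma2_spec)
  mu_i <- rnorm(I, mu, sqrt(tau2))
  ids <- sprintf("S%03d", seq_len(I))
  names(mu_i) <- names(sigma2) <- ids
  subject <- rep(ids, times = n_i)
  value <- rnorm(sum(n_i), rep(mu_i, times = n_i),
                 rep(sqrt(sigma2), times = n_i))
  tab <- data.frame(subject = subject,
                    index = unlist(lapply(n_i, seq_len), use.names = FALSE),
                    value = value, stringsAsFactors = FALSE)
  class(tab) <- c("obs_table", "data.frame")
  params <- structure(list(mu = mu, tau2 = tau2, mu_i = mu_i, sigma2 = sigma2),
                      class = "population_params")
  list(table = tab, params = params)
}

# Draw per-subject within-subject variances according to sigma2_spec.
# For list(r1, r2): IG(a, b) with mean r2*tau2 and variance r1*tau2^2 via
# a = 2 + r2^2/r1, b = (a - 1) * r2 * tau2.
draw_sigma2 <- function(I, tau2, sigma2_spec) {
  if (is.list(sigma2_spec)) {
    r1 <- sigma2_spec$r1
    r2 <- sigma2_spec$r2
    if (is.null(r1) || is.null(r2) || !is.finite(r1) || !is.finite(r2) ||
        r1 < 0 || r2 <= 0) {
      stop_data("invalid variance spec")
    }
    if (r1 == 0) return(rep(r2 * tau2, I))
    shape <- 2 + r2^2 / r1
    scale_ <- (shape - 1) * r2 * tau2
    return(scale_ / rgamma(I, shape = shape, rate = 1))
  }
  sigma2 <- rep_len(as.numeric(sigma2_spec), I)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop_data("invalid variance spec")
  }
  sigma2
}

# Per-subject sufficient statistics (n_i, sum y, sum y^2) in subject order.
subject_stats <- function(table) {
  sub <- factor(table$subject, levels = unique(table$subject))
  n_i <- as.numeric(tapply(table$value, sub, length))
  s1 <- as.numeric(tapply(table$value, sub, sum))
  s2 <- as.numeric(tapply(table$value^2, sub, sum))
  list(ids = levels(sub), n_i = n_i, s1 = s1, s2 = s2)
}

#' Assemble a reference band
#'
#' Internal-facing constructor for the per-observation band produced by the
#' static, Bayesian and EM methods. Checks that `lower < upper` everywhere and
#' derives the atypical flags from the limits.
#'
#' @param subject,index,observed,lower,upper Parallel vectors describing each
#'   entry.
#' @param method One of `"static"`, `"bayes"`, `"em"` (recycled).
#' @param alpha_level Two-sided miscoverage the band was built for.
#' @return A data.frame of class `reference_band` with columns `subject`,
#'   `index`, `value`, `lower`, `upper`, `atypical`, `method`, and an
#'   `alpha_level` attribute.
#' @export
reference_band <- function(subject, index, observed, lower, upper,
                           method, alpha_level) {
  if (any(!(lower < upper))) stop_numeric("degenerate band: lower >= upper")
  out <- data.frame(subject = as.character(subject),
                    index = as.integer(index),
                    value = as.numeric(observed),
                    lower = as.numeric(lower),
                    upper = as.numeric(upper),
                    atypical = observed < lower | observed > upper,
                    method = rep_len(method, length(lower)),
                    stringsAsFactors = FALSE)
  attr(out, "alpha_level") <- alpha_level
  class(out) <- c("reference_band", "data.frame")
  out
}
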