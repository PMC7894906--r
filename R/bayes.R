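# Fully Bayesian hierarchical normal model with subject-specific
# within-subject variances:
#
#   y_ij | mu_i, sigma_i^2 ~ N(mu_i, sigma_i^2)
#   mu_i | mu, tau^2       ~ N(mu, tau^2)
#   mu ~ N(0, nu^2),  sigma_i^2 ~ IG(a1, b1),  tau^2 ~ IG(a2, b2)
#
# All four full conditionals are conjugate, so the posterior is explored by
# a plain Gibbs sampler (compiled inner loop in src/gibbs.cpp; the
# sample_*() functions below are the same conditionals in R, one draw at a
# time, and exist so the two routes can be checked against each other).

#' Gibbs sampler configuration
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded from the front of the chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed for the run.
#' @param hyper A [hyperparameters()] object.
#' @return A list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 4000, burn_in = 1000, thin = 1, seed = 1,
                         hyper = hyperparameters()) {
  if (burn_in >= n_iter) stop_usage("burn_in must be smaller than n_iter")
  if (thin < 1) stop_usage("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 hyper = hyper),
            class = "gibbs_config")
}

#' Full conditional draw of the grand mean
#'
#' One draw from `mu | tau2, {mu_i} ~ N((sum mu_i / tau2) / (1/nu^2 + I/tau2),
#' 1 / (1/nu^2 + I/tau2))`.
#'
#' @param mu_i Current subject means.
#' @param tau2 Current between-subject variance.
#' @param hyper A [hyperparameters()] object (only `nu` is used).
#' @return A single draw (uses the current RNG state).
#' @export
sample_mu <- function(mu_i, tau2, hyper = hyperparameters()) {
  prec <- 1 / hyper$nu^2 + length(mu_i) / tau2
  rnorm(1, (sum(mu_i) / tau2) / prec, sqrt(1 / prec))
}

#' Full conditional draw of the between-subject variance
#'
#' One draw from `tau2 | mu, {mu_i} ~ IG(a2 + I/2, b2 + 0.5 sum (mu_i - mu)^2)`.
#'
#' @param mu_i Current subject means.
#' @param mu Current grand mean.
#' @param hyper A [hyperparameters()] object.
#' @return A single draw.
#' @export
sample_tau2 <- function(mu_i, mu, hyper = hyperparameters()) {
  shape <- hyper$alpha2 + length(mu_i) / 2
  rate <- hyper$beta2 + 0.5 * sum((mu_i - mu)^2)
  rate / rgamma(1, shape = shape, rate = 1)
}

#' Full conditional draw of one subject's within-subject variance
#'
#' One draw from `sigma_i^2 | mu_i, y_i ~ IG(a1 + n_i/2,
#' b1 + 0.5 sum_j (y_ij - mu_i)^2)`.
#'
#' @param y Subject's observations.
#' @param mu_i Current mean of that subject.
#' @param hyper A [hyperparameters()] object.
#' @return A single draw.
#' @export
sample_sigma2_i <- function(y, mu_i, hyper = hyperparameters()) {
  shape <- hyper$alpha1 + length(y) / 2
  rate <- hyper$beta1 + 0.5 * sum((y - mu_i)^2)
  rate / rgamma(1, shape = shape, rate = 1)
}

#' Full conditional draw of one subject's mean
#'
#' One draw from `mu_i | mu, tau2, sigma_i^2, y_i ~ N((mu/tau2 +
#' sum_j y_ij / sigma_i^2) / (1/tau2 + n_i/sigma_i^2), 1/(1/tau2 +
#' n_i/sigma_i^2))` — precision-weighted shrinkage of the subject mean toward
#' the population mean.
#'
#' @param y Subject's observations.
#' @param mu Current grand mean.
#' @param tau2 Current between-subject variance.
#' @param sigma2_i Current within-subject variance of that subject.
#' @return A single draw.
#' @export
sample_mu_i <- function(y, mu, tau2, sigma2_i) {
  prec <- 1 / tau2 + length(y) / sigma2_i
  rnorm(1, (mu / tau2 + sum(y) / sigma2_i) / prec, sqrt(1 / prec))
}

#' Fit the hierarchical model by Gibbs sampling
#'
#' Cycles `mu -> tau2 -> {sigma_i^2} -> {mu_i}` per iteration, starting from
#' method-of-moments estimates (grand mean; subject means; variance of subject
#' means; subject sample variances, with the pooled within-subject variance
#' substituted for subjects with fewer than 2 observations).
#'
#' @param table An `obs_table`.
#' @param config A [gibbs_config()].
#' @return A list of class `posterior_draws` with vectors `mu`, `tau2`,
#'   matrices `mu_i`, `sigma2_i` (draw x subject, columns named by subject),
#'   and `subject_ids`.
#' @export
gibbs_fit <- function(table, config = gibbs_config()) {
  if (is.null(table) || nrow(table) == 0L) stop_data("no data")
  st <- subject_stats(table)
  set.seed(config$seed)
  draws <- gibbs_fit_stats(st, config)
  draws
}

# Core fit from per-subject sufficient statistics; assumes the RNG state has
# been set by the caller. Shared by gibbs_fit() and the simulation study.
gibbs_fit_stats <- function(st, config) {
  h <- config$hyper
  I <- length(st$ids)
  ybar <- st$s1 / st$n_i
  mu0 <- sum(st$s1) / sum(st$n_i)
  tau20 <- max(var(ybar), 1e-8)
  if (I == 1L) tau20 <- max(st$s2[1] / st$n_i[1] - ybar[1]^2, 1e-8)
  ss_w <- pmax(st$s2 - st$s1^2 / st$n_i, 0)
  pool <- if (any(st$n_i >= 2)) {
    sum(ss_w[st$n_i >= 2]) / sum(st$n_i[st$n_i >= 2] - 1)
  } else 1
  pool <- max(pool, 1e-8)
  sigma20 <- ifelse(st$n_i >= 2, pmax(ss_w / (st$n_i - 1), 1e-8), pool)
  res <- .gibbs_core(st$n_i, st$s1, st$s2, h$nu, h$alpha1, h$beta1,
                     h$alpha2, h$beta2, config$n_iter, config$burn_in,
                     config$thin, mu0, tau20, ybar, sigma20)
  colnames(res$mu_i) <- colnames(res$sigma2_i) <- st$ids
  structure(list(mu = res$mu, tau2 = res$tau2, mu_i = res$mu_i,
                 sigma2_i = res$sigma2_i, subject_ids = st$ids),
            class = "posterior_draws")
}

#' Posterior predictive sample for one subject
#'
#' For each retained draw `t`, samples `y* ~ N(mu_i^(t), sigma_i^2(t))`,
#' giving a sample from the posterior predictive distribution of that
#' subject's next observation.
#'
#' @param draws A `posterior_draws` object from [gibbs_fit()].
#' @param subject Subject id.
#' @return Numeric vector with one predictive draw per retained posterior
#'   draw (uses the current RNG state).
#' @export
posterior_predictive <- function(draws, subject) {
  if (!subject %in% draws$subject_ids) stop_data("unknown subject")
  mu_i <- draws$mu_i[, subject]
  sigma2_i <- draws$sigma2_i[, subject]
  rnorm(length(mu_i), mu_i, sqrt(sigma2_i))
}

#' Two-sided predictive tail score
#'
#' Empirical two-sided tail probability `2 * min(Fhat(y), 1 - Fhat(y))` of an
#' observed value under a predictive sample. Small scores indicate atypical
#' observations; thresholding at `alpha` is equivalent to flagging values
#' outside the central `1 - alpha` predictive interval.
#'
#' @param predictive_samples Numeric predictive sample (>= 100 draws
#'   recommended).
#' @param observed Observed value to score.
#' @return A score in (0, 1].
#' @export
predictive_score_bayes <- function(predictive_samples, observed) {
  m <- length(predictive_samples)
  if (m == 0) stop_data("empty predictive sample")
  f <- mean(predictive_samples <= observed)
  max(2 * min(f, 1 - f), 1 / (m + 1))
}

#' Bayesian dynamic reference band for one subject
#'
#' Sequential individualised band: for observation indices `j <= 2` the
#' static tolerance interval built from all other subjects is used (the
#' subject's own variance cannot be estimated from fewer than two points);
#' for `j >= 3` the model is refitted on all other subjects' data plus the
#' subject's first `j - 1` observations, and the band is the central
#' `1 - alpha` empirical quantile interval of the posterior predictive
#' sample.
#'
#' @param table An `obs_table` with at least 2 subjects.
#' @param subject Subject id.
#' @param config A [gibbs_config()]; `config$hyper$alpha_level` sets the band
#'   coverage.
#' @param mode `"refit"` refits the sampler at every index (faithful,
#'   slower); `"final_only"` scores only the subject's last observation,
#'   fitting once on everything except that observation (the evaluation
#'   protocol of the simulation study).
#' @return A [reference_band()] with `method = "bayes"`.
#' @export
dynamic_band_bayes <- function(table, subject, config = gibbs_config(),
                               mode = c("refit", "final_only")) {
  mode <- match.arg(mode)
  alpha <- config$hyper$alpha_level
  sel <- table$subject == subject
  if (!any(sel)) stop_data("unknown subject")
  y <- table$value[sel][order(table$index[sel])]
  n <- length(y)
  others <- table[!sel, , drop = FALSE]
  if (nrow(others) == 0L) stop_data("need at least 2 subjects")
  static_ti <- tolerance_interval(others$value, p = 1 - alpha,
                                  confidence = 0.95)
  js <- if (mode == "final_only") n else seq_len(n)
  lower <- upper <- numeric(length(js))
  for (k in seq_along(js)) {
    j <- js[k]
    if (j <= 2) {
      lower[k] <- static_ti$lower
      upper[k] <- static_ti$upper
      next
    }
    hist_tab <- rbind(others,
                      table[sel, , drop = FALSE][seq_len(j - 1), , drop = FALSE])
    fit <- gibbs_fit(hist_tab, config)
    pred <- posterior_predictive(fit, subject)
    q <- quantile(pred, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
    lower[k] <- q[1]
    upper[k] <- q[2]
  }
  reference_band(subject = rep(subject, length(js)), index = js,
                 observed = y[js], lower = lower, upper = upper,
                 method = "bayes", alpha_level = alpha)
}
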