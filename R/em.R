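# Random-intercept model with subject-specific error variances, estimated by
# the EM algorithm, plus the SEMA streaming approximation that keeps only a
# few sufficient statistics per subject:
#
#   y_ij = mu_i + e_ij,  e_ij ~ N(0, sigma_i^2),  mu_i ~ N(mu, tau^2)
#
# E step (given current estimates):
#   rho_i  = tau2 / (tau2 + sigma2_i / n_i)              (shrinkage weight)
#   mu_i   = rho_i * ybar_i + (1 - rho_i) * mu           (posterior mean)
#   nu_i   = tau2 * (1 - rho_i)                          (posterior variance)
# Complete-data sufficient statistics (CDSS):
#   T1 = sum_i mu_i,  T2 = sum_i (nu_i + mu_i^2),
#   T3_i = sum_j [(y_ij - mu_i)^2 + nu_i]
# M step: mu = T1/I, tau2 = T2/I - mu^2, sigma2_i = T3_i / n_i.
#
# The streaming update (SEMA) replaces only the touched subject's CDSS
# contribution when one observation arrives and reruns the M step from the
# maintained totals, so memory and per-update cost do not grow with the
# number of observations.

EM_VAR_FLOOR <- 1e-10

#' Initialise an EM state from a table
#'
#' Method-of-moments start: grand mean, variance of subject means, subject
#' sample variances (pooled within-subject variance for subjects with fewer
#' than two observations).
#'
#' @param table An `obs_table`.
#' @return A list of class `em_state`. Fields: scalar estimates `mu_hat`,
#'   `tau2_hat`; per-subject vectors (named by subject) `sigma2_hat`,
#'   `mu_i_hat`, `nu_i_hat`, `rho_i_hat`, `T3`, `n_i`, `ybar_i`, `y2bar_i`;
#'   CDSS totals `T1`, `T2`; pooled-variance accumulators `pool_num`,
#'   `pool_den`; `iteration`; `converged`.
#' @export
em_init <- function(table) {
  st <- subject_stats(table)
  em_init_stats(st)
}

em_init_stats <- function(st) {
  I <- length(st$ids)
  ybar <- st$s1 / st$n_i
  y2bar <- st$s2 / st$n_i
  mu0 <- sum(st$s1) / sum(st$n_i)
  tau20 <- if (I >= 2) max(var(ybar), EM_VAR_FLOOR) else 1
  ss_w <- pmax(st$s2 - st$s1^2 / st$n_i, 0)
  ge2 <- st$n_i >= 2
  pool <- if (any(ge2)) sum(ss_w[ge2]) / sum(st$n_i[ge2] - 1) else tau20
  pool <- max(pool, EM_VAR_FLOOR)
  sigma2 <- ifelse(ge2, pmax(ss_w / (st$n_i - 1), EM_VAR_FLOOR), pool)
  state <- structure(list(
    ids = st$ids, n_i = st$n_i, ybar_i = ybar, y2bar_i = y2bar,
    mu_hat = mu0, tau2_hat = tau20, sigma2_hat = sigma2,
    mu_i_hat = ybar, nu_i_hat = rep(0, I), rho_i_hat = rep(1, I),
    T1 = sum(ybar), T2 = sum(ybar^2), T3 = ss_w,
    pool_num = sum(ss_w[ge2]), pool_den = sum(st$n_i[ge2]),
    iteration = 0L, converged = FALSE, loglik = NA_real_),
    class = "em_state")
  name_em_fields(state)
}

name_em_fields <- function(state) {
  for (f in c("n_i", "ybar_i", "y2bar_i", "sigma2_hat", "mu_i_hat",
              "nu_i_hat", "rho_i_hat", "T3")) {
    names(state[[f]]) <- state$ids
  }
  state
}

#' E step of the batch EM algorithm
#'
#' Computes the shrinkage weights, posterior means and variances of the
#' subject intercepts given the current parameter estimates, and refreshes
#' the CDSS.
#'
#' @param state An `em_state`.
#' @param table Optional `obs_table`; if supplied, the per-subject summaries
#'   (`n_i`, `ybar_i`, `y2bar_i`) are recomputed from it first.
#' @return The updated `em_state`.
#' @export
e_step <- function(state, table = NULL) {
  if (!is.null(table)) {
    st <- subject_stats(table)
    if (!identical(st$ids, state$ids)) stop_data("subject mismatch")
    state$n_i <- st$n_i
    state$ybar_i <- st$s1 / st$n_i
    state$y2bar_i <- st$s2 / st$n_i
    state <- name_em_fields(state)
  }
  rho <- state$tau2_hat / (state$tau2_hat + state$sigma2_hat / state$n_i)
  mu_i <- rho * state$ybar_i + (1 - rho) * state$mu_hat
  nu_i <- state$tau2_hat * (1 - rho)
  t3 <- state$n_i * (state$y2bar_i - 2 * mu_i * state$ybar_i + mu_i^2 + nu_i)
  state$rho_i_hat <- rho
  state$mu_i_hat <- mu_i
  state$nu_i_hat <- nu_i
  state$T1 <- sum(mu_i)
  state$T2 <- sum(nu_i + mu_i^2)
  state$T3 <- t3
  ge2 <- state$n_i >= 2
  state$pool_num <- sum(t3[ge2])
  state$pool_den <- sum(state$n_i[ge2])
  name_em_fields(state)
}

#' M step of the batch EM algorithm
#'
#' Recomputes the parameter estimates from the CDSS: `mu = T1/I`,
#' `tau2 = T2/I - mu^2`, `sigma2_i = T3_i/n_i`. Variances are floored at a
#' tiny positive value (with a warning) if an update would make them
#' non-positive; subjects with fewer than two observations keep the pooled
#' within-subject variance instead of their own (undefined) estimate.
#'
#' @param state An `em_state` with current CDSS.
#' @return The updated `em_state`.
#' @export
m_step <- function(state) {
  I <- length(state$ids)
  state$mu_hat <- state$T1 / I
  tau2 <- state$T2 / I - state$mu_hat^2
  if (tau2 <= 0) {
    warning("tau2 update non-positive; floored")
    tau2 <- EM_VAR_FLOOR
  }
  state$tau2_hat <- tau2
  sigma2 <- state$T3 / state$n_i
  lt2 <- state$n_i < 2
  if (any(lt2)) {
    pool <- if (state$pool_den > 0) state$pool_num / state$pool_den else tau2
    sigma2[lt2] <- pool
  }
  state$sigma2_hat <- pmax(sigma2, EM_VAR_FLOOR)
  names(state$sigma2_hat) <- state$ids
  state$iteration <- state$iteration + 1L
  state
}

# Direct M step from Eqs in primitive form (no stored CDSS); used to check
# that the CDSS route is exact.
m_step_direct <- function(state) {
  I <- length(state$ids)
  mu <- mean(state$mu_i_hat)
  tau2 <- mean(state$nu_i_hat + state$mu_i_hat^2) - mu^2
  sigma2 <- (state$n_i * (state$y2bar_i - 2 * state$mu_i_hat * state$ybar_i +
                            state$mu_i_hat^2 + state$nu_i_hat)) / state$n_i
  list(mu_hat = mu, tau2_hat = tau2, sigma2_hat = sigma2)
}

#' Marginal (observed-data) log-likelihood of the random-intercept model
#'
#' Each subject's vector is `N(mu * 1, tau2 * J + sigma_i^2 * I)`; the
#' density is evaluated in closed form through the within/between
#' decomposition, so the cost is O(I).
#'
#' @param table An `obs_table`.
#' @param mu,tau2 Population parameters.
#' @param sigma2 Per-subject variances, in subject order or named by subject.
#' @return The log-likelihood (a single number).
#' @export
em_marginal_loglik <- function(table, mu, tau2, sigma2) {
  st <- subject_stats(table)
  if (!is.null(names(sigma2))) sigma2 <- sigma2[st$ids]
  em_loglik_stats(st$n_i, st$s1 / st$n_i,
                  pmax(st$s2 - st$s1^2 / st$n_i, 0), mu, tau2, sigma2)
}

# closed-form marginal loglik from per-subject summaries (n, mean, within SS)
em_loglik_stats <- function(n, ybar, ssw, mu, tau2, sigma2) {
  sigma2 <- rep_len(as.numeric(sigma2), length(n))
  tot_var <- sigma2 + n * tau2
  sum(-0.5 * (n * log(2 * pi) + (n - 1) * log(sigma2) + log(tot_var) +
                ssw / sigma2 + n * (ybar - mu)^2 / tot_var))
}

#' Fit the random-intercept model by batch EM
#'
#' Alternates [e_step()] and [m_step()] until the relative change in the
#' observed-data log-likelihood drops below `tol` or `max_iter` is reached.
#' The observed-data log-likelihood is non-decreasing along the iterations
#' (up to the variance floor for degenerate data).
#'
#' @param table An `obs_table` with >= 2 subjects.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`.
#' @param init Optional starting `em_state` (defaults to [em_init()]).
#' @return A converged `em_state`; `state$loglik` holds the final
#'   log-likelihood and `attr(state, "loglik_trace")` the per-iteration
#'   values.
#' @export
em_fit <- function(table, tol = 1e-8, max_iter = 500L, init = NULL) {
  if (length(unique(table$subject)) < 2) stop_data("need >= 2 subjects")
  if (tol <= 0) stop_usage("tol must be > 0")
  state <- if (is.null(init)) em_init(table) else init
  ssw <- state$n_i * pmax(state$y2bar_i - state$ybar_i^2, 0)
  ll_old <- -Inf
  trace <- numeric(0)
  for (k in seq_len(max_iter)) {
    state <- e_step(state)
    state <- m_step(state)
    ll <- em_loglik_stats(state$n_i, state$ybar_i, ssw, state$mu_hat,
                          state$tau2_hat, state$sigma2_hat)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      state$converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!state$converged) warning("EM did not converge within max_iter")
  state$loglik <- ll_old
  attr(state, "loglik_trace") <- trace
  state
}

#' Single SEMA streaming update
#'
#' Processes one new observation for one subject: updates that subject's
#' running summaries (`n_i`, `ybar_i`, `y2bar_i`), recomputes its E-step
#' quantities with the current parameter estimates, swaps its contribution
#' into the CDSS totals (`T(t) = T(t-1) - T_i(t-1) + T_i(t)`), and reruns
#' the M step from the totals. Subjects not involved keep their previous
#' contributions, so the update cost does not depend on the amount of data
#' seen so far. New subject ids are admitted on the fly.
#'
#' @param state An `em_state` (typically from [em_fit()] on an initial
#'   batch, per the hybrid batch-then-stream strategy).
#' @param subject Subject id of the new observation.
#' @param new_value The observed value.
#' @return The updated `em_state`.
#' @export
sema_update <- function(state, subject, new_value) {
  i <- match(subject, state$ids)
  if (is.na(i)) {
    state$ids <- c(state$ids, as.character(subject))
    i <- length(state$ids)
    state$n_i <- c(state$n_i, 0)
    state$ybar_i <- c(state$ybar_i, 0)
    state$y2bar_i <- c(state$y2bar_i, 0)
    pool <- if (state$pool_den > 0) state$pool_num / state$pool_den
            else state$tau2_hat
    state$sigma2_hat <- c(state$sigma2_hat, max(pool, EM_VAR_FLOOR))
    state$mu_i_hat <- c(state$mu_i_hat, state$mu_hat)
    state$nu_i_hat <- c(state$nu_i_hat, state$tau2_hat)
    state$rho_i_hat <- c(state$rho_i_hat, 0)
    state$T3 <- c(state$T3, 0)
    t1_old <- 0
    t2_old <- 0
  } else {
    t1_old <- state$mu_i_hat[[i]]
    t2_old <- state$nu_i_hat[[i]] + state$mu_i_hat[[i]]^2
  }
  if (state$n_i[[i]] >= 2) {
    state$pool_num <- state$pool_num - state$T3[[i]]
    state$pool_den <- state$pool_den - state$n_i[[i]]
  }
  n <- state$n_i[[i]] + 1
  ybar <- state$ybar_i[[i]] + (new_value - state$ybar_i[[i]]) / n
  y2bar <- state$y2bar_i[[i]] + (new_value^2 - state$y2bar_i[[i]]) / n
  state$n_i[i] <- n
  state$ybar_i[i] <- ybar
  state$y2bar_i[i] <- y2bar

  tau2 <- state$tau2_hat
  sigma2 <- state$sigma2_hat[[i]]
  rho <- tau2 / (tau2 + sigma2 / n)
  mu_i <- rho * ybar + (1 - rho) * state$mu_hat
  nu_i <- tau2 * (1 - rho)
  t3 <- n * (y2bar - 2 * mu_i * ybar + mu_i^2 + nu_i)
  state$rho_i_hat[i] <- rho
  state$mu_i_hat[i] <- mu_i
  state$nu_i_hat[i] <- nu_i
  state$T1 <- state$T1 + mu_i - t1_old
  state$T2 <- state$T2 + (nu_i + mu_i^2) - t2_old
  state$T3[i] <- t3

  I <- length(state$ids)
  state$mu_hat <- state$T1 / I
  state$tau2_hat <- max(state$T2 / I - state$mu_hat^2, EM_VAR_FLOOR)
  if (n >= 2) {
    state$pool_num <- state$pool_num + t3
    state$pool_den <- state$pool_den + n
    state$sigma2_hat[i] <- max(t3 / n, EM_VAR_FLOOR)
  } else {
    pool <- if (state$pool_den > 0) state$pool_num / state$pool_den
            else state$tau2_hat
    state$sigma2_hat[i] <- max(pool, EM_VAR_FLOOR)
  }
  state$iteration <- state$iteration + 1L
  name_em_fields(state)
}

#' Hybrid batch-then-stream SEMA fit
#'
#' Runs the batch EM algorithm on the first `batch_size` rows of the table
#' (the streaming approximation needs a warm start on small histories) and
#' then applies [sema_update()] to the remaining rows one at a time, in row
#' order. The default batch size is `min(20 * I, nrow(table))`.
#'
#' @param table An `obs_table`; row order is the stream arrival order.
#' @param batch_size Rows used for the warm-up batch fit.
#' @param tol,max_iter Passed to [em_fit()] for the batch phase.
#' @return The final `em_state`.
#' @export
sema_fit <- function(table, batch_size = NULL, tol = 1e-8, max_iter = 500L) {
  N <- nrow(table)
  I <- length(unique(table$subject))
  if (is.null(batch_size)) batch_size <- min(20L * I, N)
  batch_size <- max(batch_size, min(N, 2L * I))
  batch <- table[seq_len(batch_size), , drop = FALSE]
  if (length(unique(batch$subject)) < 2) stop_data("need >= 2 subjects")
  state <- em_fit(batch, tol = tol, max_iter = max_iter)
  if (batch_size < N) {
    rest <- table[(batch_size + 1L):N, , drop = FALSE]
    state <- sema_stream(state, rest$subject, rest$value)
  }
  state
}

# Fast streaming path: same arithmetic as sema_update(), compiled loop.
sema_stream <- function(state, subjects, values) {
  subjects <- as.character(subjects)
  all_ids <- unique(c(state$ids, subjects))
  extra <- length(all_ids) - length(state$ids)
  if (extra > 0) {
    pool <- if (state$pool_den > 0) state$pool_num / state$pool_den
            else state$tau2_hat
    state$ids <- all_ids
    state$n_i <- c(state$n_i, rep(0, extra))
    state$ybar_i <- c(state$ybar_i, rep(0, extra))
    state$y2bar_i <- c(state$y2bar_i, rep(0, extra))
    state$sigma2_hat <- c(state$sigma2_hat,
                          rep(max(pool, EM_VAR_FLOOR), extra))
    state$mu_i_hat <- c(state$mu_i_hat, rep(state$mu_hat, extra))
    state$nu_i_hat <- c(state$nu_i_hat, rep(state$tau2_hat, extra))
    state$rho_i_hat <- c(state$rho_i_hat, rep(0, extra))
    state$T3 <- c(state$T3, rep(0, extra))
  }
  idx <- match(subjects, state$ids) - 1L
  res <- .sema_stream_core(idx, as.numeric(values),
                           state$n_i, state$ybar_i, state$y2bar_i,
                           state$sigma2_hat, state$mu_i_hat, state$nu_i_hat,
                           state$rho_i_hat, state$T3,
                           state$mu_hat, state$tau2_hat, state$T1, state$T2,
                           state$pool_num, state$pool_den, EM_VAR_FLOOR)
  state$n_i <- res$n_i
  state$ybar_i <- res$ybar
  state$y2bar_i <- res$y2bar
  state$sigma2_hat <- res$sigma2
  state$mu_i_hat <- res$mu_i
  state$nu_i_hat <- res$nu_i
  state$rho_i_hat <- res$rho
  state$T3 <- res$T3
  state$mu_hat <- res$mu
  state$tau2_hat <- res$tau2
  state$T1 <- res$T1
  state$T2 <- res$T2
  state$pool_num <- res$pool_num
  state$pool_den <- res$pool_den
  state$iteration <- state$iteration + length(values)
  name_em_fields(state)
}

#' Plug-in dynamic reference range limits
#'
#' Normal predictive band for subject `i`'s `j`-th observation given the
#' first `j - 1`:
#' centre `(mu/tau2 + (j-1) * ybar / sigma2_i) / (1/tau2 + (j-1)/sigma2_i)`,
#' half-width `z_{1-alpha/2} * sqrt(1/(1/tau2 + (j-1)/sigma2_i) + sigma2_i)`,
#' with all parameters replaced by their current estimates. For `j = 1` the
#' band is the population band `mu +/- z * sqrt(tau2 + sigma2_i)`.
#'
#' @param state An `em_state`.
#' @param subject Subject id (must be known to the state).
#' @param j Observation index the band is for; defaults to `n_i + 1`, the
#'   next unseen observation.
#' @param alpha Two-sided miscoverage.
#' @param ybar Mean of the subject's first `j - 1` observations; defaults to
#'   the state's running mean, which is valid when `j - 1` equals the number
#'   of recorded observations.
#' @return Named vector `c(lower, upper)`.
#' @export
dynamic_band_em <- function(state, subject, j = NULL, alpha = 0.05,
                            ybar = NULL) {
  p <- em_predictive(state, subject, j, ybar)
  z <- qnorm(1 - alpha / 2)
  c(lower = p$mean - z * p$sd, upper = p$mean + z * p$sd)
}

#' Plug-in predictive tail score
#'
#' Two-sided tail probability of an observed value under the plug-in normal
#' predictive distribution used by [dynamic_band_em()]; the abnormality score
#' of the EM method (score < alpha is equivalent to falling outside the
#' `1 - alpha` band).
#'
#' @inheritParams dynamic_band_em
#' @param observed Observed value to score.
#' @return A score in (0, 1].
#' @export
predictive_score_em <- function(state, subject, j = NULL, observed,
                                ybar = NULL) {
  p <- em_predictive(state, subject, j, ybar)
  2 * pnorm(-abs(observed - p$mean) / p$sd)
}

# Shared predictive mean/sd for the plug-in band and score.
em_predictive <- function(state, subject, j = NULL, ybar = NULL) {
  i <- match(subject, state$ids)
  if (is.na(i)) stop_data("unknown subject")
  if (is.null(j)) j <- state$n_i[[i]] + 1
  if (j < 1) stop_usage("j must be >= 1")
  m <- j - 1
  if (is.null(ybar)) {
    if (m > state$n_i[[i]]) stop_data("history mismatch")
    if (m > 0 && m != state$n_i[[i]]) {
      stop_data("history mismatch: supply ybar for a partial history")
    }
    ybar <- if (m > 0) state$ybar_i[[i]] else 0
  }
  ybar <- unname(ybar)
  tau2 <- state$tau2_hat
  sigma2 <- state$sigma2_hat[[i]]
  prec <- 1 / tau2 + m / sigma2
  centre <- (state$mu_hat / tau2 + m * ybar / sigma2) / prec
  list(mean = centre, sd = sqrt(1 / prec + sigma2))
}

#' EM dynamic reference band for one subject
#'
#' Sequential band over a subject's observed series, mirroring
#' [dynamic_band_bayes()]: indices `j <= 2` fall back to the static tolerance
#' interval built from the other subjects; for `j >= 3` the model is
#' refitted by batch EM on the other subjects plus the subject's first
#' `j - 1` observations and the plug-in limits of [dynamic_band_em()] are
#' used.
#'
#' @param table An `obs_table` with >= 2 subjects.
#' @param subject Subject id.
#' @param alpha Two-sided miscoverage.
#' @param tol,max_iter Passed to [em_fit()].
#' @return A [reference_band()] with `method = "em"`.
#' @export
em_band_for_subject <- function(table, subject, alpha = 0.05, tol = 1e-8,
                                max_iter = 500L) {
  sel <- table$subject == subject
  if (!any(sel)) stop_data("unknown subject")
  y <- table$value[sel][order(table$index[sel])]
  others <- table[!sel, , drop = FALSE]
  if (nrow(others) == 0L) stop_data("need at least 2 subjects")
  static_ti <- tolerance_interval(others$value, p = 1 - alpha,
                                  confidence = 0.95)
  n <- length(y)
  lower <- upper <- numeric(n)
  for (j in seq_len(n)) {
    if (j <= 2) {
      lower[j] <- static_ti$lower
      upper[j] <- static_ti$upper
      next
    }
    hist_tab <- rbind(others,
                      table[sel, , drop = FALSE][seq_len(j - 1), , drop = FALSE])
    state <- em_fit(hist_tab, tol = tol, max_iter = max_iter)
    lim <- dynamic_band_em(state, subject, j = j, alpha = alpha)
    lower[j] <- lim[["lower"]]
    upper[j] <- lim[["upper"]]
  }
  reference_band(subject = rep(subject, n), index = seq_len(n), observed = y,
                 lower = lower, upper = upper, method = "em",
                 alpha_level = alpha)
}

#' Serialise / restore an EM state
#'
#' JSON round trip for the streaming CLI: every field of the state is written
#' out so a stream can be resumed later without the raw data.
#'
#' @param state An `em_state`.
#' @param path File path.
#' @return `em_state_write` returns `path` invisibly; `em_state_read` returns
#'   the restored `em_state`.
#' @export
em_state_write <- function(state, path) {
  obj <- unclass(state)
  attr(obj, "loglik_trace") <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname em_state_write
#' @export
em_state_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  state <- structure(obj, class = "em_state")
  state$ids <- as.character(state$ids)
  for (f in c("n_i", "ybar_i", "y2bar_i", "sigma2_hat", "mu_i_hat",
              "nu_i_hat", "rho_i_hat", "T3")) {
    state[[f]] <- as.numeric(state[[f]])
  }
  state$iteration <- as.integer(state$iteration)
  state$converged <- isTRUE(state$converged)
  name_em_fields(state)
}

#' @export
print.em_state <- function(x, ...) {
  cat(sprintf(
    "EM state: %d subjects, mu = %.4g, tau2 = %.4g, mean sigma2 = %.4g\n",
    length(x$ids), x$mu_hat, x$tau2_hat, mean(x$sigma2_hat)))
  cat(sprintf("  iterations: %d, converged: %s\n", x$iteration,
              x$converged))
  invisible(x)
}
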