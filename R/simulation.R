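# Leave-one-subject-out simulation study comparing the abnormality-detection
# performance (ROC AUC) of the static, Bayesian and approximate-EM reference
# ranges. Each replicate simulates a hierarchical-normal population, assigns
# every subject independently to case or control, shifts a case's final
# observation by 3 * sigma_i away from its true mean, and scores that final
# observation with each method's two-sided predictive tail probability.

#' Define a simulation scenario
#'
#' @param I Number of subjects.
#' @param n_i Observations per subject.
#' @param r1 `Var(sigma_i^2) / tau2`: heterogeneity of the within-subject
#'   variances (0 = identical variances).
#' @param r2 `E(sigma_i^2) / tau2`: magnitude of within- relative to
#'   between-subject variability.
#' @param mu,tau2 Generating grand mean and between-subject variance. Results
#'   depend only on the ratios (location-scale equivariance), so the defaults
#'   0 and 1 are canonical.
#' @param n_replicates Simulation replicates.
#' @param seed Scenario seed.
#' @param case_prob Probability a subject is assigned to be a case.
#' @param shift Case-alteration magnitude in units of `sigma_i` (3 by
#'   definition of the evaluation protocol; other values are for property
#'   tests, e.g. 0 for a null run).
#' @return A list of class `scenario`.
#' @export
scenario <- function(I, n_i, r1 = 0, r2 = 0.25, mu = 0, tau2 = 1,
                     n_replicates = 200L, seed = 1L, case_prob = 0.5,
                     shift = 3) {
  if (r1 < 0 || r2 <= 0) stop_usage("need r1 >= 0 and r2 > 0")
  if (n_replicates < 1) stop_usage("n_replicates must be >= 1")
  structure(list(I = as.integer(I), n_i = as.integer(n_i), r1 = r1, r2 = r2,
                 mu = mu, tau2 = tau2, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), case_prob = case_prob,
                 shift = shift),
            class = "scenario")
}

#' Apply the case alteration rule to one subject
#'
#' With probability `case_prob` the subject becomes a case and its final
#' observation is shifted by exactly `3 * sigma_i` away from its true mean:
#' `y - 3 sigma_i` if `y < mu_i`, `y + 3 sigma_i` if `y >= mu_i`. Controls
#' are left unchanged. Uses the current RNG state.
#'
#' @param table An `obs_table`.
#' @param subject Subject id.
#' @param true_params A `population_params` object from
#'   [simulate_population()] (the true `mu_i` and `sigma2` are needed).
#' @param case_prob Probability of case assignment.
#' @return `list(table = altered table, label = "case" or "control")`.
#' @export
apply_case_alteration <- function(table, subject, true_params,
                                  case_prob = 0.5) {
  sel <- which(table$subject == subject)
  if (length(sel) == 0L) stop_data("unknown subject")
  label <- if (stats::runif(1) < case_prob) "case" else "control"
  if (label == "case") {
    last <- sel[which.max(table$index[sel])]
    y <- table$value[last]
    mu_i <- true_params$mu_i[[subject]]
    sig <- sqrt(true_params$sigma2[[subject]])
    table$value[last] <- if (y < mu_i) y - 3 * sig else y + 3 * sig
  }
  list(table = table, label = label)
}

#' AUC by the rank (Mann-Whitney) statistic
#'
#' Probability that a randomly chosen case has a more extreme abnormality
#' score than a randomly chosen control, with the midrank convention for
#' ties. `scores` are tail probabilities, so *smaller* means more abnormal.
#'
#' @param scores Numeric scores (small = atypical).
#' @param is_case Logical case labels.
#' @return AUC in `[0, 1]`, or `NA` if either class is empty.
#' @export
auc_rank <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(-scores)  # high rank = more abnormal
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Interleave a simulated subject-major table into round-robin arrival order
# (index 1 of every subject, then index 2, ...): the realistic ordering for
# a cohort monitored in parallel, and the one the streaming fit sees.
interleave_rows <- function(table) {
  table[order(table$index, table$subject), , drop = FALSE]
}

# method -> fixed RNG stream offset so that results do not depend on the
# order in which methods are evaluated
method_seed_offset <- c(static = 101L, bayes = 211L, em = 307L)

#' Run one simulation scenario
#'
#' Per replicate: simulate the population; assign every subject
#' independently to case or control and alter case finals; fit the dynamic
#' models once on the table with all final observations removed (the
#' evaluated points never enter any fit); score each subject's final
#' observation with each method; compute the replicate AUC across subjects by
#' [auc_rank()]. The static score for subject `i` uses the normal fit to the
#' pooled observations of all other subjects (leave-one-subject-out); the
#' Bayesian score is the posterior-predictive tail probability from the Gibbs
#' fit; the EM score is the plug-in predictive tail probability from the
#' hybrid batch-then-stream fit on round-robin-ordered data.
#'
#' @param scn A [scenario()].
#' @param methods Subset of `c("static", "bayes", "em")`.
#' @param gibbs_iter,gibbs_burn Gibbs run length for the Bayesian method.
#' @param alpha Flagging level for the sensitivity/specificity summaries.
#' @return A list of class `scenario_result`: `scenario`, `summary` (one row
#'   per method: mean/sd of replicate AUCs, sensitivity and specificity at
#'   `alpha`), `n_skipped` (replicates without both classes).
#' @export
run_scenario <- function(scn, methods = c("static", "bayes", "em"),
                         gibbs_iter = 1500L, gibbs_burn = 500L,
                         alpha = 0.05) {
  methods <- match.arg(methods, c("static", "bayes", "em"),
                       several.ok = TRUE)
  set.seed(scn$seed)
  rep_seeds <- sample.int(2147480000L, scn$n_replicates)
  auc <- matrix(NA_real_, scn$n_replicates, length(methods),
                dimnames = list(NULL, methods))
  flags <- labels_all <- NULL
  flag_list <- stats::setNames(vector("list", length(methods)), methods)
  label_list <- list()
  n_skipped <- 0L

  for (r in seq_len(scn$n_replicates)) {
    set.seed(rep_seeds[r])
    sim <- simulate_population(scn$I, scn$n_i, scn$mu, scn$tau2,
                               list(r1 = scn$r1, r2 = scn$r2))
    tab <- sim$table
    pp <- sim$params
    is_case <- stats::runif(scn$I) < scn$case_prob
    ids <- names(pp$mu_i)

    last_row <- cumsum(rep(scn$n_i, scn$I))  # subject-major, equal n_i
    y_last <- tab$value[last_row]
    shift <- scn$shift * sqrt(pp$sigma2) * ifelse(y_last < pp$mu_i, -1, 1)
    y_test <- y_last + ifelse(is_case, shift, 0)

    if (!any(is_case) || all(is_case)) {
      n_skipped <- n_skipped + 1L
      next
    }

    # sufficient statistics with each subject's final observation removed
    st_fit <- list(ids = ids, n_i = rep(scn$n_i - 1, scn$I),
                   s1 = as.numeric(tapply(tab$value, tab$subject, sum)) - y_last,
                   s2 = as.numeric(tapply(tab$value^2, tab$subject, sum)) -
                     y_last^2)
    scores <- matrix(NA_real_, scn$I, length(methods),
                     dimnames = list(ids, methods))

    if ("static" %in% methods) {
      tot_n <- scn$I * scn$n_i
      tot_s1 <- st_fit$s1 + y_last
      tot_s2 <- st_fit$s2 + y_last^2
      n_o <- tot_n - scn$n_i
      m_o <- (sum(tot_s1) - tot_s1) / n_o
      v_o <- (sum(tot_s2) - tot_s2 - n_o * m_o^2) / (n_o - 1)
      scores[, "static"] <- static_score(m_o, sqrt(v_o), y_test)
    }
    if ("bayes" %in% methods) {
      set.seed(rep_seeds[r] + method_seed_offset[["bayes"]])
      cfg <- gibbs_config(n_iter = gibbs_iter, burn_in = gibbs_burn,
                          seed = rep_seeds[r])
      fit <- gibbs_fit_stats(st_fit, cfg)
      K <- length(fit$mu)
      pred <- matrix(rnorm(K * scn$I, fit$mu_i, sqrt(fit$sigma2_i)),
                     K, scn$I)
      f <- colMeans(pred <= matrix(y_test, K, scn$I, byrow = TRUE))
      scores[, "bayes"] <- pmax(2 * pmin(f, 1 - f), 1 / (K + 1))
    }
    if ("em" %in% methods) {
      fit_rows <- tab[-last_row, , drop = FALSE]
      state <- suppressWarnings(sema_fit(interleave_rows(fit_rows)))
      tau2 <- state$tau2_hat
      sigma2 <- state$sigma2_hat[ids]
      m <- scn$n_i - 1
      ybar <- state$ybar_i[ids]
      prec <- 1 / tau2 + m / sigma2
      centre <- (state$mu_hat / tau2 + m * ybar / sigma2) / prec
      sd_pred <- sqrt(1 / prec + sigma2)
      scores[, "em"] <- 2 * pnorm(-abs(y_test - centre) / sd_pred)
    }

    for (meth in methods) auc[r, meth] <- auc_rank(scores[, meth], is_case)
    label_list[[length(label_list) + 1L]] <- is_case
    for (meth in methods) {
      flag_list[[meth]] <- c(flag_list[[meth]], scores[, meth] < alpha)
    }
  }

  labels_all <- unlist(label_list)
  summ <- do.call(rbind, lapply(methods, function(meth) {
    fl <- flag_list[[meth]]
    data.frame(method = meth,
               auc_mean = mean(auc[, meth], na.rm = TRUE),
               auc_sd = sd(auc[, meth], na.rm = TRUE),
               sensitivity = mean(fl[labels_all]),
               specificity = mean(!fl[!labels_all]),
               flag_rate = mean(fl),
               n_flagged_subjects = length(fl),
               stringsAsFactors = FALSE)
  }))
  structure(list(scenario = scn, summary = summ, auc = auc,
                 n_skipped = n_skipped),
            class = "scenario_result")
}

#' Build the default scenario grid
#'
#' Full crossing of subjects, series lengths and variance ratios. The
#' `r1`/`r2` grids span within-subject variability from well below to well
#' above the between-subject variability, with heterogeneity from none to
#' strong.
#'
#' @param I,n_i,r1,r2 Grid axes.
#' @param n_replicates Replicates per scenario.
#' @param seed Base seed; scenario `k` gets `seed + k`.
#' @param case_prob Case-assignment probability.
#' @return A list of [scenario()] objects.
#' @export
default_grid <- function(I = c(5, 10, 20, 100), n_i = c(5, 10, 20, 50, 100),
                         r1 = c(0, 0.1, 0.5, 1), r2 = c(0.1, 0.25, 0.5, 1, 2),
                         n_replicates = 200L, seed = 1L, case_prob = 0.5) {
  g <- expand.grid(I = I, n_i = n_i, r1 = r1, r2 = r2,
                   KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(k) {
    scenario(I = g$I[k], n_i = g$n_i[k], r1 = g$r1[k], r2 = g$r2[k],
             n_replicates = n_replicates, seed = seed + k,
             case_prob = case_prob)
  })
}

#' Benchmark grids for the method comparison
#'
#' `benchmark_grid()` builds the full evaluation grid (all crossings of
#' [default_grid()]'s axes) with the replication used for the headline
#' comparison: `replicates` per scenario for cohorts up to 20 subjects and a
#' subsampled `i100_replicates` for the expensive 100-subject column.
#' `largest_cell_grid()` builds the single largest cell (I = 100, n_i = 100)
#' across the variance-ratio grid.
#'
#' @param seed Base seed; scenario `k` gets `seed + k`.
#' @param replicates Replicates per scenario for I <= 20.
#' @param i100_replicates Replicates per scenario for I = 100.
#' @return A list of [scenario()] objects.
#' @export
benchmark_grid <- function(seed = 1, replicates = 50L, i100_replicates = 10L) {
  g <- default_grid(seed = seed, n_replicates = replicates)
  lapply(g, function(s) {
    if (s$I == 100) s$n_replicates <- as.integer(i100_replicates)
    s
  })
}

#' @rdname benchmark_grid
#' @param replicates_per_combo Replicates for each (r1, r2) combination of
#'   the largest cell.
#' @export
largest_cell_grid <- function(seed = 1, replicates_per_combo = 5L) {
  default_grid(I = 100, n_i = 100, n_replicates = replicates_per_combo,
               seed = seed + 5000)
}

#' Run a grid of scenarios
#'
#' @param scenarios A list of [scenario()] objects (e.g. from
#'   [default_grid()]).
#' @param methods Methods to evaluate.
#' @param gibbs_iter,gibbs_burn,alpha Passed to [run_scenario()].
#' @param progress Print one line per scenario.
#' @return A data.frame with one row per scenario x method (scenario fields,
#'   mean/sd AUC, sensitivity, specificity) and an attribute
#'   `grand_average`: the per-method mean over scenarios of the scenario
#'   mean AUCs.
#' @export
run_grid <- function(scenarios, methods = c("static", "bayes", "em"),
                     gibbs_iter = 1500L, gibbs_burn = 500L, alpha = 0.05,
                     progress = FALSE) {
  if (length(scenarios) == 0L) stop_usage("empty scenario grid")
  rows <- vector("list", length(scenarios))
  for (k in seq_along(scenarios)) {
    scn <- scenarios[[k]]
    res <- run_scenario(scn, methods = methods, gibbs_iter = gibbs_iter,
                        gibbs_burn = gibbs_burn, alpha = alpha)
    rows[[k]] <- cbind(data.frame(I = scn$I, n_i = scn$n_i, r1 = scn$r1,
                                  r2 = scn$r2, seed = scn$seed,
                                  n_replicates = scn$n_replicates),
                       res$summary,
                       n_skipped = res$n_skipped)
    if (progress) {
      message(sprintf("[%d/%d] I=%d n=%d r1=%.2g r2=%.2g: %s",
                      k, length(scenarios), scn$I, scn$n_i, scn$r1, scn$r2,
                      paste(sprintf("%s=%.3f", res$summary$method,
                                    res$summary$auc_mean), collapse = " ")))
    }
  }
  out <- do.call(rbind, rows)
  grand <- tapply(out$auc_mean, out$method, mean)
  attr(out, "grand_average") <- grand[methods]
  out
}
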