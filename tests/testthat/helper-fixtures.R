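# Fixtures built in code; all randomness under explicit seeds.

tiny_table <- function() {
  validate_table(data.frame(
    subject = rep(c("A", "B", "C"), each = 4),
    index = rep(1:4, 3),
    value = c(1.0, 1.2, 0.9, 1.1,
              5.0, 5.1, 4.8, 5.2,
              9.5, 10.2, 9.9, 10.1)))
}

balanced_table <- function(I, n, mu = 0, tau2 = 1, sigma2 = 1, seed = 1) {
  simulate_population(I, n, mu, tau2, sigma2, seed = seed)$table
}

# independent closed-form oracle for the random-intercept marginal loglik:
# builds each subject's full covariance matrix and sums multivariate normal
# log densities (no shortcut decomposition)
oracle_marginal_loglik <- function(table, mu, tau2, sigma2) {
  ids <- unique(table$subject)
  sum(vapply(seq_along(ids), function(i) {
    y <- table$value[table$subject == ids[i]]
    n <- length(y)
    S <- matrix(tau2, n, n) + diag(rep(sigma2[i], n))
    mvtnorm::dmvnorm(y, mean = rep(mu, n), sigma = S, log = TRUE)
  }, numeric(1)))
}

# batch-means Monte Carlo standard error (accounts for autocorrelation)
mcse_batch <- function(x, n_batches = 30) {
  bs <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  sd(means) / sqrt(n_batches)
}
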