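test_that("e_step reproduces the shrinkage identities", {
  tab <- validate_table(data.frame(subject = c("A", "B"), index = 1,
                                   value = c(2, -2)))
  state <- em_init(tab)
  state$mu_hat <- 0
  state$tau2_hat <- 1
  state$sigma2_hat[] <- 1
  state <- e_step(state)
  # n = 1, tau2 = sigma2 = 1: rho = 0.5, mu_i = ybar/2, nu_i = 0.5
  expect_equal(unname(state$rho_i_hat), c(0.5, 0.5))
  expect_equal(unname(state$mu_i_hat), c(1, -1))
  expect_equal(unname(state$nu_i_hat), c(0.5, 0.5))
  # CDSS invariants
  expect_equal(state$T1, sum(state$mu_i_hat))
  expect_equal(state$T2, sum(state$nu_i_hat + state$mu_i_hat^2))
  expect_equal(state$nu_i_hat, state$tau2_hat * (1 - state$rho_i_hat))

  # data-dominated limit: sigma2/n -> 0 pulls mu_i to ybar
  state$sigma2_hat[] <- 1e-12
  s2 <- e_step(state)
  expect_equal(unname(s2$mu_i_hat), c(2, -2), tolerance = 1e-9)
  expect_equal(unname(s2$rho_i_hat), c(1, 1), tolerance = 1e-9)
  # pooled limit: tau2 -> 0 pulls mu_i to mu
  state$tau2_hat <- 1e-14
  state$sigma2_hat[] <- 1
  s3 <- e_step(state)
  expect_equal(unname(s3$mu_i_hat), c(0, 0), tolerance = 1e-10)
})

test_that("m_step matches direct substitution and the CDSS route is exact", {
  tab <- validate_table(data.frame(subject = rep(c("A", "B"), each = 2),
                                   index = rep(1:2, 2),
                                   value = c(1, 1, 3, 3)))
  state <- em_init(tab)
  # frozen E quantities: mu_i = (1, 3), nu_i = 0
  state$mu_i_hat[] <- c(1, 3)
  state$nu_i_hat[] <- 0
  state$T1 <- 4
  state$T2 <- 10
  state$T3 <- c(A = 0, B = 0)
  out <- m_step(state)
  expect_equal(out$mu_hat, 2)
  expect_equal(out$tau2_hat, 10 / 2 - 4)   # = 1

  # sigma2 from a subject with y = (1,3), mu_i = 2, nu_i = 0 -> 1
  tab2 <- validate_table(data.frame(subject = c("A", "A", "B", "B"),
                                    index = c(1, 2, 1, 2),
                                    value = c(1, 3, 0, 0.5)))
  st2 <- em_init(tab2)
  st2$mu_i_hat[] <- c(2, 0.25)
  st2$nu_i_hat[] <- 0
  st2$T3 <- st2$n_i * (st2$y2bar_i - 2 * st2$mu_i_hat * st2$ybar_i +
                         st2$mu_i_hat^2 + st2$nu_i_hat)
  out2 <- m_step(st2)
  expect_equal(unname(out2$sigma2_hat[1]), 1)

  # CDSS M step agrees exactly with the primitive-form M step
  sim <- simulate_population(15, 6, 1, 2, list(r1 = 0.2, r2 = 0.5), seed = 51)
  st <- e_step(em_init(sim$table))
  direct <- adaptref:::m_step_direct(st)
  viacdss <- m_step(st)
  expect_identical(viacdss$mu_hat, direct$mu_hat)
  expect_identical(viacdss$tau2_hat, direct$tau2_hat)
  expect_identical(unname(viacdss$sigma2_hat), unname(direct$sigma2_hat))
})

test_that("e_step/m_step leave a converged fit unchanged (fixed point)", {
  sim <- simulate_population(20, 8, 0, 1, list(r1 = 0.1, r2 = 0.5), seed = 52)
  fit <- em_fit(sim$table, tol = 1e-12, max_iter = 2000)
  again <- m_step(e_step(fit))
  expect_equal(again$mu_hat, fit$mu_hat, tolerance = 1e-6)
  expect_equal(again$tau2_hat, fit$tau2_hat, tolerance = 1e-6)
  expect_equal(again$sigma2_hat, fit$sigma2_hat, tolerance = 1e-5)
})

test_that("marginal log-likelihood matches the multivariate normal oracle", {
  skip_if_not_installed("mvtnorm")
  sim <- simulate_population(5, 4, 1, 2, list(r1 = 0.3, r2 = 0.8), seed = 53)
  mu <- 0.8
  tau2 <- 1.7
  sigma2 <- c(0.5, 1, 2, 0.7, 1.2)
  expect_equal(em_marginal_loglik(sim$table, mu, tau2, sigma2),
               oracle_marginal_loglik(sim$table, mu, tau2, sigma2),
               tolerance = 1e-10)
})

test_that("em_fit maximises the marginal likelihood (brute-force oracle)", {
  skip_if_not_installed("mvtnorm")
  sim <- simulate_population(3, 5, 10, 4, c(0.5, 1, 2), seed = 54)
  fit <- em_fit(sim$table, tol = 1e-13, max_iter = 10000)

  nll <- function(par) {
    -oracle_marginal_loglik(sim$table, par[1], exp(par[2]), exp(par[3:5]))
  }
  ybar <- tapply(sim$table$value, sim$table$subject, mean)
  start <- c(mean(sim$table$value), log(var(as.numeric(ybar))),
             log(as.numeric(tapply(sim$table$value, sim$table$subject, var))))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_equal(fit$mu_hat, opt$par[1], tolerance = 1e-4)
  expect_equal(fit$tau2_hat, exp(opt$par[2]), tolerance = 1e-3)
  expect_equal(unname(fit$sigma2_hat), unname(exp(opt$par[3:5])),
               tolerance = 1e-3)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
})

test_that("log-likelihood is non-decreasing along EM iterations", {
  set.seed(55)
  for (r in 1:25) {
    I <- sample(3:12, 1)
    n <- sample(2:8, 1)
    sim <- simulate_population(I, n, rnorm(1), exp(rnorm(1)),
                               list(r1 = runif(1), r2 = runif(1, 0.1, 2)))
    fit <- suppressWarnings(em_fit(sim$table, tol = 1e-10, max_iter = 200))
    trace <- attr(fit, "loglik_trace")
    expect_true(all(diff(trace) > -1e-7))
  }
})

test_that("em_fit recovers generating parameters at scale", {
  sim <- simulate_population(100, 50, mu = 10, tau2 = 4,
                             sigma2_spec = list(r1 = 0.4, r2 = 0.5),
                             seed = 56)
  fit <- em_fit(sim$table)
  expect_equal(fit$mu_hat, 10, tolerance = 0.1)
  expect_equal(fit$tau2_hat, var(sim$params$mu_i), tolerance = 0.1)
  expect_lt(mean(abs(fit$sigma2_hat - sim$params$sigma2) /
                   sim$params$sigma2), 0.25)
  expect_error(em_fit(sim$table, tol = -1), "tol")
})

test_that("streaming updates match the compiled stream and the batch fit", {
  sim <- simulate_population(12, 6, 0, 1, list(r1 = 0.2, r2 = 0.5), seed = 57)
  tab <- sim$table
  head_rows <- tab$index <= 3
  state0 <- em_fit(tab[head_rows, ], tol = 1e-10)
  rest <- tab[!head_rows, ]

  # reference route: one R-level sema_update per observation
  s_ref <- state0
  for (r in seq_len(nrow(rest))) {
    s_ref <- sema_update(s_ref, rest$subject[r], rest$value[r])
  }
  # fast route: compiled loop
  s_fast <- adaptref:::sema_stream(state0, rest$subject, rest$value)
  expect_equal(s_ref$mu_hat, s_fast$mu_hat, tolerance = 1e-12)
  expect_equal(s_ref$tau2_hat, s_fast$tau2_hat, tolerance = 1e-12)
  expect_equal(s_ref$sigma2_hat, s_fast$sigma2_hat, tolerance = 1e-12)
  expect_equal(s_ref$T1, s_fast$T1, tolerance = 1e-12)
  expect_equal(s_ref$T3, s_fast$T3, tolerance = 1e-12)

  # a new subject can join mid-stream
  s_new <- sema_update(s_ref, "NEW", 0.3)
  expect_equal(s_new$n_i[["NEW"]], 1)
  expect_true("NEW" %in% s_new$ids)
})

test_that("streaming a no-information value leaves the grand mean unchanged", {
  sim <- simulate_population(10, 5, 2, 1, 0.5, seed = 58)
  state <- em_fit(sim$table)
  mu_before <- state$mu_hat
  # a value exactly at the subject's current posterior-mean-compatible spot:
  # feeding the subject's own shrunk mean keeps its contribution centred
  s <- sema_update(state, "S001", state$mu_i_hat[["S001"]])
  expect_equal(s$mu_hat, mu_before, tolerance = 0.02)
})

test_that("SEMA approaches batch EM on large data (5% contract)", {
  sim <- simulate_population(200, 50, mu = 10, tau2 = 4,
                             sigma2_spec = list(r1 = 0.4, r2 = 0.5),
                             seed = 59)
  batch <- em_fit(sim$table)
  stream <- sema_fit(adaptref:::interleave_rows(sim$table))
  expect_lt(abs(stream$mu_hat - batch$mu_hat) / abs(batch$mu_hat), 0.05)
  expect_lt(abs(stream$tau2_hat - batch$tau2_hat) / batch$tau2_hat, 0.05)

  # agreement improves with data volume
  sim_small <- simulate_population(20, 5, mu = 10, tau2 = 4,
                                   sigma2_spec = list(r1 = 0.4, r2 = 0.5),
                                   seed = 60)
  b2 <- suppressWarnings(em_fit(sim_small$table))
  s2 <- suppressWarnings(sema_fit(adaptref:::interleave_rows(sim_small$table),
                                  batch_size = 40))
  err_small <- abs(s2$tau2_hat - b2$tau2_hat) / b2$tau2_hat
  err_large <- abs(stream$tau2_hat - batch$tau2_hat) / batch$tau2_hat
  expect_lt(err_large, err_small + 1e-9)
})

test_that("state size depends on subjects only, not on observations", {
  sim_a <- simulate_population(10, 5, 0, 1, 1, seed = 61)
  sim_b <- simulate_population(10, 400, 0, 1, 1, seed = 61)
  sa <- em_fit(sim_a$table)
  sb <- em_fit(sim_b$table)
  len <- function(s) vapply(s[c("n_i", "ybar_i", "y2bar_i", "sigma2_hat",
                                "mu_i_hat", "nu_i_hat", "rho_i_hat", "T3")],
                            length, integer(1))
  expect_identical(len(sa), len(sb))
})

test_that("plug-in band matches independent normal quantiles (formula check)", {
  set.seed(62)
  for (r in 1:1000) {
    mu <- rnorm(1)
    tau2 <- exp(rnorm(1))
    sigma2 <- exp(rnorm(1))
    j <- sample(1:50, 1)
    ybar <- rnorm(1)
    alpha <- runif(1, 0.01, 0.2)
    state <- structure(list(ids = "X", n_i = j - 1, ybar_i = ybar,
                            y2bar_i = ybar^2, mu_hat = mu, tau2_hat = tau2,
                            sigma2_hat = sigma2, mu_i_hat = ybar,
                            nu_i_hat = 0, rho_i_hat = 0.5, T1 = 0, T2 = 0,
                            T3 = 0, pool_num = 0, pool_den = 0,
                            iteration = 0L, converged = TRUE),
                       class = "em_state")
    state <- adaptref:::name_em_fields(state)
    lim <- dynamic_band_em(state, "X", j = j, alpha = alpha)
    prec <- 1 / tau2 + (j - 1) / sigma2
    centre <- (mu / tau2 + (j - 1) * ybar / sigma2) / prec
    v <- 1 / prec + sigma2
    expect_equal(unname(lim), qnorm(c(alpha / 2, 1 - alpha / 2), centre,
                                    sqrt(v)), tolerance = 1e-10)
  }
})

test_that("no-history band and the score/quantile duality", {
  state <- structure(list(ids = "X", n_i = 0, ybar_i = 0, y2bar_i = 0,
                          mu_hat = 0, tau2_hat = 1, sigma2_hat = 1,
                          mu_i_hat = 0, nu_i_hat = 1, rho_i_hat = 0,
                          T1 = 0, T2 = 0, T3 = 0, pool_num = 0, pool_den = 0,
                          iteration = 0L, converged = TRUE),
                     class = "em_state")
  state <- adaptref:::name_em_fields(state)
  lim <- dynamic_band_em(state, "X", j = 1, alpha = 0.05)
  expect_equal(unname(lim), c(-1, 1) * qnorm(0.975) * sqrt(2),
               tolerance = 1e-6)
  # score at the band edge equals alpha; at the centre it is 1
  expect_equal(predictive_score_em(state, "X", j = 1,
                                   observed = lim[["upper"]]), 0.05,
               tolerance = 1e-10)
  expect_equal(predictive_score_em(state, "X", j = 1, observed = 0), 1)
  expect_error(dynamic_band_em(state, "X", j = 5), "history mismatch")
  expect_error(dynamic_band_em(state, "nope"), "unknown subject")
})

test_that("plug-in scores are approximately uniform under the model (PIT)", {
  set.seed(63)
  scores <- numeric(400)
  sim <- simulate_population(40, 30, 0, 1, list(r1 = 0.2, r2 = 0.5))
  for (r in 1:400) {
    # draw a fresh next observation for a random subject under the truth
    i <- sample(40, 1)
    id <- names(sim$params$mu_i)[i]
    y_new <- rnorm(1, sim$params$mu_i[i], sqrt(sim$params$sigma2[i]))
    if (r == 1) fit <- em_fit(sim$table)
    scores[r] <- predictive_score_em(fit, id, observed = y_new)
  }
  expect_lt(abs(mean(scores < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(scores < 0.5) - 0.5), 0.07)
})

test_that("EM state JSON round trip is faithful", {
  sim <- simulate_population(8, 6, 1, 2, list(r1 = 0.1, r2 = 0.4), seed = 64)
  state <- em_fit(sim$table)
  path <- withr::local_tempfile(fileext = ".json")
  em_state_write(state, path)
  back <- em_state_read(path)
  for (f in c("ids", "n_i", "ybar_i", "y2bar_i", "sigma2_hat", "mu_i_hat",
              "nu_i_hat", "rho_i_hat", "T3")) {
    expect_equal(back[[f]], state[[f]], tolerance = 1e-12)
  }
  expect_equal(back$mu_hat, state$mu_hat, tolerance = 1e-12)
  expect_equal(back$tau2_hat, state$tau2_hat, tolerance = 1e-12)
  # streaming continues identically from the restored state
  a <- sema_update(state, "S002", 1.5)
  b <- sema_update(back, "S002", 1.5)
  expect_equal(a$mu_hat, b$mu_hat, tolerance = 1e-12)
})

test_that("sequential EM band mirrors the static fallback and flags outliers", {
  sim <- simulate_population(8, 6, 0, 1, 0.2, seed = 65)
  tab <- sim$table
  # plant a gross outlier at the subject's last index
  k <- which(tab$subject == "S004" & tab$index == 6)
  tab$value[k] <- tab$value[k] + 25
  band <- em_band_for_subject(tab, "S004", alpha = 0.05)
  others <- tab[tab$subject != "S004", ]
  ti <- tolerance_interval(others$value, p = 0.95, confidence = 0.95)
  expect_equal(band$lower[1:2], rep(ti$lower, 2))
  expect_true(band$atypical[6])
  expect_true(all(band$lower < band$upper))
})
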