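# Inversion fixtures use the small three-region network so every fit
# runs in seconds; the full seven-region model is exercised end to end
# in the pipeline and acceptance tests.

tiny_setup <- function(modulable = FALSE, seed = 7, n_channels = 6,
                       n_times = 81) {
  net <- tiny_network(modulable)
  lf <- synthesize_leadfield(n_channels, net, seed = seed)
  times <- seq(0, 0.8, length.out = n_times)
  priors <- dcm_priors(net)
  list(net = net, lf = lf, times = times, priors = priors)
}

test_that("priors index every parameter class exactly once", {
  net <- build_study_network()
  pr <- dcm_priors(net)
  expect_equal(sum(startsWith(pr$names, "A:")), 21L)
  expect_equal(sum(startsWith(pr$names, "B:")), 21L)
  expect_equal(sum(startsWith(pr$names, "C:")), 1L)
  expect_true(all(diag(pr$cov) == 1 / 16))
  expect_identical(names(pr$mean), pr$names)
  tiny <- tiny_network(modulable = FALSE)
  pr2 <- dcm_priors(tiny)
  expect_equal(sum(startsWith(pr2$names, "B:")), 0L)
})

test_that("predicted responses differ between conditions only through B", {
  s <- tiny_setup(modulable = TRUE)
  th <- s$priors$mean
  g1 <- predicted_response(s$net, s$lf, th, "baseline", s$times)
  g3 <- predicted_response(s$net, s$lf, th, "modulated", s$times)
  expect_identical(g1$data, g3$data)  # all b_log zero
  th["B:THAL->lS1"] <- 0.4
  g3b <- predicted_response(s$net, s$lf, th, "modulated", s$times)
  g1b <- predicted_response(s$net, s$lf, th, "baseline", s$times)
  expect_identical(g1b$data, g1$data)
  expect_false(identical(g3b$data, g3$data))
})

test_that("finite-difference Jacobian matches an independent Richardson oracle", {
  skip_if_not_installed("pracma")
  s <- tiny_setup(modulable = TRUE)
  th <- s$priors$mean
  th["A:THAL->lS1"] <- 0.2
  ff <- lepdcm:::.make_forward(s$net, s$lf, s$times, stimulus_spec())
  J <- ff$jac(th, 1e-3)$J
  f <- function(v) {
    tv <- th; tv[] <- v
    ff$gvec(tv)
  }
  J_oracle <- pracma::jacobian(f, unname(th))
  expect_lt(norm(J - J_oracle, "F") / norm(J_oracle, "F"), 1e-4)
})

test_that("the batched forward map equals the reference simulation path", {
  s <- tiny_setup(modulable = TRUE)
  th <- s$priors$mean
  th["A:lS1->lS2"] <- -0.3
  th["B:lS2->THAL"] <- 0.25
  th["C:THAL"] <- 0.1
  ff <- lepdcm:::.make_forward(s$net, s$lf, s$times, stimulus_spec())
  ref <- lepdcm:::.forward_vec(th, s$net, s$lf, s$times, stimulus_spec())
  expect_equal(ff$gvec(th), ref, tolerance = 1e-12)
})

test_that("self-consistency: data generated at the prior mean refit to it", {
  s <- tiny_setup(modulable = TRUE)
  rec <- make_records(s$net, s$priors$mean, s$lf, s$times)
  fit <- dcm_fit(rec$block1, rec$block3, s$net, s$lf, s$priors,
                 settings = list(fix_lambda = log(1 / 0.05^2)))
  expect_true(all(abs(coef(fit) - s$priors$mean) < 0.05))
  expect_true(all(fit$variance_explained > 0.99))
})

test_that("a planted connection strength is recovered inside its credible interval", {
  s <- tiny_setup(modulable = FALSE)
  th <- s$priors$mean
  th["A:THAL->lS1"] <- 0.5
  rec <- make_records(s$net, th, s$lf, s$times, noise_sd = 0.02,
                      seed = 11)
  fit <- dcm_fit(rec$block1, rec$block3, s$net, s$lf, s$priors)
  est <- coef(fit)["A:THAL->lS1"]
  sd_ <- sqrt(vcov(fit)["A:THAL->lS1", "A:THAL->lS1"])
  expect_lt(abs(est - 0.5), 1.645 * sd_ + 1e-8)
  expect_gt(est, 0.2)
})

test_that("free energy is non-decreasing across accepted optimisation steps", {
  s <- tiny_setup(modulable = TRUE)
  set.seed(21)
  for (i in 1:3) {
    th <- s$priors$mean + rnorm(length(s$priors$mean), 0, 0.2)
    names(th) <- s$priors$names
    rec <- make_records(s$net, th, s$lf, s$times, noise_sd = 0.05,
                        seed = 100 + i)
    fit <- dcm_fit(rec$block1, rec$block3, s$net, s$lf, s$priors)
    expect_true(all(diff(fit$F_trace) >= -1e-6))
    expect_false(fit$diverged)
  }
})

test_that("in the linearised regime the posterior matches the conjugate solution", {
  # tiny stimulus amplitude keeps the sigmoid in its linear range, so the
  # model is effectively linear-Gaussian and the exact posterior has a
  # closed form computed here from an independently differentiated
  # forward map
  skip_if_not_installed("pracma")
  # data are generated close to the prior mean: the forward map is also
  # nonlinear in the parameters (exponential couplings), so the
  # linearisation is exact only locally
  s <- tiny_setup(modulable = FALSE)
  stim <- stimulus_spec(amplitude = 1e-3)
  th_true <- s$priors$mean
  th_true["A:THAL->lS2"] <- 0.02
  th_true["A:lS2->THAL"] <- -0.015
  g_true <- c(
    as.numeric(predicted_response(s$net, s$lf, th_true, "baseline",
                                  s$times, stim)$data),
    as.numeric(predicted_response(s$net, s$lf, th_true, "modulated",
                                  s$times, stim)$data))
  tau <- 1 / (1e-5)^2
  rec <- make_records(s$net, th_true, s$lf, s$times, stim)
  fit <- dcm_fit(rec$block1, rec$block3, s$net, s$lf, s$priors,
                 stim = stim, settings = list(fix_lambda = log(tau)))
  # oracle: numerically differentiated forward map at the prior mean
  ff <- lepdcm:::.make_forward(s$net, s$lf, s$times, stim)
  f <- function(v) {
    tv <- s$priors$mean; tv[] <- v
    ff$gvec(tv)
  }
  J <- pracma::jacobian(f, unname(s$priors$mean))
  g0 <- ff$gvec(s$priors$mean)
  oracle <- oracle_linear_posterior(g_true, g0, J,
                                    s$priors$mean, s$priors$cov, tau)
  expect_lt(max(abs(coef(fit) - oracle$mean)), 1e-3)
  # posterior never exceeds the prior covariance in this regime
  ev <- eigen(s$priors$cov - vcov(fit), symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("free energy computation matches analytic Gaussian integrals", {
  # two-parameter linear toy model evaluated against the closed-form
  # marginal likelihood (the bound is tight for linear models)
  set.seed(3)
  J <- cbind(rnorm(40), rnorm(40))
  theta0 <- c(0.3, -0.1)
  cc <- rnorm(40, sd = 0.1)
  tau <- 25
  y <- drop(J %*% theta0) + cc
  mu0 <- c(0, 0)
  V0 <- diag(c(0.5, 0.25))
  P0 <- solve(V0)
  # exact posterior
  S <- solve(tau * crossprod(J) + P0)
  mu <- drop(S %*% (tau * crossprod(J, y - cc)))
  Fpkg <- lepdcm:::.free_energy_terms(
    r = y - (drop(J %*% mu) + cc), J = J, S = S, d = mu - mu0,
    P0 = P0, logdetP0 = -determinant(V0, TRUE)$modulus[1],
    lambda = log(tau))
  Fora <- oracle_linear_evidence(y, J, cc, mu0, V0, tau)
  expect_lt(abs(Fpkg - Fora), 1e-6)
  # zero residual at the prior mean: no deviation penalty in the KL
  F0 <- lepdcm:::.free_energy_terms(
    r = rep(0, 40), J = J, S = V0, d = c(0, 0), P0 = P0,
    logdetP0 = -determinant(V0, TRUE)$modulus[1], lambda = log(tau))
  acc0 <- -0.5 * tau * sum((J %*% V0) * J) +
    0.5 * 40 * (log(tau) - log(2 * pi))
  expect_equal(F0, acc0)  # KL vanishes when q = prior and mean deviation 0
  # increasing the residual sum of squares strictly decreases F
  Fs <- vapply(c(0, 0.5, 1, 2), function(s)
    lepdcm:::.free_energy_terms(
      r = rep(s, 40), J = J, S = S, d = c(0, 0), P0 = P0,
      logdetP0 = -determinant(V0, TRUE)$modulus[1], lambda = log(tau)),
    numeric(1))
  expect_true(all(diff(Fs) < 0))
})

test_that("dcm_free_energy is deterministic and penalises worse parameter points", {
  s <- tiny_setup(modulable = FALSE)
  th <- s$priors$mean
  th["A:THAL->lS1"] <- 0.4
  rec <- make_records(s$net, th, s$lf, s$times)
  F_true <- dcm_free_energy(rec$block1, rec$block3, s$net, s$lf,
                            s$priors, th, log_precision = log(400))
  F_wrong <- dcm_free_energy(rec$block1, rec$block3, s$net, s$lf,
                             s$priors, s$priors$mean,
                             log_precision = log(400))
  expect_identical(F_true,
                   dcm_free_energy(rec$block1, rec$block3, s$net, s$lf,
                                   s$priors, th,
                                   log_precision = log(400)))
  expect_gt(F_true, F_wrong)
})

test_that("parameter recovery over a batch of synthetic subjects is accurate", {
  # twenty subjects with connection effects drawn at SD 0.25, low noise:
  # mean absolute error of the baseline log-strengths stays below 0.15
  # and signs are right for clearly nonzero effects
  s <- tiny_setup(modulable = FALSE)
  a_names <- paste0("A:", edge_names(s$net))
  err <- c(); truths <- c(); ests <- c()
  for (i in 1:20) {
    th <- s$priors$mean
    th[a_names] <- with_seed(3000 + i,
                             stats::rnorm(length(a_names), 0, 0.25))
    rec <- make_records(s$net, th, s$lf, s$times, noise_sd = 0.02,
                        seed = 400 + i)
    fit <- dcm_fit(rec$block1, rec$block3, s$net, s$lf, s$priors)
    err <- c(err, abs(coef(fit)[a_names] - th[a_names]))
    truths <- c(truths, th[a_names])
    ests <- c(ests, coef(fit)[a_names])
  }
  expect_lt(mean(err), 0.15)
  big <- abs(truths) >= 0.3
  expect_gt(mean(sign(ests[big]) == sign(truths[big])), 0.9)
})

test_that("mismatched grids and montages are rejected", {
  s <- tiny_setup()
  rec <- make_records(s$net, s$priors$mean, s$lf, s$times)
  short <- rec$block3
  short$data <- short$data[, 1:40]
  expect_error(dcm_fit(rec$block1, short, s$net, s$lf, s$priors),
               "share montage")
  other_lf <- synthesize_leadfield(5, s$net, seed = 2)
  expect_error(dcm_fit(rec$block1, rec$block3, s$net, other_lf,
                       s$priors),
               "match lead field")
})

test_that("fitted models expose the standard accessor methods", {
  s <- tiny_setup(modulable = TRUE)
  th <- s$priors$mean
  th["A:THAL->lS1"] <- 0.3
  rec <- make_records(s$net, th, s$lf, s$times, noise_sd = 0.05,
                      seed = 5)
  fit <- dcm_fit(rec$block1, rec$block3, s$net, s$lf, s$priors,
                 settings = list(max_iter = 8L))
  expect_s3_class(fit, "dcm")
  expect_named(coef(fit))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  expect_equal(unclass(logLik(fit))[1], fit$free_energy)
  pred <- predict(fit, "baseline")
  expect_s3_class(pred, "evoked_record")
  res <- residuals(fit)
  expect_equal(pred$data + res$block1, rec$block1$data)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$theta, sims[[2]]$theta))
  st <- summary(fit)
  expect_s3_class(st, "summary.dcm")
  expect_output(print(st), "DCM posterior")
  # posterior JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_posterior(fit, path)
  back <- read_posterior(path)
  expect_equal(back$mean, coef(fit), tolerance = 1e-12)
  expect_equal(back$cov, vcov(fit), tolerance = 1e-10)
  expect_equal(back$free_energy, fit$free_energy)
})
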