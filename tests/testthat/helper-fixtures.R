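# Shared fixtures and independent oracles for the test suite.

# Small three-region network (hidden relay + two cortical areas),
# optionally with modulable edges.
tiny_network <- function(modulable = FALSE) {
  regions <- data.frame(label = c("lS1", "lS2", "THAL"),
                        observed = c(TRUE, TRUE, FALSE))
  edges <- data.frame(
    source = c("THAL", "THAL", "lS1", "lS2"),
    target = c("lS1", "lS2", "lS2", "THAL"),
    class = c("forward", "forward", "forward", "backward"),
    modulable = modulable)
  lep_network(regions, edges, input_regions = "THAL")
}

# Deterministic noiseless records for a parameter point on a network.
make_records <- function(net, theta, lf, times, stim = stimulus_spec(),
                         noise_sd = 0, seed = 1L) {
  b1 <- predicted_response(net, lf, theta, "baseline", times, stim)
  b3 <- predicted_response(net, lf, theta, "modulated", times, stim)
  b1$condition <- "block1"; b3$condition <- "block3"
  if (noise_sd > 0) {
    b1 <- add_noise(b1, noise_sd, seed)
    b3 <- add_noise(b3, noise_sd, seed + 1L)
  }
  list(block1 = b1, block3 = b3)
}

# ---- Independent oracles -------------------------------------------------

# Exact two-sample permutation p value by brute-force enumeration of all
# group assignments (two-sided Welch statistic).
oracle_perm_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  wt <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  t_obs <- wt(x, y)
  sets <- utils::combn(length(pooled), nx)
  ts <- apply(sets, 2, function(i) wt(pooled[i], pooled[-i]))
  mean(abs(ts) >= abs(t_obs) - 1e-12)
}

# Closed-form Bayesian linear-regression posterior for
# y = g(mu0) + J (theta - mu0) + noise, prior N(mu0, V0), known noise
# precision tau: mean = mu0 + S tau J'(y - g(mu0)), S = (tau J'J + V0^-1)^-1.
oracle_linear_posterior <- function(y, g0, J, mu0, V0, tau) {
  S <- solve(tau * crossprod(J) + solve(V0))
  list(mean = mu0 + drop(S %*% (tau * crossprod(J, y - g0))),
       cov = S)
}

# Log evidence of the linear-Gaussian model y ~ N(J theta + c, tau^-1 I),
# theta ~ N(mu0, V0), computed through the marginal covariance (no
# variational quantities involved).
oracle_linear_evidence <- function(y, J, cc, mu0, V0, tau) {
  m <- drop(J %*% mu0) + cc
  V <- diag(length(y)) / tau + J %*% V0 %*% t(J)
  L <- chol(V)
  r <- backsolve(L, y - m, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(r^2)
}

# Second-level hierarchical-model evidence and posterior computed through
# the stacked marginal Gaussian (independent of the package's
# block-accumulation implementation). Th: p x n matrix of subject means;
# Slist: subject covariances; X: n x q design; G: between-subject cov;
# Vb0: prior covariance of stacked effects (b varies slowest by
# covariate, matching kronecker(x_i, theta)).
oracle_peb <- function(Th, Slist, X, G, Vb0) {
  p <- nrow(Th); n <- ncol(Th); q <- ncol(X)
  M <- do.call(rbind, lapply(seq_len(n), function(i)
    kronecker(matrix(X[i, ], nrow = 1), diag(p))))
  R <- matrix(0, n * p, n * p)
  for (i in seq_len(n)) {
    idx <- (i - 1) * p + seq_len(p)
    R[idx, idx] <- Slist[[i]] + G
  }
  yv <- as.vector(Th)
  V <- R + M %*% Vb0 %*% t(M)
  L <- chol(V)
  z <- backsolve(L, yv, transpose = TRUE)
  logZ <- -0.5 * n * p * log(2 * pi) - sum(log(diag(L))) -
    0.5 * sum(z^2)
  P <- t(M) %*% solve(R) %*% M + solve(Vb0)
  S <- solve(P)
  m <- drop(S %*% t(M) %*% solve(R) %*% yv)
  list(mean = m, cov = S, logZ = logZ)
}

# Synthetic subject "posteriors" for second-level tests: true subject
# effects theta_i = X beta + between-subject noise, observed with
# first-level uncertainty first_sd.
synth_posteriors <- function(n_control, n_migraine, param_names,
                             beta1 = NULL, first_sd = 0.05,
                             between_sd = 0.1, seed = 1L) {
  p <- length(param_names)
  groups <- rep(c("control", "migraine"), c(n_control, n_migraine))
  if (is.null(beta1)) beta1 <- stats::setNames(numeric(p), param_names)
  with_seed(seed, {
    post <- lapply(seq_along(groups), function(i) {
      mu <- numeric(p)
      if (groups[i] == "migraine") mu <- mu + beta1
      th <- mu + stats::rnorm(p, 0, between_sd) +
        stats::rnorm(p, 0, first_sd)
      names(th) <- param_names
      S <- diag(first_sd^2, p)
      dimnames(S) <- list(param_names, param_names)
      list(mean = th, cov = S)
    })
    list(posteriors = post, groups = groups)
  })
}
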