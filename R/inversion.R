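# Variational Laplace (free-energy) inversion of the generative model
# for one subject's pair of block-average evoked records.

#' Prior density over the DCM parameter vector
#'
#' Builds the Gaussian prior over the free parameters: one `A:` entry
#' per edge (baseline log-strength), one `B:` entry per modulable edge
#' (block-1 to block-3 log-modulation) and one `C:` entry per input
#' region (log input gain). Shrinkage priors are zero-mean with variance
#' 1/16 by default, the conventional scale for log-coupling parameters;
#' intrinsic synaptic constants are fixed, not estimated.
#'
#' @param net a `lep_network`.
#' @param mean prior mean (scalar or named vector; default 0).
#' @param variance prior variance for every parameter (default 1/16).
#' @return object of class `dcm_priors`: list with `names`, `mean`,
#'   `cov`.
#' @export
dcm_priors <- function(net, mean = 0, variance = 1 / 16) {
  nm <- c(paste0("A:", edge_names(net), recycle0 = TRUE),
          paste0("B:", edge_names(net, modulable_only = TRUE),
                 recycle0 = TRUE),
          paste0("C:", net$input_regions, recycle0 = TRUE))
  p <- length(nm)
  mu <- stats::setNames(rep_len(0, p), nm)
  if (length(mean) == 1L && is.null(names(mean))) {
    mu[] <- mean
  } else {
    bad <- setdiff(names(mean), nm)
    if (length(bad)) stop("unknown prior mean entries: ",
                          paste(bad, collapse = ", "))
    mu[names(mean)] <- mean
  }
  V <- diag(rep_len(variance, p), p)
  dimnames(V) <- list(nm, nm)
  structure(list(names = nm, mean = mu, cov = V), class = "dcm_priors")
}

# Split a named parameter vector into neural_params pieces.
.theta_to_params <- function(theta, net, base = NULL) {
  if (is.null(base)) base <- neural_params(net)
  nm <- names(theta)
  a <- theta[startsWith(nm, "A:")]
  b <- theta[startsWith(nm, "B:")]
  cc <- theta[startsWith(nm, "C:")]
  names(a) <- sub("^A:", "", names(a))
  names(b) <- sub("^B:", "", names(b))
  names(cc) <- sub("^C:", "", names(cc))
  base$a_log[names(a)] <- a
  base$b_log[names(b)] <- b
  base$c_gain[names(cc)] <- cc
  base
}

#' Predicted channel response at a parameter point
#'
#' The deterministic forward map g(theta): simulate the neural-mass
#' sources under the given condition and project them through the lead
#' field.
#'
#' @param net a `lep_network`.
#' @param lf a `lead_field`.
#' @param theta named parameter vector (entries `A:...`, `B:...`,
#'   `C:...` as in [dcm_priors()]).
#' @param condition `"baseline"` or `"modulated"`.
#' @param times output time grid (s).
#' @param stim a `stimulus_spec`.
#' @param ... further arguments to [simulate_sources()].
#' @return noiseless `evoked_record`.
#' @export
predicted_response <- function(net, lf, theta, condition, times,
                               stim = stimulus_spec(), ...) {
  params <- .theta_to_params(theta, net)
  traj <- simulate_sources(net, params, stim, condition, times, ...)
  project_sources(traj, lf, condition = condition)
}

# Stacked prediction vector for both conditions.
.forward_vec <- function(theta, net, lf, times, stim, ...) {
  g1 <- predicted_response(net, lf, theta, "baseline", times, stim, ...)
  g3 <- predicted_response(net, lf, theta, "modulated", times, stim, ...)
  c(as.numeric(g1$data), as.numeric(g3$data))
}

# Precompiled forward evaluator: precomputes every static ingredient of
# the generative model so that repeated evaluations (Gauss-Newton
# Jacobians) run through a single batched C++ sweep.
.make_forward <- function(net, lf, times, stim, oversample = 4L,
                          input_gain_base = 24, base = NULL) {
  if (is.null(base)) base <- neural_params(net)
  labs <- net$regions$label
  n <- length(labs)
  e <- net$edges
  idx <- cbind(match(e$target, labs), match(e$source, labs))
  cg_e <- unname(base$class_gains[e$class])
  is_fl <- e$class %in% c("forward", "lateral")
  is_bl <- e$class %in% c("backward", "lateral")
  mod <- as.logical(e$modulable)
  en <- edge_names(net)
  input_idx <- match(net$input_regions, labs)
  dt_out <- .check_uniform(times)
  oversample <- as.integer(oversample)
  dt_fine <- dt_out / oversample
  nt_fine <- (length(times) - 1L) * oversample + 1L
  t_fine <- times[1] + dt_fine * (seq_len(nt_fine) - 1L)
  u <- stimulus_waveform(stim, t_fine)
  constants <- c(base$kappa_e, base$kappa_i, base$h_e, base$h_i,
                 base$gamma, base$sigmoid_slope)
  gain <- lf$gain

  triple <- function(theta, condition) {
    a <- theta[paste0("A:", en)]
    w <- a
    if (condition == "modulated" && any(mod))
      w[mod] <- w[mod] + theta[paste0("B:", en[mod])]
    w <- exp(w) * cg_e
    AFL <- matrix(0, n, n); ABL <- matrix(0, n, n)
    AFL[idx[is_fl, , drop = FALSE]] <- w[is_fl]
    ABL[idx[is_bl, , drop = FALSE]] <- w[is_bl]
    Cv <- numeric(n)
    Cv[input_idx] <- input_gain_base *
      exp(theta[paste0("C:", net$input_regions)])
    list(AFL = AFL, ABL = ABL, C = Cv)
  }

  sweep <- function(triples) {
    .erp_sweep(lapply(triples, `[[`, "AFL"),
               lapply(triples, `[[`, "ABL"),
               lapply(triples, `[[`, "C"),
               constants, u, dt_fine, oversample, gain)
  }

  gvec <- function(theta) {
    out <- sweep(list(triple(theta, "baseline"),
                      triple(theta, "modulated")))
    c(out[, 1], out[, 2])
  }

  jac <- function(theta, fd_step) {
    p <- length(theta)
    nm <- names(theta)
    is_b <- startsWith(nm, "B:")
    perturb <- function(k, h) { th <- theta; th[k] <- th[k] + h; th }
    # baseline depends only on A/C parameters
    base_pts <- c(list(theta),
                  unlist(lapply(which(!is_b), function(k)
                    list(perturb(k, fd_step), perturb(k, -fd_step))),
                    recursive = FALSE))
    mod_pts <- c(list(theta),
                 unlist(lapply(seq_len(p), function(k)
                   list(perturb(k, fd_step), perturb(k, -fd_step))),
                   recursive = FALSE))
    Gb <- sweep(lapply(base_pts, triple, condition = "baseline"))
    Gm <- sweep(lapply(mod_pts, triple, condition = "modulated"))
    nb <- nrow(Gb)
    J <- matrix(0, 2L * nb, p, dimnames = list(NULL, nm))
    col <- 1L
    for (k in which(!is_b)) {
      J[1:nb, k] <- (Gb[, col + 1L] - Gb[, col + 2L]) / (2 * fd_step)
      col <- col + 2L
    }
    col <- 1L
    for (k in seq_len(p)) {
      J[(nb + 1L):(2L * nb), k] <-
        (Gm[, col + 1L] - Gm[, col + 2L]) / (2 * fd_step)
      col <- col + 2L
    }
    list(g = c(Gb[, 1], Gm[, 1]), J = J)
  }

  list(gvec = gvec, jac = jac)
}

# Central finite-difference Jacobian of the stacked forward map
# (reference path through simulate_sources; the fitter uses
# .make_forward's batched equivalent).
.forward_jacobian <- function(theta, net, lf, times, stim, fd_step, ...) {
  p <- length(theta)
  g0 <- .forward_vec(theta, net, lf, times, stim, ...)
  J <- matrix(0, length(g0), p, dimnames = list(NULL, names(theta)))
  for (k in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + fd_step
    tm[k] <- tm[k] - fd_step
    J[, k] <- (.forward_vec(tp, net, lf, times, stim, ...) -
               .forward_vec(tm, net, lf, times, stim, ...)) /
      (2 * fd_step)
  }
  list(g = g0, J = J)
}

# Laplace free energy given residuals r, Jacobian J, posterior
# covariance S, prior (mu0, P0 = inverse cov), deviation d = mu - mu0,
# and log noise precision lambda.
.free_energy_terms <- function(r, J, S, d, P0, logdetP0, lambda) {
  N <- length(r)
  tau <- exp(lambda)
  acc <- -0.5 * tau * (sum(r^2) + sum((J %*% S) * J)) +
    0.5 * N * (lambda - log(2 * pi))
  ldS <- determinant(S, logarithm = TRUE)$modulus[1]
  kl <- 0.5 * (sum((P0 %*% S) * diag(nrow(S))) +
               sum(d * (P0 %*% d)) - nrow(S) - ldS - logdetP0)
  acc - kl
}

#' Laplace free energy of a parameter point
#'
#' Evaluates the variational free energy -- accuracy (expected Gaussian
#' log-likelihood of the residuals under the local Laplace posterior)
#' minus complexity (KL divergence from the prior) -- for a pair of
#' block-average records at a given parameter point and noise log
#' precision. The Laplace posterior covariance is formed from the local
#' finite-difference Jacobian.
#'
#' @param block1,block3 `evoked_record`s (baseline / modulated block).
#' @param net,lf,priors model specification as in [dcm_fit()].
#' @param theta named parameter vector.
#' @param log_precision log noise precision (1/µV^2).
#' @param stim stimulus specification.
#' @param fd_step finite-difference step.
#' @param ... further simulation arguments.
#' @return free energy (nats).
#' @export
dcm_free_energy <- function(block1, block3, net, lf, priors, theta,
                            log_precision, stim = stimulus_spec(),
                            fd_step = 1e-3, ...) {
  y <- c(as.numeric(block1$data), as.numeric(block3$data))
  times <- evoked_times(block1)
  ff <- .make_forward(net, lf, times, stim, ...)
  fj <- ff$jac(theta, fd_step)
  P0 <- solve(priors$cov)
  tau <- exp(log_precision)
  H <- tau * crossprod(fj$J) + P0
  S <- solve((H + t(H)) / 2)
  .free_energy_terms(y - fj$g, fj$J, S, theta - priors$mean, P0,
                     -determinant(priors$cov, TRUE)$modulus[1],
                     log_precision)
}

#' Fit the DCM to one subject's pair of block averages
#'
#' Inverts the generative model (neural-mass network + lead field) on
#' the block-1 and block-3 average evoked responses jointly, treating
#' block 1 as the baseline condition and block 3 as the modulated
#' condition (the `B:` log-modulations act only there). Inference is
#' variational Laplace: Gauss-Newton ascent on the free energy with
#' step halving, a single i.i.d. channel-noise precision hyperparameter
#' updated by EM, and Gaussian shrinkage priors. Iteration stops when
#' the free-energy change stays below `tol` for `tol_count` consecutive
#' iterations, when no step (after halving) increases the free energy,
#' or at `max_iter`.
#'
#' @param block1,block3 `evoked_record`s sharing montage and grid.
#' @param net a `lep_network`.
#' @param lf a `lead_field` matching the records' montage.
#' @param priors a `dcm_priors` (default: shrinkage priors for `net`).
#' @param stim stimulus specification used by the forward model.
#' @param settings list overriding any of: `max_iter` (64), `tol`
#'   (0.01 nats), `tol_count` (3), `fd_step` (1e-3), `max_halvings` (5),
#'   `lambda0` (initial log precision; default estimated from data
#'   variance), `fix_lambda` (fix the noise log precision at this value
#'   instead of estimating it), `oversample` (4), `input_gain_base` (24).
#' @return object of class `dcm`: posterior mean/covariance over the
#'   named parameter vector, free energy and its per-iteration trace,
#'   noise log precision, variance explained per condition, and the
#'   model ingredients needed by methods.
#' @export
dcm_fit <- function(block1, block3, net, lf, priors = NULL,
                    stim = stimulus_spec(), settings = list()) {
  if (!identical(dim(block1$data), dim(block3$data)) ||
      !isTRUE(all.equal(block1$rate, block3$rate)) ||
      !isTRUE(all.equal(block1$window, block3$window)))
    stop("block1 and block3 must share montage and time grid")
  if (!identical(rownames(block1$data), lf$channels))
    stop("record channels do not match lead field")
  if (is.null(priors)) priors <- dcm_priors(net)
  s <- list(max_iter = 64L, tol = 0.01, tol_count = 3L, fd_step = 1e-3,
            max_halvings = 5L, lambda0 = NULL, fix_lambda = NULL,
            oversample = 4L, input_gain_base = 24)
  bad <- setdiff(names(settings), names(s))
  if (length(bad)) stop("unknown settings: ", paste(bad, collapse = ", "))
  s[names(settings)] <- settings

  y <- c(as.numeric(block1$data), as.numeric(block3$data))
  N <- length(y)
  times <- evoked_times(block1)
  P0 <- solve(priors$cov)
  logdetV0 <- determinant(priors$cov, TRUE)$modulus[1]

  ff <- .make_forward(net, lf, times, stim, s$oversample,
                      s$input_gain_base)
  jac <- function(th) ff$jac(th, s$fd_step)

  mu <- priors$mean
  fj <- jac(mu)
  r <- y - fj$g
  if (!is.null(s$fix_lambda)) {
    lambda <- s$fix_lambda
  } else if (!is.null(s$lambda0)) {
    lambda <- s$lambda0
  } else {
    lambda <- -log(max(stats::var(r), 1e-12))
  }

  post_cov <- function(J, lambda) {
    H <- exp(lambda) * crossprod(J) + P0
    solve((H + t(H)) / 2)
  }
  Fval <- function(r, J, S, mu, lambda)
    .free_energy_terms(r, J, S, mu - priors$mean, P0, -logdetV0, lambda)

  S <- post_cov(fj$J, lambda)
  F_cur <- Fval(r, fj$J, S, mu, lambda)
  F_trace <- F_cur
  n_small <- 0L
  diverged <- FALSE
  iter <- 0L

  while (iter < s$max_iter) {
    iter <- iter + 1L
    tau <- exp(lambda)
    dir <- S %*% (tau * crossprod(fj$J, r) - P0 %*% (mu - priors$mean))
    dir <- drop(dir)
    accepted <- FALSE
    step <- 1
    for (h in seq_len(s$max_halvings + 1L)) {
      mu_c <- mu + step * dir
      fj_c <- jac(mu_c)
      r_c <- y - fj_c$g
      if (any(!is.finite(r_c))) { step <- step / 2; next }
      lambda_c <- lambda
      if (is.null(s$fix_lambda)) {
        # EM update of the noise precision given the local posterior
        S_tmp <- post_cov(fj_c$J, lambda_c)
        ess <- sum(r_c^2) + sum((fj_c$J %*% S_tmp) * fj_c$J)
        lambda_c <- log(N / ess)
      }
      S_c <- post_cov(fj_c$J, lambda_c)
      F_c <- Fval(r_c, fj_c$J, S_c, mu_c, lambda_c)
      if (is.finite(F_c) && F_c >= F_cur - 1e-9) {
        accepted <- TRUE
        dF <- F_c - F_cur
        mu <- mu_c; fj <- fj_c; r <- r_c; lambda <- lambda_c
        S <- S_c; F_cur <- F_c
        F_trace <- c(F_trace, F_cur)
        n_small <- if (abs(dF) < s$tol) n_small + 1L else 0L
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    if (n_small >= s$tol_count) break
  }
  if (any(!is.finite(mu))) diverged <- TRUE

  nc <- length(as.numeric(block1$data))
  ve <- function(obs, pred) 1 - sum((obs - pred)^2) / sum(obs^2)
  var_expl <- c(block1 = ve(y[1:nc], fj$g[1:nc]),
                block3 = ve(y[-(1:nc)], fj$g[-(1:nc)]))

  structure(list(
    mean = mu, cov = S, free_energy = F_cur, F_trace = F_trace,
    log_precision = lambda, iterations = iter,
    variance_explained = var_expl, diverged = diverged,
    priors = priors, net = net, lf = lf, stim = stim, settings = s,
    data = list(block1 = block1, block3 = block3)),
    class = "dcm")
}

#' @export
print.dcm <- function(x, ...) {
  cat("DCM fit:", length(x$mean), "parameters,",
      x$iterations, "iterations\n")
  cat(sprintf("  free energy %.2f nats; log noise precision %.2f\n",
              x$free_energy, x$log_precision))
  cat(sprintf("  variance explained: block1 %.1f%%, block3 %.1f%%\n",
              100 * x$variance_explained[1], 100 * x$variance_explained[2]))
  if (x$diverged) cat("  WARNING: divergence reported\n")
  invisible(x)
}

#' @export
coef.dcm <- function(object, ...) object$mean

#' @export
vcov.dcm <- function(object, ...) object$cov

#' @export
logLik.dcm <- function(object, ...) {
  structure(object$free_energy, df = length(object$mean),
            class = "logLik")
}

#' @export
summary.dcm <- function(object, ...) {
  sds <- sqrt(diag(object$cov))
  z <- object$mean / sds
  tab <- data.frame(estimate = object$mean, sd = sds, z = z)
  out <- list(table = tab, free_energy = object$free_energy,
              iterations = object$iterations,
              variance_explained = object$variance_explained,
              diverged = object$diverged)
  class(out) <- "summary.dcm"
  out
}

#' @export
print.summary.dcm <- function(x, ...) {
  cat(sprintf("DCM posterior (free energy %.2f nats, %d iterations)\n",
              x$free_energy, x$iterations))
  print(round(x$table, 3))
  invisible(x)
}

#' @export
predict.dcm <- function(object, condition = c("baseline", "modulated"),
                        ...) {
  condition <- match.arg(condition)
  predicted_response(object$net, object$lf, object$mean, condition,
                     evoked_times(object$data$block1), object$stim,
                     oversample = object$settings$oversample,
                     input_gain_base = object$settings$input_gain_base)
}

#' @export
residuals.dcm <- function(object, ...) {
  list(block1 = object$data$block1$data -
         predict(object, "baseline")$data,
       block3 = object$data$block3$data -
         predict(object, "modulated")$data)
}

#' @export
simulate.dcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol((object$cov + t(object$cov)) / 2 +
                diag(1e-12, nrow(object$cov))))
  lapply(seq_len(nsim), function(i) {
    th <- object$mean + drop(L %*% stats::rnorm(length(object$mean)))
    list(theta = th,
         block1 = predicted_response(object$net, object$lf, th,
                                     "baseline",
                                     evoked_times(object$data$block1),
                                     object$stim),
         block3 = predicted_response(object$net, object$lf, th,
                                     "modulated",
                                     evoked_times(object$data$block1),
                                     object$stim))
  })
}

#' @export
plot.dcm <- function(x, condition = "baseline", ...) {
  obs <- if (condition == "baseline") x$data$block1 else x$data$block3
  pred <- predict(x, condition)
  tt <- evoked_times(obs) * 1000
  matplot(tt, t(obs$data), type = "l", lty = 1,
          col = grDevices::grey(0.7), xlab = "time (ms)",
          ylab = expression(paste("amplitude (", mu, "V)")),
          main = paste("Observed (grey) vs predicted:", condition), ...)
  graphics::matlines(tt, t(pred$data), lty = 1, col = "firebrick")
  invisible(x)
}

#' Posterior JSON I/O
#'
#' Saves a fitted `dcm` posterior (names, mean, covariance, free
#' energy, noise precision, diagnostics) as JSON; the model ingredients
#' and data are not serialized.
#'
#' @param fit a `dcm`.
#' @param path file path.
#' @return `write_posterior` returns `path` invisibly; `read_posterior`
#'   returns a list of class `dcm_posterior` usable by [peb()].
#' @export
write_posterior <- function(fit, path) {
  doc <- list(schema = "lep-posterior/1",
              names = names(fit$mean),
              mean = unname(fit$mean),
              cov = unname(fit$cov),
              free_energy = fit$free_energy,
              log_precision = fit$log_precision,
              iterations = fit$iterations,
              variance_explained = as.list(fit$variance_explained),
              subject = fit$data$block1$subject,
              group = fit$data$block1$group)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "lep-posterior/1"))
    stop("unrecognised posterior schema: ", doc$schema)
  m <- stats::setNames(doc$mean, doc$names)
  V <- matrix(unlist(doc$cov), length(m), length(m),
              dimnames = list(doc$names, doc$names))
  structure(list(mean = m, cov = V, free_energy = doc$free_energy,
                 subject = doc$subject, group = doc$group),
            class = "dcm_posterior")
}
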