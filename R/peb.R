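# Parametric empirical Bayes over subjects' DCM posteriors, with
# Bayesian model reduction and a greedy pruning search.

#' Group design matrix for the two-group study
#'
#' Column 1 is all ones (the commonality effect, beta0); column 2 is
#' the group dummy with 0 = control and 1 = migraine (the group
#' difference, beta1).
#'
#' @param groups character vector of `"control"` / `"migraine"` labels,
#'   one per subject, in subject order.
#' @return numeric matrix subjects x 2 with columns `b0`, `b1`.
#' @export
build_design <- function(groups) {
  if (!all(groups %in% c("control", "migraine")))
    stop("unknown group label: ",
         paste(setdiff(groups, c("control", "migraine")), collapse = ", "))
  X <- cbind(b0 = rep(1, length(groups)),
             b1 = as.numeric(groups == "migraine"))
  rownames(X) <- names(groups)
  X
}

# Gaussian Bayesian model reduction: given a prior/posterior pair and a
# reduced prior, return the change in log evidence and the reduced
# posterior (exact for linear-Gaussian models).
.gauss_bmr <- function(mu, S, mu0, V0, mu_r0, V_r0) {
  P <- solve(S); P0 <- solve(V0); Pr0 <- solve(V_r0)
  Pr <- P + Pr0 - P0
  Pr <- (Pr + t(Pr)) / 2
  Sr <- solve(Pr)
  hr <- P %*% mu + Pr0 %*% mu_r0 - P0 %*% mu0
  mur <- drop(Sr %*% hr)
  ld <- function(M) determinant(M, logarithm = TRUE)$modulus[1]
  dF <- 0.5 * (ld(P) + ld(Pr0) - ld(P0) - ld(Pr)) +
    0.5 * (drop(t(mur) %*% Pr %*% mur) -
           (drop(t(mu) %*% P %*% mu) +
            drop(t(mu_r0) %*% Pr0 %*% mu_r0) -
            drop(t(mu0) %*% P0 %*% mu0)))
  list(dF = dF, mean = mur, cov = Sr)
}

# Second-level Gaussian model: given subject means (p x n), subject
# covariances (list), design X (n x 2), between-subject covariance G
# (p x p) and prior (b0, Vb0) on the stacked effects, return posterior
# and log evidence.
.peb_gauss <- function(Th, Slist, X, G, Vb0, b0 = NULL) {
  p <- nrow(Th); n <- ncol(Th); q <- ncol(X)
  if (is.null(b0)) b0 <- numeric(p * q)
  improper <- any(is.infinite(diag(Vb0)))
  Pb0 <- if (improper) matrix(0, p * q, p * q) else solve(Vb0)
  Pb <- Pb0
  h <- Pb0 %*% b0
  quad <- 0
  logdet_sum <- 0
  for (i in seq_len(n)) {
    Si <- Slist[[i]] + G
    Pi <- solve(Si)
    xi <- X[i, ]
    Pb <- Pb + kronecker(tcrossprod(xi), Pi)
    h <- h + kronecker(xi, Pi %*% Th[, i])
    quad <- quad + drop(t(Th[, i]) %*% Pi %*% Th[, i])
    logdet_sum <- logdet_sum + determinant(Si, TRUE)$modulus[1]
  }
  Pb <- (Pb + t(Pb)) / 2
  Sb <- solve(Pb)
  m <- drop(Sb %*% h)
  ld <- function(M) determinant(M, logarithm = TRUE)$modulus[1]
  logZ <- if (improper) NA_real_ else
    -0.5 * n * p * log(2 * pi) - 0.5 * logdet_sum -
    0.5 * ld(Vb0) - 0.5 * ld(Pb) -
    0.5 * (quad + drop(t(b0) %*% Pb0 %*% b0) - drop(t(m) %*% Pb %*% m))
  list(mean = m, cov = Sb, logZ = logZ)
}

#' Parametric empirical Bayes over subject posteriors
#'
#' Hierarchical Bayesian linear model in which the dependent variables
#' are the subjects' (selected) DCM parameters: `theta_i = X_i beta +
#' eps_i`, with each subject's first-level posterior covariance carrying
#' its uncertainty into the group level, and isotropic between-subject
#' covariance `exp(-gamma) I` whose log precision `gamma` is optimized
#' by the second-level free energy (under a weak `N(0, 16)` prior). The
#' group effects get zero-mean Gaussian priors of variance
#' `beta_prior_var` (use `Inf` for flat priors, in which case the
#' posterior mean is the generalized least-squares solution).
#'
#' @param posteriors list of `dcm` fits or `dcm_posterior` objects
#'   sharing a parameter index map.
#' @param design subjects x 2 design matrix from [build_design()], or a
#'   character vector of group labels.
#' @param selection regular expression selecting parameters by name
#'   (e.g. `"^A:"` for first-block strengths, `"^B:"` for
#'   block-to-block modulations).
#' @param beta_prior_var prior variance of each group effect
#'   (default 1/16).
#' @param gamma fix the between-subject log precision at this value
#'   instead of optimizing it.
#' @return object of class `peb`: effect posterior (`mean`: p x 2
#'   matrix, `cov`: 2p x 2p), `pp` posterior probabilities (NA until
#'   [peb_search()]), `free_energy`, `gamma`, ingredients for reduction.
#' @export
peb <- function(posteriors, design, selection = "^A:",
                beta_prior_var = 1 / 16, gamma = NULL) {
  if (is.character(design)) design <- build_design(design)
  n <- length(posteriors)
  if (nrow(design) != n)
    stop("design rows must match number of posteriors")
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient design")
  nm0 <- names(posteriors[[1]]$mean)
  for (po in posteriors)
    if (!identical(names(po$mean), nm0))
      stop("posteriors do not share a parameter index map")
  keep <- grep(selection, nm0, value = TRUE)
  if (length(keep) == 0L) stop("selection matches no parameters")
  p <- length(keep)
  Th <- vapply(posteriors, function(po) po$mean[keep], numeric(p))
  Th <- matrix(Th, nrow = p,
               dimnames = list(keep, NULL))
  Slist <- lapply(posteriors, function(po) {
    S <- po$cov[keep, keep, drop = FALSE]
    (S + t(S)) / 2
  })
  q <- ncol(design)
  enames <- as.vector(outer(keep, colnames(design), paste, sep = "|"))
  Vb0 <- diag(rep(beta_prior_var, p * q), p * q)
  dimnames(Vb0) <- list(enames, enames)

  fit_at <- function(g) {
    G <- diag(exp(-g), p)
    .peb_gauss(Th, Slist, design, G, Vb0)
  }
  obj <- function(g) fit_at(g)$logZ - 0.5 * g^2 / 16
  if (is.infinite(beta_prior_var) && is.null(gamma))
    stop("flat effect priors require a fixed gamma")
  if (is.null(gamma)) {
    opt <- stats::optimize(obj, interval = c(-10, 15), maximum = TRUE)
    gamma <- opt$maximum
  }
  fit <- fit_at(gamma)
  m <- matrix(fit$mean, p, q, dimnames = list(keep, colnames(design)))
  dimnames(fit$cov) <- list(enames, enames)
  structure(list(
    mean = m, cov = fit$cov, free_energy = fit$logZ, gamma = gamma,
    pp = matrix(NA_real_, p, q, dimnames = dimnames(m)),
    retained = matrix(TRUE, p, q, dimnames = dimnames(m)),
    prior_mean = stats::setNames(numeric(p * q), enames),
    prior_cov = Vb0, design = design, parameters = keep,
    selection = selection, n_subjects = n, reduced = FALSE),
    class = "peb")
}

# Evidence/posterior of the model whose prior variances are shrunk to
# ~zero on the effects indicated by `off` (logical over stacked
# effects), relative to the full fitted posterior.
.peb_reduce <- function(x, off, off_var = 1e-8) {
  V_r0 <- x$prior_cov
  diag(V_r0)[off] <- off_var
  .gauss_bmr(as.vector(x$mean), x$cov, x$prior_mean, x$prior_cov,
             x$prior_mean, V_r0)
}

#' Bayesian model reduction of a PEB result
#'
#' Computes, without refitting, the log-evidence change and posterior of
#' the model in which the named effects have (numerically)
#' point-mass-at-zero priors, using the Gaussian posterior/prior algebra
#' of Bayesian model reduction. Exact for the linear second-level model.
#'
#' @param x a fitted `peb`.
#' @param zeroed character vector of effect names (`"<param>|b0"` /
#'   `"<param>|b1"`) or a logical/integer index over stacked effects.
#' @param off_var prior variance standing in for the point mass.
#' @return list with `dF` (reduced minus full free energy), `mean`,
#'   `cov` of the reduced posterior.
#' @export
bmr_evidence <- function(x, zeroed, off_var = 1e-8) {
  en <- colnames(x$prior_cov)
  off <- rep(FALSE, length(en))
  if (is.character(zeroed)) {
    bad <- setdiff(zeroed, en)
    if (length(bad)) stop("unknown effects: ", paste(bad, collapse = ", "))
    off[match(zeroed, en)] <- TRUE
  } else off[zeroed] <- TRUE
  if (!any(off))
    return(list(dF = 0, mean = as.vector(x$mean), cov = x$cov))
  .peb_reduce(x, off, off_var)
}

#' Greedy pruning search over PEB effects
#'
#' Iteratively removes (via Bayesian model reduction) the effect whose
#' removal costs the least evidence, as long as removal does not lower
#' the evidence, re-evaluating every remaining effect each round (at
#' most `max_eval` evidence evaluations). The returned posterior is the
#' Bayesian model average over the models examined in the final round,
#' weighted by their evidence. Per-effect posterior probabilities of
#' being nonzero are computed by evidence comparison of the model with
#' the effect on versus off, holding all other effects at their final
#' state (uniform model priors).
#'
#' @param x a fitted `peb`.
#' @param max_eval cap on reduction evaluations (default 256).
#' @return the reduced `peb`: `retained`, `pp`, BMA `mean`/`cov`,
#'   `free_energy` of the selected reduced model.
#' @export
peb_search <- function(x, max_eval = 256L) {
  en <- colnames(x$prior_cov)
  ne <- length(en)
  off <- rep(FALSE, ne)
  F_cur <- 0  # free energy relative to the full model
  evals <- 0L
  last_round <- list()
  repeat {
    cand_idx <- which(!off)
    if (length(cand_idx) == 0L) break
    dFs <- rep(NA_real_, length(cand_idx))
    round_models <- vector("list", length(cand_idx))
    for (j in seq_along(cand_idx)) {
      if (evals >= max_eval) break
      off_try <- off
      off_try[cand_idx[j]] <- TRUE
      red <- .peb_reduce(x, off_try)
      evals <- evals + 1L
      dFs[j] <- red$dF - F_cur
      round_models[[j]] <- list(off = off_try, F = red$dF,
                                mean = red$mean, cov = red$cov)
    }
    ok <- !is.na(dFs)
    last_round <- c(list(list(off = off, F = F_cur)), round_models[ok])
    if (!any(ok)) break
    best <- cand_idx[ok][which.max(dFs[ok])]
    if (max(dFs[ok]) >= 0) {
      off[best] <- TRUE
      F_cur <- F_cur + max(dFs[ok])
      if (evals >= max_eval) break
    } else break
  }
  # Bayesian model average over the final search generation
  Fs <- vapply(last_round, function(mdl) mdl$F, numeric(1))
  w <- exp(Fs - max(Fs)); w <- w / sum(w)
  get_post <- function(mdl) {
    if (is.null(mdl$mean)) {
      red <- .peb_reduce(x, mdl$off)
      list(mean = red$mean, cov = red$cov)
    } else mdl[c("mean", "cov")]
  }
  posts <- lapply(last_round, get_post)
  mbar <- Reduce(`+`, Map(function(po, wi) wi * po$mean, posts, w))
  Vbar <- Reduce(`+`, Map(function(po, wi)
    wi * (po$cov + tcrossprod(po$mean)), posts, w)) - tcrossprod(mbar)
  # per-effect on/off evidence comparison at the final state
  pp <- numeric(ne)
  for (k in seq_len(ne)) {
    off_on <- off; off_on[k] <- FALSE
    off_off <- off; off_off[k] <- TRUE
    F_on <- if (any(off_on)) .peb_reduce(x, off_on)$dF else 0
    F_off <- .peb_reduce(x, off_off)$dF
    pp[k] <- 1 / (1 + exp(F_off - F_on))
  }
  p <- length(x$parameters); q <- ncol(x$design)
  out <- x
  out$mean <- matrix(mbar, p, q, dimnames = dimnames(x$mean))
  out$cov <- Vbar
  dimnames(out$cov) <- dimnames(x$cov)
  out$retained <- matrix(!off, p, q, dimnames = dimnames(x$retained))
  out$pp <- matrix(pp, p, q, dimnames = dimnames(x$pp))
  out$free_energy <- x$free_energy + F_cur
  out$reduced <- TRUE
  out
}

#' @export
print.peb <- function(x, ...) {
  cat("PEB over", x$n_subjects, "subjects,", length(x$parameters),
      "parameters (selection", x$selection, ")\n")
  cat(sprintf("  free energy %.2f; between-subject log precision %.2f\n",
              x$free_energy, x$gamma))
  if (x$reduced)
    cat("  after reduction:", sum(x$retained), "of",
        length(x$retained), "effects retained\n")
  invisible(x)
}

#' @export
coef.peb <- function(object, ...) object$mean

#' @export
vcov.peb <- function(object, ...) object$cov

#' Tabulate PEB effects
#'
#' @param object a `peb` (reduced or not).
#' @param pp_threshold posterior-probability threshold used to flag
#'   effects (the study rule is 0.99).
#' @param ... unused.
#' @return `data.frame` with one row per (parameter, covariate):
#'   posterior mean, posterior SD, posterior probability, retained and
#'   above-threshold flags.
#' @export
summary.peb <- function(object, pp_threshold = 0.99, ...) {
  p <- length(object$parameters); q <- ncol(object$design)
  sds <- matrix(sqrt(diag(object$cov)), p, q)
  df <- data.frame(
    parameter = rep(object$parameters, q),
    covariate = rep(colnames(object$design), each = p),
    mean = as.vector(object$mean),
    sd = as.vector(sds),
    pp = as.vector(object$pp),
    retained = as.vector(object$retained))
  df$significant <- !is.na(df$pp) & df$pp > pp_threshold
  class(df) <- c("summary.peb", "data.frame")
  df
}

#' @export
plot.peb <- function(x, covariate = "b1", ...) {
  m <- x$mean[, covariate]
  s <- sqrt(diag(x$cov))[paste0(x$parameters, "|", covariate)]
  o <- order(m)
  mid <- graphics::barplot(m[o], horiz = TRUE, las = 1,
                           names.arg = x$parameters[o], cex.names = 0.6,
                           xlab = paste("effect", covariate), ...)
  graphics::segments(m[o] - 1.64 * s[o], mid, m[o] + 1.64 * s[o], mid)
  invisible(x)
}

#' Write a PEB summary table
#'
#' Tab-separated table (one row per effect) plus a JSON machine summary.
#'
#' @param x a `peb`.
#' @param path TSV path (the JSON sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_peb <- function(x, path) {
  df <- summary(x)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  doc <- list(schema = "lep-peb/1", selection = x$selection,
              n_subjects = x$n_subjects,
              free_energy = x$free_energy, gamma = x$gamma,
              effects = df)
  jsonlite::write_json(doc, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
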