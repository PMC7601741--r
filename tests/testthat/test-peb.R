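test_that("the design matrix encodes commonality and group difference", {
  g <- rep(c("control", "migraine"), c(20, 23))
  X <- build_design(g)
  expect_equal(dim(X), c(43L, 2L))
  expect_equal(colSums(X), c(b0 = 43, b1 = 23))
  expect_true(all(X[, 1] == 1))
  expect_true(all(X[, 2] %in% c(0, 1)))
  expect_true(all(build_design(rep("control", 5))[, 2] == 0))
  # permuting labels permutes rows identically
  set.seed(1)
  o <- sample(length(g))
  expect_identical(build_design(g[o]), X[o, ])
  expect_error(build_design(c("control", "patient")), "unknown group")
})

test_that("two identical groups give a zero group-difference posterior", {
  pn <- paste0("A:e", 1:4)
  po <- synth_posteriors(6, 6, pn, beta1 = NULL, between_sd = 0.1,
                         seed = 2)
  # make the two groups exactly identical subject-for-subject
  po$posteriors[7:12] <- po$posteriors[1:6]
  res <- peb(po$posteriors, po$groups, selection = "^A:",
             beta_prior_var = Inf, gamma = 0)
  expect_lt(max(abs(res$mean[, "b1"])), 1e-10)
  # with proper shrinkage priors the difference is still negligible
  res2 <- peb(po$posteriors, po$groups, selection = "^A:")
  expect_lt(max(abs(res2$mean[, "b1"])), 0.02)
})

test_that("with identical spherical covariances the flat-prior mean is OLS", {
  pn <- paste0("A:e", 1:3)
  po <- synth_posteriors(5, 7, pn,
                         beta1 = c("A:e1" = 0.5, "A:e2" = 0, "A:e3" = -0.3),
                         seed = 9)
  X <- build_design(po$groups)
  res <- peb(po$posteriors, X, selection = "^A:",
             beta_prior_var = Inf, gamma = 0)
  Th <- vapply(po$posteriors, function(p) p$mean, numeric(3))
  ols <- t(solve(crossprod(X), crossprod(X, t(Th))))
  expect_equal(unname(res$mean), unname(ols), tolerance = 1e-8)
})

test_that("second-level evidence and posterior match the stacked-marginal oracle", {
  pn <- paste0("A:e", 1:3)
  po <- synth_posteriors(3, 3, pn, beta1 = c("A:e1" = 0.4, "A:e2" = 0,
                                             "A:e3" = 0),
                         seed = 4)
  res <- peb(po$posteriors, po$groups, selection = "^A:", gamma = 2)
  X <- build_design(po$groups)
  Th <- vapply(po$posteriors, function(p) p$mean, numeric(3))
  Slist <- lapply(po$posteriors, function(p) p$cov)
  ora <- oracle_peb(Th, Slist, X, diag(exp(-2), 3),
                    diag(1 / 16, 6))
  expect_equal(as.vector(res$mean), ora$mean, tolerance = 1e-8)
  expect_equal(unname(res$cov), unname(ora$cov), tolerance = 1e-8)
  expect_equal(res$free_energy, ora$logZ, tolerance = 1e-8)
})

test_that("a cohort planted with the insular effect recovers it in the credible interval", {
  pn <- paste0("A:", edge_names(build_study_network()))
  beta1 <- stats::setNames(numeric(length(pn)), pn)
  beta1["A:THAL->lIns"] <- 0.47
  po <- synth_posteriors(20, 23, pn, beta1 = beta1, first_sd = 0.05,
                         between_sd = 0.1, seed = 73)
  res <- peb(po$posteriors, po$groups, selection = "^A:")
  est <- res$mean["A:THAL->lIns", "b1"]
  sd_ <- sqrt(diag(res$cov))[["A:THAL->lIns|b1"]]
  expect_gt(est, 0)
  expect_lt(abs(est - 0.47), 1.96 * sd_)
  # the estimator tracks the realised group difference of this cohort
  # draw closely (shrinkage towards zero is bounded by the prior scale)
  Th <- vapply(po$posteriors, function(p) p$mean["A:THAL->lIns"],
               numeric(1))
  realised <- mean(Th[po$groups == "migraine"]) -
    mean(Th[po$groups == "control"])
  expect_lt(abs(est - realised), 0.05)
})

test_that("Bayesian model reduction agrees with explicit shrunk-prior refits", {
  pn <- paste0("A:e", 1:3)
  po <- synth_posteriors(4, 4, pn, beta1 = c("A:e1" = 0.6, "A:e2" = 0,
                                             "A:e3" = 0),
                         seed = 12)
  res <- peb(po$posteriors, po$groups, selection = "^A:", gamma = 3)
  # empty reduction changes nothing
  r0 <- bmr_evidence(res, character(0))
  expect_equal(r0$dF, 0)
  expect_equal(r0$mean, as.vector(res$mean))
  X <- build_design(po$groups)
  Th <- vapply(po$posteriors, function(p) p$mean, numeric(3))
  Slist <- lapply(po$posteriors, function(p) p$cov)
  for (zero in list("A:e2|b1", c("A:e3|b0", "A:e3|b1"),
                    c("A:e1|b1", "A:e2|b0"))) {
    red <- bmr_evidence(res, zero)
    V_r <- diag(1 / 16, 6)
    dimnames(V_r) <- dimnames(res$prior_cov)
    diag(V_r)[zero] <- 1e-8
    refit <- oracle_peb(Th, Slist, X, diag(exp(-3), 3), V_r)
    expect_lt(abs(red$dF - (refit$logZ - res$free_energy)), 0.01)
    expect_equal(red$mean, refit$mean, tolerance = 1e-6)
  }
  # removing a truly null effect cannot lower the evidence much; here it
  # increases it (the reduced model is simpler and fits as well)
  expect_gt(bmr_evidence(res, "A:e2|b1")$dF, 0)
})

test_that("greedy search prunes null effects and keeps planted ones", {
  pn <- paste0("A:e", 1:6)
  # all-null cohort: nothing survives at the 0.99 rule
  po0 <- synth_posteriors(20, 20, pn, beta1 = NULL, seed = 5)
  res0 <- peb_search(peb(po0$posteriors, po0$groups, selection = "^A:"))
  expect_true(all(res0$pp[, "b1"] < 0.99))
  expect_true(all(!res0$retained[, "b1"]))
  # one large planted effect is retained with probability > 0.99
  beta1 <- stats::setNames(numeric(6), pn)
  beta1["A:e3"] <- 0.6
  po1 <- synth_posteriors(20, 20, pn, beta1 = beta1, seed = 6)
  res1 <- peb_search(peb(po1$posteriors, po1$groups, selection = "^A:"))
  expect_gt(res1$pp["A:e3", "b1"], 0.99)
  expect_true(res1$retained["A:e3", "b1"])
  expect_gt(res1$mean["A:e3", "b1"], 0.3)
  # deterministic: same inputs, same result
  res1b <- peb_search(peb(po1$posteriors, po1$groups, selection = "^A:"))
  expect_identical(res1$mean, res1b$mean)
  expect_identical(res1$pp, res1b$pp)
})

test_that("inflating first-level uncertainty never raises posterior probabilities", {
  pn <- paste0("A:e", 1:4)
  beta1 <- c("A:e1" = 0.5, "A:e2" = 0.25, "A:e3" = 0, "A:e4" = -0.4)
  po <- synth_posteriors(12, 12, pn, beta1 = beta1, seed = 8)
  pp_at <- function(scale) {
    posts <- lapply(po$posteriors, function(p) {
      p$cov <- p$cov * scale
      p
    })
    res <- peb_search(peb(posts, po$groups, selection = "^A:",
                          gamma = log(1 / 0.1^2)))
    res$pp[, "b1"]
  }
  # monotonicity is asserted for the genuinely nonzero effects (a null
  # effect's probability drifts towards the uninformative 1/2 from
  # below as information vanishes)
  planted <- names(beta1)[beta1 != 0]
  pp1 <- pp_at(1)
  for (sc in c(4, 16, 64)) {
    ppc <- pp_at(sc)
    expect_true(all(ppc[planted] <= pp1[planted] + 1e-6))
    pp1 <- ppc
  }
})

test_that("type-I error at the 0.99 rule stays within bounds under the null", {
  pn <- paste0("A:e", 1:5)
  crossings <- 0L
  total <- 0L
  for (rep in 1:20) {
    po <- synth_posteriors(20, 20, pn, beta1 = NULL, seed = 900 + rep)
    res <- peb_search(peb(po$posteriors, po$groups, selection = "^A:"))
    crossings <- crossings + sum(res$pp[, "b1"] > 0.99)
    total <- total + length(pn)
  }
  expect_lte(crossings / total, 0.05)
})

test_that("PEB results print, tabulate and export", {
  pn <- paste0("B:e", 1:3)
  po <- synth_posteriors(6, 6, pn, beta1 = c("B:e1" = 0.5, "B:e2" = 0,
                                             "B:e3" = 0),
                         seed = 3)
  res <- peb_search(peb(po$posteriors, po$groups, selection = "^B:"))
  expect_output(print(res), "PEB over 12 subjects")
  tab <- summary(res)
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("parameter", "covariate", "mean", "sd", "pp",
                    "retained", "significant") %in% names(tab)))
  expect_true(all(tab$pp >= 0 & tab$pp <= 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peb(res, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 6L)
  expect_true(file.exists(paste0(path, ".json")))
  # error paths
  expect_error(peb(po$posteriors, po$groups, selection = "^Z:"),
               "matches no")
  expect_error(peb(po$posteriors[1:5], po$groups), "design rows")
})
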