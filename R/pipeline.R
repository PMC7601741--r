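# End-to-end study workflow: fit every subject, run both PEB analyses
# (baseline strengths and block modulations), compute scalp-level
# habituation statistics, and consolidate a report.

#' Run the full study pipeline on a cohort
#'
#' For every subject: fit the DCM to the block-1/block-3 pair. Across
#' subjects: run parametric empirical Bayes twice -- once on the
#' baseline connection strengths (`A:` parameters) and once on the
#' block-to-block modulations (`B:` parameters) -- each followed by
#' Bayesian model reduction with greedy search; and compute the N2P2
#' habituation table with the between-group permutation test. A
#' subject whose fit fails is reported and excluded, not fatal. The
#' report is deterministic given the inputs and `seed`.
#'
#' @param cohort a `synthetic_study`, the result of [read_cohort()], or
#'   a cohort directory path.
#' @param net network (default the study network).
#' @param leadfield a `lead_field`; defaults to the study's own lead
#'   field for a `synthetic_study` (required for on-disk cohorts).
#' @param priors first-level priors (default [dcm_priors()] on `net`).
#' @param settings inversion settings passed to [dcm_fit()].
#' @param stim stimulus specification for the forward model.
#' @param peb_settings list with optional `beta_prior_var`, `max_eval`.
#' @param habituation_settings list with optional `channel`,
#'   `n2_window`, `p2_window`, `n_perm`, `alternative`.
#' @param seed integer seed (drives the permutation test).
#' @param verbose print per-stage progress?
#' @return object of class `study_report`: per-subject fit diagnostics,
#'   `peb_strengths` and `peb_modulations` (reduced `peb` objects with
#'   summary tables), `habituation` result, and -- when ground truth is
#'   available -- a recovery summary comparing recovered group effects
#'   with the planted ones.
#' @export
run_study <- function(cohort, net = build_study_network(),
                      leadfield = NULL, priors = NULL,
                      settings = list(), stim = stimulus_spec(),
                      peb_settings = list(),
                      habituation_settings = list(),
                      seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (inherits(cohort, "synthetic_study") && is.null(leadfield))
    leadfield <- cohort$leadfield
  if (is.null(leadfield))
    stop("a lead field is required for cohorts without one")
  if (is.null(priors)) priors <- dcm_priors(net)
  records <- cohort$records
  groups <- cohort$groups
  subj <- vapply(records, function(r) r$subject, character(1))
  cond <- vapply(records, function(r) r$condition, character(1))
  subjects <- unique(subj)

  fits <- list()
  diagnostics <- list()
  for (s in subjects) {
    b1 <- records[[which(subj == s & cond == "block1")[1]]]
    b3 <- records[[which(subj == s & cond == "block3")[1]]]
    res <- tryCatch(
      dcm_fit(b1, b3, net, leadfield, priors, stim, settings),
      error = function(e) e)
    if (inherits(res, "error")) {
      say("subject %s: fit FAILED (%s)", s, conditionMessage(res))
      diagnostics[[s]] <- data.frame(
        subject = s, ok = FALSE, free_energy = NA, iterations = NA,
        ve_block1 = NA, ve_block3 = NA,
        error = conditionMessage(res))
    } else {
      fits[[s]] <- res
      diagnostics[[s]] <- data.frame(
        subject = s, ok = TRUE, free_energy = res$free_energy,
        iterations = res$iterations,
        ve_block1 = res$variance_explained[1],
        ve_block3 = res$variance_explained[2], error = "")
      say("subject %s: F = %.1f, VE = %.2f/%.2f (%d iter)", s,
          res$free_energy, res$variance_explained[1],
          res$variance_explained[2], res$iterations)
    }
  }
  diagnostics <- do.call(rbind, diagnostics)
  rownames(diagnostics) <- NULL
  if (length(fits) < 2L) stop("fewer than two successful fits")

  glab <- groups[names(fits)]
  ps <- list(beta_prior_var = 1 / 16, max_eval = 256L)
  ps[names(peb_settings)] <- peb_settings
  say("PEB on baseline strengths (A) ...")
  peb_a_full <- peb(fits, glab, selection = "^A:",
                    beta_prior_var = ps$beta_prior_var)
  peb_a <- peb_search(peb_a_full, max_eval = ps$max_eval)
  say("PEB on modulations (B) ...")
  peb_b_full <- peb(fits, glab, selection = "^B:",
                    beta_prior_var = ps$beta_prior_var)
  peb_b <- peb_search(peb_b_full, max_eval = ps$max_eval)

  hs <- list(channel = NULL, n2_window = c(0.130, 0.300),
             p2_window = c(0.280, 0.500), n_perm = 5000,
             alternative = "two.sided")
  hs[names(habituation_settings)] <- habituation_settings
  hab <- habituation_test(records, channel = hs$channel,
                          n2_window = hs$n2_window,
                          p2_window = hs$p2_window, n_perm = hs$n_perm,
                          alternative = hs$alternative, seed = seed)

  recovery <- NULL
  if (inherits(cohort, "synthetic_study")) {
    cfg <- cohort$config
    planted_a <- cfg$a_effect
    planted_b <- cfg$b_migraine - cfg$b_control
    # recovery is judged on the full (unreduced) group estimates: the
    # reduction step deliberately zeroes sub-threshold effects
    rec_a <- peb_a_full$mean[paste0("A:", names(planted_a)), "b1"]
    em <- edge_names(cfg$net, modulable_only = TRUE)
    rec_b <- peb_b_full$mean[paste0("B:", em), "b1"]
    recovery <- rbind(
      data.frame(block = "A", edge = names(planted_a),
                 planted = unname(planted_a), recovered = unname(rec_a)),
      data.frame(block = "B", edge = em,
                 planted = unname(planted_b[em]),
                 recovered = unname(rec_b)))
    recovery$sign_ok <- sign(recovery$planted) == sign(recovery$recovered) |
      recovery$planted == 0
    rownames(recovery) <- NULL
  }
  say("done in %.1f s", proc.time()[3] - t0)
  structure(list(diagnostics = diagnostics, fits = fits,
                 peb_strengths = peb_a, peb_modulations = peb_b,
                 habituation = hab, recovery = recovery,
                 n_subjects = length(subjects),
                 elapsed_s = proc.time()[3] - t0),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("LEP habituation study report\n")
  cat("  subjects:", x$n_subjects, "(", sum(x$diagnostics$ok),
      "fitted )\n")
  cat(sprintf("  mean variance explained: %.2f / %.2f\n",
              mean(x$diagnostics$ve_block1, na.rm = TRUE),
              mean(x$diagnostics$ve_block3, na.rm = TRUE)))
  sa <- summary(x$peb_strengths)
  sb <- summary(x$peb_modulations)
  cat("  PEB strengths: ", sum(sa$significant & sa$covariate == "b1"),
      "group effects with pp > 0.99\n")
  cat("  PEB modulations:", sum(sb$significant & sb$covariate == "b1"),
      "group effects with pp > 0.99\n")
  print(x$habituation)
  if (!is.null(x$recovery))
    cat("  recovery: ",
        sum(x$recovery$sign_ok[x$recovery$planted != 0]), "/",
        sum(x$recovery$planted != 0),
        "nonzero planted effects with matching sign\n")
  invisible(x)
}

#' Write a study report
#'
#' JSON payload (diagnostics, both PEB tables, habituation table, group
#' test, recovery table) plus a human-readable text summary. Wall-clock
#' fields are excluded from the JSON so reruns are byte-identical.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- list(schema = "lep-report/1",
              diagnostics = report$diagnostics,
              peb_strengths = summary(report$peb_strengths),
              peb_modulations = summary(report$peb_modulations),
              habituation = list(
                table = report$habituation$table,
                channel = report$habituation$channel,
                t = report$habituation$test$t,
                p = report$habituation$test$p),
              recovery = report$recovery)
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  write_peb(report$peb_strengths, file.path(dir, "peb_strengths.tsv"))
  write_peb(report$peb_modulations,
            file.path(dir, "peb_modulations.tsv"))
  invisible(dir)
}
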