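# Seeded synthetic two-group cohorts with the statistical structure of
# the study: group differences in baseline connectivity (A) and in
# block-1 -> block-3 modulations (B), propagated through the neural and
# observation models.

#' Default planted group effects on baseline connectivity
#'
#' Named vector of migraine-minus-control differences in baseline
#' log-strength per edge (the group-difference effects reported for the
#' first block): positive values mean the connection is initially
#' stronger in migraine.
#'
#' @return named numeric vector (a subset of the study network's edges;
#'   unnamed edges have zero group difference).
#' @export
default_a_effects <- function() {
  c("THAL->rIns" = 0.33, "THAL->lIns" = 0.47, "THAL->lS1" = 0.22,
    "rS2->rIns" = 0.72, "lS2->lIns" = 0.40,
    "rIns->ACC" = -0.80, "lIns->ACC" = -0.18, "lS1->lS2" = -0.31,
    "lS2->lS1" = 0.29, "lS1->THAL" = 0.45,
    "rIns->THAL" = -0.44, "lIns->THAL" = -0.43,
    "lIns->rIns" = 0.37, "rS2->lS2" = -0.61)
}

#' Default planted block-to-block modulations per group
#'
#' Mean log-modulations (block 1 to block 3) per edge for each group:
#' the control means are the reported commonality effects and the
#' migraine means are commonality plus group difference. Negative values
#' are habituation (connection weakens over blocks).
#'
#' @return list with named vectors `control` and `migraine`.
#' @export
default_b_effects <- function() {
  list(
    control = c("THAL->rS2" = -0.13, "THAL->lS2" = -0.37,
                "THAL->lS1" = -0.27, "rIns->THAL" = 0.19,
                "lS2->THAL" = 0.00, "lS2->lIns" = 0.00,
                "lIns->rIns" = 0.14, "rIns->lIns" = -0.34),
    migraine = c("THAL->rS2" = 0.14, "THAL->lS2" = -0.05,
                 "THAL->lS1" = 0.02, "rIns->THAL" = -0.35,
                 "lS2->THAL" = 0.28, "lS2->lIns" = -0.28,
                 "lIns->rIns" = 0.44, "rIns->lIns" = 0.19))
}

#' Cohort generation configuration
#'
#' Defaults mirror the study conditions: 20 controls and 23 migraine
#' patients, baseline log-strengths centred at 0 with the reported
#' first-block group differences planted, group-specific block
#' modulations, Gaussian between-subject spread of 0.1 on all log
#' parameters, and additive channel noise.
#'
#' @param n_control,n_migraine group sizes.
#' @param a_base named vector of baseline log-strengths (default all 0).
#' @param a_effect named vector of migraine-minus-control baseline
#'   offsets (default [default_a_effects()]).
#' @param b_control,b_migraine named vectors of group mean modulations
#'   (default [default_b_effects()]).
#' @param between_subject_sd SD of subject-level Gaussian variation on
#'   every log parameter (unitless).
#' @param noise_sd channel noise SD (µV).
#' @param n_channels montage size.
#' @param rate sampling rate (Hz).
#' @param window epoch window (s).
#' @param stim stimulus specification.
#' @param net network (default the study network).
#' @param seed integer seed; the full cohort regenerates bit-identically
#'   from (config, seed).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 20, n_migraine = 23,
                          a_base = NULL,
                          a_effect = default_a_effects(),
                          b_control = default_b_effects()$control,
                          b_migraine = default_b_effects()$migraine,
                          between_subject_sd = 0.1,
                          noise_sd = 0.25,
                          n_channels = 16,
                          rate = 125,
                          window = c(0, 0.8),
                          stim = stimulus_spec(),
                          net = build_study_network(),
                          seed = 1L) {
  stopifnot(n_control >= 1, n_migraine >= 1, between_subject_sd >= 0,
            noise_sd >= 0, n_channels >= 1)
  en <- edge_names(net)
  chk <- function(v, what) {
    if (is.null(v)) return(stats::setNames(numeric(length(en)), en))
    bad <- setdiff(names(v), en)
    if (length(bad)) stop(what, " keys not in network: ",
                          paste(bad, collapse = ", "))
    out <- stats::setNames(numeric(length(en)), en)
    out[names(v)] <- v
    out
  }
  structure(list(n_control = n_control, n_migraine = n_migraine,
                 a_base = chk(a_base, "a_base"),
                 a_effect = chk(a_effect, "a_effect"),
                 b_control = chk(b_control, "b_control"),
                 b_migraine = chk(b_migraine, "b_migraine"),
                 between_subject_sd = between_subject_sd,
                 noise_sd = noise_sd, n_channels = n_channels,
                 rate = rate, window = as.numeric(window), stim = stim,
                 net = net, seed = as.integer(seed)),
            class = "cohort_config")
}

#' The 61-channel study-geometry preset
#'
#' Convenience configuration whose averages have the import geometry of
#' the original recordings: 61 channels and 206 samples spanning
#' 0-800 ms (the implied sampling rate, 206 samples over 0.8 s, is a
#' fixture constant, not a recorded fact).
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
paper_geometry_config <- function(...) {
  cohort_config(n_channels = 61, rate = 205 / 0.8, ...)
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject ground-truth parameters -- `a_log = a_base +
#' group * a_effect + N(0, between_subject_sd)` per edge, `b_log` from
#' the group's modulation means likewise -- and simulates each subject's
#' block-1 (baseline) and block-3 (modulated) average evoked records
#' through the neural and observation models with additive channel
#' noise. The lead field is synthesized once per cohort from the seed.
#'
#' @param config a `cohort_config`.
#' @return object of class `synthetic_study`: list with `records`
#'   (flat list of `evoked_record`s, two per subject), `truth` (list of
#'   per-subject `neural_params`), `groups` (named character vector),
#'   `leadfield`, `config`.
#' @export
generate_cohort <- function(config) {
  net <- config$net
  en <- edge_names(net)
  em <- edge_names(net, modulable_only = TRUE)
  n <- config$n_control + config$n_migraine
  groups <- rep(c("control", "migraine"),
                c(config$n_control, config$n_migraine))
  ids <- sprintf("sub%02d", seq_len(n))
  names(groups) <- ids
  lf <- synthesize_leadfield(config$n_channels, net,
                             seed = config$seed + 1000L)
  times <- seq(config$window[1], config$window[2],
               length.out = round(diff(config$window) * config$rate) + 1L)
  if (config$n_channels == 61 && abs(config$rate - 205 / 0.8) < 1e-6)
    times <- seq(config$window[1], config$window[2], length.out = 206)

  study <- with_seed(config$seed, {
    records <- list()
    truth <- list()
    for (i in seq_len(n)) {
      mig <- groups[i] == "migraine"
      a <- config$a_base + (if (mig) config$a_effect else 0) +
        stats::rnorm(length(en), 0, config$between_subject_sd)
      names(a) <- en
      bmean <- if (mig) config$b_migraine else config$b_control
      b <- bmean[em] + stats::rnorm(length(em), 0,
                                    config$between_subject_sd)
      names(b) <- em
      params <- neural_params(net, a_log = a, b_log = b)
      truth[[ids[i]]] <- params
      seeds <- sample.int(.Machine$integer.max - 1L, 2)
      for (blk in c("block1", "block3")) {
        cond <- if (blk == "block1") "baseline" else "modulated"
        traj <- simulate_sources(net, params, config$stim, cond, times)
        rec <- project_sources(traj, lf, subject = ids[i],
                               group = groups[[i]], condition = blk)
        rec <- add_noise(rec, config$noise_sd,
                         seed = seeds[1 + (blk == "block3")])
        records[[paste(ids[i], blk, sep = ".")]] <- rec
      }
    }
    list(records = records, truth = truth)
  })
  structure(list(records = study$records, truth = study$truth,
                 groups = groups, leadfield = lf, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic LEP cohort:", sum(x$groups == "control"), "controls +",
      sum(x$groups == "migraine"), "migraine;",
      x$config$n_channels, "channels; seed", x$config$seed, "\n")
  invisible(x)
}

#' Ground-truth parameter table
#'
#' One row per (subject, edge) with the true baseline log-strength and
#' log-modulation and the group label; used by recovery checks.
#'
#' @param study a `synthetic_study`.
#' @return `data.frame` with columns subject, group, edge, a_log, b_log
#'   (NA for non-modulable edges).
#' @export
ground_truth_table <- function(study) {
  en <- edge_names(study$config$net)
  rows <- lapply(names(study$truth), function(s) {
    p <- study$truth[[s]]
    b <- rep(NA_real_, length(en))
    b[match(names(p$b_log), en)] <- p$b_log
    data.frame(subject = s, group = study$groups[[s]], edge = en,
               a_log = unname(p$a_log[en]), b_log = b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-trial records for block averaging
#'
#' Emits single-trial noisy copies of each subject's block templates
#' (blocks 1, 2 and 3; the middle block is simulated at half the
#' subject's modulation, the geometric midpoint between the baseline and
#' fully modulated conditions). Averaging the trials of a block
#' converges to that block's template as the trial noise vanishes.
#'
#' @param study a `synthetic_study`.
#' @param trials_per_block trials per block (the study design is 5,
#'   giving 15 trials).
#' @param trial_noise_sd additive noise per trial (µV).
#' @param seed integer seed.
#' @return list of `evoked_record`s, one per (subject, trial), with
#'   `condition` of the form `"block<k>/trial<j>"`.
#' @export
make_trialset <- function(study, trials_per_block = 5,
                          trial_noise_sd = 1, seed = 1L) {
  stopifnot(trials_per_block >= 1)
  cfg <- study$config
  times <- evoked_times(study$records[[1]])
  out <- list()
  trial_seed <- seed
  for (s in names(study$truth)) {
    p <- study$truth[[s]]
    half <- p
    half$b_log <- p$b_log / 2
    templates <- list(
      block1 = simulate_sources(cfg$net, p, cfg$stim, "baseline", times),
      block2 = simulate_sources(cfg$net, half, cfg$stim, "modulated",
                                times),
      block3 = simulate_sources(cfg$net, p, cfg$stim, "modulated", times))
    for (blk in names(templates)) {
      base <- project_sources(templates[[blk]], study$leadfield,
                              subject = s, group = study$groups[[s]])
      for (j in seq_len(trials_per_block)) {
        trial_seed <- trial_seed + 1L
        rec <- add_noise(base, trial_noise_sd, seed = trial_seed)
        rec$condition <- sprintf("%s/trial%d", blk, j)
        out[[sprintf("%s.%s.t%d", s, blk, j)]] <- rec
      }
    }
  }
  out
}

#' Write / read a cohort directory
#'
#' A cohort on disk is a directory with a JSON `manifest.json` (groups,
#' geometry, generation config summary), one TSV + JSON sidecar pair
#' per record, and the ground-truth table (`truth.tsv`) when available.
#'
#' @param study a `synthetic_study`.
#' @param dir directory to create.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort`
#'   returns a list with `records`, `groups` and (if present) `truth`.
#' @export
write_cohort <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(study$records)) {
    f <- paste0(nm, ".tsv")
    write_evoked(study$records[[nm]], file.path(dir, f))
    files <- c(files, f)
  }
  manifest <- list(schema = "lep-cohort/1",
                   groups = as.list(study$groups),
                   files = files,
                   n_channels = study$config$n_channels,
                   rate = study$config$rate,
                   window = study$config$window,
                   seed = study$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(study$truth))
    utils::write.table(ground_truth_table(study),
                       file.path(dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$schema, "lep-cohort/1"))
    stop("unrecognised cohort schema")
  records <- lapply(manifest$files,
                    function(f) read_evoked(file.path(dir, f)))
  names(records) <- sub("\\.tsv$", "", manifest$files)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    utils::read.table(truth_path, sep = "\t", header = TRUE) else NULL
  list(records = records, groups = unlist(manifest$groups),
       truth = truth)
}
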