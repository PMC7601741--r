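# Memoised end-to-end study run shared by the pipeline and acceptance
# tests: a reduced two-group cohort (8 + 8 subjects) generated with the
# study's default planted effects at low noise, fitted and analysed by
# the full pipeline.
.study_cache <- new.env(parent = emptyenv())

e2e_study <- function() {
  if (is.null(.study_cache$report)) {
    cfg <- cohort_config(n_control = 8, n_migraine = 8,
                         noise_sd = 0.02, between_subject_sd = 0.1,
                         seed = 1L)
    study <- generate_cohort(cfg)
    .study_cache$study <- study
    .study_cache$report <- run_study(study, seed = 7, verbose = FALSE)
  }
  list(study = .study_cache$study, report = .study_cache$report)
}
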