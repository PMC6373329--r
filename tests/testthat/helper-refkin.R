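# Shared fixtures, built once per test run.  Cohorts are memoized because the
# identifiability and agreement tests all reuse the same deterministic runs.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Exactly SRTM2-consistent cohort: every subject shares k2' = 0.0322 1/min and
# the registry's default binding levels; no noise.
ideal_cohort <- function() memo("ideal", generate_cohort(
  cohort_config(noise_alpha = 0, k2p_sd = 0, bp_jitter_sd = 0, seed = 1)))

# Noiseless cohort under the default between-subject spread.
noiseless_cohort <- function() memo("noiseless", generate_cohort(
  cohort_config(noise_alpha = 0, seed = 1)))

ideal_fits <- function() memo("ideal_fits", fit_cohort(ideal_cohort()))

# One subject's noiseless binned TACs plus continuous curves, for oracle checks.
ideal_subject <- function() memo("ideal_subject", {
  kin <- subject_kinetics()
  t_min <- seq(0, 120, by = 0.01)
  ref_fine <- simulate_reference_tac(kin, t_min)
  sched <- build_schedule(default_schedule_spec())
  list(kin = kin, t_min = t_min, ref_fine = ref_fine, sched = sched,
       ref = bin_to_frames(t_min, ref_fine, sched, "occipital"))
})

# Target TAC simulated for given binding parameters on the shared subject.
ideal_target <- function(bp, r1 = 1, region = "target") {
  s <- ideal_subject()
  fine <- simulate_target_tac(list(true_bp = bp, r1 = r1), s$ref_fine,
                              s$kin$k2p, s$t_min)
  bin_to_frames(s$t_min, fine, s$sched, region)
}
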