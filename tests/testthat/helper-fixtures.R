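# Shared fixtures: reference parameter sets and small synthetic cohorts.

ref_gi_params <- function(...) {
  args <- list(k1 = 0.09, k2 = 0.005, k3 = 0.05, k4 = 2e-4, k5 = 1.4,
               k6 = 3, k7 = 0.12, k8 = 0.01)
  args[names(list(...))] <- list(...)
  do.call(gi_params, args)
}

ref_gig_params <- function(...) {
  args <- list(k1 = 0.09, k2 = 0.005, k3 = 0.05, k4 = 2e-4, k5 = 3.5,
               k6 = 3, k7 = 0.12, k8 = 0.01, kGN = 0.004, kGgS = 2.2,
               kGgC = 0.1, kratio = 0.4, kCPC = 0.03)
  args[names(list(...))] <- list(...)
  do.call(gig_params, args)
}

noiseless_cv <- c(Gc = 0, I = 0, Gg = 0, CP = 0)

small_cohort <- function(n = 3, group = "control", model = "gi", seed = 42,
                         noise_cv = noiseless_cv, ...) {
  generate_cohort(synthetic_config(n_subjects = n, group = group,
                                   model = model, seed = seed,
                                   noise_cv = noise_cv, ...))
}

quick_fit_config <- function(seed = 1, ...) {
  fit_config(n_parents = 16, n_generations = 60, seed = seed, ...)
}

subject_series <- function(cohort, i) {
  id <- cohort$subjects$subject_id[i]
  cohort$series[cohort$series$subject_id == id, ]
}
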