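# Shared fixtures, built once per test run. Training a full bank of 36
# networks is cheap (<1 s) but reused across files via lazy accessors.

fixture_env <- new.env(parent = emptyenv())

fx_template <- function() {
  if (is.null(fixture_env$template)) fixture_env$template <- template_bank()
  fixture_env$template
}

# noiseless profile: trials identical to the template
fx_clean_profile <- function() cohort_profile("normal")

# normal training cohort (10 subjects x 10 trials), its reference, and
# one trained network per cyclogram pair
fx_bank <- function() {
  if (is.null(fixture_env$bank)) {
    profiles <- default_profiles()
    pairs <- enumerate_pairs()
    cohort <- generate_cohort(profiles$normal, 10, 10, seed = 11)
    reference <- average_reference(cohort)
    by_subject <- split(cohort,
                        vapply(cohort, function(t) t$subject_id, character(1)))
    networks <- lapply(seq_len(nrow(pairs)), function(i) {
      arrs <- lapply(by_subject, arrange_training, pair = pairs[i, ],
                     reference = reference)
      train_network(arrs, seed = 1000 + i)
    })
    fixture_env$bank <- list(profiles = profiles, pairs = pairs,
                             cohort = cohort, reference = reference,
                             by_subject = by_subject, networks = networks)
  }
  fixture_env$bank
}

# cohort profile with a single planted deficit: one variable's excursion
# scaled at one sub-phase, no boundary jitter
fx_planted_profile <- function(variable = "knee_power", subphase = "LR",
                               scale = 0.2) {
  sc <- matrix(1, 9, 7, dimnames = list(GAIT_VARIABLES, SUBPHASE_NAMES))
  sc[variable, subphase] <- scale
  cohort_profile("transfemoral", scale = sc, subphase_jitter_sd = 0,
                 trial_noise_sd = 0.02, subject_offset_sd = 0.02)
}

# conventional curves and ranges of a pair, from a reference
fx_pair_target <- function(reference, pair) {
  list(curves = rbind(reference$mean[[pair$var_a]],
                      reference$mean[[pair$var_b]]),
       ranges = c(reference$range[[pair$var_a]],
                  reference$range[[pair$var_b]]))
}
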