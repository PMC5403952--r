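## synth: synthetic gait trial generator for normal and pathological
## cohorts. Templates are parametric periodic-spline approximations of
## normative sagittal curves; they are not digitized from any published
## figure.

# Knot tables (percent of cycle, value) for each variable. First and
# last knot share the value so the periodic spline closes over one
# stride. Shapes follow standard normative sagittal gait morphology:
# dorsiflexion/flexion angles positive, extensor (plantarflexor) moment
# positive, power positive = generation.
template_knots <- function() {
  list(
    ankle_angle  = cbind(c(0, 5, 20, 45, 62, 75, 90, 100),
                         c(0, -5, 3, 10, -18, -5, 2, 0)),
    knee_angle   = cbind(c(0, 15, 40, 55, 72, 88, 100),
                         c(5, 20, 4, 25, 62, 15, 5)),
    hip_angle    = cbind(c(0, 25, 50, 60, 75, 88, 100),
                         c(30, 10, -10, -5, 20, 32, 30)),
    ankle_moment = cbind(c(0, 8, 25, 48, 58, 65, 80, 100),
                         c(0, -0.15, 0.6, 1.4, 0.3, 0, 0, 0)),
    knee_moment  = cbind(c(0, 10, 25, 40, 52, 65, 85, 100),
                         c(-0.05, 0.45, 0.1, -0.25, 0.15, 0.05, -0.15, -0.05)),
    hip_moment   = cbind(c(0, 12, 30, 50, 62, 75, 90, 100),
                         c(0.5, 0.8, 0.2, -0.9, -0.3, 0.1, 0.2, 0.5)),
    ankle_power  = cbind(c(0, 8, 30, 45, 53, 60, 70, 85, 100),
                         c(0, -0.6, -0.4, 0.8, 3.5, 0.5, -0.1, 0, 0)),
    knee_power   = cbind(c(0, 8, 18, 35, 50, 60, 70, 80, 92, 100),
                         c(-0.3, -0.9, 0.5, -0.3, -0.8, -1.2, 0.1, -0.2,
                           -1.4, -0.3)),
    hip_power    = cbind(c(0, 12, 30, 45, 58, 70, 85, 100),
                         c(0.5, 0.9, 0.1, -0.9, 1.1, 0.3, -0.1, 0.5)))
}

#' Normative gait template bank
#'
#' Smooth one-stride periodic templates for all 9 sagittal gait
#' variables on the 50-point stride grid, built from a small set of
#' spline knots per variable, plus the canonical sub-phase boundaries.
#' These emulate the morphology of normative sagittal curves and serve
#' as the ground truth of the synthetic generator.
#'
#' @param boundaries sub-phase boundaries in percent of cycle.
#' @return object of class `template_bank` with elements `curves`
#'   (named list of 9 length-50 vectors), `boundaries`, and `subphase`
#'   (canonical labels).
#' @export
template_bank <- function(boundaries = SUBPHASE_BOUNDARIES) {
  grid <- stride_grid()
  curves <- lapply(template_knots(), function(k) {
    f <- stats::splinefun(k[, 1], k[, 2], method = "periodic")
    f(grid)
  })
  structure(list(curves = curves, boundaries = boundaries,
                 subphase = canonical_subphases(boundaries)),
            class = "template_bank")
}

#' Cohort perturbation profile
#'
#' Describes how a cohort's trials deviate from the normative template:
#' per (variable, sub-phase) excursion scales and offsets, sub-phase
#' boundary jitter, trial-level noise and subject-level offsets. The
#' normal profile has all scales 1 and offsets 0.
#'
#' @param cohort cohort name.
#' @param scale 9 x 7 matrix (variables x sub-phases) of non-negative
#'   excursion scales about each template's cycle mean; default all 1.
#' @param offset 9 x 7 matrix of additive offsets, in fractions of each
#'   template's range; default all 0.
#' @param subphase_jitter_sd sd of Gaussian jitter applied to sub-phase
#'   boundaries, in percent of cycle.
#' @param trial_noise_sd sd of additive per-sample Gaussian noise, as a
#'   fraction of each variable's template range.
#' @param subject_offset_sd sd of the per-subject constant offset, as a
#'   fraction of each variable's template range.
#' @return object of class `cohort_profile`.
#' @export
cohort_profile <- function(cohort,
                           scale = matrix(1, 9, 7,
                                          dimnames = list(GAIT_VARIABLES,
                                                          SUBPHASE_NAMES)),
                           offset = matrix(0, 9, 7,
                                           dimnames = list(GAIT_VARIABLES,
                                                           SUBPHASE_NAMES)),
                           subphase_jitter_sd = 0,
                           trial_noise_sd = 0,
                           subject_offset_sd = 0) {
  stopifnot(cohort %in% GAIT_COHORTS)
  scale <- as.matrix(scale)
  offset <- as.matrix(offset)
  stopifnot(all(dim(scale) == c(9, 7)), all(dim(offset) == c(9, 7)))
  if (any(scale < 0)) stop("amplitude scales must be >= 0")
  if (subphase_jitter_sd < 0 || trial_noise_sd < 0 || subject_offset_sd < 0)
    stop("jitter, noise and offset standard deviations must be >= 0")
  rownames(scale) <- rownames(offset) <- GAIT_VARIABLES
  colnames(scale) <- colnames(offset) <- SUBPHASE_NAMES
  structure(list(cohort = cohort, scale = scale, offset = offset,
                 subphase_jitter_sd = subphase_jitter_sd,
                 trial_noise_sd = trial_noise_sd,
                 subject_offset_sd = subject_offset_sd),
            class = "cohort_profile")
}

# helper: set scale rows by variable, columns by phase (default all)
set_scale <- function(scale, vars, value, phases = SUBPHASE_NAMES) {
  scale[vars, phases] <- value
  scale
}

#' Default cohort profiles
#'
#' Normal: small trial noise, mild boundary jitter. Orthosis: mild
#' global kinetic attenuation. Transtibial: attenuated ankle moment and
#' power. Transfemoral: strongly attenuated knee power and moment,
#' stiffened stance knee angle and distorted hip kinetics, with the
#' largest boundary jitter. Deficit severity is ordered
#' orthosis < transtibial < transfemoral so that downstream closeness
#' ranks cohorts the same way.
#'
#' @return named list of four `cohort_profile` objects.
#' @export
default_profiles <- function() {
  ones <- matrix(1, 9, 7, dimnames = list(GAIT_VARIABLES, SUBPHASE_NAMES))
  kinetics <- GAIT_VARIABLES[grepl("moment|power", GAIT_VARIABLES)]
  angles <- GAIT_VARIABLES[grepl("angle", GAIT_VARIABLES)]

  normal <- cohort_profile("normal",
                           subphase_jitter_sd = 0.5,
                           trial_noise_sd = 0.02,
                           subject_offset_sd = 0.02)

  s <- set_scale(ones, kinetics, 0.85)
  s <- set_scale(s, angles, 0.95)
  orthosis <- cohort_profile("orthosis", scale = s,
                             subphase_jitter_sd = 1.5,
                             trial_noise_sd = 0.03,
                             subject_offset_sd = 0.03)

  s <- set_scale(ones, "ankle_power", 0.45)
  s <- set_scale(s, "ankle_moment", 0.55)
  s <- set_scale(s, c("knee_power", "knee_moment"), 0.9)
  s <- set_scale(s, "ankle_angle", 0.8)
  transtibial <- cohort_profile("transtibial", scale = s,
                                subphase_jitter_sd = 2,
                                trial_noise_sd = 0.04,
                                subject_offset_sd = 0.03)

  s <- set_scale(ones, "knee_power", 0.25)
  s <- set_scale(s, "knee_moment", 0.4)
  s <- set_scale(s, "knee_angle", 0.6, c("LR", "MSt", "TSt", "PSw"))
  s <- set_scale(s, c("hip_moment", "hip_power"), 0.75)
  transfemoral <- cohort_profile("transfemoral", scale = s,
                                 subphase_jitter_sd = 2.5,
                                 trial_noise_sd = 0.05,
                                 subject_offset_sd = 0.04)

  list(normal = normal, orthosis = orthosis, transtibial = transtibial,
       transfemoral = transfemoral)
}

# Jitter canonical boundaries on the grid, keeping 7 non-empty
# contiguous runs. Returns per-sample labels.
jitter_subphases <- function(boundaries, jitter_sd) {
  if (jitter_sd == 0) return(canonical_subphases(boundaries))
  b <- sort(2 * round((boundaries + stats::rnorm(6, 0, jitter_sd)) / 2))
  # clamp so every phase keeps at least one grid sample
  b <- pmin(pmax(b, seq(2, 12, by = 2)), seq(88, 98, by = 2))
  for (i in 2:6) b[i] <- max(b[i], b[i - 1] + 2)
  canonical_subphases(b)
}

#' Generate one synthetic gait trial
#'
#' Builds a trial from the template bank under a cohort profile:
#' sub-phase boundaries are jittered, each variable's excursion about
#' its cycle mean is scaled per sub-phase, offsets are added, and
#' low-pass-smoothed Gaussian noise plus a per-subject constant offset
#' complete the series. Deterministic for a fixed seed; with all noise
#' and jitter at zero the trial equals the template exactly.
#'
#' @param profile a `cohort_profile`.
#' @param template a `template_bank`.
#' @param subject_id,trial_index identifiers.
#' @param seed integer seed for this trial's draws.
#' @param side trial side, default "left".
#' @param subject_offset optional named vector (9 variables) of
#'   per-subject offsets in raw units, shared across a subject's trials;
#'   drawn from the profile when NULL.
#' @param noise_cutoff low-pass cutoff (cycles/stride) applied to the
#'   noise component before it is added.
#' @return a `gait_trial`.
#' @export
generate_trial <- function(profile, template, subject_id, trial_index,
                           seed, side = "left", subject_offset = NULL,
                           noise_cutoff = 6) {
  stopifnot(inherits(profile, "cohort_profile"),
            inherits(template, "template_bank"))
  if (all(profile$scale == 0))
    warning("degenerate profile: all amplitude scales are zero")
  with_seed(seed, {
    labels <- jitter_subphases(template$boundaries,
                               profile$subphase_jitter_sd)
    if (is.null(subject_offset)) {
      rng <- vapply(template$curves, function(v) diff(range(v)), numeric(1))
      subject_offset <- stats::rnorm(9, 0, profile$subject_offset_sd * rng)
      names(subject_offset) <- GAIT_VARIABLES
    }
    series <- lapply(GAIT_VARIABLES, function(k) {
      tmpl <- template$curves[[k]]
      m <- mean(tmpl)
      rng <- diff(range(tmpl))
      sc <- profile$scale[k, labels]
      off <- profile$offset[k, labels] * rng
      # written as a deviation from the template so the normal profile
      # (scale 1, offsets 0) reproduces the template bit-exactly
      v <- tmpl + (sc - 1) * (tmpl - m) + off + subject_offset[[k]]
      if (profile$trial_noise_sd > 0) {
        eps <- stats::rnorm(50, 0, profile$trial_noise_sd * rng)
        v <- v + smooth_series(eps, noise_cutoff, 50)
      }
      v
    })
    names(series) <- GAIT_VARIABLES
    gait_trial(subject_id, profile$cohort, trial_index, side, series,
               labels)
  })
}

#' Generate a synthetic cohort
#'
#' `n_subjects` x `n_trials` trials; each subject gets one constant
#' offset vector shared across its trials, and every trial's seed is
#' derived deterministically from the master seed.
#'
#' @param profile a `cohort_profile`.
#' @param n_subjects,n_trials cohort dimensions; `n_trials >= 1`.
#' @param seed master integer seed.
#' @param template a `template_bank`.
#' @param subject_prefix prefix for subject identifiers; defaults to an
#'   abbreviation of the cohort name.
#' @return list of `gait_trial` objects, subject-major.
#' @export
generate_cohort <- function(profile, n_subjects, n_trials, seed,
                            template = template_bank(),
                            subject_prefix = NULL) {
  stopifnot(n_subjects >= 1, n_trials >= 1)
  if (is.null(subject_prefix))
    subject_prefix <- c(normal = "N", transtibial = "TT",
                        transfemoral = "TF", orthosis = "OT")[[profile$cohort]]
  rng <- vapply(template$curves, function(v) diff(range(v)), numeric(1))
  trials <- vector("list", n_subjects * n_trials)
  idx <- 1L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", subject_prefix, s)
    offs <- with_seed(derive_seed(seed, s, 0L), {
      stats::setNames(stats::rnorm(9, 0, profile$subject_offset_sd * rng),
                      GAIT_VARIABLES)
    })
    for (tr in seq_len(n_trials)) {
      trials[[idx]] <- generate_trial(profile, template, sid, tr,
                                      seed = derive_seed(seed, s, tr),
                                      subject_offset = offs)
      idx <- idx + 1L
    }
  }
  trials
}
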