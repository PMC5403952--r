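## cyclogram: enumeration of the 36 coupled-variable relationships,
## realization of cyclogram trajectories, and the trial-averaged normal
## reference.

#' Enumerate the 36 cyclogram pairs
#'
#' Pairs the 9 sagittal gait variables within and across the three leg
#' joints into six groups: angle-angle, moment-moment and power-power
#' across joints (3 pairs each), and angle-moment, angle-power and
#' moment-power within and across joints (9 pairs each). Same-type
#' groups never pair a joint with itself; in mixed groups the
#' first-named (kinematic where present) variable is `var_a` and joints
#' range over all ordered combinations, which is the unique reading that
#' yields 3 within-joint plus 6 across-joint pairs per mixed group.
#' Order is canonical and stable: groups in the order above, joints
#' ordered ankle < knee < hip.
#'
#' @return data.frame with one row per pair: `pair_id`, `group`,
#'   `var_a`, `var_b` (variable keys such as "knee_angle"), `label`.
#' @export
enumerate_pairs <- function() {
  joints <- GAIT_JOINTS
  same_type <- function(type) {
    combs <- utils::combn(joints, 2)
    data.frame(group = paste(type, type, sep = "-"),
               var_a = paste(combs[1, ], type, sep = "_"),
               var_b = paste(combs[2, ], type, sep = "_"),
               stringsAsFactors = FALSE)
  }
  mixed_type <- function(type_a, type_b) {
    g <- expand.grid(joint_b = joints, joint_a = joints,
                     stringsAsFactors = FALSE)[, 2:1]
    g <- g[order(match(g$joint_a, joints), match(g$joint_b, joints)), ]
    data.frame(group = paste(type_a, type_b, sep = "-"),
               var_a = paste(g$joint_a, type_a, sep = "_"),
               var_b = paste(g$joint_b, type_b, sep = "_"),
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(same_type("angle"), same_type("moment"),
                 same_type("power"),
                 mixed_type("angle", "moment"),
                 mixed_type("angle", "power"),
                 mixed_type("moment", "power"))
  pairs$pair_id <- seq_len(nrow(pairs))
  pairs$label <- paste(pairs$var_a, pairs$var_b, sep = "~")
  rownames(pairs) <- NULL
  pairs[, c("pair_id", "group", "var_a", "var_b", "label")]
}

#' Realize a cyclogram from a trial
#'
#' Projects a trial onto one cyclogram pair: the two variable series and
#' the per-sample sub-phase labels. The trajectory is closed (sample 50
#' connects back to sample 1).
#'
#' @param trial a `gait_trial`.
#' @param pair one row of `enumerate_pairs()`.
#' @return object of class `cyclogram` with `a_values`, `b_values`,
#'   `subphase`, `pair` and `source`.
#' @export
build_cyclogram <- function(trial, pair) {
  validate_gait_trial(trial)
  structure(list(pair = pair,
                 a_values = trial$series[[pair$var_a]],
                 b_values = trial$series[[pair$var_b]],
                 subphase = trial$subphase,
                 source = sprintf("%s/trial%d", trial$subject_id,
                                  trial$trial_index)),
            class = "cyclogram")
}

#' Conventional trial-averaged normal reference
#'
#' Pointwise arithmetic mean, at each stride-grid sample, of every
#' variable across a set of normal trials. This is the conventional
#' trials-averaging method: it is only meaningful for normal gait, whose
#' sub-phase durations are consistent across trials, and it is the
#' target of all disparity scoring and normal-value substitutions. The
#' per-variable range (max - min of the mean curve) is the normalization
#' denominator used downstream.
#'
#' @param trials non-empty list of normal `gait_trial`s on the stride
#'   grid.
#' @param boundaries canonical sub-phase boundaries for the reference
#'   labels.
#' @return object of class `normal_reference` with `mean` (named list
#'   of 9 length-50 curves), `min`, `range` (named numeric),
#'   `subphase` (canonical labels) and `n_trials`.
#' @export
average_reference <- function(trials, boundaries = SUBPHASE_BOUNDARIES) {
  if (length(trials) == 0L) stop("cannot average an empty list of trials")
  cohorts <- unique(vapply(trials, function(t) t$cohort, character(1)))
  if (length(cohorts) != 1L)
    stop("trials mix cohorts (", paste(cohorts, collapse = ", "),
         "); the reference is built from one cohort")
  lapply(trials, validate_gait_trial)
  means <- lapply(GAIT_VARIABLES, function(k) {
    rowMeans(vapply(trials, function(t) t$series[[k]], numeric(50)))
  })
  names(means) <- GAIT_VARIABLES
  rng <- vapply(means, function(v) diff(range(v)), numeric(1))
  if (any(rng <= 0))
    stop("degenerate reference: zero range for ",
         paste(names(rng)[rng <= 0], collapse = ", "))
  structure(list(mean = means,
                 min = vapply(means, min, numeric(1)),
                 range = rng,
                 subphase = canonical_subphases(boundaries),
                 n_trials = length(trials)),
            class = "normal_reference")
}

#' @export
print.normal_reference <- function(x, ...) {
  cat(sprintf("<normal_reference> averaged over %d trials\n", x$n_trials))
  cat("  variable ranges:",
      paste(sprintf("%s=%.2f", names(x$range), x$range), collapse = " "),
      "\n")
  invisible(x)
}

#' Serialize / read a normal reference
#'
#' Writes the mean curves to CSV (columns variable, percent_gait,
#' mean_value) and the metadata (n_trials, ranges, sub-phase labels) to
#' a JSON side file at `<path>.json`.
#'
#' @param reference a `normal_reference`.
#' @param path CSV path.
#' @export
write_reference <- function(reference, path) {
  df <- do.call(rbind, lapply(GAIT_VARIABLES, function(k) {
    data.frame(variable = k, percent_gait = stride_grid(),
               mean_value = sprintf("%.17g", reference$mean[[k]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(n_trials = reference$n_trials,
               min = as.list(reference$min),
               range = as.list(reference$range),
               subphase = reference$subphase)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  means <- lapply(GAIT_VARIABLES, function(k) {
    g <- df[df$variable == k, ]
    as.numeric(g$mean_value[order(g$percent_gait)])
  })
  names(means) <- GAIT_VARIABLES
  structure(list(mean = means,
                 min = unlist(meta$min)[GAIT_VARIABLES],
                 range = unlist(meta$range)[GAIT_VARIABLES],
                 subphase = as.integer(meta$subphase),
                 n_trials = meta$n_trials),
            class = "normal_reference")
}
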