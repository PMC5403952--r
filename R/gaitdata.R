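## gaitdata: data model and I/O for stride-normalized gait trials.

#' Construct a gait trial
#'
#' One stride of one subject: 9 sagittal variable series (ankle, knee,
#' hip x angle, moment, power) on the 50-point stride grid, with a
#' per-sample gait sub-phase label. Units are degrees for angles,
#' N·m/kg for moments and W/kg for powers.
#'
#' @param subject_id character subject identifier.
#' @param cohort one of "normal", "transtibial", "transfemoral",
#'   "orthosis".
#' @param trial_index positive integer.
#' @param side "left" or "right". Analyses default to the left
#'   (non-dominant) side.
#' @param series named list of 9 numeric vectors of length 50, names
#'   `GAIT_VARIABLES`.
#' @param subphase integer vector of length 50, labels in 1..7,
#'   non-decreasing, every label present.
#' @return an object of class `gait_trial`.
#' @export
gait_trial <- function(subject_id, cohort, trial_index, side, series,
                       subphase) {
  trial <- structure(
    list(subject_id = as.character(subject_id),
         cohort = cohort,
         trial_index = as.integer(trial_index),
         side = side,
         percent = stride_grid(),
         series = lapply(series, as.numeric),
         subphase = as.integer(subphase)),
    class = "gait_trial")
  validate_gait_trial(trial)
}

#' Validate a gait trial
#'
#' Enforces the trial invariants: exactly 9 named series of length 50,
#' sub-phase labels in 1..7 that are non-decreasing along the stride and
#' cover every phase at least once.
#'
#' @param trial a `gait_trial`.
#' @return the trial, invisibly unchanged, or an error naming the
#'   offending field.
#' @export
validate_gait_trial <- function(trial) {
  if (!inherits(trial, "gait_trial")) stop("not a gait_trial object")
  if (!trial$cohort %in% GAIT_COHORTS)
    stop("field 'cohort': got ", dQuote(trial$cohort),
         "; allowed values are ", paste(GAIT_COHORTS, collapse = ", "))
  if (!trial$side %in% GAIT_SIDES)
    stop("field 'side': got ", dQuote(trial$side),
         "; allowed values are ", paste(GAIT_SIDES, collapse = ", "))
  if (!setequal(names(trial$series), GAIT_VARIABLES) ||
      length(trial$series) != 9L)
    stop("field 'series': expected exactly the 9 variables ",
         paste(GAIT_VARIABLES, collapse = ", "))
  len <- vapply(trial$series, length, integer(1))
  if (any(len != 50L))
    stop("field 'series': every series must have length 50, got ",
         paste(names(len)[len != 50L], collapse = ", "))
  bad <- vapply(trial$series, function(v) anyNA(v) || !is.numeric(v),
                logical(1))
  if (any(bad))
    stop("field 'series': non-numeric or missing values in ",
         paste(names(bad)[bad], collapse = ", "))
  sp <- trial$subphase
  if (length(sp) != 50L || anyNA(sp))
    stop("field 'subphase': expected 50 labels without missing values")
  if (!all(sp %in% 1:7))
    stop("field 'subphase': labels must be integers in 1..7")
  if (any(diff(sp) < 0))
    stop("field 'subphase': labels must be non-decreasing along the stride")
  if (!all(1:7 %in% sp))
    stop("field 'subphase': every label 1..7 must occur at least once")
  invisible(trial)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s (%s, %s side), trial %d\n",
              x$subject_id, x$cohort, x$side, x$trial_index))
  cat("  9 series x 50 stride-grid samples; sub-phase runs:",
      paste(sprintf("%s=%d", SUBPHASE_NAMES, tabulate(x$subphase, 7)),
            collapse = " "), "\n")
  invisible(x)
}

## ---- resampling -----------------------------------------------------------

#' Resample a raw time series onto the 50-point stride grid
#'
#' Linearly interpolates a raw series, sampled at arbitrary times within
#' one stride, to values at 0, 2, ..., 98 percent of stride duration.
#' The stride is delimited by two successive ipsilateral foot strikes.
#'
#' @param timestamps strictly increasing sample times (s).
#' @param values numeric samples, same length as `timestamps`.
#' @param stride_start,stride_end foot-strike times delimiting the
#'   stride; the raw series must cover `[stride_start, grid_end]` where
#'   the last grid point is at 98 percent of the stride.
#' @return numeric vector of 50 interpolated values.
#' @export
resample_to_stride_grid <- function(timestamps, values, stride_start,
                                    stride_end) {
  if (length(timestamps) != length(values))
    stop("timestamps and values must have equal length")
  if (length(timestamps) < 2L)
    stop("need at least 2 raw samples to interpolate")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (stride_end <= stride_start)
    stop("stride_end must exceed stride_start")
  grid_t <- stride_start + (stride_grid() / 100) * (stride_end - stride_start)
  if (min(timestamps) > stride_start || max(timestamps) < max(grid_t))
    stop("raw series does not cover the stride interval")
  stats::approx(timestamps, values, xout = grid_t, method = "linear",
                ties = "ordered")$y
}

#' Normalize a joint moment series by body mass
#'
#' @param moment_series joint moment in N·m.
#' @param body_mass subject mass in kg, must be positive.
#' @return moment in N·m/kg.
#' @export
normalize_moment <- function(moment_series, body_mass) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || body_mass <= 0)
    stop("body_mass must be a single positive number")
  moment_series / body_mass
}

## ---- smoothing ------------------------------------------------------------

# One pass of an IIR filter in transposed direct form II with initial
# state `zi` (same difference equation as signal::filter).
iir_pass <- function(b, a, x, zi) {
  n <- length(x)
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z[1]
    if (nf > 2L)
      for (j in 1:(nf - 2L)) z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    z[nf - 1L] <- b[nf] * x[i] - a[nf] * y[i]
  }
  y
}

# Steady-state initial filter state for a unit-step input, so that a
# constant signal passes through with zero transient.
iir_steady_state <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  A <- cbind(-a[2:nf], rbind(diag(nf - 2L), 0))
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(nf - 1L) - A, B)
}

#' Zero-phase second-order Butterworth smoothing
#'
#' Applies a second-order low-pass Butterworth filter forward and
#' backward (zero phase lag), with odd-reflection end padding and
#' steady-state initial conditions so that a constant series is returned
#' unchanged.
#'
#' @param values numeric series.
#' @param cutoff low-pass cutoff frequency (Hz); must satisfy
#'   `0 < cutoff < sample_rate / 2`.
#' @param sample_rate sampling frequency of `values` (Hz).
#' @return filtered series of the same length.
#' @export
smooth_series <- function(values, cutoff, sample_rate) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive frequency")
  if (cutoff >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency (sample_rate / 2)")
  n <- length(values)
  if (n < 2L) return(values)
  bf <- signal::butter(2, 2 * cutoff / sample_rate, type = "low")
  b <- bf$b
  a <- bf$a
  padlen <- min(n - 1L, 3L * max(length(a), length(b)))
  x <- c(2 * values[1] - values[(padlen + 1):2],
         values,
         2 * values[n] - values[(n - 1):(n - padlen)])
  zi <- iir_steady_state(b, a)
  y <- iir_pass(b, a, x, zi * x[1])
  y <- rev(iir_pass(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

## ---- CSV I/O --------------------------------------------------------------

trial_csv_columns <- function() {
  c("subject_id", "cohort", "trial_index", "side", "percent_gait",
    "subphase",
    "ankle_angle_deg", "knee_angle_deg", "hip_angle_deg",
    "ankle_moment_nm_kg", "knee_moment_nm_kg", "hip_moment_nm_kg",
    "ankle_power_w_kg", "knee_power_w_kg", "hip_power_w_kg")
}

# maps CSV column name <-> internal variable key
csv_var_map <- function() {
  keys <- GAIT_VARIABLES
  cols <- c(angle = "%s_angle_deg", moment = "%s_moment_nm_kg",
            power = "%s_power_w_kg")
  vapply(keys, function(k) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    sprintf(cols[[parts[2]]], parts[1])
  }, character(1))
}

#' Write gait trials to CSV
#'
#' One row per (trial, grid point); numeric values are serialized at
#' full (17 significant digit) precision so that a write/read round trip
#' reproduces all values bit-equal.
#'
#' @param trials list of `gait_trial` objects.
#' @param path output CSV file.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  vm <- csv_var_map()
  rows <- lapply(trials, function(tr) {
    validate_gait_trial(tr)
    df <- data.frame(subject_id = tr$subject_id, cohort = tr$cohort,
                     trial_index = tr$trial_index, side = tr$side,
                     percent_gait = tr$percent, subphase = tr$subphase,
                     stringsAsFactors = FALSE)
    for (k in GAIT_VARIABLES) df[[vm[[k]]]] <- sprintf("%.17g", tr$series[[k]])
    df
  })
  out <- do.call(rbind, rows)[, trial_csv_columns()]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gait trials from CSV
#'
#' Reads the trial schema written by `write_trials()`: columns
#' subject_id, cohort, trial_index, side, percent_gait, subphase and the
#' nine variable columns, 50 rows per trial. All trial invariants are
#' re-validated on read.
#'
#' @param path CSV file path.
#' @return list of `gait_trial` objects.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_csv_columns(), names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  vm <- csv_var_map()
  key <- interaction(df$subject_id, df$cohort, df$trial_index, df$side,
                     drop = TRUE)
  groups <- split(df, key)
  trials <- lapply(groups, function(g) {
    if (nrow(g) != 50L)
      stop("schema error: trial ", g$subject_id[1], "/", g$trial_index[1],
           " has ", nrow(g), " rows, expected 50")
    g <- g[order(g$percent_gait), ]
    if (!isTRUE(all.equal(g$percent_gait, stride_grid())))
      stop("schema error: field 'percent_gait' must be 0, 2, ..., 98")
    series <- lapply(GAIT_VARIABLES, function(k) as.numeric(g[[vm[[k]]]]))
    names(series) <- GAIT_VARIABLES
    gait_trial(g$subject_id[1], g$cohort[1], g$trial_index[1], g$side[1],
               series, g$subphase)
  })
  names(trials) <- NULL
  trials[order(vapply(trials, function(t) t$subject_id, character(1)),
               vapply(trials, function(t) t$trial_index, integer(1)))]
}
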