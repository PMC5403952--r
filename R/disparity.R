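## disparity: Phase-2 engine. Arrange cyclogram data (30 x 50 inputs,
## 3 x 50 targets), train one 30-7-3 all-linear feed-forward network per
## cyclogram pair on normal data, simulate for any subject, and score
## closeness and per-sub-phase mean normalized errors.

#' Arrange cyclogram data for network training or simulation
#'
#' Builds the fixed input/target layout for one cyclogram pair: the
#' input matrix has 30 rows x 50 columns (rows 1-10 the first variable
#' for 10 trials, rows 11-20 the second variable, rows 21-30 the
#' per-trial sub-phase labels 1..7; columns are the stride-grid samples
#' at 2% intervals). Targets are 3 rows x 50 columns: the two
#' trial-averaged normal curves and the canonical sub-phase labels.
#'
#' @param trials exactly 10 `gait_trial`s from one subject (or cohort
#'   training group). Subjects with fewer trials can be resampled with
#'   replacement to 10 by setting `allow_resample = TRUE` (seeded); the
#'   arrangement is then flagged.
#' @param pair one row of `enumerate_pairs()`.
#' @param reference a `normal_reference`.
#' @param allow_resample resample with replacement when not exactly 10
#'   trials are supplied.
#' @param seed seed used only when resampling.
#' @return object of class `training_arrangement` with `inputs` (30x50),
#'   `targets` (3x50), `pair`, normalization parameters and flags.
#' @export
arrange_training <- function(trials, pair, reference,
                             allow_resample = FALSE, seed = NULL) {
  if (length(trials) != 10L) {
    if (!allow_resample)
      stop("expected exactly 10 trials, got ", length(trials),
           " (set allow_resample = TRUE to resample with replacement)")
    if (is.null(seed)) stop("resampling trials requires a seed")
    idx <- with_seed(seed, sample.int(length(trials), 10L, replace = TRUE))
    trials <- trials[idx]
    resampled <- TRUE
  } else resampled <- FALSE
  lapply(trials, validate_gait_trial)
  a <- t(vapply(trials, function(tr) tr$series[[pair$var_a]], numeric(50)))
  b <- t(vapply(trials, function(tr) tr$series[[pair$var_b]], numeric(50)))
  sp <- t(vapply(trials, function(tr) as.numeric(tr$subphase), numeric(50)))
  inputs <- rbind(a, b, sp)
  targets <- rbind(reference$mean[[pair$var_a]],
                   reference$mean[[pair$var_b]],
                   as.numeric(reference$subphase))
  structure(list(inputs = inputs, targets = targets, pair = pair,
                 norm = list(a_min = reference$min[[pair$var_a]],
                             a_range = reference$range[[pair$var_a]],
                             b_min = reference$min[[pair$var_b]],
                             b_range = reference$range[[pair$var_b]]),
                 resampled = resampled,
                 subjects = unique(vapply(trials, function(t) t$subject_id,
                                          character(1)))),
            class = "training_arrangement")
}

# Range-normalize an input (30 x n) or target (3 x n) matrix so the
# MSE and regression criteria are comparable across variables with
# different units: variables map to (x - min) / range of the normal
# reference curve, sub-phase labels map 1..7 -> 0..1.
normalize_arrangement <- function(mat, norm) {
  stopifnot(nrow(mat) %in% c(3L, 30L))
  k <- nrow(mat) / 3L
  ia <- 1:k; ib <- (k + 1):(2 * k); ip <- (2 * k + 1):(3 * k)
  mat[ia, ] <- (mat[ia, , drop = FALSE] - norm$a_min) / norm$a_range
  mat[ib, ] <- (mat[ib, , drop = FALSE] - norm$b_min) / norm$b_range
  mat[ip, ] <- (mat[ip, , drop = FALSE] - 1) / 6
  mat
}

denormalize_targets <- function(mat, norm) {
  mat[1, ] <- mat[1, ] * norm$a_range + norm$a_min
  mat[2, ] <- mat[2, ] * norm$b_range + norm$b_min
  mat[3, ] <- mat[3, ] * 6 + 1
  mat
}

# Exact alternating least-squares update for the all-linear 30-7-3
# network: with linear activations the composed map is a rank-limited
# linear map, so each layer's optimum given the other is a closed-form
# least-squares solve. With 3 targets and 7 hidden units the factored
# map attains the full least-squares solution.
fit_linear_net <- function(X, Tm, hidden = 7L, n_iter = 4L) {
  n_in <- nrow(X)
  W1 <- matrix(stats::rnorm(hidden * n_in, sd = 0.1), hidden, n_in)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(3L * hidden, sd = 0.1), 3L, hidden)
  b2 <- numeric(3L)
  Xaug <- rbind(X, 1)
  for (it in seq_len(n_iter)) {
    H <- W1 %*% X + b1
    Haug <- rbind(H, 1)
    C2 <- Tm %*% t(Haug) %*% MASS::ginv(Haug %*% t(Haug))
    W2 <- C2[, 1:hidden, drop = FALSE]
    b2 <- C2[, hidden + 1L]
    M <- Tm - b2
    C1 <- MASS::ginv(W2) %*% M %*% (t(Xaug) %*% MASS::ginv(Xaug %*% t(Xaug)))
    W1 <- C1[, 1:n_in, drop = FALSE]
    b1 <- C1[, n_in + 1L]
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

net_forward_norm <- function(net, Xn) {
  net$W2 %*% (net$W1 %*% Xn + net$b1) + net$b2
}

split_columns <- function(n) {
  idx <- sample.int(n)
  n_train <- round(0.6 * n)
  n_val <- round(0.2 * n)
  list(train = sort(idx[1:n_train]),
       val = sort(idx[(n_train + 1):(n_train + n_val)]),
       test = sort(idx[(n_train + n_val + 1):n]))
}

#' Train a disparity network for one cyclogram pair
#'
#' Fits the fixed 30-7-3 feed-forward network with linear activations
#' on range-normalized normal data. Columns (stride samples) are split
#' at random into training (60%), validation (20%) and test (20%) sets.
#' Weights are reinitialized and training repeated until all acceptance
#' criteria pass or `max_restarts` is reached, in which case the
#' network is returned flagged as not accepted (never silently). The
#' criteria are: (1) final training mean square error below
#' `criteria$max_mse`; (2) validation and test errors of similar
#' magnitude, `|MSE_test - MSE_val| <= similarity x max(MSE_test,
#' MSE_val)`; (3) regression R (Pearson correlation between flattened
#' predictions and targets) above `criteria$min_r` on all three splits.
#'
#' @param arrangement a `training_arrangement`, or a list of them for
#'   the same pair (their columns are pooled, e.g. 10 subjects x 50
#'   samples).
#' @param criteria list with `max_mse` (default 0.9), `min_r` (default
#'   0.9) and `similarity` (default 0.5).
#' @param seed integer seed governing the split and every weight
#'   initialization.
#' @param max_restarts maximum number of weight reinitializations.
#' @return object of class `disparity_network`: weights `W1`, `b1`,
#'   `W2`, `b2`, the pair, normalization parameters, and a training
#'   `report` (final MSE per split, R per split, criterion flags,
#'   restarts used, seed).
#' @export
train_network <- function(arrangement, criteria = list(), seed,
                          max_restarts = 10L) {
  if (inherits(arrangement, "training_arrangement"))
    arrangement <- list(arrangement)
  pair <- arrangement[[1]]$pair
  for (arr in arrangement)
    if (!identical(arr$pair$label, pair$label))
      stop("all arrangements must target the same cyclogram pair")
  crit <- utils::modifyList(list(max_mse = 0.9, min_r = 0.9,
                                 similarity = 0.5), criteria)
  if (max_restarts < 1L) stop("max_restarts must be >= 1")
  norm <- arrangement[[1]]$norm
  X <- do.call(cbind, lapply(arrangement,
                             function(a) normalize_arrangement(a$inputs, norm)))
  Tm <- do.call(cbind, lapply(arrangement,
                             function(a) normalize_arrangement(a$targets, norm)))
  mse <- function(P, Tm) mean((P - Tm)^2)
  rsplit <- function(P, Tm) {
    if (stats::sd(P) == 0 || stats::sd(Tm) == 0) return(0)
    stats::cor(as.vector(P), as.vector(Tm))
  }
  result <- with_seed(seed, {
    report <- NULL
    net <- NULL
    for (restart in seq_len(max_restarts)) {
      sp <- split_columns(ncol(X))
      fit <- fit_linear_net(X[, sp$train, drop = FALSE],
                            Tm[, sp$train, drop = FALSE])
      P <- net_forward_norm(fit, X)
      m <- vapply(sp, function(ix) mse(P[, ix, drop = FALSE],
                                       Tm[, ix, drop = FALSE]), numeric(1))
      r <- vapply(sp, function(ix) rsplit(P[, ix, drop = FALSE],
                                          Tm[, ix, drop = FALSE]), numeric(1))
      pass_mse <- m[["train"]] < crit$max_mse
      pass_sim <- abs(m[["test"]] - m[["val"]]) <=
        crit$similarity * max(m[["test"]], m[["val"]], .Machine$double.eps)
      pass_r <- all(r > crit$min_r)
      report <- list(final_mse = unname(m[["train"]]),
                     mse = as.list(m), r = as.list(r),
                     criteria = list(mse = pass_mse, similarity = pass_sim,
                                     regression = pass_r),
                     accepted = pass_mse && pass_sim && pass_r,
                     restarts = restart, seed = seed,
                     split = sp, n_columns = ncol(X))
      net <- fit
      if (report$accepted) break
    }
    list(net = net, report = report)
  })
  if (!result$report$accepted)
    warning("network for pair ", pair$label, " failed acceptance after ",
            max_restarts, " restarts; returned flagged")
  structure(c(result$net,
              list(pair = pair, norm = norm, report = result$report)),
            class = "disparity_network")
}

#' @export
print.disparity_network <- function(x, ...) {
  r <- x$report
  cat(sprintf("<disparity_network> %s  (30-7-3 linear)\n", x$pair$label))
  cat(sprintf("  accepted: %s after %d restart(s); MSE %.3g; R %s\n",
              r$accepted, r$restarts, r$final_mse,
              paste(sprintf("%s=%.4f", names(r$r), unlist(r$r)),
                    collapse = " ")))
  invisible(x)
}

#' Simulate a trained network on a subject
#'
#' Builds the subject's 30 x 50 arrangement for the network's pair,
#' forward-propagates every stride sample, and returns the predicted
#' output in raw units: rows 1-2 are the predicted variable curves as a
#' function of gait cycle percentage, row 3 the predicted sub-phase
#' signal.
#'
#' @param net a trained `disparity_network`.
#' @param subject_trials the subject's 10 trials.
#' @param pair pair the caller expects; must match the network's pair.
#' @param reference a `normal_reference`.
#' @param ... passed to `arrange_training()` (e.g. `allow_resample`).
#' @return 3 x 50 numeric matrix.
#' @export
simulate_network <- function(net, subject_trials, pair, reference, ...) {
  if (!identical(pair$label, net$pair$label))
    stop("pair mismatch: network is for ", net$pair$label,
         " but simulation was requested for ", pair$label)
  arr <- arrange_training(subject_trials, pair, reference, ...)
  Xn <- normalize_arrangement(arr$inputs, net$norm)
  denormalize_targets(net_forward_norm(net, Xn), net$norm)
}

#' Curve closeness statistic
#'
#' C = (1 - e) x 100, where e is the mean over both predicted variable
#' curves and all 50 stride samples of the range-normalized absolute
#' error against the conventional trial-averaged curves, each point
#' error clipped to at most 1 (one full range = 100% error). C = 100
#' means a perfect match to normal; C = 0 means maximal error
#' everywhere.
#'
#' @param predicted 2 x 50 matrix of predicted variable curves.
#' @param conventional 2 x 50 matrix of trial-averaged normal curves.
#' @param ranges length-2 positive normalization ranges for the two
#'   variables.
#' @return object of class `closeness_score`: list with `C` (percent)
#'   and `e_pc` (mean normalized point error in [0, 1]).
#' @export
closeness <- function(predicted, conventional, ranges) {
  predicted <- as.matrix(predicted)
  conventional <- as.matrix(conventional)
  stopifnot(nrow(predicted) == 2L, dim(predicted) == dim(conventional),
            length(ranges) == 2L)
  if (any(ranges <= 0)) stop("normalization ranges must be positive")
  err <- abs(predicted - conventional) / ranges
  e_pc <- mean(pmin(err, 1))
  structure(list(C = (1 - e_pc) * 100, e_pc = e_pc),
            class = "closeness_score")
}

#' @export
print.closeness_score <- function(x, ...) {
  cat(sprintf("<closeness_score> C = %.2f%% (e = %.4f)\n", x$C, x$e_pc))
  invisible(x)
}

#' Per-sub-phase mean normalized errors
#'
#' For each gait sub-phase, the mean over the samples labeled with that
#' phase and over the two variable curves of the range-normalized
#' absolute error between predicted and target, reported x 100 so that
#' one full range corresponds to 100. Phases with no labeled sample are
#' returned as NA (flagged missing).
#'
#' @param predicted,target 2 x 50 matrices.
#' @param subphase_labels integer labels 1..7 per stride sample used to
#'   group the errors (typically the canonical reference labels).
#' @param ranges length-2 positive normalization ranges.
#' @return named numeric vector of length 7 (`SUBPHASE_NAMES`).
#' @export
subphase_errors <- function(predicted, target, subphase_labels, ranges) {
  predicted <- as.matrix(predicted)
  target <- as.matrix(target)
  stopifnot(nrow(predicted) == 2L, dim(predicted) == dim(target),
            length(subphase_labels) == ncol(predicted))
  if (!all(subphase_labels %in% 1:7)) stop("invalid sub-phase labels")
  if (any(ranges <= 0)) stop("normalization ranges must be positive")
  err <- abs(predicted - target) / ranges
  out <- vapply(1:7, function(s) {
    ix <- subphase_labels == s
    if (!any(ix)) return(NA_real_)
    mean(err[, ix, drop = FALSE]) * 100
  }, numeric(1))
  names(out) <- SUBPHASE_NAMES
  out
}

#' Per-sub-phase error table and worst pairs for one subject
#'
#' Simulates the subject through every trained network, computes the
#' per-sub-phase mean normalized error of each cyclogram pair, and for
#' each sub-phase records the pair with the maximal error (ties broken
#' by canonical pair order). Networks flagged as not accepted are
#' excluded with a warning and noted in the result.
#'
#' @param subject_trials the subject's 10 trials.
#' @param networks list of `disparity_network`s indexed by `pair_id`.
#' @param reference a `normal_reference`.
#' @param pairs the pair table from `enumerate_pairs()`.
#' @param labels sub-phase labels used to group errors; defaults to the
#'   canonical reference labels.
#' @param ... passed to `simulate_network()`.
#' @return object of class `subphase_error_table`: `errors` (long
#'   data.frame: pair_id, pair, subphase, error), `worst` (one row per
#'   sub-phase: subphase, pair_id, pair, var_a, var_b, error),
#'   `excluded` pair ids, and `subject_id`.
#' @export
worst_pair_table <- function(subject_trials, networks, reference,
                             pairs = enumerate_pairs(),
                             labels = reference$subphase, ...) {
  excluded <- integer(0)
  err_mat <- matrix(NA_real_, nrow(pairs), 7,
                    dimnames = list(pairs$label, SUBPHASE_NAMES))
  for (i in seq_len(nrow(pairs))) {
    net <- networks[[i]]
    if (is.null(net) || !net$report$accepted) {
      excluded <- c(excluded, pairs$pair_id[i])
      next
    }
    pred <- simulate_network(net, subject_trials, pairs[i, ], reference, ...)
    targ <- rbind(reference$mean[[pairs$var_a[i]]],
                  reference$mean[[pairs$var_b[i]]])
    rng <- c(reference$range[[pairs$var_a[i]]],
             reference$range[[pairs$var_b[i]]])
    err_mat[i, ] <- subphase_errors(pred[1:2, , drop = FALSE], targ,
                                    labels, rng)
  }
  if (length(excluded))
    warning("excluded ", length(excluded),
            " non-accepted network(s): pair id(s) ",
            paste(excluded, collapse = ", "))
  worst <- do.call(rbind, lapply(1:7, function(s) {
    col <- err_mat[, s]
    if (all(is.na(col))) return(NULL)
    i <- which(col == max(col, na.rm = TRUE))[1]  # canonical tie-break
    data.frame(subphase = s, phase = SUBPHASE_NAMES[s],
               pair_id = pairs$pair_id[i], pair = pairs$label[i],
               var_a = pairs$var_a[i], var_b = pairs$var_b[i],
               error = col[i], stringsAsFactors = FALSE)
  }))
  rownames(worst) <- NULL
  long <- data.frame(pair_id = rep(pairs$pair_id, 7),
                     pair = rep(pairs$label, 7),
                     subphase = rep(1:7, each = nrow(pairs)),
                     error = as.vector(err_mat),
                     stringsAsFactors = FALSE)
  structure(list(errors = long, error_matrix = err_mat, worst = worst,
                 excluded = excluded,
                 subject_id = subject_trials[[1]]$subject_id),
            class = "subphase_error_table")
}

#' Subject-level closeness across all cyclogram pairs
#'
#' Simulates one subject through every accepted network and scores the
#' closeness C of each pair's predicted curves against the conventional
#' trial-averaged curves; the subject-level C is the mean across pairs.
#'
#' @inheritParams worst_pair_table
#' @return list with `per_pair` (data.frame pair_id, pair, C) and `C`
#'   (subject-level mean).
#' @export
subject_closeness <- function(subject_trials, networks, reference,
                              pairs = enumerate_pairs(), ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    net <- networks[[i]]
    if (is.null(net) || !net$report$accepted) return(NULL)
    pred <- simulate_network(net, subject_trials, pairs[i, ], reference, ...)
    conv <- rbind(reference$mean[[pairs$var_a[i]]],
                  reference$mean[[pairs$var_b[i]]])
    rng <- c(reference$range[[pairs$var_a[i]]],
             reference$range[[pairs$var_b[i]]])
    cs <- closeness(pred[1:2, , drop = FALSE], conv, rng)
    data.frame(pair_id = pairs$pair_id[i], pair = pairs$label[i],
               C = cs$C, stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, rows)
  list(per_pair = per_pair, C = mean(per_pair$C))
}

#' Serialize / read a disparity network as JSON
#'
#' @param net a `disparity_network`.
#' @param path JSON file path.
#' @export
write_network <- function(net, path) {
  obj <- list(pair = as.list(net$pair),
              W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
              norm = net$norm,
              report = net$report[c("final_mse", "mse", "r", "criteria",
                                    "accepted", "restarts", "seed")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W1 = as.matrix(obj$W1),
                 b1 = as.numeric(obj$b1),
                 W2 = as.matrix(obj$W2),
                 b2 = as.numeric(obj$b2),
                 pair = as.data.frame(obj$pair, stringsAsFactors = FALSE),
                 norm = obj$norm,
                 report = obj$report),
            class = "disparity_network")
}
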