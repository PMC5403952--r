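## manipulate: Phase-3 engine. Substitute normal values into one
## variable of the worst cyclogram pair per sub-phase, re-simulate
## through the unchanged trained network, and select the dominant
## parameter per sub-phase (with the knee-only restriction and the
## no-parameter mid-swing rule).

#' Substitute normal values into one variable at one sub-phase
#'
#' In each trial, the samples of the chosen variable whose sub-phase
#' label equals `subphase` are replaced by the conventional
#' trial-averaged normal curve values at the same grid points; all
#' other samples are untouched. The operation is idempotent.
#'
#' @param trials list of `gait_trial`s.
#' @param pair one row of `enumerate_pairs()`.
#' @param which `"a"` or `"b"`: which variable of the pair to
#'   substitute.
#' @param subphase target sub-phase label in 1..7.
#' @param reference a `normal_reference`.
#' @return the modified list of trials.
#' @export
substitute_normal <- function(trials, pair, which = c("a", "b"),
                              subphase, reference) {
  which <- match.arg(which)
  key <- if (which == "a") pair$var_a else pair$var_b
  if (!key %in% GAIT_VARIABLES)
    stop("variable ", key, " is not a gait variable of this pair")
  stopifnot(subphase %in% 1:7)
  lapply(trials, function(tr) {
    ix <- tr$subphase == subphase
    tr$series[[key]][ix] <- reference$mean[[key]][ix]
    tr
  })
}

#' Run both manipulation experiments per evaluable sub-phase
#'
#' For each sub-phase of the subject's worst-pair table, substitutes
#' normal values into each of the two variables of that phase's
#' worst pair in turn, re-simulates through the unchanged trained
#' network, and records the full 7-phase error vectors before and
#' after manipulation.
#'
#' @param subject_trials the subject's 10 trials.
#' @param worst a `subphase_error_table` from `worst_pair_table()`.
#' @param networks list of `disparity_network`s indexed by `pair_id`.
#' @param reference a `normal_reference`.
#' @param pairs the pair table from `enumerate_pairs()`.
#' @param labels sub-phase labels used to group errors.
#' @param ... passed to `simulate_network()`.
#' @return object of class `manipulation_experiments`: a long
#'   data.frame with columns subject_id, subphase (the manipulated
#'   phase), pair_id, pair, variable, candidate ("a"/"b"), phase (1..7),
#'   pre_error, post_error; sub-phases with a missing or non-accepted
#'   network are skipped and listed in `attr(, "skipped")`.
#' @export
evaluate_candidates <- function(subject_trials, worst, networks, reference,
                                pairs = enumerate_pairs(),
                                labels = reference$subphase, ...) {
  stopifnot(inherits(worst, "subphase_error_table"))
  rows <- list()
  skipped <- integer(0)
  for (r in seq_len(nrow(worst$worst))) {
    w <- worst$worst[r, ]
    net <- networks[[w$pair_id]]
    if (is.null(net) || !net$report$accepted) {
      skipped <- c(skipped, w$subphase)
      next
    }
    pair <- pairs[pairs$pair_id == w$pair_id, ]
    targ <- rbind(reference$mean[[pair$var_a]],
                  reference$mean[[pair$var_b]])
    rng <- c(reference$range[[pair$var_a]],
             reference$range[[pair$var_b]])
    pred0 <- simulate_network(net, subject_trials, pair, reference, ...)
    pre <- subphase_errors(pred0[1:2, , drop = FALSE], targ, labels, rng)
    for (cand in c("a", "b")) {
      mod <- substitute_normal(subject_trials, pair, cand, w$subphase,
                               reference)
      pred1 <- simulate_network(net, mod, pair, reference, ...)
      post <- subphase_errors(pred1[1:2, , drop = FALSE], targ, labels, rng)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = worst$subject_id,
        subphase = w$subphase,
        pair_id = w$pair_id, pair = pair$label,
        candidate = cand,
        variable = if (cand == "a") pair$var_a else pair$var_b,
        phase = 1:7,
        pre_error = unname(pre), post_error = unname(post),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, skipped = skipped, class = c("manipulation_experiments",
                                              class(out)))
}

# cyclically adjacent sub-phases (LR and TSw are neighbours at the
# stride boundary)
neighbor_phases <- function(s) c((s - 2L) %% 7L + 1L, s %% 7L + 1L)

#' Select the dominant parameter per sub-phase
#'
#' A candidate variable is admissible when substituting it with normal
#' values strictly reduces the error at its own sub-phase and does not
#' worsen either cyclically adjacent sub-phase by more than the relative
#' `tolerance`. Among admissible candidates the one with the lowest
#' post-manipulation own-phase error is dominant; when both lie within
#' `tolerance` (relative) of each other, both are reported (a tie, as
#' when manipulating either parameter yields the same result). When no
#' candidate is admissible the sub-phase gets no parameter ("none") —
#' the mid-swing rule, where manipulation only worsens the neighboring
#' swing phases.
#'
#' @param experiments a `manipulation_experiments` table.
#' @param tolerance relative error-difference tolerance for ties and
#'   neighbor worsening (default 0.05).
#' @return object of class `dominance_result`: data.frame with one row
#'   per evaluated sub-phase (subphase, phase, selected — comma-joined
#'   variable keys or "none", own_pre, own_post) plus a `rationale`
#'   attribute recording each candidate's deltas.
#' @export
select_dominant <- function(experiments, tolerance = 0.05) {
  stopifnot(nrow(experiments) >= 1)
  res <- list()
  rationale <- list()
  for (s in sort(unique(experiments$subphase))) {
    ex <- experiments[experiments$subphase == s, ]
    nbs <- neighbor_phases(s)
    cand <- lapply(split(ex, ex$candidate), function(e) {
      own_pre <- e$pre_error[e$phase == s]
      own_post <- e$post_error[e$phase == s]
      worsens <- vapply(nbs, function(nb) {
        pre <- e$pre_error[e$phase == nb]
        post <- e$post_error[e$phase == nb]
        if (is.na(pre) || is.na(post)) return(FALSE)
        post > pre * (1 + tolerance) + 1e-9
      }, logical(1))
      list(variable = e$variable[1], own_pre = own_pre,
           own_post = own_post,
           improves = isTRUE(own_post < own_pre),
           worsens_neighbor = any(worsens))
    })
    admissible <- Filter(function(cc) cc$improves && !cc$worsens_neighbor,
                         cand)
    if (length(admissible) == 0L) {
      selected <- "none"
      own_post <- NA_real_
    } else {
      posts <- vapply(admissible, function(cc) cc$own_post, numeric(1))
      best <- min(posts)
      tied <- posts <= best * (1 + tolerance) + 1e-9
      sel_vars <- vapply(admissible[tied], function(cc) cc$variable,
                         character(1))
      # report in canonical variable order
      sel_vars <- sel_vars[order(match(sel_vars, GAIT_VARIABLES))]
      selected <- paste(unique(sel_vars), collapse = ",")
      own_post <- best
    }
    res[[length(res) + 1L]] <- data.frame(
      subphase = s, phase = SUBPHASE_NAMES[s], selected = selected,
      own_pre = cand[[1]]$own_pre, own_post = own_post,
      stringsAsFactors = FALSE)
    rationale[[SUBPHASE_NAMES[s]]] <- cand
  }
  out <- do.call(rbind, res)
  structure(out, rationale = rationale,
            class = c("dominance_result", class(out)))
}

#' Restrict a dominance result to knee variables
#'
#' For any sub-phase whose selected variable is a hip or ankle
#' variable, substitutes the knee variable that, among the cyclogram
#' pairs coupling the selected variable with a knee variable, has the
#' lowest Phase-2 mean normalized error at that sub-phase. Knee
#' selections and "none" pass through unchanged. Sub-phases with no
#' evaluable knee-coupled pair are flagged unresolved.
#'
#' @param dominance a `dominance_result`.
#' @param error_table the subject's `subphase_error_table` (Phase-2
#'   errors for all 36 pairs).
#' @param pairs the pair table from `enumerate_pairs()`.
#' @return a `dominance_result` with a `knee_selected` column.
#' @export
restrict_to_knee <- function(dominance, error_table,
                             pairs = enumerate_pairs()) {
  stopifnot(inherits(error_table, "subphase_error_table"))
  em <- error_table$error_matrix
  knee_vars <- paste("knee", GAIT_VARTYPES, sep = "_")
  knee_for <- function(v, s) {
    if (v == "none") return("none")
    if (startsWith(v, "knee_")) return(v)
    ix <- which((pairs$var_a == v & pairs$var_b %in% knee_vars) |
                (pairs$var_b == v & pairs$var_a %in% knee_vars))
    if (length(ix) == 0L) return(NA_character_)
    errs <- em[ix, s]
    if (all(is.na(errs))) return(NA_character_)
    best <- pairs[ix[which.min(errs)], ]
    if (best$var_a %in% knee_vars) best$var_a else best$var_b
  }
  dominance$knee_selected <- vapply(seq_len(nrow(dominance)), function(r) {
    sel <- strsplit(dominance$selected[r], ",", fixed = TRUE)[[1]]
    kn <- vapply(sel, knee_for, character(1), s = dominance$subphase[r])
    if (anyNA(kn)) return(NA_character_)  # unresolved
    kn <- unique(kn[order(match(kn, c(GAIT_VARIABLES, "none")))])
    paste(kn, collapse = ",")
  }, character(1))
  if (anyNA(dominance$knee_selected))
    warning("knee restriction unresolved for sub-phase(s) ",
            paste(dominance$phase[is.na(dominance$knee_selected)],
                  collapse = ", "))
  dominance
}

#' Aggregate per-subject dominance results to a cohort table
#'
#' Majority vote across subjects, per sub-phase and per column
#' (`selected` and, when present, `knee_selected`); all selections tied
#' at the maximal vote count are reported, comma-joined.
#'
#' @param dominance_list list of `dominance_result`s, one per subject.
#' @return data.frame with one row per sub-phase.
#' @export
aggregate_dominance <- function(dominance_list) {
  stopifnot(length(dominance_list) >= 1)
  vote <- function(values) {
    values <- values[!is.na(values)]
    if (length(values) == 0L) return(NA_character_)
    tab <- sort(table(values), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    paste(sort(winners), collapse = " | ")
  }
  has_knee <- all(vapply(dominance_list,
                         function(d) "knee_selected" %in% names(d),
                         logical(1)))
  phases <- sort(unique(unlist(lapply(dominance_list,
                                      function(d) d$subphase))))
  do.call(rbind, lapply(phases, function(s) {
    sel <- vapply(dominance_list, function(d) {
      v <- d$selected[d$subphase == s]
      if (length(v)) v else NA_character_
    }, character(1))
    row <- data.frame(subphase = s, phase = SUBPHASE_NAMES[s],
                      selected = vote(sel), n_subjects = sum(!is.na(sel)),
                      stringsAsFactors = FALSE)
    if (has_knee) {
      kn <- vapply(dominance_list, function(d) {
        v <- d$knee_selected[d$subphase == s]
        if (length(v)) v else NA_character_
      }, character(1))
      row$knee_selected <- vote(kn)
    }
    row
  }))
}
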