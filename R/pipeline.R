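## pipeline: orchestration of the three-stage analysis (generate ->
## reference -> train 36 networks -> disparity -> manipulate -> report)
## with a single seeded configuration governing every stochastic stage.

#' Pipeline configuration
#'
#' A single configuration object governs every stage; the seed is
#' mandatory because every stochastic stage (generation, splits, weight
#' initialization) draws from seeds derived deterministically from it.
#'
#' @param out_dir output directory for tables and reports.
#' @param seed master integer seed (mandatory).
#' @param n_train_subjects normal subjects used to train the networks.
#' @param n_heldout_normal held-out normal subjects scored but not
#'   trained on.
#' @param n_path_subjects named vector: subjects per pathological
#'   cohort.
#' @param n_trials trials per subject (the network arrangement uses 10).
#' @param profiles named list of `cohort_profile`s (normal, orthosis,
#'   transtibial, transfemoral).
#' @param criteria training acceptance criteria, see `train_network()`.
#' @param max_restarts weight reinitialization budget per network.
#' @param tolerance tie/neighbor tolerance for `select_dominant()`.
#' @param side which side's trials enter references and analyses; the
#'   default "left" is the non-dominant side convention.
#' @param manipulate_cohorts cohorts run through Phase 3.
#' @param plots write cyclogram overlay PNGs in `render_report()`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            n_train_subjects = 10L,
                            n_heldout_normal = 5L,
                            n_path_subjects = c(orthosis = 3L,
                                                transtibial = 3L,
                                                transfemoral = 3L),
                            n_trials = 10L,
                            profiles = default_profiles(),
                            criteria = list(max_mse = 0.9, min_r = 0.9,
                                            similarity = 0.5),
                            max_restarts = 10L,
                            tolerance = 0.05,
                            side = "left",
                            manipulate_cohorts = "transfemoral",
                            plots = FALSE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config validation: a seed is mandatory for the pipeline")
  stopifnot(side %in% GAIT_SIDES, n_trials >= 1,
            all(names(n_path_subjects) %in% GAIT_COHORTS))
  if (tolerance <= 0 || max_restarts < 1)
    stop("config validation: thresholds must be positive")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_train_subjects = n_train_subjects,
                 n_heldout_normal = n_heldout_normal,
                 n_path_subjects = n_path_subjects,
                 n_trials = n_trials, profiles = profiles,
                 criteria = criteria, max_restarts = max_restarts,
                 tolerance = tolerance, side = side,
                 manipulate_cohorts = manipulate_cohorts,
                 plots = plots),
            class = "pipeline_config")
}

split_by_subject <- function(trials) {
  split(trials, vapply(trials, function(t) t$subject_id, character(1)))
}

#' Run the full three-phase pipeline
#'
#' Executes, in order: synthetic cohort generation, conventional
#' trial-averaged reference, training of the 36 disparity networks,
#' disparity scoring of every subject (closeness and worst-pair
#' tables), the manipulation stage for the configured cohorts
#' (dominance and knee-restricted dominance), and report rendering.
#' Re-running with the same configuration reproduces identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a results list: `reference`, `networks`,
#'   `closeness` table, `worst` tables, `dominance` per subject,
#'   `dominance_table` / `knee_table` cohort aggregates, and file
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[cyclogait] ", sprintf(...))
  tmpl <- template_bank()
  pairs <- enumerate_pairs()

  ## stage: generate ---------------------------------------------------------
  log_stage("generate: synthetic cohorts (seed %d)", config$seed)
  train_trials <- generate_cohort(config$profiles$normal,
                                  config$n_train_subjects, config$n_trials,
                                  seed = derive_seed(config$seed, 1),
                                  template = tmpl, subject_prefix = "NTR")
  heldout <- if (config$n_heldout_normal > 0)
    generate_cohort(config$profiles$normal, config$n_heldout_normal,
                    config$n_trials, seed = derive_seed(config$seed, 2),
                    template = tmpl, subject_prefix = "NVA")
  else list()
  path_trials <- list()
  for (i in seq_along(config$n_path_subjects)) {
    co <- names(config$n_path_subjects)[i]
    path_trials[[co]] <- generate_cohort(config$profiles[[co]],
                                         config$n_path_subjects[[i]],
                                         config$n_trials,
                                         seed = derive_seed(config$seed, 2 + i),
                                         template = tmpl)
  }
  keep_side <- function(trials)
    Filter(function(t) t$side == config$side, trials)
  train_trials <- keep_side(train_trials)

  ## stage: reference --------------------------------------------------------
  log_stage("reference: averaging %d normal trials", length(train_trials))
  reference <- average_reference(train_trials)

  ## stage: train ------------------------------------------------------------
  log_stage("train: 36 networks on %d subjects", config$n_train_subjects)
  by_subject <- split_by_subject(train_trials)
  networks <- lapply(seq_len(nrow(pairs)), function(i) {
    arrs <- lapply(by_subject, arrange_training, pair = pairs[i, ],
                   reference = reference)
    net <- train_network(arrs, criteria = config$criteria,
                         seed = derive_seed(config$seed, 100, i),
                         max_restarts = config$max_restarts)
    log_stage("train: pair %02d %s accepted=%s restarts=%d", i,
              pairs$label[i], net$report$accepted, net$report$restarts)
    net
  })

  ## stage: disparity --------------------------------------------------------
  subjects <- c(split_by_subject(keep_side(heldout)),
                unlist(lapply(path_trials,
                              function(tr) split_by_subject(keep_side(tr))),
                       recursive = FALSE))
  log_stage("disparity: scoring %d subjects", length(subjects))
  closeness_rows <- list()
  worst_tables <- list()
  for (sid in names(subjects)) {
    trs <- subjects[[sid]]
    sc <- subject_closeness(trs, networks, reference, pairs)
    closeness_rows[[sid]] <- data.frame(subject_id = trs[[1]]$subject_id,
                                        cohort = trs[[1]]$cohort,
                                        C = sc$C, stringsAsFactors = FALSE)
    worst_tables[[sid]] <- worst_pair_table(trs, networks, reference, pairs)
  }
  closeness_table <- do.call(rbind, closeness_rows)
  rownames(closeness_table) <- NULL

  ## stage: manipulate -------------------------------------------------------
  manip_subjects <- names(subjects)[vapply(subjects, function(trs)
    trs[[1]]$cohort %in% config$manipulate_cohorts, logical(1))]
  log_stage("manipulate: %d subject(s) in cohort(s) %s",
            length(manip_subjects),
            paste(config$manipulate_cohorts, collapse = ", "))
  dominance <- list()
  experiments <- list()
  for (sid in manip_subjects) {
    ex <- evaluate_candidates(subjects[[sid]], worst_tables[[sid]],
                              networks, reference, pairs)
    dom <- select_dominant(ex, tolerance = config$tolerance)
    dom <- restrict_to_knee(dom, worst_tables[[sid]], pairs)
    dom$subject_id <- subjects[[sid]][[1]]$subject_id
    experiments[[sid]] <- ex
    dominance[[sid]] <- dom
  }
  dominance_table <- if (length(dominance))
    aggregate_dominance(dominance) else NULL

  results <- list(config = config, reference = reference,
                  networks = networks, pairs = pairs,
                  closeness = closeness_table, worst = worst_tables,
                  experiments = experiments, dominance = dominance,
                  dominance_table = dominance_table,
                  subjects = subjects)

  ## stage: report -----------------------------------------------------------
  log_stage("report: writing to %s", config$out_dir)
  results$files <- render_report(results, config$out_dir,
                                 plots = config$plots)
  invisible(results)
}

#' Render the report bundle
#'
#' Writes the per-cohort closeness range table, the per-subject
#' worst-pair tables, the manipulation experiments, and the dominance
#' tables (full and knee-restricted) as CSV, plus a plain-text summary.
#' Sections whose results are missing are marked "not run" rather than
#' failing. Optional cyclogram overlay plots (subject vs normal
#' reference) are written as PNG.
#'
#' @param results results list from `run_pipeline()` (possibly
#'   partial).
#' @param out_dir output directory.
#' @param plots write overlay PNGs for the first manipulated subject.
#' @return named character vector of written file paths.
#' @export
render_report <- function(results, out_dir, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  summary_lines <- c("cyclogait pipeline report", "=========================")

  if (!is.null(results$closeness) && nrow(results$closeness)) {
    agg <- do.call(rbind, lapply(split(results$closeness,
                                       results$closeness$cohort),
                                 function(g)
      data.frame(cohort = g$cohort[1], n_subjects = nrow(g),
                 C_min = min(g$C), C_median = stats::median(g$C),
                 C_max = max(g$C), stringsAsFactors = FALSE)))
    agg <- agg[order(match(agg$cohort, GAIT_COHORTS)), ]
    rownames(agg) <- NULL
    p <- file.path(out_dir, "closeness_by_cohort.csv")
    utils::write.csv(agg, p, row.names = FALSE)
    files["closeness_by_cohort"] <- p
    p <- file.path(out_dir, "closeness_by_subject.csv")
    utils::write.csv(results$closeness, p, row.names = FALSE)
    files["closeness_by_subject"] <- p
    summary_lines <- c(summary_lines, "",
                       "Closeness C by cohort (min-median-max %):",
                       sprintf("  %-12s n=%2d  %5.1f  %5.1f  %5.1f",
                               agg$cohort, agg$n_subjects, agg$C_min,
                               agg$C_median, agg$C_max))
  } else summary_lines <- c(summary_lines, "", "Closeness: not run")

  if (length(results$worst)) {
    worst_all <- do.call(rbind, lapply(names(results$worst), function(sid) {
      w <- results$worst[[sid]]$worst
      w$subject_id <- results$worst[[sid]]$subject_id
      w
    }))
    p <- file.path(out_dir, "worst_pairs.csv")
    utils::write.csv(worst_all, p, row.names = FALSE)
    files["worst_pairs"] <- p
    summary_lines <- c(summary_lines, "",
                       sprintf("Worst-pair tables: %d subject(s), 36 pairs each",
                               length(results$worst)))
  } else summary_lines <- c(summary_lines, "", "Worst-pair tables: not run")

  if (length(results$experiments)) {
    ex_all <- do.call(rbind, results$experiments)
    p <- file.path(out_dir, "manipulation_experiments.csv")
    utils::write.csv(ex_all, p, row.names = FALSE)
    files["experiments"] <- p
  }

  if (!is.null(results$dominance_table)) {
    p <- file.path(out_dir, "dominance.csv")
    utils::write.csv(results$dominance_table, p, row.names = FALSE)
    files["dominance"] <- p
    summary_lines <- c(summary_lines, "", "Dominant parameters per sub-phase:",
                       sprintf("  %-4s full: %-28s knee-only: %s",
                               results$dominance_table$phase,
                               results$dominance_table$selected,
                               if (!is.null(results$dominance_table$knee_selected))
                                 results$dominance_table$knee_selected
                               else "-"))
  } else summary_lines <- c(summary_lines, "", "Dominance: not run")

  if (!is.null(results$networks)) {
    acc <- vapply(results$networks, function(n) n$report$accepted, logical(1))
    summary_lines <- c(summary_lines, "",
                       sprintf("Trained networks: %d (%d accepted)",
                               length(acc), sum(acc)))
  }

  if (isTRUE(plots) && length(results$subjects) && !is.null(results$reference))
    files["overlays"] <- plot_cyclogram_overlays(results, out_dir)

  p <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, p)
  files["summary"] <- p
  files
}

# Overlay of a subject's mean cyclogram vs the normal reference for a
# few representative pairs; diagnostic artifact only.
plot_cyclogram_overlays <- function(results, out_dir) {
  sid <- names(results$subjects)[1]
  trs <- results$subjects[[sid]]
  ref <- results$reference
  sel <- results$pairs[c(1, 10, 30), ]
  p <- file.path(out_dir, "cyclogram_overlays.png")
  grDevices::png(p, width = 1200, height = 400)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, nrow(sel)))
  for (i in seq_len(nrow(sel))) {
    pr <- sel[i, ]
    a <- rowMeans(vapply(trs, function(t) t$series[[pr$var_a]], numeric(50)))
    b <- rowMeans(vapply(trs, function(t) t$series[[pr$var_b]], numeric(50)))
    graphics::plot(c(ref$mean[[pr$var_a]], ref$mean[[pr$var_a]][1]),
                   c(ref$mean[[pr$var_b]], ref$mean[[pr$var_b]][1]),
                   type = "l", col = "grey40", lwd = 2,
                   xlab = pr$var_a, ylab = pr$var_b, main = pr$label)
    graphics::lines(c(a, a[1]), c(b, b[1]), col = "firebrick")
  }
  p
}
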