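# Phase-3 engine: substitution locality and idempotence, candidate
# evaluation, dominance selection, knee restriction.

test_that("normal-value substitution is local and idempotent", {
  bank <- fx_bank()
  pr <- bank$pairs[bank$pairs$label == "knee_angle~knee_power", ]
  trs <- generate_cohort(default_profiles()$transfemoral, 1, 10, seed = 55)
  mod <- substitute_normal(trs, pr, "b", subphase = 1, bank$reference)
  for (i in seq_along(trs)) {
    ix <- trs[[i]]$subphase == 1
    # substituted variable replaced at labeled samples only
    expect_equal(mod[[i]]$series$knee_power[ix],
                 bank$reference$mean$knee_power[ix])
    expect_identical(mod[[i]]$series$knee_power[!ix],
                     trs[[i]]$series$knee_power[!ix])
    # every other series untouched
    for (k in setdiff(GAIT_VARIABLES, "knee_power"))
      expect_identical(mod[[i]]$series[[k]], trs[[i]]$series[[k]])
  }
  twice <- substitute_normal(mod, pr, "b", subphase = 1, bank$reference)
  expect_identical(twice, mod)
})

test_that("substitution on an already-normal subject barely changes own-phase error", {
  bank <- fx_bank()
  trs <- generate_cohort(default_profiles()$normal, 1, 10, seed = 66)
  wt <- worst_pair_table(trs, bank$networks, bank$reference, bank$pairs)
  ex <- evaluate_candidates(trs, wt, bank$networks, bank$reference,
                            bank$pairs)
  own <- ex[ex$phase == ex$subphase, ]
  expect_true(all(abs(own$post_error - own$pre_error) < 5))
})

test_that("candidate evaluation runs two experiments per phase with a shared baseline", {
  bank <- fx_bank()
  trs <- generate_cohort(fx_planted_profile(), 1, 10, seed = 77)
  wt <- worst_pair_table(trs, bank$networks, bank$reference, bank$pairs)
  ex <- evaluate_candidates(trs, wt, bank$networks, bank$reference,
                            bank$pairs)
  for (s in unique(ex$subphase)) {
    es <- ex[ex$subphase == s, ]
    expect_setequal(es$candidate, c("a", "b"))
    expect_equal(nrow(es), 14)  # 2 candidates x 7 phases
    # both experiments share identical pre-errors
    expect_equal(es$pre_error[es$candidate == "a"],
                 es$pre_error[es$candidate == "b"])
  }
  # post-errors equal an independent recomputation through the module
  s <- 1
  w <- wt$worst[wt$worst$subphase == s, ]
  pr <- bank$pairs[bank$pairs$pair_id == w$pair_id, ]
  mod <- substitute_normal(trs, pr, "a", s, bank$reference)
  pred <- simulate_network(bank$networks[[w$pair_id]], mod, pr,
                           bank$reference)
  tgt <- fx_pair_target(bank$reference, pr)
  post <- subphase_errors(pred[1:2, ], tgt$curves, bank$reference$subphase,
                          tgt$ranges)
  got <- ex$post_error[ex$subphase == s & ex$candidate == "a"]
  expect_equal(got, unname(post), tolerance = 1e-12)
})

test_that("substituting the planted variable strictly reduces own-phase error", {
  bank <- fx_bank()
  pr <- bank$pairs[bank$pairs$label == "knee_angle~knee_power", ]
  hits <- 0
  for (s in 1:10) {
    trs <- generate_cohort(fx_planted_profile("knee_power", "LR", 0.2),
                           1, 10, seed = 900 + s)
    tgt <- fx_pair_target(bank$reference, pr)
    net <- bank$networks[[pr$pair_id]]
    pre <- subphase_errors(simulate_network(net, trs, pr,
                                            bank$reference)[1:2, ],
                           tgt$curves, bank$reference$subphase, tgt$ranges)
    mod <- substitute_normal(trs, pr, "b", 1, bank$reference)
    post <- subphase_errors(simulate_network(net, mod, pr,
                                             bank$reference)[1:2, ],
                            tgt$curves, bank$reference$subphase, tgt$ranges)
    if (post[["LR"]] < pre[["LR"]]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("substituting both variables is at least as corrective as either alone", {
  bank <- fx_bank()
  pr <- bank$pairs[bank$pairs$label == "knee_angle~knee_power", ]
  sc <- matrix(1, 9, 7, dimnames = list(GAIT_VARIABLES, SUBPHASE_NAMES))
  sc["knee_power", "LR"] <- 0.3
  sc["knee_angle", "LR"] <- 0.5
  prof <- cohort_profile("transfemoral", scale = sc, subphase_jitter_sd = 0,
                         trial_noise_sd = 0.02, subject_offset_sd = 0.02)
  trs <- generate_cohort(prof, 1, 10, seed = 42)
  tgt <- fx_pair_target(bank$reference, pr)
  net <- bank$networks[[pr$pair_id]]
  own_err <- function(trials) {
    p <- simulate_network(net, trials, pr, bank$reference)
    subphase_errors(p[1:2, ], tgt$curves, bank$reference$subphase,
                    tgt$ranges)[["LR"]]
  }
  e_a <- own_err(substitute_normal(trs, pr, "a", 1, bank$reference))
  e_b <- own_err(substitute_normal(trs, pr, "b", 1, bank$reference))
  both <- substitute_normal(substitute_normal(trs, pr, "a", 1,
                                              bank$reference),
                            pr, "b", 1, bank$reference)
  expect_lte(own_err(both), min(e_a, e_b) + 1e-9)
})

test_that("dominance selection implements argmin, ties and the no-parameter rule", {
  mk_exp <- function(subphase, post_a, post_b, pre = rep(10, 7),
                     post_rest_a = pre, post_rest_b = pre) {
    rbind(
      data.frame(subject_id = "S", subphase = subphase, pair_id = 1,
                 pair = "ankle_angle~knee_angle", candidate = "a",
                 variable = "ankle_angle", phase = 1:7,
                 pre_error = pre,
                 post_error = replace(post_rest_a, subphase, post_a)),
      data.frame(subject_id = "S", subphase = subphase, pair_id = 1,
                 pair = "ankle_angle~knee_angle", candidate = "b",
                 variable = "knee_angle", phase = 1:7,
                 pre_error = pre,
                 post_error = replace(post_rest_b, subphase, post_b)))
  }
  # clear argmin
  dom <- select_dominant(mk_exp(2, post_a = 1, post_b = 6), tolerance = 0.02)
  expect_equal(dom$selected, "ankle_angle")
  # near-tie within tolerance: both reported, canonical order
  dom2 <- select_dominant(mk_exp(2, post_a = 5.00, post_b = 5.05),
                          tolerance = 0.02)
  expect_equal(dom2$selected, "ankle_angle,knee_angle")
  # neither candidate improves own phase -> none
  dom3 <- select_dominant(mk_exp(6, post_a = 12, post_b = 11))
  expect_equal(dom3$selected, "none")
  # both improve own phase but worsen a neighboring phase -> none
  worse_nb <- rep(10, 7); worse_nb[5] <- 20   # ISw neighbours MSw
  dom4 <- select_dominant(mk_exp(6, post_a = 2, post_b = 3,
                                 post_rest_a = worse_nb,
                                 post_rest_b = worse_nb))
  expect_equal(dom4$selected, "none")
  # neighbors wrap cyclically: TSw neighbours are MSw and LR
  worse_lr <- rep(10, 7); worse_lr[1] <- 20
  dom5 <- select_dominant(mk_exp(7, post_a = 2, post_b = 3,
                                 post_rest_a = worse_lr,
                                 post_rest_b = worse_lr))
  expect_equal(dom5$selected, "none")
})

test_that("the knee restriction substitutes the best knee-coupled variable", {
  bank <- fx_bank()
  trs <- generate_cohort(fx_planted_profile("knee_power", "LR", 0.2),
                         1, 10, seed = 321)
  wt <- worst_pair_table(trs, bank$networks, bank$reference, bank$pairs)
  ex <- evaluate_candidates(trs, wt, bank$networks, bank$reference,
                            bank$pairs)
  dom <- select_dominant(ex)
  domk <- restrict_to_knee(dom, wt, bank$pairs)
  # knee selections and "none" pass through unchanged
  for (r in seq_len(nrow(domk))) {
    sel <- strsplit(domk$selected[r], ",", fixed = TRUE)[[1]]
    if (all(startsWith(sel, "knee_")) || identical(sel, "none"))
      expect_identical(domk$knee_selected[r], domk$selected[r])
    else
      expect_true(all(startsWith(
        strsplit(domk$knee_selected[r], ",", fixed = TRUE)[[1]], "knee_")))
  }
  # constructed check: hip-angle selection maps to the knee variable of
  # its lowest-error knee-coupled pair at that phase
  dom_fake <- dom[1, , drop = FALSE]
  dom_fake$subphase <- 5L
  dom_fake$selected <- "hip_angle"
  domf <- restrict_to_knee(dom_fake, wt, bank$pairs)
  knee_vars <- paste("knee", GAIT_VARTYPES, sep = "_")
  ix <- which((bank$pairs$var_a == "hip_angle" &
               bank$pairs$var_b %in% knee_vars) |
              (bank$pairs$var_b == "hip_angle" &
               bank$pairs$var_a %in% knee_vars))
  best <- bank$pairs[ix[which.min(wt$error_matrix[ix, 5])], ]
  expected <- if (best$var_a %in% knee_vars) best$var_a else best$var_b
  expect_equal(domf$knee_selected, expected)
})

test_that("cohort aggregation takes a per-phase majority vote", {
  mk_dom <- function(sel) {
    structure(data.frame(subphase = 1:2, phase = SUBPHASE_NAMES[1:2],
                         selected = sel, own_pre = 1, own_post = 0.5,
                         stringsAsFactors = FALSE),
              class = c("dominance_result", "data.frame"))
  }
  agg <- aggregate_dominance(list(mk_dom(c("knee_power", "none")),
                                  mk_dom(c("knee_power", "hip_angle")),
                                  mk_dom(c("ankle_angle", "hip_angle"))))
  expect_equal(agg$selected[agg$subphase == 1], "knee_power")
  expect_equal(agg$selected[agg$subphase == 2], "hip_angle")
  # ties reported together
  agg2 <- aggregate_dominance(list(mk_dom(c("knee_power", "none")),
                                   mk_dom(c("ankle_angle", "none"))))
  expect_equal(agg2$selected[agg2$subphase == 1], "ankle_angle | knee_power")
})

test_that("end-to-end planted deficits are recovered as dominant in >= 80% of seeds", {
  bank <- fx_bank()
  hits <- 0
  for (s in 1:20) {
    trs <- generate_cohort(fx_planted_profile("knee_power", "LR", 0.2),
                           1, 10, seed = 7000 + s)
    wt <- worst_pair_table(trs, bank$networks, bank$reference, bank$pairs)
    ex <- evaluate_candidates(trs, wt, bank$networks, bank$reference,
                              bank$pairs)
    dom <- select_dominant(ex)
    sel <- dom$selected[dom$subphase == 1]
    if (length(sel) == 1 && grepl("knee_power", sel, fixed = TRUE))
      hits <- hits + 1
  }
  expect_gte(hits, 16)
})
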