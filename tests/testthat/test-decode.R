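test_that("null simulation decodes at chance for all label types", {
  ep <- fix_null_epochs()
  tc2 <- decode_timecourse(ep, "animacy", "intact")
  tc4 <- decode_timecourse(ep, "category", "intact")
  expect_equal(tc2$chance_level, 0.5)
  expect_equal(tc4$chance_level, 0.25)
  # binomial sampling error of the mean over timepoints
  expect_lt(abs(mean(tc2$accuracy) - 0.5), 0.02)
  expect_lt(abs(mean(tc4$accuracy) - 0.25), 0.02)
  expect_true(all(tc2$accuracy >= 0 & tc2$accuracy <= 1))
})

test_that("52-way identity decoding is at 1/52 chance on null data", {
  ep <- fix_null_epochs()
  tc <- decode_timecourse(ep, "stim_id", "silhouette")
  expect_equal(tc$chance_level, 1 / 52)
  expect_lt(abs(mean(tc$accuracy) - 1 / 52), 0.01)
})

test_that("filter_medians drops exactly the median stimuli", {
  ep <- fix_epochs()
  n0 <- nrow(ep$trials)
  epf <- filter_medians(ep)
  expect_equal(nrow(epf$trials), n0 * 48 / 52)
  expect_false(any(epf$trials$shape_class == "median"))
  expect_equal(nrow(filter_medians(epf)$trials), nrow(epf$trials))
  expect_error(decode_timecourse(ep, "shape_class", "intact"),
               "filter_medians")
})

test_that("a class missing from a training fold names the held-out run", {
  ep <- fix_null_epochs()
  ep <- subset_epochs(ep, ep$trials$rendering == "intact")
  # make class 'animate' exist only in run 1: training without run 1 works,
  # but training folds that exclude other runs lose nothing; instead drop
  # 'animate' everywhere except run 1 so folds excluding run 1 lack it
  keep <- ep$trials$animacy == "inanimate" | ep$trials$run == 1
  ep2 <- subset_epochs(ep, keep)
  expect_error(decode_timecourse(ep2, "animacy"), "run")
})

test_that("parameter recovery: decoding peaks at the injected latency", {
  ep <- fix_epochs()
  epf <- filter_medians(ep)
  tc <- decode_timecourse(epf, "shape_class", "silhouette")
  peak <- tc$times_ms[which.max(tc$accuracy)]
  expect_lte(abs(peak - 95), 10)
})

test_that("leave-one-run-out results are invariant to run relabeling", {
  ep <- fix_null_epochs()
  ep <- subset_epochs(ep, ep$trials$rendering == "intact")
  ep$data <- ep$data[, , 1:5]
  ep$times_ms <- ep$times_ms[1:5]
  tc1 <- decode_timecourse(ep, "animacy")
  # permute run identities (relabel only; trial order unchanged)
  runs <- sort(unique(ep$trials$run))
  perm <- setNames(rev(runs), runs)
  ep2 <- ep
  ep2$trials$run <- perm[as.character(ep$trials$run)]
  tc2 <- decode_timecourse(ep2, "animacy")
  expect_equal(sort(tc1$accuracy), sort(tc2$accuracy), tolerance = 1e-12)
  expect_equal(mean(tc1$accuracy), mean(tc2$accuracy), tolerance = 1e-12)
})

test_that("temporal generalization diagonal equals the decoding timecourse", {
  ep <- fix_epochs()
  ep <- subset_epochs(ep, ep$trials$rendering == "intact")
  ep$data <- ep$data[, , seq(1, 181, by = 12)]
  ep$times_ms <- ep$times_ms[seq(1, 181, by = 12)]
  tg <- temporal_generalization(ep, "animacy")
  tc <- decode_timecourse(ep, "animacy")
  expect_identical(unname(diag(tg$accuracy)), tc$accuracy)
})

test_that("a sustained code generalizes off-diagonal; a flipped one dips below chance", {
  spec <- null_effect_spec()
  spec$animacy$amplitude[] <- c(1.2, 1.2)
  spec$animacy$peak_ms <- 120
  spec$animacy$duration_ms <- 60
  spec$animacy$sustained_fraction <- 1  # constant plateau after peak
  ep <- simulate_subject(fix_design(), fix_set(), spec, subject_seed = 41L)
  ep <- subset_epochs(ep, ep$trials$rendering == "intact")
  sel <- ep$times_ms %in% seq(-100, 800, by = 20)
  ep$data <- ep$data[, , sel]; ep$times_ms <- ep$times_ms[sel]
  tg <- temporal_generalization(ep, "animacy")
  t_train <- which(tg$times_ms == 160)
  t_test <- which(tg$times_ms == 400)
  expect_gt(tg$accuracy[t_train, t_test], 0.6)   # sustained block
  # now let the topography reverse sign at 300 ms
  spec$animacy$flip_ms <- 300
  epf <- simulate_subject(fix_design(), fix_set(), spec, subject_seed = 41L)
  epf <- subset_epochs(epf, epf$trials$rendering == "intact")
  epf$data <- epf$data[, , sel]; epf$times_ms <- epf$times_ms[sel]
  tgf <- temporal_generalization(epf, "animacy")
  expect_lt(tgf$accuracy[t_train, t_test], 0.4)  # below chance
  expect_gt(tgf$accuracy[t_train, t_train], 0.6) # diagonal unaffected
})

test_that("cross-decoding generalizes with shared topography, not with orthogonal", {
  base <- null_effect_spec()
  base$aspect_ratio$amplitude[] <- c(2.0, 2.0)
  ep_shared <- simulate_subject(fix_design(), fix_set(), base,
                                subject_seed = 51L)
  epf <- filter_medians(subset_epochs(ep_shared,
                                      ep_shared$trials$rendering == "intact"))
  within <- decode_timecourse(epf, "shape_class")
  xs <- cross_decode(epf, "shape_class", "animacy")
  i95 <- which(xs$times_ms == 95)
  expect_gt(xs$accuracy[i95], 0.9)
  expect_lt(abs(xs$accuracy[i95] - within$accuracy[i95]), 0.05)

  orth <- base
  orth$aspect_ratio$amplitude[] <- c(1.0, 1.0)
  orth$ar_topography_by_animacy <- TRUE
  ep_orth <- simulate_subject(fix_design(), fix_set(), orth,
                              subject_seed = 51L)
  epo <- filter_medians(subset_epochs(ep_orth,
                                      ep_orth$trials$rendering == "intact"))
  xo <- cross_decode(epo, "shape_class", "animacy")
  expect_lt(abs(xo$accuracy[i95] - 0.5), 0.1)
  # within-class decoding still works in the orthogonal regime
  wo <- decode_timecourse(epo, "shape_class")
  expect_gt(wo$accuracy[i95], 0.8)
  expect_gt(wo$accuracy[i95] - xo$accuracy[i95], 0.25)
})

test_that("cross-decoding validates its dimension arguments", {
  ep <- filter_medians(fix_null_epochs())
  expect_error(cross_decode(ep, "animacy", "animacy"), "distinct")
  expect_error(cross_decode(ep, "category", "animacy"), "distinct|members")
})
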