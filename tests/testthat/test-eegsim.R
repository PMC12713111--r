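test_that("sensor layout is a valid 64-channel 10-10 arrangement", {
  lay <- make_layout()
  expect_equal(nrow(lay), 64L)
  expect_false(anyDuplicated(lay$name) > 0)
  expect_true(all(c("Oz", "Cz", "Fpz", "T7", "T8", "Iz") %in% lay$name))
  # Oz's nearest neighbors are all posterior channels
  D <- as.matrix(dist(cbind(lay$x, lay$y)))
  oz <- which(lay$name == "Oz")
  nn <- lay$name[order(D[oz, ])][2:4]
  expect_true(all(grepl("^(O|PO|P|I)", nn)))
})

test_that("searchlight neighborhoods have size 4 and contain their center", {
  lay <- make_layout()
  nb <- sensor_neighborhoods(lay, 4L)
  expect_length(nb, 64L)
  for (i in seq_along(nb)) {
    expect_length(nb[[i]], 4L)
    expect_true(i %in% nb[[i]])
  }
  expect_error(sensor_neighborhoods(lay, 65L), "exceeds channel count")
})

test_that("epochs meet the preprocessing output contract", {
  ep <- fix_null_epochs()
  expect_equal(dim(ep$data)[2:3], c(64L, 181L))
  expect_equal(ep$times_ms, seq(-100, 800, by = 5))
  expect_equal(ep$sample_rate_hz, 200)
  expect_equal(nrow(ep$trials), dim(ep$data)[1])
  base <- ep$times_ms <= 0
  expect_lt(max(abs(rowMeans(ep$data[, , base], dims = 2L))), 1e-10)
})

test_that("simulation is deterministic per subject seed", {
  a <- simulate_subject(fix_design(), fix_set(), subject_seed = 33L)
  b <- simulate_subject(fix_design(), fix_set(), subject_seed = 33L)
  expect_identical(a$data, b$data)
  expect_identical(a$trials, b$trials)
})

test_that("injected aspect-ratio effect peaks at its specified latency", {
  spec <- null_effect_spec()
  spec$aspect_ratio$amplitude[] <- c(5, 5)  # strong, noise-dominating
  ep <- simulate_subject(fix_design(), fix_set(), spec,
                         subject_seed = 21L)
  tr <- ep$trials
  d_stub <- colMeans(ep$data[tr$shape_class == "stubby", , ], dims = 1L)
  d_spik <- colMeans(ep$data[tr$shape_class == "spiky", , ], dims = 1L)
  contrast <- sqrt(colSums((d_spik - d_stub)^2))  # channel-norm per time
  peak <- ep$times_ms[which.max(contrast)]
  expect_lte(abs(peak - spec$aspect_ratio$peak_ms), 10)
})

test_that("default effect spec encodes the expected dynamics", {
  spec <- default_effect_spec()
  expect_lt(spec$aspect_ratio$peak_ms, spec$animacy$peak_ms)
  expect_lt(spec$animacy$peak_ms, spec$category$peak_ms)
  expect_gt(spec$aspect_ratio$amplitude["silhouette"],
            spec$aspect_ratio$amplitude["intact"])
  expect_gt(spec$animacy$amplitude["intact"],
            spec$animacy$amplitude["silhouette"])
  expect_gt(spec$category$amplitude["intact"],
            spec$category$amplitude["silhouette"])
})

test_that("effect latencies outside the epoch window are rejected", {
  spec <- default_effect_spec()
  bad <- unclass(spec)
  bad$animacy$peak_ms <- 900
  expect_error(do.call(effect_spec, bad[c("aspect_ratio", "animacy",
                                          "category", "identity")]),
               "outside the epoch window")
})

test_that("decoding peak accuracy is nondecreasing in effect amplitude", {
  peaks <- vapply(c(0, 0.3, 1.5), function(a) {
    spec <- null_effect_spec()
    spec$animacy$amplitude[] <- c(a, a)
    ep <- simulate_subject(fix_design(), fix_set(), spec,
                           subject_seed = 77L)
    max(decode_timecourse(ep, "animacy", "intact")$accuracy)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("epoch containers round-trip through disk", {
  ep <- fix_null_epochs()
  path <- file.path(withr::local_tempdir(), "ep")
  save_epochs(ep, path)
  back <- load_epochs(path)
  expect_identical(back$data, ep$data)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_channels, 64L)
  # external-array adapter accepts the same shape
  ext <- as_epochs(ep$data, ep$trials)
  expect_s3_class(ext, "epochs_data")
  expect_error(as_epochs(ep$data[, 1:10, ], ep$trials), "nrow")
})
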