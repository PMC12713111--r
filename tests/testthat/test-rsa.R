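test_that("pairwise decoding produces a valid symmetric RDM series", {
  ep <- fix_null_epochs()
  rdm <- pairwise_decode(ep, "intact", times = c(0, 100, 200))
  D <- rdm$dissimilarity
  expect_equal(dim(D), c(3L, 52L, 52L))
  for (t in 1:3) {
    expect_identical(D[t, , ], t(D[t, , ]))
    expect_true(all(diag(D[t, , ]) == 0))
    off <- D[t, , ][lower.tri(D[t, , ])]
    expect_true(all(off >= 0 & off <= 1))
    # chance on null data, allowing the mild pessimistic bias of
    # cross-validation at 16 trials per pair
    expect_lt(abs(mean(off) - 0.5), 0.05)
  }
})

test_that("identity effects raise pairwise decodability at the effect latency", {
  spec <- null_effect_spec()
  spec$identity$amplitude[] <- c(8, 8)
  ep <- simulate_subject(fix_design(), fix_set(), spec, subject_seed = 71L)
  rdm <- pairwise_decode(ep, "intact", times = c(-50, 110))
  off <- function(t) {
    m <- rdm$dissimilarity[t, , ]
    mean(m[lower.tri(m)])
  }
  expect_lt(abs(off(1) - 0.5), 0.05)  # pre-stimulus at chance
  expect_gt(off(2), 0.7)              # strong at the injected latency
  expect_gt(off(2) - off(1), 0.2)
})

test_that("binary model RDMs follow the same/different coding", {
  set <- fix_set()
  m <- set$meta
  ar <- model_rdm(set, "aspect_ratio")$dissimilarity
  two_spiky <- which(m$shape_class == "spiky")[1:2]
  stub_spik <- c(which(m$shape_class == "stubby")[1],
                 which(m$shape_class == "spiky")[1])
  expect_equal(ar[two_spiky[1], two_spiky[2]], 0)
  expect_equal(ar[stub_spik[1], stub_spik[2]], 1)
  expect_true(all(ar %in% c(0, 1)))
  ca <- model_rdm(set, "category")$dissimilarity
  faces <- which(m$category == "face")[1:2]
  fb <- c(which(m$category == "face")[1], which(m$category == "body")[1])
  expect_equal(ca[faces[1], faces[2]], 0)
  expect_equal(ca[fb[1], fb[2]], 1)
  an <- model_rdm(set, "animacy")$dissimilarity
  expect_equal(sum(an), 2 * 26 * 26)  # 26 animate x 26 inanimate pairs
  # medians are folded into a side by their continuous aspect ratio
  med <- which(m$shape_class == "median")
  expect_true(all(rowSums(ar[med, , drop = FALSE] == 0) > 1))
})

test_that("pixel RDM equals the set-arithmetic Jaccard oracle", {
  set <- fix_set()
  px <- pixel_rdm(set, "silhouette")$dissimilarity
  ids <- c(1, 14, 27, 40, 52)
  for (i in ids) for (j in ids) {
    a <- set$masks[[i]]; b <- set$masks[[j]]
    expect_equal(px[i, j], 1 - sum(a & b) / sum(a | b))
  }
  expect_true(all(diag(px) == 0))
  # hand-built masks: 100 px each, 50 shared -> 1 - 50/150 = 2/3
  A <- matrix(FALSE, 20, 20); A[1:10, 1:10] <- TRUE
  B <- matrix(FALSE, 20, 20); B[6:15, 1:10] <- TRUE
  expect_equal(jaccard_distance(A, B), 2 / 3)
  expect_equal(jaccard_distance(A, A), 0)
  Cm <- matrix(FALSE, 20, 20); Cm[15:20, 15:20] <- TRUE
  expect_equal(jaccard_distance(A, Cm), 1)
  expect_error(jaccard_distance(A, matrix(FALSE, 20, 20)), "blank")
})

test_that("intensity-binned intact pixel model differs from the mask model", {
  set <- fix_set()
  mask_model <- pixel_rdm(set, "intact")
  int_model <- pixel_rdm(set, "intact", intensity_levels = 4)
  expect_identical(mask_model$dissimilarity,
                   pixel_rdm(set, "silhouette")$dissimilarity)
  expect_gt(mean(int_model$dissimilarity), mean(mask_model$dissimilarity))
})

test_that("RDM regression recovers exact and noisy model mixtures", {
  set <- fix_set()
  models <- list(aspect_ratio = model_rdm(set, "aspect_ratio"),
                 category = model_rdm(set, "category"),
                 pixel = pixel_rdm(set, "silhouette"))
  # exact copy of one regressor -> beta 1 on the raw (non-z-scored) scale
  neural <- list(dissimilarity = array(models$aspect_ratio$dissimilarity,
                                       dim = c(1, 52, 52)),
                 times_ms = 0, stimulus_ids = 1:52, rendering = "intact")
  class(neural) <- "rdm_series"
  bs <- fit_rdm_glm(neural, models, zscore = FALSE)
  expect_equal(unname(bs$betas[1, ]), c(1, 0, 0), tolerance = 1e-8)
  # known mixture with weak noise -> recovered within 0.05
  set.seed(5)
  truth <- 0.6 * models$category$dissimilarity +
    0.3 * models$pixel$dissimilarity
  noise <- matrix(rnorm(52 * 52, sd = 0.01), 52)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  neural$dissimilarity <- array(truth + noise, dim = c(1, 52, 52))
  bs2 <- fit_rdm_glm(neural, models[c("category", "pixel")], zscore = FALSE)
  expect_lt(abs(bs2$betas[1, "category"] - 0.6), 0.05)
  expect_lt(abs(bs2$betas[1, "pixel"] - 0.3), 0.05)
})

test_that("pure-noise RDM betas match OLS sampling theory", {
  set <- fix_set()
  models <- list(aspect_ratio = model_rdm(set, "aspect_ratio"))
  lt <- lower.tri(matrix(0, 52, 52))
  x <- models$aspect_ratio$dissimilarity[lt]
  sigma <- 0.05
  # analytic sd of the slope under iid noise
  slope_sd <- sigma / sqrt(sum((x - mean(x))^2))
  set.seed(9)
  betas <- replicate(100, {
    m <- matrix(rnorm(52 * 52, sd = sigma), 52)
    m <- (m + t(m)) / 2; diag(m) <- 0
    # symmetrizing averages two iid draws -> halves the variance
    neural <- structure(list(dissimilarity = array(m, c(1, 52, 52)),
                             times_ms = 0, stimulus_ids = 1:52,
                             rendering = "intact"), class = "rdm_series")
    fit_rdm_glm(neural, models, zscore = FALSE)$betas[1, 1]
  })
  expect_lt(abs(mean(betas)), 3 * slope_sd / sqrt(100))
  expect_lt(abs(sd(betas) / (slope_sd / sqrt(2)) - 1), 0.35)
})

test_that("betas are invariant to stimulus reordering", {
  ep <- fix_epochs()
  rdm <- pairwise_decode(ep, "silhouette", times = c(100, 150))
  set <- fix_set()
  models <- list(aspect_ratio = model_rdm(set, "aspect_ratio"),
                 pixel = pixel_rdm(set, "silhouette"))
  b1 <- fit_rdm_glm(rdm, models)
  perm <- sample(52)
  rdm2 <- rdm
  rdm2$dissimilarity <- rdm$dissimilarity[, perm, perm, drop = FALSE]
  rdm2$stimulus_ids <- rdm$stimulus_ids[perm]
  models2 <- lapply(models, function(m) {
    m$dissimilarity <- m$dissimilarity[perm, perm]
    m
  })
  b2 <- fit_rdm_glm(rdm2, models2)
  expect_equal(b1$betas, b2$betas, tolerance = 1e-10)
})

test_that("a single binary model's raw beta is the same/different mean gap", {
  ep <- fix_epochs()
  rdm <- pairwise_decode(ep, "silhouette", times = 100)
  set <- fix_set()
  mod <- model_rdm(set, "animacy")
  b <- fit_rdm_glm(rdm, list(animacy = mod), zscore = FALSE)
  lt <- lower.tri(matrix(0, 52, 52))
  d <- rdm$dissimilarity[1, , ][lt]
  x <- mod$dissimilarity[lt]
  expect_equal(unname(b$betas[1, 1]), mean(d[x == 1]) - mean(d[x == 0]),
               tolerance = 1e-10)
})

test_that("collinear model sets are rejected, near-collinear ones are not", {
  set <- fix_set()
  ar <- model_rdm(set, "aspect_ratio")
  models <- list(aspect_ratio = ar, dup = ar)
  rdm <- structure(list(dissimilarity = array(0.5, c(1, 52, 52)),
                        times_ms = 0, stimulus_ids = 1:52,
                        rendering = "intact"), class = "rdm_series")
  expect_error(fit_rdm_glm(rdm, models), "collinear")
  # pixel and aspect-ratio models are correlated but full-rank
  px <- pixel_rdm(set, "silhouette")
  lt <- lower.tri(matrix(0, 52, 52))
  r <- cor(ar$dissimilarity[lt], px$dissimilarity[lt])
  expect_gt(r, 0.1)
  expect_lt(r, 0.95)
  expect_silent(fit_rdm_glm(rdm, list(aspect_ratio = ar, pixel = px)))
})
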