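#' Simulate one subject's RSVP epoch data
#'
#' Generates 64-channel epochs (-100 to 800 ms at 200 Hz, 181 samples)
#' for every non-target presentation in the design, both renderings. Per
#' trial the signal is the sum over object-space dimensions of
#' `amplitude(rendering) x temporal kernel x topography x condition
#' contrast` (aspect ratio: stubby -1 / spiky +1 / median 0; animacy:
#' animate +1 / inanimate -1; category: one of four zero-sum patterns;
#' identity: a low-amplitude per-stimulus pattern), scaled by a log-normal
#' per-trial gain. Noise is Gaussian, spatially correlated across
#' channels (squared-exponential kernel over layout distances) and
#' temporally smoothed (variance-preserving Gaussian kernel). Epochs are
#' finally baseline-demeaned over -100..0 ms per trial and channel.
#' Everything is deterministic given `subject_seed`.
#'
#' @param design an [build_design()] result.
#' @param stimulus_set the matching stimulus set.
#' @param spec an [effect_spec()] (default [default_effect_spec()]).
#' @param noise a [noise_spec()] (default [default_noise_spec()]).
#' @param subject_seed integer seed for this subject.
#' @param subject subject identifier stored in the trial table.
#' @param layout sensor layout (default [make_layout()]).
#' @return an `epochs_data` object: `data` (trials x 64 x 181 array, uV),
#'   `times_ms`, `trials` (per-trial metadata), `layout`,
#'   `sample_rate_hz`.
#' @export
simulate_subject <- function(design, stimulus_set,
                             spec = default_effect_spec(),
                             noise = default_noise_spec(),
                             subject_seed = 1L, subject = 1L,
                             layout = make_layout()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(stimulus_set, "stimulus_set"))
  trials <- design_trials(design, stimulus_set)
  trials$subject <- subject
  n <- nrow(trials)
  times <- epoch_times()
  T_ <- length(times)
  nch <- nrow(layout)

  set.seed(subject_seed)
  topo <- draw_topographies(layout, stimulus_set)
  gain <- exp(rnorm(n, 0, noise$trial_gain_jitter_sd))

  # condition contrasts per trial and dimension
  contr <- list(
    aspect_ratio = ifelse(trials$shape_class == "spiky", 1,
                          ifelse(trials$shape_class == "stubby", -1, 0)),
    animacy = ifelse(trials$animacy == "animate", 1, -1))
  amp_of <- function(d) unname(spec[[d]]$amplitude[trials$rendering])

  sig <- array(0, dim = c(n, nch, T_))
  for (d in c("aspect_ratio", "animacy")) {
    k <- effect_kernel(times, spec[[d]]$peak_ms, spec[[d]]$duration_ms,
                       spec[[d]]$sustained_fraction, spec[[d]]$flip_ms)
    a <- amp_of(d) * contr[[d]] * gain
    if (all(a == 0)) next
    W <- if (d == "aspect_ratio" && isTRUE(spec$ar_topography_by_animacy)) {
      t(topo$ar_by_animacy)[, match(trials$animacy,
                                    c("animate", "inanimate")), drop = FALSE]
    } else {
      matrix(topo[[d]], nch, 1)[, rep(1, n), drop = FALSE]
    }
    # accumulate a * (topo x kernel) for each trial
    sig <- sig + outer_trials(a, t(W), k)
  }
  # category: per-category zero-sum topographies
  kcat <- effect_kernel(times, spec$category$peak_ms,
                        spec$category$duration_ms,
                        spec$category$sustained_fraction,
                        spec$category$flip_ms)
  acat <- amp_of("category") * gain
  if (any(acat != 0)) {
    Wc <- topo$category[match(trials$category, CATEGORIES), , drop = FALSE]
    sig <- sig + outer_trials(acat, Wc, kcat)
  }
  # identity: per-stimulus patterns
  kid <- effect_kernel(times, spec$identity$peak_ms,
                       spec$identity$duration_ms,
                       spec$identity$sustained_fraction,
                       spec$identity$flip_ms)
  aid <- amp_of("identity") * gain
  if (any(aid != 0)) {
    Wi <- topo$identity[trials$stim_id, , drop = FALSE]
    sig <- sig + outer_trials(aid, Wi, kid)
  }

  dat <- sig + simulate_noise(n, nch, times, layout, noise)
  # baseline demean over -100..0 ms
  base <- times <= 0
  bm <- rowMeans(dat[, , base, drop = FALSE], dims = 2L)
  dat <- dat - as.vector(bm)  # recycles over the time dimension
  structure(list(data = dat, times_ms = times, trials = trials,
                 layout = layout, sample_rate_hz = 200),
            class = "epochs_data")
}

epoch_times <- function() seq(-100, 800, by = 5)

# sum_i a_i * W_i (n x nch) x kernel (T): returns n x nch x T array
outer_trials <- function(a, W, k) {
  aW <- W * a                       # n x nch
  array(as.vector(aW) %o% k, dim = c(nrow(W), ncol(W), length(k)))
}

draw_topographies <- function(layout, stimulus_set) {
  nch <- nrow(layout)
  occ <- exp(-((layout$x - 0)^2 + (layout$y + 0.85)^2) / (2 * 0.35^2))
  draw <- function() {
    w <- occ * rnorm(nch)
    w / sqrt(sum(w^2))
  }
  cat4 <- t(replicate(4, draw()))
  cat4 <- sweep(cat4, 2, colMeans(cat4))           # zero-sum over categories
  n_stim <- nrow(stimulus_set$meta)
  idm <- t(replicate(n_stim, draw()))
  idm <- sweep(idm, 2, colMeans(idm))
  ar2 <- t(replicate(2, draw()))
  # orthogonalize the second against the first (used by the
  # ar_topography_by_animacy switch)
  ar2[2, ] <- ar2[2, ] - sum(ar2[1, ] * ar2[2, ]) * ar2[1, ]
  ar2[2, ] <- ar2[2, ] / sqrt(sum(ar2[2, ]^2))
  list(aspect_ratio = draw(), animacy = draw(), category = cat4,
       identity = idm, ar_by_animacy = ar2)
}

simulate_noise <- function(n, nch, times, layout, noise) {
  T_ <- length(times)
  if (noise$channel_noise_sd == 0) return(array(0, c(n, nch, T_)))
  D <- layout_dist(layout)
  ell <- max(noise$spatial_correlation_scale, 1e-6)
  K <- exp(-D^2 / (2 * ell^2)) + diag(1e-6, nch)
  U <- chol(K)
  Z <- matrix(rnorm(n * T_ * nch, sd = noise$channel_noise_sd),
              n * T_, nch) %*% U
  # temporal smoothing with unit-L2 rows preserves marginal variance
  if (noise$temporal_smoothing_ms > 0) {
    dt_ms <- times[2] - times[1]
    G <- outer(times, times,
               function(a, b) exp(-(a - b)^2 /
                                    (2 * noise$temporal_smoothing_ms^2)))
    G <- G / sqrt(rowSums(G^2))
    # Z rows are (trial, time) pairs: reshape to n x T per channel
    arr <- array(Z, dim = c(n, T_, nch))
    for (c_ in seq_len(nch)) arr[, , c_] <- arr[, , c_] %*% t(G)
    aperm(arr, c(1, 3, 2))
  } else {
    aperm(array(Z, dim = c(n, T_, nch)), c(1, 3, 2))
  }
}

#' @export
print.epochs_data <- function(x, ...) {
  cat(sprintf("Epochs: %d trials x %d channels x %d timepoints (%g-%g ms, %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times_ms), max(x$times_ms), x$sample_rate_hz))
  print(table(x$trials$rendering))
  invisible(x)
}

#' Subset epochs by trial
#'
#' @param epochs an `epochs_data` object.
#' @param idx logical or integer trial index.
#' @return the subsetted `epochs_data`.
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trials <- epochs$trials[idx, , drop = FALSE]
  rownames(epochs$trials) <- NULL
  epochs
}

#' Save / load an epochs container
#'
#' Serializes the epoch array via RDS next to a TSV trial table and a
#' JSON sidecar recording dimensions, units and the time axis, giving a
#' self-describing on-disk container.
#'
#' @param epochs an `epochs_data` object.
#' @param path basename; writes `<path>.rds`, `<path>_trials.tsv`,
#'   `<path>.json`.
#' @return invisibly, `path`.
#' @export
save_epochs <- function(epochs, path) {
  saveRDS(epochs, paste0(path, ".rds"))
  write.table(epochs$trials, paste0(path, "_trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  side <- list(n_trials = dim(epochs$data)[1], n_channels = dim(epochs$data)[2],
               n_times = dim(epochs$data)[3], units = "uV",
               sample_rate_hz = epochs$sample_rate_hz,
               times_ms = epochs$times_ms)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) readRDS(paste0(path, ".rds"))

#' Wrap an external epoch array for analysis
#'
#' Adapter for applying the decoding/RSA analyses to epoch data produced
#' elsewhere: any array shaped trials x channels x timepoints with a
#' matching trial table can be wrapped into an `epochs_data`.
#'
#' @param data numeric array, trials x channels x timepoints.
#' @param trials data frame with one row per trial (must include `run`,
#'   `rendering` and the label columns used by the analyses).
#' @param times_ms numeric time axis (default the package's -100..800 ms).
#' @param layout sensor layout matching the channel dimension.
#' @return an `epochs_data` object.
#' @export
as_epochs <- function(data, trials, times_ms = epoch_times(),
                      layout = make_layout()) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == nrow(trials),
            dim(data)[3] == length(times_ms), dim(data)[2] == nrow(layout))
  structure(list(data = data, times_ms = times_ms, trials = trials,
                 layout = layout,
                 sample_rate_hz = 1000 / diff(times_ms[1:2])),
            class = "epochs_data")
}
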