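#' Remove median-aspect-ratio stimuli
#'
#' Drops every trial whose stimulus is its category's median-aspect-ratio
#' object, the preprocessing required before stubby-vs-spiky decoding
#' (48 of 52 base objects remain).
#'
#' @param epochs an `epochs_data` object.
#' @return the filtered `epochs_data`.
#' @export
filter_medians <- function(epochs) {
  if (!"shape_class" %in% names(epochs$trials))
    stop("trial table has no shape_class column")
  subset_epochs(epochs, epochs$trials$shape_class != "median")
}

#' Time-resolved whole-head decoding
#'
#' Trains a shrinkage-LDA classifier on all channels at every timepoint
#' with leave-one-run-out cross-validation: for each fold, one run is
#' held out for testing and the classifier is trained on the remaining
#' runs; reported accuracy is the mean over folds of the held-out-run
#' proportion correct. Renderings are analyzed separately (pass
#' `rendering`); for `shape_class` labels the median stimuli must be
#' removed first ([filter_medians()]).
#'
#' @param epochs an `epochs_data` object (one subject).
#' @param label_column trial-table column to decode: `"shape_class"`,
#'   `"animacy"`, `"category"` or `"stim_id"`.
#' @param rendering `"intact"`, `"silhouette"`, or `NULL` for all trials.
#' @param shrinkage `"auto"` or fixed intensity in `[0, 1]`.
#' @return an `accuracy_timecourse`: `accuracy` (per timepoint),
#'   `times_ms`, `chance_level` (= 1/classes), `n_folds`, labels.
#' @export
decode_timecourse <- function(epochs, label_column,
                              rendering = NULL, shrinkage = "auto") {
  epochs <- pick_rendering(epochs, rendering)
  y <- label_factor(epochs$trials, label_column)
  folds <- loro_folds(epochs$trials)
  check_folds_have_classes(y, folds)
  acc <- cpp_lda_cv(epochs$data, as.integer(y) - 1L, folds$train,
                    folds$test, TRUE, shrink_arg(shrinkage))[, 1]
  new_accuracy_timecourse(acc, epochs$times_ms, nlevels(y),
                          length(folds$runs), label_column, rendering)
}

shrink_arg <- function(shrinkage) {
  if (identical(shrinkage, "auto")) return(-1)
  s <- as.numeric(shrinkage)
  if (is.na(s) || s < 0 || s > 1) stop("shrinkage must be 'auto' or in [0,1]")
  s
}

new_accuracy_timecourse <- function(acc, times, K, n_folds, label,
                                    rendering) {
  structure(list(accuracy = as.numeric(acc), times_ms = times,
                 chance_level = 1 / K, n_folds = n_folds,
                 label = label, rendering = rendering),
            class = "accuracy_timecourse")
}

#' @export
print.accuracy_timecourse <- function(x, ...) {
  i <- which.max(x$accuracy)
  cat(sprintf("Decoding '%s'%s: peak %.1f%% at %g ms (chance %.2f%%, %d folds)\n",
              x$label,
              if (is.null(x$rendering)) "" else paste0(" [", x$rendering, "]"),
              100 * x$accuracy[i], x$times_ms[i], 100 * x$chance_level,
              x$n_folds))
  invisible(x)
}

#' Cross-decoding across object-space dimensions
#'
#' Tests whether one dimension's code generalizes across the other:
#' classifiers for `decode_dim` are trained using only trials from one
#' class of `split_dim` and tested on trials of the held-out class
#' (e.g. train stubby-vs-spiky on animate objects, test on inanimate).
#' Folding is leave-one-run-out applied to the test class's runs; the two
#' train/test directions are averaged. Both dimensions are binary, so
#' median stimuli must be removed first.
#'
#' @param epochs an `epochs_data` object (one subject).
#' @param decode_dim dimension to decode (`"shape_class"` or
#'   `"animacy"`).
#' @param split_dim the other dimension, used to split train/test trials.
#' @param rendering `"intact"`, `"silhouette"`, or `NULL`.
#' @param shrinkage `"auto"` or fixed intensity.
#' @return an `accuracy_timecourse` (mean of the two directions).
#' @export
cross_decode <- function(epochs, decode_dim, split_dim, rendering = NULL,
                         shrinkage = "auto") {
  dims <- c("shape_class", "animacy")
  if (!decode_dim %in% dims || !split_dim %in% dims ||
      decode_dim == split_dim)
    stop("decode_dim and split_dim must be distinct members of ",
         "{shape_class, animacy}")
  epochs <- pick_rendering(epochs, rendering)
  if (any(epochs$trials$shape_class == "median"))
    stop("median stimuli present; call filter_medians() first")
  y <- label_factor(epochs$trials, decode_dim)
  s <- factor(epochs$trials[[split_dim]])
  if (nlevels(s) != 2) stop("split dimension must be binary")
  runs <- sort(unique(epochs$trials$run))
  idx <- seq_len(nrow(epochs$trials))
  train_sets <- list(); test_sets <- list()
  for (dir in 1:2) {
    a <- levels(s)[dir]; b <- levels(s)[3 - dir]
    for (r in runs) {
      tr <- idx[s == a & epochs$trials$run != r]
      te <- idx[s == b & epochs$trials$run == r]
      if (!length(tr) || !length(te))
        stop("empty train/test partition for run ", r)
      train_sets <- c(train_sets, list(tr))
      test_sets <- c(test_sets, list(te))
    }
  }
  for (i in seq_along(train_sets))
    if (length(unique(y[train_sets[[i]]])) < nlevels(y))
      stop("a decoded class is absent from a cross-decoding training set")
  acc <- cpp_lda_cv(epochs$data, as.integer(y) - 1L, train_sets, test_sets,
                    TRUE, shrink_arg(shrinkage))[, 1]
  out <- new_accuracy_timecourse(acc, epochs$times_ms, nlevels(y),
                                 length(runs), decode_dim, rendering)
  out$split <- split_dim
  out
}

#' Temporal generalization matrix
#'
#' Trains a classifier at every timepoint and tests it at all timepoints,
#' with the identical leave-one-run-out fold structure as
#' [decode_timecourse()]; the matrix diagonal therefore equals the
#' standard decoding time course exactly. Above-chance off-diagonal
#' blocks indicate temporally stable codes; below-chance cells indicate a
#' pattern that later reverses.
#'
#' @inheritParams decode_timecourse
#' @return a `tg_matrix`: `accuracy` (train-time x test-time),
#'   `times_ms`, `chance_level`.
#' @export
temporal_generalization <- function(epochs, label_column, rendering = NULL,
                                    shrinkage = "auto") {
  epochs <- pick_rendering(epochs, rendering)
  y <- label_factor(epochs$trials, label_column)
  folds <- loro_folds(epochs$trials)
  check_folds_have_classes(y, folds)
  acc <- cpp_lda_cv(epochs$data, as.integer(y) - 1L, folds$train,
                    folds$test, FALSE, shrink_arg(shrinkage))
  dimnames(acc) <- list(train = epochs$times_ms, test = epochs$times_ms)
  structure(list(accuracy = acc, times_ms = epochs$times_ms,
                 chance_level = 1 / nlevels(y),
                 n_folds = length(folds$runs), label = label_column,
                 rendering = rendering),
            class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf("Temporal generalization '%s': %d x %d timepoints, chance %.2f\n",
              x$label, nrow(x$accuracy), ncol(x$accuracy), x$chance_level))
  invisible(x)
}

#' Group mean of accuracy time courses
#'
#' @param timecourses list of `accuracy_timecourse` objects (one per
#'   subject) with matching time axes.
#' @return an `accuracy_timecourse` holding the unweighted subject mean;
#'   component `subject_matrix` keeps the subjects x timepoints matrix.
#' @export
group_mean <- function(timecourses) {
  stopifnot(length(timecourses) >= 1)
  m <- do.call(rbind, lapply(timecourses, function(t) t$accuracy))
  out <- timecourses[[1]]
  out$accuracy <- colMeans(m)
  out$subject_matrix <- m
  out
}
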