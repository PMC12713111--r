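#' Sensor searchlight decoding
#'
#' Repeats the time-resolved decoding analysis on small sensor
#' neighborhoods: for every channel the features are restricted to that
#' channel plus its 3 nearest layout neighbors (4 sensors total by
#' default), with the same leave-one-run-out fold structure as the
#' whole-head analysis. For display and summary the per-channel accuracy
#' is additionally averaged within 100 ms bins starting 50 ms before
#' stimulus onset.
#'
#' @inheritParams decode_timecourse
#' @param layout sensor layout (defaults to the layout stored in
#'   `epochs`).
#' @param neighborhood_size sensors per neighborhood (default 4).
#' @return a `sensor_map`: `accuracy` (channels x timepoints),
#'   `neighborhoods`, `binned` (channels x bins), `bin_starts_ms`,
#'   `chance_level`.
#' @export
searchlight_decode <- function(epochs, label_column, rendering = NULL,
                               layout = NULL, neighborhood_size = 4L,
                               shrinkage = "auto") {
  epochs <- pick_rendering(epochs, rendering)
  if (is.null(layout)) layout <- epochs$layout
  if (nrow(layout) != dim(epochs$data)[2])
    stop("layout does not cover the epoch channels")
  y <- label_factor(epochs$trials, label_column)
  folds <- loro_folds(epochs$trials)
  check_folds_have_classes(y, folds)
  nb <- sensor_neighborhoods(layout, neighborhood_size)
  y0 <- as.integer(y) - 1L
  sh <- shrink_arg(shrinkage)
  acc <- t(vapply(nb, function(ch) {
    cpp_lda_cv(epochs$data[, ch, , drop = FALSE], y0, folds$train,
               folds$test, TRUE, sh)[, 1]
  }, numeric(length(epochs$times_ms))))
  rownames(acc) <- layout$name
  starts <- seq(-50, max(epochs$times_ms) - 50, by = 100)
  binned <- vapply(starts, function(s) {
    sel <- epochs$times_ms >= s & epochs$times_ms < s + 100
    rowMeans(acc[, sel, drop = FALSE])
  }, numeric(nrow(acc)))
  colnames(binned) <- starts
  structure(list(accuracy = acc, neighborhoods = nb, binned = binned,
                 bin_starts_ms = starts, times_ms = epochs$times_ms,
                 chance_level = 1 / nlevels(y), label = label_column,
                 rendering = rendering),
            class = "sensor_map")
}

#' @export
print.sensor_map <- function(x, ...) {
  best <- which(x$binned == max(x$binned), arr.ind = TRUE)[1, ]
  cat(sprintf("Searchlight '%s': best bin %.1f%% at %s, bin start %s ms\n",
              x$label, 100 * max(x$binned), rownames(x$binned)[best[1]],
              colnames(x$binned)[best[2]]))
  invisible(x)
}
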