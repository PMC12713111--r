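#' Pairwise stimulus decoding (neural RDM time series)
#'
#' Trains a shrinkage-LDA classifier for every pair of base objects at
#' every timepoint with leave-one-run-out cross-validation, and stores
#' the cross-validated accuracy as the pair's neural dissimilarity. The
#' result is a symmetric dissimilarity matrix per timepoint with a zero
#' diagonal: at-chance pairs sit near 0.5, well-discriminated pairs
#' approach 1.
#'
#' @inheritParams decode_timecourse
#' @param times optional subset of the time axis (ms) at which to compute
#'   the RDMs (defaults to every timepoint).
#' @return an `rdm_series`: `dissimilarity` (timepoints x n x n array),
#'   `times_ms`, `stimulus_ids`, `rendering`.
#' @export
pairwise_decode <- function(epochs, rendering = NULL, times = NULL,
                            shrinkage = "auto") {
  epochs <- pick_rendering(epochs, rendering)
  if (!is.null(times)) {
    keep <- epochs$times_ms %in% times
    if (!any(keep)) stop("requested times not on the epoch time axis")
    epochs$data <- epochs$data[, , keep, drop = FALSE]
    epochs$times_ms <- epochs$times_ms[keep]
  }
  ids <- sort(unique(epochs$trials$stim_id))
  n_stim <- length(ids)
  T_ <- length(epochs$times_ms)
  sh <- shrink_arg(shrinkage)
  rdm <- array(0, dim = c(T_, n_stim, n_stim))
  for (i in seq_len(n_stim - 1)) {
    for (j in seq((i + 1), n_stim)) {
      sel <- which(epochs$trials$stim_id %in% c(ids[i], ids[j]))
      sub <- epochs$trials[sel, ]
      y <- factor(sub$stim_id, levels = c(ids[i], ids[j]))
      folds <- loro_folds(sub)
      check_folds_have_classes(y, folds)
      acc <- cpp_lda_cv(epochs$data[sel, , , drop = FALSE],
                        as.integer(y) - 1L, folds$train, folds$test,
                        TRUE, sh)[, 1]
      rdm[, i, j] <- acc
      rdm[, j, i] <- acc
    }
  }
  structure(list(dissimilarity = rdm, times_ms = epochs$times_ms,
                 stimulus_ids = ids, rendering = rendering),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  off <- apply(x$dissimilarity, 1, function(m) mean(m[lower.tri(m)]))
  cat(sprintf("RDM series: %d timepoints x %d stimuli; mean off-diagonal %.3f-%.3f\n",
              length(x$times_ms), length(x$stimulus_ids), min(off), max(off)))
  invisible(x)
}

#' Serialize an RDM series as long-format TSV
#'
#' @param rdms an `rdm_series`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_rdm_tsv <- function(rdms, path) {
  n <- length(rdms$stimulus_ids)
  lt <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_along(rdms$times_ms), function(t) {
    data.frame(time_ms = rdms$times_ms[t],
               stim_i = rdms$stimulus_ids[lt[, 1]],
               stim_j = rdms$stimulus_ids[lt[, 2]],
               value = rdms$dissimilarity[t, , ][lt])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
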