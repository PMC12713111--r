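#' Build a yoked RSVP experiment design
#'
#' Constructs the run structure of the 5 Hz RSVP paradigm: per rendering,
#' `n_runs_per_rendering` runs of `52 * repeats_per_run` object
#' presentations in randomized order, with 2-4 task-target shapes
#' (square/triangle events) inserted as extra stream events. The
#' silhouette run k is *yoked* to intact run k: identical base-object
#' sequence and target slots. The session-level order of the 2 x
#' `n_runs_per_rendering` runs is randomized. At the default parameters
#' this yields 40 runs, 8,320 non-target trials, 80 presentations per
#' stimulus, and run durations between 42 and 42.4 s at 200 ms per event.
#'
#' @param stimulus_set a [build_stimulus_set()] result (or any set whose
#'   `meta` has 52 ids).
#' @param n_runs_per_rendering runs per rendering (default 20).
#' @param repeats_per_run presentations of each base object per run
#'   (default 4).
#' @param targets_per_run_range integer range (lo, hi) of inserted targets
#'   per run (default `c(2, 4)`).
#' @param seed session seed.
#' @return an `experiment_design`: list of runs in session order plus
#'   design parameters. Each run records its yoke id, rendering, base
#'   `sequence`, `target_positions` (indices within the event stream) and
#'   `duration_s`.
#' @export
build_design <- function(stimulus_set, n_runs_per_rendering = 20L,
                         repeats_per_run = 4L,
                         targets_per_run_range = c(2L, 4L), seed = 0L) {
  tr <- targets_per_run_range
  if (length(tr) != 2 || any(tr < 0) || tr[1] > tr[2] ||
      any(tr != round(tr)))
    stop("invalid target range")
  ids <- stimulus_set$meta$id
  n_base <- length(ids)
  set.seed(derive_seed(seed, 1L))
  yoked <- vector("list", n_runs_per_rendering)
  for (k in seq_len(n_runs_per_rendering)) {
    seqk <- sample(rep(ids, repeats_per_run))
    n_t <- sample(seq.int(tr[1], tr[2]), 1L)
    n_events <- length(seqk) + n_t
    tpos <- sort(sample.int(n_events, n_t))
    yoked[[k]] <- list(yoke = k, sequence = seqk, target_positions = tpos,
                       n_events = n_events,
                       duration_s = n_events * 0.2)
  }
  # session order: randomized interleaving of the 2 x n runs
  slots <- data.frame(
    yoke = rep(seq_len(n_runs_per_rendering), 2L),
    rendering = rep(c("intact", "silhouette"),
                    each = n_runs_per_rendering))
  slots <- slots[sample.int(nrow(slots)), ]
  runs <- vector("list", nrow(slots))
  for (i in seq_len(nrow(slots))) {
    r <- yoked[[slots$yoke[i]]]
    r$rendering <- slots$rendering[i]
    r$session_index <- i
    runs[[i]] <- r
  }
  structure(list(runs = runs, soa_ms = 200, rate_hz = 5,
                 n_runs_per_rendering = as.integer(n_runs_per_rendering),
                 repeats_per_run = as.integer(repeats_per_run),
                 targets_per_run_range = as.integer(tr), seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  n <- length(x$runs)
  cat(sprintf("RSVP design: %d runs (%d per rendering), %d presentations/run, %d non-target trials\n",
              n, x$n_runs_per_rendering,
              length(x$runs[[1]]$sequence),
              sum(vapply(x$runs, function(r) length(r$sequence), 1L))))
  invisible(x)
}

#' Flatten a design into a per-presentation trial table
#'
#' One row per stream event, in session and stream order. Non-target rows
#' carry the base stimulus id and (if a stimulus set is supplied) its
#' category, animacy and shape-class labels.
#'
#' @param design an [build_design()] result.
#' @param stimulus_set optional stimulus set used to merge labels.
#' @param include_targets keep target events (default `FALSE`).
#' @return data frame with columns `run`, `yoke`, `rendering`, `position`,
#'   `stim_id`, `onset_s`, `is_target` (+ label columns).
#' @export
design_trials <- function(design, stimulus_set = NULL,
                          include_targets = FALSE) {
  rows <- lapply(design$runs, function(r) {
    n_events <- r$n_events
    stim <- integer(n_events)
    stim[r$target_positions] <- NA_integer_
    stim[setdiff(seq_len(n_events), r$target_positions)] <- r$sequence
    data.frame(run = r$session_index, yoke = r$yoke,
               rendering = r$rendering, position = seq_len(n_events),
               stim_id = stim, onset_s = (seq_len(n_events) - 1L) * 0.2,
               is_target = seq_len(n_events) %in% r$target_positions)
  })
  tab <- do.call(rbind, rows)
  if (!include_targets) tab <- tab[!tab$is_target, ]
  if (!is.null(stimulus_set)) {
    m <- stimulus_set$meta
    idx <- match(tab$stim_id, m$id)
    tab$category <- m$category[idx]
    tab$animacy <- m$animacy[idx]
    tab$shape_class <- m$shape_class[idx]
  }
  rownames(tab) <- NULL
  tab
}

#' Write a design trial table as TSV
#'
#' @param design an experiment design.
#' @param path output file.
#' @param stimulus_set optional set for label columns.
#' @return invisibly, `path`.
#' @export
write_design_tsv <- function(design, path, stimulus_set = NULL) {
  tab <- design_trials(design, stimulus_set, include_targets = TRUE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
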