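#' Configuration for an end-to-end simulated study
#'
#' Bundles every knob of the simulate-decode-RSA-stats pipeline. The
#' defaults reproduce the full study conditions (20 subjects, 20 runs
#' per rendering, 4 repeats per run = 8,320 trials per subject); tests
#' and examples use scaled-down configurations, which preserve all
#' structural invariants.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_runs_per_rendering,repeats_per_run,targets_per_run_range
#'   design parameters passed to [build_design()].
#' @param seed session seed; all stimulus, design and per-subject seeds
#'   derive from it deterministically.
#' @param effect_spec,noise_spec generative specifications.
#' @param analyses subset of
#'   `c("timecourse", "cross", "tg", "searchlight", "rsa", "bayes")`.
#' @param dimensions label columns decoded in the timecourse (and tg /
#'   searchlight) analyses.
#' @param rsa_models model RDMs for the RSA regression.
#' @param rsa_times optional time subset (ms) for pairwise decoding.
#' @param out_dir optional output directory for TSV/JSON results.
#' @return a `run_config` object.
#' @export
run_config <- function(n_subjects = 20L, n_runs_per_rendering = 20L,
                       repeats_per_run = 4L,
                       targets_per_run_range = c(2L, 4L), seed = 1L,
                       effect_spec = default_effect_spec(),
                       noise_spec = default_noise_spec(),
                       analyses = c("timecourse", "cross", "tg",
                                    "searchlight", "rsa", "bayes"),
                       dimensions = c("shape_class", "animacy", "category",
                                      "stim_id"),
                       rsa_models = c("aspect_ratio", "category", "pixel"),
                       rsa_times = NULL, out_dir = NULL) {
  structure(list(n_subjects = as.integer(n_subjects),
                 n_runs_per_rendering = as.integer(n_runs_per_rendering),
                 repeats_per_run = as.integer(repeats_per_run),
                 targets_per_run_range = as.integer(targets_per_run_range),
                 seed = as.integer(seed), effect_spec = effect_spec,
                 noise_spec = noise_spec, analyses = analyses,
                 dimensions = dimensions, rsa_models = rsa_models,
                 rsa_times = rsa_times, out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$effect_spec <- unclass(x$effect_spec)
  for (d in c("aspect_ratio", "animacy", "category", "identity"))
    x$effect_spec[[d]]$amplitude <-
      as.list(x$effect_spec[[d]]$amplitude)  # keep names in the YAML map
  x$noise_spec <- unclass(x$noise_spec)
  writeLines(yaml::as.yaml(x, precision = 15L), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  es <- x$effect_spec
  for (d in c("aspect_ratio", "animacy", "category", "identity"))
    es[[d]]$amplitude <- unlist(es[[d]]$amplitude)
  run_config(
    n_subjects = x$n_subjects,
    n_runs_per_rendering = x$n_runs_per_rendering,
    repeats_per_run = x$repeats_per_run,
    targets_per_run_range = x$targets_per_run_range, seed = x$seed,
    effect_spec = effect_spec(es$aspect_ratio, es$animacy, es$category,
                              es$identity,
                              isTRUE(es$ar_topography_by_animacy)),
    noise_spec = do.call(noise_spec, x$noise_spec),
    analyses = x$analyses, dimensions = x$dimensions,
    rsa_models = x$rsa_models, rsa_times = x$rsa_times,
    out_dir = x$out_dir)
}

subject_seed_of <- function(config, i) derive_seed(config$seed, 31L + i)

#' Run the full simulated study
#'
#' Executes stimulus generation, design construction, per-subject epoch
#' simulation, the requested decoding analyses per rendering, RSA and
#' Bayes-factor statistics, and collects everything in a results bundle.
#' Renderings are analyzed separately throughout. Identical
#' configurations (including seed) give bit-identical bundles.
#'
#' @param config a [run_config()].
#' @return a `results_bundle`: stimulus set, design, per-analysis group
#'   results (with subject-level matrices), Bayes-factor series and a
#'   manifest of seeds and settings.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s'%s failed: %s", name,
                   if (is.null(subject)) "" else paste0(" (subject ", subject, ")"),
                   conditionMessage(e)), call. = FALSE))
  }
  set <- stage("stimgen", NULL, build_stimulus_set(config$seed))
  design <- stage("stimgen", NULL, build_design(
    set, config$n_runs_per_rendering, config$repeats_per_run,
    config$targets_per_run_range, derive_seed(config$seed, 2L)))
  renderings <- c("intact", "silhouette")
  subj_seeds <- vapply(seq_len(config$n_subjects),
                       function(i) subject_seed_of(config, i), 1L)
  an <- config$analyses
  res <- list(timecourse = list(), cross = list(), tg = list(),
              searchlight = list(), rdm = list(), betas = list())
  for (i in seq_len(config$n_subjects)) {
    ep <- stage("eegsim", i, simulate_subject(
      design, set, config$effect_spec, config$noise_spec,
      subj_seeds[i], subject = i))
    epf <- filter_medians(ep)
    for (rend in renderings) {
      if ("timecourse" %in% an) {
        for (d in config$dimensions) {
          e <- if (d == "shape_class") epf else ep
          tc <- stage("decode", i, decode_timecourse(e, d, rend))
          res$timecourse[[rend]][[d]][[i]] <- tc
        }
      }
      if ("cross" %in% an) {
        for (d in c("shape_class", "animacy")) {
          sp <- setdiff(c("shape_class", "animacy"), d)
          res$cross[[rend]][[d]][[i]] <-
            stage("decode", i, cross_decode(epf, d, sp, rend))
        }
      }
      if ("tg" %in% an) {
        for (d in intersect(config$dimensions,
                            c("shape_class", "animacy", "category"))) {
          e <- if (d == "shape_class") epf else ep
          res$tg[[rend]][[d]][[i]] <-
            stage("decode", i, temporal_generalization(e, d, rend))
        }
      }
      if ("searchlight" %in% an) {
        for (d in intersect(config$dimensions,
                            c("shape_class", "animacy", "category"))) {
          e <- if (d == "shape_class") epf else ep
          res$searchlight[[rend]][[d]][[i]] <-
            stage("decode", i, searchlight_decode(e, d, rend))
        }
      }
      if ("rsa" %in% an) {
        rdm <- stage("decode", i,
                     pairwise_decode(ep, rend, times = config$rsa_times))
        res$rdm[[rend]][[i]] <- rdm
        models <- stage("rsa", i, make_models(set, rend, config$rsa_models))
        bs <- stage("rsa", i, fit_rdm_glm(rdm, models))
        res$betas[[rend]][[i]] <- bs
      }
    }
  }
  bundle <- aggregate_bundle(res, config, set, design, subj_seeds)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

make_models <- function(set, rendering, names_) {
  models <- list()
  for (m in names_) {
    models[[m]] <- if (m == "pixel") pixel_rdm(set, rendering)
                   else model_rdm(set, m)
  }
  models
}

aggregate_bundle <- function(res, config, set, design, subj_seeds) {
  renderings <- names(res$timecourse)
  grp <- function(lst) if (length(lst)) group_mean(lst) else NULL
  out <- list(config = config, stimulus_set = set, design = design,
              timecourse = list(), cross = list(), tg = res$tg,
              searchlight = res$searchlight, rdm = res$rdm,
              betas = res$betas, bf = list())
  for (rend in renderings) {
    for (d in names(res$timecourse[[rend]]))
      out$timecourse[[rend]][[d]] <- grp(res$timecourse[[rend]][[d]])
    for (d in names(res$cross[[rend]]))
      out$cross[[rend]][[d]] <- grp(res$cross[[rend]][[d]])
  }
  if ("bayes" %in% config$analyses && config$n_subjects >= 2) {
    for (rend in renderings) {
      for (d in names(out$timecourse[[rend]])) {
        g <- out$timecourse[[rend]][[d]]
        out$bf$timecourse[[rend]][[d]] <-
          bf_timecourse(g, g$chance_level, na_on_zero_variance = TRUE)
      }
    }
    for (d in names(out$timecourse[[renderings[1]]])) {
      if (length(renderings) == 2)
        out$bf$difference[[d]] <- bf_difference(
          out$timecourse[["intact"]][[d]],
          out$timecourse[["silhouette"]][[d]],
          na_on_zero_variance = TRUE)
    }
    for (rend in names(res$betas)) {
      bs <- res$betas[[rend]]
      if (length(bs)) {
        for (m in bs[[1]]$model_names) {
          mat <- do.call(rbind, lapply(bs, function(b) b$betas[, m]))
          out$bf$beta[[rend]][[m]] <-
            bf_beta(mat, times_ms = bs[[1]]$times_ms,
                    na_on_zero_variance = TRUE)
        }
      }
    }
  }
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("objspace")),
    session_seed = config$seed, subject_seeds = subj_seeds,
    analyses = config$analyses, dimensions = config$dimensions,
    n_subjects = config$n_subjects,
    config_hash = config_hash(config), created = "run_all")
  class(out) <- "results_bundle"
  out
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  s <- yaml::as.yaml(x, precision = 15L)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Results bundle:", x$manifest$n_subjects, "subjects; analyses:",
      paste(x$manifest$analyses, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize decoding peaks and evidence windows
#'
#' For every analysis, rendering and dimension: the peak of the
#' group-mean accuracy (latency and value) and the onset/offset of the
#' longest stretch of at least 3 consecutive timepoints with BF > 1
#' (`NA` when no such stretch exists). The returned table carries an
#' attribute `no_evidence`, `TRUE` when no dimension shows a sustained
#' stretch (>= 3 consecutive timepoints) of vs-chance BF > 3 (flagging,
#' e.g., a null simulation; isolated single-timepoint fluctuations do
#' not count as evidence).
#'
#' @param bundle a [run_all()] result.
#' @return data frame (analysis, rendering, dimension, peak_latency_ms,
#'   peak_accuracy, onset_ms, offset_ms).
#' @export
summarize_peaks <- function(bundle) {
  rows <- list()
  any_sustained <- FALSE
  seen_bf <- FALSE
  for (analysis in c("timecourse", "cross")) {
    for (rend in names(bundle[[analysis]])) {
      for (d in names(bundle[[analysis]][[rend]])) {
        g <- bundle[[analysis]][[rend]][[d]]
        i <- which.max(g$accuracy)
        bf <- if (analysis == "timecourse")
          bundle$bf$timecourse[[rend]][[d]] else NULL
        win <- c(NA_real_, NA_real_)
        if (!is.null(bf)) {
          seen_bf <- TRUE
          pos <- !is.na(bf$bf)  # degenerate timepoints carry no evidence
          strong <- longest_run_window(pos & bf$bf > 3, g$times_ms,
                                       min_len = 3L)
          if (!is.na(strong[1])) any_sustained <- TRUE
          win <- longest_run_window(pos & bf$bf > 1, g$times_ms,
                                    min_len = 3L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          analysis = analysis, rendering = rend, dimension = d,
          peak_latency_ms = g$times_ms[i], peak_accuracy = g$accuracy[i],
          onset_ms = win[1], offset_ms = win[2])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "no_evidence") <- seen_bf && !any_sustained
  out
}

longest_run_window <- function(flag, times, min_len = 3L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (!length(ok)) return(c(NA_real_, NA_real_))
  best <- ok[which.max(r$lengths[ok])]
  c(times[starts[best]], times[ends[best]])
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (analysis in c("timecourse", "cross")) {
    for (rend in names(bundle[[analysis]])) {
      for (d in names(bundle[[analysis]][[rend]])) {
        g <- bundle[[analysis]][[rend]][[d]]
        m <- g$subject_matrix
        for (s in seq_len(nrow(m)))
          rows[[length(rows) + 1L]] <- data.frame(
            analysis = analysis, rendering = rend, dimension = d,
            subject = s, time_ms = g$times_ms, accuracy = m[s, ])
      }
    }
  }
  if (length(rows))
    write.table(do.call(rbind, rows), file.path(dir, "accuracy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  bfr <- list()
  for (rend in names(bundle$bf$timecourse))
    for (d in names(bundle$bf$timecourse[[rend]])) {
      b <- bundle$bf$timecourse[[rend]][[d]]
      bfr[[length(bfr) + 1L]] <- data.frame(
        analysis = "timecourse", rendering = rend, dimension = d,
        time_ms = b$times_ms, bf = b$bf, log10_bf = b$log10_bf)
    }
  if (length(bfr))
    write.table(do.call(rbind, bfr), file.path(dir, "bayes_factors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
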