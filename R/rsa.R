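#' Binary model RDM for an object-space dimension
#'
#' Hypothesis dissimilarity matrix over the 52 base objects: pairs that
#' share the dimension's class get 0, pairs that differ get 1. For the
#' aspect-ratio model the median objects are assigned to the stubby or
#' spiky side by thresholding their continuous aspect ratio at the
#' midpoint between their category's largest stubby and smallest spiky
#' value, so all 52 objects enter the RSA.
#'
#' @param stimulus_set a [build_stimulus_set()] result.
#' @param dimension `"aspect_ratio"`, `"category"` or `"animacy"`.
#' @return a `model_rdm`: `name`, `dissimilarity` (52 x 52), `binary`.
#' @export
model_rdm <- function(stimulus_set,
                      dimension = c("aspect_ratio", "category", "animacy")) {
  dimension <- match.arg(dimension)
  m <- stimulus_set$meta
  cls <- switch(dimension,
    category = m$category,
    animacy = m$animacy,
    aspect_ratio = {
      side <- m$shape_class
      for (cat_ in unique(m$category)) {
        sel <- m$category == cat_
        mid <- (max(m$aspect_ratio[sel & side == "stubby"]) +
                  min(m$aspect_ratio[sel & side == "spiky"])) / 2
        med <- sel & side == "median"
        side[med] <- ifelse(m$aspect_ratio[med] > mid, "spiky", "stubby")
      }
      side
    })
  D <- 1 * outer(cls, cls, "!=")
  dimnames(D) <- list(m$id, m$id)
  structure(list(name = dimension, dissimilarity = D, binary = TRUE),
            class = "model_rdm")
}

#' Pixel-overlap (Jaccard) model RDM
#'
#' Dissimilarity between two stimuli as the Jaccard distance between
#' their foreground pixel sets: \eqn{1 - |F_i \cap F_j| / |F_i \cup
#' F_j|}. By default both renderings use the binarized foreground (the
#' mask), making the intact and silhouette pixel models identical for
#' this stimulus set, whose renderings share masks. With
#' `intensity_levels` set, intact images instead require pixels to fall
#' in the same of that many equal-width intensity bins to count as
#' shared, so internal texture differentiates objects with similar
#' outlines.
#'
#' @param stimulus_set a stimulus set.
#' @param rendering `"intact"` or `"silhouette"`.
#' @param intensity_levels optional bin count for intensity-aware
#'   matching of intact images (default `NULL`: mask overlap only).
#' @return a `model_rdm` with values in `[0, 1]`.
#' @export
pixel_rdm <- function(stimulus_set, rendering = c("intact", "silhouette"),
                      intensity_levels = NULL) {
  rendering <- match.arg(rendering)
  n <- nrow(stimulus_set$meta)
  masks <- stimulus_set$masks
  if (any(vapply(masks, function(m) !any(m), TRUE))) stop("blank image")
  Fm <- t(vapply(masks, as.vector, logical(length(masks[[1]]))))
  storage.mode(Fm) <- "double"
  inter <- Fm %*% t(Fm)
  area <- rowSums(Fm)
  uni <- outer(area, area, "+") - inter
  if (!is.null(intensity_levels) && rendering == "intact") {
    lv <- as.integer(intensity_levels)
    imgs <- stimulus_set$images[[rendering]]
    B <- t(vapply(imgs, function(im) {
      b <- pmin(1L + as.integer(floor(as.vector(im) * lv)), lv)
      b
    }, integer(length(masks[[1]]))))
    same_bin <- matrix(0, n, n)
    for (l in seq_len(lv)) {
      Ml <- Fm * (B == l)
      same_bin <- same_bin + Ml %*% t(Ml)
    }
    inter <- same_bin
  }
  D <- 1 - inter / uni
  diag(D) <- 0
  dimnames(D) <- list(stimulus_set$meta$id, stimulus_set$meta$id)
  structure(list(name = "pixel", dissimilarity = D, binary = FALSE,
                 rendering = rendering),
            class = "model_rdm")
}

#' Jaccard distance between two masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @return scalar in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  if (!any(a) || !any(b)) stop("blank image")
  1 - sum(a & b) / sum(a | b)
}

#' Per-timepoint regression of a neural RDM on model RDMs
#'
#' At every timepoint, ordinary least squares of the vectorized neural
#' dissimilarities (lower triangle, 1,326 pairs for 52 objects) on all
#' model regressors jointly plus an intercept. With `zscore = TRUE`
#' (default) the model regressors are standardized across pairs so betas
#' are comparable across models; the neural vector is left on its native
#' accuracy scale and the intercept absorbs overall decodability.
#'
#' @param neural an `rdm_series` from [pairwise_decode()].
#' @param models named list of `model_rdm` objects.
#' @param zscore standardize model regressors (default `TRUE`).
#' @return a `beta_series`: `betas` (timepoints x models), `intercept`,
#'   `model_names`, `times_ms`.
#' @export
fit_rdm_glm <- function(neural, models, zscore = TRUE) {
  if (!length(models)) stop("need at least one model RDM")
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, function(m) m$name, "")
  n <- length(neural$stimulus_ids)
  lt <- lower.tri(matrix(0, n, n))
  X <- vapply(models, function(m) {
    stopifnot(all(dim(m$dissimilarity) == n))
    m$dissimilarity[lt]
  }, numeric(sum(lt)))
  if (zscore) X <- scale(X)
  design <- cbind(`(intercept)` = 1, X)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    drop_cols <- setdiff(seq_len(ncol(design)), qd$pivot[seq_len(qd$rank)])
    stop("collinear model set; offending regressors: ",
         paste(colnames(design)[drop_cols], collapse = ", "))
  }
  Y <- t(apply(neural$dissimilarity, 1, function(m) m[lt]))
  # timepoints x pairs; solve all timepoints at once
  coefs <- t(qr.coef(qd, t(Y)))
  structure(list(betas = coefs[, -1, drop = FALSE],
                 intercept = coefs[, 1],
                 model_names = names(models),
                 times_ms = neural$times_ms,
                 rendering = neural$rendering),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  pk <- apply(x$betas, 2, max)
  cat("RDM regression betas over", length(x$times_ms), "timepoints; peaks:",
      paste(sprintf("%s=%.3f", x$model_names, pk), collapse = ", "), "\n")
  invisible(x)
}
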