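#' Fit a shrinkage-regularized LDA classifier
#'
#' Multiclass linear discriminant analysis with equal class covariances:
#' per-class means plus a pooled within-class covariance shrunk toward a
#' scaled identity \eqn{\nu I} (\eqn{\nu} = mean eigenvalue). With
#' `shrinkage = "auto"` the intensity is the analytic (Ledoit-Wolf-type)
#' optimum estimated from the training data, which is parameter-free and
#' guarantees a positive-definite covariance even when trials < channels.
#' Class priors are uniform; prediction is the arg-max of the linear
#' discriminant scores with ties broken toward the lowest class index.
#'
#' @param x numeric matrix, trials x channels.
#' @param y class labels (factor or vector); >= 2 classes with >= 2
#'   trials each.
#' @param shrinkage `"auto"` or a fixed intensity in `[0, 1]`.
#' @return an `lda_model` with `class_means`, `pooled_covariance`,
#'   `shrinkage_intensity`, `classes`, and discriminant weights.
#' @examples
#' x <- rbind(matrix(rnorm(40, -1), 20), matrix(rnorm(40, 1), 20))
#' y <- rep(c("a", "b"), each = 20)
#' m <- fit_lda(x, y)
#' mean(predict(m, x) == y)
#' @export
fit_lda <- function(x, y, shrinkage = "auto") {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("each class needs at least 2 training trials")
  n <- nrow(x); p <- ncol(x); K <- nlevels(y)
  M <- t(vapply(levels(y), function(l) colMeans(x[y == l, , drop = FALSE]),
                numeric(p)))
  Z <- x - M[as.integer(y), , drop = FALSE]
  S <- crossprod(Z) / n
  nu <- sum(diag(S)) / p
  if (identical(shrinkage, "auto")) {
    s2 <- sum(S^2)
    sum4 <- sum(rowSums(Z^2)^2)
    b2 <- (sum4 - n * s2) / n^2
    d2 <- s2 - p * nu^2
    lam <- if (d2 > 1e-300) min(1, max(0, b2 / d2)) else 1
  } else {
    lam <- as.numeric(shrinkage)
    if (is.na(lam) || lam < 0 || lam > 1) stop("shrinkage must be in [0,1]")
  }
  Sig <- (1 - lam) * S + diag(lam * nu, p)
  Sinv <- tryCatch(chol2inv(chol(Sig)), error = function(e)
    stop("singular pooled covariance; increase shrinkage", call. = FALSE))
  W <- Sinv %*% t(M)
  b <- -0.5 * rowSums(M * (M %*% Sinv))
  structure(list(class_means = M, pooled_covariance = Sig,
                 shrinkage_intensity = lam, classes = levels(y),
                 weights = W, bias = b),
            class = "lda_model")
}

#' @param object an `lda_model`.
#' @param newdata matrix of trials x channels.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @rdname fit_lda
#' @export
predict.lda_model <- function(object, newdata, ...) {
  sc <- as.matrix(newdata) %*% object$weights
  sc <- sweep(sc, 2, object$bias, "+")
  object$classes[max.col(sc, ties.method = "first")]
}

# ---- shared cross-validation helpers -------------------------------------

# leave-one-run-out train/test index lists on a trial table
loro_folds <- function(trials) {
  runs <- sort(unique(trials$run))
  if (length(runs) < 2) stop("leave-one-run-out needs >= 2 runs")
  idx <- seq_len(nrow(trials))
  list(runs = runs,
       train = lapply(runs, function(r) idx[trials$run != r]),
       test = lapply(runs, function(r) idx[trials$run == r]))
}

check_folds_have_classes <- function(y, folds) {
  lev <- levels(y)
  for (i in seq_along(folds$train)) {
    miss <- setdiff(lev, unique(as.character(y[folds$train[[i]]])))
    if (length(miss))
      stop("class '", miss[1], "' absent from training data when run ",
           folds$runs[i], " is held out")
  }
  invisible(TRUE)
}

pick_rendering <- function(epochs, rendering) {
  if (is.null(rendering)) return(epochs)
  stopifnot(rendering %in% c("intact", "silhouette"))
  subset_epochs(epochs, epochs$trials$rendering == rendering)
}

label_factor <- function(trials, label_column) {
  if (!label_column %in% names(trials))
    stop("trial table has no column '", label_column, "'")
  if (label_column == "shape_class" &&
      any(trials$shape_class == "median"))
    stop("median stimuli present; call filter_medians() before ",
         "shape-class decoding")
  factor(trials[[label_column]])
}
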