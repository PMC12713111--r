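# shared fixtures, built once per test run and memoized
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fix_set <- function() memo("set", build_stimulus_set(seed = 1))

fix_design <- function() memo("design", build_design(
  fix_set(), n_runs_per_rendering = 4L, repeats_per_run = 2L,
  targets_per_run_range = c(2L, 4L), seed = 2L))

# one subject, default effects
fix_epochs <- function() memo("epochs", simulate_subject(
  fix_design(), fix_set(), subject_seed = 11L))

# one subject, zero effects (pure noise)
fix_null_epochs <- function() memo("null_epochs", simulate_subject(
  fix_design(), fix_set(), spec = null_effect_spec(), subject_seed = 12L))

# small LDA problem generator: K gaussian classes in p dims
make_gaussians <- function(n_per, mu, sd = 1, seed = 1) {
  set.seed(seed)
  K <- nrow(mu)
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rnorm(n_per * ncol(mu), sd = sd), n_per) +
      matrix(mu[k, ], n_per, ncol(mu), byrow = TRUE)))
  list(x = x, y = factor(rep(letters[seq_len(K)], each = n_per)))
}

# brute-force shrinkage discriminant, independent of the package paths:
# recomputes the analytic shrinkage target and intensity from first
# principles and classifies via explicit Mahalanobis-style scores
brute_lda_predict <- function(xtr, ytr, xte) {
  ytr <- factor(ytr)
  lev <- levels(ytr)
  p <- ncol(xtr)
  mus <- lapply(lev, function(l) colMeans(xtr[ytr == l, , drop = FALSE]))
  Z <- xtr
  for (i in seq_len(nrow(xtr)))
    Z[i, ] <- xtr[i, ] - mus[[match(ytr[i], lev)]]
  n <- nrow(Z)
  S <- t(Z) %*% Z / n
  nu <- mean(diag(S))
  b2 <- (sum(apply(Z, 1, function(z) sum(z^2))^2) - n * sum(S * S)) / n^2
  d2 <- sum(S * S) - p * nu^2
  lam <- if (d2 > 0) min(1, max(0, b2 / d2)) else 1
  Sig <- (1 - lam) * S + diag(lam * nu, p)
  Si <- solve(Sig)
  scores <- sapply(mus, function(m)
    xte %*% Si %*% m - 0.5 * drop(t(m) %*% Si %*% m))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  lev[apply(scores, 1, which.max)]
}

# independent oracle: Gauss-Legendre quadrature after delta = r*tan(u),
# which maps the Cauchy prior to a flat density 1/pi on (-pi/2, pi/2)
oracle_jzs_bf <- function(tstat, n, r = 0.707) {
  gl <- pracma::gaussLegendre(401, -pi / 2 + 1e-12, pi / 2 - 1e-12)
  lik <- function(delta) suppressWarnings(dt(tstat, n - 1,
                                             ncp = delta * sqrt(n)))
  m1 <- sum(gl$w * lik(r * tan(gl$x))) / pi
  m1 / lik(0)
}

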