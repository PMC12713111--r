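// Compiled kernels: raster boundary tracing for the aspect-ratio statistic,
// and the shrinkage-LDA cross-validation engine used by all decoding analyses.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------------------------------------------------------------------------
// Mask perimeter
// ---------------------------------------------------------------------------

// Moore-neighbour boundary tracing on one connected component, starting from
// its first pixel in row-major scan order. Returns the ordered closed contour
// (row, col), pixel-centre coordinates.
static std::vector<std::pair<int, int>> trace_contour(
    const Mat<int>& lab, int comp, int r0, int c0) {
  // neighbour offsets clockwise starting W
  static const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<std::pair<int, int>> contour;
  contour.push_back({r0, c0});
  int b = 0;  // backtrack direction (points at a known background neighbour)
  int cr = r0, cc = c0;
  const int H = lab.n_rows, W = lab.n_cols;
  const size_t maxlen = (size_t)10 * H * W;
  while (true) {
    bool found = false;
    for (int k = 0; k < 8; k++) {
      int d = (b + k) % 8;
      int nr = cr + dr[d], nc = cc + dc[d];
      if (nr >= 0 && nr < H && nc >= 0 && nc < W && lab(nr, nc) == comp) {
        contour.push_back({nr, nc});
        b = (d + 5) % 8;
        cr = nr;
        cc = nc;
        found = true;
        break;
      }
    }
    if (!found) break;  // isolated pixel
    size_t n = contour.size();
    if (n > 3 && contour[n - 1] == contour[1] && contour[n - 2] == contour[0]) {
      contour.pop_back();
      contour.pop_back();
      break;
    }
    if (n > maxlen) Rcpp::stop("boundary tracing failed to terminate");
  }
  return contour;
}

static double polygon_length(const std::vector<std::pair<int, int>>& pts) {
  double L = 0.0;
  size_t n = pts.size();
  for (size_t i = 0; i < n; i++) {
    size_t j = (i + 1) % n;
    double dy = pts[j].first - pts[i].first;
    double dx = pts[j].second - pts[i].second;
    L += std::sqrt(dx * dx + dy * dy);
  }
  return L;
}

// Total outer-boundary perimeter of a binary mask. Each 8-connected
// component's outer contour is traced, resampled every `stride` points and
// measured as a closed polygon (reduces digitization bias of raw chain
// codes). Interior holes are ignored. Single-pixel components contribute 4.
// [[Rcpp::export]]
double cpp_mask_perimeter(const Rcpp::LogicalMatrix& mask, int stride) {
  const int H = mask.nrow(), W = mask.ncol();
  Mat<int> lab(H, W, fill::zeros);
  // label components (8-connectivity, BFS)
  int ncomp = 0;
  std::vector<int> qr, qc;
  for (int c = 0; c < W; c++)
    for (int r = 0; r < H; r++)
      if (mask(r, c) && lab(r, c) == 0) {
        ncomp++;
        lab(r, c) = ncomp;
        qr.assign(1, r);
        qc.assign(1, c);
        while (!qr.empty()) {
          int rr = qr.back(), cc = qc.back();
          qr.pop_back();
          qc.pop_back();
          for (int a = -1; a <= 1; a++)
            for (int b = -1; b <= 1; b++) {
              int nr = rr + a, nc = cc + b;
              if (nr >= 0 && nr < H && nc >= 0 && nc < W && mask(nr, nc) &&
                  lab(nr, nc) == 0) {
                lab(nr, nc) = ncomp;
                qr.push_back(nr);
                qc.push_back(nc);
              }
            }
        }
      }
  if (ncomp == 0) return 0.0;
  double P = 0.0;
  // first scan-order pixel of each component (row-major: by row, then col)
  std::vector<int> sr(ncomp + 1, -1), sc(ncomp + 1, -1);
  for (int r = 0; r < H; r++)
    for (int c = 0; c < W; c++) {
      int k = lab(r, c);
      if (k > 0 && sr[k] < 0) {
        sr[k] = r;
        sc[k] = c;
      }
    }
  for (int k = 1; k <= ncomp; k++) {
    std::vector<std::pair<int, int>> ct = trace_contour(lab, k, sr[k], sc[k]);
    if (ct.size() == 1) {
      P += 4.0;
    } else if ((int)ct.size() < 3 * stride) {
      P += polygon_length(ct);
    } else {
      std::vector<std::pair<int, int>> sub;
      for (size_t i = 0; i < ct.size(); i += stride) sub.push_back(ct[i]);
      P += polygon_length(sub);
    }
  }
  return P;
}

// ---------------------------------------------------------------------------
// Shrinkage LDA engine
// ---------------------------------------------------------------------------

// Ledoit-Wolf-type analytic shrinkage of the pooled within-class covariance
// toward nu*I (nu = mean eigenvalue). Fills W (p x K) and bias (K) of the
// linear discriminant; uniform class priors; MLE covariance (divide by n).
static void lda_train(const mat& Xtr, const Col<int>& ytr, int K, mat& W,
                      vec& bias, double fixed_shrink) {
  const int n = Xtr.n_rows, p = Xtr.n_cols;
  mat M(K, p, fill::zeros);
  vec cnt(K, fill::zeros);
  for (int i = 0; i < n; i++) {
    M.row(ytr(i)) += Xtr.row(i);
    cnt(ytr(i)) += 1.0;
  }
  for (int k = 0; k < K; k++) {
    if (cnt(k) < 1) Rcpp::stop("class %d absent from training set", k + 1);
    M.row(k) /= cnt(k);
  }
  mat Z = Xtr;
  for (int i = 0; i < n; i++) Z.row(i) -= M.row(ytr(i));
  mat S = (Z.t() * Z) / n;
  double nu = trace(S) / p;
  double lam;
  if (fixed_shrink >= 0) {
    lam = fixed_shrink;
  } else {
    double s2 = accu(S % S);
    double sum4 = 0.0;
    for (int i = 0; i < n; i++) {
      double q = accu(square(Z.row(i)));
      sum4 += q * q;
    }
    double b2 = (sum4 - n * s2) / ((double)n * n);
    double d2 = s2 - p * nu * nu;
    lam = (d2 > 1e-300) ? std::min(1.0, std::max(0.0, b2 / d2)) : 1.0;
  }
  mat Sig = (1.0 - lam) * S;
  Sig.diag() += lam * nu;
  mat Sinv;
  if (!inv_sympd(Sinv, Sig))
    Rcpp::stop("singular pooled covariance; increase shrinkage");
  W = Sinv * M.t();                 // p x K
  bias = -0.5 * sum(M % (M * Sinv), 1);  // K
}

// argmax with lowest-index tie-break
static inline int pred_class(const rowvec& score) {
  int best = 0;
  double bv = score(0);
  for (unsigned k = 1; k < score.n_elem; k++)
    if (score(k) > bv) {
      bv = score(k);
      best = k;
    }
  return best;
}

// Cross-validated accuracy. X: trials x channels x times cube; y0: 0-based
// integer labels; train_idx/test_idx: parallel lists of 1-based trial index
// vectors (one entry per fold / train-test set). Returns:
//   diag_only = true : T x 1 matrix, mean over sets of per-set accuracy
//                      (train and test at the same timepoint)
//   diag_only = false: T x T matrix (rows = train time, cols = test time)
// [[Rcpp::export]]
arma::mat cpp_lda_cv(const arma::cube& X, const arma::ivec& y0,
                     const Rcpp::List& train_idx, const Rcpp::List& test_idx,
                     bool diag_only, double fixed_shrink) {
  const int T = X.n_slices;
  const int nsets = train_idx.size();
  const int K = y0.max() + 1;
  mat acc(T, diag_only ? 1 : T, fill::zeros);
  Col<int> y = conv_to<Col<int>>::from(y0);
  for (int s = 0; s < nsets; s++) {
    uvec tr = Rcpp::as<uvec>(train_idx[s]) - 1;
    uvec te = Rcpp::as<uvec>(test_idx[s]) - 1;
    Col<int> ytr = y.elem(tr), yte = y.elem(te);
    const int nte = te.n_elem;
    for (int t = 0; t < T; t++) {
      mat W;
      vec bias;
      lda_train(X.slice(t).rows(tr), ytr, K, W, bias, fixed_shrink);
      if (diag_only) {
        mat score = X.slice(t).rows(te) * W;
        int correct = 0;
        for (int i = 0; i < nte; i++)
          if (pred_class(score.row(i) + bias.t()) == yte(i)) correct++;
        acc(t, 0) += (double)correct / nte;
      } else {
        for (int t2 = 0; t2 < T; t2++) {
          mat score = X.slice(t2).rows(te) * W;
          int correct = 0;
          for (int i = 0; i < nte; i++)
            if (pred_class(score.row(i) + bias.t()) == yte(i)) correct++;
          acc(t, t2) += (double)correct / nte;
        }
      }
    }
  }
  return acc / nsets;
}

// Per-trial cross-validated predictions at every timepoint (0-based classes).
// Returns a list (one element per set) of ntest x T integer matrices.
// [[Rcpp::export]]
Rcpp::List cpp_lda_cv_pred(const arma::cube& X, const arma::ivec& y0,
                           const Rcpp::List& train_idx,
                           const Rcpp::List& test_idx, double fixed_shrink) {
  const int T = X.n_slices;
  const int nsets = train_idx.size();
  const int K = y0.max() + 1;
  Col<int> y = conv_to<Col<int>>::from(y0);
  Rcpp::List out(nsets);
  for (int s = 0; s < nsets; s++) {
    uvec tr = Rcpp::as<uvec>(train_idx[s]) - 1;
    uvec te = Rcpp::as<uvec>(test_idx[s]) - 1;
    Col<int> ytr = y.elem(tr);
    const int nte = te.n_elem;
    Rcpp::IntegerMatrix pred(nte, T);
    for (int t = 0; t < T; t++) {
      mat W;
      vec bias;
      lda_train(X.slice(t).rows(tr), ytr, K, W, bias, fixed_shrink);
      mat score = X.slice(t).rows(te) * W;
      for (int i = 0; i < nte; i++)
        pred(i, t) = pred_class(score.row(i) + bias.t());
    }
    out[s] = pred;
  }
  return out;
}
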