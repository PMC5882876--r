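// Elastic-net penalized logistic regression by coordinate descent inside an
// iteratively reweighted least-squares (IRLS) loop, plus a repeated
// cross-validation tuner. The objective minimized (intercept unpenalized,
// features assumed standardized by the caller) is
//   (1/n) * sum_i -[y_i eta_i - log(1 + exp(eta_i))]
//     + lambda * ( alpha * ||beta||_1 + (1 - alpha)/2 * ||beta||_2^2 ).
// A step-halving safeguard keeps the objective non-increasing across sweeps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static double penalized_objective(const vec& y, const vec& eta,
                                  const vec& beta, double alpha,
                                  double lambda) {
  const int n = y.n_elem;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) ll += y(i) * eta(i) - softplus(eta(i));
  double pen = lambda * (alpha * norm(beta, 1) +
                         0.5 * (1.0 - alpha) * dot(beta, beta));
  return -ll / n + pen;
}

// Fit one (alpha, lambda) point; beta/b0 are warm-start in, solution out.
// Returns the objective trace (one entry per IRLS sweep, after safeguarding).
static std::vector<double> fit_point(const mat& X, const vec& y, double alpha,
                                     double lambda, vec& beta, double& b0,
                                     double tol, int maxit) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  vec eta = b0 + X * beta;
  std::vector<double> trace;
  double obj = penalized_objective(y, eta, beta, alpha, lambda);
  trace.push_back(obj);
  const double lam_l1 = lambda * alpha;
  const double lam_l2 = lambda * (1.0 - alpha);

  for (int it = 0; it < maxit; ++it) {
    vec beta_old = beta;
    double b0_old = b0;

    vec pr = 1.0 / (1.0 + exp(-eta));
    vec w = pr % (1.0 - pr);
    w.transform([](double v) { return v < 1e-5 ? 1e-5 : v; });
    vec z = eta + (y - pr) / w;
    vec r = z - eta;  // residual z - b0 - X beta
    double wsum = accu(w);
    vec v(p);
    for (int k = 0; k < p; ++k) {
      v(k) = dot(w, square(X.col(k))) / n;
    }
    // inner coordinate descent on the weighted quadratic approximation
    for (int inner = 0; inner < 500; ++inner) {
      double maxdel = 0.0;
      double db0 = dot(w, r) / wsum;
      b0 += db0;
      r -= db0;
      if (std::abs(db0) > maxdel) maxdel = std::abs(db0);
      for (int k = 0; k < p; ++k) {
        double bk = beta(k);
        double u = dot(w % X.col(k), r) / n + v(k) * bk;
        double bnew = soft_threshold(u, lam_l1) / (v(k) + lam_l2);
        double d = bnew - bk;
        if (d != 0.0) {
          beta(k) = bnew;
          r -= d * X.col(k);
          if (std::abs(d) > maxdel) maxdel = std::abs(d);
        }
      }
      if (maxdel < 1e-9) break;
    }
    eta = z - r;
    double obj_new = penalized_objective(y, eta, beta, alpha, lambda);
    // step-halving safeguard: IRLS is not guaranteed monotone
    int halvings = 0;
    while (obj_new > obj + 1e-13 && halvings < 40) {
      beta = 0.5 * (beta + beta_old);
      b0 = 0.5 * (b0 + b0_old);
      eta = b0 + X * beta;
      obj_new = penalized_objective(y, eta, beta, alpha, lambda);
      ++halvings;
    }
    if (obj_new > obj) {  // no improving step: restore and stop
      beta = beta_old;
      b0 = b0_old;
      eta = b0 + X * beta;
      break;
    }
    double delta_obj = obj - obj_new;
    obj = obj_new;
    trace.push_back(obj);
    if (delta_obj < tol) break;
  }
  return trace;
}

// [[Rcpp::export]]
Rcpp::List enet_path_cpp(const arma::mat& Xs, const arma::vec& y, double alpha,
                         const arma::vec& lambdas, double tol, int maxit) {
  const int p = Xs.n_cols;
  const int L = lambdas.n_elem;
  mat betas(p, L, fill::zeros);
  vec b0s(L, fill::zeros);
  double ybar = mean(y);
  vec beta(p, fill::zeros);
  double b0 = std::log(ybar / (1.0 - ybar));
  Rcpp::List traces(L);
  for (int l = 0; l < L; ++l) {
    std::vector<double> tr = fit_point(Xs, y, alpha, lambdas(l), beta, b0,
                                       tol, maxit);
    betas.col(l) = beta;
    b0s(l) = b0;
    traces[l] = Rcpp::NumericVector(tr.begin(), tr.end());
  }
  return Rcpp::List::create(Rcpp::Named("beta") = betas,
                            Rcpp::Named("b0") = b0s,
                            Rcpp::Named("trace") = traces);
}

// Mann-Whitney AUC with tie handling via average ranks.
static double auc_rank(const vec& score, const vec& y) {
  const int n = score.n_elem;
  uvec ord = sort_index(score);
  vec ranks(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score(ord(j + 1)) == score(ord(i))) ++j;
    double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) ranks(ord(k)) = avg;
    i = j + 1;
  }
  double n1 = accu(y);
  double n0 = n - n1;
  if (n1 == 0 || n0 == 0) return datum::nan;
  double rsum = dot(ranks, y);
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// Repeated cross-validated out-of-fold AUC over an (alpha, lambda) grid.
// fold_ids: repetitions x n matrix of fold labels in 1..folds.
// lambdas: nlambda x nalpha matrix (one descending path per alpha).
// [[Rcpp::export]]
Rcpp::List enet_cv_auc_cpp(const arma::mat& X, const arma::vec& y,
                           const arma::imat& fold_ids, const arma::vec& alphas,
                           const arma::mat& lambdas, double tol, int maxit) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int nrep = fold_ids.n_rows;
  const int nalpha = alphas.n_elem;
  const int nlambda = lambdas.n_rows;
  const int folds = fold_ids.max();

  mat auc_sum(nlambda, nalpha, fill::zeros);
  mat auc_cnt(nlambda, nalpha, fill::zeros);

  for (int r = 0; r < nrep; ++r) {
    for (int f = 1; f <= folds; ++f) {
      uvec tr_idx = find(fold_ids.row(r).t() != f);
      uvec te_idx = find(fold_ids.row(r).t() == f);
      if (tr_idx.n_elem == 0 || te_idx.n_elem == 0) continue;
      vec ytr = y(tr_idx);
      vec yte = y(te_idx);
      double ybar = mean(ytr);
      if (ybar <= 0.0 || ybar >= 1.0) continue;       // single-class training fold
      if (accu(yte) == 0 || accu(yte) == yte.n_elem) continue;  // AUC undefined
      mat Xtr = X.rows(tr_idx);
      mat Xte = X.rows(te_idx);
      rowvec mu = mean(Xtr, 0);
      rowvec sdv = stddev(Xtr, 0, 0);
      sdv.transform([](double v) { return v <= 0 ? 1.0 : v; });
      Xtr.each_row() -= mu;
      Xtr.each_row() /= sdv;
      Xte.each_row() -= mu;
      Xte.each_row() /= sdv;
      for (int a = 0; a < nalpha; ++a) {
        vec beta(p, fill::zeros);
        double b0 = std::log(ybar / (1.0 - ybar));
        for (int l = 0; l < nlambda; ++l) {
          fit_point(Xtr, ytr, alphas(a), lambdas(l, a), beta, b0, tol, maxit);
          vec eta = b0 + Xte * beta;
          double auc = auc_rank(eta, yte);
          if (std::isfinite(auc)) {
            auc_sum(l, a) += auc;
            auc_cnt(l, a) += 1.0;
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("auc_sum") = auc_sum,
                            Rcpp::Named("n_folds") = auc_cnt);
}
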