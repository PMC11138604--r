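// Cross-validated kernel ridge density-ratio fit.
//
// For each (sigma, lambda) grid point the coefficient vector solves
//   (H + lambda I) theta = h,
// with H the alpha-weighted Gram matrix of the two segments and h the mean
// kernel vector of the p segment. Model selection minimizes the held-out
// least-squares objective J = 0.5 t(theta) H theta - t(h) theta (ridge term
// excluded at evaluation), averaged over pre-assigned folds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sqdist(const mat& A, const mat& B) {
  mat D = -2.0 * (A * B.t());
  D.each_col() += sum(square(A), 1);
  D.each_row() += sum(square(B), 1).t();
  D.elem(find(D < 0)).zeros();
  return D;
}

// [[Rcpp::export]]
Rcpp::List cv_fit_cpp(const arma::mat& Yp, const arma::mat& Yq, const arma::mat& C,
                      const arma::vec& sigmas, const arma::vec& lambdas, double alpha,
                      const arma::ivec& fold_p, const arma::ivec& fold_q, int n_folds) {
  const int np = Yp.n_rows, nq = Yq.n_rows;
  const int ns = sigmas.n_elem, nl = lambdas.n_elem;
  const bool do_cv = (n_folds >= 2) && (ns * nl > 1);

  mat D2p = sqdist(Yp, C), D2q = sqdist(Yq, C);
  mat cvJ(ns, nl);
  cvJ.fill(datum::nan);

  double bestJ = datum::inf;
  int bsi = 0, bli = 0;

  if (do_cv) {
    std::vector<uvec> idx_p(n_folds), idx_q(n_folds);
    for (int f = 0; f < n_folds; ++f) {
      idx_p[f] = find(fold_p == f);
      idx_q[f] = find(fold_q == f);
    }
    for (int si = 0; si < ns; ++si) {
      const double s2 = 2.0 * sigmas[si] * sigmas[si];
      mat Kp = exp(-D2p / s2), Kq = exp(-D2q / s2);
      mat Cp = Kp.t() * Kp, Cq = Kq.t() * Kq;
      rowvec hp = sum(Kp, 0);

      std::vector<mat> Cpf(n_folds), Cqf(n_folds);
      std::vector<rowvec> hpf(n_folds);
      std::vector<int> npf(n_folds), nqf(n_folds);
      for (int f = 0; f < n_folds; ++f) {
        npf[f] = idx_p[f].n_elem;
        nqf[f] = idx_q[f].n_elem;
        mat Kpf = Kp.rows(idx_p[f]), Kqf = Kq.rows(idx_q[f]);
        Cpf[f] = Kpf.t() * Kpf;
        Cqf[f] = Kqf.t() * Kqf;
        hpf[f] = sum(Kpf, 0);
      }

      for (int li = 0; li < nl; ++li) {
        double Jsum = 0.0;
        int used = 0;
        for (int f = 0; f < n_folds; ++f) {
          const int nptr = np - npf[f], nqtr = nq - nqf[f];
          if (npf[f] == 0 || nqf[f] == 0 || nptr == 0 || nqtr == 0) continue;
          mat Htr = alpha * (Cp - Cpf[f]) / nptr + (1.0 - alpha) * (Cq - Cqf[f]) / nqtr;
          vec htr = conv_to<vec>::from(hp - hpf[f]) / nptr;
          Htr.diag() += lambdas[li];
          vec th = solve(Htr, htr, solve_opts::likely_sympd);
          mat Hva = alpha * Cpf[f] / npf[f] + (1.0 - alpha) * Cqf[f] / nqf[f];
          vec hva = conv_to<vec>::from(hpf[f]) / npf[f];
          Jsum += 0.5 * dot(th, Hva * th) - dot(hva, th);
          ++used;
        }
        if (used == 0) Rcpp::stop("cross-validation produced no usable folds");
        const double J = Jsum / used;
        cvJ(si, li) = J;
        // strict improvement: ties keep the earlier (smaller sigma, then
        // smaller lambda) grid point
        if (J < bestJ) { bestJ = J; bsi = si; bli = li; }
      }
    }
  }

  // final fit on all samples at the selected grid point
  const double s2 = 2.0 * sigmas[bsi] * sigmas[bsi];
  mat Kp = exp(-D2p / s2), Kq = exp(-D2q / s2);
  mat H = alpha * (Kp.t() * Kp) / np + (1.0 - alpha) * (Kq.t() * Kq) / nq;
  vec h = conv_to<vec>::from(sum(Kp, 0)) / np;
  mat A = H;
  A.diag() += lambdas[bli];
  vec theta = solve(A, h, solve_opts::likely_sympd);
  const double resid = norm(A * theta - h);

  return Rcpp::List::create(
      Rcpp::Named("sigma_index") = bsi + 1,
      Rcpp::Named("lambda_index") = bli + 1,
      Rcpp::Named("theta") = theta,
      Rcpp::Named("rp") = vec(Kp * theta),
      Rcpp::Named("rq") = vec(Kq * theta),
      Rcpp::Named("cv") = cvJ,
      Rcpp::Named("residual") = resid);
}
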