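#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Greedy forward variable selection in PCA score space.
//
// Z:   autoscaled observations x features matrix (zero-variance features
//      must arrive as all-zero columns)
// C:   crossprod(Z) (features x features), passed in so leave-one-out
//      callers can precompute it once per fold
// cls: 0/1 class indicator per observation (each class >= 2 members)
// n_pc, budget: number of leading PCs scored / features to rank
//
// At each step every unranked feature is tentatively added, the candidate
// set's correlation-matrix eigendecomposition gives the PCA of the
// autoscaled candidate submatrix, and the discrimination score is
// |class-mean difference of the scores| / pooled within-class sd, summed
// over the first n_pc components. Perfect separation (pooled sd = 0 with
// unequal means) is an +Inf sentinel that outranks every finite score.
// Ties keep the earliest candidate, so the caller controls the tie-break
// by passing columns in ascending identifier order.
//
// standardize = true divides the class-mean score difference by the
// pooled within-class sd; false uses the raw difference.
// [[Rcpp::export]]
Rcpp::List rank_pca_greedy_cpp(const arma::mat& Z, const arma::mat& C,
                               const arma::uvec& cls, int n_pc, int budget,
                               bool standardize) {
  const uword p = Z.n_cols;
  uvec g1 = find(cls == 1), g0 = find(cls == 0);
  const double n1 = (double)g1.n_elem, n0 = (double)g0.n_elem;

  std::vector<uword> sel;
  std::vector<double> dsel;
  sel.reserve(budget);
  dsel.reserve(budget);
  std::vector<bool> used(p, false);

  for (int step = 0; step < budget; ++step) {
    double bestD = -1.0;
    uword best = 0;
    bool bestInf = false, found = false;

    const uword k = sel.size() + 1;
    uvec cand(k);
    for (uword s = 0; s + 1 < k; ++s) cand[s] = sel[s];

    for (uword j = 0; j < p; ++j) {
      if (used[j]) continue;
      cand[k - 1] = j;

      mat M = C.submat(cand, cand);
      vec eval;
      mat evec;
      if (!eig_sym(eval, evec, M)) continue;

      const int use = std::min<int>(n_pc, (int)k);
      double D = 0.0;
      bool inf = false;
      for (int c = 0; c < use; ++c) {
        // eig_sym returns ascending eigenvalues; take from the top
        vec v = evec.col(k - 1 - c);
        vec t = Z.cols(cand) * v;
        const double m1 = mean(t(g1)), m0 = mean(t(g0));
        const double s1 = (n1 > 1) ? var(t(g1)) : 0.0;
        const double s0 = (n0 > 1) ? var(t(g0)) : 0.0;
        const double sp =
            std::sqrt(((n1 - 1.0) * s1 + (n0 - 1.0) * s0) / (n1 + n0 - 2.0));
        const double d = std::fabs(m1 - m0);
        if (!standardize) {
          D += d;
        } else if (sp < 1e-12) {
          if (d > 1e-9) inf = true;  // else contributes 0
        } else {
          D += d / sp;
        }
      }

      if (inf) {
        if (!bestInf) {
          bestInf = true;
          best = j;
          bestD = datum::inf;
          found = true;
        }
      } else if (!bestInf && (!found || D > bestD)) {
        bestD = D;
        best = j;
        found = true;
      }
    }

    if (!found) break;
    sel.push_back(best);
    used[best] = true;
    dsel.push_back(bestD);
  }

  Rcpp::IntegerVector order(sel.size());
  Rcpp::NumericVector score(dsel.size());
  for (size_t i = 0; i < sel.size(); ++i) {
    order[i] = (int)sel[i] + 1;  // 1-based for R
    score[i] = dsel[i];
  }
  return Rcpp::List::create(Rcpp::Named("order") = order,
                            Rcpp::Named("score") = score);
}
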