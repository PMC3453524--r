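// Gibbs sampler for the polygenic, genomic-mixture and combined models.
// All randomness flows through R's RNG so chains are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Positive-truncated normal draw: inverse CDF for moderate truncation,
// exponential rejection (Robert 1995) deep in the tail.
static double rtnorm_pos(double m, double sd) {
  double alpha = -m / sd;
  if (alpha < 5.0) {
    double plo = R::pnorm(0.0, m, sd, 1, 0);
    double u = unif_rand();
    double p = plo + u * (1.0 - plo);
    if (p >= 1.0) p = 1.0 - 1e-16;
    double z = R::qnorm(p, m, sd, 1, 0);
    if (z > 0.0) return z;
    // numerically degenerate; fall through to rejection
    alpha = std::max(alpha, 0.0);
  }
  double lam = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (;;) {
    double z = alpha - std::log(unif_rand()) / lam;
    double rho = std::exp(-0.5 * (z - lam) * (z - lam));
    if (unif_rand() <= rho) return m + sd * z;
  }
}

static inline double scaled_inv_chisq(double ss, double df, double lower) {
  double x = ss / R::rchisq(df);
  return (x < lower) ? lower : x;
}

// [[Rcpp::export]]
List gibbs_core(const arma::vec& y,
                const arma::mat& X,            // nObs x p fixed/covariate cols
                const IntegerVector& cage,     // 0-based per obs, -1 = none
                int nCage,
                const arma::mat& W,            // nObs x nc marker design
                const IntegerVector& colMarker,// 0-based marker per column
                int nMark,
                const IntegerVector& anim,     // 0-based pedigree idx per obs
                int N,
                const IntegerVector& AiP, const IntegerVector& AiI,
                const NumericVector& AiX,      // dgCMatrix slots of A-inverse
                bool hasU, bool hasG, bool hasCage,
                double pi1, double varG0,
                int niter, int burnin, int thin,
                List opts) {
  const int nObs = y.n_elem;
  const int p = X.n_cols;
  const int nc = hasG ? W.n_cols : 0;

  const double varE0 = as<double>(opts["varE0"]);
  const double varC0 = as<double>(opts["varC0"]);
  const double varU0 = as<double>(opts["varU0"]);
  const double varG10 = as<double>(opts["varG10"]);
  const bool fixVarE = as<bool>(opts["fixVarE"]);
  const bool fixVarC = as<bool>(opts["fixVarC"]);
  const bool fixVarU = as<bool>(opts["fixVarU"]);
  const bool fixVarG1 = as<bool>(opts["fixVarG1"]);
  const double sFix = as<double>(opts["sFix"]);     // NaN = sample
  const bool deltaFix = as<bool>(opts["deltaFix"]);
  const bool priorOnly = as<bool>(opts["priorOnly"]);
  const double minVar = as<double>(opts["minVar"]);
  const bool haveSFix = R_finite(sFix);

  double mu = priorOnly ? 0.0 : arma::mean(y);
  arma::vec b(std::max(p, 1), arma::fill::zeros);
  arma::vec cg(std::max(nCage, 1), arma::fill::zeros);
  arma::vec u(std::max(N, 1), arma::fill::zeros);
  arma::vec a(std::max(nc, 1), arma::fill::zeros);
  arma::vec s(std::max(nMark, 1), arma::fill::zeros);
  arma::ivec delta(std::max(nMark, 1), arma::fill::ones);
  if (pi1 < 1.0 && !deltaFix) delta.zeros();
  double varE = varE0, varC = varC0, varU = varU0, varG1 = varG10;

  arma::vec e = y - mu;

  // precomputations
  arma::vec xtx(std::max(p, 1));
  for (int k = 0; k < p; ++k) xtx[k] = arma::dot(X.col(k), X.col(k));
  arma::vec colSS(std::max(nc, 1));
  for (int k = 0; k < nc; ++k) colSS[k] = arma::dot(W.col(k), W.col(k));
  std::vector< std::vector<int> > markCols(nMark);
  for (int k = 0; k < nc; ++k) markCols[colMarker[k]].push_back(k);
  std::vector< std::vector<int> > cageObs(std::max(nCage, 1));
  if (hasCage)
    for (int o = 0; o < nObs; ++o)
      if (cage[o] >= 0) cageObs[cage[o]].push_back(o);
  std::vector< std::vector<int> > animObs(std::max(N, 1));
  if (hasU)
    for (int o = 0; o < nObs; ++o) animObs[anim[o]].push_back(o);

  const int nStored = (niter > burnin) ? ((niter - burnin + thin - 1) / thin)
                                       : 0;
  arma::mat outScalar(nStored, 5);
  arma::mat outB(nStored, std::max(p, 1));
  arma::mat outBeta(nStored, std::max(nc, 1));
  arma::mat outS(nStored, std::max(nMark, 1));
  arma::imat outDelta(nStored, std::max(nMark, 1));
  arma::vec uSum(std::max(N, 1), arma::fill::zeros);
  int stored = 0, nZeroSubstantial = 0, nPostBurnin = 0;

  arma::vec w(nObs, arma::fill::zeros);
  const double logPriorOdds =
      (pi1 < 1.0) ? std::log(pi1 / (1.0 - pi1)) : 0.0;

  for (int it = 0; it < niter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    if (!priorOnly) {
      // (i) general mean, flat prior
      e += mu;
      mu = arma::mean(e) + norm_rand() * std::sqrt(varE / nObs);
      e -= mu;
      // fixed effects / covariates, flat priors, single-site
      for (int k = 0; k < p; ++k) {
        e += X.col(k) * b[k];
        double mn = arma::dot(X.col(k), e) / xtx[k];
        b[k] = mn + norm_rand() * std::sqrt(varE / xtx[k]);
        e -= X.col(k) * b[k];
      }
      // (ii) cage effects
      if (hasCage) {
        for (int c = 0; c < nCage; ++c) {
          const std::vector<int>& obs = cageObs[c];
          double sum = 0.0;
          for (size_t t = 0; t < obs.size(); ++t) {
            e[obs[t]] += cg[c];
            sum += e[obs[t]];
          }
          double prec = obs.size() / varE + 1.0 / varC;
          double mn = (sum / varE) / prec;
          cg[c] = mn + norm_rand() / std::sqrt(prec);
          for (size_t t = 0; t < obs.size(); ++t) e[obs[t]] -= cg[c];
        }
      }
      // (iii) polygenic values, single-site with the sparse A-inverse
      if (hasU) {
        for (int i = 0; i < N; ++i) {
          const std::vector<int>& obs = animObs[i];
          double sumE = 0.0;
          for (size_t t = 0; t < obs.size(); ++t) {
            e[obs[t]] += u[i];
            sumE += e[obs[t]];
          }
          double aii = 0.0, soff = 0.0;
          for (int idx = AiP[i]; idx < AiP[i + 1]; ++idx) {
            int j = AiI[idx];
            if (j == i) aii += AiX[idx];
            else soff += AiX[idx] * u[j];
          }
          double prec = obs.size() / varE + aii / varU;
          double mn = (sumE / varE - soff / varU) / prec;
          u[i] = mn + norm_rand() / std::sqrt(prec);
          for (size_t t = 0; t < obs.size(); ++t) e[obs[t]] -= u[i];
        }
      }
    }
    // (iv) markers: joint (delta, s) block with s integrated analytically,
    // then s from its component full conditional, then base effects a
    int nSub = 0;
    if (hasG) {
      for (int j = 0; j < nMark; ++j) {
        const std::vector<int>& cols = markCols[j];
        int dj = 1;
        double sj;
        if (priorOnly) {
          if (pi1 < 1.0 && !deltaFix) dj = (unif_rand() < pi1) ? 1 : 0;
          if (haveSFix) sj = sFix;
          else sj = dj ? rtnorm_pos(0.0, std::sqrt(varG1))
                       : norm_rand() * std::sqrt(varG0);
          delta[j] = dj;
          s[j] = sj;
          for (size_t t = 0; t < cols.size(); ++t) a[cols[t]] = norm_rand();
          if (dj) ++nSub;
          continue;
        }
        // combined column for this marker given current base effects
        w.zeros();
        for (size_t t = 0; t < cols.size(); ++t) w += W.col(cols[t]) * a[cols[t]];
        e += w * s[j];
        double ww = arma::dot(w, w);
        double wy = arma::dot(w, e);
        if (pi1 >= 1.0 || deltaFix) {
          dj = 1;
        } else {
          double v0 = 1.0 / (ww / varE + 1.0 / varG0);
          double m0 = v0 * wy / varE;
          double v1 = 1.0 / (ww / varE + 1.0 / varG1);
          double m1 = v1 * wy / varE;
          double l0 = 0.5 * std::log(v0 / varG0) + 0.5 * m0 * m0 / v0;
          double l1 = 0.5 * std::log(v1 / varG1) + 0.5 * m1 * m1 / v1 +
                      M_LN2 + R::pnorm(m1 / std::sqrt(v1), 0.0, 1.0, 1, 1);
          double lo = logPriorOdds + l1 - l0;
          double pr = 1.0 / (1.0 + std::exp(-lo));
          dj = (unif_rand() < pr) ? 1 : 0;
        }
        if (haveSFix) {
          sj = sFix;
        } else {
          double vg = dj ? varG1 : varG0;
          double v = 1.0 / (ww / varE + 1.0 / vg);
          double mn = v * wy / varE;
          double sdv = std::sqrt(v);
          sj = dj ? rtnorm_pos(mn, sdv) : (mn + norm_rand() * sdv);
        }
        delta[j] = dj;
        s[j] = sj;
        if (dj) ++nSub;
        e -= w * sj;
        // base effects, prior N(0, 1)
        for (size_t t = 0; t < cols.size(); ++t) {
          int k = cols[t];
          e += W.col(k) * (sj * a[k]);
          double prec = sj * sj * colSS[k] / varE + 1.0;
          double mn = sj * arma::dot(W.col(k), e) / varE / prec;
          a[k] = mn + norm_rand() / std::sqrt(prec);
          e -= W.col(k) * (sj * a[k]);
        }
      }
    }
    // (v)-(vi) variances, flat scaled-inverse-chi-square (nu = -2)
    if (!priorOnly) {
      if (!fixVarE && nObs > 2)
        varE = scaled_inv_chisq(arma::dot(e, e), nObs - 2, minVar);
      if (hasCage && !fixVarC && nCage > 2)
        varC = scaled_inv_chisq(arma::dot(cg.head(nCage), cg.head(nCage)),
                                nCage - 2, minVar);
      if (hasU && !fixVarU && N > 2) {
        double q = 0.0;
        for (int i = 0; i < N; ++i)
          for (int idx = AiP[i]; idx < AiP[i + 1]; ++idx)
            q += u[i] * AiX[idx] * u[AiI[idx]];
        varU = scaled_inv_chisq(q, N - 2, minVar);
      }
      if (hasG && !fixVarG1) {
        // weakly informative scaled-inverse-chi-square prior (nu0 = 4,
        // scale = the starting per-marker variance) keeps the update proper
        // even when the substantial component is nearly empty, which would
        // otherwise be an absorbing state at small pi1
        const double nu0 = 4.0;
        double ss = 0.0;
        int n1 = 0;
        for (int j = 0; j < nMark; ++j)
          if (delta[j]) { ss += s[j] * s[j]; ++n1; }
        varG1 = scaled_inv_chisq(nu0 * varG10 + ss, nu0 + n1, minVar);
      }
    }
    if (!std::isfinite(mu) || !std::isfinite(varE) || !std::isfinite(varG1))
      stop("non-finite chain state at iteration %d", it + 1);
    if (it >= burnin) {
      ++nPostBurnin;
      if (hasG && pi1 < 1.0 && nSub == 0) ++nZeroSubstantial;
      if ((it - burnin) % thin == 0) {
        outScalar(stored, 0) = mu;
        outScalar(stored, 1) = varE;
        outScalar(stored, 2) = hasU ? varU : 0.0;
        outScalar(stored, 3) = hasCage ? varC : 0.0;
        outScalar(stored, 4) = hasG ? varG1 : 0.0;
        for (int k = 0; k < p; ++k) outB(stored, k) = b[k];
        for (int k = 0; k < nc; ++k)
          outBeta(stored, k) = s[colMarker[k]] * a[k];
        for (int j = 0; j < nMark; ++j) {
          outDelta(stored, j) = delta[j];
          outS(stored, j) = s[j];
        }
        if (hasU) uSum += u;
        ++stored;
      }
    }
  }

  return List::create(
      _["scalars"] = outScalar, _["b"] = outB, _["beta"] = outBeta,
      _["s"] = outS, _["delta"] = outDelta,
      _["uMean"] = uSum / std::max(stored, 1),
      _["stored"] = stored, _["nZeroSubstantial"] = nZeroSubstantial,
      _["nPostBurnin"] = nPostBurnin);
}
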