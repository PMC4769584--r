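// Gibbs sampler core for the four-component normal-mixture model of variant
// effects with per-class Dirichlet mixture proportions (BayesR / BayesRC).
//
// Model: y = X b + Z a + W v + e,  e ~ N(0, E sigma2_e), E = diag(1/w_j),
// v_i ~ mixture of N(0, gamma_d * sigma2_g), d = 1..4, gamma_1 = 0,
// P_c ~ Dirichlet(alpha_c + beta_c) independently per annotation class c.
//
// The per-iteration scan over variants is memory-bound, so when the raw
// dosages are integers in {0,1,2} the standardized column W_i = (x_i-c_i)/s_i
// is carried as one byte per genotype and the weighted dot product
// W_i' D e is accumulated in single precision against a float image of
// D e (refreshed every sweep); the residual itself always stays in double
// and is refreshed from scratch every `check_every` iterations with the
// worst discrepancy reported, so bookkeeping error is observable. A dense
// single-precision path covers fractional (imputed) dosages.

#include <RcppArmadillo.h>
using namespace Rcpp;

// hot dot products: per-function fast-math vectorization with runtime
// dispatch so generic builds still get SIMD where available
__attribute__((optimize("fast-math", "tree-vectorize"),
               target_clones("avx2", "default")))
static float dot_u8f(const unsigned char* __restrict col,
                     const float* __restrict x, const int n) {
  float a = 0.0f;
  for (int j = 0; j < n; ++j) a += (float)col[j] * x[j];
  return a;
}

__attribute__((optimize("fast-math", "tree-vectorize"),
               target_clones("avx2", "default")))
static float dot_fff(const float* __restrict col, const float* __restrict x,
                     const int n) {
  float a = 0.0f;
  for (int j = 0; j < n; ++j) a += col[j] * x[j];
  return a;
}

// Fisher-Yates permutation of 0..m-1 driven by R's RNG
static void rpermute(std::vector<int>& idx) {
  const int m = (int)idx.size();
  for (int i = 0; i < m; ++i) idx[i] = i;
  for (int i = m - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// one Dirichlet(alpha) draw via gammas
static void rdirichlet(const double* alpha, double* out, const int k) {
  double s = 0.0;
  for (int d = 0; d < k; ++d) {
    out[d] = R::rgamma(alpha[d], 1.0);
    s += out[d];
  }
  if (s <= 0.0) {  // pathological all-zero draw
    for (int d = 0; d < k; ++d) out[d] = 1.0 / k;
    return;
  }
  for (int d = 0; d < k; ++d) out[d] /= s;
}

// scaled inverse-chi-square draw: (nu0*s0 + ss) / chisq(nu0 + n)
static inline double rscinvchisq(const double nu0, const double s0,
                                 const double ss, const int n) {
  double df = nu0 + (double)n;
  double scale = nu0 * s0 + ss;
  if (df <= 0.0 || scale <= 0.0) return ss / std::max(1.0, (double)n);
  return scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayesrc_chain_cpp")]]
List bayesrc_chain_cpp(SEXP W_, SEXP raw_, const arma::vec& center,
                       const arma::vec& scale, const arma::vec& y,
                       const arma::mat& X, const arma::vec& wts,
                       const IntegerVector& class_index, const int n_class,
                       const arma::vec& gamma, const double sigma2_g,
                       const arma::mat& alpha,  // n_class x 4
                       const List& ped,         // empty or list(L, Q, lam)
                       const int n_iter, const int burn_in,
                       const List& opts) {
  const int n = (int)y.n_elem, p = (int)X.n_cols;
  const int K = (int)gamma.n_elem;  // 4 components
  const bool use_raw = raw_ != R_NilValue;
  const unsigned char* xraw = nullptr;
  arma::fmat Wf;
  int m;
  if (use_raw) {
    xraw = RAW(raw_);
    m = (int)(Rf_xlength(raw_) / n);
    if ((int)center.n_elem != m || (int)scale.n_elem != m)
      stop("center/scale length must match the number of variants");
  } else {
    const arma::mat& W = as<arma::mat>(W_);
    if ((int)W.n_rows != n) stop("W row count != length(y)");
    m = (int)W.n_cols;
    Wf = arma::conv_to<arma::fmat>::from(W);
  }
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");
  if ((int)class_index.size() != m) stop("class_index length != ncol(W)");
  for (int i = 0; i < m; ++i)
    if (class_index[i] < 1 || class_index[i] > n_class)
      stop("class index out of range at variant %d", i + 1);
  if (gamma[0] != 0.0) stop("first mixture component must have zero variance");
  for (int d = 1; d < K; ++d)
    if (gamma[d] * sigma2_g <= 0.0)
      stop("non-null component variance must be positive");

  // options / debug switches
  const bool fix_b = opts.containsElementNamed("fix_b") ? as<bool>(opts["fix_b"]) : false;
  const bool fix_p = opts.containsElementNamed("fix_p") ? as<bool>(opts["fix_p"]) : false;
  const bool fix_sigma_e = opts.containsElementNamed("fix_sigma_e") ? as<bool>(opts["fix_sigma_e"]) : false;
  const bool fix_sigma_a = opts.containsElementNamed("fix_sigma_a") ? as<bool>(opts["fix_sigma_a"]) : false;
  const bool geweke = opts.containsElementNamed("geweke") ? as<bool>(opts["geweke"]) : false;
  const bool update_sigma_g = opts.containsElementNamed("update_sigma_g") ? as<bool>(opts["update_sigma_g"]) : false;
  const int check_every = opts.containsElementNamed("check_every") ? as<int>(opts["check_every"]) : 500;
  const double nu_e = opts.containsElementNamed("nu_e") ? as<double>(opts["nu_e"]) : -2.0;
  const double s2_e0 = opts.containsElementNamed("s2_e0") ? as<double>(opts["s2_e0"]) : 0.0;
  const double nu_a = opts.containsElementNamed("nu_a") ? as<double>(opts["nu_a"]) : -2.0;
  const double s2_a0 = opts.containsElementNamed("s2_a0") ? as<double>(opts["s2_a0"]) : 0.0;
  IntegerVector fix_z(0);
  if (opts.containsElementNamed("fix_z") && !Rf_isNull(opts["fix_z"]))
    fix_z = as<IntegerVector>(opts["fix_z"]);
  const bool has_fix_z = fix_z.size() > 0;
  arma::mat P0;
  if (opts.containsElementNamed("P0") && !Rf_isNull(opts["P0"]))
    P0 = as<arma::mat>(opts["P0"]);

  // pedigree (polygenic) machinery: a = L u, L'DL = Q diag(lam) Q'
  const bool has_ped = ped.size() > 0;
  arma::mat Lp, Qp;
  arma::vec lam;
  if (has_ped) {
    Lp = as<arma::mat>(ped["L"]);
    Qp = as<arma::mat>(ped["Q"]);
    lam = as<arma::vec>(ped["lam"]);
    if ((int)Lp.n_rows != n) stop("pedigree factor dimension mismatch");
  }

  // fixed-effect solver pieces
  arma::mat XtDX = X.t() * (X.each_col() % wts);
  arma::mat Lx = arma::chol(XtDX, "lower");

  const double* wd = wts.memptr();
  const double sw = arma::accu(wts);

  // per-variant weighted sums: s_i = W_i' D W_i and swx_i = sum_j w_j x_ij
  arma::vec svec(m), swx(m, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    double ss = 0.0;
    if (use_raw) {
      const unsigned char* col = xraw + (size_t)i * n;
      double sx = 0.0, sxx = 0.0;
      for (int j = 0; j < n; ++j) {
        double x = (double)col[j];
        sx += wd[j] * x;
        sxx += wd[j] * x * x;
      }
      swx[i] = sx;
      double c = center[i], s = scale[i];
      ss = (sxx - 2.0 * c * sx + c * c * sw) / (s * s);
    } else {
      const float* col = Wf.colptr(i);
      for (int j = 0; j < n; ++j) {
        double x = (double)col[j];
        ss += wd[j] * x * x;
      }
    }
    svec[i] = ss;
  }

  // -- initialization (seed-independent) --
  arma::vec b(p, arma::fill::zeros);
  arma::vec v(m, arma::fill::zeros);
  std::vector<int> z(m, 0);  // component index 0..K-1
  arma::mat P(n_class, K);
  P.fill(1.0 / K);
  if (fix_p) {
    if ((int)P0.n_rows != n_class || (int)P0.n_cols != K)
      stop("P0 must be n_class x 4 when fix_p = TRUE");
    P = P0;
  }
  if (has_fix_z) {
    if ((int)fix_z.size() != m) stop("fix_z must have one entry per variant");
    for (int i = 0; i < m; ++i) z[i] = fix_z[i] - 1;
  }
  double s2g = sigma2_g;
  arma::vec a(n, arma::fill::zeros), u(n, arma::fill::zeros);

  // initial b: weighted LS solution, then residual
  {
    arma::vec bh = arma::solve(XtDX, X.t() * (wts % y),
                               arma::solve_opts::likely_sympd);
    if (!fix_b) b = bh;
    else if (opts.containsElementNamed("b0")) b = as<arma::vec>(opts["b0"]);
  }
  arma::vec e = y - X * b;
  arma::vec ew = wts % e;
  // weighted variance of the fixed-effect-adjusted phenotype (initial scale)
  const double vy = arma::dot(e, ew) / sw;
  double sigma2_e = opts.containsElementNamed("sigma_e0")
                        ? as<double>(opts["sigma_e0"]) : 0.5 * vy;
  double sigma2_a = opts.containsElementNamed("sigma_a0")
                        ? as<double>(opts["sigma_a0"]) : 0.05 * vy;
  arma::fvec ewf(n);

  // accumulators (post burn-in)
  arma::vec v_sum(m, arma::fill::zeros), pip_cnt(m, arma::fill::zeros);
  arma::mat comp_cnt(m, K, arma::fill::zeros);
  arma::vec b_sum(p, arma::fill::zeros), a_sum(n, arma::fill::zeros);
  arma::mat P_sum(n_class, K, arma::fill::zeros);
  arma::mat beta_sum(n_class, K, arma::fill::zeros);
  double s2e_sum = 0.0, s2a_sum = 0.0, s2g_sum = 0.0;
  int n_keep = 0;

  // small traces kept for every iteration
  arma::vec s2e_trace(n_iter), s2a_trace(n_iter);
  arma::cube P_trace(n_class, K, n_iter);
  double max_resid_err = 0.0;

  std::vector<int> perm(m);
  arma::mat beta(n_class, K);
  std::vector<double> logPmat(n_class * K);

  for (int it = 0; it < n_iter; ++it) {
    // (1) fixed effects: b | rest ~ N(bhat, (X'DX)^-1 sigma2_e), flat prior
    if (!fix_b) {
      e += X * b;
      arma::vec bh = arma::solve(XtDX, X.t() * (wts % e),
                                 arma::solve_opts::likely_sympd);
      arma::vec zn(p);
      for (int k = 0; k < p; ++k) zn[k] = norm_rand();
      b = bh + std::sqrt(sigma2_e) * arma::solve(arma::trimatu(Lx.t()), zn);
      e -= X * b;
      ew = wts % e;
    }

    // (2) polygenic values and variance
    if (has_ped) {
      e += a;
      arma::vec s = Qp.t() * (Lp.t() * (wts % e));
      double lambda = sigma2_e / sigma2_a;
      arma::vec un(n);
      for (int j = 0; j < n; ++j) {
        double dnj = lam[j] + lambda;
        un[j] = s[j] / dnj + norm_rand() * std::sqrt(sigma2_e / dnj);
      }
      u = Qp * un;
      a = Lp * u;
      e -= a;
      ew = wts % e;
      if (!fix_sigma_a)
        sigma2_a = rscinvchisq(nu_a, s2_a0, arma::dot(u, u), n);
    }

    // (3) variant effects in a fresh random permutation
    beta.zeros();
    for (int c = 0; c < n_class; ++c)
      for (int d = 0; d < K; ++d)
        logPmat[c * K + d] = std::log(std::max(P(c, d), 1e-300));
    rpermute(perm);
    double sum_ew = arma::accu(ew);
    for (int j = 0; j < n; ++j) ewf[j] = (float)ew[j];
    for (int t = 0; t < m; ++t) {
      const int i = perm[t];
      const int c = class_index[i] - 1;
      const double s_i = svec[i];
      const double vold = v[i];
      // r = W_i' D e with variant i's own contribution added back
      double r;
      if (use_raw) {
        const unsigned char* col = xraw + (size_t)i * n;
        r = ((double)dot_u8f(col, ewf.memptr(), n) - center[i] * sum_ew) /
            scale[i];
      } else {
        r = (double)dot_fff(Wf.colptr(i), ewf.memptr(), n);
      }
      if (vold != 0.0) r += s_i * vold;

      int d_new;
      if (has_fix_z) {
        d_new = z[i];
      } else {
        // single-precision log/exp suffice for the categorical weights
        float lw[8], lmax = -1e30f;
        for (int d = 0; d < K; ++d) {
          float l = (float)logPmat[c * K + d];
          if (gamma[d] > 0.0) {
            double tau = gamma[d] * s2g;
            double Ad = tau * s_i + sigma2_e;
            l += -0.5f * std::log((float)(Ad / sigma2_e)) +
                 (float)(0.5 * tau * r * r / (sigma2_e * Ad));
          }
          lw[d] = l;
          if (l > lmax) lmax = l;
        }
        float tot = 0.0f;
        for (int d = 0; d < K; ++d) {
          lw[d] = std::exp(lw[d] - lmax);
          tot += lw[d];
        }
        float uu = (float)unif_rand() * tot, acc = 0.0f;
        d_new = K - 1;
        for (int d = 0; d < K; ++d) {
          acc += lw[d];
          if (uu <= acc) { d_new = d; break; }
        }
      }

      double vnew = 0.0;
      if (gamma[d_new] > 0.0) {
        double tau = gamma[d_new] * s2g;
        double Ci = s_i + sigma2_e / tau;
        vnew = r / Ci + norm_rand() * std::sqrt(sigma2_e / Ci);
      }
      const double dv = vnew - vold;
      if (dv != 0.0) {
        double* ep = e.memptr();
        double* ewq = ew.memptr();
        float* ewfp = ewf.memptr();
        if (use_raw) {
          const unsigned char* col = xraw + (size_t)i * n;
          const double f1 = dv / scale[i], f2 = center[i] * dv / scale[i];
          for (int j = 0; j < n; ++j) {
            double cj = (double)col[j] * f1 - f2;
            ep[j] -= cj;
            ewq[j] -= wd[j] * cj;
            ewfp[j] = (float)ewq[j];
          }
          sum_ew -= f1 * swx[i] - f2 * sw;
        } else {
          const float* col = Wf.colptr(i);
          for (int j = 0; j < n; ++j) {
            double cj = (double)col[j] * dv;
            ep[j] -= cj;
            ewq[j] -= wd[j] * cj;
            ewfp[j] = (float)ewq[j];
          }
        }
      }
      v[i] = vnew;
      z[i] = d_new;
      beta(c, d_new) += 1.0;
    }

    // (4) per-class mixture proportions P_c ~ Dirichlet(alpha_c + beta_c)
    if (!fix_p) {
      double al[8], pr[8];
      for (int c = 0; c < n_class; ++c) {
        for (int d = 0; d < K; ++d) al[d] = alpha(c, d) + beta(c, d);
        rdirichlet(al, pr, K);
        for (int d = 0; d < K; ++d) P(c, d) = pr[d];
      }
    }

    // optional: update sigma2_g from the scaled effect sum of squares
    if (update_sigma_g) {
      double ssv = 0.0;
      int nv = 0;
      for (int i = 0; i < m; ++i)
        if (z[i] > 0) { ssv += v[i] * v[i] / gamma[z[i]]; ++nv; }
      if (nv > 0) s2g = rscinvchisq(4.0, sigma2_g / 2.0, ssv, nv);
    }

    // (5) residual variance from the weighted residual sum of squares
    if (!fix_sigma_e) {
      double ss = arma::dot(e, ew);
      sigma2_e = rscinvchisq(nu_e, s2_e0, ss, n);
    }

    // successive-conditional (prior-recovery) mode: regenerate the data from
    // the model, so parameter draws marginally follow their priors
    if (geweke) {
      for (int j = 0; j < n; ++j)
        e[j] = norm_rand() * std::sqrt(sigma2_e / wd[j]);
      ew = wts % e;
    }

    // periodic from-scratch residual refresh
    if (!geweke && check_every > 0 && (it + 1) % check_every == 0) {
      arma::vec efresh = y - X * b - a;
      for (int i = 0; i < m; ++i) {
        if (v[i] != 0.0) {
          double* ef = efresh.memptr();
          if (use_raw) {
            const unsigned char* col = xraw + (size_t)i * n;
            const double f1 = v[i] / scale[i], f2 = center[i] * v[i] / scale[i];
            for (int j = 0; j < n; ++j) ef[j] -= (double)col[j] * f1 - f2;
          } else {
            const float* col = Wf.colptr(i);
            for (int j = 0; j < n; ++j) ef[j] -= (double)col[j] * v[i];
          }
        }
      }
      double err = arma::abs(e - efresh).max();
      if (err > max_resid_err) max_resid_err = err;
      e = efresh;
      ew = wts % e;
    }

    s2e_trace[it] = sigma2_e;
    s2a_trace[it] = sigma2_a;
    P_trace.slice(it) = P;

    if (it >= burn_in) {
      ++n_keep;
      v_sum += v;
      b_sum += b;
      a_sum += a;
      P_sum += P;
      beta_sum += beta;
      s2e_sum += sigma2_e;
      s2a_sum += sigma2_a;
      s2g_sum += s2g;
      for (int i = 0; i < m; ++i) {
        if (z[i] > 0) pip_cnt[i] += 1.0;
        comp_cnt(i, z[i]) += 1.0;
      }
    }

    if ((it & 63) == 0) Rcpp::checkUserInterrupt();
    if (!e.is_finite())
      stop("non-finite residual at iteration %d: chain diverged", it + 1);
  }

  const double nk = (double)n_keep;
  return List::create(
      _["vbar"] = v_sum / nk, _["pip"] = pip_cnt / nk,
      _["comp_freq"] = comp_cnt / nk, _["b"] = b_sum / nk,
      _["a"] = a_sum / nk, _["P"] = P_sum / nk, _["beta"] = beta_sum / nk,
      _["sigma2_e"] = s2e_sum / nk, _["sigma2_a"] = s2a_sum / nk,
      _["sigma2_g"] = s2g_sum / nk, _["n_keep"] = n_keep,
      _["s2e_trace"] = s2e_trace, _["s2a_trace"] = s2a_trace,
      _["P_trace"] = P_trace, _["max_resid_err"] = max_resid_err,
      _["z_final"] = IntegerVector(z.begin(), z.end()));
}
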