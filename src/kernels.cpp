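#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-emission HMM whose emission
// likelihoods are precomputed per time point (B is H x T).
// Returns gamma (H x T), either the full pairwise posteriors xi
// (H x H x (T-1)) or their sum over t, and the log-likelihood.
// Emissions are floored at 1e-12 so that EM-driven zero cells cannot
// produce a zero scaling constant.
// [[Rcpp::export(name = ".fb_kernel")]]
List fb_kernel(NumericVector pi, NumericMatrix A, NumericMatrix B,
               bool full_xi) {
  const int H = B.nrow(), T = B.ncol();
  const double floor_ = 1e-12;
  NumericMatrix alpha(H, T), beta(H, T), gamma(H, T);
  NumericVector c(T);

  std::vector<double> Bf(H * (size_t)T);
  for (int t = 0; t < T; ++t)
    for (int h = 0; h < H; ++h)
      Bf[h + (size_t)H * t] = std::max(B(h, t), floor_);

  // forward
  double s = 0.0;
  for (int h = 0; h < H; ++h) {
    alpha(h, 0) = pi[h] * Bf[h];
    s += alpha(h, 0);
  }
  if (s <= 0.0) stop("zero forward mass at t=1");
  c[0] = s;
  for (int h = 0; h < H; ++h) alpha(h, 0) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int h = 0; h < H; ++h) {
      double a = 0.0;
      for (int g = 0; g < H; ++g) a += alpha(g, t - 1) * A(g, h);
      a *= Bf[h + (size_t)H * t];
      alpha(h, t) = a;
      s += a;
    }
    if (s <= 0.0) stop("zero forward mass at t=%d", t + 1);
    c[t] = s;
    for (int h = 0; h < H; ++h) alpha(h, t) /= s;
  }

  // backward (scaled by the forward constants)
  for (int h = 0; h < H; ++h) beta(h, T - 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int h = 0; h < H; ++h) {
      double b = 0.0;
      for (int g = 0; g < H; ++g)
        b += A(h, g) * Bf[g + (size_t)H * (t + 1)] * beta(g, t + 1);
      beta(h, t) = b / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g2 = 0.0;
    for (int h = 0; h < H; ++h) {
      gamma(h, t) = alpha(h, t) * beta(h, t);
      g2 += gamma(h, t);
    }
    for (int h = 0; h < H; ++h) gamma(h, t) /= g2;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

  List out;
  if (T > 1) {
    if (full_xi) {
      NumericVector xi(Dimension(H, H, T - 1));
      for (int t = 0; t < T - 1; ++t)
        for (int g = 0; g < H; ++g)
          for (int h = 0; h < H; ++h)
            xi[h + H * (g + (size_t)H * t)] =
              alpha(h, t) * A(h, g) * Bf[g + (size_t)H * (t + 1)] *
              beta(g, t + 1) / c[t + 1];
      out = List::create(_["gamma"] = gamma, _["xi"] = xi,
                         _["loglik"] = loglik);
    } else {
      NumericMatrix xs(H, H);
      for (int t = 0; t < T - 1; ++t)
        for (int g = 0; g < H; ++g)
          for (int h = 0; h < H; ++h)
            xs(h, g) += alpha(h, t) * A(h, g) *
              Bf[g + (size_t)H * (t + 1)] * beta(g, t + 1) / c[t + 1];
      out = List::create(_["gamma"] = gamma, _["xi_sum"] = xs,
                         _["loglik"] = loglik);
    }
  } else {
    out = List::create(_["gamma"] = gamma, _["xi"] = R_NilValue,
                       _["loglik"] = loglik);
  }
  return out;
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// Returns 1-based state indices.
// [[Rcpp::export(name = ".viterbi_kernel")]]
IntegerVector viterbi_kernel(NumericVector pi, NumericMatrix A,
                             NumericMatrix B) {
  const int H = B.nrow(), T = B.ncol();
  const double floor_ = 1e-12;
  NumericMatrix d(H, T);
  IntegerMatrix psi(H, T);
  auto lg = [](double x) { return std::log(std::max(x, 1e-300)); };
  for (int h = 0; h < H; ++h)
    d(h, 0) = lg(pi[h]) + lg(std::max(B(h, 0), floor_));
  for (int t = 1; t < T; ++t) {
    for (int h = 0; h < H; ++h) {
      double best = R_NegInf;
      int arg = 0;
      for (int g = 0; g < H; ++g) {
        double v = d(g, t - 1) + lg(A(g, h));
        if (v > best) { best = v; arg = g; }
      }
      d(h, t) = best + lg(std::max(B(h, t), floor_));
      psi(h, t) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int h = 0; h < H; ++h)
    if (d(h, T - 1) > best) { best = d(h, T - 1); arg = h; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// Full inner EM for one node and a fixed hidden-graph set: alternates the
// emission update (theta lookups along the precomputed configuration
// sequences), scaled forward-backward, and exact M-steps for pi, A (unless
// frozen) and the CPDs, until the relative log-likelihood change drops
// below tol or max_iter iterations. Mirrors the R-level operations
// (forward_backward / reestimate_pi / reestimate_A / expected_counts /
// mle_cpd) so the converged model is identical; it exists because the
// structure search calls this loop tens of thousands of times.
// [[Rcpp::export(name = ".em_refine_kernel")]]
List em_refine_kernel(NumericVector pi0, NumericMatrix A0, List theta0,
                      List jseq, IntegerVector kseq, IntegerVector q,
                      int r, bool frozen, int max_iter, double tol) {
  const int H = pi0.size();
  const int T = kseq.size();
  const double floor_ = 1e-12;

  std::vector<double> pi(pi0.begin(), pi0.end());
  NumericMatrix A = clone(A0);
  std::vector<NumericMatrix> theta(H);
  std::vector<const int*> js(H);
  for (int h = 0; h < H; ++h) {
    theta[h] = clone(as<NumericMatrix>(theta0[h]));
    js[h] = INTEGER(as<IntegerVector>(jseq[h]));
  }
  const int* ks = INTEGER(kseq);

  NumericMatrix B(H, T), alpha(H, T), beta(H, T), gamma(H, T), xs(H, H);
  NumericVector c(T);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll_prev = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int it = 0;

  while (it < max_iter) {
    ++it;
    // emission update
    for (int h = 0; h < H; ++h)
      for (int t = 0; t < T; ++t)
        B(h, t) = std::max(theta[h](js[h][t], ks[t]), floor_);
    // forward
    double s = 0.0;
    for (int h = 0; h < H; ++h) { alpha(h, 0) = pi[h] * B(h, 0); s += alpha(h, 0); }
    if (s <= 0.0) stop("zero forward mass at t=1");
    c[0] = s;
    for (int h = 0; h < H; ++h) alpha(h, 0) /= s;
    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int h = 0; h < H; ++h) {
        double a = 0.0;
        for (int g = 0; g < H; ++g) a += alpha(g, t - 1) * A(g, h);
        a *= B(h, t);
        alpha(h, t) = a;
        s += a;
      }
      if (s <= 0.0) stop("zero forward mass at t=%d", t + 1);
      c[t] = s;
      for (int h = 0; h < H; ++h) alpha(h, t) /= s;
    }
    // backward + gamma
    for (int h = 0; h < H; ++h) beta(h, T - 1) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int h = 0; h < H; ++h) {
        double b = 0.0;
        for (int g = 0; g < H; ++g)
          b += A(h, g) * B(g, t + 1) * beta(g, t + 1);
        beta(h, t) = b / c[t + 1];
      }
    for (int t = 0; t < T; ++t) {
      double g2 = 0.0;
      for (int h = 0; h < H; ++h) { gamma(h, t) = alpha(h, t) * beta(h, t); g2 += gamma(h, t); }
      for (int h = 0; h < H; ++h) gamma(h, t) /= g2;
    }
    std::fill(xs.begin(), xs.end(), 0.0);
    if (T > 1)
      for (int t = 0; t < T - 1; ++t)
        for (int g = 0; g < H; ++g)
          for (int h = 0; h < H; ++h)
            xs(h, g) += alpha(h, t) * A(h, g) * B(g, t + 1) *
              beta(g, t + 1) / c[t + 1];
    ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(c[t]);
    trace.push_back(ll);
    // M-steps: pi from the first column, A from pairwise ratios
    double p1 = 0.0;
    for (int h = 0; h < H; ++h) p1 += gamma(h, 0);
    for (int h = 0; h < H; ++h) pi[h] = gamma(h, 0) / p1;
    if (!frozen && T >= 2) {
      for (int h = 0; h < H; ++h) {
        double den = 0.0;
        for (int g = 0; g < H; ++g) den += xs(h, g);
        if (den > 1e-300)
          for (int g = 0; g < H; ++g) A(h, g) = xs(h, g) / den;
      }
    }
    // CPD M-step: soft counts, unsmoothed MLE with uniform fallback
    for (int h = 0; h < H; ++h) {
      NumericMatrix n(q[h], r);
      for (int t = 0; t < T; ++t) n(js[h][t], ks[t]) += gamma(h, t);
      for (int j = 0; j < q[h]; ++j) {
        double tot = 0.0;
        for (int k = 0; k < r; ++k) tot += n(j, k);
        if (tot > 0)
          for (int k = 0; k < r; ++k) theta[h](j, k) = n(j, k) / tot;
        else
          for (int k = 0; k < r; ++k) theta[h](j, k) = 1.0 / r;
      }
    }
    if (R_finite(ll_prev) &&
        std::fabs(ll - ll_prev) < tol * (std::fabs(ll_prev) + 1e-10)) {
      converged = true;
      ll_prev = ll;
      break;
    }
    ll_prev = ll;
  }

  List th(H);
  for (int h = 0; h < H; ++h) th[h] = theta[h];
  return List::create(_["pi"] = NumericVector(pi.begin(), pi.end()),
                      _["A"] = A, _["gamma"] = gamma, _["xi_sum"] = xs,
                      _["loglik"] = ll_prev,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged, _["n_iter"] = it);
}

// Mixed-radix parent-configuration index sequence. `x` is the N x (T+1)
// discrete data matrix (0-based states); `parents` are 1-based row indices
// ordered so that the first parent is the most significant digit. The value
// at position t is the configuration of the parents at time t-1, i.e. the
// conditioning context for the child observation x_i(t), t = 1..T.
// [[Rcpp::export(name = ".config_seq_kernel")]]
IntegerVector config_seq_kernel(IntegerMatrix x, IntegerVector parents,
                                IntegerVector arities) {
  const int T = x.ncol() - 1;
  const int m = parents.size();
  IntegerVector j(T);
  for (int t = 0; t < T; ++t) {
    int idx = 0;
    for (int p = 0; p < m; ++p)
      idx = idx * arities[p] + x(parents[p] - 1, t);
    j[t] = idx;
  }
  return j;
}

// Soft (expected) contingency counts for one hidden graph: counts[j, k] =
// sum_t gamma_t * [jseq_t == j] * [kseq_t == k].
// [[Rcpp::export(name = ".soft_counts_kernel")]]
NumericMatrix soft_counts_kernel(IntegerVector jseq, IntegerVector kseq,
                                 NumericVector gamma, int q, int r) {
  NumericMatrix n(q, r);
  const int T = jseq.size();
  for (int t = 0; t < T; ++t) n(jseq[t], kseq[t]) += gamma[t];
  return n;
}

// Emission row for one hidden graph: B[t] = theta[jseq_t, kseq_t].
// [[Rcpp::export(name = ".emission_row_kernel")]]
NumericVector emission_row_kernel(NumericMatrix theta, IntegerVector jseq,
                                  IntegerVector kseq) {
  const int T = jseq.size();
  NumericVector b(T);
  for (int t = 0; t < T; ++t) b[t] = theta(jseq[t], kseq[t]);
  return b;
}
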