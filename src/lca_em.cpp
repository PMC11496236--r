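// Multi-start EM for the pooled latent class model with an optional shared
// baseline measurement offset, operating on unique response patterns.
//
// Inputs are pattern-level: Y (G x J in {0,1}), w (pattern counts), bf
// (baseline flag per pattern group; a pattern observed under both flags
// appears as two groups). Random starts are supplied from R as a cube of
// initial posteriors so that all randomness stays under R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double BETA_MAX = 13.815510557964274; // logit(1 - 1e-6)

struct LcaModel {
  vec pi;    // K
  mat beta0; // K x J emission logits at follow-up
  vec delta; // J baseline offsets
};

static inline mat log_sigmoid(const mat& eta) {
  // log(1/(1+exp(-eta))), stable both tails
  mat out(size(eta));
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    out(i) = (e > 0) ? -std::log1p(std::exp(-e)) : e - std::log1p(std::exp(e));
  }
  return out;
}

// E-step: fill post (G x K), return weighted loglik
static double estep(const mat& Y, const vec& w, const uvec& bf,
                    const LcaModel& m, mat& post) {
  const uword K = m.pi.n_elem;
  mat eta0 = clamp(m.beta0, -BETA_MAX, BETA_MAX);
  mat eta1 = clamp(m.beta0.each_row() + m.delta.t(), -BETA_MAX, BETA_MAX);
  // log p(y=1), log p(y=0) per flag, K x J
  mat l1_f = log_sigmoid(eta0), l0_f = log_sigmoid(-eta0);
  mat l1_b = log_sigmoid(eta1), l0_b = log_sigmoid(-eta1);
  // pattern x class conditional loglik
  mat LLf = Y * l1_f.t() + (1.0 - Y) * l0_f.t();
  mat LLb = Y * l1_b.t() + (1.0 - Y) * l0_b.t();
  vec lpi = log(m.pi + 1e-300);
  double ll = 0.0;
  for (uword g = 0; g < Y.n_rows; ++g) {
    rowvec a = (bf(g) ? LLb.row(g) : LLf.row(g)) + lpi.t();
    double mx = a.max();
    rowvec e = exp(a - mx);
    double s = accu(e);
    post.row(g) = e / s;
    ll += w(g) * (mx + std::log(s));
  }
  (void)K;
  return ll;
}

// expected complete-data Bernoulli loglik for one indicator under (b, d)
static double qfun_j(const vec& b, double d, const mat& A2, const mat& S2) {
  // A2, S2: K x 2 (col 0 follow-up, col 1 baseline)
  double q = 0.0;
  for (uword c = 0; c < b.n_elem; ++c) {
    for (int fl = 0; fl < 2; ++fl) {
      double eta = b(c) + (fl ? d : 0.0);
      eta = std::min(std::max(eta, -BETA_MAX), BETA_MAX);
      double lp1 = (eta > 0) ? -std::log1p(std::exp(-eta))
                             : eta - std::log1p(std::exp(eta));
      double lp0 = lp1 - eta;
      q += S2(c, fl) * lp1 + (A2(c, fl) - S2(c, fl)) * lp0;
    }
  }
  return q;
}

// M-step with shared baseline offset: Newton steps with halving per indicator
static void mstep_delta(const mat& Y, const vec& w, const uvec& bf,
                        const mat& post, LcaModel& m, int newton_iters) {
  const uword K = post.n_cols, J = Y.n_cols;
  vec wf = w % (1.0 - conv_to<vec>::from(bf));
  vec wb = w % conv_to<vec>::from(bf);
  mat Nf = post.t() * wf;            // K x 1
  mat Nb = post.t() * wb;
  mat Sf = post.t() * (Y.each_col() % wf);  // K x J
  mat Sb = post.t() * (Y.each_col() % wb);
  vec Ntot = Nf + Nb;
  m.pi = Ntot / accu(Ntot);

  for (uword j = 0; j < J; ++j) {
    mat A2(K, 2), S2(K, 2);
    A2.col(0) = Nf; A2.col(1) = Nb;
    S2.col(0) = Sf.col(j); S2.col(1) = Sb.col(j);
    vec b = m.beta0.col(j);
    double d = m.delta(j);
    double q0 = qfun_j(b, d, A2, S2);
    for (int it = 0; it < newton_iters; ++it) {
      vec grad(K + 1, fill::zeros);
      mat H(K + 1, K + 1, fill::zeros);
      for (uword c = 0; c < K; ++c) {
        for (int fl = 0; fl < 2; ++fl) {
          double eta = b(c) + (fl ? d : 0.0);
          eta = std::min(std::max(eta, -BETA_MAX), BETA_MAX);
          double p = 1.0 / (1.0 + std::exp(-eta));
          double v = A2(c, fl) * p * (1.0 - p);
          double g = S2(c, fl) - A2(c, fl) * p;
          grad(c) += g;
          H(c, c) -= v;
          if (fl) {
            grad(K) += g;
            H(c, K) -= v; H(K, c) -= v; H(K, K) -= v;
          }
        }
      }
      H.diag() -= 1e-10;
      vec step = solve(-H, grad, solve_opts::fast + solve_opts::likely_sympd);
      double scale = 1.0;
      for (int h = 0; h < 30; ++h) {
        vec bn = clamp(b + scale * step.head(K), -BETA_MAX, BETA_MAX);
        double dn = std::min(std::max(d + scale * step(K), -BETA_MAX), BETA_MAX);
        double q1 = qfun_j(bn, dn, A2, S2);
        if (q1 >= q0 - 1e-12) { b = bn; d = dn; q0 = q1; break; }
        scale *= 0.5;
      }
    }
    m.beta0.col(j) = b;
    m.delta(j) = d;
  }
}

// closed-form M-step without baseline offset
static void mstep_plain(const mat& Y, const vec& w, const mat& post,
                        LcaModel& m) {
  vec N = post.t() * w;
  mat S = post.t() * (Y.each_col() % w);
  m.pi = N / accu(N);
  mat p = S.each_col() / (N + 1e-300);
  p = clamp(p, 1e-6, 1.0 - 1e-6);
  m.beta0 = log(p / (1.0 - p));
  m.delta.zeros();
}

// [[Rcpp::export]]
Rcpp::List lca_em_cpp(const arma::mat& Y, const arma::vec& w,
                      const arma::uvec& bf, int K,
                      const arma::cube& init_post,
                      int start_iters, int max_iter, double tol,
                      bool est_delta, int newton_iters) {
  const uword G = Y.n_rows, J = Y.n_cols, S = init_post.n_slices;
  auto run = [&](mat post, LcaModel m, bool warm, int iters, double tol_,
                 std::vector<double>* trace) {
    double ll_prev = -datum::inf, ll = -datum::inf;
    bool conv = false;
    int used = 0;
    for (int it = 0; it < iters; ++it) {
      if (!warm && it == 0 && est_delta) {
        // initialize logits from the pooled closed form, then refine
        LcaModel tmp = m;
        mstep_plain(Y, w, post, tmp);
        m.pi = tmp.pi; m.beta0 = tmp.beta0; m.delta.zeros();
        mstep_delta(Y, w, bf, post, m, newton_iters);
      } else if (est_delta) {
        mstep_delta(Y, w, bf, post, m, newton_iters);
      } else {
        mstep_plain(Y, w, post, m);
      }
      ll = estep(Y, w, bf, m, post);
      if (trace) trace->push_back(ll);
      ++used;
      if (it > 0 && std::abs(ll - ll_prev) <
          tol_ * (std::abs(ll_prev) + 1e-12)) { conv = true; break; }
      ll_prev = ll;
    }
    return std::make_tuple(m, post, ll, conv, used);
  };

  // preliminary runs
  double best_ll = -datum::inf;
  int best_s = 0;
  mat best_post;
  LcaModel best_m;
  for (uword s = 0; s < S; ++s) {
    LcaModel m{vec(K, fill::ones), mat(K, J, fill::zeros), vec(J, fill::zeros)};
    m.pi /= K;
    auto res = run(init_post.slice(s), m, false, start_iters, tol, nullptr);
    double ll = std::get<2>(res);
    if (ll > best_ll) {
      best_ll = ll; best_s = (int)s;
      best_m = std::get<0>(res);
      best_post = std::get<1>(res);
    }
  }
  // continue best start to convergence
  std::vector<double> trace;
  trace.push_back(best_ll);
  auto fin = run(best_post, best_m, true, max_iter, tol, &trace);
  LcaModel m = std::get<0>(fin);
  (void)G;
  return Rcpp::List::create(
      Rcpp::Named("pi") = m.pi,
      Rcpp::Named("beta0") = m.beta0,
      Rcpp::Named("delta") = m.delta,
      Rcpp::Named("loglik") = std::get<2>(fin),
      Rcpp::Named("posterior") = std::get<1>(fin),
      Rcpp::Named("trace") = trace,
      Rcpp::Named("converged") = std::get<3>(fin),
      Rcpp::Named("n_iter") = std::get<4>(fin),
      Rcpp::Named("best_start") = best_s + 1);
}
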