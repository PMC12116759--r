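// Fused gradient step for the conservative distributional Q-learning agent.
//
// Implements one critic + actor update exactly as the R reference engine
// (R/agent_step.R) defines it, with hand-derived gradients. All random
// quantities except dropout masks are supplied by the caller so the two
// engines can be compared at dropout_p = 0; dropout masks come from a fast
// xorshift stream seeded per step from R's RNG, so runs stay deterministic
// under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dense {
  mat W;
  rowvec b;
};

Dense get_dense(const Rcpp::List& l) {
  Dense d;
  d.W = Rcpp::as<mat>(l["W"]);
  mat bm = Rcpp::as<mat>(l["b"]);
  d.b = bm.row(0);
  return d;
}

std::vector<Dense> get_layers(const Rcpp::List& l) {
  std::vector<Dense> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(get_dense(l[i]));
  return out;
}

// Dropout masks use a fast xorshift128+ stream seeded from R's RNG once per
// gradient step, keeping runs deterministic under set.seed() without paying
// an R-API call per mask element.
struct XorShift {
  uint64_t s0, s1;
  void seed_from_r() {
    s0 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
         (uint64_t)(unif_rand() * 4294967296.0);
    s1 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
         (uint64_t)(unif_rand() * 4294967296.0);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ull;
  }
  inline double unif() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return (double)((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
  }
};

XorShift mask_rng;

mat drop_mask(uword n, uword k, double p) {
  mat m(n, k);
  double scale = 1.0 / (1.0 - p);
  for (uword j = 0; j < k; ++j)
    for (uword i = 0; i < n; ++i)
      m(i, j) = (mask_rng.unif() < p) ? 0.0 : scale;
  return m;
}

struct CriticParams {
  std::vector<Dense> base;
  Dense tau;
  Dense head1, head2;
};

CriticParams get_critic(const Rcpp::List& l) {
  CriticParams c;
  c.base = get_layers(l["base"]);
  c.tau = get_dense(l["tau"]);
  Rcpp::List head = l["head"];
  c.head1 = get_dense(head[0]);
  c.head2 = get_dense(head[1]);
  return c;
}

struct CriticGrads {
  std::vector<mat> base_W;
  std::vector<rowvec> base_b;
  mat tau_W, head1_W, head2_W;
  rowvec tau_b, head1_b, head2_b;
  void init(const CriticParams& p) {
    for (const auto& d : p.base) {
      base_W.push_back(zeros<mat>(d.W.n_rows, d.W.n_cols));
      base_b.push_back(zeros<rowvec>(d.b.n_elem));
    }
    tau_W = zeros<mat>(p.tau.W.n_rows, p.tau.W.n_cols);
    tau_b = zeros<rowvec>(p.tau.b.n_elem);
    head1_W = zeros<mat>(p.head1.W.n_rows, p.head1.W.n_cols);
    head1_b = zeros<rowvec>(p.head1.b.n_elem);
    head2_W = zeros<mat>(p.head2.W.n_rows, p.head2.W.n_cols);
    head2_b = zeros<rowvec>(p.head2.b.n_elem);
  }
};

mat cosine_embed(const vec& taus, int d_embed) {
  mat C(taus.n_elem, d_embed);
  for (int j = 0; j < d_embed; ++j)
    C.col(j) = cos(datum::pi * j * taus);
  return C;
}

// Cached forward pass state for backprop.
struct CriticPass {
  mat x0;                    // n x (d+1)
  std::vector<mat> base_act; // post-relu(-dropout) activations
  std::vector<mat> base_mask;
  mat xt;                    // tiled n*k x h
  mat C, phi, phi_pre_pos;   // cosine features, post-relu embed
  mat merged, h1, h1_pre_pos, h1_mask;
  mat Z;                     // n x k quantile values
  uword n, k;
};

// Forward; masks drawn iff train && dropout_p > 0.
CriticPass critic_forward(const CriticParams& P, const mat& s, const vec& a,
                          const vec& taus, uword k, double amax,
                          int embed_dim, double dropout_p, bool train) {
  CriticPass F;
  F.n = s.n_rows;
  F.k = k;
  F.x0 = join_rows(s, a / amax);
  mat x = F.x0;
  bool use_drop = train && dropout_p > 0;
  for (const auto& layer : P.base) {
    mat pre = x * layer.W;
    pre.each_row() += layer.b;
    mat act = clamp(pre, 0.0, datum::inf);
    if (use_drop) {
      mat m = drop_mask(act.n_rows, act.n_cols, dropout_p);
      F.base_mask.push_back(m % (pre > 0));
      act %= m;
    } else {
      F.base_mask.push_back(conv_to<mat>::from(pre > 0));
    }
    F.base_act.push_back(act);
    x = act;
  }
  // tile each row k times (gather)
  if (k > 1) {
    uvec tidx(F.n * k);
    for (uword i = 0; i < F.n * k; ++i) tidx(i) = i / k;
    F.xt = x.rows(tidx);
  } else {
    F.xt = x;
  }
  F.C = cosine_embed(taus, embed_dim);
  mat pre_phi = F.C * P.tau.W;
  pre_phi.each_row() += P.tau.b;
  F.phi_pre_pos = conv_to<mat>::from(pre_phi > 0);
  F.phi = clamp(pre_phi, 0.0, datum::inf);
  F.merged = F.xt % F.phi;
  mat pre_h1 = F.merged * P.head1.W;
  pre_h1.each_row() += P.head1.b;
  F.h1 = clamp(pre_h1, 0.0, datum::inf);
  if (use_drop) {
    mat m = drop_mask(F.h1.n_rows, F.h1.n_cols, dropout_p);
    F.h1_mask = m % (pre_h1 > 0);
    F.h1 %= m;
  } else {
    F.h1_mask = conv_to<mat>::from(pre_h1 > 0);
  }
  vec z = F.h1 * P.head2.W + as_scalar(P.head2.b);
  F.Z.set_size(F.n, k);
  for (uword i = 0; i < F.n; ++i)
    for (uword j = 0; j < k; ++j)
      F.Z(i, j) = z(i * k + j);
  return F;
}

// Backprop dL/dZ through a cached pass; accumulates into G.
// Returns dL/d(action) (length n, in action units) when want_da.
vec critic_backward(const CriticParams& P, const CriticPass& F,
                    const mat& dZ, CriticGrads& G, double amax,
                    bool want_da = false) {
  uword n = F.n, k = F.k;
  vec gz(n * k);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < k; ++j)
      gz(i * k + j) = dZ(i, j);

  G.head2_W += F.h1.t() * gz;
  G.head2_b(0) += accu(gz);
  mat g_h1 = gz * P.head2.W.t();
  g_h1 %= F.h1_mask;
  G.head1_W += F.merged.t() * g_h1;
  G.head1_b += sum(g_h1, 0);
  mat g_merged = g_h1 * P.head1.W.t();
  mat g_phi = g_merged % F.xt;
  mat g_xt = g_merged % F.phi;
  mat g_phi_pre = g_phi % F.phi_pre_pos;
  G.tau_W += F.C.t() * g_phi_pre;
  G.tau_b += sum(g_phi_pre, 0);
  // untile
  mat g_x;
  if (k > 1) {
    g_x.zeros(n, g_xt.n_cols);
    for (uword i = 0; i < n; ++i)
      g_x.row(i) = sum(g_xt.rows(i * k, i * k + k - 1), 0);
  } else {
    g_x = g_xt;
  }
  // base layers, last to first
  for (int l = (int)P.base.size() - 1; l >= 0; --l) {
    mat g_pre = g_x % F.base_mask[l];
    const mat& input = (l == 0) ? F.x0 : F.base_act[l - 1];
    G.base_W[l] += input.t() * g_pre;
    G.base_b[l] += sum(g_pre, 0);
    g_x = g_pre * P.base[l].W.t();
  }
  vec da;
  if (want_da) da = g_x.col(g_x.n_cols - 1) / amax;
  return da;
}

Rcpp::List dense_grads(const std::vector<mat>& Ws,
                       const std::vector<rowvec>& bs) {
  Rcpp::List out(Ws.size());
  for (size_t i = 0; i < Ws.size(); ++i) {
    out[i] = Rcpp::List::create(
      Rcpp::Named("W") = Ws[i],
      Rcpp::Named("b") = Rcpp::NumericMatrix(1, bs[i].n_elem,
                                             bs[i].memptr()));
  }
  return out;
}

Rcpp::List one_dense(const mat& W, const rowvec& b) {
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("b") = Rcpp::NumericMatrix(1, b.n_elem, b.memptr()));
}

} // namespace

// One gradient step of the fitted-Q evaluation critic: an MLP regression of
// Q(s, a) on fixed targets y, mean-squared-error loss. Returns per-layer
// gradients and the loss; the optimizer stays in R.
// [[Rcpp::export(name = ".fqe_step_cpp")]]
Rcpp::List fqe_step_cpp(Rcpp::List params_l, arma::mat x, arma::vec y) {
  std::vector<Dense> layers = get_layers(params_l);
  uword B = x.n_rows;
  std::vector<mat> acts;
  mat h = x;
  for (size_t l = 0; l + 1 < layers.size(); ++l) {
    mat pre = h * layers[l].W;
    pre.each_row() += layers[l].b;
    h = clamp(pre, 0.0, datum::inf);
    acts.push_back(h);
  }
  vec pred = h * layers.back().W + as_scalar(layers.back().b);
  vec resid = pred - y;
  double loss = accu(resid % resid) / (double)B;

  std::vector<mat> gW(layers.size());
  std::vector<rowvec> gb(layers.size());
  mat g = resid * (2.0 / (double)B);
  for (int l = (int)layers.size() - 1; l >= 0; --l) {
    const mat& input = (l == 0) ? x : acts[l - 1];
    gW[l] = input.t() * g;
    gb[l] = sum(g, 0);
    if (l > 0) {
      g = g * layers[l].W.t();
      g %= conv_to<mat>::from(acts[l - 1] > 0);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("grads") = dense_grads(gW, gb),
    Rcpp::Named("loss") = loss);
}

// [[Rcpp::export(name = ".dcql_step_cpp")]]
Rcpp::List dcql_step_cpp(Rcpp::List critic_l, Rcpp::List target_l,
                         Rcpp::List actor_l,
                         arma::mat s, arma::vec a, arma::vec r,
                         arma::vec cont, arma::mat s2, arma::vec a2,
                         arma::mat a_ood,
                         arma::vec taus_t, arma::vec taus_o,
                         arma::vec taus_d, arma::vec taus_m,
                         arma::vec taus_a, arma::vec eps,
                         double dropout_p, double amax, double gamma,
                         double alpha, double kappa, double ent_coeff,
                         int embed_dim) {
  Rcpp::RNGScope scope;
  if (dropout_p > 0) mask_rng.seed_from_r();
  CriticParams critic = get_critic(critic_l);
  CriticParams target = get_critic(target_l);
  std::vector<Dense> actor = get_layers(actor_l);

  uword B = s.n_rows;
  uword K = taus_o.n_elem / B;
  uword Kc = taus_d.n_elem / B;
  uword M = a_ood.n_cols;
  uword Kt = taus_t.n_elem / B;

  CriticGrads G;
  G.init(critic);

  // --- distributional Bellman target (eval mode, target net) ---
  CriticPass Ft = critic_forward(target, s2, a2, taus_t, Kt, amax,
                                 embed_dim, 0.0, false);
  mat Y(B, Kt);
  for (uword i = 0; i < B; ++i)
    Y.row(i) = r(i) + gamma * cont(i) * Ft.Z.row(i);

  // --- online quantiles & quantile Huber loss ---
  CriticPass Fo = critic_forward(critic, s, a, taus_o, K, amax,
                                 embed_dim, dropout_p, true);
  mat dZ(B, K, fill::zeros);
  double td_loss = 0.0;
  for (uword i = 0; i < B; ++i) {
    for (uword j = 0; j < Kt; ++j) {
      for (uword kk = 0; kk < K; ++kk) {
        double u = Y(i, j) - Fo.Z(i, kk);
        double tau = taus_o(i * K + kk);
        double w = std::fabs(tau - (u < 0 ? 1.0 : 0.0));
        double au = std::fabs(u);
        double hub = (au <= kappa) ? 0.5 * u * u
                                   : kappa * (au - 0.5 * kappa);
        td_loss += w * hub / kappa;
        double dhub = (au <= kappa) ? u : kappa * (u > 0 ? 1.0 : -1.0);
        dZ(i, kk) -= w * dhub / kappa;   // d/dz of huber(y - z)
      }
    }
  }
  double norm_td = 1.0 / (double)(B * Kt);
  td_loss *= norm_td;
  dZ *= norm_td;
  critic_backward(critic, Fo, dZ, G, amax);

  // --- conservative penalty ---
  CriticPass Fd = critic_forward(critic, s, a, taus_d, Kc, amax,
                                 embed_dim, dropout_p, true);
  vec q_data = mean(Fd.Z, 1);

  mat s_rep(B * M, s.n_cols);
  vec a_flat(B * M);
  for (uword i = 0; i < B; ++i)
    for (uword m = 0; m < M; ++m) {
      s_rep.row(i * M + m) = s.row(i);
      a_flat(i * M + m) = a_ood(i, m);
    }
  CriticPass Fm = critic_forward(critic, s_rep, a_flat, taus_m, Kc, amax,
                                 embed_dim, dropout_p, true);
  vec q_ood = mean(Fm.Z, 1);
  mat Q(B, M);
  for (uword i = 0; i < B; ++i)
    for (uword m = 0; m < M; ++m)
      Q(i, m) = q_ood(i * M + m);
  vec mx = max(Q, 1);
  vec lse(B);
  mat sm(B, M);
  for (uword i = 0; i < B; ++i) {
    rowvec e = exp(Q.row(i) - mx(i));
    double se = accu(e);
    lse(i) = mx(i) + std::log(se);
    sm.row(i) = e / se;
  }
  double cql_loss = mean(lse - q_data);

  // grads: d cql/d q_ood = softmax/B; d cql/d q_data = -1/B
  mat dZd(B, Kc);
  dZd.fill(-alpha / (double)(B * Kc));
  critic_backward(critic, Fd, dZd, G, amax);
  mat dZm(B * M, Kc);
  for (uword i = 0; i < B; ++i)
    for (uword m = 0; m < M; ++m)
      dZm.row(i * M + m).fill(alpha * sm(i, m) / (double)(B * Kc));
  critic_backward(critic, Fm, dZm, G, amax);

  double critic_loss = td_loss + alpha * cql_loss;

  // --- actor update ---
  // forward actor MLP (train mode w/ dropout on hidden layers)
  std::vector<mat> acts;
  std::vector<mat> amasks;
  mat x = s;
  bool use_drop = dropout_p > 0;
  for (size_t l = 0; l + 1 < actor.size(); ++l) {
    mat pre = x * actor[l].W;
    pre.each_row() += actor[l].b;
    mat act = clamp(pre, 0.0, datum::inf);
    if (use_drop) {
      mat m = drop_mask(act.n_rows, act.n_cols, dropout_p);
      amasks.push_back(m % (pre > 0));
      act %= m;
    } else {
      amasks.push_back(conv_to<mat>::from(pre > 0));
    }
    acts.push_back(act);
    x = act;
  }
  mat out = x * actor.back().W;
  out.each_row() += actor.back().b;
  vec mu = out.col(0);
  vec t2 = tanh(out.col(1));
  vec ls = 2.0 * t2 - 1.0;
  vec z = mu + exp(ls) % eps;
  vec tz = tanh(z);
  vec act_pi = amax / 2.0 * (tz + 1.0);
  vec jac = amax / 2.0 * (1.0 - tz % tz) + 1e-6;
  vec log_prob = -0.5 * eps % eps - 0.5 * std::log(2.0 * datum::pi)
                 - ls - log(jac);

  // critic value of the actor's action (eval mode, grads only wrt action)
  uword Ka = taus_a.n_elem / B;
  CriticPass Fa = critic_forward(critic, s, act_pi, taus_a, Ka, amax,
                                 embed_dim, 0.0, false);
  double q_pi_mean = accu(mean(Fa.Z, 1)) / (double)B;
  double actor_loss = ent_coeff * accu(log_prob) / (double)B - q_pi_mean;

  // critic grads must not receive the actor pass: use a discard accumulator
  CriticGrads Gdiscard;
  Gdiscard.init(critic);
  mat dZa(B, Ka);
  dZa.fill(-1.0 / (double)(B * Ka));
  vec g_act = critic_backward(critic, Fa, dZa, Gdiscard, amax, true);

  // d logp / dz = -jac' / jac with jac' = amax/2 * (-2 tz) * (1 - tz^2)
  vec djac_dz = amax / 2.0 * (-2.0 * tz) % (1.0 - tz % tz);
  vec dlogp_dz = -djac_dz / jac;
  vec dact_dz = amax / 2.0 * (1.0 - tz % tz);
  double invB = 1.0 / (double)B;
  vec gz_total = invB * ent_coeff * dlogp_dz + g_act % dact_dz;
  vec g_mu = gz_total;
  vec g_ls = invB * ent_coeff * (-1.0) + gz_total % (exp(ls) % eps);
  vec g_out2 = g_ls % (2.0 * (1.0 - t2 % t2));

  mat g_out(B, 2);
  g_out.col(0) = g_mu;
  g_out.col(1) = g_out2;

  std::vector<mat> aW(actor.size());
  std::vector<rowvec> ab(actor.size());
  mat g = g_out;
  for (int l = (int)actor.size() - 1; l >= 0; --l) {
    const mat& input = (l == 0) ? s : acts[l - 1];
    aW[l] = input.t() * g;
    ab[l] = sum(g, 0);
    if (l > 0) {
      g = g * actor[l].W.t();
      g %= amasks[l - 1];
    }
  }

  Rcpp::List critic_grads = Rcpp::List::create(
    Rcpp::Named("base") = dense_grads(G.base_W, G.base_b),
    Rcpp::Named("tau") = one_dense(G.tau_W, G.tau_b),
    Rcpp::Named("head") = Rcpp::List::create(
      one_dense(G.head1_W, G.head1_b), one_dense(G.head2_W, G.head2_b)));

  return Rcpp::List::create(
    Rcpp::Named("critic_grads") = critic_grads,
    Rcpp::Named("actor_grads") = dense_grads(aW, ab),
    Rcpp::Named("td_loss") = td_loss,
    Rcpp::Named("cql_loss") = cql_loss,
    Rcpp::Named("critic_loss") = critic_loss,
    Rcpp::Named("actor_loss") = actor_loss);
}
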