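// Minibatch Adam / Huber-loss trainer and batched predictor for the
// neural collaborative filtering model: a generalized matrix factorization
// (GMF) branch over inbred/tester embeddings, a tower neural network over
// separate inbred/tester embeddings plus genetic-group and location
// embeddings, and a 2-weight fusion layer combining the two branch scalars.
// Also hosts the second-order factorization-machine baseline trained with
// the same optimizer/loss for comparability.
//
// All indices arriving from R are 0-based. Single-threaded and fully
// deterministic given the seed: minibatch shuffling and dropout masks come
// from one std::mt19937 stream.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

namespace {

constexpr int BRANCH_FUSED = 0;
constexpr int BRANCH_GMF = 1;
constexpr int BRANCH_NN = 2;

constexpr int ACT_RELU = 0;
constexpr int ACT_TANH = 1;
constexpr int ACT_SIGMOID = 2;

inline mat activate(const mat& z, int act) {
  switch (act) {
    case ACT_RELU: return arma::clamp(z, 0.0, datum::inf);
    case ACT_TANH: return arma::tanh(z);
    default: return 1.0 / (1.0 + arma::exp(-z));
  }
}

// derivative of the activation w.r.t. its pre-activation, expressed through
// pre-activation z and activated value a
inline mat activate_grad(const mat& z, const mat& a, int act) {
  switch (act) {
    case ACT_RELU: return arma::conv_to<mat>::from(z > 0.0);
    case ACT_TANH: return 1.0 - a % a;
    default: return a % (1.0 - a);
  }
}

struct Params {
  mat W1b, W1t;      // GMF embeddings
  vec h;             // GMF output weights
  mat W2b, W2t, Wg, Wl;  // NN embeddings
  std::vector<mat> nnW;
  std::vector<vec> nnb;
  vec head_w;        // NN scalar output head
  double head_b;
  vec fusion_W;      // length 2
  double fusion_b;
};

Params params_from_list(const List& p) {
  Params P;
  P.W1b = as<mat>(p["W1b"]);
  P.W1t = as<mat>(p["W1t"]);
  P.h = as<vec>(p["h"]);
  P.W2b = as<mat>(p["W2b"]);
  P.W2t = as<mat>(p["W2t"]);
  P.Wg = as<mat>(p["Wg"]);
  P.Wl = as<mat>(p["Wl"]);
  List nw = p["nn_W"], nb = p["nn_b"];
  for (int j = 0; j < nw.size(); ++j) {
    P.nnW.push_back(as<mat>(nw[j]));
    P.nnb.push_back(as<vec>(nb[j]));
  }
  P.head_w = as<vec>(p["nn_head_w"]);
  P.head_b = as<double>(p["nn_head_b"]);
  P.fusion_W = as<vec>(p["fusion_W"]);
  P.fusion_b = as<double>(p["fusion_b"]);
  return P;
}

List params_to_list(const Params& P) {
  List nw(P.nnW.size()), nb(P.nnb.size());
  for (size_t j = 0; j < P.nnW.size(); ++j) {
    nw[j] = P.nnW[j];
    nb[j] = P.nnb[j];
  }
  return List::create(
      _["W1b"] = P.W1b, _["W1t"] = P.W1t, _["h"] = P.h, _["W2b"] = P.W2b,
      _["W2t"] = P.W2t, _["Wg"] = P.Wg, _["Wl"] = P.Wl, _["nn_W"] = nw,
      _["nn_b"] = nb, _["nn_head_w"] = P.head_w, _["nn_head_b"] = P.head_b,
      _["fusion_W"] = P.fusion_W, _["fusion_b"] = P.fusion_b);
}

// dense Adam over a flat list of parameter matrices
struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<mat*>& ps) {
    for (auto* p : ps) {
      m.push_back(zeros<mat>(p->n_rows, p->n_cols));
      v.push_back(zeros<mat>(p->n_rows, p->n_cols));
    }
  }
  void step(std::vector<mat*>& ps, std::vector<mat>& g, double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * g[i];
      v[i] = b2 * v[i] + (1.0 - b2) * (g[i] % g[i]);
      *ps[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

inline uvec take(const ivec& x, const uvec& idx) {
  ivec sub = x.elem(idx);
  return arma::conv_to<uvec>::from(sub);
}

}  // namespace

// Forward pass over a batch in eval mode (no dropout). Exposed to R for
// batched prediction; also reused internally.
static vec forward_eval(const Params& P, const uvec& bi, const uvec& ti,
                        const uvec& gi, const uvec& li, int branch,
                        bool use_parents, int act) {
  const uword B = bi.n_elem;
  vec qg, qn;
  if (branch != BRANCH_NN) {
    qg = (P.W1b.rows(bi) % P.W1t.rows(ti)) * P.h;
  }
  if (branch != BRANCH_GMF) {
    mat X = use_parents
                ? join_rows(P.W2b.rows(bi), P.W2t.rows(ti), P.Wg.rows(gi),
                            P.Wl.rows(li))
                : join_rows(P.Wg.rows(gi), P.Wl.rows(li));
    mat A = X.t();  // d_in x B
    for (size_t j = 0; j < P.nnW.size(); ++j) {
      mat Z = P.nnW[j] * A;
      Z.each_col() += P.nnb[j];
      A = activate(Z, act);
    }
    qn = (P.head_w.t() * A).t() + P.head_b;
  }
  (void)B;
  if (branch == BRANCH_GMF) return qg;
  if (branch == BRANCH_NN) return qn;
  return P.fusion_W(0) * qg + P.fusion_W(1) * qn + P.fusion_b;
}

// [[Rcpp::export]]
NumericVector ncf_predict_cpp(IntegerVector b, IntegerVector t,
                              IntegerVector g, IntegerVector l, List params,
                              int branch, bool use_parents, int activation) {
  Params P = params_from_list(params);
  ivec bv = as<ivec>(b), tv = as<ivec>(t), gv = as<ivec>(g), lv = as<ivec>(l);
  uvec all = regspace<uvec>(0, bv.n_elem - 1);
  vec out = forward_eval(P, take(bv, all), take(tv, all), take(gv, all),
                         take(lv, all), branch, use_parents, activation);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List ncf_train_cpp(IntegerVector b, IntegerVector t, IntegerVector g,
                   IntegerVector l, NumericVector y, List params, int branch,
                   bool use_parents, int activation, double dropout_keep,
                   double delta, double lr, int batch_size, int max_iter,
                   int seed, int log_every) {
  Params P = params_from_list(params);
  ivec bv = as<ivec>(b), tv = as<ivec>(t), gv = as<ivec>(g), lv = as<ivec>(l);
  vec yv = as<vec>(y);
  const int N = (int)yv.n_elem;
  const int J = (int)P.nnW.size();
  const bool use_gmf = branch != BRANCH_NN;
  const bool use_nn = branch != BRANCH_GMF;

  // parameter registry (fixed order drives Adam state)
  std::vector<mat*> ps;
  // scalars live in 1x1 views so Adam is uniform
  mat head_b_m(1, 1), fusion_b_m(1, 1);
  head_b_m(0, 0) = P.head_b;
  fusion_b_m(0, 0) = P.fusion_b;
  mat h_m(P.h), head_w_m(P.head_w), fusion_W_m(P.fusion_W);
  ps.push_back(&P.W1b);
  ps.push_back(&P.W1t);
  ps.push_back(&h_m);
  ps.push_back(&P.W2b);
  ps.push_back(&P.W2t);
  ps.push_back(&P.Wg);
  ps.push_back(&P.Wl);
  for (int j = 0; j < J; ++j) ps.push_back(&P.nnW[j]);
  std::vector<mat> nnb_m;
  for (int j = 0; j < J; ++j) nnb_m.push_back(mat(P.nnb[j]));
  for (int j = 0; j < J; ++j) ps.push_back(&nnb_m[j]);
  ps.push_back(&head_w_m);
  ps.push_back(&head_b_m);
  ps.push_back(&fusion_W_m);
  ps.push_back(&fusion_b_m);

  Adam adam;
  adam.init(ps);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  int pos = 0;

  std::vector<double> hist_it, hist_loss;
  double loss_acc = 0.0;
  int loss_n = 0;

  for (int it = 1; it <= max_iter; ++it) {
    if (pos >= N) {
      std::shuffle(order.begin(), order.end(), rng);
      pos = 0;
    }
    const int B = std::min(batch_size, N - pos);
    uvec idx(B);
    for (int i = 0; i < B; ++i) idx(i) = (uword)order[pos + i];
    pos += B;

    uvec bi = take(bv, idx), ti = take(tv, idx), gi = take(gv, idx),
         li = take(lv, idx);
    vec yb = yv.elem(idx);

    std::vector<mat> G;
    for (auto* p : ps) G.push_back(zeros<mat>(p->n_rows, p->n_cols));
    enum { iW1b = 0, iW1t, iH, iW2b, iW2t, iWg, iWl };  // then NN blocks
    const int iNNW = 7, iNNB = 7 + J, iHW = 7 + 2 * J, iHB = iHW + 1,
              iFW = iHB + 1, iFB = iFW + 1;

    // ---- forward ----
    vec qg(B, fill::zeros), qn(B, fill::zeros);
    mat D1b, D1t;
    if (use_gmf) {
      D1b = P.W1b.rows(bi);
      D1t = P.W1t.rows(ti);
      qg = (D1b % D1t) * h_m.col(0);
    }
    std::vector<mat> acts, zs, pre, drops;
    if (use_nn) {
      mat X = use_parents
                  ? join_rows(P.W2b.rows(bi), P.W2t.rows(ti), P.Wg.rows(gi),
                              P.Wl.rows(li))
                  : join_rows(P.Wg.rows(gi), P.Wl.rows(li));
      mat A = X.t();
      acts.push_back(A);
      for (int j = 0; j < J; ++j) {
        mat Z = P.nnW[j] * A;
        Z.each_col() += nnb_m[j].col(0);
        zs.push_back(Z);
        A = activate(Z, activation);
        pre.push_back(A);  // pre-dropout activation, for the backward pass
        if (dropout_keep < 1.0) {
          mat M(A.n_rows, A.n_cols);
          for (uword ii = 0; ii < M.n_elem; ++ii)
            M(ii) = (unif(rng) < dropout_keep) ? 1.0 / dropout_keep : 0.0;
          drops.push_back(M);
          A %= M;
        } else {
          drops.push_back(ones<mat>(A.n_rows, A.n_cols));
        }
        acts.push_back(A);
      }
      qn = (head_w_m.col(0).t() * A).t() + head_b_m(0, 0);
    }
    vec yhat;
    if (branch == BRANCH_GMF) yhat = qg;
    else if (branch == BRANCH_NN) yhat = qn;
    else yhat = fusion_W_m(0, 0) * qg + fusion_W_m(1, 0) * qn + fusion_b_m(0, 0);

    // ---- Huber loss and residual gradient (mean over the batch) ----
    vec r = yhat - yb;
    double L = 0.0;
    vec dy(B);
    for (int i = 0; i < B; ++i) {
      double a = std::abs(r(i));
      if (a <= delta) {
        L += 0.5 * r(i) * r(i);
        dy(i) = r(i);
      } else {
        L += delta * a - 0.5 * delta * delta;
        dy(i) = (r(i) > 0 ? delta : -delta);
      }
    }
    L /= B;
    dy /= B;
    loss_acc += L;
    ++loss_n;

    // ---- backward ----
    vec dqg(B, fill::zeros), dqn(B, fill::zeros);
    if (branch == BRANCH_FUSED) {
      dqg = fusion_W_m(0, 0) * dy;
      dqn = fusion_W_m(1, 0) * dy;
      G[iFW](0, 0) = dot(dy, qg);
      G[iFW](1, 0) = dot(dy, qn);
      G[iFB](0, 0) = accu(dy);
    } else if (branch == BRANCH_GMF) {
      dqg = dy;
    } else {
      dqn = dy;
    }

    if (use_gmf && branch != BRANCH_NN) {
      G[iH] = (D1b % D1t).t() * dqg;
      mat dP = dqg * h_m.col(0).t();  // B x k1
      mat dD1b = dP % D1t, dD1t = dP % D1b;
      for (int i = 0; i < B; ++i) {
        G[iW1b].row(bi(i)) += dD1b.row(i);
        G[iW1t].row(ti(i)) += dD1t.row(i);
      }
    }

    if (use_nn) {
      const mat& AJ = acts[J];
      G[iHW] = AJ * dqn;
      G[iHB](0, 0) = accu(dqn);
      mat dA = head_w_m.col(0) * dqn.t();  // width_J x B
      for (int j = J - 1; j >= 0; --j) {
        dA %= drops[j];
        mat dZ = dA % activate_grad(zs[j], pre[j], activation);
        G[iNNW + j] = dZ * acts[j].t();
        G[iNNB + j] = sum(dZ, 1);
        dA = P.nnW[j].t() * dZ;
      }
      // dA is now d_in x B; scatter into embedding gradients
      mat dX = dA.t();
      const uword k2 = P.W2b.n_cols, kg = P.Wg.n_cols, kl = P.Wl.n_cols;
      if (use_parents) {
        for (int i = 0; i < B; ++i) {
          G[iW2b].row(bi(i)) += dX(i, span(0, k2 - 1));
          G[iW2t].row(ti(i)) += dX(i, span(k2, 2 * k2 - 1));
          G[iWg].row(gi(i)) += dX(i, span(2 * k2, 2 * k2 + kg - 1));
          G[iWl].row(li(i)) += dX(i, span(2 * k2 + kg, 2 * k2 + kg + kl - 1));
        }
      } else {
        for (int i = 0; i < B; ++i) {
          G[iWg].row(gi(i)) += dX(i, span(0, kg - 1));
          G[iWl].row(li(i)) += dX(i, span(kg, kg + kl - 1));
        }
      }
    }

    adam.step(ps, G, lr);

    if (it % log_every == 0 || it == max_iter) {
      hist_it.push_back((double)it);
      hist_loss.push_back(loss_acc / loss_n);
      loss_acc = 0.0;
      loss_n = 0;
    }
  }

  P.h = h_m.col(0);
  P.head_w = head_w_m.col(0);
  P.fusion_W = fusion_W_m.col(0);
  P.head_b = head_b_m(0, 0);
  P.fusion_b = fusion_b_m(0, 0);
  for (int j = 0; j < J; ++j) P.nnb[j] = nnb_m[j].col(0);

  return List::create(_["params"] = params_to_list(P),
                      _["iteration"] = wrap(hist_it),
                      _["loss"] = wrap(hist_loss));
}

// ---------------------------------------------------------------------------
// Factorization machine baseline over the four one-hot blocks [x_b x_t x_g
// x_l]: global bias + per-feature linear weights + pairwise factorized
// interactions. With exactly one active feature per block, the interaction
// term is 0.5 * (|S|^2 - sum |v_i|^2) with S the sum of the four active
// factor rows. Trained with the same Adam/Huber loop as the main model.
// ---------------------------------------------------------------------------

namespace {

struct FMParams {
  double w0;
  vec wb, wt, wg, wl;
  mat Vb, Vt, Vg, Vl;
};

FMParams fm_from_list(const List& p) {
  FMParams F;
  F.w0 = as<double>(p["w0"]);
  F.wb = as<vec>(p["wb"]);
  F.wt = as<vec>(p["wt"]);
  F.wg = as<vec>(p["wg"]);
  F.wl = as<vec>(p["wl"]);
  F.Vb = as<mat>(p["Vb"]);
  F.Vt = as<mat>(p["Vt"]);
  F.Vg = as<mat>(p["Vg"]);
  F.Vl = as<mat>(p["Vl"]);
  return F;
}

vec fm_forward(const FMParams& F, const uvec& bi, const uvec& ti,
               const uvec& gi, const uvec& li) {
  mat S = F.Vb.rows(bi) + F.Vt.rows(ti) + F.Vg.rows(gi) + F.Vl.rows(li);
  vec inter = 0.5 * (sum(S % S, 1) - sum(F.Vb.rows(bi) % F.Vb.rows(bi), 1) -
                     sum(F.Vt.rows(ti) % F.Vt.rows(ti), 1) -
                     sum(F.Vg.rows(gi) % F.Vg.rows(gi), 1) -
                     sum(F.Vl.rows(li) % F.Vl.rows(li), 1));
  return F.w0 + F.wb.elem(bi) + F.wt.elem(ti) + F.wg.elem(gi) +
         F.wl.elem(li) + inter;
}

}  // namespace

// [[Rcpp::export]]
NumericVector fm_predict_cpp(IntegerVector b, IntegerVector t, IntegerVector g,
                             IntegerVector l, List params) {
  FMParams F = fm_from_list(params);
  ivec bv = as<ivec>(b), tv = as<ivec>(t), gv = as<ivec>(g), lv = as<ivec>(l);
  uvec all = regspace<uvec>(0, bv.n_elem - 1);
  vec out = fm_forward(F, take(bv, all), take(tv, all), take(gv, all),
                       take(lv, all));
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List fm_train_cpp(IntegerVector b, IntegerVector t, IntegerVector g,
                  IntegerVector l, NumericVector y, List params, double delta,
                  double lr, int batch_size, int max_iter, int seed,
                  int log_every) {
  FMParams F = fm_from_list(params);
  ivec bv = as<ivec>(b), tv = as<ivec>(t), gv = as<ivec>(g), lv = as<ivec>(l);
  vec yv = as<vec>(y);
  const int N = (int)yv.n_elem;

  mat w0_m(1, 1);
  w0_m(0, 0) = F.w0;
  mat wb_m(F.wb), wt_m(F.wt), wg_m(F.wg), wl_m(F.wl);
  std::vector<mat*> ps = {&w0_m, &wb_m, &wt_m, &wg_m, &wl_m,
                          &F.Vb, &F.Vt, &F.Vg, &F.Vl};
  Adam adam;
  adam.init(ps);

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  int pos = 0;

  std::vector<double> hist_it, hist_loss;
  double loss_acc = 0.0;
  int loss_n = 0;

  for (int it = 1; it <= max_iter; ++it) {
    if (pos >= N) {
      std::shuffle(order.begin(), order.end(), rng);
      pos = 0;
    }
    const int B = std::min(batch_size, N - pos);
    uvec idx(B);
    for (int i = 0; i < B; ++i) idx(i) = (uword)order[pos + i];
    pos += B;

    uvec bi = take(bv, idx), ti = take(tv, idx), gi = take(gv, idx),
         li = take(lv, idx);
    vec yb = yv.elem(idx);

    FMParams Fcur = F;
    Fcur.w0 = w0_m(0, 0);
    Fcur.wb = wb_m.col(0);
    Fcur.wt = wt_m.col(0);
    Fcur.wg = wg_m.col(0);
    Fcur.wl = wl_m.col(0);
    vec yhat = fm_forward(Fcur, bi, ti, gi, li);

    vec r = yhat - yb;
    double L = 0.0;
    vec dy(B);
    for (int i = 0; i < B; ++i) {
      double a = std::abs(r(i));
      if (a <= delta) {
        L += 0.5 * r(i) * r(i);
        dy(i) = r(i);
      } else {
        L += delta * a - 0.5 * delta * delta;
        dy(i) = (r(i) > 0 ? delta : -delta);
      }
    }
    L /= B;
    dy /= B;
    loss_acc += L;
    ++loss_n;

    std::vector<mat> G;
    for (auto* p : ps) G.push_back(zeros<mat>(p->n_rows, p->n_cols));
    mat S = F.Vb.rows(bi) + F.Vt.rows(ti) + F.Vg.rows(gi) + F.Vl.rows(li);
    G[0](0, 0) = accu(dy);
    for (int i = 0; i < B; ++i) {
      G[1](bi(i), 0) += dy(i);
      G[2](ti(i), 0) += dy(i);
      G[3](gi(i), 0) += dy(i);
      G[4](li(i), 0) += dy(i);
      rowvec s = S.row(i);
      G[5].row(bi(i)) += dy(i) * (s - F.Vb.row(bi(i)));
      G[6].row(ti(i)) += dy(i) * (s - F.Vt.row(ti(i)));
      G[7].row(gi(i)) += dy(i) * (s - F.Vg.row(gi(i)));
      G[8].row(li(i)) += dy(i) * (s - F.Vl.row(li(i)));
    }

    adam.step(ps, G, lr);

    if (it % log_every == 0 || it == max_iter) {
      hist_it.push_back((double)it);
      hist_loss.push_back(loss_acc / loss_n);
      loss_acc = 0.0;
      loss_n = 0;
    }
  }

  F.w0 = w0_m(0, 0);
  F.wb = wb_m.col(0);
  F.wt = wt_m.col(0);
  F.wg = wg_m.col(0);
  F.wl = wl_m.col(0);

  List out = List::create(
      _["w0"] = F.w0, _["wb"] = F.wb, _["wt"] = F.wt, _["wg"] = F.wg,
      _["wl"] = F.wl, _["Vb"] = F.Vb, _["Vt"] = F.Vt, _["Vg"] = F.Vg,
      _["Vl"] = F.Vl);
  return List::create(_["params"] = out, _["iteration"] = wrap(hist_it),
                      _["loss"] = wrap(hist_loss));
}
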