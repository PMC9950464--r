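// Feedforward network trainers used by the package: a masked multi-task MLP
// (sigmoid + binary cross-entropy or linear + squared error), the same trainer
// with a differentiable participation-ratio bonus (used for the
// dimensionality-expanding autoencoder input model), and a single-step DDPG
// actor-critic trainer. All optimisation is Adam with Keras-style defaults.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : gen(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double normal() { return norm(gen); }
  double uniform() { return unif(gen); }
};

// one dense layer stack with Adam state
struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;
  long step = 0;

  size_t n_layers() const { return W.size(); }
};

// Glorot-uniform initialisation (fan-based, the common default for dense nets)
Net init_net(const std::vector<int>& widths, Rng& rng) {
  Net net;
  for (size_t l = 0; l + 1 < widths.size(); ++l) {
    int fin = widths[l], fout = widths[l + 1];
    double lim = std::sqrt(6.0 / (fin + fout));
    mat W(fin, fout);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i)
        W(i, j) = (2.0 * rng.uniform() - 1.0) * lim;
    net.W.push_back(W);
    net.b.push_back(rowvec(fout, fill::zeros));
    net.mW.push_back(mat(fin, fout, fill::zeros));
    net.vW.push_back(mat(fin, fout, fill::zeros));
    net.mb.push_back(rowvec(fout, fill::zeros));
    net.vb.push_back(rowvec(fout, fill::zeros));
  }
  return net;
}

const double ADAM_B1 = 0.9, ADAM_B2 = 0.999, ADAM_EPS = 1e-7;

// decay, when used, is decoupled from the adaptive scaling (AdamW-style):
// folding an L2 term into the gradient lets the 1/sqrt(v) factor amplify
// the decay on quiet units and kills rectified networks
void adam_update(Net& net, const std::vector<mat>& gW,
                 const std::vector<rowvec>& gb, double lr,
                 double weight_decay = 0.0) {
  net.step += 1;
  double c1 = 1.0 - std::pow(ADAM_B1, (double)net.step);
  double c2 = 1.0 - std::pow(ADAM_B2, (double)net.step);
  for (size_t l = 0; l < net.W.size(); ++l) {
    net.mW[l] = ADAM_B1 * net.mW[l] + (1 - ADAM_B1) * gW[l];
    net.vW[l] = ADAM_B2 * net.vW[l] + (1 - ADAM_B2) * square(gW[l]);
    net.W[l] -= lr * (net.mW[l] / c1) / (sqrt(net.vW[l] / c2) + ADAM_EPS);
    if (weight_decay > 0) net.W[l] *= (1.0 - lr * weight_decay);
    net.mb[l] = ADAM_B1 * net.mb[l] + (1 - ADAM_B1) * gb[l];
    net.vb[l] = ADAM_B2 * net.vb[l] + (1 - ADAM_B2) * square(gb[l]);
    net.b[l] -= lr * (net.mb[l] / c1) / (sqrt(net.vb[l] / c2) + ADAM_EPS);
  }
}

inline mat relu(const mat& z) { return clamp(z, 0.0, datum::inf); }
inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// forward pass; acts[0] = input, acts[l] = post-activation of layer l,
// acts[L] = network output. out_act: 0 linear, 1 sigmoid, 2 tanh.
// hidden_act: 0 rectified-linear, 1 tanh.
void forward(const Net& net, const mat& X, int out_act,
             std::vector<mat>& acts, int hidden_act = 0) {
  size_t L = net.n_layers();
  acts.resize(L + 1);
  acts[0] = X;
  for (size_t l = 0; l < L; ++l) {
    mat z = acts[l] * net.W[l];
    z.each_row() += net.b[l];
    if (l + 1 < L) {
      acts[l + 1] = hidden_act == 1 ? mat(tanh(z)) : relu(z);
    } else {
      if (out_act == 1) acts[l + 1] = sigm(z);
      else if (out_act == 2) acts[l + 1] = tanh(z);
      else acts[l + 1] = z;
    }
  }
}

// backward pass given the gradient of the loss wrt the output *pre-activation*
// for linear outputs, or wrt post-activation combined with the activation
// derivative already applied by the caller. `delta` enters at the top layer
// pre-activation. extra_act_grad, if non-empty, is added to the gradient at
// the post-activation of hidden layer `extra_layer` (1-based).
void backward(const Net& net, const std::vector<mat>& acts, mat delta,
              std::vector<mat>& gW, std::vector<rowvec>& gb,
              const mat& extra_act_grad = mat(), int extra_layer = -1,
              int hidden_act = 0) {
  size_t L = net.n_layers();
  gW.resize(L);
  gb.resize(L);
  for (size_t l = L; l-- > 0;) {
    gW[l] = acts[l].t() * delta;
    gb[l] = sum(delta, 0);
    if (l > 0) {
      delta = delta * net.W[l].t();
      if ((int)l == extra_layer && extra_act_grad.n_elem > 0)
        delta += extra_act_grad;
      if (hidden_act == 1) delta %= (1.0 - square(acts[l]));
      else delta %= conv_to<mat>::from(acts[l] > 0);
    }
  }
}

Net net_from_list(const Rcpp::List& lst) {
  Rcpp::List Wl = lst["W"], bl = lst["b"];
  std::vector<int> widths;
  Net net;
  for (int l = 0; l < Wl.size(); ++l) {
    mat W = Rcpp::as<mat>(Wl[l]);
    rowvec b = Rcpp::as<rowvec>(bl[l]);
    net.W.push_back(W);
    net.b.push_back(b);
    net.mW.push_back(mat(W.n_rows, W.n_cols, fill::zeros));
    net.vW.push_back(mat(W.n_rows, W.n_cols, fill::zeros));
    net.mb.push_back(rowvec(b.n_elem, fill::zeros));
    net.vb.push_back(rowvec(b.n_elem, fill::zeros));
  }
  if (lst.containsElementNamed("adam")) {
    Rcpp::List ad = lst["adam"];
    Rcpp::List mWl = ad["mW"], vWl = ad["vW"], mbl = ad["mb"], vbl = ad["vb"];
    for (int l = 0; l < mWl.size(); ++l) {
      net.mW[l] = Rcpp::as<mat>(mWl[l]);
      net.vW[l] = Rcpp::as<mat>(vWl[l]);
      net.mb[l] = Rcpp::as<rowvec>(mbl[l]);
      net.vb[l] = Rcpp::as<rowvec>(vbl[l]);
    }
    net.step = Rcpp::as<long>(ad["step"]);
  }
  return net;
}

Rcpp::List adam_to_list(const Net& net) {
  Rcpp::List mWl(net.W.size()), vWl(net.W.size()), mbl(net.W.size()),
      vbl(net.W.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    mWl[l] = net.mW[l];
    vWl[l] = net.vW[l];
    mbl[l] = net.mb[l];
    vbl[l] = net.vb[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("mW") = mWl, Rcpp::Named("vW") = vWl,
      Rcpp::Named("mb") = mbl, Rcpp::Named("vb") = vbl,
      Rcpp::Named("step") = (double)net.step);
}

Rcpp::List net_to_list(const Net& net) {
  Rcpp::List Wl(net.W.size()), bl(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    Wl[l] = net.W[l];
    bl[l] = net.b[l];
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl);
}

// participation ratio of the rows-are-samples activation matrix A and the
// gradient of PR wrt A. PR = tr(C)^2 / tr(C^2) with C the sample covariance.
double pr_and_grad(const mat& A, mat& grad) {
  double n = (double)A.n_rows;
  mat Ac = A.each_row() - mean(A, 0);
  mat C = (Ac.t() * Ac) / (n - 1.0);
  double a = trace(C);
  double bb = accu(C % C);
  if (bb <= 0) {
    grad.zeros(A.n_rows, A.n_cols);
    return 0.0;
  }
  double pr = a * a / bb;
  // dPR/dC = (2a/b) I - (2a^2/b^2) C ; dPR/dA = 2/(n-1) * Ac * dPR/dC
  mat G = (2.0 / (n - 1.0)) * ((2.0 * a / bb) * Ac -
                               (2.0 * a * a / (bb * bb)) * (Ac * C));
  grad = G;
  return pr;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_mlp_train(const arma::mat& X, const arma::mat& Y,
                         const arma::mat& M, const std::vector<int>& hidden,
                         int out_act, double lr, int epochs, int batch_size,
                         int seed, double l1_rep, double l2_rep, int reg_layer,
                         double pr_lambda, int pr_layer,
                         Rcpp::Nullable<Rcpp::List> init_weights,
                         int loss_type = 0, int hidden_act = 0,
                         double dropout = 0.0, double weight_decay = 0.0) {
  int n = X.n_rows, p_out = Y.n_cols;
  std::vector<int> widths;
  widths.push_back(X.n_cols);
  for (int h : hidden) widths.push_back(h);
  widths.push_back(p_out);

  Rng rng((uint64_t)seed + 0x9E3779B97F4A7C15ULL);
  Net net;
  if (init_weights.isNotNull())
    net = net_from_list(Rcpp::List(init_weights));
  else
    net = init_net(widths, rng);

  Rcpp::List init_snapshot = net_to_list(net);

  vec hist_loss(epochs, fill::zeros);
  vec hist_pr(epochs, fill::zeros);
  int skipped = 0;

  uvec idx = regspace<uvec>(0, n - 1);
  std::vector<mat> acts, gW;
  std::vector<rowvec> gb;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with our own RNG for cross-call reproducibility
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng.uniform() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0, ep_pr = 0;
    int n_batches = 0, n_pr = 0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n) - 1;
      uvec bidx = idx.subvec(start, stop);
      mat Xb = X.rows(bidx), Yb = Y.rows(bidx), Mb = M.rows(bidx);
      double msum = accu(Mb);
      if (msum == 0) {
        ++skipped;
        continue;
      }
      forward(net, Xb, out_act, acts, hidden_act);
      size_t L = net.n_layers();
      std::vector<mat> dmask;
      if (dropout > 0) {
        // inverted dropout on hidden activations; the forward pass above is
        // recomputed layer by layer so the dropped activations propagate
        dmask.resize(L);
        for (size_t l = 1; l < L; ++l) {
          mat m(acts[l].n_rows, acts[l].n_cols);
          for (auto& v : m) v = rng.uniform() >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
          dmask[l] = m;
          mat z = acts[l - 1] * net.W[l - 1];
          z.each_row() += net.b[l - 1];
          acts[l] = (hidden_act == 1 ? mat(tanh(z)) : relu(z)) % m;
        }
        mat z = acts[L - 1] * net.W[L - 1];
        z.each_row() += net.b[L - 1];
        if (out_act == 1) acts[L] = sigm(z);
        else if (out_act == 2) acts[L] = tanh(z);
        else acts[L] = z;
      }
      const mat& out = acts[L];
      mat delta;
      double loss;
      if (out_act == 1 && loss_type == 0) {
        // sigmoid + masked BCE, mean over present entries
        mat pc = clamp(out, 1e-9, 1.0 - 1e-9);
        loss = -accu(Mb % (Yb % log(pc) + (1.0 - Yb) % log(1.0 - pc))) / msum;
        delta = (out - Yb) % Mb / msum;
      } else if (out_act == 1) {
        // sigmoid + masked squared error (gradient through the sigmoid)
        mat err = (out - Yb) % Mb;
        loss = accu(square(err)) / msum;
        delta = 2.0 * err % out % (1.0 - out) / msum;
      } else {  // linear + masked MSE
        mat err = (out - Yb) % Mb;
        loss = accu(square(err)) / msum;
        delta = 2.0 * err / msum;
      }

      // activity penalties / participation-ratio bonus act on hidden layers
      mat extra;
      int extra_at = -1;
      double bn = (double)Xb.n_rows;
      if (pr_lambda != 0.0 && pr_layer >= 1) {
        mat g;
        double pr = pr_and_grad(acts[pr_layer], g);
        ep_pr += pr;
        ++n_pr;
        extra = -pr_lambda * g;  // maximise PR
        extra_at = pr_layer;
        loss -= pr_lambda * pr;
      }
      if ((l1_rep != 0.0 || l2_rep != 0.0) && reg_layer >= 1) {
        const mat& A = acts[reg_layer];
        mat g = (l1_rep * sign(A) + 2.0 * l2_rep * A) / bn;
        loss += (l1_rep * accu(abs(A)) + l2_rep * accu(square(A))) / bn;
        if (extra_at == reg_layer)
          extra += g;
        else if (extra_at < 0) {
          extra = g;
          extra_at = reg_layer;
        }
      }
      if (dropout > 0) {
        // backward with the dropout masks folded into the activation
        // derivative
        size_t LL = net.n_layers();
        gW.resize(LL); gb.resize(LL);
        mat dl = delta;
        for (size_t l = LL; l-- > 0;) {
          gW[l] = acts[l].t() * dl;
          gb[l] = sum(dl, 0);
          if (l > 0) {
            dl = dl * net.W[l].t();
            if ((int)l == extra_at && extra.n_elem > 0) dl += extra;
            if (hidden_act == 1) dl %= (1.0 - square(acts[l]));
            else dl %= conv_to<mat>::from(acts[l] > 0);
            dl %= dmask[l];
          }
        }
      } else {
        backward(net, acts, delta, gW, gb, extra, extra_at, hidden_act);
      }
      adam_update(net, gW, gb, lr, weight_decay);
      ep_loss += loss;
      ++n_batches;
    }
    hist_loss[ep] = n_batches > 0 ? ep_loss / n_batches : datum::nan;
    hist_pr[ep] = n_pr > 0 ? ep_pr / n_pr : datum::nan;
    if (n_batches > 0 && !std::isfinite(hist_loss[ep]))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
  }

  // final per-task accuracy on the training set (classification only)
  vec task_acc(p_out, fill::value(datum::nan));
  if (out_act == 1) {
    forward(net, X, out_act, acts, hidden_act);
    const mat& out = acts[net.n_layers()];
    for (int j = 0; j < p_out; ++j) {
      uvec present = find(M.col(j) > 0);
      if (present.n_elem == 0) continue;
      vec pred = conv_to<vec>::from(out.col(j) > 0.5);
      vec truth = Y.col(j);
      task_acc[j] = mean(conv_to<vec>::from(
          pred.elem(present) == truth.elem(present)));
    }
  }

  Rcpp::List weights = net_to_list(net);
  weights["adam"] = adam_to_list(net);
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights, Rcpp::Named("initial") = init_snapshot,
      Rcpp::Named("loss") = hist_loss, Rcpp::Named("pr") = hist_pr,
      Rcpp::Named("task_accuracy") = task_acc,
      Rcpp::Named("skipped_batches") = skipped);
}

// [[Rcpp::export]]
Rcpp::List cpp_mlp_forward(const Rcpp::List& weights, const arma::mat& X,
                           int out_act, int hidden_act = 0) {
  Net net = net_from_list(weights);
  std::vector<mat> acts;
  forward(net, X, out_act, acts, hidden_act);
  Rcpp::List out(acts.size());
  for (size_t l = 0; l < acts.size(); ++l) out[l] = acts[l];
  return out;
}

// Single-step DDPG: the environment presents a stimulus, the actor emits a
// P-vector of actions in [-1, 1], and each coordinate is rewarded against the
// thresholded categorisation rule. With single-step episodes the discounted
// bootstrap term of the critic target vanishes, so critics regress the
// observed reward directly; everything else (replay buffer, exploration
// noise, deterministic policy gradient through the critics) is standard.
// [[Rcpp::export]]
Rcpp::List cpp_train_ddpg(const arma::mat& S, const arma::mat& labels,
                          const std::vector<int>& actor_hidden,
                          const std::vector<int>& critic_stim,
                          const std::vector<int>& critic_act,
                          const std::vector<int>& critic_shared, int epochs,
                          int batch_size, int buffer_cap, int prefill_batches,
                          double threshold, double noise_sd, double lr_actor,
                          double lr_critic, int seed,
                          int critic_warmup = 0) {
  int n = S.n_rows, m = S.n_cols, P = labels.n_cols;
  Rng rng((uint64_t)seed * 2654435761ULL + 13);

  std::vector<int> aw;
  aw.push_back(m);
  for (int h : actor_hidden) aw.push_back(h);
  aw.push_back(P);
  Net actor = init_net(aw, rng);
  // small final-layer init keeps the tanh head far from saturation early in
  // training (the standard DDPG initialisation trick); otherwise a wrong
  // early critic can pin actions at +/-1 where the tanh gradient vanishes
  actor.W.back() *= 0.01;

  // critic i: stimulus trunk (ReLU) and a linear action trunk on a_i feed a
  // shared ReLU trunk ending in a scalar linear reward prediction
  std::vector<Net> cs(P), ca(P), csh(P);
  for (int i = 0; i < P; ++i) {
    std::vector<int> ws;
    ws.push_back(m);
    for (int h : critic_stim) ws.push_back(h);
    cs[i] = init_net(ws, rng);
    std::vector<int> wa;
    wa.push_back(1);
    for (int h : critic_act) wa.push_back(h);
    ca[i] = init_net(wa, rng);
    std::vector<int> wsh;
    wsh.push_back(critic_stim.back() + critic_act.back());
    for (int h : critic_shared) wsh.push_back(h);
    wsh.push_back(1);
    csh[i] = init_net(wsh, rng);
  }

  // replay buffer of (stimulus index, executed action, reward)
  int cap = buffer_cap;
  uvec buf_s(cap, fill::zeros);
  mat buf_a(cap, P, fill::zeros), buf_r(cap, P, fill::zeros);
  int buf_n = 0, buf_head = 0;

  auto reward_of = [&](const mat& A, const uvec& sidx) {
    mat R(A.n_rows, P, fill::zeros);
    for (uword k = 0; k < A.n_rows; ++k)
      for (int j = 0; j < P; ++j) {
        double a = A(k, j);
        if (std::abs(a) > threshold)
          R(k, j) = (a > 0) == (labels(sidx[k], j) > 0) ? 1.0 : -1.0;
      }
    return R;
  };
  auto push = [&](const uvec& sidx, const mat& A, const mat& R) {
    for (uword k = 0; k < sidx.n_elem; ++k) {
      buf_s[buf_head] = sidx[k];
      buf_a.row(buf_head) = A.row(k);
      buf_r.row(buf_head) = R.row(k);
      buf_head = (buf_head + 1) % cap;
      if (buf_n < cap) ++buf_n;
    }
  };
  auto draw_states = [&](int nb) {
    uvec out(nb);
    for (int k = 0; k < nb; ++k) out[k] = (uword)(rng.uniform() * n) % n;
    return out;
  };

  // prefill with uniform random actions; once the ring buffer is full,
  // further random batches would only overwrite random data with random
  // data, so prefill is capped at buffer capacity
  int eff_prefill = std::min(prefill_batches, cap / batch_size + 1);
  for (int pb = 0; pb < eff_prefill; ++pb) {
    uvec sidx = draw_states(batch_size);
    mat A(batch_size, P);
    for (auto& v : A) v = 2.0 * rng.uniform() - 1.0;
    push(sidx, A, reward_of(A, sidx));
  }

  mat hist_reward(epochs, P, fill::zeros);
  std::vector<mat> acts, gW, s_acts, a_acts, h_acts;
  std::vector<rowvec> gb;

  // forward/backward helpers for one critic on (states, scalar actions)
  auto critic_forward = [&](int i, const mat& Sb, const vec& ab,
                            std::vector<mat>& sa, std::vector<mat>& aa,
                            std::vector<mat>& ha) {
    forward(cs[i], Sb, 0, sa);
    sa.back() = relu(sa.back());  // stimulus trunk top is ReLU
    forward(ca[i], mat(ab), 0, aa);  // linear action trunk
    mat h = join_rows(sa.back(), aa.back());
    forward(csh[i], h, 0, ha);
    return ha.back();  // n x 1 predicted reward
  };

  for (int ep = 0; ep < epochs; ++ep) {
    // act: collect one batch with exploration noise
    uvec sidx = draw_states(batch_size);
    forward(actor, S.rows(sidx), 2, acts);
    mat A = acts.back();
    for (auto& v : A) v = std::min(1.0, std::max(-1.0, v + noise_sd * rng.normal()));
    mat R = reward_of(A, sidx);
    push(sidx, A, R);
    hist_reward.row(ep) = mean(R, 0);

    // learn: sample a batch from the replay buffer
    uvec bpos(batch_size);
    for (int k = 0; k < batch_size; ++k)
      bpos[k] = (uword)(rng.uniform() * buf_n) % buf_n;
    uvec ssub = buf_s.elem(bpos);
    mat Sb = S.rows(ssub);
    mat Ab = buf_a.rows(bpos), Rb = buf_r.rows(bpos);
    double bn = (double)batch_size;

    // critic regression on observed rewards
    for (int i = 0; i < P; ++i) {
      mat q = critic_forward(i, Sb, Ab.col(i), s_acts, a_acts, h_acts);
      mat dq = 2.0 * (q - Rb.col(i)) / bn;
      // shared trunk
      backward(csh[i], h_acts, dq, gW, gb);
      mat dh = dq;
      for (size_t l = csh[i].n_layers(); l-- > 0;) {
        dh = dh * csh[i].W[l].t();
        if (l > 0) dh %= conv_to<mat>::from(h_acts[l] > 0);
      }
      adam_update(csh[i], gW, gb, lr_critic);
      int ns = s_acts.back().n_cols;
      mat dhs = dh.cols(0, ns - 1) % conv_to<mat>::from(s_acts.back() > 0);
      mat dha = dh.cols(ns, dh.n_cols - 1);
      backward(cs[i], s_acts, dhs, gW, gb);
      adam_update(cs[i], gW, gb, lr_critic);
      backward(ca[i], a_acts, dha, gW, gb);
      adam_update(ca[i], gW, gb, lr_critic);
    }

    // actor: ascend the critics' predicted reward at the current policy
    // (frozen during the critic warm-up phase, so the policy gradient is
    // only applied once the critics track the reward landscape)
    if (ep < critic_warmup) continue;
    forward(actor, Sb, 2, acts);
    mat Apol = acts.back();
    mat dA(batch_size, P, fill::zeros);
    for (int i = 0; i < P; ++i) {
      critic_forward(i, Sb, Apol.col(i), s_acts, a_acts, h_acts);
      mat dq(batch_size, 1, fill::value(1.0 / bn));
      mat dh = dq;
      for (size_t l = csh[i].n_layers(); l-- > 0;) {
        dh = dh * csh[i].W[l].t();
        if (l > 0) dh %= conv_to<mat>::from(h_acts[l] > 0);
      }
      int ns = s_acts.back().n_cols;
      mat dha = dh.cols(ns, dh.n_cols - 1);
      for (size_t l = ca[i].n_layers(); l-- > 0;) dha = dha * ca[i].W[l].t();
      dA.col(i) = dha;
    }
    mat delta = -dA % (1.0 - square(Apol));  // descend -J through tanh
    backward(actor, acts, delta, gW, gb);
    adam_update(actor, gW, gb, lr_actor);
  }

  Rcpp::List critics(P);
  for (int i = 0; i < P; ++i)
    critics[i] = Rcpp::List::create(
        Rcpp::Named("stim") = net_to_list(cs[i]),
        Rcpp::Named("act") = net_to_list(ca[i]),
        Rcpp::Named("shared") = net_to_list(csh[i]));
  return Rcpp::List::create(Rcpp::Named("actor") = net_to_list(actor),
                            Rcpp::Named("critics") = critics,
                            Rcpp::Named("reward_history") = hist_reward);
}

// [[Rcpp::export]]
arma::mat cpp_critic_predict(const Rcpp::List& critic, const arma::mat& Sb,
                             const arma::vec& ab) {
  Net s = net_from_list(critic["stim"]);
  Net a = net_from_list(critic["act"]);
  Net sh = net_from_list(critic["shared"]);
  std::vector<mat> sa, aa, ha;
  forward(s, Sb, 0, sa);
  sa.back() = relu(sa.back());
  forward(a, mat(ab), 0, aa);
  forward(sh, join_rows(sa.back(), aa.back()), 0, ha);
  return ha.back();
}
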