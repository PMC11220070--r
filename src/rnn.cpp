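// Gateless tanh recurrent network for the uncued set-shifting task.
//
// State update:  h_t = tanh(U x_t + V r*_t + F h_{t-1})
// Output:        o_t = tanh(D h_t),  decision = argmax softmax(o)
//
// Trial clock: 15 steps per trial; 3 pre-stimulus, 9 stimulus (steps 4..12),
// 3 post-stimulus; the decision is read at stimulus step 7 (trial step 10);
// the reward/punishment signal r* set by that decision is presented from
// step 11 through the last pre-stimulus step (step 3) of the next trial.
// The first trial of a sequence starts with no reward signal.
//
// Training data is the full combinatorial set of five-trial sequences
// (2 contexts x 4^5 stimulus sequences = 2048).  The network is
// deterministic, so sequences sharing a (context, stimulus-history) prefix
// have identical hidden trajectories up to the end of the prefix; forward
// and backward passes therefore run over the prefix tree of each batch,
// computing every shared prefix exactly once.  Gradients are exact batch
// gradients of the mean cross-entropy of the final-trial decision; the
// reward channel is a discrete input (decisions are not differentiated
// through).

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstring>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int T_TRIAL = 15;   // steps per trial
static const int STIM_ON = 4;    // first stimulus step (1-indexed)
static const int STIM_OFF = 12;  // last stimulus step
static const int DEC_STEP = 10;  // decision step = stimulus step 7
static const int N_TRIALS = 5;   // trials per sequence
static const int TT = N_TRIALS * T_TRIAL;

// stimulus code s in 0..3: s = 2*visual + auditory, go = 1 / no-go = 0
static inline int stim_visual(int s) { return s >> 1; }
static inline int stim_auditory(int s) { return s & 1; }

struct Level {
  cube H;        // hidden x nodes x T_TRIAL
  mat Hinit;     // hidden x nodes, state entering step 1 (parent step 15)
  uvec scol;     // stimulus code per node
  uvec target;   // contextual target (1 = go)
  uvec parent;   // index into previous level (empty at the root level)
  uvec own_r;    // reward column set by own decision: 0 success, 1 error
  uvec par_r;    // reward column active during steps 1..3 (from parent)
  uvec correct;  // own decision correct?
};

struct Tree {
  std::vector<Level> lev;       // lev[0..4]
  uvec leaf_of_seq;             // leaf column per input sequence
};

// Deduplicating prefix-tree construction for an arbitrary sequence subset.
static Tree build_tree(const ivec& context, const imat& stim) {
  const uword n = context.n_elem;
  Tree tr;
  tr.lev.resize(N_TRIALS);
  tr.leaf_of_seq.set_size(n);
  std::vector<uword> node_of_seq(n);           // current node per sequence
  std::map<std::pair<long, int>, uword> seen;  // (parent key, stim) -> node
  for (int t = 0; t < N_TRIALS; ++t) {
    seen.clear();
    std::vector<uword> sc, tg, par;
    for (uword i = 0; i < n; ++i) {
      int s = stim(i, t);
      long pkey = (t == 0) ? (long)context(i) : (long)node_of_seq[i];
      auto key = std::make_pair(pkey, s);
      auto it = seen.find(key);
      uword id;
      if (it == seen.end()) {
        id = sc.size();
        seen.emplace(key, id);
        sc.push_back((uword)s);
        tg.push_back(context(i) == 0 ? (uword)stim_visual(s)
                                     : (uword)stim_auditory(s));
        par.push_back(t == 0 ? 0u : node_of_seq[i]);
      } else {
        id = it->second;
      }
      node_of_seq[i] = id;
    }
    Level& L = tr.lev[t];
    L.scol.set_size(sc.size());
    L.target.set_size(tg.size());
    for (size_t i = 0; i < sc.size(); ++i) {
      L.scol(i) = sc[i];
      L.target(i) = tg[i];
    }
    if (t > 0) {
      L.parent.set_size(par.size());
      for (size_t i = 0; i < par.size(); ++i) L.parent(i) = par[i];
    }
  }
  for (uword i = 0; i < n; ++i) tr.leaf_of_seq(i) = node_of_seq[i];
  return tr;
}

// canonical full dataset: context-major, then lexicographic stimulus codes
// with trial 1 most significant (matches the R-level enumeration)
static void full_dataset(ivec& context, imat& stim) {
  context.set_size(2048);
  stim.set_size(2048, N_TRIALS);
  for (int c = 0; c < 2; ++c) {
    for (int id = 0; id < 1024; ++id) {
      int row = c * 1024 + id;
      context(row) = c;
      for (int t = 0; t < N_TRIALS; ++t)
        stim(row, t) = (id >> (2 * (N_TRIALS - 1 - t))) & 3;
    }
  }
}

// forward pass over a prefix tree; returns outputs at the leaf decision step
static mat forward_tree(const mat& U, const mat& V, const mat& F,
                        const mat& D, Tree& tr) {
  const int nh = U.n_rows;
  mat Ustim(nh, 4);
  for (int s = 0; s < 4; ++s)
    Ustim.col(s) = U.col(stim_visual(s) ? 0 : 1) +
                   U.col(stim_auditory(s) ? 2 : 3);
  mat Oleaf;
  for (int t = 0; t < N_TRIALS; ++t) {
    Level& L = tr.lev[t];
    const uword N = L.scol.n_elem;
    L.H.set_size(nh, N, T_TRIAL);
    if (t == 0) {
      L.Hinit.zeros(nh, N);
    } else {
      L.Hinit = tr.lev[t - 1].H.slice(T_TRIAL - 1).cols(L.parent);
      L.par_r = tr.lev[t - 1].own_r.elem(L.parent);
    }
    mat SU = Ustim.cols(L.scol);
    mat h = L.Hinit;
    mat RVpar, RVown;
    if (t > 0) RVpar = V.cols(L.par_r);
    for (int k = 1; k <= T_TRIAL; ++k) {
      mat a = F * h;
      if (k >= STIM_ON && k <= STIM_OFF) a += SU;
      if (k <= 3 && t > 0) a += RVpar;
      if (k > DEC_STEP) a += RVown;
      h = tanh(a);
      L.H.slice(k - 1) = h;
      if (k == DEC_STEP) {
        mat oraw = D * h;                     // 2 x N, rows: (go, no-go)
        mat o = tanh(oraw);
        if (t == N_TRIALS - 1) Oleaf = oraw;
        L.correct.set_size(N);
        L.own_r.set_size(N);
        for (uword j = 0; j < N; ++j) {
          // argmax of softmax == argmax of o; exact tie breaks to no-go
          int dec_go = o(0, j) > o(1, j) ? 1 : 0;
          L.correct(j) = (dec_go == (int)L.target(j)) ? 1 : 0;
          L.own_r(j) = L.correct(j) ? 0 : 1;
        }
        RVown = V.cols(L.own_r);
      }
    }
  }
  return Oleaf;
}

struct Grads { mat U, V, F, D; };

static double backward_tree(const mat& U, const mat& V, const mat& F,
                            const mat& D, Tree& tr, const mat& Oleaf,
                            Grads& g) {
  const int nh = U.n_rows;
  const uword Nleaf = Oleaf.n_cols;
  g.U.zeros(size(U)); g.V.zeros(size(V));
  g.F.zeros(size(F)); g.D.zeros(size(D));
  mat dUstim(nh, 4, fill::zeros);

  const Level& leaf = tr.lev[N_TRIALS - 1];
  mat P(2, Nleaf);
  double loss = 0.0;
  for (uword j = 0; j < Nleaf; ++j) {
    vec o = Oleaf.col(j);
    vec e = exp(o - o.max());
    vec p = e / accu(e);
    P.col(j) = p;
    int tgt_row = leaf.target(j) ? 0 : 1;     // go -> row 0
    loss -= std::log(std::max(p(tgt_row), 1e-12));
  }
  loss /= (double)Nleaf;

  mat gO = P;
  for (uword j = 0; j < Nleaf; ++j) gO(leaf.target(j) ? 0 : 1, j) -= 1.0;
  gO /= (double)Nleaf;                        // loss acts on raw logits

  mat child_delta;                            // delta into parent step 15
  for (int t = N_TRIALS - 1; t >= 0; --t) {
    Level& L = tr.lev[t];
    const uword N = L.scol.n_elem;
    int k_start = (t == N_TRIALS - 1) ? DEC_STEP : T_TRIAL;
    mat delta(nh, N, fill::zeros);
    if (t < N_TRIALS - 1) delta = child_delta;
    mat gsum_own(nh, N, fill::zeros), gsum_par(nh, N, fill::zeros);
    for (int k = k_start; k >= 1; --k) {
      if (t == N_TRIALS - 1 && k == DEC_STEP) {
        g.D += gO * L.H.slice(k - 1).t();
        delta += D.t() * gO;
      }
      mat gk = delta % (1.0 - square(L.H.slice(k - 1)));
      const mat& hprev = (k == 1) ? L.Hinit : L.H.slice(k - 2);
      g.F += gk * hprev.t();
      if (k >= STIM_ON && k <= STIM_OFF) {
        for (int s = 0; s < 4; ++s) {
          uvec idx = find(L.scol == (uword)s);
          if (idx.n_elem) dUstim.col(s) += sum(gk.cols(idx), 1);
        }
      }
      if (k > DEC_STEP) gsum_own += gk;
      if (k <= 3 && t > 0) gsum_par += gk;
      delta = F.t() * gk;
    }
    for (int r = 0; r < 2; ++r) {
      uvec io = find(L.own_r == (uword)r);
      if (io.n_elem) g.V.col(r) += sum(gsum_own.cols(io), 1);
      if (t > 0) {
        uvec ip = find(L.par_r == (uword)r);
        if (ip.n_elem) g.V.col(r) += sum(gsum_par.cols(ip), 1);
      }
    }
    if (t > 0) {
      child_delta.zeros(nh, tr.lev[t - 1].scol.n_elem);
      for (uword j = 0; j < N; ++j)
        child_delta.col(L.parent(j)) += delta.col(j);
    }
  }
  for (int s = 0; s < 4; ++s) {
    g.U.col(stim_visual(s) ? 0 : 1) += dUstim.col(s);
    g.U.col(stim_auditory(s) ? 2 : 3) += dUstim.col(s);
  }
  return loss;
}

struct W {
  int nh;
  std::vector<double> U, V, F, D;  // column-major: U nh x 4, V nh x 2,
                                   // F nh x nh, D 2 x nh
};

struct Grad { std::vector<double> U, V, F, D; };

struct Roll {
  std::vector<double> H;        // nh x TT
  std::vector<double> h0;       // state entering the sequence
  int r0 = -1;                  // reward signal entering the sequence
  int dec[N_TRIALS];
  int cor[N_TRIALS];
  double loss;
};

// forward one sequence from the state stored in r.h0 / r.r0 (zeros and no
// reward signal for independent sequences)
static void forward_seq(const W& w, const int* s, int ctx, Roll& r,
                        bool loss_tanh) {
  const int nh = w.nh;
  r.H.assign((size_t)nh * TT, 0.0);
  if ((int)r.h0.size() != nh) r.h0.assign(nh, 0.0);
  std::vector<double> h(r.h0), a(nh);
  int rstate = -1;                       // -1 none, 0 success, 1 error
  int prev_r = r.r0;
  for (int t = 0; t < N_TRIALS; ++t) {
    int st = s[t];
    int tgt = ctx == 0 ? stim_visual(st) : stim_auditory(st);
    int ucol_v = stim_visual(st) ? 0 : 1;
    int ucol_a = stim_auditory(st) ? 2 : 3;
    for (int k = 1; k <= T_TRIAL; ++k) {
      std::fill(a.begin(), a.end(), 0.0);
      for (int j = 0; j < nh; ++j) {
        double hj = h[j];
        if (hj == 0.0) continue;
        const double* Fj = &w.F[(size_t)nh * j];
        for (int i = 0; i < nh; ++i) a[i] += Fj[i] * hj;
      }
      if (k >= STIM_ON && k <= STIM_OFF) {
        for (int i = 0; i < nh; ++i)
          a[i] += w.U[i + (size_t)nh * ucol_v] + w.U[i + (size_t)nh * ucol_a];
      }
      if (k <= 3 && prev_r >= 0) {
        for (int i = 0; i < nh; ++i) a[i] += w.V[i + (size_t)nh * prev_r];
      }
      if (k > DEC_STEP && rstate >= 0) {
        for (int i = 0; i < nh; ++i) a[i] += w.V[i + (size_t)nh * rstate];
      }
      for (int i = 0; i < nh; ++i) h[i] = std::tanh(a[i]);
      std::memcpy(&r.H[(size_t)nh * (t * T_TRIAL + k - 1)], h.data(),
                  sizeof(double) * nh);
      if (k == DEC_STEP) {
        double o0 = 0.0, o1 = 0.0;
        for (int j = 0; j < nh; ++j) {
          o0 += w.D[0 + 2 * (size_t)j] * h[j];
          o1 += w.D[1 + 2 * (size_t)j] * h[j];
        }
        int dec_go = o0 > o1 ? 1 : 0;
        r.dec[t] = dec_go;
        r.cor[t] = dec_go == tgt ? 1 : 0;
        rstate = r.cor[t] ? 0 : 1;
        if (t == N_TRIALS - 1) {
          double l0 = o0, l1 = o1;
          if (loss_tanh) { l0 = std::tanh(o0); l1 = std::tanh(o1); }
          double m = std::max(l0, l1);
          double z = std::exp(l0 - m) + std::exp(l1 - m);
          double logp_go = l0 - m - std::log(z);
          double logp_ng = l1 - m - std::log(z);
          r.loss = -(tgt == 1 ? logp_go : logp_ng);
        }
      }
    }
    prev_r = rstate;
  }
  r.r0 = rstate;                         // outcome entering the next sequence
}

// backward for one sequence, accumulating gradients (loss already weighted
// by `scale`)
static void backward_seq(const W& w, const int* s, int ctx, const Roll& r,
                         double scale, bool loss_tanh, Grad& g) {
  const int nh = w.nh;
  std::vector<double> delta(nh, 0.0), gk(nh), hprev(nh);
  // output gradient at the final decision step
  int st5 = s[N_TRIALS - 1];
  int tgt = ctx == 0 ? stim_visual(st5) : stim_auditory(st5);
  const double* h70 = &r.H[(size_t)nh * (4 * T_TRIAL + DEC_STEP - 1)];
  double o0 = 0.0, o1 = 0.0;
  for (int j = 0; j < nh; ++j) {
    o0 += w.D[0 + 2 * (size_t)j] * h70[j];
    o1 += w.D[1 + 2 * (size_t)j] * h70[j];
  }
  double l0 = o0, l1 = o1, d0 = 1.0, d1 = 1.0;
  if (loss_tanh) {
    l0 = std::tanh(o0); l1 = std::tanh(o1);
    d0 = 1.0 - l0 * l0; d1 = 1.0 - l1 * l1;
  }
  double m = std::max(l0, l1);
  double e0 = std::exp(l0 - m), e1 = std::exp(l1 - m);
  double p0 = e0 / (e0 + e1), p1 = e1 / (e0 + e1);
  double go0 = (p0 - (tgt == 1 ? 1.0 : 0.0)) * d0 * scale;
  double go1 = (p1 - (tgt == 0 ? 1.0 : 0.0)) * d1 * scale;
  for (int j = 0; j < nh; ++j) {
    g.D[0 + 2 * (size_t)j] += go0 * h70[j];
    g.D[1 + 2 * (size_t)j] += go1 * h70[j];
    delta[j] = w.D[0 + 2 * (size_t)j] * go0 + w.D[1 + 2 * (size_t)j] * go1;
  }
  // reconstruct reward states per trial
  int rstate[N_TRIALS];
  for (int t = 0; t < N_TRIALS; ++t) rstate[t] = r.cor[t] ? 0 : 1;

  for (int t = N_TRIALS - 1; t >= 0; --t) {
    int stt = s[t];
    int ucol_v = stim_visual(stt) ? 0 : 1;
    int ucol_a = stim_auditory(stt) ? 2 : 3;
    int k_start = (t == N_TRIALS - 1) ? DEC_STEP : T_TRIAL;
    for (int k = k_start; k >= 1; --k) {
      const double* hk = &r.H[(size_t)nh * (t * T_TRIAL + k - 1)];
      for (int i = 0; i < nh; ++i) gk[i] = delta[i] * (1.0 - hk[i] * hk[i]);
      const double* hp;
      if (k == 1) {
        if (t == 0) {
          hp = r.h0.data();
        } else {
          hp = &r.H[(size_t)nh * ((t - 1) * T_TRIAL + T_TRIAL - 1)];
        }
      } else {
        hp = &r.H[(size_t)nh * (t * T_TRIAL + k - 2)];
      }
      for (int j = 0; j < nh; ++j) {
        if (hp[j] != 0.0) {
          double hj = hp[j];
          for (int i = 0; i < nh; ++i)
            g.F[i + (size_t)nh * j] += gk[i] * hj;
        }
      }
      if (k >= STIM_ON && k <= STIM_OFF) {
        for (int i = 0; i < nh; ++i) {
          g.U[i + (size_t)nh * ucol_v] += gk[i];
          g.U[i + (size_t)nh * ucol_a] += gk[i];
        }
      }
      if (k > DEC_STEP) {
        int rs = rstate[t];
        for (int i = 0; i < nh; ++i) g.V[i + (size_t)nh * rs] += gk[i];
      }
      if (k <= 3) {
        int rs = (t > 0) ? rstate[t - 1] : r.r0;
        if (rs >= 0) {
          for (int i = 0; i < nh; ++i) g.V[i + (size_t)nh * rs] += gk[i];
        }
      }
      // delta = F^T gk
      for (int j = 0; j < nh; ++j) {
        double acc = 0.0;
        for (int i = 0; i < nh; ++i) acc += w.F[i + (size_t)nh * j] * gk[i];
        delta[j] = acc;
      }
    }
  }
}

struct Adam {
  std::vector<double> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(size_t n) { m.assign(n, 0.0); v.assign(n, 0.0); }
  void step(std::vector<double>& w, std::vector<double>& g, double lr,
            long t) {
    double bc1 = 1.0 - std::pow(b1, (double)t);
    double bc2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < w.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * g[i];
      v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
      w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
      g[i] = 0.0;
    }
  }
};


// Train on the full 2048-sequence combinatorial dataset with minibatch
// ADAM over per-sequence backpropagation-through-time.  Sequences are
// visited in a fresh random order every epoch (deterministic in
// `shuffle_seed`); gradients are averaged over `batch_size` consecutive
// sequences per update.  The learning rate decays linearly from `lr` to
// zero over the later part of training when `lr_decay` is set (constant
// for the first `decay_start` fraction of epochs), so the escape from
// the context-blind plateau happens at the full rate while the end state
// is frozen into the late solution.
// [[Rcpp::export]]
Rcpp::List rnn_train_cpp(arma::mat U0, arma::mat V0, arma::mat F0,
                         arma::mat D0, int epochs, double lr,
                         int record_every, int batch_size,
                         int shuffle_seed, bool lr_decay = true,
                         double decay_start = 0.5,
                         bool loss_tanh = false,
                         bool carry_state = false) {
  const int nh = U0.n_rows;
  W w; w.nh = nh;
  w.U.assign(U0.begin(), U0.end());
  w.V.assign(V0.begin(), V0.end());
  w.F.assign(F0.begin(), F0.end());
  w.D.assign(D0.begin(), D0.end());
  Grad g;
  g.U.assign(w.U.size(), 0.0); g.V.assign(w.V.size(), 0.0);
  g.F.assign(w.F.size(), 0.0); g.D.assign(w.D.size(), 0.0);
  Adam aU, aV, aF, aD;
  aU.init(w.U.size()); aV.init(w.V.size());
  aF.init(w.F.size()); aD.init(w.D.size());

  const int nseq = 2048;
  std::vector<int> seqs(nseq * N_TRIALS), ctxs(nseq);
  for (int c = 0; c < 2; ++c)
    for (int id = 0; id < 1024; ++id) {
      int row = c * 1024 + id;
      ctxs[row] = c;
      for (int t = 0; t < N_TRIALS; ++t)
        seqs[row * N_TRIALS + t] = (id >> (2 * (N_TRIALS - 1 - t))) & 3;
    }
  std::vector<int> perm(nseq);
  for (int i = 0; i < nseq; ++i) perm[i] = i;
  std::mt19937 rng((unsigned)shuffle_seed);

  Roll roll;
  roll.h0.assign(nh, 0.0);
  std::vector<double> ep_out, loss_out, acc_all, acc_con, acc_inc;
  long tstep = 0;
  auto evaluate = [&](double* all, double* con, double* inc) {
    double nc = 0, ni = 0, cc = 0, ci = 0;
    Roll r2;
    for (int i = 0; i < nseq; ++i) {
      r2.h0.assign(nh, 0.0);
      r2.r0 = -1;
      forward_seq(w, &seqs[i * N_TRIALS], ctxs[i], r2, loss_tanh);
      int s5 = seqs[i * N_TRIALS + 4];
      bool con5 = stim_visual(s5) == stim_auditory(s5);
      if (con5) { nc++; cc += r2.cor[4]; } else { ni++; ci += r2.cor[4]; }
    }
    *all = (cc + ci) / (nc + ni); *con = cc / nc; *inc = ci / ni;
  };
  for (int ep = 1; ep <= epochs; ++ep) {
    double lr_ep = lr;
    if (lr_decay) {
      double hold = decay_start * epochs;
      if (ep > hold) {
        lr_ep = lr * (1.0 - ((double)ep - hold) /
                            ((double)epochs - hold + 1.0));
      }
    }
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0;
    int in_batch = 0;
    for (int i = 0; i < nseq; ++i) {
      int id = perm[i];
      if (!carry_state) {
        std::fill(roll.h0.begin(), roll.h0.end(), 0.0);
        roll.r0 = -1;
      }
      forward_seq(w, &seqs[id * N_TRIALS], ctxs[id], roll, loss_tanh);
      ep_loss += roll.loss;
      backward_seq(w, &seqs[id * N_TRIALS], ctxs[id], roll,
                   1.0 / batch_size, loss_tanh, g);
      if (carry_state) {
        std::memcpy(roll.h0.data(), &roll.H[(size_t)nh * (TT - 1)],
                    sizeof(double) * nh);
      }
      if (++in_batch == batch_size || i == nseq - 1) {
        ++tstep;
        aU.step(w.U, g.U, lr_ep, tstep); aV.step(w.V, g.V, lr_ep, tstep);
        aF.step(w.F, g.F, lr_ep, tstep); aD.step(w.D, g.D, lr_ep, tstep);
        in_batch = 0;
      }
    }
    if (ep == 1 || ep % record_every == 0 || ep == epochs) {
      double all, con, inc;
      evaluate(&all, &con, &inc);
      ep_out.push_back(ep); loss_out.push_back(ep_loss / nseq);
      acc_all.push_back(all); acc_con.push_back(con); acc_inc.push_back(inc);
    }
  }
  double all, con, inc;
  evaluate(&all, &con, &inc);
  arma::mat Uo(&w.U[0], nh, 4), Vo(&w.V[0], nh, 2), Fo(&w.F[0], nh, nh),
      Do(&w.D[0], 2, nh);
  return Rcpp::List::create(
    Rcpp::Named("U") = Uo, Rcpp::Named("V") = Vo, Rcpp::Named("F") = Fo,
    Rcpp::Named("D") = Do,
    Rcpp::Named("curve") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = ep_out, Rcpp::Named("loss") = loss_out,
      Rcpp::Named("acc_all") = acc_all,
      Rcpp::Named("acc_congruent") = acc_con,
      Rcpp::Named("acc_incongruent") = acc_inc),
    Rcpp::Named("final_acc_all") = all,
    Rcpp::Named("final_acc_congruent") = con,
    Rcpp::Named("final_acc_incongruent") = inc);
}

// Loss and exact full-dataset gradients at the given weights (no update);
// checkable against finite differences of the returned loss.
// [[Rcpp::export]]
Rcpp::List rnn_loss_grad_cpp(const arma::mat& U, const arma::mat& V,
                             const arma::mat& F, const arma::mat& D) {
  ivec context; imat stim;
  full_dataset(context, stim);
  Tree tr = build_tree(context, stim);
  mat Oleaf = forward_tree(U, V, F, D, tr);
  Grads g;
  double loss = backward_tree(U, V, F, D, tr, Oleaf, g);
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("gU") = g.U,
    Rcpp::Named("gV") = g.V, Rcpp::Named("gF") = g.F,
    Rcpp::Named("gD") = g.D);
}

// Flat rollout of explicit sequences; returns hidden states, outputs and
// per-trial decisions.  stim: n_seq x 5 integer codes 0..3; context: n_seq
// (0 visual, 1 auditory).  hidden: nh x n_seq x 75; output: 2 x n_seq x 75.
// [[Rcpp::export]]
Rcpp::List rnn_run_cpp(const arma::mat& U, const arma::mat& V,
                       const arma::mat& F, const arma::mat& D,
                       const arma::imat& stim, const arma::ivec& context) {
  const int nh = U.n_rows;
  const uword N = stim.n_rows;
  const int TT = N_TRIALS * T_TRIAL;
  mat Ustim(nh, 4);
  for (int s = 0; s < 4; ++s)
    Ustim.col(s) = U.col(stim_visual(s) ? 0 : 1) +
                   U.col(stim_auditory(s) ? 2 : 3);
  cube H(nh, N, TT), O(2, N, TT);
  imat decisions(N, N_TRIALS), correct(N, N_TRIALS);
  mat h(nh, N, fill::zeros);
  uvec rstate(N, fill::zeros), rhave(N, fill::zeros);
  for (int t = 0; t < N_TRIALS; ++t) {
    mat SU(nh, N);
    ivec tgt(N);
    for (uword j = 0; j < N; ++j) {
      int s = stim(j, t);
      SU.col(j) = Ustim.col(s);
      tgt(j) = context(j) == 0 ? stim_visual(s) : stim_auditory(s);
    }
    for (int k = 1; k <= T_TRIAL; ++k) {
      mat a = F * h;
      if (k >= STIM_ON && k <= STIM_OFF) a += SU;
      if ((k > DEC_STEP) || (k <= 3)) {
        for (uword j = 0; j < N; ++j)
          if (rhave(j)) a.col(j) += V.col(rstate(j));
      }
      h = tanh(a);
      int kk = t * T_TRIAL + k - 1;
      H.slice(kk) = h;
      mat o = tanh(D * h);
      O.slice(kk) = o;
      if (k == DEC_STEP) {
        for (uword j = 0; j < N; ++j) {
          int dec_go = o(0, j) > o(1, j) ? 1 : 0;
          decisions(j, t) = dec_go;
          correct(j, t) = dec_go == tgt(j) ? 1 : 0;
          rstate(j) = correct(j, t) ? 0 : 1;
          rhave(j) = 1;
        }
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("hidden") = H, Rcpp::Named("output") = O,
    Rcpp::Named("decision") = decisions, Rcpp::Named("correct") = correct);
}
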