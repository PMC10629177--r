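// Twin (weight-sharing) LSTM pair scorer.
//
// Each input is one kernel-matrix row presented to an LSTM as a sequence of
// d-dimensional steps (cube X: d x T x n, one slice per cell). The two
// branches share all weights; the head concatenates the two final hidden
// states and applies dense -> sigmoid -> dense -> sigmoid to a scalar score
// in (0,1), trained with binary cross-entropy against same/different pair
// targets by full backpropagation through time with Adam.
//
// Gate layout in the stacked weight matrices (rows of W, U, b):
//   [0,H)   input gate i
//   [H,2H)  forget gate f
//   [2H,3H) candidate g (tanh)
//   [3H,4H) output gate o

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmWeights {
  mat W;   // 4H x d
  mat U;   // 4H x H
  vec b;   // 4H
  mat W1;  // du x 2H
  vec b1;  // du
  mat W2;  // 1 x du
  double b2;
};

static LstmWeights unpack(const Rcpp::List& w) {
  LstmWeights lw;
  lw.W = Rcpp::as<mat>(w["W"]);
  lw.U = Rcpp::as<mat>(w["U"]);
  lw.b = Rcpp::as<vec>(w["b"]);
  lw.W1 = Rcpp::as<mat>(w["W1"]);
  lw.b1 = Rcpp::as<vec>(w["b1"]);
  lw.W2 = Rcpp::as<mat>(w["W2"]);
  lw.b2 = Rcpp::as<double>(w["b2"]);
  return lw;
}

struct LstmCache {
  cube ig, fg, gg, og, cs, tcs, hs;  // each H x B x T
};

// forward a batch of sequences Xb (d x B x T); returns final hidden (H x B)
static mat lstm_forward(const cube& Xb, const LstmWeights& w, LstmCache* cache) {
  const uword H = w.U.n_cols, B = Xb.n_cols, T = Xb.n_slices;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  if (cache) {
    cache->ig.set_size(H, B, T); cache->fg.set_size(H, B, T);
    cache->gg.set_size(H, B, T); cache->og.set_size(H, B, T);
    cache->cs.set_size(H, B, T); cache->tcs.set_size(H, B, T);
    cache->hs.set_size(H, B, T);
  }
  for (uword t = 0; t < T; ++t) {
    mat Z = w.W * Xb.slice(t) + w.U * h;
    Z.each_col() += w.b;
    mat i = sigm(Z.rows(0, H - 1));
    mat f = sigm(Z.rows(H, 2 * H - 1));
    mat g = tanh(Z.rows(2 * H, 3 * H - 1));
    mat o = sigm(Z.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    if (cache) {
      cache->ig.slice(t) = i; cache->fg.slice(t) = f;
      cache->gg.slice(t) = g; cache->og.slice(t) = o;
      cache->cs.slice(t) = c; cache->tcs.slice(t) = tc;
      cache->hs.slice(t) = h;
    }
  }
  return h;
}

struct LstmGrads {
  mat gW, gU, gW1, gW2;
  vec gb, gb1;
  double gb2;
  void zero(const LstmWeights& w) {
    gW.zeros(size(w.W)); gU.zeros(size(w.U)); gb.zeros(w.b.n_elem);
    gW1.zeros(size(w.W1)); gb1.zeros(w.b1.n_elem);
    gW2.zeros(size(w.W2)); gb2 = 0.0;
  }
};

// backprop through time; dhT is the gradient on the final hidden state
static void lstm_backward(const cube& Xb, const LstmCache& cc,
                          const LstmWeights& w, const mat& dhT, LstmGrads& g) {
  const uword H = w.U.n_cols, B = Xb.n_cols, T = Xb.n_slices;
  mat dh = dhT;
  mat dc(H, B, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat& i = cc.ig.slice(tt);
    const mat& f = cc.fg.slice(tt);
    const mat& gg = cc.gg.slice(tt);
    const mat& o = cc.og.slice(tt);
    const mat& tc = cc.tcs.slice(tt);
    mat cprev = (tt > 0) ? cc.cs.slice(tt - 1) : mat(H, B, fill::zeros);
    mat hprev = (tt > 0) ? cc.hs.slice(tt - 1) : mat(H, B, fill::zeros);

    mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    mat di = dc % gg;
    mat df = dc % cprev;
    mat dg = dc % i;

    mat dZ(4 * H, B);
    dZ.rows(0, H - 1)         = di % i % (1.0 - i);
    dZ.rows(H, 2 * H - 1)     = df % f % (1.0 - f);
    dZ.rows(2 * H, 3 * H - 1) = dg % (1.0 - gg % gg);
    dZ.rows(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);

    g.gW += dZ * Xb.slice(tt).t();
    g.gU += dZ * hprev.t();
    g.gb += sum(dZ, 1);

    dh = w.U.t() * dZ;
    dc = dc % f;
  }
}

struct Adam {
  mat mW, vW, mU, vU, mW1, vW1, mW2, vW2;
  vec mb, vb, mb1, vb1;
  double mb2 = 0, vb2 = 0;
  long t = 0;
  void init(const LstmWeights& w) {
    mW.zeros(size(w.W)); vW.zeros(size(w.W));
    mU.zeros(size(w.U)); vU.zeros(size(w.U));
    mb.zeros(w.b.n_elem); vb.zeros(w.b.n_elem);
    mW1.zeros(size(w.W1)); vW1.zeros(size(w.W1));
    mb1.zeros(w.b1.n_elem); vb1.zeros(w.b1.n_elem);
    mW2.zeros(size(w.W2)); vW2.zeros(size(w.W2));
  }
  template <typename A>
  void upd(A& p, A& m, A& v, const A& grad, double lr, double bc1, double bc2) {
    m = 0.9 * m + 0.1 * grad;
    v = 0.999 * v + 0.001 * (grad % grad);
    p -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
  }
  void step(LstmWeights& w, const LstmGrads& g, double lr) {
    ++t;
    double bc1 = 1.0 - std::pow(0.9, (double)t);
    double bc2 = 1.0 - std::pow(0.999, (double)t);
    upd(w.W, mW, vW, g.gW, lr, bc1, bc2);
    upd(w.U, mU, vU, g.gU, lr, bc1, bc2);
    upd(w.b, mb, vb, g.gb, lr, bc1, bc2);
    upd(w.W1, mW1, vW1, g.gW1, lr, bc1, bc2);
    upd(w.b1, mb1, vb1, g.gb1, lr, bc1, bc2);
    upd(w.W2, mW2, vW2, g.gW2, lr, bc1, bc2);
    mb2 = 0.9 * mb2 + 0.1 * g.gb2;
    vb2 = 0.999 * vb2 + 0.001 * g.gb2 * g.gb2;
    w.b2 -= lr * (mb2 / bc1) / (std::sqrt(vb2 / bc2) + 1e-8);
  }
};

static cube gather(const cube& X, const uvec& cells) {
  cube Xb(X.n_rows, cells.n_elem, X.n_cols);  // d x B x T
  for (uword b = 0; b < cells.n_elem; ++b) {
    for (uword t = 0; t < X.n_cols; ++t) {
      Xb.slice(t).col(b) = X.slice(cells[b]).col(t);
    }
  }
  return Xb;
}

// head forward + loss + backward; returns summed BCE loss over the batch and
// fills dh1/dh2 with mean-scaled gradients (per-batch mean loss)
static double head_pass(const mat& h1, const mat& h2, const vec& y,
                        const LstmWeights& w, LstmGrads& g, mat& dh1, mat& dh2) {
  const uword H = h1.n_rows, B = h1.n_cols;
  mat hcat = join_cols(h1, h2);              // 2H x B
  mat z1 = w.W1 * hcat;
  z1.each_col() += w.b1;
  mat a1 = sigm(z1);
  rowvec z2 = w.W2 * a1 + w.b2;
  rowvec p = 1.0 / (1.0 + exp(-z2));
  rowvec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  rowvec yr = y.t();
  double loss = -accu(yr % log(pc) + (1.0 - yr) % log(1.0 - pc));

  rowvec dz2 = (p - yr) / (double)B;
  g.gW2 += dz2 * a1.t();
  g.gb2 += accu(dz2);
  mat da1 = w.W2.t() * dz2;
  mat dz1 = da1 % a1 % (1.0 - a1);
  g.gW1 += dz1 * hcat.t();
  g.gb1 += sum(dz1, 1);
  mat dhcat = w.W1.t() * dz1;
  dh1 = dhcat.rows(0, H - 1);
  dh2 = dhcat.rows(H, 2 * H - 1);
  return loss;
}

// [[Rcpp::export]]
Rcpp::List sclstm_train_cpp(const arma::cube& X, const arma::uvec& pair_i,
                            const arma::uvec& pair_j, const arma::vec& y,
                            Rcpp::List init_weights, int epochs,
                            int batch_size, double learning_rate,
                            int shuffle_seed, double loss_tol) {
  LstmWeights w = unpack(init_weights);
  Adam opt;
  opt.init(w);
  const uword npairs = pair_i.n_elem;
  std::mt19937 rng((unsigned)shuffle_seed);
  std::vector<uword> order(npairs);
  for (uword q = 0; q < npairs; ++q) order[q] = q;

  std::vector<double> epoch_losses;
  epoch_losses.reserve(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double total = 0.0;
    for (uword start = 0; start < npairs; start += (uword)batch_size) {
      uword stop = std::min(npairs, start + (uword)batch_size);
      uvec ci(stop - start), cj(stop - start);
      vec yb(stop - start);
      for (uword q = start; q < stop; ++q) {
        ci[q - start] = pair_i[order[q]];
        cj[q - start] = pair_j[order[q]];
        yb[q - start] = y[order[q]];
      }
      cube Xa = gather(X, ci), Xb = gather(X, cj);
      LstmCache ca, cb;
      mat h1 = lstm_forward(Xa, w, &ca);
      mat h2 = lstm_forward(Xb, w, &cb);
      LstmGrads g;
      g.zero(w);
      mat dh1, dh2;
      total += head_pass(h1, h2, yb, w, g, dh1, dh2);
      lstm_backward(Xa, ca, w, dh1, g);
      lstm_backward(Xb, cb, w, dh2, g);
      opt.step(w, g, learning_rate);
    }
    double mean_loss = total / (double)npairs;
    if (!std::isfinite(mean_loss)) {
      Rcpp::stop("non-finite training loss at epoch %d (learning rate %g)",
                 ep + 1, learning_rate);
    }
    epoch_losses.push_back(mean_loss);
    if (mean_loss <= loss_tol) break;  // converged: later epochs buy nothing
    if (ep % 5 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::List::create(
          Rcpp::Named("W") = w.W, Rcpp::Named("U") = w.U,
          Rcpp::Named("b") = w.b, Rcpp::Named("W1") = w.W1,
          Rcpp::Named("b1") = w.b1, Rcpp::Named("W2") = w.W2,
          Rcpp::Named("b2") = w.b2),
      Rcpp::Named("epoch_losses") = epoch_losses);
}

// [[Rcpp::export]]
arma::mat sclstm_embed_cpp(const arma::cube& X, Rcpp::List weights) {
  LstmWeights w = unpack(weights);
  uvec all = regspace<uvec>(0, X.n_slices - 1);
  cube Xb = gather(X, all);
  mat h = lstm_forward(Xb, w, nullptr);
  return h.t();  // n x H
}

// [[Rcpp::export]]
arma::mat sclstm_score_cpp(const arma::mat& E, Rcpp::List weights) {
  // E: n x H per-cell final hidden states; returns P with P(i,j) = f(i, j)
  LstmWeights w = unpack(weights);
  const uword H = w.U.n_cols, n = E.n_rows;
  mat Et = E.t();                       // H x n
  mat Za = w.W1.cols(0, H - 1) * Et;    // du x n (branch-1 contribution)
  mat Zb = w.W1.cols(H, 2 * H - 1) * Et;
  mat P(n, n);
  for (uword j = 0; j < n; ++j) {
    mat z1 = Za;
    z1.each_col() += Zb.col(j) + w.b1;
    mat a1 = sigm(z1);
    rowvec z2 = w.W2 * a1 + w.b2;
    P.col(j) = (1.0 / (1.0 + exp(-z2))).t();
  }
  return P;
}
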