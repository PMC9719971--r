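// Bi-directional LSTM sequence autoencoder with a linear outcome head.
//
// Model: a forward and a backward LSTM read the input sequence x<1..T>;
// their final hidden states are concatenated and linearly projected to the
// embedding z. A decoder LSTM, fed z at every step, emits the reconstruction
// in reversed order; a linear layer maps decoder states to feature space and
// a linear head maps z to the outcome. Training loss is
// w_r * RMSE(observed reconstruction cells) + w_s * (RMSE | BCE)(head).
//
// Gradients are exact analytic BPTT; they are checked against numerical
// differentiation in the test suite. Gate layout in the stacked 4H rows is
// [input; forget; cell; output].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec sigm(const vec& x) {
  vec out(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    out(i) = v >= 0 ? 1.0 / (1.0 + std::exp(-v))
                    : std::exp(v) / (1.0 + std::exp(v));
  }
  return out;
}

struct Params {
  mat Wx_f, Wh_f; vec b_f;
  mat Wx_b, Wh_b; vec b_b;
  mat Wz; vec bz;
  mat Wx_d, Wh_d; vec b_d;
  mat Wo; vec bo;
  vec wy; double by;
  uword H, E, Din, Dr;
};

static Params unpack(const Rcpp::List& p) {
  Params P;
  P.Wx_f = Rcpp::as<mat>(p["Wx_f"]); P.Wh_f = Rcpp::as<mat>(p["Wh_f"]);
  P.b_f  = Rcpp::as<vec>(p["b_f"]);
  P.Wx_b = Rcpp::as<mat>(p["Wx_b"]); P.Wh_b = Rcpp::as<mat>(p["Wh_b"]);
  P.b_b  = Rcpp::as<vec>(p["b_b"]);
  P.Wz   = Rcpp::as<mat>(p["Wz"]);   P.bz   = Rcpp::as<vec>(p["bz"]);
  P.Wx_d = Rcpp::as<mat>(p["Wx_d"]); P.Wh_d = Rcpp::as<mat>(p["Wh_d"]);
  P.b_d  = Rcpp::as<vec>(p["b_d"]);
  P.Wo   = Rcpp::as<mat>(p["Wo"]);   P.bo   = Rcpp::as<vec>(p["bo"]);
  P.wy   = Rcpp::as<vec>(p["wy"]);   P.by   = Rcpp::as<vec>(p["by"])(0);
  P.H = P.Wh_f.n_cols; P.E = P.Wz.n_rows;
  P.Din = P.Wx_f.n_cols; P.Dr = P.Wo.n_rows;
  return P;
}

struct Grads {
  mat Wx_f, Wh_f; vec b_f;
  mat Wx_b, Wh_b; vec b_b;
  mat Wz; vec bz;
  mat Wx_d, Wh_d; vec b_d;
  mat Wo; vec bo;
  vec wy; double by;
  void init(const Params& P) {
    Wx_f = zeros<mat>(size(P.Wx_f)); Wh_f = zeros<mat>(size(P.Wh_f));
    b_f = zeros<vec>(P.b_f.n_elem);
    Wx_b = zeros<mat>(size(P.Wx_b)); Wh_b = zeros<mat>(size(P.Wh_b));
    b_b = zeros<vec>(P.b_b.n_elem);
    Wz = zeros<mat>(size(P.Wz)); bz = zeros<vec>(P.bz.n_elem);
    Wx_d = zeros<mat>(size(P.Wx_d)); Wh_d = zeros<mat>(size(P.Wh_d));
    b_d = zeros<vec>(P.b_d.n_elem);
    Wo = zeros<mat>(size(P.Wo)); bo = zeros<vec>(P.bo.n_elem);
    wy = zeros<vec>(P.wy.n_elem); by = 0.0;
  }
};

// Caches for one sequence (columns indexed by processing step).
struct SeqCache {
  mat Gf, Cf, Hf;        // encoder forward: gates (4H x T), cells, hiddens
  mat Gb, Cb, Hb;        // encoder backward (processing order T-1..0)
  mat Gd, Cd, Hd;        // decoder
  mat Xhat;              // Dr x T, in ORIGINAL time order
  vec z, hcat;
  double yraw;           // head output before any sigmoid
};

// One directional LSTM pass over columns `order` of X. Returns final hidden.
static void lstm_dir(const mat& Wx, const mat& Wh, const vec& b,
                     const mat& X, const uvec& order,
                     mat& G, mat& C, mat& Hs) {
  uword H = Wh.n_cols, T = order.n_elem;
  G.set_size(4 * H, T); C.set_size(H, T); Hs.set_size(H, T);
  vec h = zeros<vec>(H), c = zeros<vec>(H);
  for (uword p = 0; p < T; ++p) {
    vec pre = Wx * X.col(order(p)) + Wh * h + b;
    vec gi = sigm(pre.rows(0, H - 1));
    vec gf = sigm(pre.rows(H, 2 * H - 1));
    vec gg = tanh(pre.rows(2 * H, 3 * H - 1));
    vec go = sigm(pre.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    G.col(p) = join_vert(join_vert(gi, gf), join_vert(gg, go));
    C.col(p) = c; Hs.col(p) = h;
  }
}

static void forward_seq(const Params& P, const mat& X, SeqCache& S) {
  uword T = X.n_cols, H = P.H;
  uvec fwd = regspace<uvec>(0, T - 1);
  uvec bwd = reverse(fwd);
  lstm_dir(P.Wx_f, P.Wh_f, P.b_f, X, fwd, S.Gf, S.Cf, S.Hf);
  lstm_dir(P.Wx_b, P.Wh_b, P.b_b, X, bwd, S.Gb, S.Cb, S.Hb);
  S.hcat = join_vert(S.Hf.col(T - 1), S.Hb.col(T - 1));
  S.z = P.Wz * S.hcat + P.bz;
  // decoder: constant input z, emits reversed order
  S.Gd.set_size(4 * H, T); S.Cd.set_size(H, T); S.Hd.set_size(H, T);
  S.Xhat.set_size(P.Dr, T);
  vec h = zeros<vec>(H), c = zeros<vec>(H);
  vec xin = P.Wx_d * S.z;  // constant over steps
  for (uword s = 0; s < T; ++s) {
    vec pre = xin + P.Wh_d * h + P.b_d;
    vec gi = sigm(pre.rows(0, H - 1));
    vec gf = sigm(pre.rows(H, 2 * H - 1));
    vec gg = tanh(pre.rows(2 * H, 3 * H - 1));
    vec go = sigm(pre.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    S.Gd.col(s) = join_vert(join_vert(gi, gf), join_vert(gg, go));
    S.Cd.col(s) = c; S.Hd.col(s) = h;
    S.Xhat.col(T - 1 - s) = P.Wo * h + P.bo;  // step s reconstructs time T-1-s
  }
  S.yraw = dot(P.wy, S.z) + P.by;
}

// Backward through one directional LSTM given gradient at the FINAL hidden
// state only; accumulates parameter grads, returns nothing else.
static void lstm_dir_back(const mat& Wx, const mat& Wh,
                          const mat& X, const uvec& order,
                          const mat& G, const mat& C,
                          const mat& Hs, const vec& dh_final,
                          mat& dWx, mat& dWh, vec& db) {
  uword H = Wh.n_cols, T = order.n_elem;
  vec dh = dh_final, dc = zeros<vec>(H);
  for (uword pp = T; pp-- > 0;) {
    vec gi = G.col(pp).rows(0, H - 1);
    vec gf = G.col(pp).rows(H, 2 * H - 1);
    vec gg = G.col(pp).rows(2 * H, 3 * H - 1);
    vec go = G.col(pp).rows(3 * H, 4 * H - 1);
    vec c = C.col(pp);
    vec c_prev = pp > 0 ? vec(C.col(pp - 1)) : zeros<vec>(H);
    vec h_prev = pp > 0 ? vec(Hs.col(pp - 1)) : zeros<vec>(H);
    vec tc = tanh(c);
    dc += dh % go % (1 - tc % tc);
    vec dgo = dh % tc;
    vec dgi = dc % gg;
    vec dgg = dc % gi;
    vec dgf = dc % c_prev;
    vec dpre = join_vert(
      join_vert(dgi % gi % (1 - gi), dgf % gf % (1 - gf)),
      join_vert(dgg % (1 - gg % gg), dgo % go % (1 - go)));
    dWx += dpre * X.col(order(pp)).t();
    dWh += dpre * h_prev.t();
    db += dpre;
    dh = Wh.t() * dpre;
    dc = dc % gf;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List params, Rcpp::List xs, Rcpp::List targets,
                         Rcpp::List masks, arma::vec y, int task,
                         double wr, double ws, bool want_grad) {
  Params P = unpack(params);
  uword B = xs.size();
  const double eps = 1e-12;

  // pass 1: forward to accumulate global reconstruction SSE and head outputs
  double sse = 0.0; double nobs = 0.0;
  vec yhat(B);
  for (uword i = 0; i < B; ++i) {
    mat X = Rcpp::as<mat>(xs[i]);
    mat Tg = Rcpp::as<mat>(targets[i]);
    mat M = Rcpp::as<mat>(masks[i]);
    SeqCache S; forward_seq(P, X, S);
    mat resid = (S.Xhat - Tg) % M;
    sse += accu(resid % resid);
    nobs += accu(M);
    yhat(i) = S.yraw;
  }
  double Lr = nobs > 0 ? std::sqrt(sse / nobs) : 0.0;
  double Ls;
  vec p(B);
  if (task == 0) {
    Ls = std::sqrt(accu(square(y - yhat)) / B);
    p = yhat;
  } else {
    for (uword i = 0; i < B; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-yhat(i)));
      pi = std::min(1.0 - 1e-7, std::max(1e-7, pi));
      p(i) = pi;
    }
    Ls = accu(-y % log(p) - (1 - y) % log(1 - p)) / B;
  }
  double loss = wr * Lr + ws * Ls;
  if (!std::isfinite(loss))
    Rcpp::stop("non-finite training loss (Lr=%g, Ls=%g)", Lr, Ls);

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("lr") = Lr,
    Rcpp::Named("ls") = Ls, Rcpp::Named("yhat") = p);
  if (!want_grad) return out;

  // pass 2: forward again per sequence, then exact backward
  Grads G; G.init(P);
  double recon_scale = (Lr > eps && nobs > 0) ? wr / (nobs * Lr) : 0.0;
  for (uword i = 0; i < B; ++i) {
    mat X = Rcpp::as<mat>(xs[i]);
    mat Tg = Rcpp::as<mat>(targets[i]);
    mat M = Rcpp::as<mat>(masks[i]);
    SeqCache S; forward_seq(P, X, S);
    uword T = X.n_cols, H = P.H;

    double dyraw;
    if (task == 0) {
      dyraw = Ls > eps ? ws * (yhat(i) - y(i)) / (B * Ls) : 0.0;
    } else {
      dyraw = ws * (p(i) - y(i)) / B;  // BCE wrt logit
    }
    vec dz = dyraw * P.wy;
    G.wy += dyraw * S.z; G.by += dyraw;

    // decoder backward
    mat dResid = recon_scale * ((S.Xhat - Tg) % M);  // original time order
    vec dh_next = zeros<vec>(H), dc = zeros<vec>(H);
    for (uword s = T; s-- > 0;) {
      vec dxhat = dResid.col(T - 1 - s);
      vec h_s = S.Hd.col(s);
      G.Wo += dxhat * h_s.t(); G.bo += dxhat;
      vec dh = P.Wo.t() * dxhat + dh_next;
      vec gi = S.Gd.col(s).rows(0, H - 1);
      vec gf = S.Gd.col(s).rows(H, 2 * H - 1);
      vec gg = S.Gd.col(s).rows(2 * H, 3 * H - 1);
      vec go = S.Gd.col(s).rows(3 * H, 4 * H - 1);
      vec c = S.Cd.col(s);
      vec c_prev = s > 0 ? vec(S.Cd.col(s - 1)) : zeros<vec>(H);
      vec h_prev = s > 0 ? vec(S.Hd.col(s - 1)) : zeros<vec>(H);
      vec tc = tanh(c);
      dc += dh % go % (1 - tc % tc);
      vec dgo = dh % tc;
      vec dgi = dc % gg;
      vec dgg = dc % gi;
      vec dgf = dc % c_prev;
      vec dpre = join_vert(
        join_vert(dgi % gi % (1 - gi), dgf % gf % (1 - gf)),
        join_vert(dgg % (1 - gg % gg), dgo % go % (1 - go)));
      G.Wx_d += dpre * S.z.t();
      G.Wh_d += dpre * h_prev.t();
      G.b_d += dpre;
      dz += P.Wx_d.t() * dpre;
      dh_next = P.Wh_d.t() * dpre;
      dc = dc % gf;
    }

    // embedding projection
    G.Wz += dz * S.hcat.t(); G.bz += dz;
    vec dhcat = P.Wz.t() * dz;
    vec dh_f = dhcat.rows(0, H - 1);
    vec dh_b = dhcat.rows(H, 2 * H - 1);

    uvec fwd = regspace<uvec>(0, T - 1);
    uvec bwd = reverse(fwd);
    lstm_dir_back(P.Wx_f, P.Wh_f, X, fwd, S.Gf, S.Cf, S.Hf, dh_f,
                  G.Wx_f, G.Wh_f, G.b_f);
    lstm_dir_back(P.Wx_b, P.Wh_b, X, bwd, S.Gb, S.Cb, S.Hb, dh_b,
                  G.Wx_b, G.Wh_b, G.b_b);
  }

  out["grads"] = Rcpp::List::create(
    Rcpp::Named("Wx_f") = G.Wx_f, Rcpp::Named("Wh_f") = G.Wh_f,
    Rcpp::Named("b_f") = G.b_f,
    Rcpp::Named("Wx_b") = G.Wx_b, Rcpp::Named("Wh_b") = G.Wh_b,
    Rcpp::Named("b_b") = G.b_b,
    Rcpp::Named("Wz") = G.Wz, Rcpp::Named("bz") = G.bz,
    Rcpp::Named("Wx_d") = G.Wx_d, Rcpp::Named("Wh_d") = G.Wh_d,
    Rcpp::Named("b_d") = G.b_d,
    Rcpp::Named("Wo") = G.Wo, Rcpp::Named("bo") = G.bo,
    Rcpp::Named("wy") = G.wy,
    Rcpp::Named("by") = Rcpp::NumericVector::create(G.by));
  return out;
}

// Embedding of the full sequence (prefix handling is done by the caller
// slicing columns).
// [[Rcpp::export]]
arma::vec cpp_encode(Rcpp::List params, arma::mat X) {
  Params P = unpack(params);
  SeqCache S; forward_seq(P, X, S);
  return S.z;
}

// Embeddings for several prefixes 1..t of one sequence. The forward-direction
// states are shared across prefixes; the backward direction is rerun per
// prefix (it starts at day t).
// [[Rcpp::export]]
arma::mat cpp_encode_prefixes(Rcpp::List params, arma::mat X,
                              arma::uvec tlens) {
  Params P = unpack(params);
  uword T = X.n_cols, H = P.H;
  mat Gf, Cf, Hf;
  uvec fwd = regspace<uvec>(0, T - 1);
  lstm_dir(P.Wx_f, P.Wh_f, P.b_f, X, fwd, Gf, Cf, Hf);
  mat Z(P.E, tlens.n_elem);
  for (uword q = 0; q < tlens.n_elem; ++q) {
    uword t = tlens(q);
    if (t < 1 || t > T) Rcpp::stop("prefix length out of range");
    uvec bwd = reverse(regspace<uvec>(0, t - 1));
    mat Gb, Cb, Hb;
    lstm_dir(P.Wx_b, P.Wh_b, P.b_b, X, bwd, Gb, Cb, Hb);
    vec hcat = join_vert(Hf.col(t - 1), Hb.col(t - 1));
    Z.col(q) = P.Wz * hcat + P.bz;
  }
  return Z;
}
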