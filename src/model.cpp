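// Forward and backward passes of the three-headed convolution + multi-head
// self-attention binding model. Sequences enter at their true lengths (padded
// rows never reach the network), so attention needs no padding mask and the
// outputs are invariant to the configured maximum lengths by construction.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Config {
  int C, K, h, dg, dm, H;
  double dropout;
  bool share;
};

static Config readConfig(const Rcpp::List& cfg) {
  Config c;
  c.C = Rcpp::as<int>(cfg["channels"]);
  c.K = Rcpp::as<int>(cfg["kernel"]);
  c.h = Rcpp::as<int>(cfg["heads"]);
  c.dg = Rcpp::as<int>(cfg["geneDim"]);
  c.dm = Rcpp::as<int>(cfg["mhcDim"]);
  c.H = Rcpp::as<int>(cfg["hidden"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.share = Rcpp::as<bool>(cfg["shareChains"]);
  if (c.C % c.h != 0) Rcpp::stop("attention width must be divisible by heads");
  return c;
}

// All model parameters, extracted once per call.
struct Params {
  mat conv_ep_W, conv_b_W, conv_a_W;
  vec conv_ep_b, conv_b_b, conv_a_b;
  mat att_b_Wq, att_b_Wk, att_b_Wv, att_b_Wo;
  mat att_a_Wq, att_a_Wk, att_a_Wv, att_a_Wo;
  mat emb_bv, emb_bj, emb_av, emb_aj, emb_mhc;
  mat head_b_W1, head_a_W1, head_ab_W1;
  vec head_b_b1, head_a_b1, head_ab_b1;
  rowvec head_b_w2, head_a_w2, head_ab_w2;
  double head_b_b2, head_a_b2, head_ab_b2;
};

static Params readParams(const Rcpp::List& p) {
  Params q;
  q.conv_ep_W = Rcpp::as<mat>(p["conv_ep_W"]);
  q.conv_b_W  = Rcpp::as<mat>(p["conv_b_W"]);
  q.conv_a_W  = Rcpp::as<mat>(p["conv_a_W"]);
  q.conv_ep_b = Rcpp::as<vec>(p["conv_ep_b"]);
  q.conv_b_b  = Rcpp::as<vec>(p["conv_b_b"]);
  q.conv_a_b  = Rcpp::as<vec>(p["conv_a_b"]);
  q.att_b_Wq = Rcpp::as<mat>(p["att_b_Wq"]); q.att_b_Wk = Rcpp::as<mat>(p["att_b_Wk"]);
  q.att_b_Wv = Rcpp::as<mat>(p["att_b_Wv"]); q.att_b_Wo = Rcpp::as<mat>(p["att_b_Wo"]);
  q.att_a_Wq = Rcpp::as<mat>(p["att_a_Wq"]); q.att_a_Wk = Rcpp::as<mat>(p["att_a_Wk"]);
  q.att_a_Wv = Rcpp::as<mat>(p["att_a_Wv"]); q.att_a_Wo = Rcpp::as<mat>(p["att_a_Wo"]);
  q.emb_bv = Rcpp::as<mat>(p["emb_bv"]); q.emb_bj = Rcpp::as<mat>(p["emb_bj"]);
  q.emb_av = Rcpp::as<mat>(p["emb_av"]); q.emb_aj = Rcpp::as<mat>(p["emb_aj"]);
  q.emb_mhc = Rcpp::as<mat>(p["emb_mhc"]);
  q.head_b_W1 = Rcpp::as<mat>(p["head_b_W1"]);
  q.head_a_W1 = Rcpp::as<mat>(p["head_a_W1"]);
  q.head_ab_W1 = Rcpp::as<mat>(p["head_ab_W1"]);
  q.head_b_b1 = Rcpp::as<vec>(p["head_b_b1"]);
  q.head_a_b1 = Rcpp::as<vec>(p["head_a_b1"]);
  q.head_ab_b1 = Rcpp::as<vec>(p["head_ab_b1"]);
  q.head_b_w2 = Rcpp::as<rowvec>(p["head_b_w2"]);
  q.head_a_w2 = Rcpp::as<rowvec>(p["head_a_w2"]);
  q.head_ab_w2 = Rcpp::as<rowvec>(p["head_ab_w2"]);
  q.head_b_b2 = Rcpp::as<double>(p["head_b_b2"]);
  q.head_a_b2 = Rcpp::as<double>(p["head_a_b2"]);
  q.head_ab_b2 = Rcpp::as<double>(p["head_ab_b2"]);
  return q;
}

// Gradient accumulator with the same shapes as Params.
struct Grads {
  mat conv_ep_W, conv_b_W, conv_a_W;
  vec conv_ep_b, conv_b_b, conv_a_b;
  mat att_b_Wq, att_b_Wk, att_b_Wv, att_b_Wo;
  mat att_a_Wq, att_a_Wk, att_a_Wv, att_a_Wo;
  mat emb_bv, emb_bj, emb_av, emb_aj, emb_mhc;
  mat head_b_W1, head_a_W1, head_ab_W1;
  vec head_b_b1, head_a_b1, head_ab_b1;
  rowvec head_b_w2, head_a_w2, head_ab_w2;
  double head_b_b2, head_a_b2, head_ab_b2;
  Grads(const Params& p) {
    conv_ep_W = zeros(size(p.conv_ep_W)); conv_b_W = zeros(size(p.conv_b_W));
    conv_a_W = zeros(size(p.conv_a_W));
    conv_ep_b = zeros<vec>(p.conv_ep_b.n_elem);
    conv_b_b = zeros<vec>(p.conv_b_b.n_elem);
    conv_a_b = zeros<vec>(p.conv_a_b.n_elem);
    att_b_Wq = zeros(size(p.att_b_Wq)); att_b_Wk = zeros(size(p.att_b_Wk));
    att_b_Wv = zeros(size(p.att_b_Wv)); att_b_Wo = zeros(size(p.att_b_Wo));
    att_a_Wq = zeros(size(p.att_a_Wq)); att_a_Wk = zeros(size(p.att_a_Wk));
    att_a_Wv = zeros(size(p.att_a_Wv)); att_a_Wo = zeros(size(p.att_a_Wo));
    emb_bv = zeros(size(p.emb_bv)); emb_bj = zeros(size(p.emb_bj));
    emb_av = zeros(size(p.emb_av)); emb_aj = zeros(size(p.emb_aj));
    emb_mhc = zeros(size(p.emb_mhc));
    head_b_W1 = zeros(size(p.head_b_W1)); head_a_W1 = zeros(size(p.head_a_W1));
    head_ab_W1 = zeros(size(p.head_ab_W1));
    head_b_b1 = zeros<vec>(p.head_b_b1.n_elem);
    head_a_b1 = zeros<vec>(p.head_a_b1.n_elem);
    head_ab_b1 = zeros<vec>(p.head_ab_b1.n_elem);
    head_b_w2 = zeros<rowvec>(p.head_b_w2.n_elem);
    head_a_w2 = zeros<rowvec>(p.head_a_w2.n_elem);
    head_ab_w2 = zeros<rowvec>(p.head_ab_w2.n_elem);
    head_b_b2 = head_a_b2 = head_ab_b2 = 0.0;
  }
};

static mat reluM(const mat& X) { mat Y = X; Y.elem(find(Y < 0.0)).zeros(); return Y; }
static vec reluV(const vec& X) { vec Y = X; Y.elem(find(Y < 0.0)).zeros(); return Y; }

static mat im2col(const mat& X, int K) {
  const int L = X.n_rows, e = X.n_cols, half = K / 2;
  mat M(L, K * e, fill::zeros);
  for (int i = 0; i < L; ++i)
    for (int k = 0; k < K; ++k) {
      int src = i + k - half;
      if (src >= 0 && src < L)
        M.submat(i, k * e, i, (k + 1) * e - 1) = X.row(src);
    }
  return M;
}

// Saved intermediates of one chain's conv + attention pass.
struct ChainCache {
  mat M;          // im2col of CDR3 input
  mat Pre;        // pre-ReLU conv output (Lc x C)
  mat Z;          // concatenated token sequence (L x C)
  std::vector<mat> A;   // per-head softmax matrices (L x L)
  mat Q, Km, V;   // projections (L x C)
  mat Hcat;       // concatenated head outputs (L x C)
  int Lc, Le;
  vec pooled;     // masked mean of attn output (C)
};

// Epitope conv cache (shared across chains of one example).
struct EpCache {
  mat M, Pre, Ep; // Ep = ReLU(Pre), (Le x C)
};

static EpCache epForward(const Params& p, const mat& Xep, const Config& cfg) {
  EpCache c;
  c.M = im2col(Xep, cfg.K);
  c.Pre = c.M * p.conv_ep_W.t();
  c.Pre.each_row() += p.conv_ep_b.t();
  c.Ep = reluM(c.Pre);
  return c;
}

static ChainCache chainForward(const mat& Wc, const vec& bc,
                               const mat& Wq, const mat& Wk, const mat& Wv,
                               const mat& Wo, const mat& Xc, const mat& Ep,
                               const Config& cfg) {
  ChainCache c;
  c.Lc = Xc.n_rows; c.Le = Ep.n_rows;
  c.M = im2col(Xc, cfg.K);
  c.Pre = c.M * Wc.t();
  c.Pre.each_row() += bc.t();
  mat Cc = reluM(c.Pre);
  c.Z = join_cols(Cc, Ep);
  const int L = c.Z.n_rows, dk = cfg.C / cfg.h;
  c.Q = c.Z * Wq; c.Km = c.Z * Wk; c.V = c.Z * Wv;
  c.Hcat.set_size(L, cfg.C);
  c.A.resize(cfg.h);
  const double scale = 1.0 / std::sqrt((double)dk);
  for (int i = 0; i < cfg.h; ++i) {
    mat Qi = c.Q.cols(i * dk, (i + 1) * dk - 1);
    mat Ki = c.Km.cols(i * dk, (i + 1) * dk - 1);
    mat Vi = c.V.cols(i * dk, (i + 1) * dk - 1);
    mat S = Qi * Ki.t() * scale;
    S.each_col() -= max(S, 1);
    mat E = exp(S);
    E.each_col() /= sum(E, 1);
    c.A[i] = E;
    c.Hcat.cols(i * dk, (i + 1) * dk - 1) = E * Vi;
  }
  mat attn = c.Z + c.Hcat * Wo;
  c.pooled = mean(attn, 0).t();
  return c;
}

// Backward through one chain given d(pooled). Returns d(Ep) to accumulate
// into the shared epitope conv backward.
static mat chainBackward(const mat& Wc, const mat& Wq, const mat& Wk,
                         const mat& Wv, const mat& Wo,
                         mat& gWc, vec& gbc, mat& gWq, mat& gWk, mat& gWv,
                         mat& gWo, const ChainCache& c, const vec& dPooled,
                         const Config& cfg) {
  const int L = c.Z.n_rows, dk = cfg.C / cfg.h;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat dAttn = repmat(dPooled.t() / (double)L, L, 1);
  gWo += c.Hcat.t() * dAttn;
  mat dHcat = dAttn * Wo.t();
  mat dZ = dAttn;  // residual branch
  mat dQ(L, cfg.C), dK(L, cfg.C), dV(L, cfg.C);
  for (int i = 0; i < cfg.h; ++i) {
    mat Qi = c.Q.cols(i * dk, (i + 1) * dk - 1);
    mat Ki = c.Km.cols(i * dk, (i + 1) * dk - 1);
    mat Vi = c.V.cols(i * dk, (i + 1) * dk - 1);
    mat dHi = dHcat.cols(i * dk, (i + 1) * dk - 1);
    const mat& A = c.A[i];
    mat dA = dHi * Vi.t();
    dV.cols(i * dk, (i + 1) * dk - 1) = A.t() * dHi;
    vec rowDot = sum(dA % A, 1);
    mat dS = (dA.each_col() - rowDot) % A;
    dQ.cols(i * dk, (i + 1) * dk - 1) = dS * Ki * scale;
    dK.cols(i * dk, (i + 1) * dk - 1) = dS.t() * Qi * scale;
  }
  gWq += c.Z.t() * dQ; gWk += c.Z.t() * dK; gWv += c.Z.t() * dV;
  dZ += dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  // split into CDR3 conv rows and epitope rows
  mat dCc = dZ.rows(0, c.Lc - 1);
  mat dEp = dZ.rows(c.Lc, L - 1);
  mat dPre = dCc % conv_to<mat>::from(c.Pre > 0.0);
  gWc += dPre.t() * c.M;
  gbc += sum(dPre, 0).t();
  return dEp;
}

struct HeadParams {
  const mat* W1; const vec* b1; const rowvec* w2; double b2;
  mat* gW1; vec* gb1; rowvec* gw2; double* gb2;
};

// Forward one MLP head; optionally backward with dropout mask, writing
// d(input) into du.
static double headForward(const HeadParams& hp, const vec& u, vec& hpre,
                          vec& hdrop, const Config& cfg, std::mt19937* rng) {
  hpre = (*hp.W1) * u + (*hp.b1);
  vec h = reluV(hpre);
  hdrop = h;
  if (rng && cfg.dropout > 0.0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (uword i = 0; i < h.n_elem; ++i)
      hdrop(i) = unif(*rng) < cfg.dropout ? 0.0 : h(i) / (1.0 - cfg.dropout);
  }
  double logit = as_scalar((*hp.w2) * hdrop) + hp.b2;
  return 1.0 / (1.0 + std::exp(-logit));
}

static vec headBackward(const HeadParams& hp, const vec& u, const vec& hpre,
                        const vec& hdrop, const vec& hplain, double dlogit,
                        const Config& cfg) {
  *hp.gw2 += dlogit * hdrop.t();
  *hp.gb2 += dlogit;
  vec dhdrop = dlogit * hp.w2->t();
  // dropout backward: positions zeroed in hdrop got no flow; kept positions
  // were scaled by 1/(1-p)
  vec dh(dhdrop.n_elem);
  for (uword i = 0; i < dh.n_elem; ++i) {
    if (cfg.dropout > 0.0 && hplain(i) != 0.0)
      dh(i) = hdrop(i) == 0.0 ? 0.0 : dhdrop(i) / (1.0 - cfg.dropout);
    else if (cfg.dropout > 0.0)
      dh(i) = 0.0;  // ReLU already zero; no gradient either way
    else
      dh(i) = dhdrop(i);
  }
  vec dhpre = dh % conv_to<vec>::from(hpre > 0.0);
  *hp.gW1 += dhpre * u.t();
  *hp.gb1 += dhpre;
  return hp.W1->t() * dhpre;
}

// Assemble one example's data out of the packed arrays.
struct Example {
  mat Xb, Xa, Xep;
  int bv, bj, av, aj, mhc, hasB, hasA, label;
  double weight;
};

static Example getExample(const Rcpp::List& pack, int i,
                          const cube& beta, const cube& alpha, const cube& epi,
                          const Rcpp::IntegerVector& lenB,
                          const Rcpp::IntegerVector& lenA,
                          const Rcpp::IntegerVector& lenE,
                          const Rcpp::IntegerVector& bv, const Rcpp::IntegerVector& bj,
                          const Rcpp::IntegerVector& av, const Rcpp::IntegerVector& aj,
                          const Rcpp::IntegerVector& mhc,
                          const Rcpp::IntegerVector& hasB, const Rcpp::IntegerVector& hasA,
                          const Rcpp::IntegerVector& label,
                          const Rcpp::NumericVector& weight) {
  Example ex;
  ex.hasB = hasB[i]; ex.hasA = hasA[i];
  if (ex.hasB) ex.Xb = beta.slice(i).rows(0, lenB[i] - 1);
  if (ex.hasA) ex.Xa = alpha.slice(i).rows(0, lenA[i] - 1);
  ex.Xep = epi.slice(i).rows(0, lenE[i] - 1);
  ex.bv = bv[i]; ex.bj = bj[i]; ex.av = av[i]; ex.aj = aj[i]; ex.mhc = mhc[i];
  ex.label = label[i]; ex.weight = weight[i];
  return ex;
}

static Rcpp::List gradsToList(const Grads& g) {
  return Rcpp::List::create(
    Rcpp::Named("conv_ep_W") = g.conv_ep_W, Rcpp::Named("conv_ep_b") = g.conv_ep_b,
    Rcpp::Named("conv_b_W") = g.conv_b_W, Rcpp::Named("conv_b_b") = g.conv_b_b,
    Rcpp::Named("conv_a_W") = g.conv_a_W, Rcpp::Named("conv_a_b") = g.conv_a_b,
    Rcpp::Named("att_b_Wq") = g.att_b_Wq, Rcpp::Named("att_b_Wk") = g.att_b_Wk,
    Rcpp::Named("att_b_Wv") = g.att_b_Wv, Rcpp::Named("att_b_Wo") = g.att_b_Wo,
    Rcpp::Named("att_a_Wq") = g.att_a_Wq, Rcpp::Named("att_a_Wk") = g.att_a_Wk,
    Rcpp::Named("att_a_Wv") = g.att_a_Wv, Rcpp::Named("att_a_Wo") = g.att_a_Wo,
    Rcpp::Named("emb_bv") = g.emb_bv, Rcpp::Named("emb_bj") = g.emb_bj,
    Rcpp::Named("emb_av") = g.emb_av, Rcpp::Named("emb_aj") = g.emb_aj,
    Rcpp::Named("emb_mhc") = g.emb_mhc,
    Rcpp::Named("head_b_W1") = g.head_b_W1, Rcpp::Named("head_b_b1") = g.head_b_b1,
    Rcpp::Named("head_b_w2") = g.head_b_w2, Rcpp::Named("head_b_b2") = g.head_b_b2,
    Rcpp::Named("head_a_W1") = g.head_a_W1, Rcpp::Named("head_a_b1") = g.head_a_b1,
    Rcpp::Named("head_a_w2") = g.head_a_w2, Rcpp::Named("head_a_b2") = g.head_a_b2,
    Rcpp::Named("head_ab_W1") = g.head_ab_W1, Rcpp::Named("head_ab_b1") = g.head_ab_b1,
    Rcpp::Named("head_ab_w2") = g.head_ab_w2, Rcpp::Named("head_ab_b2") = g.head_ab_b2);
}

// Build the concatenated head inputs.
static vec headInputB(const Params& p, const vec& pooledB, int bv, int bj, int mhc) {
  return join_cols(join_cols(pooledB, p.emb_bv.row(bv - 1).t()),
                   join_cols(p.emb_bj.row(bj - 1).t(), p.emb_mhc.row(mhc - 1).t()));
}
static vec headInputA(const Params& p, const vec& pooledA, int av, int aj, int mhc) {
  return join_cols(join_cols(pooledA, p.emb_av.row(av - 1).t()),
                   join_cols(p.emb_aj.row(aj - 1).t(), p.emb_mhc.row(mhc - 1).t()));
}
static vec headInputAB(const Params& p, const vec& pooledB, const vec& pooledA,
                       int bv, int bj, int av, int aj, int mhc) {
  vec u = join_cols(join_cols(pooledB, pooledA),
                    join_cols(p.emb_bv.row(bv - 1).t(), p.emb_bj.row(bj - 1).t()));
  return join_cols(u, join_cols(join_cols(p.emb_av.row(av - 1).t(),
                                          p.emb_aj.row(aj - 1).t()),
                                p.emb_mhc.row(mhc - 1).t()));
}

static const double CLIP_EPS = 1e-7;

// [[Rcpp::export(name = "nn_forward_cpp")]]
Rcpp::NumericMatrix nn_forward_cpp(Rcpp::List params, Rcpp::List pack,
                                   Rcpp::List config) {
  Config cfg = readConfig(config);
  Params p = readParams(params);
  const cube beta = Rcpp::as<cube>(pack["beta"]);
  const cube alpha = Rcpp::as<cube>(pack["alpha"]);
  const cube epi = Rcpp::as<cube>(pack["epi"]);
  Rcpp::IntegerVector lenB = pack["lenB"], lenA = pack["lenA"], lenE = pack["lenE"],
    bv = pack["bv"], bj = pack["bj"], av = pack["av"], aj = pack["aj"],
    mhc = pack["mhc"], hasB = pack["hasB"], hasA = pack["hasA"], label = pack["label"];
  Rcpp::NumericVector weight = pack["weight"];
  const int n = Rcpp::as<int>(pack["n"]);
  Rcpp::NumericMatrix out(n, 3);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < n; ++i) {
    Example ex = getExample(pack, i, beta, alpha, epi, lenB, lenA, lenE,
                            bv, bj, av, aj, mhc, hasB, hasA, label, weight);
    EpCache epc = epForward(p, ex.Xep, cfg);
    vec hpre, hdrop;
    vec pooledB, pooledA;
    if (ex.hasB) {
      ChainCache cb = chainForward(p.conv_b_W, p.conv_b_b, p.att_b_Wq, p.att_b_Wk,
                                   p.att_b_Wv, p.att_b_Wo, ex.Xb, epc.Ep, cfg);
      pooledB = cb.pooled;
      HeadParams hb {&p.head_b_W1, &p.head_b_b1, &p.head_b_w2, p.head_b_b2,
                     nullptr, nullptr, nullptr, nullptr};
      out(i, 0) = headForward(hb, headInputB(p, pooledB, ex.bv, ex.bj, ex.mhc),
                              hpre, hdrop, cfg, nullptr);
    }
    if (ex.hasA) {
      const mat& Wc = cfg.share ? p.conv_b_W : p.conv_a_W;
      const vec& bc = cfg.share ? p.conv_b_b : p.conv_a_b;
      const mat& Wq = cfg.share ? p.att_b_Wq : p.att_a_Wq;
      const mat& Wk = cfg.share ? p.att_b_Wk : p.att_a_Wk;
      const mat& Wv = cfg.share ? p.att_b_Wv : p.att_a_Wv;
      const mat& Wo = cfg.share ? p.att_b_Wo : p.att_a_Wo;
      ChainCache ca = chainForward(Wc, bc, Wq, Wk, Wv, Wo, ex.Xa, epc.Ep, cfg);
      pooledA = ca.pooled;
      HeadParams ha {&p.head_a_W1, &p.head_a_b1, &p.head_a_w2, p.head_a_b2,
                     nullptr, nullptr, nullptr, nullptr};
      out(i, 1) = headForward(ha, headInputA(p, pooledA, ex.av, ex.aj, ex.mhc),
                              hpre, hdrop, cfg, nullptr);
    }
    if (ex.hasB && ex.hasA) {
      HeadParams hab {&p.head_ab_W1, &p.head_ab_b1, &p.head_ab_w2, p.head_ab_b2,
                      nullptr, nullptr, nullptr, nullptr};
      out(i, 2) = headForward(hab, headInputAB(p, pooledB, pooledA, ex.bv, ex.bj,
                                               ex.av, ex.aj, ex.mhc),
                              hpre, hdrop, cfg, nullptr);
    }
  }
  Rcpp::colnames(out) = Rcpp::CharacterVector::create("yb", "ya", "yab");
  return out;
}

// [[Rcpp::export(name = "nn_loss_grad_cpp")]]
Rcpp::List nn_loss_grad_cpp(Rcpp::List params, Rcpp::List pack,
                            Rcpp::IntegerVector idx, Rcpp::List config,
                            bool training, int dropoutSeed) {
  Config cfg = readConfig(config);
  Params p = readParams(params);
  Grads g(p);
  const cube beta = Rcpp::as<cube>(pack["beta"]);
  const cube alpha = Rcpp::as<cube>(pack["alpha"]);
  const cube epi = Rcpp::as<cube>(pack["epi"]);
  Rcpp::IntegerVector lenB = pack["lenB"], lenA = pack["lenA"], lenE = pack["lenE"],
    bv = pack["bv"], bj = pack["bj"], av = pack["av"], aj = pack["aj"],
    mhc = pack["mhc"], hasB = pack["hasB"], hasA = pack["hasA"], label = pack["label"];
  Rcpp::NumericVector weight = pack["weight"];
  std::mt19937 rng(dropoutSeed);
  std::mt19937* rngp = (training && cfg.dropout > 0.0) ? &rng : nullptr;
  const int N = idx.size();
  double loss = 0.0;

  for (int t = 0; t < N; ++t) {
    const int i = idx[t] - 1;
    Example ex = getExample(pack, i, beta, alpha, epi, lenB, lenA, lenE,
                            bv, bj, av, aj, mhc, hasB, hasA, label, weight);
    EpCache epc = epForward(p, ex.Xep, cfg);
    ChainCache cb, ca;
    bool useB = ex.hasB, useA = ex.hasA;
    if (useB)
      cb = chainForward(p.conv_b_W, p.conv_b_b, p.att_b_Wq, p.att_b_Wk,
                        p.att_b_Wv, p.att_b_Wo, ex.Xb, epc.Ep, cfg);
    if (useA) {
      const mat& Wc = cfg.share ? p.conv_b_W : p.conv_a_W;
      const vec& bc = cfg.share ? p.conv_b_b : p.conv_a_b;
      const mat& Wq = cfg.share ? p.att_b_Wq : p.att_a_Wq;
      const mat& Wk = cfg.share ? p.att_b_Wk : p.att_a_Wk;
      const mat& Wv = cfg.share ? p.att_b_Wv : p.att_a_Wv;
      const mat& Wo = cfg.share ? p.att_b_Wo : p.att_a_Wo;
      ca = chainForward(Wc, bc, Wq, Wk, Wv, Wo, ex.Xa, epc.Ep, cfg);
    }

    // observed head: paired -> yab; beta-only -> yb; alpha-only -> ya
    HeadParams hp;
    vec u;
    if (useB && useA) {
      hp = {&p.head_ab_W1, &p.head_ab_b1, &p.head_ab_w2, p.head_ab_b2,
            &g.head_ab_W1, &g.head_ab_b1, &g.head_ab_w2, &g.head_ab_b2};
      u = headInputAB(p, cb.pooled, ca.pooled, ex.bv, ex.bj, ex.av, ex.aj, ex.mhc);
    } else if (useB) {
      hp = {&p.head_b_W1, &p.head_b_b1, &p.head_b_w2, p.head_b_b2,
            &g.head_b_W1, &g.head_b_b1, &g.head_b_w2, &g.head_b_b2};
      u = headInputB(p, cb.pooled, ex.bv, ex.bj, ex.mhc);
    } else {
      hp = {&p.head_a_W1, &p.head_a_b1, &p.head_a_w2, p.head_a_b2,
            &g.head_a_W1, &g.head_a_b1, &g.head_a_w2, &g.head_a_b2};
      u = headInputA(p, ca.pooled, ex.av, ex.aj, ex.mhc);
    }
    vec hpre, hdrop;
    double yhat = headForward(hp, u, hpre, hdrop, cfg, rngp);
    double yc = std::min(std::max(yhat, CLIP_EPS), 1.0 - CLIP_EPS);
    loss += -ex.weight * (ex.label * std::log(yc) +
                          (1 - ex.label) * std::log(1.0 - yc));
    double dlogit = ex.weight * (yhat - (double)ex.label) / (double)N;
    vec hplain = reluV(hpre);
    vec du = headBackward(hp, u, hpre, hdrop, hplain, dlogit, cfg);

    // scatter du into pooled/embedding gradients
    const int C = cfg.C, dg = cfg.dg, dm = cfg.dm;
    mat dEp;
    if (useB && useA) {
      vec dPooledB = du.subvec(0, C - 1);
      vec dPooledA = du.subvec(C, 2 * C - 1);
      g.emb_bv.row(ex.bv - 1) += du.subvec(2 * C, 2 * C + dg - 1).t();
      g.emb_bj.row(ex.bj - 1) += du.subvec(2 * C + dg, 2 * C + 2 * dg - 1).t();
      g.emb_av.row(ex.av - 1) += du.subvec(2 * C + 2 * dg, 2 * C + 3 * dg - 1).t();
      g.emb_aj.row(ex.aj - 1) += du.subvec(2 * C + 3 * dg, 2 * C + 4 * dg - 1).t();
      g.emb_mhc.row(ex.mhc - 1) += du.subvec(2 * C + 4 * dg, 2 * C + 4 * dg + dm - 1).t();
      dEp = chainBackward(p.conv_b_W, p.att_b_Wq, p.att_b_Wk, p.att_b_Wv, p.att_b_Wo,
                          g.conv_b_W, g.conv_b_b, g.att_b_Wq, g.att_b_Wk,
                          g.att_b_Wv, g.att_b_Wo, cb, dPooledB, cfg);
      if (cfg.share)
        dEp += chainBackward(p.conv_b_W, p.att_b_Wq, p.att_b_Wk, p.att_b_Wv,
                             p.att_b_Wo, g.conv_b_W, g.conv_b_b, g.att_b_Wq,
                             g.att_b_Wk, g.att_b_Wv, g.att_b_Wo, ca, dPooledA, cfg);
      else
        dEp += chainBackward(p.conv_a_W, p.att_a_Wq, p.att_a_Wk, p.att_a_Wv,
                             p.att_a_Wo, g.conv_a_W, g.conv_a_b, g.att_a_Wq,
                             g.att_a_Wk, g.att_a_Wv, g.att_a_Wo, ca, dPooledA, cfg);
    } else if (useB) {
      vec dPooledB = du.subvec(0, C - 1);
      g.emb_bv.row(ex.bv - 1) += du.subvec(C, C + dg - 1).t();
      g.emb_bj.row(ex.bj - 1) += du.subvec(C + dg, C + 2 * dg - 1).t();
      g.emb_mhc.row(ex.mhc - 1) += du.subvec(C + 2 * dg, C + 2 * dg + dm - 1).t();
      dEp = chainBackward(p.conv_b_W, p.att_b_Wq, p.att_b_Wk, p.att_b_Wv, p.att_b_Wo,
                          g.conv_b_W, g.conv_b_b, g.att_b_Wq, g.att_b_Wk,
                          g.att_b_Wv, g.att_b_Wo, cb, dPooledB, cfg);
    } else {
      vec dPooledA = du.subvec(0, C - 1);
      g.emb_av.row(ex.av - 1) += du.subvec(C, C + dg - 1).t();
      g.emb_aj.row(ex.aj - 1) += du.subvec(C + dg, C + 2 * dg - 1).t();
      g.emb_mhc.row(ex.mhc - 1) += du.subvec(C + 2 * dg, C + 2 * dg + dm - 1).t();
      if (cfg.share)
        dEp = chainBackward(p.conv_b_W, p.att_b_Wq, p.att_b_Wk, p.att_b_Wv,
                            p.att_b_Wo, g.conv_b_W, g.conv_b_b, g.att_b_Wq,
                            g.att_b_Wk, g.att_b_Wv, g.att_b_Wo, ca, dPooledA, cfg);
      else
        dEp = chainBackward(p.conv_a_W, p.att_a_Wq, p.att_a_Wk, p.att_a_Wv,
                            p.att_a_Wo, g.conv_a_W, g.conv_a_b, g.att_a_Wq,
                            g.att_a_Wk, g.att_a_Wv, g.att_a_Wo, ca, dPooledA, cfg);
    }
    // shared epitope conv backward
    mat dPreEp = dEp % conv_to<mat>::from(epc.Pre > 0.0);
    g.conv_ep_W += dPreEp.t() * epc.M;
    g.conv_ep_b += sum(dPreEp, 0).t();
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss / (double)N,
                            Rcpp::Named("grads") = gradsToList(g));
}
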