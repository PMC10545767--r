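// Compiled per-bag training kernels for the three MIL heads.
//
// Each *_step_cpp function runs one forward pass and (optionally) the full
// analytic backward pass for a single bag, returning the loss terms and the
// parameter gradients as a named list matching the R-side parameter layout.
// The R implementations in R/ are the reference path (used by the exported
// granular operations and by predict()); the test suite asserts that these
// kernels reproduce the R losses and gradients to near machine precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double GN_EPS = 1e-5;

static double softplus1(double v) {
  return std::max(v, 0.0) + std::log1p(std::exp(-std::fabs(v)));
}
static double mish1(double v) { return v * std::tanh(softplus1(v)); }
static double mish_grad1(double v) {
  double sp = softplus1(v);
  double t = std::tanh(sp);
  double s = 1.0 / (1.0 + std::exp(-v));
  return t + v * (1.0 - t * t) * s;
}

static vec softmax_vec(const vec& x) {
  vec z = x - x.max();
  vec e = exp(z);
  return e / accu(e);
}

static double cross_entropy(const vec& logits, int cls) {
  vec z = logits - logits.max();
  return std::log(accu(exp(z))) - z(cls);
}

// ---------------------------------------------------------------------------
// group normalization
// ---------------------------------------------------------------------------

static void gn_forward(const mat& x, const vec& gamma, const vec& beta,
                       int groups, mat& y, mat& xhat, mat& inv_sd) {
  const uword n = x.n_rows, c = x.n_cols, gs = c / groups;
  xhat.set_size(n, c);
  inv_sd.set_size(n, c);
  for (int g = 0; g < groups; ++g) {
    span cols(g * gs, (g + 1) * gs - 1);
    vec mu = mean(x.cols(cols), 1);
    vec va = mean(square(x.cols(cols)), 1) - square(mu);
    vec isd = 1.0 / sqrt(va + GN_EPS);
    xhat.cols(cols) = (x.cols(cols) - repmat(mu, 1, gs)) % repmat(isd, 1, gs);
    inv_sd.cols(cols) = repmat(isd, 1, gs);
  }
  y = xhat;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
}

static mat gn_backward(const mat& dy, const mat& xhat, const mat& inv_sd,
                       const vec& gamma, int groups, vec& dgamma, vec& dbeta) {
  const uword c = dy.n_cols, gs = c / groups;
  dgamma = sum(dy % xhat, 0).t();
  dbeta = sum(dy, 0).t();
  mat dxhat = dy;
  dxhat.each_row() %= gamma.t();
  mat dx(dy.n_rows, c);
  for (int g = 0; g < groups; ++g) {
    span cols(g * gs, (g + 1) * gs - 1);
    mat dxh = dxhat.cols(cols);
    mat xh = xhat.cols(cols);
    vec m1 = mean(dxh, 1);
    vec m2 = mean(dxh % xh, 1);
    dx.cols(cols) =
        (dxh - repmat(m1, 1, gs) - xh % repmat(m2, 1, gs)) % inv_sd.cols(cols);
  }
  return dx;
}

// ---------------------------------------------------------------------------
// shared encoder: Mish(GroupNorm(Dropout(FC(x))))
// ---------------------------------------------------------------------------

struct EncCache {
  mat dr_y, drop_mask, gn_y, xhat, inv_sd, z;
  bool has_mask = false;
};

static mat enc_forward(const mat& x, const mat& W, const vec& b,
                       const vec& gamma, const vec& beta, int groups,
                       double dropout, bool train, EncCache& c) {
  mat fc = x * W;
  fc.each_row() += b.t();
  if (train && dropout > 0) {
    double keep = 1.0 - dropout;
    c.drop_mask.set_size(fc.n_rows, fc.n_cols);
    for (uword i = 0; i < fc.n_elem; ++i) {
      c.drop_mask(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    }
    fc %= c.drop_mask;
    c.has_mask = true;
  }
  c.dr_y = fc;
  gn_forward(fc, gamma, beta, groups, c.gn_y, c.xhat, c.inv_sd);
  c.z = c.gn_y;
  c.z.transform([](double v) { return mish1(v); });
  return c.z;
}

static void enc_backward(const mat& dz, const EncCache& c, const mat& x,
                         const mat& W, const vec& gamma, int groups, mat& dW,
                         vec& db, vec& dgamma, vec& dbeta) {
  mat mg = c.gn_y;
  mg.transform([](double v) { return mish_grad1(v); });
  mat dgn = dz % mg;
  mat ddr = gn_backward(dgn, c.xhat, c.inv_sd, gamma, groups, dgamma, dbeta);
  if (c.has_mask) ddr %= c.drop_mask;
  dW = x.t() * ddr;
  db = sum(ddr, 0).t();
}

// ---------------------------------------------------------------------------
// InfoNCE between foreground and background rows
// ---------------------------------------------------------------------------

struct NceCache {
  mat U, E;
  vec A, B, norms;
  uword n;
  double tau;
};

static double infonce_forward(const mat& v_f, const mat& v_b, double tau,
                              NceCache& c) {
  c.n = v_f.n_rows;
  const uword m = 2 * c.n;
  mat X = join_cols(v_f, v_b);
  c.norms = sqrt(sum(square(X), 1));
  c.norms.transform([](double v) { return std::max(v, 1e-12); });
  c.U = X.each_col() / c.norms;
  mat S = (c.U * c.U.t()) / tau;
  c.E = exp(S);
  c.E.diag().zeros();
  c.A.set_size(m);
  c.B.set_size(m);
  double loss = 0.0;
  for (uword i = 0; i < m; ++i) {
    bool fg = i < c.n;
    double a = 0.0, b = 0.0;
    for (uword j = 0; j < m; ++j) {
      if ((j < c.n) == fg) a += c.E(i, j); else b += c.E(i, j);
    }
    c.A(i) = a;
    c.B(i) = b;
    loss += -std::log(a / (a + b));
  }
  c.tau = tau;
  return loss / m;
}

static void infonce_backward(const NceCache& c, mat& dv_f, mat& dv_b) {
  const uword m = 2 * c.n;
  mat G(m, m);
  for (uword i = 0; i < m; ++i) {
    bool fg = i < c.n;
    double invAB = 1.0 / (c.A(i) + c.B(i));
    double invA = 1.0 / c.A(i);
    for (uword j = 0; j < m; ++j) {
      bool same = (j < c.n) == fg;
      G(i, j) = c.E(i, j) * (invAB - (same ? invA : 0.0)) / m;
    }
  }
  G.diag().zeros();
  mat dU = ((G + G.t()) * c.U) / c.tau;
  vec proj = sum(dU % c.U, 1);
  mat dX = dU - c.U.each_col() % proj;
  dX.each_col() /= c.norms;
  dv_f = dX.rows(0, c.n - 1);
  dv_b = dX.rows(c.n, m - 1);
}

// ---------------------------------------------------------------------------
// MIPCL step
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mipcl_step_cpp(const arma::mat& x, int label, const List& params,
                    const List& cfg, bool train, bool want_grads) {
  const mat enc_W = params["enc_W"];
  const vec enc_b = params["enc_b"], enc_gamma = params["enc_gamma"],
            enc_beta = params["enc_beta"];
  const mat dis_W = params["dis_W"];
  const vec dis_b = params["dis_b"], dis_gamma = params["dis_gamma"],
            dis_beta = params["dis_beta"];
  const mat cls_W = params["cls_W"];
  const vec cls_b = params["cls_b"];

  const int groups = cfg["groups"];
  const double dropout = cfg["dropout"], tau = cfg["temperature"],
               delta0 = cfg["delta0"], delta1 = cfg["delta1"],
               w_inst = cfg["w_inst"], w_bag = cfg["w_bag"];

  const uword n = x.n_rows;

  EncCache ec;
  mat Z = enc_forward(x, enc_W, enc_b, enc_gamma, enc_beta, groups, dropout,
                      train, ec);

  // disentangler: per-channel foreground activation map
  mat dfc = Z * dis_W;
  dfc.each_row() += dis_b.t();
  mat dgn_y, dxhat, dinv_sd;
  gn_forward(dfc, dis_gamma, dis_beta, groups, dgn_y, dxhat, dinv_sd);
  mat P = 1.0 / (1.0 + exp(-dgn_y));
  mat v_f = Z % P;
  mat v_b = Z - v_f;

  NceCache nce;
  double l_inst = (n >= 2) ? infonce_forward(v_f, v_b, tau, nce) : 0.0;

  // Grad-CAM over the activated instances Z (x) P = v_f; the preliminary
  // bag score is sum-pooled, so the pooled gradient equals the classifier
  // weights
  mat A = v_f;
  mat alpha = cls_W;
  mat pre = A * alpha;
  mat cam = pre;
  cam.transform([](double v) { return std::max(v, 0.0); });
  mat probs(n, 2);
  for (uword i = 0; i < n; ++i) {
    probs.row(i) = softmax_vec(cam.row(i).t()).t();
  }
  // selection
  std::vector<uword> sel;
  for (uword i = 0; i < n; ++i) {
    if (probs(i, 0) > delta0 || probs(i, 1) > delta1) sel.push_back(i);
  }
  // pooling set: threshold-selected instances when any exist, else the
  // whole bag (probability-weighted mean pooling before saturation)
  if (sel.empty()) {
    for (uword i = 0; i < n; ++i) sel.push_back(i);
  }
  const uword ns = sel.size();
  uvec selv(ns);
  for (uword j = 0; j < ns; ++j) selv(j) = sel[j];
  // class-wise probability-weighted pooling of the selected foreground
  // instances; class c evidence is scored by the classifier's class-c row
  mat Psel = probs.rows(selv);
  mat qs = Psel;
  qs.each_row() /= sum(Psel, 0);
  mat pooled = v_f.rows(selv).t() * qs;      // C x 2
  vec logits = sum(pooled % cls_W, 0).t() + cls_b;
  double l_bag = cross_entropy(logits, label);
  double l_total = w_inst * l_inst + w_bag * l_bag;

  List out = List::create(
      _["l_instances"] = l_inst, _["l_bag"] = l_bag, _["l_total"] = l_total,
      _["bag_logits"] = NumericVector(logits.begin(), logits.end()));
  if (!want_grads) return out;

  // ------- backward -------
  vec dlogits = w_bag * (softmax_vec(logits) - [&] {
                  vec oh(2, fill::zeros);
                  oh(label) = 1.0;
                  return oh;
                }());
  mat dcls_W = pooled;
  dcls_W.each_row() %= dlogits.t();
  vec dcls_b = dlogits;
  mat dpooled = cls_W;
  dpooled.each_row() %= dlogits.t();         // C x 2

  mat Vsel = v_f.rows(selv);
  mat dv_f(n, Z.n_cols, fill::zeros);
  mat add = qs * dpooled.t();                // ns x C
  for (uword j = 0; j < ns; ++j) dv_f.row(selv(j)) += add.row(j);
  mat dq = Vsel * dpooled;                   // ns x 2
  mat dprobs(n, 2, fill::zeros);
  for (int cc = 0; cc < 2; ++cc) {
    vec dp = (dq.col(cc) - accu(qs.col(cc) % dq.col(cc))) / accu(Psel.col(cc));
    for (uword j = 0; j < ns; ++j) dprobs(selv(j), cc) = dp(j);
  }
  mat dcam = probs % (dprobs.each_col() - sum(dprobs % probs, 1));
  mat dM = dcam % conv_to<mat>::from(pre > 0);
  mat dalpha = A.t() * dM;
  dcls_W += dalpha;
  mat dZ(n, Z.n_cols, fill::zeros);
  dv_f += dM * alpha.t();

  mat dv_b(n, Z.n_cols, fill::zeros);
  if (n >= 2) {
    mat nvf, nvb;
    infonce_backward(nce, nvf, nvb);
    dv_f += w_inst * nvf;
    dv_b += w_inst * nvb;
  }

  mat dP = (dv_f - dv_b) % Z;
  dZ += dv_f % P + dv_b % (1.0 - P);

  mat dgn = dP % P % (1.0 - P);
  vec ddis_gamma, ddis_beta;
  mat ddfc = gn_backward(dgn, dxhat, dinv_sd, dis_gamma, groups, ddis_gamma,
                         ddis_beta);
  mat ddis_W = Z.t() * ddfc;
  vec ddis_b = sum(ddfc, 0).t();
  dZ += ddfc * dis_W.t();

  mat denc_W;
  vec denc_b, denc_gamma, denc_beta;
  enc_backward(dZ, ec, x, enc_W, enc_gamma, groups, denc_W, denc_b, denc_gamma,
               denc_beta);

  out["grads"] = List::create(
      _["enc_W"] = denc_W, _["enc_b"] = denc_b, _["enc_gamma"] = denc_gamma,
      _["enc_beta"] = denc_beta, _["dis_W"] = ddis_W, _["dis_b"] = ddis_b,
      _["dis_gamma"] = ddis_gamma, _["dis_beta"] = ddis_beta,
      _["cls_W"] = dcls_W, _["cls_b"] = dcls_b);
  return out;
}

// ---------------------------------------------------------------------------
// ABMIL step
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List abmil_step_cpp(const arma::mat& x, int label, const List& params,
                    const List& cfg, bool train, bool want_grads) {
  const mat enc_W = params["enc_W"];
  const vec enc_b = params["enc_b"], enc_gamma = params["enc_gamma"],
            enc_beta = params["enc_beta"];
  const mat att_V = params["att_V"];
  const vec att_w = params["att_w"];
  const mat cls_W = params["cls_W"];
  const vec cls_b = params["cls_b"];
  const int groups = cfg["groups"];
  const double dropout = cfg["dropout"];

  EncCache ec;
  mat H = enc_forward(x, enc_W, enc_b, enc_gamma, enc_beta, groups, dropout,
                      train, ec);
  mat T = tanh(H * att_V.t());
  vec e = T * att_w;
  vec a = softmax_vec(e);
  vec z = H.t() * a;
  vec logits = cls_W.t() * z + cls_b;
  double l_bag = cross_entropy(logits, label);

  List out = List::create(
      _["l_bag"] = l_bag, _["l_total"] = l_bag,
      _["bag_logits"] = NumericVector(logits.begin(), logits.end()));
  if (!want_grads) return out;

  vec oh(2, fill::zeros);
  oh(label) = 1.0;
  vec dlogits = softmax_vec(logits) - oh;
  mat dcls_W = z * dlogits.t();
  vec dcls_b = dlogits;
  vec dz = cls_W * dlogits;
  vec da = H * dz;
  vec de = a % (da - accu(a % da));
  mat dT = de * att_w.t();
  vec dw = T.t() * de;
  mat dpre = dT % (1.0 - square(T));
  mat dV = dpre.t() * H;
  mat dH = a * dz.t() + dpre * att_V;

  mat denc_W;
  vec denc_b, denc_gamma, denc_beta;
  enc_backward(dH, ec, x, enc_W, enc_gamma, groups, denc_W, denc_b, denc_gamma,
               denc_beta);
  out["grads"] = List::create(
      _["enc_W"] = denc_W, _["enc_b"] = denc_b, _["enc_gamma"] = denc_gamma,
      _["enc_beta"] = denc_beta, _["att_V"] = dV, _["att_w"] = dw,
      _["cls_W"] = dcls_W, _["cls_b"] = dcls_b);
  return out;
}

// ---------------------------------------------------------------------------
// CLAM step
// ---------------------------------------------------------------------------

static vec smooth_svm_grad(const vec& s, int y, double margin,
                           double smoothing) {
  vec d(s.n_elem, fill::value(margin));
  d(y) = 0.0;
  vec p = softmax_vec((d + s) / smoothing);
  p(y) -= 1.0;
  return p;
}

static double smooth_svm_loss(const vec& s, int y, double margin,
                              double smoothing) {
  vec d(s.n_elem, fill::value(margin));
  d(y) = 0.0;
  vec z = (d + s) / smoothing;
  double zm = z.max();
  return smoothing * (zm + std::log(accu(exp(z - zm)))) - s(y);
}

// [[Rcpp::export]]
List clam_step_cpp(const arma::mat& x, int label, const List& params,
                   const List& cfg, bool train, bool want_grads) {
  const mat enc_W = params["enc_W"];
  const vec enc_b = params["enc_b"], enc_gamma = params["enc_gamma"],
            enc_beta = params["enc_beta"];
  const mat att_V = params["att_V"], att_U = params["att_U"];
  const vec att_w = params["att_w"];
  const mat cls_W = params["cls_W"];
  const vec cls_b = params["cls_b"];
  const mat inst_W = params["inst_W"];
  const vec inst_b = params["inst_b"];
  const int groups = cfg["groups"], B = cfg["clam_B"];
  const double dropout = cfg["dropout"], bag_weight = cfg["clam_bag_weight"],
               margin = cfg["svm_margin"], smoothing = cfg["svm_smoothing"];

  const uword n = x.n_rows;
  EncCache ec;
  mat H = enc_forward(x, enc_W, enc_b, enc_gamma, enc_beta, groups, dropout,
                      train, ec);
  mat T = tanh(H * att_V.t());
  mat G = 1.0 / (1.0 + exp(-(H * att_U.t())));
  vec e = (T % G) * att_w;
  vec a = softmax_vec(e);
  vec z = H.t() * a;
  vec logits = cls_W.t() * z + cls_b;
  double l_bag = cross_entropy(logits, label);

  // pseudo labels: top/bottom B_eff attention, ties to the lowest index
  int B_eff = std::min<int>(B, n / 2);
  std::vector<uword> lab_idx;
  std::vector<int> lab_cls;
  if (B_eff >= 1) {
    std::vector<uword> ord(n);
    for (uword i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](uword i, uword j) { return a(i) > a(j); });
    for (int j = 0; j < B_eff; ++j) {
      lab_idx.push_back(ord[j]);
      lab_cls.push_back(1);
    }
    std::stable_sort(ord.begin(), ord.end(),
                     [&](uword i, uword j) { return a(i) < a(j); });
    for (int j = 0; j < B_eff; ++j) {
      lab_idx.push_back(ord[j]);
      lab_cls.push_back(0);
    }
  }
  const uword n_lab = lab_idx.size();
  double l_inst = 0.0;
  mat inst_logits;
  if (n_lab > 0) {
    uvec li(n_lab);
    for (uword j = 0; j < n_lab; ++j) li(j) = lab_idx[j];
    inst_logits = H.rows(li) * inst_W;
    inst_logits.each_row() += inst_b.t();
    for (uword j = 0; j < n_lab; ++j) {
      l_inst += smooth_svm_loss(inst_logits.row(j).t(), lab_cls[j], margin,
                                smoothing);
    }
    l_inst /= n_lab;
  }
  double l_total = (n_lab > 0)
                       ? bag_weight * l_bag + (1.0 - bag_weight) * l_inst
                       : l_bag;

  List out = List::create(
      _["l_bag"] = l_bag, _["l_instances"] = l_inst, _["l_total"] = l_total,
      _["bag_logits"] = NumericVector(logits.begin(), logits.end()));
  if (!want_grads) return out;

  double w_bag = (n_lab > 0) ? bag_weight : 1.0;
  vec oh(2, fill::zeros);
  oh(label) = 1.0;
  vec dlogits = w_bag * (softmax_vec(logits) - oh);
  mat dcls_W = z * dlogits.t();
  vec dcls_b = dlogits;
  vec dz = cls_W * dlogits;
  vec da = H * dz;
  vec de = a % (da - accu(a % da));
  mat dTG = de * att_w.t();
  vec dw = (T % G).t() * de;
  mat dT = dTG % G;
  mat dG = dTG % T;
  mat dpre_t = dT % (1.0 - square(T));
  mat dpre_g = dG % G % (1.0 - G);
  mat dV = dpre_t.t() * H;
  mat dU = dpre_g.t() * H;
  mat dH = a * dz.t() + dpre_t * att_V + dpre_g * att_U;

  mat dinst_W(inst_W.n_rows, inst_W.n_cols, fill::zeros);
  vec dinst_b(2, fill::zeros);
  if (n_lab > 0) {
    double w_inst = 1.0 - bag_weight;
    mat dil(n_lab, 2);
    for (uword j = 0; j < n_lab; ++j) {
      dil.row(j) = smooth_svm_grad(inst_logits.row(j).t(), lab_cls[j], margin,
                                   smoothing)
                       .t() *
                   (w_inst / n_lab);
    }
    uvec li(n_lab);
    for (uword j = 0; j < n_lab; ++j) li(j) = lab_idx[j];
    mat Hlab = H.rows(li);
    dinst_W = Hlab.t() * dil;
    dinst_b = sum(dil, 0).t();
    mat add = dil * inst_W.t();
    for (uword j = 0; j < n_lab; ++j) dH.row(li(j)) += add.row(j);
  }

  mat denc_W;
  vec denc_b, denc_gamma, denc_beta;
  enc_backward(dH, ec, x, enc_W, enc_gamma, groups, denc_W, denc_b, denc_gamma,
               denc_beta);
  out["grads"] = List::create(
      _["enc_W"] = denc_W, _["enc_b"] = denc_b, _["enc_gamma"] = denc_gamma,
      _["enc_beta"] = denc_beta, _["att_V"] = dV, _["att_U"] = dU,
      _["att_w"] = dw, _["cls_W"] = dcls_W, _["cls_b"] = dcls_b,
      _["inst_W"] = dinst_W, _["inst_b"] = dinst_b);
  return out;
}
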