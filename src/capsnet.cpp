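// Capsule-network core: conv frontend -> primary capsules (conv + reshape +
// squash) -> prediction vectors -> dynamic routing -> type-capsule lengths,
// with exact reverse-mode gradients (routing unrolled through all
// iterations). Also hosts the CGR midpoint walk. Single-threaded and
// deterministic: identical inputs give bit-identical outputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Corner order A, C, G, T on [-1,1]^2 (A upper-left, T upper-right).
static const double CORNX[4] = {-1.0, -1.0, 1.0, 1.0};
static const double CORNY[4] = { 1.0, -1.0, -1.0, 1.0};

// [[Rcpp::export]]
NumericMatrix cgr_walk_cpp(IntegerVector idx) {
  int n = idx.size();
  NumericMatrix out(n, 2);
  double x = 0.0, y = 0.0;
  for (int i = 0; i < n; ++i) {
    int a = idx[i] - 1;
    if (a < 0 || a > 3) stop("internal: residue index out of range");
    x = 0.5 * (x + CORNX[a]);
    y = 0.5 * (y + CORNY[a]);
    out(i, 0) = x;
    out(i, 1) = y;
  }
  return out;
}

struct Cfg {
  int N, k1, s1, F, k2, s2, P, m, n, J, r, h1, h2, L, C;
  int head;     // 0 capsule, 1 dense
  int scaling;  // 0 per_max, 1 per_total, 2 none
  double m_plus, m_minus, lambda_down;
};

static Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.N = as<int>(cfg["input_resolution"]);
  c.k1 = as<int>(cfg["conv_kernel"]);
  c.s1 = as<int>(cfg["conv_stride"]);
  c.F = as<int>(cfg["conv_filters"]);
  c.k2 = as<int>(cfg["primary_kernel"]);
  c.s2 = as<int>(cfg["primary_stride"]);
  c.P = as<int>(cfg["primary_maps"]);
  c.m = as<int>(cfg["primary_dim"]);
  c.n = as<int>(cfg["type_dim"]);
  c.J = as<int>(cfg["n_classes"]);
  c.r = as<int>(cfg["routing_iterations"]);
  std::string head = as<std::string>(cfg["head"]);
  c.head = (head == "dense") ? 1 : 0;
  std::string sc = as<std::string>(cfg["input_scaling"]);
  c.scaling = (sc == "per_max") ? 0 : (sc == "per_total" ? 1 : 2);
  c.m_plus = as<double>(cfg["m_plus"]);
  c.m_minus = as<double>(cfg["m_minus"]);
  c.lambda_down = as<double>(cfg["lambda_down"]);
  if (c.k1 > c.N || c.s1 < 1) stop("conv frontend does not fit the input resolution");
  c.h1 = (c.N - c.k1) / c.s1 + 1;
  if (c.k2 > c.h1 || c.s2 < 1) stop("primary conv does not fit the frontend output");
  c.h2 = (c.h1 - c.k2) / c.s2 + 1;
  c.L = c.h2 * c.h2 * c.P;
  c.C = c.P * c.m;
  if (c.F < 1 || c.P < 1 || c.m < 1 || c.n < 1 || c.r < 1 || c.J < 2)
    stop("invalid network geometry");
  return c;
}

struct Params {
  mat K1; vec b1; mat K2; vec b2; cube W; mat Wd; vec bd;
};

static Params read_params(const List& p, const Cfg& c) {
  Params pp;
  NumericVector c1w = p["conv1_w"];
  if (c1w.size() != c.k1 * c.k1 * c.F) stop("conv1_w has wrong size for this config");
  pp.K1 = mat(c1w.begin(), c.k1 * c.k1, c.F);
  pp.b1 = as<vec>(p["conv1_b"]);
  NumericVector c2w = p["conv2_w"];
  if (c2w.size() != c.k2 * c.k2 * c.F * c.C) stop("conv2_w has wrong size for this config");
  pp.K2 = mat(c2w.begin(), c.k2 * c.k2 * c.F, c.C);
  pp.b2 = as<vec>(p["conv2_b"]);
  if (c.head == 0) {
    NumericVector w = p["W"];
    if (w.size() != (R_xlen_t)c.n * c.m * c.L * c.J)
      stop("routing weight W has wrong size: expected n x m x L x J = %d x %d x %d x %d",
           c.n, c.m, c.L, c.J);
    pp.W = cube(w.begin(), c.n, c.m, (uword)c.L * c.J);
  } else {
    NumericMatrix wd = p["dense_w"];
    if (wd.nrow() != c.J || wd.ncol() != c.L * c.m) stop("dense_w has wrong size");
    pp.Wd = mat(wd.begin(), c.J, c.L * c.m);
    pp.bd = as<vec>(p["dense_b"]);
  }
  return pp;
}

// squash(s) = (||s||^2 / (1 + ||s||^2)) * s / ||s||; exact zero in -> zero out
static vec squash_col(const vec& s) {
  double n2 = dot(s, s);
  if (n2 == 0.0) return zeros<vec>(s.n_elem);
  return s * (std::sqrt(n2) / (1.0 + n2));
}

// reverse of squash: ds = q * dv + (q' / ||s||) (s . dv) s,
// q = ||s||/(1+||s||^2), q' = (1-||s||^2)/(1+||s||^2)^2
static vec squash_back_col(const vec& dv, const vec& s) {
  double n2 = dot(s, s);
  if (n2 == 0.0) return zeros<vec>(s.n_elem);
  double nrm = std::sqrt(n2);
  double q = nrm / (1.0 + n2);
  double qp = (1.0 - n2) / ((1.0 + n2) * (1.0 + n2));
  return q * dv + (qp / nrm) * dot(s, dv) * s;
}

// spatial position index is r + c*h (column-major); patch column index is
// qr + qc*k (+ f*k*k for multi-channel), matching R's array layout so the
// kernel arrays map onto im2col matrices without reordering.
static void im2col_1ch(const mat& X, int k, int s, int h, mat& P) {
  for (int c0 = 0; c0 < h; ++c0)
    for (int r0 = 0; r0 < h; ++r0) {
      int pos = r0 + c0 * h;
      for (int qc = 0; qc < k; ++qc)
        for (int qr = 0; qr < k; ++qr)
          P(pos, qr + qc * k) = X(r0 * s + qr, c0 * s + qc);
    }
}

static void im2col_mch(const mat& A, int h_in, int k, int s, int h_out, int F, mat& P) {
  for (int f = 0; f < F; ++f)
    for (int c0 = 0; c0 < h_out; ++c0)
      for (int r0 = 0; r0 < h_out; ++r0) {
        int pos = r0 + c0 * h_out;
        for (int qc = 0; qc < k; ++qc)
          for (int qr = 0; qr < k; ++qr)
            P(pos, qr + qc * k + f * k * k) =
              A((r0 * s + qr) + (c0 * s + qc) * h_in, f);
      }
}

static void col2im_mch(const mat& dP, int h_in, int k, int s, int h_out, int F, mat& dA) {
  for (int f = 0; f < F; ++f)
    for (int c0 = 0; c0 < h_out; ++c0)
      for (int r0 = 0; r0 < h_out; ++r0) {
        int pos = r0 + c0 * h_out;
        for (int qc = 0; qc < k; ++qc)
          for (int qr = 0; qr < k; ++qr)
            dA((r0 * s + qr) + (c0 * s + qc) * h_in, f) +=
              dP(pos, qr + qc * k + f * k * k);
      }
}

struct Cache {
  mat P1, Z1, A1, P2, Z2, u_raw, u, Vfin, coupling;
  cube Uhat;
  std::vector<mat> Cs, Ss, Vs;
  vec p;
};

static void forward_one(const mat& Xraw, const Cfg& c, const Params& pp, Cache& K) {
  mat X = Xraw;
  if (c.scaling == 0) { double mx = X.max(); if (mx > 0) X /= mx; }
  else if (c.scaling == 1) { double s = accu(X); if (s > 0) X /= s; }
  if (!X.is_finite()) stop("non-finite input image");

  K.P1.set_size(c.h1 * c.h1, c.k1 * c.k1);
  im2col_1ch(X, c.k1, c.s1, c.h1, K.P1);
  K.Z1 = K.P1 * pp.K1;
  K.Z1.each_row() += pp.b1.t();
  K.A1 = K.Z1;
  K.A1.elem(find(K.A1 < 0)).zeros();

  K.P2.set_size(c.h2 * c.h2, c.k2 * c.k2 * c.F);
  im2col_mch(K.A1, c.h1, c.k2, c.s2, c.h2, c.F, K.P2);
  K.Z2 = K.P2 * pp.K2;
  K.Z2.each_row() += pp.b2.t();

  // primary capsule i = pos + p*npos2 takes channels p*m .. p*m + m-1
  int npos2 = c.h2 * c.h2;
  K.u_raw.set_size(c.L, c.m);
  for (int p = 0; p < c.P; ++p)
    for (int d = 0; d < c.m; ++d)
      K.u_raw.col(d).subvec(p * npos2, (p + 1) * npos2 - 1) = K.Z2.col(p * c.m + d);
  K.u.set_size(c.L, c.m);
  for (int i = 0; i < c.L; ++i)
    K.u.row(i) = squash_col(K.u_raw.row(i).t()).t();

  if (c.head == 1) {
    vec uf = vectorise(K.u);
    vec z = pp.Wd * uf + pp.bd;
    K.p = 1.0 / (1.0 + exp(-z));
    K.Vfin.zeros(c.n, c.J);
    K.coupling.zeros(c.L, c.J);
    return;
  }

  K.Uhat.set_size(c.L, c.n, c.J);
  for (int j = 0; j < c.J; ++j)
    for (int i = 0; i < c.L; ++i)
      K.Uhat.slice(j).row(i) = (pp.W.slice((uword)i + (uword)j * c.L) * K.u.row(i).t()).t();

  K.Cs.clear(); K.Ss.clear(); K.Vs.clear();
  mat b(c.L, c.J, fill::zeros), Cc, S(c.n, c.J), V(c.n, c.J);
  for (int t = 0; t < c.r; ++t) {
    mat eb = exp(b.each_col() - max(b, 1));
    Cc = eb.each_col() / sum(eb, 1);
    for (int j = 0; j < c.J; ++j) {
      S.col(j) = K.Uhat.slice(j).t() * Cc.col(j);
      V.col(j) = squash_col(S.col(j));
    }
    K.Cs.push_back(Cc); K.Ss.push_back(S); K.Vs.push_back(V);
    if (t < c.r - 1)
      for (int j = 0; j < c.J; ++j)
        b.col(j) += K.Uhat.slice(j) * V.col(j);
  }
  K.Vfin = V;
  K.coupling = Cc;
  K.p.set_size(c.J);
  for (int j = 0; j < c.J; ++j) K.p(j) = norm(V.col(j), 2);
}

// margin loss L = sum_j T_j max(0, m+ - p_j)^2 +
//                 lambda (1 - T_j) max(0, p_j - m-)^2, plus dL/dp
static double margin_loss_grad(const vec& p, int label, const Cfg& c, vec& dp) {
  double loss = 0.0;
  dp.zeros(c.J);
  for (int j = 0; j < c.J; ++j) {
    double T = (j == label) ? 1.0 : 0.0;
    double a = std::max(0.0, c.m_plus - p(j));
    double b = std::max(0.0, p(j) - c.m_minus);
    loss += T * a * a + c.lambda_down * (1.0 - T) * b * b;
    dp(j) = -2.0 * T * a + 2.0 * c.lambda_down * (1.0 - T) * b;
  }
  return loss;
}

struct Grad {
  mat K1; vec b1; mat K2; vec b2; cube W; mat Wd; vec bd;
  void init(const Cfg& c) {
    K1.zeros(c.k1 * c.k1, c.F); b1.zeros(c.F);
    K2.zeros(c.k2 * c.k2 * c.F, c.C); b2.zeros(c.C);
    if (c.head == 0) W.zeros(c.n, c.m, (uword)c.L * c.J);
    else { Wd.zeros(c.J, c.L * c.m); bd.zeros(c.J); }
  }
};

static void backward_one(const Cfg& c, const Params& pp, const Cache& K,
                         const vec& dp, Grad& G) {
  mat du(c.L, c.m, fill::zeros);
  if (c.head == 1) {
    vec dz = dp % K.p % (1.0 - K.p);
    G.bd += dz;
    vec uf = vectorise(K.u);
    G.Wd += dz * uf.t();
    du = reshape(pp.Wd.t() * dz, c.L, c.m);
  } else {
    mat dV(c.n, c.J, fill::zeros);
    for (int j = 0; j < c.J; ++j)
      if (K.p(j) > 0) dV.col(j) = dp(j) * K.Vfin.col(j) / K.p(j);

    // routing backward, unrolled: g_b carries dL/db^(t-1)
    cube dUhat(c.L, c.n, c.J, fill::zeros);
    mat g_b(c.L, c.J, fill::zeros);
    for (int t = c.r - 1; t >= 0; --t) {
      mat dVt(c.n, c.J, fill::zeros);
      if (t == c.r - 1) {
        dVt = dV;
      } else {
        // b^(t) = b^(t-1) + Uhat . V^(t): split the incoming b-gradient
        for (int j = 0; j < c.J; ++j) {
          dVt.col(j) = K.Uhat.slice(j).t() * g_b.col(j);
          dUhat.slice(j) += g_b.col(j) * K.Vs[t].col(j).t();
        }
      }
      mat dS(c.n, c.J), dc(c.L, c.J);
      for (int j = 0; j < c.J; ++j) {
        dS.col(j) = squash_back_col(dVt.col(j), K.Ss[t].col(j));
        dc.col(j) = K.Uhat.slice(j) * dS.col(j);
        dUhat.slice(j) += K.Cs[t].col(j) * dS.col(j).t();
      }
      vec rowdot = sum(K.Cs[t] % dc, 1);
      mat g_new = K.Cs[t] % (dc.each_col() - rowdot);
      g_b = (t < c.r - 1) ? mat(g_b + g_new) : g_new;
    }
    for (int j = 0; j < c.J; ++j)
      for (int i = 0; i < c.L; ++i) {
        vec duh = dUhat.slice(j).row(i).t();
        G.W.slice((uword)i + (uword)j * c.L) += duh * K.u.row(i);
        du.row(i) += (pp.W.slice((uword)i + (uword)j * c.L).t() * duh).t();
      }
  }

  mat du_raw(c.L, c.m);
  for (int i = 0; i < c.L; ++i)
    du_raw.row(i) = squash_back_col(du.row(i).t(), K.u_raw.row(i).t()).t();

  int npos2 = c.h2 * c.h2;
  mat dZ2(npos2, c.C);
  for (int p = 0; p < c.P; ++p)
    for (int d = 0; d < c.m; ++d)
      dZ2.col(p * c.m + d) = du_raw.col(d).subvec(p * npos2, (p + 1) * npos2 - 1);

  G.K2 += K.P2.t() * dZ2;
  G.b2 += sum(dZ2, 0).t();
  mat dP2 = dZ2 * pp.K2.t();
  mat dA1(c.h1 * c.h1, c.F, fill::zeros);
  col2im_mch(dP2, c.h1, c.k2, c.s2, c.h2, c.F, dA1);
  dA1 %= conv_to<mat>::from(K.Z1 > 0);  // ReLU gate
  G.K1 += K.P1.t() * dA1;
  G.b1 += sum(dA1, 0).t();
}

static NumericVector wrap_dims(const vec& v, IntegerVector dim) {
  NumericVector out(v.begin(), v.end());
  if (dim.size() > 1) out.attr("dim") = dim;
  return out;
}

// Batched forward (and optionally backward). `labels` are 0-based class
// indices, or -1 to skip the loss for that record. Returns mean loss and
// mean gradients over the batch.
// [[Rcpp::export]]
List caps_batch_cpp(NumericVector images, IntegerVector labels, List params,
                    List config, bool grad = false, bool want_primary = false,
                    bool want_type = false) {
  Cfg c = read_cfg(config);
  IntegerVector dims = images.attr("dim");
  if (dims.size() != 3 || dims[0] != c.N || dims[1] != c.N)
    stop("image array must be N x N x B with N = %d", c.N);
  int B = dims[2];
  if (labels.size() != B) stop("labels must have one entry per image");

  Params pp = read_params(params, c);
  Grad G;
  if (grad) G.init(c);

  mat P(B, c.J);
  mat prim, typ;
  if (want_primary) prim.set_size(B, c.L * c.m);
  if (want_type) typ.set_size(B, c.J * c.n);
  double loss_total = 0.0;
  int n_loss = 0;
  Cache K;
  for (int bI = 0; bI < B; ++bI) {
    mat X(images.begin() + (size_t)bI * c.N * c.N, c.N, c.N);
    forward_one(X, c, pp, K);
    P.row(bI) = K.p.t();
    if (want_primary) prim.row(bI) = vectorise(K.u).t();
    if (want_type) typ.row(bI) = vectorise(K.Vfin).t();
    if (labels[bI] >= 0) {
      vec dp(c.J);
      loss_total += margin_loss_grad(K.p, labels[bI], c, dp);
      ++n_loss;
      if (grad) backward_one(c, pp, K, dp, G);
    }
  }

  List out = List::create(
    _["p"] = wrap(P),
    _["loss"] = (n_loss > 0) ? loss_total / n_loss : NA_REAL
  );
  if (want_primary) out["primary"] = wrap(prim);
  if (want_type) out["type"] = wrap(typ);
  if (grad) {
    double inv = (n_loss > 0) ? 1.0 / n_loss : 1.0;
    List g = List::create(
      _["conv1_w"] = wrap_dims(vectorise(G.K1) * inv,
                               IntegerVector::create(c.k1, c.k1, c.F)),
      _["conv1_b"] = wrap_dims(G.b1 * inv, IntegerVector::create(c.F)),
      _["conv2_w"] = wrap_dims(vectorise(G.K2) * inv,
                               IntegerVector::create(c.k2, c.k2, c.F, c.C)),
      _["conv2_b"] = wrap_dims(G.b2 * inv, IntegerVector::create(c.C))
    );
    if (c.head == 0) {
      g["W"] = wrap_dims(vectorise(G.W) * inv,
                         IntegerVector::create(c.n, c.m, c.L, c.J));
    } else {
      NumericMatrix wd = wrap(mat(G.Wd * inv));
      g["dense_w"] = wd;
      g["dense_b"] = wrap_dims(G.bd * inv, IntegerVector::create(c.J));
    }
    out["grads"] = g;
  }
  return out;
}

// Single-record forward exposing intermediates (primary capsules, type
// capsules, coupling coefficients) for tests and embedding export.
// [[Rcpp::export]]
List caps_forward_cpp(NumericMatrix image, List params, List config) {
  Cfg c = read_cfg(config);
  if (image.nrow() != c.N || image.ncol() != c.N)
    stop("image must be %d x %d for this config", c.N, c.N);
  Params pp = read_params(params, c);
  mat X(image.begin(), c.N, c.N);
  Cache K;
  forward_one(X, c, pp, K);
  return List::create(
    _["p"] = wrap(conv_to<std::vector<double>>::from(K.p)),
    _["primary"] = wrap(K.u),
    _["type"] = wrap(K.Vfin),
    _["coupling"] = wrap(K.coupling)
  );
}
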