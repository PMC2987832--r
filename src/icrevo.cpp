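// Core numerics: exact Gillespie simulation of a trinucleotide
// context-dependent substitution process along a branch, and an EM optimizer
// for the composite likelihood of central-site columns. The flanking context
// of a column is fixed per branch (ancestral flank states reconstructed by
// parsimony, supplied from R), so each branch of a column's pruning pass uses
// the 4x4 generator of its own context. Expected substitution counts and
// state exposures per branch are computed from the eigendecomposition of the
// context generators (matrix-exponential fallback for near-defective cases).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int qidx4(int l, int x, int r, int y) {
  // column-major index into the [l, x, r, y] 4x4x4x4 rate array (0-based)
  return l + 4 * x + 16 * r + 64 * y;
}

// ---------------------------------------------------------------------------
// Gillespie simulation
// ---------------------------------------------------------------------------

// seq0: states 1..4; qarr: rate array [l, x, r, y]; t: branch length in the
// model's time units. Boundary sites use phantom 'A' flanks.
// [[Rcpp::export]]
IntegerVector sim_branch_cpp(IntegerVector seq0, NumericVector qarr, double t) {
  if (t < 0) stop("negative branch length");
  const int n = seq0.size();
  if (n < 3) stop("sequence length must be >= 3");
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = seq0[i] - 1;
    if (s[i] < 0 || s[i] > 3) stop("states must be in 1..4");
  }
  const double *q = qarr.begin();
  auto left = [&](int i) { return i == 0 ? 0 : s[i - 1]; };
  auto right = [&](int i) { return i == n - 1 ? 0 : s[i + 1]; };
  auto site_rate = [&](int i) {
    int l = left(i), x = s[i], r = right(i);
    double tot = 0.0;
    for (int y = 0; y < 4; ++y)
      if (y != x) tot += q[qidx4(l, x, r, y)];
    return tot;
  };
  std::vector<double> rate(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) { rate[i] = site_rate(i); total += rate[i]; }

  double tcur = 0.0;
  long events = 0;
  while (total > 0) {
    double dt = R::exp_rand() / total;
    tcur += dt;
    if (tcur > t) break;
    // choose site
    double u = unif_rand() * total;
    int i = 0;
    double acc = 0.0;
    for (; i < n - 1; ++i) {
      acc += rate[i];
      if (u <= acc) break;
    }
    // choose target state
    int l = left(i), x = s[i], r = right(i);
    double ru = unif_rand() * rate[i];
    int y = -1;
    double a2 = 0.0;
    for (int yy = 0; yy < 4; ++yy) {
      if (yy == x) continue;
      a2 += q[qidx4(l, x, r, yy)];
      if (ru <= a2) { y = yy; break; }
    }
    if (y < 0) { // numerical edge: pick the last non-diagonal state
      for (int yy = 3; yy >= 0; --yy) if (yy != x) { y = yy; break; }
    }
    s[i] = y;
    for (int j = std::max(0, i - 1); j <= std::min(n - 1, i + 1); ++j) {
      total -= rate[j];
      rate[j] = site_rate(j);
      total += rate[j];
    }
    if ((++events & 4095) == 0) { // refresh against drift
      total = 0.0;
      for (int j = 0; j < n; ++j) total += rate[j];
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = s[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// EM for the composite likelihood
// ---------------------------------------------------------------------------

struct EmData {
  arma::imat tips;       // n_tip x U, states 0..3
  arma::imat qmat;       // n_edge x U, per-branch context class, 0-based
  arma::ivec rootq;      // U, context class at the root, 0-based
  arma::ivec rootstate;  // U, plug-in root state 0..3, or -1 to use pi
  arma::ivec cmap;       // n_qclass x 4 x 4 flattened (q + nq*(x + 4*y)), -1 diag
  int n_tip, n_node, n_edge, n_qclass, n_class, root;
  arma::imat edge;       // n_edge x 2, 0-based node ids, postorder
  arma::ivec egroup;     // per-edge tie group (0-based); grouped edges share
                         // one branch-scale update (e.g. halves of a branch)
  int n_group;
  std::vector<std::vector<int>> children_edges; // per node, edge indices
};

struct EmOpts {
  int max_iter;
  double tol;
  double min_rate;
  double min_t;
  bool estimate_pi;
  bool renormalize;
  int inner_iter;
};

struct EmState {
  arma::vec rates;       // n_class
  arma::vec tlen;        // n_edge
  arma::mat pi;          // n_qclass x 4 (rows sum to 1)
};

struct EmResult {
  double logCL;
  int iter;
  bool converged;
  bool degenerate;
  arma::vec class_events;   // n_class
  arma::vec class_exposure; // n_class
  arma::mat state_exposure; // n_qclass x 4
  arma::vec edge_events;    // n_edge
};

static void build_Q(const EmData &D, const arma::vec &rates, int qc, arma::mat &Q) {
  Q.zeros(4, 4);
  for (int x = 0; x < 4; ++x) {
    double rowsum = 0.0;
    for (int y = 0; y < 4; ++y) {
      if (x == y) continue;
      int k = D.cmap[qc + D.n_qclass * (x + 4 * y)];
      double r = (k >= 0) ? rates[k] : 0.0;
      Q(x, y) = r;
      rowsum += r;
    }
    Q(x, x) = -rowsum;
  }
}

struct QDecomp {
  bool ok;                 // eigendecomposition usable
  arma::cx_vec d;
  arma::cx_mat V, U;       // Q = V diag(d) U with U = inv(V)
  arma::mat Q;
};

static QDecomp decompose_Q(const arma::mat &Q) {
  QDecomp out;
  out.Q = Q;
  out.ok = false;
  arma::cx_vec d;
  arma::cx_mat V;
  bool s1 = arma::eig_gen(d, V, Q);
  if (s1) {
    arma::cx_mat U;
    if (arma::inv(U, V)) {
      arma::cx_mat rec = V * arma::diagmat(d) * U;
      double err = arma::norm(arma::real(rec) - Q, "fro");
      double scale = arma::norm(Q, "fro") + 1e-12;
      if (err / scale < 1e-8 && arma::norm(arma::imag(rec), "fro") / scale < 1e-8) {
        out.ok = true;
        out.d = d; out.V = V; out.U = U;
      }
    }
  }
  return out;
}

static arma::mat pmat_from(const QDecomp &dec, double t) {
  arma::mat P;
  if (dec.ok) {
    arma::cx_vec e = arma::exp(dec.d * t);
    P = arma::real(dec.V * arma::diagmat(e) * dec.U);
  } else {
    P = arma::expmat(dec.Q * t);
  }
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      if (P(a, b) < 1e-300) P(a, b) = 1e-300;
  return P;
}

// Integrals J_ij(a,b) = int_0^t [e^{Qs}]_{a,i} [e^{Q(t-s)}]_{j,b} ds for all
// (i, j), written to J[(i*4+j)*16 + a*4 + b]. Excludes the q_ij factor.
// Allocation-free eigendecomposition path; matrix-exponential fallback for
// near-defective generators.
static void joint_integrals(const QDecomp &dec, double t, double *J) {
  typedef std::complex<double> cx;
  if (dec.ok) {
    cx ed[4], Phi[16], V[16], U[16];
    for (int k = 0; k < 4; ++k) ed[k] = std::exp(dec.d[k] * t);
    for (int k = 0; k < 4; ++k)
      for (int l = 0; l < 4; ++l) {
        cx diff = dec.d[k] - dec.d[l];
        Phi[k * 4 + l] = (std::abs(diff) < 1e-9) ? t * ed[k]
                                                 : (ed[k] - ed[l]) / diff;
      }
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 4; ++k) {
        V[a * 4 + k] = dec.V(a, k); // row-major [row][col]
        U[a * 4 + k] = dec.U(a, k);
      }
    cx X[16], VX[16];
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        for (int k = 0; k < 4; ++k)
          for (int l = 0; l < 4; ++l)
            X[k * 4 + l] = U[k * 4 + i] * V[j * 4 + l] * Phi[k * 4 + l];
        for (int a = 0; a < 4; ++a)
          for (int l = 0; l < 4; ++l) {
            cx s(0.0, 0.0);
            for (int k = 0; k < 4; ++k) s += V[a * 4 + k] * X[k * 4 + l];
            VX[a * 4 + l] = s;
          }
        double *Jij = J + (i * 4 + j) * 16;
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            cx s(0.0, 0.0);
            for (int l = 0; l < 4; ++l) s += VX[a * 4 + l] * U[l * 4 + b];
            Jij[a * 4 + b] = s.real();
          }
      }
  } else {
    // auxiliary-matrix fallback: expm([[Q, E_ij],[0, Q]] t) top-right block
    arma::mat A(8, 8, arma::fill::zeros);
    A.submat(0, 0, 3, 3) = dec.Q;
    A.submat(4, 4, 7, 7) = dec.Q;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        A.submat(0, 4, 3, 7).zeros();
        A(i, 4 + j) = 1.0;
        arma::mat E = arma::expmat(A * t);
        double *Jij = J + (i * 4 + j) * 16;
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) Jij[a * 4 + b] = E(a, 4 + b);
      }
  }
}

// One EM pass. If update = false only the log composite likelihood is
// computed. Otherwise accumulates expected sufficient statistics in res and
// advances the state by one (E + M) step.
static double em_pass(const EmData &D, const arma::vec &counts, EmState &st,
                      const EmOpts &opts, EmResult &res, bool update) {
  const int U = D.tips.n_cols;
  const int nq = D.n_qclass, ne = D.n_edge, nn = D.n_node, nt = D.n_tip;

  // generator decompositions and per-(edge, context) transition matrices
  std::vector<QDecomp> dec(nq);
  for (int c = 0; c < nq; ++c) {
    arma::mat Q;
    build_Q(D, st.rates, c, Q);
    dec[c] = decompose_Q(Q);
  }
  std::vector<double> P(ne * nq * 16);
  for (int e = 0; e < ne; ++e)
    for (int c = 0; c < nq; ++c) {
      arma::mat Pm = pmat_from(dec[c], st.tlen[e]);
      double *dst = &P[(e * nq + c) * 16];
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          dst[a * 4 + b] = Pm(a, b); // row-major [a][b]
    }

  // accumulators
  std::vector<double> C; // endpoint joint expected counts, (e,c) blocks of 16
  if (update) C.assign(ne * nq * 16, 0.0);
  arma::mat pi_acc(nq, 4, arma::fill::zeros);

  std::vector<double> L(4 * nn), logsc(nn), msg(4 * ne), Dn(4 * nn);
  std::vector<char> init(nn);
  double logCL = 0.0;

  const int *edge0 = D.edge.colptr(0);
  const int *edge1 = D.edge.colptr(1);

  for (int u = 0; u < U; ++u) {
    const double w = counts[u];
    if (w <= 0) continue;
    const int *qcol = D.qmat.colptr(u);
    // ---- up pass (postorder: child subtrees first) ----
    std::fill(L.begin(), L.end(), 0.0);
    std::fill(logsc.begin(), logsc.end(), 0.0);
    std::fill(init.begin(), init.end(), 0);
    const int *tipcol = D.tips.colptr(u);
    for (int v = 0; v < nt; ++v) L[4 * v + tipcol[v]] = 1.0;
    for (int e = 0; e < ne; ++e) {
      const int p = edge0[e], v = edge1[e];
      const double *Pe = &P[(e * nq + qcol[e]) * 16];
      const double *Lv = &L[4 * v];
      double *me = &msg[4 * e];
      for (int a = 0; a < 4; ++a) {
        me[a] = Pe[a * 4 + 0] * Lv[0] + Pe[a * 4 + 1] * Lv[1] +
                Pe[a * 4 + 2] * Lv[2] + Pe[a * 4 + 3] * Lv[3];
      }
      double *Lp = &L[4 * p];
      if (!init[p]) {
        Lp[0] = me[0]; Lp[1] = me[1]; Lp[2] = me[2]; Lp[3] = me[3];
        logsc[p] = logsc[v];
        init[p] = 1;
      } else {
        Lp[0] *= me[0]; Lp[1] *= me[1]; Lp[2] *= me[2]; Lp[3] *= me[3];
        logsc[p] += logsc[v];
      }
      double mx = std::max(std::max(Lp[0], Lp[1]), std::max(Lp[2], Lp[3]));
      if (mx > 0 && mx < 1e-200) {
        for (int a = 0; a < 4; ++a) Lp[a] *= 1e200;
        logsc[p] += std::log(1e-200);
      }
    }
    const int root = D.root;
    const int rq = D.rootq[u];
    const int rs = D.rootstate[u];
    double prior[4];
    if (rs >= 0) {
      // plug-in (parsimony-reconstructed) root state, lightly smoothed
      const double eps = 1e-3;
      for (int x = 0; x < 4; ++x) prior[x] = (x == rs) ? 1.0 - 3 * eps : eps;
    } else {
      for (int x = 0; x < 4; ++x) prior[x] = st.pi(rq, x);
    }
    double tot = 0.0;
    for (int x = 0; x < 4; ++x) tot += prior[x] * L[4 * root + x];
    if (tot <= 0) { logCL += w * (-745.0 + logsc[root]); continue; }
    logCL += w * (std::log(tot) + logsc[root]);
    if (!update) continue;

    for (int x = 0; x < 4; ++x)
      pi_acc(rq, x) += w * prior[x] * L[4 * root + x] / tot;

    // ---- down pass: reverse postorder gives parents before children ----
    for (int x = 0; x < 4; ++x) Dn[4 * root + x] = prior[x];
    for (int e = ne - 1; e >= 0; --e) {
      const int p = edge0[e], v = edge1[e];
      double M[4];
      const double *Dp = &Dn[4 * p];
      M[0] = Dp[0]; M[1] = Dp[1]; M[2] = Dp[2]; M[3] = Dp[3];
      for (int se : D.children_edges[p]) {
        if (se == e) continue;
        const double *ms = &msg[4 * se];
        M[0] *= ms[0]; M[1] *= ms[1]; M[2] *= ms[2]; M[3] *= ms[3];
      }
      const double *Pe = &P[(e * nq + qcol[e]) * 16];
      const double *Lv = &L[4 * v];
      // joint posterior of (parent, child) states; per-edge normalization
      // makes all node-local rescalings cancel
      double psi[16];
      double z = 0.0;
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          double val = M[a] * Pe[a * 4 + b] * Lv[b];
          psi[a * 4 + b] = val;
          z += val;
        }
      if (z > 0) {
        double *Ce = &C[(e * nq + qcol[e]) * 16];
        double wz = w / z;
        for (int k = 0; k < 16; ++k) Ce[k] += wz * psi[k];
      }
      double *Dv = &Dn[4 * v];
      for (int b = 0; b < 4; ++b) {
        Dv[b] = M[0] * Pe[0 * 4 + b] + M[1] * Pe[1 * 4 + b] +
                M[2] * Pe[2 * 4 + b] + M[3] * Pe[3 * 4 + b];
      }
      double dmx = std::max(std::max(Dv[0], Dv[1]), std::max(Dv[2], Dv[3]));
      if (dmx > 0 && dmx < 1e-200)
        for (int b = 0; b < 4; ++b) Dv[b] *= 1e200;
    }
  }

  if (!update) return logCL;

  // expected events and exposures per edge from the endpoint joints
  arma::vec Nk(D.n_class, arma::fill::zeros);
  arma::vec Ne(ne, arma::fill::zeros);
  arma::mat Texp(nq, 4, arma::fill::zeros);          // total state exposure
  std::vector<arma::mat> A(ne);                      // per-edge exposure (nq x 4)
  for (int e = 0; e < ne; ++e) A[e].zeros(nq, 4);

  double J[256]; // 16 (i,j) blocks of 4x4
  for (int e = 0; e < ne; ++e) {
    for (int c = 0; c < nq; ++c) {
      const double *Ce = &C[(e * nq + c) * 16];
      double csum = 0.0;
      for (int k = 0; k < 16; ++k) csum += Ce[k];
      if (csum <= 0) continue;
      const double *Pe = &P[(e * nq + c) * 16];
      joint_integrals(dec[c], st.tlen[e], J);
      // precompute C/P ratios once
      double CP[16];
      for (int k = 0; k < 16; ++k) CP[k] = (Ce[k] > 0) ? Ce[k] / Pe[k] : 0.0;
      for (int i = 0; i < 4; ++i) {
        const double *Jii = J + (i * 4 + i) * 16;
        double ti = 0.0;
        for (int k = 0; k < 16; ++k)
          if (CP[k] > 0) ti += CP[k] * std::max(Jii[k], 0.0);
        A[e](c, i) += ti;
        Texp(c, i) += ti;
        for (int j = 0; j < 4; ++j) {
          if (i == j) continue;
          int k = D.cmap[c + nq * (i + 4 * j)];
          if (k < 0) continue;
          double qij = dec[c].Q(i, j);
          if (qij <= 0) continue;
          const double *Jij = J + (i * 4 + j) * 16;
          double nij = 0.0;
          for (int m = 0; m < 16; ++m)
            if (CP[m] > 0) nij += CP[m] * std::max(Jij[m], 0.0);
          nij *= qij;
          Nk[k] += nij;
          Ne[e] += nij;
        }
      }
    }
  }

  res.class_events = Nk;
  res.edge_events = Ne;
  res.state_exposure = Texp;

  double Ntot = arma::accu(Nk);
  res.degenerate = (Ntot <= 1e-12);

  // M step: alternate closed-form updates of class rates and per-edge scale
  arma::vec r = st.rates;
  arma::vec s(ne, arma::fill::ones);
  arma::vec Tk(D.n_class);
  for (int inner = 0; inner < opts.inner_iter; ++inner) {
    Tk.zeros();
    for (int e = 0; e < ne; ++e) {
      for (int c = 0; c < nq; ++c)
        for (int i = 0; i < 4; ++i) {
          double a = A[e](c, i) * s[e];
          if (a <= 0) continue;
          for (int j = 0; j < 4; ++j) {
            if (i == j) continue;
            int k = D.cmap[c + nq * (i + 4 * j)];
            if (k >= 0) Tk[k] += a;
          }
        }
    }
    for (int k = 0; k < D.n_class; ++k)
      r[k] = (Tk[k] > 0) ? std::max(Nk[k] / Tk[k], opts.min_rate) : opts.min_rate;
    arma::vec gnum(D.n_group, arma::fill::zeros);
    arma::vec gden(D.n_group, arma::fill::zeros);
    for (int e = 0; e < ne; ++e) {
      double denom = 0.0;
      for (int c = 0; c < nq; ++c)
        for (int i = 0; i < 4; ++i) {
          double a = A[e](c, i);
          if (a <= 0) continue;
          double Ri = 0.0;
          for (int j = 0; j < 4; ++j) {
            if (i == j) continue;
            int k = D.cmap[c + nq * (i + 4 * j)];
            if (k >= 0) Ri += r[k];
          }
          denom += a * Ri;
        }
      gnum[D.egroup[e]] += Ne[e];
      gden[D.egroup[e]] += denom;
    }
    for (int e = 0; e < ne; ++e) {
      double den = gden[D.egroup[e]];
      s[e] = (den > 0) ? gnum[D.egroup[e]] / den : 0.0;
    }
  }
  res.class_exposure = Tk;

  // renormalize so the exposure-weighted mean rate is 1
  if (opts.renormalize && !res.degenerate) {
    double num = 0.0, den = 0.0;
    for (int e = 0; e < ne; ++e)
      for (int c = 0; c < nq; ++c)
        for (int i = 0; i < 4; ++i) {
          double a = A[e](c, i) * s[e];
          if (a <= 0) continue;
          double Ri = 0.0;
          for (int j = 0; j < 4; ++j) {
            if (i == j) continue;
            int k = D.cmap[c + nq * (i + 4 * j)];
            if (k >= 0) Ri += r[k];
          }
          num += a * Ri;
          den += a;
        }
    if (num > 0 && den > 0) {
      double mu = num / den;
      r /= mu;
      s *= mu;
    }
  }

  for (int e = 0; e < ne; ++e)
    st.tlen[e] = std::max(st.tlen[e] * s[e], opts.min_t);
  st.rates = r;
  if (opts.estimate_pi) {
    for (int c = 0; c < nq; ++c) {
      double rs = arma::accu(pi_acc.row(c));
      if (rs > 0)
        for (int x = 0; x < 4; ++x) st.pi(c, x) = pi_acc(c, x) / rs;
    }
  }
  return logCL;
}

static EmData make_data(const IntegerMatrix &tips, const IntegerMatrix &qmat,
                        const IntegerVector &rootq, const IntegerVector &rootstate,
                        const IntegerVector &cmap, int n_qclass, int n_class,
                        const IntegerMatrix &edge, const IntegerVector &egroup,
                        int n_node, int root) {
  EmData D;
  D.n_tip = tips.nrow();
  D.tips.set_size(tips.nrow(), tips.ncol());
  for (int i = 0; i < tips.nrow(); ++i)
    for (int j = 0; j < tips.ncol(); ++j)
      D.tips(i, j) = tips(i, j) - 1;
  D.qmat.set_size(qmat.nrow(), qmat.ncol());
  for (int i = 0; i < qmat.nrow(); ++i)
    for (int j = 0; j < qmat.ncol(); ++j)
      D.qmat(i, j) = qmat(i, j) - 1;
  D.rootq.set_size(rootq.size());
  for (int i = 0; i < rootq.size(); ++i) D.rootq[i] = rootq[i] - 1;
  D.rootstate.set_size(rootstate.size());
  for (int i = 0; i < rootstate.size(); ++i) D.rootstate[i] = rootstate[i] - 1;
  D.cmap.set_size(cmap.size());
  for (int i = 0; i < cmap.size(); ++i) D.cmap[i] = cmap[i] - 1; // 0 diag -> -1
  D.n_qclass = n_qclass;
  D.n_class = n_class;
  D.n_edge = edge.nrow();
  D.n_node = n_node;
  D.root = root - 1;
  D.edge.set_size(D.n_edge, 2);
  D.children_edges.assign(n_node, {});
  D.egroup.set_size(D.n_edge);
  D.n_group = 0;
  for (int e = 0; e < D.n_edge; ++e) {
    D.edge(e, 0) = edge(e, 0) - 1;
    D.edge(e, 1) = edge(e, 1) - 1;
    D.children_edges[D.edge(e, 0)].push_back(e);
    D.egroup[e] = egroup[e] - 1;
    D.n_group = std::max(D.n_group, egroup[e]);
  }
  return D;
}

static List run_em(const EmData &D, const arma::vec &counts, EmState st,
                   const EmOpts &opts) {
  EmResult res;
  res.class_events.zeros(D.n_class);
  res.class_exposure.zeros(D.n_class);
  res.state_exposure.zeros(D.n_qclass, 4);
  res.edge_events.zeros(D.n_edge);
  double prev = R_NegInf;
  double logCL = R_NegInf;
  int it = 0;
  bool converged = false;
  bool degenerate = false;
  for (it = 1; it <= opts.max_iter; ++it) {
    logCL = em_pass(D, counts, st, opts, res, true);
    degenerate = res.degenerate;
    if (degenerate) break;
    if (it > 1 && logCL - prev < opts.tol) { converged = true; break; }
    prev = logCL;
    Rcpp::checkUserInterrupt();
  }
  // likelihood at the final parameter values
  EmResult dummy;
  double final_logCL = em_pass(D, counts, st, opts, dummy, false);
  return List::create(
    _["rates"] = NumericVector(st.rates.begin(), st.rates.end()),
    _["edge_length"] = NumericVector(st.tlen.begin(), st.tlen.end()),
    _["pi"] = wrap(st.pi),
    _["logCL"] = final_logCL,
    _["iterations"] = it,
    _["converged"] = converged,
    _["degenerate"] = degenerate,
    _["class_events"] = NumericVector(res.class_events.begin(), res.class_events.end()),
    _["class_exposure"] = NumericVector(res.class_exposure.begin(), res.class_exposure.end()),
    _["state_exposure"] = wrap(res.state_exposure),
    _["edge_events"] = NumericVector(res.edge_events.begin(), res.edge_events.end())
  );
}

static EmOpts opts_from_list(List opts) {
  EmOpts o;
  o.max_iter = as<int>(opts["max_iter"]);
  o.tol = as<double>(opts["tol"]);
  o.min_rate = as<double>(opts["min_rate"]);
  o.min_t = as<double>(opts["min_t"]);
  o.estimate_pi = as<bool>(opts["estimate_pi"]);
  o.renormalize = as<bool>(opts["renormalize"]);
  o.inner_iter = as<int>(opts["inner_iter"]);
  return o;
}

// [[Rcpp::export]]
List em_fit_cpp(IntegerMatrix tips, IntegerMatrix qmat, IntegerVector rootq,
                IntegerVector root_state, NumericVector counts,
                IntegerVector cmap, int n_qclass, int n_class,
                IntegerMatrix edge, IntegerVector edge_group, int n_node, int root,
                NumericVector edge_len0, NumericVector rates0,
                NumericMatrix pi0, List opts) {
  EmData D = make_data(tips, qmat, rootq, root_state, cmap, n_qclass, n_class,
                       edge, edge_group, n_node, root);
  EmState st;
  st.rates = arma::vec(rates0.begin(), rates0.size());
  st.tlen = arma::vec(edge_len0.begin(), edge_len0.size());
  st.pi = as<arma::mat>(pi0);
  arma::vec cnt(counts.begin(), counts.size());
  return run_em(D, cnt, st, opts_from_list(opts));
}

// [[Rcpp::export]]
double em_loglik_cpp(IntegerMatrix tips, IntegerMatrix qmat, IntegerVector rootq,
                     IntegerVector root_state, NumericVector counts,
                     IntegerVector cmap, int n_qclass, int n_class,
                     IntegerMatrix edge, IntegerVector edge_group, int n_node, int root,
                     NumericVector edge_len, NumericVector rates,
                     NumericMatrix pi, List opts) {
  EmData D = make_data(tips, qmat, rootq, root_state, cmap, n_qclass, n_class,
                       edge, edge_group, n_node, root);
  EmState st;
  st.rates = arma::vec(rates.begin(), rates.size());
  st.tlen = arma::vec(edge_len.begin(), edge_len.size());
  st.pi = as<arma::mat>(pi);
  arma::vec cnt(counts.begin(), counts.size());
  EmResult dummy;
  return em_pass(D, cnt, st, opts_from_list(opts), dummy, false);
}

// Block bootstrap driver. Columns are grouped into blocks; blocks are
// resampled with replacement within each region; the EM is re-run
// warm-started from the point estimates on each resampled weighting.
//
// block_col_ptr: (n_block+1) 0-based offsets into block_col_pattern
// block_col_pattern: pattern index (1-based) of each usable column, grouped by block
// region_block_ptr: (n_region+1) 0-based offsets delimiting each region's blocks
// [[Rcpp::export]]
List em_boot_cpp(IntegerMatrix tips, IntegerMatrix qmat, IntegerVector rootq,
                 IntegerVector root_state,
                 IntegerVector cmap, int n_qclass, int n_class,
                 IntegerMatrix edge, IntegerVector edge_group, int n_node, int root,
                 IntegerVector block_col_ptr, IntegerVector block_col_pattern,
                 IntegerVector region_block_ptr,
                 NumericVector edge_len0, NumericVector rates0,
                 NumericMatrix pi0, int B, List opts,
                 bool recompute_pi, IntegerVector rootstate_freq) {
  EmData D = make_data(tips, qmat, rootq, root_state, cmap, n_qclass, n_class,
                       edge, edge_group, n_node, root);
  const int U = tips.ncol();
  const int n_region = region_block_ptr.size() - 1;
  EmOpts o = opts_from_list(opts);

  NumericMatrix rates_out(B, n_class);
  NumericMatrix expo_out(B, n_qclass * 4);
  LogicalVector degen(B);

  arma::vec cnt(U);
  for (int b = 0; b < B; ++b) {
    cnt.zeros();
    for (int rg = 0; rg < n_region; ++rg) {
      int b0 = region_block_ptr[rg], b1 = region_block_ptr[rg + 1];
      int nb = b1 - b0;
      for (int k = 0; k < nb; ++k) {
        int pick = b0 + (int)std::floor(unif_rand() * nb);
        if (pick >= b1) pick = b1 - 1;
        for (int ci = block_col_ptr[pick]; ci < block_col_ptr[pick + 1]; ++ci) {
          cnt[block_col_pattern[ci] - 1] += 1.0;
        }
      }
    }
    EmState st;
    st.rates = arma::vec(rates0.begin(), rates0.size());
    st.tlen = arma::vec(edge_len0.begin(), edge_len0.size());
    st.pi = as<arma::mat>(pi0);
    if (recompute_pi) {
      // the fixed per-context root prior is itself an estimate; re-derive it
      // from each resample's reconstructed root-state frequencies
      st.pi.fill(0.5);
      for (int u = 0; u < U; ++u) {
        if (cnt[u] > 0)
          st.pi(rootq[u] - 1, rootstate_freq[u] - 1) += cnt[u];
      }
      for (int c = 0; c < n_qclass; ++c) {
        double rs = arma::accu(st.pi.row(c));
        st.pi.row(c) /= rs;
      }
    }
    EmResult res;
    double prev = R_NegInf;
    bool dg = false;
    for (int it = 1; it <= o.max_iter; ++it) {
      double ll = em_pass(D, cnt, st, o, res, true);
      if (res.degenerate) { dg = true; break; }
      if (it > 1 && ll - prev < o.tol) break;
      prev = ll;
    }
    degen[b] = dg;
    for (int k = 0; k < n_class; ++k) rates_out(b, k) = st.rates[k];
    for (int c = 0; c < n_qclass; ++c)
      for (int x = 0; x < 4; ++x)
        expo_out(b, c + n_qclass * x) = res.state_exposure(c, x);
    if ((b & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["rates"] = rates_out,
    _["state_exposure"] = expo_out,
    _["degenerate"] = degen
  );
}
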