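// Computational cores: LCMV/eLORETA filter construction and all-pairs
// frequency-resolved connectivity (undirected metrics and VAR-based
// spectral Granger causality). Small per-voxel / per-pair matrix problems
// dominate these loops, which is why they live in C++.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Zero-phase IIR filtering of each row of X: forward pass, backward pass.
// Edges are odd-reflection padded (MATLAB filtfilt style) to suppress
// startup transients.
// [[Rcpp::export]]
arma::mat cpp_filtfilt_rows(const arma::mat& X, const arma::vec& b,
                            const arma::vec& a) {
  const uword nb = b.n_elem, na = a.n_elem;
  const uword np = 3 * (std::max(na, nb) - 1);
  const uword n = X.n_cols;
  if (n <= np + 1) Rcpp::stop("series too short for filtering");
  mat Y(X.n_rows, n);
  vec ext(n + 2 * np), tmp(n + 2 * np);
  auto filt = [&](vec& x) {
    vec y(x.n_elem, fill::zeros);
    for (uword t = 0; t < x.n_elem; ++t) {
      double acc = 0;
      for (uword i = 0; i < nb && i <= t; ++i) acc += b[i] * x[t - i];
      for (uword j = 1; j < na && j <= t; ++j) acc -= a[j] * y[t - j];
      y[t] = acc / a[0];
    }
    x = y;
  };
  for (uword r = 0; r < X.n_rows; ++r) {
    rowvec xr = X.row(r);
    for (uword i = 0; i < np; ++i) ext[i] = 2 * xr[0] - xr[np - i];
    for (uword i = 0; i < n; ++i) ext[np + i] = xr[i];
    for (uword i = 0; i < np; ++i)
      ext[np + n + i] = 2 * xr[n - 1] - xr[n - 2 - i];
    filt(ext);
    ext = reverse(ext);
    filt(ext);
    ext = reverse(ext);
    Y.row(r) = ext.subvec(np, np + n - 1).t();
  }
  return Y;
}

static cx_cube make_cx_cube(const Rcpp::ComplexVector& s,
                            const Rcpp::IntegerVector& dims) {
  const int m = dims[0], m2 = dims[1], nf = dims[2];
  cx_cube C(reinterpret_cast<const cx_double*>(s.begin()), m, m2, nf);
  return C;
}

// LCMV beamformer: per-voxel filter P_v = Cinv * L_v * (L_v' Cinv L_v)^-1
// (unit gain per voxel). L is Ns x (3 Nv).
// [[Rcpp::export]]
arma::mat cpp_lcmv_filter(const arma::mat& L, const arma::mat& Cinv) {
  const uword ns = L.n_rows, nv3 = L.n_cols;
  if (nv3 % 3 != 0) Rcpp::stop("leadfield column count must be 3*Nv");
  const uword nv = nv3 / 3;
  mat P(ns, nv3);
  mat CL = Cinv * L;
  for (uword v = 0; v < nv; ++v) {
    mat Lv = L.cols(3 * v, 3 * v + 2);
    mat CLv = CL.cols(3 * v, 3 * v + 2);
    mat G = Lv.t() * CLv;
    mat Gi;
    if (!inv_sympd(Gi, symmatu(G))) Gi = pinv(G);
    P.cols(3 * v, 3 * v + 2) = CLv * Gi;
  }
  return P;
}

// eLORETA weight iteration: W_v = [L_v' M L_v]^{1/2},
// M = pinv(L W^-1 L' + a K), K = common-average centering matrix.
// Returns the filter P = M L W^-1 (so J = P' Q) and the weights.
// [[Rcpp::export]]
Rcpp::List cpp_eloreta(const arma::mat& L, double a, int max_iter,
                       double tol, Rcpp::Nullable<Rcpp::NumericVector> W0) {
  const uword ns = L.n_rows, nv3 = L.n_cols;
  if (nv3 % 3 != 0) Rcpp::stop("leadfield column count must be 3*Nv");
  const uword nv = nv3 / 3;
  mat K = eye(ns, ns) - ones(ns, ns) / double(ns);

  cube W(3, 3, nv);
  if (W0.isNotNull()) {
    Rcpp::NumericVector w0(W0);
    cube Wt(w0.begin(), 3, 3, nv);
    W = Wt;
  } else {
    for (uword v = 0; v < nv; ++v) W.slice(v) = eye(3, 3);
  }

  mat M(ns, ns);
  double delta = datum::inf;
  int it = 0;
  for (; it < max_iter; ++it) {
    mat LWL(ns, ns, fill::zeros);
    cube Winv(3, 3, nv);
    for (uword v = 0; v < nv; ++v) {
      mat Wi;
      if (!inv_sympd(Wi, symmatu(W.slice(v)))) Wi = pinv(W.slice(v));
      Winv.slice(v) = Wi;
      mat Lv = L.cols(3 * v, 3 * v + 2);
      LWL += Lv * Wi * Lv.t();
    }
    M = pinv(symmatu(LWL + a * K));
    delta = 0.0;
    for (uword v = 0; v < nv; ++v) {
      mat Lv = L.cols(3 * v, 3 * v + 2);
      mat G = symmatu(Lv.t() * M * Lv);
      vec ev; mat V;
      eig_sym(ev, V, G);
      ev = clamp(ev, ev.max() * 1e-12, datum::inf);
      mat Wnew = V * diagmat(sqrt(ev)) * V.t();
      double num = norm(Wnew - W.slice(v), "fro");
      double den = norm(W.slice(v), "fro");
      delta = std::max(delta, num / std::max(den, 1e-300));
      W.slice(v) = Wnew;
    }
    if (delta < tol) { ++it; break; }
  }

  // final M with converged weights, then filter P = M L W^-1
  mat LWL(ns, ns, fill::zeros);
  cube Winv(3, 3, nv);
  for (uword v = 0; v < nv; ++v) {
    mat Wi;
    if (!inv_sympd(Wi, symmatu(W.slice(v)))) Wi = pinv(W.slice(v));
    Winv.slice(v) = Wi;
    mat Lv = L.cols(3 * v, 3 * v + 2);
    LWL += Lv * Wi * Lv.t();
  }
  M = pinv(symmatu(LWL + a * K));
  mat P(ns, nv3);
  for (uword v = 0; v < nv; ++v) {
    P.cols(3 * v, 3 * v + 2) = M * L.cols(3 * v, 3 * v + 2) * Winv.slice(v);
  }
  return Rcpp::List::create(
      Rcpp::Named("P") = P, Rcpp::Named("W") = W,
      Rcpp::Named("iterations") = it, Rcpp::Named("delta") = delta,
      Rcpp::Named("converged") = delta < tol);
}

static mat inv_sqrt_spd(const mat& A, double ridge = 1e-10) {
  vec ev; mat V;
  eig_sym(ev, V, symmatu(A));
  double mx = ev.max();
  ev = clamp(ev, mx * ridge, datum::inf);
  return V * diagmat(1.0 / sqrt(ev)) * V.t();
}

static mat inv_spd_ridge(const mat& A) {
  mat Ai;
  mat As = symmatu(A);
  if (rcond(As) < 1e-10) As += eye(size(As)) * (1e-10 * trace(As));
  if (!inv_sympd(Ai, As)) Ai = pinv(As);
  return Ai;
}

// Undirected FC metrics (COH, iCOH, MIM, MIC) for every region pair at
// every frequency. S is the (m x m x nf) cross-spectrum of all stacked
// region components; membership maps each component to its region (1..R);
// pairs is npairs x 2 (1-based region indices).
// [[Rcpp::export]]
Rcpp::List cpp_undirected_pairs(const Rcpp::ComplexVector& Sv,
                                const Rcpp::IntegerVector& dims,
                                const Rcpp::IntegerVector& membership,
                                const Rcpp::IntegerMatrix& pairs) {
  cx_cube S = make_cx_cube(Sv, dims);
  const uword m = S.n_rows, nf = S.n_slices;
  const int npairs = pairs.nrow();
  int nreg = 0;
  for (int i = 0; i < (int)m; ++i) nreg = std::max(nreg, membership[i]);
  std::vector<uvec> ridx(nreg);
  for (int r = 0; r < nreg; ++r) {
    std::vector<uword> ix;
    for (uword i = 0; i < m; ++i)
      if (membership[i] == r + 1) ix.push_back(i);
    ridx[r] = uvec(ix);
  }
  mat coh(npairs, nf), icoh(npairs, nf), mimv(npairs, nf), micv(npairs, nf);
  for (uword f = 0; f < nf; ++f) {
    cx_mat Sf = S.slice(f);
    vec d = real(Sf.diag());
    vec sc = 1.0 / sqrt(clamp(d, 1e-300, datum::inf));
    cx_mat Cf = Sf % (sc * sc.t());
    for (int p = 0; p < npairs; ++p) {
      const uvec& ix = ridx[pairs(p, 0) - 1];
      const uvec& iy = ridx[pairs(p, 1) - 1];
      cx_mat Cxy = Cf.submat(ix, iy);
      coh(p, f) = mean(mean(abs(Cxy)));
      mat Cxyi = imag(Cxy);
      icoh(p, f) = mean(mean(abs(Cxyi)));
      mat Cxx = real(Cf.submat(ix, ix));
      mat Cyy = real(Cf.submat(iy, iy));
      mat Xi = inv_spd_ridge(Cxx), Yi = inv_spd_ridge(Cyy);
      mimv(p, f) = trace(Xi * Cxyi * Yi * Cxyi.t());
      mat Wm = inv_sqrt_spd(Cxx) * Cxyi * inv_sqrt_spd(Cyy);
      vec sv = svd(Wm);
      micv(p, f) = sv.max();
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("coh") = coh, Rcpp::Named("icoh") = icoh,
      Rcpp::Named("mim") = mimv, Rcpp::Named("mic") = micv);
}

// Whittle / multichannel Levinson recursion on autocovariance lags 0..q.
static bool whittle_cpp(const cube& G, cube& A, mat& Sigma) {
  const uword m = G.n_rows, q = G.n_slices - 1;
  cube AF(m, m, q, fill::zeros), AB(m, m, q, fill::zeros);
  mat Vf = G.slice(0), Vb = G.slice(0);
  for (uword k = 1; k <= q; ++k) {
    mat D = G.slice(k);
    for (uword j = 1; j < k; ++j) D -= AF.slice(j - 1) * G.slice(k - j);
    mat Vbi, Vfi;
    if (!inv(Vbi, Vb) || !inv(Vfi, Vf)) return false;
    mat Akk = D * Vbi;
    mat Bkk = D.t() * Vfi;
    if (k > 1) {
      cube AFo = AF, ABo = AB;
      for (uword j = 1; j < k; ++j) {
        AF.slice(j - 1) = AFo.slice(j - 1) - Akk * ABo.slice(k - j - 1);
        AB.slice(j - 1) = ABo.slice(j - 1) - Bkk * AFo.slice(k - j - 1);
      }
    }
    AF.slice(k - 1) = Akk;
    AB.slice(k - 1) = Bkk;
    Vf -= Akk * D.t();
    Vb -= Bkk * D;
  }
  A = AF;
  Sigma = symmatu((Vf + Vf.t()) / 2.0);
  return Sigma.is_finite();
}

static double herm_logdet(const cx_mat& M) {
  cx_double ld;
  double sign;
  if (!log_det(ld, sign, M)) return datum::nan;
  if (sign <= 0) return datum::nan;
  return ld.real();
}

// Spectral GC in both directions from VAR parameters, at the frequency
// bins `fsel` (0-based) of the nfft-point DFT grid.
static void var_gc_spectrum(const cube& A, const mat& Sigma,
                            const uvec& bx, const uvec& by,
                            const uvec& fsel, double nfft,
                            rowvec& Fxy, rowvec& Fyx) {
  const uword m = Sigma.n_rows, q = A.n_slices;
  const double n = nfft;
  mat Sxx = Sigma.submat(bx, bx), Syy = Sigma.submat(by, by);
  mat Sxy = Sigma.submat(bx, by);
  mat Sig_xx_y = Sxx - Sxy * solve(Syy, Sxy.t());
  mat Sig_yy_x = Syy - Sxy.t() * solve(Sxx, Sxy);
  cx_mat Sig_c = conv_to<cx_mat>::from(Sigma);
  for (uword fi = 0; fi < fsel.n_elem; ++fi) {
    const uword f = fsel[fi];
    double w = 2.0 * datum::pi * f / n;
    cx_mat Aw = eye<cx_mat>(m, m);
    for (uword p = 1; p <= q; ++p)
      Aw -= conv_to<cx_mat>::from(A.slice(p - 1)) *
            std::exp(cx_double(0, -w * double(p)));
    cx_mat H;
    if (!inv(H, Aw)) { Fxy(fi) = datum::nan; Fyx(fi) = datum::nan; continue; }
    cx_mat Sm = H * Sig_c * H.t();
    cx_mat Smyy = Sm.submat(by, by), Smxx = Sm.submat(bx, bx);
    cx_mat Hyx = H.submat(by, bx), Hxy = H.submat(bx, by);
    double dyy = herm_logdet(Smyy);
    double dxx = herm_logdet(Smxx);
    double ryy = herm_logdet(Smyy - Hyx * Sig_xx_y * Hyx.t());
    double rxx = herm_logdet(Smxx - Hxy * Sig_yy_x * Hxy.t());
    Fxy(fi) = dyy - ryy;
    Fyx(fi) = dxx - rxx;
  }
}

// Autocovariance lags 0..np of the (dsub x dsub x nf) one-sided spectrum.
static cube autocov_from_csd(const cx_cube& Ssub, uword np) {
  const uword d = Ssub.n_rows, nf = Ssub.n_slices;
  const uword n = 2 * (nf - 1);
  cube G(d, d, np + 1);
  for (uword p = 0; p <= np; ++p) {
    cx_mat acc(d, d, fill::zeros);
    for (uword k = 0; k < nf; ++k)
      acc += Ssub.slice(k) * std::exp(cx_double(0, 2.0 * datum::pi *
                                                   double(k) * double(p) / n));
    for (uword j = 1; j + 1 < nf; ++j)
      acc += conj(Ssub.slice(nf - 1 - j)) *
             std::exp(cx_double(0, 2.0 * datum::pi *
                                   double(nf - 1 + j) * double(p) / n));
    G.slice(p) = real(acc) / double(n);
  }
  return G;
}

// Forward and time-reversed spectral GC for every region pair, evaluated
// at the frequency bins `freq_sel` (1-based indices into the grid of S).
// Returns npairs x length(freq_sel) matrices Fxy, Fyx (forward fit) and
// Fxy_r, Fyx_r (fit on the transposed autocovariance sequence).
// [[Rcpp::export]]
Rcpp::List cpp_gc_pairs(const Rcpp::ComplexVector& Sv,
                        const Rcpp::IntegerVector& dims,
                        const Rcpp::IntegerVector& membership,
                        const Rcpp::IntegerMatrix& pairs, int np,
                        const Rcpp::IntegerVector& freq_sel,
                        bool time_reversed = true) {
  cx_cube S = make_cx_cube(Sv, dims);
  const uword m = S.n_rows, nf = S.n_slices;
  uvec fsel(freq_sel.size());
  for (int i = 0; i < freq_sel.size(); ++i) fsel[i] = freq_sel[i] - 1;
  const uword nsel = fsel.n_elem;
  const double nfft = 2.0 * (nf - 1);
  const int npairs = pairs.nrow();
  int nreg = 0;
  for (int i = 0; i < (int)m; ++i) nreg = std::max(nreg, membership[i]);
  std::vector<uvec> ridx(nreg);
  for (int r = 0; r < nreg; ++r) {
    std::vector<uword> ix;
    for (uword i = 0; i < m; ++i)
      if (membership[i] == r + 1) ix.push_back(i);
    ridx[r] = uvec(ix);
  }
  mat Fxy(npairs, nsel, fill::value(datum::nan));
  mat Fyx(npairs, nsel, fill::value(datum::nan));
  mat Fxy_r(npairs, nsel, fill::value(datum::nan));
  mat Fyx_r(npairs, nsel, fill::value(datum::nan));
  for (int p = 0; p < npairs; ++p) {
    const uvec& ix = ridx[pairs(p, 0) - 1];
    const uvec& iy = ridx[pairs(p, 1) - 1];
    uvec all = join_cols(ix, iy);
    const uword d = all.n_elem;
    uvec bx = regspace<uvec>(0, ix.n_elem - 1);
    uvec by = regspace<uvec>(ix.n_elem, d - 1);
    cx_cube Ssub(d, d, nf);
    for (uword f = 0; f < nf; ++f) Ssub.slice(f) = S.slice(f).submat(all, all);
    cube G = autocov_from_csd(Ssub, (uword)np);
    cube A; mat Sig;
    rowvec fx(nsel), fy(nsel);
    if (whittle_cpp(G, A, Sig)) {
      var_gc_spectrum(A, Sig, bx, by, fsel, nfft, fx, fy);
      Fxy.row(p) = fx; Fyx.row(p) = fy;
    }
    if (time_reversed) {
      cube Gt = G;
      for (uword l = 0; l < G.n_slices; ++l) Gt.slice(l) = G.slice(l).t();
      if (whittle_cpp(Gt, A, Sig)) {
        var_gc_spectrum(A, Sig, bx, by, fsel, nfft, fx, fy);
        Fxy_r.row(p) = fx; Fyx_r.row(p) = fy;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("Fxy") = Fxy, Rcpp::Named("Fyx") = Fyx,
      Rcpp::Named("Fxy_r") = Fxy_r, Rcpp::Named("Fyx_r") = Fyx_r);
}
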