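// Multi-layer bidirectional GRU: forward pass with caches and full
// backpropagation through time. Gate layout follows the common convention
// of stacking reset (r), update (z), and candidate (n) rows:
//   r_t = sigmoid(Wx_r x_t + bx_r + Wh_r h_{t-1} + bh_r)
//   z_t = sigmoid(Wx_z x_t + bx_z + Wh_z h_{t-1} + bh_z)
//   n_t = tanh(Wx_n x_t + bx_n + r_t .* (Wh_n h_{t-1} + bh_n))
//   h_t = (1 - z_t) .* n_t + z_t .* h_{t-1}
// Parameters per direction: Wx (3h x din), Wh (3h x h), bx (3h), bh (3h).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static inline vec sigmoid_vec(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// One direction of one layer. Fills caches needed for backprop.
static mat dir_forward(const mat& X, const mat& Wx, const mat& Wh,
                       const vec& bx, const vec& bh, bool rev,
                       mat& Xp, mat& R, mat& Z, mat& N, mat& Un, mat& Hprev) {
  const arma::uword T = X.n_rows;
  const arma::uword h = Wh.n_cols;
  Xp = X * Wx.t();
  Xp.each_row() += rowvec(bx.t());
  R.set_size(T, h); Z.set_size(T, h); N.set_size(T, h);
  Un.set_size(T, h); Hprev.set_size(T, h);
  mat H(T, h);
  vec hprev(h, arma::fill::zeros);
  for (arma::uword step = 0; step < T; ++step) {
    arma::uword t = rev ? (T - 1 - step) : step;
    vec u = Wh * hprev + bh;
    vec a = Xp.row(t).t();
    vec r = sigmoid_vec(a.subvec(0, h - 1) + u.subvec(0, h - 1));
    vec z = sigmoid_vec(a.subvec(h, 2 * h - 1) + u.subvec(h, 2 * h - 1));
    vec un = u.subvec(2 * h, 3 * h - 1);
    vec n = arma::tanh(a.subvec(2 * h, 3 * h - 1) + r % un);
    vec hcur = (1.0 - z) % n + z % hprev;
    R.row(t) = r.t(); Z.row(t) = z.t(); N.row(t) = n.t();
    Un.row(t) = un.t(); Hprev.row(t) = hprev.t();
    H.row(t) = hcur.t();
    hprev = hcur;
  }
  return H;
}

// Backward for one direction; accumulates parameter grads, returns dX.
static mat dir_backward(const mat& dHout, const mat& X, const mat& Wx,
                        const mat& Wh, const mat& Xp, const mat& R,
                        const mat& Z, const mat& N, const mat& Un,
                        const mat& Hprev, bool rev,
                        mat& dWx, mat& dWh, vec& dbx, vec& dbh) {
  const arma::uword T = X.n_rows;
  const arma::uword h = Wh.n_cols;
  mat dXp(T, 3 * h, arma::fill::zeros);
  vec dh_carry(h, arma::fill::zeros);
  for (arma::uword step = 0; step < T; ++step) {
    // iterate in the reverse of the forward order
    arma::uword t = rev ? step : (T - 1 - step);
    vec dh = dHout.row(t).t() + dh_carry;
    vec r = R.row(t).t(), z = Z.row(t).t(), n = N.row(t).t();
    vec un = Un.row(t).t(), hprev = Hprev.row(t).t();
    vec dn = dh % (1.0 - z);
    vec dz = dh % (hprev - n);
    vec dhp = dh % z;
    vec dpre_n = dn % (1.0 - n % n);
    vec dun = dpre_n % r;
    vec dr = dpre_n % un;
    vec dpre_r = dr % r % (1.0 - r);
    vec dpre_z = dz % z % (1.0 - z);
    vec du(3 * h);
    du.subvec(0, h - 1) = dpre_r;
    du.subvec(h, 2 * h - 1) = dpre_z;
    du.subvec(2 * h, 3 * h - 1) = dun;
    dWh += du * hprev.t();
    dbh += du;
    dhp += Wh.t() * du;
    dXp(t, arma::span(0, h - 1)) = dpre_r.t();
    dXp(t, arma::span(h, 2 * h - 1)) = dpre_z.t();
    dXp(t, arma::span(2 * h, 3 * h - 1)) = dpre_n.t();
    dh_carry = dhp;
  }
  dWx += dXp.t() * X;
  dbx += arma::sum(dXp, 0).t();
  return dXp * Wx;
}

// params: list of layers, each list(fwd = list(Wx, Wh, bx, bh), bwd = ...)
// [[Rcpp::export]]
List cpp_bigru_forward(const arma::mat& X, List params) {
  int L = params.size();
  List caches(L);
  List inputs(L);
  mat cur = X;
  mat H;
  for (int l = 0; l < L; ++l) {
    inputs[l] = cur;
    List layer = params[l];
    List out(2);
    mat Hcat;
    for (int d = 0; d < 2; ++d) {
      List pd = (d == 0) ? List(layer["fwd"]) : List(layer["bwd"]);
      mat Wx = pd["Wx"], Wh = pd["Wh"];
      vec bx = pd["bx"], bh = pd["bh"];
      mat Xp, R, Z, N, Un, Hprev;
      mat Hd = dir_forward(cur, Wx, Wh, bx, bh, d == 1, Xp, R, Z, N, Un, Hprev);
      out[d] = List::create(_["Xp"] = Xp, _["R"] = R, _["Z"] = Z,
                            _["N"] = N, _["Un"] = Un, _["Hprev"] = Hprev);
      Hcat = (d == 0) ? Hd : mat(arma::join_rows(Hcat, Hd));
    }
    caches[l] = out;
    cur = Hcat;
  }
  return List::create(_["H"] = cur, _["caches"] = caches, _["inputs"] = inputs);
}

// [[Rcpp::export]]
List cpp_bigru_backward(const arma::mat& dH, List params, List caches,
                        List inputs) {
  int L = params.size();
  List grads(L);
  mat dcur = dH;
  for (int l = L - 1; l >= 0; --l) {
    List layer = params[l];
    List cache = caches[l];
    mat Xl = as<mat>(inputs[l]);
    List gl(2);
    mat dX(Xl.n_rows, Xl.n_cols, arma::fill::zeros);
    arma::uword h = as<mat>(List(layer["fwd"])["Wh"]).n_cols;
    for (int d = 0; d < 2; ++d) {
      List pd = (d == 0) ? List(layer["fwd"]) : List(layer["bwd"]);
      List cd = cache[d];
      mat Wx = pd["Wx"], Wh = pd["Wh"];
      mat dWx(arma::size(Wx), arma::fill::zeros);
      mat dWh(arma::size(Wh), arma::fill::zeros);
      vec dbx(Wx.n_rows, arma::fill::zeros), dbh(Wx.n_rows, arma::fill::zeros);
      mat dHd = dcur.cols(d * h, (d + 1) * h - 1);
      dX += dir_backward(dHd, Xl, Wx, Wh, cd["Xp"], cd["R"], cd["Z"],
                         cd["N"], cd["Un"], cd["Hprev"], d == 1,
                         dWx, dWh, dbx, dbh);
      gl[d] = List::create(_["Wx"] = dWx, _["Wh"] = dWh,
                           _["bx"] = dbx, _["bh"] = dbh);
    }
    grads[l] = List::create(_["fwd"] = gl[0], _["bwd"] = gl[1]);
    dcur = dX;
  }
  return List::create(_["grads"] = grads, _["dX"] = dcur);
}
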