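#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Extended phase graphs (EPG) simulation of an inversion-prepared,
// gradient-spoiled (FISP-type) transient-state sequence with a variable
// flip-angle train and constant RF phase.
//
// States are stored as (F+k, F-k, Zk), k = 0..kmax, where F-k denotes
// conj(F(-k)). With the RF phase fixed at 90 degrees and an equilibrium
// longitudinal state, all configuration states stay real-valued, so the
// recursion is carried out in real arithmetic; the recorded signal is the
// primary transverse state F+0 immediately after each pulse, decayed by
// exp(-TE/T2).
//
// Per repetition: RF rotation -> echo record -> relaxation over TR ->
// one unit gradient-spoiler shift of the configuration orders.

// [[Rcpp::export]]
NumericMatrix epg_fisp_batch_cpp(NumericVector t1_ms,
                                 NumericVector t2_ms,
                                 NumericVector pd,
                                 NumericVector flip_rad,
                                 double tr_ms,
                                 double te_ms,
                                 double ti_ms,
                                 double inv_flip_rad,
                                 int kmax) {
  const int n = t1_ms.size();
  const int nrep = flip_rad.size();
  if (t2_ms.size() != n || pd.size() != n)
    stop("t1, t2 and pd must have equal length");
  if (kmax < 2) stop("kmax must be >= 2");

  NumericMatrix out(n, nrep);

  // precompute per-repetition rotation coefficients (shared by all tissues)
  std::vector<double> c2(nrep), s2(nrep), sa(nrep), ca(nrep);
  for (int r = 0; r < nrep; ++r) {
    const double a = flip_rad[r];
    const double ch = std::cos(a / 2.0), sh = std::sin(a / 2.0);
    c2[r] = ch * ch;
    s2[r] = sh * sh;
    sa[r] = std::sin(a);
    ca[r] = std::cos(a);
  }
  const double civ = std::cos(inv_flip_rad);
  const double siv = std::sin(inv_flip_rad);
  const double c2iv = std::cos(inv_flip_rad / 2.0) * std::cos(inv_flip_rad / 2.0);
  const double s2iv = std::sin(inv_flip_rad / 2.0) * std::sin(inv_flip_rad / 2.0);

  std::vector<double> fp(kmax + 1), fm(kmax + 1), z(kmax + 1);

  for (int i = 0; i < n; ++i) {
    const double T1 = t1_ms[i], T2 = t2_ms[i], rho = pd[i];
    if (!(T1 > 0.0) || !(T2 > 0.0) || !(rho >= 0.0) ||
        !std::isfinite(T1) || !std::isfinite(T2) || !std::isfinite(rho))
      stop("non-finite or non-positive tissue parameters at index %d", i + 1);

    const double e1 = std::exp(-tr_ms / T1);
    const double e2 = std::exp(-tr_ms / T2);
    const double e1ti = std::exp(-ti_ms / T1);
    const double e2ti = std::exp(-ti_ms / T2);
    const double ete = std::exp(-te_ms / T2);

    std::fill(fp.begin(), fp.end(), 0.0);
    std::fill(fm.begin(), fm.end(), 0.0);
    std::fill(z.begin(), z.end(), 0.0);
    z[0] = 1.0;

    // inversion pulse at t = 0 (only k = 0 is populated)
    {
      const double f0 = fp[0], g0 = fm[0], z0 = z[0];
      fp[0] = c2iv * f0 - s2iv * g0 + siv * z0;
      fm[0] = -s2iv * f0 + c2iv * g0 + siv * z0;
      z[0]  = -0.5 * siv * (f0 + g0) + civ * z0;
    }
    // free relaxation over TI
    fp[0] *= e2ti;
    fm[0] *= e2ti;
    z[0] = 1.0 + (z[0] - 1.0) * e1ti;

    int kact = 0;  // highest populated configuration order
    for (int r = 0; r < nrep; ++r) {
      // RF rotation on all populated orders
      const double cc = c2[r], ss = s2[r], s = sa[r], c = ca[r];
      for (int k = 0; k <= kact; ++k) {
        const double f = fp[k], g = fm[k], zz = z[k];
        fp[k] = cc * f - ss * g + s * zz;
        fm[k] = -ss * f + cc * g + s * zz;
        z[k]  = -0.5 * s * (f + g) + c * zz;
      }
      // echo: F+0 right after the pulse, decayed to TE
      out(i, r) = rho * fp[0] * ete;

      // relaxation over TR
      for (int k = 0; k <= kact; ++k) {
        fp[k] *= e2;
        fm[k] *= e2;
        z[k] *= e1;
      }
      z[0] += (1.0 - e1);

      // unit gradient-spoiler shift: F(k) -> F(k+1)
      int ktop = std::min(kact + 1, kmax);
      for (int k = ktop; k >= 1; --k) fp[k] = fp[k - 1];
      fp[0] = fm[1];  // conj(F(-1)) becomes the new F(0); real states
      for (int k = 0; k < ktop; ++k) fm[k] = fm[k + 1];
      fm[ktop] = 0.0;
      kact = ktop;
    }
  }
  return out;
}
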