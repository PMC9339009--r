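#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Piecewise-linear interpolation on an increasing grid.
// Below the first node returns `lo`, above the last returns `hi`.
static inline double interp_clamped(const std::vector<double>& x,
                                    const std::vector<double>& y,
                                    double xv, double lo, double hi) {
  const int n = (int)x.size();
  if (xv < x[0]) return lo;
  if (xv >= x[n - 1]) return hi;
  int a = 0, b = n - 1;
  while (b - a > 1) {
    int m = (a + b) / 2;
    if (x[m] <= xv) a = m; else b = m;
  }
  double t = (xv - x[a]) / (x[b] - x[a]);
  return y[a] + t * (y[b] - y[a]);
}

static std::vector<double> as_std(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// Stochastic efficacy dynamics of the consolidation model.
//
// Memories arrive at integer times 1..n_mem with initial efficacies A0.
// Between arrivals each efficacy decays by the exact factor exp(-dt/tau)
// and, while above the critical efficacy, receives increments b as an
// inhomogeneous Poisson process with rate lam * F(A/A_c) (thinning with
// per-step probability lam*F*dt).  The interference noise
// Delta^2 = (f/N) * sum A^2 is recomputed from the state each step.
//
// mode 0: fixed-activity neurons, A_c = a_f * Delta.
// mode 1: fixed firing threshold,  A_c = table lookup A_c(Delta); an
//         off-table Delta means no stable retrieval (A_c = +Inf).
//
// Perturbations: additive synaptic white noise with diffusion D inside
// [noise_on, noise_off) adds a saturating variance term to Delta^2
// (integrated exactly per step); dilution of a fraction dil_p of synapses
// from dil_on scales effective efficacies by (1-p) and Delta by sqrt(1-p).
//
// Uses R's RNG stream: results are reproducible under set.seed().
// [[Rcpp::export]]
List sim_core(int n_mem, NumericVector A0, double f, double N_neur,
              double tau, double lam, double b, double dt, double T,
              double a_f, NumericVector basin_x, NumericVector basin_F,
              int mode, NumericVector acmap_delta, NumericVector acmap_ac,
              double noise_D, double noise_on, double noise_off,
              double dil_p, double dil_on,
              double snapshot_dt, double bin_width, double age_max,
              double trunc_tol, double trunc_age) {
  RNGScope scope;
  const std::vector<double> bx = as_std(basin_x), bF = as_std(basin_F);
  const std::vector<double> ax = as_std(acmap_delta), ay = as_std(acmap_ac);

  std::vector<double> A, birth;          // active set
  std::vector<int> id;                   // memory index (0-based) of active entries
  A.reserve(n_mem); birth.reserve(n_mem); id.reserve(n_mem);
  std::vector<double> max_eff(n_mem, 0.0);

  const int n_steps = (int)std::ceil(T / dt);
  const int n_snap = std::max(1, (int)std::floor(T / snapshot_dt));
  const int n_bins = (int)std::ceil(age_max / bin_width);
  IntegerMatrix curve_k(n_snap, n_bins), curve_n(n_snap, n_bins);
  NumericVector snap_t(n_snap), snap_ac(n_snap), snap_delta(n_snap);
  IntegerVector snap_above(n_snap);

  const double dec = std::exp(-dt / tau);
  const double e2 = std::exp(-2.0 * dt / tau);
  // Saturation level of the additive-noise field variance, in the same
  // normalization as Delta^2 = (f/N) sum A^2.
  const double v_sat = f * tau * noise_D * noise_D / (2.0 * N_neur);

  double t = 0.0, v_noise = 0.0, ac_ref = 0.0;
  int next_mem = 1, isnap = 0;
  double next_snap = snapshot_dt;

  for (int s = 0; s < n_steps; ++s) {
    t += dt;

    // 1. exact exponential decay
    const int M = (int)A.size();
    double sumsq = 0.0;
    for (int i = 0; i < M; ++i) { A[i] *= dec; sumsq += A[i] * A[i]; }

    // 2. interference noise (+ additive synaptic noise variance)
    if (t > noise_on && t <= noise_off)
      v_noise = v_noise * e2 + v_sat * (1.0 - e2);
    else
      v_noise *= e2;
    double delta2 = f / N_neur * sumsq + v_noise;
    const double sdil = (t >= dil_on) ? (1.0 - dil_p) : 1.0;
    const double delta_eff = std::sqrt(sdil * delta2);

    // 3. critical efficacy
    double a_c;
    if (mode == 0) {
      a_c = a_f * delta_eff;
    } else {
      a_c = (ax.empty() || delta_eff >= ax.back())
        ? R_PosInf
        : interp_clamped(ax, ay, delta_eff, ay.front(), R_PosInf);
    }
    if (R_finite(a_c) && a_c > 0) ac_ref = a_c;

    // 4. rehearsal draws (Poisson thinning)
    if (delta_eff <= 0.0) {
      // startup: no interference yet, every encoded memory is a full
      // attractor, F -> 1
      for (int i = 0; i < M; ++i)
        if (A[i] > 0 && unif_rand() < lam * dt) {
          A[i] += b;
          if (A[i] > max_eff[id[i]]) max_eff[id[i]] = A[i];
        }
    } else if (R_finite(a_c)) {
      for (int i = 0; i < M; ++i) {
        const double aeff = sdil * A[i];
        if (aeff >= a_c) {
          const double Fv = interp_clamped(bx, bF, aeff / a_c, 0.0, 1.0);
          if (Fv > 0 && unif_rand() < lam * Fv * dt) {
            A[i] += b;
            if (A[i] > max_eff[id[i]]) max_eff[id[i]] = A[i];
          }
        }
      }
    }

    // 5. new memory arrivals (one per unit time)
    while (next_mem <= t && next_mem <= n_mem) {
      A.push_back(A0[next_mem - 1]);
      birth.push_back((double)next_mem);
      id.push_back(next_mem - 1);
      if (A0[next_mem - 1] > max_eff[next_mem - 1])
        max_eff[next_mem - 1] = A0[next_mem - 1];
      ++next_mem;
    }

    // 6. drop long-forgotten memories (negligible Delta contribution)
    if (ac_ref > 0 && (s & 0x3F) == 0) {
      size_t w = 0;
      const double cut = trunc_tol * ac_ref;
      for (size_t i = 0; i < A.size(); ++i) {
        if (!(A[i] < cut && (t - birth[i]) > trunc_age)) {
          A[w] = A[i]; birth[w] = birth[i]; id[w] = id[i]; ++w;
        }
      }
      A.resize(w); birth.resize(w); id.resize(w);
    }

    // 7. snapshot bookkeeping.  The retrieved count per age bin comes from
    // the active set; the bin population is exact (one arrival per unit
    // time), so memories dropped from the active set still count as
    // unretrievable in the denominator.
    if (t >= next_snap && isnap < n_snap) {
      snap_t[isnap] = t;
      snap_ac[isnap] = a_c;
      snap_delta[isnap] = delta_eff;
      int above = 0;
      for (size_t i = 0; i < A.size(); ++i) {
        const double aeff = sdil * A[i];
        const bool ret = R_finite(a_c) && aeff > a_c;
        if (ret) {
          ++above;
          const double age = t - birth[i];
          if (age >= 0 && age < age_max)
            curve_k(isnap, (int)(age / bin_width)) += 1;
        }
      }
      const double l_max = std::min(std::floor(t), (double)n_mem);
      for (int bin = 0; bin < n_bins; ++bin) {
        double hi = std::min(t - bin * bin_width, l_max);
        double lo = std::max(t - (bin + 1) * bin_width, 0.0);
        if (hi > lo)
          curve_n(isnap, bin) = (int)(std::floor(hi) - std::floor(lo));
      }
      snap_above[isnap] = above;
      ++isnap;
      next_snap += snapshot_dt;
    }
  }

  return List::create(
    _["snap_t"] = snap_t, _["snap_ac"] = snap_ac, _["snap_delta"] = snap_delta,
    _["snap_above"] = snap_above,
    _["curve_k"] = curve_k, _["curve_n"] = curve_n,
    _["max_eff"] = max_eff,
    _["final_A"] = NumericVector(A.begin(), A.end()),
    _["final_birth"] = NumericVector(birth.begin(), birth.end()),
    _["final_t"] = t);
}

// Heterogeneous synaptic decay times: each memory's efficacy is tracked per
// decay-rate quantile bin (rates eps, probability masses w).  Rehearsals are
// one point process per memory, shared across bins: an event adds b to every
// bin.  The mean efficacy drives retrieval/rehearsal; Delta^2 uses the
// second moment across bins.
// [[Rcpp::export]]
List sim_core_hetero(int n_mem, double A0, double f, double N_neur,
                     double lam, double b, double dt, double T,
                     double a_f, NumericVector basin_x, NumericVector basin_F,
                     NumericVector eps, NumericVector w,
                     double snapshot_dt, double bin_width, double age_max,
                     double trunc_tol, double trunc_age) {
  RNGScope scope;
  const std::vector<double> bx = as_std(basin_x), bF = as_std(basin_F);
  const int K = eps.size();
  std::vector<double> dec(K), wv = as_std(w);
  for (int k = 0; k < K; ++k) dec[k] = std::exp(-eps[k] * dt);

  std::vector<double> Abin;              // K values per active memory
  std::vector<double> birth, meanA;
  std::vector<int> id;
  std::vector<double> max_eff(n_mem, 0.0);

  const int n_steps = (int)std::ceil(T / dt);
  const int n_snap = std::max(1, (int)std::floor(T / snapshot_dt));
  const int n_bins = (int)std::ceil(age_max / bin_width);
  IntegerMatrix curve_k(n_snap, n_bins), curve_n(n_snap, n_bins);
  NumericVector snap_t(n_snap), snap_ac(n_snap);
  IntegerVector snap_above(n_snap);

  double t = 0.0, ac_ref = 0.0;
  int next_mem = 1, isnap = 0;
  double next_snap = snapshot_dt;

  for (int s = 0; s < n_steps; ++s) {
    t += dt;
    const int M = (int)birth.size();

    double sum2 = 0.0;
    for (int i = 0; i < M; ++i) {
      double m1 = 0.0, m2 = 0.0;
      double* a = &Abin[(size_t)i * K];
      for (int k = 0; k < K; ++k) {
        a[k] *= dec[k];
        m1 += wv[k] * a[k];
        m2 += wv[k] * a[k] * a[k];
      }
      meanA[i] = m1;
      sum2 += m2;
    }
    const double delta = std::sqrt(f / N_neur * sum2);
    const double a_c = a_f * delta;
    if (a_c > 0) ac_ref = a_c;

    if (delta <= 0.0) {
      for (int i = 0; i < M; ++i)
        if (meanA[i] > 0 && unif_rand() < lam * dt) {
          double* a = &Abin[(size_t)i * K];
          double m1 = 0.0;
          for (int k = 0; k < K; ++k) { a[k] += b; m1 += wv[k] * a[k]; }
          meanA[i] = m1;
          if (m1 > max_eff[id[i]]) max_eff[id[i]] = m1;
        }
    } else {
      for (int i = 0; i < M; ++i) {
        if (meanA[i] >= a_c) {
          const double Fv = interp_clamped(bx, bF, meanA[i] / a_c, 0.0, 1.0);
          if (Fv > 0 && unif_rand() < lam * Fv * dt) {
            double* a = &Abin[(size_t)i * K];
            double m1 = 0.0;
            for (int k = 0; k < K; ++k) { a[k] += b; m1 += wv[k] * a[k]; }
            meanA[i] = m1;
            if (m1 > max_eff[id[i]]) max_eff[id[i]] = m1;
          }
        }
      }
    }

    while (next_mem <= t && next_mem <= n_mem) {
      for (int k = 0; k < K; ++k) Abin.push_back(A0);
      birth.push_back((double)next_mem);
      meanA.push_back(A0);
      id.push_back(next_mem - 1);
      if (A0 > max_eff[next_mem - 1]) max_eff[next_mem - 1] = A0;
      ++next_mem;
    }

    if (ac_ref > 0 && (s & 0x3F) == 0) {
      size_t wpos = 0;
      const double cut = trunc_tol * ac_ref;
      for (size_t i = 0; i < birth.size(); ++i) {
        if (!(meanA[i] < cut && (t - birth[i]) > trunc_age)) {
          if (wpos != i) {
            std::copy(&Abin[i * K], &Abin[i * K] + K, &Abin[wpos * K]);
            birth[wpos] = birth[i]; meanA[wpos] = meanA[i]; id[wpos] = id[i];
          }
          ++wpos;
        }
      }
      birth.resize(wpos); meanA.resize(wpos); id.resize(wpos);
      Abin.resize(wpos * K);
    }

    if (t >= next_snap && isnap < n_snap) {
      snap_t[isnap] = t;
      snap_ac[isnap] = a_c;
      int above = 0;
      for (size_t i = 0; i < birth.size(); ++i) {
        const bool ret = meanA[i] > a_c && a_c > 0;
        if (ret) {
          ++above;
          const double age = t - birth[i];
          if (age >= 0 && age < age_max)
            curve_k(isnap, (int)(age / bin_width)) += 1;
        }
      }
      const double l_max = std::min(std::floor(t), (double)n_mem);
      for (int bin = 0; bin < n_bins; ++bin) {
        double hi = std::min(t - bin * bin_width, l_max);
        double lo = std::max(t - (bin + 1) * bin_width, 0.0);
        if (hi > lo)
          curve_n(isnap, bin) = (int)(std::floor(hi) - std::floor(lo));
      }
      snap_above[isnap] = above;
      ++isnap;
      next_snap += snapshot_dt;
    }
  }

  return List::create(
    _["snap_t"] = snap_t, _["snap_ac"] = snap_ac, _["snap_above"] = snap_above,
    _["curve_k"] = curve_k, _["curve_n"] = curve_n,
    _["max_eff"] = max_eff, _["final_meanA"] = NumericVector(meanA.begin(), meanA.end()),
    _["final_birth"] = NumericVector(birth.begin(), birth.end()),
    _["final_t"] = t);
}
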