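#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulation helpers written to match base R's numerics (long-double
// accumulators; mean() applies R's two-pass correction), so the compiled
// engine and the R reference engine can be compared move-for-move.

static double r_sum(const double* x, int n) {
  long double s = 0.0L;
  for (int i = 0; i < n; ++i) s += x[i];
  return (double)s;
}

static double r_mean(const double* x, int n) {
  long double s = 0.0L;
  for (int i = 0; i < n; ++i) s += x[i];
  s /= n;
  long double t = 0.0L;
  for (int i = 0; i < n; ++i) t += (x[i] - s);
  s += t / n;
  return (double)s;
}

// var()/cov()-style moment: simple long-double mean, products in long double
static double r_var(const double* x, const double* y, int n) {
  long double mx = 0.0L, my = 0.0L;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  long double s = 0.0L;
  for (int i = 0; i < n; ++i) s += ((long double)x[i] - mx) * ((long double)y[i] - my);
  return (double)(s / (n - 1));
}

enum CostId { UIQI = 1, RSE = 2, SSIM = 3, MAE = 4, RAE = 5, RMSE = 6,
              RMSLE = 7 };

struct ViewStats {            // per-view constants of the measured sinogram
  double mean, sd, rse_den, rae_den, range, c1, c2, c3;
};

// per-view cost, formula-for-formula the same as the R view_cost()
static double view_cost_cpp(int id, const double* pm, const double* pp,
                            int n, const ViewStats& st,
                            std::vector<double>& buf) {
  switch (id) {
  case MAE: {
    for (int i = 0; i < n; ++i) buf[i] = std::fabs(pm[i] - pp[i]);
    return r_mean(buf.data(), n);
  }
  case RMSE: {
    for (int i = 0; i < n; ++i) { double d = pm[i] - pp[i]; buf[i] = d * d; }
    return std::sqrt(r_mean(buf.data(), n));
  }
  case RMSLE: {
    for (int i = 0; i < n; ++i) {
      double d = std::log1p(pm[i]) - std::log1p(pp[i]);
      buf[i] = d * d;
    }
    return std::sqrt(r_mean(buf.data(), n));
  }
  case RSE: {
    for (int i = 0; i < n; ++i) { double d = pm[i] - pp[i]; buf[i] = d * d; }
    return r_sum(buf.data(), n) / st.rse_den;
  }
  case RAE: {
    for (int i = 0; i < n; ++i) buf[i] = std::fabs(pm[i] - pp[i]);
    return r_sum(buf.data(), n) / st.rae_den;
  }
  case UIQI: {
    double my = r_mean(pp, n);
    double sy = std::sqrt(r_var(pp, pp, n));
    double mx = st.mean, sx = st.sd;
    for (int i = 0; i < n; ++i) buf[i] = (pm[i] - mx) * (pp[i] - my);
    double sxy = r_sum(buf.data(), n) / (n - 1);
    return (sxy / (sx * sy)) * (2.0 * mx * my / (mx * mx + my * my)) *
           (2.0 * sx * sy / (sx * sx + sy * sy));
  }
  case SSIM: {
    double my = r_mean(pp, n);
    double sy = std::sqrt(r_var(pp, pp, n));
    double mx = st.mean, sx = st.sd;
    for (int i = 0; i < n; ++i) buf[i] = (pm[i] - mx) * (pp[i] - my);
    double sxy = r_sum(buf.data(), n) / (n - 1);
    double l = (2.0 * mx * my + st.c1) / (mx * mx + my * my + st.c1);
    double cc = (2.0 * sx * sy + st.c2) / (sx * sx + sy * sy + st.c2);
    double s = (sxy + st.c3) / (sx * sy + st.c3);
    return l * cc * s;
  }
  }
  return NA_REAL;
}

static double aggregate_cost_cpp(int id, bool error_type,
                                 const NumericMatrix& pm,
                                 const std::vector<double>& pp,
                                 int nb, int nv,
                                 const std::vector<ViewStats>& stats,
                                 std::vector<double>& buf,
                                 std::vector<double>& per_view) {
  for (int m = 0; m < nv; ++m)
    per_view[m] = view_cost_cpp(id, &pm(0, m), &pp[(size_t)m * nb], nb,
                                stats[m], buf);
  double mu = r_mean(per_view.data(), nv);
  return error_type ? mu : 1.0 - mu;
}

// [[Rcpp::export]]
List sa_engine(NumericMatrix pm, IntegerMatrix bin_idx, int side, int nb,
               int levels, double t0, double tn, int n_iter, int slab,
               int cost_id, bool error_type, double stop_tol,
               IntegerMatrix f0) {
  const int nv = pm.ncol();
  const int npix = side * side;

  // per-view constants of the measured data
  std::vector<ViewStats> stats(nv);
  for (int m = 0; m < nv; ++m) {
    const double* col = &pm(0, m);
    ViewStats st;
    st.mean = r_mean(col, nb);
    st.sd = std::sqrt(r_var(col, col, nb));
    std::vector<double> tmp(nb);
    for (int i = 0; i < nb; ++i) {
      double d = st.mean - col[i];
      tmp[i] = d * d;
    }
    st.rse_den = r_sum(tmp.data(), nb);
    for (int i = 0; i < nb; ++i) tmp[i] = std::fabs(st.mean - col[i]);
    st.rae_den = r_sum(tmp.data(), nb);
    double lo = col[0], hi = col[0];
    for (int i = 1; i < nb; ++i) {
      if (col[i] < lo) lo = col[i];
      if (col[i] > hi) hi = col[i];
    }
    st.range = hi - lo;
    st.c1 = (0.01 * st.range) * (0.01 * st.range);
    st.c2 = (0.03 * st.range) * (0.03 * st.range);
    st.c3 = st.c2 / 2.0;
    stats[m] = st;
  }

  // current estimate (integer levels) and its postulated sinogram
  std::vector<int> f(f0.begin(), f0.end());
  std::vector<double> pp((size_t)nb * nv, 0.0);
  {
    // same accumulation as base rowsum(): long double per bin
    std::vector<long double> acc((size_t)nb * nv, 0.0L);
    for (int m = 0; m < nv; ++m)
      for (int p = 0; p < npix; ++p)
        acc[(size_t)m * nb + (bin_idx(p, m) - 1)] +=
          (double)f[p] / (double)(levels - 1);
    for (size_t i = 0; i < pp.size(); ++i) pp[i] = (double)acc[i];
  }

  std::vector<double> buf(nb), per_view(nv);
  double cost = aggregate_cost_cpp(cost_id, error_type, pm, pp, nb, nv,
                                   stats, buf, per_view);
  std::vector<int> best_f(f);
  double best_cost = cost;

  const int n_slabs = (n_iter + slab - 1) / slab;
  NumericMatrix trace(n_slabs + 1, 5);
  trace(0, 0) = 0; trace(0, 1) = (t0 - tn) / std::cosh(0.0) + tn;
  trace(0, 2) = cost; trace(0, 3) = best_cost; trace(0, 4) = NA_REAL;
  int row = 1;

  std::vector<int> touched_bin(nv);
  std::vector<double> old_val(nv);

  long accepted_total = 0, accepted_slab = 0;
  int k = 0;
  bool stop_early = false;
  double prev_best = best_cost;

  while (k < n_iter && !stop_early) {
    int ks = (k / slab) * slab;
    double temp = (t0 - tn) / std::cosh(10.0 * (double)ks / (double)n_iter)
                  + tn;

    double u1 = unif_rand();
    int idx0 = (int)std::floor(u1 * npix);
    if (idx0 > npix - 1) idx0 = npix - 1;
    double u2 = unif_rand();
    int level = (int)std::floor(u2 * levels);
    if (level > levels - 1) level = levels - 1;

    double newval = (double)level / (double)(levels - 1);
    double oldval = (double)f[idx0] / (double)(levels - 1);
    double d = newval - oldval;

    double cost2;
    if (d == 0.0) {
      cost2 = cost;
    } else {
      for (int m = 0; m < nv; ++m) {
        int b = bin_idx(idx0, m) - 1;
        touched_bin[m] = b;
        old_val[m] = pp[(size_t)m * nb + b];
        pp[(size_t)m * nb + b] = old_val[m] + d;
      }
      cost2 = aggregate_cost_cpp(cost_id, error_type, pm, pp, nb, nv,
                                 stats, buf, per_view);
    }
    double dc = cost2 - cost;

    bool accept;
    if (dc < 0.0) accept = true;
    else accept = unif_rand() < std::exp(-dc / temp);

    if (accept) {
      f[idx0] = level;
      cost = cost2;
      ++accepted_total; ++accepted_slab;
      if (cost < best_cost) { best_cost = cost; best_f = f; }
    } else if (d != 0.0) {
      for (int m = 0; m < nv; ++m)
        pp[(size_t)m * nb + touched_bin[m]] = old_val[m];
    }

    ++k;
    if (k % slab == 0 || k == n_iter) {
      trace(row, 0) = k; trace(row, 1) = temp; trace(row, 2) = cost;
      trace(row, 3) = best_cost;
      trace(row, 4) = (double)accepted_slab / (double)slab;
      ++row;
      if (stop_tol > 0 && error_type &&
          (prev_best - best_cost) < stop_tol * best_cost)
        stop_early = true;
      prev_best = best_cost;
      accepted_slab = 0;
    }
  }

  IntegerMatrix f_out(side, side), best_out(side, side);
  std::copy(f.begin(), f.end(), f_out.begin());
  std::copy(best_f.begin(), best_f.end(), best_out.begin());
  NumericMatrix pp_out(nb, nv);
  std::copy(pp.begin(), pp.end(), pp_out.begin());

  return List::create(
    _["f"] = f_out, _["best_f"] = best_out, _["pp"] = pp_out,
    _["cost"] = cost, _["best_cost"] = best_cost,
    _["trace"] = trace(Range(0, row - 1), Range(0, 4)),
    _["iterations"] = k, _["accepted"] = (int)accepted_total);
}
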