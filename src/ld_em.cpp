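#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-locus EM on a 3x3 genotype table n[g1][g2] (dosages 0/1/2).
// Haplotype frequencies f[0]=p_AB, f[1]=p_Ab, f[2]=p_aB, f[3]=p_ab, where
// "A"/"B" are the counted alleles at the two loci. Only the double
// heterozygote cell has latent phase; its E-step split is
// p_AB*p_ab / (p_AB*p_ab + p_Ab*p_aB).

static double loglik_table(const double n[3][3], const double f[4]) {
  // cell probabilities under random union of gametes
  double P[3][3];
  P[2][2] = f[0] * f[0];
  P[2][1] = 2.0 * f[0] * f[1];
  P[2][0] = f[1] * f[1];
  P[1][2] = 2.0 * f[0] * f[2];
  P[1][1] = 2.0 * (f[0] * f[3] + f[1] * f[2]);
  P[1][0] = 2.0 * f[1] * f[3];
  P[0][2] = f[2] * f[2];
  P[0][1] = 2.0 * f[2] * f[3];
  P[0][0] = f[3] * f[3];
  double ll = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      if (n[a][b] > 0.0)
        ll += n[a][b] * std::log(std::max(P[a][b], 1e-300));
  return ll;
}

struct EMResult {
  double f[4];
  double loglik;
  bool converged;
  int n_iter;
  int status;     // 0 ok, 1 monomorphic
  double n_total; // individuals in the table
};

static void em_iterate(const double n[3][3], double f[4], double N2,
                       double tol, int max_iter, bool &converged,
                       int &n_iter, std::vector<double> *trace) {
  // fixed (phase-unambiguous) haplotype contributions
  double base_AB = 2.0 * n[2][2] + n[2][1] + n[1][2];
  double base_Ab = 2.0 * n[2][0] + n[2][1] + n[1][0];
  double base_aB = 2.0 * n[0][2] + n[0][1] + n[1][2];
  double base_ab = 2.0 * n[0][0] + n[0][1] + n[1][0];
  double ndh = n[1][1];
  converged = false;
  n_iter = 0;
  for (int it = 0; it < max_iter; ++it) {
    double coup = f[0] * f[3];
    double rep = f[1] * f[2];
    double w = (coup + rep > 0.0) ? coup / (coup + rep) : 0.5;
    double nf[4] = {
      (base_AB + w * ndh) / N2,
      (base_Ab + (1.0 - w) * ndh) / N2,
      (base_aB + (1.0 - w) * ndh) / N2,
      (base_ab + w * ndh) / N2
    };
    double delta = 0.0;
    for (int k = 0; k < 4; ++k) {
      delta = std::max(delta, std::fabs(nf[k] - f[k]));
      f[k] = nf[k];
    }
    ++n_iter;
    if (trace) trace->push_back(loglik_table(n, f));
    if (delta < tol) { converged = true; break; }
  }
}

static EMResult em_fit(const double n[3][3], double tol, int max_iter) {
  EMResult res;
  double N = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) N += n[a][b];
  res.n_total = N;
  double N2 = 2.0 * N;
  double nA = 0.0, nB = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) { nA += a * n[a][b]; nB += b * n[a][b]; }
  double pA = nA / N2, pB = nB / N2;
  if (pA <= 0.0 || pA >= 1.0 || pB <= 0.0 || pB >= 1.0) {
    res.status = 1;
    res.f[0] = pA * pB; res.f[1] = pA * (1 - pB);
    res.f[2] = (1 - pA) * pB; res.f[3] = (1 - pA) * (1 - pB);
    res.loglik = NA_REAL; res.converged = true; res.n_iter = 0;
    return res;
  }
  res.status = 0;

  // deterministic multi-start: LE, and D offset to half its +/- bounds
  double dmax_pos = std::min(pA * (1 - pB), (1 - pA) * pB);
  double dmax_neg = std::min(pA * pB, (1 - pA) * (1 - pB));
  double offsets[3] = {0.0, 0.5 * dmax_pos, -0.5 * dmax_neg};
  double best_f[4] = {0, 0, 0, 0};
  double best_ll = R_NegInf, best_absD = R_PosInf;
  bool best_conv = false;
  int best_iter = 0;
  for (int s = 0; s < 3; ++s) {
    double D0 = offsets[s];
    double f[4] = {pA * pB + D0, pA * (1 - pB) - D0,
                   (1 - pA) * pB - D0, (1 - pA) * (1 - pB) + D0};
    bool conv; int nit;
    em_iterate(n, f, N2, tol, max_iter, conv, nit, nullptr);
    double ll = loglik_table(n, f);
    double absD = std::fabs(f[0] * f[3] - f[1] * f[2]);
    bool better = (ll > best_ll + 1e-8) ||
                  (ll > best_ll - 1e-8 && absD < best_absD - 1e-12);
    if (s == 0 || better) {
      for (int k = 0; k < 4; ++k) best_f[k] = f[k];
      best_ll = ll; best_absD = absD; best_conv = conv; best_iter = nit;
    }
  }
  for (int k = 0; k < 4; ++k) res.f[k] = best_f[k];
  res.loglik = best_ll;
  res.converged = best_conv;
  res.n_iter = best_iter;
  return res;
}

static void as_array(const NumericMatrix &counts, double n[3][3]) {
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) n[a][b] = counts(a, b);
}

// [[Rcpp::export]]
List em_haplotype_cpp(NumericMatrix counts, double tol, int max_iter) {
  double n[3][3];
  as_array(counts, n);
  EMResult r = em_fit(n, tol, max_iter);
  return List::create(
    _["p_AB"] = r.f[0], _["p_Ab"] = r.f[1],
    _["p_aB"] = r.f[2], _["p_ab"] = r.f[3],
    _["loglik"] = r.loglik, _["converged"] = r.converged,
    _["n_iter"] = r.n_iter, _["status"] = r.status,
    _["n_alleles"] = (int)(2.0 * r.n_total)
  );
}

// [[Rcpp::export]]
NumericVector em_trace_cpp(NumericMatrix counts, double tol, int max_iter) {
  double n[3][3];
  as_array(counts, n);
  double N = 0.0, nA = 0.0, nB = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      N += n[a][b]; nA += a * n[a][b]; nB += b * n[a][b];
    }
  double pA = nA / (2.0 * N), pB = nB / (2.0 * N);
  double f[4] = {pA * pB, pA * (1 - pB), (1 - pA) * pB,
                 (1 - pA) * (1 - pB)};
  std::vector<double> trace;
  bool conv; int nit;
  em_iterate(n, f, 2.0 * N, tol, max_iter, conv, nit, &trace);
  return wrap(trace);
}

// Batch scan: all within-chromosome pairs with 1 <= distance <= max_dist.
// geno: samples x loci integer matrix, NA = missing. Loci must be sorted by
// (chrom, pos). Returns parallel vectors incl. a status code per pair
// (0 ok, 1 monomorphic in the pairwise-complete subset, 2 fewer than two
// pairwise-complete individuals).
// [[Rcpp::export]]
List ld_scan_cpp(IntegerMatrix geno, CharacterVector chrom,
                 IntegerVector pos, double max_dist,
                 double tol, int max_iter) {
  int ns = geno.nrow(), m = geno.ncol();
  std::vector<int> out_i, out_j, out_n, out_status;
  std::vector<double> out_D, out_Dp, out_r2;
  std::vector<int> out_conv;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      if (chrom[j] != chrom[i]) break;
      double d = (double)pos[j] - (double)pos[i];
      if (d > max_dist) break;
      if (d < 1.0) continue;
      double n[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      double tot = 0.0;
      for (int s = 0; s < ns; ++s) {
        int a = geno(s, i), b = geno(s, j);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        n[a][b] += 1.0;
        tot += 1.0;
      }
      out_i.push_back(i + 1);
      out_j.push_back(j + 1);
      if (tot < 2.0) {
        out_status.push_back(2);
        out_n.push_back((int)(2 * tot));
        out_D.push_back(NA_REAL); out_Dp.push_back(NA_REAL);
        out_r2.push_back(NA_REAL); out_conv.push_back(0);
        continue;
      }
      EMResult r = em_fit(n, tol, max_iter);
      out_status.push_back(r.status);
      out_n.push_back((int)(2.0 * r.n_total));
      if (r.status != 0) {
        out_D.push_back(NA_REAL); out_Dp.push_back(NA_REAL);
        out_r2.push_back(NA_REAL); out_conv.push_back(0);
        continue;
      }
      double pA = r.f[0] + r.f[1], pB = r.f[0] + r.f[2];
      double D = r.f[0] * r.f[3] - r.f[1] * r.f[2];
      double dmax = (D > 0.0) ? std::min(pA * (1 - pB), (1 - pA) * pB)
                              : std::min(pA * pB, (1 - pA) * (1 - pB));
      double Dp = (D == 0.0) ? 0.0 : D / dmax;
      double r2 = D * D / (pA * (1 - pA) * pB * (1 - pB));
      out_D.push_back(D); out_Dp.push_back(Dp); out_r2.push_back(r2);
      out_conv.push_back(r.converged ? 1 : 0);
    }
  }
  return List::create(
    _["i"] = wrap(out_i), _["j"] = wrap(out_j),
    _["n_alleles"] = wrap(out_n), _["status"] = wrap(out_status),
    _["D"] = wrap(out_D), _["Dprime"] = wrap(out_Dp),
    _["r2"] = wrap(out_r2),
    _["converged"] = LogicalVector(out_conv.begin(), out_conv.end())
  );
}

// Two-locus Wright-Fisher: multinomial resampling of 2Ne gametes per
// generation, recombination at fraction c applied to expected gamete
// frequencies. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
List wf_r2_cpp(int Ne, double c, int n_generations, int n_sample,
               int n_replicates, double tol, int max_iter) {
  int n_gam = 2 * Ne;
  NumericVector out(n_replicates);
  int n_regen = 0;
  int guard = 0;
  for (int rep = 0; rep < n_replicates; ++rep) {
    bool ok = false;
    double h[4];
    while (!ok) {
      if (++guard > 1000000) stop("Wright-Fisher regeneration limit reached");
      h[0] = h[1] = h[2] = h[3] = 0.25;
      bool fixed = false;
      int counts[4];
      for (int g = 0; g < n_generations; ++g) {
        double Dh = h[0] * h[3] - h[1] * h[2];
        double p[4] = {h[0] - c * Dh, h[1] + c * Dh,
                       h[2] + c * Dh, h[3] - c * Dh};
        for (int k = 0; k < 4; ++k) p[k] = std::max(p[k], 0.0);
        double s = p[0] + p[1] + p[2] + p[3];
        for (int k = 0; k < 4; ++k) p[k] /= s;
        rmultinom(n_gam, p, 4, counts);
        for (int k = 0; k < 4; ++k) h[k] = (double)counts[k] / n_gam;
        double pA = h[0] + h[1], pB = h[0] + h[2];
        if (pA <= 0.0 || pA >= 1.0 || pB <= 0.0 || pB >= 1.0) {
          fixed = true;
          break;
        }
      }
      if (fixed) { ++n_regen; continue; }
      // draw a diploid sample and estimate raw r2 by EM, as in the pipeline
      int gam[4];
      rmultinom(2 * n_sample, h, 4, gam);
      // pair gametes at random: expand, shuffle, pair consecutive
      std::vector<int> pool_v;
      pool_v.reserve(2 * n_sample);
      for (int k = 0; k < 4; ++k)
        for (int t = 0; t < gam[k]; ++t) pool_v.push_back(k);
      for (int t = (int)pool_v.size() - 1; t > 0; --t) {
        int u = (int)std::floor(unif_rand() * (t + 1));
        std::swap(pool_v[t], pool_v[u]);
      }
      double n[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int s = 0; s < n_sample; ++s) {
        int h1 = pool_v[2 * s], h2 = pool_v[2 * s + 1];
        int a = (h1 < 2 ? 1 : 0) + (h2 < 2 ? 1 : 0);     // copies of A
        int b = (h1 % 2 == 0 ? 1 : 0) + (h2 % 2 == 0 ? 1 : 0); // copies of B
        n[a][b] += 1.0;
      }
      EMResult r = em_fit(n, tol, max_iter);
      if (r.status != 0) { ++n_regen; continue; } // sample monomorphic
      double pA = r.f[0] + r.f[1], pB = r.f[0] + r.f[2];
      double D = r.f[0] * r.f[3] - r.f[1] * r.f[2];
      out[rep] = D * D / (pA * (1 - pA) * pB * (1 - pB));
      ok = true;
    }
  }
  return List::create(_["r2"] = out, _["n_regenerated"] = n_regen);
}
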