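#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Build one generation of gametes for a Wright-Fisher population.
//
// H   : parent haplotypes (rows) x segregating sites (columns), 0/1.
// par : G x 2 matrix of 0-based row indices into H; row g holds the two
//       haplotypes of the parent diploid that produces gamete g.
// pos : per-column physical positions in bp (need not be sorted).
// rho_bp, L : per-bp per-generation crossover rate and sequence length;
//       crossover count per gamete is Poisson(rho_bp * L), breakpoints
//       uniform on (0, L).
// n_new : total number of new all-zero columns appended this generation
//       (the union of new mutations across all populations, so every
//       population keeps an identical global site registry).
// mut_gamete / mut_col : for the mutations arising in THIS population,
//       the 0-based receiving gamete and the 0-based offset of its column
//       within the appended block.
//
// All random draws use R's RNG in a fixed order (Poisson count, leading
// haplotype, breakpoints; gamete by gamete), so results are reproducible
// under set.seed() across platforms.
// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& H, const IntegerMatrix& par,
                               const NumericVector& pos, double rho_bp, double L,
                               int n_new, const IntegerVector& mut_gamete,
                               const IntegerVector& mut_col) {
  const int G = par.nrow();
  const int S = H.ncol();
  const int K = mut_gamete.size();
  const int P = H.nrow();
  IntegerMatrix out(G, S + n_new);

  // draw all recombination randomness first, gamete by gamete, in a fixed
  // order (Poisson count, leading haplotype, breakpoints)
  std::vector<int> hapA(G), hapB(G), start(G), off(G + 1, 0);
  std::vector<double> brk;
  for (int g = 0; g < G; ++g) {
    hapA[g] = par(g, 0);
    hapB[g] = par(g, 1);
    const int k = (int) R::rpois(rho_bp * L);
    start[g] = (unif_rand() < 0.5) ? 0 : 1;
    for (int i = 0; i < k; ++i) brk.push_back(unif_rand() * L);
    std::sort(brk.begin() + off[g], brk.end());
    off[g + 1] = (int) brk.size();
  }

  // fill column by column: the destination is written sequentially and the
  // source stays within one (cache-resident) column of H
  const int* Hp = INTEGER(H);
  int* op = INTEGER(out);
  for (int j = 0; j < S; ++j) {
    const int* hcol = Hp + (size_t) j * P;
    int* ocol = op + (size_t) j * G;
    const double p = pos[j];
    for (int g = 0; g < G; ++g) {
      const int a = hcol[hapA[g]];
      const int b = hcol[hapB[g]];
      if (a == b) { ocol[g] = a; continue; }
      int nb = 0;
      for (int i = off[g]; i < off[g + 1]; ++i) nb += (brk[i] < p);
      ocol[g] = ((start[g] + nb) & 1) ? b : a;
    }
  }
  for (int i = 0; i < K; ++i) out(mut_gamete[i], S + mut_col[i]) = 1;
  return out;
}

// Stepwise EHH refinement away from a core site.
//
// H     : haplotypes x sites, 0/1 (NA allowed; treated as a third allele
//         that breaks haplotype identity).
// rows  : 0-based haplotype rows entering the statistic.
// grp0  : initial partition labels (0-based); a single shared label for a
//         carrier-class curve, a core-allele split for pooled curves.
// core  : 0-based core column; dir = +1 (right) or -1 (left).
// cutoff: stop after recording the first value < cutoff; pass a negative
//         cutoff to disable early stopping (forced-span scans).
// max_steps : cap on the number of sites examined.
//
// Returns EHH after incorporating each successive site. A value of exactly
// zero always ends the scan (all later values are zero by monotonicity).
// [[Rcpp::export]]
NumericVector cpp_ehh_steps(const IntegerMatrix& H, const IntegerVector& rows,
                            const IntegerVector& grp0, int core, int dir,
                            double cutoff, int max_steps) {
  const int m = rows.size();
  std::vector<double> out;
  if (m < 2 || max_steps <= 0) return NumericVector(0);
  const int S = H.ncol();
  const double denom = (double) m * (m - 1);
  std::vector<long long> grp(m);
  for (int i = 0; i < m; ++i) grp[i] = grp0[i];
  std::unordered_map<long long, int> relab;
  std::vector<int> cnt;
  int j = core;
  for (int step = 1; step <= max_steps; ++step) {
    j += dir;
    if (j < 0 || j >= S) break;
    relab.clear();
    cnt.clear();
    int next = 0;
    for (int i = 0; i < m; ++i) {
      int a = H(rows[i], j);
      if (a == NA_INTEGER) a = 2;
      const long long key = grp[i] * 4 + a;
      auto it = relab.find(key);
      int id;
      if (it == relab.end()) {
        id = next++;
        relab.emplace(key, id);
        cnt.push_back(0);
      } else {
        id = it->second;
      }
      grp[i] = id;
      cnt[id]++;
    }
    double hom = 0.0;
    for (int id = 0; id < next; ++id) hom += (double) cnt[id] * (cnt[id] - 1);
    const double e = hom / denom;
    out.push_back(e);
    if (cutoff >= 0.0 && e < cutoff) break;
    if (e == 0.0) break;
  }
  return wrap(out);
}
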