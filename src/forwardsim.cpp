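// Forward-in-time simulation of a randomly mating population on a single
// chromosome. Recombination follows a binomial map: the crossover count per
// meiosis is Binomial(max_xo, xo_prob) with breakpoints uniform on the
// chromosome (interference through the cap). Mutation is a recurrent
// two-allele flip per locus per gamete. Discrete non-overlapping generations,
// constant size, monoecious random union of gametes (selfing allowed).

#include <Rcpp.h>
using namespace Rcpp;

typedef std::vector<unsigned char> HapVec;  // (2N) x L row-major haplotypes

// form one gamete from parent haplotypes h0/h1 (each length L)
static void make_gamete(const unsigned char* h0, const unsigned char* h1,
                        const std::vector<double>& pos, double chrom_len,
                        int max_xo, double xo_prob, double mut_rate,
                        unsigned char* out) {
  const int L = (int)pos.size();
  int n_xo = (int)R::rbinom((double)max_xo, xo_prob);
  if (n_xo == 0) {
    const unsigned char* src = (R::unif_rand() < 0.5) ? h0 : h1;
    std::copy(src, src + L, out);
  } else {
    std::vector<double> bp(n_xo);
    for (int j = 0; j < n_xo; ++j) bp[j] = R::unif_rand() * chrom_len;
    std::sort(bp.begin(), bp.end());
    int cur = (R::unif_rand() < 0.5) ? 0 : 1;
    int j = 0;
    for (int l = 0; l < L; ++l) {
      while (j < n_xo && bp[j] <= pos[l]) {
        cur = 1 - cur;
        ++j;
      }
      out[l] = (cur == 0) ? h0[l] : h1[l];
    }
  }
  // mutations: Binomial(L, mu) flips at loci drawn without replacement
  int n_mut = (int)R::rbinom((double)L, mut_rate);
  if (n_mut > 0) {
    std::vector<int> idx;
    idx.reserve(n_mut);
    while ((int)idx.size() < n_mut) {
      int l = (int)std::floor(R::unif_rand() * L);
      if (l >= L) l = L - 1;
      if (std::find(idx.begin(), idx.end(), l) == idx.end()) idx.push_back(l);
    }
    for (int l : idx) out[l] = 1 - out[l];
  }
}

// [[Rcpp::export]]
IntegerMatrix forward_sim_cpp(int n_ind, int n_gen, NumericVector positions,
                              double chrom_len, double mut_rate, int max_xo,
                              double xo_prob) {
  const int L = positions.size();
  std::vector<double> pos(positions.begin(), positions.end());
  HapVec cur((size_t)2 * n_ind * L), nxt((size_t)2 * n_ind * L);
  // base population: allele 1 with frequency 0.5, haplotypes independent
  for (size_t i = 0; i < cur.size(); ++i)
    cur[i] = (R::unif_rand() < 0.5) ? 1 : 0;
  for (int g = 0; g < n_gen; ++g) {
    for (int i = 0; i < n_ind; ++i) {
      int sire = (int)std::floor(R::unif_rand() * n_ind);
      int dam = (int)std::floor(R::unif_rand() * n_ind);
      if (sire >= n_ind) sire = n_ind - 1;
      if (dam >= n_ind) dam = n_ind - 1;
      make_gamete(&cur[(size_t)(2 * sire) * L], &cur[(size_t)(2 * sire + 1) * L],
                  pos, chrom_len, max_xo, xo_prob, mut_rate,
                  &nxt[(size_t)(2 * i) * L]);
      make_gamete(&cur[(size_t)(2 * dam) * L], &cur[(size_t)(2 * dam + 1) * L],
                  pos, chrom_len, max_xo, xo_prob, mut_rate,
                  &nxt[(size_t)(2 * i + 1) * L]);
    }
    cur.swap(nxt);
    if ((g & 15) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix haps(2 * n_ind, L);
  for (int i = 0; i < 2 * n_ind; ++i)
    for (int l = 0; l < L; ++l) haps(i, l) = cur[(size_t)i * L + l];
  return haps;
}

// produce one offspring per (sire, dam) pair from stored haplotypes
// [[Rcpp::export]]
IntegerMatrix mate_pairs_cpp(IntegerMatrix haps, IntegerVector sire,
                             IntegerVector dam, NumericVector positions,
                             double chrom_len, double mut_rate, int max_xo,
                             double xo_prob) {
  const int L = positions.size();
  const int n_off = sire.size();
  std::vector<double> pos(positions.begin(), positions.end());
  const int n_par_hap = haps.nrow();
  HapVec par((size_t)n_par_hap * L);
  for (int i = 0; i < n_par_hap; ++i)
    for (int l = 0; l < L; ++l) par[(size_t)i * L + l] = (unsigned char)haps(i, l);
  IntegerMatrix off(2 * n_off, L);
  std::vector<unsigned char> gam(L);
  for (int i = 0; i < n_off; ++i) {
    int s = sire[i], d = dam[i];  // 0-based individual indices
    make_gamete(&par[(size_t)(2 * s) * L], &par[(size_t)(2 * s + 1) * L], pos,
                chrom_len, max_xo, xo_prob, mut_rate, gam.data());
    for (int l = 0; l < L; ++l) off(2 * i, l) = gam[l];
    make_gamete(&par[(size_t)(2 * d) * L], &par[(size_t)(2 * d + 1) * L], pos,
                chrom_len, max_xo, xo_prob, mut_rate, gam.data());
    for (int l = 0; l < L; ++l) off(2 * i + 1, l) = gam[l];
  }
  return off;
}
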