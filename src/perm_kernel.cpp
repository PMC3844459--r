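#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// splitmix64: small, fast, reproducible across platforms. One generator per
// permutation, seeded by that permutation's own seed, so results are
// invariant to how permutations are partitioned across workers.
static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static void fill_signs(uint64_t seed, int n_fam, int n_chrom,
                       std::vector<signed char> &signs) {
  // chromosome-major order: signs[c * n_fam + f]
  uint64_t state = seed;
  for (int c = 0; c < n_chrom; ++c) {
    for (int f = 0; f < n_fam; ++f) {
      signs[(size_t)c * n_fam + f] =
          (splitmix64_next(state) & 1ULL) ? (signed char)1 : (signed char)-1;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix sign_matrix_cpp(double seed, int n_fam, int n_chrom) {
  std::vector<signed char> signs((size_t)n_fam * n_chrom);
  fill_signs((uint64_t)seed, n_fam, n_chrom, signs);
  IntegerMatrix out(n_fam, n_chrom);
  for (int c = 0; c < n_chrom; ++c)
    for (int f = 0; f < n_fam; ++f)
      out(f, c) = signs[(size_t)c * n_fam + f];
  return out;
}

// Enrichment scores for every pathway under K sign-flip permutations.
//
// d:          families x SNPs matrix of PDT summands (informative SNPs only)
// chrom:      0-based chromosome index per SNP (one sign per family per chrom)
// n_chrom:    number of chromosome blocks
// denom:      sqrt(sum d^2) per SNP, all > 0
// gene_snps:  per gene, 0-based indices of its SNP columns; genes are in
//             gene-symbol ascending order (the rank tie-break order)
// pathways:   per pathway, 0-based indices into the gene list
// w:          gene-score weight exponent
// squared:    gene score = z^2 if true, |z| otherwise
// perm_seeds: one seed per permutation
//
// Returns pathways x K matrix of permuted ES values.
// [[Rcpp::export]]
NumericMatrix perm_es_kernel(const NumericMatrix &d, const IntegerVector &chrom,
                             int n_chrom, const NumericVector &denom,
                             const List &gene_snps, const List &pathways,
                             double w, bool squared,
                             const NumericVector &perm_seeds) {
  const int n_fam = d.nrow();
  const int n_snp = d.ncol();
  const int n_gene = gene_snps.size();
  const int n_path = pathways.size();
  const int K = perm_seeds.size();

  std::vector<std::vector<int>> gsnp(n_gene);
  for (int g = 0; g < n_gene; ++g)
    gsnp[g] = as<std::vector<int>>(gene_snps[g]);

  std::vector<std::vector<int>> pgenes(n_path);
  std::vector<std::vector<char>> member(n_path, std::vector<char>(n_gene, 0));
  for (int p = 0; p < n_path; ++p) {
    pgenes[p] = as<std::vector<int>>(pathways[p]);
    for (int g : pgenes[p]) member[p][g] = 1;
  }

  NumericMatrix es(n_path, K);
  std::vector<signed char> signs((size_t)n_fam * n_chrom);
  std::vector<double> zz(n_snp), r(n_gene), rw(n_gene);
  std::vector<int> rank_idx(n_gene);

  for (int k = 0; k < K; ++k) {
    fill_signs((uint64_t)perm_seeds[k], n_fam, n_chrom, signs);

    for (int s = 0; s < n_snp; ++s) {
      const double *col = &d(0, s);
      const signed char *sg = &signs[(size_t)chrom[s] * n_fam];
      double acc = 0.0;
      for (int f = 0; f < n_fam; ++f) acc += col[f] * sg[f];
      const double z = acc / denom[s];
      zz[s] = squared ? z * z : std::fabs(z);
    }

    for (int g = 0; g < n_gene; ++g) {
      double best = 0.0;
      for (int s : gsnp[g])
        if (zz[s] > best) best = zz[s];
      r[g] = best;
      rw[g] = (w == 1.0) ? best : std::pow(best, w);
    }

    // rank genes by score descending; stable sort keeps symbol-order ties
    for (int g = 0; g < n_gene; ++g) rank_idx[g] = g;
    std::stable_sort(rank_idx.begin(), rank_idx.end(),
                     [&](int a, int b) { return r[a] > r[b]; });

    for (int p = 0; p < n_path; ++p) {
      double n_r = 0.0;
      for (int g : pgenes[p]) n_r += rw[g];
      const int n_h = (int)pgenes[p].size();
      const double miss = 1.0 / (double)(n_gene - n_h);
      const double hit_scale = (n_r > 0.0) ? 1.0 / n_r : 0.0;
      double run = 0.0, best = R_NegInf;
      const std::vector<char> &mb = member[p];
      for (int i = 0; i < n_gene; ++i) {
        const int g = rank_idx[i];
        run += mb[g] ? rw[g] * hit_scale : -miss;
        if (run > best) best = run;
      }
      es(p, k) = best;
    }
  }
  return es;
}
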