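#include <Rcpp.h>
using namespace Rcpp;

// Tetraploid meiosis: per column, the 4 homologs form two bivalents
// according to `pairing` (1: 12|34, 2: 13|24, 3: 14|23, sampled in R), each
// bivalent yields one recombinant product, and the gamete is the pair of
// products (returned as two loci x n matrices).
// [[Rcpp::export]]
List tetra_gametes_cpp(NumericMatrix h1, NumericMatrix h2, NumericMatrix h3,
                       NumericMatrix h4, NumericVector cadj,
                       IntegerVector pairing) {
  const int nj = cadj.size(), n = pairing.size();
  NumericMatrix g1(nj, n), g2(nj, n);
  const double* H[4] = {h1.begin(), h2.begin(), h3.begin(), h4.begin()};
  const int rep[4] = {h1.ncol() == 1, h2.ncol() == 1, h3.ncol() == 1,
                      h4.ncol() == 1};
  // bivalent membership per pairing case (0-based homolog ids)
  const int A[3] = {0, 0, 0}, B[3] = {1, 2, 3};
  const int C[3] = {2, 1, 1}, D[3] = {3, 3, 2};
  const double* c = cadj.begin();
  double* p1 = g1.begin();
  double* p2 = g2.begin();
  for (int col = 0; col < n; ++col) {
    const int pc = pairing[col] - 1;
    const double* a = H[A[pc]] + (rep[A[pc]] ? 0 : col) * nj;
    const double* b = H[B[pc]] + (rep[B[pc]] ? 0 : col) * nj;
    const double* d = H[C[pc]] + (rep[C[pc]] ? 0 : col) * nj;
    const double* e = H[D[pc]] + (rep[D[pc]] ? 0 : col) * nj;
    int o1 = 0, o2 = 0;
    for (int j = 0; j < nj; ++j) {
      if (unif_rand() < c[j]) o1 = 1 - o1;
      if (unif_rand() < c[j]) o2 = 1 - o2;
      p1[j] = o1 ? b[j] : a[j];
      p2[j] = o2 ? e[j] : d[j];
    }
    p1 += nj; p2 += nj;
  }
  return List::create(g1, g2);
}

// One meiosis product per output column from a pair of haplotypes.
//
// h1, h2: loci x n matrices (single-column matrices are recycled across
// columns, for a fixed parent). cadj: per-interval origin-switch
// probability -- the Haldane recombination fraction between consecutive
// loci, 0.5 at every chromosome start so each chromosome begins on a random
// homolog. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix meiosis_gametes_cpp(NumericMatrix h1, NumericMatrix h2,
                                  NumericVector cadj, int n) {
  const int nj = cadj.size();
  const bool rep1 = h1.ncol() == 1, rep2 = h2.ncol() == 1;
  NumericMatrix out(nj, n);
  const double* c = cadj.begin();
  const double* b1 = h1.begin();
  const double* b2 = h2.begin();
  double* po = out.begin();
  for (int col = 0; col < n; ++col) {
    const double* a = b1 + (rep1 ? 0 : col) * nj;
    const double* b = b2 + (rep2 ? 0 : col) * nj;
    int o = 0;
    for (int j = 0; j < nj; ++j) {
      if (unif_rand() < c[j]) o = 1 - o;
      po[j] = o ? b[j] : a[j];
    }
    po += nj;
  }
  return out;
}
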