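#include <Rcpp.h>
using namespace Rcpp;

// Draw one recombinant gamete per offspring from the designated parent.
//
// hap1/hap2: parental haplotypes (individuals x loci, 0/1 alleles).
// parent:    1-based parent row index, one per gamete to produce.
// cswitch:   per-locus switch probability between the two parental
//            haplotypes when moving from the previous locus. The first
//            locus of every chromosome carries 0.5, which both starts the
//            walk from a fair coin and makes chromosomes independent; the
//            remaining entries are Haldane recombination fractions of the
//            inter-locus map distance, so crossover counts per interval
//            are parity-equivalent to a Poisson process on the genetic map.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix wf_gametes_cpp(const IntegerMatrix& hap1,
                             const IntegerMatrix& hap2,
                             const IntegerVector& parent,
                             const NumericVector& cswitch) {
  const int n = parent.size();
  const int L = hap1.ncol();
  if (hap2.ncol() != L || cswitch.size() != L)
    stop("haplotype and switch-probability dimensions disagree");
  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i) {
    const int p = parent[i] - 1;
    if (p < 0 || p >= hap1.nrow()) stop("parent index out of range");
    int cur = 0;
    for (int l = 0; l < L; ++l) {
      if (unif_rand() < cswitch[l]) cur = 1 - cur;
      out(i, l) = cur ? hap1(p, l) : hap2(p, l);
    }
  }
  return out;
}
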