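#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of the forward simulator. All kernels consume R's RNG stream
// (unif_rand), so results are governed entirely by set.seed() on the R side.
// R's Mersenne-Twister uniforms carry 32 random bits; the fair-coin and
// Bernoulli kernels below slice those bits instead of spending one uniform
// per draw.

namespace {

inline int bv_select(int a, int b, unsigned int bit) {
  return bit ? a : b;
}

inline unsigned int rng32() {
  return (unsigned int)(unif_rand() * 4294967296.0);
}

struct BitPool {
  unsigned int cache = 0;
  int nbits = 0;
  inline int bit() {
    if (nbits == 0) {
      cache = rng32();
      nbits = 32;
    }
    int b = cache & 1u;
    cache >>= 1;
    --nbits;
    return b;
  }
};

} // namespace

// Draw an n x m haplotype matrix; entry (i, j) ~ Bernoulli(freq[j]).
// An 8-bit threshold decides all but the boundary bucket (probability
// 2^-8), which is refined with a full uniform, so the draw is exact.
// [[Rcpp::export]]
IntegerMatrix draw_haplotypes_cpp(int n, NumericVector freq) {
  int m = freq.size();
  IntegerMatrix H = no_init_matrix(n, m);
  for (int j = 0; j < m; ++j) {
    double p = freq[j];
    if (p <= 0.0 || p >= 1.0) stop("frequencies must lie strictly in (0,1)");
    unsigned int thr = (unsigned int)(p * 256.0);
    double frac = p * 256.0 - thr;
    int *col = &H(0, j);
    int i = 0;
    while (i < n) {
      unsigned int u = rng32();
      int lim = i + 4 < n ? i + 4 : n;
      for (; i < lim; ++i) {
        unsigned int v = u & 0xFFu;
        u >>= 8;
        if (v < thr) col[i] = 1;
        else if (v > thr) col[i] = 0;
        else col[i] = (unif_rand() < frac) ? 1 : 0;
      }
    }
  }
  return H;
}

// One meiosis per row: for every SNP pick one of the parent's two haplotype
// alleles with probability 1/2 as transmitted; the other is nontransmitted.
// [[Rcpp::export]]
List transmit_cpp(IntegerMatrix h1, IntegerMatrix h2) {
  int n = h1.nrow(), m = h1.ncol();
  if (h2.nrow() != n || h2.ncol() != m)
    stop("haplotype matrices must have identical dimensions");
  IntegerMatrix tr = no_init_matrix(n, m), nt = no_init_matrix(n, m);
  BitPool pool;
  for (int j = 0; j < m; ++j) {
    const int *a = &h1(0, j), *b = &h2(0, j);
    int *t = &tr(0, j), *u = &nt(0, j);
    for (int i = 0; i < n; ++i) {
      if (pool.bit()) { t[i] = a[i]; u[i] = b[i]; }
      else            { t[i] = b[i]; u[i] = a[i]; }
    }
  }
  return List::create(_["transmitted"] = tr, _["nontransmitted"] = nt);
}

// Row sums of (h1 + h2) over a 1-based column subset: the unweighted
// allele-count score, computed without materializing the genotype matrix.
// [[Rcpp::export]]
NumericVector score_sums_cpp(IntegerMatrix h1, IntegerMatrix h2,
                             IntegerVector cols) {
  int n = h1.nrow();
  NumericVector out(n);
  for (int k = 0; k < cols.size(); ++k) {
    int j = cols[k] - 1;
    if (j < 0 || j >= h1.ncol()) stop("column index out of range");
    const int *a = &h1(0, j), *b = &h2(0, j);
    for (int i = 0; i < n; ++i) out[i] += a[i] + b[i];
  }
  return out;
}

// Mate couples: children of all slots in one call. Row i of output block k
// (rows k*n .. k*n+n-1) is child slot k of couple i; hap1 = maternal
// transmitted, hap2 = paternal transmitted. Bit consumption is block-wise
// per parent (mother first), column-major within a block. Nontransmitted
// haplotypes are not materialized: parent genotype minus transmitted.
// [[Rcpp::export]]
List mate_cpp(IntegerMatrix mh1, IntegerMatrix mh2, IntegerVector wife,
              IntegerMatrix fh1, IntegerMatrix fh2, IntegerVector husband,
              int n_off) {
  int n = wife.size(), m = mh1.ncol();
  if (husband.size() != n) stop("wife and husband index lengths differ");
  if (fh1.ncol() != m) stop("parent panels differ in SNP count");
  if (n_off < 1 || n_off > 2) stop("n_off must be 1 or 2");
  IntegerMatrix oh1 = no_init_matrix(n_off * n, m),
                oh2 = no_init_matrix(n_off * n, m);
  for (int parent = 0; parent < 2; ++parent) {
    const IntegerVector &rows = parent == 0 ? wife : husband;
    const IntegerMatrix &p1 = parent == 0 ? mh1 : fh1;
    const IntegerMatrix &p2 = parent == 0 ? mh2 : fh2;
    IntegerMatrix &tr = parent == 0 ? oh1 : oh2;
    int nr = p1.nrow();
    for (int i = 0; i < n; ++i)
      if (rows[i] < 1 || rows[i] > nr) stop("couple index out of range");
    const int *rp = &rows[0];
    for (int j = 0; j < m; ++j) {
      const int *a = &p1(0, j), *b = &p2(0, j);
      int *t1 = &tr(0, j);
      if (n_off == 2) {
        int *t2 = t1 + n;
        int i = 0;
        while (i < n) {
          unsigned int u = rng32();
          int lim = i + 16 < n ? i + 16 : n;
          for (; i < lim; ++i) {
            int r = rp[i] - 1;
            int av = a[r], bv = b[r], d = av - bv;
            t1[i] = bv + (int)(u & 1u) * d;
            u >>= 1;
            t2[i] = bv + (int)(u & 1u) * d;
            u >>= 1;
          }
        }
      } else {
        int i = 0;
        while (i < n) {
          unsigned int u = rng32();
          int lim = i + 32 < n ? i + 32 : n;
          for (; i < lim; ++i) {
            int r = rp[i] - 1;
            t1[i] = bv_select(a[r], b[r], u & 1u);
            u >>= 1;
          }
        }
      }
    }
  }
  return List::create(_["hap1"] = oh1, _["hap2"] = oh2);
}

// Genotype (h1 + h2) for a 1-based row subset, as an integer matrix.
// [[Rcpp::export]]
IntegerMatrix genotype_rows_cpp(IntegerMatrix h1, IntegerMatrix h2,
                                IntegerVector rows) {
  int n = rows.size(), m = h1.ncol();
  IntegerMatrix G = no_init_matrix(n, m);
  for (int j = 0; j < m; ++j) {
    const int *a = &h1(0, j), *b = &h2(0, j);
    int *g = &G(0, j);
    for (int i = 0; i < n; ++i) {
      int r = rows[i] - 1;
      if (r < 0 || r >= h1.nrow()) stop("row index out of range");
      g[i] = a[r] + b[r];
    }
  }
  return G;
}

#if defined(__GLIBC__)
#include <malloc.h>
#endif

// The simulator allocates many multi-megabyte genotype matrices per
// replicate; with glibc's default mmap threshold each one is mapped and
// unmapped, paying page-fault and zeroing costs every time. Raising the
// thresholds lets the heap reuse those blocks across replicates.
// [[Rcpp::export]]
void tune_allocator_cpp() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// Assemble all trio matrices in one pass: offspring genotype, optionally
// parent genotypes, transmitted and nontransmitted haplotypes for the
// analyzed child (1-based offspring rows row_of, parent rows wife/husband).
// [[Rcpp::export]]
List trio_matrices_cpp(IntegerMatrix oh1, IntegerMatrix oh2,
                       IntegerMatrix ph1, IntegerMatrix ph2,
                       IntegerVector row_of, IntegerVector wife,
                       IntegerVector husband, bool transmitted, bool parents) {
  int n = row_of.size(), m = oh1.ncol();
  if (wife.size() != n || husband.size() != n) stop("index lengths differ");
  IntegerMatrix g_o = no_init_matrix(n, m);
  IntegerMatrix g_m, g_f, nt_m, nt_f, t_m, t_f;
  if (parents) {
    g_m = no_init_matrix(n, m); g_f = no_init_matrix(n, m);
    nt_m = no_init_matrix(n, m); nt_f = no_init_matrix(n, m);
  }
  if (transmitted) { t_m = no_init_matrix(n, m); t_f = no_init_matrix(n, m); }
  for (int i = 0; i < n; ++i) {
    if (row_of[i] < 1 || row_of[i] > oh1.nrow()) stop("offspring row out of range");
    if (wife[i] < 1 || wife[i] > ph1.nrow() ||
        husband[i] < 1 || husband[i] > ph1.nrow()) stop("parent row out of range");
  }
  for (int j = 0; j < m; ++j) {
    const int *o1 = &oh1(0, j), *o2 = &oh2(0, j);
    const int *p1 = &ph1(0, j), *p2 = &ph2(0, j);
    int *go = &g_o(0, j);
    int *gm = parents ? &g_m(0, j) : (int *)0;
    int *gf = parents ? &g_f(0, j) : (int *)0;
    int *um = parents ? &nt_m(0, j) : (int *)0;
    int *uf = parents ? &nt_f(0, j) : (int *)0;
    int *tm = transmitted ? &t_m(0, j) : (int *)0;
    int *tf = transmitted ? &t_f(0, j) : (int *)0;
    for (int i = 0; i < n; ++i) {
      int ro = row_of[i] - 1;
      int a = o1[ro], b = o2[ro];
      if (tm) { tm[i] = a; tf[i] = b; }
      go[i] = a + b;
      if (gm) {
        int rw = wife[i] - 1, rh = husband[i] - 1;
        int gmv = p1[rw] + p2[rw], gfv = p1[rh] + p2[rh];
        gm[i] = gmv; gf[i] = gfv;
        um[i] = gmv - a; uf[i] = gfv - b;
      }
    }
  }
  List out = List::create(_["g_o"] = g_o);
  if (parents) {
    out["g_m"] = g_m; out["g_f"] = g_f;
    out["nt_m"] = nt_m; out["nt_f"] = nt_f;
  }
  if (transmitted) { out["t_m"] = t_m; out["t_f"] = t_f; }
  return out;
}
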