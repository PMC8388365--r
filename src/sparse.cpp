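// Gabor dictionary construction, GA atom search and the OMP loop.
// These are the hot paths of the sparse-decomposition denoiser; everything
// else in the package stays in R. Atoms have compact (Gaussian) support, so
// inner products only run over the stored support window; repeated GA
// fitness evaluations of the same gene are memoized per search.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// gene ranges for frame length N (power of two): j in 1..log2(N),
// 0 <= p < N*2^(1-j), 0 <= k < 2^(j+1), 0 <= i <= 12
struct GeneGrid {
  int N, J;
  std::vector<int> p_count, k_count;
  std::vector<long> offset;  // column offset of (j, 0, 0, 0)
  long total;
  explicit GeneGrid(int N_) : N(N_) {
    J = 0;
    while ((1 << (J + 1)) <= N) ++J;  // log2(N)
    p_count.resize(J + 1);
    k_count.resize(J + 1);
    offset.resize(J + 1);
    long off = 0;
    for (int j = 1; j <= J; ++j) {
      p_count[j] = (N << 1) >> j;  // N * 2^(1-j)
      k_count[j] = 1 << (j + 1);
      offset[j] = off;
      off += (long)p_count[j] * k_count[j] * 13L;
    }
    total = off;
  }
  long index(int j, int p, int k, int i) const {
    return offset[j] + (((long)p * k_count[j] + k) * 13L + i);
  }
};

// unnormalized atom; returns squared norm
static double fill_atom(double* a, int N, int j, int p, int k, int i) {
  double s = (double)(1 << j);
  double mu = p * s / 2.0;
  double v = k * PI / s;
  double w = i * PI / 6.0;
  double inv_sqrt_s = 1.0 / std::sqrt(s);
  double nrm2 = 0.0;
  for (int t = 0; t < N; ++t) {
    double tau = (t - mu) / s;
    double val = inv_sqrt_s * std::exp(-PI * tau * tau) * std::cos(v * t + w);
    a[t] = val;
    nrm2 += val * val;
  }
  return nrm2;
}

// view of a prebuilt dictionary passed down from R
struct Dict {
  const double* atoms;
  const int* sup_start;  // 0-based first sample of the support window
  const int* sup_end;    // 0-based last sample (inclusive)
  int N;
  long D;
  explicit Dict(const List& dict) {
    NumericMatrix a = dict["atoms"];
    IntegerVector ss = dict["sup_start"], se = dict["sup_end"];
    atoms = REAL(a);
    sup_start = INTEGER(ss);
    sup_end = INTEGER(se);
    N = a.nrow();
    D = a.ncol();
  }
  double fitness(long col, const double* r) const {
    const double* c = atoms + col * (long)N;
    double dot = 0.0;
    for (int t = sup_start[col]; t <= sup_end[col]; ++t) dot += c[t] * r[t];
    return std::fabs(dot);
  }
};

// [[Rcpp::export]]
List build_gabor_dictionary_cpp(int N) {
  GeneGrid grid(N);
  NumericMatrix atoms(N, (int)grid.total);
  IntegerMatrix genes((int)grid.total, 4);
  IntegerVector sup_start((int)grid.total), sup_end((int)grid.total);
  LogicalVector valid((int)grid.total);
  std::vector<double> buf(N);
  long col = 0;
  for (int j = 1; j <= grid.J; ++j) {
    for (int p = 0; p < grid.p_count[j]; ++p) {
      for (int k = 0; k < grid.k_count[j]; ++k) {
        for (int i = 0; i <= 12; ++i, ++col) {
          double nrm2 = fill_atom(buf.data(), N, j, p, k, i);
          genes(col, 0) = j; genes(col, 1) = p;
          genes(col, 2) = k; genes(col, 3) = i;
          int lo = 0, hi = N - 1;
          if (nrm2 > 1e-20) {
            double inv = 1.0 / std::sqrt(nrm2);
            double* dst = &atoms(0, col);
            for (int t = 0; t < N; ++t) dst[t] = buf[t] * inv;
            while (lo < N - 1 && std::fabs(dst[lo]) < 1e-18) ++lo;
            while (hi > lo && std::fabs(dst[hi]) < 1e-18) --hi;
            valid[col] = true;
          } else {
            valid[col] = false;  // degenerate gene: atom identically ~0
            hi = lo;
          }
          sup_start[col] = lo;
          sup_end[col] = hi;
        }
      }
    }
  }
  return List::create(_["atoms"] = atoms, _["genes"] = genes,
                      _["valid"] = valid, _["sup_start"] = sup_start,
                      _["sup_end"] = sup_end, _["n_scales"] = grid.J);
}

struct Chrom { int j, p, k, i; double fit; };

static void clamp_chrom(Chrom& c, const GeneGrid& g) {
  if (c.p >= g.p_count[c.j]) c.p = g.p_count[c.j] - 1;
  if (c.k >= g.k_count[c.j]) c.k = g.k_count[c.j] - 1;
}

static int runif_int(int n) {  // uniform on 0..n-1 using R's RNG
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

static Chrom random_chrom(const GeneGrid& g) {
  Chrom c;
  c.j = 1 + runif_int(g.J);
  c.p = runif_int(g.p_count[c.j]);
  c.k = runif_int(g.k_count[c.j]);
  c.i = runif_int(13);
  c.fit = -1.0;
  return c;
}

// GA search for the atom with maximal |<residual, atom>|.
// Integer-coded chromosome (j,p,k,i); tournament selection (size 2),
// single-point crossover, per-gene uniform mutation, elitism; best-ever kept.
// Two refinements keep the fixed evaluation budget effective on the highly
// multimodal fitness surface: when the best fitness stagnates for three
// generations, all non-elite individuals are reseeded uniformly (restart),
// and the best-ever individual is finally polished by hill climbing over its
// (p +/- 2, k +/- 2, all phases) neighbourhood.
static Chrom ga_search(const double* r, const Dict& dict,
                       const GeneGrid& grid, int pop_size, int generations,
                       double pc, double pm, int elitism) {
  const int stag_limit = 3;
  std::vector<Chrom> pop(pop_size);
  for (int m = 0; m < pop_size; ++m) pop[m] = random_chrom(grid);
  std::unordered_map<long, double> memo;
  memo.reserve(4 * pop_size);
  Chrom best; best.fit = -1.0;
  int stag = 0;
  for (int gen = 0; gen < generations; ++gen) {
    double gen_best_before = best.fit;
    for (int m = 0; m < pop_size; ++m) {
      if (pop[m].fit < 0) {
        long idx = grid.index(pop[m].j, pop[m].p, pop[m].k, pop[m].i);
        auto it = memo.find(idx);
        if (it != memo.end()) {
          pop[m].fit = it->second;
        } else {
          pop[m].fit = dict.fitness(idx, r);
          memo.emplace(idx, pop[m].fit);
        }
      }
      if (pop[m].fit > best.fit) best = pop[m];
    }
    if (best.fit > gen_best_before * (1.0 + 1e-12)) stag = 0; else ++stag;
    if (gen == generations - 1) break;
    if (stag >= stag_limit) {
      std::sort(pop.begin(), pop.end(),
                [](const Chrom& a, const Chrom& b) { return a.fit > b.fit; });
      for (int m = elitism; m < pop_size; ++m) pop[m] = random_chrom(grid);
      stag = 0;
      continue;
    }
    std::sort(pop.begin(), pop.end(),
              [](const Chrom& a, const Chrom& b) { return a.fit > b.fit; });
    std::vector<Chrom> next;
    next.reserve(pop_size);
    for (int e = 0; e < elitism && e < pop_size; ++e) next.push_back(pop[e]);
    while ((int)next.size() < pop_size) {
      // tournament selection, size 2
      const Chrom& p1a = pop[runif_int(pop_size)];
      const Chrom& p1b = pop[runif_int(pop_size)];
      const Chrom& p2a = pop[runif_int(pop_size)];
      const Chrom& p2b = pop[runif_int(pop_size)];
      Chrom c1 = (p1a.fit >= p1b.fit) ? p1a : p1b;
      Chrom c2 = (p2a.fit >= p2b.fit) ? p2a : p2b;
      if (unif_rand() < pc) {  // single-point crossover on (j,p,k,i)
        int cut = 1 + runif_int(3);
        if (cut <= 1) std::swap(c1.p, c2.p);
        if (cut <= 2) std::swap(c1.k, c2.k);
        std::swap(c1.i, c2.i);
        c1.fit = c2.fit = -1.0;
      }
      Chrom kids[2] = {c1, c2};
      for (int q = 0; q < 2 && (int)next.size() < pop_size; ++q) {
        Chrom c = kids[q];
        if (unif_rand() < pm) { c.j = 1 + runif_int(grid.J); c.fit = -1.0; }
        if (unif_rand() < pm) { c.p = runif_int(grid.p_count[c.j]); c.fit = -1.0; }
        if (unif_rand() < pm) { c.k = runif_int(grid.k_count[c.j]); c.fit = -1.0; }
        if (unif_rand() < pm) { c.i = runif_int(13); c.fit = -1.0; }
        clamp_chrom(c, grid);
        next.push_back(c);
      }
    }
    pop.swap(next);
  }
  // memetic polish: hill-climb the best-ever gene to its local optimum
  bool improved = true;
  while (improved) {
    improved = false;
    int j = best.j;
    for (int dp = -2; dp <= 2; ++dp) {
      int p = best.p + dp;
      if (p < 0 || p >= grid.p_count[j]) continue;
      for (int dk = -2; dk <= 2; ++dk) {
        int k = best.k + dk;
        if (k < 0 || k >= grid.k_count[j]) continue;
        for (int i = 0; i <= 12; ++i) {
          long idx = grid.index(j, p, k, i);
          double f;
          auto it = memo.find(idx);
          if (it != memo.end()) {
            f = it->second;
          } else {
            f = dict.fitness(idx, r);
            memo.emplace(idx, f);
          }
          if (f > best.fit * (1.0 + 1e-12)) {
            best.j = j; best.p = p; best.k = k; best.i = i; best.fit = f;
            improved = true;
          }
        }
      }
    }
  }
  return best;
}

static long exhaustive_best(const double* r, const Dict& dict, double* fit_out) {
  long best_idx = 0;
  double best_fit = -1.0;
  for (long c = 0; c < dict.D; ++c) {
    double f = dict.fitness(c, r);
    if (f > best_fit * (1.0 + 1e-12) && f > best_fit + 1e-15) {
      best_fit = f;
      best_idx = c;
    }
  }
  *fit_out = best_fit;
  return best_idx;
}

// [[Rcpp::export]]
List ga_select_cpp(NumericVector residual, List dictionary, int pop_size,
                   int generations, double pc, double pm, int elitism) {
  Dict dict(dictionary);
  GeneGrid grid(dict.N);
  Chrom best = ga_search(REAL(residual), dict, grid, pop_size, generations,
                         pc, pm, elitism);
  long idx = grid.index(best.j, best.p, best.k, best.i);
  return List::create(
      _["gene"] = IntegerVector::create(best.j, best.p, best.k, best.i),
      _["fitness"] = best.fit, _["index"] = (double)(idx + 1));
}

// [[Rcpp::export]]
List exhaustive_select_cpp(NumericVector residual, List dictionary) {
  Dict dict(dictionary);
  double fit = 0.0;
  long idx = exhaustive_best(REAL(residual), dict, &fit);
  return List::create(_["fitness"] = fit, _["index"] = (double)(idx + 1));
}

// [[Rcpp::export]]
List omp_decompose_cpp(NumericVector frame, List dictionary, int n_atoms,
                       bool use_ga, int pop_size, int generations, double pc,
                       double pm, int elitism) {
  Dict dict(dictionary);
  int N = dict.N;
  GeneGrid grid(N);
  arma::vec f(REAL(frame), N);
  arma::vec resid = f;
  std::vector<long> sel;
  arma::mat A(N, 0);
  arma::vec coef;
  for (int m = 0; m < n_atoms; ++m) {
    long idx;
    if (use_ga) {
      Chrom best = ga_search(resid.memptr(), dict, grid, pop_size,
                             generations, pc, pm, elitism);
      idx = grid.index(best.j, best.p, best.k, best.i);
    } else {
      double fit = 0.0;
      idx = exhaustive_best(resid.memptr(), dict, &fit);
    }
    if (std::find(sel.begin(), sel.end(), idx) != sel.end()) continue;  // duplicate
    arma::vec a(dict.atoms + idx * (long)N, N);
    if (arma::norm(a) < 1e-12) continue;  // degenerate atom, skip
    sel.push_back(idx);
    A.insert_cols(A.n_cols, a);
    coef = arma::solve(A, f);             // orthogonal (least-squares) update
    resid = f - A * coef;
  }
  NumericVector approx(N), residual(N), coefficients(sel.size());
  arma::vec ap = sel.empty() ? arma::vec(N, arma::fill::zeros)
                             : arma::vec(A * coef);
  for (int t = 0; t < N; ++t) { approx[t] = ap[t]; residual[t] = f[t] - ap[t]; }
  IntegerMatrix genes((int)sel.size(), 4);
  for (size_t q = 0; q < sel.size(); ++q) {
    // invert the lexicographic column index back to (j,p,k,i)
    long idx = sel[q];
    int j = 1;
    while (j < grid.J && idx >= grid.offset[j + 1]) ++j;
    long rem = idx - grid.offset[j];
    int i = (int)(rem % 13L); rem /= 13L;
    int k = (int)(rem % grid.k_count[j]);
    int p = (int)(rem / grid.k_count[j]);
    genes(q, 0) = j; genes(q, 1) = p; genes(q, 2) = k; genes(q, 3) = i;
    coefficients[q] = coef[q];
  }
  return List::create(_["genes"] = genes, _["coefficients"] = coefficients,
                      _["approx"] = approx, _["residual"] = residual);
}
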