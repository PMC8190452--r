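#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Individual-based core of the colony-population simulator.
//
// Layout of a haploid network (length 4k): queen survival ages 1..k,
// queen fecundity, worker survival, worker fecundity. Diploid genomes are
// two such vectors; traits are logistic(allelic sum), fecundity scaled by m.
//
// All randomness goes through R's RNG (unif_rand / norm_rand / R::rpois),
// so a set.seed() in R fully determines a replicate.

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Dip {
  std::vector<double> a, b;
};

struct Worker {
  int age;
  Dip g;
};

struct Colony {
  bool alive = false;
  int queen_age = 0;
  Dip queen;
  std::vector<double> sperm;   // stored mate gamete (single mating)
  std::vector<Worker> workers;
  std::vector<Dip> eggs_cur;   // diploid eggs laid this step
  std::vector<Dip> eggs_hatch; // diploid eggs laid last step (hatch this step)
  double z = 0.0;              // queen foraging fraction used this step
};

// Sample an index proportional to non-negative weights (1-based on return to
// R). This exact routine drives egg-weighted requeening in the simulator.
static int sample_weighted(const std::vector<double>& w) {
  double tot = 0.0;
  for (double x : w) tot += x;
  if (!(tot > 0.0)) stop("weighted sampling requires a positive total weight");
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u < acc) return static_cast<int>(i);
  }
  return static_cast<int>(w.size()) - 1; // guard against rounding at u ~ tot
}

// [[Rcpp::export]]
int sample_weighted_index_cpp(NumericVector weights) {
  std::vector<double> w(weights.begin(), weights.end());
  for (double x : w)
    if (x < 0 || !R_finite(x)) stop("weights must be finite and non-negative");
  return sample_weighted(w) + 1;
}

struct MutCtx {
  double mu, b;
  int n;                        // 4k
  const double* root;           // n x n, column-major; Sigma = root root^T
  std::vector<double> zbuf;
};

static void maybe_mutate(std::vector<double>& g, MutCtx& ctx) {
  if (ctx.mu <= 0.0 || unif_rand() >= ctx.mu) return;
  const int n = ctx.n;
  for (int i = 0; i < n; ++i) ctx.zbuf[i] = norm_rand();
  // delta = b + root %*% z, accumulated column-wise
  std::vector<double> delta(n, ctx.b);
  for (int j = 0; j < n; ++j) {
    const double zj = ctx.zbuf[j];
    if (zj == 0.0) continue;
    const double* col = ctx.root + (size_t)j * n;
    for (int i = 0; i < n; ++i) delta[i] += col[i] * zj;
  }
  for (int i = 0; i < n; ++i) g[i] += delta[i];
}

static std::vector<double> gamete(const Dip& g, bool recombine, int n) {
  if (!recombine) return (unif_rand() < 0.5) ? g.a : g.b;
  std::vector<double> out(n);
  for (int i = 0; i < n; ++i) out[i] = (unif_rand() < 0.5) ? g.a[i] : g.b[i];
  return out;
}

// [[Rcpp::export]]
List run_sim_cpp(int N, int T, int k, double h_ext, double mu, double m,
                 double init_value, double b, NumericMatrix root,
                 bool recombine, int checkpoint_every, bool check_invariants) {
  if (N < 2) stop("need at least 2 colonies");
  if (k < 1) stop("need at least 1 age class");
  if (h_ext < 0 || h_ext > 1) stop("h_ext must be in [0, 1]");
  const int n = 4 * k;
  if (root.nrow() != n || root.ncol() != n)
    stop("covariance root must be 4k x 4k");

  MutCtx ctx{mu, b, n, REAL(root), std::vector<double>(n)};
  const int qs = 0, qf = k, ws = 2 * k, wf = 3 * k;

  std::vector<Colony> col(N);
  {
    std::vector<double> founder(n, init_value);
    for (int c = 0; c < N; ++c) {
      col[c].alive = true;
      col[c].queen_age = 1;
      col[c].queen.a = founder;
      col[c].queen.b = founder;
      col[c].sperm = founder;
    }
  }

  std::vector<std::vector<double>> male_pool;
  long requeen_events = 0, requeen_fallback = 0;
  int status = 0; // 0 completed, 1 extinct, 2 no males at requeening
  int steps_done = 0;

  // checkpoint buffer: step, n_queens, n_workers, then 4k mean trait values
  std::vector<std::vector<double>> ts;
  auto record = [&](int t) {
    std::vector<double> row(3 + n, NA_REAL);
    row[0] = t;
    int nq = 0; long nw = 0;
    std::vector<double> qacc(2 * k, 0.0), wacc(2 * k, 0.0);
    for (const Colony& c : col) {
      if (!c.alive) continue;
      ++nq;
      for (int a = 0; a < k; ++a) {
        qacc[a] += logistic(c.queen.a[qs + a] + c.queen.b[qs + a]);
        qacc[k + a] += m * logistic(c.queen.a[qf + a] + c.queen.b[qf + a]);
      }
      for (const Worker& wk : c.workers) {
        ++nw;
        for (int a = 0; a < k; ++a) {
          wacc[a] += logistic(wk.g.a[ws + a] + wk.g.b[ws + a]);
          wacc[k + a] += m * logistic(wk.g.a[wf + a] + wk.g.b[wf + a]);
        }
      }
    }
    row[1] = nq;
    row[2] = (double)nw;
    if (nq > 0)
      for (int j = 0; j < 2 * k; ++j) row[3 + j] = qacc[j] / nq;
    if (nw > 0)
      for (int j = 0; j < 2 * k; ++j) row[3 + 2 * k + j] = wacc[j] / nw;
    ts.push_back(std::move(row));
  };

  record(0);

  for (int t = 1; t <= T; ++t) {
    if (t % 2048 == 0) Rcpp::checkUserInterrupt();
    male_pool.clear(); // males mature and die within one step

    // (1) reproduction
    for (Colony& c : col) {
      if (!c.alive) continue;
      const int a = c.queen_age - 1;
      const double fa = m * logistic(c.queen.a[qf + a] + c.queen.b[qf + a]);
      const double w = (double)c.workers.size();
      double z = 1.0 - (1.0 + w) / (1.0 + fa);
      if (z < 0.0) z = 0.0;
      c.z = z;
      const double E = fa * (1.0 - z);
      const double R = z + w;
      const double F = (E + R > 0.0) ? E * R / (E + R) : 0.0;
      const int n_off = (F > 0.0) ? (int)R::rpois(F) : 0;
      for (int o = 0; o < n_off; ++o) {
        Dip egg;
        egg.a = gamete(c.queen, recombine, n);
        maybe_mutate(egg.a, ctx);
        egg.b = c.sperm;
        maybe_mutate(egg.b, ctx);
        c.eggs_cur.push_back(std::move(egg));
        // one haploid (male) egg per diploid egg, from a fresh queen gamete
        std::vector<double> male = gamete(c.queen, recombine, n);
        maybe_mutate(male, ctx);
        male_pool.push_back(std::move(male));
      }
    }

    // (2) survival and ageing
    for (Colony& c : col) {
      if (!c.alive) continue;
      size_t keep = 0;
      for (size_t i = 0; i < c.workers.size(); ++i) {
        Worker& wk = c.workers[i];
        const double s = logistic(wk.g.a[ws + wk.age - 1] + wk.g.b[ws + wk.age - 1]);
        const bool lives = unif_rand() < s * (1.0 - h_ext) && wk.age < k;
        if (lives) {
          wk.age += 1;
          if (keep != i) c.workers[keep] = std::move(wk);
          ++keep;
        }
      }
      c.workers.resize(keep);
      const double sq = logistic(c.queen.a[qs + c.queen_age - 1] +
                                 c.queen.b[qs + c.queen_age - 1]);
      const double d_ext = 1.0 - std::pow(1.0 - h_ext, c.z);
      const bool queen_lives = unif_rand() < sq * (1.0 - d_ext) && c.queen_age < k;
      if (queen_lives) {
        c.queen_age += 1;
      } else {
        c.alive = false; // collapse handled below
      }
    }

    // (3) collapse of queenless colonies: queen and workers die. The egg
    // pools of a colony that collapsed this step remain available to this
    // step's requeening draw (new queens hatch from eggs of any colony,
    // sampled proportionally to egg counts); eggs not withdrawn as queens
    // die with their colony at the end of the step.
    for (Colony& c : col) {
      if (!c.alive && c.queen_age != 0) {
        c.queen_age = 0;
        c.workers.clear();
      }
    }

    // (4) requeening: fill vacant slots from hatching eggs, egg-weighted
    {
      std::vector<double> weights(N), weights_cur(N);
      double tot_hatch = 0.0, tot_cur = 0.0;
      for (int i = 0; i < N; ++i) {
        weights[i] = (double)col[i].eggs_hatch.size();
        weights_cur[i] = (double)col[i].eggs_cur.size();
        tot_hatch += weights[i];
        tot_cur += weights_cur[i];
      }
      for (int i = 0; i < N && status == 0; ++i) {
        if (col[i].alive) continue;
        bool use_fallback = !(tot_hatch > 0.0);
        if (use_fallback && !(tot_cur > 0.0)) break; // nothing to found from
        std::vector<double>& wvec = use_fallback ? weights_cur : weights;
        int src = sample_weighted(wvec);
        std::vector<Dip>& pool = use_fallback ? col[src].eggs_cur : col[src].eggs_hatch;
        Dip egg = std::move(pool.back());
        pool.pop_back();
        wvec[src] -= 1.0;
        (use_fallback ? tot_cur : tot_hatch) -= 1.0;
        if (use_fallback) ++requeen_fallback;
        if (male_pool.empty()) { status = 2; break; }
        const size_t mi = (size_t)(unif_rand() * male_pool.size()) % male_pool.size();
        Colony& c = col[i];
        // the slot's own orphaned eggs (minus any just withdrawn) die now
        tot_hatch -= weights[i];   weights[i] = 0.0;
        tot_cur   -= weights_cur[i]; weights_cur[i] = 0.0;
        c.alive = true;
        c.queen_age = 1;
        c.queen = std::move(egg);
        c.sperm = male_pool[mi];
        c.workers.clear();
        c.eggs_cur.clear();
        c.eggs_hatch.clear();
        c.z = 0.0;
        ++requeen_events;
      }
    }
    if (status == 2) { steps_done = t; break; }

    // (5) hatch: last step's eggs become age-1 workers; this step's eggs
    // move to the hatching pool
    long n_queens = 0, n_eggs = 0;
    for (Colony& c : col) {
      if (!c.alive) { // unfounded slot: any orphaned eggs die with it
        c.eggs_cur.clear();
        c.eggs_hatch.clear();
        continue;
      }
      ++n_queens;
      for (Dip& egg : c.eggs_hatch)
        c.workers.push_back(Worker{1, std::move(egg)});
      c.eggs_hatch = std::move(c.eggs_cur);
      c.eggs_cur.clear();
      n_eggs += (long)c.eggs_hatch.size();
    }

    if (check_invariants) {
      if ((int)col.size() != N) stop("invariant violated: colony slot count");
      for (const Colony& c : col) {
        if (c.alive && (c.queen_age < 1 || c.queen_age > k))
          stop("invariant violated: queen age out of range");
        if (!c.alive && (c.queen_age != 0 || !c.workers.empty()))
          stop("invariant violated: dead colony retains members");
        for (const Worker& wk : c.workers)
          if (wk.age < 1 || wk.age > k)
            stop("invariant violated: worker age out of range");
      }
    }

    steps_done = t;
    if (n_queens == 0 && n_eggs == 0) { status = 1; break; }
    if (t % checkpoint_every == 0 || t == T) record(t);
  }

  // assemble outputs
  int nq = 0; long nw = 0;
  for (const Colony& c : col) {
    if (c.alive) { ++nq; nw += (long)c.workers.size(); }
  }
  NumericMatrix queen_a(nq, n), queen_b(nq, n), sperm_mat(nq, n);
  IntegerVector queen_age(nq), queen_colony(nq), queen_workers(nq);
  NumericMatrix worker_a(nw, n), worker_b(nw, n);
  IntegerVector worker_age(nw), worker_colony(nw);
  {
    int iq = 0; long iw = 0;
    for (int cidx = 0; cidx < N; ++cidx) {
      const Colony& c = col[cidx];
      if (!c.alive) continue;
      for (int j = 0; j < n; ++j) {
        queen_a(iq, j) = c.queen.a[j];
        queen_b(iq, j) = c.queen.b[j];
        sperm_mat(iq, j) = c.sperm[j];
      }
      queen_age[iq] = c.queen_age;
      queen_colony[iq] = cidx + 1;
      queen_workers[iq] = (int)c.workers.size();
      ++iq;
      for (const Worker& wk : c.workers) {
        for (int j = 0; j < n; ++j) {
          worker_a(iw, j) = wk.g.a[j];
          worker_b(iw, j) = wk.g.b[j];
        }
        worker_age[iw] = wk.age;
        worker_colony[iw] = cidx + 1;
        ++iw;
      }
    }
  }
  NumericMatrix tsm((int)ts.size(), 3 + n);
  for (size_t i = 0; i < ts.size(); ++i)
    for (int j = 0; j < 3 + n; ++j) tsm((int)i, j) = ts[i][j];

  return List::create(
    _["status"] = status,
    _["steps_run"] = steps_done,
    _["timeseries"] = tsm,
    _["queen_a"] = queen_a, _["queen_b"] = queen_b,
    _["queen_sperm"] = sperm_mat,
    _["queen_age"] = queen_age, _["queen_colony"] = queen_colony,
    _["queen_workers"] = queen_workers,
    _["worker_a"] = worker_a, _["worker_b"] = worker_b,
    _["worker_age"] = worker_age, _["worker_colony"] = worker_colony,
    _["requeen_events"] = (double)requeen_events,
    _["requeen_fallback"] = (double)requeen_fallback);
}
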