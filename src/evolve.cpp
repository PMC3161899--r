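// Search operators (steepest-ascent hill-climbing mutation, random
// hill-climbing mutation, collision-avoiding one-point crossover in
// hill-climbing mode, Hamming-based diversification) and the generational
// engine for the EA / EAD / EAHC / EAHCD variants.

#include <algorithm>
#include <chrono>
#include <climits>
#include <map>

#include "hp.h"

namespace hp {

struct Pop {
  std::vector<std::string> chrom;
  std::vector<int> E;
  int size() const { return static_cast<int>(chrom.size()); }
};

// Run context: best-to-date trace, early-stop target, operator counters.
struct Ctx {
  int gen = 0;
  int best = INT_MAX;
  double stop_at = -1e18;
  bool stopped = false;
  std::vector<int> ev_gen, ev_E;
  long cross_repl = 0, mut_repl = 0, mut_touched = 0, div_repl = 0,
       offspring_failed = 0;
  void note(int E) {
    if (E < best) {
      best = E;
      ev_gen.push_back(gen);
      ev_E.push_back(E);
      if (static_cast<double>(E) <= stop_at) stopped = true;
    }
  }
};

static int hamming(const std::string& a, const std::string& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}

struct Ops {
  std::vector<char> isH;
  int n;
  Grid g, g2;
  Conf cur, cand, nb, rconf;
  std::vector<Move> mbuf;

  explicit Ops(const Rcpp::LogicalVector& h)
      : isH(h.size()), n(h.size()), g(h.size()), g2(h.size()) {
    for (int i = 0; i < n; ++i) isH[i] = h[i] ? 1 : 0;
  }

  int energy_of(const Conf& c) {
    fill_grid(c, g2);
    int e = energy_filled(isH, c, g2);
    g2.clear();
    return e;
  }

  // Decode a trusted (already validated) chromosome.
  void decode(const std::string& mv, Conf& c) {
    c.x.resize(n);
    c.y.resize(n);
    int x = 0, y = 0;
    c.x[0] = 0;
    c.y[0] = 0;
    for (int i = 0; i < n - 1; ++i) {
      x += dir_dx(mv[i]);
      y += dir_dy(mv[i]);
      c.x[i + 1] = x;
      c.y[i + 1] = y;
    }
  }

  // Grow a self-avoiding walk with uniform choice among free directions,
  // restarting from scratch on dead ends (the initialization procedure).
  std::string random_chromosome() {
    std::string mv(n - 1, 'L');
    for (;;) {
      g.clear();
      g.set(0, 0, 1);
      int x = 0, y = 0;
      bool ok = true;
      for (int i = 0; i < n - 1; ++i) {
        char opts[4];
        int no = 0;
        for (char d : DIRS)
          if (!g.at(x + dir_dx(d), y + dir_dy(d))) opts[no++] = d;
        if (no == 0) {
          ok = false;
          break;
        }
        char d = opts[rand_int(no)];
        mv[i] = d;
        x += dir_dx(d);
        y += dir_dy(d);
        g.set(x, y, i + 2);
      }
      g.clear();
      if (ok) return mv;
    }
  }

  // Full pull-move neighbourhood of c; true when a strictly better neighbour
  // exists, in which case `best`/`bestE` hold the steepest one (ties resolved
  // to the first in the deterministic enumeration order).
  bool best_neighbor(const Conf& c, int curE, Conf& best, int& bestE) {
    fill_grid(c, g);
    mbuf.clear();
    for (int p = 0; p < n; ++p) enumerate_moves(c, g, p, mbuf);
    g.clear();
    bestE = curE;
    bool found = false;
    for (const Move& m : mbuf) {
      apply_move(c, m, cand);
      int e = energy_of(cand);
      if (e < bestE) {
        bestE = e;
        best = cand;
        found = true;
      }
    }
    return found;
  }

  // Random hill-climbing: one uniformly drawn pull move per step, accepted
  // only on strict improvement; stops after `patience` consecutive failures.
  void rhc(Conf& c, int& E, int patience) {
    int fails = 0;
    fill_grid(c, g);
    while (fails < patience) {
      int p = rand_int(n);
      mbuf.clear();
      enumerate_moves(c, g, p, mbuf);
      if (mbuf.empty()) {
        ++fails;
        continue;
      }
      const Move& m = mbuf[rand_int(static_cast<int>(mbuf.size()))];
      apply_move(c, m, cand);
      int e = energy_of(cand);
      if (e < E) {
        c = cand;
        E = e;
        fails = 0;
        fill_grid(c, g);
      } else {
        ++fails;
      }
    }
    g.clear();
  }

  void write_back(Pop& P, int i, const Conf& c, int E, Ctx& ctx) {
    P.chrom[i] = encode_conf(c);
    P.E[i] = E;
    ctx.note(E);
  }

  void steepest_hc(Pop& P, int hc, Ctx& ctx) {
    if (hc <= 0 || P.size() == 0) return;
    int m = P.size();
    int ri = rand_int(m);
    Conf hill;
    decode(P.chrom[ri], hill);
    int hillE = P.E[ri], origE = hillE;
    ++ctx.mut_touched;
    for (int it = 0; it < hc && !ctx.stopped; ++it) {
      int nbE;
      if (best_neighbor(hill, hillE, nb, nbE)) {
        hill = nb;
        hillE = nbE;
      } else {
        if (hillE < origE) ++ctx.mut_repl;
        write_back(P, ri, hill, hillE, ctx);
        ri = rand_int(m);
        decode(P.chrom[ri], hill);
        hillE = P.E[ri];
        origE = hillE;
        ++ctx.mut_touched;
      }
    }
    if (hillE < origE) ++ctx.mut_repl;
    write_back(P, ri, hill, hillE, ctx);
  }

  // One offspring: prefix (cut genes) from A, remainder from B with uniform
  // random repair of colliding genes; false when the walk dead-ends.
  bool make_offspring(const std::string& A, const std::string& B, int cut,
                      std::string& out, int& outE) {
    out.resize(n - 1);
    g.clear();
    g.set(0, 0, 1);
    cand.x.resize(n);
    cand.y.resize(n);
    cand.x[0] = 0;
    cand.y[0] = 0;
    int x = 0, y = 0;
    for (int i = 0; i < n - 1; ++i) {
      char d;
      if (i < cut) {
        d = A[i];  // prefix of a valid walk: never collides
      } else {
        d = B[i];
        if (g.at(x + dir_dx(d), y + dir_dy(d))) {
          char opts[4];
          int no = 0;
          for (char dd : DIRS)
            if (!g.at(x + dir_dx(dd), y + dir_dy(dd))) opts[no++] = dd;
          if (no == 0) {
            g.clear();
            return false;
          }
          d = opts[rand_int(no)];
        }
      }
      out[i] = d;
      x += dir_dx(d);
      y += dir_dy(d);
      cand.x[i + 1] = x;
      cand.y[i + 1] = y;
      g.set(x, y, i + 2);
    }
    outE = energy_filled(isH, cand, g);
    g.clear();
    return true;
  }

  void pick_pair(int m, int& i1, int& i2) {
    i1 = rand_int(m);
    do {
      i2 = rand_int(m);
    } while (i2 == i1);
  }

  void hc_crossover(Pop& P, int hc, int k, Ctx& ctx) {
    int m = P.size();
    if (hc <= 0 || m < 2 || n < 3) return;
    int i1, i2;
    std::string best_o, off;
    int bestE, offE;
    pick_pair(m, i1, i2);
    auto init_best = [&]() {
      if (P.E[i1] <= P.E[i2]) {
        best_o = P.chrom[i1];
        bestE = P.E[i1];
      } else {
        best_o = P.chrom[i2];
        bestE = P.E[i2];
      }
    };
    init_best();
    for (int it = 0; it < hc && !ctx.stopped; ++it) {
      bool found = false;
      for (int j = 0; j < k; ++j) {
        int cut = 1 + rand_int(n - 2);
        for (int s = 0; s < 2; ++s) {
          const std::string& A = s ? P.chrom[i2] : P.chrom[i1];
          const std::string& B = s ? P.chrom[i1] : P.chrom[i2];
          if (make_offspring(A, B, cut, off, offE)) {
            if (offE < bestE) {
              bestE = offE;
              best_o = off;
              found = true;
            }
          } else {
            ++ctx.offspring_failed;
          }
        }
      }
      if (found) {
        decode(best_o, rconf);
        int rE = bestE;
        rhc(rconf, rE, n);
        int wi = (P.E[i1] > P.E[i2]) ? i1 : i2;  // replace the worse parent
        if (rE < bestE) {
          P.chrom[wi] = encode_conf(rconf);
          P.E[wi] = rE;
        } else {
          P.chrom[wi] = best_o;
          P.E[wi] = bestE;
        }
        ctx.note(P.E[wi]);
        ++ctx.cross_repl;
        // keep climbing with the updated pair at the same slots
      } else {
        pick_pair(m, i1, i2);
        init_best();
      }
    }
  }

  // Group by exact energy, leader-cluster within groups by Hamming distance
  // (< thr joins the first matching leader), replace all non-leaders with
  // fresh random conformations improved by one RHC pass.
  void diversify(Pop& P, double thr, Ctx& ctx) {
    int m = P.size();
    std::map<int, std::vector<int>> leaders;
    std::vector<int> repl;
    for (int i = 0; i < m; ++i) {
      std::vector<int>& L = leaders[P.E[i]];
      bool similar = false;
      for (int li : L)
        if (hamming(P.chrom[li], P.chrom[i]) < thr) {
          similar = true;
          break;
        }
      if (similar)
        repl.push_back(i);
      else
        L.push_back(i);
    }
    for (int i : repl) {
      std::string c = random_chromosome();
      decode(c, rconf);
      int E = energy_of(rconf);
      rhc(rconf, E, n);
      write_back(P, i, rconf, E, ctx);
      ++ctx.div_repl;
    }
  }

  // Plain generational pass for EA/EAD: per individual, probabilistic
  // crossover with a tournament-selected mate (best valid offspring replaces
  // the focal individual if strictly better), then a probabilistic single
  // random pull move accepted on strict improvement.
  void basic_generation(Pop& P, double pc, double pm, Ctx& ctx) {
    int m = P.size();
    std::string off;
    int offE;
    for (int i = 0; i < m && !ctx.stopped; ++i) {
      if (m >= 2 && n >= 3 && unif_rand() < pc) {
        int a, b;
        pick_pair(m, a, b);
        int mate = (P.E[a] <= P.E[b]) ? a : b;
        int cut = 1 + rand_int(n - 2);
        int bE = INT_MAX;
        std::string bo;
        for (int s = 0; s < 2; ++s) {
          const std::string& A = s ? P.chrom[mate] : P.chrom[i];
          const std::string& B = s ? P.chrom[i] : P.chrom[mate];
          if (make_offspring(A, B, cut, off, offE)) {
            if (offE < bE) {
              bE = offE;
              bo = off;
            }
          } else {
            ++ctx.offspring_failed;
          }
        }
        if (bE < P.E[i]) {
          P.chrom[i] = bo;
          P.E[i] = bE;
          ctx.note(bE);
          ++ctx.cross_repl;
        }
      }
      if (unif_rand() < pm) {
        decode(P.chrom[i], cur);
        fill_grid(cur, g);
        int p = rand_int(n);
        mbuf.clear();
        enumerate_moves(cur, g, p, mbuf);
        g.clear();
        if (!mbuf.empty()) {
          const Move& mv = mbuf[rand_int(static_cast<int>(mbuf.size()))];
          apply_move(cur, mv, cand);
          int e = energy_of(cand);
          if (e < P.E[i]) {
            write_back(P, i, cand, e, ctx);
            ++ctx.mut_repl;
          }
        }
      }
    }
  }
};

static void validate_population(Ops& ops, const std::vector<std::string>& pop,
                                Pop& P) {
  if (pop.empty()) Rcpp::stop("population is empty");
  Conf c;
  Grid g(ops.n);
  for (size_t i = 0; i < pop.size(); ++i) {
    if (static_cast<int>(pop[i].size()) != ops.n - 1)
      Rcpp::stop("chromosome %d has length %d, expected %d",
                 static_cast<int>(i + 1), static_cast<int>(pop[i].size()),
                 ops.n - 1);
    for (char d : pop[i])
      if (!is_dir(d)) Rcpp::stop("invalid direction '%c'", d);
    if (!decode_conf(pop[i], c, g))
      Rcpp::stop("chromosome %d is not self-avoiding",
                 static_cast<int>(i + 1));
    P.chrom.push_back(pop[i]);
    P.E.push_back(ops.energy_of(c));
  }
}

static Rcpp::List pop_result(const Pop& P, const Ctx& ctx) {
  return Rcpp::List::create(
      Rcpp::Named("population") = P.chrom, Rcpp::Named("energy") = P.E,
      Rcpp::Named("report") = Rcpp::List::create(
          Rcpp::Named("crossover_replacements") = ctx.cross_repl,
          Rcpp::Named("mutation_replacements") = ctx.mut_repl,
          Rcpp::Named("individuals_touched") = ctx.mut_touched,
          Rcpp::Named("diversify_replacements") = ctx.div_repl,
          Rcpp::Named("offspring_failed") = ctx.offspring_failed));
}

}  // namespace hp

using namespace hp;

// [[Rcpp::export]]
std::vector<std::string> cpp_init_population(int n, int pop_size) {
  if (n < 2) Rcpp::stop("sequence must have at least 2 residues");
  if (pop_size < 1) Rcpp::stop("pop_size must be >= 1");
  Rcpp::LogicalVector dummy(n, false);
  Ops ops(dummy);
  std::vector<std::string> out;
  out.reserve(pop_size);
  for (int i = 0; i < pop_size; ++i) out.push_back(ops.random_chromosome());
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_rhc(Rcpp::LogicalVector isH, std::string chrom, int patience) {
  Ops ops(isH);
  Pop P;
  std::vector<std::string> one{chrom};
  validate_population(ops, one, P);
  Conf c;
  ops.decode(P.chrom[0], c);
  int E = P.E[0];
  ops.rhc(c, E, patience);
  return Rcpp::List::create(Rcpp::Named("chromosome") = encode_conf(c),
                            Rcpp::Named("energy") = E);
}

// [[Rcpp::export]]
Rcpp::List cpp_crossover(Rcpp::LogicalVector isH, std::string p1,
                         std::string p2, int cut) {
  Ops ops(isH);
  Pop P;
  std::vector<std::string> two{p1, p2};
  validate_population(ops, two, P);
  if (cut < 1 || cut > ops.n - 2)
    Rcpp::stop("cut must be in 1..%d", ops.n - 2);
  Rcpp::CharacterVector off(2);
  Rcpp::IntegerVector en(2);
  Rcpp::LogicalVector ok(2);
  std::string o;
  int e;
  for (int s = 0; s < 2; ++s) {
    if (ops.make_offspring(P.chrom[s], P.chrom[1 - s], cut, o, e)) {
      off[s] = o;
      en[s] = e;
      ok[s] = true;
    } else {
      off[s] = NA_STRING;
      en[s] = NA_INTEGER;
      ok[s] = false;
    }
  }
  return Rcpp::List::create(Rcpp::Named("offspring") = off,
                            Rcpp::Named("energy") = en,
                            Rcpp::Named("valid") = ok);
}

// [[Rcpp::export]]
Rcpp::List cpp_steepest_hc(Rcpp::LogicalVector isH,
                           std::vector<std::string> population, int hc) {
  Ops ops(isH);
  Pop P;
  validate_population(ops, population, P);
  Ctx ctx;
  for (int e : P.E) ctx.best = std::min(ctx.best, e);
  ops.steepest_hc(P, hc, ctx);
  return pop_result(P, ctx);
}

// [[Rcpp::export]]
Rcpp::List cpp_hc_crossover(Rcpp::LogicalVector isH,
                            std::vector<std::string> population, int hc,
                            int k) {
  Ops ops(isH);
  Pop P;
  validate_population(ops, population, P);
  if (P.size() < 2) Rcpp::stop("population size must be >= 2");
  if (k < 1) Rcpp::stop("k must be >= 1");
  Ctx ctx;
  for (int e : P.E) ctx.best = std::min(ctx.best, e);
  ops.hc_crossover(P, hc, k, ctx);
  return pop_result(P, ctx);
}

// [[Rcpp::export]]
Rcpp::List cpp_diversify(Rcpp::LogicalVector isH,
                         std::vector<std::string> population,
                         double threshold) {
  Ops ops(isH);
  Pop P;
  validate_population(ops, population, P);
  Ctx ctx;
  for (int e : P.E) ctx.best = std::min(ctx.best, e);
  ops.diversify(P, threshold, ctx);
  return pop_result(P, ctx);
}

// [[Rcpp::export]]
Rcpp::List cpp_run(Rcpp::LogicalVector isH, std::string variant, int pop_size,
                   int generations, int hc, int k, int kd, double pc,
                   double pm, double stop_at, double time_limit) {
  bool hcmode = (variant == "EAHCD" || variant == "EAHC");
  bool divmode = (variant == "EAHCD" || variant == "EAD");
  if (!hcmode && variant != "EA" && variant != "EAD")
    Rcpp::stop("unknown variant '%s'", variant.c_str());
  if (pop_size < 2) Rcpp::stop("pop_size must be >= 2");
  if (generations < 0) Rcpp::stop("generations must be >= 0");
  if (hcmode && hc < 1) Rcpp::stop("hc must be >= 1 for variant %s",
                                   variant.c_str());
  if (divmode && kd < 1) Rcpp::stop("kd must be >= 1 for variant %s",
                                    variant.c_str());
  Ops ops(isH);
  int n = ops.n;
  if (n < 2) Rcpp::stop("sequence must have at least 2 residues");

  Pop P;
  Ctx ctx;
  ctx.stop_at = stop_at;
  for (int i = 0; i < pop_size; ++i) {
    std::string c = ops.random_chromosome();
    Conf cf;
    ops.decode(c, cf);
    P.chrom.push_back(c);
    P.E.push_back(ops.energy_of(cf));
  }
  ctx.gen = 0;
  ctx.note(*std::min_element(P.E.begin(), P.E.end()));

  double thr = (n - 1) / 4.0;
  auto t0 = std::chrono::steady_clock::now();
  auto elapsed = [&]() {
    return std::chrono::duration<double>(std::chrono::steady_clock::now() - t0)
        .count();
  };
  int gens_done = 0;
  bool timed_out = false;
  for (int gen = 1; gen <= generations; ++gen) {
    if (ctx.stopped) break;
    if (elapsed() > time_limit) {
      timed_out = true;
      break;
    }
    ctx.gen = gen;
    if (hcmode) {
      ops.hc_crossover(P, hc, k, ctx);
      if (!ctx.stopped) ops.steepest_hc(P, hc, ctx);
    } else {
      ops.basic_generation(P, pc, pm, ctx);
    }
    if (divmode && !ctx.stopped && gen % kd == 0) ops.diversify(P, thr, ctx);
    gens_done = gen;
    Rcpp::checkUserInterrupt();
  }

  int bi = 0;
  for (int i = 1; i < P.size(); ++i)
    if (P.E[i] < P.E[bi]) bi = i;
  return Rcpp::List::create(
      Rcpp::Named("population") = P.chrom, Rcpp::Named("energy") = P.E,
      Rcpp::Named("best_chromosome") = P.chrom[bi],
      Rcpp::Named("best_energy") = P.E[bi],
      Rcpp::Named("trace_generation") = ctx.ev_gen,
      Rcpp::Named("trace_energy") = ctx.ev_E,
      Rcpp::Named("generations_run") = gens_done,
      Rcpp::Named("stopped_early") = ctx.stopped,
      Rcpp::Named("timed_out") = timed_out,
      Rcpp::Named("elapsed") = elapsed(),
      Rcpp::Named("report") = Rcpp::List::create(
          Rcpp::Named("crossover_replacements") = ctx.cross_repl,
          Rcpp::Named("mutation_replacements") = ctx.mut_repl,
          Rcpp::Named("individuals_touched") = ctx.mut_touched,
          Rcpp::Named("diversify_replacements") = ctx.div_repl,
          Rcpp::Named("offspring_failed") = ctx.offspring_failed));
}
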