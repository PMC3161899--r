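// Lattice primitives: absolute-move decoding, H-H contact energy, and the
// pull-move neighbourhood on the 2D square lattice.

#include "hp.h"

namespace hp {

bool decode_conf(const std::string& mv, Conf& c, Grid& g) {
  int n = static_cast<int>(mv.size()) + 1;
  c.x.resize(n);
  c.y.resize(n);
  c.x[0] = 0;
  c.y[0] = 0;
  g.clear();
  g.set(0, 0, 1);
  bool valid = true;
  int x = 0, y = 0;
  for (int i = 0; i < n - 1; ++i) {
    x += dir_dx(mv[i]);
    y += dir_dy(mv[i]);
    c.x[i + 1] = x;
    c.y[i + 1] = y;
    if (g.at(x, y))
      valid = false;  // collision: keep walking, caller sees the flag
    else
      g.set(x, y, i + 2);
  }
  g.clear();
  return valid;
}

void fill_grid(const Conf& c, Grid& g) {
  g.clear();
  for (int i = 0; i < c.n(); ++i) g.set(c.x[i], c.y[i], i + 1);
}

// Each unordered H-H contact is counted once by scanning only the +x and +y
// neighbours of every H residue in the occupancy grid.
int energy_filled(const std::vector<char>& isH, const Conf& c, Grid& g) {
  int contacts = 0;
  int n = c.n();
  for (int i = 0; i < n; ++i) {
    if (!isH[i]) continue;
    int j = g.at(c.x[i] + 1, c.y[i]);
    if (j && isH[j - 1] && std::abs(j - 1 - i) > 1) ++contacts;
    j = g.at(c.x[i], c.y[i] + 1);
    if (j && isH[j - 1] && std::abs(j - 1 - i) > 1) ++contacts;
  }
  return -contacts;
}

std::string encode_conf(const Conf& c) {
  int n = c.n();
  std::string mv(n - 1, '?');
  for (int i = 0; i < n - 1; ++i) {
    int dx = c.x[i + 1] - c.x[i], dy = c.y[i + 1] - c.y[i];
    if (dx == -1 && dy == 0)
      mv[i] = 'L';
    else if (dx == 1 && dy == 0)
      mv[i] = 'R';
    else if (dx == 0 && dy == 1)
      mv[i] = 'U';
    else if (dx == 0 && dy == -1)
      mv[i] = 'D';
    else
      Rcpp::stop("chain connectivity broken between residues %d and %d", i + 1,
                 i + 2);
  }
  return mv;
}

// Candidate L locations at position pos (0-based): diagonal neighbours of
// residue pos that are orthogonally adjacent to its anchor (successor for
// interior/head positions, predecessor for the tail). Grid must hold c.
void enumerate_moves(const Conf& c, const Grid& g, int pos,
                     std::vector<Move>& out) {
  int n = c.n();
  if (n < 2) return;
  bool tail = (pos == n - 1);
  int anchor = tail ? pos - 1 : pos + 1;
  int ux = c.x[anchor] - c.x[pos], uy = c.y[anchor] - c.y[pos];
  int vx = -uy, vy = ux;  // unit vector perpendicular to the chain step
  Move cand[2];
  int nc = 0;
  for (int s = -1; s <= 1; s += 2) {
    int Lx = c.x[anchor] + s * vx, Ly = c.y[anchor] + s * vy;
    if (g.at(Lx, Ly)) continue;
    Move m;
    m.pos = pos;
    m.Lx = Lx;
    m.Ly = Ly;
    if (pos == 0 || tail) {
      m.Cx = m.Cy = 0;
      m.kind = END;
    } else {
      m.Cx = c.x[pos] + Lx - c.x[pos + 1];
      m.Cy = c.y[pos] + Ly - c.y[pos + 1];
      int occ = g.at(m.Cx, m.Cy);
      if (occ == pos)  // occupant index+1 == pos  <=>  residue pos-1
        m.kind = C_PREV;
      else if (occ == 0)
        m.kind = C_FREE;
      else
        continue;
    }
    cand[nc++] = m;
  }
  if (nc == 2 &&
      (cand[1].Lx < cand[0].Lx ||
       (cand[1].Lx == cand[0].Lx && cand[1].Ly < cand[0].Ly))) {
    Move t = cand[0];
    cand[0] = cand[1];
    cand[1] = t;
  }
  for (int i = 0; i < nc; ++i) out.push_back(cand[i]);
}

void apply_move(const Conf& c, const Move& m, Conf& out) {
  out = c;
  int p = m.pos;
  out.x[p] = m.Lx;
  out.y[p] = m.Ly;
  if (m.kind == END || m.kind == C_PREV) return;
  out.x[p - 1] = m.Cx;
  out.y[p - 1] = m.Cy;
  // Pull toward residue 1: residue j steps into the location residue j+2
  // vacated, stopping as soon as the chain is reconnected.
  for (int j = p - 2; j >= 0; --j) {
    int dx = c.x[j] - out.x[j + 1], dy = c.y[j] - out.y[j + 1];
    if (std::abs(dx) + std::abs(dy) == 1) break;
    out.x[j] = c.x[j + 2];
    out.y[j] = c.y[j + 2];
  }
}

static void check_moves(const std::string& mv) {
  if (mv.empty()) Rcpp::stop("chromosome must have at least one move");
  for (char d : mv)
    if (!is_dir(d))
      Rcpp::stop("invalid direction '%c' (alphabet is L, U, R, D)", d);
}

static std::vector<char> as_isH(const Rcpp::LogicalVector& isH) {
  std::vector<char> v(isH.size());
  for (int i = 0; i < isH.size(); ++i) v[i] = isH[i] ? 1 : 0;
  return v;
}

}  // namespace hp

using namespace hp;

// [[Rcpp::export]]
Rcpp::List cpp_decode(std::string moves) {
  check_moves(moves);
  int n = static_cast<int>(moves.size()) + 1;
  Grid g(n);
  Conf c;
  bool valid = decode_conf(moves, c, g);
  return Rcpp::List::create(Rcpp::Named("x") = c.x, Rcpp::Named("y") = c.y,
                            Rcpp::Named("valid") = valid);
}

// [[Rcpp::export]]
std::string cpp_encode(Rcpp::IntegerVector x, Rcpp::IntegerVector y) {
  if (x.size() != y.size() || x.size() < 2)
    Rcpp::stop("need matching x/y vectors of length >= 2");
  Conf c;
  c.x.assign(x.begin(), x.end());
  c.y.assign(y.begin(), y.end());
  return encode_conf(c);
}

// [[Rcpp::export]]
int cpp_energy(Rcpp::LogicalVector isH, std::string moves) {
  check_moves(moves);
  if (isH.size() != static_cast<int>(moves.size()) + 1)
    Rcpp::stop("sequence length (%d) must equal chromosome length + 1 (%d)",
               static_cast<int>(isH.size()),
               static_cast<int>(moves.size()) + 1);
  int n = isH.size();
  Grid g(n);
  Conf c;
  if (!decode_conf(moves, c, g))
    Rcpp::stop("conformation is not self-avoiding");
  std::vector<char> h = as_isH(isH);
  fill_grid(c, g);
  int e = energy_filled(h, c, g);
  g.clear();
  return e;
}

// [[Rcpp::export]]
Rcpp::DataFrame cpp_enumerate_moves(std::string moves, int position) {
  check_moves(moves);
  int n = static_cast<int>(moves.size()) + 1;
  if (position < 1 || position > n)
    Rcpp::stop("position must be in 1..%d", n);
  Grid g(n);
  Conf c;
  if (!decode_conf(moves, c, g))
    Rcpp::stop("conformation is not self-avoiding");
  fill_grid(c, g);
  std::vector<Move> mv;
  enumerate_moves(c, g, position - 1, mv);
  g.clear();
  int m = static_cast<int>(mv.size());
  Rcpp::IntegerVector pos(m), Lx(m), Ly(m), Cx(m), Cy(m);
  Rcpp::CharacterVector kind(m);
  for (int i = 0; i < m; ++i) {
    pos[i] = mv[i].pos + 1;
    Lx[i] = mv[i].Lx;
    Ly[i] = mv[i].Ly;
    if (mv[i].kind == END) {
      Cx[i] = NA_INTEGER;
      Cy[i] = NA_INTEGER;
      kind[i] = "end_move";
    } else {
      Cx[i] = mv[i].Cx;
      Cy[i] = mv[i].Cy;
      kind[i] = (mv[i].kind == C_PREV) ? "C_equals_prev" : "C_free";
    }
  }
  return Rcpp::DataFrame::create(
      Rcpp::Named("position") = pos, Rcpp::Named("case") = kind,
      Rcpp::Named("Lx") = Lx, Rcpp::Named("Ly") = Ly, Rcpp::Named("Cx") = Cx,
      Rcpp::Named("Cy") = Cy, Rcpp::Named("stringsAsFactors") = false);
}

// [[Rcpp::export]]
std::string cpp_apply_move(std::string moves, int position, int Lx, int Ly) {
  check_moves(moves);
  int n = static_cast<int>(moves.size()) + 1;
  if (position < 1 || position > n)
    Rcpp::stop("position must be in 1..%d", n);
  Grid g(n);
  Conf c;
  if (!decode_conf(moves, c, g))
    Rcpp::stop("conformation is not self-avoiding");
  fill_grid(c, g);
  std::vector<Move> mv;
  enumerate_moves(c, g, position - 1, mv);
  g.clear();
  for (const Move& m : mv) {
    if (m.Lx == Lx && m.Ly == Ly) {
      Conf out;
      apply_move(c, m, out);
      return encode_conf(out);
    }
  }
  Rcpp::stop("no legal pull move at position %d with L = (%d, %d)", position,
             Lx, Ly);
}
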