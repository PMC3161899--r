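#pragma once

#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdlib>

namespace hp {

// Occupancy grid over the square lattice, sized so that any walk of n residues
// started at the origin (plus one lattice step of slack for pull-move targets)
// stays in bounds. Cells hold residue index + 1; 0 means free.
struct Grid {
  int off, side;
  std::vector<int> cell;
  std::vector<int> dirty;
  explicit Grid(int n) : off(n + 1), side(2 * n + 3),
                         cell(static_cast<size_t>(side) * side, 0) {
    dirty.reserve(n + 4);
  }
  inline int idx(int x, int y) const { return (x + off) * side + (y + off); }
  inline int at(int x, int y) const { return cell[idx(x, y)]; }
  inline void set(int x, int y, int v) {
    int i = idx(x, y);
    cell[i] = v;
    dirty.push_back(i);
  }
  inline void clear() {
    for (int i : dirty) cell[i] = 0;
    dirty.clear();
  }
};

struct Conf {
  std::vector<int> x, y;
  int n() const { return static_cast<int>(x.size()); }
};

static const char DIRS[4] = {'L', 'U', 'R', 'D'};

inline int dir_dx(char d) { return d == 'L' ? -1 : (d == 'R' ? 1 : 0); }
inline int dir_dy(char d) { return d == 'U' ? 1 : (d == 'D' ? -1 : 0); }
inline bool is_dir(char d) {
  return d == 'L' || d == 'U' || d == 'R' || d == 'D';
}

// Pull-move cases. C_PREV: corner equals the predecessor, only residue i moves.
// C_FREE: corner free, i moves to L, i-1 to C, pull propagates toward residue 1.
// END: chain terminus, single relocation with no corner condition.
enum MoveKind { C_PREV = 0, C_FREE = 1, END = 2 };

struct Move {
  int pos;  // 0-based residue index
  int Lx, Ly, Cx, Cy;
  int kind;
};

bool decode_conf(const std::string& mv, Conf& c, Grid& g);
void fill_grid(const Conf& c, Grid& g);
int energy_filled(const std::vector<char>& isH, const Conf& c, Grid& g);
std::string encode_conf(const Conf& c);
void enumerate_moves(const Conf& c, const Grid& g, int pos,
                     std::vector<Move>& out);
void apply_move(const Conf& c, const Move& m, Conf& out);

inline int rand_int(int m) {
  int r = static_cast<int>(unif_rand() * m);
  return r >= m ? m - 1 : r;
}

}  // namespace hp
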