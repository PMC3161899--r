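# Independent reference implementations used as oracles: plain-R decoding by
# cumulative displacement and an O(n^2) all-pairs contact scan, sharing no
# code with the package's occupancy-map routines.

oracle_decode <- function(chromosome) {
  mv <- strsplit(chromosome, "")[[1]]
  dx <- c(L = -1, U = 0, R = 1, D = 0)[mv]
  dy <- c(L = 0, U = 1, R = 0, D = -1)[mv]
  cbind(x = cumsum(c(0, dx)), y = cumsum(c(0, dy)))
}

oracle_energy <- function(h, coords) {
  n <- length(h)
  manh <- abs(outer(coords[, 1], coords[, 1], "-")) +
    abs(outer(coords[, 2], coords[, 2], "-"))
  chainsep <- abs(outer(seq_len(n), seq_len(n), "-"))
  -sum(manh == 1 & chainsep > 1 & outer(h, h, "&")) / 2
}

random_h <- function(n) sample(c(TRUE, FALSE), n, replace = TRUE)

as_seq <- function(h) hp_sequence(ifelse(h, "H", "P"))

# All pull-move neighbours of a chromosome, as chromosome strings.
all_neighbours <- function(chromosome) {
  n <- nchar(chromosome) + 1L
  out <- character(0)
  for (p in seq_len(n)) {
    mv <- enumerate_pull_moves(chromosome, p)
    if (nrow(mv))
      out <- c(out, vapply(seq_len(nrow(mv)), function(i)
        apply_pull_move(chromosome, p, c(mv$Lx[i], mv$Ly[i])),
        character(1)))
  }
  out
}
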