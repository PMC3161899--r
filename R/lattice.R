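#' Decode an absolute-move chromosome
#'
#' A chromosome of n-1 symbols over \{L, U, R, D\} places residue 1 at the
#' origin and each subsequent residue one lattice step from its predecessor
#' (L = (-1,0), R = (+1,0), U = (0,+1), D = (0,-1)). Decoding never fails:
#' a self-intersecting walk is returned with `valid = FALSE` so that callers
#' (e.g. crossover repair) can inspect partial geometry.
#'
#' @param chromosome a single string over `L`, `U`, `R`, `D`.
#' @return An object of class `hp_conformation`: a list with `coords`
#'   (integer matrix n x 2), `valid` (logical), and `chromosome`.
#' @examples
#' decode_chromosome("RRUURURDDD")
#' decode_chromosome("RL")$valid  # immediate backtrack collides
#' @export
decode_chromosome <- function(chromosome) {
  stopifnot(is.character(chromosome), length(chromosome) == 1L)
  d <- cpp_decode(chromosome)
  structure(
    list(coords = cbind(x = d$x, y = d$y), valid = d$valid,
         chromosome = chromosome),
    class = "hp_conformation")
}

#' Re-encode lattice coordinates as a chromosome
#'
#' Inverse of [decode_chromosome()]: consecutive coordinate differences are
#' mapped back to L/U/R/D moves. Errors if consecutive points are not unit
#' lattice steps.
#'
#' @param coords integer matrix with two columns (x, y) or an
#'   `hp_conformation`.
#' @return A chromosome string.
#' @export
encode_conformation <- function(coords) {
  if (inherits(coords, "hp_conformation")) coords <- coords$coords
  coords <- as.matrix(coords)
  cpp_encode(as.integer(coords[, 1]), as.integer(coords[, 2]))
}

#' HP contact energy of a conformation
#'
#' Counts unordered pairs of H residues that are adjacent on the lattice
#' (horizontally or vertically) but not consecutive in the chain; each such
#' topological contact contributes -1.
#'
#' @param sequence an [hp_sequence] (or coercible) of n residues.
#' @param chromosome a chromosome string of n-1 moves, or an
#'   `hp_conformation`. Must decode to a self-avoiding walk.
#' @return Integer energy (<= 0).
#' @examples
#' s <- hp_sequence("HHHPHPPPPPH")
#' hp_energy(s, "RULURURDDD")
#' @export
hp_energy <- function(sequence, chromosome) {
  if (inherits(chromosome, "hp_conformation"))
    chromosome <- chromosome$chromosome
  cpp_energy(is_h(sequence), chromosome)
}

#' @export
print.hp_conformation <- function(x, ...) {
  cat("HP lattice conformation -", nrow(x$coords), "residues,",
      if (x$valid) "self-avoiding" else "INVALID (self-intersecting)", "\n")
  cat("  chromosome:", x$chromosome, "\n")
  invisible(x)
}

#' @export
as.data.frame.hp_conformation <- function(x, ..., sequence = NULL) {
  df <- data.frame(index = seq_len(nrow(x$coords)),
                   x = x$coords[, 1], y = x$coords[, 2])
  if (!is.null(sequence)) df$residue <- unclass(hp_sequence(sequence))
  df
}

#' Write a conformation as a TSV coordinate table
#'
#' Emits one row per residue: index, residue class (when a sequence is
#' given), x, y; the chromosome string goes on a leading comment line.
#'
#' @param conformation an `hp_conformation`.
#' @param file output path or connection.
#' @param sequence optional [hp_sequence] for the residue column.
#' @return The written data frame, invisibly.
#' @export
write_conformation <- function(conformation, file, sequence = NULL) {
  df <- as.data.frame(conformation, sequence = sequence)
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  writeLines(paste0("# chromosome\t", conformation$chromosome), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Plot a lattice conformation
#'
#' Draws the chain on the square lattice with H residues filled and P
#' residues open; H-H topological contacts are shown as dashed segments.
#'
#' @param x an `hp_conformation`.
#' @param sequence optional [hp_sequence]; without it all residues are drawn
#'   alike and contacts are omitted.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hp_conformation <- function(x, sequence = NULL, ...) {
  co <- x$coords
  graphics::plot(co[, 1], co[, 2], type = "n", asp = 1,
                 xlab = "x", ylab = "y", ...)
  graphics::lines(co[, 1], co[, 2], col = "grey40")
  if (!is.null(sequence)) {
    h <- is_h(sequence)
    n <- nrow(co)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 2, length.out = max(0, n - i - 1))) {
        if (h[i] && h[j] &&
            sum(abs(co[i, ] - co[j, ])) == 1)
          graphics::segments(co[i, 1], co[i, 2], co[j, 1], co[j, 2],
                             lty = 2, col = "firebrick")
      }
    }
    graphics::points(co[, 1], co[, 2], pch = ifelse(h, 19, 21),
                     bg = "white", cex = 1.2)
  } else {
    graphics::points(co[, 1], co[, 2], pch = 19, cex = 1.2)
  }
  graphics::points(co[1, 1], co[1, 2], pch = 0, cex = 2)
  invisible(x)
}

#' Enumerate legal pull moves at a position
#'
#' Interior positions admit up to two candidate locations L (diagonal to
#' residue i, orthogonally adjacent to residue i+1), each legal when the
#' corner C is free (`C_free`) or equals residue i-1 (`C_equals_prev`).
#' Chain termini admit degenerate end moves: the terminal residue may hop to
#' any free point diagonal to it and adjacent to its neighbour. Candidates
#' are ordered lexicographically by L.
#'
#' @param chromosome a valid chromosome string.
#' @param position residue index, 1-based.
#' @return A data frame with columns `position`, `case`, `Lx`, `Ly`,
#'   `Cx`, `Cy` (corner columns are `NA` for end moves).
#' @examples
#' enumerate_pull_moves("RRUURURDDD", 3)
#' @export
enumerate_pull_moves <- function(chromosome, position) {
  cpp_enumerate_moves(chromosome, as.integer(position))
}

#' Apply a pull move
#'
#' Relocates residue `position` to the free location `L` and, when the
#' corner is free, pulls predecessors toward residue 1 (each residue steps
#' into the location vacated two places up the chain) until connectivity is
#' restored. The move must be legal, i.e. returned by
#' [enumerate_pull_moves()] for this conformation.
#'
#' @param chromosome a valid chromosome string.
#' @param position residue index, 1-based.
#' @param L integer vector `c(x, y)`, the target location.
#' @return The transformed chromosome string (always a valid self-avoiding
#'   walk).
#' @examples
#' apply_pull_move("RRUURURDDD", 3, c(3, 1))  # -> "RULURURDDD"
#' @export
apply_pull_move <- function(chromosome, position, L) {
  stopifnot(length(L) == 2)
  cpp_apply_move(chromosome, as.integer(position),
                 as.integer(L[1]), as.integer(L[2]))
}

#' Hamming distance between chromosomes
#'
#' The number of positions at which two equal-length chromosomes differ;
#' the similarity measure used by the diversification stage.
#'
#' @param c1,c2 chromosome strings of equal length.
#' @return Integer distance.
#' @export
hamming_distance <- function(c1, c2) {
  if (nchar(c1) != nchar(c2))
    stop("chromosomes must have equal length")
  sum(utf8ToInt(c1) != utf8ToInt(c2))
}
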