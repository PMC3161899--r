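#' Random valid population
#'
#' Each chromosome is grown one residue at a time with a uniform choice
#' among the directions leading to a free lattice point, restarting from
#' scratch on dead ends, so every individual is a self-avoiding walk.
#'
#' @param sequence an [hp_sequence], or a single integer chain length.
#' @param pop_size number of individuals.
#' @return Character vector of `pop_size` valid chromosomes.
#' @examples
#' set.seed(1)
#' init_population(20, 5)
#' @export
init_population <- function(sequence, pop_size) {
  n <- if (is.numeric(sequence)) as.integer(sequence) else length(hp_sequence(sequence))
  cpp_init_population(n, as.integer(pop_size))
}

#' Random hill-climbing (RHC) mutation
#'
#' Repeatedly samples one position uniformly and one legal pull move there
#' (uniformly among candidates), accepting the move only on strict energy
#' improvement. Stops after `patience` consecutive non-improving samples
#' (default: the sequence length).
#'
#' @param sequence an [hp_sequence].
#' @param chromosome a valid chromosome string.
#' @param patience consecutive failed samples tolerated before stopping.
#' @return A list with `chromosome` and `energy` of the (possibly improved)
#'   individual. The result's energy never exceeds the input's.
#' @export
rhc_mutation <- function(sequence, chromosome, patience = NULL) {
  h <- is_h(sequence)
  if (is.null(patience)) patience <- length(h)
  cpp_rhc(h, chromosome, as.integer(patience))
}

#' Collision-avoiding one-point crossover
#'
#' Offspring 1 copies genes `1..cut` from `p1`; each later gene takes `p2`'s
#' direction unless it would collide with an already placed residue, in
#' which case a uniformly random direction to a free point is substituted.
#' Offspring 2 swaps the parent roles. An offspring whose partial walk
#' dead-ends (no free direction) is marked failed.
#'
#' @param sequence an [hp_sequence] of n residues.
#' @param p1,p2 valid parent chromosome strings.
#' @param cut cut point in `1..(n-2)`: the number of genes taken from the
#'   first parent.
#' @return A list with `offspring` (character, `NA` on failure), `energy`
#'   and `valid` — each of length 2.
#' @export
one_point_crossover <- function(sequence, p1, p2, cut) {
  cpp_crossover(is_h(sequence), p1, p2, as.integer(cut))
}

#' Steepest-ascent hill-climbing mutation
#'
#' Implements the population-level pull-move mutation: a random individual
#' becomes the current hilltop; each iteration evaluates the full pull-move
#' neighbourhood (every position, every candidate location) and moves to
#' the best neighbour when it strictly improves the energy; otherwise the
#' climbed individual is written back into its population slot (visible
#' within the same generation) and a new random individual is selected.
#' The final hilltop is written back when the `hc` iteration budget is
#' exhausted.
#'
#' @param sequence an [hp_sequence].
#' @param population character vector of valid chromosomes.
#' @param hc hill-climbing iteration budget (full neighbourhood sweeps).
#' @return A list with the updated `population`, its `energy` vector, and a
#'   `report` of counts (individuals touched, improvements written back).
#' @export
steepest_hc_mutation <- function(sequence, population, hc) {
  cpp_steepest_hc(is_h(sequence), population, as.integer(hc))
}

#' Hill-climbing crossover
#'
#' Selects a random pair of parents; the incumbent `best_o` starts as the
#' better parent. Each of the `hc` iterations draws `k` random cut points,
#' generating two offspring per cut; if the best offspring strictly beats
#' the incumbent it is RHC-mutated and the better of (offspring, mutant)
#' replaces the worse member of the pair in place, the search continuing
#' with the updated pair. Otherwise a fresh random pair is selected.
#' Because insertions must beat the better parent, the population's best
#' energy never worsens.
#'
#' @inheritParams steepest_hc_mutation
#' @param k offspring cut points drawn per hill-climbing iteration.
#' @return As [steepest_hc_mutation()]; the report additionally counts
#'   replacements and failed (dead-ended) offspring.
#' @export
hc_crossover <- function(sequence, population, hc, k) {
  cpp_hc_crossover(is_h(sequence), population, as.integer(hc),
                   as.integer(k))
}

#' Diversification stage
#'
#' Partitions the population by exact energy; within each energy group,
#' individuals are clustered in population order by single-pass leader
#' clustering (an individual joins the first leader at Hamming distance
#' below the threshold, else becomes a new leader). Per cluster the leader
#' is kept and every other member is replaced with a fresh random valid
#' chromosome improved by one RHC pass.
#'
#' @inheritParams steepest_hc_mutation
#' @param threshold Hamming similarity threshold; defaults to the
#'   real-valued (n-1)/4 with strict `<` comparison.
#' @return As [steepest_hc_mutation()]; the report counts replacements.
#' @export
diversify <- function(sequence, population, threshold = NULL) {
  h <- is_h(sequence)
  if (is.null(threshold)) threshold <- (length(h) - 1) / 4
  cpp_diversify(h, population, as.numeric(threshold))
}
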