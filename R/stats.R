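#' Best-to-date envelope over replicate runs
#'
#' For each grid point T, a run's best-to-date energy is its last strict
#' improvement at or before T (generation-indexed, so the summary is
#' hardware-independent). Over the runs that have produced a value by T the
#' summary reports the count and the min / mean / variance / max, the
#' envelope statistics used to compare algorithm variants.
#'
#' @param runs an `hp_fold_multi` object or a list of `hp_fold` fits.
#' @param grid sorted integer vector of generation indices; defaults to
#'   every generation up to the longest run.
#' @return A data frame with columns `T`, `n`, `min`, `avg`, `var`, `max`.
#' @examples
#' runs <- hp_fold_multi("S1", n_runs = 2, generations = 3, seed_base = 1)
#' best_to_date(runs, grid = c(1, 3))
#' @export
best_to_date <- function(runs, grid = NULL) {
  fits <- if (inherits(runs, "hp_fold_multi")) runs$fits else runs
  stopifnot(length(fits) >= 1)
  if (is.null(grid))
    grid <- seq(0, max(vapply(fits, function(f)
      max(f$generations_run, f$trace$generation), numeric(1))))
  if (length(grid) == 0)
    return(data.frame(T = numeric(0), n = integer(0), min = numeric(0),
                      avg = numeric(0), var = numeric(0), max = numeric(0)))
  grid <- sort(grid)
  rows <- lapply(grid, function(tt) {
    vals <- unlist(lapply(fits, function(f) {
      i <- which(f$trace$generation <= tt)
      if (length(i)) f$trace$energy[max(i)] else NULL
    }))
    if (is.null(vals) || length(vals) == 0)
      return(data.frame(T = tt, n = 0L, min = NA_real_, avg = NA_real_,
                        var = NA_real_, max = NA_real_))
    data.frame(T = tt, n = length(vals), min = min(vals), avg = mean(vals),
               var = if (length(vals) > 1) stats::var(vals) else 0,
               max = max(vals))
  })
  do.call(rbind, rows)
}

#' Signed Student t between two best-to-date summaries
#'
#' Welch's two-sample t statistic computed from summary triples
#' (n, avg, var), with the sign convention that a positive value means the
#' first algorithm's mean best-to-date energy is higher — i.e. its results
#' are poorer — than the second's. `signed_t(a, b) == -signed_t(b, a)`.
#'
#' With zero variance in both samples the statistic is 0 for equal means
#' and a signed infinity for unequal means.
#'
#' @param a1,a2 either one-row data frames / lists with elements `n`, `avg`
#'   and `var` (as returned by [best_to_date()]), or full [best_to_date()]
#'   tables over the same grid, in which case a vector of t values is
#'   returned.
#' @return Numeric t statistic(s).
#' @examples
#' signed_t(list(n = 25, avg = -8, var = 1), list(n = 25, avg = -9, var = 1))
#' @export
signed_t <- function(a1, a2) {
  if (is.data.frame(a1) && nrow(a1) > 1) {
    stopifnot(is.data.frame(a2), nrow(a2) == nrow(a1))
    return(vapply(seq_len(nrow(a1)), function(i)
      signed_t(a1[i, ], a2[i, ]), numeric(1)))
  }
  n1 <- as.numeric(a1$n); n2 <- as.numeric(a2$n)
  if (n1 < 2 || n2 < 2)
    stop("signed_t needs at least two runs per summary")
  se2 <- a1$var / n1 + a2$var / n2
  d <- a1$avg - a2$avg
  if (se2 == 0) {
    if (d == 0) return(0)
    return(sign(d) * Inf)
  }
  d / sqrt(se2)
}

#' Population free energy
#'
#' Boltzmann-weighted free energy of a set of conformer energies,
#' F = -kT log(sum_i exp(-E_i / kT)), computed with the log-sum-exp trick.
#' Every population member counts as one conformer, so duplicated
#' conformations enter with their multiplicity. F equals E for a single
#' conformer, E - kT log(m) for m degenerate conformers at energy E, and
#' tends to min(E) as kT tends to 0.
#'
#' @param energies numeric vector of conformer energies.
#' @param kT temperature factor (> 0) in energy units.
#' @return The free energy (numeric scalar, always <= min(energies)).
#' @examples
#' population_free_energy(c(-9, -9, -9), kT = 1)  # -9 - log(3)
#' @export
population_free_energy <- function(energies, kT = 1) {
  if (length(energies) < 1) stop("need at least one energy")
  if (!is.numeric(kT) || length(kT) != 1 || kT <= 0)
    stop("kT must be a positive scalar")
  z <- -energies / kT
  m <- max(z)
  -kT * (m + log(sum(exp(z - m))))
}
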