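#' Fold an HP sequence with the hill-climbing evolutionary algorithm
#'
#' Runs one seeded search for the minimum-energy self-avoiding conformation
#' of an HP sequence on the 2D square lattice. Four variants are available:
#'
#' * `"EAHCD"` (default): hill-climbing crossover, steepest-ascent
#'   hill-climbing pull-move mutation, and periodic diversification;
#' * `"EAHC"`: the hill-climbing operators without diversification;
#' * `"EAD"`: plain generational operators plus diversification;
#' * `"EA"`: plain generational operators only (per-individual crossover
#'   with probability `crossover_prob`, mate picked by binary tournament,
#'   and a single random pull move with probability `mutation_prob`, each
#'   accepted only on strict improvement).
#'
#' Each EAHC(D) generation applies hill-climbing crossover (budget `hc`
#' iterations of `k` cut points), then steepest-ascent mutation (budget
#' `hc` sweeps); diversifying variants run the diversification stage on
#' every `kd`-th generation. Replacement is asynchronous: improved
#' individuals are visible to later operator calls in the same generation.
#'
#' @param sequence an [hp_sequence], a string in either HP notation, or a
#'   benchmark id `"S1"`-`"S8"`.
#' @param variant one of `"EAHCD"`, `"EAHC"`, `"EAD"`, `"EA"`.
#' @param pop_size population size (default 100).
#' @param generations number of generations (default 300).
#' @param hc hill-climbing iteration budget per operator phase (default 100;
#'   HC variants only).
#' @param k offspring cut points per crossover hill-climbing iteration
#'   (default 50).
#' @param kd diversification period in generations (default 30, i.e. 10% of
#'   the default generation count; use `kd = 1` to diversify every
#'   generation).
#' @param crossover_prob,mutation_prob per-individual operator
#'   probabilities for the non-HC variants (defaults 0.8 and 0.2).
#' @param seed optional integer seed; when given, `set.seed(seed)` is
#'   applied so runs are bit-reproducible.
#' @param stop_at optional target energy: the run stops as soon as the
#'   population best reaches it (e.g. the known optimum).
#' @param time_limit optional wall-clock limit in seconds; the run
#'   truncates cleanly at a generation boundary.
#' @return An object of class `hp_fold` with components
#'   `best_energy`, `best_chromosome`, `trace` (data frame of
#'   generation-stamped strict improvements of the population best),
#'   `population` (final chromosomes and energies), `report` (operator
#'   counters), `generations_run`, `stopped_early`, `elapsed` and the echoed
#'   configuration.
#' @examples
#' fit <- hp_fold("S1", generations = 5, seed = 1)
#' fit
#' coef(fit)
#' @seealso [hp_fold_multi()] for seeded replicate runs,
#'   [best_to_date()] for multi-run envelopes.
#' @export
hp_fold <- function(sequence,
                    variant = c("EAHCD", "EAHC", "EAD", "EA"),
                    pop_size = 100, generations = 300,
                    hc = 100, k = 50, kd = 30,
                    crossover_prob = 0.8, mutation_prob = 0.2,
                    seed = NULL, stop_at = NULL, time_limit = NULL) {
  variant <- match.arg(variant)
  sequence <- resolve_sequence(sequence)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run(is_h(sequence), variant,
                 as.integer(pop_size), as.integer(generations),
                 as.integer(hc), as.integer(k), as.integer(kd),
                 as.numeric(crossover_prob), as.numeric(mutation_prob),
                 if (is.null(stop_at)) -Inf else as.numeric(stop_at),
                 if (is.null(time_limit)) Inf else as.numeric(time_limit))
  structure(
    list(sequence = sequence,
         variant = variant,
         config = list(pop_size = pop_size, generations = generations,
                       hc = hc, k = k, kd = kd,
                       crossover_prob = crossover_prob,
                       mutation_prob = mutation_prob,
                       seed = seed, stop_at = stop_at,
                       time_limit = time_limit),
         best_energy = res$best_energy,
         best_chromosome = res$best_chromosome,
         trace = data.frame(generation = res$trace_generation,
                            energy = res$trace_energy),
         population = data.frame(chromosome = res$population,
                                 energy = res$energy,
                                 stringsAsFactors = FALSE),
         report = res$report,
         generations_run = res$generations_run,
         stopped_early = res$stopped_early,
         timed_out = res$timed_out,
         elapsed = res$elapsed),
    class = "hp_fold")
}

resolve_sequence <- function(sequence) {
  if (inherits(sequence, "hp_sequence")) return(sequence)
  if (is.character(sequence) && length(sequence) == 1L &&
      grepl("^S[1-8]$", sequence))
    return(hp_instance(sequence))
  if (is.character(sequence) && length(sequence) == 1L)
    return(parse_hp_sequence(sequence))
  hp_sequence(sequence)
}

#' @export
print.hp_fold <- function(x, ...) {
  lab <- attr(x$sequence, "label")
  cat("HP fold (", x$variant, ") - ",
      if (!is.null(lab)) paste0(lab, ", "), length(x$sequence),
      " residues\n", sep = "")
  cat("  best energy: ", x$best_energy,
      if (!is.null(attr(x$sequence, "optimum")))
        paste0("  (best known: ", attr(x$sequence, "optimum"), ")"),
      "\n", sep = "")
  cat("  best chromosome: ", x$best_chromosome, "\n", sep = "")
  cat("  generations run: ", x$generations_run,
      if (x$stopped_early) "  [stopped at target]",
      if (x$timed_out) "  [time limit]", "\n", sep = "")
  invisible(x)
}

#' @export
summary.hp_fold <- function(object, ...) {
  pop <- object$population$energy
  out <- list(fit = object,
              pop_energy = stats::setNames(
                c(min(pop), mean(pop), stats::var(pop), max(pop)),
                c("min", "avg", "var", "max")),
              n_improvements = nrow(object$trace) - 1L,
              first_hit = if (object$stopped_early)
                object$trace$generation[nrow(object$trace)] else NA_integer_)
  class(out) <- "summary.hp_fold"
  out
}

#' @export
print.summary.hp_fold <- function(x, ...) {
  print(x$fit)
  cat("  final population energy: min ", x$pop_energy[["min"]],
      ", avg ", round(x$pop_energy[["avg"]], 2),
      ", var ", round(x$pop_energy[["var"]], 2),
      ", max ", x$pop_energy[["max"]], "\n", sep = "")
  cat("  strict improvements of the population best:",
      x$n_improvements, "\n")
  if (!is.na(x$first_hit))
    cat("  target energy first reached at generation", x$first_hit, "\n")
  cat("  elapsed:", round(x$fit$elapsed, 2), "s\n")
  invisible(x)
}

#' @describeIn hp_fold the best chromosome found (named with its energy).
#' @param object,... method arguments.
#' @export
coef.hp_fold <- function(object, ...) {
  stats::setNames(object$best_chromosome, object$best_energy)
}

#' Plot a search trace
#'
#' Step plot of the best-to-date energy against generation; optionally adds
#' the known optimum of a benchmark sequence as a dashed line.
#'
#' @param x an `hp_fold` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hp_fold <- function(x, ...) {
  tr <- x$trace
  gmax <- max(x$generations_run, tr$generation, 1L)
  graphics::plot(c(tr$generation, gmax), c(tr$energy, min(tr$energy)),
                 type = "s", xlab = "generation",
                 ylab = "best-to-date energy", ...)
  opt <- attr(x$sequence, "optimum")
  if (!is.null(opt)) graphics::abline(h = opt, lty = 2, col = "grey50")
  invisible(x)
}

#' Replicate seeded runs
#'
#' Runs [hp_fold()] for `n_runs` consecutive seeds (`seed_base`,
#' `seed_base + 1`, ...), the replication scheme used for the benchmark
#' comparisons.
#'
#' @inheritParams hp_fold
#' @param n_runs number of independent runs.
#' @param seed_base seed of the first run.
#' @param ... further arguments to [hp_fold()].
#' @return An object of class `hp_fold_multi`: a list of `hp_fold` fits
#'   with the sequence attached.
#' @examples
#' runs <- hp_fold_multi("S1", n_runs = 2, generations = 3, seed_base = 1)
#' summary(runs)
#' @export
hp_fold_multi <- function(sequence, n_runs = 10, seed_base = 1, ...) {
  sequence <- resolve_sequence(sequence)
  fits <- lapply(seq_len(n_runs) - 1L, function(i)
    hp_fold(sequence, seed = seed_base + i, ...))
  structure(list(sequence = sequence, fits = fits,
                 seeds = seed_base + seq_len(n_runs) - 1L),
            class = "hp_fold_multi")
}

#' @export
print.hp_fold_multi <- function(x, ...) {
  e <- vapply(x$fits, function(f) f$best_energy, numeric(1))
  lab <- attr(x$sequence, "label")
  cat("HP fold, ", length(x$fits), " seeded runs",
      if (!is.null(lab)) paste0(" on ", lab), "\n", sep = "")
  cat("  final best energies:", paste(e, collapse = " "), "\n")
  cat("  minimum over runs:", min(e), "\n")
  invisible(x)
}

#' @export
summary.hp_fold_multi <- function(object, ...) {
  e <- vapply(object$fits, function(f) f$best_energy, numeric(1))
  fh <- vapply(object$fits, function(f) {
    opt <- attr(object$sequence, "optimum")
    tgt <- if (!is.null(f$config$stop_at)) f$config$stop_at else opt
    if (is.null(tgt)) NA_real_ else first_hit_generation(f, tgt)
  }, numeric(1))
  structure(list(n = length(e),
                 energy = c(min = min(e), avg = mean(e),
                            var = stats::var(e), max = max(e)),
                 first_hit = fh),
            class = "summary.hp_fold_multi")
}

#' @export
print.summary.hp_fold_multi <- function(x, ...) {
  cat("Runs:", x$n, "\n")
  cat("Final best energy: min ", x$energy[["min"]],
      ", avg ", round(x$energy[["avg"]], 2),
      ", var ", round(x$energy[["var"]], 3),
      ", max ", x$energy[["max"]], "\n", sep = "")
  if (any(is.finite(x$first_hit)))
    cat("Median first-hit generation (target reached):",
        stats::median(x$first_hit[is.finite(x$first_hit)]), "\n")
  invisible(x)
}

#' First generation at which a run reaches an energy
#'
#' @param fit an `hp_fold` object.
#' @param energy target energy level.
#' @return The generation index of the first trace event at or below
#'   `energy`, or `Inf` when the run never reached it.
#' @export
first_hit_generation <- function(fit, energy) {
  hit <- which(fit$trace$energy <= energy)
  if (length(hit)) fit$trace$generation[hit[1L]] else Inf
}
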