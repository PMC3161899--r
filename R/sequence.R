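#' HP sequences
#'
#' An HP sequence is an ordered vector of residue classes over \{H, P\}:
#' H for hydrophobic, P for polar. Only H residues contribute to the
#' lattice contact energy.
#'
#' @param residues character vector with elements `"H"` or `"P"`
#'   (case-insensitive), or a single string such as `"HPHPPH"`.
#' @param label optional instance label (e.g. `"S1"`).
#' @return An object of class `hp_sequence`: a character vector of `"H"`/`"P"`
#'   with attributes `label`.
#' @examples
#' hp_sequence("HPHPPHHPH")
#' hp_sequence(c("H", "P", "H"))
#' @export
hp_sequence <- function(residues, label = NULL) {
  if (inherits(residues, "hp_sequence")) return(residues)
  if (is.character(residues) && length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L)
    stop("an HP sequence needs at least one residue")
  bad <- setdiff(unique(residues), c("H", "P"))
  if (length(bad))
    stop("invalid residue symbol(s): ", paste(bad, collapse = ", "))
  structure(residues, label = label, class = "hp_sequence")
}

#' Parse an HP sequence from text
#'
#' Accepts either a plain string over \{H, P\} or the run-length notation used
#' for the benchmark tables, e.g. `"1H 1P 1H 2P 2H"` expands to `"HPHPPHH"`.
#' Run-length tokens are `<count><H|P>`; whitespace between tokens is
#' optional, so typeset artifacts such as `"1H3P"` parse as `1H 3P`.
#'
#' @param text a single string in either notation.
#' @param label optional instance label attached to the result.
#' @return An [hp_sequence] object.
#' @examples
#' parse_hp_sequence("1H 1P 1H 2P 2H 1P 1H 2P 1H 1P 2H 2P 1H 1P 1H")
#' parse_hp_sequence("hph")
#' @export
parse_hp_sequence <- function(text, label = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single string")
  raw <- trimws(text)
  if (nchar(raw) == 0L)
    stop("empty HP sequence")
  if (grepl("^[HPhp]+$", raw))
    return(hp_sequence(raw, label = label))
  compact <- gsub("[[:space:]]+", "", raw)
  if (!grepl("[0-9]", compact))
    stop("not a valid HP sequence: ", raw)
  tokens <- regmatches(compact, gregexpr("([0-9]+)([HPhp])", compact))[[1]]
  covered <- paste(tokens, collapse = "")
  if (!identical(covered, compact)) {
    # locate the first stretch the tokenizer could not consume
    bad <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", covered)),
               "", compact)
    if (identical(bad, compact) || nchar(bad) == 0L) bad <- compact
    stop("malformed run-length token near: ", substr(bad, 1L, 8L))
  }
  counts <- as.integer(sub("[HPhp]$", "", tokens))
  if (any(counts < 1L))
    stop("zero or negative count in token: ",
         tokens[which(counts < 1L)[1L]])
  sym <- toupper(substr(tokens, nchar(tokens), nchar(tokens)))
  hp_sequence(rep(sym, counts), label = label)
}

#' @export
print.hp_sequence <- function(x, ...) {
  lab <- attr(x, "label")
  cat("HP sequence", if (!is.null(lab)) paste0("[", lab, "]"), "- n =",
      length(x), "residues,", sum(x == "H"), "hydrophobic\n")
  cat(" ", paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' @export
as.character.hp_sequence <- function(x, ...) paste(unclass(x), collapse = "")

is_h <- function(sequence) {
  if (!inherits(sequence, "hp_sequence")) sequence <- hp_sequence(sequence)
  unclass(sequence) == "H"
}

#' Benchmark 2D HP instances
#'
#' The eight standard square-lattice HP benchmark sequences of 20 to 64
#' residues (S1-S8) with their best known energies, shipped as a plain-text
#' table in the package's `extdata` and expanded on load.
#'
#' @return A data frame with columns `id`, `length`, `optimum` and
#'   `sequence` (run-length notation).
#' @examples
#' hp_benchmarks()
#' @export
hp_benchmarks <- function() {
  path <- system.file("extdata", "hp_benchmarks.tsv", package = "hpfold")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Look up one benchmark instance
#'
#' @param id instance identifier, `"S1"` to `"S8"`.
#' @return An [hp_sequence] with the known optimum energy stored in the
#'   `optimum` attribute.
#' @examples
#' hp_instance("S4")
#' attr(hp_instance("S4"), "optimum")
#' @export
hp_instance <- function(id) {
  tab <- hp_benchmarks()
  row <- tab[tab$id == id, ]
  if (nrow(row) != 1L)
    stop("unknown instance id '", id, "' (expected one of ",
         paste(tab$id, collapse = ", "), ")")
  s <- parse_hp_sequence(row$sequence, label = id)
  if (length(s) != row$length)
    stop("packaged instance ", id, " expands to ", length(s),
         " residues, expected ", row$length)
  attr(s, "optimum") <- row$optimum
  s
}

#' Read HP sequences from a text file
#'
#' One sequence per line, in plain or run-length notation. Lines that match
#' a benchmark id (`S1`-`S8`) resolve to the packaged instance. Blank lines
#' and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return A list of [hp_sequence] objects.
#' @export
read_hp_sequences <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- hp_benchmarks()$id
  lapply(lines, function(l) {
    if (l %in% ids) hp_instance(l) else parse_hp_sequence(l)
  })
}
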