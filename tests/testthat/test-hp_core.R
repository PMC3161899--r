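test_that("run-length and plain HP notations parse and expand correctly", {
  s1 <- parse_hp_sequence("1H 1P 1H 2P 2H 1P 1H 2P 1H 1P 2H 2P 1H 1P 1H")
  expect_length(s1, 20)
  expect_identical(as.character(s1), "HPHPPHHPHPPHPHHPPHPH")

  expect_identical(unclass(parse_hp_sequence("HPH"))[1:3], c("H", "P", "H"))
  expect_length(parse_hp_sequence("hph"), 3)

  s4 <- parse_hp_sequence("3P 2H 2P 2H 5P 7H 2P 2H 4P 2H 2P 1H 2P")
  expect_length(s4, 36)

  # typeset artifact: glued tokens still expand
  expect_length(parse_hp_sequence("4P 1H3P 1H"), 9)
})

test_that("malformed sequence text is rejected with the offending token", {
  expect_error(parse_hp_sequence(""), "empty")
  expect_error(parse_hp_sequence("   "), "empty")
  expect_error(parse_hp_sequence("2H 0P 1H"), "zero or negative.*0P")
  expect_error(parse_hp_sequence("2H 3X"), "3X|not a valid")
  expect_error(parse_hp_sequence("ABC"), "not a valid|invalid")
  expect_error(hp_sequence("HPX"), "X")
})

test_that("chromosomes decode to lattice walks with residue 1 at the origin", {
  d <- decode_chromosome("RR")
  expect_true(d$valid)
  expect_equal(unname(d$coords), cbind(c(0, 1, 2), c(0, 0, 0)))

  d <- decode_chromosome("RRUURURDDD")
  expect_true(d$valid)
  expect_equal(nrow(unique(d$coords)), 11)
  expect_equal(unname(d$coords[11, ]), c(4, 0))

  # immediate backtrack: residue 3 lands on residue 1
  d <- decode_chromosome("RL")
  expect_false(d$valid)
  expect_equal(unname(d$coords[3, ]), unname(d$coords[1, ]))
})

test_that("decode then re-encode is the identity on chromosomes", {
  set.seed(11)
  for (n in c(5, 20, 48)) {
    for (ch in init_population(n, 20)) {
      expect_identical(encode_conformation(decode_chromosome(ch)), ch)
    }
  }
})

test_that("energy counts each H-H topological contact once", {
  s <- hp_sequence("HHHPHPPPPPH")
  expect_identical(hp_energy(s, "RRUURURDDD"), 0L)
  expect_identical(hp_energy(s, "RULURURDDD"), -1L)

  allP <- hp_sequence(strrep("P", 11))
  expect_identical(hp_energy(allP, "RULURURDDD"), 0L)

  expect_error(hp_energy(s, "RRUURURDD"), "length")
  expect_error(hp_energy(hp_sequence("HHH"), "RL"), "self-avoiding")
})

test_that("occupancy-map energy agrees with the O(n^2) pair-scan oracle", {
  set.seed(21)
  for (n in c(20, 25, 36, 64)) {
    h <- random_h(n)
    s <- as_seq(h)
    for (ch in init_population(n, 30)) {
      expect_identical(hp_energy(s, ch),
                       as.integer(oracle_energy(h, oracle_decode(ch))))
    }
  }
})

test_that("energy is invariant under global lattice rotation and reflection", {
  rotate <- function(ch) chartr("LURD", "URDL", ch)   # 90 degrees
  reflect <- function(ch) chartr("LR", "RL", ch)      # mirror in x
  set.seed(31)
  h <- random_h(25)
  s <- as_seq(h)
  for (ch in init_population(25, 25)) {
    e <- hp_energy(s, ch)
    expect_identical(hp_energy(s, rotate(ch)), e)
    expect_identical(hp_energy(s, reflect(ch)), e)
  }
})

test_that("benchmark instances expand to their catalogued lengths and optima", {
  tab <- hp_benchmarks()
  expect_identical(tab$id, paste0("S", 1:8))
  expect_identical(tab$length, c(20L, 24L, 25L, 36L, 48L, 50L, 60L, 64L))
  expect_identical(tab$optimum, c(-9L, -9L, -8L, -14L, -23L, -21L, -36L, -42L))
  for (i in seq_len(nrow(tab))) {
    s <- hp_instance(tab$id[i])
    expect_length(s, tab$length[i])
    expect_identical(attr(s, "optimum"), tab$optimum[i])
  }
  expect_error(hp_instance("S9"), "unknown instance")
})

test_that("sequence files and conformation tables round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# two ways to say the same instance", "S1",
               "1H 1P 1H 2P 2H 1P 1H 2P 1H 1P 2H 2P 1H 1P 1H", "HPH"), f)
  seqs <- read_hp_sequences(f)
  expect_length(seqs, 3)
  expect_identical(as.character(seqs[[1]]), as.character(seqs[[2]]))
  expect_length(seqs[[3]], 3)

  out <- withr::local_tempfile(fileext = ".tsv")
  conf <- decode_chromosome("RULURURDDD")
  write_conformation(conf, out, sequence = hp_sequence("HHHPHPPPPPH"))
  lines <- readLines(out)
  expect_match(lines[1], "RULURURDDD")
  tab <- utils::read.delim(out, comment.char = "#")
  expect_identical(nrow(tab), 11L)
  expect_identical(tab$residue[1:3], c("H", "H", "H"))
})
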