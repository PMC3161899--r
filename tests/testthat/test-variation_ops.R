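seq_fig <- hp_sequence("HHHPHPPPPPH")

test_that("steepest-ascent mutation takes the best strictly improving neighbour", {
  # brute-force oracle: the minimum over the full pull-move neighbourhood
  nb <- all_neighbours("RRUURURDDD")
  h <- unclass(seq_fig) == "H"
  nbE <- vapply(nb, function(x) oracle_energy(h, oracle_decode(x)), numeric(1))
  expect_lte(min(nbE), -1)

  set.seed(51)
  res <- steepest_hc_mutation(seq_fig, "RRUURURDDD", hc = 1)
  expect_identical(res$energy, as.integer(min(nbE)))
})

test_that("a local optimum individual survives steepest mutation unchanged", {
  # with an all-P sequence every conformation has energy 0: no strict
  # improvement exists, so the single individual is re-selected and
  # written back untouched while the budget is consumed
  allP <- hp_sequence(strrep("P", 12))
  set.seed(52)
  ch <- init_population(12, 1)
  res <- steepest_hc_mutation(allP, ch, hc = 10)
  expect_identical(res$population, ch)
  expect_identical(res$energy, 0L)
  expect_gte(res$report$individuals_touched, 10)
})

test_that("an empty hill-climbing budget leaves the population untouched", {
  set.seed(53)
  pop <- init_population(20, 6)
  res <- steepest_hc_mutation(hp_instance("S1"), pop, hc = 0)
  expect_identical(res$population, pop)
})

test_that("RHC mutation never worsens and finds accessible improvements", {
  allP <- hp_sequence(strrep("P", 12))
  set.seed(54)
  ch <- init_population(12, 1)
  res <- rhc_mutation(allP, ch, patience = 5)
  expect_identical(res$chromosome, ch)

  s1 <- hp_instance("S1")
  straight <- strrep("R", 19)
  res <- rhc_mutation(s1, straight)
  expect_lte(res$energy, 0)
  expect_identical(res$energy, hp_energy(s1, res$chromosome))

  res <- rhc_mutation(seq_fig, "RRUURURDDD", patience = 200)
  expect_lte(res$energy, -1)
})

test_that("crossover copies a prefix and repairs collisions randomly", {
  s1 <- hp_instance("S1")
  set.seed(55)
  p <- init_population(20, 1)
  x <- one_point_crossover(s1, p, p, cut = 9)
  expect_identical(x$offspring, c(p, p))  # clone parents: no collision

  # parent prefixes are inherited verbatim
  p2 <- init_population(20, 1)
  x <- one_point_crossover(s1, p, p2, cut = 9)
  if (x$valid[1]) {
    expect_identical(substr(x$offspring[1], 1, 9), substr(p, 1, 9))
    expect_true(decode_chromosome(x$offspring[1])$valid)
  }

  expect_error(one_point_crossover(s1, p, p2, cut = 0), "cut")
  expect_error(one_point_crossover(s1, p, p2, cut = 19), "cut")
})

test_that("colliding genes are replaced by valid non-colliding directions", {
  s <- as_seq(random_h(8))
  right <- strrep("R", 7)
  left <- strrep("L", 7)
  set.seed(56)
  for (cut in c(1, 3, 6)) {
    x <- one_point_crossover(s, right, left, cut)
    expect_true(x$valid[1])
    o <- x$offspring[1]
    expect_identical(substr(o, 1, cut), strrep("R", cut))
    # the first inherited gene would step back onto the chain: never L
    expect_false(substr(o, cut + 1, cut + 1) == "L")
    expect_true(decode_chromosome(o)$valid)
  }
})

test_that("hill-climbing crossover never raises the population minimum", {
  s4 <- hp_instance("S4")
  set.seed(57)
  pop <- init_population(36, 10)
  before <- min(vapply(pop, function(c) hp_energy(s4, c), integer(1)))
  res <- hc_crossover(s4, pop, hc = 20, k = 10)
  expect_lte(min(res$energy), before)
  expect_length(res$population, 10)
  expect_true(all(vapply(res$population,
                         function(c) decode_chromosome(c)$valid,
                         logical(1))))
})

test_that("a clone population yields no crossover replacements", {
  s1 <- hp_instance("S1")
  set.seed(58)
  pop <- rep(init_population(20, 1), 6)
  res <- hc_crossover(s1, pop, hc = 10, k = 5)
  expect_identical(res$population, pop)
  expect_equal(res$report$crossover_replacements, 0)
})

test_that("operators are bit-reproducible under a fixed seed", {
  s5 <- hp_instance("S5")
  set.seed(59)
  pop <- init_population(48, 8)
  run_ops <- function() {
    set.seed(99)
    a <- hc_crossover(s5, pop, hc = 5, k = 5)
    b <- steepest_hc_mutation(s5, a$population, hc = 5)
    diversify(s5, b$population)
  }
  expect_identical(run_ops(), run_ops())
})
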