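test_that("initial populations are valid and uniformly grown", {
  set.seed(71)
  p2 <- init_population(2, 50)
  expect_true(all(p2 %in% c("L", "U", "R", "D")))

  pop <- init_population(20, 100)
  expect_length(pop, 100)
  expect_true(all(vapply(pop, function(c) decode_chromosome(c)$valid,
                         logical(1))))

  # the first gene of a freshly grown walk is unconstrained: its empirical
  # distribution over 10,000 draws should be uniform on the four directions
  g1 <- substr(init_population(20, 10000), 1, 1)
  counts <- table(factor(g1, levels = c("L", "U", "R", "D")))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("a zero-generation run reports only the initial best", {
  f <- hp_fold("S1", generations = 0, seed = 7)
  expect_identical(nrow(f$trace), 1L)
  expect_identical(f$trace$generation, 0L)
  expect_identical(f$best_energy, f$trace$energy)
  expect_identical(f$generations_run, 0L)
})

test_that("identical seeds give identical runs for every variant", {
  for (v in c("EAHCD", "EAHC", "EAD", "EA")) {
    a <- hp_fold("S2", variant = v, generations = 4, hc = 10, k = 5,
                 kd = 2, seed = 123)
    b <- hp_fold("S2", variant = v, generations = 4, hc = 10, k = 5,
                 kd = 2, seed = 123)
    expect_identical(a$trace, b$trace)
    expect_identical(a$population, b$population)
    expect_identical(a$best_chromosome, b$best_chromosome)
  }
})

test_that("all variants keep the population valid and at fixed size", {
  for (v in c("EAHCD", "EAHC", "EAD", "EA")) {
    f <- hp_fold("S3", variant = v, pop_size = 12, generations = 5,
                 hc = 5, k = 5, kd = 2, seed = 77)
    expect_identical(nrow(f$population), 12L)
    expect_true(all(vapply(f$population$chromosome,
                           function(c) decode_chromosome(c)$valid,
                           logical(1))))
    expect_identical(
      f$population$energy,
      vapply(f$population$chromosome,
             function(c) hp_energy(hp_instance("S3"), c), integer(1),
             USE.NAMES = FALSE))
    # the trace is strictly decreasing in energy, non-decreasing in time
    expect_true(all(diff(f$trace$energy) < 0))
    expect_true(all(diff(f$trace$generation) >= 0))
    expect_identical(f$best_energy, min(f$trace$energy))
  }
})

test_that("early stopping and time limits truncate runs cleanly", {
  f <- hp_fold("S1", seed = 5, stop_at = -6)
  expect_true(f$stopped_early)
  expect_lte(f$best_energy, -6)
  expect_lt(f$generations_run, 300)

  f <- hp_fold("S6", seed = 5, generations = 1000, time_limit = 0.3)
  expect_true(f$timed_out)
  expect_lt(f$generations_run, 1000)
})

test_that("the steepest-ascent engine recovers known optima on small instances", {
  # parameter-recovery: S1-S3 reached in >= 9/10 seeded runs
  for (id in c("S1", "S2", "S3")) {
    opt <- attr(hp_instance(id), "optimum")
    runs <- hp_fold_multi(id, n_runs = 10, seed_base = 100, stop_at = opt)
    hits <- sum(vapply(runs$fits, `[[`, integer(1), "best_energy") <= opt)
    expect_gte(hits, 9)
  }
})

test_that("fit objects expose the classic modelling surface", {
  f <- hp_fold("S1", generations = 3, seed = 9)
  expect_s3_class(f, "hp_fold")
  expect_output(print(f), "best energy")
  s <- summary(f)
  expect_output(print(s), "final population energy")
  expect_identical(unname(coef(f)), f$best_chromosome)
  expect_identical(names(coef(f)), as.character(f$best_energy))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(f))
  expect_silent(plot(decode_chromosome(f$best_chromosome),
                     sequence = f$sequence))

  m <- hp_fold_multi("S1", n_runs = 2, generations = 2, seed_base = 1)
  expect_output(print(m), "seeded runs")
  expect_output(print(summary(m)), "Final best energy")
})
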