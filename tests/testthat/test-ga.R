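# Genetic algorithm engine: codec, initialization, fitness, operators,
# and the greedy-closure evolution loop.

test_that("tag/index codec is the base-4 bijection", {
  expect_identical(index_to_tag(0, 4), "AAAA")
  expect_identical(tag_to_index("AAAC"), 1)
  expect_identical(index_to_tag(4^4 - 1, 4), "TTTT")
  expect_error(index_to_tag(16, 2), "range")
  set.seed(14)
  for (n in c(4, 7, 10)) {
    idx <- floor(runif(100, 0, 4^n))
    expect_identical(tag_to_index(index_to_tag(idx, n)), idx)
  }
})

test_that("even initialization spreads the population equidistantly", {
  expect_identical(init_population_even(4, 2), c("AA", "CA", "GA", "TA"))
  expect_identical(init_population_even(2, 1), c("A", "G"))
  expect_error(init_population_even(17, 2), "infeasible")
  for (k in c(3, 10, 100)) for (n in c(4, 5)) {
    idx <- tag_to_index(init_population_even(k, n))
    expect_identical(anyDuplicated(idx), 0L)
    # consecutive spacings differ by at most 1 (floor arithmetic)
    expect_lte(diff(range(diff(idx))), 1)
  }
})

test_that("fitness is TTE with a lethal filter and an empty-set sentinel", {
  bare <- constraint_profile(1, gc_mode = "off", continuity_max = 6,
                             complementarity = "none")
  expect_equal(fitness("ACTG", c("CAGT", "GAGT"), bare), 3)
  # homopolymer violation is lethal regardless of distance
  capped <- constraint_profile(1, gc_mode = "off", continuity_max = 2,
                               complementarity = "none")
  expect_equal(fitness("AAATTG", c("CCGCCG"), capped), 0)
  expect_identical(fitness("ACTG", character(0), bare), Inf)
  # cross mode: the reverse complement of a set member is lethal
  cross <- constraint_profile(1, gc_mode = "off", continuity_max = 6,
                              complementarity = "cross")
  expect_equal(fitness("TTGAC", c("GTCAA"), cross), 0)
})

test_that("binary tournaments pick the fitter contestant and split ties 50/50", {
  cfg <- ga_config(tournament_fraction = 0.5)  # one tournament per call here
  set.seed(77)
  # contestants are drawn with replacement from {1, 2}; the fitter index 1
  # wins unless the draw was {2, 2}, so it wins 3/4 of tournaments
  w <- replicate(4000, tournament_select(c(3, 1), cfg))
  expect_equal(mean(w == 1L), 0.75, tolerance = 0.05)
  # a population of identical individuals selects that individual
  expect_true(all(tournament_select(c(2, 2, 2), cfg) %in% 1:3))
  # tie case: empirical 50/50 within 2 points over 10,000 tournaments
  wins <- replicate(10000, tournament_select(c(4, 4), cfg)[1])
  expect_equal(mean(wins == 1L), 0.5, tolerance = 0.02)
  # Inf (unconstrained) fitness always beats a finite contestant
  w2 <- replicate(2000, tournament_select(c(1, Inf), cfg))
  expect_equal(mean(w2 == 2L), 0.75, tolerance = 0.06)
})

test_that("three-point crossover exchanges alternating segments", {
  expect_identical(crossover_exchange("AAAA", "TTTT", c(1, 2, 3)),
                   c("ATAT", "TATA"))
  expect_identical(crossover_exchange("ACGTAC", "TGCATG", 3),
                   c("ACGATG", "TGCTAC"))
  expect_error(crossover_exchange("AAAA", "TTTT", 4), "cuts")
  # rate 0 returns copies
  cfg0 <- ga_config(crossover_rate = 0)
  set.seed(1)
  expect_identical(three_point_crossover("ACGTAA", "TTGCAT", cfg0),
                   c("ACGTAA", "TTGCAT"))
  # column multisets are conserved under forced crossover
  cfg1 <- ga_config(crossover_rate = 1)
  set.seed(2)
  for (i in 1:25) {
    p <- random_tags(2, 8)
    ch <- three_point_crossover(p[1], p[2], cfg1)
    for (pos in 1:8) {
      parents <- sort(substring(p, pos, pos))
      children <- sort(substring(ch, pos, pos))
      expect_identical(children, parents)
    }
  }
})

test_that("dynamic mutation rate follows the fitness-vs-mean rule", {
  cfg <- ga_config()
  expect_equal(dynamic_mutation_rate(5, 3.2, cfg), 0.01)
  expect_equal(dynamic_mutation_rate(3.2, 3.2, cfg), 0.03)
  expect_equal(dynamic_mutation_rate(1, 3.2, cfg), 0.3)
  # sentinel fitness is excluded from rate escalation
  expect_equal(dynamic_mutation_rate(Inf, 3.2, cfg), 0.01)
  expect_equal(dynamic_mutation_rate(c(5, 3.2, 1), 3.2, cfg),
               c(0.01, 0.03, 0.3))
})

test_that("evolve is deterministic for a fixed seed and config", {
  p <- constraint_profile(3)
  cfg <- ga_config(population_size = 80, generations = 25, rng_seed = 42)
  a <- evolve(6, p, cfg)
  b <- evolve(6, p, cfg)
  expect_identical(a$set$tags, b$set$tags)
  expect_identical(a$log, b$log)
  cfg2 <- cfg; cfg2$rng_seed <- 43
  c_ <- evolve(6, p, cfg2)
  # different seed explores differently (sets may coincide in size only)
  expect_false(identical(a$set$tags, c_$set$tags))
})

test_that("evolve output always passes its own profile", {
  cfg <- ga_config(population_size = 120, generations = 30, rng_seed = 7)
  for (tmpl in c("range_gc", "fixed_gc", "cross_comp")) {
    res <- evolve(6, design_profile(tmpl, 3), cfg)
    expect_true(validate_set(res$set)$pass)
    expect_gt(length(res$set), 1)
  }
})

test_that("with only the distance rule at d = 1 the set absorbs distinct words", {
  bare <- constraint_profile(1, gc_mode = "off", continuity_max = 4,
                             complementarity = "none")
  res <- evolve(4, bare, ga_config(population_size = 100, generations = 15,
                                   rng_seed = 3))
  expect_identical(anyDuplicated(res$set$tags), 0L)
  expect_gt(length(res$set), 50)  # d = 1 admits every distinct word seen
  expect_true(validate_set(res$set)$pass)
})

test_that("population re-initialization fires at most once, on stall", {
  # d = n makes growth stall almost immediately at tiny population
  p <- constraint_profile(5, gc_mode = "off", continuity_max = 5,
                          complementarity = "none")
  cfg <- ga_config(population_size = 30, generations = 60, g_stall = 10,
                   rng_seed = 5)
  res <- evolve(5, p, cfg)
  expect_true(is.logical(res$reinit_used))
  cfg_off <- cfg; cfg_off$reinit_policy <- "off"
  res2 <- evolve(5, p, cfg_off)
  expect_false(res2$reinit_used)
  # the log covers every generation either way
  expect_identical(nrow(res$log), 60L)
  expect_identical(res$log$generation, 1:60)
})

test_that("evolve rejects infeasible profiles before evolving", {
  expect_error(evolve(4, constraint_profile(5)), "infeasible")
  expect_error(evolve(4, constraint_profile(2, gc_mode = "fixed",
                                            gc_fixed_count = 9)),
               "infeasible")
  expect_error(evolve(3, constraint_profile(2, gc_mode = "range",
                                            gc_min = 41, gc_max = 59)),
               "infeasible")
})

test_that("run_experiments reports the max over per-run sizes", {
  p <- constraint_profile(3)
  cfg <- ga_config(population_size = 60, generations = 15, rng_seed = 9)
  one <- run_experiments(6, p, cfg, runs = 1)
  expect_identical(length(one$best_set), one$sizes[1])
  expect_identical(one$best_set$tags, evolve(6, p, cfg)$set$tags)
  multi <- run_experiments(6, p, cfg, runs = 4)
  expect_identical(length(multi$best_set), max(multi$sizes))
  expect_identical(multi$sizes[1], one$sizes[1])
  expect_true(validate_set(multi$best_set)$pass)
})
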