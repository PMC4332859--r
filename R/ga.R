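# Modified genetic algorithm with greedy closure.
#
# A population evolves over the 4^n word space; every generation, each
# individual that satisfies the single-tag rules and whose tag-tag edit
# distance (TTE) to the growing result set is at least d is appended to
# that set, with the TTE rechecked after every append so the closure
# invariant can never break.

#' Genetic algorithm configuration
#'
#' Hyperparameters of the greedy-closure GA. Defaults correspond to the
#' reference study conditions: population 500, crossover rate 0.45,
#' dynamic per-individual mutation rates 0.01 / 0.03 / 0.3 depending on
#' fitness relative to the population mean, 200 generations, binary
#' tournaments repeated for 10% of the population, and a single
#' population re-initialization when set growth stalls.
#'
#' @param population_size number of individuals (capped at `4^n` by
#'   [evolve()], since an evenly spread initial population cannot exceed
#'   the word space).
#' @param crossover_rate probability a parent pair undergoes three-point
#'   crossover.
#' @param mutation_rate_base per-base mutation rate for individuals fitter
#'   than the population mean.
#' @param mutation_rate_equal rate at the mean (within 1e-9).
#' @param mutation_rate_low rate below the mean (high churn for poor
#'   individuals).
#' @param generations number of generations to run.
#' @param tournament_size individuals per tournament.
#' @param tournament_fraction fraction of the population selected per
#'   generation by tournament.
#' @param reinit_policy `"stall"` re-initializes the population (once per
#'   run) after `g_stall` generations without result-set growth; `"off"`
#'   disables re-initialization.
#' @param g_stall stall length, in generations, that triggers the single
#'   re-initialization.
#' @param rng_seed integer seed; every random draw of a run flows from it.
#' @return an object of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 500,
                      crossover_rate = 0.45,
                      mutation_rate_base = 0.01,
                      mutation_rate_equal = 0.03,
                      mutation_rate_low = 0.3,
                      generations = 200,
                      tournament_size = 2,
                      tournament_fraction = 0.10,
                      reinit_policy = c("stall", "off"),
                      g_stall = 20,
                      rng_seed = 1) {
  reinit_policy <- match.arg(reinit_policy)
  rates <- c(crossover_rate, mutation_rate_base, mutation_rate_equal,
             mutation_rate_low, tournament_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  if (population_size < 2) stop("'population_size' must be >= 2", call. = FALSE)
  if (generations < 1) stop("'generations' must be >= 1", call. = FALSE)
  if (tournament_size < 2) stop("'tournament_size' must be >= 2", call. = FALSE)
  structure(
    list(population_size = as.integer(population_size),
         crossover_rate = crossover_rate,
         mutation_rate_base = mutation_rate_base,
         mutation_rate_equal = mutation_rate_equal,
         mutation_rate_low = mutation_rate_low,
         generations = as.integer(generations),
         tournament_size = as.integer(tournament_size),
         tournament_fraction = tournament_fraction,
         reinit_policy = reinit_policy,
         g_stall = as.integer(g_stall),
         rng_seed = as.integer(rng_seed)),
    class = "ga_config")
}

#' @export
print.ga_config <- function(x, ...) {
  cat("GA configuration\n",
      "  population ", x$population_size,
      ", generations ", x$generations,
      ", crossover ", x$crossover_rate, "\n",
      "  mutation rates ", x$mutation_rate_base, " / ",
      x$mutation_rate_equal, " / ", x$mutation_rate_low,
      " (above / at / below mean fitness)\n",
      "  tournament size ", x$tournament_size, ", fraction ",
      x$tournament_fraction, ", re-init ", x$reinit_policy,
      " (stall ", x$g_stall, "), seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Convert between tags and base-4 indices
#'
#' Bijection between length-n words over A/C/G/T and the integers
#' `0 .. 4^n - 1`, via base-4 positional encoding with A=0, C=1, G=2,
#' T=3 and the most significant digit first. Defines the "value range"
#' over which the initial population is spread evenly.
#'
#' @param index numeric vector of indices in `[0, 4^n)`.
#' @param n tag length.
#' @return `index_to_tag`: character vector of tags.
#' @examples
#' index_to_tag(0, 4)    # "AAAA"
#' tag_to_index("AAAC")  # 1
#' @export
index_to_tag <- function(index, n) {
  n <- as.integer(n)
  if (any(index < 0 | index >= 4^n | index != floor(index)))
    stop("index out of range [0, 4^n)", call. = FALSE)
  mat_to_tags(index_to_mat(index, n))
}

#' @rdname index_to_tag
#' @param tag character vector of tags.
#' @return `tag_to_index`: numeric vector of indices.
#' @export
tag_to_index <- function(tag) {
  tag <- check_tags(tag, require_equal_length = TRUE)
  encode_rows(tags_to_mat(tag))
}

index_to_mat <- function(index, n) {
  m <- matrix(0L, length(index), n)
  for (j in seq_len(n))
    m[, j] <- as.integer(floor(index / 4^(n - j)) %% 4)
  m
}

#' Evenly distributed initial population
#'
#' Deterministically places `k` individuals at the indices
#' `floor(i * 4^n / k)`, `i = 0..k-1`, i.e. equidistantly across the whole
#' 4^n solution space. This evenly distributed initialization gives the
#' population global coverage that uniform random sampling lacks.
#'
#' @param k population size (`k <= 4^n`).
#' @param n tag length.
#' @return character vector of `k` tags.
#' @examples
#' init_population_even(4, 2)  # "AA" "CA" "GA" "TA"
#' @export
init_population_even <- function(k, n) {
  mat_to_tags(init_population_mat(k, n))
}

init_population_mat <- function(k, n) {
  k <- as.integer(k); n <- as.integer(n)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (k > 4^n)
    stop("infeasible: population size ", k, " exceeds the 4^", n,
         " word space", call. = FALSE)
  index_to_mat(floor((0:(k - 1L)) * 4^n / k), n)
}

#' GA fitness of a candidate tag
#'
#' The objective being maximized is the tag-tag edit distance of the
#' individual to the current result set, `f(i) = TTE(u_i)`. Individuals
#' violating any single-tag rule of the profile (GC, homopolymer cap,
#' self-complementarity, or — in cross mode — complementarity to a set
#' member) are lethal and score 0. Against an empty set the TTE is
#' vacuous and the fitness is `Inf` (any such tag may seed the set).
#'
#' @param u candidate DNA sequence(s); vectorized.
#' @param S the current result set ([tag_set()] or character vector,
#'   possibly empty).
#' @param profile a [constraint_profile()].
#' @return numeric vector of fitness values (0, positive integers, or
#'   `Inf`).
#' @examples
#' fitness("ACTG", c("CAGT", "GAGT"), constraint_profile(1, gc_mode = "off",
#'   continuity_max = 4, complementarity = "none"))  # 3
#' @export
fitness <- function(u, S, profile) {
  u <- check_tags(u)
  tags <- if (inherits(S, "tag_set")) S$tags else
    if (length(S) == 0L) character(0) else check_tags(S)
  mat <- tags_to_mat(u)
  s_mat <- if (length(tags)) tags_to_mat(tags) else
    matrix(integer(0), 0L, ncol(mat))
  fitness_mat(mat, s_mat, if (length(tags)) encode_rows(s_mat) else numeric(0),
              profile)
}

# fitness on internal representation
fitness_mat <- function(pop, s_mat, s_enc, profile) {
  ok <- single_tag_ok_mat(pop, profile)
  if (profile$complementarity == "cross" && nrow(s_mat) > 0L)
    ok <- ok & !(encode_rows(revcomp_mat(pop)) %in% s_enc)
  if (nrow(s_mat) == 0L) return(ifelse(ok, Inf, 0))
  t <- as.numeric(tte_cpp(pop, s_mat))
  t[is.na(t)] <- Inf
  ifelse(ok, t, 0)
}

#' Dynamic per-individual mutation rate
#'
#' Individuals fitter than the population mean mutate gently
#' (`mutation_rate_base`), individuals at the mean slightly more
#' (`mutation_rate_equal`), and individuals below the mean aggressively
#' (`mutation_rate_low`), so poor regions of the population are churned
#' while good candidates are preserved. `Inf` (unconstrained) fitness
#' values are excluded from the mean and always receive the gentle rate.
#'
#' @param fitness numeric vector of fitness values.
#' @param mean_fitness mean of the finite fitness values of the
#'   population.
#' @param config a [ga_config()] (supplies the three rates).
#' @param tol equality tolerance.
#' @return numeric vector of per-base mutation probabilities.
#' @export
dynamic_mutation_rate <- function(fitness, mean_fitness,
                                  config = ga_config(), tol = 1e-9) {
  ifelse(!is.finite(fitness), config$mutation_rate_base,
    ifelse(abs(fitness - mean_fitness) <= tol, config$mutation_rate_equal,
      ifelse(fitness > mean_fitness, config$mutation_rate_base,
             config$mutation_rate_low)))
}

#' Tournament selection
#'
#' Runs `ceiling(tournament_fraction * length(fitness))` independent
#' tournaments. Contestants are drawn uniformly with replacement; the
#' highest fitness wins and ties are broken uniformly at random.
#'
#' @param fitness numeric vector of population fitness values.
#' @param config a [ga_config()].
#' @return integer vector of winning indices (the selected parents).
#' @export
tournament_select <- function(fitness, config = ga_config()) {
  k <- length(fitness)
  if (k == 0L) stop("empty population", call. = FALSE)
  n_t <- ceiling(config$tournament_fraction * k)
  draws <- matrix(sample.int(k, n_t * config$tournament_size, replace = TRUE),
                  nrow = n_t)
  vapply(seq_len(n_t), function(i) {
    cand <- draws[i, ]
    f <- fitness[cand]
    best <- cand[f == max(f)]
    if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  }, integer(1))
}

#' Deterministic segment exchange at given cut points
#'
#' The crossover core: cuts the parents after the given internal
#' positions and swaps alternating segments (the second, fourth, ...
#' segment come from the other parent). With three cuts this is the
#' three-point crossover used by the designer.
#'
#' @param p1,p2 equal-length parent sequences.
#' @param cuts distinct cut positions in `1 .. nchar(p1) - 1`.
#' @return character vector of the two children.
#' @examples
#' crossover_exchange("AAAA", "TTTT", c(1, 2, 3))  # "ATAT" "TATA"
#' @export
crossover_exchange <- function(p1, p2, cuts) {
  p1 <- check_tags(p1); p2 <- check_tags(p2)
  n <- nchar(p1)
  if (nchar(p2) != n) stop("parents must have equal length", call. = FALSE)
  cuts <- sort(unique(as.integer(cuts)))
  if (any(cuts < 1L | cuts > n - 1L))
    stop("cuts must lie in 1..n-1", call. = FALSE)
  a <- strsplit(p1, "", fixed = TRUE)[[1]]
  b <- strsplit(p2, "", fixed = TRUE)[[1]]
  seg <- findInterval(seq_len(n) - 1L, cuts) + 1L
  swap <- seg %% 2L == 0L
  c1 <- a; c1[swap] <- b[swap]
  c2 <- b; c2[swap] <- a[swap]
  c(paste(c1, collapse = ""), paste(c2, collapse = ""))
}

#' Three-point crossover
#'
#' With probability `crossover_rate`, draws three distinct cut positions
#' uniformly from the `n - 1` internal boundaries and exchanges
#' alternating segments between the parents; otherwise the children are
#' copies of the parents. For words shorter than 4 nt there are fewer
#' than three internal boundaries and a single-point crossover is used
#' instead.
#'
#' @param p1,p2 equal-length parent sequences.
#' @param config a [ga_config()].
#' @return character vector of the two children.
#' @export
three_point_crossover <- function(p1, p2, config = ga_config()) {
  n <- nchar(p1)
  if (runif(1) >= config$crossover_rate) return(c(toupper(p1), toupper(p2)))
  n_cuts <- if (n >= 4L) 3L else 1L
  crossover_exchange(p1, p2, sample.int(n - 1L, n_cuts))
}

#' Design a tag set with the greedy-closure genetic algorithm
#'
#' Evolves a population of candidate tags for `config$generations`
#' generations. Each generation the fitness of every individual is
#' recomputed against the current result set; every individual passing
#' all single-tag rules with TTE at least `profile$d` is appended to the
#' result set (in population order, with the TTE rechecked after every
#' append). The population then evolves steady-state: the tournament
#' winners (10% of the population) are recombined by three-point
#' crossover and their offspring displace the lowest-fitness
#' individuals, after which the whole population (except the incumbent
#' best) undergoes dynamic-rate mutation. The population is
#' re-initialized at random at most once, when the result set has not
#' grown for `config$g_stall` generations.
#'
#' The returned set always passes [validate_set()] under its own profile.
#'
#' @param n tag length.
#' @param profile a [constraint_profile()].
#' @param config a [ga_config()]; `config$rng_seed` makes the run fully
#'   reproducible.
#' @return an object of class `"ga_result"`: a list with `set` (a
#'   [tag_set()]), `log` (per-generation data.frame with columns
#'   `generation`, `set_size`, `mean_fitness`, `max_fitness`),
#'   `reinit_used`, `n`, `config`.
#' @examples
#' res <- evolve(5, constraint_profile(d = 3),
#'               ga_config(population_size = 100, generations = 20))
#' length(res$set)
#' @export
evolve <- function(n, profile, config = ga_config()) {
  n <- as.integer(n)
  stopifnot(inherits(profile, "constraint_profile"),
            inherits(config, "ga_config"))
  if (profile$d > n)
    stop("infeasible: d = ", profile$d, " exceeds the tag length ", n,
         call. = FALSE)
  if (profile$gc_mode == "fixed" && resolve_gc_count(profile, n) > n)
    stop("infeasible: gc_fixed_count exceeds the tag length", call. = FALSE)
  if (profile$gc_mode == "range" &&
      !any(100 * (0:n) / n >= profile$gc_min - 1e-9 &
           100 * (0:n) / n <= profile$gc_max + 1e-9))
    stop("infeasible: no G/C count of an n-mer falls in the GC range",
         call. = FALSE)

  set.seed(config$rng_seed)
  k <- min(config$population_size, as.integer(4^min(n, 15L)))
  pop <- init_population_mat(k, n)
  s_mat <- matrix(integer(0), 0L, n)
  s_enc <- numeric(0)

  # seed the result set: scan from a random offset for the first
  # individual passing the single-tag rules
  start <- sample.int(k, 1L)
  scan <- c(start:k, if (start > 1L) 1:(start - 1L))
  ok0 <- single_tag_ok_mat(pop, profile)
  first <- scan[which(ok0[scan])[1L]]
  if (!is.na(first)) {
    s_mat <- pop[first, , drop = FALSE]
    s_enc <- encode_rows(s_mat)
  }

  reinit_used <- FALSE
  stall <- 0L
  log_rows <- vector("list", config$generations)

  for (gen in seq_len(config$generations)) {
    fit <- fitness_mat(pop, s_mat, s_enc, profile)
    pop_enc <- encode_rows(pop)

    # greedy closure: append qualifying individuals in population order,
    # revalidating against the enlarged set after every append
    appended <- 0L
    for (i in which(fit >= profile$d)) {
      if (pop_enc[i] %in% s_enc) next
      if (nrow(s_mat) > 0L) {
        t_i <- tte_cpp(pop[i, , drop = FALSE], s_mat)[1L]
        if (!is.na(t_i) && t_i < profile$d) next
        if (profile$complementarity == "cross" &&
            encode_rows(revcomp_mat(pop[i, , drop = FALSE])) %in% s_enc) next
      }
      s_mat <- rbind(s_mat, pop[i, ])
      s_enc <- c(s_enc, pop_enc[i])
      appended <- appended + 1L
    }
    stall <- if (appended > 0L) 0L else stall + 1L

    finite <- fit[is.finite(fit)]
    log_rows[[gen]] <- data.frame(
      generation = gen, set_size = nrow(s_mat),
      mean_fitness = if (length(finite)) mean(finite) else NA_real_,
      max_fitness = max(fit))

    if (gen == config$generations) break

    if (!reinit_used && config$reinit_policy == "stall" &&
        stall >= config$g_stall) {
      # one-shot random re-initialization to escape premature convergence
      pop <- matrix(sample.int(4L, k * n, replace = TRUE) - 1L, k, n)
      reinit_used <- TRUE
      stall <- 0L
      next
    }

    # steady-state replacement: the tournament winners (10% of the
    # population) breed, and their offspring displace the lowest-fitness
    # slots; the rest of the population is carried over so the global
    # coverage of the even initialization persists
    winners <- tournament_select(fit, config)
    nw <- length(winners)
    pa <- winners[sample.int(nw, ceiling(nw / 2), replace = TRUE)]
    pb <- winners[sample.int(nw, ceiling(nw / 2), replace = TRUE)]
    child1 <- pop[pa, , drop = FALSE]
    child2 <- pop[pb, , drop = FALSE]
    n_cuts <- if (n >= 4L) 3L else if (n >= 2L) 1L else 0L
    if (n_cuts > 0L) {
      do_x <- runif(length(pa)) < config$crossover_rate
      for (p in which(do_x)) {
        cuts <- sort(sample.int(n - 1L, n_cuts))
        seg <- findInterval(seq_len(n) - 1L, cuts) + 1L
        swap <- seg %% 2L == 0L
        tmp <- child1[p, swap]
        child1[p, swap] <- child2[p, swap]
        child2[p, swap] <- tmp
      }
    }
    offspring <- rbind(child1, child2)[seq_len(nw), , drop = FALSE]
    displaced <- order(fit)[seq_len(nw)]
    pop[displaced, ] <- offspring
    # offspring inherit the fitness class of the parent they derive from
    fit[displaced] <- fit[c(pa, pb)][seq_len(nw)]

    # population-wide dynamic mutation; the current best is exempt so the
    # incumbent is never lost (elitism of 1)
    finite2 <- fit[is.finite(fit)]
    mean_fit <- if (length(finite2)) mean(finite2) else 0
    rate <- dynamic_mutation_rate(fit, mean_fit, config)
    rate[which.max(fit)] <- 0
    mut <- matrix(runif(k * n), k, n) < matrix(rate, k, n)
    n_mut <- sum(mut)
    if (n_mut > 0L)
      pop[mut] <- (pop[mut] + sample.int(3L, n_mut, replace = TRUE)) %% 4L
  }

  structure(
    list(set = tag_set(mat_to_tags(s_mat), profile),
         log = do.call(rbind, log_rows),
         reinit_used = reinit_used, n = n, config = config),
    class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Greedy-closure GA run (n = ", x$n, ", d = ", x$set$profile$d,
      ", seed ", x$config$rng_seed, ")\n",
      "  result set size : ", length(x$set), "\n",
      "  re-init used    : ", x$reinit_used, "\n", sep = "")
  invisible(x)
}

#' Repeated GA runs with independent seeds
#'
#' Runs [evolve()] `runs` times with seeds `rng_seed + 0 .. runs - 1` and
#' reports the largest result set found, the argmax run, and all
#' per-run sizes. Because the designer is stochastic, published set
#' sizes are maxima over repeated runs; this mirrors that protocol.
#'
#' @param n tag length.
#' @param profile a [constraint_profile()].
#' @param config a [ga_config()]; its `rng_seed` is the base seed.
#' @param runs number of independent runs.
#' @return an object of class `"ga_experiment"`: list with `best_set`,
#'   `best_seed`, `sizes` (per-run), `runs`.
#' @export
run_experiments <- function(n, profile, config = ga_config(), runs = 25) {
  runs <- as.integer(runs)
  if (runs < 1L) stop("'runs' must be >= 1", call. = FALSE)
  sizes <- integer(runs)
  best <- NULL
  best_seed <- NA_integer_
  for (r in seq_len(runs)) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + r - 1L
    res <- evolve(n, profile, cfg)
    sizes[r] <- length(res$set)
    if (is.null(best) || sizes[r] > length(best)) {
      best <- res$set
      best_seed <- cfg$rng_seed
    }
  }
  structure(list(best_set = best, best_seed = best_seed,
                 sizes = sizes, runs = runs, n = n),
            class = "ga_experiment")
}

#' @export
print.ga_experiment <- function(x, ...) {
  cat("GA experiment: ", x$runs, " runs, n = ", x$n, ", d = ",
      x$best_set$profile$d, "\n",
      "  best set size : ", length(x$best_set),
      " (seed ", x$best_seed, ")\n",
      "  per-run sizes : ", paste(x$sizes, collapse = " "), "\n", sep = "")
  invisible(x)
}
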