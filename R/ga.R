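# Genetic algorithm over custom-cell genomes.
#
# A genome is one row of a numeric matrix: a scaling factor per searchable
# channel (uniform on [1e-4, 10] at initialization), a gap-junction scale
# (same range, applied to the 1 nS baseline), and the integer custom-cell
# count n_custom (discrete uniform on 1..5). One generation = selection
# (pairwise tournament, two passes), crossover (0.9 per pair, 0.5 per
# parameter), mutation (0.01 per parameter, log-normal sigma 0.2), elitism
# (top 10% overwrite bottom 10%).

#' Genetic-algorithm configuration
#'
#' @param population Population size (even; 2500 for replication runs).
#' @param generations Number of generations (5 for replication runs).
#' @param crossover_prob Probability that a random pair recombines.
#' @param swap_prob Per-parameter exchange probability within a recombining pair.
#' @param mutation_prob Per-parameter mutation probability.
#' @param mutation_sd_log Standard deviation of the mutation multiplier in
#'   natural-log space. The default 0.2 puts >99.9% of multipliers inside a
#'   0.5- to 2-fold change.
#' @param elite_frac Fraction of the population copied over the worst
#'   individuals each generation.
#' @param seed RNG seed, recorded in outputs.
#' @param scaling_range Initialization range for continuous scalings
#'   (0.01% to 1000% of baseline).
#' @param n_custom_range Integer range for the coupled-cell count.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population = 2500L, generations = 5L,
                      crossover_prob = 0.9, swap_prob = 0.5,
                      mutation_prob = 0.01, mutation_sd_log = 0.2,
                      elite_frac = 0.10, seed = 1L,
                      scaling_range = c(1e-4, 10),
                      n_custom_range = c(1L, 5L)) {
  stopifnot(population >= 2, population %% 2 == 0, generations >= 0,
            crossover_prob >= 0, crossover_prob <= 1,
            swap_prob >= 0, swap_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            mutation_sd_log >= 0, elite_frac >= 0, elite_frac <= 0.5,
            scaling_range[1] > 0, scaling_range[2] > scaling_range[1])
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob, swap_prob = swap_prob,
                 mutation_prob = mutation_prob,
                 mutation_sd_log = mutation_sd_log,
                 elite_frac = elite_frac, seed = as.integer(seed),
                 scaling_range = scaling_range,
                 n_custom_range = as.integer(n_custom_range)),
            class = "ga_config")
}

genome_colnames <- function(channels) c(channels, "g_gap_scale", "n_custom")

#' Initialize a genome population
#'
#' Continuous parameters (channel scalings and the gap-junction scale) are
#' i.i.d. uniform on the linear `scaling_range`; `n_custom` is discrete
#' uniform on `n_custom_range`.
#'
#' @param cfg A [ga_config()].
#' @param channels Character vector of searchable channel names. An empty
#'   roster is an error unless `.allow_empty` (used internally by the
#'   control presets whose only searchable parameters are the gap-junction
#'   scale and cell count).
#' @param .allow_empty Permit zero searchable channels.
#' @return Numeric matrix, one genome per row.
#' @export
init_population <- function(cfg, channels, .allow_empty = FALSE) {
  stopifnot(inherits(cfg, "ga_config"))
  if (length(channels) == 0 && !.allow_empty)
    stop("empty channel roster")
  n <- cfg$population
  ncont <- length(channels) + 1
  pop <- matrix(runif(n * ncont, cfg$scaling_range[1], cfg$scaling_range[2]),
                nrow = n)
  pop <- cbind(pop, sample(cfg$n_custom_range[1]:cfg$n_custom_range[2], n,
                           replace = TRUE))
  colnames(pop) <- genome_colnames(channels)
  pop
}

score_frame <- function(rmse_ap, rmse_cat) {
  rmse_ap[!is.finite(rmse_ap)] <- Inf
  rmse_cat[!is.finite(rmse_cat)] <- Inf
  data.frame(rmse_ap = rmse_ap, rmse_cat = rmse_cat,
             n_pass = (rmse_ap < 0.5) + (rmse_cat < 0.5),
             total = rmse_ap + rmse_cat)
}

# winner of a single pair: more objectives < 0.5 wins; tie -> lower summed
# RMSE; tie of ties -> the first of the pair
pair_winner <- function(scores, i, j) {
  ni <- scores$n_pass[i]; nj <- scores$n_pass[j]
  if (ni != nj) return(if (ni > nj) i else j)
  ti <- scores$total[i]; tj <- scores$total[j]
  if (ti <= tj) i else j
}

#' Pairwise tournament selection
#'
#' Random pairing of the full population with the winner of each pair kept,
#' performed twice independently so the advancing count equals the population
#' size (each individual advances 0, 1, or 2 times).
#'
#' @param population Genome matrix.
#' @param scores Score data.frame from the objective (one row per genome).
#' @return List with the selected `population` and `scores` (row-matched),
#'   plus the selected `idx`.
#' @export
tournament_select <- function(population, scores) {
  n <- nrow(population)
  if (n %% 2 != 0) stop("population size must be even for pairing")
  pick <- integer(0)
  for (pass in 1:2) {
    perm <- sample.int(n)
    for (k in seq_len(n / 2)) {
      i <- perm[2 * k - 1]; j <- perm[2 * k]
      pick <- c(pick, pair_winner(scores, i, j))
    }
  }
  list(population = population[pick, , drop = FALSE],
       scores = scores[pick, , drop = FALSE], idx = pick)
}

#' Crossover of one genome pair
#'
#' With probability `crossover_prob` the pair recombines: each parameter
#' independently exchanges between the two genomes with probability
#' `swap_prob`. Otherwise the pair is returned unchanged.
#'
#' @param a,b Genomes (named numeric vectors or single-row matrices).
#' @param cfg A [ga_config()].
#' @return List with elements `a` and `b`.
#' @export
crossover_pair <- function(a, b, cfg) {
  a <- drop(a); b <- drop(b)
  if (runif(1) < cfg$crossover_prob) {
    swap <- runif(length(a)) < cfg$swap_prob
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  list(a = a, b = b)
}

# population-level crossover: random re-pairing, then pairwise exchange
crossover_population <- function(population, cfg) {
  n <- nrow(population)
  perm <- sample.int(n)
  out <- population
  for (k in seq_len(n / 2)) {
    i <- perm[2 * k - 1]; j <- perm[2 * k]
    cp <- crossover_pair(population[i, ], population[j, ], cfg)
    out[i, ] <- cp$a; out[j, ] <- cp$b
  }
  out
}

#' Mutate a genome population
#'
#' Each parameter independently mutates with probability `mutation_prob`; a
#' mutated parameter is multiplied by `exp(N(0, mutation_sd_log))`. Mutated
#' continuous values may leave the initialization range (fold-changes beyond
#' 10x arise this way); the integer cell count is multiplied, rounded, and
#' clamped to `n_custom_range`.
#'
#' @param population Genome matrix (or a single genome as a named vector).
#' @param cfg A [ga_config()].
#' @return Mutated population of the same shape.
#' @export
mutate_population <- function(population, cfg) {
  single <- is.null(dim(population))
  if (single) population <- matrix(population, nrow = 1,
                                   dimnames = list(NULL, names(population)))
  n <- nrow(population); p <- ncol(population)
  mask <- matrix(runif(n * p) < cfg$mutation_prob, n, p)
  mult <- matrix(1, n, p)
  nm <- sum(mask)
  if (nm > 0) mult[mask] <- exp(rnorm(nm, 0, cfg$mutation_sd_log))
  out <- population * mult
  nc <- p  # n_custom is the last column
  out[, nc] <- pmin(pmax(round(out[, nc]), cfg$n_custom_range[1]),
                    cfg$n_custom_range[2])
  if (single) out <- out[1, ] else out
}

#' Elitism
#'
#' Ranks by (number of objectives < 0.5 descending, summed normalized RMSE
#' ascending) and overwrites the worst `elite_frac` fraction of `population`
#' with copies of the best. By default the elites come from the same
#' population; [run_ga()] passes the previous generation as `elite_from`, so
#' each generation's top 10% survive into the next (which is what guarantees
#' the best summed RMSE never worsens under a deterministic objective).
#'
#' @param population Genome matrix.
#' @param scores Matching score data.frame.
#' @param elite_frac Fraction copied (default from the replication protocol).
#' @param elite_from Optional list(population, scores) supplying the elites
#'   (defaults to `population`/`scores`).
#' @return List with updated `population` and `scores`.
#' @export
elitism <- function(population, scores, elite_frac = 0.10, elite_from = NULL) {
  n <- nrow(population)
  k <- floor(n * elite_frac)
  if (k < 1) return(list(population = population, scores = scores))
  src_pop <- if (is.null(elite_from)) population else elite_from$population
  src_sc <- if (is.null(elite_from)) scores else elite_from$scores
  best <- order(-src_sc$n_pass, src_sc$total)[seq_len(k)]
  ord <- order(-scores$n_pass, scores$total)
  worst <- ord[(n - k + 1):n]
  population[worst, ] <- src_pop[best, , drop = FALSE]
  scores[worst, ] <- src_sc[best, , drop = FALSE]
  list(population = population, scores = scores)
}

#' Run the genetic algorithm
#'
#' Evaluates the initial population (generation 0) and then applies
#' `generations` rounds of selection, crossover, mutation, and elitism, in
#' that order, re-evaluating after mutation. Individuals whose simulation
#' fails receive worst-case scores (infinite RMSE) instead of aborting the
#' run. The whole run is deterministic given `cfg$seed`.
#'
#' @param cfg A [ga_config()].
#' @param channels Searchable channel names (genome columns; may be empty for
#'   control presets).
#' @param objective Function mapping a genome matrix to a data.frame with
#'   columns `rmse_ap` and `rmse_cat` (one row per genome). Build one from a
#'   coupled-simulation preset with [make_objective()], or supply a surrogate.
#' @return Object of class `generation_log`: list with `generations` (a list
#'   of data.frames: genome columns + rmse_ap + rmse_cat + n_pass + accepted;
#'   element 1 is generation 0), `cfg`, and `channels`.
#' @export
run_ga <- function(cfg, channels, objective) {
  stopifnot(inherits(cfg, "ga_config"), is.function(objective))
  set.seed(cfg$seed)
  pop <- init_population(cfg, channels, .allow_empty = TRUE)
  sc <- eval_objective(objective, pop)
  gens <- list(log_generation(pop, sc))
  if (cfg$generations > 0) {
    for (g in seq_len(cfg$generations)) {
      sel <- tournament_select(pop, sc)
      pop2 <- crossover_population(sel$population, cfg)
      pop3 <- mutate_population(pop2, cfg)
      sc3 <- eval_objective(objective, pop3)
      el <- elitism(pop3, sc3, cfg$elite_frac,
                    elite_from = list(population = pop, scores = sc))
      pop <- el$population; sc <- el$scores
      gens[[g + 1]] <- log_generation(pop, sc)
    }
  }
  structure(list(generations = gens, cfg = cfg, channels = channels),
            class = "generation_log")
}

eval_objective <- function(objective, pop) {
  res <- objective(pop)
  stopifnot(is.data.frame(res), nrow(res) == nrow(pop),
            all(c("rmse_ap", "rmse_cat") %in% names(res)))
  score_frame(res$rmse_ap, res$rmse_cat)
}

log_generation <- function(pop, sc) {
  df <- as.data.frame(pop)
  df$rmse_ap <- sc$rmse_ap
  df$rmse_cat <- sc$rmse_cat
  df$n_pass <- sc$n_pass
  df$accepted <- sc$n_pass == 2
  df
}

#' @export
print.generation_log <- function(x, ...) {
  cat("<generation_log>", length(x$generations) - 1, "generation(s), population",
      x$cfg$population, "\n")
  for (g in seq_along(x$generations)) {
    df <- x$generations[[g]]
    cat(sprintf("  gen %d: accepted %d/%d, best total RMSE %.3f\n",
                g - 1, sum(df$accepted), nrow(df),
                min(df$rmse_ap + df$rmse_cat)))
  }
  invisible(x)
}
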