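# GA operators and the full loop on surrogate objectives (no simulator).

chans2 <- c("cm_cal", "cm_k1")

# deterministic surrogate: quadratic bowls around known optima, mapped into
# the normalized-RMSE scale
sphere_objective <- function(opt_ap = c(cm_cal = 4, g_gap_scale = 7),
                             opt_cat = c(cm_k1 = 3, n_custom = 4)) {
  function(pop) {
    ap <- 0.2 + ((pop[, "cm_cal"] - opt_ap[["cm_cal"]]) / 10)^2 +
      ((pop[, "g_gap_scale"] - opt_ap[["g_gap_scale"]]) / 10)^2
    ca <- 0.2 + ((pop[, "cm_k1"] - opt_cat[["cm_k1"]]) / 10)^2 +
      ((pop[, "n_custom"] - opt_cat[["n_custom"]]) / 5)^2
    data.frame(rmse_ap = ap, rmse_cat = ca)
  }
}

test_that("initial population has the stated marginals and is seed-reproducible", {
  cfg <- ga_config(population = 2500L, seed = 99L)
  set.seed(cfg$seed)
  pop <- init_population(cfg, chans2)
  expect_identical(dim(pop), c(2500L, 4L))
  expect_identical(colnames(pop), c(chans2, "g_gap_scale", "n_custom"))
  # uniform on [1e-4, 10]: mean ~ 5.00005, sd ~ 10/sqrt(12); 3 standard errors
  se <- (10 / sqrt(12)) / sqrt(2500)
  for (cn in c(chans2, "g_gap_scale")) {
    expect_lt(abs(mean(pop[, cn]) - 5.00005), 3 * se)
    expect_gte(min(pop[, cn]), 1e-4)
    expect_lte(max(pop[, cn]), 10)
  }
  # n_custom ~ discrete uniform over 1..5 (chi-square sanity at alpha ~ 1e-4)
  counts <- table(factor(pop[, "n_custom"], levels = 1:5))
  chi2 <- sum((counts - 500)^2 / 500)
  expect_lt(chi2, 23.5)
  # determinism
  set.seed(cfg$seed)
  expect_identical(init_population(cfg, chans2), pop)
  # empty roster guard
  expect_error(init_population(cfg, character(0)), "empty")
})

test_that("tournament selection implements the pass-count and tie-break rules", {
  sf <- cellforge:::score_frame
  # A wins on objective count: one value < 0.5 beats zero
  s <- sf(c(0.40, 0.60), c(0.60, 0.60))
  expect_identical(cellforge:::pair_winner(s, 1L, 2L), 1L)
  expect_identical(cellforge:::pair_winner(s, 2L, 1L), 1L)   # order-independent
  # tie on count -> lower summed RMSE
  s <- sf(c(0.60, 0.55), c(0.60, 0.70))
  expect_identical(cellforge:::pair_winner(s, 1L, 2L), 1L)   # 1.20 < 1.25
  # tie of ties -> first of pair
  s <- sf(c(0.6, 0.6), c(0.6, 0.6))
  expect_identical(cellforge:::pair_winner(s, 1L, 2L), 1L)
  expect_identical(cellforge:::pair_winner(s, 2L, 1L), 2L)
  # two passes keep the population size; each individual advances 0..2 times
  cfg <- ga_config(population = 100L, seed = 5L)
  set.seed(5)
  pop <- init_population(cfg, chans2)
  sc <- sf(runif(100), runif(100))
  sel <- tournament_select(pop, sc)
  expect_identical(nrow(sel$population), 100L)
  expect_true(all(table(sel$idx) <= 2))
  # odd population errors
  expect_error(tournament_select(pop[1:99, ], sc[1:99, ]), "even")
})

test_that("crossover identities and composed swap probability", {
  cfg0 <- ga_config(population = 10L, crossover_prob = 0)
  a <- c(cm_cal = 1, cm_k1 = 2, g_gap_scale = 3, n_custom = 4)
  b <- c(cm_cal = 5, cm_k1 = 6, g_gap_scale = 7, n_custom = 2)
  set.seed(1)
  cp <- crossover_pair(a, b, cfg0)
  expect_identical(cp$a, a); expect_identical(cp$b, b)
  # identical parents are invariant under any draws
  cfg <- ga_config(population = 10L)
  set.seed(2)
  cp <- crossover_pair(a, a, cfg)
  expect_identical(cp$a, a); expect_identical(cp$b, a)
  # Monte Carlo: per-parameter swap frequency = 0.9 * 0.5 over 1e5 pairs
  set.seed(314)
  n <- 1e5
  swapped <- logical(n)
  for (k in seq_len(n)) {
    cp <- crossover_pair(c(x = 0, y = 0), c(x = 1, y = 1), cfg)
    swapped[k] <- cp$a[["x"]] == 1
  }
  p <- mean(swapped)
  se <- sqrt(0.45 * 0.55 / n)
  expect_lt(abs(p - 0.45), 3 * se)
})

test_that("mutation identities, multiplier range, and integer clamping", {
  a <- c(cm_cal = 1, cm_k1 = 2, g_gap_scale = 3, n_custom = 4)
  cfg0 <- ga_config(population = 10L, mutation_prob = 0)
  set.seed(3)
  expect_identical(mutate_population(a, cfg0), a)
  # forced mutation of 1e6 continuous parameters: multipliers within [0.5, 2]
  # with frequency > 0.999, median ~ 1 (log-symmetry)
  cfg1 <- ga_config(population = 10L, mutation_prob = 1)
  set.seed(17)
  vals <- matrix(1, 1e6, 2,
                 dimnames = list(NULL, c("g_gap_scale", "n_custom")))
  vals[, 2] <- 3
  out <- mutate_population(vals, cfg1)
  mult <- out[, 1]                     # input was 1, so output == multiplier
  expect_gt(mean(mult >= 0.5 & mult <= 2), 0.999)
  expect_equal(median(mult), 1, tolerance = 0.005)
  # n_custom stays integer inside [1, 5]
  expect_true(all(out[, 2] == round(out[, 2])))
  expect_gte(min(out[, 2]), 1); expect_lte(max(out[, 2]), 5)
})

test_that("elitism copies the best over the worst and fixes degenerate cases", {
  pop <- matrix(1:20, nrow = 10,
                dimnames = list(NULL, c("g_gap_scale", "n_custom")))
  sc <- cellforge:::score_frame(seq(0.51, 0.60, by = 0.01), rep(0.6, 10))
  out <- elitism(pop, sc, elite_frac = 0.10)
  # worst individual (row 10) replaced by a copy of the best (row 1)
  expect_identical(out$population[10, ], pop[1, ])
  expect_identical(out$scores$total[10], sc$total[1])
  expect_identical(nrow(out$population), 10L)
  # all-identical population unchanged
  same <- cellforge:::score_frame(rep(0.6, 10), rep(0.6, 10))
  out2 <- elitism(pop, same, 0.10)
  expect_identical(out2$scores, same)
})

test_that("GA on a quadratic surrogate improves and respects constraints", {
  obj <- sphere_objective()
  dist_best <- function(df) {
    i <- which.min(df$rmse_ap + df$rmse_cat)
    sqrt((df$cm_cal[i] - 4)^2 + (df$g_gap_scale[i] - 7)^2 + (df$cm_k1[i] - 3)^2)
  }
  deltas <- acc0 <- accN <- numeric(10)
  for (sd_ in 1:10) {
    cfg <- ga_config(population = 60L, generations = 4L, seed = sd_)
    log <- run_ga(cfg, chans2, obj)
    g0 <- log$generations[[1]]; gN <- log$generations[[5]]
    # elitism guarantee: best total never worsens across generations
    bests <- sapply(log$generations, function(df) min(df$rmse_ap + df$rmse_cat))
    expect_true(all(diff(bests) <= 1e-12))
    # bounds and integrality after all operators
    for (df in log$generations) {
      expect_true(all(df$n_custom %in% 1:5))
      expect_true(all(df[c(chans2, "g_gap_scale")] > 0))
    }
    deltas[sd_] <- dist_best(gN) - dist_best(g0)
    acc0[sd_] <- mean(g0$accepted); accN[sd_] <- mean(gN$accepted)
  }
  # across seeds: the best genome moves toward the optimum and acceptance grows
  expect_lt(mean(deltas), 0)
  expect_gt(mean(accN), mean(acc0))
})

test_that("generations = 0 returns the scored initial population; seeded reruns are identical", {
  obj <- sphere_objective()
  cfg <- ga_config(population = 20L, generations = 0L, seed = 8L)
  log <- run_ga(cfg, chans2, obj)
  expect_length(log$generations, 1)
  expect_identical(nrow(log$generations[[1]]), 20L)
  log2 <- run_ga(cfg, chans2, obj)
  expect_identical(log, log2)
})

test_that("failed evaluations get worst-case scores instead of aborting", {
  obj <- function(pop) {
    data.frame(rmse_ap = c(NA, 0.4, Inf)[seq_len(nrow(pop)) %% 3 + 1],
               rmse_cat = 0.4)
  }
  cfg <- ga_config(population = 6L, generations = 1L, seed = 2L)
  log <- run_ga(cfg, chans2, obj)
  g0 <- log$generations[[1]]
  expect_true(all(is.finite(g0$n_pass)))
  expect_true(any(!is.finite(g0$rmse_ap)))
})
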