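test_that("empirical P follows the add-one tail convention", {
  toy <- structure(list(counts = c(5L, 10L, 15L), B = 3L, mu = 10,
                        sd = 5, nb = fit_null_nb(c(5L, 10L, 15L))),
                   class = "null_count_distribution")
  expect_equal(empirical_p(10, toy), 3 / 4)        # r = 2 counts >= 10
  expect_equal(empirical_p(0, toy), 1)             # every count >= 0
  expect_equal(empirical_p(100, toy), 1 / 4)       # exceeds all counts
  expect_equal(empirical_p(10, toy, add_one = FALSE), 2 / 3)
})

test_that("z-score is the standardized deviation from the null mean", {
  null <- structure(list(counts = integer(), B = 0L, mu = 98.3, sd = 23.8),
                    class = "null_count_distribution")
  expect_equal(null_zscore(159, null), (159 - 98.3) / 23.8)  # ~2.55
  expect_equal(round(null_zscore(159, null), 2), 2.55)
  expect_equal(null_zscore(98.3, null), 0)
  degen <- structure(list(mu = 5, sd = 0), class = "null_count_distribution")
  expect_true(is.na(null_zscore(7, degen)))
  expect_equal(attr(null_zscore(7, degen), "flag"), "sd_zero")
})

test_that("NB-modified P matches the generating tail and is monotone", {
  set.seed(31)
  ## null counts drawn from NB(mu = 100, var = 600)
  mu <- 100; v <- 600
  size <- mu^2 / (v - mu); prob <- mu / v
  counts <- rnbinom(1000, size = size, prob = prob)
  null <- structure(list(counts = counts, B = 1000L, mu = mean(counts),
                         sd = sd(counts), nb = fit_null_nb(counts)),
                    class = "null_count_distribution")
  p_fit <- nb_modified_p(170, null)
  p_true <- pnbinom(169, size = size, prob = prob, lower.tail = FALSE)
  expect_lt(abs(log10(p_fit / p_true)), 0.3)
  ## strictly decreasing in N_obs; N_obs = 0 has full mass above it
  grid <- vapply(0:250, nb_modified_p, numeric(1), null = null)
  expect_equal(grid[1], 1)
  expect_true(all(diff(grid) < 0))
  ## method-of-moments invariant: fitted NB reproduces the null mean
  fit <- null$nb
  expect_equal(fit$size * (1 - fit$prob) / fit$prob, mean(counts),
               tolerance = 1e-9)
  ## underdispersed counts fall back to Poisson
  expect_equal(fit_null_nb(rep(3L, 50))$family, "poisson")
})

test_that("permutation nulls are deterministic and shared across genes", {
  co <- null_cohort(seed = 32, n_patients = 60, n_features = 100)
  norm <- tmm_normalize(co$counts)
  de <- fast_engine()
  n1 <- simulate_null(co, 0.20, B = 100, seed = 7, de = de, norm = norm)
  n2 <- simulate_null(co, 0.20, B = 100, seed = 7, de = de, norm = norm)
  expect_identical(n1$counts, n2$counts)           # byte-identical
  expect_equal(n1$n_mutant, round(0.20 * 60))
  ## two genes with the same category score against the identical null
  nulls <- build_null_distributions(co, c(0.20, 0.20, 0.35), B = 100,
                                    master_seed = 3, de = de, norm = norm)
  expect_named(nulls, c("0.20", "0.35"))
  expect_error(simulate_null(co, 0.22, B = 100), "grid")
  expect_warning(simulate_null(co, 0.20, B = 50, seed = 1, de = de,
                               norm = norm), "unstable")
})

test_that("extreme counts are rare under an exchangeable null", {
  co <- null_cohort(seed = 33, n_patients = 100, n_features = 200)
  norm <- tmm_normalize(co$counts)
  de <- fast_engine()
  hi <- simulate_null(co, 0.50, B = 150, seed = 6, de = de, norm = norm)
  expect_lte(mean(hi$counts >= hi$mu + 3 * hi$sd), 0.02)
})

test_that("assess_impact wires N_obs to all three statistics", {
  sim <- simulate_cohort(sim_config(seed = 34, n_patients = 80,
                                    n_features = 150, n_genes = 2,
                                    mutation_freqs = c(0.25, 0.3),
                                    effects = list(list(gene = 1, k = 50,
                                                        log2fc = 1.5))))
  co <- sim$cohort
  norm <- tmm_normalize(co$counts)
  de <- fast_engine()
  ctx <- build_contexts(sim$mutations, co)
  cats <- unique(vapply(ctx, `[[`, numeric(1), "category"))
  nulls <- build_null_distributions(co, cats, B = 150, master_seed = 9,
                                    de = de, norm = norm)
  tab <- assess_impacts(ctx, co, nulls, de = de, norm = norm)
  expect_equal(nrow(tab), length(ctx))
  g1 <- tab[tab$gene == "GENE01", ]
  g2 <- tab[tab$gene == "GENE02", ]
  expect_true(g1$significant)                      # true impacted gene
  expect_gt(g1$z, 1.96)
  expect_false(g2$significant)                     # null gene
  ## missing null category is an instructive error
  expect_error(assess_impact(ctx[[1]], co, nulls["0.35"], de = de,
                             norm = norm), "simulate_null")
})

test_that("null cache round-trips through TSV + JSON", {
  co <- null_cohort(seed = 35, n_patients = 40, n_features = 60)
  de <- fast_engine()
  norm <- tmm_normalize(co$counts)
  null <- simulate_null(co, 0.25, B = 100, seed = 2, de = de, norm = norm)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "null.tsv"); js <- file.path(dir, "null.json")
  write_null_distribution(null, tsv, js)
  back <- read_null_distribution(tsv, js)
  expect_identical(back$counts, null$counts)
  expect_equal(back$mu, null$mu)
  expect_equal(back$nb, null$nb)
})
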