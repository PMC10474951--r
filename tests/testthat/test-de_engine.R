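test_that("TMM factors are symmetric, scale-equivariant, and agree with edgeR", {
  set.seed(21)
  y <- matrix(rnbinom(200 * 6, mu = 50, size = 5), nrow = 200,
              dimnames = list(NULL, paste0("s", 1:6)))
  ## identical samples -> unit factors
  two <- cbind(a = y[, 1], b = y[, 1])
  nf <- tmm_normalize(two)
  expect_equal(unname(nf$scale_factor), c(1, 1))
  ## doubling a sample is absorbed by the library size, not the factor
  dbl <- cbind(a = y[, 1], b = 2 * y[, 1])
  nf2 <- tmm_normalize(dbl)
  expect_equal(unname(nf2$scale_factor), c(1, 1), tolerance = 1e-6)
  ## tripling one sample triples its effective library size (within 1%)
  nf_a <- tmm_normalize(y)
  y3 <- y; y3[, 3] <- y3[, 3] * 3
  nf_b <- tmm_normalize(y3)
  ratio <- effective_lib_size(nf_b)[3] / effective_lib_size(nf_a)[3]
  expect_lt(abs(ratio - 3) / 3, 0.01)
  ## geometric-mean-1 invariant
  expect_equal(exp(mean(log(nf_a$scale_factor))), 1, tolerance = 1e-12)
  expect_error(tmm_normalize(cbind(y[, 1], 0)), "positive total")
  ## independent cross-check against edgeR on heterogeneous libraries
  skip_if_not_installed("edgeR")
  set.seed(22)
  yy <- matrix(rnbinom(500 * 8, mu = exp(runif(500, 0, 6)), size = 3),
               nrow = 500)
  yy[, 1] <- yy[, 1] * 4L
  ours <- tmm_normalize(yy)$scale_factor
  theirs <- edgeR::calcNormFactors(yy, method = "TMM")
  expect_lt(max(abs(log(ours / theirs))), 0.05)
})

test_that("moment dispersion estimates recover the truth", {
  set.seed(23)
  n <- 200
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  lib <- rep(1e4, n)
  ## Poisson counts: estimated dispersion should be near zero
  mu <- exp(runif(300, log(5), log(500)))
  ypois <- matrix(rpois(300 * n, rep(mu, n)), nrow = 300)
  norm <- tmm_normalize(ypois)
  d0 <- estimate_dispersions(ypois, labels, norm, shrink_weight = 0)
  expect_lte(median(d0), 0.05)
  ## NB with dispersion 0.4: median estimate in [0.25, 0.6]
  ynb <- matrix(rnbinom(300 * n, mu = rep(mu, n), size = 1 / 0.4), nrow = 300)
  d4 <- estimate_dispersions(ynb, labels, tmm_normalize(ynb),
                             shrink_weight = 0)
  expect_gte(median(d4), 0.25)
  expect_lte(median(d4), 0.6)
  ## degenerate all-zero feature gets the common dispersion, not NaN
  yz <- rbind(ynb, 0)
  dz <- estimate_dispersions(yz, labels, tmm_normalize(yz))
  expect_true(is.finite(dz[nrow(yz)]) && dz[nrow(yz)] > 0)
})

test_that("NB-GLM raw p-values are null-calibrated under label exchange", {
  set.seed(24)
  n <- 100
  mu <- exp(runif(2000, log(10), log(1000)))
  y <- matrix(rnbinom(2000 * n, mu = rep(mu, n), size = 1 / 0.2), nrow = 2000)
  labels <- sample(rep(c(TRUE, FALSE), each = n / 2))
  de <- nb_glm_test(y, labels)
  p <- de$raw_p[de$tested]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  ## rejection rate within 3 binomial SDs of alpha
  for (alpha in c(0.01, 0.05, 0.1)) {
    frac <- mean(p < alpha)
    expect_lt(abs(frac - alpha), 3 * sqrt(alpha * (1 - alpha) / length(p)) + 1e-9)
  }
})

test_that("NB-GLM detects strong true effects and flags no-signal features", {
  set.seed(25)
  n <- 200
  labels <- rep(c(TRUE, FALSE), each = 100)
  mu <- exp(runif(300, log(20), log(500)))
  fc <- ifelse(seq_len(300) <= 30, 2, 0)           # 10% with |log2FC| = 2
  mumat <- outer(mu, rep(1, n)) * 2^(fc %o% labels)
  y <- matrix(rnbinom(300 * n, mu = mumat, size = 1 / 0.2), nrow = 300)
  de <- nb_glm_test(y, labels)
  expect_gte(mean(de$q[1:30] < 0.05), 0.90)
  expect_gt(median(de$logFC[1:30]), 1.5)           # direction and magnitude
  ## constant feature: p = 1, logFC = 0
  yc <- rbind(y, 7L)
  dec <- nb_glm_test(yc, labels, min_total_count = 5)
  expect_equal(dec$raw_p[nrow(yc)], 1)
  expect_equal(dec$logFC[nrow(yc)], 0)
  ## N is non-increasing as the FDR threshold tightens
  n10 <- attr(nb_glm_test(y, labels, fdr_threshold = 0.10), "N")
  n05 <- attr(nb_glm_test(y, labels, fdr_threshold = 0.05), "N")
  n01 <- attr(nb_glm_test(y, labels, fdr_threshold = 0.01), "N")
  expect_true(n10 >= n05 && n05 >= n01)
})

test_that("BH adjustment matches the brute-force oracle and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(26)
  for (i in 1:200) {
    p <- round(runif(sample(1:50, 1)), 3)
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the edgeR backend agrees with the in-package engine on strong signal", {
  skip_if_not_installed("edgeR")
  set.seed(27)
  sim <- simulate_cohort(sim_config(seed = 27, n_patients = 80,
                                    n_features = 150, n_genes = 1,
                                    mutation_freqs = 0.4,
                                    effects = list(list(gene = 1, k = 40,
                                                        log2fc = 2))))
  labels <- sim$mutations[1, ] == 1
  ours <- de_engine_nbglm()(sim$cohort$counts, labels)
  theirs <- de_engine_edger()(sim$cohort$counts, labels)
  truth <- sim$truth$responsive$feature
  hit <- function(de) de$feature[!is.na(de$q) & de$q < 0.05]
  ## both engines recover essentially the same responsive set
  expect_gte(length(intersect(hit(ours), truth)) / length(truth), 0.85)
  expect_gte(length(intersect(hit(ours), hit(theirs))) /
               length(union(hit(ours), hit(theirs))), 0.8)
})
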