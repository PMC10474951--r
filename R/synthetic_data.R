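#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort
#' generator.  Defaults describe a mid-sized sequencing cohort: 100
#' patients, 300 features, library sizes log-normal around one million
#' reads with 30% coefficient of variation, per-feature baseline means
#' log-uniform over 1-1000 counts, NB dispersions log-uniform over
#' 0.05-0.5, and exponential survival with ~30% independent censoring.
#'
#' @param seed Master seed.
#' @param n_patients,n_features,n_genes Cohort dimensions.
#' @param mutation_freqs Per-gene mutation probabilities in (0.05, 0.95);
#'   defaults to an even spread over 0.10-0.40.
#' @param library_size_meanlog,library_size_sdlog Log-normal library-size
#'   parameters.
#' @param baseline_mean_range Range of per-feature baseline mean counts
#'   (drawn log-uniform).
#' @param dispersion_range Range of per-feature NB dispersions (drawn
#'   log-uniform).
#' @param effects List of per-gene effect specs, each a list with `gene`
#'   (name or index), `k` (number of responsive features), `log2fc`
#'   (effect magnitude; signs are drawn at random per feature).
#' @param n_latent,latent_sd Latent sample-heterogeneity factors emulating
#'   the hidden structure of real cohorts (molecular subtypes, tumor
#'   purity, batch): each factor has sparse feature loadings (half the
#'   features, `N(0, latent_sd)` on the log2 scale) and standard-normal
#'   per-sample scores.  Off by default (`n_latent = 0`), which keeps the
#'   marginal counts exactly NB.
#' @param survival List with `baseline_hazard` (events/day), `beta`
#'   (log-HR per unit of the composite of the prognostic features),
#'   `prognostic_features` (indices or names; empty for no effect),
#'   `censoring_rate` (expected fraction censored).
#' @param dss_missing_rate Fraction of patients with missing DSS.
#' @param cancer_type Cohort label.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_patients = 100, n_features = 300,
                       n_genes = 10, mutation_freqs = NULL,
                       library_size_meanlog = log(1e6),
                       library_size_sdlog = 0.3,
                       baseline_mean_range = c(1, 1000),
                       dispersion_range = c(0.05, 0.5),
                       effects = list(),
                       n_latent = 0, latent_sd = 0,
                       survival = list(baseline_hazard = 1 / 1000, beta = 0,
                                       prognostic_features = integer(0),
                                       censoring_rate = 0.3),
                       dss_missing_rate = 0.1,
                       cancer_type = "SYNTH") {
  if (is.null(mutation_freqs))
    mutation_freqs <- seq(0.10, 0.40, length.out = n_genes)
  if (length(mutation_freqs) != n_genes)
    stop("need one mutation frequency per gene")
  if (any(mutation_freqs <= 0.05 | mutation_freqs >= 0.95))
    stop("mutation frequencies must respect the context filter (0.05, 0.95)")
  .check_prob(dss_missing_rate, "dss_missing_rate")
  .check_prob(survival$censoring_rate %||% 0.3, "censoring_rate")
  for (ef in effects) {
    if (is.null(ef$gene) || is.null(ef$k) || is.null(ef$log2fc))
      stop("each effect spec needs gene, k, log2fc")
    if (ef$k > n_features) stop("responsive subset larger than n_features")
  }
  structure(list(seed = seed, n_patients = n_patients,
                 n_features = n_features, n_genes = n_genes,
                 mutation_freqs = mutation_freqs,
                 library_size_meanlog = library_size_meanlog,
                 library_size_sdlog = library_size_sdlog,
                 baseline_mean_range = baseline_mean_range,
                 dispersion_range = dispersion_range,
                 effects = effects, n_latent = n_latent,
                 latent_sd = latent_sd, survival = survival,
                 dss_missing_rate = dss_missing_rate,
                 cancer_type = cancer_type),
            class = "sim_config")
}

#' Simulate a synthetic cohort with known truth
#'
#' Generates a cohort with the statistical structure the framework
#' assumes: per-gene Bernoulli mutation status, NB counts whose means are
#' baseline times library size, multiplicative `2^log2fc` shifts on each
#' impacted gene's responsive feature subset in mutant samples, and
#' exponential survival whose hazard is `baseline * exp(beta * composite)`
#' of the designated prognostic features, with independent exponential
#' censoring tuned to the requested censoring rate.  DSS endpoints are an
#' independent draw from the same survival model with a missingness mask.
#' The truth ledger records every responsive (gene, feature, log2fc) pair
#' and the prognostic subset, enabling exact recall/precision computation
#' downstream.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_cohort`: list with `cohort` ([new_cohort()]), `mutations`
#'   (gene-by-patient 0/1 matrix), and `truth` (list with `responsive`
#'   data.frame, `prognostic_features`, `beta`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  np <- cfg$n_patients; nf <- cfg$n_features; ng <- cfg$n_genes
  patients <- sprintf("PT%04d", seq_len(np))
  features <- sprintf("feat-%03d", seq_len(nf))
  genes <- sprintf("GENE%02d", seq_len(ng))

  mut <- matrix(stats::rbinom(ng * np, 1, rep(cfg$mutation_freqs, np)),
                nrow = ng, dimnames = list(genes, patients))

  lib <- stats::rlnorm(np, cfg$library_size_meanlog, cfg$library_size_sdlog)
  base <- exp(stats::runif(nf, log(cfg$baseline_mean_range[1]),
                           log(cfg$baseline_mean_range[2])))
  phi <- exp(stats::runif(nf, log(cfg$dispersion_range[1]),
                          log(cfg$dispersion_range[2])))

  lfc <- matrix(0, nrow = nf, ncol = np)   # per-cell log2 effect, cumulative
  responsive <- list()
  for (ef in cfg$effects) {
    g <- if (is.character(ef$gene)) ef$gene else genes[ef$gene]
    idx <- sample.int(nf, ef$k)
    signs <- sample(c(-1, 1), ef$k, replace = TRUE)
    fc <- signs * abs(ef$log2fc)
    carriers <- which(mut[g, ] == 1)
    lfc[idx, carriers] <- lfc[idx, carriers] + fc
    responsive[[length(responsive) + 1]] <-
      data.frame(gene = g, feature = features[idx], log2fc = fc,
                 stringsAsFactors = FALSE)
  }
  if (cfg$n_latent > 0 && cfg$latent_sd > 0) {
    load <- matrix(stats::rnorm(nf * cfg$n_latent, 0, cfg$latent_sd) *
                     stats::rbinom(nf * cfg$n_latent, 1, 0.5), nrow = nf)
    scores <- matrix(stats::rnorm(cfg$n_latent * np), nrow = cfg$n_latent)
    lfc <- lfc + load %*% scores
  }
  mu <- (base %o% (lib / mean(lib))) * 2^lfc
  counts <- matrix(stats::rnbinom(nf * np, mu = mu, size = rep(1 / phi, np)),
                   nrow = nf, dimnames = list(features, patients))

  sv <- cfg$survival
  prog <- sv$prognostic_features %||% integer(0)
  if (is.character(prog)) prog <- match(prog, features)
  score <- if (length(prog) > 0 && (sv$beta %||% 0) != 0) {
    lc <- log2(sweep(counts[prog, , drop = FALSE] + 0.5, 2, lib / 1e6, "/"))
    sds <- apply(lc, 1, stats::sd)
    keep <- sds > 0
    if (any(keep))
      colMeans((lc[keep, , drop = FALSE] - rowMeans(lc[keep, , drop = FALSE])) /
                 sds[keep])
    else rep(0, np)
  } else rep(0, np)
  haz <- (sv$baseline_hazard %||% 1 / 1000) * exp((sv$beta %||% 0) * score)
  cr <- sv$censoring_rate %||% 0.3
  sim_endpoint <- function() {
    tt <- stats::rexp(np, haz)
    if (cr > 0) {
      cc <- stats::rexp(np, haz * cr / (1 - cr))
      list(time = pmin(tt, cc), event = as.integer(tt <= cc))
    } else list(time = tt, event = rep(1L, np))
  }
  os <- sim_endpoint()
  dss <- sim_endpoint()
  miss <- stats::runif(np) < cfg$dss_missing_rate
  clinical <- data.frame(patient = patients,
                         os_time = os$time, os_event = os$event,
                         dss_time = ifelse(miss, NA, dss$time),
                         dss_event = ifelse(miss, NA, dss$event),
                         stringsAsFactors = FALSE)

  truth <- list(responsive = if (length(responsive))
                  do.call(rbind, responsive)
                else data.frame(gene = character(), feature = character(),
                                log2fc = numeric()),
                prognostic_features = features[prog],
                beta = sv$beta %||% 0,
                base_mean = stats::setNames(base, features),
                dispersion = stats::setNames(phi, features))
  structure(list(cohort = new_cohort(cfg$cancer_type, counts, clinical),
                 mutations = mut, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort as the pipeline's input TSV dialects
#'
#' Emits `mutations.tsv` (MAF-compatible columns, synthetic positional
#' fields), `counts.tsv`, and `clinical.tsv` under `dir`, so the simulator
#' doubles as a fixture generator for integration tests of the file-based
#' pipeline.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort_tsv <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- which(sim$mutations == 1, arr.ind = TRUE)
  maf <- data.frame(Hugo_Symbol = rownames(sim$mutations)[idx[, 1]],
                    Tumor_Sample_Barcode = colnames(sim$mutations)[idx[, 2]],
                    Chromosome = "1",
                    Start_Position = 1000L + idx[, 1],
                    Reference_Allele = "A", Tumor_Seq_Allele2 = "T",
                    Variant_Classification = "Missense_Mutation",
                    stringsAsFactors = FALSE)
  pm <- file.path(dir, "mutations.tsv")
  utils::write.table(maf, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  pc <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(feature = rownames(sim$cohort$counts),
                                sim$cohort$counts, check.names = FALSE),
                     pc, sep = "\t", quote = FALSE, row.names = FALSE)
  pl <- file.path(dir, "clinical.tsv")
  utils::write.table(sim$cohort$clinical, pl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mutations = pm, counts = pc, clinical = pl))
}

#' Null sweep over sample size and class imbalance
#'
#' The structural-confounding experiment: for each sample size, a null
#' cohort (no mutation effects) is simulated, its labels are permuted
#' `reps` times per frequency category, and the DE count is recorded each
#' time.  The resulting table shows how the false-discovery magnitude
#' grows with sample size and with lesser class imbalance even though no
#' label carries information.  The null cohort carries strong latent
#' sample heterogeneity by default (`n_latent = 3`, `latent_sd = 2`, on
#' the order of pronounced molecular-subtype separation), because that
#' hidden structure — not the NB sampling noise — is what converts
#' arbitrary sample splits into apparent differential expression in real
#' cohorts.
#'
#' @param n_grid Sample sizes.
#' @param categories Frequency categories on [category_grid()].
#' @param reps Permutations per (n, category) cell.
#' @param n_features Features per null cohort.
#' @param seed Master seed.
#' @param de DE engine.
#' @param n_latent,latent_sd Heterogeneity of the null cohort (see
#'   [sim_config()]).
#' @details One population cohort is simulated at `2 * max(n_grid)`
#'   patients; every permutation rep then draws a fresh subsample of size
#'   `n` from it before assigning `round(category * n)` patients to the
#'   mutant class.  Resampling the subcohort anew per rep integrates out
#'   which patients (with which latent scores) happen to be included, so
#'   each cell estimates the typical null DE count at that sample size and
#'   class ratio rather than the idiosyncrasy of one fixed subsample.
#' @return Data.frame with columns `n`, `category`, `rep`, `N`.
#' @export
simulate_null_sweep <- function(n_grid, categories, reps = 100,
                                n_features = 500, seed = 1,
                                de = de_engine_nbglm(), n_latent = 3,
                                latent_sd = 2) {
  if (length(n_grid) == 0 || length(categories) == 0)
    stop("grids must be non-empty")
  n_pop <- 2 * max(n_grid)
  cfg <- sim_config(seed = .derive_seed(seed, 1), n_patients = n_pop,
                    n_features = n_features, n_genes = 1,
                    mutation_freqs = 0.5, n_latent = n_latent,
                    latent_sd = latent_sd, cancer_type = "NULL")
  sim <- simulate_cohort(cfg)
  counts <- sim$cohort$counts
  out <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    for (j in seq_along(categories)) {
      k <- round(categories[j] * n)
      if (k < 2 || n - k < 2)
        stop("each permuted class needs at least 2 patients")
      set.seed(.derive_seed(seed, 100 * i + j))
      Ns <- vapply(seq_len(reps), function(b) {
        sub <- sample.int(n_pop, n)
        y <- counts[, sub, drop = FALSE]
        mut <- logical(n)
        mut[sample.int(n, k)] <- TRUE
        de_count(de(y, mut, tmm_normalize(y)))
      }, integer(1))
      out[[length(out) + 1]] <- data.frame(n = n, category = categories[j],
                                           rep = seq_len(reps), N = Ns)
    }
  }
  do.call(rbind, out)
}
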