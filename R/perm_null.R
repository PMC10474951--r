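#' Simulate a frequency-matched permutation null of DE counts
#'
#' For one cohort and one discrete mutation-frequency category, draws `B`
#' label permutations in which exactly `round(category * n)` patients are
#' assigned to the mutant class uniformly at random (class-ratio-controlled
#' permutation), runs the DE engine on each, and records the DE count.
#' One distribution is built per (cohort, category) pair and reused by
#' every gene mapping to that category, so two genes with the same category
#' are scored against the identical null.
#'
#' @param cohort A [new_cohort()] object.
#' @param category A value on [category_grid()].
#' @param B Number of permutations (default 1000; fewer than 100 triggers a
#'   warning because the NB tail fit becomes unstable).
#' @param seed Integer seed for this distribution's generator.
#' @param de DE engine, a function `(counts, labels, norm) -> de_result`;
#'   defaults to [de_engine_nbglm()].
#' @param norm Optional precomputed `norm_factors` (label-independent, so
#'   it can be shared across permutations and categories).
#' @param n_mutant Optional exact mutant-class size, overriding
#'   `round(category * n)` (to match a specific observed context).
#' @return A `null_count_distribution`: list with `cancer_type`,
#'   `category`, `B`, `counts` (B integers), `mu`, `sd`, `nb` (method-of-
#'   moments fit, see [fit_null_nb()]), and `seed`.
#' @export
simulate_null <- function(cohort, category, B = 1000, seed = 1,
                          de = de_engine_nbglm(), norm = NULL,
                          n_mutant = NULL) {
  if (!any(abs(category - category_grid()) < 1e-9))
    stop("category must lie on the grid seq(0.05, 0.50, by = 0.05)")
  if (B < 100) warning("B < 100 permutations gives an unstable NB fit")
  n <- length(cohort$patients)
  k <- n_mutant %||% round(category * n)
  if (k < 2 || n - k < 2)
    stop("each permuted class needs at least 2 patients")
  if (is.null(norm)) norm <- tmm_normalize(cohort$counts)
  counts <- integer(B)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(B)) {
    mut <- logical(n)
    mut[sample.int(n, k)] <- TRUE
    counts[b] <- de_count(de(cohort$counts, mut, norm))
  }
  structure(list(cancer_type = cohort$cancer_type, category = category,
                 B = B, counts = counts, mu = mean(counts),
                 sd = stats::sd(counts), nb = fit_null_nb(counts),
                 seed = seed, n_mutant = k, n = n),
            class = "null_count_distribution")
}

## Preserve the caller's RNG state around seeded sections.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Method-of-moments Negative Binomial fit to null counts
#'
#' With mean `mu` and variance `v`, the NB parameters are
#' `size r = mu^2 / (v - mu)` and `p_success = mu / v`.  If the counts are
#' underdispersed (`v <= mu`) the fit falls back to a Poisson with rate
#' `mu`.
#'
#' @param counts Integer vector of null DE counts.
#' @return List with `family` (`"nbinom"` or `"poisson"`) and parameters
#'   (`size`, `prob`) or (`lambda`).
#' @export
fit_null_nb <- function(counts) {
  mu <- mean(counts)
  v <- stats::var(counts)
  if (is.finite(v) && v > mu && mu > 0) {
    list(family = "nbinom", size = mu^2 / (v - mu), prob = mu / v)
  } else {
    list(family = "poisson", lambda = mu)
  }
}

#' @export
print.null_count_distribution <- function(x, ...) {
  cat(sprintf("permutation null (%s, category %.2f): B = %d, mean %.1f, sd %.1f [%s fit]\n",
              x$cancer_type, x$category, x$B, x$mu, x$sd, x$nb$family))
  invisible(x)
}

#' Build permutation nulls for several categories
#'
#' One seeded generator per category, derived from the master seed via a
#' counter, so distributions are reproducible and mutually independent.
#'
#' @param cohort A cohort.
#' @param categories Values on [category_grid()].
#' @param B Permutations per category.
#' @param master_seed Master integer seed.
#' @param de DE engine.
#' @param norm Optional shared `norm_factors`.
#' @return Named list (names `sprintf("%.2f", category)`) of
#'   `null_count_distribution` objects.
#' @export
build_null_distributions <- function(cohort, categories, B = 1000,
                                     master_seed = 1,
                                     de = de_engine_nbglm(), norm = NULL) {
  if (is.null(norm)) norm <- tmm_normalize(cohort$counts)
  categories <- sort(unique(categories))
  nulls <- lapply(categories, function(cat) {
    idx <- which(abs(cat - category_grid()) < 1e-9)
    simulate_null(cohort, cat, B = B, seed = .derive_seed(master_seed, idx),
                  de = de, norm = norm)
  })
  names(nulls) <- sprintf("%.2f", categories)
  nulls
}

#' Empirical permutation P-value
#'
#' The proportion of permutation DE counts at or above the observed count.
#' With the default add-one convention `p = (r + 1) / (B + 1)` the smallest
#' attainable value at `B = 1000` is `1/1001` (0.001 to three decimals),
#' the permutation floor; `add_one = FALSE` gives the raw `r / B` variant.
#'
#' @param N_obs Observed DE count.
#' @param null A `null_count_distribution`.
#' @param add_one Use the add-one estimator (default `TRUE`).
#' @return The empirical P-value.
#' @export
empirical_p <- function(N_obs, null, add_one = TRUE) {
  r <- sum(null$counts >= N_obs)
  if (add_one) (r + 1) / (null$B + 1) else r / null$B
}

#' Gaussian z-score against the permutation null
#'
#' `z = (N_obs - mu) / sd` with the null's moments; 1.96 is the
#' conventional conspicuousness threshold.  A degenerate null (`sd = 0`)
#' yields `NA` with attribute `flag = "sd_zero"`.
#'
#' @inheritParams empirical_p
#' @return The z-score (possibly flagged `NA`).
#' @export
null_zscore <- function(N_obs, null) {
  if (!is.finite(null$sd) || null$sd == 0) {
    z <- NA_real_
    attr(z, "flag") <- "sd_zero"
    return(z)
  }
  (N_obs - null$mu) / null$sd
}

#' Negative-Binomial-modified permutation P-value
#'
#' Upper-tail probability `P(X >= N_obs)` of the method-of-moments NB fit
#' to the null counts (Poisson fallback when underdispersed).  The tail is
#' evaluated with [stats::pnbinom()], which uses the regularized incomplete
#' beta function, so extreme observed counts keep numerical resolution far
#' below the empirical floor `1/(B+1)`.
#'
#' @inheritParams empirical_p
#' @return The modified P-value in (0, 1].
#' @export
nb_modified_p <- function(N_obs, null) {
  if (N_obs <= 0) return(1)
  fit <- null$nb
  if (fit$family == "nbinom") {
    stats::pnbinom(N_obs - 1, size = fit$size, prob = fit$prob,
                   lower.tail = FALSE)
  } else {
    lam <- fit$lambda
    if (lam <= 0) {            # fully degenerate null: pseudo-rate, flagged
      p <- stats::ppois(N_obs - 1, lambda = 0.5 / null$B, lower.tail = FALSE)
      attr(p, "flag") <- "degenerate_null"
      return(p)
    }
    stats::ppois(N_obs - 1, lambda = lam, lower.tail = FALSE)
  }
}

#' Score one mutation context against its matched null
#'
#' Runs the DE engine on the context's true labels to get the observed DE
#' count, then evaluates the three statistics against the null of the
#' context's frequency category: empirical P, z-score, and NB-modified P.
#' Following the framework, significance is declared on the modified P.
#'
#' @param context A `mutation_context`.
#' @param cohort The cohort it belongs to.
#' @param nulls Named list from [build_null_distributions()]; must contain
#'   the context's category.
#' @param de DE engine (must match the one used for the nulls).
#' @param alpha Significance level on the NB-modified P.
#' @param norm Optional shared `norm_factors`.
#' @return An `impact_result`: list with `cancer_type`, `gene`, `f`,
#'   `category`, `N_obs`, `p_emp`, `z`, `p_nb`, `significant`, and the
#'   per-feature `de` table.
#' @export
assess_impact <- function(context, cohort, nulls, de = de_engine_nbglm(),
                          alpha = 0.05, norm = NULL) {
  key <- sprintf("%.2f", context$category)
  if (!key %in% names(nulls))
    stop(sprintf("no null distribution for category %s; run simulate_null()/build_null_distributions() first", key))
  null <- nulls[[key]]
  if (is.null(norm)) norm <- tmm_normalize(cohort$counts)
  labels <- context$labels[cohort$patients]
  deres <- de(cohort$counts, .as_mutant(labels), norm)
  N_obs <- de_count(deres)
  p_nb <- nb_modified_p(N_obs, null)
  structure(list(cancer_type = context$cancer_type, gene = context$gene,
                 f = context$f, category = context$category, N_obs = N_obs,
                 p_emp = empirical_p(N_obs, null),
                 z = null_zscore(N_obs, null),
                 p_nb = as.numeric(p_nb),
                 significant = as.numeric(p_nb) < alpha,
                 de = deres),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("impact %s / %s: N = %d, p_emp = %.4g, z = %.2f, p_nb = %.3g%s\n",
              x$cancer_type, x$gene, x$N_obs, x$p_emp, x$z, x$p_nb,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Score many contexts and tabulate
#'
#' @param contexts List of `mutation_context` objects.
#' @param cohort Their cohort.
#' @inheritParams assess_impact
#' @return Data.frame with one row per context: cohort, gene, f, category,
#'   N_obs, p_emp, z, p_nb, significant.  Per-context results are attached
#'   as attribute `results`.
#' @export
assess_impacts <- function(contexts, cohort, nulls, de = de_engine_nbglm(),
                           alpha = 0.05, norm = NULL) {
  if (is.null(norm)) norm <- tmm_normalize(cohort$counts)
  res <- lapply(contexts, assess_impact, cohort = cohort, nulls = nulls,
                de = de, alpha = alpha, norm = norm)
  tab <- do.call(rbind, lapply(res, function(r) {
    data.frame(cohort = r$cancer_type, gene = r$gene, f = r$f,
               category = r$category, N_obs = r$N_obs, p_emp = r$p_emp,
               z = as.numeric(r$z), p_nb = r$p_nb,
               significant = r$significant, stringsAsFactors = FALSE)
  }))
  attr(tab, "results") <- res
  tab
}

#' Write / read a null distribution cache
#'
#' The permutation counts go to a TSV (one row per permutation) and the
#' metadata (moments, NB parameters, seed, B) to a JSON sidecar, so cached
#' nulls can be inspected and reused across runs.
#'
#' @param null A `null_count_distribution`.
#' @param path_tsv,path_json Cache file paths.
#' @export
write_null_distribution <- function(null, path_tsv, path_json) {
  utils::write.table(data.frame(perm = seq_len(null$B), N = null$counts),
                     path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- null[c("cancer_type", "category", "B", "mu", "sd", "seed",
                 "n_mutant", "n")]
  meta$nb <- null$nb
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_null_distribution
#' @return `read_null_distribution()` returns the reconstructed
#'   `null_count_distribution`.
#' @export
read_null_distribution <- function(path_tsv, path_json) {
  counts <- utils::read.delim(path_tsv)$N
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  structure(list(cancer_type = meta$cancer_type, category = meta$category,
                 B = meta$B, counts = counts, mu = mean(counts),
                 sd = stats::sd(counts), nb = fit_null_nb(counts),
                 seed = meta$seed, n_mutant = meta$n_mutant, n = meta$n),
            class = "null_count_distribution")
}
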