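#' Log counts per million
#'
#' @param counts Feature-by-sample count matrix.
#' @param norm Optional `norm_factors`; computed if `NULL`.
#' @param prior Prior count added before the log (default 0.5).
#' @return Matrix of `log2` CPM values on effective library sizes.
#' @export
log_cpm <- function(counts, norm = NULL, prior = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(norm)) norm <- tmm_normalize(counts)
  e <- effective_lib_size(norm)
  log2(sweep(counts + prior, 2, (e + 1) / 1e6, "/"))
}

## Internal: one Cox PH fit via survival::coxph.fit (skips the formula
## machinery, which matters inside permutation loops).  Returns the
## coefficient and the likelihood-ratio p-value.
.cox_lrt <- function(x, time, event) {
  ok <- is.finite(x) & !is.na(time) & !is.na(event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 2 || stats::sd(x) == 0)
    return(list(coef = NA_real_, p = NA_real_, flag = "degenerate"))
  fit <- tryCatch(
    survival::coxph.fit(matrix(x, ncol = 1), survival::Surv(time, event),
                        strata = NULL, offset = NULL, init = 0,
                        control = survival::coxph.control(), weights = NULL,
                        method = "efron", rownames = NULL),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$coefficients[1]))
    return(list(coef = NA_real_, p = 1, flag = "nonconvergent"))
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  list(coef = unname(fit$coefficients[1]),
       p = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
       flag = NA_character_)
}

#' Per-feature Cox proportional hazards screen
#'
#' Univariate Cox fit of the endpoint on each feature's standardized
#' log-CPM; hazard ratios are therefore per standard deviation of
#' log-expression, comparable across features.  P-values come from the
#' 1-df likelihood-ratio test.  Patients with a missing endpoint are
#' dropped; fewer than two observed events makes all results missing.
#'
#' @param expr Feature-by-patient matrix of log-CPM values.
#' @param time,event Survival endpoint per patient (days; event 0/1);
#'   missing allowed.
#' @return Data.frame with columns `feature`, `hr` (per SD), `cox_p`,
#'   `flag`.
#' @export
cox_per_feature <- function(expr, time, event) {
  expr <- as.matrix(expr)
  ok <- !is.na(time) & !is.na(event)
  if (sum(event[ok]) < 2) {
    return(data.frame(feature = rownames(expr) %||% as.character(seq_len(nrow(expr))),
                      hr = NA_real_, cox_p = NA_real_,
                      flag = "too_few_events", stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ok]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      return(list(coef = NA_real_, p = NA_real_, flag = "constant"))
    .cox_lrt((x - mean(x)) / s, time[ok], event[ok])
  })
  data.frame(feature = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             hr = exp(vapply(res, `[[`, numeric(1), "coef")),
             cox_p = vapply(res, `[[`, numeric(1), "p"),
             flag = vapply(res, `[[`, character(1), "flag"),
             stringsAsFactors = FALSE)
}

#' Cox score-statistic directions
#'
#' Sign of each feature's univariate Cox (Breslow) score statistic,
#' `U = sum over events of (x_i - mean of x over the risk set)`, computed
#' for all features at once by cumulative sums over the time-ordered
#' samples.  The sign of `U` agrees with the sign of the Cox log-HR
#' estimate, so this gives the per-feature prognostic direction without
#' iterative fitting — important inside the composite-score permutation
#' loop, where directions must be re-selected per permutation.
#'
#' @inheritParams cox_per_feature
#' @return Integer vector of directions in `{-1, +1}` (zero scores map to
#'   `+1`).
#' @export
cox_directions <- function(expr, time, event) {
  expr <- as.matrix(expr)
  ok <- !is.na(time) & !is.na(event)
  x <- expr[, ok, drop = FALSE]
  tt <- time[ok]; ev <- event[ok]
  ord <- order(tt, decreasing = TRUE)     # risk set = a prefix in this order
  x <- x[, ord, drop = FALSE]; tt <- tt[ord]; ev <- ev[ord]
  cs <- t(apply(x, 1, cumsum))
  if (nrow(x) == 1) cs <- matrix(cs, nrow = 1)
  last <- stats::ave(seq_along(tt), tt, FUN = max)  # ties share the risk set
  ev_idx <- which(ev == 1)
  u <- rowSums(x[, ev_idx, drop = FALSE]) -
    rowSums(sweep(cs[, last[ev_idx], drop = FALSE], 2, last[ev_idx], "/"))
  ifelse(u < 0, -1L, 1L)
}

#' Composite expression score
#'
#' Per-patient aggregate of a responsive feature set: the mean over
#' features of `direction * z-scored log-CPM`.  Zero-variance features are
#' excluded from the mean (logged in attribute `n_excluded`).  Flipping
#' every direction negates every score.
#'
#' @param expr Feature-by-patient log-CPM matrix for the feature subset.
#' @param directions Per-feature signs in `{-1, +1}`, typically from
#'   [cox_directions()].
#' @return Numeric per-patient score vector.
#' @export
composite_score <- function(expr, directions) {
  expr <- as.matrix(expr)
  if (nrow(expr) == 0) stop("the feature subset must be non-empty")
  if (length(directions) != nrow(expr))
    stop("one direction per feature required")
  sds <- apply(expr, 1, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) stop("all features have zero variance")
  z <- (expr[keep, , drop = FALSE] -
          rowMeans(expr[keep, , drop = FALSE])) / sds[keep]
  score <- colMeans(directions[keep] * z)
  attr(score, "n_excluded") <- sum(!keep)
  score
}

#' Composite-score prognosis statistic
#'
#' The aggregative statistic for a feature set: per-feature directions are
#' selected from the data ([cox_directions()]), the direction-adjusted
#' composite score is formed, and the statistic `s` is the likelihood-ratio
#' p-value of the Cox fit of the endpoint on that score — a number in
#' `[0, 1]`, small when the set is collectively prognostic.  Because the
#' directions are chosen on the same data, `s` is optimistically biased;
#' the permutation procedure ([cges_permutation_p()]) repeats the selection
#' inside the null and so removes the bias.
#'
#' @inheritParams cox_per_feature
#' @return The statistic `s` in `[0, 1]` (1 with attribute `flag` on
#'   degenerate input).
#' @export
cges_statistic <- function(expr, time, event) {
  expr <- as.matrix(expr)
  ok <- !is.na(time) & !is.na(event)
  if (sum(event[ok]) < 2) {
    s <- 1
    attr(s, "flag") <- "too_few_events"
    return(s)
  }
  dirs <- cox_directions(expr, time, event)
  sc <- composite_score(expr[, ok, drop = FALSE], dirs)
  fit <- .cox_lrt(sc, time[ok], event[ok])
  if (!is.na(fit$flag)) {
    s <- 1
    attr(s, "flag") <- fit$flag
    return(s)
  }
  fit$p
}

#' Permutation P-value of the composite-score statistic
#'
#' Permutes the `(time, event)` pairs jointly across patients `B` times
#' (the expression matrix is untouched, so permuting survival identities),
#' recomputing the statistic with in-permutation re-selection of the
#' directions so that selection bias is part of the null, and returns
#' `p_perm = (#\{s_perm <= s_obs\} + 1) / (B + 1)`.
#'
#' @inheritParams cox_per_feature
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `s_obs`, `p_perm`, and the vector `stats` of permuted
#'   statistics.
#' @export
cges_permutation_p <- function(expr, time, event, B = 1000, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  expr <- as.matrix(expr)
  s_obs <- as.numeric(cges_statistic(expr, time, event))
  n <- length(time)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stats_vec <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n)
    as.numeric(cges_statistic(expr, time[idx], event[idx]))
  }, numeric(1))
  list(s_obs = s_obs,
       p_perm = (sum(stats_vec <= s_obs) + 1) / (B + 1),
       stats = stats_vec)
}

#' Beta-approximated P-value
#'
#' The permuted statistics live in `[0, 1]`, so their null distribution is
#' approximated by a Beta fitted by the method of moments
#' (`alpha = m (m(1-m)/v - 1)`, `beta = (1-m)(m(1-m)/v - 1)`); the
#' Beta-distribution P-value is the CDF at the observed statistic, which
#' resolves ties below the permutation floor.  If the moments admit no
#' Beta (`v >= m(1-m)`), the fit is invalid and the caller should fall
#' back to the permutation P (flagged in the return).
#'
#' @param s_obs Observed statistic in `[0, 1]`.
#' @param stats Vector of permuted statistics in `[0, 1]`.
#' @return List with `p_beta`, `alpha`, `beta`, `valid`.
#' @export
beta_p <- function(s_obs, stats) {
  .check_prob(stats, "stats"); .check_prob(s_obs, "s_obs")
  m <- mean(stats); v <- stats::var(stats)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m))
    return(list(p_beta = NA_real_, alpha = NA_real_, beta = NA_real_,
                valid = FALSE))
  phi <- m * (1 - m) / v - 1
  a <- m * phi; b <- (1 - m) * phi
  list(p_beta = stats::pbeta(s_obs, a, b), alpha = a, beta = b,
       valid = TRUE)
}

#' Aggregative prognosis of a responsive feature set
#'
#' Full per-endpoint prognosis analysis: per-feature Cox screen, composite
#' statistic, permutation P with in-null direction re-selection, and the
#' Beta-approximated P (falling back to the permutation P when the Beta
#' fit is invalid).  OS and DSS are analyzed separately and never share
#' event vectors; patients missing the requested endpoint are dropped from
#' that endpoint only.
#'
#' @param cohort A cohort carrying clinical data.
#' @param features Feature IDs (rows of the count matrix) forming the
#'   responsive set.
#' @param endpoint `"OS"` or `"DSS"`.
#' @param B Permutations.
#' @param seed Integer seed.
#' @param norm Optional `norm_factors`.
#' @return A `prognosis_result`: list with `endpoint`, `n_features`,
#'   per-feature table `features`, `s_obs`, `p_perm`, `p_beta`, `alpha`,
#'   `beta`, `beta_valid`, `n_used` (patients with the endpoint).
#' @export
assess_prognosis <- function(cohort, features, endpoint = c("OS", "DSS"),
                             B = 1000, seed = 1, norm = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(cohort$clinical)) stop("cohort has no clinical table")
  if (length(features) == 0) stop("features must be non-empty")
  miss <- setdiff(features, rownames(cohort$counts))
  if (length(miss)) stop("features absent from counts: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  cl <- cohort$clinical
  if (endpoint == "OS") { time <- cl$os_time; event <- cl$os_event }
  else { time <- cl$dss_time; event <- cl$dss_event }
  if (is.null(norm)) norm <- tmm_normalize(cohort$counts)
  expr <- log_cpm(cohort$counts, norm)[features, , drop = FALSE]
  pf <- cox_per_feature(expr, time, event)
  perm <- cges_permutation_p(expr, time, event, B = B, seed = seed)
  bfit <- beta_p(perm$s_obs, perm$stats)
  p_beta <- if (bfit$valid) bfit$p_beta else perm$p_perm
  structure(list(cancer_type = cohort$cancer_type, endpoint = endpoint,
                 n_features = length(features), features = pf,
                 s_obs = perm$s_obs, p_perm = perm$p_perm,
                 p_beta = p_beta, alpha = bfit$alpha, beta = bfit$beta,
                 beta_valid = bfit$valid,
                 n_used = sum(!is.na(time) & !is.na(event))),
            class = "prognosis_result")
}

#' @export
print.prognosis_result <- function(x, ...) {
  cat(sprintf("prognosis (%s, %s): %d features, s = %.4g, p_perm = %.4g, p_beta = %.4g\n",
              x$cancer_type, x$endpoint, x$n_features, x$s_obs, x$p_perm,
              x$p_beta))
  invisible(x)
}
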