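#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scale factors against a reference sample (the
#' sample whose upper quartile of relative counts is closest to the mean
#' upper quartile).  For each sample, log2 ratios (M) against the reference
#' are trimmed by 30% on each tail and log2 average abundances (A) by 5% on
#' each tail; the remaining M-values are combined with inverse-variance
#' (delta-method) weights.  Factors are renormalized so their geometric
#' mean is 1, so normalization does not change the global scale.
#'
#' @param counts Feature-by-sample matrix of non-negative counts.
#' @param logratio_trim Fraction of M-values trimmed from each tail.
#' @param sum_trim Fraction of A-values trimmed from each tail.
#' @return An object of class `norm_factors`: list with per-sample
#'   `lib_size` (column totals) and `scale_factor` (geometric mean 1).
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive total count")
  keep <- rowSums(counts) > 0            # all-zero features carry no signal
  y <- counts[keep, , drop = FALSE]
  p <- sweep(y, 2, lib, "/")
  uq <- apply(p, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  sf <- vapply(seq_len(ncol(y)), function(j) {
    .tmm_pair(y[, j], y[, ref], lib[j], lib[ref], logratio_trim, sum_trim)
  }, numeric(1))
  sf <- sf / .geomean(sf)
  structure(list(lib_size = lib, scale_factor = sf,
                 ref_sample = colnames(counts)[ref] %||% ref),
            class = "norm_factors")
}

## One sample against the reference: weighted trimmed mean of M-values.
.tmm_pair <- function(y, yr, n, nr, logratio_trim, sum_trim) {
  pos <- y > 0 & yr > 0
  if (!any(pos)) return(1)
  y <- y[pos]; yr <- yr[pos]
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)  # delta-method variance of M
  lm <- stats::quantile(m, c(logratio_trim, 1 - logratio_trim), names = FALSE)
  la <- stats::quantile(a, c(sum_trim, 1 - sum_trim), names = FALSE)
  keep <- m >= lm[1] & m <= lm[2] & a >= la[1] & a <= la[2]
  if (!any(keep) || all(w[keep] == 0)) return(1)
  f <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Effective library sizes
#'
#' @param norm A `norm_factors` object.
#' @return Per-sample effective library size `lib_size * scale_factor`,
#'   used as the GLM offset.
#' @export
effective_lib_size <- function(norm) norm$lib_size * norm$scale_factor

#' Method-of-moments dispersion estimates
#'
#' Per-feature negative binomial dispersions from within-group variances of
#' normalized counts, corrected for unequal exposures, pooled across the
#' two classes by degrees of freedom, then shrunk toward the common
#' (median) dispersion: `phi* = (1 - w) phi + w median(phi)`.  Degenerate
#' features (no positive counts, or a single usable group) receive the
#' common dispersion.  Estimates are floored at `1e-6`.
#'
#' @param counts Feature-by-sample count matrix.
#' @param labels Mutant/wild-type labels (logical, 0/1, or
#'   `"mutant"`/`"wild-type"`); both classes must be non-empty.
#' @param norm `norm_factors` for `counts`; computed if `NULL`.
#' @param shrink_weight Weight `w` of the common dispersion in `[0, 1]`.
#' @return Numeric vector of per-feature dispersions.
#' @export
estimate_dispersions <- function(counts, labels, norm = NULL,
                                 shrink_weight = 0.5) {
  counts <- as.matrix(counts)
  mut <- .as_mutant(labels)
  if (!any(mut) || all(mut)) stop("both classes must be non-empty")
  if (shrink_weight < 0 || shrink_weight > 1)
    stop("shrink_weight must be in [0, 1]")
  if (is.null(norm)) norm <- tmm_normalize(counts)
  e <- effective_lib_size(norm)
  z <- sweep(counts, 2, mean(e) / e, "*")     # normalized to common scale
  phi_raw <- rep(NA_real_, nrow(counts))
  num <- den <- rep(0, nrow(counts))
  for (grp in list(which(mut), which(!mut))) {
    if (length(grp) < 2) next
    zg <- z[, grp, drop = FALSE]
    mg <- rowMeans(zg)
    vg <- apply(zg, 1, stats::var)
    cg <- mean(mean(e) / e[grp])              # exposure-heterogeneity term
    ok <- mg > 0
    phig <- ifelse(ok, (vg - mg * cg) / mg^2, NA_real_)
    wgt <- length(grp) - 1
    num <- num + ifelse(ok, wgt * pmax(phig, 0), 0)
    den <- den + ifelse(ok, wgt, 0)
  }
  phi_raw <- ifelse(den > 0, num / den, NA_real_)
  common <- stats::median(phi_raw, na.rm = TRUE)
  if (!is.finite(common)) common <- 0.1
  phi <- ifelse(is.na(phi_raw), common,
                (1 - shrink_weight) * phi_raw + shrink_weight * common)
  pmax(phi, 1e-6)
}

## Fisher-scoring fit of a single NB rate (log link, offset log e) for a
## block of features at once.  Returns per-feature log-rate and log-lik.
.nb_fit_block <- function(y, e, phi, maxit = 30L, tol = 1e-8) {
  tot <- rowSums(y)
  beta <- log((tot + 0.5) / sum(e))
  for (it in seq_len(maxit)) {
    mu <- exp(beta) %o% e
    denom <- 1 + phi * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    beta <- pmin(pmax(beta + step, -50), 50)
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% e
  size <- rep(1 / phi, times = ncol(y))
  ll <- rowSums(matrix(stats::dnbinom(as.vector(y), size = size,
                                      mu = as.vector(pmax(mu, 1e-300)),
                                      log = TRUE), nrow = nrow(y)))
  list(beta = beta, loglik = ll)
}

#' Two-group negative binomial GLM likelihood-ratio test
#'
#' Per feature, fits a log-link NB GLM with intercept plus mutation
#' indicator and offset `log(lib_size * scale_factor)`, with the dispersion
#' held fixed at its estimate, and compares it to the intercept-only model
#' by a 1-df likelihood-ratio test.  Features whose total count is below
#' `min_total_count` are excluded from testing (and from the BH adjustment
#' and the DE count).  Log fold changes (mutant over wild-type) are
#' reported in log2 with a prior count of 0.125 on the mean-count scale so
#' they stay finite.
#'
#' @param counts Feature-by-sample count matrix.
#' @param labels Mutant/wild-type labels (see [estimate_dispersions()]).
#' @param norm `norm_factors`; computed from `counts` if `NULL`.
#' @param dispersions Per-feature dispersions; estimated if `NULL`.
#' @param fdr_threshold BH-adjusted significance threshold defining the DE
#'   count `N`.
#' @param min_total_count Features with fewer total counts are not tested.
#' @return A `de_result`: data.frame with columns `feature`, `logFC`,
#'   `raw_p`, `q`, `tested`, plus attributes `N` (number of features with
#'   `q < fdr_threshold`), `fdr_threshold`, and `n_unconverged`.
#' @export
nb_glm_test <- function(counts, labels, norm = NULL, dispersions = NULL,
                        fdr_threshold = 0.05, min_total_count = 10) {
  counts <- as.matrix(counts)
  mut <- .as_mutant(labels)
  if (length(mut) != ncol(counts)) stop("labels must match count columns")
  if (!any(mut) || all(mut)) stop("both classes must be non-empty")
  if (is.null(norm)) norm <- tmm_normalize(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, mut, norm)
  e <- effective_lib_size(norm)
  nf <- nrow(counts)
  tested <- rowSums(counts) >= min_total_count

  logFC <- rep(0, nf); raw_p <- rep(NA_real_, nf)
  n_uncon <- 0L
  if (any(tested)) {
    y <- counts[tested, , drop = FALSE]
    phi <- dispersions[tested]
    f0 <- .nb_fit_block(y, e, phi)
    fm <- .nb_fit_block(y[, mut, drop = FALSE], e[mut], phi)
    fw <- .nb_fit_block(y[, !mut, drop = FALSE], e[!mut], phi)
    lrt <- 2 * (fm$loglik + fw$loglik - f0$loglik)
    lrt <- pmax(lrt, 0)
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    bad <- !is.finite(p)
    n_uncon <- sum(bad)
    p[bad] <- 1
    ebar <- mean(e)
    lfc <- log2((exp(fm$beta) * ebar + 0.125) / (exp(fw$beta) * ebar + 0.125))
    ## no-signal guard: a feature constant across all samples carries none
    const <- apply(y, 1, function(r) length(unique(r)) == 1L)
    p[const] <- 1; lfc[const] <- 0
    raw_p[tested] <- p
    logFC[tested] <- lfc
  }
  q <- rep(NA_real_, nf)
  q[tested] <- bh_adjust(raw_p[tested])
  res <- data.frame(feature = rownames(counts) %||% as.character(seq_len(nf)),
                    logFC = logFC, raw_p = raw_p, q = q, tested = tested,
                    stringsAsFactors = FALSE)
  attr(res, "N") <- sum(q < fdr_threshold, na.rm = TRUE)
  attr(res, "fdr_threshold") <- fdr_threshold
  attr(res, "n_unconverged") <- n_uncon
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (delegated to
#' [stats::p.adjust()]); input must lie in `[0, 1]`.
#'
#' @param p Vector of p-values.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  .check_prob(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' DE count of a result
#'
#' @param de A `de_result`.
#' @return `N`, the number of features with `q` below the result's FDR
#'   threshold — the framework's per-context test statistic.
#' @export
de_count <- function(de) attr(de, "N")

#' Default DE engine (in-package NB GLM)
#'
#' The permutation layer is DE-engine-agnostic: any function
#' `(counts, labels, norm) -> de_result` can score a context.  This factory
#' returns the package's NB-GLM likelihood-ratio engine with the given
#' settings baked in.
#'
#' @param fdr_threshold,min_total_count,shrink_weight Passed through to
#'   [nb_glm_test()] / [estimate_dispersions()].
#' @return A DE engine function.
#' @export
de_engine_nbglm <- function(fdr_threshold = 0.05, min_total_count = 10,
                            shrink_weight = 0.5) {
  function(counts, labels, norm = NULL) {
    if (is.null(norm)) norm <- tmm_normalize(counts)
    disp <- estimate_dispersions(counts, labels, norm, shrink_weight)
    nb_glm_test(counts, labels, norm, disp,
                fdr_threshold = fdr_threshold,
                min_total_count = min_total_count)
  }
}

#' edgeR backend DE engine
#'
#' Alternative engine delegating dispersion estimation and testing to
#' edgeR's classic `estimateDisp`/`glmFit`/`glmLRT` path (requires the
#' edgeR package).  Produces the same `de_result` surface as
#' [de_engine_nbglm()].
#'
#' @inheritParams de_engine_nbglm
#' @return A DE engine function.
#' @export
de_engine_edger <- function(fdr_threshold = 0.05, min_total_count = 10) {
  if (!requireNamespace("edgeR", quietly = TRUE))
    stop("the edgeR package is required for this backend")
  function(counts, labels, norm = NULL) {
    mut <- .as_mutant(labels)
    keep <- rowSums(counts) >= min_total_count
    y <- edgeR::DGEList(counts = counts[keep, , drop = FALSE],
                        group = factor(ifelse(mut, "mutant", "wild")))
    y <- edgeR::calcNormFactors(y)
    design <- stats::model.matrix(~mut)
    y <- edgeR::estimateDisp(y, design)
    fit <- edgeR::glmFit(y, design)
    lrt <- edgeR::glmLRT(fit, coef = 2)
    tab <- lrt$table
    nf <- nrow(counts)
    res <- data.frame(feature = rownames(counts) %||% as.character(seq_len(nf)),
                      logFC = 0, raw_p = NA_real_, q = NA_real_,
                      tested = keep, stringsAsFactors = FALSE)
    res$logFC[keep] <- tab$logFC
    res$raw_p[keep] <- tab$PValue
    res$q[keep] <- bh_adjust(tab$PValue)
    attr(res, "N") <- sum(res$q < fdr_threshold, na.rm = TRUE)
    attr(res, "fdr_threshold") <- fdr_threshold
    attr(res, "n_unconverged") <- 0L
    class(res) <- c("de_result", "data.frame")
    res
  }
}

#' Write a DE result as TSV
#'
#' Columns `feature`, `logFC`, `raw_p`, `q`; header comment lines carry the
#' context metadata (cohort, gene, f, category, N).
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @param context Optional `mutation_context` for the header.
#' @export
write_de_result <- function(de, path, context = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(context)) {
    writeLines(sprintf("# cohort=%s gene=%s f=%.6g category=%.2f",
                       context$cancer_type, context$gene, context$f,
                       context$category), con)
  }
  writeLines(sprintf("# N=%d fdr_threshold=%g", attr(de, "N"),
                     attr(de, "fdr_threshold")), con)
  utils::write.table(de[, c("feature", "logFC", "raw_p", "q")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
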