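#' Annotation collection for over-representation analysis
#'
#' A universe of feature IDs plus named annotation sets (for example a
#' disease-to-miRNA map).  Set members outside the universe are dropped
#' with a message; sets left empty are removed.
#'
#' @param universe Character vector of feature IDs.
#' @param sets Named list of character vectors.
#' @return An `annotation_collection`.
#' @export
annotation_collection <- function(universe, sets) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every annotation set needs a name")
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  dropped <- sum(!vapply(sets, length, integer(1)) > 0)
  if (dropped) message(sprintf("%d empty annotation set(s) removed", dropped))
  sets <- Filter(length, sets)
  structure(list(universe = universe, sets = sets),
            class = "annotation_collection")
}

#' Read an annotation map
#'
#' Two-column TSV `term <tab> feature` (HMDD-style disease-miRNA map, GO
#' slims, any term-to-feature table).
#'
#' @param path Path to the TSV (header `term`, `feature`).
#' @param universe Feature universe; defaults to all features appearing in
#'   the file, but should normally be the set of features tested for DE.
#' @return An [annotation_collection()].
#' @export
read_annotations <- function(path, universe = NULL) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("term", "feature") %in% names(d)))
    stop("annotation TSV needs columns 'term' and 'feature'")
  if (is.null(universe)) universe <- unique(d$feature)
  annotation_collection(universe, split(d$feature, d$term))
}

#' Hypergeometric over-representation test
#'
#' For each annotation term with `K` features in a universe of size `N`,
#' and a selected set of size `n` overlapping the term in `k` features,
#' computes the upper-tail hypergeometric probability `P(X >= k)`, the
#' gene ratio `k/n`, and BH-adjusted q-values across terms.  Selected
#' features outside the universe are dropped with a warning.
#'
#' @param selected Character vector of selected feature IDs (non-empty
#'   after universe filtering).
#' @param ann An [annotation_collection()].
#' @return Data.frame sorted by `p` with columns `term`, `k`, `K`, `n`,
#'   `N`, `gene_ratio`, `p`, `q`.
#' @export
hypergeom_enrich <- function(selected, ann) {
  if (!inherits(ann, "annotation_collection"))
    stop("ann must be an annotation_collection")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, ann$universe)
  if (length(outside))
    warning(sprintf("%d selected feature(s) outside the universe dropped",
                    length(outside)))
  selected <- intersect(selected, ann$universe)
  if (length(selected) == 0) stop("no selected features in the universe")
  N <- length(ann$universe); n <- length(selected)
  rows <- lapply(names(ann$sets), function(term) {
    set <- ann$sets[[term]]
    K <- length(set); k <- length(intersect(set, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               gene_ratio = k / n, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
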