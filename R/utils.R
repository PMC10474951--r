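`%||%` <- function(a, b) if (is.null(a)) b else a

.geomean <- function(x) exp(mean(log(x)))

## Canonical mutant/wild-type label handling: accept a logical vector
## (TRUE = mutant), a 0/1 vector, or a character/factor containing "mutant".
.as_mutant <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("mutant", "wild-type")))
    stop("labels must be logical, 0/1, or 'mutant'/'wild-type'")
  lab == "mutant"
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must be in [0, 1]", name))
  invisible(x)
}

## Small deterministic seed stream: seed for the k-th consumer derived from a
## master seed by a counter, kept below .Machine$integer.max.
.derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 9973 * as.numeric(counter)) %% 2147483647)
}
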