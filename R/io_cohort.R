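#' Default nonsilent consequence classes
#'
#' Consequence tokens counted as nonsilent (protein-altering) when mutation
#' records are aggregated to gene-level binary status.  Covers the standard
#' MAF `Variant_Classification` vocabulary plus lower-case generic tokens so
#' that minimal three-column mutation tables work out of the box.  MAF
#' dialects differ, so the set is an argument everywhere it is used.
#'
#' @return Character vector of consequence tokens.
#' @export
default_nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site",
    "missense", "nonsense", "nonstop", "frameshift_indel", "inframe_indel",
    "splice_site", "translation_start")
}

#' Read a somatic mutation table
#'
#' Accepts either a MAF-compatible TSV (columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`;
#' 1-based inclusive coordinates) or a minimal three-column dialect with
#' columns `patient`, `gene`, `consequence`.  Column order does not matter;
#' extra columns are ignored.
#'
#' @param path Path to a tab-separated mutation table.
#' @return A data.frame with columns `patient_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `consequence` (positional columns are `NA` for the
#'   minimal dialect).
#' @export
read_mutation_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "#")
  maf_cols <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome",
                "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                "Variant_Classification")
  if (all(maf_cols %in% names(d))) {
    rec <- data.frame(patient_id = as.character(d$Tumor_Sample_Barcode),
                      gene = as.character(d$Hugo_Symbol),
                      chrom = as.character(d$Chromosome),
                      pos = as.integer(d$Start_Position),
                      ref = as.character(d$Reference_Allele),
                      alt = as.character(d$Tumor_Seq_Allele2),
                      consequence = as.character(d$Variant_Classification),
                      stringsAsFactors = FALSE)
  } else if (all(c("patient", "gene", "consequence") %in% names(d))) {
    rec <- data.frame(patient_id = as.character(d$patient),
                      gene = as.character(d$gene),
                      chrom = NA_character_, pos = NA_integer_,
                      ref = NA_character_, alt = NA_character_,
                      consequence = as.character(d$consequence),
                      stringsAsFactors = FALSE)
  } else {
    stop("unrecognized mutation table: need MAF headers or patient/gene/consequence")
  }
  validate_mutation_records(rec)
  rec
}

#' Validate mutation records
#'
#' Enforces the record invariants: positions (where present) are >= 1,
#' reference and alternate alleles differ, and the consequence is a
#' non-empty token.
#'
#' @param records Data.frame as returned by [read_mutation_table()].
#' @return The records, invisibly; errors on violation.
#' @export
validate_mutation_records <- function(records) {
  need <- c("patient_id", "gene", "consequence")
  if (!all(need %in% names(records)))
    stop("mutation records need columns patient_id, gene, consequence")
  if (any(!is.na(records$pos) & records$pos < 1))
    stop("mutation positions must be >= 1 (1-based)")
  same <- !is.na(records$ref) & !is.na(records$alt) &
    records$ref == records$alt
  if (any(same))
    stop("mutation records with ref == alt are not variants")
  if (any(is.na(records$consequence) | records$consequence == ""))
    stop("every mutation record needs a non-empty consequence token")
  invisible(records)
}

#' Read a feature-by-sample count matrix
#'
#' TSV with the feature identifier in the first column and one column of
#' non-negative integer counts per patient.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, features in rows, patients in columns.
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("count matrix entries must be non-negative and finite")
  m
}

#' Read a clinical survival table
#'
#' TSV with columns `patient`, `os_time`, `os_event`, `dss_time`,
#' `dss_event`; missing values are allowed as empty fields or NA.
#'
#' @param path Path to the TSV.
#' @return Data.frame keyed by `patient`.
#' @export
read_clinical_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("patient", "os_time", "os_event", "dss_time", "dss_event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("os_event", "dss_event")) {
    bad <- !is.na(d[[col]]) & !(d[[col]] %in% c(0, 1))
    if (any(bad)) stop(col, " must be 0/1 or missing")
  }
  for (col in c("os_time", "dss_time")) {
    bad <- !is.na(d[[col]]) & d[[col]] <= 0
    if (any(bad)) stop(col, " must be positive where present")
  }
  d[need]
}

#' Construct a cohort
#'
#' A cohort bundles one cancer type's patients, their feature-by-patient raw
#' count matrix, and (optionally) per-patient survival endpoints.
#'
#' @param cancer_type Cohort label.
#' @param counts Feature-by-patient matrix of non-negative counts; column
#'   names are the patient IDs.
#' @param clinical Optional data.frame as from [read_clinical_table()];
#'   every clinical patient must appear in `colnames(counts)`.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(cancer_type, counts, clinical = NULL) {
  if (is.null(colnames(counts))) stop("counts must have patient column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  patients <- colnames(counts)
  if (anyDuplicated(patients)) stop("duplicated patient IDs in counts")
  if (!is.null(clinical)) {
    extra <- setdiff(clinical$patient, patients)
    if (length(extra))
      stop("clinical patients absent from counts: ",
           paste(utils::head(extra, 5), collapse = ", "))
    clinical <- clinical[match(patients, clinical$patient), , drop = FALSE]
    clinical$patient <- patients   # keep full roster; unmatched rows are NA
    rownames(clinical) <- NULL
  }
  structure(list(cancer_type = cancer_type, patients = patients,
                 counts = counts, clinical = clinical),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort '%s': %d features x %d patients; clinical: %s\n",
              x$cancer_type, nrow(x$counts), length(x$patients),
              if (is.null(x$clinical)) "none" else "OS/DSS"))
  invisible(x)
}

#' Aggregate mutation records to gene-level binary status
#'
#' A gene is considered mutated in a patient if at least one record with a
#' nonsilent consequence falls in the gene for that patient; aggregation is
#' an OR over records, so duplicates and record order are irrelevant.
#' Records for patients outside `patients` are dropped with a warning (the
#' dropped count is kept in attribute `n_dropped`).
#'
#' @param records Mutation records (see [read_mutation_table()]).
#' @param patients Character vector of cohort patient IDs (non-empty).
#' @param nonsilent_classes Consequence tokens treated as nonsilent.
#' @return Binary gene-by-patient matrix (0/1); patients with no nonsilent
#'   record get all-zero columns.
#' @export
aggregate_mutations <- function(records, patients,
                                nonsilent_classes = default_nonsilent_classes()) {
  if (length(patients) == 0) stop("patients must be non-empty")
  if (length(nonsilent_classes) == 0) stop("nonsilent_classes must be non-empty")
  validate_mutation_records(records)
  unknown <- !(records$patient_id %in% patients)
  if (any(unknown)) {
    warning(sprintf("dropping %d mutation record(s) for unknown patient IDs",
                    sum(unknown)))
  }
  rec <- records[!unknown & records$consequence %in% nonsilent_classes, ,
                 drop = FALSE]
  genes <- sort(unique(records$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(patients),
              dimnames = list(genes, patients))
  if (nrow(rec)) {
    idx <- cbind(match(rec$gene, genes), match(rec$patient_id, patients))
    m[idx] <- 1L
  }
  attr(m, "n_dropped") <- sum(unknown)
  m
}

#' Map a mutation frequency to its discrete category
#'
#' Permutation nulls are shared across genes through ten discrete frequency
#' categories `{0.05, 0.10, ..., 0.50}`.  Because label permutation is
#' symmetric in the two classes, only the minority-class fraction
#' `f_effective = min(f, 1 - f)` matters; it is mapped to the grid either by
#' nearest-value rounding (default; exact midpoints round down) or by
#' rounding up (`"ceil"`), and clamped to `[0.05, 0.50]`.
#'
#' @param f Mutation frequency (vectorized), each in the open interval
#'   (0.05, 0.95) enforced by the two-sided frequency filter.
#' @param rounding `"nearest"` (default) or `"ceil"`.
#' @return Numeric vector of grid categories.
#' @export
map_frequency_category <- function(f, rounding = c("nearest", "ceil")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(f) | f <= 0.05 | f >= 0.95))
    stop("mutation frequency must lie in (0.05, 0.95)")
  f_eff <- pmin(f, 1 - f)
  d <- round((f_eff - 0.05) / 0.05, 9)
  k <- if (rounding == "nearest") ceiling(d - 0.5) else ceiling(d)
  k <- pmin(pmax(k, 0), 9)
  0.05 + 0.05 * k
}

#' Frequency category grid
#' @return The ten discrete categories `seq(0.05, 0.50, by = 0.05)`.
#' @export
category_grid <- function() seq(0.05, 0.50, by = 0.05)

#' Build frequency-filtered mutation contexts
#'
#' For each gene, splits the cohort's patients into mutant and wild-type by
#' binary mutation status and keeps the split only when both classes exceed
#' `min_freq` (two-sided 5% filter by default).  Patients present in the
#' cohort but absent from the mutation matrix are treated as wild-type
#' (absence of a call means no mutation), with a message.
#'
#' @param mutmatrix Gene-by-patient binary matrix from
#'   [aggregate_mutations()].
#' @param cohort A [new_cohort()] object.
#' @param min_freq Minimum class fraction, in (0, 0.5).
#' @param rounding Category rounding mode, see [map_frequency_category()].
#' @return List of `mutation_context` objects, each with fields
#'   `cancer_type`, `gene`, `labels` (named character, `"mutant"` /
#'   `"wild-type"`, ordered as the cohort's patients), `f`, `f_effective`,
#'   `category`.
#' @export
build_contexts <- function(mutmatrix, cohort, min_freq = 0.05,
                           rounding = c("nearest", "ceil")) {
  rounding <- match.arg(rounding)
  if (min_freq <= 0 || min_freq >= 0.5) stop("min_freq must be in (0, 0.5)")
  patients <- cohort$patients
  common <- intersect(colnames(mutmatrix), patients)
  if (length(common) == 0)
    stop("no overlap between mutation-table patients and cohort patients")
  absent <- setdiff(patients, colnames(mutmatrix))
  if (length(absent))
    message(sprintf("%d cohort patient(s) without mutation calls treated as wild-type",
                    length(absent)))
  full <- matrix(0L, nrow = nrow(mutmatrix), ncol = length(patients),
                 dimnames = list(rownames(mutmatrix), patients))
  full[, common] <- mutmatrix[, common]
  n <- length(patients)
  f <- rowSums(full) / n
  keep <- which(f > min_freq & f < 1 - min_freq)
  lapply(keep, function(i) {
    labels <- ifelse(full[i, ] == 1L, "mutant", "wild-type")
    names(labels) <- patients
    structure(list(cancer_type = cohort$cancer_type,
                   gene = rownames(full)[i],
                   labels = labels,
                   f = f[[i]],
                   f_effective = min(f[[i]], 1 - f[[i]]),
                   category = map_frequency_category(f[[i]], rounding)),
              class = "mutation_context")
  })
}

#' @export
print.mutation_context <- function(x, ...) {
  cat(sprintf("mutation context %s / %s: f = %.3f (category %.2f), %d mutant / %d wild-type\n",
              x$cancer_type, x$gene, x$f, x$category,
              sum(x$labels == "mutant"), sum(x$labels == "wild-type")))
  invisible(x)
}
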