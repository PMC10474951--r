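#' Pipeline run configuration
#'
#' @param mutation_file,counts_file,clinical_file Input TSV paths
#'   (`clinical_file` optional; without it the prognosis stage is skipped).
#' @param out_dir Output directory.
#' @param cancer_type Cohort label.
#' @param annotation_file Optional term-feature TSV for enrichment.
#' @param fdr_threshold DE significance threshold (defines the DE count).
#' @param min_freq Two-sided context frequency filter.
#' @param B_impact,B_cges Permutation counts for the impact and prognosis
#'   stages.
#' @param alpha Per-context significance level on the NB-modified P.
#' @param seed Master seed.
#' @param rounding Category rounding mode (`"nearest"` or `"ceil"`).
#' @param min_total_count DE engine count filter.
#' @param prognosis_all Run prognosis on every context instead of only the
#'   impact-significant ones.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mutation_file, counts_file, clinical_file = NULL,
                       out_dir = "mirimpact_run", cancer_type = "COHORT",
                       annotation_file = NULL, fdr_threshold = 0.05,
                       min_freq = 0.05, B_impact = 1000, B_cges = 1000,
                       alpha = 0.05, seed = 1,
                       rounding = c("nearest", "ceil"),
                       min_total_count = 10, prognosis_all = FALSE) {
  rounding <- match.arg(rounding)
  for (v in c(fdr_threshold, min_freq, alpha))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)")
  if (B_impact < 100 || B_cges < 100) stop("B must be at least 100")
  structure(list(mutation_file = mutation_file, counts_file = counts_file,
                 clinical_file = clinical_file, out_dir = out_dir,
                 cancer_type = cancer_type,
                 annotation_file = annotation_file,
                 fdr_threshold = fdr_threshold, min_freq = min_freq,
                 B_impact = B_impact, B_cges = B_cges, alpha = alpha,
                 seed = seed, rounding = rounding,
                 min_total_count = min_total_count,
                 prognosis_all = prognosis_all),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

## Content key for the null cache: inputs + the settings the null depends on.
.null_cache_key <- function(cfg, category) {
  md5 <- unname(tools::md5sum(cfg$counts_file))
  sprintf("%s_B%d_fdr%g_mtc%d_seed%d_cat%.2f",
          substr(md5, 1, 12), cfg$B_impact, cfg$fdr_threshold,
          cfg$min_total_count, cfg$seed, category)
}

#' Run the full mutation-impact workflow
#'
#' Executes the three-step framework for one cohort: (1) mutation contexts
#' and per-context DE, (2) frequency-matched permutation nulls (cached on
#' disk, keyed by input content and configuration) and impact statistics,
#' (3) aggregative prognosis of the responsive feature sets — by default
#' only for contexts that pass the impact test at `alpha`, mirroring the
#' framework's gating — plus optional hypergeometric enrichment.  Each
#' context fails soft with a logged reason; only I/O errors abort the run.
#' No multiple-testing correction is applied across contexts: each
#' context's modified P is thresholded at `alpha` on its own, exactly as
#' in the framework this package implements.
#'
#' @param cfg A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the main tables (`contexts`, `impact`,
#'   `prognosis`, `enrichment`) and the manifest; everything is also
#'   written under `cfg$out_dir` as TSV plus `manifest.json`.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "nulls"), showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "de"), showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[%s] %s",
                                           format(Sys.time(), "%H:%M:%S"),
                                           sprintf(...)))

  counts <- read_count_matrix(cfg$counts_file)
  clinical <- if (!is.null(cfg$clinical_file))
    read_clinical_table(cfg$clinical_file) else NULL
  cohort <- new_cohort(cfg$cancer_type, counts, clinical)
  records <- read_mutation_table(cfg$mutation_file)
  mut <- aggregate_mutations(records, cohort$patients)
  contexts <- build_contexts(mut, cohort, min_freq = cfg$min_freq,
                             rounding = cfg$rounding)
  log_msg("%s: %d mutated genes, %d contexts pass the %.0f%% filter",
          cfg$cancer_type, nrow(mut), length(contexts), 100 * cfg$min_freq)

  ctab <- if (length(contexts)) do.call(rbind, lapply(contexts, function(cx)
    data.frame(cohort = cx$cancer_type, gene = cx$gene, f = cx$f,
               f_effective = cx$f_effective, category = cx$category,
               stringsAsFactors = FALSE)))
  else data.frame(cohort = character(), gene = character(), f = numeric(),
                  f_effective = numeric(), category = numeric())
  utils::write.table(ctab, file.path(cfg$out_dir, "contexts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  de <- de_engine_nbglm(fdr_threshold = cfg$fdr_threshold,
                        min_total_count = cfg$min_total_count)
  norm <- tmm_normalize(counts)

  nulls <- list()
  for (cat in sort(unique(ctab$category))) {
    key <- .null_cache_key(cfg, cat)
    tsv <- file.path(cfg$out_dir, "nulls", paste0(key, ".tsv"))
    js <- file.path(cfg$out_dir, "nulls", paste0(key, ".json"))
    if (file.exists(tsv) && file.exists(js)) {
      nulls[[sprintf("%.2f", cat)]] <- read_null_distribution(tsv, js)
      log_msg("null category %.2f: cache hit", cat)
    } else {
      idx <- which(abs(cat - category_grid()) < 1e-9)
      null <- simulate_null(cohort, cat, B = cfg$B_impact,
                            seed = .derive_seed(cfg$seed, idx),
                            de = de, norm = norm)
      write_null_distribution(null, tsv, js)
      nulls[[sprintf("%.2f", cat)]] <- null
      log_msg("null category %.2f: B = %d built", cat, cfg$B_impact)
    }
  }

  impact_rows <- list(); responsive_rows <- list(); failures <- list()
  results <- list()
  for (cx in contexts) {
    r <- tryCatch(assess_impact(cx, cohort, nulls, de = de,
                                alpha = cfg$alpha, norm = norm),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failures[[cx$gene]] <- conditionMessage(r)
      next
    }
    results[[cx$gene]] <- r
    impact_rows[[cx$gene]] <- data.frame(
      cohort = r$cancer_type, gene = r$gene, f = r$f, category = r$category,
      N_obs = r$N_obs, p_emp = r$p_emp, z = as.numeric(r$z), p_nb = r$p_nb,
      significant = r$significant, stringsAsFactors = FALSE)
    write_de_result(r$de, file.path(cfg$out_dir, "de",
                                    paste0(cx$gene, ".tsv")), cx)
    resp <- r$de$feature[!is.na(r$de$q) & r$de$q < cfg$fdr_threshold]
    if (length(resp))
      responsive_rows[[cx$gene]] <- data.frame(gene = r$gene,
                                               feature = resp,
                                               stringsAsFactors = FALSE)
  }
  impact <- if (length(impact_rows)) do.call(rbind, impact_rows)
  else data.frame(cohort = character(), gene = character(), f = numeric(),
                  category = numeric(), N_obs = integer(), p_emp = numeric(),
                  z = numeric(), p_nb = numeric(), significant = logical())
  rownames(impact) <- NULL
  utils::write.table(impact, file.path(cfg$out_dir, "impact.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  responsive <- if (length(responsive_rows)) do.call(rbind, responsive_rows)
  else data.frame(gene = character(), feature = character())
  rownames(responsive) <- NULL
  utils::write.table(responsive, file.path(cfg$out_dir, "responsive.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## OncoPrint-style table: context genes by patients, 0/1 mutation status
  op_genes <- intersect(rownames(mut), unique(ctab$gene))
  op <- data.frame(gene = op_genes,
                   mut[op_genes, cohort$patients, drop = FALSE],
                   check.names = FALSE)
  utils::write.table(op, file.path(cfg$out_dir, "oncoprint.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prog_rows <- list()
  if (!is.null(clinical)) {
    sel <- if (cfg$prognosis_all) impact$gene
           else impact$gene[impact$significant]
    for (g in sel) {
      feats <- responsive$feature[responsive$gene == g]
      if (length(feats) == 0) next
      for (ep in c("OS", "DSS")) {
        pr <- tryCatch(
          assess_prognosis(cohort, feats, ep, B = cfg$B_cges,
                           seed = .derive_seed(cfg$seed,
                                               1000 + match(g, impact$gene)),
                           norm = norm),
          error = function(e) e)
        if (inherits(pr, "error")) {
          failures[[paste(g, ep, sep = ":")]] <- conditionMessage(pr)
          next
        }
        dir.create(file.path(cfg$out_dir, "prognosis_features"),
                   showWarnings = FALSE)
        utils::write.table(pr$features,
                           file.path(cfg$out_dir, "prognosis_features",
                                     sprintf("%s_%s.tsv", g, ep)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        prog_rows[[paste(g, ep)]] <- data.frame(
          cohort = cfg$cancer_type, gene = g, endpoint = ep,
          n_features = pr$n_features, s_obs = pr$s_obs,
          p_perm = pr$p_perm, p_beta = pr$p_beta,
          alpha = pr$alpha, beta = pr$beta, stringsAsFactors = FALSE)
      }
    }
  }
  prognosis <- if (length(prog_rows)) do.call(rbind, prog_rows)
  else data.frame(cohort = character(), gene = character(),
                  endpoint = character(), n_features = integer(),
                  s_obs = numeric(), p_perm = numeric(), p_beta = numeric(),
                  alpha = numeric(), beta = numeric())
  rownames(prognosis) <- NULL
  utils::write.table(prognosis, file.path(cfg$out_dir, "prognosis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  enrichment <- NULL
  if (!is.null(cfg$annotation_file) && nrow(responsive)) {
    tested <- rownames(counts)[rowSums(counts) >= cfg$min_total_count]
    ann <- read_annotations(cfg$annotation_file, universe = tested)
    enr_rows <- lapply(unique(responsive$gene), function(g) {
      out <- tryCatch(
        hypergeom_enrich(responsive$feature[responsive$gene == g], ann),
        error = function(e) NULL)
      if (is.null(out)) return(NULL)
      cbind(gene = g, out)
    })
    enrichment <- do.call(rbind, Filter(Negate(is.null), enr_rows))
    if (!is.null(enrichment))
      utils::write.table(enrichment,
                         file.path(cfg$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirimpact")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = unclass(cfg),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(
      cfg$mutation_file, cfg$counts_file, cfg$clinical_file)))),
    counts = list(patients = length(cohort$patients),
                  features = nrow(counts),
                  mutated_genes = sum(rowSums(mut) > 0),
                  contexts = length(contexts),
                  impacting = sum(impact$significant),
                  prognostic_OS = sum(prognosis$endpoint == "OS" &
                                        prognosis$p_beta < cfg$alpha),
                  prognostic_DSS = sum(prognosis$endpoint == "DSS" &
                                         prognosis$p_beta < cfg$alpha)),
    failures = failures,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done: %d contexts, %d impacting, %d prognosis rows",
          length(contexts), sum(impact$significant), nrow(prognosis))
  invisible(list(contexts = ctab, impact = impact, prognosis = prognosis,
                 responsive = responsive, enrichment = enrichment,
                 manifest = manifest, results = results))
}

#' Summarize one or more completed runs
#'
#' Cross-context summary tables rebuilt purely from the stage outputs on
#' disk: per-cohort counts of mutated, miRNA-impacting, and prognostic
#' genes; per-gene cross-cohort responsive-set intersection sizes; and the
#' per-patient gene-by-mutation presence matrix.  Partial runs are
#' summarized with their gaps flagged in `$missing`.
#'
#' @param run_dirs Character vector of [run_all()] output directories.
#' @return List with `gene_counts`, `intersections`, `oncoprint`,
#'   `missing`.
#' @export
summarize_results <- function(run_dirs) {
  read_or_null <- function(path) if (file.exists(path))
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  else NULL
  gene_counts <- list(); resp <- list(); oncoprint <- list(); missing <- list()
  for (d in run_dirs) {
    imp <- read_or_null(file.path(d, "impact.tsv"))
    prg <- read_or_null(file.path(d, "prognosis.tsv"))
    rsp <- read_or_null(file.path(d, "responsive.tsv"))
    man_path <- file.path(d, "manifest.json")
    man <- if (file.exists(man_path)) jsonlite::read_json(man_path) else NULL
    for (f in c("impact.tsv", "responsive.tsv", "manifest.json"))
      if (!file.exists(file.path(d, f)))
        missing[[d]] <- c(missing[[d]], f)
    cohort <- if (!is.null(imp) && nrow(imp)) imp$cohort[1] else basename(d)
    gene_counts[[d]] <- data.frame(
      cohort = cohort,
      mutated = man$counts$mutated_genes %||% NA_integer_,
      contexts = if (is.null(imp)) 0L else nrow(imp),
      impacting = if (is.null(imp)) 0L else sum(imp$significant == "TRUE" |
                                                  imp$significant == TRUE),
      prognostic = if (is.null(prg) || !nrow(prg)) 0L
                   else length(unique(prg$gene[prg$p_beta < 0.05])),
      stringsAsFactors = FALSE)
    if (!is.null(rsp) && nrow(rsp)) {
      rsp$cohort <- cohort
      resp[[d]] <- rsp
    }
    op <- read_or_null(file.path(d, "oncoprint.tsv"))
    if (!is.null(op)) oncoprint[[cohort]] <- op
  }
  gene_counts <- if (length(gene_counts)) do.call(rbind, gene_counts)
  else data.frame(cohort = character(), mutated = integer(),
                  contexts = integer(), impacting = integer(),
                  prognostic = integer())
  rownames(gene_counts) <- NULL
  respall <- if (length(resp)) do.call(rbind, resp)
  else data.frame(gene = character(), feature = character(),
                  cohort = character())
  inter <- list()
  for (g in unique(respall$gene)) {
    sub <- respall[respall$gene == g, ]
    cohorts <- unique(sub$cohort)
    if (length(cohorts) < 2) next
    sets <- lapply(cohorts, function(cc) sub$feature[sub$cohort == cc])
    inter[[g]] <- data.frame(gene = g, n_cohorts = length(cohorts),
                             union = length(Reduce(union, sets)),
                             intersection = length(Reduce(intersect, sets)),
                             stringsAsFactors = FALSE)
  }
  inter <- if (length(inter)) do.call(rbind, inter)
  else data.frame(gene = character(), n_cohorts = integer(),
                  union = integer(), intersection = integer())
  rownames(inter) <- NULL
  list(gene_counts = gene_counts, intersections = inter,
       oncoprint = oncoprint, missing = missing)
}
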