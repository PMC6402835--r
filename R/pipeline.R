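#' Build and validate a pipeline run configuration
#'
#' Collects the input paths and analysis thresholds of an end-to-end run and
#' validates every threshold range before any stage executes. Paths follow
#' the fixture layout written by [simulateStudy()].
#'
#' @param input_dir directory holding catalog.tsv, variants.tsv,
#'   segments.seg, edges.tsv, expr.tsv, samples.tsv, dependency.csv,
#'   cellline_mutations.csv, ic50.csv.
#' @param min_patients recurrent-point-mutation patient minimum (default 3).
#' @param min_freq recurrent-CNA patient fraction (default 0.10).
#' @param quantile_cut CNA magnitude quantile filter (default 0.90).
#' @param max_chrom_fraction focality bound (default 0.25).
#' @param alpha significance level for all Wilcoxon screens (default 0.05).
#' @param dependency_threshold dependency probability cut (default 0.95).
#' @param min_diff minimum median dependency difference (default 0.20).
#' @param rho_cut dependency-IC50 correlation threshold (default -0.25).
#' @param master_out master-regulator out-degree cut (default 10).
#' @param strict_deleteriousness exclude missense variants lacking
#'   SIFT/PolyPhen flags.
#' @param focal_only restrict network CNA analyses to focal-recurrent calls.
#' @param interface_rule `"and"` or `"or"` UC/EM-i rule variant.
#' @param seed integer seed recorded in the log (analyses are deterministic;
#'   the seed covers permutation options).
#' @return validated list of class `RunConfig`.
#' @export
runConfig <- function(input_dir, min_patients = 3L, min_freq = 0.10,
                      quantile_cut = 0.90, max_chrom_fraction = 0.25,
                      alpha = 0.05, dependency_threshold = 0.95,
                      min_diff = 0.20, rho_cut = -0.25, master_out = 10L,
                      strict_deleteriousness = FALSE, focal_only = FALSE,
                      interface_rule = c("and", "or"), seed = 1L) {
  interface_rule <- match.arg(interface_rule)
  cfg <- as.list(environment())
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      stop(sprintf("%s must lie in [%s, %s]", nm, lo, hi))
  }
  chk(cfg$min_freq, 0, 1, "min_freq")
  chk(cfg$quantile_cut, 0, 1, "quantile_cut")
  chk(cfg$max_chrom_fraction, 0, 1, "max_chrom_fraction")
  chk(cfg$alpha, 0, 1, "alpha")
  chk(cfg$dependency_threshold, 0, 1, "dependency_threshold")
  chk(cfg$min_diff, 0, 1, "min_diff")
  chk(cfg$rho_cut, -1, 0, "rho_cut")
  if (cfg$min_patients < 1) stop("min_patients must be at least 1")
  if (cfg$master_out < 1) stop("master_out must be at least 1")
  structure(cfg, class = "RunConfig")
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config)[order(names(unclass(config)))], file = tmp)
  unname(md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — gene ages, recurrence, phylostratum
#' enrichment, regulatory network, expression, regulator/target CNA
#' exclusivity, cell-line dependency — writing per-stage tidy TSVs, a
#' machine-readable JSON summary and a log recording every threshold, the
#' seed and exclusion counts. Any stage failure aborts with the stage name;
#' outputs of completed stages are retained.
#'
#' @param config a [runConfig()].
#' @param out_dir output directory.
#' @return (invisibly) the summary list.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- configHash(config)
  logfile <- file.path(out_dir, "run.log")
  logline <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  }
  unlink(logfile)
  logline("config_hash: ", hash)
  logline("seed: ", config$seed)
  for (nm in setdiff(names(unclass(config)), c("input_dir", "seed")))
    logline(nm, ": ", config[[nm]])
  set.seed(config$seed)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  p <- function(f) file.path(config$input_dir, f)
  summary <- list(config_hash = hash)

  # -- ages ------------------------------------------------------------
  catalog <- stage("ages", loadGeneCatalog(p("catalog.tsv")))
  counts <- groupCounts(catalog)
  summary$ages <- list(n_genes = nGenes(catalog),
                       age_group = as.list(counts$age_group))
  logline("ages: dropped_no_age=",
          catalog@metadata$n_dropped_no_age %||% 0L)

  # -- recurrence ------------------------------------------------------
  rec <- stage("recurrence", {
    variants <- readVariants(p("variants.tsv"),
                             strict = config$strict_deleteriousness)
    segments <- readSegments(p("segments.seg"))
    calls <- callGeneCNA(segments, catalog,
                         quantile_cut = config$quantile_cut)
    cohort <- sort(unique(variants$patient))
    point <- recurrentPointGenes(variants, config$min_patients)
    cna <- recurrentCnaGenes(calls, length(cohort), config$min_freq)
    focal <- focalRecurrentCnaGenes(calls, catalog, length(cohort),
                                    config$max_chrom_fraction,
                                    config$min_freq)
    list(variants = variants, calls = calls, cohort = cohort,
         point = point, cna = cna, focal = focal)
  })
  emit(rec$point, "recurrence_point")
  emit(rec$cna, "recurrence_cna")
  emit(rec$focal, "recurrence_focal")
  summary$recurrence <- list(
    n_recurrent_point = sum(rec$point$recurrent_point),
    n_recurrent_amp = sum(rec$cna$recurrent_amp),
    n_recurrent_del = sum(rec$cna$recurrent_del),
    n_variants_excluded = sum(rec$variants$class == "excluded"))
  logline("recurrence: excluded_variants=",
          summary$recurrence$n_variants_excluded)

  # -- enrichment ------------------------------------------------------
  enr <- stage("enrichment", {
    sets <- list(
      point = rec$point$gene[rec$point$recurrent_point],
      amplification = rec$cna$gene[rec$cna$recurrent_amp],
      deletion = rec$cna$gene[rec$cna$recurrent_del])
    res <- lapply(sets, function(s) stratumEnrichment(catalog, s))
    tidy <- do.call(rbind, lapply(names(res), function(nm) {
      r <- res[[nm]]
      data.frame(alteration = nm, phylostratum = 1:16,
                 fraction = as.numeric(r$fraction),
                 rank = as.numeric(r$rank),
                 statistic = unname(r$trend$statistic),
                 p = r$trend$p.value, stringsAsFactors = FALSE)
    }))
    trend_p <- vapply(res, function(r) r$trend$p.value, numeric(1))
    tidy$p_adj <- p.adjust(trend_p, "BH")[tidy$alteration]
    list(results = res, tidy = tidy,
         trend_p_adj = p.adjust(trend_p, "BH"))
  })
  emit(enr$tidy, "enrichment")
  summary$enrichment <- list(trend_p_adj = as.list(enr$trend_p_adj))

  # -- grn -------------------------------------------------------------
  grn <- stage("grn", {
    net <- buildGRN(readEdgeTable(p("edges.tsv")),
                    interaction_filter = NULL)
    prof <- degreeProfiles(net, catalog, rule = config$interface_rule)
    masters <- masterRegulators(prof, config$master_out)
    regs <- prof$gene[prof$k_out > 0]
    em <- ageEnrichmentFisher(regs, geneIds(catalog), catalog, "EM")
    list(net = net, prof = prof, masters = masters, em_fisher = em)
  })
  emit(grn$prof, "grn_profiles")
  reg_prof <- grn$prof[grn$prof$k_out > 0, ]
  summary$grn <- list(
    n_nodes = length(grn$net@nodes), n_edges = edgeCount(grn$net),
    n_regulators = nrow(reg_prof), n_masters = length(grn$masters),
    pct_em_regulators = 100 * mean(reg_prof$age_group == "EM",
                                   na.rm = TRUE),
    em_fisher_p = grn$em_fisher$p.value,
    class_counts = as.list(table(reg_prof$reg_class)))
  logline("grn: self_loops_removed=", grn$net@removed$self_loops,
          " duplicates_removed=", grn$net@removed$duplicates)

  # -- expression ------------------------------------------------------
  expr <- stage("expression", {
    se <- readExpressionSet(p("expr.tsv"), p("samples.tsv"))
    nonsyn <- rec$variants[rec$variants$class %in% c("missense", "LoF"), ]
    mut_by_gene <- split(nonsyn$patient, nonsyn$gene)
    rec_genes <- rec$point$gene[rec$point$recurrent_point]
    de_mut <- do.call(rbind, lapply(rec_genes, function(gn)
      deOnMutation(se, gn, unique(mut_by_gene[[gn]]), config$alpha,
                   config$min_patients)))
    de_amp <- cnaFoldChangeDE(se, rec$calls, "amplification", config$alpha,
                              config$min_patients)
    de_del <- cnaFoldChangeDE(se, rec$calls, "deletion", config$alpha,
                              config$min_patients)
    cd <- colData(se)
    sample_of <- setNames(rownames(cd)[cd$tissue == "tumor"],
                          cd$patient[cd$tissue == "tumor"])
    impact <- do.call(rbind, lapply(grn$masters, function(reg) {
      mut_pats <- unique(mut_by_gene[[reg]])
      downstreamImpact(se, reg, targetsOf(grn$net, reg),
                       unname(sample_of[intersect(mut_pats,
                                                  names(sample_of))]),
                       config$alpha, config$min_patients)
    }))
    list(se = se, de_mut = de_mut, de_amp = de_amp, de_del = de_del,
         impact = impact)
  })
  if (!is.null(expr$de_mut)) emit(expr$de_mut, "expression_de_mutation")
  emit(expr$de_amp, "expression_de_amplification")
  emit(expr$de_del, "expression_de_deletion")
  if (!is.null(expr$impact)) emit(expr$impact, "expression_impact")
  pctDE <- function(de, dir) {
    ag <- as.character(ageGroups(catalog)[de$gene])
    out <- lapply(split(de$de, factor(ag, levels = AGE_GROUPS)),
                  function(x) if (length(x)) 100 * mean(x) else NA_real_)
    out
  }
  summary$expression <- list(
    pct_de_amp_by_age = pctDE(expr$de_amp),
    pct_de_del_by_age = pctDE(expr$de_del),
    n_impact_tested = if (is.null(expr$impact)) 0L
                      else sum(!expr$impact$skipped))

  # -- cna_network -----------------------------------------------------
  cnet <- stage("cna_network", {
    calls <- rec$calls
    if (config$focal_only) {
      foc <- rec$focal[rec$focal$focal_recurrent, c("gene", "direction")]
      calls <- merge(calls, foc, by = c("gene", "direction"))
    }
    fr <- targetCnaFractions(grn$net, calls, rec$cohort)
    ex <- exclusivityTest(fr, alpha = config$alpha)
    classes <- setNames(grn$prof$reg_class, grn$prof$gene)
    summ <- classExclusivitySummary(ex, classes)
    list(fractions = fr, test = ex, summary = summ)
  })
  emit(cnet$test, "cna_network_exclusivity")
  emit(cnet$summary, "cna_network_class_summary")
  summary$cna_network <- list(
    n_regulators_tested = nrow(cnet$test),
    pct_cnn_higher = if (nrow(cnet$test)) {
      100 * mean(cnet$test$direction == "CNN_higher")
    } else NA_real_)

  # -- dependency ------------------------------------------------------
  dep <- stage("dependency", {
    read_mat <- function(f) {
      tab <- read.csv(p(f), check.names = FALSE)
      m <- as.matrix(tab[, -1, drop = FALSE])
      rownames(m) <- tab[[1L]]
      m
    }
    dmat <- read_mat("dependency.csv")
    ic50 <- read_mat("ic50.csv")
    muts <- read.csv(p("cellline_mutations.csv"),
                     stringsAsFactors = FALSE)
    ann_path <- p("cellline_annotation.csv")
    if (file.exists(ann_path)) {
      ann <- read.csv(ann_path, stringsAsFactors = FALSE)
      keep <- ann$cell_line[ann$tissue != "haematopoietic_and_lymphoid"]
      dmat <- dmat[intersect(rownames(dmat), keep), , drop = FALSE]
      ic50 <- ic50[intersect(rownames(ic50), keep), , drop = FALSE]
      muts <- muts[muts$cell_line %in% keep, , drop = FALSE]
    }
    classes <- setNames(grn$prof$reg_class, grn$prof$gene)
    flags <- dependencyFlags(dmat, config$dependency_threshold)
    or <- classDependencyOR(flags, classes)
    md <- mutationDependency(dmat, muts, min_diff = config$min_diff,
                             alpha = config$alpha)
    dc <- drugDependencyCorr(dmat, ic50, rho_cut = config$rho_cut,
                             alpha = config$alpha)
    list(or = or, mutdep = md, drugcorr = dc)
  })
  emit(dep$or, "dependency_class_or")
  emit(dep$mutdep, "dependency_mutation")
  emit(dep$drugcorr, "dependency_drug_corr")
  or_med <- tapply(dep$or$odds_ratio, dep$or$reg_class, median)
  summary$dependency <- list(
    median_or_by_class = as.list(or_med),
    n_mutation_hits = sum(dep$mutdep$hit, na.rm = TRUE),
    n_drug_hits = sum(dep$drugcorr$hit, na.rm = TRUE))

  write_json(summary, file.path(out_dir, "summary.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  logline("completed: 7 stages")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
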