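#' Configuration for the synthetic-study generator
#'
#' Bundles every parameter of the seeded generator that emulates the
#' statistical structure of the pipeline inputs: a phylostratum-annotated
#' gene catalog laid out on chromosomes, a directed regulatory network with
#' known regulator archetypes, a tumor cohort (point mutations, CNA segments
#' as a focal/broad mixture, paired tumor/normal expression with CNA dosage
#' and regulator knock-on effects), gene-level CNA calls with
#' regulator-conditioned target alteration (mutual exclusivity), and a
#' cell-line bundle (dependency probabilities, mutations, IC50s).
#'
#' Defaults encode the study conditions the analyses are calibrated against:
#' stratum weights proportional to the human gene-age distribution (6719 UC /
#' 7939 EM / 2660 MM), an early-metazoan excess of non-synonymous point
#' mutation rates (3x UC/MM), EM-enriched regulator probabilities, an
#' out-degree power law whose upper quartile sits at out-degree 10, dosage
#' responsiveness decreasing with gene age (UC 0.6 > EM 0.4 > MM 0.1), and
#' target-CNA suppression when the regulator itself is copy-number altered
#' (0.40 under CNN vs 0.05 under CNA).
#'
#' @param seed integer master seed; sub-generators use fixed offsets from it
#'   so components can be regenerated independently.
#' @param n_genes,n_chromosomes,n_patients,n_cell_lines,n_drugs problem sizes.
#' @param stratum_weights 16 non-negative sampling weights for phylostrata.
#' @param point_rate_by_group per-patient probability of a non-synonymous
#'   point mutation per gene, by age group.
#' @param syn_rate background per-patient synonymous mutation probability.
#' @param lof_share fraction of non-synonymous mutations that are LoF.
#' @param n_focal,n_broad CNA events per patient of each kind.
#' @param focal_frac,broad_frac length-2 ranges of the fraction of a
#'   chromosome's genes covered by focal/broad events.
#' @param amp_prob probability an event is an amplification.
#' @param focal_mag_range,broad_mag_range segment-mean magnitude ranges
#'   (log-ratio scale) for focal and broad events; focal events carry
#'   high-level changes, broad events low-level ones, so the magnitude
#'   quantile filter of the CNA caller concentrates on focal calls.
#' @param hotspot_prob probability a focal event centres on a recurrent
#'   hotspot gene rather than a freshly drawn one.
#' @param n_hotspots number of hotspot centre genes (drawn once per cohort
#'   with the age-group placement weights), giving the recurrently altered
#'   loci real cohorts show.
#' @param focal_enrichment_by_group placement weights for focal-event centre
#'   genes, by age group.
#' @param regulator_prob_by_group probability a gene of each age group is a
#'   regulator.
#' @param outdeg_alpha,outdeg_max power-law exponent and truncation of the
#'   regulator out-degree distribution (minimum 1).
#' @param archetype_probs sampling probabilities of the regulator archetypes
#'   `UC_t`, `EM_t`, `UC_EM_i`.
#' @param mixing_by_archetype 3x3 matrix of target-age mixing weights (rows =
#'   archetypes, columns = UC/EM/MM). Target counts are allocated by largest
#'   remainder so archetypes are identifiable at moderate out-degree.
#' @param dosage_responsiveness_by_group probability a gene's expression
#'   responds to its copy-number dose, by age group.
#' @param regulator_effect_fraction,regulator_effect_size fraction of a
#'   mutated regulator's targets shifted, and the shift size (log2 units).
#' @param expr_log_mean,expr_log_gene_sd,expr_noise_sd baseline log2
#'   expression mean, between-gene SD and residual SD.
#' @param exclusivity_suppression named pair `c(cnn = , cna = )`: per-patient
#'   target-CNA probability when the regulator is CNN vs CNA.
#' @param regulator_cna_prob per-patient probability a regulator is CNA in
#'   the exclusivity generator.
#' @param dependency_base_by_class mean dependency probability per regulator
#'   class.
#' @param dependency_conc beta concentration of dependency probabilities.
#' @param dependency_shift added to dependency in mutated cell lines.
#' @param cellline_mutation_prob,cellline_amp_prob per-line probabilities of
#'   a point mutation / amplification in a regulator.
#' @param ic50_coupling `NULL` or data.frame (`drug`, `gene`, `slope`,
#'   `sigma`): IC50 generated as `slope * dependency + N(0, sigma)` for the
#'   listed pairs; independent noise otherwise. A `gene` of `NA` is filled
#'   with the first interface regulator at generation time.
#' @param ic50_noise_sd SD of uncoupled IC50 values.
#' @param cohort_name cohort label written into sample annotations.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    seed = 1L,
    n_genes = 1600L, n_chromosomes = 8L, n_patients = 50L,
    n_cell_lines = 60L, n_drugs = 10L,
    stratum_weights = c(rep(6719 / 3, 3), rep(7939 / 6, 6), rep(2660 / 7, 7)),
    point_rate_by_group = c(UC = 0.02, EM = 0.06, MM = 0.02),
    syn_rate = 0.01, lof_share = 0.3,
    n_focal = 6L, n_broad = 2L,
    focal_frac = c(0.02, 0.15), broad_frac = c(0.40, 0.90),
    amp_prob = 0.5,
    focal_mag_range = c(0.5, 2.0), broad_mag_range = c(0.1, 0.4),
    hotspot_prob = 0.6, n_hotspots = 12L,
    focal_enrichment_by_group = c(UC = 2, EM = 3, MM = 0.5),
    regulator_prob_by_group = c(UC = 0.08, EM = 0.12, MM = 0.03),
    outdeg_alpha = 1.6, outdeg_max = 60L,
    archetype_probs = c(UC_t = 0.30, EM_t = 0.35, UC_EM_i = 0.35),
    mixing_by_archetype = rbind(UC_t = c(0.92, 0.06, 0.02),
                                EM_t = c(0.06, 0.92, 0.02),
                                UC_EM_i = c(0.48, 0.48, 0.04)),
    dosage_responsiveness_by_group = c(UC = 0.6, EM = 0.4, MM = 0.1),
    regulator_effect_fraction = 0.3, regulator_effect_size = 1.5,
    expr_log_mean = 8, expr_log_gene_sd = 1.5, expr_noise_sd = 0.5,
    exclusivity_suppression = c(cnn = 0.40, cna = 0.05),
    regulator_cna_prob = 0.4,
    dependency_base_by_class = c(UC_t = 0.92, EM_t = 0.35,
                                 UC_EM_i = 0.92, MM_t = 0.35),
    dependency_conc = 25, dependency_shift = 0.3,
    cellline_mutation_prob = 0.10, cellline_amp_prob = 0.06,
    ic50_coupling = data.frame(drug = "drug_01", gene = NA_character_,
                               slope = -6, sigma = 0.5,
                               stringsAsFactors = FALSE),
    ic50_noise_sd = 1, cohort_name = "cohortA") {
  cfg <- as.list(environment())
  probs <- c(cfg$point_rate_by_group, cfg$syn_rate, cfg$lof_share,
             cfg$amp_prob, cfg$dosage_responsiveness_by_group,
             cfg$exclusivity_suppression, cfg$regulator_cna_prob,
             cfg$dependency_base_by_class, cfg$cellline_mutation_prob,
             cfg$cellline_amp_prob, cfg$archetype_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$stratum_weights) != 16L || any(cfg$stratum_weights < 0) ||
      sum(cfg$stratum_weights) <= 0)
    stop("stratum_weights must be 16 non-negative weights with positive sum")
  if (any(cfg$mixing_by_archetype < 0))
    stop("mixing weights must be non-negative")
  structure(cfg, class = "SimulationConfig")
}

# offsets of the per-component RNG substreams
SIM_SEED_OFFSETS <- c(catalog = 1L, grn = 2L, variants = 3L, segments = 4L,
                      expression = 5L, exclusivity = 6L, cell_lines = 7L)

simSeed <- function(config, component) {
  set.seed(config$seed + SIM_SEED_OFFSETS[[component]])
}

#' Simulate a phylostratum-annotated gene catalog
#'
#' Genes draw their phylostratum multinomially from `stratum_weights` and are
#' laid out in order across `n_chromosomes` equally sized chromosomes with
#' 1 kb gene bodies spaced 10 kb apart.
#'
#' @param config a [simulationConfig()].
#' @return a [GeneCatalog-class] with coordinates.
#' @export
simulateCatalog <- function(config) {
  simSeed(config, "catalog")
  n <- config$n_genes
  if (n == 0L)
    return(GeneCatalog(character(), integer(), character(),
                       chrom_index = integer()))
  strata <- sample(1:16, n, replace = TRUE,
                   prob = config$stratum_weights / sum(config$stratum_weights))
  chrom <- rep_len(paste0("chr", seq_len(config$n_chromosomes)), n)
  idx <- integer(n)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    idx[sel] <- seq_along(sel) - 1L
  }
  start <- idx * 10000L + 1L
  GeneCatalog(sprintf("g%04d", seq_len(n)), strata, chrom,
              chrom_index = idx, start = start, end = start + 999L)
}

# largest-remainder allocation of k units over weights w
allocCounts <- function(k, w) {
  w <- w / sum(w)
  base <- floor(k * w)
  rem <- k - sum(base)
  if (rem > 0) {
    frac <- k * w - base
    idx <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1L
  }
  as.integer(base)
}

#' Simulate a regulatory network with known regulator archetypes
#'
#' Regulators are drawn per age group by `regulator_prob_by_group`;
#' out-degrees follow a truncated power law (exponent `outdeg_alpha`,
#' maximum `outdeg_max`); each regulator is assigned an archetype and its
#' target-age counts are allocated from the archetype mixing weights by
#' largest remainder, with targets sampled uniformly within each age group.
#'
#' @param config a [simulationConfig()].
#' @param catalog a [GeneCatalog-class] from [simulateCatalog()].
#' @return list with `network` (a [RegulatoryNetwork-class]) and `labels`
#'   (data.frame `gene`, `archetype`, `k_out`).
#' @export
simulateGRN <- function(config, catalog) {
  simSeed(config, "grn")
  g <- catalog@genes
  grp <- as.character(g$age_group)
  is_reg <- runif(nrow(g)) < config$regulator_prob_by_group[grp]
  regs <- g$gene_id[is_reg]
  if (length(regs) == 0L)
    return(list(network = buildGRN(data.frame(source = character(),
                                              target = character()),
                                   interaction_filter = NULL),
                labels = data.frame(gene = character(),
                                    archetype = character(),
                                    k_out = integer())))
  alpha <- config$outdeg_alpha
  k <- floor(runif(length(regs))^(-1 / (alpha - 1)))
  k <- pmin(pmax(k, 1L), config$outdeg_max, nrow(g) - 1L)
  arche <- sample(names(config$archetype_probs), length(regs),
                  replace = TRUE, prob = config$archetype_probs)
  pool <- split(g$gene_id, grp)[AGE_GROUPS]
  edges <- vector("list", length(regs))
  for (i in seq_along(regs)) {
    want <- allocCounts(k[i], config$mixing_by_archetype[arche[i], ])
    tg <- character(0)
    short <- 0L
    for (j in seq_along(AGE_GROUPS)) {
      avail <- setdiff(pool[[j]], regs[i])
      take <- min(want[j], length(avail))
      short <- short + want[j] - take
      if (take > 0L)
        tg <- c(tg, sample(avail, take))
    }
    if (short > 0L) {  # group exhausted: top up from the remaining genes
      avail <- setdiff(g$gene_id, c(tg, regs[i]))
      tg <- c(tg, sample(avail, min(short, length(avail))))
    }
    edges[[i]] <- data.frame(source = regs[i], target = tg,
                             stringsAsFactors = FALSE)
  }
  edge_df <- do.call(rbind, edges)
  net <- buildGRN(edge_df, interaction_filter = NULL)
  list(network = net,
       labels = data.frame(gene = regs, archetype = arche,
                           k_out = as.integer(k), stringsAsFactors = FALSE))
}

patientIds <- function(n) sprintf("P%03d", seq_len(n))

#' Simulate a cohort's somatic point mutations
#'
#' Per gene and patient, a non-synonymous mutation occurs with the
#' age-group-specific rate (missense or LoF per `lof_share`) and a
#' synonymous mutation with the background `syn_rate`. All variants are
#' canonical, outside the last exon, and carry passing deleteriousness flags.
#'
#' @param config a [simulationConfig()].
#' @param catalog a [GeneCatalog-class].
#' @return data.frame in the MAF-like interface (`patient`, `gene`,
#'   `effect`, `sift`, `polyphen`, `canonical`, `last_exon`).
#' @export
simulateVariants <- function(config, catalog) {
  simSeed(config, "variants")
  g <- catalog@genes
  npat <- config$n_patients
  pats <- patientIds(npat)
  rate <- config$point_rate_by_group[as.character(g$age_group)]
  # gene-major layout: cell (i, p) = gene i under patient p
  hit <- which(runif(nrow(g) * npat) < rep(rate, times = npat))
  lof_effects <- c("frameshift", "stop_gain", "splice_acceptor",
                   "splice_donor")
  nonsyn <- data.frame(
    patient = pats[(hit - 1L) %/% nrow(g) + 1L],
    gene = g$gene_id[(hit - 1L) %% nrow(g) + 1L],
    stringsAsFactors = FALSE)
  is_lof <- runif(nrow(nonsyn)) < config$lof_share
  nonsyn$effect <- ifelse(is_lof,
                          sample(lof_effects, nrow(nonsyn), replace = TRUE),
                          "missense")
  shit <- which(runif(nrow(g) * npat) < config$syn_rate)
  syn <- data.frame(
    patient = pats[(shit - 1L) %/% nrow(g) + 1L],
    gene = g$gene_id[(shit - 1L) %% nrow(g) + 1L],
    effect = rep("synonymous", length(shit)), stringsAsFactors = FALSE)
  v <- rbind(nonsyn, syn)
  v <- v[order(v$patient, v$gene, v$effect), , drop = FALSE]
  v$sift <- rep(TRUE, nrow(v))
  v$polyphen <- rep(TRUE, nrow(v))
  v$canonical <- rep(TRUE, nrow(v))
  v$last_exon <- rep(FALSE, nrow(v))
  rownames(v) <- NULL
  v
}

#' Simulate CNA segments as a focal/broad mixture
#'
#' Each patient receives `n_broad` broad events (uniform chromosome, span a
#' `broad_frac` fraction of its genes) and `n_focal` focal events whose
#' centre gene is drawn with age-group weights `focal_enrichment_by_group`
#' (span a `focal_frac` fraction). Directions are amplification with
#' probability `amp_prob`; magnitudes are uniform on `seg_mean_range`.
#' Segment coordinates fully cover the genes they span.
#'
#' @param config a [simulationConfig()].
#' @param catalog a [GeneCatalog-class] with coordinates.
#' @return data.frame of segments in the SEG interface.
#' @export
simulateSegments <- function(config, catalog) {
  simSeed(config, "segments")
  g <- catalog@genes
  g <- g[order(g$chromosome, g$chrom_index), ]
  by_chr <- split(g, g$chromosome)
  chroms <- names(by_chr)
  w_focal <- config$focal_enrichment_by_group[as.character(g$age_group)]
  hotspots <- if (config$n_hotspots > 0L)
    sample(nrow(g), min(config$n_hotspots, nrow(g)), prob = w_focal)
  else integer(0)
  segs <- list()
  mkseg <- function(pat, chr_genes, i0, i1, dir, mag) {
    data.frame(patient = pat, chromosome = chr_genes$chromosome[1L],
               start = chr_genes$start[i0] - 10L,
               end = chr_genes$end[i1] + 10L,
               num_probes = 10L + rpois(1L, 40),
               segment_mean = if (dir == "amplification") mag else -mag,
               stringsAsFactors = FALSE)
  }
  for (pat in patientIds(config$n_patients)) {
    for (b in seq_len(config$n_broad)) {
      cg <- by_chr[[sample(length(chroms), 1L)]]
      span <- max(1L, round(runif(1L, config$broad_frac[1L],
                                  config$broad_frac[2L]) * nrow(cg)))
      i0 <- sample(nrow(cg) - span + 1L, 1L)
      dir <- if (runif(1L) < config$amp_prob) "amplification" else "deletion"
      segs[[length(segs) + 1L]] <-
        mkseg(pat, cg, i0, i0 + span - 1L, dir,
              runif(1L, config$broad_mag_range[1L],
                    config$broad_mag_range[2L]))
    }
    for (f in seq_len(config$n_focal)) {
      centre <- if (length(hotspots) && runif(1L) < config$hotspot_prob)
        hotspots[sample.int(length(hotspots), 1L)]
      else sample(nrow(g), 1L, prob = w_focal)
      cg <- by_chr[[g$chromosome[centre]]]
      span <- max(1L, round(runif(1L, config$focal_frac[1L],
                                  config$focal_frac[2L]) * nrow(cg)))
      ci <- g$chrom_index[centre] + 1L
      i0 <- min(max(1L, ci - span %/% 2L), nrow(cg) - span + 1L)
      dir <- if (runif(1L) < config$amp_prob) "amplification" else "deletion"
      segs[[length(segs) + 1L]] <-
        mkseg(pat, cg, i0, i0 + span - 1L, dir,
              runif(1L, config$focal_mag_range[1L],
                    config$focal_mag_range[2L]))
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(patient = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      num_probes = integer(), segment_mean = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate paired tumor/normal expression with dosage and regulator effects
#'
#' Baseline log2 expression is gene-specific Gaussian. In tumor samples,
#' dosage-responsive genes (drawn per gene with the age-group probability
#' `dosage_responsiveness_by_group`) add their summed covering segment means
#' to the log2 level; point-mutated regulators shift a fixed
#' `regulator_effect_fraction` of their targets by `regulator_effect_size`
#' (random fixed sign per target). Matched normals carry baseline plus noise
#' only. Expression is returned on the positive scale `2^(log2 level)`.
#'
#' @param config a [simulationConfig()].
#' @param catalog a [GeneCatalog-class].
#' @param variants cohort variants ([simulateVariants()]).
#' @param segments cohort segments ([simulateSegments()]).
#' @param net optional [RegulatoryNetwork-class] for regulator knock-on
#'   effects (skipped when `NULL`).
#' @return list with `expression` (a SummarizedExperiment) and `truth`
#'   (responsive genes, per-regulator affected targets and signs).
#' @export
simulateExpression <- function(config, catalog, variants, segments,
                               net = NULL) {
  simSeed(config, "expression")
  g <- catalog@genes
  pats <- patientIds(config$n_patients)
  n <- nrow(g); npat <- length(pats)
  mu <- rnorm(n, config$expr_log_mean, config$expr_log_gene_sd)
  responsive <- runif(n) <
    config$dosage_responsiveness_by_group[as.character(g$age_group)]

  # summed covering segment means per (gene, patient), sign-based (no filter)
  dose <- matrix(0, n, npat, dimnames = list(g$gene_id, pats))
  raw <- callGeneCNA(segments, catalog, quantile_cut = 0, min_probes = 0L)
  if (nrow(raw)) {
    agg <- aggregate(value ~ patient + gene, raw, sum)
    dose[cbind(match(agg$gene, g$gene_id), match(agg$patient, pats))] <-
      agg$value
  }
  dose[!responsive, ] <- 0

  regfx <- matrix(0, n, npat, dimnames = list(g$gene_id, pats))
  truth_targets <- list()
  if (!is.null(net)) {
    nonsyn <- variants[variants$effect != "synonymous", , drop = FALSE]
    for (reg in intersect(regulators(net), unique(nonsyn$gene))) {
      tg <- targetsOf(net, reg)
      n_aff <- ceiling(config$regulator_effect_fraction * length(tg))
      if (n_aff == 0L) next
      aff <- sample(tg, n_aff)
      sgn <- sample(c(-1, 1), n_aff, replace = TRUE)
      mut_pats <- unique(nonsyn$patient[nonsyn$gene == reg])
      regfx[cbind(rep(match(aff, g$gene_id), length(mut_pats)),
                  rep(match(mut_pats, pats), each = n_aff))] <-
        rep(sgn * config$regulator_effect_size, length(mut_pats))
      truth_targets[[reg]] <- data.frame(target = aff, sign = sgn,
                                         stringsAsFactors = FALSE)
    }
  }

  noise_t <- matrix(rnorm(n * npat, 0, config$expr_noise_sd), n, npat)
  noise_n <- matrix(rnorm(n * npat, 0, config$expr_noise_sd), n, npat)
  tum <- 2^(mu + dose + regfx + noise_t)
  nor <- 2^(mu + noise_n)
  mat <- cbind(tum, nor)
  colnames(mat) <- c(paste0(pats, "-T"), paste0(pats, "-N"))
  rownames(mat) <- g$gene_id
  samples <- data.frame(
    sample = colnames(mat), patient = rep(pats, 2L),
    cohort = config$cohort_name,
    tissue = rep(c("tumor", "normal"), each = npat),
    stringsAsFactors = FALSE)
  list(expression = makeExpressionSet(mat, samples),
       truth = list(responsive = g$gene_id[responsive],
                    regulator_targets = truth_targets))
}

#' Simulate a complete tumor cohort
#'
#' Composition of [simulateVariants()], [simulateSegments()] and
#' [simulateExpression()].
#'
#' @inheritParams simulateExpression
#' @return list with `variants`, `segments`, `expression`, `truth`.
#' @export
simulateCohort <- function(config, catalog, net = NULL) {
  variants <- simulateVariants(config, catalog)
  segments <- simulateSegments(config, catalog)
  ex <- simulateExpression(config, catalog, variants, segments, net)
  list(variants = variants, segments = segments,
       expression = ex$expression, truth = ex$truth)
}

#' Simulate gene-level CNA calls with regulator/target mutual exclusivity
#'
#' Per patient, each regulator (with at least two targets) is copy-number
#' altered with probability `regulator_cna_prob`; each of its targets is
#' altered with probability `exclusivity_suppression["cna"]` when the
#' regulator is CNA and `exclusivity_suppression["cnn"]` when it is CNN.
#' Regulator and target calls are emitted as amplifications of unit
#' magnitude (the exclusivity analysis is direction-agnostic). When targets
#' are shared between regulators, a target is altered if any of its
#' regulators' conditional draws fire.
#'
#' @param config a [simulationConfig()].
#' @param net a [RegulatoryNetwork-class].
#' @return list with `calls` (gene-level CNA call data.frame) and
#'   `regulator_status` (data.frame `patient`, `regulator`, `status`).
#' @export
simulateExclusivityCalls <- function(config, net) {
  simSeed(config, "exclusivity")
  tsplit <- split(net@edges$target, net@edges$regulator)
  tsplit <- tsplit[lengths(tsplit) >= 2L]
  regs <- names(tsplit)
  pats <- patientIds(config$n_patients)
  sup <- config$exclusivity_suppression
  calls <- list(); status <- list()
  for (pat in pats) {
    reg_cna <- runif(length(regs)) < config$regulator_cna_prob
    altered <- regs[reg_cna]
    for (i in seq_along(regs)) {
      p_t <- if (reg_cna[i]) sup[["cna"]] else sup[["cnn"]]
      tg <- tsplit[[i]]
      altered <- c(altered, tg[runif(length(tg)) < p_t])
    }
    altered <- unique(altered)
    if (length(altered))
      calls[[pat]] <- data.frame(patient = pat, gene = altered,
                                 direction = "amplification", value = 1,
                                 stringsAsFactors = FALSE)
    status[[pat]] <- data.frame(patient = pat, regulator = regs,
                                status = ifelse(reg_cna, "CNA", "CNN"),
                                stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       regulator_status = do.call(rbind, c(status,
                                           list(make.row.names = FALSE))))
}

#' Simulate the cell-line dependency / mutation / IC50 bundle
#'
#' Dependency probabilities are beta-distributed around class-specific
#' baselines (`dependency_base_by_class`, concentration `dependency_conc`);
#' point-mutated or amplified lines shift by `dependency_shift` (clamped to
#' `[0, 1]`). IC50 values are `slope * dependency + N(0, sigma)` for coupled
#' (drug, gene) pairs and independent Gaussian noise otherwise.
#'
#' @param config a [simulationConfig()].
#' @param classes named character vector of regulator classes (gene ->
#'   class), e.g. from generated archetype labels or [degreeProfiles()].
#' @return list of class `DependencyBundle`: `dependency` (lines x genes
#'   matrix), `mutations` (`cell_line`, `gene`, `lesion`), `ic50` (lines x
#'   drugs matrix), `annotation` (`cell_line`, `tissue`), `classes`.
#' @export
simulateCellLines <- function(config, classes) {
  simSeed(config, "cell_lines")
  classes <- classes[!is.na(classes) & classes != "unclassified"]
  genes <- names(classes)
  if (length(genes) == 0L) stop("no classified regulators supplied")
  lines <- sprintf("CL%03d", seq_len(config$n_cell_lines))
  base <- config$dependency_base_by_class[as.character(classes)]
  conc <- config$dependency_conc
  dep <- matrix(rbeta(length(lines) * length(genes),
                      rep(base, each = length(lines)) * conc,
                      rep(1 - base, each = length(lines)) * conc),
                nrow = length(lines), ncol = length(genes),
                dimnames = list(lines, genes))

  u <- matrix(runif(length(lines) * length(genes)), length(lines))
  pm <- u < config$cellline_mutation_prob
  am <- !pm & u < config$cellline_mutation_prob + config$cellline_amp_prob
  mut_idx <- which(pm | am, arr.ind = TRUE)
  mutations <- data.frame(
    cell_line = lines[mut_idx[, 1L]], gene = genes[mut_idx[, 2L]],
    lesion = ifelse(pm[mut_idx], "point_mutated", "amplified"),
    stringsAsFactors = FALSE)
  dep[pm | am] <- pmin(1, pmax(0, dep[pm | am] + config$dependency_shift))

  drugs <- sprintf("drug_%02d", seq_len(config$n_drugs))
  ic50 <- matrix(rnorm(length(lines) * length(drugs), 3, config$ic50_noise_sd),
                 length(lines), length(drugs),
                 dimnames = list(lines, drugs))
  coupling <- config$ic50_coupling
  if (!is.null(coupling) && nrow(coupling)) {
    iface <- genes[classes == "UC_EM_i"]
    for (i in seq_len(nrow(coupling))) {
      gn <- coupling$gene[i]
      if (is.na(gn)) gn <- if (length(iface)) sort(iface)[1L] else genes[1L]
      dr <- coupling$drug[i]
      if (!gn %in% genes || !dr %in% drugs) next
      ic50[, dr] <- coupling$slope[i] * dep[, gn] +
        rnorm(length(lines), 0, coupling$sigma[i])
      attr(ic50, "coupled") <- rbind(attr(ic50, "coupled"),
                                     data.frame(drug = dr, gene = gn))
    }
  }
  structure(list(dependency = dep, mutations = mutations, ic50 = ic50,
                 annotation = data.frame(cell_line = lines, tissue = "solid",
                                         stringsAsFactors = FALSE),
                 classes = classes),
            class = "DependencyBundle")
}

#' Drop haematopoietic and lymphoid cell lines from a bundle
#'
#' @param bundle a `DependencyBundle`.
#' @param exclude tissue labels to drop.
#' @return the filtered bundle.
#' @export
excludeHaemLines <- function(bundle,
                             exclude = "haematopoietic_and_lymphoid") {
  keep <- bundle$annotation$cell_line[!bundle$annotation$tissue %in% exclude]
  bundle$dependency <- bundle$dependency[keep, , drop = FALSE]
  bundle$ic50 <- bundle$ic50[keep, , drop = FALSE]
  bundle$mutations <- bundle$mutations[bundle$mutations$cell_line %in% keep, ,
                                       drop = FALSE]
  bundle$annotation <- bundle$annotation[bundle$annotation$cell_line %in%
                                           keep, , drop = FALSE]
  bundle
}

#' Generate and write a complete synthetic study
#'
#' Runs every generator and writes the full fixture directory: catalog.tsv,
#' edges.tsv, variants.tsv, segments.seg, expr.tsv, samples.tsv,
#' dependency.csv, cellline_mutations.csv, ic50.csv,
#' cellline_annotation.csv and truth.json (generative labels and scalar
#' parameters). Outputs are byte-identical across runs with the same
#' configuration.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if missing); `NULL` skips writing.
#' @return (invisibly) list with all generated objects: `catalog`, `grn`,
#'   `cohort`, `bundle`.
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  catalog <- simulateCatalog(config)
  grn <- simulateGRN(config, catalog)
  cohort <- simulateCohort(config, catalog, grn$network)
  classes <- setNames(grn$labels$archetype, grn$labels$gene)
  bundle <- simulateCellLines(config, classes)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeGeneCatalog(catalog, p("catalog.tsv"))
    writeEdgeTable(grn$network, p("edges.tsv"))
    write.table(cohort$variants, p("variants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeSegments(cohort$segments, p("segments.seg"))
    writeExpressionSet(cohort$expression, p("expr.tsv"), p("samples.tsv"))
    write.csv(data.frame(cell_line = rownames(bundle$dependency),
                         bundle$dependency, check.names = FALSE),
              p("dependency.csv"), row.names = FALSE, quote = FALSE)
    write.csv(bundle$mutations, p("cellline_mutations.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(data.frame(cell_line = rownames(bundle$ic50), bundle$ic50,
                         check.names = FALSE),
              p("ic50.csv"), row.names = FALSE, quote = FALSE)
    write.csv(bundle$annotation, p("cellline_annotation.csv"),
              row.names = FALSE, quote = FALSE)
    scalars <- Filter(function(x) !is.matrix(x) && !is.data.frame(x),
                      unclass(config))
    write_json(list(labels = grn$labels,
                    responsive = cohort$truth$responsive,
                    config = scalars),
               p("truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(catalog = catalog, grn = grn, cohort = cohort,
                 bundle = bundle))
}
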