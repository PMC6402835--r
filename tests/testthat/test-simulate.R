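test_that("simulation config validates probabilities and weights", {
  expect_s3_class(simulationConfig(), "SimulationConfig")
  expect_error(simulationConfig(syn_rate = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(stratum_weights = rep(1, 5)), "16")
  expect_error(simulationConfig(stratum_weights = rep(0, 16)), "positive")
})

test_that("catalog generator respects weights, layout and degenerate sizes", {
  w <- rep(0, 16); w[5] <- 1
  cfg <- simulationConfig(seed = 2, n_genes = 200, stratum_weights = w)
  cat5 <- simulateCatalog(cfg)
  expect_true(all(phylostrata(cat5) == 5L))
  expect_true(all(ageGroups(cat5) == "EM"))
  expect_equal(nGenes(simulateCatalog(simulationConfig(n_genes = 0))), 0L)
  # chi-square goodness of fit of realized stratum proportions
  cfg2 <- simulationConfig(seed = 3, n_genes = 10000)
  cat2 <- simulateCatalog(cfg2)
  obs <- groupCounts(cat2)$phylostratum
  p <- cfg2$stratum_weights / sum(cfg2$stratum_weights)
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("GRN generator produces identifiable archetypes", {
  cfg <- simulationConfig(seed = 4)
  cat1 <- simulateCatalog(cfg)
  grn <- simulateGRN(cfg, cat1)
  net <- grn$network
  prof <- degreeProfiles(net, cat1)
  expect_equal(sum(prof$k_out), edgeCount(net))
  expect_equal(sum(prof$k_in), edgeCount(net))
  m <- merge(prof, grn$labels, by = "gene")
  big <- m[m$k_out.x >= 10, ]
  expect_gt(nrow(big), 5)
  expect_gte(mean(as.character(big$reg_class) == big$archetype), 0.95)
  # all-UC mixing yields all-UC targets
  cfg2 <- simulationConfig(seed = 4,
                           mixing_by_archetype = rbind(UC_t = c(1, 0, 0),
                                                       EM_t = c(1, 0, 0),
                                                       UC_EM_i = c(1, 0, 0)))
  grn2 <- simulateGRN(cfg2, cat1)
  tage <- ageGroups(cat1)[grn2$network@edges$target]
  expect_true(all(tage == "UC"))
})

test_that("cohort generator responds to its rate parameters", {
  cat0 <- simulateCatalog(simulationConfig(seed = 7, n_genes = 300))
  cfg0 <- simulationConfig(seed = 7, n_genes = 300, n_patients = 10,
                           point_rate_by_group = c(UC = 0, EM = 0, MM = 0),
                           syn_rate = 0, n_focal = 0L, n_broad = 0L)
  v0 <- simulateVariants(cfg0, cat0)
  expect_equal(nrow(v0), 0L)
  s0 <- simulateSegments(cfg0, cat0)
  expect_equal(nrow(s0), 0L)
  cfg1 <- simulationConfig(seed = 8, n_genes = 300, n_patients = 10)
  v1 <- simulateVariants(cfg1, cat0)
  expect_true(all(v1$effect %in% c("missense", "frameshift", "stop_gain",
                                   "splice_acceptor", "splice_donor",
                                   "synonymous")))
  # EM excess in realized non-synonymous rates
  nonsyn <- v1[v1$effect != "synonymous", ]
  grp <- as.character(ageGroups(cat0)[nonsyn$gene])
  n_by <- groupCounts(cat0)$age_group
  rate <- table(factor(grp, c("UC", "EM", "MM"))) / n_by
  expect_gt(rate[["EM"]], rate[["UC"]])
  expect_gt(rate[["EM"]], rate[["MM"]])
})

test_that("generated files round-trip and are byte-identical across runs", {
  cfg <- simulationConfig(seed = 10, n_genes = 200, n_patients = 6,
                          n_cell_lines = 10, n_drugs = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st1 <- simulateStudy(cfg, d1)
  simulateStudy(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  # readers reproduce the in-memory objects
  back <- loadGeneCatalog(file.path(d1, "catalog.tsv"))
  expect_equal(geneTable(back), geneTable(st1$catalog))
  segs <- readSegments(file.path(d1, "segments.seg"))
  expect_equal(segs$segment_mean, st1$cohort$segments$segment_mean)
  net <- buildGRN(readEdgeTable(file.path(d1, "edges.tsv")))
  expect_equal(edgeCount(net), edgeCount(st1$grn$network))
  se <- readExpressionSet(file.path(d1, "expr.tsv"),
                          file.path(d1, "samples.tsv"))
  expect_equal(dim(se), dim(st1$cohort$expression))
  v <- readVariants(file.path(d1, "variants.tsv"))
  expect_equal(v$gene, st1$cohort$variants$gene)
})

test_that("cell-line generator plants dependency shifts and IC50 couplings", {
  classes <- setNames(rep(c("UC_t", "EM_t", "UC_EM_i"), each = 10),
                      sprintf("r%02d", 1:30))
  cfg <- simulationConfig(seed = 12, n_cell_lines = 100,
                          dependency_base_by_class = c(UC_t = 0.97,
                                                       EM_t = 0.30,
                                                       UC_EM_i = 0.97,
                                                       MM_t = 0.30))
  b <- simulateCellLines(cfg, classes)
  expect_true(all(b$dependency >= 0 & b$dependency <= 1))
  flags <- dependencyFlags(b$dependency)
  or <- classDependencyOR(flags, classes)
  med <- tapply(or$odds_ratio, or$reg_class, median)
  expect_gt(med[["UC_t"]], 1)
  expect_gt(med[["UC_EM_i"]], 1)
  expect_lt(med[["EM_t"]], 1)
  # planted coupling is recovered by the correlation screen
  coupled <- attr(b$ic50, "coupled")
  expect_equal(nrow(coupled), 1L)
  res <- drugDependencyCorr(b$dependency, b$ic50,
                            genes = coupled$gene, drugs = coupled$drug)
  expect_lt(res$rho, -0.25)
  # mutation shift: delta = 0 gives no hits beyond chance
  cfg0 <- simulationConfig(seed = 13, n_cell_lines = 60,
                           dependency_shift = 0)
  b0 <- simulateCellLines(cfg0, classes)
  md0 <- mutationDependency(b0$dependency, b0$mutations)
  tested <- md0[md0$reason == "", ]
  expect_lt(mean(tested$hit), 0.12)
})

test_that("haematopoietic cell lines are excluded by annotation", {
  classes <- c(r1 = "UC_t", r2 = "EM_t")
  cfg <- simulationConfig(seed = 14, n_cell_lines = 8, n_drugs = 2)
  b <- simulateCellLines(cfg, classes)
  b$annotation$tissue[1:3] <- "haematopoietic_and_lymphoid"
  b2 <- excludeHaemLines(b)
  expect_equal(nrow(b2$dependency), 5L)
  expect_false(any(b2$mutations$cell_line %in%
                     b$annotation$cell_line[1:3]))
})
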