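test_that("variant classification follows the inclusion rules", {
  expect_equal(classifyVariant("frameshift"), "LoF")
  expect_equal(classifyVariant(c("stop_gain", "splice_acceptor",
                                 "splice_donor")), rep("LoF", 3))
  expect_equal(classifyVariant(c("missense", "inframe_indel")),
               rep("missense", 2))
  expect_equal(classifyVariant("synonymous"), "synonymous")
  expect_equal(classifyVariant("missense", deleterious_sift = FALSE),
               "excluded")
  expect_equal(classifyVariant("missense", damaging_polyphen = FALSE),
               "excluded")
  expect_equal(classifyVariant("frameshift", last_exon = TRUE), "excluded")
  expect_equal(classifyVariant("frameshift", canonical = FALSE), "excluded")
  expect_equal(classifyVariant("missense", gene = "TTN"), "excluded")
  expect_equal(classifyVariant("missense", gene = "MUC16"), "excluded")
  expect_equal(classifyVariant("missense", gene = "ORC1"), "missense")
  expect_warning(cls <- classifyVariant("weird_effect"), "unknown")
  expect_equal(cls, "excluded")
  # missing deleteriousness flags pass unless strict
  expect_equal(classifyVariant("missense"), "missense")
  expect_equal(classifyVariant("missense", strict = TRUE), "excluded")
})

test_that("gene CNA calls require full coverage, probes and magnitude", {
  cat4 <- miniCatalog(c(1, 5, 12, 6))  # starts 1,1001,2001,3001; len 100
  g <- geneTable(cat4)
  # partial coverage: segment ends inside the gene body
  seg_part <- data.frame(patient = "P1", chromosome = "chr1", start = 1L,
                         end = g$start[1] + 50L, num_probes = 30L,
                         segment_mean = 1.2)
  expect_equal(nrow(callGeneCNA(seg_part, cat4, quantile_cut = 0)), 0L)

  # two covering amplification segments: maximum mean wins
  segs <- rbind(segmentFor(cat4, "P1", "g001", 0.5),
                segmentFor(cat4, "P1", "g001", 1.1))
  call <- callGeneCNA(segs, cat4, quantile_cut = 0)
  expect_equal(nrow(call), 1L)
  expect_equal(call$value, 1.1)
  expect_equal(call$direction, "amplification")

  # deletions take the minimum (most negative) mean
  segs <- rbind(segmentFor(cat4, "P1", "g002", -0.4),
                segmentFor(cat4, "P1", "g002", -1.3))
  expect_equal(callGeneCNA(segs, cat4, quantile_cut = 0)$value, -1.3)

  # probe filter
  seg10 <- segmentFor(cat4, "P1", "g001", 2, num_probes = 9L)
  expect_equal(nrow(callGeneCNA(seg10, cat4, quantile_cut = 0)), 0L)

  # 20 amp calls with distinct magnitudes, 0.90 quantile keeps the top two
  segs <- do.call(rbind, lapply(1:20, function(i)
    segmentFor(cat4, sprintf("P%02d", i), "g001", i)))
  kept <- callGeneCNA(segs, cat4, quantile_cut = 0.90)
  expect_setequal(kept$value, c(19, 20))

  # quantile computed per direction: one extreme deletion must not mask amps
  segs2 <- rbind(segs, segmentFor(cat4, "P99", "g002", -100))
  kept2 <- callGeneCNA(segs2, cat4, quantile_cut = 0.90)
  expect_setequal(kept2$value[kept2$direction == "amplification"], c(19, 20))

  no_coords <- GeneCatalog("x", 1L, "chr1", chrom_index = 0L)
  expect_error(callGeneCNA(segs, no_coords), "coordinates")
})

test_that("point-mutation recurrence uses deduplicated patient counts", {
  v <- function(pat, gene, cls) data.frame(patient = pat, gene = gene,
                                           class = cls)
  tab <- rbind(v(c("a", "b", "c"), "G1", "missense"),
               v(c("a", "b", "c"), "G2", "missense"),
               v(c("d", "e", "f"), "G2", "synonymous"),
               v(rep("a", 5), "G3", "LoF"))
  res <- recurrentPointGenes(tab)
  expect_true(res$recurrent_point[res$gene == "G1"])
  expect_false(res$recurrent_point[res$gene == "G2"])  # 3 vs 3, not strict
  expect_false(res$recurrent_point[res$gene == "G3"])  # one patient only
  expect_equal(res$n_nonsyn_patients[res$gene == "G3"], 1L)
  expect_equal(nrow(recurrentPointGenes(tab[0, ])), 0L)
})

test_that("CNA recurrence thresholds directions independently", {
  mkcalls <- function(n_amp, n_del, gene = "G1") rbind(
    if (n_amp) data.frame(patient = paste0("a", seq_len(n_amp)), gene = gene,
                          direction = "amplification", value = 1),
    if (n_del) data.frame(patient = paste0("d", seq_len(n_del)), gene = gene,
                          direction = "deletion", value = -1))
  r <- recurrentCnaGenes(mkcalls(10, 0), 100)
  expect_true(r$recurrent_amp); expect_false(r$recurrent_del)
  expect_false(recurrentCnaGenes(mkcalls(9, 0), 100)$recurrent_amp)
  r2 <- recurrentCnaGenes(mkcalls(12, 3), 100)
  expect_true(r2$recurrent_amp); expect_false(r2$recurrent_del)
  expect_error(recurrentCnaGenes(mkcalls(1, 0), 0), "positive")
})

test_that("focality is strict and per patient-chromosome-direction", {
  cat100 <- miniCatalog(rep(1:4, 25))  # 100 genes, one chromosome
  genes <- geneIds(cat100)
  event <- function(pat, n) data.frame(patient = pat, gene = genes[seq_len(n)],
                                       direction = "amplification", value = 1)
  # 24 of 100 genes altered -> focal; 25 of 100 -> not (strict <)
  foc <- focalRecurrentCnaGenes(event("P1", 24), cat100, 10)
  expect_true(all(foc$n_focal_patients == 1L))
  broad <- focalRecurrentCnaGenes(event("P1", 25), cat100, 10)
  expect_equal(nrow(broad), 0L)
  # focal in 15% of a 20-patient cohort -> included
  calls <- do.call(rbind, lapply(1:3, function(i) event(paste0("P", i), 5)))
  foc <- focalRecurrentCnaGenes(calls, cat100, 20)
  expect_true(all(foc$focal_recurrent))
  expect_equal(unique(foc$freq), 0.15)
})

test_that("recurrence flags are order-invariant and threshold-monotone", {
  set.seed(31)
  v <- data.frame(
    patient = sample(paste0("P", 1:8), 120, replace = TRUE),
    gene = sample(paste0("G", 1:15), 120, replace = TRUE),
    class = sample(c("missense", "LoF", "synonymous"), 120, replace = TRUE))
  base <- recurrentPointGenes(v)
  shuf <- recurrentPointGenes(v[sample(nrow(v)), ])
  expect_equal(base, shuf)
  sets <- lapply(1:6, function(m) {
    r <- recurrentPointGenes(v, min_patients = m)
    r$gene[r$recurrent_point]
  })
  for (i in 2:6) expect_true(all(sets[[i]] %in% sets[[i - 1]]))

  calls <- data.frame(
    patient = sample(paste0("P", 1:10), 150, replace = TRUE),
    gene = sample(paste0("G", 1:12), 150, replace = TRUE),
    direction = sample(c("amplification", "deletion"), 150, replace = TRUE),
    value = 1)
  csets <- lapply(c(0.1, 0.2, 0.3, 0.5), function(f) {
    r <- recurrentCnaGenes(calls, 10, min_freq = f)
    r$gene[r$recurrent_amp]
  })
  for (i in 2:4) expect_true(all(csets[[i]] %in% csets[[i - 1]]))
})

test_that("recurrence rules match the exhaustive recount on micro-cohorts", {
  set.seed(77)
  for (i in 1:60) {
    npat <- sample(2:10, 1); ngene <- sample(3:20, 1)
    v <- data.frame(
      patient = sample(paste0("P", seq_len(npat)), 40, replace = TRUE),
      gene = sample(paste0("G", seq_len(ngene)), 40, replace = TRUE),
      class = sample(c("missense", "LoF", "synonymous"), 40, replace = TRUE))
    r <- recurrentPointGenes(v)
    expect_equal(sort(r$gene[r$recurrent_point]), recountPointRecurrent(v))
    calls <- data.frame(
      patient = sample(paste0("P", seq_len(npat)), 30, replace = TRUE),
      gene = sample(paste0("G", seq_len(ngene)), 30, replace = TRUE),
      direction = sample(c("amplification", "deletion"), 30, replace = TRUE),
      value = 1)
    rc <- recurrentCnaGenes(calls, npat)
    oracle <- recountCnaRecurrent(calls, npat)
    expect_equal(sort(rc$gene[rc$recurrent_amp]), oracle$amplification)
    expect_equal(sort(rc$gene[rc$recurrent_del]), oracle$deletion)
  }
})
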