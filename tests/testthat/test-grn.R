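test_that("network construction filters, dedupes and drops self-loops", {
  tab <- data.frame(
    source = c("A", "A", "B", "B", "C"),
    interaction_type = c("controls-expression-of", "controls-expression-of",
                         "in-complex-with", "controls-expression-of",
                         "controls-expression-of"),
    target = c("X", "X", "Y", "Y", "C"))
  expect_message(net <- buildGRN(tab), "self-loop")
  expect_equal(edgeCount(net), 2L)  # A->X deduped, B->Y kept, C->C dropped
  expect_equal(net@removed$duplicates, 1L)
  expect_equal(net@removed$self_loops, 1L)
  expect_setequal(regulators(net), c("A", "B"))
  expect_error(buildGRN(data.frame(a = 1)), "source")
})

test_that("degree profiles conserve edges and define dual-role ratios", {
  # star: hub -> 5 leaves; plus a dual-role gene D (4 out, 2 in)
  edges <- data.frame(
    source = c(rep("hub", 5), rep("D", 4), "L1", "L2"),
    target = c(paste0("L", 1:5), paste0("T", 1:4), "D", "D"))
  net <- buildGRN(edges, interaction_filter = NULL)
  prof <- degreeProfiles(net)
  expect_equal(prof$k_out[prof$gene == "hub"], 5L)
  expect_equal(prof$k_in[prof$gene == "L1"], 1L)
  expect_equal(prof$out_in_ratio_log2[prof$gene == "D"], 1)
  expect_true(is.na(prof$out_in_ratio_log2[prof$gene == "hub"]))
  expect_equal(sum(prof$k_out), edgeCount(net))
  expect_equal(sum(prof$k_in), edgeCount(net))
  # random graphs conserve degree
  set.seed(4)
  for (i in 1:10) {
    e <- unique(data.frame(source = sample(letters, 60, TRUE),
                           target = sample(LETTERS, 60, TRUE)))
    net <- buildGRN(e, interaction_filter = NULL)
    prof <- degreeProfiles(net)
    expect_equal(sum(prof$k_out), edgeCount(net))
    expect_equal(sum(prof$k_in), edgeCount(net))
  }
})

test_that("master regulator cut behaves at the boundary and by quartile", {
  prof <- data.frame(gene = paste0("R", 1:5), k_out = c(0L, 3L, 9L, 10L, 30L))
  expect_setequal(masterRegulators(prof), c("R4", "R5"))
  expect_false("R3" %in% masterRegulators(prof))
  # quartile rule over regulators (k_out >= 1)
  q <- quantile(c(3, 9, 10, 30), 0.75, names = FALSE)
  expect_setequal(masterRegulators(prof, min_out = NULL),
                  prof$gene[prof$k_out >= q])
})

test_that("regulator classification is total and follows the 2/3 and 1/10 rules", {
  expect_equal(as.character(classifyRegulator(0.70, 0.25, 0.05)), "UC_t")
  expect_equal(as.character(classifyRegulator(0.40, 0.55, 0.05)), "UC_EM_i")
  expect_equal(as.character(classifyRegulator(0.40, 0.40, 0.20)),
               "unclassified")
  expect_equal(as.character(classifyRegulator(0.05, 0.90, 0.05)), "EM_t")
  expect_equal(as.character(classifyRegulator(0.45, 0.45, 0.1)),
               "unclassified")  # MM at exactly 1/10 fails the strict rule
  expect_equal(as.character(classifyRegulator(2 / 3, 1 / 3, 0)),
               "UC_EM_i")      # 2/3 rule is strict
  expect_warning(cls <- classifyRegulator(NA, NA, NA), "unclassified")
  expect_equal(as.character(cls), "unclassified")
  # OR-variant of the interface rule
  expect_equal(as.character(classifyRegulator(0.05, 0.62, 0.33, rule = "or")),
               "unclassified")
  expect_equal(as.character(classifyRegulator(0.05, 0.90, 0.05, rule = "or")),
               "EM_t")
  # totality: every random composition receives exactly one class
  set.seed(8)
  p <- matrix(runif(300), ncol = 3)
  p <- p / rowSums(p)
  cls <- classifyRegulator(p[, 1], p[, 2], p[, 3])
  expect_false(anyNA(cls))
})

test_that("age enrichment Fisher test matches hypergeometric enumeration", {
  cat20 <- miniCatalog(c(rep(5, 10), rep(1, 10)))  # 10 EM then 10 UC
  genes <- geneIds(cat20)
  em <- geneTable(cat20)$gene_id[geneTable(cat20)$phylostratum == 5]
  # members: 8 EM + 2 UC of a 10-gene set
  members <- c(em[1:8], setdiff(genes, em)[1:2])
  res <- ageEnrichmentFisher(members, genes, cat20, "EM")
  expect_equal(res$odds_ratio, 16)  # (8*8)/(2*2)
  # exhaustive hypergeometric: P(X >= 8) drawing 10 of 10 EM among 20
  p_exact <- sum(dhyper(8:10, 10, 10, 10))
  expect_equal(res$p.value, p_exact, tolerance = 1e-12)
  # zero-cell correction keeps the odds ratio finite
  res0 <- ageEnrichmentFisher(em, genes, cat20, "EM")
  expect_true(is.finite(res0$odds_ratio))
  expect_error(ageEnrichmentFisher("a", character(), cat20, "EM"), "universe")
})

test_that("balanced membership table gives OR 1 and one-sided p 1", {
  cat20 <- miniCatalog(c(rep(5, 10), rep(1, 10)))
  tab <- geneTable(cat20)
  em <- tab$gene_id[tab$phylostratum == 5]
  uc <- tab$gene_id[tab$phylostratum == 1]
  members <- c(em[1:5], uc[1:5])
  res <- ageEnrichmentFisher(members, geneIds(cat20), cat20, "EM")
  expect_equal(res$odds_ratio, 1)
  expect_gt(res$p.value, 0.5)
})

test_that("PPI degree dedupes orientations and obeys the handshake lemma", {
  tri <- data.frame(source = c("a", "b", "c", "c"),
                    target = c("b", "c", "a", "a"))  # one duplicated edge
  deg <- ppiDegree(tri)
  expect_equal(unname(deg), c(2L, 2L, 2L))
  set.seed(6)
  e <- data.frame(source = sample(letters[1:12], 40, TRUE),
                  target = sample(letters[1:12], 40, TRUE))
  deg <- ppiDegree(e)
  lo <- pmin(e$source, e$target); hi <- pmax(e$source, e$target)
  n_edges <- length(unique(paste(lo, hi)[lo != hi]))
  expect_equal(sum(deg), 2L * n_edges)
})

test_that("out/in ratio summaries take medians over dual-role genes", {
  prof <- data.frame(gene = c("a", "b", "c", "d"),
                     out_in_ratio_log2 = c(0.5, NA, NA, NA))
  expect_equal(outInRatioSummary(prof, "a")$median, 0.5)
  prof2 <- data.frame(gene = c("a", "b", "c"),
                      out_in_ratio_log2 = c(-1, 0, 1))
  expect_equal(outInRatioSummary(prof2)$median, 0)
  expect_true(is.na(outInRatioSummary(prof, "b")$median))
  set.seed(3)
  r <- rnorm(21)
  prof3 <- data.frame(gene = paste0("g", 1:21), out_in_ratio_log2 = r)
  expect_equal(outInRatioSummary(prof3)$median, sort(r)[11])
})
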