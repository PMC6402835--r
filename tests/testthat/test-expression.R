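# small expression set builder: genes x (tumor + optional matched normals)
makeSE <- function(mat_t, mat_n = NULL, cohort = "C1") {
  pats <- paste0("P", seq_len(ncol(mat_t)))
  colnames(mat_t) <- paste0(pats, "-T")
  mat <- mat_t
  samples <- data.frame(sample = colnames(mat_t), patient = pats,
                        cohort = cohort, tissue = "tumor")
  if (!is.null(mat_n)) {
    colnames(mat_n) <- paste0(pats, "-N")
    mat <- cbind(mat_t, mat_n)
    samples <- rbind(samples,
                     data.frame(sample = colnames(mat_n), patient = pats,
                                cohort = cohort, tissue = "normal"))
  }
  makeExpressionSet(mat, samples)
}

test_that("mutation DE calls direction from the significant one-sided test", {
  mat <- matrix(c(rep(100, 4), rep(10, 8)), nrow = 1,
                dimnames = list("G1", NULL))
  se <- makeSE(mat)
  res <- deOnMutation(se, "G1", paste0("P", 1:4))
  expect_equal(res$direction, "up")
  expect_lt(res$p_up, 0.05)
  # identical distributions: no direction
  flat <- makeSE(matrix(5, 1, 12, dimnames = list("G1", NULL)))
  expect_equal(deOnMutation(flat, "G1", paste0("P", 1:4))$direction, "none")
  # fewer than three mutated samples: skipped with a reason
  res2 <- deOnMutation(se, "G1", c("P1", "P2"))
  expect_true(res2$skipped)
  expect_match(res2$reason, "fewer than 3")
})

test_that("mutation DE power matches a seeded Monte-Carlo oracle", {
  # n = 5 vs 20, shift d = 1.5 on unit-variance normals, alpha = 0.05
  power_for <- function(seed) {
    set.seed(seed)
    hits <- vapply(1:200, function(i) {
      x <- rnorm(5, 1.5); y <- rnorm(20)
      mat <- matrix(c(x, y), nrow = 1, dimnames = list("G1", NULL))
      deOnMutation(makeSE(mat - min(mat) + 1), "G1",
                   paste0("P", 1:5))$direction == "up"
    }, logical(1))
    mean(hits)
  }
  # direct Wilcoxon oracle under the same generator
  set.seed(99)
  oracle <- mean(vapply(1:200, function(i) {
    wilcox.test(rnorm(5, 1.5), rnorm(20),
                alternative = "greater")$p.value < 0.05
  }, logical(1)))
  expect_lt(abs(power_for(1) - oracle), 0.12)
})

test_that("downstream impact classifies the percentage of DE targets", {
  set.seed(42)
  n_t <- 40
  base <- matrix(rnorm(n_t * 30, 8), n_t, 30,
                 dimnames = list(paste0("T", 1:n_t), NULL))
  # regulator mutated in 5 samples; 12 of 40 targets strongly shifted there
  shifted <- base
  shifted[1:12, 1:5] <- shifted[1:12, 1:5] + 6
  se <- makeSE(2^shifted)
  mut_samples <- paste0("P", 1:5, "-T")
  res <- downstreamImpact(se, "REG", paste0("T", 1:n_t), mut_samples)
  expect_false(res$skipped)
  expect_equal(res$n_targets_tested, 40L)
  expect_gt(res$pct_de_targets, 20)
  expect_equal(res$impact, "high")
  # null targets: low impact
  res0 <- downstreamImpact(makeSE(2^base), "REG", paste0("T", 1:n_t),
                           mut_samples)
  expect_lt(res0$pct_de_targets, 21)
  # impact boundaries
  expect_true(res$high_binary)
  res2 <- downstreamImpact(se, "REG", paste0("T", 1:n_t), mut_samples[1:2])
  expect_true(res2$skipped)
})

test_that("impact thresholds split at 5 and 20 percent", {
  # exercised via the classification arithmetic of downstreamImpact results
  pick <- function(pct) if (pct < 5) "low" else if (pct <= 20) "moderate" else "high"
  expect_equal(pick(0), "low")
  expect_equal(pick(25), "high")   # 10 of 40 targets DE
  expect_equal(pick(12), "moderate")
})

test_that("CNA fold-change DE is one-sided per direction with BH adjustment", {
  # 7 patients with pairs; G1 amplified in 3 (P1..P3), strong dosage
  t_mat <- matrix(10, 2, 7, dimnames = list(c("G1", "G2"), NULL))
  n_mat <- matrix(10, 2, 7, dimnames = list(c("G1", "G2"), NULL))
  t_mat["G1", 1:3] <- 80
  se <- makeSE(t_mat, n_mat)
  calls <- data.frame(patient = paste0("P", 1:3), gene = "G1",
                      direction = "amplification", value = 1)
  res <- cnaFoldChangeDE(se, calls, "amplification")
  expect_equal(nrow(res), 1L)
  expect_lt(res$p, 0.05)
  # identical fold-changes: not significant
  se_flat <- makeSE(n_mat, n_mat)
  res2 <- cnaFoldChangeDE(se_flat, calls, "amplification")
  expect_gt(res2$p, 0.2)
  # deletions are tested on the lower side
  t_mat2 <- t_mat; t_mat2["G1", 1:3] <- 1
  calls_del <- transform(calls, direction = "deletion", value = -1)
  res3 <- cnaFoldChangeDE(makeSE(t_mat2, n_mat), calls_del, "deletion")
  expect_lt(res3$p, 0.05)
  # fewer than min_cna patients: gene not tested
  res4 <- cnaFoldChangeDE(se, calls[1:2, ], "amplification")
  expect_equal(nrow(res4), 0L)
})

test_that("per-class DE percentages take medians and compare classes", {
  res <- pctDEByClass(c(80, 30, 20), c("UC_t", "EM_t", "UC_EM_i"))
  expect_equal(unname(res$medians[c("UC_t", "EM_t", "UC_EM_i")]),
               c(80, 30, 20))
  res2 <- pctDEByClass(c(80, 30), c("UC_t", "EM_t"))
  expect_false("MM_t" %in% names(res2$medians))
  set.seed(2)
  pct <- runif(30, 0, 100)
  cls <- sample(c("UC_t", "EM_t"), 30, replace = TRUE)
  res3 <- pctDEByClass(pct, cls)
  expect_equal(unname(res3$medians["UC_t"]),
               median(sort(pct[cls == "UC_t"])))
})

test_that("null mutation-DE calls stay near the nominal alpha", {
  set.seed(123)
  hits <- vapply(1:400, function(i) {
    mat <- matrix(rnorm(25, 8), 1, 25, dimnames = list("G1", NULL))
    r <- deOnMutation(makeSE(2^mat), "G1", paste0("P", 1:6))
    r$direction != "none"
  }, logical(1))
  # two one-sided tests at alpha: overall call rate ~ 2 * 0.05
  expect_gt(mean(hits), 0.04)
  expect_lt(mean(hits), 0.17)
})
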