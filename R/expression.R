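#' Assemble an expression SummarizedExperiment
#'
#' Wraps a genes x samples matrix of non-negative, normalized expression
#' values with the sample annotations the pipeline needs: cohort label,
#' tissue class (`tumor`/`normal`) and patient id (matched normals share the
#' patient id of their tumor sample).
#'
#' @param mat numeric matrix, rows = genes, columns = samples.
#' @param samples data.frame with columns `sample`, `patient`, `cohort`,
#'   `tissue`; rows are matched to `colnames(mat)`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `expr`.
#' @export
makeExpressionSet <- function(mat, samples) {
  need <- c("sample", "patient", "cohort", "tissue")
  if (!all(need %in% names(samples)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  if (!all(colnames(mat) %in% samples$sample))
    stop("every matrix column needs a sample annotation row")
  if (any(mat < 0)) stop("expression values must be non-negative")
  samples <- samples[match(colnames(mat), samples$sample), , drop = FALSE]
  if (!all(samples$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  SummarizedExperiment(assays = list(expr = mat),
                       colData = S4Vectors::DataFrame(samples,
                                                      row.names = samples$sample))
}

#' Read an expression matrix and sample annotation TSV pair
#' @param expr_path TSV whose first column is the gene id, remaining columns
#'   samples.
#' @param samples_path TSV with columns `sample`, `patient`, `cohort`,
#'   `tissue`.
#' @return a SummarizedExperiment (see [makeExpressionSet()]).
#' @export
readExpressionSet <- function(expr_path, samples_path) {
  tab <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  makeExpressionSet(mat, read.delim(samples_path, stringsAsFactors = FALSE))
}

#' Write an expression SummarizedExperiment to the TSV pair
#' @param se SummarizedExperiment from [makeExpressionSet()].
#' @param expr_path,samples_path output paths.
#' @return invisible NULL.
#' @export
writeExpressionSet <- function(se, expr_path, samples_path) {
  mat <- assay(se, "expr")
  out <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(out, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(colData(se)), samples_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

tumorSamples <- function(se) colnames(se)[colData(se)$tissue == "tumor"]

#' Differential expression of a gene by its own mutation status
#'
#' Compares the tumor expression of `gene` in patients carrying a mutation
#' against patients where the gene is unmodified, using two one-sided
#' Wilcoxon rank-sum tests (over- and under-expression). The direction is the
#' significant side at `alpha`; genes mutated in fewer than `min_mutated`
#' tumor samples are skipped with the reason recorded.
#'
#' @param se expression SummarizedExperiment ([makeExpressionSet()]).
#' @param gene gene id (must be a row of the matrix).
#' @param mutated_patients patient ids carrying the mutation.
#' @param alpha significance level (default 0.05).
#' @param min_mutated minimum mutated tumor samples (default 3).
#' @return one-row data.frame: `gene`, `n_mut`, `n_wild`, `p_up`, `p_down`,
#'   `p`, `direction` (`up`/`down`/`none`), `skipped`, `reason`.
#' @export
deOnMutation <- function(se, gene, mutated_patients, alpha = 0.05,
                         min_mutated = 3L) {
  rec <- data.frame(gene = gene, n_mut = 0L, n_wild = 0L,
                    p_up = NA_real_, p_down = NA_real_, p = NA_real_,
                    direction = "none", skipped = TRUE, reason = "",
                    stringsAsFactors = FALSE)
  if (!gene %in% rownames(se)) {
    rec$reason <- "gene not in expression matrix"
    return(rec)
  }
  ts <- tumorSamples(se)
  pat <- colData(se)[ts, "patient"]
  x <- assay(se, "expr")[gene, ts]
  mut <- pat %in% mutated_patients
  rec$n_mut <- sum(mut); rec$n_wild <- sum(!mut)
  if (sum(mut) < min_mutated) {
    rec$reason <- sprintf("fewer than %d mutated samples", min_mutated)
    return(rec)
  }
  if (sum(!mut) == 0L) {
    rec$reason <- "no unmutated samples"
    return(rec)
  }
  rec$p_up <- suppressWarnings(
    wilcox.test(x[mut], x[!mut], alternative = "greater")$p.value)
  rec$p_down <- suppressWarnings(
    wilcox.test(x[mut], x[!mut], alternative = "less")$p.value)
  rec$p <- min(rec$p_up, rec$p_down)
  rec$skipped <- FALSE
  if (rec$p_up < alpha || rec$p_down < alpha)
    rec$direction <- if (rec$p_up <= rec$p_down) "up" else "down"
  rec
}

#' Downstream expression impact of point mutations in a regulator
#'
#' Pools tumor samples across cohorts and compares each target's expression
#' between samples where the regulator is point mutated and unmutated samples
#' (two-sided Wilcoxon at `alpha`). The comparison pool is restricted to
#' cohorts that contribute at least one mutated sample. The percentage of
#' differentially expressed targets is classified as low (<5), moderate
#' (5-20) or high (>20) impact; `binary_cut` additionally flags regulators
#' above a single percentage threshold (default 5, the coarse high/low
#' split).
#'
#' @param se pooled expression SummarizedExperiment.
#' @param regulator regulator gene id (bookkeeping only).
#' @param targets character vector of downstream target genes.
#' @param mutated_samples tumor sample ids where the regulator is mutated.
#' @param alpha significance level (default 0.05).
#' @param min_mutated minimum mutated samples pooled (default 3).
#' @param binary_cut percentage for the binary high/low flag (default 5).
#' @return one-row data.frame: `regulator`, `n_mutated_samples`,
#'   `n_targets_tested`, `n_de_targets`, `pct_de_targets`, `impact`
#'   (`low`/`moderate`/`high`), `high_binary`, `skipped`, `reason`.
#' @export
downstreamImpact <- function(se, regulator, targets, mutated_samples,
                             alpha = 0.05, min_mutated = 3L, binary_cut = 5) {
  rec <- data.frame(regulator = regulator, n_mutated_samples = 0L,
                    n_targets_tested = 0L, n_de_targets = 0L,
                    pct_de_targets = NA_real_, impact = NA_character_,
                    high_binary = NA, skipped = TRUE, reason = "",
                    stringsAsFactors = FALSE)
  ts <- tumorSamples(se)
  mutated_samples <- intersect(mutated_samples, ts)
  rec$n_mutated_samples <- length(mutated_samples)
  if (length(mutated_samples) < min_mutated) {
    rec$reason <- sprintf("fewer than %d mutated samples", min_mutated)
    return(rec)
  }
  cohorts <- unique(colData(se)[mutated_samples, "cohort"])
  pool <- ts[colData(se)[ts, "cohort"] %in% cohorts]
  wild <- setdiff(pool, mutated_samples)
  targets <- intersect(targets, rownames(se))
  if (length(targets) == 0L || length(wild) == 0L) {
    rec$reason <- "no targets with expression data"
    return(rec)
  }
  mat <- assay(se, "expr")
  de <- vapply(targets, function(tg) {
    p <- suppressWarnings(
      wilcox.test(mat[tg, mutated_samples], mat[tg, wild])$p.value)
    !is.na(p) && p < alpha
  }, logical(1))
  rec$n_targets_tested <- length(targets)
  rec$n_de_targets <- sum(de)
  rec$pct_de_targets <- 100 * mean(de)
  rec$impact <- if (rec$pct_de_targets < 5) "low"
                else if (rec$pct_de_targets <= 20) "moderate" else "high"
  rec$high_binary <- rec$pct_de_targets > binary_cut
  rec$skipped <- FALSE
  rec
}

#' Dosage effect of CNAs via paired tumor/normal fold-changes
#'
#' Per patient and gene, the fold-change is `log2((tumor + 1) / (normal + 1))`
#' over matched tumor/normal pairs. For each gene with at least `min_cna`
#' CNA patients in the requested direction, the fold-changes of CNA patients
#' are compared with those of copy-number-normal (CNN) patients by a
#' one-sided Wilcoxon test (amplification: greater; deletion: less), followed
#' by Benjamini-Hochberg correction across the genes tested.
#'
#' @param se expression SummarizedExperiment with matched normals.
#' @param calls gene-level CNA calls (see [callGeneCNA()]); CNN status for a
#'   gene means no call in either direction for that patient.
#' @param direction `"amplification"` or `"deletion"`.
#' @param alpha significance level (default 0.05).
#' @param min_cna minimum CNA patients with pairs (default 3).
#' @param genes optional restriction of the genes tested.
#' @return data.frame: `gene`, `direction`, `n_cna`, `n_cnn`, `p`, `p_adj`,
#'   `de` (adjusted p < alpha).
#' @export
cnaFoldChangeDE <- function(se, calls, direction = c("amplification",
                                                     "deletion"),
                            alpha = 0.05, min_cna = 3L, genes = NULL) {
  direction <- match.arg(direction)
  cd <- colData(se)
  tum <- colnames(se)[cd$tissue == "tumor"]
  nor <- colnames(se)[cd$tissue == "normal"]
  tp <- cd[tum, "patient"]; np <- cd[nor, "patient"]
  paired <- intersect(tp, np)
  tum <- tum[match(paired, tp)]
  nor <- nor[match(paired, np)]
  mat <- assay(se, "expr")
  fc <- log2((mat[, tum, drop = FALSE] + 1) / (mat[, nor, drop = FALSE] + 1))
  colnames(fc) <- paired

  dir_calls <- calls[calls$direction == direction, , drop = FALSE]
  cand <- if (is.null(genes)) unique(dir_calls$gene)
          else intersect(genes, dir_calls$gene)
  cand <- intersect(cand, rownames(fc))
  any_key <- paste(calls$patient, calls$gene, sep = "\r")
  res <- lapply(cand, function(gn) {
    cna_pat <- intersect(dir_calls$patient[dir_calls$gene == gn], paired)
    if (length(cna_pat) < min_cna) return(NULL)
    cnn_pat <- setdiff(paired, calls$patient[calls$gene == gn])
    if (length(cnn_pat) == 0L) return(NULL)
    p <- suppressWarnings(wilcox.test(
      fc[gn, cna_pat], fc[gn, cnn_pat],
      alternative = if (direction == "amplification") "greater" else "less"
    )$p.value)
    data.frame(gene = gn, direction = direction,
               n_cna = length(cna_pat), n_cnn = length(cnn_pat), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene = character(), direction = character(),
                      n_cna = integer(), n_cnn = integer(), p = numeric(),
                      p_adj = numeric(), de = logical(),
                      stringsAsFactors = FALSE))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$de <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Median percentage of differentially expressed CNA targets per class
#'
#' Given per-regulator percentages of differentially expressed CNA targets,
#' returns the class medians and pairwise two-sided Wilcoxon comparisons
#' between classes.
#'
#' @param pct numeric vector of per-regulator percentages (0-100).
#' @param class regulator class per entry (character or factor).
#' @return list with `medians` (named numeric, `NA` for empty classes) and
#'   `tests` (data.frame of pairwise comparisons, `NULL` when fewer than two
#'   classes have data).
#' @export
pctDEByClass <- function(pct, class) {
  class <- factor(as.character(class),
                  levels = intersect(REG_CLASSES, unique(as.character(class))))
  med <- tapply(pct, class, median)
  present <- names(med)[!is.na(med)]
  tests <- NULL
  if (length(present) >= 2L) {
    cmb <- utils::combn(present, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1L, i]; b <- cmb[2L, i]
      p <- suppressWarnings(
        wilcox.test(pct[class == a], pct[class == b])$p.value)
      data.frame(class_a = a, class_b = b, p = p, stringsAsFactors = FALSE)
    }))
  }
  list(medians = setNames(as.numeric(med), names(med)), tests = tests)
}
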