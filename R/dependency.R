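#' Threshold dependency probabilities into binary dependency flags
#'
#' A cell line is dependent on a gene when its probability of dependency
#' reaches `threshold` (default 0.95; the boundary value counts as dependent
#' unless `strict = TRUE`).
#'
#' @param dependency numeric matrix, rows = cell lines, columns = genes,
#'   values in `[0, 1]`.
#' @param threshold dependency probability cut (default 0.95).
#' @param strict when `TRUE`, require strictly greater than `threshold`.
#' @return logical matrix of the same shape.
#' @export
dependencyFlags <- function(dependency, threshold = 0.95, strict = FALSE) {
  if (any(dependency < 0 | dependency > 1, na.rm = TRUE))
    stop("dependency probabilities must lie in [0, 1]")
  if (strict) dependency > threshold else dependency >= threshold
}

#' Per-cell-line odds ratio of dependency by regulator class
#'
#' For each cell line and regulator class, the odds ratio of the 2x2 table
#' (regulator in class vs other classes) x (dependent vs not dependent) over
#' the universe of classified regulators. OR > 1 indicates enrichment of the
#' class among the regulators the cell line depends on. The Haldane-Anscombe
#' 0.5 correction is applied when any cell is zero.
#'
#' @param flags logical matrix from [dependencyFlags()] (cell lines x genes).
#' @param classes named character/factor of regulator classes (names = gene
#'   ids); genes with class `unclassified` or no class are excluded from the
#'   universe.
#' @return data.frame: `cell_line`, `reg_class`, `a`, `b`, `c`, `d` (table
#'   counts: in-class dependent / in-class not / out-class dependent /
#'   out-class not) and `odds_ratio`.
#' @export
classDependencyOR <- function(flags, classes) {
  classes <- classes[!is.na(classes) & classes != "unclassified"]
  genes <- intersect(colnames(flags), names(classes))
  if (length(genes) == 0L) stop("no classified regulators in flag matrix")
  flags <- flags[, genes, drop = FALSE]
  cls <- as.character(classes[genes])
  out <- list()
  for (cl in sort(unique(cls))) {
    inc <- cls == cl
    a <- rowSums(flags[, inc, drop = FALSE])
    b <- sum(inc) - a
    cc <- rowSums(flags[, !inc, drop = FALSE])
    d <- sum(!inc) - cc
    or <- numeric(length(a))
    zero <- a == 0 | b == 0 | cc == 0 | d == 0
    or[!zero] <- (a[!zero] * d[!zero]) / (b[!zero] * cc[!zero])
    or[zero] <- ((a[zero] + 0.5) * (d[zero] + 0.5)) /
      ((b[zero] + 0.5) * (cc[zero] + 0.5))
    out[[cl]] <- data.frame(cell_line = rownames(flags), reg_class = cl,
                            a = as.integer(a), b = as.integer(b),
                            c = as.integer(cc), d = as.integer(d),
                            odds_ratio = or, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mutation-conditioned shifts in cell-line dependency
#'
#' For each regulator and lesion type with at least `min_mutated` mutated
#' cell lines, compares dependency probabilities between mutated and
#' non-mutated lines. A regulator is a hit when the absolute difference in
#' median dependency is at least `min_diff` and the two-sided Wilcoxon
#' p-value is below `alpha`. Point mutations and amplifications are
#' evaluated independently.
#'
#' @param dependency numeric matrix, cell lines x genes.
#' @param mutations data.frame with columns `cell_line`, `gene`, `lesion`
#'   (`point_mutated` or `amplified`).
#' @param genes genes to screen (default: all mutated genes present in the
#'   dependency matrix).
#' @param min_mutated minimum mutated lines (default 3).
#' @param min_diff minimum absolute difference in median dependency
#'   (default 0.20).
#' @param alpha Wilcoxon significance level (default 0.05).
#' @return data.frame: `gene`, `lesion`, `n_mutated`, `n_wild`,
#'   `median_mutated`, `median_wild`, `diff`, `p`, `hit`, `direction`
#'   (`more_dependent`/`less_dependent`), plus skipped genes with a `reason`.
#' @export
mutationDependency <- function(dependency, mutations, genes = NULL,
                               min_mutated = 3L, min_diff = 0.20,
                               alpha = 0.05) {
  lines <- rownames(dependency)
  if (is.null(genes)) genes <- unique(mutations$gene)
  genes <- intersect(genes, colnames(dependency))
  out <- list()
  for (les in c("point_mutated", "amplified")) {
    msub <- mutations[mutations$lesion == les, , drop = FALSE]
    for (gn in intersect(genes, unique(msub$gene))) {
      mut_lines <- intersect(msub$cell_line[msub$gene == gn], lines)
      wild <- setdiff(lines, mut_lines)
      rec <- data.frame(gene = gn, lesion = les,
                        n_mutated = length(mut_lines), n_wild = length(wild),
                        median_mutated = NA_real_, median_wild = NA_real_,
                        diff = NA_real_, p = NA_real_, hit = FALSE,
                        direction = NA_character_, reason = "",
                        stringsAsFactors = FALSE)
      if (length(mut_lines) < min_mutated) {
        rec$reason <- sprintf("fewer than %d mutated cell lines", min_mutated)
      } else if (length(wild) == 0L) {
        rec$reason <- "no non-mutated cell lines"
      } else {
        dm <- dependency[mut_lines, gn]
        dw <- dependency[wild, gn]
        rec$median_mutated <- median(dm)
        rec$median_wild <- median(dw)
        rec$diff <- rec$median_mutated - rec$median_wild
        rec$p <- suppressWarnings(wilcox.test(dm, dw)$p.value)
        rec$hit <- abs(rec$diff) >= min_diff && !is.na(rec$p) && rec$p < alpha
        rec$direction <- if (rec$diff >= 0) "more_dependent" else "less_dependent"
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), lesion = character(),
                      n_mutated = integer(), n_wild = integer(),
                      median_mutated = numeric(), median_wild = numeric(),
                      diff = numeric(), p = numeric(), hit = logical(),
                      direction = character(), reason = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Dependency-IC50 correlation screen
#'
#' Spearman correlation between the dependency probabilities for each gene
#' and the IC50 of each drug over cell lines with both measurements.
#' Benjamini-Hochberg correction is applied across all tested (gene, drug)
#' pairs; a pair is a hit when rho falls below `rho_cut` and the adjusted p
#' is below `alpha` (high dependency coupled to drug sensitivity at low
#' concentration). Pairs with fewer than `min_pairs` complete observations
#' are skipped.
#'
#' @param dependency numeric matrix, cell lines x genes.
#' @param ic50 numeric matrix, cell lines x drugs (used as provided; Spearman
#'   is rank-based).
#' @param genes,drugs optional restrictions of the columns screened.
#' @param rho_cut correlation threshold (default -0.25).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param min_pairs minimum complete pairs (default 10).
#' @return data.frame sorted by adjusted p: `gene`, `drug`, `n`, `rho`, `p`,
#'   `p_adj`, `hit`.
#' @export
drugDependencyCorr <- function(dependency, ic50, genes = colnames(dependency),
                               drugs = colnames(ic50), rho_cut = -0.25,
                               alpha = 0.05, min_pairs = 10L) {
  lines <- intersect(rownames(dependency), rownames(ic50))
  out <- list()
  for (gn in genes) {
    dep <- dependency[lines, gn]
    for (dr in drugs) {
      y <- ic50[lines, dr]
      ok <- complete.cases(dep, y)
      if (sum(ok) < min_pairs) next
      ct <- suppressWarnings(cor.test(dep[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        gene = gn, drug = dr, n = sum(ok),
        rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(gene = character(), drug = character(), n = integer(),
                      rho = numeric(), p = numeric(), p_adj = numeric(),
                      hit = logical(), stringsAsFactors = FALSE))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$hit <- res$rho < rho_cut & res$p_adj < alpha
  res <- res[order(res$p_adj, res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
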