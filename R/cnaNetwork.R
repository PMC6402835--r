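#' Per-patient fraction of a regulator's targets carrying CNAs
#'
#' For every regulator with at least `min_targets` targets and every patient,
#' the fraction of the regulator's targets carrying any CNA call
#' (amplification or deletion) in that patient, together with the regulator's
#' own copy-number status (CNA when it carries any call, CNN otherwise).
#' Conditioning on CNN-regulator patients, when required, is applied by the
#' caller (see [cohortMedianFraction()]).
#'
#' @param net a [RegulatoryNetwork-class].
#' @param calls gene-level CNA calls (see [callGeneCNA()]).
#' @param patients patient ids defining the cohort (patients without calls
#'   contribute zero fractions).
#' @param min_targets minimum number of targets per regulator (default 2).
#' @param target_universe optional restriction of the targets counted in the
#'   denominator (e.g. genes with CNA data); targets outside it are excluded.
#' @return data.frame: `regulator`, `patient`, `regulator_status`
#'   (`CNA`/`CNN`), `n_targets`, `n_altered`, `fraction`.
#' @export
targetCnaFractions <- function(net, calls, patients, min_targets = 2L,
                               target_universe = NULL) {
  e <- net@edges
  if (!is.null(target_universe))
    e <- e[e$target %in% target_universe, , drop = FALSE]
  tsplit <- split(e$target, e$regulator)
  tsplit <- tsplit[lengths(tsplit) >= min_targets]
  regs <- names(tsplit)
  alt_by_pat <- split(calls$gene, calls$patient)
  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pat <- patients[i]
    altered <- unique(alt_by_pat[[pat]])
    n_alt <- vapply(tsplit, function(tg) sum(unique(tg) %in% altered),
                    integer(1))
    n_tot <- vapply(tsplit, function(tg) length(unique(tg)), integer(1))
    out[[i]] <- data.frame(
      regulator = regs, patient = pat,
      regulator_status = ifelse(regs %in% altered, "CNA", "CNN"),
      n_targets = n_tot, n_altered = n_alt, fraction = n_alt / n_tot,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regulator/target CNA mutual-exclusivity test
#'
#' For each regulator observed CNA in at least `min_each` patients and CNN in
#' at least `min_each` patients, compares the per-patient target-CNA
#' fractions between the two regulator states with a two-sided Wilcoxon test,
#' Benjamini-Hochberg corrected across all tested regulators (pooled over
#' cohorts). The direction is the sign of the median difference: `CNN_higher`
#' (targets more altered when the regulator is copy-number normal — the
#' mutual-exclusivity signature) or `CNA_higher`.
#'
#' @param fractions data.frame from [targetCnaFractions()].
#' @param min_each minimum patients per regulator state (default 3).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame: `regulator`, `n_patients_cnn`, `n_patients_cna`,
#'   `median_cnn`, `median_cna`, `diff` (CNA minus CNN), `p`, `p_adj`,
#'   `direction`, `significant`.
#' @export
exclusivityTest <- function(fractions, min_each = 3L, alpha = 0.05) {
  res <- lapply(split(fractions, fractions$regulator), function(fr) {
    cna <- fr$fraction[fr$regulator_status == "CNA"]
    cnn <- fr$fraction[fr$regulator_status == "CNN"]
    if (length(cna) < min_each || length(cnn) < min_each) return(NULL)
    p <- suppressWarnings(wilcox.test(cna, cnn)$p.value)
    mcna <- median(cna); mcnn <- median(cnn)
    data.frame(regulator = fr$regulator[1L],
               n_patients_cnn = length(cnn), n_patients_cna = length(cna),
               median_cnn = mcnn, median_cna = mcna, diff = mcna - mcnn,
               p = p,
               direction = if (mcnn > mcna) "CNN_higher"
                           else if (mcna > mcnn) "CNA_higher" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(regulator = character(), n_patients_cnn = integer(),
                      n_patients_cna = integer(), median_cnn = numeric(),
                      median_cna = numeric(), diff = numeric(), p = numeric(),
                      direction = character(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out[order(out$p_adj, out$regulator), , drop = FALSE]
}

#' Per-class summary of regulator/target CNA exclusivity
#'
#' Percentage of regulators per class whose targets are more often CNA when
#' the regulator is CNN (diff < 0), and the class median of the fraction
#' difference (CNA minus CNN), with pairwise one-sided Wilcoxon comparisons
#' of the per-regulator differences between classes.
#'
#' @param results data.frame from [exclusivityTest()].
#' @param classes named vector/factor of regulator classes (names = gene ids)
#'   or a [degreeProfiles()] data.frame.
#' @param significant_only when `TRUE`, percentages count only regulators
#'   with adjusted p < alpha in the CNN-higher direction.
#' @return data.frame per class: `reg_class`, `n_regulators`,
#'   `pct_cnn_higher`, `median_diff`.
#' @export
classExclusivitySummary <- function(results, classes,
                                    significant_only = FALSE) {
  if (is.data.frame(classes))
    classes <- setNames(as.character(classes$reg_class), classes$gene)
  cls <- as.character(classes[results$regulator])
  keep <- !is.na(cls)
  results <- results[keep, , drop = FALSE]
  cls <- cls[keep]
  hit <- results$direction == "CNN_higher"
  if (significant_only) hit <- hit & results$significant
  out <- do.call(rbind, lapply(split(seq_along(cls), cls), function(sel) {
    data.frame(reg_class = cls[sel[1L]], n_regulators = length(sel),
               pct_cnn_higher = 100 * mean(hit[sel]),
               median_diff = median(results$diff[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-regulator median target-CNA fraction under a regulator state
#'
#' @param fractions data.frame from [targetCnaFractions()].
#' @param condition regulator state to condition on (`"CNN"`, `"CNA"` or
#'   `NULL` for all patients).
#' @return named numeric vector of medians (names = regulators with at least
#'   one eligible patient).
#' @export
cohortMedianFraction <- function(fractions, condition = "CNN") {
  if (!is.null(condition))
    fractions <- fractions[fractions$regulator_status == condition, ,
                           drop = FALSE]
  med <- tapply(fractions$fraction, fractions$regulator, median)
  setNames(as.numeric(med), names(med))
}
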