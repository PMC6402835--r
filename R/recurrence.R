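#' Default blacklist of mutation-call false-positive gene families
#'
#' Gene families with high background mutation rates or frequent artefactual
#' calls (titin, mucins, ryanodine receptors, dyneins, PCLO, cub/sushi-domain
#' proteins, neurexins, contactins, PARK2 and olfactory receptors) are removed
#' before recurrence calling. The list ships as a plain-text file of regular
#' expressions matched against gene symbols, one per line, and can be replaced
#' by the user.
#'
#' @param path optional path to an alternative blacklist file.
#' @return character vector of regular expressions.
#' @export
defaultBlacklist <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_blacklist.txt", package = "phylogrn")
  pats <- readLines(path)
  pats[nzchar(pats) & !startsWith(pats, "#")]
}

VARIANT_EFFECTS <- c("synonymous", "missense", "inframe_indel", "frameshift",
                     "stop_gain", "splice_acceptor", "splice_donor", "other")

#' Classify point mutations as synonymous, missense, LoF or excluded
#'
#' Implements the variant-inclusion rules used throughout the recurrence
#' analysis: missense variants and in-frame indels count as missense;
#' frameshift, stop-gain and splice acceptor/donor variants count as
#' loss-of-function (LoF). Variants are excluded when non-canonical, located
#' in the last exon, in a blacklisted gene family, or (for missense) not
#' called both deleterious by SIFT and probably damaging by PolyPhen.
#' Synthetic inputs typically lack the deleteriousness flags; missing flags
#' pass unless `strict = TRUE`.
#'
#' @param effect character vector of effect labels (see
#'   `phylogrn:::VARIANT_EFFECTS`); unknown labels are excluded with a warning.
#' @param canonical,last_exon logical vectors (recycled).
#' @param deleterious_sift,damaging_polyphen logical vectors, `NA` when the
#'   annotation is unavailable.
#' @param gene optional gene symbols, matched against `blacklist`.
#' @param blacklist character vector of regular expressions; `NULL` disables
#'   blacklist filtering.
#' @param strict when `TRUE`, missense variants with missing deleteriousness
#'   flags are excluded rather than retained.
#' @return character vector with values `synonymous`, `missense`, `LoF`,
#'   `excluded`.
#' @examples
#' classifyVariant("frameshift")
#' classifyVariant("missense", deleterious_sift = FALSE)
#' @export
classifyVariant <- function(effect, canonical = TRUE, last_exon = FALSE,
                            deleterious_sift = NA, damaging_polyphen = NA,
                            gene = NULL, blacklist = defaultBlacklist(),
                            strict = FALSE) {
  n <- length(effect)
  canonical <- rep_len(as.logical(canonical), n)
  last_exon <- rep_len(as.logical(last_exon), n)
  sift <- rep_len(as.logical(deleterious_sift), n)
  poly <- rep_len(as.logical(damaging_polyphen), n)

  unknown <- !(effect %in% VARIANT_EFFECTS)
  if (any(unknown))
    warning("unknown effect value(s) excluded: ",
            paste(unique(effect[unknown]), collapse = ", "))

  cls <- rep("excluded", n)
  cls[effect == "synonymous"] <- "synonymous"
  cls[effect %in% c("missense", "inframe_indel")] <- "missense"
  cls[effect %in% c("frameshift", "stop_gain",
                    "splice_acceptor", "splice_donor")] <- "LoF"

  # missense deleteriousness: FALSE always fails; NA fails only in strict mode
  miss <- cls == "missense"
  failFlag <- function(f) if (strict) !isTRUEvec(f) else (!is.na(f) & !f)
  cls[miss & (failFlag(sift) | failFlag(poly))] <- "excluded"

  cls[!canonical | last_exon] <- "excluded"
  if (!is.null(gene) && length(blacklist)) {
    black <- Reduce(`|`, lapply(blacklist, grepl, x = gene))
    cls[black] <- "excluded"
  }
  cls
}

isTRUEvec <- function(x) !is.na(x) & x

#' Read a MAF-like variant table and classify its rows
#'
#' The TSV interface carries columns `patient`, `gene`, `effect` and
#' optionally `sift`, `polyphen`, `canonical`, `last_exon` (logical). A
#' `class` column is appended via [classifyVariant()].
#'
#' @param path path to the variant TSV.
#' @param ... passed to [classifyVariant()] (e.g. `strict`, `blacklist`).
#' @return data.frame of variants with a `class` column.
#' @export
readVariants <- function(path, ...) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  classifyVariantTable(v, ...)
}

#' @rdname readVariants
#' @param variants data.frame with at least `patient`, `gene`, `effect`.
#' @export
classifyVariantTable <- function(variants, ...) {
  need <- c("patient", "gene", "effect")
  if (!all(need %in% names(variants)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  grab <- function(col, default) {
    if (col %in% names(variants)) variants[[col]] else default
  }
  variants$class <- classifyVariant(
    variants$effect,
    canonical = grab("canonical", TRUE),
    last_exon = grab("last_exon", FALSE),
    deleterious_sift = grab("sift", NA),
    damaging_polyphen = grab("polyphen", NA),
    gene = variants$gene, ...
  )
  variants
}

#' Read copy-number segments in SEG format
#'
#' Accepts either the classic SEG header (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`) or the package's plain names
#' (`patient`, `chromosome`, `start`, `end`, `num_probes`, `segment_mean`).
#' Coordinates are 1-based inclusive.
#'
#' @param path path to a tab-separated segment file.
#' @return data.frame with the plain column names.
#' @export
readSegments <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  alias <- c(ID = "patient", chrom = "chromosome", loc.start = "start",
             loc.end = "end", num.mark = "num_probes", seg.mean = "segment_mean")
  hit <- names(s) %in% names(alias)
  names(s)[hit] <- alias[names(s)[hit]]
  need <- c("patient", "chromosome", "start", "end", "num_probes", "segment_mean")
  if (!all(need %in% names(s)))
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  s[need]
}

#' Write segments in SEG format
#' @param segments data.frame as returned by [readSegments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegments <- function(segments, path) {
  out <- data.frame(ID = segments$patient, chrom = segments$chromosome,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$num_probes,
                    seg.mean = segments$segment_mean)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call per-patient gene-level CNAs from segments
#'
#' A gene is called amplified (deleted) in a patient only when the gene is
#' covered entirely by a segment with positive (negative) segment mean, after
#' discarding segments supported by fewer than `min_probes` probes.
#' Amplifications take the maximum positive covering segment mean, deletions
#' the minimum negative. Within the cohort, calls whose absolute value falls
#' below the `quantile_cut` quantile of absolute values are dropped, per
#' direction (amplification and deletion magnitudes are not comparable, so the
#' cut is never pooled across directions). `quantile_cut = 0` keeps every
#' sign-based call.
#'
#' @param segments data.frame of segments (see [readSegments()]).
#' @param catalog a [GeneCatalog-class] with gene coordinates.
#' @param quantile_cut per-direction magnitude quantile below which calls are
#'   dropped (default 0.90, i.e. only the top decile of magnitudes is kept).
#' @param min_probes minimum probe support per segment (default 10).
#' @return data.frame with columns `patient`, `gene`, `direction`
#'   (`amplification`/`deletion`) and `value` (the assigned segment mean).
#' @export
callGeneCNA <- function(segments, catalog, quantile_cut = 0.90,
                        min_probes = 10L) {
  stopifnot(is(catalog, "GeneCatalog"))
  empty <- data.frame(patient = character(), gene = character(),
                      direction = character(), value = numeric(),
                      stringsAsFactors = FALSE)
  segments <- segments[segments$num_probes >= min_probes, , drop = FALSE]
  if (nrow(segments) == 0L) return(empty)
  genes_gr <- geneRanges(catalog)
  seg_gr <- GRanges(segments$chromosome, IRanges(segments$start, segments$end))
  ov <- findOverlaps(genes_gr, seg_gr, type = "within")
  if (length(ov) == 0L) return(empty)
  hit <- data.frame(
    gene = names(genes_gr)[queryHits(ov)],
    patient = segments$patient[subjectHits(ov)],
    value = segments$segment_mean[subjectHits(ov)],
    stringsAsFactors = FALSE
  )
  hit <- hit[hit$value != 0, , drop = FALSE]
  if (nrow(hit) == 0L) return(empty)

  pick <- function(h, fun, label) {
    if (nrow(h) == 0L) return(empty)
    key <- paste(h$patient, h$gene, sep = "\r")
    v <- tapply(h$value, key, fun)
    parts <- strsplit(names(v), "\r", fixed = TRUE)
    data.frame(patient = vapply(parts, `[`, "", 1L),
               gene = vapply(parts, `[`, "", 2L),
               direction = label, value = as.numeric(v),
               stringsAsFactors = FALSE)
  }
  calls <- rbind(pick(hit[hit$value > 0, ], max, "amplification"),
                 pick(hit[hit$value < 0, ], min, "deletion"))
  if (quantile_cut > 0) {
    keep <- logical(nrow(calls))
    for (dir in unique(calls$direction)) {
      sel <- calls$direction == dir
      thr <- quantile(abs(calls$value[sel]), quantile_cut, names = FALSE)
      keep[sel] <- abs(calls$value[sel]) >= thr
    }
    calls <- calls[keep, , drop = FALSE]
  }
  rownames(calls) <- NULL
  calls[order(calls$patient, calls$gene, calls$direction), , drop = FALSE]
}

#' Identify recurrently point-mutated genes in a cohort
#'
#' A gene is recurrently point mutated when at least `min_patients` distinct
#' patients in the cohort carry a missense or LoF mutation in it, and that
#' patient count strictly exceeds the number of distinct patients with a
#' synonymous mutation in the same gene (a per-gene background-rate control).
#' Counts are deduplicated at the patient level: many mutations in one patient
#' count once.
#'
#' @param variants classified variant data.frame (columns `patient`, `gene`,
#'   `class`; see [classifyVariantTable()]).
#' @param min_patients minimum distinct mutated patients (default 3).
#' @return data.frame with per-gene patient counts (`n_missense_patients`,
#'   `n_lof_patients`, `n_nonsyn_patients`, `n_syn_patients`) and a logical
#'   `recurrent_point` flag. The recurrent gene set is
#'   `gene[recurrent_point]`.
#' @export
recurrentPointGenes <- function(variants, min_patients = 3L) {
  out0 <- data.frame(gene = character(), n_missense_patients = integer(),
                     n_lof_patients = integer(), n_nonsyn_patients = integer(),
                     n_syn_patients = integer(), recurrent_point = logical(),
                     stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(out0)
  if (!"class" %in% names(variants))
    stop("variants must carry a 'class' column; see classifyVariantTable()")
  v <- variants[variants$class %in% c("missense", "LoF", "synonymous"), ,
                drop = FALSE]
  if (nrow(v) == 0L) return(out0)
  v <- unique(v[c("patient", "gene", "class")])
  genes <- sort(unique(v$gene))
  cnt <- function(sel) {
    # distinct patients per gene within selection
    u <- unique(v[sel, c("patient", "gene")])
    tab <- table(factor(u$gene, levels = genes))
    as.integer(tab)
  }
  n_mis <- cnt(v$class == "missense")
  n_lof <- cnt(v$class == "LoF")
  n_non <- cnt(v$class %in% c("missense", "LoF"))
  n_syn <- cnt(v$class == "synonymous")
  data.frame(gene = genes, n_missense_patients = n_mis,
             n_lof_patients = n_lof, n_nonsyn_patients = n_non,
             n_syn_patients = n_syn,
             recurrent_point = n_non >= min_patients & n_non > n_syn,
             stringsAsFactors = FALSE)
}

#' Identify recurrently copy-number-altered genes
#'
#' A gene is recurrently amplified (deleted) when it carries an amplification
#' (deletion) call in at least `min_freq` of the cohort. The two directions
#' are evaluated independently.
#'
#' @param calls gene-level CNA calls from [callGeneCNA()].
#' @param cohort_size number of patients in the cohort (> 0).
#' @param min_freq minimum patient fraction (default 0.10).
#' @return data.frame with per-gene patient counts, frequencies and
#'   `recurrent_amp` / `recurrent_del` flags.
#' @export
recurrentCnaGenes <- function(calls, cohort_size, min_freq = 0.10) {
  if (length(cohort_size) != 1L || is.na(cohort_size) || cohort_size <= 0)
    stop("cohort_size must be a positive scalar")
  genes <- sort(unique(calls$gene))
  cnt <- function(dir) {
    u <- unique(calls[calls$direction == dir, c("patient", "gene")])
    as.integer(table(factor(u$gene, levels = genes)))
  }
  n_amp <- cnt("amplification")
  n_del <- cnt("deletion")
  data.frame(gene = genes,
             n_amp_patients = n_amp, n_del_patients = n_del,
             amp_freq = n_amp / cohort_size, del_freq = n_del / cohort_size,
             recurrent_amp = n_amp / cohort_size >= min_freq,
             recurrent_del = n_del / cohort_size >= min_freq,
             stringsAsFactors = FALSE)
}

#' Identify focally and recurrently copy-number-altered genes
#'
#' A call is focal when, within its patient and chromosome, the genes altered
#' in the same direction make up strictly less than `max_chrom_fraction` of
#' the genes on that chromosome. A gene enters the focal-recurrent set for a
#' direction when focal calls occur in at least `min_freq` of the cohort.
#'
#' @inheritParams recurrentCnaGenes
#' @param catalog a [GeneCatalog-class] (chromosome gene totals).
#' @param max_chrom_fraction focality bound on the per-chromosome altered
#'   fraction (default 0.25, strict inequality).
#' @return data.frame with columns `gene`, `direction`, `n_focal_patients`,
#'   `freq`, `focal_recurrent`.
#' @export
focalRecurrentCnaGenes <- function(calls, catalog, cohort_size,
                                   max_chrom_fraction = 0.25,
                                   min_freq = 0.10) {
  if (nrow(calls) == 0L)
    return(data.frame(gene = character(), direction = character(),
                      n_focal_patients = integer(), freq = numeric(),
                      focal_recurrent = logical(), stringsAsFactors = FALSE))
  g <- catalog@genes
  chrom_n <- table(g$chromosome)
  calls$chromosome <- g$chromosome[match(calls$gene, g$gene_id)]
  key <- paste(calls$patient, calls$chromosome, calls$direction, sep = "\r")
  n_alt <- table(key)[key]  # genes altered in same patient/chrom/direction
  frac <- as.integer(n_alt) / as.integer(chrom_n[calls$chromosome])
  focal <- calls[frac < max_chrom_fraction, , drop = FALSE]
  if (nrow(focal) == 0L)
    return(data.frame(gene = character(), direction = character(),
                      n_focal_patients = integer(), freq = numeric(),
                      focal_recurrent = logical(), stringsAsFactors = FALSE))
  u <- unique(focal[c("patient", "gene", "direction")])
  tab <- as.data.frame(table(gene = u$gene, direction = u$direction),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(gene = tab$gene, direction = tab$direction,
                    n_focal_patients = as.integer(tab$Freq),
                    freq = tab$Freq / cohort_size,
                    stringsAsFactors = FALSE)
  out$focal_recurrent <- out$freq >= min_freq
  rownames(out) <- NULL
  out[order(out$gene, out$direction), , drop = FALSE]
}
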