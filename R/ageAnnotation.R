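#' GeneCatalog: per-gene phylostratum and chromosome layout
#'
#' The catalog is the gene universe for every fraction statistic in the
#' package. Each gene carries a phylostratum (1-16), the derived
#' macro-evolutionary age group (UC = phylostrata 1-3, EM = 4-9, MM = 10-16),
#' a chromosome label and a 0-based ordinal position along its chromosome.
#' Genomic start/end coordinates (1-based inclusive) are optional but required
#' for segment-level CNA calling.
#'
#' @slot genes data.frame with columns `gene_id`, `phylostratum`, `age_group`,
#'   `chromosome`, `chrom_index` and optionally `start`, `end`.
#' @slot metadata list of load bookkeeping (e.g. number of genes dropped for
#'   missing phylostratum).
#' @aliases GeneCatalog-class
#' @seealso [loadGeneCatalog()], [assignAgeGroup()], [groupCounts()]
#' @export
setClass("GeneCatalog",
  representation(genes = "data.frame", metadata = "list"),
  prototype(metadata = list())
)

setValidity("GeneCatalog", function(object) {
  g <- object@genes
  need <- c("gene_id", "phylostratum", "age_group", "chromosome", "chrom_index")
  if (!all(need %in% names(g)))
    return(paste("missing columns:", paste(setdiff(need, names(g)), collapse = ", ")))
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$gene_id)) return("gene_id values must be unique")
  if (any(g$phylostratum < 1L | g$phylostratum > 16L))
    return("phylostratum outside [1,16]")
  expected <- as.character(assignAgeGroup(g$phylostratum))
  if (!identical(as.character(g$age_group), expected))
    return("age_group inconsistent with phylostratum mapping")
  for (chr in unique(g$chromosome)) {
    idx <- sort(g$chrom_index[g$chromosome == chr])
    if (!identical(idx, seq(0L, length(idx) - 1L)))
      return(sprintf("chrom_index on chromosome %s is not contiguous 0..n-1", chr))
  }
  TRUE
})

#' Map phylostrata to macro-evolutionary age groups
#'
#' Deterministic grouping of the 16 phylostrata into the three age groups used
#' throughout the analysis: genes dating to unicellular ancestors
#' (phylostrata 1-3, UC), early metazoans (4-9, EM) and mammals (10-16, MM).
#'
#' @param phylostratum integer vector with values in `[1, 16]`.
#' @return factor with levels `UC`, `EM`, `MM`.
#' @examples
#' assignAgeGroup(c(2, 9, 12))
#' @export
assignAgeGroup <- function(phylostratum) {
  ps <- phylostratum
  if (length(ps) == 0L) return(factor(character(), levels = AGE_GROUPS))
  if (!is.numeric(ps) || anyNA(ps) || any(ps != as.integer(ps)))
    stop("phylostratum must be integer-valued with no missing entries")
  bad <- ps < 1 | ps > 16
  if (any(bad))
    stop("phylostratum out of range [1,16]: ",
         paste(unique(ps[bad]), collapse = ", "))
  factor(ifelse(ps <= 3, "UC", ifelse(ps <= 9, "EM", "MM")), levels = AGE_GROUPS)
}

#' Construct a gene catalog
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param phylostratum integer vector in `[1, 16]`, one per gene.
#' @param chromosome chromosome label per gene.
#' @param chrom_index optional 0-based ordinal position along the chromosome;
#'   derived from `start` order when omitted.
#' @param start,end optional 1-based inclusive genomic coordinates.
#' @param metadata optional list of bookkeeping values.
#' @return a [GeneCatalog-class] object.
#' @examples
#' GeneCatalog(c("g1", "g2"), c(1L, 5L), c("1", "1"), chrom_index = c(0L, 1L))
#' @export
GeneCatalog <- function(gene_id, phylostratum, chromosome,
                        chrom_index = NULL, start = NULL, end = NULL,
                        metadata = list()) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicated gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  phylostratum <- as.integer(phylostratum)
  chromosome <- as.character(chromosome)
  if (is.null(chrom_index)) {
    if (is.null(start))
      stop("supply either chrom_index or start coordinates")
    chrom_index <- rep(NA_integer_, length(gene_id))
    for (chr in unique(chromosome)) {
      sel <- which(chromosome == chr)
      chrom_index[sel[order(start[sel])]] <- seq_along(sel) - 1L
    }
  }
  genes <- data.frame(
    gene_id = gene_id,
    phylostratum = phylostratum,
    age_group = assignAgeGroup(phylostratum),
    chromosome = chromosome,
    chrom_index = as.integer(chrom_index),
    stringsAsFactors = FALSE
  )
  if (!is.null(start)) {
    genes$start <- as.integer(start)
    genes$end <- as.integer(end)
    if (any(genes$start > genes$end)) stop("gene start > end")
  }
  new("GeneCatalog", genes = genes, metadata = metadata)
}

#' Read a gene catalog from a TSV file
#'
#' Expected columns: `gene`, `phylostratum`, `chromosome` and optionally
#' `start`, `end` (1-based inclusive) or a precomputed `chrom_index`. Genes
#' with a missing phylostratum are dropped; the count is recorded in the
#' catalog metadata and reported.
#'
#' @param path path to a tab-separated catalog file.
#' @return a [GeneCatalog-class].
#' @seealso [writeGeneCatalog()] for the round-trip writer.
#' @export
loadGeneCatalog <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  makeGeneCatalog(tab)
}

#' @rdname loadGeneCatalog
#' @param table a data.frame with the same columns as the TSV interface.
#' @export
makeGeneCatalog <- function(table) {
  need <- c("gene", "phylostratum", "chromosome")
  if (!all(need %in% names(table)))
    stop("catalog table must have columns: ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) {
    warning("empty catalog table")
    return(GeneCatalog(character(), integer(), character(),
                       chrom_index = integer(),
                       metadata = list(n_dropped_no_age = 0L)))
  }
  if (anyDuplicated(table$gene))
    stop("duplicated gene identifiers in catalog: ",
         paste(unique(table$gene[duplicated(table$gene)]), collapse = ", "))
  ps <- table$phylostratum
  if (!is.numeric(ps)) stop("phylostratum column must be numeric")
  if (any(!is.na(ps) & ps != as.integer(ps)))
    stop("phylostratum column must be integer-valued")
  drop <- is.na(ps)
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    message(n_dropped, " gene(s) without phylostratum dropped from catalog")
    table <- table[!drop, , drop = FALSE]
  }
  GeneCatalog(
    gene_id = table$gene,
    phylostratum = table$phylostratum,
    chromosome = table$chromosome,
    chrom_index = if ("chrom_index" %in% names(table)) table$chrom_index,
    start = if ("start" %in% names(table)) table$start,
    end = if ("end" %in% names(table)) table$end,
    metadata = list(n_dropped_no_age = n_dropped)
  )
}

#' Write a gene catalog back to the TSV interface
#'
#' @param catalog a [GeneCatalog-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneCatalog <- function(catalog, path) {
  g <- catalog@genes
  out <- data.frame(gene = g$gene_id, phylostratum = g$phylostratum,
                    chromosome = g$chromosome, chrom_index = g$chrom_index,
                    stringsAsFactors = FALSE)
  if (!is.null(g$start)) {
    out$start <- g$start
    out$end <- g$end
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn GeneCatalog-class number of genes in the catalog
#' @param catalog a [GeneCatalog-class].
#' @export
nGenes <- function(catalog) nrow(catalog@genes)

#' @describeIn GeneCatalog-class gene identifiers
#' @export
geneIds <- function(catalog) catalog@genes$gene_id

#' @describeIn GeneCatalog-class named integer vector of phylostrata
#' @export
phylostrata <- function(catalog)
  setNames(catalog@genes$phylostratum, catalog@genes$gene_id)

#' @describeIn GeneCatalog-class named factor of age groups
#' @export
ageGroups <- function(catalog)
  setNames(catalog@genes$age_group, catalog@genes$gene_id)

#' @describeIn GeneCatalog-class genes as a data.frame
#' @param x a [GeneCatalog-class].
#' @export
geneTable <- function(x) x@genes

#' @describeIn GeneCatalog-class gene coordinates as a GRanges (requires
#'   start/end columns)
#' @export
geneRanges <- function(catalog) {
  g <- catalog@genes
  if (is.null(g$start))
    stop("catalog has no coordinates; supply start/end or use ",
         "pre-called gene-level CNA input")
  gr <- GRanges(g$chromosome, IRanges(g$start, g$end))
  names(gr) <- g$gene_id
  gr
}

setMethod("show", "GeneCatalog", function(object) {
  g <- object@genes
  cat("GeneCatalog with", nrow(g), "genes on",
      length(unique(g$chromosome)), "chromosome(s)\n")
  if (nrow(g) > 0L) {
    tab <- table(g$age_group)
    cat("  age groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat("  coordinates:", if (is.null(g$start)) "absent" else "present", "\n")
  }
})

#' Count genes per age group and per phylostratum
#'
#' @param catalog a [GeneCatalog-class].
#' @return list with elements `age_group` (length-3 named integer) and
#'   `phylostratum` (length-16 named integer); both sum to `nGenes(catalog)`.
#' @examples
#' cat3 <- GeneCatalog(c("a", "b", "c"), c(1L, 5L, 12L), rep("1", 3),
#'                     chrom_index = 0:2)
#' groupCounts(cat3)$age_group
#' @export
groupCounts <- function(catalog) {
  g <- catalog@genes
  grp <- table(factor(g$age_group, levels = AGE_GROUPS))
  ps <- table(factor(g$phylostratum, levels = 1:16))
  list(age_group = setNames(as.integer(grp), names(grp)),
       phylostratum = setNames(as.integer(ps), names(ps)))
}
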