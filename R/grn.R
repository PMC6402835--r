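#' RegulatoryNetwork: a directed gene regulatory network
#'
#' Deduplicated regulator -> target edges with self-loops removed. A node
#' with at least one outgoing edge is a regulator; a node with at least one
#' incoming edge is a target.
#'
#' @slot edges data.frame with character columns `regulator`, `target`.
#' @slot nodes character vector of all node identifiers.
#' @slot removed list recording how many self-loops and duplicate rows were
#'   dropped at construction.
#' @aliases RegulatoryNetwork-class
#' @seealso [buildGRN()], [degreeProfiles()]
#' @export
setClass("RegulatoryNetwork",
  representation(edges = "data.frame", nodes = "character", removed = "list"),
  prototype(removed = list(self_loops = 0L, duplicates = 0L))
)

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges
  if (!all(c("regulator", "target") %in% names(e)))
    return("edges must have columns regulator, target")
  if (nrow(e)) {
    if (any(e$regulator == e$target)) return("self-loops present")
    if (anyDuplicated(paste(e$regulator, e$target, sep = "\r")))
      return("duplicate edges present")
    if (!all(c(e$regulator, e$target) %in% object@nodes))
      return("edge endpoints missing from nodes")
  }
  TRUE
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "directed edges\n")
  cat("  regulators:", length(unique(object@edges$regulator)),
      " targets:", length(unique(object@edges$target)), "\n")
})

#' Build a directed regulatory network from an interaction table
#'
#' Retains rows whose interaction type matches `interaction_filter` (the
#' expression-control edges of pathway databases), collapses duplicate edges
#' and removes self-loops, logging both counts.
#'
#' @param edge_table data.frame with columns `source`, `interaction_type`,
#'   `target` (SIF column order). A table with only `source`/`target` (or
#'   `regulator`/`target`) is accepted and used as-is.
#' @param interaction_filter interaction type to keep (default
#'   `"controls-expression-of"`); `NULL` keeps all rows.
#' @return a [RegulatoryNetwork-class].
#' @export
buildGRN <- function(edge_table, interaction_filter = "controls-expression-of") {
  nm <- names(edge_table)
  if ("regulator" %in% nm && !"source" %in% nm)
    names(edge_table)[nm == "regulator"] <- "source"
  if (!all(c("source", "target") %in% names(edge_table)))
    stop("edge table must have columns source (or regulator) and target")
  if (!is.null(interaction_filter)) {
    if (!"interaction_type" %in% names(edge_table))
      stop("edge table must have an interaction_type column ",
           "(or pass interaction_filter = NULL)")
    edge_table <- edge_table[edge_table$interaction_type %in%
                               interaction_filter, , drop = FALSE]
  }
  e <- data.frame(regulator = as.character(edge_table$source),
                  target = as.character(edge_table$target),
                  stringsAsFactors = FALSE)
  dup <- duplicated(paste(e$regulator, e$target, sep = "\r"))
  loops <- e$regulator == e$target & !dup
  if (any(loops))
    message(sum(loops), " self-loop(s) removed from network")
  e <- e[!dup & !(e$regulator == e$target), , drop = FALSE]
  rownames(e) <- NULL
  new("RegulatoryNetwork", edges = e,
      nodes = sort(unique(c(e$regulator, e$target))),
      removed = list(self_loops = sum(loops), duplicates = sum(dup)))
}

#' @describeIn RegulatoryNetwork-class number of directed edges
#' @param net a [RegulatoryNetwork-class].
#' @export
edgeCount <- function(net) nrow(net@edges)

#' @describeIn RegulatoryNetwork-class genes with at least one outgoing edge
#' @export
regulators <- function(net) sort(unique(net@edges$regulator))

#' @describeIn RegulatoryNetwork-class targets of one regulator, or all
#'   target genes when `regulator` is `NULL`
#' @param regulator optional regulator id.
#' @export
targetsOf <- function(net, regulator = NULL) {
  if (is.null(regulator)) return(sort(unique(net@edges$target)))
  sort(net@edges$target[net@edges$regulator == regulator])
}

#' Read a SIF-style edge list (source, interaction_type, target)
#' @param path tab-separated file with a header.
#' @return data.frame.
#' @export
readEdgeTable <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write a network as a SIF-style TSV
#' @param net a [RegulatoryNetwork-class].
#' @param path output path.
#' @param interaction_type value written in the middle column.
#' @return `path`, invisibly.
#' @export
writeEdgeTable <- function(net, path,
                           interaction_type = "controls-expression-of") {
  out <- data.frame(source = net@edges$regulator,
                    interaction_type = interaction_type,
                    target = net@edges$target)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Degree and target-age profiles for every network node
#'
#' Computes out-degree and in-degree per node (so that both degree sums equal
#' the edge count), the log2 out/in ratio for dual-role genes (defined only
#' when both degrees are positive), and for regulators the age composition of
#' their age-annotated targets together with the regulator class from
#' [classifyRegulator()]. Targets absent from the catalog are excluded from
#' composition denominators.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param catalog a [GeneCatalog-class] (for target ages and regulator age
#'   annotation); may be omitted for pure degree profiles.
#' @param rule interface-rule variant passed to [classifyRegulator()].
#' @return data.frame with one row per node: `gene`, `k_out`, `k_in`,
#'   `out_in_ratio_log2`, `p_UC`, `p_EM`, `p_MM`, `n_aged_targets`,
#'   `reg_class`, `age_group`.
#' @export
degreeProfiles <- function(net, catalog = NULL, rule = c("and", "or")) {
  rule <- match.arg(rule)
  e <- net@edges
  nodes <- net@nodes
  gr <- graph_from_data_frame(e, directed = TRUE, vertices = nodes)
  k_out <- degree(gr, mode = "out")[nodes]
  k_in <- degree(gr, mode = "in")[nodes]
  prof <- data.frame(gene = nodes, k_out = as.integer(k_out),
                     k_in = as.integer(k_in), stringsAsFactors = FALSE)
  prof$out_in_ratio_log2 <- ifelse(prof$k_out > 0 & prof$k_in > 0,
                                   log2(prof$k_out / prof$k_in), NA_real_)
  prof$p_UC <- prof$p_EM <- prof$p_MM <- NA_real_
  prof$n_aged_targets <- 0L
  prof$reg_class <- NA_character_
  prof$age_group <- NA_character_
  if (!is.null(catalog)) {
    ages <- ageGroups(catalog)
    prof$age_group <- as.character(ages[prof$gene])
    tage <- ages[e$target]
    keep <- !is.na(tage)
    if (any(keep)) {
      comp <- unclass(table(factor(e$regulator[keep], levels = nodes),
                            factor(tage[keep], levels = AGE_GROUPS)))
      tot <- rowSums(comp)
      prof$n_aged_targets <- as.integer(tot)
      has <- tot > 0
      prof$p_UC[has] <- comp[has, "UC"] / tot[has]
      prof$p_EM[has] <- comp[has, "EM"] / tot[has]
      prof$p_MM[has] <- comp[has, "MM"] / tot[has]
    }
    is_reg <- prof$k_out > 0
    prof$reg_class[is_reg] <- as.character(
      classifyRegulator(prof$p_UC[is_reg], prof$p_EM[is_reg],
                        prof$p_MM[is_reg], rule = rule))
  }
  rownames(prof) <- NULL
  prof
}

#' Classify a regulator by the age composition of its targets
#'
#' A regulator is UC-t, EM-t or MM-t when more than 2/3 of its age-annotated
#' targets fall in the respective group (the 2/3 rules are mutually exclusive
#' by arithmetic). Otherwise it is a UC/EM interface (UC/EM-i) regulator when
#' at least 1/10 of targets are UC and at least 1/10 are EM while fewer than
#' 1/10 are MM; anything else is unclassified. `rule = "or"` relaxes the
#' interface condition to UC or EM reaching 1/10 (a sensitivity variant).
#' Regulators with no age-annotated targets are unclassified with a warning.
#'
#' @param p_uc,p_em,p_mm numeric vectors of target-age proportions (each
#'   regulator's proportions sum to 1 over its age-annotated targets).
#' @param rule `"and"` (default) or `"or"` interface rule.
#' @return factor with levels `UC_t`, `EM_t`, `MM_t`, `UC_EM_i`,
#'   `unclassified`.
#' @examples
#' classifyRegulator(0.70, 0.25, 0.05)
#' classifyRegulator(0.40, 0.55, 0.05)
#' @export
classifyRegulator <- function(p_uc, p_em, p_mm, rule = c("and", "or")) {
  rule <- match.arg(rule)
  n <- max(length(p_uc), length(p_em), length(p_mm))
  p_uc <- rep_len(p_uc, n); p_em <- rep_len(p_em, n); p_mm <- rep_len(p_mm, n)
  cls <- rep("unclassified", n)
  none <- is.na(p_uc) | is.na(p_em) | is.na(p_mm)
  if (any(none))
    warning(sum(none), " regulator(s) without age-annotated targets ",
            "left unclassified")
  two3 <- 2 / 3
  cls[!none & p_uc > two3] <- "UC_t"
  cls[!none & p_em > two3] <- "EM_t"
  cls[!none & p_mm > two3] <- "MM_t"
  open <- !none & cls == "unclassified"
  iface <- if (rule == "and") p_uc >= 0.1 & p_em >= 0.1 & p_mm < 0.1
           else (p_uc >= 0.1 | p_em >= 0.1) & p_mm < 0.1
  cls[open & iface] <- "UC_EM_i"
  factor(cls, levels = REG_CLASSES)
}

#' Master regulators by out-degree
#'
#' Regulators with at least `min_out` downstream targets. When `min_out` is
#' `NULL` the cut is the upper quartile (0.75 quantile) of out-degree over
#' regulators, which on the pathway-database network corresponds to
#' out-degree 10.
#'
#' @param profiles data.frame from [degreeProfiles()].
#' @param min_out out-degree threshold (default 10) or `NULL` for the upper
#'   quartile rule.
#' @return character vector of master-regulator gene ids.
#' @export
masterRegulators <- function(profiles, min_out = 10L) {
  k_out <- profiles$k_out
  if (is.null(min_out)) {
    reg <- k_out[k_out >= 1L]
    min_out <- quantile(reg, 0.75, names = FALSE)
  }
  sort(profiles$gene[k_out >= min_out])
}

#' One-sided Fisher enrichment of an age group within a gene set
#'
#' Tests whether `members` are enriched for genes of `group` relative to
#' `universe` via a one-sided Fisher exact test on the 2x2 membership-by-age
#' table. The reported odds ratio is the sample cross-product ratio, with the
#' Haldane-Anscombe 0.5 correction applied when any cell is zero.
#'
#' @param members gene set of interest (subset of `universe`).
#' @param universe background gene set.
#' @param catalog a [GeneCatalog-class] providing ages.
#' @param group one of `"UC"`, `"EM"`, `"MM"`.
#' @return list with `odds_ratio`, `p.value` and the 2x2 `table`.
#' @export
ageEnrichmentFisher <- function(members, universe, catalog, group) {
  group <- match.arg(group, AGE_GROUPS)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(members %in% universe)) stop("members must be a subset of universe")
  ages <- ageGroups(catalog)[universe]
  inset <- universe %in% members
  ingrp <- !is.na(ages) & ages == group
  tab <- matrix(c(sum(inset & ingrp), sum(inset & !ingrp),
                  sum(!inset & ingrp), sum(!inset & !ingrp)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("member", "nonmember"),
                                c(group, paste0("non", group))))
  p <- fisher.test(tab, alternative = "greater")$p.value
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = unname(or), p.value = p, table = tab)
}

#' Degree per gene in an undirected PPI network
#'
#' Deduplicates undirected edges (each unordered pair counted once, either
#' orientation), removes self-loops and returns the total degree per node.
#'
#' @param edge_table data.frame with columns `source`, `target` (an
#'   `interaction_type` column, if present, is ignored).
#' @return named integer vector of degrees.
#' @export
ppiDegree <- function(edge_table) {
  a <- as.character(edge_table$source)
  b <- as.character(edge_table$target)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r")) & lo != hi
  nodes <- sort(unique(c(a, b)))
  deg <- table(factor(c(lo[keep], hi[keep]), levels = nodes))
  setNames(as.integer(deg), nodes)
}

#' Median out/in-degree ratio over dual-role genes
#'
#' Summarizes the regulatory bias of a gene subset (e.g. the point-mutated EM
#' genes of one cohort): the median log2(out/in) ratio over genes that act as
#' both regulator and target, with the inter-quartile range.
#'
#' @param profiles data.frame from [degreeProfiles()].
#' @param genes gene subset; defaults to all profile genes.
#' @return list with `median`, `q25`, `q75` and `n_dual`; values are `NA`
#'   when the subset has no dual-role gene.
#' @export
outInRatioSummary <- function(profiles, genes = profiles$gene) {
  r <- profiles$out_in_ratio_log2[profiles$gene %in% genes]
  r <- r[!is.na(r)]
  if (length(r) == 0L)
    return(list(median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                n_dual = 0L))
  q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2L], q25 = q[1L], q75 = q[3L], n_dual = length(r))
}
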