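# Independent reference implementations used to cross-check the package.
# These deliberately use the most literal possible algorithms (double loops,
# exhaustive enumeration, per-gene recounts) and share no code with R/.

# JT statistic straight from its definition: sum over ordered group pairs of
# Mann-Whitney counts with ties counted one half.
jtBruteForce <- function(x, g) {
  if (is.numeric(g)) g <- match(g, sort(unique(g)))
  else g <- match(as.character(g), levels(droplevels(as.factor(g))))
  k <- max(g)
  J <- 0
  for (i in seq_len(k - 1)) {
    xi <- x[g == i]
    for (j in (i + 1):k) {
      xj <- x[g == j]
      for (a in xi) J <- J + sum(xj > a) + 0.5 * sum(xj == a)
    }
  }
  J
}

# Exact permutation p-value by enumerating every distinct ordering of the
# pooled multiset against the fixed group-label vector.
jtExhaustiveP <- function(x, g, alternative) {
  obs <- jtBruteForce(x, g)
  u <- sort(unique(x))
  counts <- as.integer(table(match(x, u)))
  n <- length(x)
  stats <- numeric(0)
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      stats[length(stats) + 1L] <<- jtBruteForce(prefix, g)
      return(invisible())
    }
    for (i in seq_along(u)) {
      if (counts[i] > 0L) {
        counts[i] <- counts[i] - 1L
        rec(c(prefix, u[i]), counts)
        counts[i] <- counts[i] + 1L
      }
    }
  }
  rec(numeric(0), counts)
  if (alternative == "increasing") mean(stats >= obs - 1e-9)
  else mean(stats <= obs + 1e-9)
}

# Literal per-gene recount of the point-mutation recurrence rule.
recountPointRecurrent <- function(variants, min_patients = 3L) {
  out <- character(0)
  for (gn in unique(variants$gene)) {
    vg <- variants[variants$gene == gn, ]
    non <- unique(vg$patient[vg$class %in% c("missense", "LoF")])
    syn <- unique(vg$patient[vg$class == "synonymous"])
    if (length(non) >= min_patients && length(non) > length(syn))
      out <- c(out, gn)
  }
  sort(out)
}

# Literal per-gene, per-direction recount of the CNA recurrence rule.
recountCnaRecurrent <- function(calls, cohort_size, min_freq = 0.10) {
  out <- list(amplification = character(0), deletion = character(0))
  for (dir in names(out)) {
    for (gn in unique(calls$gene)) {
      pats <- unique(calls$patient[calls$gene == gn & calls$direction == dir])
      if (length(pats) / cohort_size >= min_freq)
        out[[dir]] <- c(out[[dir]], gn)
    }
    out[[dir]] <- sort(out[[dir]])
  }
  out
}

# Small catalog on one or more chromosomes with explicit strata.
miniCatalog <- function(strata, n_chrom = 1L) {
  n <- length(strata)
  chrom <- rep_len(paste0("chr", seq_len(n_chrom)), n)
  idx <- integer(n)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    idx[sel] <- seq_along(sel) - 1L
  }
  start <- idx * 1000L + 1L
  GeneCatalog(sprintf("g%03d", seq_len(n)), strata, chrom,
              chrom_index = idx, start = start, end = start + 99L)
}

# One fully-covering segment per (patient, gene) from a mini catalog.
segmentFor <- function(catalog, patient, gene, mean, num_probes = 20L) {
  g <- geneTable(catalog)
  row <- g[g$gene_id == gene, ]
  data.frame(patient = patient, chromosome = row$chromosome,
             start = row$start - 5L, end = row$end + 5L,
             num_probes = num_probes, segment_mean = mean,
             stringsAsFactors = FALSE)
}
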