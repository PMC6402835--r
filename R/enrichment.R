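#' Per-phylostratum alteration counts
#'
#' Builds the count table underlying every enrichment fraction: for each
#' phylostratum i, the number of catalog genes N_i, the number with a
#' recurrent alteration, and (when the altered universe is supplied) the
#' number altered but not recurrently.
#'
#' @param catalog a [GeneCatalog-class]; its genes are the denominators.
#' @param recurrent character vector of recurrently altered genes.
#' @param altered optional character vector of all altered genes (for the
#'   non-recurrent fraction).
#' @return data.frame with columns `phylostratum`, `n_genes`, `n_recurrent`,
#'   `n_nonrecurrent`.
#' @export
phylostratumCounts <- function(catalog, recurrent, altered = NULL) {
  g <- catalog@genes
  lev <- 1:16
  ps <- factor(g$phylostratum, levels = lev)
  recurrent <- intersect(recurrent, g$gene_id)
  n_rec <- table(ps[g$gene_id %in% recurrent])
  out <- data.frame(phylostratum = lev,
                    n_genes = as.integer(table(ps)),
                    n_recurrent = as.integer(n_rec))
  if (!is.null(altered)) {
    nonrec <- setdiff(intersect(altered, g$gene_id), recurrent)
    out$n_nonrecurrent <- as.integer(table(ps[g$gene_id %in% nonrec]))
  } else {
    out$n_nonrecurrent <- NA_integer_
  }
  out
}

#' Fraction of genes recurrently altered per phylostratum
#'
#' `fraction_i = N_recurrent_i / N_i`. Strata with no genes are reported as
#' `NA` with a warning and are excluded from downstream ranking.
#'
#' @param counts data.frame from [phylostratumCounts()].
#' @return named numeric vector of fractions (names = phylostrata).
#' @export
stratumFractions <- function(counts) {
  f <- ifelse(counts$n_genes > 0, counts$n_recurrent / counts$n_genes, NA_real_)
  if (anyNA(f))
    warning("phylostratum with no genes reported as undefined: ",
            paste(counts$phylostratum[is.na(f)], collapse = ", "))
  setNames(f, counts$phylostratum)
}

#' Fraction of altered genes that are non-recurrent, per phylostratum
#'
#' `N_nonrecurrent_i / (N_nonrecurrent_i + N_recurrent_i)`; undefined (NA)
#' when no gene in the stratum is altered at all.
#'
#' @inheritParams stratumFractions
#' @return named numeric vector.
#' @export
nonrecurrentFractions <- function(counts) {
  den <- counts$n_nonrecurrent + counts$n_recurrent
  f <- ifelse(!is.na(den) & den > 0, counts$n_nonrecurrent / den,
              ifelse(!is.na(den) & den == 0, NA_real_, NA_real_))
  setNames(f, counts$phylostratum)
}

#' Rank phylostrata by alteration fraction
#'
#' Rank 1 is the most altered stratum, rank 16 the least; ties receive the
#' average of the tied rank positions. Undefined fractions stay `NA` and do
#' not consume a rank.
#'
#' @param fractions numeric vector of per-stratum fractions.
#' @return numeric vector of ranks, same length and names as `fractions`.
#' @examples
#' rankStrata(c(0.3, 0.3, 0.1))
#' @export
rankStrata <- function(fractions) {
  ok <- !is.na(fractions)
  if (sum(ok) < 2L) stop("need at least two defined fractions to rank")
  r <- rep(NA_real_, length(fractions))
  r[ok] <- rank(-fractions[ok], ties.method = "average")
  names(r) <- names(fractions)
  r
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests for a monotone trend in a response across ordered groups (here:
#' per-gene alteration indicators across phylostrata ordered by age). The
#' statistic is the sum over ordered group pairs (i < j) of pairwise
#' Mann-Whitney counts, ties counted 1/2:
#' `J = sum_{i<j} sum_{x in G_i, y in G_j} (I(y > x) + I(y == x)/2)`.
#'
#' With `method = "normal"` the p-value comes from the tie-corrected normal
#' approximation of the permutation null. With `method = "exact"` the
#' permutation distribution is used directly: exhaustively enumerated when the
#' number of distinct group assignments is at most `exact_limit`, otherwise
#' estimated from `nperm` random permutations drawn with the caller's RNG
#' state (set a seed for reproducibility). The exact option is intended for
#' total n up to about 200.
#'
#' @param x numeric response vector.
#' @param g group labels, ordered; numeric vectors are ordered numerically,
#'   factors by their level order. Empty groups are dropped.
#' @param alternative `"increasing"` (response rises with group order) or
#'   `"decreasing"`.
#' @param method `"normal"` or `"exact"`.
#' @param nperm number of random permutations when enumeration is infeasible.
#' @param exact_limit maximum number of distinct assignments to enumerate.
#' @return an object of class `htest` with the JT `statistic` and one-sided
#'   `p.value`.
#' @examples
#' jtTrendTest(c(1, 1, 0, 0), c(1, 1, 2, 2), alternative = "decreasing")
#' @export
jtTrendTest <- function(x, g, alternative = c("increasing", "decreasing"),
                        method = c("normal", "exact"), nperm = 10000L,
                        exact_limit = 200000) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(x) != length(g)) stop("x and g must have equal length")
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  if (is.numeric(g)) g <- factor(g, levels = sort(unique(g)))
  g <- droplevels(as.factor(g))
  if (nlevels(g) < 2L)
    stop("need at least two non-empty groups for a trend test")

  J <- jtStatistic(x, g)
  ni <- as.integer(table(g))
  N <- sum(ni)
  mu <- (N^2 - sum(ni^2)) / 4

  if (method == "normal") {
    tj <- as.integer(table(x))
    v1 <- N * (N - 1) * (2 * N + 5) -
      sum(ni * (ni - 1) * (2 * ni + 5)) -
      sum(tj * (tj - 1) * (2 * tj + 5))
    v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
    v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
    sigma2 <- v1 / 72 + v2 / (36 * N * (N - 1) * (N - 2)) +
      v3 / (8 * N * (N - 1))
    if (sigma2 <= 0) {
      p <- 1  # constant response: no evidence for any trend
    } else {
      z <- (J - mu) / sqrt(sigma2)
      p <- if (alternative == "increasing") pnorm(z, lower.tail = FALSE)
           else pnorm(z)
    }
    meth <- "Jonckheere-Terpstra test (tie-corrected normal approximation)"
  } else {
    perms <- jtPermutationDistribution(x, ni, exact_limit, nperm)
    p <- if (alternative == "increasing") mean(perms >= J - 1e-9)
         else mean(perms <= J + 1e-9)
    meth <- sprintf("Jonckheere-Terpstra test (%s permutation)",
                    if (attr(perms, "exhaustive")) "exhaustive" else "sampled")
  }
  structure(list(statistic = c(JT = J), p.value = p,
                 alternative = alternative, method = meth,
                 data.name = sprintf("%d observations in %d ordered groups",
                                     N, nlevels(g)),
                 parameter = c(n = N, groups = nlevels(g))),
            class = "htest")
}

# JT statistic via per-group value counts: O(k^2 * #distinct values)
jtStatistic <- function(x, g) {
  vals <- sort(unique(x))
  cnt <- unclass(table(g, factor(x, levels = vals)))
  k <- nrow(cnt)
  J <- 0
  for (i in seq_len(k - 1L)) {
    ci <- cnt[i, ]
    for (j in (i + 1L):k) {
      cj <- cnt[j, ]
      # for each value v in group i: count of group-j values strictly above v
      above <- rev(cumsum(rev(cj)))
      gt <- c(above[-1L], 0)
      J <- J + sum(ci * gt) + 0.5 * sum(ci * cj)
    }
  }
  J
}

# Permutation null of the JT statistic. Enumerate all distinct assignments of
# the pooled observations to groups of the given sizes when feasible.
jtPermutationDistribution <- function(x, ni, exact_limit, nperm) {
  n_assign <- exp(lgamma(sum(ni) + 1) - sum(lgamma(ni + 1)))
  lev <- paste0("g", seq_along(ni))
  if (n_assign <= exact_limit) {
    stats <- numeric(0)
    recurse <- function(pool_idx, sizes) {
      if (length(sizes) == 1L) return(list(list(pool_idx)))
      picks <- utils::combn(seq_along(pool_idx), sizes[1L], simplify = FALSE)
      out <- list()
      for (p in picks) {
        rest <- recurse(pool_idx[-p], sizes[-1L])
        for (r in rest) out[[length(out) + 1L]] <- c(list(pool_idx[p]), r)
      }
      out
    }
    assigns <- recurse(seq_along(x), ni)
    stats <- vapply(assigns, function(a) {
      gg <- integer(length(x))
      for (i in seq_along(a)) gg[a[[i]]] <- i
      jtStatistic(x, factor(lev[gg], levels = lev))
    }, numeric(1))
    structure(stats, exhaustive = TRUE)
  } else {
    glab <- factor(rep(lev, ni), levels = lev)
    stats <- vapply(seq_len(nperm), function(i) {
      jtStatistic(sample(x), glab)
    }, numeric(1))
    structure(stats, exhaustive = FALSE)
  }
}

#' Phylostratum enrichment of a recurrent gene set
#'
#' Convenience composition of [phylostratumCounts()], [stratumFractions()],
#' [rankStrata()] and [jtTrendTest()]: computes per-stratum fractions and
#' ranks for a recurrently altered gene set and tests for a monotone trend of
#' the per-gene alteration indicator across phylostrata (the JT observation
#' unit is the gene, so group sizes equal the stratum totals N_i).
#'
#' @param catalog a [GeneCatalog-class].
#' @param recurrent character vector of recurrently altered genes.
#' @param alternative trend direction passed to [jtTrendTest()]; the
#'   decreasing alternative asks whether older strata are more altered.
#' @param ... further arguments to [jtTrendTest()].
#' @return list with `counts`, `fraction` (named vector), `rank` (named
#'   vector) and `trend` (the `htest`).
#' @export
stratumEnrichment <- function(catalog, recurrent,
                              alternative = "decreasing", ...) {
  counts <- phylostratumCounts(catalog, recurrent)
  frac <- suppressWarnings(stratumFractions(counts))
  rk <- rankStrata(frac)
  g <- catalog@genes
  ind <- as.integer(g$gene_id %in% recurrent)
  trend <- jtTrendTest(ind, g$phylostratum, alternative = alternative, ...)
  list(counts = counts, fraction = frac, rank = rk, trend = trend)
}

#' Chromosomal context of CNAs by gene age
#'
#' For each patient, chromosome and direction, the fraction of the
#' chromosome's genes affected by CNA calls, together with the set of
#' phylostrata present among the altered genes. Per stratum, the mean altered
#' fraction is averaged over all records where the stratum is present; small
#' means indicate genes hit by focal events, large means by broad events. An
#' increasing trend of the per-record fractions across strata (older to
#' younger) indicates younger genes ride on broader events.
#'
#' @param calls gene-level CNA calls (see [callGeneCNA()]).
#' @param catalog a [GeneCatalog-class].
#' @return list with `records` (patient, chromosome, direction,
#'   fraction_altered), `presence` (long record/stratum pairs),
#'   `stratum_means` (per stratum and direction) and `trend` (per-direction
#'   [jtTrendTest()] results, increasing alternative).
#' @export
chromosomeCnaContext <- function(calls, catalog) {
  g <- catalog@genes
  chrom_n <- table(g$chromosome)
  calls$chromosome <- g$chromosome[match(calls$gene, g$gene_id)]
  calls$phylostratum <- g$phylostratum[match(calls$gene, g$gene_id)]
  key <- paste(calls$patient, calls$chromosome, calls$direction, sep = "\r")
  ukey <- !duplicated(key)
  n_alt <- as.integer(table(key)[key[ukey]])
  records <- data.frame(
    patient = calls$patient[ukey], chromosome = calls$chromosome[ukey],
    direction = calls$direction[ukey],
    fraction_altered = n_alt / as.integer(chrom_n[calls$chromosome[ukey]]),
    stringsAsFactors = FALSE)
  records$record_id <- seq_len(nrow(records))
  rec_of <- match(key, key[ukey])
  presence <- unique(data.frame(record_id = rec_of,
                                phylostratum = calls$phylostratum))
  presence <- presence[order(presence$record_id, presence$phylostratum), ]
  rownames(presence) <- NULL

  frac <- records$fraction_altered[presence$record_id]
  dirs <- records$direction[presence$record_id]
  means <- aggregate(frac,
                     by = list(phylostratum = presence$phylostratum,
                               direction = dirs),
                     FUN = mean)
  names(means)[3L] <- "mean_fraction"
  trend <- lapply(split(seq_along(frac), dirs), function(sel) {
    if (length(unique(presence$phylostratum[sel])) < 2L) return(NULL)
    jtTrendTest(frac[sel], presence$phylostratum[sel],
                alternative = "increasing")
  })
  list(records = records, presence = presence,
       stratum_means = means, trend = trend)
}

#' Genes under focal copy-number selection
#'
#' Per gene, the mean chromosomal-context fraction over the patients in which
#' it is altered; per chromosome, the genes in the most-focal quantile
#' (smallest mean fractions, boundary ties included) form the focal set.
#'
#' @param context result of [chromosomeCnaContext()].
#' @param calls the gene-level CNA calls used to build `context`.
#' @param catalog a [GeneCatalog-class].
#' @param quantile focal quantile (default 0.25).
#' @return character vector of focal genes, with the per-gene mean context
#'   fractions attached as attribute `"means"`.
#' @export
focalGeneSet <- function(context, calls, catalog, quantile = 0.25) {
  g <- catalog@genes
  calls$chromosome <- g$chromosome[match(calls$gene, g$gene_id)]
  rec <- context$records
  rkey <- paste(rec$patient, rec$chromosome, rec$direction, sep = "\r")
  ckey <- paste(calls$patient, calls$chromosome, calls$direction, sep = "\r")
  frac <- rec$fraction_altered[match(ckey, rkey)]
  mean_frac <- tapply(frac, calls$gene, mean)
  chrom <- g$chromosome[match(names(mean_frac), g$gene_id)]
  keep <- unlist(lapply(split(seq_along(mean_frac), chrom), function(sel) {
    cut <- quantile(mean_frac[sel], quantile, names = FALSE)
    sel[mean_frac[sel] <= cut]
  }), use.names = FALSE)
  out <- sort(names(mean_frac)[keep])
  attr(out, "means") <- mean_frac
  out
}
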