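---
title: "Evolutionary age-aware analysis of somatic mutations on regulatory networks"
author: "phylogrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary age-aware analysis of somatic mutations on regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogrn)
```

## The scientific question

Solid tumors of very different genetic backgrounds converge on common
hallmarks — uncontrolled proliferation, dedifferentiation, loss of cell–cell
cooperation — that read like a loss of multicellularity. phylogrn implements
an analysis framework that asks whether the somatic mutations accumulating in
tumors are structured by the *evolutionary age* of the genes they hit and by
those genes' position in the directed gene regulatory network (GRN).

Genes are dated by phylostratigraphy into 16 ordinal phylostrata, from genes
shared with all cellular life (phylostratum 1) to human-specific genes (16),
and grouped as unicellular (UC, strata 1–3), early metazoan (EM, 4–9) and
mammal-specific (MM, 10–16). The analyses then quantify, per tumor cohort:

1. which phylostrata are enriched for *recurrent* point mutations and
   copy-number aberrations (CNAs), with an ordered trend test across strata;
2. whether CNAs of old genes sit in focal (selected) or broad (passenger)
   chromosomal events;
3. how regulators of the GRN distribute over age groups, and how each
   regulator's *targets* distribute — yielding the regulator classes UC-t,
   EM-t, MM-t and the UC/EM interface class UC/EM-i;
4. the transcriptional consequences of mutations: differential expression of
   mutated genes, knock-on effects of point-mutated regulators on their
   targets, and CNA dosage effects via paired tumor/normal fold-changes;
5. mutual exclusivity between a regulator's own CNA status and CNAs of its
   targets; and
6. in cell lines, whether CRISPR dependency on a regulator class, mutations,
   and drug IC50s are associated.

Because the original inputs (tumor mutation archives, pathway databases,
dependency screens) require large downloads, the package ships a fully
seeded synthetic-study generator that reproduces the statistical *structure*
of each input, so every analysis runs, and is tested, end to end offline.

## Recurrence calling

**Point mutations.** Variants are classified as synonymous; missense
(missense, in-frame indels); or loss-of-function (frameshift, stop-gain,
splice acceptor/donor). Missense variants must be called deleterious by SIFT
*and* probably damaging by PolyPhen; non-canonical and last-exon variants and
a configurable blacklist of artefact-prone families (titin, mucins,
ryanodine receptors, dyneins, PCLO, CSMD, neurexins, contactins, PARK2,
olfactory receptors) are excluded. A gene is *recurrently point mutated* in a
cohort when ≥ 3 distinct patients carry missense/LoF mutations and that count
strictly exceeds the count of patients with synonymous mutations in the same
gene — a cheap per-gene background-rate control. Counts are always
deduplicated at the patient level.

**CNAs.** Segments with fewer than 10 probes are dropped. A gene is called
only when *entirely* covered by a segment; amplifications take the maximum
positive covering segment mean, deletions the minimum negative. Calls whose
magnitude falls below the 0.90 quantile of |segment mean| are discarded —
computed per cohort and per direction, because amplification and deletion
magnitudes are not on a comparable scale. A gene is *recurrently* amplified
(deleted) when called in ≥ 10% of patients; a call is *focal* when the genes
altered in the same direction on that patient's chromosome are < 25% of the
chromosome's genes (strict inequality at the boundary).

## Phylostratum enrichment and the trend test

For stratum $i$, the enrichment fraction is
$F_i = N_{\mathrm{recurrent},i} / N_i$ over the catalog universe (genes
without a phylostratum are excluded from all denominators). Strata are ranked
1 (most altered) to 16 (least), ties receiving average ranks; strata with no
genes are dropped with a warning rather than ranked last.

The ordered trend across strata is tested with a Jonckheere–Terpstra (JT)
statistic on per-gene binary alteration indicators grouped by stratum, so
group sizes equal the stratum totals and the test is one of monotone
proportions:

$$J=\sum_{i<j}\sum_{x\in G_i}\sum_{y\in G_j}
  \left[\mathbb{1}(y>x)+\tfrac12\,\mathbb{1}(y=x)\right].$$

The default p-value uses the tie-corrected normal approximation of the
permutation null (mean $(N^2-\sum n_i^2)/4$; the three-term tie-corrected
variance). An exact option enumerates the permutation distribution
exhaustively when the number of distinct group assignments is feasible, and
otherwise samples seeded permutations; it is intended for total $n \lesssim
200$. With binary data at $n\le 8$ the permutation CDF jumps in steps of
0.1–0.3, so the normal approximation is only trusted at moderate $n$; the
test suite verifies the statistic against a brute-force double loop, the
exact path against independent exhaustive enumeration, and the one-sided
rejection rate at the study layout (16 strata × 100 genes) against the
nominal 0.05.

For the chromosomal context, each (patient, chromosome, direction) record
carries the fraction of the chromosome's genes altered; a stratum's mean
context is averaged over records where it is present. Small means indicate
focal selection; the increasing trend of context with stratum order asks
whether young genes ride on broad events. The focal gene set takes, per
chromosome, the quartile of genes with the smallest mean context
(boundary ties included).

## Regulator classification

The GRN is a directed graph of expression-control edges (deduplicated;
self-loops removed, since a self-edge would corrupt out/in ratios). A
regulator is any node with out-degree ≥ 1; master regulators have out-degree
≥ 10, which corresponds to the upper quartile of regulator out-degree in the
pathway-database network (the quartile rule is used when no threshold is
given). Dual-role genes report $\log_2(k_{out}/k_{in})$.

A regulator's class depends only on the age mix of its age-annotated
targets: UC-t/EM-t/MM-t when one group exceeds 2/3, else UC/EM-i when UC and
EM each reach 1/10 while MM stays strictly below 1/10, else unclassified.
Where descriptions of the interface rule differ between an AND and an OR
reading of the 1/10 condition, the AND reading is the default (the OR
reading destabilises the boundary with the unclassified set) and the OR
variant is available as a configuration switch for sensitivity analysis.
MM-t regulators are labelled but typically excluded from comparative
analyses: they are a ~2% minority.

## Expression analyses

All location tests are Wilcoxon rank-sum tests, which makes the analyses
invariant to monotone normalisation of the expression matrix. Mutation DE
uses two one-sided tests (over/under) at α = 0.05 with ≥ 3 mutated tumor
samples. Downstream impact of a point-mutated regulator pools tumor samples
across cohorts (restricted to cohorts contributing at least one mutated
sample), tests each target two-sided, and classifies the percentage of DE
targets as low (< 5), moderate (5–20) or high (> 20) impact; a binary
high/low flag at 5% is also reported, and outputs state which cut was used.
CNA dosage uses per-patient fold-changes $\log_2((t+1)/(n+1))$ over matched
pairs — the pseudocount guards against zeros in count-like data —
one-sided per direction, Benjamini–Hochberg corrected within cohort and test
family; both raw and adjusted p-values are emitted.

## CNA mutual exclusivity on the network

For each regulator with ≥ 2 targets and each patient, the fraction of its
targets carrying any CNA call. Per-patient regulator status (CNA/CNN) uses
the same quantile-filtered gene-level calls; recurrence filtering is *not*
applied here because per-patient status, not cohort recurrence, drives the
question. Regulators CNA and CNN in ≥ 3 patients each are tested two-sided,
BH-corrected pooled across cohorts; direction CNN-higher (targets more
altered when the regulator is intact) is the mutual-exclusivity signature.

## Cell-line dependency and drugs

A cell line depends on a gene when its dependency probability is ≥ 0.95 (the
boundary counts; a strict-mode switch exists because descriptions differ on
the boundary). Per cell line, each class's enrichment among depended-on
regulators is an odds ratio over the classified-regulator universe, with the
Haldane–Anscombe 0.5 correction on zero cells. Mutation-conditioned shifts
require ≥ 3 mutated lines, an absolute median-dependency difference ≥ 0.20
and two-sided Wilcoxon p < 0.05, evaluated independently for point mutations
and amplifications. Dependency–IC50 association uses Spearman correlation
(IC50s enter as provided — ranks are transform-invariant), requires ≥ 10
complete pairs (rank p-values are unstable below that), and flags pairs with
ρ < −0.25 and BH-adjusted p < 0.05. Haematopoietic/lymphoid lines are
excluded by annotation.

## What the generator emulates

`simulationConfig()` fixes the study conditions; the defaults are chosen
once and are not tuned per analysis:

* **Catalog** — 1,600 genes over 8 chromosomes; stratum weights proportional
  to the human gene-age distribution (6,719 UC / 7,939 EM / 2,660 MM), 1 kb
  gene bodies every 10 kb.
* **Point mutations** — per-patient, per-gene rates 0.02/0.06/0.02 for
  UC/EM/MM (the early-metazoan excess), synonymous background 0.01, 30% of
  non-synonymous events LoF. All variants canonical with passing
  deleteriousness flags; missing flags in user data pass unless strict mode.
* **Segments** — per patient 2 broad events (40–90% of a chromosome,
  low-level magnitudes 0.1–0.4) and 6 focal events (2–15%, high-level
  magnitudes 0.5–2.0), matching the focal-high/broad-low amplitude
  distinction copy-number callers rely on. Focal centres fall on a set of 12
  recurrent hotspot genes with probability 0.6 (drawn once with age-group
  placement weights UC 2 / EM 3 / MM 0.5), producing the recurrently altered
  loci real cohorts show.
* **Network** — regulator probabilities 0.08/0.12/0.03 by age group (an
  EM-enriched regulator pool); out-degrees from a truncated power law with
  exponent 1.6 and cap 60, placing the upper quartile near out-degree 10.
  Each regulator draws an archetype (UC-t 0.30 / EM-t 0.35 / UC/EM-i 0.35)
  and its target-age counts are allocated from the archetype mixing weights
  by largest remainder rather than iid sampling — compositions are then
  identifiable, so archetype-recovery experiments measure the classifier,
  not multinomial noise; at out-degree < 10 rounding can still flip labels,
  which is the intended small-degree regime.
* **Expression** — gene baselines $\log_2$-normal (mean 8, SD 1.5; residual
  SD 0.5). A gene responds to copy-number dose with age-graded probability
  π = 0.6/0.4/0.1 (UC/EM/MM); responsive genes add their summed covering
  segment means on the log2 scale. Point-mutated regulators shift a fixed
  30% of their targets by 1.5 log2 units with fixed random signs. Matched
  normals carry baseline plus noise. The generator works on a positive
  continuous scale, not counts: every downstream test is rank-based, so the
  distributional family is immaterial, but count-specific phenomena
  (overdispersion, library-size effects, zeros) are *not* emulated and
  passing tests say nothing about normalisation pipelines.
* **Exclusivity** — a dedicated gene-level generator alters each regulator
  with probability 0.4 per patient and its targets with probability 0.40
  when the regulator is CNN versus 0.05 when CNA. This layer is gene-level
  by design: per-regulator conditioning cannot be expressed through
  spatially contiguous segments.
* **Cell lines** — dependency Beta-distributed around class baselines
  (UC-t 0.92, UC/EM-i 0.92, EM-t 0.35, MM-t 0.35; concentration 25),
  reproducing the qualitative contrast of high dependence on UC-t and
  interface regulators; mutated lines shift by +0.3; one drug's IC50 is
  linearly coupled to a chosen regulator's dependency, the rest are noise.

One master seed fans out to fixed per-component offsets, so any component
can be regenerated independently and full runs are byte-identical.

## Experiment designs and their rationale

* **Trend calibration** uses the uniform layout of 16 strata × 100 genes, a
  flat alteration probability of 0.2 and 1,000 replicates; the one-sided
  rejection rate at α = 0.05 must sit inside the 95% binomial CI.
* **EM-enrichment recovery** also uses the uniform-stratum catalog. This is
  deliberate: under the realistic stratum sizes (UC genes ≈ 2.5× MM genes) an
  EM-peaked rate hump yields $E[J]-\mu \propto (q_{EM}-q_{low})\,N_{EM}
  (N_{UC}-N_{MM}) > 0$, so a *decreasing* trend is unreachable regardless of
  effect size; with equal stratum sizes MM's seven strata outweigh UC's
  three and the hump produces the decreasing signal the analysis looks for.
* **Dosage-ordering recovery** gives every event the detectable magnitude
  range 0.5–1.5 and disables hotspot lumping, so the recovered %-DE ordering
  reflects the responsiveness parameters π rather than event-amplitude
  structure, and uses sign-based calls (quantile filter off) so per-gene
  amplified-patient counts support the ≥ 3-sample rule.
* **Problem sizes** — recovery experiments run 50 seeds at 800–1,600 genes ×
  40–50 patients, dependency screens 100 seeds at 50–100 cell lines; these
  sizes put Monte-Carlo error well below the decision margins while keeping
  a full test run in about a minute.

## Numerical choices and degenerate inputs

Quantiles are R's default type 7; magnitude cuts use ≥ at the threshold.
Constant-response trend tests (zero permutation variance) return p = 1.
Empty cohorts, empty classes, regulators without age-annotated targets,
genes with too few mutated samples, and correlation pairs below the
complete-pair minimum all return typed empty results or skip records with
reasons rather than errors. Wilcoxon and Spearman p-values use the tie-safe
normal approximations (`exact = FALSE` where ties are expected).

## Known limitations

The generator does not emulate real gene symbols, mutation spectra,
signature composition, GC/replication-timing covariates of mutation rate, or
TCGA cohort sizes; enrichment results on synthetic data validate the
*machinery*, not biological claims. Phylostratum assignments are consumed,
never computed. MutSig2CV/GISTIC probability models are out of scope: their
gene lists can be supplied as plain one-gene-per-line inputs wherever a
recurrent set is accepted. The exclusivity analysis reproduces the
fraction-comparison design; formal margin-preserving mutual-exclusivity
models are not implemented.
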