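---
title: "Dating duplications from Ks distributions, and profiling genome content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating duplications from Ks distributions, and profiling genome content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(synteks)
```

# What this package models

Large, repeat-rich plant genomes such as hop (*Humulus lupulus*) and hemp
(*Cannabis sativa*) carry the residue of repeated large-scale duplication:
pairs of paralogous genes laid down by whole-genome or segmental
duplication, and blocks of conserved gene order (syntenic blocks) within
and between genomes. Because synonymous substitutions accumulate at a
roughly constant rate, the synonymous divergence Ks of a gene pair is a
molecular clock: a histogram of Ks over many collinear ("anchor") gene
pairs shows peaks at the ages of duplication and speciation events, and a
peak at mean Ks converts to an absolute age through

$$T = \frac{K_s}{2\lambda},$$

with $\lambda$ the synonymous substitution rate per site per year. The
factor 2 counts both lineages since their split.

`synteks` implements that analysis end to end — Ks estimation, log-scale
mixture modelling with ICL model selection, peak interpretation and
rate-sensitivity dating — together with the genome-content analyses that
surround it in practice: syntenic-block detection and content statistics,
feature-class co-occurrence and term enrichment, merging of gene-model
sets from two annotation sources, assembly composition and k-mer
profiling, and a sex-association marker scan for nominating a sex
chromosome in a dioecious species. Every stage can be exercised on
synthetic data with known ground truth; the generators are first-class,
tested code.

# Ks estimation (NG86)

`ks_ng86()` implements the Nei–Gojobori (1986) counting method with the
Jukes–Cantor correction:

* **Sites.** For each codon, each position contributes the fraction of its
  single-base changes that are synonymous under the standard genetic code.
  Changes that would create a stop codon are excluded from the
  opportunity, and the per-position fraction is renormalised over the
  remaining changes, so each used codon contributes exactly 3 sites and
  `S + N = 3 * codons_used` holds identically.
* **Differences.** Codon pairs differing at 1–3 positions are scored by
  averaging synonymous/nonsynonymous step counts over all minimal
  mutational pathways that avoid stop codons; in the rare case that every
  pathway passes through a stop, all pathways are used and stop-passing
  steps count as nonsynonymous.
* **Correction.** Proportions are corrected with
  $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; $p \ge 3/4$ is reported as a
  `saturated` flag with `Ks = NA`, never as a fabricated number.

Published analyses of this kind typically use the yn00 estimator, which
weights by transition/transversion bias and codon frequencies; NG86 was
chosen because it is fully specifiable and oracle-checkable — the test
suite verifies the implementation against an independent
pathway-enumeration oracle on **all** 61 × 61 sense-codon pairs. On data
generated under NG86's own model (see below) the two estimators agree far
within the tolerances used here.

Raw estimates are filtered to $0.01 \le K_s \le 2.0$ (`filter_ks()`,
bounds inclusive): the lower bound excludes allelic variation between
haplotypes, the upper bound avoids the saturation regime.

# The log-Ks mixture model

`fit_ks_mixture()` fits finite Gaussian mixtures to $\ln K_s$ by EM with
component-specific variances. Working on the log scale makes the
right-skewed Ks peaks approximately Gaussian and stops the oldest peak
from swamping the youngest. Model selection maximises the integrated
complete-data likelihood,

$$\mathrm{ICL} = \mathrm{BIC} - 2E, \qquad
  E = -\sum_{ij} \hat z_{ij}\ln \hat z_{ij},$$

with $\mathrm{BIC} = 2\log L - (3K-1)\log n$. The entropy term penalises
strongly overlapping components, so ICL prefers the well-separated peaks
one wants to read as discrete duplication events (plain BIC is always
reported alongside). Numerical choices, all visible in the function
signature:

* convergence at relative log-likelihood change $< 10^{-8}$ or 1000
  iterations; the log-likelihood is asserted non-decreasing at every step;
* `n_restarts = 10` k-means++-style initialisations per component count,
  run through a short burn-in with the best start polished to full
  tolerance;
* a variance floor of $10^{-6}$ (log-scale), which also resolves the
  degenerate all-identical-values input as a forced single component;
* component means are reported back on the Ks scale as `exp(mu_log)`.
  The natural log is used throughout; since means are exponentiated back,
  the base would only matter for axis labels.

`select_primary_component()` reproduces the usual reading of such plots:
the modal peak of the $\ln K_s$ histogram (Freedman–Diaconis bin width,
reported) marks the primary duplication/speciation event, and the
component whose mean is nearest the mode is "the" peak; ties go to the
smaller mean. `divergence_time()` then applies $T = K_s/2\lambda$,
vectorised over $\lambda$ to produce rate-sensitivity tables, since
plausible plant rates span $1.23$–$15 \times 10^{-9}$ subs/site/year and
the choice dominates the headline date. `clock_lrt()` supplies the
likelihood-ratio test $-2(\ln L_s - \ln L_g)$ for strict vs relaxed
molecular clocks with an upper-tail $\chi^2$ p-value; a negative statistic
(possible only when the models were not truly nested as fitted) is
reported with a warning flag rather than clamped to zero.

# Synteny

`detect_blocks()` is a deliberately simplified MCScanX-style chainer:
within each scaffold pair, homology match points in gene-rank coordinates
are chained by dynamic programming, requiring strict monotonicity on both
axes (decreasing on one axis for inverted blocks) and rank gaps of at most
`max_gap = 25`; chains shorter than `min_anchors` are discarded and each
match point joins at most one block (greedy longest-first extraction).
The chain score is the anchor count — the downstream statistics consume
block membership, not alignment scores, so e-value-weighted scoring would
add a parameter with no consumer. Both field presets ship:
`min_anchors = 5` (a default MCScanX run) and `min_anchors = 10` (the
MATCH_SIZE-9 convention used for genome-wide visualisation); neither is
asserted as canonical. Optionally, runs of rank-consecutive genes of the
same family are collapsed to their first member before chaining, the
standard guard against tandem arrays inflating single-row "blocks". The
DP is verified against exhaustive chain enumeration on all small
instances, and gene ranks are used for chaining while base pairs are used
for spans (reported 1-based closed).

`block_stats()` summarises each block's anchor count, spans, inter-anchor
gaps, and the fraction of inter-anchor bases covered by repeat (LTR)
intervals — interval unions, so overlapping annotations are not double
counted. `scaffold_feature_counts()` tallies labelled (e.g. defense or
terpene) genes in blocks once per scaffold. The MCScanX `.collinearity`
dialect is parsed and written directly (`parse_collinearity()`,
`write_collinearity()`); a header whose anchor count disagrees with its
`N=` field is a hard parse error with a line number, because silently
repairing a truncated file would corrupt every downstream count.

# Enrichment and co-occurrence

`hypergeom_enrichment()` performs the standard one-sided hypergeometric
test per term with Benjamini–Hochberg q-values (`bh_fdr()`, FDR threshold
0.05 by default; depletion behind a flag). For two feature classes on $N$
syntenic blocks, `block_cooccurrence()` reports the observed number of
blocks carrying both against the block-level independence expectation
$n_A n_B / N$, an enrichment ratio, and a fixed-margins hypergeometric
tail probability. Block-level marginal rates are an assumption: published
expected counts of this kind could also have been derived from gene-level
rates, and the two differ when blocks vary in size. GO-graph propagation
is out of scope — term maps are taken as given.

# Gene-model merging and repeat filtering

`merge_gene_models()` gives priority to the expression-evidence
(primary) source: a secondary ab initio model is dropped when at least
1 bp of its exons overlaps a primary model's exons on the same scaffold
and strand. One base pair is the strictest reading of "overlapping exon
coordinates on the same strand"; the threshold is a visible argument for
users who want a looser rule. `classify_annotations()` partitions genes
by UniProt/Pfam support at a configurable similarity threshold (default
e-value ≤ 1e-5 — the original pipeline states no threshold, so this is a
declared assumption, not a reproduction). `filter_repeat_associated()`
removes genes whose *best* hit (lowest e-value, ties by identity then
subject id) matches a repeat keyword; the default keyword list lives in
`inst/extdata/repeat_keywords.txt`, not in code. Note that substring
matching with the conventional keyword set is aggressive — `"pol"`
matches any polymerase description — which is why the filter operates on
a user-editable configuration file.

# Assembly and k-mer profiling

`assembly_stats()` reports N50/N90 ("length at which the sorted
cumulative sum first reaches ≥50%/≥90% of the total"), GC over non-N
bases, and top-k cumulative fractions. `oligo_composition()` counts
overlapping words on the given strand only (no reverse-complement
folding, so strand-symmetric users can fold externally) and compares them
with a zero-order mononucleotide product model — the simplest defensible
null for observed/expected contrasts such as CG depletion and CHH
enrichment; windows containing N are skipped.

`kmer_profile()` is a simplified diploid profiler, not a GenomeScope-type
negative-binomial mixture fit. On a 3-bin smoothed histogram it finds the
error trough and coverage peaks, then applies three rules worth stating
explicitly:

* The homozygous peak is the **deepest** significant local maximum, not
  the highest-count one. At the heterozygosity this package's defaults
  emulate (~5% with k = 21), about two thirds of k-mer loci overlap a
  heterozygous site, so the half-coverage heterozygous peak carries the
  most k-mers; picking the highest-count maximum would halve the inferred
  coverage and double the genome size.
* At that heterozygosity the homozygous component may not be a local
  maximum at all, only a shoulder on the heterozygous peak's tail. A lone
  peak with more than 10% of the k-mer mass beyond 1.5× its depth is
  therefore read as the heterozygous peak, with homozygous coverage at
  twice its depth.
* Peak depths are de-quantized by three-point parabolic interpolation
  plus the half-bin Poisson mode-to-mean offset, and the dominant peak's
  apex anchors the 2:1 hom:het depth relation, because each peak's apex
  is dragged toward the other by the other's tail.

Genome size is then non-error k-mer mass divided by homozygous depth.
Heterozygosity inverts the heterozygous mass fraction exactly:
$h = 1 - (1-m)^{1/k}$, where $m$ is the share of non-error mass on the
heterozygous side of the midpoint between the peaks. The common
first-order form $m/k$ is badly biased exactly where these defaults
operate ($kh \approx 1$), which is why the exact inversion is used; the
same inversion gives the read-error rate from the error-region mass. A
histogram with no coverage peak above the trough is an explicit error —
the profiler refuses to fabricate a size.

# The mapping-population scan

`sex_association_scan()` tests each marker's genotype-class × sex table
with Pearson's chi-squared (no continuity correction), excluding missing
calls and dropping unobserved classes with the degrees of freedom
adjusted; single-class markers are flagged uninformative with p = 1.
Significance defaults to raw p < 0.05 — matching how such tracks are
conventionally drawn — with a BH-adjusted mode available.
`putative_sex_chromosome()` nominates the scaffold with the most
significant markers, reports ties as ambiguous, and returns an explicit
no-call for zero significant markers. The underlying published marker
pipeline is described only in supporting material not reproduced here, so
the test choice is a declared stand-in, validated on synthetic
populations. `segregation_qc()` supplies the 1:1 / 1:2:1 goodness-of-fit
distortion flags used in map construction, as QC only —
genetic-map estimation itself (JoinMap-style) is out of scope.
`map_summary()` defines the mean inter-marker gap as total length over
(markers − groups), the only denominator under which every counted gap is
well-defined; published maps sometimes print a larger mean gap (e.g.
1269.5 cM over 4090 markers in 10 groups is 0.311 cM/gap by this
definition, versus a printed 0.35), so the definition travels with the
output in a `notes` field.

# What the generators emulate — and what they don't

Every module runs end to end on output of the `simulate_*` family; a
single seed fans out to fixed-offset child streams so each generator is
independently reproducible, and all generators are bit-reproducible.

* **`simulate_divergent_pairs()`** draws $\ln K_s$ from a mixture whose
  defaults are the three peaks a hop-like paralog analysis shows
  (Ks 0.027, 0.251, 1.616; weights 0.3/0.5/0.2; 0.35 ln-units spread —
  the recent-duplication, WGD and ancient/saturating peaks), then applies
  synonymous single-base substitutions until the pair's realised NG86 Ks
  first reaches its target. Mutating only synonymously guarantees the
  estimator's input matches its model without a full codon-model (GY94)
  simulator; the cost is that Ka is ~0 by construction and
  transition/transversion structure is absent. Draws beyond the JC
  saturation bound (unavoidable in the tail of the ancient component) are
  truncated to the bound and counted; a component *mean* beyond the bound
  is an error.
* **`simulate_synteny_dataset()`** builds collinear anchor runs with
  random orientation, Poisson noise genes, spacer genes between blocks,
  per-block terpene/defense labels (a comonotone-mixture copula gives
  `P(both)` rising linearly in the dependence parameter), and LTR
  intervals in inter-anchor gaps. Real genomes add tandem arrays, nested
  and fragmented blocks, and many-to-many homology, none of which are
  emulated.
* **`simulate_kmer_histogram()`** uses the locus model behind the
  profiler: heterozygous k-mer loci (probability $1-(1-h)^k$) contribute
  two k-mers at half coverage, homozygous loci one at full effective
  coverage $c(1-e)^k$, errors a depth-1 spike with total mass consistent
  with genome_size × coverage. Defaults are a hop-like 5% heterozygosity
  and 0.48% read error at 30× and k = 21. Repeats — the dominant feature
  of real hop histograms at high depth — are deliberately absent, so
  passing recovery tests says nothing about repeat-rich tails.
* **`simulate_mapping_population()`** emulates a 281-offspring
  bi-parental cross genotyped at A/H/B markers: test-cross (1:1) and
  F2-type (1:2:1) segregation, with a sex-linked subset planted on one
  designated scaffold (males H, females A, optional error/missingness).
  Linkage between markers is not simulated — markers are independent —
  so the scan's type-I calibration holds per marker, not per correlated
  bin.
* **`simulate_genome()`** places non-overlapping exon-structured genes on
  i.i.d.-composition scaffolds, enough to exercise GFF3/FASTA I/O,
  merging and composition code paths; it makes no attempt at realistic
  gene structure or isochores.

Passing the recovery tests therefore demonstrates internal consistency
of estimator and generator under the stated models and conditions — the
study-scale conditions themselves (sample sizes like n = 5000 pairs for
mixture recovery, 500 pairs for Ks recovery, 400 blocks for co-occurrence
calibration, 2000 markers × 281 offspring for the scan, megabase genomes
at 25–40× for k-mer profiling) — not correctness on any real genome.

# Known limitations

* NG86 underestimates Ks relative to yn00 when transition/transversion
  bias is strong; use the documented divergence-pair interface to bring
  externally computed estimates into the mixture stage if that matters.
* The k-mer profiler has no repeat component and assumes one diploid
  individual; its heterozygosity inversion assumes independent
  heterozygous sites.
* The DP chainer's greedy block extraction can, in principle, split an
  optimal two-block decomposition differently than MCScanX's scored
  chaining; on the generator's block geometry this does not occur at
  zero noise (and is tested).
* The co-occurrence "expected" uses block-level marginal rates; with very
  uneven block sizes a gene-level model would differ.
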