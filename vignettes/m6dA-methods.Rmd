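---
title: "Methods: calling and characterizing m6dA from SMRT-seq kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterizing m6dA from SMRT-seq kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Single-molecule real-time (SMRT) sequencing reads each strand of a
circular DNA template repeatedly and records the inter-pulse duration
(IPD) before every base incorporation. N6-methyldeoxyadenosine (m6dA)
slows the polymerase, so the ratio of the observed IPD to the IPD
expected for unmodified DNA — the IPD ratio — is elevated at methylated
adenosines. Because each sequenced molecule is an unamplified genomic
fragment, molecules covering the same position come from homologous
chromosomes or different cells, and the share of molecules carrying the
mark at a position — the *methylated fraction* — measures how
homogeneously a cell population is methylated there. `m6dAtools`
implements the downstream characterization of such data: site calling,
fraction estimation, enrichment statistics, cluster detection,
haplotype- and family-resolved comparisons, and the link to gene
expression.

All statistics treat the two strands of one genomic position as distinct
sites, because SMRT sequencing is strand-specific. Internally the
package uses 1-based positions and 1-based closed intervals — the native
convention of the GenomicRanges/IRanges/Biostrings stack that performs
every interval operation — so GFF coordinates pass through unchanged and
BED intervals are shifted by one on read. Both conversions are exact
bijections and are covered by round-trip tests.

## Kinetic model and fraction estimation

Per-molecule mean log IPDs at a site are modeled as a two-component
normal mixture with fixed component means:

$$x_i \sim w\,\mathcal N(\mu_0 + \delta,\ \sigma^2/n_i)
      + (1-w)\,\mathcal N(\mu_0,\ \sigma^2/n_i),$$

where $\mu_0$ is the unmodified mean log IPD, $\delta$ the additive
log-scale shift of a methylated base (a fully methylated site has
expected IPD ratio $e^\delta$), $\sigma$ the per-pass noise and $n_i$
the number of circular-consensus passes of molecule $i$ (multi-pass
reading averages the noise down). Only the weight $w$ is free; it is
estimated by EM to tolerance $10^{-8}$ (at most 500 iterations, error on
non-convergence), with responsibilities computed on the log scale for
stability. The methylated fraction is the converged posterior share of
the methylated component, clamped to $[0,1]$; the methylated molecule
count is the fraction times the coverage, rounded half up (half-up
rounding is used everywhere a fractional count becomes an integer, so
results do not depend on the platform's round-half-to-even).

Two numerical facts matter for interpreting accuracy. First, with the
default parameters ($\sigma = 0.5$, $n = 10$ passes) the components sit
many molecule-level standard deviations apart, so EM effectively reduces
to assigning each molecule to the nearer component; the estimator is
then information-bounded by the binomial proportion of methylated
molecules, and its RMSE at coverage $c$ is about
$\sqrt{f(1-f)/c}$ — roughly 0.07 at coverage 40 over the default
fraction mixture, improving with coverage. No estimator from the same
data can beat this bound, which is why the recovery tests assert the
binomially attainable accuracy rather than an arbitrary tighter one.
Second, when only site-level summaries are available a method-of-moments
fallback inverts the raw-scale ratio, $f = (r-1)/(e^\delta-1)$, clamped
to $[0,1]$; it is documented as cruder and is not used where molecule
data exist.

The site IPD ratio is $\exp(\overline{x} - \mu_0)$, the geometric-mean
deviation, matching the multiplicative character of the statistic.

## Calling filters

A called m6dA site requires coverage $\ge 20$ distinct molecules on its
strand and IPD ratio $\ge 4$. Published descriptions of such filters
alternate between strict and non-strict inequalities; the package uses
inclusive bounds on both (configurable), because inclusive bounds are
unambiguous to reproduce. Sites failing either filter but with coverage
$\ge 11$ — enough to estimate a fraction at all — form the
*failed-filter null set*. This set, not the genome at large, is the
background for motif enrichment: it carries the same detection biases as
the called set, so Fisher contrasts against it cancel part of the
motif-dependent detection artifact.

## Feature annotation and enrichment

Promoters are the 1 kb immediately upstream of the transcription start
site; the downstream feature is the 1 kb past the transcript end;
introns are the gaps between a transcript's exons; intergenic space is
the complement. Each site receives exactly one label under the
precedence promoter > 5'UTR > 3'UTR > exon > intron > downstream >
intergenic, with ties inside a level broken by the lowest gene id —
conventional peak-annotation behavior, fixed here so assignment is
deterministic under overlapping transcripts.

m6dA/dA ratios divide site counts by the number of strand-specific
deoxyadenosine positions (an `A` on the plus strand and a `T` in the
plus-strand sequence are distinct assayable positions). Chromosome
profiles split each chromosome into 200 equal-width bins by default (the
last bin absorbs the division remainder). Fold enrichment of a feature
is its m6dA/dA ratio over the genome-wide ratio; significance comes from
shuffling site locations over the dA universe. Because a shuffle is a
uniform without-replacement draw of universe positions, the permutation
is executed on the universe's precomputed feature labels, which is
mathematically identical to shuffling and re-annotating but orders of
magnitude faster.

## Permutation convention

Empirical p-values use $(b+1)/N$, where $b$ counts null draws at least
as extreme as the observed statistic: with $N = 1000$ shuffles and no
exceedance the attainable minimum is exactly 0.001. Shuffles preserve
per-chromosome site counts and sample strand with the chromosome's dA
composition; a flag for genome-wide (cross-chromosome) shuffling exists
because the convention is not universal. Two-sided permutation tests
measure $|$fold$-1|$; directional tests are available per call.

## Clusters

A cluster is a run of 500 bp holding at least 10 m6dA, with strands
pooled per genomic position (regions are positional). Candidate windows
are anchored at site positions; qualifying windows are merged when they
overlap (merging avoids double-counting and makes the procedure
equal to exhaustive window enumeration, which the tests verify on
hundreds of random layouts); all sites inside a merged span are cluster
members. Cluster statistics report the A/T fraction of the span and the
median successive-site spacing. Cluster abundance significance shuffles
the sites and re-runs the identical detection.

## Motifs

A site *has* dinucleotide XY when XY equals the upstream neighbor plus
the methylated A, or the methylated A plus the downstream neighbor. All
16 dinucleotides are tested two-sided by Fisher's exact test against the
failed-filter null set (two-sided because the analysis reports
enrichment without pre-specifying a direction), Bonferroni-corrected
across the 16 motifs at $\alpha = 0.05$. Significant dinucleotides
overlapping by one base are merged into 3-mers and chained once more
into 4-mers; a combined motif is counted as present when it occurs at an
offset covering the central methylated A. The merged-core reading is one
of two defensible constructions of "combined 4-mers"; the alternative —
an occurrence anywhere in the 41-base context window — is available via
`motif_presence(mode = "window")`.

## Haplotypes, differential methylation, and the family trio

Reads tagged by phased SNPs are split into the two haplotypes and the
standard calling is applied independently to HP1, HP2 and the pooled
(diploid) molecule set; untagged molecules count only toward the diploid
call. A site enters the haplotype comparison table when it is called in
the diploid analysis and has at least 20x coverage on *each* haplotype.
The diploid fraction is regressed on the two haplotype fractions by
ordinary least squares with intercept; under balanced haplotype coverage
the construction weights are (0.5, 0.5), which parameter-recovery tests
confirm within ±0.05.

Differential gene methylation between two samples sums, per gene, the
methylated-cell counts and coverages over the union of methylated
positions, compares the two proportions by continuity-corrected
chi-squared, and adjusts across genes by Benjamini-Hochberg. The test is
symmetric in the samples.

The family-trio analysis filters each member's candidate sites at half
that member's total coverage (strand-specific sequencing sees half the
fragments per strand), rounded half up, plus the IPD filter. Pairwise
exact-site overlaps are tested by drawing equal-size random sets from
each member's failed-filter pool; the *relatedness* question uses the
asymmetric two-proportion construction: overlap(mother, father) over the
parent's call-set size against overlap(parent, son) over the son's
call-set size, which accounts for the son's larger set. Two properties
of this construction are worth knowing. The two overlap counts share the
parent's call set, so they are positively correlated, and the
Yates-corrected test assumes independent samples: under the null the
test is therefore conservative (its realized type-I error sits well
below the nominal 0.05 in the calibration suite, i.e. it stays
non-significant in more than 95% of null runs). Conservative null
behavior with high power at inheritance 0.5 is exactly the regime the
analysis needs.

## Expression link

Genes are split by whether a called m6dA lies in a named feature of the
gene (promoter, exon and intron panels, or a gene-level union) and TPM
is compared by a two-sided Wilcoxon rank-sum test — rank-based, hence
invariant to monotone rescaling of the expression unit. Allele-specific
expression (ASE) per gene is a two-sided exact binomial test of the
hap1 count against 0.5, BH-adjusted over tested genes; genes below a
depth floor (default total count 20) are not tested, because shallow
genes carry almost no information and only dilute the FDR correction.
The intersection of ASE genes with haplotype-differentially methylated
genes is assessed by the upper-tail hypergeometric test within the
common gene universe.

# The synthetic-data generator

Every stage is exercised on ground-truthed synthetic data produced from
one master seed. Each generator stage draws from its own named
substream (`substream_seed()`), so adding a stage never perturbs the
draws of an earlier one, and the whole bundle is byte-reproducible per
seed.

The generator emulates, at desk scale, the statistical structure the
analysis assumes:

* a 3 x 200 kb genome at 41% GC with ~45 packed genes (exons,
  introns, terminal-exon UTRs) — large enough for stable feature
  denominators, small enough that the full suite runs in minutes;
* m6dA planted only on strand-specific adenosines, with placement odds
  multiplied by a per-feature bias (enriched in genic features,
  depleted intergenic) and by an AG/GA motif bias;
* per-site true fractions from a mixture of a spike at 1.0 (weight
  0.15) and a Beta(2, 2) body — a visible fully-methylated spike over a
  broad heterogeneous bulk, the qualitative shape of the real fraction
  density, without claiming the real density itself;
* AT-rich 500 bp cluster regions (A/T fraction 0.67) carrying ≥ 10
  sites each, with cluster-site fractions drawn low (Beta(2, 4)),
  mirroring the observation that clustered marks are less homogeneously
  methylated;
* log-normal per-molecule IPDs with methylated shift $\delta = \log 6$
  by default, so a fully methylated site has expected IPD ratio 6 and
  passes the ratio-4 filter with margin while partially methylated
  sites honestly risk failing it — the simplest model consistent with
  the IPD ratio being a multiplicative statistic (the real kinetic
  model is unpublished; this stand-in is documented as such);
* per-site coverage Poisson with mean 40 and a lower clamp;
* binary haplotype methylation status: a haplotype is a single
  chromosome copy, so a mark present on it is carried by every molecule
  from that copy; population-level heterogeneity arises from the
  restricted/shared site mixture (70% of haplotype sites methylated on
  exactly one haplotype by default) and from molecule sampling noise;
* a family trio in which each member holds ~2,000 called sites drawn
  from the dA universe plus a conserved common pool (200 sites, each
  included with probability 0.5) that creates the above-chance overlap
  between unrelated parents, and a son who inherits each parental site
  with probability 0.5 and otherwise looks exactly like a parent — the
  exchangeability that makes the zero-inheritance null meaningful;
* expression with log-TPM effect +1 for genes carrying m6dA and
  binomial allele counts at depth 100 with an 80:20 bias in ASE genes,
  the ASE genes drawn from the differentially methylated set with
  configurable linkage.

What the generator does *not* emulate: alignment and mappability
artifacts in repetitive regions (the real cluster signal may partly be
such an artifact), sequence-context-specific kinetic signatures beyond
the single shift $\delta$, other modifications (m5dC, m4dC), polymerase
error profiles, and linkage between SNP density and methylation.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the stated model — not that the biological
conclusions transfer to any particular real genome.

# Problem sizes and numerical choices

The test and acceptance runs use: 1,000 simulated sites for fraction
recovery at coverages 40 and 80; ≥ 500 planted foreground sites for
motif recovery with bias 5 and 100 seeds for the null calibration; 500
random layouts (≤ 200 sites) for the cluster-detection oracle; 1,200
haplotype sites for exclusivity recovery; 100 generator seeds per trio
condition at 2,000 sites per member; 400 genes (200 per group) for the
expression link. These sizes were chosen so each check's Monte-Carlo
error is small relative to its tolerance.

Further fixed choices: EM tolerance $10^{-8}$, maximum 500 iterations;
half-up rounding for all fractional counts (including the trio
half-coverage filters, where published filter values imply inconsistent
rounding of .5 across individuals — a per-member override exists);
feature-precedence tie-break by lowest gene id; cluster windows merged
only when overlapping (adjacent windows stay separate clusters);
degenerate inputs (empty site sets, zero-coverage records, all-untagged
molecule tables, collinear regression designs) raise informative errors
rather than guessing.

# Known limitations

* The methylated fraction inherits the binomial information bound of
  the coverage; at 20x the RMSE floor is ~0.1 for mid fractions.
  Fraction-based comparisons at the coverage filter boundary are
  correspondingly noisy.
* The failed-filter null set only partially cancels detection bias; a
  motif that modulates *coverage* rather than IPD would not be fully
  controlled.
* The relatedness proportion test is conservative under the null (see
  above); its p-values should be read as upper bounds.
* Cluster detection pools strands by position; a strand-exclusive dense
  region and a double-stranded one are not distinguished at detection
  time (the member records keep their strands for downstream tests).
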