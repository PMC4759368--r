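---
title: "Differential DNase hypersensitivity and enhancer-gene linkage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential DNase hypersensitivity and enhancer-gene linkage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhslink)
```

# Scope and model

`dhslink` compares DNase I hypersensitive site (DHS) landscapes between cell
states — for example a proliferating control versus cells undergoing early
osteoblast commitment in basal or osteogenic-induction medium — and links the
accessibility changes to genes and gene programs. The package works from
peak calls and per-bp cut-count tracks; peak calling itself, read alignment
and motif discovery are out of scope (the motif step is served only by
exporting fixed-width candidate windows).

Every user-facing coordinate is 0-based half-open (BED convention). Two
intervals overlap when they share at least one base.

## MaxD and depth normalization

Each DHS carries a maximal tag density (MaxD): the largest per-bp cut count
inside the site. Raw MaxD values depend on sequencing depth, so they are
scaled to a common depth of 10 million reads:

$$\mathrm{MaxD}_{norm} = \mathrm{MaxD}_{raw} \times \frac{10^7}{N_{reads}}.$$

`normalize_maxd()` is exactly this linear map; it is applied inside
`hotspot_set()` so every site table carries both values.

## Replicate concordance

A condition is represented by the sites supported by both biological
replicates (`replicate_concordant()`). Concordant sites are unions of
replicate intervals that overlap by at least one bp (connected overlap
clusters are merged into one interval spanning their union). Neither the
merge rule nor the summary statistic is canonical in the field, so the
package makes a definite choice: the concordant normalized MaxD is the mean
of the two replicates' normalized peak values, and both raw replicate
counts are retained for testing.

## Testing MaxD differences

For a site observed with raw peak counts $k_a, k_b$ in libraries of depth
$d_a, d_b$, the null hypothesis of equal underlying density implies, after
conditioning on $n = k_a + k_b$,

$$k_a \mid n \sim \mathrm{Binomial}\!\left(n, \frac{d_a}{d_a + d_b}\right).$$

`maxd_difference_test()` computes the exact two-sided binomial p-value
(minimum-likelihood method, via `stats::binom.test`), which stays valid at
the small counts typical of peak-bp statistics; $n = 0$ yields $p = 1$. The
default pipeline applies no multiple-testing correction — each site is
reported with its own exact p — but `compare_two(p_adjust = "BH")` switches
the significance flag to Benjamini–Hochberg-adjusted values. When
replicate-concordant sets are compared, counts are pooled across replicates
and depths summed, so the test conditions on all four libraries at once.

## Common/unique partitions

`compare_two()` classifies every site as unique (no cross-set overlap) or
common, merging each connected cluster of overlapping sites into one
differential interval with per-side summed counts, the signed difference of
normalized MaxD (`delta_norm_maxd`, second minus first condition), the exact
p-value, and a status (`unique_a`, `unique_b`, `common_modified` at
$p < \alpha$, otherwise `common_unchanged`). `compare_three()` assigns each
site of three sets to one of the seven Venn regions by direct pairwise
overlap. Both partitions are verified in the tests against a brute-force
all-pairs oracle; "unique" deliberately means *non-overlapping* — sites that
overlap but change significantly are reported separately as
`common_modified`, so either notion of condition-specific sites can be
recovered downstream.

## Genomic annotation

`annotate_all()` assigns exactly one category per site with the priority
promoter > exon > intron > distal. The promoter window is
$[\mathrm{TSS} - 2500, \mathrm{TSS} + 2500)$ (half-open, strand-aware: the
TSS of a minus-strand gene is `tx_end - 1`). A site failing all gene-linked
categories is `distal_upstream` or `downstream` according to whether its
midpoint lies 5' or 3' of the nearest gene's TSS; "nearest" is measured
midpoint-to-TSS with ties to the lexicographically smaller gene id, and no
distance cap is imposed. Within a priority level the site is assigned to
the gene with the nearest TSS. These distal and tie-break rules are package
decisions where the field's usage is loose; they are deterministic and
exhaustively tested on constructed overlap patterns.

`aggregation_profile()` summarizes a cut-count track around TSSs:
strand-oriented windows of `2 * flank` bp are binned, depth-normalized to
10 million reads and averaged across genes. Genes whose window would cross
a chromosome boundary are dropped from the average (the count is reported
as an attribute). The profile is linear in the track, which the tests
exploit.

## Titration-of-digestion (TOD) quality control

DNase titrations are monitored by qPCR at benchmark sensitive and resistant
loci. With amplification efficiency $E \in (1, 2]$ per cycle, a digested
fraction $f$ leaves $1 - f$ of the template intact, so

$$\mathrm{Cq}(u) = \mathrm{Cq}_0 - \log_E\bigl(1 - f(u)\bigr),
\qquad f = 1 - E^{\,\mathrm{Cq}_0 - \mathrm{Cq}},$$

clamped to $[0, 1]$. `fraction_digested()` flags a digested sample that
amplifies *earlier* than its undigested control (`"negative dCq"`, clamped
to 0) and treats a missing Cq as complete digestion (`"no amplification"`,
fraction 1). Replicate Cq values are averaged *before* the transform —
the curve point is the transform of the mean — and the replicate spread is
propagated numerically as the SD of per-replicate fractions. The default
efficiency is 2 (ideal doubling) and is configurable per assay since
primer-level efficiencies are rarely reported.

`select_replica()` picks the smallest DNase concentration whose mean
sensitive-site fraction falls in the target window (default 70–80%
digestion, the optimum for reproducible hypersensitivity libraries) while
the mean resistant-site fraction stays at or below 0.10. Choosing the
*gentlest* qualifying digestion minimizes over-digestion artifacts; the
resistant threshold makes the informal "no digestion at negative controls"
criterion explicit and configurable. The window itself is configurable
because the optimum is quoted both as a 70–80% range and as an 80% point in
practice; the range is the default.

## Enhancer definition and gene linkage

Condition-unique sites outside promoter windows — exonic, intronic and
intergenic combined — are treated as enhancers (`define_enhancers()`).
`link_enhancers_to_genes()` pairs each enhancer with *every* gene whose TSS
lies within 50 kb (inclusive) of the nearer site border; a TSS inside the
site has distance 0. One enhancer may link many genes and vice versa; the
link count is monotone in the distance bound.

`gene_intensity_table()` collapses links to one signed intensity per gene.
The default keeps the signed value of the link with the largest absolute
MaxD change (`max_abs`) so a strong closing enhancer is not cancelled by a
weak opening one; summation is available (`mode = "sum"`) since no
canonical collapse rule exists for multi-enhancer genes.

## Gene-set enrichment — an open substitution

The annotation of linked genes against a commercial pathway knowledge base
is deliberately replaced by an open equivalent: user-supplied GMT gene
sets tested by the one-sided hypergeometric over-representation p

$$p = P(X \ge k), \qquad X \sim
\mathrm{Hypergeom}(N_{bg}, K_{set}, n_{query}),$$

with Benjamini–Hochberg correction across sets (`enrich_gene_sets()`).
Sets are intersected with the background first; the background defaults to
all genes in the annotation, not only linked genes. This is the one
intentional methodological substitution in the package: results name the
user's gene sets, not proprietary pathway labels. `overlay_expression()`
then joins per-gene intensities with log2 expression ratios, keeping and
flagging genes absent from the expression data.

## Expression processing

`replicate_average()` takes per-(condition, time) arithmetic means.
`relative_log2_ratio()` divides each mean by the per-gene average across
the time course and returns log2 values, so the per-gene mean of the
pre-log ratios is exactly 1; a control-referenced mode
(`ref = "control"`) is provided because "change in expression" is used in
both senses in practice. Zero intensities are rejected rather than
silently pseudocounted — the caller decides on any pseudocount.
`select_top_genes()` keeps genes reaching a fold-change threshold (default
5; the threshold is exposed because 2-fold and 5-fold are both quoted for
the same kind of heatmap) and `cluster_genes()` cuts an average-linkage
Euclidean dendrogram — the conventional heatmap defaults — into `k = 6`
groups.

# The synthetic-data generator

`make_genome()`, `make_hotspot_truth()`, `simulate_tags()`,
`simulate_titration()`, `simulate_expression()` and `make_fixture()` build
a fully synthetic study with known ground truth, so that every downstream
claim is checked against planted facts rather than against the package's
own output.

What it emulates:

* a multi-exon gene annotation on a small genome (default 2 chromosomes of
  5 Mb, 200 genes of 2–15 kb with 2–10 exons, both strands);
* per-condition hotspot sets sharing a common complement (200 sites), with
  condition-specific unique sites (defaults 15 for the control and
  basal-medium day 1, 25 at day 2, 33 and 90 for induced days 1 and 2 —
  induced conditions gain several-fold more unique sites and roughly double
  from day 1 to 2) and a 10% fraction of shared sites carrying log-normal
  MaxD shifts;
* 12 planted "gained" enhancers for the induced day-1 condition, placed
  outside every promoter window and within 40 kb of the TSS of 8 planted
  genes — linkable by construction at the 50 kb bound;
* per-bp Poisson tag counts whose site profile is triangular with the peak
  mean calibrated so the raw MaxD matches the per-10M truth at the
  simulated depth (2 x 10^6 reads per replicate by default), plus a uniform
  background that conserves total library mass; replicate peak calls jitter
  the true boundaries by at most 10 bp, and replicate noise is Poisson, not
  Gaussian, to match the count nature of the data;
* qPCR titrations with a Hill-like digestion curve whose 40 U point
  (0.73) is the only one inside the 70–80% window, plus resistant sites
  with near-zero digestion and Gaussian Cq noise (SD 0.15);
* an expression matrix in which the planted genes carry an additive +2
  log2 effect in induced samples over a 0/1/2-day design with triplicates;
* a GMT collection holding the planted gene set plus 20 size-matched decoy
  sets drawn uniformly from the non-planted genes.

What it does **not** emulate — and hence what passing tests do not show
about real data: realistic sequence content or mappability, copy-number
and GC biases, correlated replicate noise, overdispersion beyond Poisson,
peak-caller idiosyncrasies (calls here are jittered truth), genome-scale
gene density, or biologically structured gene sets. The generator
validates the *computations*, not the biology.

All randomness flows through one explicit seed: a fixed seed makes the
entire fixture byte-identical on disk, which the tests assert by hashing.

# Numerical and design choices

* Coordinates 0-based half-open everywhere; GRanges conversion is internal.
* Overlap means >= 1 shared bp; adjacent (touching) intervals do not
  overlap, and interval union during merging never bridges a gap.
* Clamps: digested fractions to [0, 1]; motif windows to chromosome
  bounds (flagged when clipped; width must be even so the centre is
  unambiguous).
* Tie-breaks are all deterministic: nearest-gene ties go to the smaller
  gene id, site rankings break ties by (chromosome, start), top-gene ties
  by gene id, and qualifying DNase concentrations by the smallest value.
* Degenerate inputs: empty site lists annotate to zero counts without
  error; an empty overlap yields an empty concordant set; `n = 0` tests
  return p = 1; genes whose aggregation window leaves the chromosome are
  skipped; a chromosome without genes makes distal classification an
  explicit error rather than a silent guess.
* Problem sizes used by the test-suite and the acceptance script — chosen
  as the smallest designs at which every decision the pipeline makes is
  exercised with comfortable statistical margins: oracle checks on 50
  random instances of up to 600 intervals; 10,000 Poisson pairs for the
  type-I error; 1,000 random queries for the enrichment null; 100
  randomized titration designs; 20 seeded end-to-end runs on the 10 Mb /
  200-gene study design.

# Known limitations

* The exact conditional binomial test is conservative at small counts;
  its empirical type-I error runs below the nominal level.
* The hypergeometric null is discrete, so enrichment p-values are
  super-uniform for small backgrounds; uniformity holds in the
  large-background regime the tests probe.
* `compare_two` pools replicate counts rather than modelling replicate
  variance; with two replicates per condition there is little information
  to estimate overdispersion, and the exact test's conservatism partly
  compensates.
* Enhancer-gene pairing by TSS distance is a proximity heuristic: a
  linked gene is a candidate target, not a validated one.
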