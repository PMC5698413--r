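---
title: "Methods: dating, diversity and network analysis of Y-chromosome lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating, diversity and network analysis of Y-chromosome lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

## Scope

`ylineage` implements the analysis chain used in haplogroup-level studies
of the human Y chromosome, where jointly typed SNPs (from whole-Y
resequencing) and Y-STRs (forensic-panel microsatellites) are used to ask
when a paternal lineage arose, how its diversity is distributed among
populations, and whether its internal structure reflects geography.  The
package covers: variant filtering from a raw VCF to an analysis-ready
haploid matrix; deterministic tree building and haplogroup assignment;
rho-statistic TMRCA estimation; STR diversity statistics and their
correlation with longitude; hierarchical AMOVA with permutation tests;
median-joining networks; and a coalescent simulator that generates joint
SNP+STR panels from genealogies with known history, so that every
estimator in the package can be validated against truth.

Upstream read mapping and variant calling, Bayesian (MCMC) node dating and
skyline reconstruction, and ordination (PCA) are out of scope: they belong
to external tools, and the package's role starts at the called VCF.

## The filter cascade

Raw haploid call sets carry three artefact classes with distinct causes:
low-coverage calls (undersampled sites), heterozygous diploid calls
(impossible on the male-specific Y; almost always mismapping from
repeated or X-homologous sequence), and low-quality samples.  The cascade
applies, in order:

1. **Region mask** — only sites inside a user-supplied BED mask of unique,
   high-quality Y sequence are kept (conventionally about 4.88 Mb once
   ampliconic, heterochromatic, pseudoautosomal and X-transposed regions
   are excluded).  BED intervals are 0-based half-open, VCF positions
   1-based; the conversion lives in one reader layer and nowhere else.
2. **Callable-depth filter** — genotypes supported by fewer than 5 reads
   (inclusive threshold: depth 5 passes) are set to *missing*, never to
   the reference state; coding depth failures as ancestral would deflate
   every downstream mutation count and bias rho dates young.
3. **Heterozygote removal** — heterozygous calls become missing; the
   matrix is strictly haploid afterwards.
4. **Sample QC** — samples with ≥ 5% missing calls or mean read depth
   below 10x are removed.  Mean depth is computed over the retained sites
   (the alternative, genome-wide mean depth, is also reported in the QC
   table but does not gate removal; with roughly uniform coverage the two
   agree).

Each stage can only remove sites or samples, the cascade is idempotent on
its own output, and the per-stage counts are reported so that a published
filtering narrative can be checked number by number.  Counts upstream of
the mask (raw calls, caller-level hard filtering) belong to the external
caller and are labelled as such.

## Tree building and haplogroup assignment

Y-SNPs in the callable unique region are effectively homoplasy-free, so
the genealogy is reconstructed as a **perfect phylogeny** rather than by
heuristic maximum-parsimony search: each variant must label exactly one
edge, which is possible iff every pair of derived-carrier sets is nested
or disjoint (the four-gamete condition with a known ancestral state).
This makes the builder deterministic — the same matrix always yields the
same tree — and makes data errors loud: a four-gamete violation raises an
error naming an offending site pair instead of being averaged away by a
tree search.  Missing calls are imputed to the site's majority state
(ties to ancestral) and the imputation count is reported.  Variants
sharing a carrier set stack on one edge, and edge lengths are mutation
counts, which is exactly the input the rho statistic needs.

Haplogroup assignment walks a defining-SNP hierarchy (a TSV of
child/parent/variants rows, so newly discovered subclades are additive
edits).  A sample is assigned to the deepest node whose whole defining
path is derived; a node with known subclades for which the sample is
ancestral or unresolved yields the starred paraclade label (`SM001*`).
Two conservative choices are deliberate: an edge whose defining variants
are all missing *blocks* descent (shallow assignment, logged), and a
derived call below an ancestral ancestor is an error, not a silent
majority vote.  The shipped default hierarchy is the E-M183 subclade tree
(M183 → SM001 → {Z5009, CTS12227, PF6794 → PF6789}).

Frequency tables report counts per population and haplogroup label plus
the percentage of chromosomes inside the top clade, rounded half-up to
two decimals — the rounding convention of published frequency tables,
which `base::round()`'s banker's rounding would not reproduce.

## Rho dating

The rho statistic is the mean number of mutations separating sampled
lineages from their common ancestor,

$$\rho = \frac{1}{n}\sum_{\text{tips } i} m_i
       = \sum_{\text{branches } b} \frac{n_b}{n}\, l_b,$$

with the Saillard standard error
$\sigma_\rho = \sqrt{\sum_b (n_b/n)^2\, l_b}$, which treats branch counts
as independent Poisson draws.  Under rate constancy $\rho = \mu T$, so

* **SNP mode**: $T = \rho / (\mu_{\text{site}} \times L)$ with
  $\mu_{\text{site}}$ the per-site per-year substitution rate and $L$ the
  callable length.  Two conventional rates are built in: a "fast" rate of
  $10^{-9}$ and a "slow" rate of $6.17\times10^{-10}$
  substitutions/site/year; both are parameters, not constants.
* **STR mode**: $T = \rho \times 858$ under the default YHRD-derived rate
  of one mutation per haplotype per 858 years for the single-copy YFiler
  panel.  The founder haplotype defaults to the per-locus modal vector
  (standard practice); it is overridable because published analyses do
  not always state their choice.  Note that the modal vector minimises
  the mean single-step distance only when each locus has a majority
  allele; for skewed allele distributions the per-locus median is the L1
  minimiser, which is why the founder is exposed as a parameter.

The confidence interval is $T \pm 1.96\,\sigma_T$.  The 1.96 multiplier
is a choice (normal 95% interval); published rho intervals do not always
state theirs, so the multiplier is an explicit argument.  For STR rho the
standard error uses the star-genealogy approximation
$\sigma = \sqrt{\rho/n}$, the regime appropriate for rapidly radiating
haplogroups; on a literal star tree the Saillard estimator collapses to
exactly this value.

For configuring external clock analyses on variable-sites-only
alignments, `effective_rate_per_variable_site()` rescales a genomic rate
by callable length over variable-site count (e.g.
$10^{-9} \times 4{,}880{,}000 / 4{,}269 = 1.1431\times10^{-6}$ per
variable site per year).

## STR diversity and geography

Per population (or any grouping) the package computes Nei's unbiased gene
diversity $D = \frac{n}{n-1}(1-\sum p_i^2)$ over whole-haplotype
frequencies with Nei's sampling variance, mean pairwise differences
(loci-differing or stepwise metric), per-locus unbiased heterozygosity,
and per-locus allele-size variance with the $n-1$ denominator (the
Arlequin convention; stated here because published methods sections
rarely do).

Correlations of these statistics with longitude use Spearman's rank
correlation.  With at most 8 units the two-sided P-value is computed by
full permutation enumeration; longitude analyses of this kind typically
involve about six populations, where the t approximation is invalid.  At
$n = 6$ and $\rho = 0.8857$ the exact two-sided P is $24/720 = 0.033$.
Ties get midranks.

## AMOVA

The hierarchical analysis of molecular variance partitions the total
molecular variance into among-group, among-population-within-group, and
within-population components from a matrix of squared inter-haplotype
distances (Excoffier's sums-of-squared-deviations formulation with the
standard unequal-sample-size coefficients), yielding the distance-based
fixation indices $\Phi_{CT}$, $\Phi_{SC}$, $\Phi_{ST}$.  The default
distance is the count of differing loci (the F\_ST-style haplotype
metric); the squared stepwise distance (R\_ST-style) is available for
sensitivity analysis.  Design conventions follow Arlequin: populations of
size one are excluded with a warning; negative variance components are
reported, not truncated; a two-level design with a single group collapses
to the one-level result.  P-values come from label permutations — samples
among populations for $\Phi_{ST}$, whole populations among groups for
$\Phi_{CT}$, samples within groups for $\Phi_{SC}$ — with
$p = (\#\{ \text{perm} \ge \text{obs}\} + 1)/(B + 1)$.  The default
$B = 1{,}000$ (10,000 in the shipped example configs) keeps desk runtime
in seconds; published "$P < 10^{-5}$" claims imply $B \ge 100{,}000$,
which the `n_perm` argument supports directly.  A coastal-versus-inland
grouping of North African populations ships as a documented example
configuration (`inst/extdata/coastal_inland_groups.csv`), not as
hard-coded behaviour, because the precise membership of such groupings is
an analysis decision.

## Median-joining networks

The network stage follows Bandelt's two-phase construction for
multi-state (repeat count) data, with no binarisation.  Phase one builds
the ε-relaxed **minimum spanning network**: clusters agglomerate at
increasing connection cost σ, and every inter-cluster link with weight
≤ σ + ε is kept, so at ε = 0 the network is exactly the union of all
minimum spanning trees.  Phase two repeatedly generates candidate
**median vectors** (per-locus medians of triplets with at least two pairs
linked in the current network), adds those whose connection cost is
within ε of the best candidate, and recomputes the network until no new
median arises; an iteration cap of 50 guards termination and raises a
diagnostic error rather than looping.  Median nodes that end with degree
≤ 2 have no Steiner role and are pruned.  Distances are weighted stepwise
(uniform weights by default; per-locus weights are a parameter because
published analyses set them interactively).  Duplicate observed
haplotypes collapse into one node carrying their frequency; nodes are
ordered canonically so output is independent of input row order.

The qualitative "star-like network" claim is quantified by
`star_index()`: the fraction of observed haplotypes lying one mutational
step from the highest-frequency node (ties broken lexicographically).  A
perfect star scores 1; simulated star genealogies score systematically
higher than constant-size coalescent genealogies of comparable depth.

## The simulator

The generator produces joint SNP+STR panels from genealogies with known
history:

* **Genealogies.**  `star` places every tip at exactly `tmrca` years (the
  idealised rapid-radiation genealogy under which rho is unbiased);
  `coalescent_const` is a Kingman coalescent whose time-scale parameter
  (effective size × generation time, in years) is supplied through the
  same `tmrca` field — for two lineages it is the *expected* coalescence
  time, and the realized (random) TMRCA is recorded as the truth;
  `coalescent_growth` accelerates coalescence backwards in time at rate
  $g$ per year via inversion of the integrated hazard.  A generation time
  of 30 years is exposed as the package constant `GENERATION_TIME_YEARS`
  for converting generation-scaled quantities.
* **SNPs.**  Each branch receives Poisson(rate × callable length ×
  years) mutations at fresh sites (infinite sites, no back mutation), so
  every site pair passes the four-gamete test by construction and the
  perfect-phylogeny builder recovers the genealogy whenever every branch
  carries at least one mutation.  Default rate 1e-9/site/year over
  4.88 Mb.
* **STRs.**  Mutations arrive per branch at the per-haplotype rate
  (default 1/858 per year), are assigned to loci by configurable weights
  (uniform by default — published haplotype rates are not decomposed per
  locus), and step the repeat count ±1 with equal probability (the
  strict single-step model that underlies YHRD-derived haplotype rates).
  Repeat counts cannot drop below one: a downward step at one reflects
  upward.  The default founder is a representative 13-locus YFiler
  haplotype.
* **Panels.**  Multi-population configurations attach labels and
  longitudes; populations may be simulated from disjoint genealogies or
  as arbitrary label-blocks of one shared genealogy (the exchangeable
  null for AMOVA).  Sites are drawn from one positional pool so the
  infinite-sites property holds panel-wide.  Panels round-trip through
  VCF / CSV / Newick / JSON.

One number worth spelling out: the *expected mutation count* per lineage
after time $T$ is $T/858$, but the expected *stepwise distance* from the
founder is smaller, because two mutations at the same locus can cancel.
At $T = 2000$ years over 13 loci the exact expectation (Poisson number of
±1 steps per locus, enumerated) is ≈ 2.14 rather than 2.33, and STR-rho
dates of star genealogies are accordingly biased slightly young at this
depth.  The tests validate the simulator against the exact enumeration,
not against the naive Poisson mean; SNP rho, which evolves without
back-mutation, is unbiased and is the estimator the calibration
properties are stated for.

What the simulator does *not* emulate: locus-specific published STR
rates, multi-step mutations, recombination (none on the MSY), population
structure within a population, and sequencing error beyond uniform read
depth.  Passing tests therefore demonstrate estimator correctness under
the stated models, not robustness to real-data artefacts such as
mismapping or allele dropout — the filter cascade exists precisely
because real data violate these idealisations.

## Problem sizes, tolerances and numerical choices

The validation suite uses desk-scale problem sizes chosen to make
Monte-Carlo assertions sharp without being wasteful: 200 replicate panels
of 50 tips for rho calibration (mean TMRCA within 5% of truth, 95% CI
coverage ≥ 90%), 10,000 replicates for pairwise-coalescent means, exact
enumeration for MSTs (≤ 7 haplotypes), AMOVA oracles (≤ 12 samples) and
Spearman permutations (n ≤ 8).  Monte-Carlo checks use 3-standard-error
tolerances around exact expectations.  Stochastic stages derive
per-stage sub-seeds from one master seed, so pipeline runs are
bit-reproducible; seeded runs are asserted identical in the tests.

Degenerate inputs are handled explicitly rather than by coercion:
empty variant sets write and read as header-only VCFs; monomorphic STR
panels have zero diversity (valid, not an error); populations with a
single sample are excluded from AMOVA with a warning; a sample-QC stage
that would remove every sample is an error; and division by zero in
subclade percentages (a population with no top-clade chromosomes) is
flagged in the output instead of producing NaN.

## Reproducing published E-M183 results

The package ships the published per-population haplogroup counts for
E-M183 (`inst/extdata/em183_published_counts.csv`); building the
frequency table from them reproduces the published "% E-M183" column
exactly (e.g. Western Sahara 76.92, Morocco 62.14).  The full
whole-sequence and supplementary-STR reproductions (rho TMRCA about
1730 [1481, 1979] years at the fast rate from the public VCF; STR rho
about 2012 [1583, 2441] years; AMOVA 8.1% / 16.5% / 8.6%; DYS458*17 at
71% vs 31%) require downloading the public datasets and are provided as
the documented optional workflow `inst/integration/reproduce_published.R`.

## Known limitations

* Perfect phylogeny is the right model for callable-region Y-SNPs but
  will refuse genuinely homoplasic or recurrent sites; such sites must be
  filtered or excluded upstream.
* The STR rho clock inherits the biases of single-step models: saturation
  (and hence young bias) grows with time depth, as quantified above.
* The median-joining implementation targets the panel sizes of haplogroup
  studies (hundreds of samples collapsing to tens of distinct
  haplotypes); its triplet scan is cubic in distinct haplotypes and is
  not intended for thousands of distinct sequences.
* AMOVA P-values are permutation-based; the default 1,000 permutations
  bound the resolution at P = 1/1001.
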