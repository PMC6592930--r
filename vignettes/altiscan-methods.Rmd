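---
title: "altiscan: methods, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{altiscan: methods, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altiscan)
```

altiscan implements the comparative-genomics workflow used to contrast
two small resequencing cohorts of the same species — canonically highland
versus lowland chicken ecotypes — from variant calls (VCF) to candidate
genes.  This vignette records how each stage is defined, which knobs
matter, and where the design was genuinely open and a decision had to be
made.

## Data model and coordinates

Variant identity is the literal tuple (chrom, pos, ref, alt).  No
left-alignment or normalisation is performed: the package consumes calls
that were compared positionally upstream, and normalisation is a
documented non-goal.  Multi-allelic VCF lines are split into one record
per alternate allele; a sample carries a record when its genotype
contains at least one copy of that allele.  A site listed only in other
samples' files is taken as homozygous reference — variant *detection*
semantics, not allele dosage.  Sites at which no sample carries an
alternate allele never become records.

VCF and GFF3 are 1-based inclusive at the I/O boundary; all internal
interval arithmetic (scan windows, dense regions) is 0-based half-open,
with conversion confined to the boundary.  This removes any off-by-one
ambiguity in window membership: a SNV at 1-based position $p$ lies in
window $[s, e)$ iff $s \le p - 1 < e$.

Five variant classes are used: SNV (1 bp substitution), MNV
(equal-length multi-base substitution), insertion (reference a proper
prefix of the alternate), deletion (alternate a proper prefix of the
reference) and *replacement*.  Replacement is the catch-all for
length-changing non-prefix edits; whether such an edit with both alleles
longer than one base should be its own class is not derivable from the
five-class scheme itself, so the prefix rule above is the package's
definition and is applied uniformly.

Chicken sex chromosomes are handled by expected ploidy: males are ZZ,
females ZW; MT and W are haploid (diploid-style genotypes on those
contigs are tolerated and collapsed to carriage), and W is absent in
males.

## Population contrast

For threshold $t$ and a sex stratum (male, female, or pooled), a variant
is **differential** for population A when it has at least one carrier in
A's stratum samples, no carrier in B's, and carrier fraction
$\ge t/100$ in A's stratum; ties at the threshold are included ("at
least").  The carrier-fraction denominator is the focal population's
stratum size, not the combined cohort.  A variant observed in both
populations is a common candidate and is never differential at any
threshold.  The conventional thresholds are 0/25/50/75/100%; other
values run with a warning.

Two readings of "common" are both reported: *any-carriage* (at least one
carrier on each side) and *strict* (carried by every stratum sample of
both populations, the set selected when the threshold is pushed to
100%).  The strict set is the headline; the any-carriage set is retained
because the two differ sharply at small sample sizes.

Whether thresholds apply within sex strata or across all samples was an
open choice; the default is within-stratum (sexed comparisons are the
primary reporting unit) and the pooled mode is exposed alongside.

Novelty is allele-aware: a record is *known* only if its full
(chrom, pos, ref, alt) key appears in the known-variants VCF; a
different alternate allele at a known position is still novel.

## Coding consequences

A variant is *coding* when its reference span intersects any CDS
interval.  For length-preserving substitutions lying fully inside one
CDS exon, the affected codons of the first overlapping transcript are
translated before and after the edit with the standard genetic code
(minus-strand transcripts are handled by mapping into spliced reading
coordinates and reverse-complementing the allele), giving synonymous,
missense, or nonsense (stop gain).  Everything else in a CDS — indels
(frameshifts), edits spanning exon junctions, stop-codon losses — is
reported as *other*: those consequences are real but not expressible as
a single amino-acid change.  Nonsense is kept as its own class and also
counts toward amino-acid-change totals.  The classifier is verified
against an independent oracle that rebuilds and translates the whole
transcript before and after each edit, on both strands.

## Distribution tests

The variant-type spectrum is compared with an exact Fisher test per
type.  The contingency construction is *type-versus-rest* per
population: $[[n_{v,\mathrm{high}}, n_{\neg v,\mathrm{high}}],
[n_{v,\mathrm{low}}, n_{\neg v,\mathrm{low}}]]$.  The construction used
by the web tool that inspired this analysis is not recoverable, so the
choice is documented and a $k \times 2$ chi-square over the full
spectrum is emitted as well.  The two-sided Fisher p-value uses the
minimum-likelihood convention — the sum of hypergeometric probabilities
not exceeding that of the observed table (with the customary
$1 + 10^{-7}$ tolerance factor) — matching common reference
implementations so results are reproducible elsewhere.

Per-chromosome tests are Pearson chi-square (df = 1) on on-chromosome
versus off-chromosome counts per population, within each
(sex, variant type) cell, with no continuity correction by default (none
is implied by the analysis being emulated; Yates is a toggle).  Cells
with a zero expected count are marked untestable rather than dropped
silently.  Because most cells are expected to be significant in a real
contrast, the condensed report lists the *non-significant* chromosomes
per (sex, type).

Benjamini–Hochberg adjustment is the standard step-up with monotonicity
enforcement, preserving input order; it is cross-checked against
`p.adjust` in the test suite.

## Weir–Cockerham F_ST and the selection scan

Per bi-allelic SNV, the two-population variance components are

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right],$$
$$b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],
\qquad c = \frac{\bar h}{2},$$

with $r = 2$ populations, sample sizes $n_i$, frequencies $p_i$,
observed heterozygote proportions $h_i$, and the usual
$\bar n, n_c, \bar p, s^2, \bar h$; the estimate is
$\hat\theta = a/(a+b+c)$.  Decisions:

- the full three-level form with *observed* heterozygosity is used,
  because the input is diploid genotype calls, not allele counts;
- negative $\hat\theta$ is reported as computed and retained in window
  means (truncation at zero is available but off: truncation biases
  window means upward in low-divergence regions);
- sites monomorphic for the same allele in both populations have
  $a+b+c = 0$ and are flagged undefined, not zero;
- samples whose expected ploidy at the contig is not 2 are excluded, and
  the scan itself excludes Z, W and MT.

Windows are 100 kb with a 50 kb step, constructed per contig at starts
$0, s, 2s, \dots$ while the next step point is still inside the contig;
the final window is truncated at the contig end, and a contig shorter
than the window yields a single truncated window.  The window statistic
is the **unweighted mean** of per-SNV $\hat\theta$ ("average F_ST of the
SNVs in the window"); the ratio-of-sums estimator
$\sum a / \sum (a+b+c)$ is available as an option since it is the other
common convention.  Windows need `min_snvs` (default 1 — no minimum is
implied by the emulated analysis, so none is imposed) defined SNVs to be
ranked.  The top 5% is selected globally across all ranked windows (not
per chromosome; the global rule is the default because the per-chromosome
variant is a trivial stratification of it), taking the
$\lceil 0.05\,n \rceil$ largest means with ties at the cutoff all
included.

Candidate genes are all genes whose span intersects any top window.
Enrichment against a user-supplied gene → term table is the
hypergeometric upper tail $P(X \ge \mathrm{overlap})$ with universe
defaulting to all annotated genes, BH-adjusted across terms, significant
at adjusted $p < 0.01$.

## Variant-density enrichment

Per chromosome, the *standard frequency* is variants per Mb of
chromosome length (lengths from the annotation, not the maximum variant
position).  The chromosome maximising it is selected per stratum, its
cumulative variant curve is emitted, and the densest region is found
algorithmically: among windows of width `target_fraction` × chromosome
length (default 0.2, of the order of the published dense-region examples)
anchored at zero and at every variant position, the window with the most
variants wins, ties to the smallest start.  The original selection of
such regions was done by eye from the cumulative plot; the fixed-width
maximum-count window is this package's deterministic, oracle-checkable
surrogate, not a claim about the original procedure.  Reported
alongside are the exact fraction of variants captured and the fraction
of chromosome length, plus the genes and transcripts intersecting the
region.

## Structure and phenotypes

**Nei's standard distance.**  Allele frequencies per population are
computed from genotype dosages over called alleles; loci fixed for the
same allele in both populations are skipped (they carry no information
and only inflate identity).  Then $J_x, J_y, J_{xy}$ are means over loci
of $\sum_a x_a^2$, $\sum_a y_a^2$, $\sum_a x_a y_a$, and
$D = -\ln\left(J_{xy}/\sqrt{J_xJ_y}\right)$, with an infinite-distance
flag when no alleles are shared.  The published "3 percent" figure for
the motivating study is scale-ambiguous ($D$ versus $1 - I$) and is not
reproduced.

**UPGMA** is average-linkage agglomeration with node heights at half
the join distance, via `hclust` + `ape`; the output is ultrametric, and
tied merges follow `hclust`'s deterministic order.

**MCA** is plain correspondence analysis of the genotype indicator
matrix: masses from row/column sums, SVD of the standardised residuals,
row principal coordinates, inertia shares from squared singular values.
No Benzécri/Greenacre inertia correction is applied (only "MCA" is
specified by the emulated analysis; the correction is a toggle-free
deliberate omission to keep the closed-form total inertia $(K-J)/J$ as a
verifiable invariant, for $J$ SNV blocks and $K$ categories).  Blocks
with missing entries or a single category are dropped with a warning;
axis signs are fixed by making the largest-magnitude coordinate
positive, so results are deterministic up to that convention.  The
genotype subsample for structure analysis (default 10,000 sites) is a
seeded uniform draw of bi-allelic SNVs genotyped in every sample; how
the original per-sample collection of genotypes was pooled is unclear,
so a uniform subset of shared sites is the package's sampler.

**Phenotypes.**  PCA is of the trait correlation matrix (traits are
measured on wildly different scales), so eigenvalues sum to the trait
count.  The discriminant step uses the smallest number of leading
components reaching a cumulative-variance target (default 0.92,
matching the published six-component choice) and a pooled-covariance
linear discriminant.  The default confusion matrix is resubstitution —
the published "put into group / true group" layout is a resubstitution
table — with leave-one-out available; per-group proportion correct is
per *true* group.

## The synthetic study

The generator emulates the study conditions: 10 diploid birds (highland
3 males + 2 females, lowland 2 males + 3 females), autosomes plus Z, W
and MT (16.5 kb), five variant classes, a known-variant subset, CDS
features permitting missense/synonymous calls, a 24-trait phenotype
table for 16 birds (10 lowland / 6 highland, the phenotyping cohort)
and a 5-sample highland replication cohort.  Divergence is
Balding–Nichols: per-population frequencies are Beta-distributed with
mean $p$ (ancestral, uniform on [0.05, 0.95]) and variance
$\theta p(1-p)$ — the simplest generative model whose parameter *is* the
target F_ST.  Defaults are desk-scale and are the conditions under which
the package's checks run: five 1 Mb autosomes, ~1 variant per kb
(~5,000 sites), background $\theta = 0.02$, three planted grid-aligned
100 kb windows at $\theta = 0.5$, 20% of non-sweep sites private to one
population (a quarter of those fixed, providing exact differential
truth), 30% of sites "known", and a 3-standard-deviation shift on 6 of
24 phenotype traits.  A single master seed drives per-stage substreams,
so stages re-run independently and outputs are byte-identical under the
same seed.

What it deliberately does not emulate: linkage disequilibrium and
recombination (sites are independent), coalescent genealogies,
sequencing and genotyping error, read-level data, allele-frequency
spectra of real populations, and transcript isoform complexity.
Passing tests therefore demonstrate correctness of the *computations*
and recovery under the stated generative model — not calibration of the
scan on real, LD-structured genomes.

## Numerical conventions and problem sizes

Fisher/hypergeometric tails are accumulated from `dhyper`/`phyper` with
the standard $1+10^{-7}$ inclusion tolerance; estimator agreement with
enumeration oracles is asserted to $10^{-12}$ (Fisher, hypergeometric,
BH) and $10^{-10}$ (Weir–Cockerham components) in the test suite.  The
routine checks run on the default synthetic study (~5,000 sites, 100
scan windows, 10 samples) and on a reduced two-autosome configuration
for orchestration tests; estimator calibration uses 250 diploids per
population at 400 sites.  These sizes were chosen so the whole suite
exercises every stage at realistic shape while remaining quick on a
laptop.

## Known limitations

- Variant identity is positional; the same underlying indel represented
  two ways in different VCFs will not match (normalisation is out of
  scope).
- Consequence calls report the first overlapping transcript; isoform
  selection beyond that is out of scope.
- With five samples per population, carrier fractions are coarse
  (multiples of 20%), so neighbouring thresholds often coincide.
- The F_ST estimator is computed from detection-level genotypes; sites
  not called in a population are treated as homozygous reference there,
  which at very low coverage would understate minor-allele frequencies.
- Gene-set enrichment is only as good as the supplied annotation table;
  no live ontology services are consulted.
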