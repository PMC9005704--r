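---
title: "Methods: transposable-element insertion polymorphism, selection scans and cis-eQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposable-element insertion polymorphism, selection scans and cis-eQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEpopgen)
```

# Scope and data model

TEpopgen analyses transposable-element (TE) insertion polymorphism across
a cohort of assembled genomes — the setting in which each strain has its
own de novo assembly and TE annotation, and questions about population
frequency, selection and expression effects are asked of the insertions
themselves. The pipeline has five stages:

1. **Orthology transfer** — project each strain's TE annotations onto a
   common reference through their flanking sequences, classify each
   transfer as reliable or unreliable, and cluster reliable transfers of
   the same family into orthologous insertion loci. The central product
   is a `PresenceMatrix`: strains x loci, boolean.
2. **Frequency spectrum** — classify loci into rare (< 10% of genomes),
   common (10–95%, both bounds inclusive) and fixed (> 95%), with
   rarefaction over genome counts and geographic set intersections.
3. **Selection scan** — extended haplotype homozygosity statistics (iHS,
   nSL, iHH12) on phased SNP panels, standardized in ten derived-allele
   frequency bins per chromosome, with significance calibrated on SNPs
   in the 5' ends of small introns.
4. **Candidate screen** — pair significant SNPs with TEs within 1 kb,
   apply carrier co-occurrence rules and the candidate filters
   (frequency 10–95%, recombination > 0, exclusion of the anciently
   abundant INE-1 and LARD families).
5. **cis-eQTL** — associate TE presence with expression of genes whose
   span lies within 1 kb, using a permutation pass with a
   beta-distribution approximation for multiple-testing adjustment.

A synthetic-cohort generator with a complete truth table stands in for a
real 47-genome cohort so that every stage is testable end to end.

# The EHH statistics

For a core SNP and the set of $n_a$ haplotypes carrying a given core
allele, EHH at distance $x$ is the probability that two randomly drawn
carriers are identical at every site from the core out to $x$:
$$\mathrm{EHH}(x) = \frac{\sum_h \binom{c_h}{2}}{\binom{n_a}{2}},$$
where $c_h$ are the sizes of the identical-haplotype classes among the
carriers. The implementation extends site by site with a partition
refinement (classes split and never merge, so each curve is
non-increasing per side); the tests verify every curve against an
$O(n^2 m)$ pair-counting oracle.

* **iHH** is the trapezoidal integral of EHH over distance, each side
  integrated outward up to *and including* the first point with EHH
  below the cutoff (default 0.05, configurable), then summed over the
  two sides. Sites whose curve reaches the chromosome end while still
  above the cutoff are flagged and excluded from standardization.
* **iHS** $= \ln(\mathrm{iHH}_A / \mathrm{iHH}_D)$, ancestral over
  derived. Long haplotypes around a derived allele — an incomplete
  sweep — drive it strongly negative. Integration uses genetic distance
  when the panel carries a map, physical distance otherwise.
* **nSL** replaces map distance with numbers of segregating sites: for
  each carrier pair, $L$ is the site count of the maximal interval
  around the core over which the pair is identical (the core counts as
  one site); $\mathrm{SL}$ is the mean of $L$ over pairs, and
  $\mathrm{nSL} = \ln(\mathrm{SL}_A/\mathrm{SL}_D)$. It is computed via
  the identity $\mathrm{SL} = 1 + \sum_k \mathrm{EHH}(k)$ summed over
  site steps on both sides, with no cutoff, which the tests check
  against direct pair enumeration.
* **iHH12** integrates EHH12, computed over *all* haplotypes with the
  two largest extended-haplotype classes pooled before pair counting —
  the pooling is what gives power against soft sweeps with two swept
  haplotypes.

**Standardization.** Unstandardized values are z-scored within ten
equal-width derived-frequency bins per chromosome, using the sample
standard deviation; bins with fewer than two values (or zero spread)
leave their sites unstandardizable. **Significance** is calibrated on
SNPs at offsets 8–30 bp (1-based, transcribed strand) of introns of at
most 65 bp — a class of sites evolving close to neutrally. Per
statistic, the threshold is the 95th percentile (linear interpolation
between order statistics) of the neutral standardized values; sites
strictly above it are flagged. iHS and nSL are thresholded on $|z|$
(sweeps push either tail depending on polarity), iHH12 on $z$; both
choices are switchable. Ancestral alleles default to the VCF REF, with
the caveat that mispolarized sites flip the sign of iHS/nSL — another
reason the $|z|$ convention is the default.

# Orthology transfer

Flanks of `flankBp` (default 1000 bp) are extracted on each side of an
insertion and placed on the reference. The internal placement mode does
full-length matching (exact by default — appropriate for assemblies that
derive from the reference; a percent-identity allowance is available for
diverged genomes), falling back to the TE-proximal half of a flank,
whose hits are classified *partial*. Each flank is unequivocal /
multiple / partial / unmapped; discordant orientations between two
unequivocal flanks demote both to multiple. Users with diverged real
assemblies can instead supply PAF alignments from a long-read aligner.

A transfer is **reliable** when both flanks are unequivocal, concordant,
on one chromosome, and the reference gap between them is either 0–50 bp
(insertion absent from the reference; the projected interval is the gap,
zero-length allowed) or within 50 bp of the TE length (insertion present
in the reference). A single multiple-mapping flank is rescued when its
placement nearest the other flank shares the same nearest gene on strain
and reference — the synteny anchor. Everything else is unreliable with a
recorded reason; counts are conserved (records in = reliable +
unreliable).

Reliable transfers cluster into ortholog groups by family-aware
single-linkage on interval midpoints within 100 bp (configurable). Two
same-strain members in one group keep the nearer one and flag the other
as tandem. Group ids are minted `chrom_start_end_family` from the modal
projected interval. Groups in which at most half the members exceed
120 bp are dropped (the length-majority filter, strict "more than
half"), and raw annotations can be pre-filtered (copies under 100 bp;
copies more than 80% under satellite annotation).

# Frequency classes and rarefaction

Class boundaries are compared on *counts*, not floats: present in $k$ of
$n$ genomes is rare iff $100k < 10n$, fixed iff $100k > 95n$ — so 95%
exactly is common and 19/20 never misclassifies through floating-point
representation. Rarefaction draws 30 random subsets (configurable, or
exhaustive enumeration when $\binom{N}{k}$ is small) per genome count
$k$; frequencies use the sampled $k$ as denominator and insertions
absent from every sampled strain are unobservable at that $k$ and not
counted. At $k = N$ the classification equals the full-cohort one with
zero SD by construction.

# The candidate screen

Significant SNPs pair with TEs at a minimum gap strictly below 1 kb
(distance 0 inside the TE). The carrier co-occurrence rule follows the
printed thresholds: TEs present in 5–6 strains need at least 4 strains
carrying both the swept allele and the TE; TEs in 7 or more need a
strict majority; and in all cases the TE must be absent from 100% of
strains lacking the swept allele. The tallies keep "strain has TE and
allele" separate from "strain entirely without the allele but with the
TE" because under phased diploids a strain can carry the swept allele on
a haplotype other than the TE's; under the haploid-per-strain default
the absence clause effectively requires the TE carriers to be a subset
of the allele carriers. The swept allele at a flagged site is the
derived allele when the standardized iHS/nSL is negative, the ancestral
when positive, and for iHH12 the allele with the larger integrated EHH.

The candidate pool keeps groups at frequency 10–95% (inclusive, exact
count comparisons), in windows of strictly positive recombination, and
outside the INE-1 and LARD families, which are old enough to have
drifted to high frequency neutrally. Each group is attributed to the
first filter that removes it (frequency, then recombination, then
family), so the audit sums to the input count.

# cis-eQTL with beta-approximated permutation p-values

Genes pair with TEs intersecting the gene span extended by 1 kb (the
window anchors on the span, not the TSS, because associations are
sought around the whole gene, introns included). The nominal pass
residualizes expression and genotype on covariates (by default the
first two principal components of the presence matrix, a stand-in for
population structure; meaningful only when the presence matrix is
genome-wide — with a handful of loci the PCs collapse onto the
genotypes themselves, and structure adjustment should be disabled or
supplied externally), then computes the Pearson correlation and its
exact t-transform p-value with covariate-adjusted degrees of freedom.

The permutation pass shuffles expression across strains, records the
smallest nominal p over the gene's cis TEs per permutation, fits a
Beta($a$,$b$) to the minima by maximum likelihood (method-of-moments
start; moments fallback on optimizer failure; empirical rank p with a
warning if even that degenerates), and reports the fitted Beta CDF at
the observed best p as the adjusted p. Ties at the best nominal p (for
example two TEs with identical presence vectors) are all reported as
top variants. Fewer than 100 permutations are refused — the fit is
unstable there. The production default is 100,000 permutations; the
package's tests and acceptance checks use 200–1000, which is where the
Monte-Carlo error of the fit, not the method, limits resolution.
Significant associations require adjusted p strictly below 0.05 and a
TE in positive recombination.

# What the synthetic generator emulates — and what it does not

`simulateCohort()` plants TE insertions (verbatim family-consensus
copies) into a random reference at loci spaced at least two flank
lengths apart, with per-strain presence drawn from target frequencies
spanning a rare-heavy spectrum; strain genomes are rebuilt by actual
sequence insertion so that strain coordinates shift exactly as real
assemblies would. `simulateHaplotypes()` uses a founder-mosaic model:
founder haplotypes carry derived alleles at 1/k-spectrum frequencies,
sampled haplotypes are founder mosaics with geometric breakpoints, and
private mutations are sprinkled on top — enough LD structure for EHH
statistics with zero heavy dependencies (a coalescent backend could be
plugged in). `plantSweep()` copies a donor haplotype onto the chosen
carriers over per-carrier geometric tracts, directly producing the long
shared haplotypes the statistics detect.

Defaults are the cohort conditions the package targets: 47 strains
(the frequency-spectrum arm), 46–40 haplotypes for the selection arm, a
60% carrier fraction for the planted incomplete sweep, a 1 Mb region
with 500 SNPs. The sweep tract scale defaults to 50 kb per side: a
realistic footprint for a recent incomplete sweep under Drosophila-like
recombination, which also keeps the large majority of the simulated
region neutral — important because the frequency-bin standardization
assumes a mostly neutral background, and a sweep occupying half the
region would be absorbed into its own bin's mean. Chromosome and locus
counts are scaled so that complete cohorts simulate in about a second
(the test suite runs 30-seed replicates of several stages).

What the generator does **not** emulate: realistic demography or
selection-drift forward dynamics, sequencing error and assembly
artifacts, truncated or internally deleted TE copies, nested
insertions, reference-genome annotation errors, and linkage between TE
presence and the SNP background beyond the explicitly planted sweep.
Passing tests therefore demonstrate the correctness of the algorithms
under clean conditions, not robustness to the full messiness of real
assemblies.

# Numerical and design choices

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7); standard deviations are sample ($n-1$).
* EHH truncation keeps the first sub-cutoff point inside the integral;
  the cutoff (0.05) and the rule are configurable.
* Exact count comparisons at every percent boundary (10%, 95%).
* The co-occurrence "majority" for 7+ carriers is strictly more than
  half; at the 5–6 domain the threshold is the printed "at least 4".
* Beta fit: L-BFGS-B on the log-likelihood with a small positive lower
  bound; permutation minima are clamped away from 0/1 by 1e-12.
* Ortholog-group representative interval: the modal (start, end) pair,
  smallest on ties — deterministic and order-independent (tests permute
  input order).
* Strain metadata in the generator assigns two synthetic continents
  round-robin, exercising the geographic intersection logic.
* Haploid-per-strain is the default genotype interpretation (inbred /
  isofemale consensus genomes); the VCF reader and co-occurrence
  tallies handle phased diploids, in which case a strain carries an
  allele when either haplotype does.

# Known limitations

* The internal flank placement is exact-match based; diverged real
  assemblies should come with external PAF alignments.
* iHS/nSL polarity depends on correct ancestral-allele assignment; REF
  is a convention, not an inference.
* The founder-mosaic haplotype model has no calibrated relationship
  between its recombination parameter and cM; panels carrying a real
  genetic map integrate in cM, simulated panels in bp.
* With few loci, presence-matrix PCs are not a usable population
  structure proxy (see the eQTL section).
* Rarefaction SDs at small replicate counts (the default 30) are noisy;
  the exhaustive mode is exact but limited to small cohorts.
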