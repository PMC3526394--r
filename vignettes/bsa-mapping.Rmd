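---
title: "Mapping recessive mutations by pooled-exome bulk segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive mutations by pooled-exome bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The mapping problem

A recessive mutation recovered in a forward-genetic screen must be located
in the genome before its gene can be identified. Bulk segregant analysis
(BSA) does this with two pooled DNA samples instead of hundreds of
individual genotypings. A carrier of the mutagenized strain (alleles
labelled *N*) is crossed to a divergent mapcross strain; F1 carriers, both
N/mapcross heterozygotes, are intercrossed; and the progeny are sorted by
phenotype into a mutant bulk (all N-homozygous at the causal locus) and a
wildtype bulk. When both bulks are sequenced as pools — here, exome capture
over an assembly that may be fragmented — every informative marker tells
the same story:

* unlinked markers are heterozygous in both pools (N-allele frequency 1/2);
* markers linked to the mutation lose heterozygosity in the mutant pool:
  at recombination fraction $\theta$ from the locus, the expected
  mapcross-allele frequency among mutant-pool chromosomes is just
  $\theta$, because each chromosome was transmitted through one meiosis
  conditioned to carry N at the locus;
* the wildtype pool stays close to balanced. Conditioned on not being
  mutant, causal-locus genotypes occur 2:1 het : mapcross-homozygous, so
  the expected N-allele frequency at the locus itself is 1/3, relaxing to
  1/2 with distance as $\tfrac13 + \tfrac{\theta}{3}$.

The package's scan statistic aggregates this signal per region as the
homozygosity ratio $r = n_h / n_t$: the fraction of putative SNPs in the
region that look homozygous in the mutant pool. Near the causal locus $r$
approaches 1; elsewhere it stays near the small false-homozygosity rate of
pooled sampling at finite depth.

## From pileup to SNP calls

Inputs are two samtools pileup text files (6-column dialect: scaffold,
1-based position, reference base, depth, encoded base calls, base
qualities), one per pool, aligned to the same reference. The parser decodes
the base-string grammar to per-base counts: strand case is merged (the
calling criteria use total allele fractions, with no strand term), base
qualities are ignored (quality trimming is assumed upstream), and deletion
stars, reference skips and N calls are counted as *skipped* — they never
enter an allele-fraction denominator, since the method analyzes
substitution SNPs only. If a record's decoded symbols disagree with its
depth column the decoded counts win and the discrepancy is reported as a
warning, which tolerates the rare malformed records real pileups contain.
The two files are inner-joined by (scaffold, position): a position covered
in only one pool can never meet the joint depth requirement.

Calling applies three rules, all at their stated boundaries inclusive:

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10 reads | required in **each** pool |
| `wt_maf_lo`, `wt_maf_hi` | 0.50, 0.75 | wildtype-pool MAF band marking a heterozygous site |
| `hom_threshold` | 0.90 | mutant-pool MAF at/above which the site is homozygous |

A site is a putative SNP when (i) the wildtype MAF lies in the band, **or**
(ii) the two pools' major alleles differ — a pure OR, with the satisfied
criterion recorded per call. The band's upper bound excludes sites where
the wildtype pool itself looks skewed (possible paralogy or reference
bias); criterion (ii) rescues strongly informative sites whose wildtype
MAF drifted outside the band by sampling noise. Major-allele ties are
broken in fixed A<C<G<T order so calls are deterministic; tied sites are
flagged, since the tie-break can make criterion (ii) hold asymmetrically.
The reference base plays no role in calling and is only carried into the
VCF export.

## The windowed LOH scan

Regions are whole scaffolds up to the `long_scaffold_cutoff` (default: the
window size) and consecutive non-overlapping 0.5 Mb windows beyond it —
per-scaffold scoring suits fragmented assemblies, windows suit
chromosome-scale ones. The final short remainder window is retained and
subject to the same filter. Regions with fewer than 20 SNPs are excluded
(`min_region_snps`; exactly 20 is kept): with roughly one informative
marker per 10 kb, a 0.5 Mb window far below 20 SNPs indicates poor capture
or alignment, where a handful of false calls could fake a peak. The
excluded genome fraction is reported so users can verify the filter costs
little territory. Ranking is by ratio descending, ties by $n_t$ descending
and then coordinates — the tie-breaks are a determinism decision, not a
statistical claim (see below).

## What the scan can and cannot localize

With $n$ embryos per bulk there are $2n$ informative meioses. At the
package's standard scale (50 embryos, 1.2 cM/Mb), $\theta$ across an
entire 2 Mb scaffold is at most ~0.024, so the expected number of
recombinant chromosomes between the locus and *any* marker on its scaffold
is a handful out of 100 — and at depth 30 a marker needs roughly four
non-major reads before it drops below the 0.90 homozygosity threshold.
Consequently every window on the causal scaffold tends to attain $r = 1$
exactly: the scan saturates, and which of the tied windows ranks first is
decided by the marker-count tie-break, i.e. by Poisson noise in how many
markers each window happens to hold. The package therefore treats
**scaffold-level** localization as the scan's deliverable at this scale
(the top-ranked region lands on the causal scaffold in every test
replicate), while **window-level** resolution requires more meioses —
that is precisely why fine mapping on large embryo panels (hundreds of
embryos, RFLP genotyping of individuals) follows the scan rather than
being replaced by it. The acceptance suite keeps an explicit check of
window-exact top ranking at 50 + 50 embryos; it fails by design of the
experiment, and this section is the analysis of why.

## Fine mapping support

**CAPS/RFLP markers.** For a candidate SNP with flanking sequence, the
package reports every restriction enzyme whose recognition site is present
in exactly one allele's flank. Matching is IUPAC-aware; non-palindromic
sites are also searched as their reverse complement, reported in
given-strand coordinates; palindromes count once per position. Each
emitted site must span the SNP — anything else would cut both alleles.
Fragment lengths come from digesting each allele's flank at *all* of its
sites, constitutive ones included, so the reported patterns are what a gel
shows; their sums always equal the flank length. When an enzyme's cleavage
offset is unknown the site midpoint is used — fragment lengths are for
resolvability triage, not precise digests. A differential site closer than
`end_margin` (default 50 bp) to a flank end is flagged as impractical for
a 100–250 bp amplicon. Primer design itself is out of scope.

**Genetic distance.** Distance is the direct recombination-fraction
estimate $100 \cdot \text{recombinants} / \text{meioses}$ cM with two
informative meioses per embryo; no map function is applied because at the
sub-cM distances of fine mapping the correction is far below counting
error. From genotype tables, recombinants are counted per chromosome
(het = 1, mapcross-homozygote = 2), which matches the meiosis denominator;
at sub-cM distances double recombinants are vanishingly rare and this
coincides with counting non-N-homozygous embryos.

**Misassembly flag.** A single recessive locus cannot produce saturated
LOH on two scaffolds; if non-excluded regions reach the threshold ratio
(default 0.9) on more than one scaffold, the flag lists them. The
threshold is configurable; 0.9 keeps the flag insensitive to the one or
two stray homozygous-looking windows that finite depth can produce while
still catching a relocated linked block, whose windows saturate.

## The simulator

`sim_config()` describes the whole experiment; its defaults are the
package's standard study: 10 scaffolds of 2 Mb, markers at mean 10 kb
spacing (exponential gaps — capture targets are irregular), causal locus
at the midpoint of scaffold `s05`, 50 embryos per bulk, Poisson mean depth
30, per-base miscall rate 0.002, and map density 1.2 cM/Mb — bulk sizes,
depth and marker density chosen as typical of a pooled exome-capture
mapping experiment in a diploid vertebrate, and small enough that a full
20-replicate recovery study runs in seconds.

Meiosis is a sequential Markov walk per scaffold: the first marker's
parental origin is a fair coin and adjacent origins switch with Haldane
probability $\theta = \tfrac12(1 - e^{-2m})$, $m$ the inter-marker map
distance in Morgans. Haldane (no interference) was chosen for its closed
form, which the tests compare against directly. Embryos are two
independent gametes; rejection sampling fills the mutant bulk with
N-homozygotes at the causal marker and the wildtype bulk with the rest,
reproducing the 2:1 conditional composition noted above. The truth table
carries *analytic* expected allele frequencies for every marker
($1-\theta$ mutant pool, $\tfrac13 + \tfrac{\theta}{3}$ wildtype pool), so
tests compare simulation to closed form rather than to hard-coded numbers.
Sequencing draws Poisson depth per marker per pool, samples chromosomes
uniformly, and miscalls each read to a uniform other base with the error
rate. Output goes through the package's own pileup writer, so simulated
data exercise the same parser users run.

An optional fixture re-addresses a marker block to another scaffold,
displacing the native markers of the landing interval — modelling an
assembly that placed that sequence on the wrong scaffold — with genotypes
untouched. This is what the misassembly-flag tests run against.

Deliberate simplifications: no mapping bias, duplicates, indels, capture
efficiency variation or read-level artifacts; equal DNA contribution per
embryo; uniform miscalls. Passing tests therefore validate the calling and
scanning logic and the meiotic statistics, not robustness to alignment
artifacts in real libraries. One seed governs all randomness; identical
configs reproduce outputs byte-for-byte.

## Numerical and interface decisions

* Coordinates are 1-based inclusive throughout, converting to 0-based
  half-open only in BED export.
* All threshold comparisons are inclusive at their printed values (band
  ends, homozygosity 0.90, the 20-SNP filter keeping exactly 20).
* Zero-depth regions have an undefined ratio (never 0/0 = 0) and are
  excluded by the SNP-count filter.
* The classic 6-column pileup subset is parsed; the mpileup multi-sample
  dialect is out of scope, and the two pools arrive as two files.
* Degenerate inputs: empty pileups produce empty outputs and a zero exit
  through the command interface; unsorted or duplicated positions are
  errors naming the offending record; an all-zero count vector is an error
  at the `major_allele()` level because callers must gate on depth first.

## Scale of the shipped experiments

The test suite and the acceptance script run the standard study (20
replicates, plus 20 with the relocation fixture), the caller against a
brute-force criterion oracle on 10,000 randomized sites, and a 10,000-site
pileup round-trip — sizes chosen so the full suite completes in about a
minute on one core while leaving the statistical assertions three-standard-
error headroom.

## Limitations

Indels and multi-allelic sites are not called; likelihood-based genotyping
is out of scope (the criteria are deliberately the simple, auditable
fraction rules); LOH peaks are ranked, not assigned significance; and a
second segregating mutant allele at the same locus — which depresses
homozygosity ratios in real crosses — is not modelled by the simulator.
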