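---
title: "Multi-platform de novo mutation inference in trios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-platform de novo mutation inference in trios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmtrio)
library(data.table)
```

# The problem

A de novo mutation (DNM) is a variant present in a child and absent from
both parents. In families sequenced on multiple platforms — PacBio HiFi and
Oxford Nanopore (ONT) long reads plus Illumina short reads — long reads make
two things possible that short reads cannot do reliably: assigning almost
every DNM to a parental haplotype with nearby informative SNPs, and
distinguishing *germline* mutations (inherited from a parental gamete,
present on every read of the haplotype of origin) from *postzygotic*
mutations (PZMs, arising after fertilization and present on only a fraction
of reads from one haplotype — effectively a third haplotype).

`dnmtrio` implements that inference end to end: candidate selection from
trio genotypes, a tri-platform read-validation cascade, inheritance-score
phasing, germline/postzygotic classification, callable-genome mutation-rate
estimation with exact Poisson intervals, and mutation-spectrum, clustering
and parental-age statistics. Because real multi-platform family data are
controlled-access, the package also ships a synthetic cohort generator
whose defaults encode the cohort-level parameters of a published
73-child, 42-family study; every stage is tested against that generator's
ground truth.

# The validation cascade

Candidates are sites where both parents are genotyped `0/0`, the child
carries an alternate allele, and the child's genotype quality is at least
20. The subsequent filters are all pure predicates, so their order cannot
change the result:

* **Cluster filter.** Any SNV in a 1-kbp window containing three or more
  candidate SNVs of the same child is excluded — such runs are the
  signature of a haplotype dropped by the caller in one parent, which makes
  every inherited het on that haplotype look de novo.
* **Read partition.** Long reads below MAPQ 59 are excluded (short reads
  are never MAPQ-filtered). Bases above Q20 are *high quality*, Q10–Q20
  *low quality*, and below Q10 discarded.
* **Per-platform verdicts.** On HiFi and Illumina a parent passes with zero
  high-quality and at most one low-quality read carrying the de novo
  allele; ONT, being noisier, tolerates one and two. The child needs at
  least one retained allele-carrying read. A variant is *inherited* if any
  platform says so, *validated* if at least two platforms independently
  support it. Children with only cell-line HiFi must instead show elevated
  (≥ 2 high-quality) Illumina blood support.
* **Recurrence.** The de novo allele must be unique to the child: one
  high-quality HiFi read in any unrelated sample kills the candidate
  (inside tandem repeats, one unrelated carrier is tolerated). This removes
  recurrent sequencing errors and under-called segregating alleles.
* **Allele-balance floors** for repeat annotations (mean AB > 0.05 in TRs;
  ≥ 0.1 for RepeatMasker + TR; ≥ 0.08 for RepeatMasker alone) and a
  **homopolymer filter** that removes variants in or within 1 bp of runs of
  ≥ 4 bp when the reference or alternate allele equals the run base.
* **Indels** (tandem-repeat indels are excluded outright) require reads at
  MAPQ 60 spanning the site with ≥ 10 bp flanks; any parental or sibling
  supporting read marks them inherited, and validation requires the allele
  in both HiFi and Illumina. Sites with more than two distinct spurious
  alleles across the trio's reads are failed — a programmatic proxy for the
  visual curation the original analysis performed.
* **Sex chromosomes.** Female X uses the autosomal rules; male X/Y compare
  against the orthogonal parent only and require AB = 1, which also means
  PZMs cannot be called there.

# Phasing and classification

For each DNM we collect informative SNPs in an 80-kbp centered window —
sites where one parent is `0/0`, the other carries an alternate allele and
the child is `0/1`, so the child's alternate allele has a forced origin.
Each child blood-HiFi read receives an *inheritance score*: tags of −1
(paternal) or +1 (maternal) per observed SNP, averaged with weights
$w_i = 1/d_i$, the inverse distance to the DNM ($1/d^2$ is available as an
option; the default follows the plain inverse weighting). Negative scores
mean paternal. If every allele-carrying read lands on one haplotype, that
parent is the origin; alleles on both haplotypes are a conflict. ONT reads,
scored identically, phase variants HiFi could not; HiFi wins disagreements;
variants that conflict in both platforms are discarded as presumed error.

Classification combines three signals per variant:

1. **Haplotype composition** per long-read platform on the assigned
   haplotype: ≥ 2 reference reads alongside ≥ 1 alternate read ⇒
   postzygotic; ≥ 1 alternate with zero reference ⇒ germline; otherwise
   ambiguous.
2. **AB concordance** across platforms: a chi-squared test on the
   platform × (alt, ref) table (zero-coverage platforms dropped; the Yates
   correction applies to 2×2 tables, matching the common contingency-test
   implementation).
3. **Pooled binomial test**: if concordant, the one-sided exact probability
   $P(X \le k \mid n, 0.5)$; significantly low AB predicts postzygotic.

Resolution precedence: agreeing unambiguous HiFi and ONT verdicts win;
disagreements defer to the AB prediction; double-ambiguity uses the AB
prediction; with nothing evaluable the variant defaults to germline. Both
significance thresholds default to α = 0.05 (unstated in the source
analysis; configurable). Indels use a looser rule — postzygotic only when
more than three haplotype reads carry a different allele — because indel
alignment noise makes germline indels look mosaic.

# Rates

A site is callable when both parents are `0/0` and all trio members have at
least one MAPQ ≥ 59 HiFi read with a base ≥ Q20 (child restricted to blood;
male X/Y consult only the orthogonal parent). Rates divide counts by
ploidy × callable bp (ploidy 2 on autosomes, 1 per parental haplotype for
parent-specific rates); intervals are exact Poisson (Garwood) — the
interval method is unstated in the source, and the exact interval is the
conservative default choice. Region-stratified rates intersect both
variants and masks with annotation tracks; strata are compared to the
genome-wide rate with one-sample t-tests on per-sample differences,
Benjamini–Hochberg corrected. (Whether the original per-region tests were
paired is not stated; the paired difference form was chosen because
per-sample callable space varies.)

# What the generator emulates

The generator's defaults *are* the published cohort's stated world:

| parameter | default | meaning |
|---|---|---|
| `germline_rate` | 1.30e-8 | substitutions/bp/generation |
| `pzm_rate` | 2.30e-9 | postzygotic substitutions/bp/generation |
| `paternal_fraction` | 0.799 | 3.98:1 paternal bias (PZMs: 1.15:1) |
| `paternal_age_slope` | 1.32/yr | extra germline DNMs per year of father's age |
| `maternal_age_slope` | 0.46/yr | same for mother |
| `germline_ab_mean` | 0.48 | mean sampled allele balance of a het |
| `mosaic_ab_mean` | 0.22 | mean allele balance of PZMs |
| `snp_density` | 1/1200 bp | informative SNPs |
| parental ages | N(31.4, 5), ≥ 18 | age at birth |
| depths | 30×/30×/40× | HiFi/ONT/Illumina (not published; typical values) |

Design choices worth knowing:

* **Parent-specific Poisson counts.** Each child's paternal and maternal
  germline counts are separate Poissons whose means split the genome-wide
  expectation by `paternal_fraction` and add the respective age slope.
  A single thinned Poisson could reproduce the paternal share *or* the
  parent-specific slopes, not both.
* **Slope scaling.** Age slopes are defined per 2.66-Gbp callable diploid
  genome and scaled by `genome_length / 2.66e9`, so scaled-down simulations
  keep the per-bp age effect without the slope swamping the base count.
* **Reference bias as biased haplotype sampling.** A het child's reads come
  from the mutant haplotype with probability 0.48, so the mean AB is 0.48
  while the mutant haplotype remains free of reference reads — germline
  DNMs must look germline to the haplotype classifier. Mosaics sample
  haplotypes evenly; mutant-haplotype reads carry the allele with
  probability equal to the cell fraction, drawn from a Beta with mean
  2 × 0.22 and concentration 8 (dispersion unpublished; implementer's
  choice).
* **Quality-calibrated errors.** Erroneous base calls draw their quality
  from a low distribution (mean Q12) — that is what calibration means — and
  substitution errors hit one of the three other bases uniformly. This is
  the property that makes the strict parental ceilings and the recurrence
  filter workable, exactly as on real data.
* **Normalized region multipliers.** Track multipliers reshape *where*
  mutations land without changing the genome-wide expectation, so the
  track/complement density ratio equals the multiplier and rate recovery
  stays unbiased. The homopolymer track carries multiplier 0: the pipeline
  removes homopolymer-subunit variants by design (the published rate is a
  lower bound partly for this reason), so placing true variants there would
  build an irrecoverable bias into every rate test.
* **Abstract coordinates.** There is no nucleotide sequence: sites carry
  reference/alternate bases and 5′/3′ context labels (with an
  origin-specific CpG probability for C>T, encoding the postzygotic CpG
  depletion), and reads carry allele calls, qualities and covered-SNP
  observations rather than sequence. FASTQ-level simulation is explicitly
  out of scope.
* **Artifacts.** Dropped-haplotype runs are genuine inherited hets — the
  child and one parent carry the allele while the genotypes claim `0/0` —
  injected as 3–5 sites within 1 kbp; recurrent errors appear as
  low-fraction alleles in the index child plus high-quality HiFi error
  reads in two unrelated samples. The cluster and recurrence filters,
  respectively, are expected to remove every one of them, and tests assert
  that they do.

What a green test does **not** establish: the generator has no alignment
artifacts beyond these two classes, no mapping ambiguity in repeats, no
platform-specific context errors, no somatic (post-embryonic) mutations,
no sequence-level homopolymer noise. Sensitivity and specificity on this
synthetic world are therefore upper bounds on real-data performance; the
filter *logic*, the phasing algebra, the classification tests and the rate
arithmetic are what is actually being verified.

A deliberate consequence of simulating the published *truth* rates: the
pipeline's measured postzygotic rate sits a few percent below the
generating 2.30e-9, because the lowest-fraction mosaics are genuinely
undetectable at 30–40× depth and the highest-fraction ones are
indistinguishable from germline — the same selection the original analysis
was subject to. We report the measured value rather than tuning the
generator to hide the selection.

# Numerical choices and degenerate inputs

* Binomial and chi-squared tests use `stats::pbinom` / `stats::chisq.test`;
  the exact binomial p matches direct pmf summation to 1e-12 (tested to
  n = 50).
* A read score of exactly 0 (balanced tags) leaves the read unassigned —
  no random tie-break, determinism matters more than a marginal read.
* Distances for SNP weights are floored at 1 bp; distances between
  clustered variants are differences of 1-based positions ("immediately
  adjacent" = 1). Multinucleotide-mutation chains are transitive (a–b and
  b–c merge even if a–c > 500 bp); pairwise distances are also emitted
  because the source analysis reasons about pairs. Assembly-based MnM
  validation is replaced by the synthetic truth table and is out of scope
  for real data, as is the interlocus-gene-conversion candidate scan
  (requires parental assemblies).
* Zero-coverage platforms are dropped before the concordance test; fewer
  than two covered platforms makes AB not evaluable, and a not-evaluable
  AB with no haplotype signal defaults to germline.
* Empty cohorts, zero-length genomes, zero depths, and all-zero paired
  counts (Wilcoxon p = 1) all return well-formed empty results rather than
  errors; the only hard errors are structural (unknown platform, chrY
  candidates in females, zero callable denominators, degenerate regression
  designs).

# Known limitations

Sensitivity/specificity claims transfer to real data only insofar as the
read model does; recurrence filtering assumes independent errors, while
real recurrent artifacts are systematic; the generator's male/female sex
chromosomes are not simulated (the sex-chromosome rules are covered by
constructed-evidence tests); and visual-curation steps of the original
analysis are approximated by explicit thresholds. All thresholds live in
`filter_params()` and all generator knobs in `sim_config()`.
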