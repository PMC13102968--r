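# dnmtrio

De novo mutation (DNM) inference in sequenced parent–child families from
multi-platform read evidence, in R.

## What it does, and for whom

For genomicists studying germline mutation, `dnmtrio` implements the full
long-read-era DNM workflow on trio cohorts sequenced with PacBio HiFi,
Oxford Nanopore (ONT) and Illumina:

* **Discovery & validation** — candidates are sites with parents `0/0`,
  child carrying an alternate allele, child GQ ≥ 20, pushed through a
  filter cascade: a 1-kbp/3-SNV cluster filter (dropped parental
  haplotypes), tri-platform read validation (a parent may show at most
  0 high-quality / 1 low-quality reads with the allele on HiFi/Illumina,
  1/2 on ONT; two supporting platforms validate, one inherited-looking
  platform rejects), a cohort-wide recurrence filter (the allele must be
  unique to the child), allele-balance floors in repeats, and a
  homopolymer-subunit filter. Indels additionally require MAPQ-60 reads
  with 10-bp flanks and child support in both HiFi and Illumina.
* **Phasing** — each child read gets an inheritance score: ±1 tags from
  informative SNPs in an 80-kbp window (sites where trio genotypes force
  the parental origin), averaged with inverse-distance weights
  `w = 1/d`. Negative = paternal. ONT backs up HiFi; conflicts in both
  platforms discard the variant.
* **Germline vs postzygotic classification** — a germline DNM is on *all*
  reads of its parental haplotype; a postzygotic mutation (PZM) shows
  ≥ 2 reference + ≥ 1 alternate reads there (a third haplotype).
  Platform disagreements are resolved by an allele-balance prediction:
  chi-squared concordance across platforms, then a one-sided exact
  binomial test of pooled AB < 0.5.
* **Rates** — callable sites (parents `0/0`, every trio member ≥ 1
  MAPQ-59+/Q20+ HiFi read) give the denominator; rate = count /
  (2 × callable bp) with exact Poisson 95% intervals; region-stratified
  and parent-specific (per-haplotype) rates with BH-corrected t-tests.
* **Statistics** — purine-collapsed dinucleotide spectra with per-category
  chi-squared enrichment (BH), Ti/Tv, multinucleotide-mutation clusters
  (pairs within 500 bp), parental-age regressions, Wilcoxon/Z paternal-bias
  tests.

Real multi-platform trio data are controlled-access, so the package ships a
**synthetic cohort generator** (`simulate_cohort()`) whose defaults encode
the published cohort world: germline rate 1.30×10⁻⁸ and PZM rate
2.30×10⁻⁹ per bp per generation, 3.98:1 paternal bias, age slopes
1.32/0.46 DNMs/yr, allele-balance means 0.48 (germline) and 0.22 (mosaic),
informative SNPs every ~1200 bp, plus injected dropped-haplotype runs and
recurrent errors for the filters to catch. See the methods vignette
(`vignettes/dnmtrio-methods.Rmd`) for the model and its limits.

## Worked example

```r
library(dnmtrio)

cfg <- sim_config(n_families = 10, quad_fraction = 0.5,
                  genome_length = 2e7, seed = 42)
b   <- simulate_cohort(cfg)        # pedigree, VCF-style genotypes, reads,
                                   # informative SNPs, tracks, truth
run <- run_cohort_pipeline(b)      # validate -> phase -> classify -> rates
s   <- run$summary
```

With this (small) configuration the run prints:

```
children 15 | validated SNVs 16 (1.1/child) | PZM 1 (6.2%)
germline rate 2.5e-08 (CI 1.4e-08-4.12e-08) | PZM rate 1.67e-09
paternal:maternal 4.00 | phased 100.0% | AB germ 0.50 / PZM 0.30 | Ti/Tv 1.14
```

Reading this: 16 SNVs survived the cascade across 15 children (a 20-Mbp
genome holds few DNMs, hence the wide Poisson interval around the
2.5×10⁻⁸ estimate — the generating rate 1.3×10⁻⁸ is inside it); one
variant was classified postzygotic from its haplotype composition; all
phased variants split 4:1 paternal:maternal, matching the configured
0.799 paternal fraction. At full cohort scale (73 children, many
replicates) the estimates concentrate on the generating values — that is
what `scripts/acceptance.R` measures. Ground truth checks:

```r
compare_to_truth(run, b$truth, cfg)   # sensitivity, confusion matrix,
                                      # phasing accuracy, rate bias
```

A CLI wrapping simulate/validate/run-all/compare-truth is installed at
`system.file("cli", "dnmpipe", package = "dnmtrio")`.

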