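#' Simulation configuration for synthetic trio cohorts
#'
#' Builds the configuration object consumed by [simulate_cohort()] and its
#' component generators. Defaults encode the cohort-level parameters of a
#' large multi-platform family study of de novo mutation: a germline
#' substitution rate of 1.30e-8 per bp per generation, a postzygotic (PZM)
#' rate of 2.30e-9, a paternal fraction of 0.799 among germline mutations
#' (3.98:1 paternal:maternal), parental-age effects of 1.32 (paternal) and
#' 0.46 (maternal) additional DNMs per year on a 2.66-Gbp diploid callable
#' genome, a mean sampled allele balance of 0.48 for constitutional
#' heterozygotes, a mean mosaic allele balance of 0.22, and informative-SNP
#' density of 1/1200 bp.
#'
#' Parental-age slopes are expressed per year on the reference diploid
#' callable genome (`age_slope_reference_bp`, 2.66e9 bp); when a smaller
#' synthetic genome is simulated the slopes are scaled proportionally so
#' that the per-bp age effect is preserved.
#'
#' @param n_families Number of families.
#' @param quad_fraction Fraction of families with two children (quads);
#'   the remainder are trios. The default reproduces 31 quads + 11 trios.
#' @param genome_length Length in bp of each synthetic chromosome. The
#'   default equals the mean callable autosomal genome (2.66 Gbp); scale it
#'   down for tractable simulations.
#' @param n_chromosomes Number of synthetic chromosomes.
#' @param germline_rate Germline substitutions/bp/generation.
#' @param pzm_rate Postzygotic substitutions/bp/generation.
#' @param indel_fraction Ratio of germline indel count to SNV count
#'   (533/6062 in the emulated study).
#' @param pzm_indel_fraction Fraction of indels that are postzygotic.
#' @param paternal_fraction Probability a germline DNM is paternal.
#' @param pzm_paternal_fraction Probability a PZM is paternal (1.15:1).
#' @param paternal_age_slope,maternal_age_slope Additional germline DNMs per
#'   year of parental age, on the reference genome scale.
#' @param pzm_paternal_age_slope,pzm_maternal_age_slope Additional PZMs per
#'   year of parental age.
#' @param age_slope_reference_bp Diploid-halved genome size (bp) on which
#'   the age slopes are expressed.
#' @param parental_age_mean,parental_age_sd,parental_age_min Normal
#'   parameters (years) for parental age at birth, truncated below.
#' @param germline_ab_mean Expected sampled allele balance of a
#'   constitutional heterozygote. Modeled as reference-biased loss of
#'   mutant-haplotype reads.
#' @param mosaic_ab_mean,mosaic_ab_concentration Mean and Beta concentration
#'   (alpha+beta) of the expected allele-balance distribution for PZMs; the
#'   cell fraction is twice the allele balance.
#' @param snp_density Informative (tagging) SNPs per bp.
#' @param snp_window_bp Window centered on a DNM within which informative
#'   SNPs are generated/used (80 kbp).
#' @param platform_profiles Named list (`hifi`, `ont`, `illumina`) of
#'   per-platform profiles; see [platform_profile()].
#' @param region_tracks `data.table` with columns `track`, `fraction`,
#'   `germline_mult`, `pzm_mult` describing annotation tracks, the genome
#'   fraction they cover and local rate multipliers (normalized so that the
#'   genome-wide expected count is unchanged).
#' @param cpg_fraction Baseline probability that the 3' neighbor of a
#'   C-reference site is G (used for non-C>T classes).
#' @param cpg_given_ct_germline,cpg_given_ct_pzm Probability that a C>T
#'   substitution sits at a CpG, by origin; the lower postzygotic value
#'   encodes the relative CpG>TpG depletion of mosaic mutations.
#' @param indel_read_noise Probability that a read spanning a carried
#'   indel reports a spurious alternative allele instead.
#' @param germline_spectrum,pzm_spectrum Named probability vectors over the
#'   six collapsed substitution classes (`A>C`,`A>G`,`A>T`,`C>A`,`C>G`,
#'   `C>T`). Defaults give Ti/Tv 2.10 (germline) and 1.35 (postzygotic).
#' @param dropped_hap_run_rate Expected dropped-haplotype artifact runs per
#'   bp per child.
#' @param recurrent_error_rate Expected recurrent-error artifact sites per
#'   bp per child.
#' @param gq_mean,gq_sd Genotype-quality distribution for simulated child
#'   genotypes.
#' @param seed Integer seed; fixed seed gives byte-identical bundles.
#' @return A list of class `dnm_sim_config`.
#' @export
sim_config <- function(n_families = 42L,
                       quad_fraction = 31 / 42,
                       genome_length = 2.66e9,
                       n_chromosomes = 1L,
                       germline_rate = 1.30e-8,
                       pzm_rate = 2.30e-9,
                       indel_fraction = 533 / 6062,
                       pzm_indel_fraction = 0.242,
                       paternal_fraction = 0.799,
                       pzm_paternal_fraction = 1.15 / 2.15,
                       paternal_age_slope = 1.32,
                       maternal_age_slope = 0.46,
                       pzm_paternal_age_slope = 0.26,
                       pzm_maternal_age_slope = 0.16,
                       age_slope_reference_bp = 2.66e9,
                       parental_age_mean = 31.4,
                       parental_age_sd = 5,
                       parental_age_min = 18,
                       germline_ab_mean = 0.48,
                       mosaic_ab_mean = 0.22,
                       mosaic_ab_concentration = 8,
                       snp_density = 1 / 1200,
                       snp_window_bp = 80000L,
                       platform_profiles = default_platform_profiles(),
                       region_tracks = default_region_tracks(),
                       cpg_fraction = 0.21,
                       cpg_given_ct_germline = 0.40,
                       cpg_given_ct_pzm = 0.31,
                       indel_read_noise = 0.05,
                       germline_spectrum = default_spectrum("germline"),
                       pzm_spectrum = default_spectrum("pzm"),
                       dropped_hap_run_rate = 2e-8,
                       recurrent_error_rate = 2e-8,
                       gq_mean = 60,
                       gq_sd = 15,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    quad_fraction = quad_fraction,
    genome_length = genome_length,
    n_chromosomes = as.integer(n_chromosomes),
    germline_rate = germline_rate,
    pzm_rate = pzm_rate,
    indel_fraction = indel_fraction,
    pzm_indel_fraction = pzm_indel_fraction,
    paternal_fraction = paternal_fraction,
    pzm_paternal_fraction = pzm_paternal_fraction,
    paternal_age_slope = paternal_age_slope,
    maternal_age_slope = maternal_age_slope,
    pzm_paternal_age_slope = pzm_paternal_age_slope,
    pzm_maternal_age_slope = pzm_maternal_age_slope,
    age_slope_reference_bp = age_slope_reference_bp,
    parental_age_mean = parental_age_mean,
    parental_age_sd = parental_age_sd,
    parental_age_min = parental_age_min,
    germline_ab_mean = germline_ab_mean,
    mosaic_ab_mean = mosaic_ab_mean,
    mosaic_ab_concentration = mosaic_ab_concentration,
    snp_density = snp_density,
    snp_window_bp = as.integer(snp_window_bp),
    platform_profiles = platform_profiles,
    region_tracks = data.table::as.data.table(region_tracks),
    cpg_fraction = cpg_fraction,
    cpg_given_ct_germline = cpg_given_ct_germline,
    cpg_given_ct_pzm = cpg_given_ct_pzm,
    indel_read_noise = indel_read_noise,
    germline_spectrum = germline_spectrum,
    pzm_spectrum = pzm_spectrum,
    dropped_hap_run_rate = dropped_hap_run_rate,
    recurrent_error_rate = recurrent_error_rate,
    gq_mean = gq_mean,
    gq_sd = gq_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "dnm_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "dnm_sim_config"))
  if (cfg$n_families < 1L) {
    stop("configuration error: n_families must be >= 1", call. = FALSE)
  }
  rates <- c(
    cfg$germline_rate, cfg$pzm_rate, cfg$snp_density,
    cfg$dropped_hap_run_rate, cfg$recurrent_error_rate
  )
  if (any(rates < 0)) stop("configuration error: rates must be >= 0", call. = FALSE)
  fracs <- c(
    cfg$paternal_fraction, cfg$pzm_paternal_fraction, cfg$quad_fraction,
    cfg$germline_ab_mean, cfg$mosaic_ab_mean, cfg$cpg_fraction
  )
  if (any(fracs < 0 | fracs > 1)) {
    stop("configuration error: fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$genome_length < 0) {
    stop("configuration error: genome_length must be >= 0", call. = FALSE)
  }
  for (nm in names(cfg$platform_profiles)) {
    p <- cfg$platform_profiles[[nm]]
    if (p$depth < 0) stop("configuration error: depths must be >= 0", call. = FALSE)
  }
  spectra <- list(cfg$germline_spectrum, cfg$pzm_spectrum)
  for (sp in spectra) {
    if (!setequal(names(sp), c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T"))) {
      stop("configuration error: spectrum must name the six collapsed classes",
        call. = FALSE
      )
    }
    if (abs(sum(sp) - 1) > 1e-8) {
      stop("configuration error: spectrum must sum to 1", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Per-platform sequencing profile
#'
#' @param depth Mean read depth (Poisson).
#' @param read_span Read length in bp (governs how many informative SNPs a
#'   read covers).
#' @param tissue Tissue of origin (`blood` or `cell_line`).
#' @param error_rate Per-base substitution error rate of retained bases.
#'   An erroneous call is one of the three non-true bases, uniformly.
#' @param bq_mean,bq_sd Base-quality (phred) distribution of correct calls.
#' @param bq_err_mean,bq_err_sd Base-quality distribution of erroneous
#'   calls. Miscalls carry low quality, as a calibrated instrument reports.
#' @param mapq_values,mapq_probs Mapping-quality distribution.
#' @param snp_obs_error Probability an informative-SNP allele is misread on
#'   a read.
#' @return A list describing the platform.
#' @export
platform_profile <- function(depth, read_span, tissue, error_rate,
                             bq_mean, bq_sd, bq_err_mean = 12, bq_err_sd = 4,
                             mapq_values = c(60L, 59L, 30L),
                             mapq_probs = c(0.95, 0.03, 0.02),
                             snp_obs_error = error_rate) {
  list(
    depth = depth, read_span = read_span, tissue = tissue,
    error_rate = error_rate, bq_mean = bq_mean, bq_sd = bq_sd,
    bq_err_mean = bq_err_mean, bq_err_sd = bq_err_sd,
    mapq_values = as.integer(mapq_values), mapq_probs = mapq_probs,
    snp_obs_error = snp_obs_error
  )
}

#' Default tri-platform profiles
#'
#' HiFi 30x blood, ONT 30x cell line, Illumina 40x blood. Depths are not
#' published for the emulated study; these are typical values for the
#' platforms. Error rates reflect retained, quality-filtered bases.
#' @return Named list of [platform_profile()] objects.
#' @export
default_platform_profiles <- function() {
  list(
    hifi = platform_profile(
      depth = 30, read_span = 15000L, tissue = "blood",
      error_rate = 1e-4, bq_mean = 35, bq_sd = 4
    ),
    ont = platform_profile(
      depth = 30, read_span = 30000L, tissue = "cell_line",
      error_rate = 5e-3, bq_mean = 25, bq_sd = 5
    ),
    illumina = platform_profile(
      depth = 40, read_span = 150L, tissue = "blood",
      error_rate = 1e-3, bq_mean = 32, bq_sd = 4,
      mapq_values = c(60L, 30L), mapq_probs = c(0.97, 0.03)
    )
  )
}

#' Default annotation tracks for the synthetic genome
#'
#' Fractions approximate the human autosomes; the segmental-duplication
#' (SD) germline multiplier encodes the 18.5% rate increase over the
#' autosome-wide rate and the SD postzygotic multiplier a two-fold
#' enrichment. Homopolymers carry multiplier 0: true DNMs involving a
#' homopolymer subunit are removed by design in the emulated pipeline, so
#' the generator does not place true variants there.
#' @return `data.table` with columns `track`, `fraction`, `germline_mult`,
#'   `pzm_mult`.
#' @export
default_region_tracks <- function() {
  data.table::data.table(
    track = c("segdup", "tandem_repeat", "repeatmasker", "homopolymer", "exon"),
    fraction = c(0.05, 0.03, 0.45, 0.02, 0.05),
    germline_mult = c(1.185, 1, 1, 0, 1),
    pzm_mult = c(2.0, 1, 1, 0, 1)
  )
}

#' Default substitution spectra
#'
#' Probabilities over the six purine/pyrimidine-collapsed substitution
#' classes. The germline spectrum has Ti/Tv = 2.10 and the postzygotic
#' spectrum Ti/Tv = 1.35, with the postzygotic class depleted for A>G and
#' CpG transitions and enriched for A>C / A>T transversions.
#'
#' @param origin `"germline"` or `"pzm"`.
#' @return Named numeric vector summing to 1.
#' @export
default_spectrum <- function(origin = c("germline", "pzm")) {
  origin <- match.arg(origin)
  ti <- function(x) x / (1 + x) # transition fraction from Ti/Tv ratio x
  if (origin == "germline") {
    t_frac <- ti(2.10) # 0.6774
    c(
      "A>G" = t_frac * 0.40, "C>T" = t_frac * 0.60,
      "A>C" = (1 - t_frac) * 0.18, "A>T" = (1 - t_frac) * 0.22,
      "C>A" = (1 - t_frac) * 0.28, "C>G" = (1 - t_frac) * 0.32
    )[c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")]
  } else {
    t_frac <- ti(1.35) # 0.5745
    c(
      "A>G" = t_frac * 0.30, "C>T" = t_frac * 0.70,
      "A>C" = (1 - t_frac) * 0.24, "A>T" = (1 - t_frac) * 0.28,
      "C>A" = (1 - t_frac) * 0.24, "C>G" = (1 - t_frac) * 0.24
    )[c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")]
  }
}

#' Filtering and testing parameters for the validation pipeline
#'
#' All thresholds of the discovery/validation cascade, named after the
#' read-validation vocabulary. Defaults implement the published cascade:
#' child genotype quality >= 20; a 1-kbp cluster window holding >= 3 SNVs;
#' long reads dropped below MAPQ 59; base-quality partitions at 10 and 20;
#' HiFi/Illumina parents allowed 0 high-quality and at most 1 low-quality
#' read with the de novo allele (ONT: at most 1 and 2); two supporting
#' platforms to validate; recurrence tolerating one unrelated carrier only
#' in tandem repeats; mean-AB floors of 0.05 (TR), 0.1 (RepeatMasker + TR)
#' and 0.08 (RepeatMasker only); homopolymer runs of >= 4 bp; indel reads
#' at MAPQ 60 with 10-bp flanks; and alpha = 0.05 for the concordance and
#' pooled binomial tests.
#'
#' @param child_min_gq Minimum child genotype quality for candidacy.
#' @param cluster_window_bp Sliding window for the cluster filter.
#' @param cluster_min_snvs Minimum SNVs in a window to trigger exclusion.
#' @param long_read_min_mapq MAPQ below which HiFi/ONT reads are excluded.
#' @param bq_high,bq_low High/low base-quality partition bounds: quality
#'   > `bq_high` is high; `bq_low`..`bq_high` low; below `bq_low` discarded.
#' @param parent_hq_alt_max,parent_lq_alt_max Per-parent ceilings on
#'   high/low-quality de novo-allele reads for HiFi and Illumina.
#' @param parent_hq_alt_max_ont,parent_lq_alt_max_ont The looser ONT
#'   ceilings.
#' @param min_support_platforms Platforms that must independently support a
#'   variant for validation.
#' @param cellline_min_illumina_alt Minimum high-quality Illumina blood
#'   alt reads required when the child has no blood HiFi data.
#' @param recurrence_max_unrelated,recurrence_max_unrelated_tr Maximum
#'   unrelated carriers tolerated outside/inside tandem repeats.
#' @param ab_min_tr,ab_min_rm_tr,ab_min_rm Mean-allele-balance floors.
#' @param homopolymer_min_len Minimum run length for the homopolymer
#'   filter.
#' @param homopolymer_max_offset Maximum distance (bp) from a run for a
#'   variant to count as adjacent.
#' @param indel_min_mapq,indel_min_flank Read requirements for indel
#'   validation.
#' @param indel_max_other_alleles Distinct non-called alleles tolerated
#'   across trio reads before an indel is failed as multi-allelic noise.
#' @param indel_pzm_min_discordant Discordant haplotype reads above which
#'   an indel is called postzygotic (strictly greater than).
#' @param male_x_ab_tolerance Allowed deviation from AB = 1 on male sex
#'   chromosomes.
#' @param alpha_concordance,alpha_pooled Significance levels for the
#'   allele-balance concordance chi-squared test and the pooled binomial
#'   test.
#' @return A list of class `dnm_filter_params`.
#' @export
filter_params <- function(child_min_gq = 20,
                          cluster_window_bp = 1000L,
                          cluster_min_snvs = 3L,
                          long_read_min_mapq = 59L,
                          bq_high = 20,
                          bq_low = 10,
                          parent_hq_alt_max = 0L,
                          parent_lq_alt_max = 1L,
                          parent_hq_alt_max_ont = 1L,
                          parent_lq_alt_max_ont = 2L,
                          min_support_platforms = 2L,
                          cellline_min_illumina_alt = 2L,
                          recurrence_max_unrelated = 0L,
                          recurrence_max_unrelated_tr = 1L,
                          ab_min_tr = 0.05,
                          ab_min_rm_tr = 0.1,
                          ab_min_rm = 0.08,
                          homopolymer_min_len = 4L,
                          homopolymer_max_offset = 1L,
                          indel_min_mapq = 60L,
                          indel_min_flank = 10L,
                          indel_max_other_alleles = 2L,
                          indel_pzm_min_discordant = 3L,
                          male_x_ab_tolerance = 0,
                          alpha_concordance = 0.05,
                          alpha_pooled = 0.05) {
  p <- as.list(environment())
  class(p) <- "dnm_filter_params"
  p
}
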