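# Shared fixture builders. Everything is constructed in code; no files.

library(data.table)

tiny_config <- function(...) {
  sim_config(
    n_families = 4, quad_fraction = 0.5, genome_length = 2e6,
    seed = 11, ...
  )
}

# A single hand-built trio pedigree in the generator's schema.
ped_trio <- function(fam = "fam001", father_age = 32, mother_age = 30,
                     child_sex = 1L) {
  data.table(
    family = fam,
    sample_id = paste0(fam, c(".fa", ".mo", ".c1")),
    father = c("0", "0", paste0(fam, ".fa")),
    mother = c("0", "0", paste0(fam, ".mo")),
    sex = c(1L, 2L, child_sex),
    phenotype = c(1L, 1L, 2L),
    role = c("father", "mother", "child"),
    father_age = c(NA, NA, father_age),
    mother_age = c(NA, NA, mother_age)
  )
}

# One long-format genotype row.
gt_row <- function(fam, sample_id, chrom = "chr1", pos = 100, ref = "A",
                   alt = "T", gt = "0/0", gq = 60L) {
  data.table(
    family = fam, chrom = chrom, pos = pos, ref = ref, alt = alt,
    sample_id = sample_id, gt = gt, gq = as.integer(gq)
  )
}

# Trio genotypes at one site.
trio_gt <- function(fam = "fam001", chrom = "chr1", pos = 100,
                    gt_father = "0/0", gt_mother = "0/0", gt_child = "0/1",
                    gq_child = 30L, ref = "A", alt = "T") {
  rbind(
    gt_row(fam, paste0(fam, ".fa"), chrom, pos, ref, alt, gt_father),
    gt_row(fam, paste0(fam, ".mo"), chrom, pos, ref, alt, gt_mother),
    gt_row(fam, paste0(fam, ".c1"), chrom, pos, ref, alt, gt_child, gq_child)
  )
}

# Aggregated evidence rows in the schema of aggregate_site_evidence().
ev_row <- function(role, platform, hq_alt = 0L, lq_alt = 0L, hq_ref = 0L,
                   lq_ref = 0L, n_other = 0L, child = "fam001.c1",
                   chrom = "chr1", pos = 100, family = "fam001") {
  n_ret <- hq_alt + lq_alt + hq_ref + lq_ref + n_other
  denom <- hq_alt + lq_alt + hq_ref + lq_ref
  data.table(
    family = family, child = child, chrom = chrom, pos = pos, role = role,
    platform = platform, hq_alt = as.integer(hq_alt),
    lq_alt = as.integer(lq_alt), hq_ref = as.integer(hq_ref),
    lq_ref = as.integer(lq_ref), n_other = as.integer(n_other),
    n_retained = as.integer(n_ret),
    ab = if (denom > 0) (hq_alt + lq_alt) / denom else NA_real_
  )
}

# Healthy trio evidence: both parents clean, child het-like, all platforms.
clean_trio_evidence <- function(child = "fam001.c1", chrom = "chr1",
                                pos = 100, family = "fam001") {
  rbindlist(lapply(c("hifi", "ont", "illumina"), function(pf) {
    rbind(
      ev_row("child", pf, hq_alt = 14L, hq_ref = 15L,
        child = child, chrom = chrom, pos = pos, family = family
      ),
      ev_row("father", pf, hq_ref = 30L,
        child = child, chrom = chrom, pos = pos, family = family
      ),
      ev_row("mother", pf, hq_ref = 30L,
        child = child, chrom = chrom, pos = pos, family = family
      )
    )
  }))
}

# One raw read row in the schema of simulate_reads()$reads.
read_row <- function(sample, allele, platform = "hifi", tissue = "blood",
                     bq = 30L, mapq = 60L, chrom = "chr1", pos = 100,
                     family = "fam001", flank5 = 100L, flank3 = 100L,
                     read_id = NULL) {
  data.table(
    family = family, sample = sample, chrom = chrom, pos = pos,
    site_id = sprintf("%s:%s:%d", sample, chrom, pos), class = "SNV",
    platform = platform, tissue = tissue, haplotype = "paternal",
    base_quality = as.integer(bq), allele = allele,
    mapping_quality = as.integer(mapq), flank5 = as.integer(flank5),
    flank3 = as.integer(flank3),
    read_id = read_id %||% paste0(sample, "_", platform, "_", stats::runif(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Candidate row with annotation columns for the predicate filters.
cand_row <- function(child = "fam001.c1", chrom = "chr1", pos = 100,
                     ref = "A", alt = "T", class = "SNV", in_tr = FALSE,
                     in_repeatmasker = FALSE, hp_base = NA_character_,
                     hp_len = NA_integer_, hp_offset = NA_integer_,
                     family = "fam001") {
  data.table(
    family = family, child = child, chrom = chrom, pos = pos, ref = ref,
    alt = alt, class = class, gq = 40L, in_tr = in_tr,
    in_repeatmasker = in_repeatmasker, in_segdup = FALSE,
    sd_identity = NA_character_, in_exon = FALSE, hp_base = hp_base,
    hp_len = as.integer(hp_len), hp_offset = as.integer(hp_offset)
  )
}

# Brute-force oracle for the cluster filter: a site is excluded iff some
# 1-kbp window anchored at a candidate position contains >= k candidates.
cluster_oracle <- function(pos, w = 1000, k = 3) {
  excluded <- logical(length(pos))
  for (i in seq_along(pos)) {
    inwin <- which(pos >= pos[i] & pos <= pos[i] + w)
    if (length(inwin) >= k) excluded[inwin] <- TRUE
  }
  excluded
}
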