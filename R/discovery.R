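# Candidate selection and the tri-platform validation cascade.
#
# Every filter is a pure predicate on a candidate plus its evidence; the
# driver computes all predicates and intersects them, so the cascade is
# order-stable by construction.

LONG_READ_PLATFORMS <- c("hifi", "ont")
PLATFORMS <- c("hifi", "ont", "illumina")

#' Select candidate de novo variants from trio genotypes
#'
#' Keeps sites where both parents are genotyped `0/0`, the child carries at
#' least one alternate allele, and the child genotype quality is at least
#' `child_min_gq` (20). SNVs and indels are distinguished by allele length.
#'
#' @param genotypes Long-format genotype records: `family`, `chrom`, `pos`,
#'   `ref`, `alt`, `sample_id`, `gt`, `gq`.
#' @param pedigree Pedigree table (see [simulate_pedigree()]).
#' @param params A [filter_params()] object.
#' @return `data.table` of candidates: `family`, `child`, `chrom`, `pos`,
#'   `ref`, `alt`, `class`, `gq`.
#' @export
select_candidates <- function(genotypes, pedigree, params = filter_params()) {
  children <- pedigree[role == "child", .(family, child = sample_id, father, mother)]
  if (nrow(children) == 0L) stop("pedigree error: no children in pedigree")
  missing_child <- setdiff(children$child, genotypes$sample_id)
  if (length(missing_child) == nrow(children) && nrow(genotypes) > 0L) {
    stop("pedigree error: no child of the pedigree appears in the genotypes")
  }
  g <- genotypes[, .(family, chrom, pos, ref, alt, sample_id, gt, gq)]
  cand <- g[children, on = c("family", sample_id = "child"),
    allow.cartesian = TRUE, nomatch = NULL,
    .(family, child = sample_id, father, mother, chrom, pos, ref, alt, gt, gq)
  ]
  cand[
    g, on = c("family", "chrom", "pos", father = "sample_id"),
    gt_father := i.gt
  ]
  cand[
    g, on = c("family", "chrom", "pos", mother = "sample_id"),
    gt_mother := i.gt
  ]
  cand <- cand[
    !is.na(gt_father) & !is.na(gt_mother) &
      gt_father == "0/0" & gt_mother == "0/0" &
      grepl("1", gt, fixed = TRUE) & gq >= params$child_min_gq,
    .(family, child, chrom, pos, ref, alt, gq)
  ]
  cand[, class := fifelse(
    nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
    fifelse(nchar(alt) > nchar(ref), "insertion", "deletion")
  )]
  setkey(cand, family, child, chrom, pos)
  cand[]
}

#' Annotate candidates with region and homopolymer context
#'
#' Flags tandem-repeat, RepeatMasker, segmental-duplication and exon
#' membership, and attaches the nearest homopolymer run (base, length,
#' offset) when the variant lies in or within `homopolymer_max_offset` bp
#' of one.
#'
#' @param candidates Candidate table from [select_candidates()].
#' @param tracks Annotation tracks (BED-style, half-open 0-based).
#' @param params A [filter_params()] object.
#' @return The candidate table with annotation columns added.
#' @export
annotate_candidates <- function(candidates, tracks, params = filter_params()) {
  dt <- copy(candidates)
  dt <- .label_regions(dt, tracks)
  dt[, `:=`(hp_base = NA_character_, hp_len = NA_integer_, hp_offset = NA_integer_)]
  hp <- tracks[track == "homopolymer"]
  if (nrow(hp) > 0L && nrow(dt) > 0L) {
    pad <- params$homopolymer_max_offset
    for (chr in unique(dt$chrom)) {
      hc <- hp[chrom == chr][order(start)]
      if (nrow(hc) == 0L) next
      rows <- which(dt$chrom == chr)
      p0 <- dt$pos[rows] - 1 # 0-based site
      idx <- findInterval(p0, hc$start - pad)
      ok <- idx >= 1L & p0 < hc$end[pmax(idx, 1L)] + pad
      hit <- rows[ok]
      if (length(hit) == 0L) next
      i <- idx[ok]
      off <- pmax(0L, pmax(hc$start[i] - p0[ok], p0[ok] - (hc$end[i] - 1L)))
      set(dt, hit, "hp_base", hc$hp_base[i])
      set(dt, hit, "hp_len", hc$hp_len[i])
      set(dt, hit, "hp_offset", as.integer(off))
    }
  }
  dt[]
}

#' Cluster filter for candidate SNVs
#'
#' Excludes every SNV candidate for which some 1-kbp window containing it
#' holds at least three candidate SNVs of the same child (the signature of
#' a dropped parental haplotype). Implemented on sorted positions: a site
#' is excluded iff it belongs to a run of `cluster_min_snvs` consecutive
#' candidates spanning at most `cluster_window_bp`, which is equivalent to
#' the brute-force scan over all windows.
#'
#' @param candidates Candidate table (SNVs of one or more children).
#' @param params A [filter_params()] object.
#' @return Input with a logical column `cluster_excluded` added.
#' @export
filter_clusters <- function(candidates, params = filter_params()) {
  dt <- copy(candidates)
  k <- params$cluster_min_snvs
  w <- params$cluster_window_bp
  dt[, cluster_excluded := FALSE]
  snv <- dt[class == "SNV", .I[order(pos)], by = .(child, chrom)]
  dt[class == "SNV", cluster_excluded := {
    p <- sort(pos)
    n <- length(p)
    exc <- logical(n)
    if (n >= k) {
      # window of k consecutive candidates fitting in w bp excludes them all
      starts <- which(p[seq_len(n - k + 1L) + k - 1L] - p[seq_len(n - k + 1L)] <= w)
      for (s in starts) exc[s:(s + k - 1L)] <- TRUE
    }
    exc[rank(pos, ties.method = "first")]
  }, by = .(child, chrom)]
  dt[]
}

#' Partition a read by base and mapping quality
#'
#' Long reads (HiFi, ONT) with mapping quality below `long_read_min_mapq`
#' are excluded outright; short reads are never excluded on mapping
#' quality. Remaining reads are `HIGH` (base quality > 20), `LOW` (10-20),
#' or `DISCARD` (< 10).
#'
#' @param base_quality,mapping_quality Phred values (vectorized).
#' @param platform `"hifi"`, `"ont"` or `"illumina"` (recycled).
#' @param params A [filter_params()] object.
#' @return Character vector of quality classes.
#' @export
classify_read <- function(base_quality, mapping_quality, platform,
                          params = filter_params()) {
  if (!all(platform %in% PLATFORMS)) {
    stop("unknown platform: ", paste(setdiff(platform, PLATFORMS), collapse = ", "))
  }
  if (any(base_quality < 0) || any(mapping_quality < 0)) {
    stop("qualities must be non-negative phred values")
  }
  out <- fifelse(
    platform %in% LONG_READ_PLATFORMS & mapping_quality < params$long_read_min_mapq,
    "MAPQ_EXCLUDED",
    fifelse(
      base_quality > params$bq_high, "HIGH",
      fifelse(base_quality >= params$bq_low, "LOW", "DISCARD")
    )
  )
  out
}

#' Aggregate per-site, per-individual, per-platform read evidence
#'
#' Applies [classify_read()], drops discarded and MAPQ-excluded reads,
#' restricts child HiFi evidence to blood tissue (parental blood and
#' cell-line reads are both retained), and counts high/low-quality
#' reference and alternate reads per trio role and platform.
#'
#' @param candidates Candidate table (`family`, `child`, `chrom`, `pos`).
#' @param reads Read-evidence table.
#' @param pedigree Pedigree table.
#' @param params A [filter_params()] object.
#' @return `data.table` keyed by (`child`, `chrom`, `pos`, `role`,
#'   `platform`) with columns `hq_alt`, `lq_alt`, `hq_ref`, `lq_ref`,
#'   `n_other`, `n_retained`, `ab`.
#' @export
aggregate_site_evidence <- function(candidates, reads, pedigree,
                                    params = filter_params()) {
  fam_members <- pedigree[, .(family, sample_id, role)]
  cand_members <- candidates[, .(family, child, chrom, pos)][
    fam_members,
    on = "family", allow.cartesian = TRUE, nomatch = NULL
  ]
  cand_members[, role := fifelse(sample_id == child, "child",
    fifelse(role == "child", "sibling", role)
  )]
  ev <- reads[cand_members,
    on = c("family", "sample" = "sample_id", "chrom", "pos"),
    nomatch = NULL,
    .(
      family, child = i.child, chrom, pos, sample, role = i.role, platform,
      tissue, allele, base_quality, mapping_quality, flank5, flank3
    )
  ]
  if (nrow(ev) == 0L) {
    return(data.table(
      family = character(), child = character(), chrom = character(),
      pos = numeric(), role = character(), platform = character(),
      hq_alt = integer(), lq_alt = integer(), hq_ref = integer(),
      lq_ref = integer(), n_other = integer(), n_retained = integer(),
      ab = numeric()
    ))
  }
  ev[, quality_class := classify_read(base_quality, mapping_quality, platform, params)]
  ev <- ev[quality_class %in% c("HIGH", "LOW")]
  ev <- ev[!(role == "child" & platform == "hifi" & tissue != "blood")]
  out <- ev[, .(
    hq_alt = sum(quality_class == "HIGH" & allele == "alt"),
    lq_alt = sum(quality_class == "LOW" & allele == "alt"),
    hq_ref = sum(quality_class == "HIGH" & allele == "ref"),
    lq_ref = sum(quality_class == "LOW" & allele == "ref"),
    n_other = sum(!allele %in% c("ref", "alt"))
  ), by = .(family, child, chrom, pos, role, platform)]
  out[, n_retained := hq_alt + lq_alt + hq_ref + lq_ref + n_other]
  out[, ab := fifelse(
    hq_alt + lq_alt + hq_ref + lq_ref > 0,
    (hq_alt + lq_alt) / (hq_alt + lq_alt + hq_ref + lq_ref),
    NA_real_
  )]
  setkey(out, child, chrom, pos, role, platform)
  out[]
}

#' Per-platform SNV validation verdicts
#'
#' For each candidate and platform: a parent passes when its de novo-allele
#' read counts stay below the platform ceilings (HiFi/Illumina: zero
#' high-quality and at most one low-quality; ONT: at most one and two); the
#' child must have at least one retained read with the allele. The verdict
#' is `DE_NOVO` when both parents pass and the child is supported,
#' `INHERITED` when a parent fails, `UNSUPPORTED` when the child lacks
#' support or a role has no usable reads on that platform.
#'
#' @param evidence Output of [aggregate_site_evidence()].
#' @param params A [filter_params()] object.
#' @return `data.table`: `child`, `chrom`, `pos`, `platform`, `verdict`.
#' @export
validate_snv_platform <- function(evidence, params = filter_params()) {
  grid <- CJ(
    key = unique(evidence[, paste(child, chrom, pos, sep = "\r")]),
    platform = PLATFORMS
  )
  grid[, c("child", "chrom", "pos") := tstrsplit(key, "\r")]
  grid[, `:=`(pos = as.numeric(pos), key = NULL)]
  ev <- dcast(
    evidence[role %in% c("child", "father", "mother")],
    child + chrom + pos + platform ~ role,
    value.var = c("hq_alt", "lq_alt", "n_retained"), fill = NA
  )
  need <- c(
    "hq_alt_child", "lq_alt_child", "n_retained_child",
    "hq_alt_father", "lq_alt_father", "n_retained_father",
    "hq_alt_mother", "lq_alt_mother", "n_retained_mother"
  )
  for (col in setdiff(need, names(ev))) ev[, (col) := NA_integer_]
  v <- ev[grid, on = c("child", "chrom", "pos", "platform")]

  hq_max <- fifelse(v$platform == "ont", params$parent_hq_alt_max_ont,
    params$parent_hq_alt_max
  )
  lq_max <- fifelse(v$platform == "ont", params$parent_lq_alt_max_ont,
    params$parent_lq_alt_max
  )
  fa_fail <- v$hq_alt_father > hq_max | v$lq_alt_father > lq_max
  mo_fail <- v$hq_alt_mother > hq_max | v$lq_alt_mother > lq_max
  child_support <- (v$hq_alt_child + v$lq_alt_child) >= 1L
  usable <- !is.na(v$n_retained_child) & v$n_retained_child > 0L &
    !is.na(v$n_retained_father) & v$n_retained_father > 0L &
    !is.na(v$n_retained_mother) & v$n_retained_mother > 0L

  v[, verdict := "UNSUPPORTED"]
  v[usable & (fa_fail | mo_fail), verdict := "INHERITED"]
  v[usable & !fa_fail & !mo_fail & child_support, verdict := "DE_NOVO"]
  v[, .(child, chrom, pos, platform, verdict)]
}

#' Combine per-platform verdicts into a site-level verdict
#'
#' A variant is `INHERITED` if it looks inherited in at least one platform,
#' `VALIDATED` if supported de novo in at least `min_support_platforms`
#' platforms, otherwise `FAILED`. Children with only cell-line HiFi data
#' (no blood HiFi reads) additionally require
#' `cellline_min_illumina_alt` high-quality Illumina blood alt reads.
#'
#' @param platform_verdicts Output of [validate_snv_platform()].
#' @param evidence Evidence table (used for the cell-line-only rule);
#'   optional.
#' @param params A [filter_params()] object.
#' @return `data.table`: `child`, `chrom`, `pos`, `combined`.
#' @export
combine_platform_verdicts <- function(platform_verdicts, evidence = NULL,
                                      params = filter_params()) {
  out <- platform_verdicts[, .(
    combined = if (any(verdict == "INHERITED")) {
      "INHERITED"
    } else if (sum(verdict == "DE_NOVO") >= params$min_support_platforms) {
      "VALIDATED"
    } else {
      "FAILED"
    }
  ), by = .(child, chrom, pos)]
  if (!is.null(evidence) && nrow(evidence) > 0L) {
    hifi_child <- platform_verdicts[
      platform == "hifi",
      .(child, chrom, pos, hifi_verdict = verdict)
    ]
    ill <- evidence[
      role == "child" & platform == "illumina",
      .(child, chrom, pos, ill_hq_alt = hq_alt)
    ]
    out <- ill[out, on = c("child", "chrom", "pos")]
    out <- hifi_child[out, on = c("child", "chrom", "pos")]
    out[
      combined == "VALIDATED" & hifi_verdict == "UNSUPPORTED" &
        (is.na(ill_hq_alt) | ill_hq_alt < params$cellline_min_illumina_alt),
      combined := "FAILED"
    ]
    out <- out[, .(child, chrom, pos, combined)]
  }
  out[]
}

#' Recurrence filter: the de novo allele must be unique to the child
#'
#' Counts unrelated individuals (outside the candidate's family) with at
#' least one retained high-quality HiFi read carrying the de novo allele.
#' Outside tandem repeats any unrelated carrier fails the candidate; inside
#' a tandem repeat one unrelated carrier is tolerated.
#'
#' @param candidates Candidate table with `in_tr` annotation.
#' @param reads Cohort-wide read-evidence table.
#' @param params A [filter_params()] object.
#' @return Input with columns `n_unrelated_carriers` and
#'   `recurrence_pass`.
#' @export
recurrence_filter <- function(candidates, reads, params = filter_params()) {
  dt <- copy(candidates)
  hifi_alt <- reads[
    platform == "hifi" & allele == "alt" &
      mapping_quality >= params$long_read_min_mapq &
      base_quality > params$bq_high,
    .(family, sample, chrom, pos)
  ]
  carr <- hifi_alt[dt[, .(family, child, chrom, pos)],
    on = c("chrom", "pos"), allow.cartesian = TRUE, nomatch = NULL
  ]
  carr <- carr[family != i.family | is.na(i.family)]
  cnt <- carr[, .(n_unrelated_carriers = uniqueN(sample)), by = .(child, chrom, pos)]
  dt <- cnt[dt, on = c("child", "chrom", "pos")]
  dt[is.na(n_unrelated_carriers), n_unrelated_carriers := 0L]
  max_ok <- fifelse(
    !is.na(dt$in_tr) & dt$in_tr,
    params$recurrence_max_unrelated_tr, params$recurrence_max_unrelated
  )
  dt[, recurrence_pass := n_unrelated_carriers <= max_ok]
  dt[]
}

#' Allele-balance filters for repeat-region variants
#'
#' Tandem-repeat variants require a mean allele balance across platforms
#' strictly greater than `ab_min_tr`; RepeatMasker-flagged variants require
#' mean AB of at least `ab_min_rm_tr` when also in a tandem repeat and
#' `ab_min_rm` otherwise. The mean is taken over child platforms with
#' retained reads; a candidate with no retained reads anywhere fails.
#'
#' @param candidates Annotated candidate table.
#' @param evidence Evidence table from [aggregate_site_evidence()].
#' @param params A [filter_params()] object.
#' @return Input with columns `mean_ab`, `ab_pass`, `ab_reason`.
#' @export
ab_filters <- function(candidates, evidence, params = filter_params()) {
  dt <- copy(candidates)
  abs_ <- evidence[role == "child" & !is.na(ab),
    .(mean_ab = mean(ab)),
    by = .(child, chrom, pos)
  ]
  dt <- abs_[dt, on = c("child", "chrom", "pos")]
  dt[, `:=`(ab_pass = TRUE, ab_reason = NA_character_)]
  dt[is.na(mean_ab), `:=`(ab_pass = FALSE, ab_reason = "no evidence")]
  dt[
    ab_pass & in_tr & mean_ab <= params$ab_min_tr,
    `:=`(ab_pass = FALSE, ab_reason = "TR AB <= 0.05")
  ]
  dt[
    ab_pass & in_repeatmasker & in_tr & mean_ab < params$ab_min_rm_tr,
    `:=`(ab_pass = FALSE, ab_reason = "RM+TR AB < 0.1")
  ]
  dt[
    ab_pass & in_repeatmasker & !in_tr & mean_ab < params$ab_min_rm,
    `:=`(ab_pass = FALSE, ab_reason = "RM AB < 0.08")
  ]
  dt[]
}

#' Homopolymer filter
#'
#' Fails an SNV lying in or within one bp of a homopolymer run of at least
#' `homopolymer_min_len` bp when its reference or alternate allele equals
#' the homopolymer base (for example an A-to-T substitution on the edge of
#' an A run).
#'
#' @param candidates Annotated candidate table (`hp_base`, `hp_len`,
#'   `hp_offset`).
#' @param params A [filter_params()] object.
#' @return Input with logical column `hp_pass` added.
#' @export
homopolymer_filter <- function(candidates, params = filter_params()) {
  dt <- copy(candidates)
  dt[, hp_pass := !(
    class == "SNV" &
      !is.na(hp_base) & !is.na(hp_len) &
      hp_len >= params$homopolymer_min_len &
      hp_offset <= params$homopolymer_max_offset &
      (ref == hp_base | alt == hp_base)
  )]
  dt[is.na(hp_pass), hp_pass := TRUE]
  dt[]
}

#' Validate candidate indels
#'
#' Indel evidence is restricted to reads with the maximum mapping quality
#' (60) that span the site with at least 10 bp of flank on both sides. A
#' candidate is `INHERITED` when one parent or a sibling has any
#' supporting read in any platform, `FAILED` when more than
#' `indel_max_other_alleles` distinct non-called alleles appear across the
#' family's reads (multi-allelic noise; a proxy for visual curation), and
#' `VALIDATED` only when the child shows the allele in both HiFi and
#' Illumina data.
#'
#' @param candidates Indel candidate rows.
#' @param reads Read-evidence table.
#' @param pedigree Pedigree table.
#' @param params A [filter_params()] object.
#' @return Candidate table with a `combined` verdict column.
#' @export
validate_indel <- function(candidates, reads, pedigree, params = filter_params()) {
  dt <- copy(candidates)
  if (nrow(dt) == 0L) {
    dt[, combined := character()]
    return(dt)
  }
  fam_members <- pedigree[, .(family, sample_id, role)]
  cand_members <- dt[, .(family, child, chrom, pos)][
    fam_members,
    on = "family", allow.cartesian = TRUE, nomatch = NULL
  ]
  cand_members[, role := fifelse(sample_id == child, "child",
    fifelse(role == "child", "sibling", role)
  )]
  ev <- reads[cand_members,
    on = c("family", "sample" = "sample_id", "chrom", "pos"), nomatch = NULL,
    .(
      child = i.child, chrom, pos, role = i.role, platform, allele,
      mapping_quality, flank5, flank3
    )
  ]
  ev <- ev[
    mapping_quality >= params$indel_min_mapq &
      flank5 >= params$indel_min_flank & flank3 >= params$indel_min_flank
  ]
  stats <- ev[, .(
    inherited = any(allele == "alt" & role %in% c("father", "mother", "sibling")),
    child_hifi = any(allele == "alt" & role == "child" & platform == "hifi"),
    child_ill = any(allele == "alt" & role == "child" & platform == "illumina"),
    n_other_alleles = uniqueN(allele[!allele %in% c("ref", "alt")])
  ), by = .(child, chrom, pos)]
  dt <- stats[dt, on = c("child", "chrom", "pos")]
  dt[, combined := "FAILED"]
  dt[which(child_hifi & child_ill), combined := "VALIDATED"]
  dt[which(n_other_alleles > params$indel_max_other_alleles), combined := "FAILED"]
  dt[which(inherited), combined := "INHERITED"]
  dt[, c("inherited", "child_hifi", "child_ill") := NULL]
  dt[]
}

#' Validate sex-chromosome candidates
#'
#' Female chrX candidates flow through the autosomal cascade. Male chrX
#' candidates are compared against the mother only and chrY against the
#' father only, using the platform parent ceilings; male sex-chromosome
#' SNVs additionally require an allele balance of 1 across retained reads
#' (within `male_x_ab_tolerance`), which also precludes postzygotic calls
#' there.
#'
#' @param candidates Candidate rows with a `chrom` of `"chrX"`/`"chrY"`.
#' @param evidence Evidence table from [aggregate_site_evidence()].
#' @param child_sex Named integer vector (1 = male, 2 = female) by child id.
#' @param params A [filter_params()] object.
#' @return Candidate table with `combined` verdict and `sex_chrom_rule`
#'   columns; female X rows get `sex_chrom_rule == "autosomal"` and no
#'   verdict (route them through the autosomal cascade).
#' @export
validate_sex_chromosome <- function(candidates, evidence, child_sex,
                                    params = filter_params()) {
  dt <- copy(candidates)
  dt[, sex := child_sex[child]]
  if (any(dt$chrom == "chrY" & dt$sex == 2L)) {
    stop("input error: chrY candidate in a female child")
  }
  dt[, sex_chrom_rule := fifelse(
    sex == 2L, "autosomal",
    fifelse(chrom == "chrX", "male_x", "male_y")
  )]
  male <- dt[sex_chrom_rule != "autosomal"]
  if (nrow(male) == 0L) {
    dt[, combined := NA_character_]
    return(dt[])
  }
  other_parent <- fifelse(male$sex_chrom_rule == "male_x", "mother", "father")
  ev <- evidence[male[, .(child, chrom, pos, parent = other_parent)],
    on = c("child", "chrom", "pos"), allow.cartesian = TRUE, nomatch = NULL
  ]
  par_ev <- ev[role == parent]
  hq_max <- fifelse(par_ev$platform == "ont", params$parent_hq_alt_max_ont,
    params$parent_hq_alt_max
  )
  lq_max <- fifelse(par_ev$platform == "ont", params$parent_lq_alt_max_ont,
    params$parent_lq_alt_max
  )
  par_stat <- par_ev[, .(
    inherited = any(hq_alt > hq_max | lq_alt > lq_max)
  ), by = .(child, chrom, pos)]
  child_stat <- ev[role == "child", .(
    n_support = sum((hq_alt + lq_alt) >= 1L),
    alt = sum(hq_alt + lq_alt), ref = sum(hq_ref + lq_ref)
  ), by = .(child, chrom, pos)]
  male <- par_stat[male, on = c("child", "chrom", "pos")]
  male <- child_stat[male, on = c("child", "chrom", "pos")]
  male[, combined := "FAILED"]
  male[
    !is.na(n_support) & n_support >= params$min_support_platforms &
      (is.na(inherited) | !inherited) &
      (class != "SNV" |
        (alt / pmax(alt + ref, 1L)) >= 1 - params$male_x_ab_tolerance),
    combined := "VALIDATED"
  ]
  male[!is.na(inherited) & inherited, combined := "INHERITED"]
  out <- rbind(
    dt[sex_chrom_rule == "autosomal"][, combined := NA_character_],
    male[, names(dt), with = FALSE][
      , combined := male$combined
    ],
    fill = TRUE
  )
  out[]
}

#' Run the full SNV/indel validation cascade on a cohort
#'
#' Orchestrates candidate selection, annotation, the cluster filter, the
#' tri-platform read validation, and the recurrence, allele-balance and
#' homopolymer filters for SNVs; indels are routed through
#' [validate_indel()] (tandem-repeat indels are excluded from the indel
#' stream). All predicates are computed independently and intersected.
#'
#' @param genotypes,pedigree,reads,tracks Cohort tables (see
#'   [simulate_cohort()]).
#' @param params A [filter_params()] object.
#' @return Candidate table with per-filter columns and a final `verdict`
#'   (`VALIDATED`, `INHERITED`, `FAILED`, or `EXCLUDED_<reason>`).
#' @export
validate_variants <- function(genotypes, pedigree, reads, tracks,
                              params = filter_params()) {
  cand <- select_candidates(genotypes, pedigree, params)
  cand <- annotate_candidates(cand, tracks, params)
  cand <- filter_clusters(cand, params)

  snv <- cand[class == "SNV" & cluster_excluded == FALSE]
  indel <- cand[class != "SNV"]

  if (nrow(snv) > 0L) {
    ev <- aggregate_site_evidence(snv, reads, pedigree, params)
    pv <- validate_snv_platform(ev, params)
    comb <- combine_platform_verdicts(pv, ev, params)
    snv <- comb[snv, on = c("child", "chrom", "pos")]
    snv <- recurrence_filter(snv, reads, params)
    snv <- ab_filters(snv, ev, params)
    snv <- homopolymer_filter(snv, params)
    snv[, verdict := fifelse(
      combined == "INHERITED", "INHERITED",
      fifelse(
        combined == "VALIDATED" & recurrence_pass & ab_pass & hp_pass,
        "VALIDATED", "FAILED"
      )
    )]
    pvw <- dcast(pv, child + chrom + pos ~ platform, value.var = "verdict")
    setnames(pvw, PLATFORMS, paste0("verdict_", PLATFORMS), skip_absent = TRUE)
    snv <- pvw[snv, on = c("child", "chrom", "pos")]
  } else {
    snv[, verdict := character()]
  }

  excluded <- cand[class == "SNV" & cluster_excluded == TRUE]
  excluded[, verdict := "EXCLUDED_CLUSTER"]

  if (nrow(indel) > 0L) {
    indel_tr <- indel[in_tr == TRUE]
    indel_tr[, verdict := "EXCLUDED_TR"]
    indel_ok <- validate_indel(indel[in_tr == FALSE], reads, pedigree, params)
    indel_ok[, verdict := combined]
    indel <- rbind(indel_tr, indel_ok, fill = TRUE)
  } else {
    indel[, verdict := character()]
  }

  out <- rbind(snv, excluded, indel, fill = TRUE)
  setkey(out, family, child, chrom, pos)
  out[]
}
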