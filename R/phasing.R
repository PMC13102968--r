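# Read-backed parent-of-origin phasing via distance-weighted
# informative-SNP inheritance scores.

#' Find informative SNPs around a DNM site
#'
#' An informative (tagging) SNP is a site where one parent is `0/0`, the
#' other parent carries at least one alternate allele, and the child is
#' `0/1`: the parental origin of the child's alternate allele is then
#' forced. Only SNPs inside the window centered on the DNM are returned,
#' with signed origin and distance.
#'
#' @param genotypes Long-format genotype records for the family.
#' @param child,father,mother Sample identifiers of the trio.
#' @param chrom,dnm_pos Coordinates of the DNM.
#' @param window_bp Window width centered on the DNM (default 80 kbp).
#' @return `data.table`: `chrom`, `pos`, `parent_of_origin`, `distance`.
#' @export
find_informative_snps <- function(genotypes, child, father, mother,
                                  chrom, dnm_pos, window_bp = 80000L) {
  inf <- informative_snps_family(genotypes, child, father, mother)
  half <- window_bp / 2
  chr <- chrom
  out <- inf[
    chrom == chr & abs(pos - dnm_pos) <= half & pos != dnm_pos
  ]
  out[, distance := pmax(1, abs(pos - dnm_pos))]
  out[, .(chrom, pos, parent_of_origin, distance)]
}

#' All informative SNPs of one trio
#'
#' Family-level bulk version of [find_informative_snps()] without the
#' window restriction (applied later per DNM).
#'
#' @inheritParams find_informative_snps
#' @return `data.table`: `chrom`, `pos`, `parent_of_origin`.
#' @export
informative_snps_family <- function(genotypes, child, father, mother) {
  ped <- data.table(
    family = "f", sample_id = c(child, father, mother),
    role = c("child", "father", "mother"), father = father, mother = mother
  )
  g <- copy(genotypes[sample_id %in% c(child, father, mother)])
  g[, family := "f"]
  .informative_snps_all(g, ped)[, .(chrom, pos, parent_of_origin)]
}

# Vectorized informative-SNP derivation for every trio in the pedigree.
.informative_snps_all <- function(genotypes, pedigree) {
  ch <- pedigree[role == "child", .(family, child = sample_id, father, mother)]
  g <- genotypes[, .(family, chrom, pos, sample_id, gt)]
  x <- g[ch, on = c("family", sample_id = "child"),
    allow.cartesian = TRUE, nomatch = NULL,
    .(family, child = sample_id, father, mother, chrom, pos, gt_child = gt)
  ]
  x <- x[gt_child == "0/1"]
  x[g, on = c("family", "chrom", "pos", father = "sample_id"), gt_father := i.gt]
  x[g, on = c("family", "chrom", "pos", mother = "sample_id"), gt_mother := i.gt]
  has_alt <- function(gt) !is.na(gt) & grepl("1", gt, fixed = TRUE)
  pat <- x[!is.na(gt_mother) & gt_mother == "0/0" & has_alt(gt_father)]
  mat <- x[!is.na(gt_father) & gt_father == "0/0" & has_alt(gt_mother)]
  rbind(
    pat[, .(family, child, chrom, pos, parent_of_origin = "paternal")],
    mat[, .(family, child, chrom, pos, parent_of_origin = "maternal")]
  )
}

#' Inheritance score of a single read
#'
#' Tagging SNPs observed on the read are assigned -1 (paternal) or +1
#' (maternal) — a read showing a SNP's alternate allele is tagged with the
#' SNP's parent of origin, a read showing the reference allele with the
#' other parent — and averaged with weights inversely proportional to each
#' SNP's distance from the DNM site. A negative score indicates a
#' paternally inherited read, a positive score a maternal one; a score of
#' exactly zero, or an empty SNP set, leaves the read unassigned.
#'
#' @param observations `data.table` with columns `snp_pos` and `allele`
#'   (`"ref"`/`"alt"`) for SNPs observed on the read.
#' @param snps Informative SNPs (`pos`, `parent_of_origin`).
#' @param dnm_pos DNM coordinate used for distance weighting.
#' @param weighting `"1/d"` (default) or `"1/d^2"`.
#' @return `list(score =, haplotype =)` with haplotype in
#'   `paternal`/`maternal`/`unassigned`.
#' @export
score_read <- function(observations, snps, dnm_pos, weighting = c("1/d", "1/d^2")) {
  weighting <- match.arg(weighting)
  obs <- merge(
    as.data.table(observations), as.data.table(snps)[, .(pos, parent_of_origin)],
    by.x = "snp_pos", by.y = "pos"
  )
  if (nrow(obs) == 0L) {
    return(list(score = NA_real_, haplotype = "unassigned"))
  }
  d <- pmax(1, abs(obs$snp_pos - dnm_pos))
  w <- if (weighting == "1/d") 1 / d else 1 / d^2
  tag_parent <- fifelse(
    obs$allele == "alt", obs$parent_of_origin,
    fifelse(obs$parent_of_origin == "paternal", "maternal", "paternal")
  )
  s <- fifelse(tag_parent == "paternal", -1, 1)
  score <- sum(s * w) / sum(w)
  hap <- if (score < 0) "paternal" else if (score > 0) "maternal" else "unassigned"
  list(score = score, haplotype = hap)
}

#' Phase one variant from its scored reads
#'
#' If all reads carrying the de novo allele fall on one haplotype the
#' variant is assigned to that parent; alleles on both haplotypes yield a
#' conflict; no assignable carrier reads leave it unphased.
#'
#' @param phased_reads `data.table` with `carries_dnm_allele` (logical) and
#'   `haplotype` (`paternal`/`maternal`/`unassigned`).
#' @return One of `"paternal"`, `"maternal"`, `"unphased"`, `"conflict"`.
#' @export
phase_variant <- function(phased_reads) {
  pr <- as.data.table(phased_reads)
  haps <- unique(pr[
    carries_dnm_allele == TRUE & haplotype %in% c("paternal", "maternal"),
    haplotype
  ])
  if (length(haps) == 0L) {
    "unphased"
  } else if (length(haps) == 1L) {
    haps
  } else {
    "conflict"
  }
}

#' Combine HiFi and ONT phase calls
#'
#' The HiFi assignment is preferred; ONT is used when HiFi is unphased or
#' conflicted. Variants with tagging SNPs that conflict in both platforms
#' are flagged for exclusion as presumed sequencing error.
#'
#' @param hifi_call,ont_call Outputs of [phase_variant()] (`ont_call` may
#'   be `NA` when no ONT reads exist).
#' @return `list(parent_of_origin =, source =, exclude =)`.
#' @export
phase_with_fallback <- function(hifi_call, ont_call = NA_character_) {
  phased <- c("paternal", "maternal")
  if (hifi_call %in% phased) {
    return(list(parent_of_origin = hifi_call, source = "hifi", exclude = FALSE))
  }
  if (!is.na(ont_call) && ont_call %in% phased) {
    return(list(parent_of_origin = ont_call, source = "ont", exclude = FALSE))
  }
  if (hifi_call == "conflict" && (!is.na(ont_call) && ont_call == "conflict")) {
    return(list(parent_of_origin = "conflict", source = "none", exclude = TRUE))
  }
  if (hifi_call == "conflict" || (!is.na(ont_call) && ont_call == "conflict")) {
    return(list(parent_of_origin = "conflict", source = "none", exclude = TRUE))
  }
  list(parent_of_origin = "unphased", source = "none", exclude = FALSE)
}

# Bulk scoring: per-read inheritance scores for child long reads at the
# given variants. Returns one row per (variant, read) with score and
# haplotype.
.score_reads_bulk <- function(variants, reads, read_snps, inf_snps, params,
                              weighting = "1/d", window_bp = 80000L) {
  vr <- reads[variants[, .(family, child, chrom, pos)],
    on = c("family", "sample" = "child", "chrom", "pos"), nomatch = NULL,
    .(
      family, child = sample, chrom, pos, platform, tissue, allele,
      base_quality, mapping_quality, read_id
    )
  ]
  vr <- vr[
    platform %in% LONG_READ_PLATFORMS &
      mapping_quality >= params$long_read_min_mapq &
      base_quality >= params$bq_high &
      !(platform == "hifi" & tissue != "blood")
  ]
  if (nrow(vr) == 0L) {
    return(data.table(
      family = character(), child = character(), chrom = character(),
      pos = numeric(), platform = character(), read_id = character(),
      carries_dnm_allele = logical(), score = numeric(), haplotype = character()
    ))
  }
  obs <- read_snps[vr[, .(family, child, chrom, pos, platform, read_id)],
    on = c("family", "sample" = "child", "chrom", "read_id"),
    nomatch = NULL, allow.cartesian = TRUE,
    .(family, child = sample, chrom, pos, platform, read_id, snp_pos, allele)
  ]
  obs <- merge(obs, inf_snps,
    by.x = c("child", "chrom", "snp_pos"), by.y = c("child", "chrom", "pos")
  )
  obs <- obs[abs(snp_pos - pos) <= window_bp / 2 & snp_pos != pos]
  if (nrow(obs) > 0L) {
    obs[, d := pmax(1, abs(snp_pos - pos))]
    obs[, w := if (weighting == "1/d") 1 / d else 1 / d^2]
    obs[, tag := fifelse(
      xor(allele == "alt", parent_of_origin == "paternal"), 1, -1
    )]
    sc <- obs[, .(score = sum(tag * w) / sum(w)), by = .(read_id, pos)]
  } else {
    sc <- data.table(read_id = character(), pos = numeric(), score = numeric())
  }
  out <- sc[vr, on = c("read_id", "pos")]
  out[, haplotype := fifelse(
    is.na(score) | score == 0, "unassigned",
    fifelse(score < 0, "paternal", "maternal")
  )]
  out[, carries_dnm_allele := allele == "alt"]
  out[, .(
    family, child, chrom, pos, platform, read_id, carries_dnm_allele,
    score, haplotype
  )]
}

#' Phase validated variants across a cohort
#'
#' Computes per-read inheritance scores for child blood HiFi and cell-line
#' ONT reads, phases each variant per platform, and combines platforms
#' with HiFi preference. Informative SNPs are derived from the family
#' genotype records.
#'
#' @param variants Validated variant table (`family`, `child`, `chrom`,
#'   `pos`).
#' @param genotypes,pedigree,reads,read_snps Cohort tables.
#' @param params A [filter_params()] object.
#' @param window_bp Phasing window (80 kbp).
#' @param weighting Distance weighting of SNP tags.
#' @return `list(calls =, read_haplotypes =)`: per-variant
#'   `parent_of_origin` (`paternal`/`maternal`/`unphased`/`conflict`),
#'   `phase_source` and `phase_exclude`, plus the per-read haplotype table
#'   used downstream by the origin classifier.
#' @export
phase_variants <- function(variants, genotypes, pedigree, reads, read_snps,
                           params = filter_params(), window_bp = 80000L,
                           weighting = "1/d") {
  inf <- .informative_snps_all(genotypes, pedigree)
  rh <- .score_reads_bulk(
    variants, reads, read_snps, inf, params, weighting, window_bp
  )
  pv <- rh[, .(
    call = phase_variant(.SD)
  ), by = .(family, child, chrom, pos, platform)]
  pvw <- dcast(pv, family + child + chrom + pos ~ platform, value.var = "call")
  for (col in c("hifi", "ont")) {
    if (!col %in% names(pvw)) pvw[, (col) := NA_character_]
  }
  base <- variants[, .(family, child, chrom, pos)]
  if (nrow(base) == 0L) {
    return(list(
      calls = data.table(
        family = character(), child = character(), chrom = character(),
        pos = numeric(), parent_of_origin = character(),
        phase_source = character(), phase_exclude = logical(),
        hifi_call = character(), ont_call = character()
      ),
      read_haplotypes = rh
    ))
  }
  pvw <- pvw[base, on = c("family", "child", "chrom", "pos")]
  pvw[is.na(hifi), hifi := "unphased"]
  calls <- pvw[, {
    r <- phase_with_fallback(hifi, ont)
    .(
      parent_of_origin = r$parent_of_origin, phase_source = r$source,
      phase_exclude = r$exclude, hifi_call = hifi, ont_call = ont
    )
  }, by = .(family, child, chrom, pos)]
  list(calls = calls, read_haplotypes = rh)
}
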