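# Synthetic trio-cohort generator.
#
# The generator builds abstract-coordinate genomes (no nucleotide sequence;
# reference/alternate bases and dinucleotide context labels are attached to
# each site) and emulates the statistical structure the downstream analyses
# assume: germline DNMs with paternal bias and parental-age effects, mosaic
# postzygotic mutations, tri-platform read evidence with quality-calibrated
# errors, informative SNPs at configurable density, and two artifact
# classes (dropped parental haplotypes, recurrent cross-sample errors).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.track_mean_len <- c(
  segdup = 4e4, tandem_repeat = 2e3, repeatmasker = 5e3,
  homopolymer = 8, exon = 2e3
)

#' Simulate a pedigree of quad and trio families
#'
#' Each family has two parents with ages at birth drawn from the configured
#' (truncated) normal distribution and one or two children with random sex.
#' The first child of each family is flagged as the proband (phenotype 2).
#'
#' @param config A [sim_config()] object.
#' @return `data.table` with columns `family`, `sample_id`, `father`,
#'   `mother`, `sex` (1 = male, 2 = female), `phenotype`, `role`
#'   (father/mother/child), `father_age`, `mother_age` (children only).
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  n_quads <- as.integer(round(config$n_families * config$quad_fraction))
  n_children <- c(rep(2L, n_quads), rep(1L, config$n_families - n_quads))
  fams <- sprintf("fam%03d", seq_len(config$n_families))

  draw_age <- function(n) {
    a <- rnorm(n, config$parental_age_mean, config$parental_age_sd)
    pmax(a, config$parental_age_min)
  }
  fa_age <- draw_age(config$n_families)
  mo_age <- draw_age(config$n_families)

  parents <- data.table(
    family = rep(fams, each = 2L),
    sample_id = paste0(rep(fams, each = 2L), c(".fa", ".mo")),
    father = "0", mother = "0",
    sex = rep(c(1L, 2L), config$n_families),
    phenotype = 1L,
    role = rep(c("father", "mother"), config$n_families),
    father_age = NA_real_, mother_age = NA_real_
  )
  kids <- data.table(
    family = rep(fams, n_children),
    idx = unlist(lapply(n_children, seq_len))
  )
  kids[, `:=`(
    sample_id = sprintf("%s.c%d", family, idx),
    father = paste0(family, ".fa"),
    mother = paste0(family, ".mo"),
    sex = sample(c(1L, 2L), .N, replace = TRUE),
    phenotype = ifelse(idx == 1L, 2L, 1L),
    role = "child",
    father_age = rep(fa_age, n_children),
    mother_age = rep(mo_age, n_children)
  )]
  kids[, idx := NULL]
  ped <- rbind(parents, kids)
  setkey(ped, family, sample_id)
  ped[]
}

#' Simulate annotation tracks over the synthetic genome
#'
#' Draws non-overlapping intervals per track and chromosome until the
#' configured genome fraction is approximately covered. Segmental
#' duplications carry a percent-identity bin, homopolymers a base and run
#' length. Intervals are half-open and 0-based, BED style.
#'
#' @param config A [sim_config()] object.
#' @return `data.table`: `track`, `chrom`, `start`, `end`, `identity`,
#'   `hp_base`, `hp_len`.
#' @export
simulate_region_tracks <- function(config) {
  tracks <- config$region_tracks
  out <- vector("list", 0L)
  if (is.null(tracks) || nrow(tracks) == 0L || config$genome_length <= 0) {
    return(data.table(
      track = character(), chrom = character(), start = numeric(),
      end = numeric(), identity = character(), hp_base = character(),
      hp_len = integer()
    ))
  }
  L <- config$genome_length
  for (chr_i in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", chr_i)
    for (ti in seq_len(nrow(tracks))) {
      tname <- tracks$track[ti]
      frac <- tracks$fraction[ti]
      if (frac <= 0) next
      mlen <- if (tname %in% names(.track_mean_len)) {
        .track_mean_len[[tname]]
      } else {
        5e3
      }
      n <- max(1L, as.integer(round(frac * L / mlen)))
      start <- sort(floor(runif(n, 0, L)))
      len <- if (tname == "homopolymer") {
        sample(4:15, n, replace = TRUE)
      } else {
        pmax(1, round(rexp(n, 1 / mlen)))
      }
      end <- pmin(start + len, L)
      # greedy drop of intervals overlapping an earlier one
      keep <- start >= shift(cummax(end), fill = -1)
      start <- start[keep]
      end <- end[keep]
      n <- length(start)
      dt <- data.table(
        track = tname, chrom = chrom, start = start, end = end,
        identity = NA_character_, hp_base = NA_character_,
        hp_len = NA_integer_
      )
      if (tname == "segdup") {
        dt[, identity := sample(c("90-95", "95-98", "98-99", ">99"), .N,
          replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)
        )]
      }
      if (tname == "homopolymer") {
        dt[, `:=`(
          hp_base = sample(c("A", "C", "G", "T"), .N, replace = TRUE),
          hp_len = as.integer(end - start)
        )]
      }
      out[[length(out) + 1L]] <- dt
    }
  }
  rbindlist(out)
}

# Piecewise-constant placement weights per chromosome. Returns a table of
# segments [start, end) with germline and postzygotic weights, normalized so
# the length-weighted mean weight is 1 (multipliers redistribute mutations,
# they do not change the genome-wide expectation).
.placement_segments <- function(config, tracks) {
  L <- config$genome_length
  cfgt <- config$region_tracks
  segs <- vector("list", config$n_chromosomes)
  for (chr_i in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", chr_i)
    tr <- tracks[tracks$chrom == chrom]
    breaks <- sort(unique(c(0, L, tr$start, tr$end)))
    s <- data.table(
      chrom = chrom, start = breaks[-length(breaks)], end = breaks[-1],
      wg = 1, wp = 1
    )
    if (nrow(tr) > 0L && !is.null(cfgt) && nrow(cfgt) > 0L) {
      mid <- (s$start + s$end) / 2
      for (ti in seq_len(nrow(cfgt))) {
        tt <- tr[track == cfgt$track[ti]]
        if (nrow(tt) == 0L) next
        idx <- findInterval(mid, tt$start)
        covered <- idx >= 1L & mid < tt$end[pmax(idx, 1L)]
        s[covered, `:=`(
          wg = wg * cfgt$germline_mult[ti],
          wp = wp * cfgt$pzm_mult[ti]
        )]
      }
    }
    segs[[chr_i]] <- s
  }
  segs <- rbindlist(segs)
  len <- segs$end - segs$start
  segs[, wg := wg / sum(wg * len) * sum(len)]
  segs[, wp := wp / sum(wp * len) * sum(len)]
  segs[]
}

# Sample n 1-based positions from the piecewise-uniform placement density.
.sample_positions <- function(n, segs, weight_col) {
  if (n == 0L) {
    return(data.table(chrom = character(), pos = numeric()))
  }
  w <- segs[[weight_col]] * (segs$end - segs$start)
  i <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
  data.table(
    chrom = segs$chrom[i],
    pos = floor(runif(n, segs$start[i], segs$end[i])) + 1
  )
}

# Draw substitution classes, reference/alt bases and dinucleotide context
# labels for n SNVs of a given origin; half are stored on the minus strand.
.draw_snv_context <- function(n, origin, config) {
  spec <- if (origin == "germline") config$germline_spectrum else config$pzm_spectrum
  cls <- sample(names(spec), n, replace = TRUE, prob = spec)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  p_cpg <- ifelse(
    cls == "C>T",
    if (origin == "germline") config$cpg_given_ct_germline else config$cpg_given_ct_pzm,
    config$cpg_fraction
  )
  ctx3 <- ifelse(
    ref == "C" & runif(n) < p_cpg, "G",
    sample(c("A", "C", "T"), n, replace = TRUE)
  )
  ctx5 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  flip <- runif(n) < 0.5
  out <- data.table(ref = ref, alt = alt, ctx5 = ctx5, ctx3 = ctx3)
  out[flip, `:=`(
    ref = COMPLEMENT[ref], alt = COMPLEMENT[alt],
    ctx5 = COMPLEMENT[ctx3], ctx3 = COMPLEMENT[ctx5]
  )]
  out[]
}

.draw_indel_alleles <- function(n) {
  len <- 1L + stats::rgeom(n, 0.2)
  ins <- runif(n) < 182 / 533
  data.table(
    class = ifelse(ins, "insertion", "deletion"),
    ref = ifelse(ins, "A", paste0("A", strrep("T", len))),
    alt = ifelse(ins, paste0("A", strrep("T", len)), "A")
  )
}

#' Simulate ground-truth de novo variants for a cohort
#'
#' Per child, paternal and maternal germline counts are Poisson with means
#' `base * fraction + slope * (age - mean age)`, where `base` is the
#' genome-wide expectation `germline_rate * 2 * genome_length` and slopes
#' are scaled to the simulated genome size; postzygotic counts follow the
#' analogous model at `pzm_rate`. Mosaic allele fractions are Beta-drawn.
#' Region multipliers reshape local placement density without changing the
#' genome-wide expectation.
#'
#' @param config A [sim_config()] object.
#' @param pedigree Output of [simulate_pedigree()].
#' @param tracks Annotation tracks from [simulate_region_tracks()]; `NULL`
#'   simulates them (or uses none when the config has no tracks).
#' @return `data.table` of truth variants with context and region labels.
#' @export
simulate_truth_variants <- function(config, pedigree, tracks = NULL) {
  validate_sim_config(config)
  if (is.null(tracks)) tracks <- simulate_region_tracks(config)
  children <- pedigree[role == "child"]
  L_tot <- config$genome_length * config$n_chromosomes
  if (L_tot <= 0 || nrow(children) == 0L) {
    return(.empty_truth())
  }
  scale <- L_tot / config$age_slope_reference_bp
  base_g <- config$germline_rate * 2 * L_tot
  base_p <- config$pzm_rate * 2 * L_tot

  lam <- function(base, frac, slope, age) {
    l <- base * frac + slope * scale * (age - config$parental_age_mean)
    if (any(l < 0)) {
      warning("negative expected DNM count after age adjustment; clamped at 0")
    }
    pmax(l, 0)
  }
  lam_gp <- lam(base_g, config$paternal_fraction, config$paternal_age_slope,
    children$father_age)
  lam_gm <- lam(base_g, 1 - config$paternal_fraction, config$maternal_age_slope,
    children$mother_age)
  lam_pp <- lam(base_p, config$pzm_paternal_fraction, config$pzm_paternal_age_slope,
    children$father_age)
  lam_pm <- lam(base_p, 1 - config$pzm_paternal_fraction, config$pzm_maternal_age_slope,
    children$mother_age)
  lam_ind <- base_g * config$indel_fraction

  segs <- .placement_segments(config, tracks)

  make_block <- function(counts, origin, parent, snv = TRUE) {
    n <- sum(counts)
    if (n == 0L) {
      return(NULL)
    }
    posd <- .sample_positions(n, segs, if (origin == "germline") "wg" else "wp")
    dt <- data.table(
      family = rep(children$family, counts),
      child = rep(children$sample_id, counts),
      chrom = posd$chrom, pos = posd$pos,
      true_origin = origin, true_parent = parent
    )
    if (snv) {
      dt <- cbind(dt, .draw_snv_context(n, origin, config))
      dt[, class := "SNV"]
    } else {
      dt <- cbind(dt, .draw_indel_alleles(n))
      dt[, `:=`(ctx5 = NA_character_, ctx3 = NA_character_)]
    }
    if (origin == "postzygotic") {
      # cell fraction ~ Beta(conc * mean_cf, conc * (1 - mean_cf)),
      # mean_cf = 2 * mosaic_ab_mean (allele balance is half the fraction)
      m <- rbeta(
        n,
        config$mosaic_ab_concentration * 2 * config$mosaic_ab_mean,
        config$mosaic_ab_concentration * (1 - 2 * config$mosaic_ab_mean)
      )
      dt[, true_mosaic_fraction := m]
    } else {
      dt[, true_mosaic_fraction := 1.0]
    }
    dt
  }

  blocks <- list(
    make_block(rpois(nrow(children), lam_gp), "germline", "paternal"),
    make_block(rpois(nrow(children), lam_gm), "germline", "maternal"),
    make_block(rpois(nrow(children), lam_pp), "postzygotic", "paternal"),
    make_block(rpois(nrow(children), lam_pm), "postzygotic", "maternal")
  )
  n_ind <- rpois(nrow(children), lam_ind)
  if (sum(n_ind) > 0L) {
    pz <- runif(sum(n_ind)) < config$pzm_indel_fraction
    posd <- .sample_positions(sum(n_ind), segs, "wg")
    ind <- data.table(
      family = rep(children$family, n_ind),
      child = rep(children$sample_id, n_ind),
      chrom = posd$chrom, pos = posd$pos,
      true_origin = ifelse(pz, "postzygotic", "germline"),
      true_parent = ifelse(
        runif(sum(n_ind)) < config$paternal_fraction, "paternal", "maternal"
      )
    )
    ind <- cbind(ind, .draw_indel_alleles(sum(n_ind)))
    ind[, `:=`(ctx5 = NA_character_, ctx3 = NA_character_)]
    ind[, true_mosaic_fraction := ifelse(
      true_origin == "postzygotic",
      rbeta(
        .N, config$mosaic_ab_concentration * 2 * config$mosaic_ab_mean,
        config$mosaic_ab_concentration * (1 - 2 * config$mosaic_ab_mean)
      ),
      1.0
    )]
    blocks[[length(blocks) + 1L]] <- ind
  }
  truth <- rbindlist(blocks, use.names = TRUE, fill = TRUE)
  if (nrow(truth) == 0L) {
    return(.empty_truth())
  }
  truth <- unique(truth, by = c("child", "chrom", "pos"))
  truth <- .label_regions(truth, tracks)
  truth[, variant_id := sprintf("%s:%s:%.0f", child, chrom, pos)]
  setkey(truth, family, child, chrom, pos)
  truth[]
}

.empty_truth <- function() {
  data.table(
    family = character(), child = character(), chrom = character(),
    pos = numeric(), true_origin = character(), true_parent = character(),
    ref = character(), alt = character(), ctx5 = character(),
    ctx3 = character(), class = character(), true_mosaic_fraction = numeric(),
    in_segdup = logical(), sd_identity = character(), in_tr = logical(),
    in_repeatmasker = logical(), in_exon = logical(), variant_id = character()
  )
}

# Attach region-membership labels to a table with chrom/pos columns.
.label_regions <- function(dt, tracks) {
  dt[, `:=`(
    in_segdup = FALSE, sd_identity = NA_character_, in_tr = FALSE,
    in_repeatmasker = FALSE, in_exon = FALSE
  )]
  if (nrow(tracks) == 0L || nrow(dt) == 0L) {
    return(dt)
  }
  flag <- function(tname, col, idcol = NULL) {
    tt <- tracks[track == tname]
    if (nrow(tt) == 0L) {
      return(invisible(NULL))
    }
    for (chr in unique(dt$chrom)) {
      tc <- tt[chrom == chr]
      if (nrow(tc) == 0L) next
      rows <- which(dt$chrom == chr)
      idx <- findInterval(dt$pos[rows] - 1, tc$start) # 0-based site start
      hit <- idx >= 1L & (dt$pos[rows] - 1) < tc$end[pmax(idx, 1L)]
      set(dt, rows[hit], col, TRUE)
      if (!is.null(idcol)) {
        set(dt, rows[hit], idcol, tc$identity[idx[hit]])
      }
    }
  }
  flag("segdup", "in_segdup", "sd_identity")
  flag("tandem_repeat", "in_tr")
  flag("repeatmasker", "in_repeatmasker")
  flag("exon", "in_exon")
  dt
}

#' Simulate informative (tagging) SNPs around truth variants
#'
#' Generates Poisson-distributed informative SNPs at the configured density
#' inside the phasing window centered on each SNV/indel truth site, each
#' with an unambiguous parent of origin.
#'
#' @param truth Truth table from [simulate_truth_variants()].
#' @param config A [sim_config()] object.
#' @return `data.table`: `family`, `child`, `chrom`, `pos`,
#'   `parent_of_origin`, `ref`, `alt`.
#' @export
simulate_informative_snps <- function(truth, config) {
  sites <- truth[!grepl("^artifact", true_origin)]
  if (nrow(sites) == 0L) {
    return(data.table(
      family = character(), child = character(), chrom = character(),
      pos = numeric(), parent_of_origin = character(), ref = character(),
      alt = character()
    ))
  }
  half <- config$snp_window_bp / 2
  lo <- pmax(1, sites$pos - half)
  hi <- pmin(config$genome_length, sites$pos + half)
  n <- rpois(nrow(sites), (hi - lo + 1) * config$snp_density)
  idx <- rep(seq_len(nrow(sites)), n)
  snps <- data.table(
    family = sites$family[idx],
    child = sites$child[idx],
    chrom = sites$chrom[idx],
    pos = floor(runif(sum(n), lo[idx], hi[idx] + 1)),
    parent_of_origin = sample(c("paternal", "maternal"), sum(n), replace = TRUE),
    ref = "A", alt = "G"
  )
  snps <- snps[!sites[, .(child, chrom, pos)], on = c("child", "chrom", "pos")]
  unique(snps, by = c("family", "child", "chrom", "pos"))
}

# Internal engine: per-read evidence for a set of sites. `sites` must carry
# family, child, chrom, pos, class, model parameters per member resolved by
# the caller into a long (site x member) carrier table.
.reads_for_carriers <- function(carriers, config) {
  profs <- config$platform_profiles
  blocks <- vector("list", length(profs))
  bi <- 1L
  for (pf in names(profs)) {
    p <- profs[[pf]]
    if (p$depth <= 0) next
    depth <- rpois(nrow(carriers), p$depth)
    idx <- rep(seq_len(nrow(carriers)), depth)
    if (length(idx) == 0L) next
    r <- carriers[idx, .(
      family, sample_id, chrom, pos, site_id, class, model, mutant_parent,
      alt_prob
    )]
    n <- nrow(r)
    r[, platform := pf]
    r[, tissue := p$tissue]

    # haplotype sampled per read; constitutional hets use reference-biased
    # haplotype sampling so the expected allele balance is germline_ab_mean
    p_mut <- fifelse(
      r$model == "het", config$germline_ab_mean,
      fifelse(r$model %in% c("mosaic", "none", "lowfrac"), 0.5, 0.5)
    )
    on_mut <- runif(n) < p_mut
    r[, haplotype := fifelse(
      xor(on_mut, mutant_parent == "paternal"), "maternal", "paternal"
    )]
    # true allele on the read
    true_alt <- (r$model == "het" & on_mut) |
      (r$model == "mosaic" & on_mut & runif(n) < r$alt_prob) |
      (r$model == "lowfrac" & runif(n) < r$alt_prob)
    is_indel <- r$class != "SNV"
    noise <- is_indel & true_alt & runif(n) < config$indel_read_noise
    err <- runif(n) < p$error_rate & !is_indel
    u <- runif(n)
    allele <- fifelse(true_alt, "alt", "ref")
    allele[noise] <- "other:X"
    allele[err & true_alt] <- fifelse(u[err & true_alt] < 1 / 3, "ref", "other:N")
    allele[err & !true_alt] <- fifelse(u[err & !true_alt] < 1 / 3, "alt", "other:N")
    correct <- !err & !noise
    r[, base_quality := as.integer(pmin(60, pmax(2, round(
      fifelse(correct, rnorm(n, p$bq_mean, p$bq_sd),
        rnorm(n, p$bq_err_mean, p$bq_err_sd)
      )
    ))))]
    r[, allele := allele]
    r[, mapping_quality := sample(p$mapq_values, n, replace = TRUE, prob = p$mapq_probs)]
    off <- floor(runif(n, 0, p$read_span))
    r[, flank5 := as.integer(off)]
    r[, flank3 := as.integer(p$read_span - off - 1)]
    r[, read_id := sprintf("%s|%s|%s|%d", sample_id, platform, site_id, seq_len(.N))]
    blocks[[bi]] <- r
    bi <- bi + 1L
  }
  out <- rbindlist(blocks[seq_len(bi - 1L)])
  if (nrow(out) == 0L) {
    return(.empty_reads())
  }
  out[, c("model", "mutant_parent", "alt_prob") := NULL]
  setnames(out, "sample_id", "sample")
  out[]
}

.empty_reads <- function() {
  data.table(
    family = character(), sample = character(), chrom = character(),
    pos = numeric(), site_id = character(), class = character(),
    platform = character(), tissue = character(), haplotype = character(),
    base_quality = integer(), allele = character(),
    mapping_quality = integer(), flank5 = integer(), flank3 = integer(),
    read_id = character()
  )
}

# Build the (site x family-member) carrier table for truth (non-artifact)
# variants: the child carries the allele, parents and siblings do not.
.truth_carriers <- function(truth, pedigree) {
  members <- pedigree[, .(family, sample_id, role)]
  carriers <- truth[, .(
    family, child, chrom, pos, site_id = variant_id, class,
    true_origin, true_mosaic_fraction, true_parent
  )][members, on = "family", allow.cartesian = TRUE, nomatch = NULL]
  carriers[, model := "none"]
  carriers[sample_id == child & true_origin == "germline", model := "het"]
  carriers[sample_id == child & true_origin == "postzygotic", model := "mosaic"]
  carriers[, alt_prob := fifelse(model == "mosaic", true_mosaic_fraction, 1.0)]
  carriers[, mutant_parent := true_parent]
  carriers[, c("true_origin", "true_mosaic_fraction", "true_parent", "role", "child") := NULL]
  carriers
}

#' Simulate tri-platform read evidence for truth variants
#'
#' Per site, individual and platform, read depth is Poisson at the profile
#' mean. A constitutional heterozygous child samples the mutant haplotype
#' with probability `germline_ab_mean` (reference bias); a mosaic child
#' samples haplotypes evenly and mutant-haplotype reads carry the allele
#' with probability equal to the mosaic cell fraction. Sequencing errors
#' replace the true base with one of the three others and carry low base
#' quality. Parents and siblings never carry the child's truth allele
#' except through injected artifacts.
#'
#' Informative-SNP observations are produced for child HiFi and ONT reads:
#' each SNP inside the read span is observed with the allele implied by the
#' read's haplotype, flipped with the platform's SNP observation error.
#'
#' @param truth Truth table.
#' @param config A [sim_config()] object.
#' @param pedigree Pedigree table.
#' @param snps Informative SNPs from [simulate_informative_snps()].
#' @return `list(reads = data.table, read_snps = data.table)`.
#' @export
simulate_reads <- function(truth, config, pedigree, snps = NULL) {
  stopifnot(all(c("hifi", "ont", "illumina") %in% names(config$platform_profiles)))
  carriers <- .truth_carriers(truth, pedigree)
  reads <- .reads_for_carriers(carriers, config)
  read_snps <- .observe_snps(reads, truth, snps, config)
  list(reads = reads, read_snps = read_snps)
}

# Informative-SNP observations on child long reads.
.observe_snps <- function(reads, truth, snps, config) {
  empty <- data.table(
    family = character(), sample = character(), read_id = character(),
    chrom = character(), snp_pos = numeric(), allele = character()
  )
  if (is.null(snps) || nrow(snps) == 0L || nrow(reads) == 0L) {
    return(empty)
  }
  cr <- reads[
    platform %in% c("hifi", "ont") &
      paste(sample, chrom, pos) %in% truth[, paste(child, chrom, pos)]
  ]
  if (nrow(cr) == 0L) {
    return(empty)
  }
  cr <- cr[, .(
    family, sample, read_id, chrom, platform, haplotype,
    rstart = pos - flank5, rend = pos + flank3, pos
  )]
  sn <- snps[, .(family, child, chrom, snp_pos = pos, parent_of_origin)]
  obs <- cr[sn,
    on = .(family, sample = child, chrom, rstart <= snp_pos, rend >= snp_pos),
    nomatch = NULL,
    .(family, sample, read_id, chrom, platform, haplotype,
      snp_pos = snp_pos, parent_of_origin, pos = x.pos)
  ]
  obs <- obs[snp_pos != pos]
  if (nrow(obs) == 0L) {
    return(empty)
  }
  err_rate <- vapply(config$platform_profiles, function(p) p$snp_obs_error, 0)
  flip <- runif(nrow(obs)) < err_rate[obs$platform]
  hit <- obs$haplotype == obs$parent_of_origin
  obs[, allele := fifelse(xor(hit, flip), "alt", "ref")]
  obs[, c("platform", "haplotype", "parent_of_origin", "pos") := NULL]
  unique(obs, by = c("read_id", "chrom", "snp_pos"))
}

# Genotype records (long format) for truth + artifact + SNP sites.
.build_genotypes <- function(truth, snps, pedigree, config) {
  members <- pedigree[, .(family, sample_id, role)]
  gt_clamp <- function(n) {
    as.integer(pmin(99, pmax(0, round(rnorm(n, config$gq_mean, config$gq_sd)))))
  }
  tg <- truth[, .(family, child, chrom, pos, ref, alt)][
    members,
    on = "family", allow.cartesian = TRUE, nomatch = NULL
  ]
  tg[, gt := fifelse(sample_id == child, "0/1", "0/0")]
  tg[, gq := gt_clamp(.N)]
  tg[, c("child", "role") := NULL]
  out <- tg
  if (!is.null(snps) && nrow(snps) > 0L) {
    sped <- pedigree[, .(family, sample_id, father, mother)]
    kid <- sped[snps, on = c("family", sample_id = "child")]
    sg <- snps[members, on = "family", allow.cartesian = TRUE, nomatch = NULL]
    sg <- sg[, .(family, child, chrom, pos, ref, alt, parent_of_origin,
      sample_id, role
    )]
    sg[, gt := "0/0"]
    sg[sample_id == child, gt := "0/1"]
    sg[
      (role == "father" & parent_of_origin == "paternal") |
        (role == "mother" & parent_of_origin == "maternal"),
      gt := "0/1"
    ]
    sg[, gq := gt_clamp(.N)]
    sg <- sg[, .(family, chrom, pos, ref, alt, sample_id, gt, gq)]
    out <- rbind(out, sg)
  }
  unique(out, by = c("family", "chrom", "pos", "sample_id"))
}

#' Inject artifact classes into a synthetic bundle
#'
#' Adds (a) dropped-haplotype runs: clusters of three to five false
#' candidate sites within 1 kbp where one parent actually carries the
#' allele but was genotyped homozygous reference, and (b) recurrent
#' sequencing errors: identical false alleles visible in the HiFi reads of
#' at least two unrelated samples. Both classes are recorded in the truth
#' table with `true_origin` values `artifact_dropped_hap` and
#' `artifact_recurrent`.
#'
#' @param bundle A cohort bundle (see [simulate_cohort()]).
#' @param config A [sim_config()] object.
#' @return The augmented bundle.
#' @export
inject_artifacts <- function(bundle, config) {
  ped <- bundle$pedigree
  children <- ped[role == "child"]
  L_tot <- config$genome_length * config$n_chromosomes
  n_runs <- rpois(nrow(children), config$dropped_hap_run_rate * L_tot)
  n_rec <- rpois(nrow(children), config$recurrent_error_rate * L_tot)
  if (sum(n_runs) + sum(n_rec) == 0L) {
    return(bundle)
  }

  art <- list()
  if (sum(n_runs) > 0L) {
    runs <- data.table(
      family = rep(children$family, n_runs),
      child = rep(children$sample_id, n_runs)
    )
    runs[, `:=`(
      chrom = paste0("chr", sample.int(config$n_chromosomes, .N, replace = TRUE)),
      start = floor(runif(.N, 1, pmax(2, config$genome_length - 1000))),
      k = sample(3:5, .N, replace = TRUE),
      dropped = sample(c("paternal", "maternal"), .N, replace = TRUE)
    )]
    idx <- rep(seq_len(nrow(runs)), runs$k)
    dh <- runs[idx, .(family, child, chrom, dropped)]
    dh[, pos := runs$start[idx] + floor(runif(.N, 0, 801))]
    dh <- unique(dh, by = c("child", "chrom", "pos"))
    dh[, `:=`(
      ref = "A", alt = "T", ctx5 = "A", ctx3 = "A", class = "SNV",
      true_origin = "artifact_dropped_hap", true_parent = dropped,
      true_mosaic_fraction = 1.0
    )]
    dh[, dropped := NULL]
    art[[length(art) + 1L]] <- dh
  }
  if (sum(n_rec) > 0L) {
    rec <- data.table(
      family = rep(children$family, n_rec),
      child = rep(children$sample_id, n_rec)
    )
    rec[, `:=`(
      chrom = paste0("chr", sample.int(config$n_chromosomes, .N, replace = TRUE)),
      pos = floor(runif(.N, 1, config$genome_length + 1)),
      ref = "C", alt = "A", ctx5 = "A", ctx3 = "A", class = "SNV",
      true_origin = "artifact_recurrent", true_parent = NA_character_,
      true_mosaic_fraction = 1.0
    )]
    art[[length(art) + 1L]] <- rec
  }
  art <- rbindlist(art, use.names = TRUE, fill = TRUE)
  art <- .label_regions(art, bundle$tracks)
  art[, variant_id := sprintf("%s:%s:%.0f", child, chrom, pos)]

  # carrier models: dropped-haplotype sites are genuine inherited hets (the
  # child and one parent both carry); recurrent errors are low-fraction
  # noise in the index child plus high-quality error reads in >= 2
  # unrelated samples.
  members <- ped[, .(family, sample_id, role)]
  carriers <- art[, .(
    family, child, chrom, pos, site_id = variant_id, class, true_origin,
    true_parent
  )][members, on = "family", allow.cartesian = TRUE, nomatch = NULL]
  carriers[, `:=`(model = "none", alt_prob = 1.0, mutant_parent = true_parent)]
  carriers[
    true_origin == "artifact_dropped_hap" &
      (sample_id == child |
        (role == "father" & true_parent == "paternal") |
        (role == "mother" & true_parent == "maternal")),
    model := "het"
  ]
  carriers[true_origin == "artifact_recurrent" & sample_id == child,
    `:=`(model = "lowfrac", alt_prob = 0.15, mutant_parent = "paternal")
  ]
  carriers[is.na(mutant_parent), mutant_parent := "paternal"]
  carriers[, c("true_origin", "true_parent", "role", "child") := NULL]
  art_reads <- .reads_for_carriers(carriers, config)

  # recurrent-error reads in two unrelated children (HiFi, high quality)
  rec_sites <- art[true_origin == "artifact_recurrent"]
  if (nrow(rec_sites) > 0L && nrow(children) > 2L) {
    hifi <- config$platform_profiles$hifi
    ns <- nrow(rec_sites)
    # two unrelated children per recurrent site (rejection-resampled)
    picks <- matrix(sample.int(nrow(children), 2L * ns, replace = TRUE), ncol = 2L)
    for (it in 1:20) {
      bad <- children$family[picks[, 1]] == rec_sites$family |
        children$family[picks[, 2]] == rec_sites$family |
        picks[, 1] == picks[, 2]
      if (!any(bad)) break
      picks[bad, ] <- sample.int(nrow(children), 2L * sum(bad), replace = TRUE)
    }
    carriers2 <- data.table(
      site = rep(seq_len(ns), 2L), pick = as.vector(picks)
    )
    k <- pmax(1L, rbinom(nrow(carriers2), max(1, round(hifi$depth)), 0.1))
    idx <- rep(seq_len(nrow(carriers2)), k)
    n <- length(idx)
    si <- carriers2$site[idx]
    pi <- carriers2$pick[idx]
    extra <- data.table(
      family = children$family[pi], sample = children$sample_id[pi],
      chrom = rec_sites$chrom[si], pos = rec_sites$pos[si],
      site_id = rec_sites$variant_id[si], class = "SNV",
      platform = "hifi", tissue = hifi$tissue, haplotype = "paternal",
      base_quality = as.integer(pmin(60, pmax(2, round(
        rnorm(n, hifi$bq_mean, hifi$bq_sd)
      )))),
      allele = "alt",
      mapping_quality = sample(hifi$mapq_values, n,
        replace = TRUE, prob = hifi$mapq_probs
      ),
      flank5 = 100L, flank3 = 100L,
      read_id = sprintf(
        "%s|hifi|%s|rec%d", children$sample_id[pi],
        rec_sites$variant_id[si], seq_len(n)
      )
    )
    extra <- extra[children$family[pi] != rec_sites$family[si]]
    art_reads <- rbind(art_reads, extra, use.names = TRUE)
  }

  art_gt <- .build_genotypes(art, NULL, ped, config)

  bundle$truth <- rbind(bundle$truth, art, use.names = TRUE, fill = TRUE)
  bundle$reads <- rbind(bundle$reads, art_reads, use.names = TRUE, fill = TRUE)
  bundle$genotypes <- rbind(bundle$genotypes, art_gt, use.names = TRUE)
  setkey(bundle$truth, family, child, chrom, pos)
  bundle
}

#' Simulate a complete synthetic trio-cohort bundle
#'
#' Runs the full generator: pedigree, annotation tracks, truth variants,
#' informative SNPs, tri-platform read evidence (with SNP observations on
#' long reads), genotype records and injected artifacts. All randomness
#' flows from `config$seed`; a fixed seed yields an identical bundle.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `dnm_bundle` with elements `pedigree`,
#'   `genotypes`, `reads`, `read_snps`, `snps`, `tracks`, `truth`, and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  ped <- simulate_pedigree(config)
  tracks <- simulate_region_tracks(config)
  truth <- simulate_truth_variants(config, ped, tracks)
  snps <- simulate_informative_snps(truth, config)
  rd <- simulate_reads(truth, config, ped, snps)
  genotypes <- .build_genotypes(truth, snps, ped, config)
  bundle <- structure(
    list(
      pedigree = ped, genotypes = genotypes, reads = rd$reads,
      read_snps = rd$read_snps, snps = snps, tracks = tracks,
      truth = truth, config = config
    ),
    class = "dnm_bundle"
  )
  bundle <- inject_artifacts(bundle, config)
  # per-site 5'/3' context labels stand in for the reference sequence
  bundle$contexts <- unique(
    bundle$truth[!is.na(ctx5), .(chrom, pos, ctx5, ctx3)],
    by = c("chrom", "pos")
  )
  bundle
}
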