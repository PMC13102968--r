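# Callable-genome masks and mutation-rate estimation.
#
# A site is callable for a trio when both parents are genotyped 0/0 and
# every trio member has at least one high-quality read (long-read MAPQ
# >= 59) with a base of quality >= 20 at the site. Rates divide de novo
# counts by the ploidy-adjusted callable denominator; intervals are exact
# Poisson (Garwood).

#' Compute a per-trio callable mask from site-level genotypes and reads
#'
#' Evaluates callability at every genotyped site and merges runs of
#' adjacent callable sites into half-open intervals. HiFi reads only;
#' children restricted to blood-derived reads where available. For male
#' sex chromosomes pass `parents = "mother"` (chrX) or `"father"` (chrY):
#' only that parent's evidence is consulted and the 0/0 requirement applies
#' to that parent alone.
#'
#' @param genotypes Long-format genotype records covering the evaluated
#'   sites.
#' @param reads Read-evidence table.
#' @param child,father,mother Trio sample identifiers.
#' @param params A [filter_params()] object.
#' @param parents `"both"` (default), `"mother"` or `"father"`.
#' @return `list(intervals = data.table(chrom, start, end), callable_bp =)`.
#' @export
compute_callable_mask <- function(genotypes, reads, child, father, mother,
                                  params = filter_params(), parents = "both") {
  members <- switch(parents,
    both = c(child, father, mother),
    mother = c(child, mother),
    father = c(child, father),
    stop("parents must be 'both', 'mother' or 'father'")
  )
  par_ids <- setdiff(members, child)
  g <- genotypes[sample_id %in% members]
  gw <- dcast(g, chrom + pos ~ sample_id, value.var = "gt")
  ok_parents <- rep(TRUE, nrow(gw))
  for (id in par_ids) {
    ok_parents <- ok_parents & !is.na(gw[[id]]) & gw[[id]] == "0/0"
  }
  sites <- gw[ok_parents, .(chrom, pos)]
  if (nrow(sites) == 0L) {
    return(list(
      intervals = data.table(chrom = character(), start = numeric(), end = numeric()),
      callable_bp = 0
    ))
  }
  r <- reads[
    platform == "hifi" & sample %in% members &
      mapping_quality >= params$long_read_min_mapq &
      base_quality >= params$bq_high &
      !(sample == child & tissue != "blood")
  ]
  cov <- r[sites, on = c("chrom", "pos"), nomatch = NULL][
    , .(n_cov = uniqueN(sample)), by = .(chrom, pos)
  ]
  callable <- cov[n_cov == length(members), .(chrom, pos)]
  setkey(callable, chrom, pos)
  iv <- callable[, {
    p <- sort(pos)
    grp <- cumsum(c(1L, diff(p) != 1))
    dd <- data.table(pos = p, grp = grp)
    dd[, .(start = min(pos) - 1, end = max(pos)), by = grp][, .(start, end)]
  }, by = chrom]
  list(intervals = iv, callable_bp = sum(iv$end - iv$start))
}

# Merge half-open intervals (per chromosome) with IRanges.
.merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) {
    return(iv)
  }
  out <- iv[, {
    r <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
    .(start = BiocGenerics::start(r) - 1, end = BiocGenerics::end(r))
  }, by = chrom]
  out[]
}

#' Stratify a callable mask by annotation tracks
#'
#' Computes interval-intersection base pairs of the mask with each track,
#' and with segmental-duplication percent-identity bins. Intervals are
#' merged before intersection so nested or overlapping records are not
#' double-counted.
#'
#' @param mask Mask intervals (`chrom`, `start`, `end`; half-open 0-based).
#' @param tracks Track table (`track`, `chrom`, `start`, `end`,
#'   optionally `identity`).
#' @return `data.table`: `stratum`, `bp`.
#' @export
stratify_mask <- function(mask, tracks) {
  mask <- .merge_intervals(as.data.table(mask))
  total <- sum(mask$end - mask$start)
  out <- list(data.table(stratum = "genome", bp = total))
  strata <- unique(tracks$track)
  add <- function(name, tt) {
    bp <- 0
    for (chr in unique(mask$chrom)) {
      m <- mask[chrom == chr]
      t2 <- .merge_intervals(tt[chrom == chr])
      if (nrow(m) == 0L || nrow(t2) == 0L) next
      ir <- IRanges::intersect(
        IRanges::IRanges(m$start + 1, m$end),
        IRanges::IRanges(t2$start + 1, t2$end)
      )
      bp <- bp + sum(BiocGenerics::width(ir))
    }
    data.table(stratum = name, bp = bp)
  }
  for (tr in strata) {
    out[[length(out) + 1L]] <- add(tr, tracks[track == tr])
  }
  if ("identity" %in% names(tracks)) {
    for (idb in stats::na.omit(unique(tracks$identity))) {
      out[[length(out) + 1L]] <- add(
        paste0("segdup_", idb), tracks[track == "segdup" & identity == idb]
      )
    }
  }
  rbindlist(out)
}

#' Point estimate and exact Poisson interval for a mutation rate
#'
#' `rate = count / (ploidy * callable_bp)`; the 95% interval is the exact
#' (Garwood) Poisson interval on the count divided by the same
#' denominator.
#'
#' @param count Mutation count.
#' @param callable_bp Callable base pairs.
#' @param ploidy 2 for autosomes and female X, 1 for male X/Y or
#'   haplotype-specific rates.
#' @param conf_level Confidence level.
#' @return `list(count, denominator_bp, rate, ci_lower, ci_upper)`.
#' @export
mutation_rate <- function(count, callable_bp, ploidy = 2, conf_level = 0.95) {
  if (callable_bp <= 0) stop("zero callable denominator")
  d <- ploidy * callable_bp
  a <- (1 - conf_level) / 2
  lower <- if (count == 0) 0 else qgamma(a, count) / d
  upper <- qgamma(1 - a, count + 1) / d
  list(
    count = count, denominator_bp = d, rate = count / d,
    ci_lower = lower, ci_upper = upper
  )
}

#' Region-stratified germline and postzygotic rates
#'
#' Per stratum and origin class, computes cohort rates (pooled counts over
#' a shared per-sample callable denominator) plus per-sample rate vectors,
#' and compares each stratum to the genome-wide rate with a one-sample
#' t-test on per-sample differences, Benjamini-Hochberg corrected across
#' strata.
#'
#' @param variants Classified variants with `final_origin` and logical
#'   region columns (`in_segdup`, `in_tr`, ...), plus `child`.
#' @param strata_bp `data.table(stratum, bp)` of callable bp per stratum
#'   (per sample; assumed shared across samples, as in the synthetic
#'   cohorts).
#' @param children Vector of all child ids (zero-count samples included).
#' @param ploidy Ploidy factor (2 autosomal).
#' @return `data.table` with per-stratum counts, rates, CIs, t-test p and
#'   BH q values per origin class.
#' @export
stratified_rates <- function(variants, strata_bp, children, ploidy = 2) {
  strata_bp <- as.data.table(strata_bp)
  region_col <- c(
    genome = NA, segdup = "in_segdup", tandem_repeat = "in_tr",
    repeatmasker = "in_repeatmasker", exon = "in_exon"
  )
  out <- list()
  for (orig in c("germline", "postzygotic")) {
    v <- variants[final_origin == orig]
    per_sample <- list()
    for (i in seq_len(nrow(strata_bp))) {
      st <- strata_bp$stratum[i]
      bp <- strata_bp$bp[i]
      if (bp <= 0) next
      if (st == "genome") {
        vs <- v
      } else if (st %in% names(region_col) && !is.na(region_col[[st]])) {
        vs <- v[v[[region_col[[st]]]] == TRUE]
      } else if (startsWith(st, "segdup_")) {
        idb <- sub("^segdup_", "", st)
        vs <- v[in_segdup == TRUE & sd_identity == idb]
      } else {
        next
      }
      cnt <- vs[, .N, by = child][
        data.table(child = children),
        on = "child"
      ]
      cnt[is.na(N), N := 0L]
      rates <- cnt$N / (ploidy * bp)
      mr <- mutation_rate(sum(cnt$N), length(children) * bp, ploidy)
      per_sample[[st]] <- rates
      out[[length(out) + 1L]] <- data.table(
        origin = orig, stratum = st, count = sum(cnt$N),
        callable_bp = bp, rate = mr$rate,
        ci_lower = mr$ci_lower, ci_upper = mr$ci_upper,
        mean_sample_rate = mean(rates)
      )
    }
    # one-sample t-tests of per-sample (stratum - genome) differences
    if (!is.null(per_sample$genome)) {
      idx <- which(vapply(out, function(x) x$origin[1] == orig, TRUE))
      pvals <- rep(NA_real_, length(idx))
      for (j in seq_along(idx)) {
        st <- out[[idx[j]]]$stratum
        if (st == "genome") next
        dif <- per_sample[[st]] - per_sample$genome
        if (length(dif) > 1 && stats::sd(dif) > 0) {
          pvals[j] <- stats::t.test(dif)$p.value
        }
      }
      qvals <- rep(NA_real_, length(pvals))
      has <- !is.na(pvals)
      qvals[has] <- p.adjust(pvals[has], method = "BH")
      for (j in seq_along(idx)) {
        out[[idx[j]]][, `:=`(p_value = pvals[j], q_value = qvals[j])]
      }
    }
  }
  rbindlist(out, fill = TRUE)
}

#' Parent-specific germline mutation rates
#'
#' Rates per parental haplotype use haplotype-specific denominators: one
#' haplotype per parent, so `callable_bp * 1` each. Unphased variants are
#' excluded and reported as a remainder.
#'
#' @param variants Classified variants with `parent_of_origin` and
#'   `final_origin`.
#' @param callable_bp Callable bp per sample.
#' @param n_children Number of children in the cohort.
#' @return `data.table` with paternal/maternal rates, the
#'   paternal:maternal ratio and the unphased remainder count.
#' @export
parent_specific_rates <- function(variants, callable_bp, n_children) {
  v <- variants[final_origin == "germline"]
  n_pat <- v[parent_of_origin == "paternal", .N]
  n_mat <- v[parent_of_origin == "maternal", .N]
  n_unphased <- v[!parent_of_origin %in% c("paternal", "maternal"), .N]
  denom <- callable_bp * n_children # one haplotype per parent
  pat <- mutation_rate(n_pat, denom, ploidy = 1)
  mat <- mutation_rate(n_mat, denom, ploidy = 1)
  data.table(
    parent = c("paternal", "maternal"),
    count = c(n_pat, n_mat),
    rate = c(pat$rate, mat$rate),
    ci_lower = c(pat$ci_lower, mat$ci_lower),
    ci_upper = c(pat$ci_upper, mat$ci_upper),
    ratio = if (n_mat > 0) n_pat / n_mat else NA_real_,
    n_unphased = n_unphased
  )
}
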