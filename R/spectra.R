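# Mutation-spectrum, clustering and cohort-level statistics.

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")
SNV_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")
MNM_BIN_BREAKS <- c(1, 2, 11, 51, 101, 501)
MNM_BIN_LABELS <- c("1", "2-10", "11-50", "51-100", "101-500")

# Collapse a substitution (with 5'/3' context) onto the purine strand so
# every variant is keyed on an A or C reference base. On the minus strand
# the 3' neighbor is the complement of the plus-strand 5' neighbor.
.collapse_strand <- function(ref, alt, ctx5, ctx3) {
  flip <- ref %in% c("G", "T")
  data.table(
    ref = fifelse(flip, COMPLEMENT[ref], ref),
    alt = fifelse(flip, COMPLEMENT[alt], alt),
    ctx5 = fifelse(flip, COMPLEMENT[ctx3], ctx5),
    ctx3 = fifelse(flip, COMPLEMENT[ctx5], ctx3)
  )
}

#' Six-class substitution labels
#'
#' Purine-strand collapsed `"A>C"`-style labels for SNVs (vectorized).
#'
#' @param ref,alt Reference/alternate bases.
#' @return Character vector of collapsed classes.
#' @export
snv_class <- function(ref, alt) {
  cc <- .collapse_strand(ref, alt, "N", "N")
  paste0(cc$ref, ">", cc$alt)
}

#' Dinucleotide mutation spectrum
#'
#' Counts variants per dinucleotide category (reference base plus 3'
#' context, e.g. `CpG>TpG`), collapsed to the purine strand so categories
#' are keyed on A or C. Variants with unknown context fall into
#' `"other"`.
#'
#' @param variants Table with `ref`, `alt`, `ctx5`, `ctx3` (SNVs).
#' @return `data.table(category, count)` summing to the input count.
#' @export
build_spectrum <- function(variants) {
  v <- as.data.table(variants)
  if (nrow(v) == 0L) {
    return(data.table(category = character(), count = integer()))
  }
  cc <- .collapse_strand(v$ref, v$alt, v$ctx5, v$ctx3)
  bad <- is.na(cc$ref) | is.na(cc$alt) | is.na(cc$ctx3) |
    !cc$ref %in% c("A", "C") | !cc$ctx3 %in% c("A", "C", "G", "T")
  cat <- fifelse(
    bad, "other",
    paste0(cc$ref, "p", cc$ctx3, ">", cc$alt, "p", cc$ctx3)
  )
  data.table(category = cat)[, .(count = .N), by = category][order(category)]
}

#' Per-category enrichment between two spectra
#'
#' For each category, a two-sided chi-squared test on the 2x2 table
#' (category vs rest x class A vs class B), Benjamini-Hochberg corrected
#' across categories. Categories absent from both spectra are skipped.
#'
#' @param spec_a,spec_b Spectrum tables from [build_spectrum()].
#' @return `data.table` with per-category counts, direction
#'   (`enriched_in_b`/`depleted_in_b`), `p_value` and `q_value`.
#' @export
spectrum_enrichment <- function(spec_a, spec_b) {
  a <- as.data.table(spec_a)
  b <- as.data.table(spec_b)
  stopifnot(sum(a$count) > 0, sum(b$count) > 0)
  cats <- union(a$category, b$category)
  m <- data.table(category = cats)
  m <- a[m, on = "category"]
  setnames(m, "count", "count_a")
  m <- b[m, on = "category"]
  setnames(m, "count", "count_b")
  m[is.na(count_a), count_a := 0L]
  m[is.na(count_b), count_b := 0L]
  m <- m[count_a + count_b > 0L]
  tot_a <- sum(m$count_a)
  tot_b <- sum(m$count_b)
  m[, p_value := {
    vapply(seq_len(.N), function(i) {
      tab <- matrix(
        c(
          count_a[i], tot_a - count_a[i],
          count_b[i], tot_b - count_b[i]
        ),
        nrow = 2
      )
      suppressWarnings(chisq.test(tab)$p.value)
    }, 0)
  }]
  m[, q_value := p.adjust(p_value, method = "BH")]
  m[, direction := fifelse(
    count_b / tot_b > count_a / tot_a, "enriched_in_b", "depleted_in_b"
  )]
  m[order(category)]
}

#' Transition/transversion ratio
#'
#' @param variants Table of SNVs with `ref` and `alt`.
#' @return `list(titv, transitions, transversions)`; `titv` is `NA` when
#'   there are no transversions.
#' @export
titv <- function(variants) {
  v <- as.data.table(variants)
  cls <- paste0(v$ref, ">", v$alt)
  ti <- sum(cls %in% TRANSITIONS)
  tv <- nrow(v) - ti
  list(
    titv = if (tv == 0) NA_real_ else ti / tv,
    transitions = ti, transversions = tv
  )
}

#' Find multinucleotide-mutation (MnM) clusters
#'
#' Links variants of the same child on the same chromosome whose
#' consecutive distances are at most `max_gap` bp into maximal chains
#' (transitive: a-b and b-c merge even when a-c exceeds the gap), and bins
#' the pairwise consecutive distances for distance-stratified spectra.
#' Distance is the difference of 1-based positions; immediately adjacent
#' SNVs have distance 1.
#'
#' @param variants Table with `child`, `chrom`, `pos`, `variant_id`.
#' @param max_gap Maximum distance linking two variants (500 bp).
#' @return `list(clusters =, pairs =)`: per-variant cluster membership and
#'   consecutive-pair distances with bin labels (`1`, `2-10`, `11-50`,
#'   `51-100`, `101-500`).
#' @export
find_mnms <- function(variants, max_gap = 500L) {
  v <- as.data.table(variants)[order(child, chrom, pos)]
  if (!"variant_id" %in% names(v)) {
    v[, variant_id := sprintf("%s:%s:%.0f", child, chrom, pos)]
  }
  v[, dist_bp := c(NA, diff(pos)), by = .(child, chrom)]
  v[, cluster_id := cumsum(is.na(dist_bp) | dist_bp > max_gap)]
  v[, n_members := .N, by = cluster_id]
  if (!any(v$n_members >= 2L)) {
    return(list(
      clusters = data.table(
        cluster_id = integer(), child = character(), chrom = character(),
        members = list(), n_members = integer(), span = numeric()
      ),
      pairs = data.table(
        child = character(), chrom = character(), pos = numeric(),
        variant_id = character(), dist_bp = numeric(),
        bin = factor(character(), levels = MNM_BIN_LABELS)
      )
    ))
  }
  clusters <- v[n_members >= 2L, .(
    child = child[1], chrom = chrom[1],
    members = list(variant_id), n_members = .N,
    span = max(pos) - min(pos)
  ), by = cluster_id]
  pairs <- v[!is.na(dist_bp) & dist_bp <= max_gap, .(
    child, chrom, pos, variant_id, dist_bp
  )]
  pairs[, bin := cut(
    dist_bp,
    breaks = c(0.5, 1.5, 10.5, 50.5, 100.5, 500.5),
    labels = MNM_BIN_LABELS
  )]
  list(clusters = clusters, pairs = pairs)
}

#' Parental-age regressions for phased germline counts
#'
#' Two separate ordinary-least-squares fits: per-child paternal-haplotype
#' DNM count on paternal age, and maternal count on maternal age. Slopes
#' are additional DNMs per year.
#'
#' @param counts `data.table` with `child`, `father_age`, `mother_age`,
#'   `n_paternal`, `n_maternal`.
#' @return `list(paternal =, maternal =)`, each with `slope`, `intercept`,
#'   `ci` (95%), and `p_value`.
#' @export
parental_age_regression <- function(counts) {
  dt <- as.data.table(counts)
  if (nrow(dt) < 3L) stop("need at least 3 children for the age regression")
  fit_one <- function(y, x) {
    if (stats::sd(x) == 0) stop("degenerate design: constant parental age")
    fit <- lm(y ~ x)
    sm <- summary(fit)
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      ci = unname(confint(fit)[2, ]), p_value = sm$coefficients[2, 4]
    )
  }
  list(
    paternal = fit_one(dt$n_paternal, dt$father_age),
    maternal = fit_one(dt$n_maternal, dt$mother_age)
  )
}

#' Paternal-bias ratio and tests
#'
#' Cohort paternal:maternal ratio of phased counts, a two-sided Wilcoxon
#' signed-rank test of per-child paternal vs maternal counts, and (when a
#' second class is supplied) a two-sided two-proportion Z-test comparing
#' the paternal fractions of the two classes.
#'
#' @param counts `data.table` with per-child `n_paternal`, `n_maternal`.
#' @param counts2 Optional second class for the proportion comparison.
#' @return `list(ratio, wilcoxon_p, z_p)`.
#' @export
parental_bias_tests <- function(counts, counts2 = NULL) {
  dt <- as.data.table(counts)
  tot_p <- sum(dt$n_paternal)
  tot_m <- sum(dt$n_maternal)
  ratio <- if (tot_m > 0) tot_p / tot_m else NA_real_
  wp <- if (tot_p + tot_m == 0) {
    NA_real_
  } else if (all(dt$n_paternal == dt$n_maternal)) {
    1 # no nonzero paired differences: no evidence of bias
  } else {
    suppressWarnings(
      wilcox.test(dt$n_paternal, dt$n_maternal, paired = TRUE)$p.value
    )
  }
  zp <- NA_real_
  if (!is.null(counts2)) {
    d2 <- as.data.table(counts2)
    n1 <- tot_p + tot_m
    n2 <- sum(d2$n_paternal) + sum(d2$n_maternal)
    if (n1 > 0 && n2 > 0) {
      p1 <- tot_p / n1
      p2 <- sum(d2$n_paternal) / n2
      pp <- (tot_p + sum(d2$n_paternal)) / (n1 + n2)
      se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      if (se > 0) zp <- 2 * pnorm(-abs((p1 - p2) / se))
    }
  }
  list(ratio = ratio, wilcoxon_p = wp, z_p = zp)
}
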