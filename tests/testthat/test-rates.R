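# Callable masks, stratification, rate estimation.

test_that("compute_callable_mask applies the genotype and coverage rules", {
  fam <- "fam001"
  ids <- paste0(fam, c(".fa", ".mo", ".c1"))
  g <- rbindlist(lapply(1:10, function(p) {
    trio_gt(fam, pos = p, gt_father = if (p == 5) "0/1" else "0/0")
  }))
  mk_reads <- function(sample, pos, bq = 30L, mapq = 60L, tissue = "blood") {
    rbindlist(lapply(pos, function(p) {
      read_row(sample, "ref", "hifi", tissue, bq = bq, mapq = mapq, pos = p)
    }))
  }
  reads <- rbind(
    mk_reads(ids[1], 1:10), mk_reads(ids[2], 1:10),
    mk_reads(ids[3], setdiff(1:10, 7)) # child uncovered at 7
  )
  m <- compute_callable_mask(g, reads, ids[3], ids[1], ids[2])
  # callable: 1..10 minus {5: parent het, 7: child uncovered}
  expect_equal(m$callable_bp, 8)
  expect_equal(
    m$intervals[, .(start, end)],
    data.table(start = c(0, 5, 7), end = c(4, 6, 10))
  )

  # a low-MAPQ long read does not rescue coverage
  reads2 <- rbind(reads, mk_reads(ids[3], 7, mapq = 58L))
  expect_equal(compute_callable_mask(g, reads2, ids[3], ids[1], ids[2])$callable_bp, 8)
  # cell-line child HiFi is ignored
  reads3 <- rbind(reads, mk_reads(ids[3], 7, tissue = "cell_line"))
  expect_equal(compute_callable_mask(g, reads3, ids[3], ids[1], ids[2])$callable_bp, 8)
  # base quality >= 20 qualifies (callable uses >=, not >)
  reads4 <- rbind(reads, mk_reads(ids[3], 7, bq = 20L))
  expect_equal(compute_callable_mask(g, reads4, ids[3], ids[1], ids[2])$callable_bp, 9)

  # mother-only evaluation (male chrX rule): father genotype/coverage ignored
  g2 <- rbindlist(lapply(1:4, function(p) {
    trio_gt(fam, pos = p, gt_father = "0/1")
  }))
  reads5 <- rbind(mk_reads(ids[2], 1:4), mk_reads(ids[3], 1:4))
  m2 <- compute_callable_mask(g2, reads5, ids[3], ids[1], ids[2], parents = "mother")
  expect_equal(m2$callable_bp, 4)
})

test_that("stratify_mask performs half-open interval intersection", {
  mask <- data.table(chrom = "chr1", start = 0, end = 100)
  tracks <- data.table(
    track = "segdup", chrom = "chr1", start = 50, end = 150,
    identity = ">99"
  )
  out <- stratify_mask(mask, tracks)
  expect_equal(out[stratum == "genome", bp], 100)
  expect_equal(out[stratum == "segdup", bp], 50)
  expect_equal(out[stratum == "segdup_>99", bp], 50)

  disjoint <- data.table(
    track = "exon", chrom = "chr1", start = 200, end = 300
  )
  expect_equal(stratify_mask(mask, disjoint)[stratum == "exon", bp], 0)

  # nested/overlapping records sum without double counting: brute force
  set.seed(8)
  for (i in 1:15) {
    m <- data.table(
      chrom = "chr1",
      start = sample.int(500, 6), len = sample.int(80, 6)
    )[, end := start + len][, len := NULL]
    t2 <- data.table(
      track = "x", chrom = "chr1",
      start = sample.int(500, 6), len = sample.int(80, 6)
    )[, end := start + len][, len := NULL]
    bp <- stratify_mask(m, t2)[stratum == "x", bp]
    # per-bp membership oracle
    in_m <- logical(700)
    for (j in seq_len(nrow(m))) in_m[(m$start[j] + 1):m$end[j]] <- TRUE
    in_t <- logical(700)
    for (j in seq_len(nrow(t2))) in_t[(t2$start[j] + 1):t2$end[j]] <- TRUE
    expect_equal(bp, sum(in_m & in_t), label = paste("case", i))
  }
})

test_that("mask conservation: disjoint track partition sums to the total", {
  mask <- data.table(
    chrom = "chr1", start = c(0, 150, 400), end = c(100, 300, 500)
  )
  # partition of [0, 500) into disjoint tracks
  parts <- data.table(
    track = c("a", "b", "c"), chrom = "chr1",
    start = c(0, 200, 350), end = c(200, 350, 500)
  )
  out <- stratify_mask(mask, parts)
  expect_equal(
    out[stratum %in% c("a", "b", "c"), sum(bp)],
    out[stratum == "genome", bp]
  )
})

test_that("mutation_rate arithmetic and Poisson interval", {
  r <- mutation_rate(80, 2.66e9, ploidy = 2)
  expect_equal(r$rate, 80 / (2 * 2.66e9), tolerance = 1e-12)
  expect_equal(r$rate, 1.504e-8, tolerance = 1e-3)
  expect_true(r$ci_lower <= r$rate && r$rate <= r$ci_upper)

  r0 <- mutation_rate(0, 1e9)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_lower, 0)
  expect_gt(r0$ci_upper, 0)
  expect_error(mutation_rate(5, 0), "zero callable")
})

test_that("95% Poisson intervals cover the generating rate >= 93% of the time", {
  set.seed(101)
  lambda <- 40
  bp <- 1e9
  true_rate <- lambda / (2 * bp)
  hits <- vapply(1:200, function(i) {
    k <- rpois(1, lambda)
    ci <- mutation_rate(k, bp, ploidy = 2)
    ci$ci_lower <= true_rate && true_rate <= ci$ci_upper
  }, TRUE)
  expect_gte(mean(hits), 0.93)
})

test_that("rate estimator is unbiased over 200 truth-level cohorts", {
  set.seed(55)
  # slopes off so the expectation does not depend on the one fixed pedigree
  cfg <- sim_config(
    n_families = 8, quad_fraction = 0.5, genome_length = 2e8,
    paternal_age_slope = 0, maternal_age_slope = 0,
    pzm_paternal_age_slope = 0, pzm_maternal_age_slope = 0,
    region_tracks = data.table::data.table()
  )
  ped <- simulate_pedigree(cfg)
  nk <- ped[role == "child", .N]
  est <- vapply(1:200, function(i) {
    truth <- simulate_truth_variants(cfg, ped)
    n <- truth[true_origin == "germline" & class == "SNV", .N]
    mutation_rate(n, cfg$genome_length * nk, ploidy = 2)$rate
  }, 0)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - cfg$germline_rate), 2 * mc_se)
})

test_that("stratified_rates controls type I error under the null", {
  set.seed(12)
  strata_bp <- data.table(
    stratum = c("genome", "segdup", "tandem_repeat"),
    bp = c(1e7, 5e5, 3e5)
  )
  children <- sprintf("c%02d", 1:60)
  any_sig <- vapply(1:100, function(i) {
    # uniform placement: per-child counts Poisson, region membership
    # independent of child (multiplier 1 everywhere)
    n <- rpois(length(children), 50)
    v <- data.table(
      child = rep(children, n),
      pos = runif(sum(n), 0, 1e7)
    )
    v[, `:=`(
      final_origin = "germline",
      in_segdup = pos < 5e5,
      in_tr = pos >= 5e5 & pos < 8e5,
      in_repeatmasker = FALSE, in_exon = FALSE, sd_identity = NA_character_
    )]
    out <- stratified_rates(v, strata_bp, children)
    any(!is.na(out$q_value) & out$q_value <= 0.05)
  }, TRUE)
  # nominal 5% FWER; allow 3-sigma binomial slack
  expect_lte(sum(any_sig), 5 + ceiling(3 * sqrt(100 * 0.05 * 0.95)))
})

test_that("parent_specific_rates uses haplotype denominators", {
  v <- data.table(
    final_origin = "germline",
    parent_of_origin = c(rep("paternal", 30), rep("maternal", 10), "unphased")
  )
  out <- parent_specific_rates(v, callable_bp = 1e9, n_children = 5)
  expect_equal(out[parent == "paternal", rate], 30 / 5e9)
  expect_equal(out[parent == "maternal", rate], 10 / 5e9)
  expect_equal(out$ratio[1], 3)
  expect_equal(out$n_unphased[1], 1)

  v2 <- v[parent_of_origin == "paternal"]
  out2 <- parent_specific_rates(v2, 1e9, 5)
  expect_equal(out2[parent == "maternal", rate], 0)
})
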