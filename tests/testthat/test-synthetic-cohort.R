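# Generator: pedigree structure, truth-variant statistics, read evidence,
# artifacts, determinism.

test_that("simulate_pedigree reproduces the cohort structure", {
  set.seed(1)
  cfg <- sim_config(n_families = 42, quad_fraction = 31 / 42)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 157) # 42 families, 31 quads + 11 trios
  expect_equal(ped[role == "child", .N], 73)
  expect_equal(uniqueN(ped$family), 42)

  ped1 <- simulate_pedigree(sim_config(n_families = 1, quad_fraction = 0))
  expect_equal(nrow(ped1), 3)
  expect_equal(ped1[role == "child", .N], 1)

  set.seed(5)
  a <- simulate_pedigree(cfg)
  set.seed(5)
  b <- simulate_pedigree(cfg)
  expect_identical(a, b)

  ages <- ped[role == "child", c(father_age, mother_age)]
  expect_true(all(ages >= cfg$parental_age_min))
})

test_that("truth-variant totals and paternal share match the configuration", {
  set.seed(20)
  # many children via many trio families; truth-level only, no reads
  cfg <- sim_config(
    n_families = 400, quad_fraction = 0, genome_length = 5e7,
    region_tracks = data.table::data.table()
  )
  ped <- simulate_pedigree(cfg)
  truth <- simulate_truth_variants(cfg, ped)
  nk <- ped[role == "child", .N]
  g <- truth[true_origin == "germline" & class == "SNV"]
  exp_g <- cfg$germline_rate * 2 * cfg$genome_length * nk
  expect_lt(abs(nrow(g) - exp_g), 3 * sqrt(exp_g))
  # empirical paternal share of germline variants
  share <- g[, mean(true_parent == "paternal")]
  se <- sqrt(0.799 * 0.201 / nrow(g))
  expect_lt(abs(share - 0.799), 3 * se)
  # postzygotic mosaic fractions strictly below 1, germline exactly 1
  expect_true(all(truth[true_origin == "postzygotic", true_mosaic_fraction < 1]))
  expect_true(all(truth[true_origin == "germline", true_mosaic_fraction == 1]))
  expect_true(all(truth$pos >= 1 & truth$pos <= cfg$genome_length))
})

test_that("zero-length genome and zero age slopes behave as stated", {
  cfg0 <- sim_config(genome_length = 0)
  ped <- simulate_pedigree(sim_config(n_families = 2))
  expect_equal(nrow(simulate_truth_variants(cfg0, ped)), 0)

  set.seed(3)
  cfg <- sim_config(
    n_families = 150, quad_fraction = 0, genome_length = 5e7,
    paternal_age_slope = 0, maternal_age_slope = 0,
    pzm_paternal_age_slope = 0, pzm_maternal_age_slope = 0,
    region_tracks = data.table::data.table()
  )
  ped <- simulate_pedigree(cfg)
  truth <- simulate_truth_variants(cfg, ped)
  counts <- truth[true_origin == "germline",
    .N,
    by = .(child)
  ][ped[role == "child"], on = c(child = "sample_id")]
  counts[is.na(N), N := 0]
  fit <- lm(N ~ father_age, data = counts)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(coef(fit)[2]), 3 * se) # null slope
})

test_that("sampled allele balance matches the configured means", {
  set.seed(77)
  cfg <- sim_config(
    n_families = 1, quad_fraction = 0, genome_length = 1e9,
    germline_rate = 1.2e-7, pzm_rate = 6e-8, indel_fraction = 0,
    region_tracks = data.table::data.table(),
    platform_profiles = list(
      hifi = platform_profile(30, 15000L, "blood", 1e-4, 35, 4),
      ont = platform_profile(0, 30000L, "cell_line", 5e-3, 25, 5),
      illumina = platform_profile(0, 150L, "blood", 1e-3, 32, 4)
    )
  )
  ped <- simulate_pedigree(cfg)
  truth <- simulate_truth_variants(cfg, ped)
  expect_gt(truth[true_origin == "germline", .N], 150)
  rd <- simulate_reads(truth, cfg, ped)$reads
  child_reads <- rd[sample %in% ped[role == "child", sample_id]]
  ab <- child_reads[truth[, .(chrom, pos, true_origin, child)],
    on = c("chrom", "pos", sample = "child"), nomatch = NULL
  ][, .(ab = mean(allele == "alt")), by = .(chrom, pos, true_origin)]

  abg <- ab[true_origin == "germline"]
  se_g <- sd(abg$ab) / sqrt(nrow(abg))
  expect_lt(abs(mean(abg$ab) - 0.48), 3 * se_g + 0.005)

  abp <- ab[true_origin == "postzygotic"]
  se_p <- sd(abp$ab) / sqrt(nrow(abp))
  expect_lt(abs(mean(abp$ab) - 0.22), 3 * se_p + 0.005)

  # zero-depth platforms emit no reads
  expect_false(any(rd$platform %in% c("ont", "illumina")))
})

test_that("region multipliers shape local truth density as configured", {
  set.seed(9)
  tracks_cfg <- data.table::data.table(
    track = "segdup", fraction = 0.1, germline_mult = 1.185, pzm_mult = 2
  )
  cfg <- sim_config(
    n_families = 4, quad_fraction = 0, genome_length = 1e7,
    germline_rate = 5e-5, pzm_rate = 0, indel_fraction = 0,
    pzm_paternal_age_slope = 0, pzm_maternal_age_slope = 0,
    region_tracks = tracks_cfg
  )
  ped <- simulate_pedigree(cfg)
  tracks <- simulate_region_tracks(cfg)
  truth <- simulate_truth_variants(cfg, ped, tracks)
  sd_bp <- tracks[track == "segdup", sum(end - start)]
  tot_bp <- cfg$genome_length
  n_in <- truth[in_segdup == TRUE, .N]
  n_out <- nrow(truth) - n_in
  dens_ratio <- (n_in / sd_bp) / (n_out / (tot_bp - sd_bp))
  se <- dens_ratio * sqrt(1 / n_in + 1 / n_out)
  expect_lt(abs(dens_ratio - 1.185), 3 * se)
})

test_that("fixed seed gives an identical bundle; artifacts are flagged", {
  cfg <- tiny_config()
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  for (nm in c("pedigree", "genotypes", "reads", "read_snps", "snps", "tracks", "truth")) {
    expect_identical(b1[[nm]], b2[[nm]], label = nm)
  }

  cfg2 <- tiny_config(dropped_hap_run_rate = 0, recurrent_error_rate = 0)
  b3 <- simulate_cohort(cfg2)
  expect_equal(b3$truth[grepl("^artifact", true_origin), .N], 0)

  # dropped-haplotype runs: >= 3 sites within 1 kbp, parent carries reads
  cfg3 <- tiny_config(dropped_hap_run_rate = 2e-6, recurrent_error_rate = 2e-6)
  b4 <- simulate_cohort(cfg3)
  dh <- b4$truth[true_origin == "artifact_dropped_hap"]
  expect_gt(nrow(dh), 0)
  spans <- dh[, .(span = max(pos) - min(pos), n = .N), by = .(child, chrom)]
  expect_true(all(spans$span <= 1000 | spans$n >= 6)) # runs fit in 1 kbp
  rec <- b4$truth[true_origin == "artifact_recurrent"]
  expect_gt(nrow(rec), 0)
  # recurrent alleles visible in unrelated samples' HiFi reads
  one <- rec[1]
  carriers <- b4$reads[
    chrom == one$chrom & pos == one$pos & allele == "alt" & platform == "hifi",
    unique(sample)
  ]
  fams <- b4$pedigree[sample_id %in% carriers, unique(family)]
  expect_gte(length(setdiff(fams, one$family)), 1)
})

test_that("every truth variant has read evidence on every nonzero platform", {
  b <- simulate_cohort(tiny_config())
  chk <- b$reads[b$truth,
    on = c(sample = "child", "chrom", "pos"), nomatch = NULL
  ][, uniqueN(platform), by = .(chrom, pos)]
  expect_true(all(chk$V1 == 3L))
})
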