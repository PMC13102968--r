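# Candidate selection and the validation cascade.

test_that("select_candidates applies the trio genotype and GQ rules", {
  ped <- ped_trio()
  g <- rbind(
    trio_gt(pos = 100, gq_child = 30), # candidate
    trio_gt(pos = 200, gq_child = 19), # GQ below 20
    trio_gt(pos = 300, gt_father = "0/1"), # parent carries alt
    trio_gt(pos = 400, gt_child = "0/0"), # child reference
    trio_gt(pos = 500, gt_child = "1/1", gq_child = 50) # hom-alt child kept
  )
  cand <- select_candidates(g, ped)
  expect_setequal(cand$pos, c(100, 500))
  expect_true(all(cand$class == "SNV"))

  ind <- trio_gt(pos = 600, ref = "N", alt = "NAAAA")
  cand2 <- select_candidates(rbind(g, ind), ped)
  expect_equal(cand2[pos == 600, class], "insertion")

  expect_error(
    select_candidates(g[sample_id != "fam001.c1"], ped),
    "pedigree error"
  )
})

test_that("cluster filter matches its stated examples and the window oracle", {
  mk <- function(pos) {
    data.table(
      family = "f", child = "c", chrom = "chr1", pos = pos, class = "SNV"
    )
  }
  expect_true(all(filter_clusters(mk(c(100, 500, 900)))$cluster_excluded))
  expect_false(any(filter_clusters(mk(c(100, 900)))$cluster_excluded))
  expect_false(any(filter_clusters(mk(c(0, 600, 1200)))$cluster_excluded))

  set.seed(42)
  for (i in 1:40) {
    pos <- sort(sample.int(20000, sample(3:40, 1)))
    got <- filter_clusters(mk(pos))[order(pos), cluster_excluded]
    expect_identical(got, cluster_oracle(pos), label = paste("case", i))
  }
})

test_that("classify_read partitions quality as published", {
  expect_equal(classify_read(25, 60, "hifi"), "HIGH")
  expect_equal(classify_read(15, 60, "ont"), "LOW")
  expect_equal(classify_read(30, 58, "hifi"), "MAPQ_EXCLUDED")
  expect_equal(classify_read(30, 10, "illumina"), "HIGH") # short reads keep low MAPQ
  expect_equal(classify_read(9, 60, "hifi"), "DISCARD")
  expect_equal(classify_read(10, 60, "hifi"), "LOW")
  expect_equal(classify_read(20, 60, "hifi"), "LOW") # 20 is low, >20 high
  expect_error(classify_read(30, 60, "nanopore"), "unknown platform")
  expect_error(classify_read(-1, 60, "hifi"), "non-negative")
})

test_that("per-platform validation enforces the parent read ceilings", {
  base <- clean_trio_evidence()
  v <- validate_snv_platform(base)
  expect_setequal(v$verdict, "DE_NOVO")

  # parent HiFi with one high-quality alt read looks inherited
  ev <- copy(base)[role == "father" & platform == "hifi", hq_alt := 1L]
  v <- validate_snv_platform(ev)
  expect_equal(v[platform == "hifi", verdict], "INHERITED")
  expect_equal(v[platform == "ont", verdict], "DE_NOVO")

  # parent HiFi low-quality alt: one tolerated, two inherited
  ev <- copy(base)[role == "mother" & platform == "hifi", lq_alt := 1L]
  expect_equal(validate_snv_platform(ev)[platform == "hifi", verdict], "DE_NOVO")
  ev <- copy(base)[role == "mother" & platform == "hifi", lq_alt := 2L]
  expect_equal(validate_snv_platform(ev)[platform == "hifi", verdict], "INHERITED")

  # ONT is looser: 1 HQ + 2 LQ alt reads still pass
  ev <- copy(base)[
    role == "father" & platform == "ont",
    `:=`(hq_alt = 1L, lq_alt = 2L)
  ]
  expect_equal(validate_snv_platform(ev)[platform == "ont", verdict], "DE_NOVO")
  ev <- copy(base)[
    role == "father" & platform == "ont",
    `:=`(hq_alt = 2L, lq_alt = 0L)
  ]
  expect_equal(validate_snv_platform(ev)[platform == "ont", verdict], "INHERITED")

  # child without alt support is unsupported
  ev <- copy(base)[
    role == "child" & platform == "illumina",
    `:=`(hq_alt = 0L, lq_alt = 0L)
  ]
  expect_equal(
    validate_snv_platform(ev)[platform == "illumina", verdict], "UNSUPPORTED"
  )

  # a role with no usable reads makes the platform unsupported
  ev <- base[!(role == "father" & platform == "ont")]
  expect_equal(validate_snv_platform(ev)[platform == "ont", verdict], "UNSUPPORTED")
})

test_that("platform verdicts combine by the two-platform / one-inherited rule", {
  mk <- function(h, o, i) {
    data.table(
      child = "c", chrom = "chr1", pos = 1,
      platform = c("hifi", "ont", "illumina"), verdict = c(h, o, i)
    )
  }
  expect_equal(
    combine_platform_verdicts(mk("DE_NOVO", "UNSUPPORTED", "DE_NOVO"))$combined,
    "VALIDATED"
  )
  expect_equal(
    combine_platform_verdicts(mk("DE_NOVO", "INHERITED", "DE_NOVO"))$combined,
    "INHERITED"
  )
  expect_equal(
    combine_platform_verdicts(mk("DE_NOVO", "UNSUPPORTED", "UNSUPPORTED"))$combined,
    "FAILED"
  )

  # cell-line-only child: validated only with elevated Illumina support
  pv <- mk("UNSUPPORTED", "DE_NOVO", "DE_NOVO")
  ev_weak <- ev_row("child", "illumina",
    hq_alt = 1L, hq_ref = 20L, child = "c", pos = 1
  )
  ev_strong <- ev_row("child", "illumina",
    hq_alt = 2L, hq_ref = 20L, child = "c", pos = 1
  )
  expect_equal(combine_platform_verdicts(pv, ev_weak)$combined, "FAILED")
  expect_equal(combine_platform_verdicts(pv, ev_strong)$combined, "VALIDATED")
})

test_that("recurrence filter tolerates one unrelated carrier only in TRs", {
  cand <- rbind(
    cand_row(pos = 100, in_tr = FALSE),
    cand_row(pos = 200, in_tr = TRUE),
    cand_row(pos = 300, in_tr = TRUE),
    cand_row(pos = 400, in_tr = FALSE)
  )
  reads <- rbind(
    read_row("fam002.c1", "alt", pos = 100, family = "fam002"),
    read_row("fam002.c1", "alt", pos = 200, family = "fam002"),
    read_row("fam002.c1", "alt", pos = 300, family = "fam002"),
    read_row("fam003.c1", "alt", pos = 300, family = "fam003"),
    # same family carrier does not count
    read_row("fam001.fa", "alt", pos = 400, family = "fam001"),
    # low-quality unrelated carrier does not count
    read_row("fam002.c1", "alt", pos = 400, family = "fam002", bq = 15L)
  )
  out <- recurrence_filter(cand, reads)
  expect_equal(out[order(pos), recurrence_pass], c(FALSE, TRUE, FALSE, TRUE))
})

test_that("AB filters use the published repeat-region floors", {
  mk_ev <- function(ab_each) {
    rbindlist(lapply(seq_along(ab_each), function(i) {
      ev_row("child", c("hifi", "ont", "illumina")[i],
        hq_alt = round(ab_each[i] * 100), hq_ref = round((1 - ab_each[i]) * 100)
      )
    }))
  }
  tr <- cand_row(in_tr = TRUE)
  expect_false(ab_filters(tr, mk_ev(c(0.04, 0.04, 0.04)))$ab_pass)
  expect_true(ab_filters(tr, mk_ev(c(0.06, 0.06, 0.06)))$ab_pass)

  rmtr <- cand_row(in_tr = TRUE, in_repeatmasker = TRUE)
  expect_false(ab_filters(rmtr, mk_ev(c(0.09, 0.09, 0.09)))$ab_pass)
  expect_true(ab_filters(rmtr, mk_ev(c(0.11, 0.11, 0.11)))$ab_pass)

  rm_ <- cand_row(in_repeatmasker = TRUE)
  expect_true(ab_filters(rm_, mk_ev(c(0.09, 0.09, 0.09)))$ab_pass)
  expect_false(ab_filters(rm_, mk_ev(c(0.07, 0.07, 0.07)))$ab_pass)

  # no evidence at all fails with a reason
  out <- ab_filters(cand_row(), ev_row("child", "hifi")[0])
  expect_false(out$ab_pass)
  expect_equal(out$ab_reason, "no evidence")
})

test_that("homopolymer filter requires subunit involvement", {
  # A->T on the edge of an A run fails
  expect_false(homopolymer_filter(
    cand_row(ref = "A", alt = "T", hp_base = "A", hp_len = 5L, hp_offset = 1L)
  )$hp_pass)
  # C->T adjacent to an A run passes (subunit not involved)
  expect_true(homopolymer_filter(
    cand_row(ref = "C", alt = "T", hp_base = "A", hp_len = 5L, hp_offset = 1L)
  )$hp_pass)
  # far from any run passes
  expect_true(homopolymer_filter(cand_row())$hp_pass)
  # run below the length threshold passes
  expect_true(homopolymer_filter(
    cand_row(ref = "A", alt = "T", hp_base = "A", hp_len = 3L, hp_offset = 0L)
  )$hp_pass)
  # alt equal to the homopolymer base also fails
  expect_false(homopolymer_filter(
    cand_row(ref = "C", alt = "A", hp_base = "A", hp_len = 6L, hp_offset = 0L)
  )$hp_pass)
})

test_that("indel validation follows the read-support and noise rules", {
  ped <- rbind(ped_trio(), {
    sib <- ped_trio()[role == "child"]
    sib[, `:=`(sample_id = "fam001.c2", phenotype = 1L)]
    sib
  })
  cand <- cand_row(class = "insertion", ref = "N", alt = "NAA")
  mk <- function(...) rbind(...)

  base <- mk(
    read_row("fam001.c1", "alt", "hifi"),
    read_row("fam001.c1", "alt", "illumina"),
    read_row("fam001.fa", "ref", "hifi"),
    read_row("fam001.mo", "ref", "hifi")
  )
  expect_equal(validate_indel(cand, base, ped)$combined, "VALIDATED")

  # MAPQ 59 reads are not counted for indels: support vanishes
  low <- copy(base)[sample == "fam001.c1" & platform == "hifi", mapping_quality := 59L]
  expect_equal(validate_indel(cand, low, ped)$combined, "FAILED")

  # short flank reads are not counted either
  fl <- copy(base)[sample == "fam001.c1" & platform == "hifi", flank5 := 5L]
  expect_equal(validate_indel(cand, fl, ped)$combined, "FAILED")

  # a sibling carrying the allele marks it inherited
  sib <- mk(base, read_row("fam001.c2", "alt", "ont"))
  expect_equal(validate_indel(cand, sib, ped)$combined, "INHERITED")

  # HiFi-only child support is insufficient
  hifi_only <- base[!(sample == "fam001.c1" & platform == "illumina")]
  expect_equal(validate_indel(cand, hifi_only, ped)$combined, "FAILED")

  # multi-allelic noise across the trio fails (manual-curation proxy)
  noisy <- mk(
    base,
    read_row("fam001.c1", "other:NA", "hifi"),
    read_row("fam001.fa", "other:NAA", "hifi"),
    read_row("fam001.mo", "other:NAAA", "hifi")
  )
  expect_equal(validate_indel(cand, noisy, ped)$combined, "FAILED")
})

test_that("sex-chromosome rules: male AB = 1, orthogonal parent, female autosomal", {
  sexes <- c("fam001.c1" = 1L)
  mkev <- function(ab, parent_alt = 0L) {
    rbindlist(lapply(c("hifi", "ont", "illumina"), function(pf) {
      rbind(
        ev_row("child", pf,
          hq_alt = round(ab * 20), hq_ref = 20L - round(ab * 20),
          chrom = "chrX", pos = 10
        ),
        ev_row("mother", pf, hq_alt = parent_alt, hq_ref = 30L,
          chrom = "chrX", pos = 10
        )
      )
    }))
  }
  cand <- cand_row(chrom = "chrX", pos = 10)

  out <- validate_sex_chromosome(cand, mkev(0.9), sexes)
  expect_equal(out$combined, "FAILED") # AB below 1

  out <- validate_sex_chromosome(cand, mkev(1.0), sexes)
  expect_equal(out$combined, "VALIDATED")

  out <- validate_sex_chromosome(cand, mkev(1.0, parent_alt = 2L), sexes)
  expect_equal(out$combined, "INHERITED")

  # chrY checked against the father
  candy <- cand_row(chrom = "chrY", pos = 20)
  evy <- rbindlist(lapply(c("hifi", "ont", "illumina"), function(pf) {
    rbind(
      ev_row("child", pf, hq_alt = 20L, chrom = "chrY", pos = 20),
      ev_row("father", pf, hq_ref = 30L, chrom = "chrY", pos = 20)
    )
  }))
  expect_equal(validate_sex_chromosome(candy, evy, sexes)$combined, "VALIDATED")

  # female chrX flows through the autosomal cascade
  out <- validate_sex_chromosome(cand, mkev(0.5), c("fam001.c1" = 2L))
  expect_equal(out$sex_chrom_rule, "autosomal")
  expect_true(is.na(out$combined))

  # chrY candidate in a female is an input error
  expect_error(
    validate_sex_chromosome(candy, evy, c("fam001.c1" = 2L)),
    "chrY"
  )
})

test_that("the cascade is order-stable: predicates intersect identically", {
  b <- simulate_cohort(tiny_config(
    germline_rate = 5e-6, dropped_hap_run_rate = 1e-6,
    recurrent_error_rate = 1e-6
  ))
  out <- validate_variants(b$genotypes, b$pedigree, b$reads, b$tracks)
  snv <- out[class == "SNV" & !cluster_excluded]
  # the final verdict is the conjunction of independent predicates: any
  # evaluation order yields the same validated set
  orders <- list(
    c("recurrence_pass", "ab_pass", "hp_pass"),
    c("hp_pass", "recurrence_pass", "ab_pass"),
    c("ab_pass", "hp_pass", "recurrence_pass")
  )
  sets <- lapply(orders, function(o) {
    keep <- snv$combined == "VALIDATED"
    for (col in o) keep <- keep & snv[[col]]
    sort(snv[keep, paste(child, chrom, pos)])
  })
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[1]], sets[[3]])
  expect_identical(sets[[1]], sort(snv[verdict == "VALIDATED", paste(child, chrom, pos)]))
})
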