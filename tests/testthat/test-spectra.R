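# Spectra, MnM clustering, age and bias statistics.

test_that("build_spectrum collapses strands and conserves totals", {
  v <- data.table(
    ref = "C", alt = "T", ctx5 = "A", ctx3 = "G"
  )
  sp <- build_spectrum(v)
  expect_equal(sp[category == "CpG>TpG", count], 1L)

  # G>A with 5' C is the minus-strand image of CpG>TpG
  v2 <- data.table(ref = "G", alt = "A", ctx5 = "C", ctx3 = "T")
  sp2 <- build_spectrum(v2)
  expect_equal(sp2[category == "CpG>TpG", count], 1L)

  # order and strand invariance on a random set
  set.seed(4)
  n <- 500
  v3 <- data.table(
    ref = sample(c("A", "C"), n, TRUE),
    ctx5 = sample(c("A", "C", "G", "T"), n, TRUE),
    ctx3 = sample(c("A", "C", "G", "T"), n, TRUE)
  )
  v3[, alt := ifelse(ref == "A", sample(c("C", "G", "T"), n, TRUE),
    sample(c("A", "G", "T"), n, TRUE)
  )]
  v3[ref == alt, alt := "G"] # guard, A!=G and C!=G always
  sp_plus <- build_spectrum(v3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_minus <- v3[, .(
    ref = comp[ref], alt = comp[alt], ctx5 = comp[ctx3], ctx3 = comp[ctx5]
  )]
  sp_minus <- build_spectrum(v_minus)
  expect_equal(sp_plus, sp_minus)
  expect_equal(build_spectrum(v3[sample(n)]), sp_plus)
  expect_equal(sum(sp_plus$count), n)

  expect_equal(nrow(build_spectrum(v3[0])), 0)
  # unknown context falls into "other"
  expect_equal(
    build_spectrum(data.table(
      ref = "C", alt = "T", ctx5 = "A", ctx3 = NA_character_
    ))$category, "other"
  )
})

test_that("spectrum_enrichment: identity, BH monotonicity, power for CpG deficit", {
  sp <- data.table(category = c("x", "y"), count = c(50L, 50L))
  out <- spectrum_enrichment(sp, sp)
  expect_true(all(out$q_value == 1))

  # BH q-values are monotone in the rank of p
  set.seed(2)
  a <- data.table(category = letters[1:8], count = rpois(8, 60) + 1L)
  b <- data.table(category = letters[1:8], count = rpois(8, 60) + 1L)
  out <- spectrum_enrichment(a, b)
  o <- order(out$p_value)
  expect_true(all(diff(out$q_value[o]) >= -1e-12))

  # the generator's postzygotic CpG>TpG deficit is detectable
  set.seed(6)
  cfg <- sim_config()
  draw <- function(origin, n) {
    build_spectrum(dnmtrio:::.draw_snv_context(n, origin, cfg))
  }
  gsp <- draw("germline", 10000)
  psp <- draw("pzm", 3000)
  out <- spectrum_enrichment(gsp, psp)
  cpg <- out[category == "CpG>TpG"]
  expect_lt(cpg$q_value, 0.05)
  expect_equal(cpg$direction, "depleted_in_b")
})

test_that("titv matches category membership and the generating spectra", {
  r <- titv(data.table(
    ref = c("A", "C", "A"), alt = c("G", "T", "C")
  ))
  expect_equal(r$titv, 2.0)
  expect_true(is.na(titv(data.table(ref = "A", alt = "G"))$titv))

  set.seed(10)
  cfg <- sim_config()
  g <- dnmtrio:::.draw_snv_context(20000, "germline", cfg)
  p <- dnmtrio:::.draw_snv_context(20000, "pzm", cfg)
  tg <- titv(g)
  tp <- titv(p)
  # binomial error on the transition fraction propagated to the ratio
  se_ratio <- function(t) {
    f <- t$transitions / (t$transitions + t$transversions)
    se <- sqrt(f * (1 - f) / (t$transitions + t$transversions))
    se / (1 - f)^2
  }
  expect_lt(abs(tg$titv - 2.10), 3 * se_ratio(tg))
  expect_lt(abs(tp$titv - 1.35), 3 * se_ratio(tp))
})

test_that("find_mnms chains within 500 bp and matches transitive closure", {
  mk <- function(pos, child = "c") {
    data.table(child = child, chrom = "chr1", pos = pos)
  }
  r <- find_mnms(mk(c(100, 550)))
  expect_equal(nrow(r$clusters), 1)
  expect_equal(r$pairs$dist_bp, 450)
  expect_equal(as.character(r$pairs$bin), "101-500")

  r <- find_mnms(mk(c(100, 101)))
  expect_equal(as.character(r$pairs$bin), "1")

  r <- find_mnms(mk(c(100, 601)))
  expect_equal(nrow(r$clusters), 0)
  expect_equal(nrow(r$pairs), 0)

  # different children never chain
  two <- rbind(mk(100, "c1"), mk(300, "c2"))
  expect_equal(nrow(find_mnms(two)$clusters), 0)

  # transitive chaining equals brute-force closure on random instances
  set.seed(14)
  for (i in 1:20) {
    pos <- sort(sample.int(10000, sample(5:60, 1)))
    r <- find_mnms(mk(pos))
    # oracle: connected components of the <=500 bp adjacency graph
    comp <- seq_along(pos)
    for (a in seq_along(pos)) {
      for (b in seq_along(pos)) {
        if (abs(pos[a] - pos[b]) <= 500) {
          old <- comp[b]
          comp[comp == old] <- comp[a]
        }
      }
    }
    oracle_sizes <- sort(as.vector(table(comp)[table(comp) >= 2]))
    expect_equal(sort(r$clusters$n_members), oracle_sizes, label = paste("case", i))
    # conservation: binned pair counts equal the consecutive close pairs
    expect_equal(nrow(r$pairs), sum(diff(pos) <= 500))
    expect_equal(sum(table(r$pairs$bin)), nrow(r$pairs))
  }
})

test_that("parental_age_regression recovers exact and null slopes", {
  counts <- data.table(
    child = sprintf("c%d", 1:10),
    father_age = seq(20, 38, by = 2),
    mother_age = seq(19, 37, by = 2)
  )
  counts[, `:=`(n_paternal = 2 * father_age, n_maternal = 3 * mother_age)]
  # noiseless fixture: lm warns about the perfect fit, which is the point
  fit <- suppressWarnings(parental_age_regression(counts))
  expect_equal(fit$paternal$slope, 2.0, tolerance = 1e-10)
  expect_equal(fit$maternal$slope, 3.0, tolerance = 1e-10)
  expect_true(fit$paternal$ci[1] <= 2.0 && 2.0 <= fit$paternal$ci[2])

  # permuted ages: slope indistinguishable from zero
  set.seed(3)
  null_slopes <- vapply(1:50, function(i) {
    cc <- copy(counts)[, father_age := sample(father_age)]
    suppressWarnings(parental_age_regression(cc))$paternal$slope
  }, 0)
  expect_lt(abs(mean(null_slopes)), 3 * sd(null_slopes) / sqrt(50))

  expect_error(
    parental_age_regression(copy(counts)[, father_age := 30]),
    "degenerate"
  )
  expect_error(parental_age_regression(counts[1:2]), "at least 3")
})

test_that("parental_bias_tests: ratio, Wilcoxon, and two-class Z-test", {
  counts <- data.table(
    n_paternal = c(100, 40, 26), n_maternal = c(30, 10, 8)
  )
  r <- parental_bias_tests(counts)
  expect_equal(r$ratio, 166 / 48)

  same <- data.table(n_paternal = c(5, 7), n_maternal = c(5, 7))
  r2 <- parental_bias_tests(same)
  expect_equal(r2$ratio, 1)
  expect_equal(r2$wilcoxon_p, 1)

  # strongly differing paternal fractions give a small Z-test p
  r3 <- parental_bias_tests(
    data.table(n_paternal = 800, n_maternal = 200),
    data.table(n_paternal = 500, n_maternal = 500)
  )
  expect_lt(r3$z_p, 1e-10)

  # simulated cohort at the configured paternal fraction: Wilcoxon power
  set.seed(9)
  sig <- vapply(1:40, function(i) {
    n <- rpois(73, 70)
    np <- rbinom(73, n, 0.799)
    parental_bias_tests(
      data.table(n_paternal = np, n_maternal = n - np)
    )$wilcoxon_p < 0.05
  }, TRUE)
  expect_gte(mean(sig), 0.95)
})
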