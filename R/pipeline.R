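# End-to-end orchestration: validate -> phase -> classify -> rates ->
# spectra, with a machine-readable summary and a truth-comparison harness
# for synthetic runs.

#' Deterministic fingerprint of a table
#'
#' A cheap content digest (dimensions, column names, numeric column sums,
#' character column hash) used in run manifests to assert that identical
#' config + seed reproduce identical stage outputs.
#'
#' @param dt A data.frame/data.table.
#' @return A single character fingerprint.
#' @export
table_fingerprint <- function(dt) {
  dt <- as.data.frame(dt)
  num <- vapply(dt, function(col) {
    if (is.numeric(col)) sum(as.numeric(col), na.rm = TRUE) else 0
  }, 0)
  chr <- vapply(dt, function(col) {
    if (is.character(col)) sum(utf8ToInt(paste(substr(col, 1, 4), collapse = ""))) else 0
  }, 0)
  sprintf(
    "%dx%d|%s|%.6g|%.6g",
    nrow(dt), ncol(dt), paste(substr(names(dt), 1, 3), collapse = ""),
    sum(num), sum(chr)
  )
}

#' Run the full DNM pipeline on a cohort bundle
#'
#' Executes candidate selection and the validation cascade, phases
#' validated variants, classifies them as germline or postzygotic,
#' estimates cohort and parent-specific mutation rates, and computes
#' spectrum and age-effect statistics. For synthetic bundles the callable
#' denominator is the simulated genome size (the read model guarantees
#' qualifying coverage essentially everywhere at the default depths).
#'
#' @param bundle A `dnm_bundle`.
#' @param params A [filter_params()] object.
#' @return A list of class `dnm_run`: `validated` (all candidates with
#'   per-filter columns), `callset` (final classified variants),
#'   `rates`, `parent_rates`, `stratified`, `spectra`, `stats`, and
#'   `summary` (flat named list suitable for JSON).
#' @export
run_cohort_pipeline <- function(bundle, params = filter_params()) {
  ped <- bundle$pedigree
  children <- ped[role == "child"]
  n_children <- nrow(children)
  callable_bp <- bundle$config$genome_length * bundle$config$n_chromosomes
  timings <- c()
  clock <- function(stage, t0) {
    timings[stage] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  t0 <- Sys.time()
  validated <- validate_variants(
    bundle$genotypes, ped, bundle$reads, bundle$tracks, params
  )
  clock("validate", t0)
  val <- validated[verdict == "VALIDATED"]

  t0 <- Sys.time()
  ph <- phase_variants(
    val, bundle$genotypes, ped, bundle$reads, bundle$read_snps, params
  )
  clock("phase", t0)
  val <- ph$calls[val, on = c("family", "child", "chrom", "pos")]
  # conflicting phase in both platforms: presumed sequencing error, dropped
  callset <- val[phase_exclude == FALSE | is.na(phase_exclude)]

  t0 <- Sys.time()
  ev <- aggregate_site_evidence(callset, bundle$reads, ped, params)
  callset <- classify_origin(callset, ph$read_haplotypes, ev, params)
  clock("classify", t0)
  t0 <- Sys.time()
  if (!is.null(bundle$contexts)) {
    callset <- merge(
      callset, bundle$contexts,
      by = c("chrom", "pos"), all.x = TRUE, sort = FALSE
    )
  } else {
    callset[, `:=`(ctx5 = NA_character_, ctx3 = NA_character_)]
  }

  # rates -------------------------------------------------------------
  n_g <- callset[final_origin == "germline" & class == "SNV", .N]
  n_p <- callset[final_origin == "postzygotic" & class == "SNV", .N]
  rate_g <- mutation_rate(n_g, callable_bp * n_children, ploidy = 2)
  rate_p <- mutation_rate(n_p, callable_bp * n_children, ploidy = 2)
  parent_rates <- parent_specific_rates(
    callset[class == "SNV"], callable_bp, n_children
  )

  strata_bp <- rbind(
    data.table(stratum = "genome", bp = callable_bp),
    bundle$tracks[, .(bp = sum(end - start)), by = .(stratum = track)],
    bundle$tracks[
      track == "segdup" & !is.na(identity),
      .(bp = sum(end - start)),
      by = .(stratum = paste0("segdup_", identity))
    ]
  )
  stratified <- stratified_rates(
    callset[class == "SNV"], strata_bp, children$sample_id
  )

  # spectra and cohort statistics --------------------------------------
  snvs <- callset[class == "SNV"]
  spec_g <- build_spectrum(snvs[final_origin == "germline"])
  spec_p <- build_spectrum(snvs[final_origin == "postzygotic"])
  titv_g <- titv(snvs[final_origin == "germline"])
  titv_p <- titv(snvs[final_origin == "postzygotic"])
  enrich <- if (sum(spec_g$count) > 0 && sum(spec_p$count) > 0) {
    spectrum_enrichment(spec_g, spec_p)
  } else {
    NULL
  }
  mnms <- find_mnms(snvs)

  phased_counts <- snvs[
    final_origin == "germline" & parent_of_origin %in% c("paternal", "maternal"),
    .N,
    by = .(child, parent_of_origin)
  ]
  pc <- dcast(phased_counts, child ~ parent_of_origin, value.var = "N", fill = 0L)
  pc <- pc[children[, .(child = sample_id, father_age, mother_age)], on = "child"]
  for (col in c("paternal", "maternal")) {
    if (!col %in% names(pc)) pc[, (col) := 0L]
  }
  pc[is.na(paternal), paternal := 0L]
  pc[is.na(maternal), maternal := 0L]
  setnames(pc, c("paternal", "maternal"), c("n_paternal", "n_maternal"))

  age_fit <- tryCatch(
    parental_age_regression(pc),
    error = function(e) NULL
  )
  pzm_counts <- snvs[
    final_origin == "postzygotic" & parent_of_origin %in% c("paternal", "maternal"),
    .N,
    by = .(child, parent_of_origin)
  ]
  pz <- dcast(pzm_counts, child ~ parent_of_origin, value.var = "N", fill = 0L)
  for (col in c("paternal", "maternal")) {
    if (!col %in% names(pz)) pz[, (col) := 0L]
  }
  setnames(pz, c("paternal", "maternal"), c("n_paternal", "n_maternal"))
  bias <- parental_bias_tests(pc, if (nrow(pz) > 0) pz else NULL)

  n_phased <- snvs[parent_of_origin %in% c("paternal", "maternal"), .N]
  phasing_fraction <- if (nrow(snvs) > 0) n_phased / nrow(snvs) else NA_real_

  mean_ab_pzm <- snvs[final_origin == "postzygotic", mean(pooled_ab)]
  mean_ab_germ <- snvs[final_origin == "germline", mean(pooled_ab)]

  summary <- list(
    n_children = n_children,
    callable_bp = callable_bp,
    n_validated_snv = nrow(snvs),
    n_validated_indel = callset[class != "SNV", .N],
    n_germline_snv = n_g,
    n_postzygotic_snv = n_p,
    snv_per_child = nrow(snvs) / n_children,
    pzm_fraction = if (nrow(snvs) > 0) n_p / nrow(snvs) else NA_real_,
    germline_rate = rate_g$rate,
    germline_rate_ci = c(rate_g$ci_lower, rate_g$ci_upper),
    pzm_rate = rate_p$rate,
    pzm_rate_ci = c(rate_p$ci_lower, rate_p$ci_upper),
    paternal_maternal_ratio = parent_rates$ratio[1],
    phasing_fraction = phasing_fraction,
    mean_ab_germline = mean_ab_germ,
    mean_ab_postzygotic = mean_ab_pzm,
    titv_germline = titv_g$titv,
    titv_postzygotic = titv_p$titv,
    paternal_age_slope = if (!is.null(age_fit)) age_fit$paternal$slope else NA_real_,
    maternal_age_slope = if (!is.null(age_fit)) age_fit$maternal$slope else NA_real_,
    wilcoxon_p_paternal_bias = bias$wilcoxon_p
  )

  clock("rates_spectra", t0)
  manifest <- list(
    seed = bundle$config$seed,
    config = unclass(bundle$config),
    stage_timings = as.list(timings),
    table_fingerprints = list(
      validated = table_fingerprint(validated),
      callset = table_fingerprint(callset)
    )
  )

  structure(
    list(
      manifest = manifest,
      validated = validated, callset = callset, rates = list(
        germline = rate_g, postzygotic = rate_p
      ),
      parent_rates = parent_rates, stratified = stratified,
      spectra = list(
        germline = spec_g, postzygotic = spec_p, enrichment = enrich,
        titv_germline = titv_g, titv_postzygotic = titv_p
      ),
      mnms = mnms, age_fit = age_fit, phased_counts = pc,
      stats = bias, summary = summary
    ),
    class = "dnm_run"
  )
}

#' Compare a pipeline run against the generator's truth table
#'
#' Reports per-class sensitivity, artifact leak-through, the
#' origin-classification confusion matrix, phasing accuracy among phased
#' true variants, and rate bias relative to the generating rates.
#'
#' @param run A `dnm_run` from [run_cohort_pipeline()].
#' @param truth Truth table of the bundle.
#' @param config The generating [sim_config()].
#' @return A list with `sensitivity`, `artifacts_removed`,
#'   `origin_confusion`, `phasing_accuracy`, `rate_bias`.
#' @export
compare_to_truth <- function(run, truth, config) {
  if (is.null(truth) || nrow(truth) == 0L) stop("truth table missing")
  cs <- run$callset
  key <- c("child", "chrom", "pos")
  truth <- as.data.table(truth)
  real <- truth[!grepl("^artifact", true_origin)]
  hit <- cs[real, on = key, nomatch = NULL]

  sens <- real[, .(
    n_truth = .N
  ), by = .(true_origin, class)]
  found <- hit[, .(n_found = .N), by = .(true_origin, class)]
  sens <- found[sens, on = c("true_origin", "class")]
  sens[is.na(n_found), n_found := 0L]
  sens[, sensitivity := n_found / n_truth]

  art <- truth[grepl("^artifact", true_origin)]
  art_called <- cs[art, on = key, nomatch = NULL]
  artifacts_removed <- list(
    n_injected = nrow(art), n_validated = nrow(art_called),
    removed_fraction = if (nrow(art) > 0) 1 - nrow(art_called) / nrow(art) else NA_real_
  )

  conf <- hit[, table(
    truth = true_origin, called = final_origin
  )]

  phased <- hit[parent_of_origin %in% c("paternal", "maternal")]
  phasing_accuracy <- if (nrow(phased) > 0) {
    mean(phased$parent_of_origin == phased$true_parent)
  } else {
    NA_real_
  }

  rate_bias <- list(
    germline = run$rates$germline$rate / config$germline_rate - 1,
    postzygotic = run$rates$postzygotic$rate / config$pzm_rate - 1
  )

  list(
    sensitivity = sens, artifacts_removed = artifacts_removed,
    origin_confusion = conf, phasing_accuracy = phasing_accuracy,
    rate_bias = rate_bias
  )
}

#' Headline cohort summary identities
#'
#' Derived per-child means and class fractions from raw cohort counts:
#' mean SNVs and indels per child, postzygotic fractions, callable
#' fraction, and the combined germline + postzygotic rate. Pure
#' arithmetic on its inputs; used to reproduce published summary-table
#' figures from their printed inputs.
#'
#' @param n_snv Validated autosomal SNVs.
#' @param n_classified_snv SNVs with a germline/postzygotic classification
#'   (denominator of the postzygotic fraction).
#' @param n_pzm_snv SNVs classified postzygotic.
#' @param n_insertion,n_deletion Validated indels by class.
#' @param n_pzm_indel Indels classified postzygotic.
#' @param n_children Children in the cohort.
#' @param callable_gbp,genome_gbp Callable and total genome (Gbp).
#' @param germline_rate,pzm_rate Per-bp per-generation rates.
#' @return Named list of derived summary values.
#' @export
cohort_headline_stats <- function(n_snv, n_classified_snv, n_pzm_snv,
                                  n_insertion, n_deletion, n_pzm_indel,
                                  n_children, callable_gbp, genome_gbp,
                                  germline_rate, pzm_rate) {
  n_indel <- n_insertion + n_deletion
  list(
    snv_per_child = n_snv / n_children,
    indel_per_child = n_indel / n_children,
    pzm_snv_per_child = n_pzm_snv / n_children,
    pzm_snv_fraction = n_pzm_snv / n_classified_snv,
    pzm_indel_fraction = n_pzm_indel / n_indel,
    callable_fraction = callable_gbp / genome_gbp,
    combined_rate = germline_rate + pzm_rate
  )
}
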