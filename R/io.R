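# Plain-text serialization of cohort bundles.
#
# Formats: 6-column PED; VCF 4.2 with GT:GQ (one file per family,
# positions 1-based); BED3+ tracks (half-open 0-based, the segdup track
# carries a percent-identity column, the homopolymer track base and run
# length); TSV for read evidence, SNP observations, informative SNPs,
# truth and the full pedigree.

#' Write a cohort bundle to a directory
#'
#' @param bundle A `dnm_bundle` (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("I/O error: cannot write to directory ", dir)
  }
  files <- character()
  wt <- function(dt, name) {
    path <- file.path(dir, name)
    fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
    files <<- c(files, path)
  }

  ped6 <- bundle$pedigree[, .(family, sample_id, father, mother, sex, phenotype)]
  path <- file.path(dir, "cohort.ped")
  fwrite(ped6, path, sep = "\t", quote = FALSE, col.names = FALSE)
  files <- c(files, path)
  wt(bundle$pedigree, "pedigree.tsv")

  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (fam in unique(bundle$pedigree$family)) {
    p <- file.path(vcf_dir, paste0(fam, ".vcf"))
    write_family_vcf(bundle$genotypes, bundle$pedigree, fam, p)
    files <- c(files, p)
  }

  bed_dir <- file.path(dir, "tracks")
  dir.create(bed_dir, showWarnings = FALSE)
  for (tr in unique(bundle$tracks$track)) {
    tt <- bundle$tracks[track == tr]
    p <- file.path(bed_dir, paste0(tr, ".bed"))
    if (tr == "segdup") {
      fwrite(tt[, .(chrom, start, end, identity)], p,
        sep = "\t", quote = FALSE, col.names = FALSE
      )
    } else if (tr == "homopolymer") {
      fwrite(tt[, .(chrom, start, end, hp_base, hp_len)], p,
        sep = "\t", quote = FALSE, col.names = FALSE
      )
    } else {
      fwrite(tt[, .(chrom, start, end)], p,
        sep = "\t", quote = FALSE, col.names = FALSE
      )
    }
    files <- c(files, p)
  }

  wt(bundle$reads, "read_evidence.tsv")
  wt(bundle$read_snps, "read_snp_observations.tsv")
  wt(bundle$snps, "informative_snps.tsv")
  wt(bundle$truth, "truth.tsv")
  if (!is.null(bundle$contexts)) wt(bundle$contexts, "site_contexts.tsv")

  cfg <- bundle$config
  cfg$region_tracks <- as.data.frame(cfg$region_tracks)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  files <- c(files, file.path(dir, "config.json"))
  invisible(files)
}

#' Write one family's genotypes as a VCF 4.2 file
#'
#' @param genotypes Long-format genotype records.
#' @param pedigree Pedigree table.
#' @param fam Family identifier.
#' @param path Output path.
#' @export
write_family_vcf <- function(genotypes, pedigree, fam, path) {
  samples <- pedigree[family == fam][
    order(match(role, c("father", "mother", "child")), sample_id), sample_id
  ]
  g <- genotypes[family == fam]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
  writeLines(hdr, path)
  if (nrow(g) == 0L) {
    return(invisible(path))
  }
  g[, gtgq := paste0(gt, ":", gq)]
  w <- dcast(g, chrom + pos + ref + alt ~ sample_id, value.var = "gtgq")
  for (s in setdiff(samples, names(w))) w[, (s) := "./.:0"]
  setorder(w, chrom, pos)
  body <- w[, do.call(paste, c(
    list(chrom, sprintf("%.0f", pos), ".", ref, alt, ".", "PASS", ".", "GT:GQ"),
    lapply(samples, function(s) get(s)),
    sep = "\t"
  ))]
  con <- file(path, "a")
  writeLines(body, con)
  close(con)
  invisible(path)
}

#' Read one family VCF back into long genotype records
#'
#' @param path VCF path.
#' @param fam Family identifier attached to the records.
#' @return Long-format genotype `data.table`.
#' @export
read_family_vcf <- function(path, fam) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  cols <- strsplit(sub("^#", "", lines[hdr_i]), "\t")[[1]]
  body <- lines[-seq_len(hdr_i)]
  if (length(body) == 0L) {
    return(data.table(
      family = character(), chrom = character(), pos = numeric(),
      ref = character(), alt = character(), sample_id = character(),
      gt = character(), gq = integer()
    ))
  }
  dt <- fread(text = body, header = FALSE, sep = "\t")
  setnames(dt, cols)
  samples <- cols[-(1:9)]
  long <- melt(
    dt[, c("CHROM", "POS", "REF", "ALT", samples), with = FALSE],
    id.vars = c("CHROM", "POS", "REF", "ALT"),
    variable.name = "sample_id", value.name = "gtgq",
    variable.factor = FALSE
  )
  long[, c("gt", "gq") := tstrsplit(gtgq, ":", fixed = TRUE)]
  long[, .(
    family = fam, chrom = CHROM, pos = as.numeric(POS), ref = REF, alt = ALT,
    sample_id, gt, gq = as.integer(gq)
  )]
}

#' Read a cohort bundle from a directory
#'
#' Inverse of [write_bundle()]: genotype records are reconstructed from
#' the per-family VCFs, tracks from the BED files, everything else from
#' TSV.
#'
#' @param dir Bundle directory.
#' @return A `dnm_bundle` list.
#' @export
read_bundle <- function(dir) {
  rd <- function(name) {
    dt <- fread(file.path(dir, name), sep = "\t", na.strings = "NA")
    for (col in intersect(c("pos", "snp_pos", "start", "end"), names(dt))) {
      dt[, (col) := as.numeric(get(col))]
    }
    dt
  }
  ped <- rd("pedigree.tsv")
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$", full.names = TRUE)
  genotypes <- rbindlist(lapply(vcfs, function(p) {
    read_family_vcf(p, sub("\\.vcf$", "", basename(p)))
  }))

  bed_files <- list.files(file.path(dir, "tracks"), pattern = "\\.bed$",
    full.names = TRUE
  )
  tracks <- rbindlist(lapply(bed_files, function(p) {
    tr <- sub("\\.bed$", "", basename(p))
    b <- fread(p, header = FALSE)
    out <- data.table(
      track = tr, chrom = b$V1, start = b$V2, end = b$V3,
      identity = NA_character_, hp_base = NA_character_, hp_len = NA_integer_
    )
    if (tr == "segdup" && ncol(b) >= 4) out[, identity := b$V4]
    if (tr == "homopolymer" && ncol(b) >= 5) {
      out[, `:=`(hp_base = b$V4, hp_len = as.integer(b$V5))]
    }
    out[, `:=`(start = as.numeric(start), end = as.numeric(end))]
    out
  }), fill = TRUE)

  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg_raw$region_tracks <- as.data.table(cfg_raw$region_tracks)
  cfg_raw$platform_profiles <- lapply(cfg_raw$platform_profiles, function(p) {
    p$mapq_values <- as.integer(p$mapq_values)
    p
  })
  cfg <- cfg_raw
  class(cfg) <- "dnm_sim_config"

  structure(
    list(
      pedigree = ped,
      genotypes = genotypes,
      reads = rd("read_evidence.tsv"),
      read_snps = rd("read_snp_observations.tsv"),
      snps = rd("informative_snps.tsv"),
      tracks = tracks,
      truth = rd("truth.tsv"),
      contexts = if (file.exists(file.path(dir, "site_contexts.tsv"))) {
        rd("site_contexts.tsv")
      } else {
        NULL
      },
      config = cfg
    ),
    class = "dnm_bundle"
  )
}
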