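# VCF serialization of simulated pairs. Writing emits minimal VCF v4.2
# text (two sample columns, FORMAT GT:AD:DP:GQ, trinucleotide context in
# INFO/CTX); reading goes through vcfR so the package consumes the same
# format any caller would produce.

GT_TO_VCF <- c(RefRef = "0/0", RefAlt = "0/1", AltAlt = "1/1",
               Missing = "./.")

#' Write one twin pair's genotypes as a VCF file
#'
#' Serializes a pair table (as produced by [simulate_cohort()]) as VCF
#' v4.2 with two sample columns and per-sample GT:AD:DP:GQ. Positions are
#' 1-based and records are written sorted by chromosome then position; the
#' trinucleotide reference context travels in the INFO field `CTX` so no
#' reference FASTA is needed downstream.
#'
#' @param pair data.frame with columns chrom, pos, ref, alt, context and
#'   per-twin gt/dp/gq/ad_ref/ad_alt (suffixes 1 and 2). May have zero
#'   rows (header-only VCF).
#' @param path Output file path.
#' @param sample_names Names for the two sample columns.
#' @return `path`, invisibly.
#' @export
write_vcf_pair <- function(pair, path, sample_names = c("twin1", "twin2")) {
  stopifnot(length(sample_names) == 2L)
  ord <- order(match(pair$chrom, names(HG38_AUTOSOMES)), pair$pos)
  if (is.unsorted(ord)) stop("pair table must be sorted by chromosome then position")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=twinpzm",
    '##INFO=<ID=CTX,Number=1,Type=String,Description="Trinucleotide reference context centred on POS">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  fmt_sample <- function(gt, ad_ref, ad_alt, dp, gq)
    paste0(GT_TO_VCF[gt], ":", ad_ref, ",", ad_alt, ":", dp, ":", gq)
  body <- if (nrow(pair)) {
    paste(pair$chrom, pair$pos, ".", pair$ref, pair$alt, ".", ".",
          paste0("CTX=", pair$context), "GT:AD:DP:GQ",
          fmt_sample(pair$gt1, pair$ad_ref1, pair$ad_alt1, pair$dp1, pair$gq1),
          fmt_sample(pair$gt2, pair$ad_ref2, pair$ad_alt2, pair$dp2, pair$gq2),
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-sample VCF into a pair table
#'
#' Parses a VCF written by [write_vcf_pair()] (or any two-sample VCF with
#' GT:AD:DP:GQ and an INFO `CTX` tag) through `vcfR` and returns the
#' package's pair-table layout. Round-trips [write_vcf_pair()] output
#' losslessly.
#'
#' @param path VCF file path.
#' @return data.frame with columns chrom, pos, ref, alt, context, gt1,
#'   dp1, gq1, ad_ref1, ad_alt1, gt2, dp2, gq2, ad_ref2, ad_alt2.
#' @export
read_vcf_pair <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      context = character(0),
                      gt1 = character(0), dp1 = integer(0), gq1 = integer(0),
                      ad_ref1 = integer(0), ad_alt1 = integer(0),
                      gt2 = character(0), dp2 = integer(0), gq2 = integer(0),
                      ad_ref2 = integer(0), ad_alt2 = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0L) return(empty)
  if (ncol(v@gt) != 3L) stop("expected exactly two sample columns")
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  ad_split <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, character(1), 1L)),
         alt = as.integer(vapply(parts, `[`, character(1), 2L)))
  }
  ad1 <- ad_split(ad[, 1L]); ad2 <- ad_split(ad[, 2L])
  vcf_to_gt <- stats::setNames(names(GT_TO_VCF), GT_TO_VCF)
  class_of <- function(g) {
    g[is.na(g)] <- "./."
    out <- vcf_to_gt[g]
    if (any(is.na(out))) stop("unsupported genotype string: ",
                              paste(unique(g[is.na(out)]), collapse = ", "))
    unname(out)
  }
  ctx <- vcfR::extract.info(v, element = "CTX")
  data.frame(chrom = unname(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             ref = unname(v@fix[, "REF"]),
             alt = unname(v@fix[, "ALT"]),
             context = unname(ctx),
             gt1 = class_of(gt[, 1L]), dp1 = as.integer(dp[, 1L]),
             gq1 = as.integer(gq[, 1L]),
             ad_ref1 = ad1$ref, ad_alt1 = ad1$alt,
             gt2 = class_of(gt[, 2L]), dp2 = as.integer(dp[, 2L]),
             gq2 = as.integer(gq[, 2L]),
             ad_ref2 = ad2$ref, ad_alt2 = ad2$alt,
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Writes one VCF per pair plus the truth table and cohort metadata as
#' TSVs.
#'
#' @param cohort A `twinpzm_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the VCF paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twinpzm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(cohort$pairs), function(id) {
    p <- file.path(dir, paste0(id, ".vcf"))
    write_vcf_pair(cohort$pairs[[id]], p,
                   sample_names = paste0(id, c("_twin1", "_twin2")))
    p
  }, character(1))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a directory of twin-pair VCFs as a cohort
#'
#' Ingests every `*.vcf` in `dir` (one two-sample VCF per pair; pair ids
#' from file names) plus an optional `metadata.tsv` with pair_id, age, sex.
#'
#' @param dir Directory of per-pair VCF files.
#' @return List with `pairs` and `meta` in the [simulate_cohort()] layout.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  if (length(files) == 0L) stop("no .vcf files found in ", dir)
  pairs <- lapply(files, read_vcf_pair)
  names(pairs) <- sub("\\.vcf$", "", basename(files))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  else data.frame(pair_id = names(pairs), age = NA_real_,
                  sex = NA_character_, stringsAsFactors = FALSE)
  list(pairs = pairs, meta = meta)
}
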