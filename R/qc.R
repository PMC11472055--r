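# Genotype- and variant-level quality control reproducing the germline
# calling workflow's filter cascade: per-genotype DP/GQ masking, cohort
# call-rate exclusion, region masks, SNV/autosome restriction, and the
# per-individual VAF / alt-read-count filter.

#' Quality-control thresholds
#'
#' Defaults follow the study workflow: genotypes are masked when DP < 5,
#' GQ < 20, or DP > 60 with GQ < 95; variants with call rate below 0.90
#' are excluded; non-reference genotypes with VAF below 10% or fewer than
#' 2 alt-supporting reads are removed. All boundary values are retained
#' (the printed rules are strict inequalities).
#'
#' @param min_dp,min_gq Minimum read depth / genotype quality.
#' @param high_dp,high_dp_min_gq Genotypes with depth above `high_dp` must
#'   reach `high_dp_min_gq` quality.
#' @param min_call_rate Minimum fraction of called samples per variant.
#' @param min_vaf Minimum variant allele frequency for a non-reference
#'   genotype.
#' @param min_alt_count Minimum alt-supporting read count.
#' @return List of class `twinpzm_qc`.
#' @export
qc_thresholds <- function(min_dp = 5, min_gq = 20,
                          high_dp = 60, high_dp_min_gq = 95,
                          min_call_rate = 0.90,
                          min_vaf = 0.10, min_alt_count = 2) {
  stopifnot(min_dp >= 0, min_gq >= 0, high_dp >= 0, high_dp_min_gq >= 0,
            min_call_rate >= 0, min_call_rate <= 1,
            min_vaf >= 0, min_vaf <= 1, min_alt_count >= 0)
  structure(list(min_dp = min_dp, min_gq = min_gq, high_dp = high_dp,
                 high_dp_min_gq = high_dp_min_gq,
                 min_call_rate = min_call_rate,
                 min_vaf = min_vaf, min_alt_count = min_alt_count),
            class = "twinpzm_qc")
}

#' Fully permissive thresholds (all QC filters disabled)
#' @return A `twinpzm_qc` object that retains every genotype and variant.
#' @export
qc_disabled <- function() {
  qc_thresholds(min_dp = 0, min_gq = 0, high_dp = Inf, high_dp_min_gq = 0,
                min_call_rate = 0, min_vaf = 0, min_alt_count = 0)
}

#' Per-genotype depth/quality filter
#'
#' A genotype is masked (set Missing) iff `dp < min_dp`, `gq < min_gq`, or
#' `dp > high_dp` with `gq < high_dp_min_gq`. Missing dp/gq values fail.
#'
#' @param dp,gq Read depth and genotype quality vectors.
#' @param thresholds A [qc_thresholds()].
#' @return Logical vector: TRUE where the genotype is retained.
#' @export
filter_genotype <- function(dp, gq, thresholds = qc_thresholds()) {
  t <- thresholds
  ok <- !is.na(dp) & !is.na(gq) &
    dp >= t$min_dp & gq >= t$min_gq &
    !(dp > t$high_dp & gq < t$high_dp_min_gq)
  unname(ok)
}

#' Variant call-rate filter
#'
#' @param called Logical vector: is the genotype called (non-Missing) in
#'   each sample; or an integer count of called samples.
#' @param n_samples Total sample count (required when `called` is a
#'   count).
#' @param thresholds A [qc_thresholds()].
#' @return TRUE iff the called fraction is at least `min_call_rate`.
#' @export
filter_call_rate <- function(called, n_samples = length(called),
                             thresholds = qc_thresholds()) {
  force(n_samples)
  if (is.logical(called)) called <- sum(called)
  if (n_samples == 0L) stop("zero samples: call rate undefined")
  (called / n_samples) >= thresholds$min_call_rate
}

#' Per-genotype VAF / alt-count filter
#'
#' VAF is computed from the VCF allele depths as
#' `ad_alt / (ad_ref + ad_alt)`. A non-reference genotype is retained iff
#' VAF >= `min_vaf` and `ad_alt >= min_alt_count`; zero total allele depth
#' fails.
#'
#' @param ad_ref,ad_alt Reference/alternative allele read counts.
#' @param thresholds A [qc_thresholds()].
#' @return Logical vector: TRUE where retained.
#' @export
filter_vaf <- function(ad_ref, ad_alt, thresholds = qc_thresholds()) {
  tot <- ad_ref + ad_alt
  vaf <- ifelse(tot > 0, ad_alt / tot, NA_real_)
  out <- !is.na(vaf) & vaf >= thresholds$min_vaf &
    ad_alt >= thresholds$min_alt_count
  unname(out)
}

#' Restrict a site table to biallelic autosomal SNVs
#'
#' Keeps only sites on chr1-chr22 whose REF and ALT are single A/C/G/T
#' bases; multiallelic records (comma in ALT) are dropped entirely.
#'
#' @param sites data.frame with chrom, ref, alt columns.
#' @return The filtered data.frame.
#' @export
restrict_snv_autosomes <- function(sites) {
  chrom <- sub("^chr", "", sites$chrom)
  keep <- chrom %in% as.character(1:22) &
    sites$ref %in% DNA_BASES & sites$alt %in% DNA_BASES
  sites[keep, , drop = FALSE]
}

#' Read a BED mask as a GRanges
#'
#' BED intervals are 0-based half-open; conversion to 1-based closed
#' coordinates happens here, at the reader boundary, via
#' `rtracklayer::import`.
#'
#' @param path BED file path.
#' @param label Mask-class label stored in the `mask_class` metadata
#'   column (e.g. low-complexity, cytoband-excluded, low-accessibility).
#' @return A `GRanges` of mask intervals.
#' @export
read_bed_mask <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr)$mask_class <- label
  gr
}

#' Remove sites falling in masked regions
#'
#' Drops every site whose 1-based position intersects any mask interval.
#'
#' @param sites data.frame with chrom and pos (1-based) columns.
#' @param mask A `GRanges` of mask intervals (e.g. from
#'   [read_bed_mask()]), or a list of them (concatenated), or NULL for a
#'   no-op.
#' @return The filtered data.frame.
#' @export
apply_region_mask <- function(sites, mask) {
  if (is.null(mask) || nrow(sites) == 0L) return(sites)
  if (is.list(mask) && !inherits(mask, "GRanges"))
    mask <- do.call(c, mask)
  if (length(mask) == 0L) return(sites)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L))
  hit <- IRanges::overlapsAny(gr, mask)
  sites[!hit, , drop = FALSE]
}

# mask one pair's genotypes on DP/GQ; returns pair with gt set Missing
mask_low_quality_genotypes <- function(pair, thresholds) {
  for (s in 1:2) {
    ok <- filter_genotype(pair[[paste0("dp", s)]], pair[[paste0("gq", s)]],
                          thresholds)
    pair[[paste0("gt", s)]][!ok] <- "Missing"
  }
  pair
}

# mask non-reference genotypes failing the VAF/alt-count filter
mask_low_vaf_genotypes <- function(pair, thresholds) {
  for (s in 1:2) {
    nonref <- pair[[paste0("gt", s)]] %in% c("RefAlt", "AltAlt")
    ok <- filter_vaf(pair[[paste0("ad_ref", s)]],
                     pair[[paste0("ad_alt", s)]], thresholds)
    pair[[paste0("gt", s)]][nonref & !ok] <- "Missing"
  }
  pair
}

#' Apply the full QC cascade to a cohort
#'
#' Order: SNV/autosome restriction, region masks, per-genotype DP/GQ
#' masking, then (by default) the per-genotype VAF/alt-count masking, and
#' finally the cohort call-rate exclusion over the masked genotypes, which
#' makes the cascade idempotent. Samples whose pair table does not contain a site
#' are counted as called reference for the call-rate computation, matching
#' joint-genotyped VCF semantics.
#'
#' @param pairs Named list of pair tables.
#' @param thresholds A [qc_thresholds()].
#' @param mask Optional mask `GRanges` (or list of them).
#' @param vaf_stage When the VAF filter runs: `"pre_concordance"`
#'   (default, before the concordance matrix and PZM extraction),
#'   `"post_concordance"` (caller applies [mask_vaf()] later), or
#'   `"off"`.
#' @return List with `pairs` (filtered) and `log` (data.frame: pair_id,
#'   stage, sites_in, sites_out counting per-stage site retention, with
#'   genotype-masking stages reporting masked genotype counts).
#' @export
apply_qc <- function(pairs, thresholds = qc_thresholds(), mask = NULL,
                     vaf_stage = c("pre_concordance", "post_concordance",
                                   "off")) {
  vaf_stage <- match.arg(vaf_stage)
  log <- list()
  note <- function(pair_id, stage, n_in, n_out)
    data.frame(pair_id = pair_id, stage = stage,
               n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)

  for (id in names(pairs)) {
    p <- pairs[[id]]
    n0 <- nrow(p)
    p <- restrict_snv_autosomes(p)
    log[[length(log) + 1L]] <- note(id, "snv_autosomes", n0, nrow(p))
    n0 <- nrow(p)
    p <- apply_region_mask(p, mask)
    log[[length(log) + 1L]] <- note(id, "region_mask", n0, nrow(p))
    miss0 <- sum(p$gt1 == "Missing") + sum(p$gt2 == "Missing")
    p <- mask_low_quality_genotypes(p, thresholds)
    miss1 <- sum(p$gt1 == "Missing") + sum(p$gt2 == "Missing")
    log[[length(log) + 1L]] <- note(id, "genotype_dp_gq", 2L * nrow(p),
                                    2L * nrow(p) - (miss1 - miss0))
    if (vaf_stage == "pre_concordance") {
      # masked before the call-rate tally so the cascade is idempotent
      p <- mask_low_vaf_genotypes(p, thresholds)
      miss2 <- sum(p$gt1 == "Missing") + sum(p$gt2 == "Missing")
      log[[length(log) + 1L]] <- note(id, "vaf_alt_count", 2L * nrow(p),
                                      2L * nrow(p) - (miss2 - miss1))
    }
    pairs[[id]] <- p
  }

  # cohort call rate over 2 * n_pairs samples
  n_samples <- 2L * length(pairs)
  keys <- lapply(pairs, function(p) paste(p$chrom, p$pos, p$ref, p$alt))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  missing_per_site <- stats::setNames(integer(length(all_keys)), all_keys)
  for (id in names(pairs)) {
    p <- pairs[[id]]
    n_miss <- (p$gt1 == "Missing") + (p$gt2 == "Missing")
    missing_per_site[keys[[id]]] <-
      missing_per_site[keys[[id]]] + n_miss
  }
  rate <- (n_samples - missing_per_site) / n_samples
  keep_keys <- all_keys[rate >= thresholds$min_call_rate]
  for (id in names(pairs)) {
    p <- pairs[[id]]
    n0 <- nrow(p)
    p <- p[keys[[id]] %in% keep_keys, , drop = FALSE]
    log[[length(log) + 1L]] <- note(id, "call_rate", n0, nrow(p))
    rownames(p) <- NULL
    pairs[[id]] <- p
  }
  list(pairs = pairs, log = do.call(rbind, log))
}

#' Apply the VAF/alt-count filter to a cohort's pairs
#'
#' Convenience wrapper for the `"post_concordance"` configuration: masks
#' non-reference genotypes failing [filter_vaf()] in every pair table.
#'
#' @param pairs Named list of pair tables.
#' @param thresholds A [qc_thresholds()].
#' @return The list of pair tables with failing genotypes set Missing.
#' @export
mask_vaf <- function(pairs, thresholds = qc_thresholds()) {
  lapply(pairs, mask_low_vaf_genotypes, thresholds = thresholds)
}
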