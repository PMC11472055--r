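# End-to-end orchestration: (simulate | ingest VCFs) -> QC -> concordance
# -> PZM discovery -> spectra and signature attribution -> report. Every
# stage is an exported function; this module only composes them and writes
# the tabular outputs.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a cohort from `sim`) or `"vcf_dir"`
#'   (ingest per-pair VCFs from `vcf_dir`).
#' @param sim A [simulation_config()] (simulate mode).
#' @param vcf_dir Directory of per-pair two-sample VCFs (vcf_dir mode).
#' @param thresholds A [qc_thresholds()].
#' @param mask Optional region-mask `GRanges` (or list of them).
#' @param exons Optional exon `GRanges` for functional labelling.
#' @param germline_db Optional data.frame of known germline sites
#'   (chrom, pos, ref, alt).
#' @param signatures Reference signature matrix (default: packaged
#'   synthetic set).
#' @param cutoff High-concordance cutoff (fraction).
#' @param discordant_classes Genotype-pair classes treated as PZM
#'   candidates.
#' @param vaf_stage Placement of the VAF filter (see [apply_qc()]).
#' @param out_dir Optional directory for the tabular outputs.
#' @return List of class `twinpzm_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "vcf_dir"),
                            sim = simulation_config(),
                            vcf_dir = NULL,
                            thresholds = qc_thresholds(),
                            mask = NULL, exons = NULL, germline_db = NULL,
                            signatures = NULL,
                            cutoff = 0.99,
                            discordant_classes = DISCORDANT_CLASSES,
                            vaf_stage = "pre_concordance",
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "vcf_dir" && (is.null(vcf_dir) || !dir.exists(vcf_dir)))
    stop("vcf_dir mode requires an existing directory of VCFs")
  if (is.null(signatures)) signatures <- twinpzm_signatures()
  structure(list(mode = mode, sim = sim, vcf_dir = vcf_dir,
                 thresholds = thresholds, mask = mask, exons = exons,
                 germline_db = germline_db, signatures = signatures,
                 cutoff = cutoff, discordant_classes = discordant_classes,
                 vaf_stage = vaf_stage, out_dir = out_dir),
            class = "twinpzm_config")
}

#' Run the full PZM pipeline
#'
#' Composes all stages and returns a run report. Deterministic given the
#' configuration (simulation seed included). When `out_dir` is set, writes
#' `concordance.tsv` (per-pair contingency counts and rates),
#' `pzm_records.tsv`, `similarity.tsv` (pairs x signatures),
#' `substitution_classes.tsv` (6-class marginals per pair) and
#' `report.json`.
#'
#' @param config A [pipeline_config()].
#' @return List of class `twinpzm_report` with elements `concordance`
#'   (per-pair table), `pzm` (records), `counts` (per-pair PZM counts with
#'   exonic split), `summaries` (cohort statistics), `regression`
#'   (count ~ age + sex and, when VAFs are available, the per-mutation VAF
#'   model), `exonic_test`, `spectra` (96 x pairs count matrix),
#'   `artefact` (pooled low-concordance profile or NULL), `similarity`
#'   (high-concordance pairs x signatures score matrix), `best_signature`
#'   (named vector), `qc_log`, `truth` (simulate mode), and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "twinpzm_config"))
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$sim)
    pairs <- cohort$pairs; meta <- cohort$meta; truth <- cohort$truth
  } else {
    ing <- read_cohort(config$vcf_dir)
    pairs <- ing$pairs; meta <- ing$meta; truth <- NULL
  }

  qc <- apply_qc(pairs, config$thresholds, mask = config$mask,
                 vaf_stage = config$vaf_stage)
  conc <- concordance_table(qc$pairs, cutoff = config$cutoff,
                            discordant_classes = config$discordant_classes)

  if (config$vaf_stage == "post_concordance")
    qc$pairs <- mask_vaf(qc$pairs, config$thresholds)

  recs <- do.call(rbind, lapply(names(qc$pairs), function(id)
    extract_discordant(qc$pairs[[id]], id,
                       classes = config$discordant_classes)))
  recs <- filter_known_germline(recs, config$germline_db)
  n_germline_removed <- attr(recs, "n_removed")
  recs <- classify_functional_region(recs, config$exons)

  ids <- conc$pair_id
  counts <- data.frame(
    pair_id = ids,
    n_pzm = as.integer(table(factor(recs$pair_id, levels = ids))),
    n_exonic = as.integer(table(factor(
      recs$pair_id[recs$region_label == "exonic"], levels = ids))),
    stringsAsFactors = FALSE)
  counts$n_nonexonic <- counts$n_pzm - counts$n_exonic
  meta_ord <- meta[match(ids, meta$pair_id), ]

  high <- conc$high_concordance
  summaries <- list(
    concordance = cohort_concordance_summary(conc$rate),
    n_high = sum(high),
    pzm_all = summarize_pzm_counts(counts$n_pzm),
    pzm_high = if (any(high)) summarize_pzm_counts(counts$n_pzm, high)
    else NULL)

  regression <- list()
  if (!anyNA(meta_ord$age) && length(unique(meta_ord$sex)) > 1L &&
      nrow(counts) >= 6L) {
    regression$counts <- regress_counts_on_covariates(
      counts$n_pzm, meta_ord$age, meta_ord$sex)
    m <- match(recs$pair_id, ids)
    ok <- !is.na(recs$vaf)
    if (sum(ok) >= 10L)
      regression$vaf <- regress_vaf(recs$vaf[ok], conc$rate[m][ok],
                                    meta_ord$age[m][ok],
                                    meta_ord$sex[m][ok])
  }
  exonic_test <- if (nrow(counts) >= 2L)
    compare_exonic_burden(counts$n_exonic, counts$n_nonexonic) else NULL

  # 96-motif spectra and signature attribution
  spectra <- vapply(ids, function(id)
    build_spectrum(recs$motif[recs$pair_id == id]), integer(96))
  rownames(spectra) <- motif_levels()
  low_ids <- ids[!high]
  artefact <- NULL
  if (length(low_ids) && sum(spectra[, low_ids, drop = FALSE]) > 0)
    artefact <- build_artefact_profile(spectra[, low_ids, drop = FALSE])
  sigs_c <- complement_zeros(config$signatures)
  artefact_c <- if (is.null(artefact)) NULL else complement_zeros(artefact)
  high_ids <- ids[high & colSums(spectra)[ids] > 0]
  similarity <- NULL; best <- NULL
  if (length(high_ids)) {
    sims <- lapply(high_ids, function(id)
      corrected_similarity(spectra[, id], sigs_c, artefact_c))
    similarity <- do.call(rbind, lapply(sims, `[[`, "scores"))
    rownames(similarity) <- high_ids
    best <- stats::setNames(vapply(sims, `[[`, character(1), "best"),
                            high_ids)
  }
  subcls <- t(apply(spectra, 2L, substitution_marginals))

  report <- structure(list(
    concordance = conc, pzm = recs, counts = counts,
    summaries = summaries, regression = regression,
    exonic_test = exonic_test,
    spectra = spectra, artefact = artefact,
    similarity = similarity, best_signature = best,
    substitution_classes = subcls,
    qc_log = qc$log, truth = truth, meta = meta,
    provenance = list(
      seed = if (config$mode == "simulate") config$sim$seed else NA,
      n_germline_db_removed = n_germline_removed,
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("twinpzm")))),
    class = "twinpzm_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Hash of a pipeline configuration
#'
#' MD5 of the deparsed configuration (matrices and functions included by
#' value), recorded in the report provenance so a rerun can verify it used
#' the same settings.
#'
#' @param config A [pipeline_config()] (or any R object).
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)  # scratch only; the digest is of the serialized bytes
  unname(tools::md5sum(f))
}

#' Write a run report's tables to a directory
#'
#' @param report A `twinpzm_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name)
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(report$concordance, "concordance.tsv")
  wt(report$pzm, "pzm_records.tsv")
  wt(cbind(pair_id = colnames(report$spectra),
           as.data.frame(t(report$spectra))), "spectra.tsv")
  wt(cbind(pair_id = rownames(report$substitution_classes),
           as.data.frame(report$substitution_classes)),
     "substitution_classes.tsv")
  if (!is.null(report$similarity))
    wt(cbind(pair_id = rownames(report$similarity),
             as.data.frame(report$similarity),
             best_signature = report$best_signature[rownames(report$similarity)]),
       "similarity.tsv")
  jsonlite::write_json(
    list(summaries = report$summaries, regression = report$regression,
         exonic_test = report$exonic_test,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}

read_table1_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_participants.tsv",
                        package = "twinpzm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Summarize the packaged participant characteristics table
#'
#' Recomputes the cohort-level summaries from the transcribed participant
#' table (per-pair age, sex, mean depths, genotype concordance and
#' discordant-variant counts): mean age, female ratio, mean depth,
#' concordance mean/median, and discordant-count statistics over all
#' pairs and over the high-concordance subset.
#'
#' @param path Optional path to a participant TSV; default is the
#'   packaged fixture.
#' @param cutoff High-concordance cutoff on the percentage scale.
#' @return List with `n_pairs`, `mean_age`, `female_ratio`,
#'   `mean_depth`, `concordance` (mean/median/min/max, percent),
#'   `discordant_all` and `discordant_high` ([summarize_pzm_counts()]
#'   blocks), `n_high`, and `exonic_test` (rank-sum comparison of exonic
#'   vs non-exonic per-pair counts).
#' @export
summarize_table1_fixture <- function(path = NULL, cutoff = 99) {
  t1 <- read_table1_fixture(path)
  need <- c("pair", "age", "sex", "depth_twin1", "depth_twin2",
            "concordance_pct", "n_discordant")
  if (!all(need %in% names(t1)))
    stop("participant table must have columns: ",
         paste(need, collapse = ", "))
  high <- t1$concordance_pct >= cutoff
  list(n_pairs = nrow(t1),
       mean_age = mean(t1$age),
       female_ratio = mean(t1$sex == "F"),
       mean_depth = mean(c(t1$depth_twin1, t1$depth_twin2)),
       concordance = list(mean = mean(t1$concordance_pct),
                          median = stats::median(t1$concordance_pct),
                          min = min(t1$concordance_pct),
                          max = max(t1$concordance_pct)),
       discordant_all = summarize_pzm_counts(t1$n_discordant),
       discordant_high = summarize_pzm_counts(t1$n_discordant, high),
       n_high = sum(high),
       exonic_test = compare_exonic_burden(t1$n_exonic,
                                           t1$n_discordant - t1$n_exonic))
}
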