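# PZM discovery: extract discordant-genotype sites as candidate
# postzygotic somatic mutations, exclude known germline variants, label
# exonic vs non-exonic, and compute the cohort summary statistics and
# association models.

#' Extract discordant sites as candidate PZMs
#'
#' One record per QC-passed site whose unordered genotype pair belongs to
#' a discordant class. The carrier is the twin with more alt alleles; its
#' VAF is computed from the allele depths. The trinucleotide motif index
#' follows [motif_of()] (strand-collapsed), so records on either reference
#' strand map to the same motif.
#'
#' @param pair Pair table (QC-passed).
#' @param pair_id Pair identifier attached to each record.
#' @param classes Discordant genotype-pair classes to extract (default
#'   rr_ra, rr_aa, ra_aa).
#' @return data.frame with pair_id, chrom, pos, ref, alt, context,
#'   gt_pair, carrier (1 or 2), vaf, motif.
#' @export
extract_discordant <- function(pair, pair_id = "pair",
                               classes = DISCORDANT_CLASSES) {
  stopifnot(all(classes %in% DISCORDANT_CLASSES))
  cls <- pair_class(pair$gt1, pair$gt2)
  keep <- !is.na(cls) & cls %in% classes
  p <- pair[keep, , drop = FALSE]
  cls <- cls[keep]
  alt_dose <- function(gt) c(RefRef = 0L, RefAlt = 1L, AltAlt = 2L)[gt]
  carrier <- ifelse(alt_dose(p$gt1) >= alt_dose(p$gt2), 1L, 2L)
  ad_ref <- ifelse(carrier == 1L, p$ad_ref1, p$ad_ref2)
  ad_alt <- ifelse(carrier == 1L, p$ad_alt1, p$ad_alt2)
  tot <- ad_ref + ad_alt
  out <- data.frame(pair_id = rep(pair_id, nrow(p)),
                    chrom = p$chrom, pos = p$pos,
                    ref = p$ref, alt = p$alt, context = p$context,
                    gt_pair = cls,
                    carrier = as.integer(carrier),
                    vaf = ifelse(tot > 0, ad_alt / tot, NA_real_),
                    stringsAsFactors = FALSE)
  out$motif <- if (nrow(out)) motif_of(out$context, out$ref, out$alt)
  else integer(0)
  rownames(out) <- NULL
  out
}

#' Remove variants present in a germline database
#'
#' Exclusion is keyed on the full (chrom, pos, ref, alt) tuple: a database
#' entry with a different alternative allele at the same position does not
#' remove the record.
#'
#' @param records PZM records from [extract_discordant()].
#' @param db data.frame of known germline sites with chrom, pos, ref, alt
#'   columns (or NULL / zero rows for a no-op).
#' @return The filtered records; the number removed is attached as
#'   attribute `n_removed`.
#' @export
filter_known_germline <- function(records, db) {
  if (is.null(db) || nrow(db) == 0L) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  key <- function(d) paste(sub("^chr", "", d$chrom), d$pos, d$ref, d$alt)
  hit <- key(records) %in% key(db)
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Label records as exonic or non-exonic
#'
#' A record is exonic iff its position overlaps any exon interval.
#'
#' @param records PZM records.
#' @param exons `GRanges` of exon intervals (e.g. from
#'   [read_bed_mask()]), or NULL to label everything non-exonic.
#' @return The records with a `region_label` column
#'   (`"exonic"`/`"non-exonic"`).
#' @export
classify_functional_region <- function(records, exons = NULL) {
  if (nrow(records) == 0L) {
    records$region_label <- character(0)
    return(records)
  }
  lab <- rep("non-exonic", nrow(records))
  if (!is.null(exons) && length(exons) > 0L) {
    gr <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos, width = 1L))
    lab[IRanges::overlapsAny(gr, exons)] <- "exonic"
  }
  records$region_label <- lab
  records
}

#' Summary statistics of per-pair PZM counts
#'
#' @param counts Non-negative per-pair PZM counts.
#' @param subset Optional logical/integer index restricting the pairs
#'   (e.g. the high-concordance subset).
#' @return List with n, mean, sd (sample, n-1 denominator), min, max.
#' @export
summarize_pzm_counts <- function(counts, subset = NULL) {
  if (!is.null(subset)) counts <- counts[subset]
  if (length(counts) == 0L) stop("empty subset")
  stopifnot(all(counts >= 0))
  list(n = length(counts), mean = mean(counts),
       sd = if (length(counts) > 1L) stats::sd(counts) else 0,
       min = min(counts), max = max(counts))
}

#' Ordinary least squares with an explicit singularity check
#'
#' Fits `y ~ .` over the given covariates by `lm`. Standard errors, t
#' statistics and two-sided p-values come from the t distribution with
#' n - p - 1 degrees of freedom; p-values are reported unadjusted. A
#' rank-deficient design (e.g. a duplicated covariate) raises an explicit
#' error rather than silently aliasing coefficients.
#'
#' @param y Response vector.
#' @param covariates data.frame of covariates (characters are treated as
#'   factors).
#' @return Coefficient data.frame with term, beta, se, t, p.
#' @export
regress_table <- function(y, covariates) {
  stopifnot(is.data.frame(covariates), length(y) == nrow(covariates))
  d <- covariates
  for (j in seq_along(d)) if (is.character(d[[j]])) d[[j]] <- factor(d[[j]])
  X <- stats::model.matrix(~ ., d)
  if (nrow(d) < ncol(X) + 2L) stop("too few observations for the design")
  if (qr(X)$rank < ncol(X))
    stop("singular design matrix: covariates are linearly dependent")
  d$.y <- y
  s <- summary(stats::lm(.y ~ ., data = d))$coefficients
  data.frame(term = rownames(s),
             beta = s[, "Estimate"], se = s[, "Std. Error"],
             t = s[, "t value"], p = s[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress per-pair PZM counts on age and sex
#'
#' Ordinary least squares via [regress_table()]: `count ~ age + sex`.
#'
#' @param counts Per-pair PZM counts.
#' @param ages Ages in years.
#' @param sexes Sex labels (coerced to factor).
#' @return Coefficient data.frame with term, beta, se, t, p.
#' @export
regress_counts_on_covariates <- function(counts, ages, sexes) {
  regress_table(counts, data.frame(age = ages, sex = factor(sexes)))
}

#' Regress per-mutation VAF on pair concordance, age and sex
#'
#' Ordinary least squares via [regress_table()] over per-mutation rows:
#' `vaf ~ concordance + age + sex`.
#'
#' @param vaf Per-mutation variant allele frequencies.
#' @param concordance The carrier pair's genotype concordance rate,
#'   repeated per mutation.
#' @param ages,sexes The carrier pair's age and sex, repeated per
#'   mutation.
#' @return Coefficient data.frame with term, beta, se, t, p.
#' @export
regress_vaf <- function(vaf, concordance, ages, sexes) {
  regress_table(vaf, data.frame(concordance = concordance, age = ages,
                                sex = factor(sexes)))
}

#' Compare exonic and non-exonic PZM burdens
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of per-pair exonic vs
#' non-exonic counts; exact for small samples without ties, normal
#' approximation otherwise (`stats::wilcox.test` semantics).
#'
#' @param exonic,nonexonic Per-pair counts (both non-empty).
#' @return List with `statistic` (the rank-sum U/W) and `p.value`.
#' @export
compare_exonic_burden <- function(exonic, nonexonic) {
  stopifnot(length(exonic) > 0L, length(nonexonic) > 0L)
  w <- suppressWarnings(stats::wilcox.test(exonic, nonexonic,
                                           alternative = "two.sided"))
  list(statistic = unname(w$statistic), p.value = min(w$p.value, 1))
}
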