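# Twin genotype concordance from the 3x3 genotype contingency matrix.
# Both-reference sites are uncountable in a variant-only VCF, so the
# concordance rate is defined over the five observable non-(RefRef,RefRef)
# genotype-pair classes.

PAIR_CLASSES <- c("rr_ra", "rr_aa", "ra_ra", "ra_aa", "aa_aa")
CONCORDANT_CLASSES <- c("ra_ra", "aa_aa")
DISCORDANT_CLASSES <- c("rr_ra", "rr_aa", "ra_aa")

# unordered genotype-pair class of two genotype class vectors; NA for
# (RefRef,RefRef) or any Missing
pair_class <- function(gt1, gt2) {
  code <- c(RefRef = 0L, RefAlt = 1L, AltAlt = 2L, Missing = NA_integer_)
  a <- code[gt1]; b <- code[gt2]
  lo <- pmin(a, b); hi <- pmax(a, b)
  cls <- rep(NA_character_, length(lo))
  ok <- !is.na(lo)
  key <- paste0(lo, hi)
  map <- c(`01` = "rr_ra", `02` = "rr_aa", `11` = "ra_ra",
           `12` = "ra_aa", `22` = "aa_aa")
  cls[ok] <- map[key[ok]]
  cls
}

#' Build the genotype contingency counts for one twin pair
#'
#' Tallies QC-passed sites into the five observable unordered
#' genotype-pair classes. Sites Missing in either twin and
#' (RefRef,RefRef) sites are excluded; swapping the twin columns leaves
#' the counts unchanged.
#'
#' @param pair Pair table with gt1 and gt2 genotype-class columns.
#' @return Named integer vector with elements rr_ra, rr_aa, ra_ra, ra_aa,
#'   aa_aa.
#' @export
build_contingency <- function(pair) {
  cls <- pair_class(pair$gt1, pair$gt2)
  counts <- table(factor(cls, levels = PAIR_CLASSES))
  out <- as.integer(counts)
  names(out) <- PAIR_CLASSES
  out
}

#' Genotype concordance rate of a twin pair
#'
#' The fraction of concordant non-reference genotype pairs:
#' `(ra_ra + aa_aa) / (rr_ra + rr_aa + ra_ra + ra_aa + aa_aa)`.
#'
#' @param contingency Named counts from [build_contingency()].
#' @return The concordance rate in `[0, 1]`.
#' @export
concordance_rate <- function(contingency) {
  stopifnot(all(PAIR_CLASSES %in% names(contingency)))
  denom <- sum(contingency[PAIR_CLASSES])
  if (denom == 0) stop("no non-reference genotype pairs: rate undefined")
  unname(sum(contingency[CONCORDANT_CLASSES]) / denom)
}

#' Count discordant genotype pairs
#'
#' @param contingency Named counts from [build_contingency()].
#' @param classes Which genotype-pair classes count as discordant
#'   (default: all three of rr_ra, rr_aa, ra_aa).
#' @return Integer count.
#' @export
n_discordant <- function(contingency, classes = DISCORDANT_CLASSES) {
  stopifnot(all(classes %in% PAIR_CLASSES))
  sum(contingency[classes])
}

#' Classify pairs at the high-concordance cutoff
#'
#' A pair is high-concordance iff its unrounded rate is at least the
#' cutoff (default 99%).
#'
#' @param rates Numeric vector of per-pair concordance rates.
#' @param cutoff High-concordance threshold.
#' @return Logical vector: TRUE for high-concordance pairs.
#' @export
classify_pairs <- function(rates, cutoff = 0.99) {
  stopifnot(all(is.finite(rates)))
  rates >= cutoff
}

#' Cohort-level concordance summary
#'
#' @param rates Numeric vector of per-pair concordance rates (fractions).
#' @return List with mean, median, min, max (fractions; the median of an
#'   even count is the midpoint average).
#' @export
cohort_concordance_summary <- function(rates) {
  if (length(rates) == 0L) stop("empty cohort")
  list(mean = mean(rates), median = stats::median(rates),
       min = min(rates), max = max(rates))
}

#' Per-pair concordance over a QC-passed cohort
#'
#' Convenience wrapper: builds each pair's contingency counts and returns
#' a per-pair results table.
#'
#' @param pairs Named list of QC-passed pair tables.
#' @param cutoff High-concordance cutoff passed to [classify_pairs()].
#' @param discordant_classes Classes counted by [n_discordant()].
#' @return data.frame with pair_id, the five class counts, rate,
#'   n_discordant and high_concordance.
#' @export
concordance_table <- function(pairs, cutoff = 0.99,
                              discordant_classes = DISCORDANT_CLASSES) {
  rows <- lapply(names(pairs), function(id) {
    ct <- build_contingency(pairs[[id]])
    data.frame(pair_id = id, t(ct),
               rate = concordance_rate(ct),
               n_discordant = n_discordant(ct, discordant_classes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$high_concordance <- classify_pairs(out$rate, cutoff)
  out
}
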