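# Mutational-spectrum construction and likelihood-based signature
# attribution. A spectrum is a named integer vector of 96 motif counts; a
# signature profile is a named numeric vector of 96 probabilities; a
# signature matrix is a 96 x S numeric matrix (rows in canonical motif
# order, one column per signature).

#' Build a 96-motif mutational spectrum
#'
#' Tallies motif indices (see [motif_of()]) into the canonical 96-component
#' count vector.
#'
#' @param motifs Integer vector of motif indices in 1..96 (one per
#'   mutation). May be empty.
#' @return Named integer vector of length 96; names are [motif_levels()]
#'   and `sum()` equals `length(motifs)`.
#' @export
#' @examples
#' build_spectrum(motif_of("ACG", "C", "T"))
build_spectrum <- function(motifs) {
  motifs <- as.integer(motifs)
  if (length(motifs) && (any(is.na(motifs)) || any(motifs < 1L | motifs > 96L)))
    stop("motif indices must be in 1..96")
  x <- tabulate(motifs, nbins = 96L)
  names(x) <- motif_levels()
  x
}

#' Six-class substitution marginals of a spectrum
#'
#' Collapses a 96-motif spectrum over flanking bases to the six pyrimidine
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G).
#'
#' @param x Numeric vector of length 96 in canonical motif order.
#' @return Named numeric vector of length 6.
#' @export
substitution_marginals <- function(x) {
  stopifnot(length(x) == 96L)
  m <- vapply(seq_along(SUBSTITUTIONS),
              function(i) sum(x[((i - 1L) * 16L + 1L):(i * 16L)]),
              numeric(1))
  names(m) <- SUBSTITUTIONS
  m
}

#' Pool an artefact profile from low-concordance pairs
#'
#' Low-concordance twin pairs are enriched for sequencing artefacts; their
#' pooled motif counts, normalized to probabilities, serve as a background
#' profile against which signature likelihoods are corrected.
#'
#' @param spectra A list of 96-count spectra (or a 96 x P matrix of counts,
#'   one column per pair) from the low-concordance pairs.
#' @return Named numeric probability vector of length 96 summing to 1.
#' @export
build_artefact_profile <- function(spectra) {
  if (is.list(spectra)) {
    if (length(spectra) == 0L)
      stop("no low-concordance pairs: skip the artefact correction")
    spectra <- do.call(cbind, spectra)
  }
  stopifnot(is.numeric(spectra), nrow(spectra) == 96L)
  pooled <- rowSums(spectra)
  total <- sum(pooled)
  if (total <= 0)
    stop("pooled artefact spectrum is empty: skip the artefact correction")
  p <- pooled / total
  names(p) <- motif_levels()
  p
}

#' Replace zero probabilities by half the minimum positive value
#'
#' Zero entries of a signature profile would make the multinomial
#' log-likelihood degenerate (-Inf) whenever the corresponding motif is
#' observed. Each zero is replaced by half of the smallest positive entry
#' and the profile is renormalized to sum to 1. Matrices are complemented
#' column-wise.
#'
#' @param p Probability vector, or matrix with one profile per column.
#' @return Object of the same shape with strictly positive entries, each
#'   profile summing to 1.
#' @export
#' @examples
#' complement_zeros(c(0.5, 0.5, 0))  # 0.4 0.4 0.2
complement_zeros <- function(p) {
  if (is.matrix(p)) return(apply(p, 2L, complement_zeros))
  stopifnot(is.numeric(p), all(p >= 0))
  pos <- p[p > 0]
  if (length(pos) == 0L) stop("profile has no positive entries")
  p[p == 0] <- min(pos) / 2
  p / sum(p)
}

#' Multinomial log-likelihood of a spectrum under a profile
#'
#' Computes `log n! - sum(log x_k!) + sum(x_k log p_k)` for observed counts
#' `x` with `n = sum(x)` under motif probabilities `p`. Log-factorials use
#' the log-gamma function for numerical stability.
#'
#' @param x Non-negative integer count vector.
#' @param p Probability vector of the same length, strictly positive
#'   wherever `x > 0` (apply [complement_zeros()] first).
#' @return The log-likelihood (a scalar).
#' @export
#' @examples
#' multinomial_loglik(c(1, 1), c(0.5, 0.5))  # -log(2)
multinomial_loglik <- function(x, p) {
  stopifnot(length(x) == length(p), all(x >= 0), all(p >= 0))
  if (any(x > 0 & p == 0))
    stop("profile has zero probability at an observed motif; complement zeros first")
  n <- sum(x)
  pos <- x > 0
  lgamma(n + 1) - sum(lgamma(x + 1)) + sum(x[pos] * log(p[pos]))
}

#' Artefact-corrected signature similarity scores
#'
#' Scores a pair's spectrum against each reference signature by the
#' per-mutation log-likelihood difference from the artefact background:
#' `score_s = (logL(x, p_s) - logL(x, p_artefact)) / n`. Dividing by the
#' mutation count keeps scores comparable across pairs with different
#' burdens; subtracting the artefact log-likelihood removes the shared
#' combinatorial constant and penalizes signatures that fit no better than
#' the sequencing-noise background. The best signature attains the row
#' maximum; ties break deterministically toward the lowest signature index.
#'
#' @param x 96-count spectrum with `sum(x) >= 1`.
#' @param signatures 96 x S signature matrix, zero-complemented.
#' @param artefact Artefact probability profile (length 96,
#'   zero-complemented), or `NULL` to skip the artefact subtraction (scores
#'   are then `logL/n`).
#' @return List with `scores` (named numeric, one per signature), `best`
#'   (signature name), `best_index`, and `tie` (logical: was the argmax
#'   tied).
#' @export
corrected_similarity <- function(x, signatures, artefact = NULL) {
  stopifnot(is.matrix(signatures), nrow(signatures) == length(x))
  n <- sum(x)
  if (n < 1) stop("spectrum is empty")
  ll <- apply(signatures, 2L, function(p) multinomial_loglik(x, p))
  base <- if (is.null(artefact)) 0 else multinomial_loglik(x, artefact)
  scores <- (ll - base) / n
  best_index <- which.max(scores)  # which.max takes the first maximum
  tie <- sum(scores == scores[best_index]) > 1L
  list(scores = scores,
       best = colnames(signatures)[best_index],
       best_index = unname(best_index),
       tie = tie)
}

#' Read a signature probability table in COSMIC v2 layout
#'
#' Parses a tab-separated signature file with columns `Substitution Type`,
#' `Trinucleotide`, `Somatic Mutation Type` and one numeric column per
#' signature, and maps the 96 rows into the package's canonical motif order
#' regardless of the file's row order. Each signature column must sum to 1
#' within `tol` and is renormalized exactly.
#'
#' @param path Path to the TSV file.
#' @param tol Allowed deviation of each column sum from 1 before
#'   renormalization.
#' @return 96 x S numeric matrix; rownames are [motif_levels()], colnames
#'   the signature names from the file header.
#' @export
read_signature_matrix <- function(path, tol = 1e-3) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Substitution Type", "Trinucleotide", "Somatic Mutation Type")
  if (!all(need %in% names(tab)))
    stop("signature file must have columns: ", paste(need, collapse = ", "))
  sig_cols <- setdiff(names(tab), need)
  if (length(sig_cols) == 0L) stop("no signature columns found")
  labels <- tab[["Somatic Mutation Type"]]
  canon <- motif_levels()
  if (anyDuplicated(labels))
    stop("duplicate motif rows: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  missing <- setdiff(canon, labels)
  if (length(missing))
    stop("signature file is missing motif rows: ",
         paste(missing, collapse = ", "))
  ord <- match(canon, labels)
  m <- as.matrix(tab[ord, sig_cols, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in signature columns")
  sums <- colSums(m)
  off <- abs(sums - 1) > tol
  if (any(off))
    stop("signature columns do not sum to 1 within tolerance: ",
         paste(sig_cols[off], collapse = ", "))
  m <- sweep(m, 2L, sums, "/")
  rownames(m) <- canon
  m
}

#' Packaged synthetic reference signature matrix
#'
#' Loads the 30-signature reference matrix shipped with the package. This
#' matrix is a synthetic stand-in constructed from published qualitative
#' descriptions of the COSMIC v2 signatures (substitution-class weights and
#' hallmark context preferences such as NpCpG C>T for Signature 1 or the
#' flat, T>C-leaning clock-like shape of Signature 5); it is not the COSMIC
#' download and carries no COSMIC numerical content.
#'
#' @return 96 x 30 probability matrix, columns `Signature 1` .. `Signature 30`.
#' @export
twinpzm_signatures <- function() {
  path <- system.file("extdata", "signatures_v2_synthetic.tsv",
                      package = "twinpzm", mustWork = TRUE)
  read_signature_matrix(path)
}

#' Sample a spectrum from a signature profile
#'
#' Draws `n` mutations i.i.d. from a 96-motif probability profile and
#' returns the resulting count spectrum. Thin wrapper over
#' [stats::rmultinom()]; uses the current RNG state.
#'
#' @param n Number of mutations.
#' @param p Probability vector of length 96.
#' @return Named integer spectrum of length 96 summing to `n`.
#' @export
sample_spectrum <- function(n, p) {
  stopifnot(length(p) == 96L)
  x <- as.integer(stats::rmultinom(1L, size = n, prob = p)[, 1L])
  names(x) <- motif_levels()
  x
}

#' Uniform 96-motif profile
#' @return Numeric vector of length 96, all entries 1/96.
#' @export
uniform_profile <- function() {
  p <- rep(1 / 96, 96L)
  names(p) <- motif_levels()
  p
}
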