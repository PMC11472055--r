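# Canonical 96-motif order shared by spectra, the signature reader and all
# outputs: substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank
# A,C,G,T, then 3' flank A,C,G,T.

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' Canonical trinucleotide motif labels
#'
#' Returns the 96 single-base-substitution motif labels in the package's
#' canonical order: substitution class varies slowest (C>A, C>G, C>T, T>A,
#' T>C, T>G), then the 5' flanking base (A, C, G, T), then the 3' flanking
#' base (A, C, G, T). All references are collapsed to the pyrimidine strand,
#' so labels look like `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' motif_levels()[1:4]
motif_levels <- function() {
  grid <- expand.grid(f3 = DNA_BASES, f5 = DNA_BASES, sub = SUBSTITUTIONS,
                      stringsAsFactors = FALSE)
  paste0(grid$f5, "[", grid$sub, "]", grid$f3)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Map a substitution in context to its canonical motif index
#'
#' Collapses a single-base substitution with its trinucleotide reference
#' context onto the pyrimidine strand: when the reference allele is a purine
#' (A or G) the context is reverse-complemented and both alleles are
#' complemented before lookup, since sequencing cannot distinguish the two
#' DNA strands. Vectorized over all arguments.
#'
#' @param context Character vector of 3-base reference contexts; the middle
#'   base must equal `ref`.
#' @param ref,alt Single reference/alternative bases (`ref != alt`).
#' @return Integer vector of motif indices in 1..96, following
#'   [motif_levels()].
#' @export
#' @examples
#' motif_levels()[motif_of("ACG", "C", "T")]  # "A[C>T]G"
#' motif_levels()[motif_of("TGA", "G", "A")]  # strand-collapsed to "T[C>T]A"
motif_of <- function(context, ref, alt) {
  n <- max(length(context), length(ref), length(alt))
  context <- rep_len(toupper(context), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (any(nchar(context) != 3L))
    stop("context must be exactly 3 bases")
  if (any(!grepl("^[ACGT]{3}$", context)) ||
      any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES))
    stop("context, ref and alt must be A/C/G/T only")
  if (any(substr(context, 2L, 2L) != ref))
    stop("middle base of context must equal ref")
  if (any(ref == alt))
    stop("ref and alt must differ")

  purine <- ref %in% c("A", "G")
  if (any(purine)) {
    context[purine] <- revcomp(context[purine])
    ref[purine] <- complement_base(ref[purine])
    alt[purine] <- complement_base(alt[purine])
  }
  sub_i <- match(paste0(ref, ">", alt), SUBSTITUTIONS)
  f5_i <- match(substr(context, 1L, 1L), DNA_BASES)
  f3_i <- match(substr(context, 3L, 3L), DNA_BASES)
  (sub_i - 1L) * 16L + (f5_i - 1L) * 4L + f3_i
}

#' Decompose canonical motif indices
#'
#' Inverse of [motif_of()] on the pyrimidine strand: returns the
#' substitution class, flanking bases, context, ref and alt for each motif
#' index.
#'
#' @param idx Integer vector of motif indices in 1..96.
#' @return data.frame with columns `motif`, `label`, `substitution`,
#'   `f5`, `f3`, `context`, `ref`, `alt`.
#' @export
motif_components <- function(idx) {
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 1L | idx > 96L))
    stop("motif indices must be in 1..96")
  if (length(idx) == 0L)
    return(data.frame(motif = integer(0), label = character(0),
                      substitution = character(0), f5 = character(0),
                      f3 = character(0), context = character(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  sub_i <- (idx - 1L) %/% 16L + 1L
  rest <- (idx - 1L) %% 16L
  f5 <- DNA_BASES[rest %/% 4L + 1L]
  f3 <- DNA_BASES[rest %% 4L + 1L]
  sub <- SUBSTITUTIONS[sub_i]
  ref <- substr(sub, 1L, 1L)
  alt <- substr(sub, 3L, 3L)
  data.frame(motif = idx,
             label = paste0(f5, "[", sub, "]", f3),
             substitution = sub, f5 = f5, f3 = f3,
             context = paste0(f5, ref, f3), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' The 32 pyrimidine-centred trinucleotide contexts
#'
#' All contexts with a C or T middle base, ordered middle base C then T,
#' then 5' flank A,C,G,T, then 3' flank A,C,G,T. Used by the simulator's
#' configurable context frequency table.
#'
#' @return Character vector of length 32.
#' @export
pyrimidine_contexts <- function() {
  grid <- expand.grid(f3 = DNA_BASES, f5 = DNA_BASES, mid = c("C", "T"),
                      stringsAsFactors = FALSE)
  paste0(grid$f5, grid$mid, grid$f3)
}
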