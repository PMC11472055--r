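---
title: "Detecting postzygotic somatic mutations between monozygotic twins: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting postzygotic somatic mutations between monozygotic twins: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpzm)
```

## The problem

Monozygotic co-twins are genetically identical at conception. In adult
whole-genome sequencing of a twin pair, a site where the two twins carry
different genotypes is therefore either a postzygotic somatic mutation
(PZM) — a mutation that arose after the zygote split, and, if early enough,
spread to most cells with a variant allele frequency (VAF) near 0.5 (2-cell
stage) or 0.25 (4-cell stage) — or a sequencing artefact. The package
treats PZM discovery as a genotype-discordance problem over stringently
filtered germline-style calls, deliberately targeting high-VAF early
mutations rather than late low-VAF mosaicism: a germline-calling workflow
is far better calibrated for ~0.5-VAF variants than somatic callers tuned
for rare clones, and low-VAF calls are where artefacts concentrate.

## Concordance model

All QC-passed biallelic autosomal SNVs of a pair are tallied into a 3×3
genotype contingency matrix. A variant-only VCF cannot count
both-reference sites, so the concordance rate conditions on the five
observable unordered genotype-pair classes,

$$\mathrm{rate} = \frac{n_{RA\sim RA}+n_{AA\sim AA}}
{n_{RR\sim RA}+n_{RR\sim AA}+n_{RA\sim RA}+n_{RA\sim AA}+n_{AA\sim AA}},$$

and sites Missing in either twin are excluded (the formula has no missing
class). Classification at the 99% cutoff uses `rate >= 0.99` on the
unrounded value; percentages are rounded to one decimal only for display.
Which discordant classes count as PZM candidates is configurable; the
default is the superset {RR–RA, RR–AA, RA–AA}, since restricting to a
subset is a strictly narrower query that the `classes` argument expresses
directly.

## QC cascade

Thresholds (all boundaries *retained*, i.e. the rules are strict
inequalities): genotypes are masked at DP < 5 reads, GQ < 20, or DP > 60
with GQ < 95 (deep sites with mediocre quality are likelier to sit in
collapsed repeats); non-reference genotypes are masked at VAF < 10% or
fewer than 2 alt reads, with VAF computed from the VCF AD fields — the
same counts a BAM walk would give at desk scale; variants are dropped at
cohort call rate < 0.90, inside region masks (BED, 0-based half-open,
converted at the reader boundary only), off the autosomes, or when not
biallelic SNVs (multiallelic records are dropped, not decomposed). The
VAF masking runs before the call-rate tally, which makes the cascade
idempotent — rerunning it on its own output is a no-op, a property the
test suite checks. Whether VAF masking precedes concordance is
configurable (`vaf_stage`); the default applies it before both
concordance and PZM extraction so that the same site set underlies both.

## Signature attribution

Each PZM is annotated with its trinucleotide context, collapsed onto the
pyrimidine strand (a purine reference reverse-complements context and
alleles), giving 6 substitution classes × 16 flank combinations = 96
motifs in a fixed canonical order (substitution-major, then 5′ A/C/G/T,
then 3′ A/C/G/T) pinned in one table shared by the spectrum builder, the
signature reader and all outputs. A pair's spectrum $x$ with $n = \sum_k
x_k$ is scored against a signature profile $p$ by the multinomial
log-likelihood

$$\log L(x \mid p) = \log n! - \sum_k \log x_k! + \sum_k x_k \log p_k,$$

computed through log-gamma. Zeros in every profile are first replaced by
half the profile's minimum positive entry; the complemented profile is
renormalized to sum to one, since an unnormalized vector would make
$\log L$ not a log-probability. The artefact correction subtracts the
log-likelihood under a background profile pooled from the low-concordance
pairs' spectra and divides by $n$:

$$\mathrm{score}_s = \frac{\log L(x \mid p_s) - \log L(x \mid
p_{\mathrm{artefact}})}{n}.$$

Dividing the whole difference (rather than only the artefact term) keeps
scores comparable across pairs with different mutation counts, which is
the stated purpose of the normalization; it also makes the combinatorial
terms cancel exactly, so the score equals $\sum_k f_k \log(p_{sk} /
p_{ak})$ with $f = x/n$ — a per-mutation log-likelihood ratio. The best
signature is the argmax, ties broken deterministically toward the lowest
signature index. The artefact profile itself is not a candidate: the
score is defined relative to it, and it would win trivially for any
artefact-like spectrum.

### The synthetic reference signature set

The packaged 96 × 30 signature matrix is a synthetic stand-in generated by
`data-raw/make_signatures.R` from qualitative descriptions of the COSMIC
v2 signatures — dominant substitution classes plus hallmark flank
preferences (NpCpG C>T deamination for Signature 1, TpC APOBEC context
for Signatures 2/13, the flat clock-like T>C/C>T shape for Signature 5,
and so on) with seeded cell-level texture. It reproduces the qualitative
structure the attribution method needs (distinct, renormalized profiles;
a Signature 5 dominated by C>T and T>C) but carries no COSMIC numerical
content, so absolute scores are not comparable to runs against the real
COSMIC download; any COSMIC-format TSV can be supplied through
`read_signature_matrix()` instead.

## The cohort simulator

`simulate_cohort()` emulates the study conditions: 30 twin pairs (packaged
participant ages and sexes; 50% female, mean age ≈ 50), mean depth 24×
(site-level Poisson, minimum one read), 20,000 cohort-shared germline
variant sites per pair (class probabilities 0.2/0.5/0.3 for
RefRef/RefAlt/AltAlt, chosen so the non-reference denominator of the
concordance rate is ~16,000 and a ~90-PZM pair lands near 99.4%
concordance), 90 injected PZMs per pair with motifs i.i.d. from a chosen
signature profile (default: the clock-like Signature 5) and VAFs from a
0.7/0.3 mixture of Beta components centred at 0.5 and 0.25 (concentration
60), and Poisson low-VAF artefact noise (true VAF < 0.25, most mass below
0.10, motifs from a configurable artefact profile defaulting to a
C>A/T>C-weighted background). The 30-pair default gives the last 7 pairs
a heavy artefact load (3,000 expected noise sites vs 40), which pushes
them below the 99% cutoff and reproduces the 23-high/7-low structure that
the artefact pooling needs. GQ is modelled as 4×depth plus Gaussian noise
(sd 8), capped at 99, so depth-starved genotypes fail the GQ rule the way
real calls do.

Emitted genotype classes are truth-consistent: read depths and alt counts
are redrawn (bounded rejection) until the naive allele-depth caller
(`call_genotype()`: alt fraction ≥ 0.9 hom, ≥ 0.1 het) reproduces the
intended class. This guarantees two invariants the tests rely on — with
zero noise the discordant set equals the truth set exactly for any seed,
and with zero injected differences the twins are identical everywhere —
at the cost of slightly truncating the read-sampling distribution near
call boundaries. Trinucleotide contexts travel in the VCF INFO field
(`CTX`), so no reference FASTA is required; germline contexts come from a
configurable 32-context table (default uniform), not the hg38 composition.
What the simulator does *not* model: read-level errors, alignment
artefacts, linkage between sites, indels, sex chromosomes, GC-dependent
depth, or any calibrated artefact mechanism — the noise model is a
stand-in, so passing tests demonstrate the correctness of the analysis
machinery, not the error profile of any particular sequencing platform.

## Association models

Per-pair counts are modelled by OLS (`count ~ age + sex`), per-mutation
VAFs by `vaf ~ concordance + age + sex`; rank-deficient designs raise an
explicit error rather than silently aliasing. P-values are two-sided from
the t distribution and reported unadjusted. The exonic vs non-exonic
burden uses the two-sided Wilcoxon rank-sum test, exact for small
tie-free samples. The published regression coefficients for this design
depend on the unreleased cohort data; the package instead verifies the
machinery by calibration — under a null simulation the concordance term
rejects at the nominal 5% rate, and an injected positive VAF–concordance
effect is recovered with a positive sign essentially always.

## Numerical and testing choices

Problem sizes were chosen to keep the default test run light: truth
recovery uses 10 pairs × 2,000 germline sites × 100 PZMs; signature
recovery uses 200 spectra of 500 mutations (the initial oracle run
recovered the generator in 200/200 replicates across seeds, and the
frozen test threshold of 95% sits safely below that); the regression null
uses 1,000 replicates of 600 mutations. Multinomial sampling checks
tolerate the handful of >3-standard-error cells a 96-cell multinomial
legitimately produces and bound gross deviations at 5. The log-likelihood
is validated against a direct factorial oracle for n ≤ 20. A single
integer seed drives each simulation; sub-analyses derive small offsets
from it.

## Known limitations

Exonic labelling is interval overlap against a supplied exon BED — no
transcript-level consequence annotation. The germline-database exclusion
is exact-allele matching; position-only matching was rejected as
needlessly lossy. Concordance is undefined (an error) for a pair with no
observable non-reference sites. The packaged signature matrix is
synthetic (above); conclusions about real cohorts require the real
reference set and real region masks.
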