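# twinpzm

Monozygotic (MZ) twins are genetically identical at conception, so any
genotype difference between adult co-twins is either a postzygotic somatic
mutation (PZM) or a sequencing artefact. `twinpzm` implements the full
desk-scale analysis of PZMs from paired whole-genome genotype calls: it is
aimed at statistical geneticists who want to detect early somatic mutations
as twin genotype discordances, quantify their burden and allele-frequency
structure, and attribute their trinucleotide spectrum to known mutational
processes.

## What it computes

**Concordance.** For each twin pair, QC-passed biallelic autosomal SNVs are
tallied into a 3×3 genotype contingency matrix over {Ref/Ref, Ref/Alt,
Alt/Alt}. Both-reference sites are uncountable in a variant-only VCF, so the
concordance rate is defined over the five observable unordered classes:

    rate = (n_RA~RA + n_AA~AA) /
           (n_RR~RA + n_RR~AA + n_RA~RA + n_RA~AA + n_AA~AA)

Pairs with rate ≥ 0.99 are the high-concordance set; the rest contribute a
pooled sequencing-artefact motif profile.

**QC cascade.** Genotypes are masked when DP < 5, GQ < 20, or DP > 60 with
GQ < 95; non-reference genotypes with VAF < 10% (from the AD fields) or
fewer than 2 alt reads are masked; variants with call rate < 0.90 across the
cohort, variants in region masks (low-complexity, cytoband-excluded,
low-accessibility BED files), non-SNVs and non-autosomal sites are removed.

**PZM discovery.** Discordant genotype pairs (by default Ref/Ref–Ref/Alt,
Ref/Ref–Alt/Alt and Ref/Alt–Alt/Alt) become candidate PZMs after exclusion
of known germline sites keyed on (chrom, pos, ref, alt). Burdens are
summarized per pair, compared between exonic and non-exonic regions by
Wilcoxon rank-sum, and modelled by ordinary least squares (count ~ age +
sex; per-mutation VAF ~ concordance + age + sex).

**Signature attribution.** Each pair's PZMs are collapsed onto the
pyrimidine strand into the canonical 96 trinucleotide motifs. A spectrum
`x` (n mutations) is scored against each reference signature profile `p_s`
by the artefact-corrected per-mutation multinomial log-likelihood

    logL(x | p) = log n! − Σ_k log x_k! + Σ_k x_k log p_k
    score_s     = ( logL(x | p_s) − logL(x | p_artefact) ) / n

after replacing zeros in every profile by half its minimum positive entry
(renormalized). The best signature is the argmax. The packaged 30-signature
reference matrix is a **synthetic stand-in** generated from qualitative
descriptions of the COSMIC v2 signatures (see
`data-raw/make_signatures.R`); it carries no COSMIC numerical content.

A seeded cohort simulator (`simulate_cohort()`) generates paired twin VCFs
with shared germline variants, PZMs drawn from a chosen signature with VAFs
clustered near 0.5/0.25, low-VAF artefact noise, and a truth table, so every
stage is testable without protected data.

## Worked example

```r
library(twinpzm)

cfg <- pipeline_config(sim = simulation_config(seed = 11))
rep <- run_pipeline(cfg)

rep$summaries$n_high
#> [1] 23
round(100 * rep$summaries$concordance$mean, 1)
#> [1] 98.6
round(unlist(rep$summaries$pzm_high[c("mean", "sd")]), 1)
#>  mean    sd
#>  99.8   3.1
table(rep$best_signature)
#> Signature 5
#>          23
rep$regression$vaf[2, c("term", "beta", "p")]
#>          term     beta p
#> 2 concordance 6.035592 0
```

The default simulation emulates a 30-pair cohort at ~24× depth: 23 pairs
exceed the 99% concordance cutoff; the 7 noisy pairs supply the artefact
profile. All 23 high-concordance spectra are attributed to the clock-like
Signature 5 they were generated from, and the per-mutation VAF model
recovers the strong positive association between VAF and pair concordance
that the injected low-VAF artefacts induce.

The numbered scripts under `analysis/` run the same workflow stage by stage
(simulate → QC/concordance → PZM discovery → signature attribution →
participant-table summaries), writing tables under `results/`.

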