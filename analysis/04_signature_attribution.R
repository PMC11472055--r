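#!/usr/bin/env Rscript
# Stage 4: build per-pair 96-motif spectra, pool the artefact profile from
# the low-concordance pairs, and attribute each high-concordance pair's
# spectrum to a reference signature by artefact-corrected per-mutation
# log-likelihood.

library(twinpzm)

recs <- read.delim("results/pzm_records.tsv")
conc <- read.delim("results/concordance.tsv")

ids <- conc$pair_id
spectra <- vapply(ids, function(id)
  build_spectrum(recs$motif[recs$pair_id == id]), integer(96))
rownames(spectra) <- motif_levels()

low <- ids[!conc$high_concordance]
artefact <- build_artefact_profile(spectra[, low, drop = FALSE])
sigs <- complement_zeros(twinpzm_signatures())
art_c <- complement_zeros(artefact)

high <- ids[conc$high_concordance]
sims <- lapply(high, function(id)
  corrected_similarity(spectra[, id], sigs, art_c))
similarity <- do.call(rbind, lapply(sims, `[[`, "scores"))
rownames(similarity) <- high
best <- vapply(sims, `[[`, character(1), "best")

write.table(cbind(pair_id = high, as.data.frame(similarity),
                  best_signature = best),
            "results/similarity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(pair_id = ids,
                  as.data.frame(t(apply(spectra, 2, substitution_marginals)))),
            "results/substitution_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("artefact profile pooled over", length(low), "low-concordance pairs;",
    "dominant classes:",
    paste(names(sort(substitution_marginals(artefact),
                     decreasing = TRUE))[1:2], collapse = ", "), "\n")
cat("best-signature assignments:\n")
print(table(best))
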