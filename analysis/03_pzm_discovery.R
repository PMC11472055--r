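#!/usr/bin/env Rscript
# Stage 3: extract discordant-genotype sites as candidate PZMs, label a
# synthetic exon model, and fit the association models: per-pair count on
# age + sex, per-mutation VAF on concordance + age + sex, and the exonic
# vs non-exonic burden comparison.

library(twinpzm)

qc_pairs <- readRDS("results/qc_pairs.rds")
conc <- read.delim("results/concordance.tsv")
meta <- read.delim("results/cohort/metadata.tsv")

recs <- do.call(rbind, lapply(names(qc_pairs), function(id)
  extract_discordant(qc_pairs[[id]], id)))

# synthetic exon model: ~1.5% of each autosome in 150 bp islands, the
# genome-wide coding fraction at desk scale
set.seed(1)
starts <- replicate(22, sort(sample.int(2.4e8, 2000)), simplify = FALSE)
exons <- GenomicRanges::GRanges(
  rep(paste0("chr", 1:22), each = 2000),
  IRanges::IRanges(unlist(starts), width = 150))
recs <- classify_functional_region(recs, exons)

ids <- conc$pair_id
counts <- data.frame(
  pair_id = ids,
  n_pzm = as.integer(table(factor(recs$pair_id, levels = ids))),
  n_exonic = as.integer(table(factor(
    recs$pair_id[recs$region_label == "exonic"], levels = ids))))
counts$n_nonexonic <- counts$n_pzm - counts$n_exonic

m <- match(ids, meta$pair_id)
fit_counts <- regress_counts_on_covariates(counts$n_pzm, meta$age[m],
                                           meta$sex[m])
r <- match(recs$pair_id, ids)
fit_vaf <- regress_vaf(recs$vaf, conc$rate[r], meta$age[m][r],
                       meta$sex[m][r])
burden <- compare_exonic_burden(counts$n_exonic, counts$n_nonexonic)

write.table(recs, "results/pzm_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(counts, "results/pzm_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rbind(cbind(model = "count", fit_counts),
                  cbind(model = "vaf", fit_vaf)),
            "results/regressions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

high <- conc$high_concordance
s_all <- summarize_pzm_counts(counts$n_pzm)
s_high <- summarize_pzm_counts(counts$n_pzm, high)
cat(sprintf("PZMs/pair: all %.1f; high subset %.1f +/- %.1f (range %d-%d)\n",
            s_all$mean, s_high$mean, s_high$sd, s_high$min, s_high$max))
cat(sprintf("VAF ~ concordance: beta %.2f p %.2e\n",
            fit_vaf$beta[2], fit_vaf$p[2]))
cat(sprintf("count ~ age: beta %.2f p %.3f\n",
            fit_counts$beta[2], fit_counts$p[2]))
cat(sprintf("exonic vs non-exonic burden: p %.2e\n", burden$p.value))
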