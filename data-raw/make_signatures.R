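# Builds inst/extdata/signatures_v2_synthetic.tsv: a SYNTHETIC 30-signature
# reference matrix in the COSMIC v2 file layout (96 motif rows x 30
# signature columns). The numbers are generated here, seeded, from
# qualitative descriptions of the signatures (dominant substitution classes
# and hallmark flank preferences); no COSMIC numerical content is used.
# Run from the package root: Rscript data-raw/make_signatures.R

set.seed(20240922)

bases <- c("A", "C", "G", "T")
subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
grid <- expand.grid(f3 = bases, f5 = bases, sub = subs, stringsAsFactors = FALSE)
grid <- grid[, c("sub", "f5", "f3")]
labels <- paste0(grid$f5, "[", grid$sub, "]", grid$f3)
trinuc <- paste0(grid$f5, substr(grid$sub, 1, 1), grid$f3)

# substitution-class weights per signature (rows sum to 1)
w <- rbind(
  c(.04, .04, .78, .04, .06, .04),  # 1: CpG deamination C>T
  c(.05, .12, .68, .05, .05, .05),  # 2: APOBEC-like TpC C>T/C>G
  c(.18, .14, .20, .14, .20, .14),  # 3: flat (HR-deficiency-like)
  c(.55, .08, .15, .07, .10, .05),  # 4: bulky-adduct C>A
  c(.08, .06, .30, .08, .40, .08),  # 5: flat clock-like, T>C + C>T
  c(.07, .05, .65, .05, .13, .05),  # 6: MMR-deficiency-like C>T
  c(.05, .05, .75, .04, .06, .05),  # 7: UV-like dipyrimidine C>T
  c(.45, .15, .15, .08, .10, .07),  # 8
  c(.10, .05, .10, .15, .50, .10),  # 9: T>C
  c(.45, .05, .40, .03, .04, .03),  # 10: POLE-like TpC hotspots
  c(.06, .05, .70, .05, .09, .05),  # 11: alkylating non-CpG C>T
  c(.07, .05, .15, .08, .55, .10),  # 12: T>C
  c(.06, .60, .20, .05, .05, .04),  # 13: APOBEC-like TpC C>G
  c(.35, .10, .35, .06, .09, .05),  # 14
  c(.15, .08, .55, .06, .10, .06),  # 15
  c(.07, .05, .12, .08, .60, .08),  # 16: ApT T>C
  c(.05, .04, .06, .10, .15, .60),  # 17: CpTpT T>G
  c(.55, .12, .12, .07, .08, .06),  # 18: C>A
  c(.10, .10, .55, .08, .10, .07),  # 19
  c(.12, .08, .45, .07, .20, .08),  # 20
  c(.05, .04, .08, .08, .70, .05),  # 21: T>C
  c(.08, .05, .08, .60, .12, .07),  # 22: aristolochic-like T>A
  c(.08, .06, .62, .07, .10, .07),  # 23
  c(.55, .10, .20, .05, .06, .04),  # 24: aflatoxin-like C>A
  c(.10, .08, .15, .40, .20, .07),  # 25
  c(.09, .05, .36, .09, .33, .08),  # 26
  c(.08, .06, .10, .50, .18, .08),  # 27: T>A
  c(.06, .05, .08, .10, .16, .55),  # 28: T>G
  c(.50, .15, .15, .06, .08, .06),  # 29: tobacco-chewing-like C>A
  c(.10, .07, .55, .07, .14, .07))  # 30

# hallmark context multipliers: list of (signature, predicate on grid, factor)
boost <- function(p, sig, rows, f) { p[rows, sig] <- p[rows, sig] * f; p }

p <- matrix(0, 96, 30)
for (s in 1:30) {
  cls <- match(grid$sub, subs)
  base <- w[s, cls] / 16          # spread class weight over 16 flank cells
  noise <- rgamma(96, shape = 12, rate = 12)   # generic cell-level texture
  p[, s] <- base * noise
}
p <- boost(p, 1, grid$sub == "C>T" & grid$f3 == "G", 8)
p <- boost(p, 2, grid$sub %in% c("C>T", "C>G") & grid$f5 == "T", 10)
p <- boost(p, 5, grid$sub == "T>C" & grid$f5 == "A", 2)
p <- boost(p, 6, grid$sub == "C>T" & grid$f5 == "G", 6)
p <- boost(p, 7, grid$sub == "C>T" & grid$f5 %in% c("C", "T"), 6)
p <- boost(p, 10, grid$sub %in% c("C>A", "C>T") & grid$f5 == "T", 8)
p <- boost(p, 11, grid$sub == "C>T" & grid$f3 != "G", 4)
p <- boost(p, 13, grid$sub == "C>G" & grid$f5 == "T", 10)
p <- boost(p, 15, grid$sub == "C>T" & grid$f3 == "T", 4)
p <- boost(p, 16, grid$sub == "T>C" & grid$f5 == "A", 5)
p <- boost(p, 17, grid$sub == "T>G" & grid$f5 == "C" & grid$f3 == "T", 6)
p <- boost(p, 18, grid$sub == "C>A" & grid$f3 == "A", 3)
p <- boost(p, 22, grid$sub == "T>A" & grid$f5 == "C", 4)
p <- boost(p, 24, grid$sub == "C>A" & grid$f3 == "C", 3)
p <- boost(p, 29, grid$sub == "C>A" & grid$f5 == "C", 3)

p <- sweep(p, 2, colSums(p), "/")
p <- round(p, 6)

out <- data.frame(`Substitution Type` = grid$sub,
                  Trinucleotide = trinuc,
                  `Somatic Mutation Type` = labels,
                  check.names = FALSE)
sig <- as.data.frame(p)
names(sig) <- paste("Signature", 1:30)
out <- cbind(out, sig)
# shuffle rows: the reader must not depend on file order
out <- out[sample(nrow(out)), ]
write.table(out, "inst/extdata/signatures_v2_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(out), "rows x", ncol(out), "cols\n")
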