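# shared helpers: small cohort configurations and hand-built pair tables

small_sim <- function(n_pairs = 3L, n_germline_sites = 300L, n_pzm = 20L,
                      noise_rate = 10, seed = 42L, ...) {
  simulation_config(n_pairs = n_pairs, n_germline_sites = n_germline_sites,
                    n_pzm = n_pzm, noise_rate = noise_rate,
                    ages = seq(25L, length.out = n_pairs, by = 7L),
                    sexes = rep_len(c("F", "M"), n_pairs),
                    seed = seed, ...)
}

# hand-built pair table; gt defaults cover all classes, reads consistent
make_pair <- function(gt1, gt2, chrom = "chr1",
                      pos = seq_along(gt1) * 100L,
                      dp1 = 24L, gq1 = 90L, dp2 = 24L, gq2 = 90L,
                      vaf1 = NULL, vaf2 = NULL,
                      ref = "C", alt = "T", context = "ACA") {
  n <- length(gt1)
  stopifnot(length(gt2) == n)
  ad_of <- function(gt, dp, vaf) {
    alt <- switch(gt, RefRef = 0L, RefAlt = as.integer(round(dp / 2)),
                  AltAlt = dp, Missing = 0L)
    alt
  }
  dp1 <- rep_len(dp1, n); dp2 <- rep_len(dp2, n)
  ad_alt1 <- as.integer(mapply(ad_of, gt1, dp1, 0))
  ad_alt2 <- as.integer(mapply(ad_of, gt2, dp2, 0))
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             context = rep_len(context, n),
             gt1 = gt1, dp1 = dp1, gq1 = rep_len(gq1, n),
             ad_ref1 = dp1 - ad_alt1, ad_alt1 = ad_alt1,
             gt2 = gt2, dp2 = dp2, gq2 = rep_len(gq2, n),
             ad_ref2 = dp2 - ad_alt2, ad_alt2 = ad_alt2,
             stringsAsFactors = FALSE)
}

# brute-force multinomial pmf via factorials (oracle, n <= 20 only)
brute_multinom_pmf <- function(x, p) {
  stopifnot(sum(x) <= 20)
  factorial(sum(x)) / prod(factorial(x)) * prod(p^x)
}

# brute-force per-site interval scan (oracle for region masking)
brute_in_mask <- function(chrom, pos, m_chrom, m_start1, m_end1) {
  vapply(seq_along(chrom), function(i)
    any(m_chrom == chrom[i] & pos[i] >= m_start1 & pos[i] <= m_end1),
    logical(1))
}
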