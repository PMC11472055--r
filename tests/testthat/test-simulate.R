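test_that("simulation is deterministic given the seed", {
  c1 <- simulate_cohort(small_sim(seed = 99))
  c2 <- simulate_cohort(small_sim(seed = 99))
  expect_identical(c1$pairs, c2$pairs)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(small_sim(seed = 100))
  expect_false(identical(c1$pairs, c3$pairs))
})

test_that("without injected PZMs and noise the twins are identical everywhere", {
  co <- simulate_cohort(small_sim(n_pzm = 0L, noise_rate = 0, seed = 5))
  expect_equal(nrow(co$truth), 0L)
  for (p in co$pairs) expect_identical(p$gt1, p$gt2)
})

test_that("injected PZM counts are exact and discordant in the pair tables", {
  co <- simulate_cohort(small_sim(n_pzm = 50L, noise_rate = 0, seed = 8))
  for (id in names(co$pairs)) {
    tr <- co$truth[co$truth$pair_id == id, ]
    expect_equal(nrow(tr), 50L)
    p <- co$pairs[[id]]
    m <- match(paste(tr$chrom, tr$pos), paste(p$chrom, p$pos))
    expect_false(anyNA(m))
    carrier_gt <- ifelse(tr$carrier == 1L, p$gt1[m], p$gt2[m])
    other_gt <- ifelse(tr$carrier == 1L, p$gt2[m], p$gt1[m])
    expect_true(all(carrier_gt == "RefAlt"))
    expect_true(all(other_gt == "RefRef"))
  }
})

test_that("PZM motifs follow the configured signature profile", {
  cfg <- small_sim(n_pairs = 1L, n_germline_sites = 50L, n_pzm = 10000L,
                   noise_rate = 0, seed = 13)
  co <- simulate_cohort(cfg)
  p <- cfg$signatures[, cfg$pzm_signature]
  freq <- tabulate(co$truth$motif, 96) / nrow(co$truth)
  se <- sqrt(p * (1 - p) / nrow(co$truth))
  z <- abs(freq - p) / se
  expect_lte(sum(z > 3), 3)   # see the sampling note in test-signatures.R
  expect_true(all(z < 5))
  # the recorded context/ref/alt collapse back to the truth motif even for
  # sites stored on the purine strand
  expect_identical(motif_of(co$truth$context, co$truth$ref, co$truth$alt),
                   co$truth$motif)
})

test_that("true PZM VAFs mode near 0.5 when that component dominates", {
  co <- simulate_cohort(small_sim(n_pairs = 2L, n_pzm = 2000L,
                                  noise_rate = 0, seed = 21))
  v <- co$truth$true_vaf[co$truth$class == "pzm"]
  h <- hist(v, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  mode_bin <- h$mids[which.max(h$counts)]
  expect_gte(mode_bin, 0.4)
  expect_lte(mode_bin, 0.6)
})

test_that("noise sites carry VAF below 0.25 with most mass below 0.10", {
  co <- simulate_cohort(small_sim(n_pairs = 2L, n_pzm = 0L,
                                  noise_rate = 2000, seed = 31))
  v <- co$truth$true_vaf[co$truth$class == "noise"]
  expect_true(all(v < 0.25))
  expect_gt(mean(v < 0.10), 0.5)
})

test_that("VCF serialization round-trips all fields", {
  co <- simulate_cohort(small_sim(seed = 77))
  for (id in names(co$pairs)) {
    path <- tempfile(fileext = ".vcf")
    write_vcf_pair(co$pairs[[id]], path)
    back <- read_vcf_pair(path)
    expect_equal(back, co$pairs[[id]], ignore_attr = TRUE)
  }
})

test_that("header-only and single-record VCFs parse correctly", {
  empty <- make_pair(character(0), character(0))
  path <- tempfile(fileext = ".vcf")
  write_vcf_pair(empty, path)
  expect_equal(nrow(read_vcf_pair(path)), 0L)

  one <- make_pair("RefAlt", "RefRef")
  one$ad_ref1 <- 12L; one$ad_alt1 <- 11L; one$dp1 <- 23L
  write_vcf_pair(one, path)
  back <- read_vcf_pair(path)
  expect_equal(back$ad_alt1 / (back$ad_ref1 + back$ad_alt1), 11 / 23)
})

test_that("a cohort written to disk reads back identically", {
  co <- simulate_cohort(small_sim(seed = 55))
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(names(back$pairs), names(co$pairs))
  for (id in names(co$pairs))
    expect_equal(back$pairs[[id]], co$pairs[[id]], ignore_attr = TRUE)
  expect_equal(back$meta$age, co$meta$age)
})

test_that("configuration validation rejects inconsistent inputs", {
  expect_error(simulation_config(pzm_vaf_weights = c(0.6, 0.6)), "sum to 1")
  expect_error(simulation_config(pzm_signature = "Signature 99"), "unknown signature")
  expect_error(simulation_config(n_pairs = 3, ages = c(30, 40)), "length n_pairs")
})
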