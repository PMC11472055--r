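test_that("depth/quality genotype filter fires on each printed rule", {
  t <- qc_thresholds()
  expect_false(filter_genotype(4, 99, t))    # DP < 5
  expect_false(filter_genotype(30, 19, t))   # GQ < 20
  expect_false(filter_genotype(61, 94, t))   # DP > 60 and GQ < 95
  expect_true(filter_genotype(30, 50, t))
  # strict boundaries: values at the printed thresholds are retained
  expect_true(filter_genotype(5, 20, t))
  expect_true(filter_genotype(60, 94, t))
  expect_true(filter_genotype(61, 95, t))
  expect_false(filter_genotype(NA, 50, t))
})

test_that("call-rate filter excludes strictly below 0.90", {
  t <- qc_thresholds()
  expect_true(filter_call_rate(54, 60, t))   # exactly 0.90
  expect_false(filter_call_rate(53, 60, t))
  expect_true(filter_call_rate(rep(TRUE, 60), thresholds = t))
  expect_error(filter_call_rate(logical(0), thresholds = t), "zero samples")
})

test_that("VAF/alt-count filter keeps the printed boundaries", {
  t <- qc_thresholds()
  expect_true(filter_vaf(18, 2, t))    # VAF 0.10, alt 2: both boundaries keep
  expect_false(filter_vaf(19, 1, t))   # VAF 0.05
  expect_true(filter_vaf(5, 5, t))
  expect_false(filter_vaf(0, 0, t))    # zero depth
  expect_false(filter_vaf(20, 1, t))   # alt count below 2
})

test_that("region masking matches a brute-force interval scan", {
  sites <- make_pair(rep("RefAlt", 4), rep("RefAlt", 4),
                     pos = c(100L, 150L, 151L, 500L))
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))  # BED [50,150)
  out <- apply_region_mask(sites, mask)
  expect_equal(out$pos, c(151L, 500L))
  expect_equal(apply_region_mask(sites, NULL), sites)  # empty mask: identity

  set.seed(17)
  n <- 300
  sites <- make_pair(rep("RefAlt", n), rep("RefAlt", n),
                     chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
                     pos = sample.int(10000L, n))
  m_chrom <- sample(paste0("chr", 1:5), 20, replace = TRUE)
  m_start0 <- sample.int(9000L, 20)          # BED 0-based half-open
  m_end0 <- m_start0 + sample.int(500L, 20)
  mask <- GenomicRanges::GRanges(m_chrom, IRanges::IRanges(m_start0 + 1, m_end0))
  out <- apply_region_mask(sites, mask)
  oracle <- brute_in_mask(sites$chrom, sites$pos, m_chrom, m_start0 + 1, m_end0)
  expect_equal(out, sites[!oracle, ], ignore_attr = TRUE)
})

test_that("BED masks are converted to 1-based closed at the reader", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t50\t150", bed)
  gr <- read_bed_mask(bed, label = "low-complexity")
  expect_equal(GenomicRanges::start(gr), 51)
  expect_equal(GenomicRanges::end(gr), 150)
  expect_equal(S4Vectors::mcols(gr)$mask_class, "low-complexity")
  sites <- make_pair("RefAlt", "RefAlt", pos = 100L)
  expect_equal(nrow(apply_region_mask(sites, gr)), 0L)
})

test_that("SNV/autosome restriction drops sex chromosomes and multiallelics", {
  sites <- make_pair(rep("RefAlt", 4), rep("RefAlt", 4))
  sites$chrom <- c("chrX", "chr7", "chr7", "chr22")
  sites$alt <- c("T", "T,G", "T", "T")
  out <- restrict_snv_autosomes(sites)
  expect_equal(out$chrom, c("chr7", "chr22"))
  expect_false(any(grepl(",", out$alt)))
})

test_that("the QC cascade is idempotent and commutes across site-level filters", {
  co <- simulate_cohort(small_sim(seed = 61))
  t <- qc_thresholds()
  once <- apply_qc(co$pairs, t)
  twice <- apply_qc(once$pairs, t)
  expect_identical(twice$pairs, once$pairs)

  # region mask and SNV restriction commute
  p <- co$pairs[[1]]
  mask <- GenomicRanges::GRanges(p$chrom[3], IRanges::IRanges(1, p$pos[3]))
  a <- apply_region_mask(restrict_snv_autosomes(p), mask)
  b <- restrict_snv_autosomes(apply_region_mask(p, mask))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("tightening any single threshold never increases retention", {
  co <- simulate_cohort(small_sim(seed = 71, depth_mean = 10))
  n_kept <- function(t) {
    out <- apply_qc(co$pairs, t)
    sum(vapply(out$pairs, function(p)
      sum(p$gt1 != "Missing" & p$gt2 != "Missing"), numeric(1)))
  }
  base <- n_kept(qc_thresholds())
  tighter <- list(qc_thresholds(min_dp = 8),
                  qc_thresholds(min_gq = 40),
                  qc_thresholds(high_dp = 20),
                  qc_thresholds(high_dp_min_gq = 99),
                  qc_thresholds(min_call_rate = 0.99),
                  qc_thresholds(min_vaf = 0.3),
                  qc_thresholds(min_alt_count = 5))
  for (t in tighter) expect_lte(n_kept(t), base)
  expect_gte(n_kept(qc_disabled()), base)
})
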