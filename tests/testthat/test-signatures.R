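test_that("complement_zeros replaces zeros by half the minimum and renormalizes", {
  expect_equal(complement_zeros(c(0.5, 0.5, 0)), c(0.4, 0.4, 0.2))
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(complement_zeros(p), p)   # no zeros: identity
  set.seed(1)
  for (i in 1:20) {
    q <- stats::runif(96); q[sample.int(96, 10)] <- 0; q <- q / sum(q)
    out <- complement_zeros(q)
    expect_true(all(out > 0))
    expect_equal(sum(out), 1)
  }
  expect_error(complement_zeros(rep(0, 4)), "no positive")
})

test_that("multinomial log-likelihood matches closed forms", {
  expect_equal(multinomial_loglik(c(1, 1), c(0.5, 0.5)), -log(2))
  expect_equal(multinomial_loglik(c(2, 0), c(0.5, 0.5)), 2 * log(0.5) + log(2) - log(2))
  expect_error(multinomial_loglik(c(1, 1), c(1, 0)), "zero probability")
})

test_that("multinomial log-likelihood matches the factorial pmf oracle", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    n <- sample(1:20, 1)
    p <- stats::runif(k); p <- p / sum(p)
    x <- as.vector(stats::rmultinom(1, n, p))
    expect_equal(exp(multinomial_loglik(x, p)), brute_multinom_pmf(x, p),
                 tolerance = 1e-10)
  }
})

test_that("the empirical frequency profile maximizes the log-likelihood", {
  set.seed(11)
  for (i in 1:10) {
    p0 <- stats::runif(96); p0 <- p0 / sum(p0)
    x <- as.vector(stats::rmultinom(1, 50, p0))
    ll_hat <- multinomial_loglik(x, x / sum(x))
    for (j in 1:20) {
      q <- stats::rgamma(96, 1); q <- q / sum(q)
      expect_lte(multinomial_loglik(x, q), ll_hat)
    }
  }
})

test_that("build_spectrum tallies motifs and tracks totals", {
  expect_equal(sum(build_spectrum(integer(0))), 0)
  x <- build_spectrum(rep(motif_of("ACG", "C", "T"), 10))
  expect_equal(unname(x["A[C>T]G"]), 10)
  expect_equal(sum(x), 10)
  expect_error(build_spectrum(200), "1..96")
})

test_that("spectra sampled from a signature match it within 3 standard errors", {
  sigs <- twinpzm_signatures()
  p <- sigs[, "Signature 5"]
  set.seed(19)
  n <- 10000
  x <- sample_spectrum(n, p)
  se <- sqrt(p * (1 - p) / n)
  z <- abs(x / n - p) / se
  # a multinomial realization legitimately exceeds 3 SE at a few of the 96
  # cells (expected ~0.3); gross deviations would indicate a wrong sampler
  expect_lte(sum(z > 3), 3)
  expect_true(all(z < 5))
})

test_that("artefact profile pools counts and normalizes", {
  x1 <- build_spectrum(c(1, 1, 2))
  prof <- build_artefact_profile(list(x1))
  expect_equal(unname(prof[1]), 2 / 3)
  expect_equal(build_artefact_profile(list(x1, x1)), prof)  # pooling invariance
  set.seed(3)
  xs <- lapply(1:4, function(i) build_spectrum(sample.int(96, 50, replace = TRUE)))
  pooled <- Reduce(`+`, xs)
  expect_equal(build_artefact_profile(xs), pooled / sum(pooled))
  expect_error(build_artefact_profile(list()), "skip")
})

test_that("corrected similarity is zero against its own artefact and per-mutation", {
  sigs <- complement_zeros(twinpzm_signatures())
  set.seed(5)
  x <- sample_spectrum(200, twinpzm_signatures()[, "Signature 5"])
  res <- corrected_similarity(x, sigs, artefact = sigs[, "Signature 3"])
  expect_equal(unname(res$scores["Signature 3"]), 0)
  # combinatorial terms cancel in the correction: doubling every count
  # leaves the per-mutation score unchanged
  res2 <- corrected_similarity(2 * x, sigs, artefact = sigs[, "Signature 3"])
  expect_equal(res2$scores, res$scores)
  f <- x / sum(x)
  direct <- colSums(f * log(sweep(sigs, 1, sigs[, "Signature 3"], "/")))
  expect_equal(res$scores, direct)
})

test_that("argmax ties break toward the lowest signature index", {
  p <- complement_zeros(uniform_profile())
  sigs <- cbind(`Signature A` = p, `Signature B` = p)
  res <- corrected_similarity(build_spectrum(c(1, 5, 9)), sigs)
  expect_identical(res$best, "Signature A")
  expect_true(res$tie)
})

test_that("the signature reader is order-independent and validates rows", {
  sigs <- twinpzm_signatures()
  expect_identical(dim(sigs), c(96L, 30L))
  expect_equal(unname(colSums(sigs)), rep(1, 30))
  expect_identical(rownames(sigs), motif_levels())

  path <- system.file("extdata", "signatures_v2_synthetic.tsv",
                      package = "twinpzm")
  tab <- read.delim(path, check.names = FALSE)
  shuffled <- tempfile(fileext = ".tsv")
  set.seed(2)
  write.table(tab[sample(nrow(tab)), ], shuffled, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_equal(read_signature_matrix(shuffled), sigs)

  broken <- tempfile(fileext = ".tsv")
  write.table(tab[-5, ], broken, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(broken), "missing motif",
               ignore.case = TRUE)
  dup <- tempfile(fileext = ".tsv")
  write.table(tab[c(1, seq_len(nrow(tab) - 1)), ], dup, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(dup), "duplicate")
})
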