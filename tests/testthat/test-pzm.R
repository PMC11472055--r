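test_that("discordant extraction identifies carrier and class", {
  p <- make_pair(c("RefRef", "RefAlt", "RefAlt", "AltAlt"),
                 c("RefAlt", "RefAlt", "AltAlt", "RefRef"))
  recs <- extract_discordant(p, "pairA")
  expect_equal(nrow(recs), 3L)                 # (RefAlt,RefAlt) is concordant
  expect_equal(recs$gt_pair, c("rr_ra", "ra_aa", "rr_aa"))
  expect_equal(recs$carrier, c(2L, 2L, 1L))
  # restricting the class set restricts the records
  recs2 <- extract_discordant(p, "pairA", classes = c("rr_ra", "rr_aa"))
  expect_equal(recs2$gt_pair, c("rr_ra", "rr_aa"))
})

test_that("noise-free discovery recovers the truth set exactly", {
  co <- simulate_cohort(small_sim(n_pzm = 30L, noise_rate = 0, seed = 41))
  for (id in names(co$pairs)) {
    recs <- extract_discordant(co$pairs[[id]], id)
    tr <- co$truth[co$truth$pair_id == id, ]
    key <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt))
    expect_identical(key(recs), key(tr))
    expect_identical(sort(recs$motif), sort(tr$motif))
  }
})

test_that("germline-database exclusion is keyed on the full allele", {
  recs <- extract_discordant(
    make_pair(c("RefRef", "RefRef"), c("RefAlt", "RefAlt"),
              pos = c(100L, 200L)), "p")
  expect_equal(filter_known_germline(recs, NULL), recs, ignore_attr = TRUE)
  db <- data.frame(chrom = "chr1", pos = 100L, ref = "C", alt = "T")
  out <- filter_known_germline(recs, db)
  expect_equal(out$pos, 200L)
  expect_equal(attr(out, "n_removed"), 1L)
  db2 <- data.frame(chrom = "chr1", pos = 100L, ref = "C", alt = "A")
  expect_equal(nrow(filter_known_germline(recs, db2)), 2L)  # allele mismatch
})

test_that("exonic labelling matches a brute-force overlap scan", {
  recs <- extract_discordant(
    make_pair(rep("RefRef", 50), rep("RefAlt", 50),
              pos = sample.int(5000L, 50)), "p")
  expect_true(all(classify_functional_region(recs, NULL)$region_label ==
                    "non-exonic"))
  m_start0 <- c(100L, 2000L); m_end0 <- c(600L, 2500L)
  exons <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(m_start0 + 1, m_end0))
  lab <- classify_functional_region(recs, exons)$region_label
  oracle <- brute_in_mask(recs$chrom, recs$pos, rep("chr1", 2),
                          m_start0 + 1, m_end0)
  expect_identical(lab == "exonic", oracle)
})

test_that("count summaries use the sample standard deviation", {
  s <- summarize_pzm_counts(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(summarize_pzm_counts(rep(7, 5))$sd, 0)
  set.seed(5)
  x <- rpois(20, 50)
  expect_equal(summarize_pzm_counts(sample(x)), summarize_pzm_counts(x))
  expect_error(summarize_pzm_counts(x, subset = rep(FALSE, 20)), "empty")
})

test_that("OLS coefficients match the closed-form normal equations", {
  set.seed(29)
  n <- 40
  age <- rnorm(n, 50, 10); sex <- sample(c("F", "M"), n, replace = TRUE)
  y <- 5 + 0.3 * age + 2 * (sex == "M") + rnorm(n)
  tab <- regress_counts_on_covariates(y, age, sex)
  X <- cbind(1, age, sex == "M")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(tab$beta, as.vector(beta))
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (n - 3)
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  expect_equal(tab$se, unname(se))
  expect_equal(tab$p, 2 * pt(-abs(tab$beta / tab$se), df = n - 3))
})

test_that("degenerate regression designs behave as specified", {
  set.seed(31)
  age <- rnorm(20, 50, 10)
  expect_error(regress_table(rnorm(20), data.frame(a = age, b = age)),
               "singular")
  # exact linear response: slope recovered, zero standard error
  tab <- suppressWarnings(regress_table(3 + 2 * age, data.frame(age = age)))
  expect_equal(tab$beta[2], 2)
  expect_equal(tab$se[2], 0)
  # standardizing covariates leaves t statistics unchanged
  y <- rnorm(20, 10 + 0.2 * age)
  sex <- rep(c("F", "M"), 10)
  t_raw <- regress_counts_on_covariates(y, age, sex)$t
  t_std <- regress_counts_on_covariates(y, as.vector(scale(age)), sex)$t
  expect_equal(t_std[-1], t_raw[-1])
})

test_that("exonic burden comparison uses the exact rank-sum distribution", {
  same <- compare_exonic_burden(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  res <- compare_exonic_burden(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(res$statistic), 0)
  # enumeration oracle: all choose(6,3) rank assignments
  pool <- c(1, 2, 3, 10, 11, 12)
  combos <- combn(6, 3)
  u_obs <- 0
  u_all <- apply(combos, 2, function(ix) {
    r <- rank(pool)
    sum(r[ix]) - 3 * 4 / 2
  })
  p_exact <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  expect_equal(res$p.value, p_exact)
})

test_that("rank-sum rejection rate grows with the location shift", {
  set.seed(47)
  rej <- vapply(c(0, 1.5, 4), function(shift) {
    mean(replicate(100, {
      a <- rnorm(15); b <- rnorm(15) + shift
      compare_exonic_burden(a, b)$p.value < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(rej) >= 0))
  expect_lt(rej[1], 0.15)
  expect_gt(rej[3], 0.9)
})
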