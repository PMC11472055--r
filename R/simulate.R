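# Synthetic twin-cohort simulator. Generates paired genotype tables with
# known truth: cohort-shared germline variants (identical within each
# pair), postzygotic somatic mutations (PZMs) injected into one twin with
# trinucleotide motifs drawn from a chosen signature profile and VAFs
# clustered near 0.5 / 0.25, and low-VAF artefact noise. Stands in for the
# study's protected WGS data so every downstream stage is testable.

# approximate hg38 autosome lengths (bp), used only to place sites
HG38_AUTOSOMES <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468)

#' Default artefact motif profile for simulated sequencing noise
#'
#' A background of library-preparation C>A damage mixed with a flat T>C
#' excess, matching the qualitative character of the noise seen in
#' low-concordance twin pairs; the remainder is uniform. Purely a modelling
#' default — the true artefact-generating mechanism is unknown and the
#' profile is fully configurable.
#'
#' @return Named probability vector of length 96.
#' @export
default_artefact_profile <- function() {
  comp <- motif_components(1:96)
  p <- rep(1, 96)
  p[comp$substitution == "C>A"] <- 4
  p[comp$substitution == "T>C"] <- 6
  p <- p / sum(p)
  names(p) <- motif_levels()
  p
}

#' Configuration for the twin-cohort simulator
#'
#' Defaults emulate the study cohort: 30 twin pairs with the packaged
#' participant ages and sexes, ~24x mean depth, around 90 injected PZMs per
#' pair drawn from the clock-like Signature 5 profile with VAFs mixed
#' around 0.5 (weight 0.7) and 0.25 (weight 0.3), and a low rate of low-VAF
#' artefact sites.
#'
#' @param n_pairs Number of twin pairs.
#' @param n_germline_sites Cohort-shared germline variant sites per pair
#'   table.
#' @param n_pzm Injected PZMs per pair.
#' @param pzm_signature Column name in `signatures` whose profile generates
#'   PZM motifs.
#' @param signatures 96 x S signature probability matrix (default: the
#'   packaged synthetic reference set).
#' @param pzm_vaf_weights Mixture weights for the VAF components centred at
#'   0.5 and 0.25 (non-negative, summing to 1).
#' @param pzm_vaf_concentration Beta concentration of each VAF component
#'   (larger = tighter around its centre).
#' @param noise_rate Expected number of low-VAF artefact sites per pair
#'   (Poisson mean); a scalar or one value per pair. The 30-pair default
#'   mirrors the study cohort's structure: a low background (40) for the
#'   first 23 pairs and a heavy artefact load (3000) for the last 7, which
#'   pushes those pairs below the 99% concordance cutoff and supplies the
#'   low-concordance artefact profile.
#' @param artefact_profile 96-motif probability profile for noise-site
#'   motifs.
#' @param depth_mean Mean sequencing depth per site per sample (reads);
#'   depths are Poisson, truncated at a minimum of 1 read.
#' @param gq_slope,gq_sd,gq_max Genotype quality model: GQ is
#'   `gq_slope * depth` plus Gaussian noise with sd `gq_sd`, clamped to
#'   `[0, gq_max]` (Phred).
#' @param germline_class_probs Probabilities of the shared germline
#'   genotype classes RefRef, RefAlt, AltAlt within a pair.
#' @param context_probs Optional named probability vector over the 32
#'   pyrimidine-centred trinucleotide contexts used for germline sites
#'   (default uniform).
#' @param ages,sexes Per-pair ages (years) and sexes (`"M"`/`"F"`); lengths
#'   must equal `n_pairs`. Defaults: the packaged participant table when
#'   `n_pairs` is 30, otherwise an age grid over 21-82 with alternating
#'   sexes.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A validated configuration list of class `twinpzm_sim_config`.
#' @export
simulation_config <- function(n_pairs = 30L,
                              n_germline_sites = 20000L,
                              n_pzm = 90L,
                              pzm_signature = "Signature 5",
                              signatures = NULL,
                              pzm_vaf_weights = c(vaf50 = 0.7, vaf25 = 0.3),
                              pzm_vaf_concentration = 60,
                              noise_rate = NULL,
                              artefact_profile = default_artefact_profile(),
                              depth_mean = 24,
                              gq_slope = 4, gq_sd = 8, gq_max = 99,
                              germline_class_probs = c(RefRef = 0.2,
                                                       RefAlt = 0.5,
                                                       AltAlt = 0.3),
                              context_probs = NULL,
                              ages = NULL, sexes = NULL,
                              seed = 1L) {
  n_pairs <- as.integer(n_pairs)
  if (is.null(noise_rate))
    noise_rate <- if (n_pairs == 30L) c(rep(40, 23L), rep(3000, 7L)) else 40
  noise_rate <- rep_len(noise_rate, n_pairs)
  stopifnot(n_pairs >= 1L, n_germline_sites >= 1L, n_pzm >= 0L,
            all(noise_rate >= 0), depth_mean > 0)
  if (is.null(signatures)) signatures <- twinpzm_signatures()
  if (!pzm_signature %in% colnames(signatures))
    stop("unknown signature id: ", pzm_signature)
  if (any(pzm_vaf_weights < 0) || abs(sum(pzm_vaf_weights) - 1) > 1e-9)
    stop("pzm_vaf_weights must be non-negative and sum to 1")
  if (any(germline_class_probs < 0) ||
      abs(sum(germline_class_probs) - 1) > 1e-9)
    stop("germline_class_probs must be non-negative and sum to 1")
  stopifnot(length(artefact_profile) == 96L, all(artefact_profile >= 0))
  if (is.null(context_probs)) {
    context_probs <- rep(1 / 32, 32L)
    names(context_probs) <- pyrimidine_contexts()
  }
  stopifnot(length(context_probs) == 32L, all(context_probs >= 0))
  if (is.null(ages) || is.null(sexes)) {
    if (n_pairs == 30L) {
      t1 <- read_table1_fixture()
      if (is.null(ages)) ages <- t1$age
      if (is.null(sexes)) sexes <- t1$sex
    } else {
      if (is.null(ages)) ages <- round(seq(21, 82, length.out = n_pairs))
      if (is.null(sexes)) sexes <- rep_len(c("F", "M"), n_pairs)
    }
  }
  if (length(ages) != n_pairs || length(sexes) != n_pairs)
    stop("ages and sexes must each have length n_pairs")
  structure(list(n_pairs = n_pairs,
                 n_germline_sites = as.integer(n_germline_sites),
                 n_pzm = as.integer(n_pzm),
                 pzm_signature = pzm_signature,
                 signatures = signatures,
                 pzm_vaf_weights = pzm_vaf_weights,
                 pzm_vaf_concentration = pzm_vaf_concentration,
                 noise_rate = noise_rate,
                 artefact_profile = artefact_profile,
                 depth_mean = depth_mean,
                 gq_slope = gq_slope, gq_sd = gq_sd, gq_max = gq_max,
                 germline_class_probs = germline_class_probs,
                 context_probs = context_probs,
                 ages = ages, sexes = as.character(sexes),
                 seed = as.integer(seed)),
            class = "twinpzm_sim_config")
}

#' Naive genotype call from allele depths
#'
#' Stands in for a full variant caller: calls AltAlt when the alt read
#' fraction is at least `hom_frac`, RefAlt when it is at least `het_frac`
#' with at least one alt read, RefRef otherwise, and Missing at zero depth.
#'
#' @param ad_ref,ad_alt Reference/alternative allele read counts.
#' @param hom_frac,het_frac Alt-fraction thresholds for homozygous and
#'   heterozygous calls.
#' @return Character vector of genotype classes.
#' @export
call_genotype <- function(ad_ref, ad_alt, hom_frac = 0.9, het_frac = 0.1) {
  dp <- ad_ref + ad_alt
  frac <- ifelse(dp > 0, ad_alt / dp, NA_real_)
  out <- rep("RefRef", length(dp))
  out[!is.na(frac) & frac >= het_frac & ad_alt >= 1] <- "RefAlt"
  out[!is.na(frac) & frac >= hom_frac] <- "AltAlt"
  out[dp == 0] <- "Missing"
  out
}

# positions sampled uniformly over autosomes, rejected on key collision
sample_positions <- function(n, exclude_keys = character()) {
  chroms <- character(0); pos <- integer(0)
  probs <- HG38_AUTOSOMES / sum(HG38_AUTOSOMES)
  seen <- exclude_keys
  while (length(chroms) < n) {
    m <- n - length(chroms)
    c_i <- sample(names(HG38_AUTOSOMES), m, replace = TRUE, prob = probs)
    # keep away from contig ends so a flanking context always exists
    p_i <- floor(stats::runif(m, min = 2, max = HG38_AUTOSOMES[c_i] - 1))
    key <- paste0(c_i, ":", p_i)
    ok <- !duplicated(key) & !(key %in% seen)
    chroms <- c(chroms, c_i[ok]); pos <- c(pos, as.integer(p_i[ok]))
    seen <- c(seen, key[ok])
  }
  data.frame(chrom = chroms, pos = pos, stringsAsFactors = FALSE)
}

# depth/allele-depth draws consistent with an intended genotype call:
# redraw until the naive caller reproduces the intended class
draw_reads <- function(class, vaf, depth_mean, max_tries = 50L) {
  n <- length(class)
  dp <- stats::rpois(n, depth_mean)
  while (any(dp < 1L)) dp[dp < 1L] <- stats::rpois(sum(dp < 1L), depth_mean)
  alt <- stats::rbinom(n, dp, vaf)
  need_het <- class == "RefAlt" & vaf >= 0.1     # true het: call must agree
  tries <- 0L
  repeat {
    frac <- alt / dp
    bad <- need_het & !(alt >= 1L & frac >= 0.1 & frac < 0.9)
    if (!any(bad) || tries >= max_tries) break
    k <- sum(bad)
    dpn <- stats::rpois(k, depth_mean); dpn[dpn < 2L] <- 2L
    dp[bad] <- dpn
    alt[bad] <- stats::rbinom(k, dpn, vaf[bad])
    tries <- tries + 1L
  }
  # degenerate survivors (vaf extremely close to a call boundary): force
  frac <- alt / dp
  bad <- need_het & !(alt >= 1L & frac >= 0.1 & frac < 0.9)
  if (any(bad)) {
    dp[bad] <- pmax(dp[bad], 4L)
    alt[bad] <- pmin(pmax(round(vaf[bad] * dp[bad]), 1L), dp[bad] - 1L)
  }
  # artefact het calls (true vaf below the het threshold): at least 1 read
  spurious <- class == "RefAlt" & vaf < 0.1
  alt[spurious] <- pmax(alt[spurious], 1L)
  list(dp = dp, alt = alt)
}

rbeta_mean <- function(n, mean, conc) stats::rbeta(n, conc * mean, conc * (1 - mean))

#' Simulate a twin cohort with known truth
#'
#' Generates one genotype table per twin pair plus a truth table of every
#' injected PZM and noise site. Germline sites are shared across the cohort
#' and their genotype classes are identical within each pair; each PZM
#' appears as a heterozygous call in exactly one twin; noise sites appear
#' as spurious heterozygous calls with low VAF in one twin. Read depths are
#' Poisson around `depth_mean` (minimum 1) with binomial alt counts at the
#' true VAF, resampled where needed so the emitted genotype class agrees
#' with the naive allele-depth call ([call_genotype()]). Deterministic
#' given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of class `twinpzm_cohort` with elements `pairs` (named list
#'   of per-pair site data.frames with columns chrom, pos, ref, alt,
#'   context, gt1, dp1, gq1, ad_ref1, ad_alt1, gt2, dp2, gq2, ad_ref2,
#'   ad_alt2), `truth` (pair_id, chrom, pos, ref, alt, context, carrier,
#'   true_vaf, motif, class = pzm|noise), `meta` (pair_id, age, sex) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "twinpzm_sim_config"))
  set.seed(config$seed)
  profile <- config$signatures[, config$pzm_signature]

  # cohort-shared germline scaffold
  germ <- sample_positions(config$n_germline_sites)
  ctx <- sample(names(config$context_probs), nrow(germ), replace = TRUE,
                prob = config$context_probs)
  germ$context <- ctx
  germ$ref <- substr(ctx, 2L, 2L)
  germ$alt <- vapply(germ$ref,
                     function(r) sample(setdiff(DNA_BASES, r), 1L),
                     character(1))
  germ_keys <- paste0(germ$chrom, ":", germ$pos)

  gq_of <- function(dp) {
    pmin(pmax(round(config$gq_slope * dp +
                      stats::rnorm(length(dp), 0, config$gq_sd)), 0),
         config$gq_max)
  }

  pairs <- vector("list", config$n_pairs)
  truth_list <- vector("list", config$n_pairs)
  pair_ids <- sprintf("pair%02d", seq_len(config$n_pairs))

  for (i in seq_len(config$n_pairs)) {
    g_class <- sample(names(config$germline_class_probs), nrow(germ),
                      replace = TRUE, prob = config$germline_class_probs)
    g_vaf <- c(RefRef = 0, RefAlt = 0.5, AltAlt = 1)[g_class]

    # injected PZMs: motifs i.i.d. from the chosen signature profile
    n_pzm <- config$n_pzm
    pz_pos <- sample_positions(n_pzm, exclude_keys = germ_keys)
    pz_motif <- sample.int(96L, n_pzm, replace = TRUE, prob = profile)
    comp <- motif_components(pz_motif)
    pz_ctx <- comp$context; pz_ref <- comp$ref; pz_alt <- comp$alt
    flip <- stats::runif(n_pzm) < 0.5   # record some on the purine strand
    if (any(flip)) {
      pz_ctx[flip] <- revcomp(pz_ctx[flip])
      pz_ref[flip] <- complement_base(pz_ref[flip])
      pz_alt[flip] <- complement_base(pz_alt[flip])
    }
    pz_carrier <- sample(1:2, n_pzm, replace = TRUE)
    n50 <- stats::rbinom(1L, n_pzm, config$pzm_vaf_weights[1])
    centre <- sample(c(rep(0.5, n50), rep(0.25, n_pzm - n50)))
    pz_vaf <- rbeta_mean(n_pzm, centre, config$pzm_vaf_concentration)
    pz_vaf <- pmin(pmax(pz_vaf, 0.12), 0.88)  # keep within het-call range

    # low-VAF artefact noise, motifs from the artefact profile
    n_noise <- stats::rpois(1L, config$noise_rate[i])
    no_pos <- sample_positions(n_noise,
                               exclude_keys = c(germ_keys,
                                                paste0(pz_pos$chrom, ":", pz_pos$pos)))
    no_motif <- if (n_noise > 0)
      sample.int(96L, n_noise, replace = TRUE, prob = config$artefact_profile)
    else integer(0)
    ncomp <- motif_components(no_motif)
    no_vaf <- rbeta_mean(n_noise, 0.05, 40)
    while (any(no_vaf >= 0.25))
      no_vaf[no_vaf >= 0.25] <- rbeta_mean(sum(no_vaf >= 0.25), 0.05, 40)
    no_carrier <- sample(1:2, n_noise, replace = TRUE)

    site <- data.frame(
      chrom = c(germ$chrom, pz_pos$chrom, no_pos$chrom),
      pos = c(germ$pos, pz_pos$pos, no_pos$pos),
      ref = c(germ$ref, pz_ref, ncomp$ref),
      alt = c(germ$alt, pz_alt, ncomp$alt),
      context = c(germ$context, pz_ctx, ncomp$context),
      stringsAsFactors = FALSE)
    n_site <- nrow(site)
    class1 <- c(g_class, ifelse(pz_carrier == 1L, "RefAlt", "RefRef"),
                ifelse(no_carrier == 1L, "RefAlt", "RefRef"))
    class2 <- c(g_class, ifelse(pz_carrier == 2L, "RefAlt", "RefRef"),
                ifelse(no_carrier == 2L, "RefAlt", "RefRef"))
    vaf1 <- c(g_vaf, ifelse(pz_carrier == 1L, pz_vaf, 0),
              ifelse(no_carrier == 1L, no_vaf, 0))
    vaf2 <- c(g_vaf, ifelse(pz_carrier == 2L, pz_vaf, 0),
              ifelse(no_carrier == 2L, no_vaf, 0))

    r1 <- draw_reads(class1, vaf1, config$depth_mean)
    r2 <- draw_reads(class2, vaf2, config$depth_mean)
    site$gt1 <- class1; site$dp1 <- r1$dp; site$gq1 <- gq_of(r1$dp)
    site$ad_ref1 <- r1$dp - r1$alt; site$ad_alt1 <- r1$alt
    site$gt2 <- class2; site$dp2 <- r2$dp; site$gq2 <- gq_of(r2$dp)
    site$ad_ref2 <- r2$dp - r2$alt; site$ad_alt2 <- r2$alt

    ord <- order(match(site$chrom, names(HG38_AUTOSOMES)), site$pos)
    pairs[[i]] <- site[ord, , drop = FALSE]
    rownames(pairs[[i]]) <- NULL

    truth_list[[i]] <- data.frame(
      pair_id = rep(pair_ids[i], n_pzm + n_noise),
      chrom = c(pz_pos$chrom, no_pos$chrom),
      pos = c(pz_pos$pos, no_pos$pos),
      ref = c(pz_ref, ncomp$ref),
      alt = c(pz_alt, ncomp$alt),
      context = c(pz_ctx, ncomp$context),
      carrier = c(pz_carrier, no_carrier),
      true_vaf = c(pz_vaf, no_vaf),
      motif = c(pz_motif, no_motif),
      class = c(rep("pzm", n_pzm), rep("noise", n_noise)),
      stringsAsFactors = FALSE)
  }
  names(pairs) <- pair_ids
  structure(list(pairs = pairs,
                 truth = do.call(rbind, truth_list),
                 meta = data.frame(pair_id = pair_ids,
                                   age = config$ages,
                                   sex = config$sexes,
                                   stringsAsFactors = FALSE),
                 config = config),
            class = "twinpzm_cohort")
}
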