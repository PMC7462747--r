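test_that("maximum credible AF reproduces the closed form and its scaling laws", {
  # contribution product 0.036 back-solved so the closed form gives 4.5e-5;
  # oracle = direct arithmetic 0.0005 * 0.036 * 0.5 / 0.2
  m <- disease_model(prevalence = 0.0005, genetic_contribution = 0.12,
                     allelic_contribution = 0.30, inheritance_factor = 0.5,
                     penetrance = 0.2)
  expect_equal(max_credible_af(m), 0.0005 * 0.036 * 0.5 / 0.2)
  expect_equal(max_credible_af(m), 4.5e-5)

  # identity factors
  m1 <- disease_model(0.001, 1, 1, 0.5, 1)
  expect_equal(max_credible_af(m1), 5e-4)

  # doubling penetrance exactly halves the threshold
  m2 <- disease_model(0.0005, 0.12, 0.30, 0.5, 0.4)
  expect_equal(max_credible_af(m2), max_credible_af(m) / 2)

  # multiplicative in prevalence
  set.seed(11)
  for (k in runif(5, 0.1, 1.9)) {
    base <- disease_model(prevalence = 1e-4)
    scaled <- disease_model(prevalence = k * 1e-4)
    expect_equal(max_credible_af(scaled), k * max_credible_af(base))
  }

  expect_error(disease_model(prevalence = 0), "prevalence")
  expect_error(disease_model(penetrance = 1.5), "penetrance")
})

test_that("AF_max takes the popmax over qualifying populations or the overall AF", {
  cfg <- stratification_config()

  # NFE qualifies at 3e-5 > overall 1.6e-5; AFR excluded with a single allele
  expect_equal(
    compute_af_max(4, 250000, c(NFE = 3, AFR = 1), c(NFE = 100000, AFR = 20000), cfg),
    3e-5)
  # no population with AC >= 2: fall back to the overall AF
  expect_equal(
    compute_af_max(1, 50000, c(NFE = 1), c(NFE = 30000), cfg),
    1 / 50000)
  # absent from the reference entirely
  expect_equal(compute_af_max(0, 250000, c(NFE = 0), c(NFE = 100000), cfg), 0)
  # excluded population never contributes even when frequent
  expect_equal(
    compute_af_max(10, 250000, c(OTH = 10), c(OTH = 1000), cfg),
    10 / 250000)
  expect_error(compute_af_max(1, 0), "positive")
})

test_that("AF_max dominates the overall AF on random frequency records", {
  cfg <- stratification_config()
  set.seed(42)
  for (i in 1:200) {
    an <- sample(1000:100000, 3)
    ac <- vapply(an, function(n) rbinom(1, n, runif(1, 0, 1e-3)), integer(1))
    names(ac) <- names(an) <- c("NFE", "AFR", "OTH")
    overall_an <- sum(an)
    overall_ac <- sum(ac)
    af_max <- compute_af_max(overall_ac, overall_an, ac, an, cfg)
    expect_gte(af_max, overall_ac / overall_an)
  }
})

test_that("rarity uses a strict threshold", {
  cfg <- stratification_config()
  expect_true(classify_rare(0.000044, cfg))
  expect_false(classify_rare(0.000045, cfg))  # boundary is not rare
  expect_true(classify_rare(0, cfg))
})

test_that("DS equals a brute-force recount over random predictor panels", {
  preds <- default_predictors()
  set.seed(7)
  for (i in 1:200) {
    scores <- stats::setNames(runif(6, -3, 3), preds$name)
    scores[runif(6) < 0.3] <- NA  # sparse availability
    got <- suppressWarnings(compute_ds(scores, preds))
    want <- oracle_ds(as.list(scores), preds)
    expect_identical(got$ds, want$ds)
    expect_identical(got$n_available, want$n_available)
    expect_lte(got$ds, 6L)
    expect_gte(got$ds, 0L)
  }
})

test_that("DS handles degenerate and invalid panels", {
  preds <- default_predictors()
  all_missing <- stats::setNames(rep(NA_real_, 6), preds$name)
  expect_warning(res <- compute_ds(all_missing, preds), "no predictor scores")
  expect_identical(res$ds, 0L)
  expect_identical(res$n_available, 0L)

  # all six exceed: maximum of the 0-6 range
  all_hit <- stats::setNames(
    ifelse(preds$higher_is_deleterious, preds$threshold + 1, preds$threshold - 1),
    preds$name)
  expect_identical(compute_ds(all_hit, preds)$ds, 6L)

  dup <- rbind(preds, preds[1, ])
  expect_error(compute_ds(all_hit, dup), "duplicated")
})

test_that("LoF classification covers exactly the four truncating classes", {
  expect_true(all(classify_lof(c("frameshift", "stop_gain",
                                 "splice_donor", "splice_acceptor"))))
  expect_false(any(classify_lof(c("missense", "utr5", "synonymous",
                                  "inframe_indel", "other"))))
  expect_error(classify_lof("splice_region"), "accepted values")
})

test_that("damaging = LoF or DS at threshold; unevaluable missense is flagged", {
  cfg <- stratification_config()
  expect_true(classify_damaging("stop_gain", ds = 0, cfg))
  expect_true(classify_damaging("missense", ds = 4, cfg))
  expect_false(classify_damaging("missense", ds = 3, cfg))
  expect_warning(
    res <- classify_damaging("missense", ds = 0, cfg, n_available = 0L),
    "unevaluable")
  expect_false(res)
})

test_that("the joint filter keeps rare damaging variants and reports failures", {
  cfg <- stratification_config()
  variants <- rbind(
    make_variant("lof_rare", "frameshift", 0, 250000),
    # damaging missense excluded on frequency alone (AF_max = 7e-4)
    make_variant("ms_frequent", "missense", 175, 250000,
                 nfe_ac = 70L, nfe_an = 100000L, ds_hits = 6L),
    make_variant("ms_damaging", "missense", 1, 250000, ds_hits = 4L),
    make_variant("ms_benign", "missense", 1, 250000, ds_hits = 2L)
  )
  res <- stratify_cohort(variants, cfg)
  expect_setequal(res$kept$variant_id, c("lof_rare", "ms_damaging"))
  rep <- res$report
  expect_equal(rep$failed_rules[rep$variant_id == "ms_frequent"], "frequency")
  expect_equal(rep$failed_rules[rep$variant_id == "ms_benign"], "deleteriousness")
  expect_equal(rep$af_max[rep$variant_id == "ms_frequent"], 7e-4)
  expect_true(all(rep$kept == (rep$rare & rep$damaging)))

  # empty input
  empty <- stratify_cohort(variants[0, ], cfg)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$report), 0)
})

test_that("stratification is idempotent and invariant to input order", {
  sim <- simulate_variant_table(variant_sim_params(n_variants = 120, seed = 5))
  res <- stratify_cohort(sim$variants)
  again <- stratify_cohort(res$kept)
  expect_setequal(again$kept$variant_id, res$kept$variant_id)

  shuffled <- sim$variants[rev(seq_len(nrow(sim$variants))), ]
  res2 <- stratify_cohort(shuffled)
  expect_setequal(res2$kept$variant_id, res$kept$variant_id)
})

test_that("kept set is monotone in both thresholds", {
  sim <- simulate_variant_table(variant_sim_params(n_variants = 150, seed = 9))
  kept_ids <- function(af_thr, ds_thr) {
    cfg <- stratification_config(af_threshold = af_thr, ds_threshold = ds_thr)
    stratify_cohort(sim$variants, cfg)$kept$variant_id
  }
  af_grid <- c(1e-6, 4.5e-5, 1e-3, 1e-1)
  for (i in seq_len(length(af_grid) - 1)) {
    expect_true(all(kept_ids(af_grid[i], 4) %in% kept_ids(af_grid[i + 1], 4)))
  }
  for (ds in 1:5) {
    expect_true(all(kept_ids(4.5e-5, ds + 1) %in% kept_ids(4.5e-5, ds)))
  }
})

test_that("uATG detection matches a brute-force trinucleotide scan", {
  # no ATG formed
  res <- detect_upstream_atg("CCGTGCC", 4, "G", "T", 5)
  expect_false(res$creates_uatg)

  # pre-existing ATG elsewhere is not 'created'
  res <- detect_upstream_atg("CCATGCC", 6, "C", "A", 3)
  expect_false(res$creates_uatg)

  # edit 9 bases 5' of the main ATG creating an out-of-frame uATG:
  # "ATC" -> "ATG" with distance 9 - 2 = 7, not a multiple of 3
  utr <- "CCATCGGCC"
  res <- detect_upstream_atg(utr, 4, "C", "G", 9)
  want <- oracle_uatg(utr, 4, "C", "G", 9)
  expect_true(res$creates_uatg)
  expect_false(res$in_frame_with_main_orf)
  expect_identical(res$creates_uatg, want$creates_uatg)
  expect_identical(res$in_frame_with_main_orf, want$in_frame_with_main_orf)

  # in-frame case: distance a multiple of 3
  res <- detect_upstream_atg("CCATCGGCC", 4, "C", "G", 10)
  expect_true(res$in_frame_with_main_orf)

  expect_error(detect_upstream_atg("CCATT", 2, "G", "A", 3), "mismatch")
  expect_error(detect_upstream_atg("CCNTT", 2, "N", "A", 3), "A, C, G, T")
})

test_that("uATG detection agrees with the oracle on random edits", {
  set.seed(13)
  for (i in 1:300) {
    n <- sample(6:20, 1)
    utr <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    pos <- sample(0:(n - 1), 1)
    ref <- substr(utr, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    offset <- sample(1:15, 1)
    got <- detect_upstream_atg(utr, pos, ref, alt, offset)
    want <- oracle_uatg(utr, pos, ref, alt, offset)
    expect_identical(got$creates_uatg, want$creates_uatg,
                     info = sprintf("%s pos=%d %s>%s", utr, pos, ref, alt))
    if (got$creates_uatg) {
      expect_identical(got$in_frame_with_main_orf, want$in_frame_with_main_orf)
    }
  }
})
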