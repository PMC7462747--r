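## Seeded simulators for variant tables and nuclear-family pedigrees with
## the statistical structure the analysis assumes, so stratification,
## burden and family statistics can be exercised against known truth.
## All randomness is confined to a locally seeded RNG; the caller's
## .Random.seed is left untouched.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Parameters for the synthetic variant-table generator
#'
#' Defaults emulate a gnomAD-v2-like frequency structure: six populations
#' with exome-scale allele numbers, benign variants spanning four orders of
#' magnitude of allele frequency (log-uniform, some above and some below
#' the rarity threshold), and pathogenic variants kept rare by construction
#' (at most one observed allele per population, AF below `pathogenic_af_cap`).
#' Predictor panels differ between classes through the per-predictor
#' probability of a deleterious call (0.9 pathogenic vs 0.15 benign).
#'
#' @param n_variants Number of variants to simulate.
#' @param fraction_pathogenic Fraction simulated as truly pathogenic.
#' @param benign_af_range Log-uniform bounds for benign allele frequencies.
#' @param pathogenic_af_cap Upper bound on true pathogenic AF (default 1e-5,
#'   below the 4.5e-5 rarity threshold).
#' @param predictor_exceed_prob_pathogenic,predictor_exceed_prob_benign
#'   Per-predictor probability that the score is on the deleterious side of
#'   its threshold.
#' @param lof_fraction_among_pathogenic Fraction of pathogenic variants
#'   drawn as loss-of-function (the rest are missense); default 0.5,
#'   matching a cohort where roughly half the implicated probands carry LoF
#'   alleles.
#' @param population_allele_numbers Named integer vector of per-population
#'   allele numbers (chromosomes sampled).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `variant_sim_params`.
#' @export
variant_sim_params <- function(n_variants = 200L,
                               fraction_pathogenic = 0.1,
                               benign_af_range = c(1e-6, 1e-2),
                               pathogenic_af_cap = 1e-5,
                               predictor_exceed_prob_pathogenic = 0.9,
                               predictor_exceed_prob_benign = 0.15,
                               lof_fraction_among_pathogenic = 0.5,
                               population_allele_numbers = c(
                                 NFE = 113000L, AFR = 16000L, EAS = 18000L,
                                 SAS = 30000L, AMR = 34000L, OTH = 6000L),
                               seed = 1L) {
  stopifnot(n_variants > 0,
            fraction_pathogenic >= 0, fraction_pathogenic <= 1,
            length(benign_af_range) == 2L,
            benign_af_range[1] > 0, benign_af_range[2] <= 1,
            benign_af_range[1] <= benign_af_range[2],
            pathogenic_af_cap > 0, pathogenic_af_cap < 1,
            predictor_exceed_prob_pathogenic >= 0,
            predictor_exceed_prob_pathogenic <= 1,
            predictor_exceed_prob_benign >= 0,
            predictor_exceed_prob_benign <= 1,
            lof_fraction_among_pathogenic >= 0,
            lof_fraction_among_pathogenic <= 1,
            length(population_allele_numbers) >= 1,
            !is.null(names(population_allele_numbers)),
            all(population_allele_numbers > 0))
  structure(as.list(environment()), class = "variant_sim_params")
}

## score on the requested side of a predictor's threshold
draw_score <- function(exceed, threshold, higher_is_deleterious, n) {
  offset <- stats::runif(n, 0.01, 1)
  ## deleterious side is above the threshold when higher_is_deleterious,
  ## below it otherwise
  ifelse(exceed == higher_is_deleterious, threshold + offset, threshold - offset)
}

#' Simulate a variant table with known truth labels
#'
#' Pathogenic variants are rare by construction (per-population allele
#' counts truncated at 1, keeping AF_max below the default credibility
#' threshold) and are either LoF or missense with predictor panels drawn at
#' the pathogenic exceedance probability — so the joint rare-plus-damaging
#' filter has sensitivity 1 for pathogenic LoF variants by construction.
#' Benign variants are missense with log-uniform allele frequencies (some
#' rare, some common) and benign-exceedance panels. Per-population allele
#' counts are binomial draws at the configured allele numbers, so realised
#' AFs are consistent with the drawn frequencies.
#'
#' @param params A [variant_sim_params()].
#' @return List with `variants` (a variant table data frame as accepted by
#'   [stratify_cohort()] and [read_variant_table()]) and `truth` (data frame
#'   `variant_id`, `pathogenic`).
#' @export
simulate_variant_table <- function(params = variant_sim_params()) {
  stopifnot(inherits(params, "variant_sim_params"))
  with_local_seed(params$seed, {
    n <- params$n_variants
    n_path <- round(n * params$fraction_pathogenic)
    pathogenic <- rep(c(TRUE, FALSE), c(n_path, n - n_path))
    pops <- names(params$population_allele_numbers)
    an <- params$population_allele_numbers

    af_true <- numeric(n)
    lu <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))
    af_true[pathogenic] <- lu(n_path, 1e-8, params$pathogenic_af_cap)
    af_true[!pathogenic] <- lu(n - n_path, params$benign_af_range[1],
                               params$benign_af_range[2])

    consequence <- rep("missense", n)
    if (n_path > 0) {
      n_lof <- round(n_path * params$lof_fraction_among_pathogenic)
      lof_classes <- sample(LOF_CLASSES, n_lof, replace = TRUE)
      consequence[seq_len(n_lof)] <- lof_classes
    }

    ac <- matrix(0L, nrow = n, ncol = length(pops),
                 dimnames = list(NULL, pops))
    for (j in seq_along(pops)) {
      ac[, j] <- stats::rbinom(n, an[j], af_true)
      ac[pathogenic, j] <- pmin(ac[pathogenic, j], 1L)  # rare by construction
    }

    preds <- default_predictors()
    p_exceed <- ifelse(pathogenic, params$predictor_exceed_prob_pathogenic,
                       params$predictor_exceed_prob_benign)
    score_cols <- lapply(seq_len(nrow(preds)), function(i) {
      exceed <- stats::runif(n) < p_exceed
      draw_score(exceed, preds$threshold[i], preds$higher_is_deleterious[i], n)
    })
    names(score_cols) <- preds$name

    variants <- data.frame(
      variant_id = sprintf("var%04d", seq_len(n)),
      gene = "SMAD6",
      consequence = consequence,
      hgvs_c = NA_character_,
      hgvs_p = NA_character_,
      proband_id = sprintf("P%04d", seq_len(n)),
      overall_ac = as.integer(rowSums(ac)),
      overall_an = as.integer(sum(an)),
      stringsAsFactors = FALSE
    )
    for (p in pops) {
      variants[[paste0(p, "_ac")]] <- as.integer(ac[, p])
      variants[[paste0(p, "_an")]] <- as.integer(an[[p]])
    }
    for (nm in names(score_cols)) variants[[nm]] <- score_cols[[nm]]
    variants$cadd <- stats::rnorm(n, mean = ifelse(pathogenic, 25, 10), sd = 4)

    ## shuffle so class is not encoded in row order
    ord <- sample.int(n)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    truth <- data.frame(variant_id = variants$variant_id,
                        pathogenic = pathogenic[ord],
                        stringsAsFactors = FALSE)
    list(variants = variants, truth = truth)
  })
}

#' Parameters for the synthetic nuclear-family generator
#'
#' Defaults describe the inheritance model of a low-penetrance dominant
#' craniosynostosis gene: one heterozygous carrier parent per family (or a
#' de novo proband), Mendelian 50% transmission, penetrance 0.16, and a
#' biallelic modifier SNP with non-Finnish-European risk-allele frequency
#' 0.327 drawn at Hardy-Weinberg proportions. Families are ascertained
#' through a proband: an affected carrier offspring whose presence is
#' guaranteed, with additional offspring simulated freely — so recurrence
#' among the additional offspring is an unbiased estimate of
#' transmission x penetrance.
#'
#' @param n_families Number of families.
#' @param penetrance Probability an offspring carrier manifests disease.
#' @param transmission_prob Probability a carrier parent transmits (0.5).
#' @param de_novo_rate Fraction of families whose proband's variant is de
#'   novo (both parents noncarriers); default 0.12, roughly 3 in 26.
#' @param offspring_range Integer bounds (inclusive) on the number of
#'   *additional* offspring beyond the proband.
#' @param modifier_risk_allele_freq Population frequency of the modifier
#'   risk allele C (default 0.327).
#' @param modifier_effect `NULL` for no modifier effect, or a numeric pair
#'   `c(with_risk, without_risk)`: penetrance applied to offspring carriers
#'   with/without at least one risk allele.
#' @param ascertain If TRUE (default) every family contains a designated
#'   proband (affected carrier offspring); set FALSE for unbiased marginal
#'   checks (all offspring simulated freely, no affection guarantee).
#' @param seed Integer seed.
#' @return A list of class `family_sim_params`.
#' @export
family_sim_params <- function(n_families = 26L,
                              penetrance = 0.16,
                              transmission_prob = 0.5,
                              de_novo_rate = 0.12,
                              offspring_range = c(0L, 3L),
                              modifier_risk_allele_freq = 0.327,
                              modifier_effect = NULL,
                              ascertain = TRUE,
                              seed = 1L) {
  stopifnot(n_families > 0,
            penetrance >= 0, penetrance <= 1,
            transmission_prob > 0, transmission_prob <= 1,
            de_novo_rate >= 0, de_novo_rate <= 1,
            length(offspring_range) == 2L, offspring_range[1] >= 0,
            offspring_range[1] <= offspring_range[2],
            modifier_risk_allele_freq >= 0, modifier_risk_allele_freq <= 1)
  if (!is.null(modifier_effect)) {
    stopifnot(length(modifier_effect) == 2L,
              all(modifier_effect >= 0), all(modifier_effect <= 1))
  }
  structure(as.list(environment()), class = "family_sim_params")
}

genotype_from_alleles <- function(n_c) c("TT", "CT", "CC")[n_c + 1L]

#' Simulate nuclear families under the major-gene + modifier model
#'
#' Each family comprises two parents and offspring. Unless the proband is
#' de novo, one randomly chosen parent is a heterozygous carrier (clinically
#' unaffected, as in proband-ascertained low-penetrance cohorts); each
#' offspring inherits the variant with `transmission_prob` and, if a
#' carrier, is affected with the applicable penetrance (modified by the
#' offspring's own modifier genotype when `modifier_effect` is set).
#' Modifier alleles segregate Mendelianly from parental genotypes drawn at
#' Hardy-Weinberg proportions. Affected individuals receive a suture class
#' drawn from a metopic-dominated distribution. Deterministic given
#' `params$seed`.
#'
#' @param params A [family_sim_params()].
#' @return A pedigree data frame (see [read_pedigree()] for the column
#'   contract) with one designated proband per family when
#'   `params$ascertain` is TRUE.
#' @export
simulate_families <- function(params = family_sim_params()) {
  stopifnot(inherits(params, "family_sim_params"))
  with_local_seed(params$seed, {
    suture_probs <- c(metopic = 0.50, sagittal = 0.17, unicoronal = 0.08,
                      bicoronal = 0.04, lambdoid = 0.01, multisuture = 0.12,
                      unspecified = 0.08)
    rows <- vector("list", params$n_families)
    for (f in seq_len(params$n_families)) {
      fid <- sprintf("F%04d", f)
      de_novo <- stats::runif(1) < params$de_novo_rate
      carrier_parent <- if (de_novo) NA_character_ else
        sample(c("father", "mother"), 1L)
      ## modifier alleles: two per parent, Bernoulli(risk freq) => HWE
      fa_alleles <- stats::rbinom(2, 1, params$modifier_risk_allele_freq)
      mo_alleles <- stats::rbinom(2, 1, params$modifier_risk_allele_freq)

      pen_for <- function(geno) {
        if (is.null(params$modifier_effect)) return(params$penetrance)
        if (geno %in% c("CC", "CT")) params$modifier_effect[1]
        else params$modifier_effect[2]
      }
      make_child <- function(id, forced_proband = FALSE) {
        inherited <- c(sample(fa_alleles, 1L), sample(mo_alleles, 1L))
        geno <- genotype_from_alleles(sum(inherited))
        if (forced_proband) {
          carrier <- TRUE
          affected <- TRUE
        } else {
          carrier <- if (de_novo) FALSE else
            stats::runif(1) < params$transmission_prob
          affected <- carrier && stats::runif(1) < pen_for(geno)
        }
        list(individual_id = id, carrier = carrier, affected = affected,
             modifier_genotype = geno)
      }

      n_extra_choices <- params$offspring_range[1]:params$offspring_range[2]
      n_extra <- n_extra_choices[sample.int(length(n_extra_choices), 1L)]
      kids <- list()
      if (params$ascertain) {
        kids[[1]] <- make_child(paste0(fid, "_P"), forced_proband = TRUE)
      }
      for (s in seq_len(n_extra)) {
        kids[[length(kids) + 1L]] <- make_child(paste0(fid, "_S", s))
      }

      fam_rows <- data.frame(
        family_id = fid,
        individual_id = c(paste0(fid, "_FA"), paste0(fid, "_MO"),
                          vapply(kids, `[[`, "", "individual_id")),
        father_id = c("0", "0", rep(paste0(fid, "_FA"), length(kids))),
        mother_id = c("0", "0", rep(paste0(fid, "_MO"), length(kids))),
        sex = c(1L, 2L, sample(1:2, length(kids), replace = TRUE)),
        affected = c("unaffected", "unaffected",
                     ifelse(vapply(kids, `[[`, NA, "affected"),
                            "affected", "unaffected")),
        carrier = c(
          if (identical(carrier_parent, "father")) "carrier" else "noncarrier",
          if (identical(carrier_parent, "mother")) "carrier" else "noncarrier",
          ifelse(vapply(kids, `[[`, NA, "carrier"), "carrier", "noncarrier")),
        suture = NA_character_,
        modifier_genotype = c(genotype_from_alleles(sum(fa_alleles)),
                              genotype_from_alleles(sum(mo_alleles)),
                              vapply(kids, `[[`, "", "modifier_genotype")),
        stringsAsFactors = FALSE
      )
      aff <- fam_rows$affected == "affected"
      fam_rows$suture[aff] <- sample(names(suture_probs), sum(aff),
                                     replace = TRUE, prob = suture_probs)
      rows[[f]] <- fam_rows
    }
    ped <- do.call(rbind, rows)
    rownames(ped) <- NULL
    ped
  })
}

#' Operating characteristics of the two-locus test and penetrance estimator
#'
#' Monte Carlo evaluation over replicated synthetic cohorts: the rejection
#' fraction of the one-tailed two-locus Fisher test at level `alpha` (the
#' type-I error when `modifier_effect` is unset or equal-penetrance, the
#' power otherwise), and the bias and RMSE of the sib-recurrence penetrance
#' estimator. Each replicate simulates families, builds the carrier table
#' with [two_locus_table()], and estimates penetrance via
#' [sib_recurrence_counts()] and [estimate_penetrance()]. Deterministic
#' given `seed`; replicate seeds are `seed + 1:n_reps`.
#'
#' @param n_reps Number of replicates (>= 100).
#' @param fam_params A [family_sim_params()] (its own seed is ignored).
#' @param alpha Nominal test level.
#' @param seed Integer base seed.
#' @return List with `rejection_rate`, `mc_se` (binomial Monte Carlo
#'   standard error of the rejection rate), `penetrance_bias`,
#'   `penetrance_rmse`, `n_penetrance_reps` (replicates with >= 1
#'   additional offspring), `n_reps`, `alpha`, and `true_penetrance`.
#' @export
evaluate_operating_characteristics <- function(n_reps = 1000L,
                                               fam_params = family_sim_params(),
                                               alpha = 0.05,
                                               seed = 1L) {
  stopifnot(n_reps >= 100L, alpha > 0, alpha < 1)
  reject <- logical(n_reps)
  pen_hat <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    p <- fam_params
    p$seed <- seed + r
    ped <- simulate_families(p)
    tl <- two_locus_table(ped)
    reject[r] <- tl$p_one_tailed <= alpha
    counts <- sib_recurrence_counts(ped)
    if (counts$total_offspring > 0) {
      rec <- sib_recurrence(counts$affected_additional, counts$total_offspring)
      pen_hat[r] <- suppressWarnings(
        estimate_penetrance(rec, p$transmission_prob)$penetrance)
    }
  }
  true_pen <- if (is.null(fam_params$modifier_effect)) fam_params$penetrance
              else NA_real_
  ok <- !is.na(pen_hat)
  rate <- mean(reject)
  list(
    rejection_rate = rate,
    mc_se = sqrt(rate * (1 - rate) / n_reps),
    penetrance_bias = if (is.na(true_pen)) NA_real_
                      else mean(pen_hat[ok]) - true_pen,
    penetrance_rmse = if (is.na(true_pen)) NA_real_
                      else sqrt(mean((pen_hat[ok] - true_pen)^2)),
    n_penetrance_reps = sum(ok),
    n_reps = n_reps,
    alpha = alpha,
    true_penetrance = true_pen
  )
}
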