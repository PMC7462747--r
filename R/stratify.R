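#' Recognised consequence classes
#'
#' One consequence class per variant. The four classes `frameshift`,
#' `stop_gain`, `splice_donor` and `splice_acceptor` are treated as
#' loss-of-function (LoF); splice-region changes outside the canonical
#' +/-1,2 dinucleotides are *not* auto-LoF and must be supplied as `other`
#' or `missense` as appropriate.
#'
#' @export
CONSEQUENCE_CLASSES <- c(
  "frameshift", "stop_gain", "splice_donor", "splice_acceptor",
  "missense", "inframe_indel", "utr5", "synonymous", "other"
)

LOF_CLASSES <- c("frameshift", "stop_gain", "splice_donor", "splice_acceptor")

#' Default in-silico predictor panel
#'
#' Six commonly used missense deleteriousness predictors with dbNSFP-style
#' score conventions. A score is called deleterious when it meets or exceeds
#' its threshold in the deleterious direction (`higher_is_deleterious` gives
#' the direction; SIFT and FATHMM call low scores deleterious). The panel is
#' fully configurable — pass your own data frame with the same columns to
#' [stratification_config()]; these defaults are provisional and exist so
#' the deleteriousness score (DS) is computable out of the box.
#'
#' @return A data frame with columns `name`, `threshold`,
#'   `higher_is_deleterious`.
#' @export
default_predictors <- function() {
  data.frame(
    name = c("sift", "polyphen2_hdiv", "polyphen2_hvar",
             "mutationtaster", "mutationassessor", "fathmm"),
    threshold = c(0.05, 0.446, 0.446, 0.5, 1.935, -1.5),
    higher_is_deleterious = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Stratification configuration
#'
#' Thresholds and conventions for the joint rare-plus-damaging filter.
#'
#' @param af_threshold Rarity threshold on AF_max; a variant is rare iff
#'   AF_max is *strictly* below it. Default 4.5e-5, the maximum credible
#'   allele frequency under the default [disease_model()]; pass
#'   `max_credible_af(your_model)` to derive it from other assumptions.
#' @param ds_threshold Minimum deleteriousness score (DS) for a non-LoF
#'   variant to count as damaging, in 0..6. Default 4.
#' @param min_population_allele_count Minimum allele count for a population
#'   to contribute to AF_max (default 2): populations where the allele was
#'   seen only once carry no frequency information beyond the overall AF.
#'   Applies to per-population counts only, never to the overall fallback.
#' @param excluded_populations Population codes excluded from the AF_max
#'   maximisation (default `"OTH"`, the heterogeneous "Other" grouping).
#'   Bottleneck populations (e.g. `c("OTH", "ASJ", "FIN")`) may be added.
#' @param predictors Predictor panel data frame (see [default_predictors()]);
#'   at most 6 rows count toward the DS.
#'
#' @return An object of class `stratification_config`.
#' @export
stratification_config <- function(af_threshold = 4.5e-5,
                                  ds_threshold = 4L,
                                  min_population_allele_count = 2L,
                                  excluded_populations = "OTH",
                                  predictors = default_predictors()) {
  stopifnot(is.numeric(af_threshold), length(af_threshold) == 1L,
            af_threshold > 0, af_threshold < 1)
  ds_threshold <- as.integer(ds_threshold)
  if (is.na(ds_threshold) || ds_threshold < 0L || ds_threshold > 6L) {
    stop("ds_threshold must be an integer in [0, 6]", call. = FALSE)
  }
  stopifnot(is.data.frame(predictors),
            all(c("name", "threshold", "higher_is_deleterious") %in% names(predictors)))
  if (nrow(predictors) > 6L) {
    stop("at most 6 predictors may count toward the DS; got ", nrow(predictors),
         call. = FALSE)
  }
  if (anyDuplicated(predictors$name)) {
    stop("duplicated predictor name(s): ",
         paste(unique(predictors$name[duplicated(predictors$name)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      af_threshold = af_threshold,
      ds_threshold = ds_threshold,
      min_population_allele_count = as.integer(min_population_allele_count),
      excluded_populations = toupper(as.character(excluded_populations)),
      predictors = predictors
    ),
    class = "stratification_config"
  )
}

#' Popmax-style AF_max from per-population allele counts
#'
#' AF_max is the greater of (1) the maximum allele frequency observed in any
#' non-excluded population in which at least `min_population_allele_count`
#' alleles were seen, and (2) the overall allele frequency. When no
#' population qualifies, the overall AF is returned, so AF_max is always at
#' least the overall AF.
#'
#' @param overall_ac,overall_an Overall allele count and allele number
#'   (`overall_an` > 0).
#' @param pop_ac,pop_an Named vectors (population code -> allele count /
#'   allele number) for the per-population records; may be empty.
#' @param config A [stratification_config()].
#' @return A single allele frequency in \[0, 1\].
#' @export
#' @examples
#' cfg <- stratification_config()
#' compute_af_max(4, 250000, c(NFE = 3, AFR = 1), c(NFE = 100000, AFR = 20000), cfg)
compute_af_max <- function(overall_ac, overall_an, pop_ac = numeric(),
                           pop_an = numeric(), config = stratification_config()) {
  if (length(overall_an) != 1L || is.na(overall_an) || overall_an <= 0) {
    stop("overall allele number must be a positive integer", call. = FALSE)
  }
  if (is.na(overall_ac) || overall_ac < 0 || overall_ac > overall_an) {
    stop("overall allele count must satisfy 0 <= AC <= AN", call. = FALSE)
  }
  overall_af <- overall_ac / overall_an
  if (length(pop_ac) == 0L) {
    return(overall_af)
  }
  if (is.null(names(pop_ac)) || is.null(names(pop_an)) ||
      !setequal(names(pop_ac), names(pop_an))) {
    stop("pop_ac and pop_an must be named by the same population codes",
         call. = FALSE)
  }
  pop_an <- pop_an[names(pop_ac)]
  keep <- !(toupper(names(pop_ac)) %in% config$excluded_populations) &
    !is.na(pop_ac) & !is.na(pop_an)
  pop_ac <- pop_ac[keep]
  pop_an <- pop_an[keep]
  if (any(pop_an == 0 & pop_ac > 0)) {
    stop("population record with allele_number = 0 but nonzero allele count",
         call. = FALSE)
  }
  qualifies <- pop_ac >= config$min_population_allele_count & pop_an > 0
  if (!any(qualifies)) {
    return(overall_af)
  }
  max(max(pop_ac[qualifies] / pop_an[qualifies]), overall_af)
}

#' Assign AF_max to every row of a variant table
#'
#' Discovers per-population count columns by the `<POP>_ac` / `<POP>_an`
#' naming convention (excluding `overall_ac`/`overall_an`) and adds an
#' `af_max` column.
#'
#' @param variants A variant table data frame (see [read_variant_table()]).
#' @param config A [stratification_config()].
#' @return `variants` with an `af_max` column appended (or replaced).
#' @export
assign_af_max <- function(variants, config = stratification_config()) {
  pops <- discover_populations(variants)
  n <- nrow(variants)
  af_max <- numeric(n)
  for (i in seq_len(n)) {
    pop_ac <- vapply(pops, function(p) as.numeric(variants[[paste0(p, "_ac")]][i]),
                     numeric(1))
    pop_an <- vapply(pops, function(p) as.numeric(variants[[paste0(p, "_an")]][i]),
                     numeric(1))
    names(pop_ac) <- names(pop_an) <- pops
    af_max[i] <- compute_af_max(variants$overall_ac[i], variants$overall_an[i],
                                pop_ac, pop_an, config)
  }
  variants$af_max <- af_max
  variants
}

## population codes present as <pop>_ac/<pop>_an column pairs
discover_populations <- function(variants) {
  ac_cols <- grep("_ac$", names(variants), value = TRUE)
  ac_cols <- setdiff(ac_cols, "overall_ac")
  pops <- sub("_ac$", "", ac_cols)
  missing_an <- pops[!paste0(pops, "_an") %in% names(variants)]
  if (length(missing_an)) {
    stop("population column(s) without a matching _an column: ",
         paste(missing_an, collapse = ", "), call. = FALSE)
  }
  pops
}

#' Is a variant rare?
#'
#' Rarity uses a strict inequality: a variant with AF_max exactly at the
#' threshold is *not* rare.
#'
#' @param af_max Allele frequency (or vector thereof) in \[0, 1\].
#' @param config A [stratification_config()].
#' @return Logical vector.
#' @export
classify_rare <- function(af_max, config = stratification_config()) {
  stopifnot(all(is.na(af_max) | (af_max >= 0 & af_max <= 1)))
  af_max < config$af_threshold
}

#' Deleteriousness score (DS) from an in-silico predictor panel
#'
#' Counts the predictors whose score meets its threshold in the deleterious
#' direction. Missing (NA) scores count as not deleterious; the number of
#' available scores is returned alongside so a DS of 4 with 4 scores
#' available is distinguishable from 4 of 6.
#'
#' @param scores Named numeric vector of raw predictor scores; names must
#'   match `predictors$name`. NA = predictor unavailable for this variant.
#' @param predictors Predictor panel data frame ([default_predictors()]).
#' @return A list with `ds` (integer in 0..nrow(predictors)), `n_available`,
#'   and `calls` (named logical vector, NA where unavailable).
#' @export
#' @examples
#' compute_ds(c(sift = 0.01, polyphen2_hdiv = 0.99, polyphen2_hvar = 0.2,
#'              mutationtaster = 1, mutationassessor = 0.5, fathmm = 2))
compute_ds <- function(scores, predictors = default_predictors()) {
  if (anyDuplicated(predictors$name)) {
    stop("duplicated predictor name(s) in panel", call. = FALSE)
  }
  if (nrow(predictors) > 6L) {
    stop("at most 6 predictors may count toward the DS", call. = FALSE)
  }
  calls <- rep(NA, nrow(predictors))
  names(calls) <- predictors$name
  for (i in seq_len(nrow(predictors))) {
    s <- scores[[predictors$name[i]]]
    if (is.null(s) || is.na(s)) next
    calls[i] <- if (predictors$higher_is_deleterious[i]) {
      s >= predictors$threshold[i]
    } else {
      s <= predictors$threshold[i]
    }
  }
  n_available <- sum(!is.na(calls))
  if (n_available == 0L) {
    warning("no predictor scores available; DS = 0 reflects missing data, ",
            "not a benign prediction", call. = FALSE)
  }
  list(ds = sum(calls, na.rm = TRUE), n_available = n_available, calls = calls)
}

#' Is a consequence class loss-of-function?
#'
#' LoF comprises frameshift, stop-gain and canonical splice donor/acceptor
#' changes. 5' UTR, missense, in-frame indel and synonymous classes are not
#' LoF (UTR variants with possible translational effects are analysed
#' separately; see [detect_upstream_atg()]).
#'
#' @param consequence Character vector of consequence classes
#'   (see [CONSEQUENCE_CLASSES]).
#' @return Logical vector.
#' @export
classify_lof <- function(consequence) {
  bad <- setdiff(unique(consequence), CONSEQUENCE_CLASSES)
  if (length(bad)) {
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
         "; accepted values are: ", paste(CONSEQUENCE_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  consequence %in% LOF_CLASSES
}

#' Is a variant predicted damaging?
#'
#' A variant is damaging when it is loss-of-function or its deleteriousness
#' score meets the DS threshold (default DS >= 4 of 6). A missense variant
#' with no available predictor scores is unevaluable and returns FALSE with
#' a warning.
#'
#' @param consequence Consequence class (scalar).
#' @param ds DS for the variant (integer; ignored for LoF classes).
#' @param config A [stratification_config()].
#' @param n_available Number of available predictor scores behind `ds`
#'   (used only to flag unevaluable missense variants; default assumed > 0).
#' @return Logical scalar.
#' @export
classify_damaging <- function(consequence, ds, config = stratification_config(),
                              n_available = NULL) {
  if (classify_lof(consequence)) {
    return(TRUE)
  }
  if (!is.null(n_available) && n_available == 0L && consequence == "missense") {
    warning("missense variant with no available predictor scores is ",
            "unevaluable; classified not damaging", call. = FALSE)
    return(FALSE)
  }
  if (is.na(ds)) {
    return(FALSE)
  }
  ds >= config$ds_threshold
}

#' Joint rare-plus-damaging stratification of a variant table
#'
#' Applies the full triage: AF_max assignment, rarity (strict threshold),
#' DS computation from the configured predictor panel, and the damaging rule
#' (LoF and/or DS at threshold). A variant is kept iff it is both rare and
#' damaging.
#'
#' @param variants A variant table data frame; required columns
#'   `variant_id`, `gene`, `consequence`, `overall_ac`, `overall_an`, plus
#'   any `<POP>_ac`/`<POP>_an` pairs and predictor score columns named after
#'   `config$predictors$name`.
#' @param config A [stratification_config()].
#' @return A list with `kept` (the retained rows, original columns plus
#'   `af_max` and `ds`) and `report` (one row per input variant: `af_max`,
#'   `ds`, `ds_available`, `lof`, `rare`, `damaging`, `kept`, and
#'   `failed_rules`, a comma-separated list of the rule(s) a dropped variant
#'   failed).
#' @export
stratify_cohort <- function(variants, config = stratification_config()) {
  stopifnot(is.data.frame(variants))
  required <- c("variant_id", "gene", "consequence", "overall_ac", "overall_an")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(variants)
  if (n == 0L) {
    empty_rep <- data.frame(variant_id = character(), af_max = numeric(),
                            ds = integer(), ds_available = integer(),
                            lof = logical(), rare = logical(),
                            damaging = logical(), kept = logical(),
                            failed_rules = character(),
                            stringsAsFactors = FALSE)
    kept <- variants
    kept$af_max <- numeric(0)
    kept$ds <- integer(0)
    return(list(kept = kept, report = empty_rep))
  }
  variants <- assign_af_max(variants, config)
  lof <- classify_lof(variants$consequence)
  rare <- classify_rare(variants$af_max, config)

  predictor_names <- config$predictors$name
  ds <- integer(n)
  ds_avail <- integer(n)
  for (i in seq_len(n)) {
    scores <- vapply(predictor_names, function(p) {
      if (p %in% names(variants)) as.numeric(variants[[p]][i]) else NA_real_
    }, numeric(1))
    res <- suppressWarnings(compute_ds(scores, config$predictors))
    ds[i] <- res$ds
    ds_avail[i] <- res$n_available
  }
  unevaluable <- !lof & variants$consequence == "missense" & ds_avail == 0L
  if (any(unevaluable)) {
    warning(sum(unevaluable), " missense variant(s) with no available ",
            "predictor scores are unevaluable and classified not damaging",
            call. = FALSE)
  }
  damaging <- lof | (ds >= config$ds_threshold & ds_avail > 0L)
  kept_flag <- rare & damaging

  failed <- character(n)
  failed[!rare & damaging] <- "frequency"
  failed[rare & !damaging] <- "deleteriousness"
  failed[!rare & !damaging] <- "frequency,deleteriousness"

  variants$ds <- ds
  report <- data.frame(
    variant_id = variants$variant_id,
    af_max = variants$af_max,
    ds = ds,
    ds_available = ds_avail,
    lof = lof,
    rare = rare,
    damaging = damaging,
    kept = kept_flag,
    failed_rules = failed,
    stringsAsFactors = FALSE
  )
  list(kept = variants[kept_flag, , drop = FALSE], report = report)
}
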