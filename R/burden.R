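#' Recognised suture classes
#' @export
SUTURE_CLASSES <- c("metopic", "sagittal", "unicoronal", "bicoronal",
                    "lambdoid", "multisuture", "unspecified")

#' Syndromic vs nonsyndromic presentation
#'
#' A proband is classified syndromic when any of the following holds:
#' additional dysmorphic features or congenital anomalies, significant
#' developmental delay, or an affected first-degree relative (familial cases
#' are grouped with syndromic presentations).
#'
#' @param dysmorphic_or_anomalies,significant_developmental_delay,affected_first_degree_relative
#'   Logical vectors (recycled to common length).
#' @return Logical vector: TRUE = syndromic.
#' @export
classify_presentation <- function(dysmorphic_or_anomalies = FALSE,
                                  significant_developmental_delay = FALSE,
                                  affected_first_degree_relative = FALSE) {
  dysmorphic_or_anomalies | significant_developmental_delay |
    affected_first_degree_relative
}

#' Prevalence of gene-positive probands by suture class
#'
#' Cross-tabulates a proband table by suture class and syndromic status,
#' reporting totals, gene-positive counts, and percentages, with a combined
#' column and a combined row whose margins are consistent by construction
#' (combined = syndromic + nonsyndromic).
#'
#' @param probands Data frame with columns `proband_id` (unique), `suture`
#'   (one of [SUTURE_CLASSES]), `syndromic` (logical) and `gene_positive`
#'   (logical).
#' @return A data frame with one row per suture class plus `"combined"`, and
#'   columns `<group>_total`, `<group>_positive`, `<group>_percent` for
#'   groups nonsyndromic, syndromic and combined. Percentages are
#'   positive/total x 100 (NA for empty cells).
#' @export
prevalence_table <- function(probands) {
  stopifnot(is.data.frame(probands),
            all(c("proband_id", "suture", "syndromic", "gene_positive") %in%
                  names(probands)))
  if (anyDuplicated(probands$proband_id)) {
    stop("proband ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(probands$suture), SUTURE_CLASSES)
  if (length(bad)) {
    stop("unknown suture class(es): ", paste(bad, collapse = ", "),
         "; accepted values are: ", paste(SUTURE_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  suture <- factor(probands$suture, levels = SUTURE_CLASSES)
  cell <- function(mask) {
    total <- as.integer(table(suture[mask]))
    pos <- as.integer(table(suture[mask & probands$gene_positive]))
    list(total = c(total, sum(total)), positive = c(pos, sum(pos)))
  }
  nonsyn <- cell(!probands$syndromic)
  syn <- cell(probands$syndromic)
  comb <- list(total = nonsyn$total + syn$total,
               positive = nonsyn$positive + syn$positive)
  pct <- function(g) ifelse(g$total > 0, g$positive / g$total * 100, NA_real_)
  data.frame(
    suture = c(SUTURE_CLASSES, "combined"),
    nonsyndromic_total = nonsyn$total,
    nonsyndromic_positive = nonsyn$positive,
    nonsyndromic_percent = pct(nonsyn),
    syndromic_total = syn$total,
    syndromic_positive = syn$positive,
    syndromic_percent = pct(syn),
    combined_total = comb$total,
    combined_positive = comb$positive,
    combined_percent = pct(comb),
    stringsAsFactors = FALSE
  )
}

#' Fisher's exact test for a 2x2 table, with fixed tail conventions
#'
#' Exact hypergeometric test with the margins fixed. `"one_tailed"` sums the
#' tail in the direction of the observed association; `"greater"` and
#' `"less"` fix the direction a priori (association of row 1 with column 1).
#' `"two_tailed"` sums the probabilities of all tables with the same margins
#' whose point probability does not exceed that of the observed table — the
#' convention of mainstream statistical software.
#'
#' A table with a zero margin carries no information; it returns P = 1 with
#' a `"degenerate"` attribute rather than an error.
#'
#' @param x A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @param sided One of `"two_tailed"`, `"one_tailed"`, `"greater"`, `"less"`.
#' @return A single P value in (0, 1\].
#' @export
#' @examples
#' fisher_exact(c(2, 0, 0, 2), "one_tailed")   # 1/6
#' fisher_exact(c(15, 1, 6, 19), "greater")    # 1.1e-05
fisher_exact <- function(x, sided = c("two_tailed", "one_tailed",
                                      "greater", "less")) {
  sided <- match.arg(sided)
  m <- as_table_2x2(x)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(structure(1, degenerate = "zero margin: table carries no information"))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  if (sided == "one_tailed") {
    expected_a <- r1 * c1 / (r1 + r2)
    sided <- if (a >= expected_a) "greater" else "less"
  }
  p <- switch(sided,
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]),
    two_tailed = sum(probs[probs <= p_obs * (1 + 1e-7)])
  )
  min(p, 1)
}

as_table_2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    m <- x
  } else {
    stopifnot(length(x) == 4L)
    m <- matrix(x, nrow = 2, byrow = TRUE)
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("2x2 table entries must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Loss-of-function burden enrichment against a reference population
#'
#' Fold enrichment of a count rate in cases over a reference population
#' (e.g. LoF carrier chromosomes in a disease cohort vs gnomAD), with a
#' one-tailed Fisher's exact P value for the excess. Denominators are on
#' whatever scale the counts are — for heterozygous carriers compared with
#' population allele counts, use allele denominators (2 x probands).
#'
#' @param case_count,case_denominator Counts in the case cohort.
#' @param ref_count,ref_denominator Counts in the reference population.
#' @return An object of class `enrichment_result`: list with `fold`
#'   (`Inf` with a note when the reference rate is zero), `p_value`
#'   (one-tailed, direction case > reference), and `table` (the 2x2 matrix
#'   tested).
#' @export
#' @examples
#' lof_enrichment(9, 2 * 795, 9, 29066)   # ~18.3-fold
lof_enrichment <- function(case_count, case_denominator, ref_count,
                           ref_denominator) {
  stopifnot(case_count >= 0, ref_count >= 0,
            case_denominator > 0, ref_denominator > 0,
            case_count <= case_denominator, ref_count <= ref_denominator)
  tab <- matrix(c(case_count, case_denominator - case_count,
                  ref_count, ref_denominator - ref_count),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "reference"),
                                c("count", "remainder")))
  case_rate <- case_count / case_denominator
  ref_rate <- ref_count / ref_denominator
  note <- NULL
  if (ref_rate == 0) {
    fold <- Inf
    note <- "reference rate is zero: fold enrichment undefined (+Inf)"
  } else {
    fold <- case_rate / ref_rate
  }
  structure(
    list(fold = fold, p_value = fisher_exact(tab, "greater"),
         table = tab, note = note),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %s-fold, one-tailed Fisher P = %s\n",
              format_fold(x$fold), format_p(x$p_value)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  print(x$table)
  invisible(x)
}

#' Rate contrast between two cohort subtypes
#'
#' Ratio of gene-positive rates between two subgroups (e.g. metopic vs
#' sagittal synostosis) with a two-tailed Fisher's exact P value.
#'
#' @param pos_a,n_a Positives and total in group A.
#' @param pos_b,n_b Positives and total in group B.
#' @return A list with `rate_ratio` (`Inf` with a note if group B has no
#'   positives), `p_two_tailed` and `table`.
#' @export
#' @examples
#' subtype_contrast(12, 207, 3, 316)   # 6.1-fold, P = 0.002
subtype_contrast <- function(pos_a, n_a, pos_b, n_b) {
  stopifnot(pos_a >= 0, pos_b >= 0, n_a > 0, n_b > 0,
            pos_a <= n_a, pos_b <= n_b)
  tab <- matrix(c(pos_a, n_a - pos_a, pos_b, n_b - pos_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("positive", "negative")))
  note <- NULL
  if (pos_b == 0) {
    ratio <- Inf
    note <- "group B rate is zero: rate ratio undefined (+Inf)"
  } else {
    ratio <- (pos_a / n_a) / (pos_b / n_b)
  }
  list(rate_ratio = ratio, p_two_tailed = fisher_exact(tab, "two_tailed"),
       table = tab, note = note)
}

#' Spearman rank correlation with midranks for ties
#'
#' Thin, convention-fixing wrapper: decreasing y with increasing x gives a
#' negative coefficient; ties receive midranks. A constant vector leaves the
#' coefficient undefined (NA with a warning) rather than raising an error.
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return Spearman's rho in \[-1, 1\], or NA when undefined.
#' @export
rank_correlation <- function(xs, ys) {
  stopifnot(is.numeric(xs), is.numeric(ys))
  if (length(xs) != length(ys)) {
    stop("xs and ys must have equal length", call. = FALSE)
  }
  if (length(xs) < 3L) {
    stop("rank correlation needs at least 3 observations", call. = FALSE)
  }
  if (length(unique(xs)) == 1L || length(unique(ys)) == 1L) {
    warning("rank correlation undefined for a constant vector; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(xs, ys, method = "spearman")
}
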