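## Pedigrees are plain data frames, one row per individual, with columns
## family_id, individual_id, father_id, mother_id, sex (1 = male, 2 =
## female, 0 = unknown), affected ("affected"/"unaffected"/"unknown"),
## carrier ("carrier"/"noncarrier"/"unknown") for the major-gene variant,
## optional suture, and modifier_genotype ("CC"/"CT"/"TT"/"unknown") for
## the modifier SNP (risk allele C). "0" in father_id/mother_id means the
## parent is absent (PED convention). See read_pedigree().

AFFECTED_LEVELS <- c("affected", "unaffected", "unknown")
CARRIER_LEVELS <- c("carrier", "noncarrier", "unknown")
GENOTYPE_LEVELS <- c("CC", "CT", "TT", "unknown")

validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  required <- c("family_id", "individual_id", "father_id", "mother_id",
                "affected", "carrier")
  missing_cols <- setdiff(required, names(ped))
  if (length(missing_cols)) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(ped$family_id, ped$individual_id)
  if (anyDuplicated(key)) {
    stop("duplicate individual id(s) within a family: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  self_parent <- ped$individual_id == ped$father_id |
    ped$individual_id == ped$mother_id
  if (any(self_parent)) {
    stop("individual(s) listed as their own parent: ",
         paste(ped$individual_id[self_parent], collapse = ", "), call. = FALSE)
  }
  invisible(ped)
}

## rows of ped (one family) that have at least one in-family parent link
offspring_rows <- function(fam) {
  fam$father_id %in% fam$individual_id | fam$mother_id %in% fam$individual_id
}

## look up a parent row by id; returns NULL when absent ("0" or not listed)
parent_row <- function(fam, id) {
  if (is.na(id) || id == "0" || !id %in% fam$individual_id) return(NULL)
  fam[fam$individual_id == id, , drop = FALSE]
}

## first affected carrier offspring of a family (the designated proband)
proband_row <- function(fam) {
  off <- fam[offspring_rows(fam), , drop = FALSE]
  hit <- off$affected == "affected" & off$carrier == "carrier"
  if (!any(hit)) return(NULL)
  off[which(hit)[1L], , drop = FALSE]
}

#' Classify the parental origin of each family's variant
#'
#' For each family the designated proband is the first affected carrier
#' offspring. The variant is de novo when both parents are known
#' noncarriers, maternal/paternal when exactly the mother/father carries it,
#' and of unknown origin when no parent is a known carrier but at least one
#' parent is missing or of unknown carrier status. Families in which both
#' parents carry the variant are surfaced as anomalies and counted
#' separately, never silently assigned.
#'
#' @param ped Pedigree data frame (see [read_pedigree()]).
#' @return An object of class `transmission_summary`: list with integer
#'   counts `de_novo`, `maternal`, `paternal`, `unknown_origin`,
#'   `both_parents_carriers`, and `n_families` (their sum). Families without
#'   an affected carrier offspring are skipped with a warning.
#' @export
summarize_transmission <- function(ped) {
  validate_pedigree(ped)
  counts <- c(de_novo = 0L, maternal = 0L, paternal = 0L,
              unknown_origin = 0L, both_parents_carriers = 0L)
  skipped <- character()
  for (fid in unique(ped$family_id)) {
    fam <- ped[ped$family_id == fid, , drop = FALSE]
    pro <- proband_row(fam)
    if (is.null(pro)) {
      skipped <- c(skipped, fid)
      next
    }
    fa <- parent_row(fam, pro$father_id)
    mo <- parent_row(fam, pro$mother_id)
    fa_status <- if (is.null(fa) || is.na(fa$carrier)) "unknown" else fa$carrier
    mo_status <- if (is.null(mo) || is.na(mo$carrier)) "unknown" else mo$carrier
    cls <- if (fa_status == "carrier" && mo_status == "carrier") {
      "both_parents_carriers"
    } else if (mo_status == "carrier") {
      "maternal"
    } else if (fa_status == "carrier") {
      "paternal"
    } else if (fa_status == "noncarrier" && mo_status == "noncarrier") {
      "de_novo"
    } else {
      "unknown_origin"
    }
    counts[cls] <- counts[cls] + 1L
  }
  if (length(skipped)) {
    warning("family(ies) without an affected carrier offspring skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  structure(c(as.list(counts), list(n_families = sum(counts))),
            class = "transmission_summary")
}

#' @export
print.transmission_summary <- function(x, ...) {
  cat("Variant origin across", x$n_families, "families:\n")
  cat(sprintf("  de novo: %d   maternal: %d   paternal: %d   unknown origin: %d\n",
              x$de_novo, x$maternal, x$paternal, x$unknown_origin))
  if (x$both_parents_carriers > 0) {
    cat("  ANOMALY - both parents carriers:", x$both_parents_carriers, "\n")
  }
  invisible(x)
}

#' Sib recurrence risk
#'
#' Fraction of additional (non-proband) offspring of transmitting parents
#' who are affected.
#'
#' @param affected_additional Affected offspring beyond the probands.
#' @param total_offspring Total offspring beyond the probands (> 0).
#' @return Recurrence risk in \[0, 1\].
#' @export
#' @examples
#' sib_recurrence(2, 25)  # 0.08
sib_recurrence <- function(affected_additional, total_offspring) {
  stopifnot(length(affected_additional) == 1L, length(total_offspring) == 1L)
  if (is.na(total_offspring) || total_offspring <= 0) {
    stop("total_offspring must be positive", call. = FALSE)
  }
  if (affected_additional < 0 || affected_additional > total_offspring) {
    stop("affected_additional must lie in [0, total_offspring]", call. = FALSE)
  }
  affected_additional / total_offspring
}

#' Count additional offspring of carrier parents in a pedigree
#'
#' Restricts to families whose proband's variant was parentally transmitted
#' (mother or father is a known carrier), drops the proband, and counts the
#' remaining offspring of that couple and how many of them are affected —
#' the inputs to [sib_recurrence()].
#'
#' @param ped Pedigree data frame.
#' @return List with `affected_additional`, `total_offspring` and
#'   `n_transmitting_families`.
#' @export
sib_recurrence_counts <- function(ped) {
  validate_pedigree(ped)
  affected_additional <- 0L
  total <- 0L
  n_fam <- 0L
  for (fid in unique(ped$family_id)) {
    fam <- ped[ped$family_id == fid, , drop = FALSE]
    pro <- proband_row(fam)
    if (is.null(pro)) next
    fa <- parent_row(fam, pro$father_id)
    mo <- parent_row(fam, pro$mother_id)
    carrier_parent <- (!is.null(fa) && fa$carrier == "carrier") ||
      (!is.null(mo) && mo$carrier == "carrier")
    if (!carrier_parent) next
    n_fam <- n_fam + 1L
    sibs <- fam[offspring_rows(fam) & fam$individual_id != pro$individual_id, ,
                drop = FALSE]
    total <- total + nrow(sibs)
    affected_additional <- affected_additional + sum(sibs$affected == "affected")
  }
  list(affected_additional = affected_additional, total_offspring = total,
       n_transmitting_families = n_fam)
}

#' Penetrance from sib recurrence under a transmission assumption
#'
#' When unaffected offspring are not genotyped, penetrance cannot be read
#' off carrier status directly; under Mendelian transmission each offspring
#' of a heterozygous carrier parent inherits the variant with probability
#' 0.5, so the recurrence risk among all offspring is transmission x
#' penetrance and penetrance = recurrence / transmission. Estimates
#' exceeding 1 are capped with a warning. Note the estimate inherits any
#' ascertainment bias present in the recurrence counts.
#'
#' @param recurrence Sib recurrence risk in \[0, 1\].
#' @param transmission_prob Transmission probability in (0, 1\] (default 0.5,
#'   heterozygous carrier parent).
#' @param counts Optional list with `affected_additional` and
#'   `total_offspring` (e.g. from [sib_recurrence_counts()]), carried along
#'   for reporting.
#' @return Object of class `penetrance_estimate`: list with `recurrence`,
#'   `transmission_prob`, `penetrance`, `capped`, `counts`.
#' @export
#' @examples
#' estimate_penetrance(sib_recurrence(2, 25))  # penetrance 0.16
estimate_penetrance <- function(recurrence, transmission_prob = 0.5,
                                counts = NULL) {
  stopifnot(length(recurrence) == 1L, recurrence >= 0, recurrence <= 1)
  if (is.na(transmission_prob) || transmission_prob <= 0 || transmission_prob > 1) {
    stop("transmission_prob must lie in (0, 1]", call. = FALSE)
  }
  penetrance <- recurrence / transmission_prob
  capped <- penetrance > 1
  if (capped) {
    warning("penetrance estimate ", signif(penetrance, 3),
            " exceeds 1; capped at 1", call. = FALSE)
    penetrance <- 1
  }
  structure(
    list(recurrence = recurrence, transmission_prob = transmission_prob,
         penetrance = penetrance, capped = capped, counts = counts),
    class = "penetrance_estimate"
  )
}

#' @export
print.penetrance_estimate <- function(x, ...) {
  cat(sprintf("Penetrance ~%s (recurrence %s / transmission %s)%s\n",
              format_percent(x$penetrance * 100, 0),
              signif(x$recurrence, 3), x$transmission_prob,
              if (x$capped) " [capped at 1]" else ""))
  if (!is.null(x$counts)) {
    cat(sprintf("  from %d affected of %d additional offspring\n",
                x$counts$affected_additional, x$counts$total_offspring))
  }
  invisible(x)
}

#' Transmission disequilibrium test
#'
#' McNemar-type chi-square on transmitted vs untransmitted alleles from
#' heterozygous parents to affected offspring: chi2 = (b - c)^2 / (b + c)
#' with 1 df, no continuity correction; symmetric in its arguments.
#'
#' @param transmitted,untransmitted Non-negative allele counts, sum > 0.
#' @return List with `chi_square`, `p_value`, `transmitted`, `untransmitted`.
#' @export
#' @examples
#' tdt(12, 7)  # chi2 = 1.32, P = 0.25
tdt <- function(transmitted, untransmitted) {
  stopifnot(transmitted >= 0, untransmitted >= 0)
  n <- transmitted + untransmitted
  if (n == 0) {
    stop("tdt requires at least one informative transmission", call. = FALSE)
  }
  chi <- (transmitted - untransmitted)^2 / n
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       transmitted = transmitted, untransmitted = untransmitted)
}

genotype_c_count <- function(g) {
  switch(g, CC = 2L, CT = 1L, TT = 0L, NA_integer_)
}

## possible number of risk (C) alleles a parent can contribute
contribution_set <- function(g) {
  switch(g, CC = 1L, TT = 0L, CT = c(0L, 1L), c(0L, 1L))  # unknown: 0 or 1
}

#' Count transmitted vs untransmitted risk alleles for the TDT
#'
#' Walks every affected offspring with a known modifier genotype and, for
#' each heterozygous (CT) parent, infers which allele that parent
#' transmitted whenever the offspring genotype and the other parent's
#' possible contribution pin it down. Ambiguous configurations (e.g. both
#' parents CT with a CT offspring) are reported as unresolved, never
#' guessed. Trios whose genotypes admit no Mendelian solution are flagged
#' and skipped.
#'
#' @param ped Pedigree data frame with a `modifier_genotype` column.
#' @return List with `transmitted` (risk C alleles), `untransmitted`
#'   (T alleles), `unresolved` (offspring with >= 1 undeterminable
#'   heterozygous-parent transmission) and `mendelian_errors` (character
#'   vector of offending offspring ids).
#' @export
count_tdt_alleles <- function(ped) {
  validate_pedigree(ped)
  if (!"modifier_genotype" %in% names(ped)) {
    stop("pedigree has no modifier_genotype column", call. = FALSE)
  }
  transmitted <- 0L
  untransmitted <- 0L
  unresolved <- 0L
  mendel <- character()
  for (fid in unique(ped$family_id)) {
    fam <- ped[ped$family_id == fid, , drop = FALSE]
    kids <- fam[offspring_rows(fam) & fam$affected == "affected", , drop = FALSE]
    for (k in seq_len(nrow(kids))) {
      kid <- kids[k, , drop = FALSE]
      kid_c <- genotype_c_count(kid$modifier_genotype)
      if (is.na(kid_c)) next
      fa <- parent_row(fam, kid$father_id)
      mo <- parent_row(fam, kid$mother_id)
      g_fa <- if (is.null(fa) || is.na(fa$modifier_genotype)) "unknown" else fa$modifier_genotype
      g_mo <- if (is.null(mo) || is.na(mo$modifier_genotype)) "unknown" else mo$modifier_genotype
      if (g_fa != "CT" && g_mo != "CT") next  # no informative parent
      set_fa <- contribution_set(g_fa)
      set_mo <- contribution_set(g_mo)
      sols <- expand.grid(fa = set_fa, mo = set_mo)
      sols <- sols[sols$fa + sols$mo == kid_c, , drop = FALSE]
      if (nrow(sols) == 0L) {
        mendel <- c(mendel, kid$individual_id)
        next
      }
      ambiguous <- FALSE
      for (side in c("fa", "mo")) {
        if ((if (side == "fa") g_fa else g_mo) != "CT") next
        vals <- unique(sols[[side]])
        if (length(vals) == 1L) {
          if (vals == 1L) transmitted <- transmitted + 1L
          else untransmitted <- untransmitted + 1L
        } else {
          ambiguous <- TRUE
        }
      }
      if (ambiguous) unresolved <- unresolved + 1L
    }
  }
  if (length(mendel)) {
    warning("Mendelian inconsistency in trio(s) of offspring: ",
            paste(mendel, collapse = ", "), "; excluded from the count",
            call. = FALSE)
  }
  list(transmitted = transmitted, untransmitted = untransmitted,
       unresolved = unresolved, mendelian_errors = mendel)
}

#' Two-locus association table: modifier risk allele vs affection in carriers
#'
#' Dichotomises major-gene carriers by presence of the modifier risk allele
#' (dominant coding: CC or CT vs TT) against affection status, and computes
#' a one-tailed Fisher's exact P for the a-priori direction "risk allele
#' increases the probability of manifesting disease". Individuals with
#' unknown affection or genotype are excluded and counted.
#'
#' @param individuals Pedigree-style data frame rows; only rows with
#'   `carrier == "carrier"` are used (others are dropped with a message in
#'   the result).
#' @return Object of class `two_locus_table`: list with `table` (2x2 matrix,
#'   rows risk allele present/absent, columns affected/unaffected),
#'   `p_one_tailed`, `n_included`, `n_excluded`, and `note` for degenerate
#'   tables.
#' @export
two_locus_table <- function(individuals) {
  stopifnot(is.data.frame(individuals),
            all(c("carrier", "affected", "modifier_genotype") %in%
                  names(individuals)))
  carriers <- individuals[individuals$carrier == "carrier", , drop = FALSE]
  usable <- carriers$affected %in% c("affected", "unaffected") &
    carriers$modifier_genotype %in% c("CC", "CT", "TT")
  inc <- carriers[usable, , drop = FALSE]
  risk <- inc$modifier_genotype %in% c("CC", "CT")
  aff <- inc$affected == "affected"
  tab <- matrix(c(sum(risk & aff), sum(risk & !aff),
                  sum(!risk & aff), sum(!risk & !aff)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("risk_allele_present", "risk_allele_absent"),
                                c("affected", "unaffected")))
  p <- fisher_exact(tab, "greater")
  note <- attr(p, "degenerate")
  structure(
    list(table = tab, p_one_tailed = as.numeric(p),
         n_included = nrow(inc), n_excluded = nrow(carriers) - nrow(inc),
         note = note),
    class = "two_locus_table"
  )
}

#' Merge two two-locus association tables
#'
#' Elementwise sum of two 2x2 tables with the same row/column semantics
#' (e.g. this study's counts with a previously published study's), with the
#' one-tailed Fisher P recomputed on the merged counts. Associative and
#' commutative.
#'
#' @param t1,t2 `two_locus_table` objects or bare 2x2 matrices.
#' @return A `two_locus_table` for the summed counts.
#' @export
merge_two_locus <- function(t1, t2) {
  m1 <- if (inherits(t1, "two_locus_table")) t1$table else as_table_2x2(t1)
  m2 <- if (inherits(t2, "two_locus_table")) t2$table else as_table_2x2(t2)
  tab <- m1 + m2
  dimnames(tab) <- list(c("risk_allele_present", "risk_allele_absent"),
                        c("affected", "unaffected"))
  p <- fisher_exact(tab, "greater")
  structure(
    list(table = tab, p_one_tailed = as.numeric(p),
         n_included = sum(tab), n_excluded = NA_integer_,
         note = attr(p, "degenerate")),
    class = "two_locus_table"
  )
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat("Two-locus association (risk allele x affection in carriers)\n")
  print(x$table)
  cat(sprintf("one-tailed Fisher P = %s", format_p(x$p_one_tailed)))
  if (!is.null(x$note)) cat("  [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}
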