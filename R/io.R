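## Readers and writers for the pipeline's plain-text formats: TSV variant
## tables (gnomAD-style <POP>_ac/<POP>_an column pairs), PED pedigrees with
## a sidecar metadata TSV, and JSON/markdown result reports. TSV is UTF-8,
## tab-separated, unquoted, with NA for missing values.

#' Read a cohort variant table (TSV)
#'
#' Required columns: `variant_id`, `gene`, `consequence`, `overall_ac`,
#' `overall_an`. Per-population allele counts are auto-discovered from
#' `<POP>_ac` / `<POP>_an` column pairs; predictor score columns are taken
#' as named in the configuration. Rows violating AC <= AN are rejected with
#' line-numbered messages (line 1 = header), as are unknown consequence
#' classes — no silent coercion.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param config A [stratification_config()]; used only to warn when
#'   configured predictor columns are absent.
#' @return A variant table data frame.
#' @export
read_variant_table <- function(path, config = stratification_config()) {
  if (!file.exists(path)) {
    stop("variant table not found: ", path, call. = FALSE)
  }
  variants <- utils::read.delim(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE, quote = "",
                                na.strings = "NA", check.names = FALSE)
  required <- c("variant_id", "gene", "consequence", "overall_ac", "overall_an")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variant table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # all-NA optional identifier columns must stay character, not logical
  for (col in intersect(c("hgvs_c", "hgvs_p", "proband_id"), names(variants))) {
    variants[[col]] <- as.character(variants[[col]])
  }
  bad_cons <- !variants$consequence %in% CONSEQUENCE_CLASSES
  if (any(bad_cons)) {
    stop("unknown consequence class at line(s) ",
         paste(which(bad_cons) + 1L, collapse = ", "), " of ", path,
         "; accepted values are: ", paste(CONSEQUENCE_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  check_ac_an <- function(ac, an, label) {
    bad <- !is.na(ac) & !is.na(an) & (ac < 0 | an <= 0 | ac > an)
    if (any(bad)) {
      stop("invalid ", label, " allele counts (need 0 <= AC <= AN, AN > 0) ",
           "at line(s) ", paste(which(bad) + 1L, collapse = ", "),
           " of ", path, call. = FALSE)
    }
  }
  check_ac_an(variants$overall_ac, variants$overall_an, "overall")
  for (p in discover_populations(variants)) {
    check_ac_an(variants[[paste0(p, "_ac")]], variants[[paste0(p, "_an")]], p)
  }
  absent <- setdiff(config$predictors$name, names(variants))
  if (length(absent) && length(absent) < nrow(config$predictors)) {
    warning("predictor column(s) absent from ", path, ": ",
            paste(absent, collapse = ", "),
            "; they will count as unavailable", call. = FALSE)
  }
  variants
}

#' Write a variant table (TSV)
#'
#' Inverse of [read_variant_table()]: tab-separated, header, `NA` for
#' missing, no quoting.
#'
#' @param variants Variant table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pedigree (PED + sidecar metadata TSV)
#'
#' The PED file is the standard headerless six-column format (family_id,
#' individual_id, father_id, mother_id, sex, affection) with `0` denoting a
#' missing parent, sex 1 = male / 2 = female / 0 = unknown, and affection
#' 2 = affected / 1 = unaffected / 0 or -9 = unknown. The sidecar TSV has a
#' header and is keyed by `individual_id`, with columns `carrier`
#' (carrier/noncarrier/unknown), optional `suture` and `modifier_genotype`
#' (CC/CT/TT/unknown). Individuals present in the sidecar but not in the
#' PED file trigger a warning; duplicated ids, self-parentage and cyclic
#' parentage are errors.
#'
#' @param ped_path Path to the PED file.
#' @param meta_path Optional path to the sidecar TSV; when `NULL`, carrier
#'   and genotype columns are filled with `"unknown"`.
#' @return A pedigree data frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affected`, `carrier`, `suture`,
#'   `modifier_genotype`.
#' @export
read_pedigree <- function(ped_path, meta_path = NULL) {
  if (!file.exists(ped_path)) {
    stop("pedigree file not found: ", ped_path, call. = FALSE)
  }
  ped6 <- utils::read.table(ped_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  if (ncol(ped6) < 6L) {
    stop("PED file ", ped_path, " must have at least 6 columns ",
         "(family, individual, father, mother, sex, affection)", call. = FALSE)
  }
  ped <- data.frame(
    family_id = ped6[[1]],
    individual_id = ped6[[2]],
    father_id = ped6[[3]],
    mother_id = ped6[[4]],
    sex = suppressWarnings(as.integer(ped6[[5]])),
    affected = unname(c("1" = "unaffected", "2" = "affected")[ped6[[6]]]),
    stringsAsFactors = FALSE
  )
  ped$affected[is.na(ped$affected)] <- "unknown"

  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) {
      stop("pedigree metadata file not found: ", meta_path, call. = FALSE)
    }
    meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "",
                              na.strings = "NA")
    if (!"individual_id" %in% names(meta)) {
      stop("pedigree metadata must have an individual_id column", call. = FALSE)
    }
    orphans <- setdiff(meta$individual_id, ped$individual_id)
    if (length(orphans)) {
      warning("individual(s) in metadata but not in PED file: ",
              paste(orphans, collapse = ", "), call. = FALSE)
    }
    idx <- match(ped$individual_id, meta$individual_id)
    for (col in c("carrier", "suture", "modifier_genotype")) {
      ped[[col]] <- if (col %in% names(meta)) as.character(meta[[col]][idx])
                    else NA_character_
    }
  } else {
    ped$carrier <- "unknown"
    ped$suture <- NA_character_
    ped$modifier_genotype <- "unknown"
  }
  ped$carrier[is.na(ped$carrier)] <- "unknown"
  ped$modifier_genotype[is.na(ped$modifier_genotype)] <- "unknown"

  bad_carrier <- setdiff(unique(ped$carrier), CARRIER_LEVELS)
  if (length(bad_carrier)) {
    stop("invalid carrier value(s): ", paste(bad_carrier, collapse = ", "),
         "; accepted: ", paste(CARRIER_LEVELS, collapse = ", "), call. = FALSE)
  }
  bad_geno <- setdiff(unique(ped$modifier_genotype), GENOTYPE_LEVELS)
  if (length(bad_geno)) {
    stop("invalid modifier_genotype value(s): ",
         paste(bad_geno, collapse = ", "),
         "; accepted: ", paste(GENOTYPE_LEVELS, collapse = ", "), call. = FALSE)
  }
  validate_pedigree(ped)
  check_acyclic(ped)
  ped
}

## walk parent links; a repeat visit within one walk means a cycle.
## ids are only unique within a family, so walk each family separately
check_acyclic <- function(ped) {
  for (fid in unique(ped$family_id)) {
    check_acyclic_family(ped[ped$family_id == fid, , drop = FALSE])
  }
  invisible(TRUE)
}

check_acyclic_family <- function(ped) {
  parent_of <- stats::setNames(
    paste(ped$father_id, ped$mother_id, sep = "\r"), ped$individual_id)
  for (start in ped$individual_id) {
    frontier <- start
    seen <- character()
    while (length(frontier)) {
      seen <- c(seen, frontier)
      parents <- unlist(strsplit(parent_of[frontier[frontier %in% names(parent_of)]],
                                 "\r", fixed = TRUE), use.names = FALSE)
      frontier <- setdiff(parents[parents != "0" & !is.na(parents)], "0")
      hit <- intersect(frontier, seen)
      if (length(hit)) {
        stop("cyclic parentage involving individual(s): ",
             paste(hit, collapse = ", "), call. = FALSE)
      }
      frontier <- frontier[frontier %in% names(parent_of)]
    }
  }
  invisible(TRUE)
}

#' Write a pedigree as PED + sidecar metadata TSV
#'
#' @param ped Pedigree data frame (see [read_pedigree()]).
#' @param ped_path,meta_path Output paths.
#' @return `ped_path`, invisibly.
#' @export
write_pedigree <- function(ped, ped_path, meta_path) {
  affection <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affected]
  ped6 <- data.frame(ped$family_id, ped$individual_id, ped$father_id,
                     ped$mother_id, ped$sex, affection)
  utils::write.table(ped6, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- data.frame(individual_id = ped$individual_id,
                     carrier = ped$carrier,
                     suture = ped$suture,
                     modifier_genotype = ped$modifier_genotype,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(ped_path)
}

#' Formatters matching reporting precision conventions
#'
#' Fold changes print to 1 decimal place, P values to 2 significant
#' figures, percentages to a configurable number of decimals (2 in tables,
#' 1 in prose).
#'
#' @param x,p Numeric values.
#' @param digits Decimal places for percentages.
#' @return Character vector.
#' @export
format_fold <- function(x) {
  ifelse(is.infinite(x), "Inf", formatC(x, format = "f", digits = 1))
}

#' @rdname format_fold
#' @export
format_p <- function(p) {
  out <- signif(p, 2)
  ifelse(out >= 1e-4, formatC(out, format = "fg", digits = 2, flag = "#"),
         formatC(out, format = "g", digits = 2))
}

#' @rdname format_fold
#' @export
format_percent <- function(x, digits = 2) {
  paste0(formatC(x, format = "f", digits = digits), "%")
}

#' Write an analysis report bundle (JSON, optionally markdown)
#'
#' Serialises a named list of results to JSON with full numeric precision
#' (every statistic remains recomputable from its raw counts, which the
#' result objects carry), plus an optional human-readable markdown summary
#' using the standard precision conventions ([format_fold()] etc.).
#'
#' @param results Named list of result objects (tables, enrichment results,
#'   penetrance estimates, plain values).
#' @param path Output path for the JSON report.
#' @param markdown_path Optional path for a markdown rendering.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, markdown_path = NULL) {
  stopifnot(is.list(results))
  strip <- function(x) {
    if (is.matrix(x)) return(apply(x, 1, as.vector, simplify = FALSE))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(lapply(results, strip), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(markdown_path)) {
    lines <- c("# Analysis report", "")
    for (nm in names(results)) {
      lines <- c(lines, paste0("## ", nm), "",
                 utils::capture.output(print(results[[nm]])), "")
    }
    writeLines(lines, markdown_path)
  }
  invisible(path)
}
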