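# Fixture builders and independent oracles shared across the test files.
# Everything is constructed in code; no data files.

# ---- independent Fisher oracle: enumerate all tables with fixed margins,
# probabilities from binomial coefficients (not dhyper) -------------------
oracle_fisher <- function(a, b, c, d, sided) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  }, numeric(1))
  p_obs <- prob[support == a]
  switch(sided,
    greater = sum(prob[support >= a]),
    less = sum(prob[support <= a]),
    two_tailed = sum(prob[prob <= p_obs * (1 + 1e-7)])
  )
}

# ---- brute-force DS recount --------------------------------------------
oracle_ds <- function(scores, predictors) {
  count <- 0L
  avail <- 0L
  for (i in seq_len(nrow(predictors))) {
    s <- scores[[predictors$name[i]]]
    if (is.null(s) || is.na(s)) next
    avail <- avail + 1L
    hit <- if (predictors$higher_is_deleterious[i]) s >= predictors$threshold[i]
           else s <= predictors$threshold[i]
    if (hit) count <- count + 1L
  }
  list(ds = count, n_available = avail)
}

# ---- brute-force uATG scan: all ATG start offsets in a sequence --------
atg_offsets <- function(seq_chars) {
  n <- length(seq_chars)
  if (n < 3) return(integer())
  starts <- seq_len(n - 2) - 1L
  starts[vapply(starts, function(s) {
    identical(seq_chars[(s + 1):(s + 3)], c("A", "T", "G"))
  }, logical(1))]
}

oracle_uatg <- function(utr, position, ref, alt, cds_offset) {
  before <- strsplit(utr, "")[[1]]
  after <- before
  after[position + 1] <- alt
  new_atg <- setdiff(atg_offsets(after), atg_offsets(before))
  new_atg <- new_atg[new_atg <= position & new_atg + 2 >= position]
  if (!length(new_atg)) {
    return(list(creates_uatg = FALSE, in_frame_with_main_orf = NA))
  }
  dist <- (position + cds_offset) - new_atg[1]
  list(creates_uatg = TRUE, in_frame_with_main_orf = dist %% 3 == 0)
}

# ---- pedigree builders --------------------------------------------------
# members: list of lists with fields id, role ("father"/"mother"/"child"),
# carrier, affected, geno (modifier genotype); parents optional.
make_family <- function(fid, members) {
  has_fa <- any(vapply(members, function(m) m$role == "father", logical(1)))
  has_mo <- any(vapply(members, function(m) m$role == "mother", logical(1)))
  rows <- lapply(members, function(m) {
    data.frame(
      family_id = fid,
      individual_id = paste0(fid, "_", m$id),
      father_id = if (m$role == "child" && has_fa) paste0(fid, "_FA") else "0",
      mother_id = if (m$role == "child" && has_mo) paste0(fid, "_MO") else "0",
      sex = switch(m$role, father = 1L, mother = 2L, 0L),
      affected = if (is.null(m$affected)) "unknown" else m$affected,
      carrier = if (is.null(m$carrier)) "unknown" else m$carrier,
      suture = NA_character_,
      modifier_genotype = if (is.null(m$geno)) "unknown" else m$geno,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# nuclear trio shortcut: one child, roles fixed
make_trio <- function(fid, fa_carrier, mo_carrier, child_carrier = "carrier",
                      child_affected = "affected", fa_geno = "unknown",
                      mo_geno = "unknown", child_geno = "unknown") {
  make_family(fid, list(
    list(id = "FA", role = "father", carrier = fa_carrier,
         affected = "unaffected", geno = fa_geno),
    list(id = "MO", role = "mother", carrier = mo_carrier,
         affected = "unaffected", geno = mo_geno),
    list(id = "C1", role = "child", carrier = child_carrier,
         affected = child_affected, geno = child_geno)
  ))
}

# cohort-aggregate transmission fixture: 3 de novo, 11 maternal, 9 paternal,
# 3 unknown-origin families
transmission_fixture <- function() {
  fams <- list()
  k <- 0
  add <- function(ped) { k <<- k + 1; fams[[k]] <<- ped }
  for (i in 1:3) add(make_trio(sprintf("DN%02d", i), "noncarrier", "noncarrier"))
  for (i in 1:11) add(make_trio(sprintf("MA%02d", i), "noncarrier", "carrier"))
  for (i in 1:9) add(make_trio(sprintf("PA%02d", i), "carrier", "noncarrier"))
  for (i in 1:3) {
    # one parent unavailable, the other a noncarrier
    add(make_family(sprintf("UN%02d", i), list(
      list(id = "MO", role = "mother", carrier = "noncarrier",
           affected = "unaffected"),
      list(id = "C1", role = "child", carrier = "carrier",
           affected = "affected")
    )))
  }
  do.call(rbind, fams)
}

# carrier individuals realising given two-locus cell counts
two_locus_fixture <- function(risk_affected, risk_unaffected,
                              norisk_affected, norisk_unaffected) {
  n <- risk_affected + risk_unaffected + norisk_affected + norisk_unaffected
  data.frame(
    family_id = sprintf("T%03d", seq_len(n)),
    individual_id = sprintf("T%03d_I", seq_len(n)),
    father_id = "0", mother_id = "0", sex = 0L,
    affected = rep(c("affected", "unaffected", "affected", "unaffected"),
                   c(risk_affected, risk_unaffected,
                     norisk_affected, norisk_unaffected)),
    carrier = "carrier",
    suture = NA_character_,
    modifier_genotype = {
      n_risk <- risk_affected + risk_unaffected
      c(rep("CT", max(0, n_risk - 1)), rep("CC", min(1, n_risk)),
        rep("TT", norisk_affected + norisk_unaffected))
    },
    stringsAsFactors = FALSE
  )
}

# families whose heterozygous-parent transmissions yield the given C/T counts
tdt_fixture <- function(n_c_transmitted, n_t_transmitted) {
  fams <- lapply(seq_len(n_c_transmitted + n_t_transmitted), function(i) {
    child_geno <- if (i <= n_c_transmitted) "CT" else "TT"
    make_trio(sprintf("TD%02d", i), "carrier", "noncarrier",
              fa_geno = "CT", mo_geno = "TT", child_geno = child_geno)
  })
  do.call(rbind, fams)
}

# proband table realising the cohort's suture-by-status counts
cohort_probands <- function() {
  counts <- data.frame(
    suture = c("metopic", "sagittal", "unicoronal", "bicoronal",
               "lambdoid", "multisuture", "unspecified"),
    nonsyn_total = c(167, 279, 150, 11, 7, 35, 0),
    nonsyn_pos = c(9, 2, 1, 0, 0, 1, 0),
    syn_total = c(40, 37, 16, 11, 3, 29, 10),
    syn_pos = c(3, 1, 0, 0, 0, 1, 0),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (syn in c(FALSE, TRUE)) {
      total <- if (syn) counts$syn_total[i] else counts$nonsyn_total[i]
      pos <- if (syn) counts$syn_pos[i] else counts$nonsyn_pos[i]
      if (total == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        suture = counts$suture[i],
        syndromic = syn,
        gene_positive = rep(c(TRUE, FALSE), c(pos, total - pos)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$proband_id <- sprintf("CRS%04d", seq_len(nrow(out)))
  out
}

# minimal well-formed variant table rows
make_variant <- function(variant_id, consequence, overall_ac, overall_an,
                         nfe_ac = 0L, nfe_an = 100000L, ds_hits = 0L) {
  preds <- default_predictors()
  row <- data.frame(variant_id = variant_id, gene = "SMAD6",
                    consequence = consequence,
                    overall_ac = overall_ac, overall_an = overall_an,
                    NFE_ac = nfe_ac, NFE_an = nfe_an,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(preds))) {
    exceed <- i <= ds_hits
    delta <- if (exceed == preds$higher_is_deleterious[i]) 0.1 else -0.1
    row[[preds$name[i]]] <- preds$threshold[i] + delta
  }
  row
}
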