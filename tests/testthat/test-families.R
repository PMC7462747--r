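test_that("parental origin classification partitions the families", {
  # a single trio with two noncarrier parents is de novo
  trio <- make_trio("F01", "noncarrier", "noncarrier")
  s <- summarize_transmission(trio)
  expect_equal(s$de_novo, 1L)
  expect_equal(s$n_families, 1L)

  # cohort-scale fixture: 3 de novo, 11 maternal, 9 paternal, 3 unknown
  ped <- transmission_fixture()
  s <- summarize_transmission(ped)
  expect_equal(s$de_novo, 3L)
  expect_equal(s$maternal, 11L)
  expect_equal(s$paternal, 9L)
  expect_equal(s$unknown_origin, 3L)
  expect_equal(s$n_families, 26L)
  expect_equal(s$de_novo + s$maternal + s$paternal + s$unknown_origin +
                 s$both_parents_carriers, s$n_families)

  # empty input: all zeros
  s0 <- summarize_transmission(ped[0, ])
  expect_equal(s0$n_families, 0L)

  # both parents carriers is surfaced as an anomaly, never silently assigned
  anom <- make_trio("F99", "carrier", "carrier")
  s <- summarize_transmission(anom)
  expect_equal(s$both_parents_carriers, 1L)
  expect_equal(s$maternal + s$paternal + s$de_novo, 0L)
})

test_that("sib recurrence and penetrance follow the transmission arithmetic", {
  expect_equal(sib_recurrence(2, 25), 0.08)
  expect_equal(sib_recurrence(0, 10), 0)
  expect_equal(sib_recurrence(10, 10), 1)
  expect_error(sib_recurrence(1, 0), "positive")
  expect_error(sib_recurrence(5, 3), "\\[0, total_offspring\\]")

  pen <- estimate_penetrance(0.08, 0.5)
  expect_equal(pen$penetrance, 0.16)
  expect_equal(estimate_penetrance(0, 0.5)$penetrance, 0)
  expect_warning(capped <- estimate_penetrance(0.6, 0.5), "capped")
  expect_equal(capped$penetrance, 1)
  expect_true(capped$capped)
  expect_error(estimate_penetrance(0.1, 0), "transmission_prob")
})

test_that("sib recurrence counts restrict to transmitting families and drop the proband", {
  # carrier-mother family with proband + 2 sibs, one affected
  fam1 <- make_family("T01", list(
    list(id = "FA", role = "father", carrier = "noncarrier", affected = "unaffected"),
    list(id = "MO", role = "mother", carrier = "carrier", affected = "unaffected"),
    list(id = "C1", role = "child", carrier = "carrier", affected = "affected"),
    list(id = "C2", role = "child", carrier = "carrier", affected = "affected"),
    list(id = "C3", role = "child", carrier = "noncarrier", affected = "unaffected")
  ))
  # de novo family: its sibs must not count
  fam2 <- make_family("T02", list(
    list(id = "FA", role = "father", carrier = "noncarrier", affected = "unaffected"),
    list(id = "MO", role = "mother", carrier = "noncarrier", affected = "unaffected"),
    list(id = "C1", role = "child", carrier = "carrier", affected = "affected"),
    list(id = "C2", role = "child", carrier = "noncarrier", affected = "unaffected")
  ))
  counts <- sib_recurrence_counts(rbind(fam1, fam2))
  expect_equal(counts$n_transmitting_families, 1L)
  expect_equal(counts$total_offspring, 2L)
  expect_equal(counts$affected_additional, 1L)
})

test_that("TDT chi-square has no continuity correction and is symmetric", {
  res <- tdt(12, 7)
  expect_equal(res$chi_square, (12 - 7)^2 / 19)
  expect_equal(res$chi_square, 1.316, tolerance = 1e-3)
  expect_equal(round(res$p_value, 2), 0.25)

  # symmetry and the k = k null
  expect_equal(tdt(7, 12)$chi_square, res$chi_square)
  expect_equal(tdt(7, 12)$p_value, res$p_value)
  expect_equal(tdt(5, 5)$chi_square, 0)
  expect_equal(tdt(5, 5)$p_value, 1)
  expect_error(tdt(0, 0), "at least one")

  # exact binomial cross-check: same order of magnitude, both nonsignificant
  p_binom <- stats::binom.test(12, 19, 0.5)$p.value
  expect_gt(res$p_value, 0.05)
  expect_gt(p_binom, 0.05)
  expect_lt(abs(log10(res$p_value) - log10(p_binom)), 1)
})

test_that("TDT allele counting resolves transmissions by Mendelian logic", {
  # CT x TT, affected child CT: the C came from the het parent
  t1 <- make_trio("A01", "carrier", "noncarrier",
                  fa_geno = "CT", mo_geno = "TT", child_geno = "CT")
  res <- count_tdt_alleles(t1)
  expect_equal(res$transmitted, 1L)
  expect_equal(res$untransmitted, 0L)

  # CT x TT, affected child TT: the het parent sent T
  t2 <- make_trio("A02", "carrier", "noncarrier",
                  fa_geno = "CT", mo_geno = "TT", child_geno = "TT")
  res <- count_tdt_alleles(t2)
  expect_equal(res$transmitted, 0L)
  expect_equal(res$untransmitted, 1L)

  # both parents CT, child CT: ambiguous, counted as unresolved, not guessed
  t3 <- make_trio("A03", "carrier", "noncarrier",
                  fa_geno = "CT", mo_geno = "CT", child_geno = "CT")
  res <- count_tdt_alleles(t3)
  expect_equal(res$transmitted + res$untransmitted, 0L)
  expect_equal(res$unresolved, 1L)

  # both parents CT, child CC: both transmissions forced to C
  t4 <- make_trio("A04", "carrier", "noncarrier",
                  fa_geno = "CT", mo_geno = "CT", child_geno = "CC")
  res <- count_tdt_alleles(t4)
  expect_equal(res$transmitted, 2L)
  expect_equal(res$unresolved, 0L)

  # Mendelian inconsistency: CC x CT cannot produce TT
  t5 <- make_trio("A05", "carrier", "noncarrier",
                  fa_geno = "CC", mo_geno = "CT", child_geno = "TT")
  expect_warning(res <- count_tdt_alleles(t5), "Mendelian")
  expect_equal(res$transmitted + res$untransmitted, 0L)
  expect_match(res$mendelian_errors, "A05")

  # the 12 C / 7 T aggregate fixture feeds tdt() end to end
  ped <- tdt_fixture(12, 7)
  counts <- count_tdt_alleles(ped)
  expect_equal(counts$transmitted, 12L)
  expect_equal(counts$untransmitted, 7L)
  expect_equal(round(tdt(counts$transmitted, counts$untransmitted)$p_value, 2),
               0.25)
})

test_that("two-locus tables dichotomise carriers and fix the test direction", {
  this_work <- two_locus_table(two_locus_fixture(17, 12, 11, 8))
  expect_equal(unname(this_work$table),
               matrix(c(17, 12, 11, 8), 2, byrow = TRUE))
  expect_equal(round(this_work$p_one_tailed, 2), 0.60)
  expect_equal(this_work$n_included, 48)

  prior <- two_locus_table(two_locus_fixture(15, 1, 6, 19))
  expect_equal(prior$p_one_tailed, 1.1e-5, tolerance = 1e-2)

  # unknowns are excluded and counted; noncarriers never enter
  ind <- two_locus_fixture(3, 2, 2, 1)
  ind$modifier_genotype[1] <- "unknown"
  ind$affected[2] <- "unknown"
  extra <- ind[1, ]
  extra$individual_id <- "X_noncarrier"
  extra$family_id <- "X"
  extra$carrier <- "noncarrier"
  tl <- two_locus_table(rbind(ind, extra))
  expect_equal(tl$n_included + tl$n_excluded, nrow(ind))
  expect_equal(tl$n_excluded, 2)
  expect_equal(sum(tl$table), tl$n_included)

  # no risk-allele carriers at all: degenerate row, P = 1
  none <- two_locus_table(two_locus_fixture(0, 0, 4, 3))
  expect_equal(none$p_one_tailed, 1)
  expect_match(none$note, "zero margin")
})

test_that("merging two-locus tables sums cells and is associative/commutative", {
  a <- two_locus_table(two_locus_fixture(17, 12, 11, 8))
  b <- two_locus_table(two_locus_fixture(15, 1, 6, 19))
  m <- merge_two_locus(a, b)
  expect_equal(unname(m$table), matrix(c(32, 13, 17, 27), 2, byrow = TRUE))
  expect_equal(round(m$p_one_tailed, 3), 0.002)

  # identity, commutativity, associativity
  zero <- matrix(0, 2, 2)
  expect_equal(merge_two_locus(a, zero)$table, a$table)
  expect_equal(merge_two_locus(a, b)$table, merge_two_locus(b, a)$table)
  c_ <- two_locus_table(two_locus_fixture(2, 3, 4, 5))
  expect_equal(merge_two_locus(merge_two_locus(a, b), c_)$table,
               merge_two_locus(a, merge_two_locus(b, c_))$table)
})
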