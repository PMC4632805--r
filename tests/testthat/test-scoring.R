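test_that("sequence parsing accepts one- and three-letter forms and names bad positions", {
  expect_equal(as_peptide("wy"), "WY")
  expect_equal(as_peptide("Trp-Tyr"), "WY")
  expect_equal(as_peptide("Met-Ala-Lys"), "MAK")
  expect_error(as_peptide("WBY"), "position 2")
  expect_error(as_peptide("Trp-Xxx"), "Xxx")
  expect_error(as_peptide(""), "non-empty")
})

test_that("redox sites enumerate the union set in ascending order", {
  expect_equal(find_redox_sites("WY"), c(1L, 2L))
  expect_equal(find_redox_sites("GGA"), integer(0))
  expect_equal(find_redox_sites("YGMCH"), c(1L, 3L, 4L, 5L))
})

test_that("rule matching honours terminal positions and ordered pairs", {
  m <- match_rules("WY", "ORAC")
  expect_equal(nrow(m), 1)
  expect_equal(m$pattern, "WY")
  expect_equal(m$effect, 1L)

  m <- match_rules("GM", "ORAC")
  expect_equal(m$kind, "terminal")
  expect_equal(m$position, 2L)

  # same pair, opposite sign across assays
  expect_equal(match_rules("KY", "ORAC")$effect, -1L)
  expect_equal(match_rules("KY", "TEAC")$effect, 1L)

  expect_equal(nrow(match_rules("AAA", "ORAC")), 0)
  expect_equal(nrow(match_rules("AAA", "TEAC")), 0)

  # ordered: YK matches Tyr-Lys (+1 ORAC), not Lys-Tyr
  expect_equal(match_rules("YK", "ORAC")$pattern, "YK")

  # overlapping matches all count: KYH under TEAC hits Lys-Tyr and Tyr-His
  m <- match_rules("KYH", "TEAC")
  expect_setequal(m$pattern, c("KY", "YH"))

  # terminal rule only fires at the terminus: internal M is not C-terminal
  expect_equal(nrow(match_rules("AMA", "ORAC")), 0)

  # repeated motif occurrences are each reported
  m <- match_rules("WYWY", "ORAC")
  expect_equal(sum(m$pattern == "WY"), 2)
})

test_that("integral score follows the formula with worked examples", {
  s <- score_peptide("WY", "ORAC")
  expect_equal(s$sum_effects, 1L)
  expect_equal(s$n_redox, 2L)
  expect_equal(s$length, 2L)
  expect_equal(s$score, 2.5)

  expect_equal(score_peptide("GM", "ORAC")$score, 5.0)
  expect_equal(score_peptide("AAA", "ORAC")$score, 0)
  expect_equal(score_peptide("YW", "TEAC")$score, 2.5)

  # single residue: position 1 is both termini
  expect_equal(score_peptide("M", "ORAC")$score, 10)
})

test_that("scoring equals the hand-enumerated oracle on all relevant dipeptides", {
  alphabet <- c("Y", "W", "M", "C", "H", "K", "R", "E", "D", "G", "A")
  grid <- expand.grid(a = alphabet, b = alphabet, stringsAsFactors = FALSE)
  seqs <- paste0(grid$a, grid$b)
  for (assay in c("ORAC", "TEAC")) {
    scored <- score_peptides(tibble::tibble(sequence = seqs), assay)
    expected <- vapply(seqs, oracle_integral_score, numeric(1), assay = assay)
    expect_equal(scored$score, unname(expected))
    expected_sums <- vapply(seqs, oracle_sum_effects, numeric(1), assay = assay)
    expect_equal(as.numeric(scored$sum_effects), unname(expected_sums))
  }
})

test_that("score scales as 1/N for fixed matches and redox count", {
  # pad WY with non-redox, non-matching residues: matches and n unchanged
  base <- score_peptide("WY", "ORAC")
  padded <- score_peptide("WYGG", "ORAC")
  expect_equal(padded$sum_effects, base$sum_effects)
  expect_equal(padded$n_redox, base$n_redox)
  expect_equal(padded$score, base$score * base$length / padded$length)
  # doubling length halves I
  expect_equal(padded$score, base$score / 2)
})

test_that("scoring is deterministic and bounded on random peptides", {
  peps <- sim_peptides(200, length_range = c(1, 12), seed = 99)
  s1 <- score_peptides(peps, "ORAC")
  s2 <- score_peptides(peps, "ORAC")
  expect_identical(s1, s2)
  # |I| <= (matches / n) * 10 / N <= 10 * matches; with n >= 1
  n_matches <- vapply(s1$matches, nrow, integer(1))
  expect_true(all(abs(s1$sum_effects) <= n_matches))
  ok <- s1$n_redox > 0
  expect_true(all(abs(s1$score[ok]) <=
    (n_matches[ok] / s1$n_redox[ok]) * (10 / s1$length[ok])))
  expect_true(all(s1$score[!ok] == 0))
})

test_that("window enumeration produces all deduplicated substrings", {
  expect_equal(enumerate_peptides("ACD", 2, 2)$sequence, c("AC", "CD"))
  # count law: L - k + 1 windows of width k before dedup (all distinct here)
  out <- enumerate_peptides("ACDEFGHIKL", 3, 3)
  expect_equal(nrow(out), 10 - 3 + 1)
  # duplicates collapse
  out2 <- enumerate_peptides("AAAA", 2, 2)
  expect_equal(out2$sequence, "AA")
  expect_error(enumerate_peptides("ACD", 3, 2), "min_len")
})

test_that("tryptic digestion cleaves after K/R except before P", {
  expect_equal(enumerate_peptides("AKPGRM", 1, 10, "tryptic")$sequence, c("AKPGR", "M"))
  expect_equal(enumerate_peptides("AKGR", 1, 10, "tryptic")$sequence, c("AK", "GR"))
  # length filter applies after digestion
  expect_equal(enumerate_peptides("AKPGRM", 2, 10, "tryptic")$sequence, "AKPGR")
  expect_equal(enumerate_peptides("GGG", 1, 10, "tryptic")$sequence, "GGG")
})

test_that("ranking is by descending score with lexicographic tie-break", {
  r <- rank_peptides(c("WY", "GM"), "ORAC")
  expect_equal(r$sequence, c("GM", "WY"))
  expect_equal(r$rank, 1:2)

  # identical scores: lexicographic order
  tied <- rank_peptides(c("GGY", "GGW"), "ORAC") # both 0 matches, n=1
  expect_equal(tied$sequence, sort(tied$sequence))

  empty <- rank_peptides(character(0), "ORAC")
  expect_equal(nrow(empty), 0)

  top1 <- rank_peptides(c("WY", "GM", "AAA"), "ORAC", top = 1)
  expect_equal(top1$sequence, "GM")
})
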