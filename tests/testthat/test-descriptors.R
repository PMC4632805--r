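test_that("descriptor formulas satisfy their algebraic identities", {
  set.seed(11)
  for (i in 1:50) {
    e_lumo <- runif(1, -3, 1)
    e_homo <- e_lumo - runif(1, 0.1, 8)
    chi <- electronegativity(e_homo, e_lumo)
    eta <- hardness(e_homo, e_lumo)
    # chi +/- eta recover the frontier energies exactly
    expect_equal(chi + eta, -e_homo)
    expect_equal(chi - eta, -e_lumo)
    expect_equal(homo_lumo_gap(e_homo, e_lumo), 2 * eta)
    # the two electrophilicity conventions differ by exactly 4
    expect_equal(
      electrophilicity(chi, eta, "standard"),
      4 * electrophilicity(chi, eta, "paper")
    )
    # Koopmans IP is negation-involutive
    expect_equal(koopmans_ip(-koopmans_ip(e_homo)), -e_homo)
  }
})

test_that("descriptor edge cases and input validation", {
  expect_equal(electronegativity(0, 0), 0)
  expect_equal(hardness(-2, -2), 0)
  expect_equal(koopmans_ip(0), 0)
  expect_error(hardness(-1, -2), "e_homo")
  expect_error(homo_lumo_gap(-1, -2), "e_homo")
  expect_error(electronegativity(NA_real_, 0), "finite")
  expect_error(electrophilicity(3, 0), "undefined")
  expect_error(electrophilicity(3, -1), "undefined")
})

test_that("total-energy descriptors use the stated conversion constants", {
  expect_equal(adiabatic_ip(-100, -100), 0)
  expect_equal(adiabatic_ip(-100.0, -99.7), 0.3 * 27.2114)
  expect_warning(ip_neg <- adiabatic_ip(-99.7, -100.0), "sign")
  expect_equal(ip_neg, -0.3 * 27.2114)

  expect_equal(bde(-630.0, -629.5, -0.5), 0)
  expect_equal(bde(-630.0, -629.4, -0.5), 0.1 * 627.509)
  # hydrogen-atom energy default is configurable
  expect_equal(bde(-630.0, -629.5, -0.6), -0.1 * 627.509)
})

test_that("derived descriptors reproduce the printed reference table", {
  computed <- compute_descriptors(amino_acid_orbitals())
  ref <- amino_acid_descriptors()
  joined <- dplyr::left_join(computed, ref, by = "species", suffix = c("", "_ref"))
  expect_equal(nrow(joined), 5)
  expect_true(all(abs(joined$chi_ev - joined$chi_ev_ref) < 0.02))
  expect_true(all(abs(joined$eta_ev - joined$eta_ev_ref) < 0.02))
  expect_true(all(abs(joined$omega_ev - joined$omega_ev_ref) < 0.01))
  expect_true(all(abs(joined$ipo_ev - joined$ipo_ev_ref) < 0.02))
  expect_true(all(abs(joined$gap_ev - joined$gap_ev_ref) < 0.02))
})

test_that("compute_descriptors derives IPe and BDE when total energies exist", {
  tab <- tibble::tibble(
    species = "X", e_homo_ev = -6, e_lumo_ev = -1,
    e_neutral_hartree = -630.0, e_cation_hartree = -629.7,
    e_radical_hartree = -629.4
  )
  out <- compute_descriptors(tab)
  expect_equal(out$ipe_ev, 0.3 * 27.2114)
  expect_equal(out$bde_kcal_mol, 0.1 * 627.509)
  expect_error(compute_descriptors(tibble::tibble(e_homo_ev = -6)), "missing column")
})

test_that("electron-density ranking picks the most negative Mulliken charges", {
  his <- dplyr::filter(mulliken_charges("His"), state == "neutral")
  top <- max_density_atoms(his, atoms = c("C1", "C19", "C16"))
  expect_equal(top$atom, "C19")

  tyr_ring <- dplyr::filter(
    mulliken_charges("Tyr"), state == "neutral",
    atom %in% c("C13", "C14", "C15", "C16", "C18", "C20")
  )
  ranked <- max_density_atoms(tyr_ring, tie_epsilon = 0.02)
  expect_equal(ranked$atom, c("C16", "C18"))

  # all-equal charges tie: the whole subset comes back
  flat <- tibble::tibble(atom = c("A1", "A2", "A3"), charge_e = rep(-0.2, 3))
  expect_equal(nrow(max_density_atoms(flat)), 3)

  expect_error(max_density_atoms(his, atoms = "C99"), "unknown atom")
  expect_error(max_density_atoms(his[0, ]), "empty")
  expect_error(max_density_atoms(his, tie_epsilon = -1), ">= 0")
})

test_that("Mulliken reference charges show the expected ionization trends", {
  ch <- mulliken_charges()
  # cation radicals lose electron density on sulfur for Met and Cys
  s_met <- dplyr::filter(ch, species == "Met", atom == "S14")
  expect_gt(
    s_met$charge_e[s_met$state == "cation_radical"],
    s_met$charge_e[s_met$state == "neutral"]
  )
  s_cys <- dplyr::filter(ch, species == "Cys", atom == "S9")
  expect_gt(
    s_cys$charge_e[s_cys$state == "cation_radical"],
    s_cys$charge_e[s_cys$state == "neutral"]
  )
  # atom labels unique within every species/state table
  expect_false(any(duplicated(ch[, c("species", "state", "atom")])))
})
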