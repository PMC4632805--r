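#' Conceptual-DFT reactivity descriptors from frontier-orbital energies
#'
#' Global reactivity indices computed from tabulated quantum-chemistry output
#' (B3LYP-type gas-phase calculations): electronegativity
#' \eqn{\chi = -(E_{HOMO}+E_{LUMO})/2}, chemical hardness
#' \eqn{\eta = (E_{LUMO}-E_{HOMO})/2}, the HOMO-LUMO gap, the Koopmans
#' (orbital) ionization potential \eqn{IP_o = -E_{HOMO}}, the adiabatic
#' ionization potential \eqn{IP_e = E(\mathrm{cation}) - E(\mathrm{neutral})},
#' and the O-H bond dissociation energy
#' \eqn{BDE = E(\mathrm{radical}) + E(\mathrm{H}) - E(\mathrm{parent})}.
#'
#' For electrophilicity two conventions are exposed. `mode = "paper"`
#' (default) uses \eqn{\omega = \chi^2/(8\eta)}, equivalently
#' \eqn{\chi^2/(4\,(E_{LUMO}-E_{HOMO}))}, which reproduces the packaged
#' reference descriptor table for all five redox-active amino acids;
#' `mode = "standard"` uses the textbook Parr form \eqn{\omega = \chi^2/(2\eta)}
#' (exactly four times larger).
#'
#' All orbital-energy arguments are in eV; total energies are in Hartree and
#' converted with 27.2114 eV/Hartree and 627.509 kcal mol^-1/Hartree.
#'
#' @param e_homo,e_lumo Frontier-orbital energies (eV).
#' @param chi,eta Electronegativity and hardness (eV).
#' @param mode Electrophilicity convention, `"paper"` or `"standard"`.
#' @param e_neutral,e_cation,e_parent,e_radical Total electronic energies
#'   (Hartree).
#' @param e_h_atom Electronic energy of the hydrogen atom (Hartree); the exact
#'   value depends on the level of theory, default -0.5.
#'
#' @return Numeric vector (eV, except `bde()` in kcal/mol).
#' @examples
#' electronegativity(-6.55, -0.971) # 3.7605 eV (Tyr)
#' hardness(-6.55, -0.971)          # 2.7895 eV
#' electrophilicity(3.7605, 2.7895) # 0.634 eV
#' @name dft_descriptors
NULL

check_finite <- function(..., .names = NULL) {
  args <- list(...)
  nms <- if (is.null(.names)) paste0("arg", seq_along(args)) else .names
  for (i in seq_along(args)) {
    if (any(!is.finite(args[[i]]))) {
      abort(sprintf("'%s' must be finite", nms[i]))
    }
  }
  invisible(NULL)
}

#' @rdname dft_descriptors
#' @export
electronegativity <- function(e_homo, e_lumo) {
  check_finite(e_homo, e_lumo, .names = c("e_homo", "e_lumo"))
  -(e_homo + e_lumo) / 2
}

#' @rdname dft_descriptors
#' @export
hardness <- function(e_homo, e_lumo) {
  check_finite(e_homo, e_lumo, .names = c("e_homo", "e_lumo"))
  if (any(e_homo > e_lumo)) {
    abort("e_homo must not exceed e_lumo (occupied below unoccupied)")
  }
  (e_lumo - e_homo) / 2
}

#' @rdname dft_descriptors
#' @export
electrophilicity <- function(chi, eta, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  check_finite(chi, eta, .names = c("chi", "eta"))
  if (any(eta <= 0)) {
    abort("electrophilicity is undefined for eta <= 0")
  }
  denom <- if (mode == "paper") 8 else 2
  chi^2 / (denom * eta)
}

#' @rdname dft_descriptors
#' @export
koopmans_ip <- function(e_homo) {
  check_finite(e_homo, .names = "e_homo")
  -e_homo
}

#' @rdname dft_descriptors
#' @export
adiabatic_ip <- function(e_neutral, e_cation) {
  check_finite(e_neutral, e_cation, .names = c("e_neutral", "e_cation"))
  ip <- (e_cation - e_neutral) * EV_PER_HARTREE
  if (any(ip < 0)) {
    warn("negative adiabatic ionization potential: check the sign convention of the total energies")
  }
  ip
}

#' @rdname dft_descriptors
#' @export
bde <- function(e_parent, e_radical, e_h_atom = -0.5) {
  check_finite(e_parent, e_radical, e_h_atom,
    .names = c("e_parent", "e_radical", "e_h_atom")
  )
  (e_radical + e_h_atom - e_parent) * KCALMOL_PER_HARTREE
}

#' @rdname dft_descriptors
#' @export
homo_lumo_gap <- function(e_homo, e_lumo) {
  check_finite(e_homo, e_lumo, .names = c("e_homo", "e_lumo"))
  if (any(e_homo > e_lumo)) {
    abort("e_homo must not exceed e_lumo (occupied below unoccupied)")
  }
  e_lumo - e_homo
}

#' Compute derived descriptors for a table of species
#'
#' Data-frame-first wrapper around the descriptor calculus. Expects orbital
#' energies in eV (`e_homo_ev`, `e_lumo_ev`) and, optionally, total electronic
#' energies in Hartree (`e_neutral_hartree`, `e_cation_hartree`,
#' `e_radical_hartree`). Derived columns are appended: `ipo_ev`, `chi_ev`,
#' `eta_ev`, `omega_ev`, `gap_ev`, and — where the total energies are present —
#' `ipe_ev` and `bde_kcal_mol`.
#'
#' @param data A data frame, one row per species.
#' @param omega_mode Electrophilicity convention (see
#'   [electrophilicity()]).
#' @param e_h_atom Hydrogen-atom electronic energy (Hartree) for the BDE.
#' @return `data` as a tibble with derived descriptor columns appended.
#' @examples
#' compute_descriptors(amino_acid_orbitals())
#' @export
compute_descriptors <- function(data, omega_mode = c("paper", "standard"),
                                e_h_atom = -0.5) {
  omega_mode <- match.arg(omega_mode)
  data <- tibble::as_tibble(data)
  need <- c("e_homo_ev", "e_lumo_ev")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::mutate(data,
    ipo_ev = koopmans_ip(.data$e_homo_ev),
    chi_ev = electronegativity(.data$e_homo_ev, .data$e_lumo_ev),
    eta_ev = hardness(.data$e_homo_ev, .data$e_lumo_ev),
    omega_ev = electrophilicity(.data$chi_ev, .data$eta_ev, mode = omega_mode),
    gap_ev = homo_lumo_gap(.data$e_homo_ev, .data$e_lumo_ev)
  )
  if (all(c("e_neutral_hartree", "e_cation_hartree") %in% names(out))) {
    out$ipe_ev <- (out$e_cation_hartree - out$e_neutral_hartree) * EV_PER_HARTREE
  }
  if (all(c("e_neutral_hartree", "e_radical_hartree") %in% names(out))) {
    out$bde_kcal_mol <- (out$e_radical_hartree + e_h_atom - out$e_neutral_hartree) *
      KCALMOL_PER_HARTREE
  }
  out
}

#' Reference frontier-orbital energies of the redox-active amino acids
#'
#' Gas-phase (298 K) HOMO/LUMO energies of the five redox-active free amino
#' acids, as tabulated from DFT calculations (B3LYP/6-311++G(d,p)).
#'
#' @return A tibble with columns `species`, `e_homo_ev`, `e_lumo_ev`,
#'   `provenance`.
#' @export
amino_acid_orbitals <- function() {
  tibble::tribble(
    ~species, ~e_homo_ev, ~e_lumo_ev, ~provenance,
    "Tyr",    -6.55,      -0.971,     "printed",
    "Trp",    -5.80,      -0.577,     "printed",
    "Cys",    -6.76,      -1.102,     "printed",
    "Met",    -6.22,      -0.776,     "printed",
    "His",    -6.67,      -0.894,     "printed"
  )
}

#' Reference descriptor table of the redox-active amino acids
#'
#' The tabulated thermodynamic and energy parameters of the five redox-active
#' amino acids in the gas phase: BDE (kcal/mol; not available for Met, whose
#' antioxidant chemistry is not H-atom transfer from an O-H group), adiabatic
#' and Koopmans ionization potentials, frontier-orbital energies,
#' electronegativity, hardness, electrophilicity and the HOMO-LUMO gap.
#' These are the printed reference values that [compute_descriptors()]
#' reproduces from the orbital energies alone.
#'
#' @return A tibble, one row per species, `provenance = "printed"`.
#' @export
amino_acid_descriptors <- function() {
  tibble::tribble(
    ~species, ~bde_kcal_mol, ~ipe_ev, ~ipo_ev, ~e_homo_ev, ~e_lumo_ev, ~chi_ev, ~eta_ev, ~omega_ev, ~gap_ev, ~provenance,
    "Tyr",    83.50,         7.77,    6.55,    -6.55,      -0.971,     3.762,   2.791,   0.634,     5.58,    "printed",
    "Trp",    90.39,         7.15,    5.80,    -5.80,      -0.577,     3.186,   2.609,   0.486,     5.22,    "printed",
    "Cys",    106.99,        8.67,    6.76,    -6.76,      -1.102,     3.933,   2.830,   0.683,     5.66,    "printed",
    "Met",    NA,            8.43,    6.22,    -6.22,      -0.776,     3.496,   2.721,   0.562,     5.44,    "printed",
    "His",    89.82,         8.21,    6.67,    -6.67,      -0.894,     3.783,   2.889,   0.619,     5.79,    "printed"
  )
}
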