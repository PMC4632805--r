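#' Reference Mulliken charge distributions
#'
#' Mulliken partial charges (in units of e) on the key atoms of the five
#' redox-active amino acids and their radicals and cation radicals, from
#' gas-phase DFT calculations. Atom labels follow the numbering of the
#' optimized free amino acid structures. Missing entries (e.g. the phenolic
#' hydrogen in the Tyr radical, which has been abstracted) are omitted.
#'
#' @param species Optional species filter (`"Tyr"`, `"Trp"`, `"Cys"`, `"Met"`,
#'   `"His"`).
#' @return A tibble with columns `species`, `state` (`"neutral"`, `"radical"`,
#'   `"cation_radical"`), `atom`, `charge_e`, `provenance`.
#' @export
mulliken_charges <- function(species = NULL) {
  tab <- dplyr::bind_rows(
    # Met: neutral and cation radical
    charge_block("Met", "neutral",
      c(S14 = 0.014, C9 = -0.224, C5 = -0.150, C3 = -0.351)),
    charge_block("Met", "cation_radical",
      c(S14 = 0.260, C9 = -0.289, C5 = -0.444, C3 = -0.279)),
    # Tyr: ring carbons and phenolic group
    charge_block("Tyr", "neutral",
      c(C13 = -0.010, C14 = -0.104, C16 = -0.177, C20 = 0.257,
        C18 = -0.165, C15 = -0.139, O23 = -0.622, H24 = 0.370)),
    charge_block("Tyr", "radical",
      c(C13 = -0.028, C14 = -0.066, C16 = -0.175, C20 = 0.211,
        C18 = -0.170, C15 = -0.102, O23 = -0.362)),
    charge_block("Tyr", "cation_radical",
      c(C13 = -0.006, C14 = -0.058, C16 = -0.122, C20 = 0.285,
        C18 = -0.130, C15 = -0.030, O23 = -0.542, H24 = 0.416)),
    # Trp: indole ring
    charge_block("Trp", "neutral",
      c(C1 = 1.342, C2 = -0.419, C3 = -0.687, C4 = -0.143, C5 = -0.548,
        C6 = -0.638, C7 = 1.225, C8 = -0.431, N14 = -0.052, H15 = 0.292)),
    charge_block("Trp", "radical",
      c(C1 = 0.607, C2 = -0.580, C3 = -0.392, C4 = -0.218, C5 = -0.373,
        C6 = -0.504, C7 = 0.995, C8 = 0.026, N14 = -0.008)),
    charge_block("Trp", "cation_radical",
      c(C1 = 0.653, C2 = -0.512, C3 = -0.385, C4 = 0.004, C5 = -0.384,
        C6 = -0.381, C7 = 0.682, C8 = -0.075, N14 = -0.191, H15 = 0.369)),
    # His: imidazole region
    charge_block("His", "neutral",
      c(C1 = 0.775, C19 = -0.533, C16 = 0.153, N20 = -0.134, N15 = -0.173)),
    charge_block("His", "radical",
      c(C1 = 0.923, C19 = -0.324, C16 = 0.141, N20 = -0.096, N15 = -0.154)),
    charge_block("His", "cation_radical",
      c(C1 = 0.451, C19 = 0.164, C16 = 0.221, N20 = -0.135, N15 = -0.272)),
    # Cys: thiol group
    charge_block("Cys", "neutral",
      c(S9 = -0.035, C5 = -0.526, C3 = 0.174, H12 = 0.028)),
    charge_block("Cys", "radical",
      c(S9 = 0.093, C5 = -0.650, C3 = -0.175)),
    charge_block("Cys", "cation_radical",
      c(S9 = 0.313, C5 = -0.472, C3 = -0.207, H12 = 0.145))
  )
  if (!is.null(species)) {
    sp <- species
    tab <- dplyr::filter(tab, .data$species %in% sp)
    if (nrow(tab) == 0) abort(sprintf("no charge data for species '%s'", paste(species, collapse = ", ")))
  }
  tab
}

charge_block <- function(species, state, charges) {
  tibble::tibble(
    species = species, state = state,
    atom = names(charges), charge_e = unname(charges),
    provenance = "printed"
  )
}

#' Rank atoms by electron density from Mulliken charges
#'
#' The most negative Mulliken charge marks the highest local electron density
#' and hence the preferred site of electrophilic/radical attack. Given a
#' charge table for one species/ionization state, returns the atoms whose
#' charge lies within `tie_epsilon` of the minimum, most negative first.
#'
#' @param charges A data frame with columns `atom` and `charge_e` (one
#'   species/state; extra columns are ignored but must be constant).
#' @param atoms Optional subset of atom labels to consider.
#' @param tie_epsilon Charges within this margin (e) of the minimum count as
#'   tied maxima of electron density.
#' @return A tibble with columns `atom`, `charge_e`, ordered by increasing
#'   charge (decreasing electron density).
#' @examples
#' his <- dplyr::filter(mulliken_charges("His"), state == "neutral")
#' max_density_atoms(his, atoms = c("C1", "C19", "C16"))
#' @export
max_density_atoms <- function(charges, atoms = NULL, tie_epsilon = 0.005) {
  charges <- tibble::as_tibble(charges)
  if (!all(c("atom", "charge_e") %in% names(charges))) {
    abort("charges must have columns 'atom' and 'charge_e'")
  }
  if (tie_epsilon < 0) abort("tie_epsilon must be >= 0")
  if (anyDuplicated(charges$atom)) {
    abort("duplicate atom labels: pass a single species/ionization state")
  }
  if (!is.null(atoms)) {
    unknown <- setdiff(atoms, charges$atom)
    if (length(unknown) > 0) {
      abort(paste0("unknown atom label(s): ", paste(unknown, collapse = ", ")))
    }
    charges <- dplyr::filter(charges, .data$atom %in% atoms)
  }
  if (nrow(charges) == 0) abort("no atoms to rank (empty subset)")
  qmin <- min(charges$charge_e)
  out <- dplyr::filter(charges, .data$charge_e <= qmin + tie_epsilon)
  dplyr::arrange(out[, c("atom", "charge_e")], .data$charge_e, .data$atom)
}
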