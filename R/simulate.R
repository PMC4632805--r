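#' Simulate an ORAC kinetic plate
#'
#' Generates a long-format fluorescein-decay plate with trolox calibrants,
#' blanks and antioxidant samples of known trolox-equivalent value, suitable
#' for end-to-end testing of the ORAC quantification pipeline.
#'
#' The decay model is a protected-fraction mixture: a fraction
#' \eqn{p = \alpha \cdot c \cdot TE} of the fluorescein pool follows a lagged
#' decay \eqn{e^{-k\,\max(0, t-L)}} (protected until the antioxidant is
#' consumed) while the rest decays immediately as \eqn{e^{-kt}}; the signal is
#' \eqn{F_0[(1-p)e^{-kt} + p\,e^{-k\max(0,t-L)}]}. Because the signal is
#' affine in \eqn{p} at every time point and trapezoidal integration is a
#' linear functional, the net AUC is exactly linear in TE-equivalent
#' concentration — so a noise-free plate round-trips through [orac_aoc()] to
#' machine precision. This is a test-harness model of the assay response, not
#' a mechanistic radical-kinetics claim.
#'
#' @param te_samples Named numeric vector of sample trolox-equivalent values
#'   (µmol TE/µmol); names become `sample_id`s.
#' @param sample_conc_um Final in-well sample concentration (µM).
#' @param calib_conc_um Trolox calibrant concentrations (µM), default 1-10.
#' @param noise_sd Multiplicative Gaussian noise SD (fraction of signal).
#' @param seed Integer seed; identical arguments give identical plates.
#' @param t_end,by Time grid in minutes (default 0-60 min every 1 min,
#'   mirroring 1-h registration at 60-s intervals).
#' @param decay_rate Fluorescein decay rate k (1/min).
#' @param lag_full Lag L (min) of the fully protected fraction.
#' @param f0 Initial fluorescence.
#' @param protect_per_um Protected fraction per µM of TE-equivalent
#'   concentration (\eqn{\alpha}); \eqn{\alpha \cdot c \cdot TE} must not
#'   exceed 1.
#' @param n_blank Number of blank wells.
#' @return A long-format plate tibble (`well`, `sample_id`, `role`,
#'   `conc_um`, `time`, `signal`).
#' @examples
#' plate <- sim_orac_plate(c(Tyr = 1.02), seed = 1)
#' tidy(orac_aoc(plate))
#' @export
sim_orac_plate <- function(te_samples = c(Tyr = 1.02, Trp = 2.79),
                           sample_conc_um = 2,
                           calib_conc_um = 1:10,
                           noise_sd = 0, seed = 1,
                           t_end = 60, by = 1,
                           decay_rate = 0.25, lag_full = 30, f0 = 1,
                           protect_per_um = 0.06, n_blank = 2) {
  stopifnot(all(te_samples >= 0), noise_sd >= 0, lag_full < t_end)
  if (is.null(names(te_samples))) {
    names(te_samples) <- paste0("sample", seq_along(te_samples))
  }
  times <- seq(0, t_end, by = by)
  d_fast <- exp(-decay_rate * times)
  d_lag <- exp(-decay_rate * pmax(0, times - lag_full))

  signal_for <- function(te_conc) {
    p <- protect_per_um * te_conc
    if (p > 1) abort("protected fraction exceeds 1: lower the concentration or TE value")
    f0 * ((1 - p) * d_fast + p * d_lag)
  }

  layout <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = paste0("blank", seq_len(n_blank)), role = "blank",
      conc_um = 0, te_conc = 0
    ),
    tibble::tibble(
      sample_id = paste0("trolox_", calib_conc_um, "uM"), role = "calibrant",
      conc_um = calib_conc_um, te_conc = as.numeric(calib_conc_um)
    ),
    tibble::tibble(
      sample_id = names(te_samples), role = "sample",
      conc_um = sample_conc_um, te_conc = sample_conc_um * unname(te_samples)
    )
  )
  layout$well <- sprintf("W%02d", seq_len(nrow(layout)))

  withr::with_seed(as.integer(seed), {
    purrr::pmap(layout, function(sample_id, role, conc_um, te_conc, well) {
      s <- signal_for(te_conc)
      if (noise_sd > 0) s <- s * (1 + stats::rnorm(length(s), 0, noise_sd))
      tibble::tibble(
        well = well, sample_id = sample_id, role = role,
        conc_um = conc_um, time = times, signal = pmax(s, 0)
      )
    }) |> dplyr::bind_rows()
  })
}

#' Simulate a TEAC kinetic plate
#'
#' Generates an ABTS decolorization plate: control wells hold the radical
#' baseline OD, and antioxidant wells decline towards
#' \eqn{OD(t) = OD_0 - \gamma \cdot c \cdot TE \,(1 - e^{-rt})}, so the OD
#' decline at the read time is exactly linear in TE-equivalent concentration
#' and a noise-free plate round-trips through [teac_aoc()] to machine
#' precision.
#'
#' @inheritParams sim_orac_plate
#' @param od0 Baseline OD at 734 nm of the radical solution.
#' @param rate Quenching rate r (1/min).
#' @param dod_per_um OD decline per µM of TE-equivalent concentration at
#'   plateau (\eqn{\gamma}).
#' @param n_control Number of control wells.
#' @param t_end,by Time grid (default 0-41 min every 1 min, covering the
#'   40.5-min read).
#' @return A long-format plate tibble.
#' @examples
#' plate <- sim_teac_plate(c(Tyr = 3.38), seed = 1)
#' tidy(teac_aoc(plate))
#' @export
sim_teac_plate <- function(te_samples = c(Tyr = 3.38, Trp = 3.33),
                           sample_conc_um = 5,
                           calib_conc_um = 1:10,
                           noise_sd = 0, seed = 1,
                           t_end = 41, by = 1,
                           od0 = 1.0, rate = 0.15, dod_per_um = 0.02,
                           n_control = 2) {
  stopifnot(all(te_samples >= 0), noise_sd >= 0)
  if (is.null(names(te_samples))) {
    names(te_samples) <- paste0("sample", seq_along(te_samples))
  }
  times <- seq(0, t_end, by = by)
  rise <- 1 - exp(-rate * times)

  od_for <- function(te_conc) {
    od <- od0 - dod_per_um * te_conc * rise
    if (any(od < 0)) abort("OD would go negative: lower the concentration or TE value")
    od
  }

  layout <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = paste0("control", seq_len(n_control)), role = "control",
      conc_um = 0, te_conc = 0
    ),
    tibble::tibble(
      sample_id = paste0("trolox_", calib_conc_um, "uM"), role = "calibrant",
      conc_um = calib_conc_um, te_conc = as.numeric(calib_conc_um)
    ),
    tibble::tibble(
      sample_id = names(te_samples), role = "sample",
      conc_um = sample_conc_um, te_conc = sample_conc_um * unname(te_samples)
    )
  )
  layout$well <- sprintf("W%02d", seq_len(nrow(layout)))

  withr::with_seed(as.integer(seed), {
    purrr::pmap(layout, function(sample_id, role, conc_um, te_conc, well) {
      s <- od_for(te_conc)
      if (noise_sd > 0) s <- s * (1 + stats::rnorm(length(s), 0, noise_sd))
      tibble::tibble(
        well = well, sample_id = sample_id, role = role,
        conc_um = conc_um, time = times, signal = pmax(s, 0)
      )
    }) |> dplyr::bind_rows()
  })
}

#' Simulate a descriptor-activity table
#'
#' Draws a multivariate Gaussian table in which each descriptor has a
#' prescribed population correlation with the activity column, via the
#' single-factor construction \eqn{x_j = \rho_j z + \sqrt{1-\rho_j^2}\,
#' \varepsilon_j} with the activity as the common factor \eqn{z} (a valid
#' factorization of the target correlation matrix for any \eqn{|\rho_j| \le
#' 1}). Each row carries a random Met-dipeptide sequence built from
#' non-ionogenic partners, plus optional ionogenic decoy rows for testing the
#' exclusion rule.
#'
#' @param n Number of peptides (rows), >= 3.
#' @param rho Named vector of target correlations between each descriptor and
#'   the activity; defaults mirror the inverse correlations reported for
#'   methionine dipeptides.
#' @param seed Integer seed.
#' @param n_ionogenic Number of additional decoy rows whose sequences contain
#'   ionogenic residues (excluded by [filter_ionogenic()]).
#' @return A tibble with columns `sequence`, `aoc`, and one column per
#'   descriptor.
#' @examples
#' sim_descriptor_table(n = 14, seed = 42)
#' @export
sim_descriptor_table <- function(n,
                                 rho = c(ipe = -0.819, chi = -0.874, omega = -0.818),
                                 seed = 1, n_ionogenic = 0) {
  if (n < 3) abort("need n >= 3 rows for a correlation screen")
  if (any(abs(rho) > 1)) abort("target correlations must lie in [-1, 1]")
  if (is.null(names(rho))) abort("rho must be a named vector (descriptor names)")
  nonionic <- setdiff(AA_ALPHABET, c(IONOGENIC, "M"))
  withr::with_seed(as.integer(seed), {
    z <- stats::rnorm(n)
    tab <- tibble::tibble(
      sequence = paste0("M", sample(nonionic, n, replace = TRUE)),
      aoc = z
    )
    for (j in names(rho)) {
      tab[[j]] <- rho[[j]] * z + sqrt(1 - rho[[j]]^2) * stats::rnorm(n)
    }
    if (n_ionogenic > 0) {
      zi <- stats::rnorm(n_ionogenic)
      decoy <- tibble::tibble(
        sequence = paste0("M", sample(IONOGENIC, n_ionogenic, replace = TRUE)),
        aoc = zi
      )
      for (j in names(rho)) {
        # decoys deliberately break the correlation structure
        decoy[[j]] <- stats::rnorm(n_ionogenic)
      }
      tab <- dplyr::bind_rows(tab, decoy)
    }
    tab
  })
}

#' Simulate random peptides
#'
#' Reproducible random peptide sequences for property tests of the scoring
#' engine.
#'
#' @param n Number of peptides.
#' @param length_range Inclusive length bounds.
#' @param seed Integer seed.
#' @param weights Optional sampling weights over the 20 canonical residues
#'   (named or in alphabet order); uniform by default.
#' @return A tibble with columns `id`, `sequence`.
#' @examples
#' sim_peptides(5, seed = 7)
#' @export
sim_peptides <- function(n, length_range = c(2, 10), seed = 1, weights = NULL) {
  stopifnot(n >= 0, length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  if (!is.null(weights)) {
    if (!is.null(names(weights))) weights <- weights[AA_ALPHABET]
    if (length(weights) != length(AA_ALPHABET) || any(is.na(weights)) || any(weights < 0)) {
      abort("weights must cover the 20 canonical residues and be non-negative")
    }
  }
  withr::with_seed(as.integer(seed), {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = weights), collapse = "")
    }, character(1))
    tibble::tibble(id = paste0("pep", seq_len(n)), sequence = seqs)
  })
}
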