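#' Theoretical (additive) antioxidant capacity of a dipeptide
#'
#' The additive expectation for a dipeptide's antioxidant capacity is the sum
#' of the contribution of its N-terminal residue and the contribution of its
#' C-terminal residue, looked up in a terminal-contribution table (µmol
#' TE/µmol). A missing contribution raises an explicit lookup error rather
#' than silently contributing zero.
#'
#' @param n_res,c_res One-letter codes of the N- and C-terminal residues
#'   (vectorized).
#' @param assay `"ORAC"` or `"TEAC"`.
#' @param contributions Contribution table, see [terminal_contributions()].
#' @return Numeric vector of theoretical AOC values (µmol TE/µmol).
#' @examples
#' theoretical_aoc("W", "Y", "TEAC") # 3.30 + 1.70 = 5.0
#' @export
theoretical_aoc <- function(n_res, c_res, assay,
                            contributions = terminal_contributions()) {
  assay <- match_assay(assay)
  contributions <- tibble::as_tibble(contributions)
  lookup <- function(res, terminus) {
    vapply(toupper(res), function(r) {
      hit <- contributions$value[
        contributions$residue == r &
          contributions$terminus == terminus &
          contributions$assay == assay
      ]
      if (length(hit) != 1) {
        abort(sprintf(
          "no %s-terminal %s contribution for residue '%s' in the table",
          terminus, assay, r
        ))
      }
      hit
    }, numeric(1), USE.NAMES = FALSE)
  }
  lookup(n_res, "N") + lookup(c_res, "C")
}

#' Classify residue interactions in a dipeptide
#'
#' Compares the measured antioxidant capacity of a dipeptide with its additive
#' expectation. The relative deviation
#' \eqn{(exp - theo)/theo} is classified as `additive` when within
#' `rel_tol`, `synergic` when the measured value exceeds the additive
#' expectation by more than `rel_tol`, and `infra_additive` when it falls
#' short by more than `rel_tol`. When measurement SDs are supplied the
#' additive band is widened to
#' `max(rel_tol * theoretical, 2 * sqrt(sd_theoretical^2 + sd_experimental^2))`
#' so that calls are never finer than the measurement uncertainty.
#'
#' @param theoretical,experimental AOC values (µmol TE/µmol), vectorized.
#' @param rel_tol Relative half-width of the additive band (default 0.10).
#' @param sd_theoretical,sd_experimental Optional measurement SDs.
#' @return A tibble with columns `theoretical`, `experimental`,
#'   `relative_deviation`, `label` (factor with levels `infra_additive`,
#'   `additive`, `synergic`).
#' @examples
#' classify_interaction(5.0, 5.17)  # additive
#' classify_interaction(6.48, 5.62) # infra_additive
#' classify_interaction(3.6, 5.1)   # synergic
#' @export
classify_interaction <- function(theoretical, experimental, rel_tol = 0.10,
                                 sd_theoretical = NULL, sd_experimental = NULL) {
  if (any(!is.finite(theoretical)) || any(!is.finite(experimental))) {
    abort("theoretical and experimental values must be finite")
  }
  if (any(theoretical <= 0)) {
    abort("classification is undefined for theoretical AOC <= 0")
  }
  if (rel_tol <= 0) abort("rel_tol must be > 0")
  dev <- (experimental - theoretical) / theoretical
  band <- rel_tol * theoretical
  if (!is.null(sd_theoretical) || !is.null(sd_experimental)) {
    s1 <- if (is.null(sd_theoretical)) 0 else sd_theoretical
    s2 <- if (is.null(sd_experimental)) 0 else sd_experimental
    band <- pmax(band, 2 * sqrt(s1^2 + s2^2))
  }
  diff <- experimental - theoretical
  label <- ifelse(abs(diff) <= band, "additive",
    ifelse(diff > 0, "synergic", "infra_additive")
  )
  tibble::tibble(
    theoretical = theoretical, experimental = experimental,
    relative_deviation = dev,
    label = factor(label, levels = c("infra_additive", "additive", "synergic"))
  )
}

#' Additivity calls for a table of dipeptides
#'
#' Data-frame-first pipeline: for each dipeptide, looks up the additive
#' expectation from the terminal contributions, compares it with the measured
#' value and attaches the interaction call.
#'
#' @param data A data frame with columns `sequence` (2-residue peptides) and
#'   `experimental` (µmol TE/µmol); an optional `sd` column widens the
#'   additive band (see [classify_interaction()]).
#' @param assay `"ORAC"` or `"TEAC"`.
#' @param rel_tol Relative additive band half-width.
#' @param contributions Terminal contribution table.
#' @return `data` with columns `theoretical`, `relative_deviation`, `label`
#'   appended.
#' @examples
#' additivity_calls(
#'   tibble::tibble(sequence = "WY", experimental = 5.17),
#'   assay = "TEAC"
#' )
#' @export
additivity_calls <- function(data, assay, rel_tol = 0.10,
                             contributions = terminal_contributions()) {
  data <- tibble::as_tibble(data)
  if (!all(c("sequence", "experimental") %in% names(data))) {
    abort("data must have columns 'sequence' and 'experimental'")
  }
  seqs <- as_peptide(data$sequence)
  if (any(nchar(seqs) != 2)) {
    abort("additivity analysis is defined for dipeptides (length-2 sequences)")
  }
  n_res <- substr(seqs, 1, 1)
  c_res <- substr(seqs, 2, 2)
  theo <- theoretical_aoc(n_res, c_res, assay, contributions)
  call <- classify_interaction(
    theo, data$experimental,
    rel_tol = rel_tol,
    sd_experimental = if ("sd" %in% names(data)) data$sd else NULL
  )
  dplyr::bind_cols(
    dplyr::mutate(data, sequence = seqs),
    call[, c("theoretical", "relative_deviation", "label")]
  )
}
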