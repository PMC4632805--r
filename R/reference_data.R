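#' Empirical effect rules for peptide antioxidant scoring
#'
#' The packaged rule set maps sequence motifs — terminal residues and ordered
#' adjacent residue pairs — to an integer effect (+1 favourable, -1
#' unfavourable) on antioxidant activity, separately for the ORAC (peroxyl
#' radical) and TEAC (ABTS cation radical) assays. These rules encode the
#' empirical structure-activity observations on tyrosine and methionine
#' dipeptides that the integral score is built from: the favourable C-terminal
#' Met position against the peroxyl radical, N-terminal Tyr/Trp against ABTS,
#' intramolecular synergy motifs (Trp-Tyr in ORAC; Tyr-His, His-Tyr, Met-Tyr
#' in TEAC), and the influence of flanking ionogenic residues (Lys/Arg/Glu/Asp)
#' on the redox activity of an adjacent Tyr.
#'
#' A custom rule table can be supplied via `file` (CSV, JSON or YAML with
#' columns/fields `assay`, `kind`, `pattern`, `terminus`, `effect`, `label`);
#' it is validated against the same schema as the packaged table.
#'
#' @param assay `"both"` (default), `"ORAC"` or `"TEAC"` (case-insensitive).
#' @param file Optional path to an override rule table.
#'
#' @return A tibble with columns `assay`, `kind` (`"terminal"` or
#'   `"adjacent_pair"`), `pattern` (one residue or an ordered residue pair in
#'   one-letter code), `terminus` (`"N"`, `"C"` or `NA`), `effect` (-1 or +1)
#'   and `label`.
#' @examples
#' aox_rules("ORAC")
#' @export
aox_rules <- function(assay = c("both", "ORAC", "TEAC"), file = NULL) {
  assay <- match_assay(assay[[1]], allow_both = TRUE)
  rules <- if (is.null(file)) default_rules() else read_rules(file)
  rules <- validate_rules(rules)
  if (assay != "both") rules <- dplyr::filter(rules, .data$assay == !!assay)
  rules
}

default_rules <- function() {
  tibble::tribble(
    ~assay, ~kind,            ~pattern, ~terminus, ~effect, ~label,
    "ORAC", "terminal",       "M",      "C",        1L, "C-terminal Met",
    "ORAC", "adjacent_pair",  "WY",     NA,         1L, "Trp-Tyr synergy",
    "ORAC", "adjacent_pair",  "KY",     NA,        -1L, "Lys-Tyr ionogenic",
    "ORAC", "adjacent_pair",  "RY",     NA,        -1L, "Arg-Tyr ionogenic",
    "ORAC", "adjacent_pair",  "YE",     NA,        -1L, "Tyr-Glu ionogenic",
    "ORAC", "adjacent_pair",  "YD",     NA,        -1L, "Tyr-Asp ionogenic",
    "ORAC", "adjacent_pair",  "YK",     NA,         1L, "Tyr-Lys ionogenic",
    "ORAC", "adjacent_pair",  "YR",     NA,         1L, "Tyr-Arg ionogenic",
    "TEAC", "terminal",       "Y",      "N",        1L, "N-terminal Tyr",
    "TEAC", "terminal",       "W",      "N",        1L, "N-terminal Trp",
    "TEAC", "adjacent_pair",  "YH",     NA,         1L, "Tyr-His synergy",
    "TEAC", "adjacent_pair",  "HY",     NA,         1L, "His-Tyr synergy",
    "TEAC", "adjacent_pair",  "MY",     NA,         1L, "Met-Tyr synergy",
    "TEAC", "adjacent_pair",  "KY",     NA,         1L, "Lys-Tyr ionogenic",
    "TEAC", "adjacent_pair",  "RY",     NA,         1L, "Arg-Tyr ionogenic"
  )
}

validate_rules <- function(rules) {
  rules <- tibble::as_tibble(rules)
  required <- c("assay", "kind", "pattern", "effect")
  missing <- setdiff(required, names(rules))
  if (length(missing) > 0) {
    abort(paste0("rule table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"terminus" %in% names(rules)) rules$terminus <- NA_character_
  if (!"label" %in% names(rules)) rules$label <- rules$pattern
  rules$assay <- toupper(as.character(rules$assay))
  rules$kind <- as.character(rules$kind)
  rules$pattern <- toupper(as.character(rules$pattern))
  rules$terminus <- toupper(as.character(rules$terminus))
  rules$terminus[rules$terminus %in% c("", "NONE", "NA")] <- NA_character_
  rules$effect <- as.integer(rules$effect)
  rules$label <- as.character(rules$label)

  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    bad <- function(msg) abort(sprintf("rule table row %d: %s", i, msg))
    if (!r$assay %in% c("ORAC", "TEAC")) bad(sprintf("unknown assay '%s'", r$assay))
    if (!r$kind %in% c("terminal", "adjacent_pair")) bad(sprintf("unknown kind '%s'", r$kind))
    if (is.na(r$effect) || !r$effect %in% c(-1L, 1L)) {
      bad(sprintf("effect must be -1 or +1, got %s", r$effect))
    }
    letters_i <- strsplit(r$pattern, "")[[1]]
    if (!all(letters_i %in% AA_ALPHABET)) bad(sprintf("pattern '%s' contains a non-canonical residue", r$pattern))
    if (r$kind == "terminal") {
      if (nchar(r$pattern) != 1) bad("terminal rule pattern must be a single residue")
      if (is.na(r$terminus) || !r$terminus %in% c("N", "C")) bad("terminal rule needs terminus 'N' or 'C'")
    } else {
      if (nchar(r$pattern) != 2) bad("adjacent_pair rule pattern must be exactly 2 residues")
    }
  }
  rules[, c("assay", "kind", "pattern", "terminus", "effect", "label")]
}

#' Redox-active amino acid sets
#'
#' Tyr, Trp, Met, Cys and His are redox-active against the peroxyl radical
#' (ORAC assay); against the ABTS cation radical (TEAC assay) only Tyr, Trp
#' and Cys show activity. The `"union"` set is used as the redox-residue count
#' in the integral score for both assays.
#'
#' @param assay `"ORAC"`, `"TEAC"` or `"union"` (case-insensitive).
#' @return Character vector of one-letter residue codes.
#' @examples
#' redox_set("TEAC")
#' @export
redox_set <- function(assay = c("union", "ORAC", "TEAC")) {
  assay <- match_assay(assay[[1]], allow_union = TRUE)
  switch(assay,
    ORAC = c("Y", "W", "M", "C", "H"),
    TEAC = c("Y", "W", "C"),
    union = c("Y", "W", "M", "C", "H")
  )
}

#' Reference antioxidant capacities of free amino acids
#'
#' Measured antioxidant capacities (mean and SD, µmol trolox equivalents per
#' µmol) of the five redox-active free amino acids against the peroxyl radical
#' (ORAC) and the ABTS cation radical (TEAC). All entries carry
#' `provenance = "printed"`.
#'
#' @return A tibble with columns `species`, `assay`, `mean`, `sd`,
#'   `provenance`.
#' @export
aa_activity <- function() {
  tibble::tribble(
    ~species, ~assay,  ~mean,  ~sd,   ~provenance,
    "Tyr",    "ORAC",  1.02,   0.03,  "printed",
    "Trp",    "ORAC",  2.79,   0.05,  "printed",
    "Cys",    "ORAC",  0.49,   0.04,  "printed",
    "Met",    "ORAC",  0.49,   0.03,  "printed",
    "His",    "ORAC",  0.078,  0.003, "printed",
    "Tyr",    "TEAC",  3.38,   0.07,  "printed",
    "Trp",    "TEAC",  3.33,   0.05,  "printed",
    "Cys",    "TEAC",  2.04,   0.12,  "printed",
    "Met",    "TEAC",  0,      0,     "printed",
    "His",    "TEAC",  0,      0,     "printed"
  )
}

#' Terminal-residue contributions to dipeptide antioxidant capacity
#'
#' Additive contributions (µmol TE/µmol) of a residue placed at the N- or
#' C-terminus of a dipeptide, used to compute theoretical (additive)
#' dipeptide antioxidant capacities. Provenance flags distinguish values
#' printed in the source measurements (`"printed"`: the mean TEAC of
#' N-/C-terminal Tyr dipeptides, 4.81/1.70; the ORAC of C-terminal Met
#' dipeptides, 0.45), values derived by arithmetic on printed numbers
#' (`"derived"`: e.g. the TEAC Trp terminals 3.30/2.60 read off Trp-Met and
#' Met-Trp given that Met contributes nothing against ABTS), and coarse
#' bar-chart approximations (`"figure"`). Figure-provenance values are
#' approximate and must not be used in exact comparisons.
#'
#' @return A tibble with columns `residue`, `terminus`, `assay`, `value`,
#'   `provenance`.
#' @export
terminal_contributions <- function() {
  tibble::tribble(
    ~residue, ~terminus, ~assay,  ~value, ~provenance,
    "Y",      "N",       "TEAC",  4.81,   "printed",
    "Y",      "C",       "TEAC",  1.70,   "printed",
    "W",      "N",       "TEAC",  3.30,   "derived",
    "W",      "C",       "TEAC",  2.60,   "derived",
    "M",      "N",       "TEAC",  0,      "printed",
    "M",      "C",       "TEAC",  0,      "printed",
    "H",      "N",       "TEAC",  0,      "printed",
    "H",      "C",       "TEAC",  0,      "printed",
    "Y",      "N",       "ORAC",  1.0,    "figure",
    "Y",      "C",       "ORAC",  1.0,    "figure",
    "W",      "N",       "ORAC",  2.6,    "figure",
    "W",      "C",       "ORAC",  2.6,    "figure",
    "M",      "N",       "ORAC",  0.39,   "derived",
    "M",      "C",       "ORAC",  0.45,   "printed",
    "H",      "N",       "ORAC",  0.078,  "derived",
    "H",      "C",       "ORAC",  0.078,  "derived"
  )
}

# normalize an assay label; errors on anything unknown
match_assay <- function(assay, allow_both = FALSE, allow_union = FALSE) {
  if (length(assay) != 1 || is.na(assay)) abort("assay must be a single label")
  a <- toupper(as.character(assay))
  if (a == "UNION") a <- "union"
  if (a == "BOTH") a <- "both"
  ok <- c("ORAC", "TEAC", if (allow_both) "both", if (allow_union) "union")
  if (!a %in% ok) {
    abort(sprintf("unknown assay '%s' (expected one of: %s)", assay, paste(ok, collapse = ", ")))
  }
  a
}
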