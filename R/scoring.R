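#' Parse and validate peptide sequences
#'
#' `as_peptide()` normalizes a peptide given either in one-letter code
#' (`"WY"`) or hyphenated three-letter code (`"Trp-Tyr"`) to an upper-case
#' one-letter string over the 20 canonical residues; non-canonical letters
#' raise an error naming the offending position.
#'
#' @param x Character vector of sequences.
#' @return Character vector of validated one-letter sequences.
#' @examples
#' as_peptide("Trp-Tyr")
#' @export
as_peptide <- function(x) {
  vapply(as.character(x), parse_one_peptide, character(1), USE.NAMES = FALSE)
}

parse_one_peptide <- function(s) {
  if (is.na(s) || nchar(s) == 0) abort("peptide sequence must be non-empty")
  if (grepl("-", s, fixed = TRUE)) {
    three <- strsplit(s, "-", fixed = TRUE)[[1]]
    # invert Biostrings' one->three letter map, case-insensitively
    code <- Biostrings::AMINO_ACID_CODE[AA_ALPHABET]
    lookup <- setNames(names(code), toupper(code))
    one <- lookup[toupper(three)]
    if (any(is.na(one))) {
      bad <- which(is.na(one))[1]
      abort(sprintf("unknown residue name '%s' at position %d of '%s'", three[bad], bad, s))
    }
    return(paste(one, collapse = ""))
  }
  seq <- toupper(s)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("invalid residue '%s' at position %d of '%s'", chars[bad[1]], bad[1], s))
  }
  seq
}

#' Positions of redox-active residues
#'
#' Returns the 1-based positions of residues belonging to the redox-active set
#' (Tyr, Trp, Met, Cys, His — the union over both assays, which is the count
#' `n` entering the integral score).
#'
#' @param sequence A single peptide sequence (one-letter or `Xxx-Yyy` form).
#' @return Integer vector of positions, ascending.
#' @examples
#' find_redox_sites("YGMCH")
#' @export
find_redox_sites <- function(sequence) {
  seq <- as_peptide(sequence)
  chars <- strsplit(seq, "")[[1]]
  which(chars %in% redox_set("union"))
}

#' Match effect rules against a peptide
#'
#' Terminal rules are tested against the first and last residue only;
#' adjacent-pair rules are tested against every consecutive ordered residue
#' pair. Each occurrence is reported once with its effect; overlapping
#' matches all count.
#'
#' @param sequence A single peptide sequence.
#' @param assay `"ORAC"` or `"TEAC"`.
#' @param rules A rule table from [aox_rules()].
#' @return A tibble with columns `label`, `kind`, `pattern`, `position`
#'   (1-based position of the matched residue or of the first residue of the
#'   pair), `effect`. Zero rows when nothing matches.
#' @examples
#' match_rules("WY", "ORAC")
#' @export
match_rules <- function(sequence, assay, rules = aox_rules()) {
  assay <- match_assay(assay)
  seq <- as_peptide(sequence)
  chars <- strsplit(seq, "")[[1]]
  n_len <- length(chars)
  rules <- dplyr::filter(validate_rules(rules), .data$assay == !!assay)

  hits <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (r$kind == "terminal") {
      pos <- if (r$terminus == "N") 1L else n_len
      if (chars[pos] == r$pattern) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          label = r$label, kind = r$kind, pattern = r$pattern,
          position = pos, effect = r$effect
        )
      }
    } else {
      if (n_len >= 2) {
        pairs <- paste0(chars[-n_len], chars[-1])
        at <- which(pairs == r$pattern)
        if (length(at) > 0) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            label = r$label, kind = r$kind, pattern = r$pattern,
            position = as.integer(at), effect = r$effect
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(
      label = character(), kind = character(), pattern = character(),
      position = integer(), effect = integer()
    ))
  }
  dplyr::bind_rows(hits)
}

#' Integral antioxidant score of a peptide
#'
#' Computes the integral scoring parameter
#' \deqn{I = \left[\frac{\sum_i E_i}{n}\right] \times \frac{10}{N}}
#' where the \eqn{E_i} are the effects (+/-1) of all matched empirical rules
#' (each matched motif occurrence counted once), \eqn{n} is the number of
#' redox-active residues (Tyr/Trp/Met/Cys/His) in the peptide and \eqn{N} is
#' its length. The 10/N factor encodes the empirical decline of peptide
#' antioxidant capacity with chain length, normalized to the ~10-residue
#' length typical of active peptides. A peptide with no redox-active residues
#' has no radical chemistry available and scores 0 by convention. `I` is a
#' dimensionless ranking score, not a quantitative activity prediction.
#'
#' `score_peptide()` scores one sequence; `score_peptides()` is the
#' data-frame-first verb (column `sequence`, extra columns preserved).
#'
#' @param sequence A single peptide sequence.
#' @param assay `"ORAC"` or `"TEAC"`.
#' @param rules Rule table, see [aox_rules()].
#' @return A one-row tibble with columns `sequence`, `assay`, `score` (I),
#'   `sum_effects`, `n_redox`, `length` and a list-column `matches` holding
#'   the full match breakdown.
#' @examples
#' score_peptide("WY", "ORAC") # I = (1/2) * (10/2) = 2.5
#' @export
score_peptide <- function(sequence, assay, rules = aox_rules()) {
  assay <- match_assay(assay)
  seq <- as_peptide(sequence)
  m <- match_rules(seq, assay, rules)
  n_redox <- length(find_redox_sites(seq))
  n_len <- nchar(seq)
  sum_effects <- sum(m$effect)
  score <- if (n_redox == 0) 0 else (sum_effects / n_redox) * (10 / n_len)
  tibble::tibble(
    sequence = seq, assay = assay, score = score,
    sum_effects = as.integer(sum_effects), n_redox = as.integer(n_redox),
    length = as.integer(n_len), matches = list(m)
  )
}

#' @rdname score_peptide
#' @param data A data frame with a `sequence` column.
#' @export
score_peptides <- function(data, assay, rules = aox_rules()) {
  data <- tibble::as_tibble(data)
  if (!"sequence" %in% names(data)) abort("data must have a 'sequence' column")
  if (nrow(data) == 0) {
    return(tibble::tibble(
      sequence = character(), assay = character(), score = numeric(),
      sum_effects = integer(), n_redox = integer(), length = integer(),
      matches = list()
    ))
  }
  scored <- purrr::map(data$sequence, score_peptide, assay = assay, rules = rules)
  scored <- dplyr::bind_rows(scored)
  extra <- data[, setdiff(names(data), names(scored)), drop = FALSE]
  dplyr::bind_cols(extra, scored)
}

#' Enumerate candidate peptides from a protein sequence
#'
#' `mode = "window"` returns every substring with length in
#' `[min_len, max_len]`, deduplicated by sequence (first occurrence kept).
#' `mode = "tryptic"` performs an in-silico tryptic digest — cleavage after
#' Lys/Arg except when the next residue is Pro — and then applies the length
#' bounds to the fragments.
#'
#' @param protein A single protein sequence (one-letter code).
#' @param min_len,max_len Length bounds (default 2-10, the size range of
#'   typical antioxidant peptides).
#' @param mode `"window"` or `"tryptic"`.
#' @return A tibble with columns `sequence`, `start` (1-based position in the
#'   protein), `length`.
#' @examples
#' enumerate_peptides("ACD", min_len = 2, max_len = 2)
#' @export
enumerate_peptides <- function(protein, min_len = 2, max_len = 10,
                               mode = c("window", "tryptic")) {
  mode <- match.arg(mode)
  seq <- as_peptide(protein)
  n <- nchar(seq)
  if (!(min_len >= 1 && min_len <= max_len)) {
    abort("need 1 <= min_len <= max_len")
  }
  if (mode == "window") {
    out <- list()
    for (k in seq(min_len, min(max_len, n))) {
      starts <- seq_len(n - k + 1)
      out[[length(out) + 1]] <- tibble::tibble(
        sequence = substring(seq, starts, starts + k - 1),
        start = starts, length = k
      )
    }
    res <- dplyr::bind_rows(out)
    res[!duplicated(res$sequence), ]
  } else {
    frags <- tryptic_fragments(seq)
    res <- dplyr::filter(frags, .data$length >= min_len, .data$length <= max_len)
    res
  }
}

tryptic_fragments <- function(seq) {
  # cleave after K/R unless followed by P
  cut_after <- gregexpr("(?<=[KR])(?!P)", seq, perl = TRUE)[[1]]
  cuts <- if (cut_after[1] == -1) integer() else as.integer(cut_after) - 1L
  bounds <- c(0L, cuts[cuts < nchar(seq)], nchar(seq))
  starts <- utils::head(bounds, -1) + 1L
  ends <- bounds[-1]
  tibble::tibble(
    sequence = substring(seq, starts, ends),
    start = starts, length = ends - starts + 1L
  )
}

#' Score and rank candidate peptides
#'
#' Scores every sequence and orders the result by decreasing integral score,
#' breaking ties lexicographically by sequence so that the ranking is
#' deterministic.
#'
#' @param data A data frame with a `sequence` column (e.g. from
#'   [enumerate_peptides()]), or a character vector of sequences.
#' @param assay `"ORAC"` or `"TEAC"`.
#' @param rules Rule table.
#' @param top Optionally keep only the `top` highest-scoring peptides.
#' @return A scored tibble (see [score_peptides()]) in rank order, with a
#'   `rank` column prepended.
#' @examples
#' rank_peptides(c("GM", "WY", "AAA"), "ORAC")
#' @export
rank_peptides <- function(data, assay, rules = aox_rules(), top = NULL) {
  if (is.character(data)) data <- tibble::tibble(sequence = data)
  scored <- score_peptides(data, assay, rules)
  scored <- dplyr::arrange(scored, dplyr::desc(.data$score), .data$sequence)
  if (!is.null(top)) scored <- utils::head(scored, top)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(scored))), scored)
}
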