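#' Read peptide or protein sequences from FASTA
#'
#' Sequences are upper-cased and validated against the 20-letter canonical
#' alphabet; record order and ids are preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(sprintf("no FASTA records in %s", path))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0) {
      abort(sprintf(
        "record %d ('%s'): non-canonical residue '%s' at position %d",
        i, names(set)[i], chars[bad[1]], bad[1]
      ))
    }
  }
  tibble::tibble(id = names(set), sequence = unname(seqs))
}

#' Read a long-format kinetic plate CSV
#'
#' Expects columns `well`, `sample_id`, `role`, `conc_um`, `time`, `signal`.
#' Rows are sorted by well and time; duplicate time points within a well and
#' non-increasing time grids are rejected.
#'
#' @param path Path to the CSV file.
#' @param time_unit `"min"` (default) or `"s"`; seconds are converted to
#'   minutes.
#' @return A validated plate tibble.
#' @export
read_plate_csv <- function(path, time_unit = c("min", "s")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  plate <- readr::read_csv(path, show_col_types = FALSE)
  validate_plate(plate, time_unit)
}

#' Write a plate table to CSV
#'
#' @param plate A plate tibble (see [read_plate_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  readr::write_csv(plate, path)
  invisible(path)
}

# read a rule override table: CSV, JSON or YAML by extension
read_rules <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE),
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    yml = ,
    yaml = dplyr::bind_rows(lapply(yaml::read_yaml(path), tibble::as_tibble)),
    abort(sprintf("unsupported rule file format '.%s' (use csv, json or yaml)", ext))
  )
  raw
}
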