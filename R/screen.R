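#' Pearson correlation with a t-based significance test
#'
#' Product-moment correlation between two numeric vectors with the usual
#' two-sided p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return A one-row tibble with columns `r`, `p_value`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation is undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  tibble::tibble(r = r, p_value = p, n = as.integer(n))
}

#' Drop peptides containing ionogenic residues
#'
#' Peptides with charged side chains (Asp, Glu, Lys, Arg) have gas-phase
#' descriptors dominated by the ionogenic group rather than the redox-active
#' residue, so they are excluded before descriptor-activity correlation.
#'
#' @param data A data frame with a `sequence` column.
#' @return The retained rows, original order preserved; warns if everything
#'   was removed.
#' @examples
#' filter_ionogenic(tibble::tibble(sequence = c("MK", "MA", "EM")))
#' @export
filter_ionogenic <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"sequence" %in% names(data)) abort("data must have a 'sequence' column")
  seqs <- as_peptide(data$sequence)
  keep <- !stringr::str_detect(seqs, paste0("[", paste(IONOGENIC, collapse = ""), "]"))
  out <- data[keep, ]
  if (nrow(data) > 0 && nrow(out) == 0) {
    warn("all peptides contain ionogenic residues; nothing retained")
  }
  out
}

# greek descriptor symbols accepted as aliases of the ascii column names
descriptor_alias <- function(x) {
  map <- c(
    "χ" = "chi", "η" = "eta", "ω" = "omega",
    "CHI" = "chi", "ETA" = "eta", "OMEGA" = "omega",
    "IPE" = "ipe", "IPO" = "ipo", "BDE" = "bde", "GAP" = "gap"
  )
  out <- x
  hit <- match(x, names(map))
  out[!is.na(hit)] <- map[hit[!is.na(hit)]]
  hit2 <- match(toupper(x), names(map))
  out[!is.na(hit2)] <- map[hit2[!is.na(hit2)]]
  out
}

#' Descriptor-activity correlation screen
#'
#' Correlates an activity column against each requested descriptor column,
#' optionally after removing ionogenic peptides, and reports Pearson r, the
#' two-sided p-value, n, and a significance flag at `alpha`. A constant
#' descriptor column is reported with `r = NA` (undefined) without affecting
#' the others. Greek symbols for electronegativity, hardness and
#' electrophilicity are accepted as aliases of `chi`, `eta`, `omega`.
#'
#' @param data A data frame with the activity column, descriptor columns and
#'   (if `apply_filter`) a `sequence` column.
#' @param descriptors Character vector of descriptor column names.
#' @param response Name of the activity column (default `"aoc"`).
#' @param alpha Significance level (default 0.05).
#' @param apply_filter Exclude ionogenic peptides first (default `TRUE`).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, matching a per-descriptor report; `"bonferroni"`
#'   available).
#' @return A tibble with columns `descriptor`, `r`, `p_value`, `n`,
#'   `significant`.
#' @examples
#' tab <- sim_descriptor_table(n = 14, seed = 1)
#' screen_descriptors(tab, c("ipe", "chi", "omega"))
#' @export
screen_descriptors <- function(data, descriptors, response = "aoc",
                               alpha = 0.05, apply_filter = TRUE,
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  data <- tibble::as_tibble(data)
  if (apply_filter && "sequence" %in% names(data)) {
    data <- filter_ionogenic(data)
  }
  descriptors_resolved <- descriptor_alias(descriptors)
  names(data) <- ifelse(names(data) %in% c("χ", "η", "ω"),
    descriptor_alias(names(data)), names(data)
  )
  if (!response %in% names(data)) {
    abort(sprintf("activity column '%s' not found", response))
  }
  missing <- setdiff(descriptors_resolved, names(data))
  if (length(missing) > 0) {
    abort(paste0("descriptor column(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 3) abort("fewer than 3 peptides after filtering")

  res <- purrr::map2(descriptors_resolved, descriptors, function(col, shown) {
    x <- data[[col]]
    y <- data[[response]]
    if (stats::sd(x) == 0) {
      tibble::tibble(descriptor = shown, r = NA_real_, p_value = NA_real_,
                     n = as.integer(length(x)))
    } else {
      pc <- pearson_cor(x, y)
      tibble::tibble(descriptor = shown, r = pc$r, p_value = pc$p_value, n = pc$n)
    }
  })
  out <- dplyr::bind_rows(res)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
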