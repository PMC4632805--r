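# Independent oracles used across test files. These deliberately do not call
# the package's rule table or scoring engine: the motif dictionaries are
# written out literally and the arithmetic is re-derived from first
# principles, so agreement is a genuine cross-check.

# brute-force product-moment correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# literal effect dictionaries (ordered pairs / terminal residues -> effect)
oracle_pair_effects <- list(
  ORAC = c(WY = 1, KY = -1, RY = -1, YE = -1, YD = -1, YK = 1, YR = 1),
  TEAC = c(YH = 1, HY = 1, MY = 1, KY = 1, RY = 1)
)
oracle_terminal_effects <- list(
  ORAC = list(N = c(), C = c(M = 1)),
  TEAC = list(N = c(Y = 1, W = 1), C = c())
)
oracle_redox <- c("Y", "W", "M", "C", "H")

# sum of matched effects for a peptide, enumerated by hand logic
oracle_sum_effects <- function(seq, assay) {
  chars <- strsplit(seq, "")[[1]]
  n_len <- length(chars)
  total <- 0
  term <- oracle_terminal_effects[[assay]]
  if (chars[1] %in% names(term$N)) total <- total + term$N[[chars[1]]]
  if (chars[n_len] %in% names(term$C)) total <- total + term$C[[chars[n_len]]]
  pairs <- oracle_pair_effects[[assay]]
  if (n_len >= 2) {
    for (i in seq_len(n_len - 1)) {
      pp <- paste0(chars[i], chars[i + 1])
      if (pp %in% names(pairs)) total <- total + pairs[[pp]]
    }
  }
  total
}

oracle_integral_score <- function(seq, assay) {
  chars <- strsplit(seq, "")[[1]]
  n_redox <- sum(chars %in% oracle_redox)
  if (n_redox == 0) {
    return(0)
  }
  (oracle_sum_effects(seq, assay) / n_redox) * (10 / length(chars))
}

# analytic trapezoid of exp(-k t) on an even grid (closed form of the sum)
oracle_trapz_exp <- function(k, h, n_steps) {
  q <- exp(-k * h)
  h * ((1 + q^n_steps) / 2 + (q - q^n_steps) / (1 - q))
}
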