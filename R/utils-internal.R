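# Internal helpers shared across modules.

# NFKC-normalize, trim, and case-fold Latin letters. All fuzzy matching and
# vocabulary intersection happens in this canonical space so that full-width
# and half-width variants of the same string compare equal.
canonicalize <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- stringr::str_trim(x)
  # fold A-Z only; non-Latin scripts are left to NFKC
  chartr(paste(LETTERS, collapse = ""), paste(letters, collapse = ""), x)
}

# Zero-truncated Poisson draw (support >= 1) via the inverse-CDF trick, so a
# single runif() call per value keeps the RNG stream easy to reason about.
rtpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

# Random lowercase-letter strings, the surface alphabet of the generator.
rand_lower <- function(n, min_len = 8L, max_len = 12L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(k) {
    paste(sample(letters, k, replace = TRUE), collapse = "")
  }, character(1))
}

# Random digit strings used as filler tokens (disjoint alphabet from
# surfaces, so the substring tagger can never match inside filler).
rand_filler <- function(n, len = 12L) {
  vapply(seq_len(n), function(i) {
    paste(sample(0:9, len, replace = TRUE), collapse = "")
  }, character(1))
}

abort_bad <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

icd_pattern <- "^[A-Z][0-9]{2,3}[0-9]?$"

is_icd_shaped <- function(x) stringr::str_detect(x, icd_pattern)
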