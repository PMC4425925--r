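#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how rates and
#' enrichment ratios are conventionally displayed (base [round()] uses
#' round-half-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(0.65, 1)  # 0.7
#' roundHalfUp(2.45, 1)  # 2.5
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

## Internal: derive a stream-specific 32-bit seed from a master seed.
## Keeps every sub-generator reproducible under one user-facing seed.
.splitSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 1009L + (stream %% 997L)
}

.isNucleotide <- function(x) {
  all(grepl("^[ACGTUNacgtun]*$", x))
}

## Half-open interval overlap on 0-based coordinates.
.overlapsHalfOpen <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
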