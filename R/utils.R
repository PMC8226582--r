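#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' all printed percentages and megabase spans in this package), rather than
#' the round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a stream name,
# so each simulator stage draws from its own stream.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Internal call coding used throughout: mutant-background parent = A,
# mapping parent = B.
.call_levels <- c("HOM_A", "HET", "HOM_B", "MISSING")

# A-allele dosage of a diploid call (NA for MISSING).
call_dosage <- function(call) {
  unname(c(HOM_A = 2, HET = 1, HOM_B = 0, MISSING = NA_real_)[call])
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
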