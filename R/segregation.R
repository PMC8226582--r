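#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit test of observed phenotype-class counts against an
#' expected integer ratio such as 3:1 (single recessive gene) or 15:1
#' (duplicate recessive genes), with `classes - 1` degrees of freedom and no
#' continuity correction. The observed ratio is also reported as
#' `"x.xx:1"` using the first and last classes, e.g. `"2.58:1"` for 62
#' green : 24 yellowish-green seedlings.
#'
#' @param observed Integer vector of observed class counts (length >= 2).
#' @param ratio Expected integer ratio, same length (default `c(3, 1)`).
#' @param classes Optional class names.
#' @return Object of class `segregation_test`: list with `observed`,
#'   `expected`, `ratio`, `classes`, `chi_square`, `df`, `p_value`,
#'   `ratio_text`.
#' @export
#' @examples
#' chi_square_segregation(c(62, 24), c(3, 1)) # p = 0.53, ratio "2.58:1"
chi_square_segregation <- function(observed, ratio = c(3, 1), classes = NULL) {
  if (length(observed) < 2 || length(ratio) != length(observed)) {
    stop("need >= 2 classes with a matching expected ratio", call. = FALSE)
  }
  if (sum(observed) <= 0) stop("total count must be positive", call. = FALSE)
  if (any(ratio <= 0)) stop("expected ratio classes must be positive", call. = FALSE)
  p <- ratio / sum(ratio)
  ht <- suppressWarnings(stats::chisq.test(observed, p = p))
  structure(
    list(
      observed = observed,
      expected = unname(ht$expected),
      ratio = ratio,
      classes = classes %||% paste0("class", seq_along(observed)),
      chi_square = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = unname(ht$p.value),
      ratio_text = sprintf(
        "%.2f:1",
        round_half_up(observed[1] / observed[length(observed)], 2)
      )
    ),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(
    "Segregation test: observed %s (%s) vs expected %s\n  chi-square = %.4g, df = %d, p = %.3g\n",
    paste(x$observed, collapse = ":"), x$ratio_text,
    paste(x$ratio, collapse = ":"), x$chi_square, x$df, x$p_value
  ))
  invisible(x)
}

#' Abortion rate as a percentage
#'
#' `100 * abortive / total`, rounded half-up to two decimals — the
#' convention for reporting ovule/seed abortion rates in cross progenies
#' (an elevated rate in heterozygote progenies is the phenotypic signature
#' of a recessive lethal).
#'
#' @param abortive Number of abortive ovules/seeds.
#' @param total Total ovules/seeds counted (> 0).
#' @return Percentage with two decimals.
#' @export
#' @examples
#' abortion_rate(209, 789) # 26.49
abortion_rate <- function(abortive, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(abortive < 0) || any(abortive > total)) {
    stop("abortive count must lie in [0, total]", call. = FALSE)
  }
  round_half_up(100 * abortive / total, 2)
}
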