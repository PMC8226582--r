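#' Marker index of a pooled allele count
#'
#' The fraction of reads supporting one allele at a site,
#' `alt / (alt + ref)`. In a phenotype-selected pool the marker index at a
#' site measures the frequency of the mutant-background parent's allele
#' (after orientation, see [orient_to_mutant_background()]): near 1 around a
#' causal locus in a homozygous F2 design, near 0.5 in a heterozygous
#' backcross design, and near the unlinked background elsewhere.
#'
#' @param alt_count,ref_count Non-negative read counts (vectorized).
#' @return Fraction in `[0, 1]`; `NA` where `alt_count + ref_count == 0`
#'   (such sites are later removed by [depth_filter()]).
#' @export
#' @examples
#' marker_index(13, 27) # 0.325
#' marker_index(20, 0)  # 1
marker_index <- function(alt_count, ref_count) {
  total <- alt_count + ref_count
  ifelse(total > 0, alt_count / total, NA_real_)
}

#' Delta marker index between mutant and control pools
#'
#' Mutant-pool index minus control-pool index, so that causal regions are
#' positive. Around a causal locus the expectation is about 1 for a
#' homozygous F2 design and about 0.5 for a heterozygous backcross design.
#'
#' @param mut_index,ctrl_index Fractions in `[0, 1]` (vectorized).
#' @return Signed fraction in `[-1, 1]`.
#' @export
delta_index <- function(mut_index, ctrl_index) {
  mut_index - ctrl_index
}

#' Orient pooled counts to the mutant-background parent's allele
#'
#' The genome scan counts the mutant-background parent's allele, but variant
#' callers report counts relative to the reference genome, which may match
#' either parent at any given site. This swaps `ref`/`alt` slots (alleles and
#' counts, both pools) where needed so that the `alt` slots always hold the
#' mutant-background allele. The operation is idempotent.
#'
#' When `background_is_ref` is `NULL`, the parental state is inferred from
#' the control pool (a resequenced mapping-parent pool): a control index
#' `<= fixed_low` means the mapping parent is fixed for the reference allele,
#' so the background parent carries the alternate (no swap); `>= fixed_high`
#' means the reverse (swap). Sites with intermediate control index cannot be
#' oriented and are flagged `ambiguous` (excluded from scans).
#'
#' @param variants Tibble of pooled variants with columns `chrom`, `pos`,
#'   `ref`, `alt`, `mut_ref`, `mut_alt`, `ctrl_ref`, `ctrl_alt`.
#' @param background_is_ref Optional logical vector (recycled): `TRUE` where
#'   the mutant-background parent carries the reference allele. If `NULL`,
#'   inferred from the control pool as described above.
#' @param fixed_low,fixed_high Control-index thresholds used to call the
#'   mapping parent's allele when inferring orientation.
#' @return The input tibble with counts/alleles swapped where needed and two
#'   logical columns: `swapped` (the mapping parent carries the non-reference
#'   allele here, i.e. the site is a parental polymorphism visible in the
#'   control pool) and `ambiguous` (orientation could not be resolved; such
#'   sites are dropped by [pool_site_stats()]).
#' @export
orient_to_mutant_background <- function(variants, background_is_ref = NULL,
                                        fixed_low = 0.1, fixed_high = 0.9) {
  assert_columns(variants, c("ref", "alt", "mut_ref", "mut_alt", "ctrl_ref", "ctrl_alt"))
  ambiguous <- rep(FALSE, nrow(variants))
  if (is.null(background_is_ref)) {
    ctrl_idx <- marker_index(variants$ctrl_alt, variants$ctrl_ref)
    # control fixed alt => mapping parent carries alt => background carries ref
    background_is_ref <- !is.na(ctrl_idx) & ctrl_idx >= fixed_high
    ambiguous <- is.na(ctrl_idx) | (ctrl_idx > fixed_low & ctrl_idx < fixed_high)
  } else {
    background_is_ref <- rep_len(as.logical(background_is_ref), nrow(variants))
  }
  swap <- background_is_ref & !ambiguous
  out <- variants
  out[swap, c("ref", "alt")] <- variants[swap, c("alt", "ref")]
  out[swap, c("mut_ref", "mut_alt")] <- variants[swap, c("mut_alt", "mut_ref")]
  out[swap, c("ctrl_ref", "ctrl_alt")] <- variants[swap, c("ctrl_alt", "ctrl_ref")]
  out$swapped <- swap
  out$ambiguous <- ambiguous
  out
}

#' G statistic for a 2x2 pooled allele-count table
#'
#' Log-likelihood-ratio statistic `G = 2 * sum(n_i * log(n_i / nhat_i))` over
#' the allele-by-pool table with counts `n1` (mutant pool, allele A),
#' `n2` (mutant pool, allele B), `n3` (control pool, allele A), `n4`
#' (control pool, allele B). Expected counts `nhat_i` come from the
#' independence margins (row total x column total / grand total). Large
#' values flag sites whose pooled allele proportions differ between pools,
#' i.e. sites linked to the selected phenotype.
#'
#' Conventions: `0 * log(0/x) = 0`; a table with a zero row or column margin
#' is degenerate and returns `G = 0`, so scans never emit non-finite values.
#'
#' @param n1,n2,n3,n4 Non-negative read counts (vectorized).
#' @return Non-negative G values; 0 whenever the two pools have identical
#'   allele proportions.
#' @export
#' @examples
#' g_statistic(10, 10, 10, 10) # 0
#' g_statistic(20, 0, 10, 10)  # > 0
g_statistic <- function(n1, n2, n3, n4) {
  n <- cbind(n1, n2, n3, n4)
  total <- rowSums(n)
  # margins: pools are rows (n1,n2 | n3,n4), alleles are columns (n1,n3 | n2,n4)
  pool1 <- n1 + n2
  pool2 <- n3 + n4
  alleleA <- n1 + n3
  alleleB <- n2 + n4
  expected <- cbind(pool1 * alleleA, pool1 * alleleB, pool2 * alleleA, pool2 * alleleB) /
    ifelse(total > 0, total, 1)
  term <- ifelse(n > 0 & expected > 0, n * log(n / expected), 0)
  g <- 2 * rowSums(term)
  degenerate <- total == 0 | pool1 == 0 | pool2 == 0 | alleleA == 0 | alleleB == 0
  g[degenerate] <- 0
  pmax(unname(g), 0)
}

#' Per-site scan statistics from pooled variant counts
#'
#' Computes, for every pooled variant, the mutant- and control-pool marker
#' indexes, their difference (delta index) and the G statistic, together with
#' the per-pool read support used by [depth_filter()].
#'
#' @param variants Tibble of pooled variants (see [read_pooled_variants()]);
#'   rows flagged `ambiguous` by [orient_to_mutant_background()] are dropped.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `vclass`,
#'   `support_mut`, `support_ctrl`, `mut_index`, `ctrl_index`, `delta_index`,
#'   `g_value`, ordered by (`chrom`, `pos`).
#' @export
pool_site_stats <- function(variants) {
  assert_columns(variants, c("chrom", "pos", "mut_ref", "mut_alt", "ctrl_ref", "ctrl_alt"))
  if ("ambiguous" %in% names(variants)) {
    variants <- dplyr::filter(variants, !.data$ambiguous)
  }
  out <- variants |>
    dplyr::mutate(
      support_mut = .data$mut_alt + .data$mut_ref,
      support_ctrl = .data$ctrl_alt + .data$ctrl_ref,
      mut_index = marker_index(.data$mut_alt, .data$mut_ref),
      ctrl_index = marker_index(.data$ctrl_alt, .data$ctrl_ref),
      delta_index = delta_index(.data$mut_index, .data$ctrl_index),
      g_value = g_statistic(.data$mut_alt, .data$mut_ref, .data$ctrl_alt, .data$ctrl_ref)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  keep <- intersect(
    c(
      "chrom", "pos", "ref", "alt", "vclass", "support_mut", "support_ctrl",
      "mut_index", "ctrl_index", "delta_index", "g_value"
    ),
    names(out)
  )
  tibble::as_tibble(out[keep])
}

#' Filter sites by per-pool read support
#'
#' Retains sites whose supporting reads exceed `min_exceeded` in *both*
#' pools (strictly more than, so the default keeps sites with at least 9
#' supporting reads per pool). Order is preserved; the number of removed
#' sites is reported as a message and in the `removed` attribute.
#'
#' @param stats Tibble with `support_mut` and `support_ctrl` columns
#'   (see [pool_site_stats()]).
#' @param min_exceeded Support threshold that must be exceeded (default 8).
#' @param quiet Suppress the removal message.
#' @return Filtered tibble with attribute `removed` = number of dropped rows.
#' @export
depth_filter <- function(stats, min_exceeded = 8, quiet = FALSE) {
  assert_columns(stats, c("support_mut", "support_ctrl"))
  keep <- !is.na(stats$support_mut) & !is.na(stats$support_ctrl) &
    stats$support_mut > min_exceeded & stats$support_ctrl > min_exceeded
  out <- stats[keep, , drop = FALSE]
  removed <- sum(!keep)
  if (!quiet && removed > 0) {
    message(sprintf("depth_filter: removed %d site(s) with <= %d supporting reads in a pool", removed, min_exceeded))
  }
  attr(out, "removed") <- removed
  out
}
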