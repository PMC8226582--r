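#' Sliding-window delta-index profile
#'
#' Averages the per-site delta index in sliding windows along each
#' chromosome. Windows are anchored at position 1 and advance by `step`
#' while the window start does not exceed the chromosome length; each window
#' spans `[start, start + window - 1]`. Windows holding fewer than
#' `min_sites` sites are masked (`mean_delta = NA`): sparse windows say
#' nothing reliable about the local allele frequency.
#'
#' The defaults mirror common practice for pooled scans of this kind:
#' a 100 kb window advanced in 20 kb steps (use 500 kb / 100 kb for sparser
#' marker sets).
#'
#' @param stats Per-site statistics tibble (see [pool_site_stats()]), sorted
#'   by position within each chromosome; unsorted input is an error.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp); must
#'   cover every chromosome present in `stats`.
#' @param window Window size in bp (default 100,000).
#' @param step Step size in bp (default 20,000); `0 < step <= window`.
#' @param min_sites Minimum sites for a window to carry a value (default 3).
#' @return Tibble of class `bsa_profile` with columns `chrom`, `start`,
#'   `end`, `n_sites`, `mean_delta` and attributes `window` and `step`.
#' @export
sliding_window_profile <- function(stats, chrom_lengths, window = 1e5, step = 2e4,
                                   min_sites = 3) {
  assert_columns(stats, c("chrom", "pos", "delta_index"))
  stopifnot(step > 0, step <= window)
  chroms <- unique(stats$chrom)
  missing_len <- setdiff(chroms, names(chrom_lengths))
  if (length(missing_len) > 0) {
    stop("no chromosome length for: ", paste(missing_len, collapse = ", "), call. = FALSE)
  }
  unsorted <- stats |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
  if (any(!unsorted$ok)) {
    stop("sites must be sorted by position within chromosome", call. = FALSE)
  }
  profile <- purrr::map_dfr(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(1, len, by = step)
    s <- stats[stats$chrom == chr, ]
    n_sites <- integer(length(starts))
    mean_delta <- rep(NA_real_, length(starts))
    if (nrow(s) > 0) {
      # window k covers [starts[k], starts[k]+window-1]; a site at pos p falls in
      # windows with start in (p-window, p]
      for (k in seq_along(starts)) {
        in_win <- s$pos >= starts[k] & s$pos <= starts[k] + window - 1
        n_sites[k] <- sum(in_win)
        if (n_sites[k] >= min_sites) {
          mean_delta[k] <- mean(s$delta_index[in_win], na.rm = TRUE)
        }
      }
    }
    tibble::tibble(
      chrom = chr, start = starts, end = pmin(starts + window - 1, Inf),
      n_sites = n_sites, mean_delta = mean_delta
    )
  })
  profile <- tibble::new_tibble(profile, class = "bsa_profile")
  attr(profile, "window") <- window
  attr(profile, "step") <- step
  attr(profile, "min_sites") <- min_sites
  profile
}

#' Call candidate regions from a window profile
#'
#' Maximal runs of consecutive unmasked windows whose mean delta index meets
#' the threshold are merged into intervals spanning from the first window's
#' start to the last window's end. Masked windows (too few sites) break
#' runs. Typical thresholds for this statistic are 0.45-0.6 depending on the
#' design and noise level.
#'
#' @param profile A `bsa_profile` from [sliding_window_profile()].
#' @param threshold Minimum window mean delta index (inclusive).
#' @return Interval tibble: `chrom`, `start`, `end`, `label`, `source`
#'   (`"window_scan"`), `n_windows`, `peak_delta`.
#' @export
call_candidate_regions <- function(profile, threshold) {
  assert_columns(profile, c("chrom", "start", "end", "mean_delta"))
  hits <- profile |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      hit = !is.na(.data$mean_delta) & .data$mean_delta >= threshold,
      run = cumsum(.data$hit & !dplyr::lag(.data$hit, default = FALSE))
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$hit)
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      label = character(), source = character(),
      n_windows = integer(), peak_delta = numeric()
    ))
  }
  hits |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_windows = dplyr::n(),
      peak_delta = max(.data$mean_delta),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(
      label = sprintf("%s:%d-%d", .data$chrom, as.integer(.data$start), as.integer(.data$end)),
      source = "window_scan"
    ) |>
    dplyr::select("chrom", "start", "end", "label", "source", "n_windows", "peak_delta")
}

#' Top-quantile G-value sites
#'
#' Returns the `ceiling(q * N)` sites with the largest G values; ties at the
#' cutoff are all included (never silently dropped). The conventional cut is
#' the top 0.1% of sites.
#'
#' @param stats Per-site statistics tibble with a `g_value` column.
#' @param q Upper quantile fraction (default 0.001).
#' @return The selected rows, sorted by (`chrom`, `pos`).
#' @export
top_quantile_sites <- function(stats, q = 0.001) {
  assert_columns(stats, c("chrom", "pos", "g_value"))
  stopifnot(q > 0, q < 1)
  n <- nrow(stats)
  if (n == 0) {
    return(stats)
  }
  k <- ceiling(q * n)
  cutoff <- sort(stats$g_value, decreasing = TRUE)[k]
  stats |>
    dplyr::filter(.data$g_value >= cutoff) |>
    dplyr::arrange(.data$chrom, .data$pos)
}
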