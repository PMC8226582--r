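#' Candidate variants inside a mapping interval
#'
#' Filters per-site statistics to the sites inside a (closed, 1-based)
#' interval whose delta index meets `delta_min` — the expected delta index at
#' a causal site is about 1 in a homozygous design and about 0.5 in a
#' heterozygous design, so sites below the design's expectation are removed.
#' Output is sorted by descending delta index, then position.
#'
#' @param stats Per-site statistics tibble (depth-filtered and oriented; see
#'   [pool_site_stats()], [depth_filter()]).
#' @param interval One-row tibble (or list) with `chrom`, `start`, `end`.
#' @param delta_min Minimum delta index, inclusive (default 0.5).
#' @return Filtered tibble of candidate sites.
#' @export
candidates_in_interval <- function(stats, interval, delta_min = 0.5) {
  assert_columns(stats, c("chrom", "pos", "delta_index"))
  stats |>
    dplyr::filter(
      .data$chrom == interval$chrom[[1]],
      .data$pos >= interval$start[[1]],
      .data$pos <= interval$end[[1]],
      !is.na(.data$delta_index),
      .data$delta_index >= delta_min
    ) |>
    dplyr::arrange(dplyr::desc(.data$delta_index), .data$pos)
}

#' Remove parental polymorphisms from a candidate list
#'
#' Variants segregating between the two parental genomes are not induced
#' mutations; any candidate whose exact (`chrom`, `pos`, `ref`, `alt`)
#' occurs among the parental sites is flagged `parental_polymorphism` and
#' (by default) excluded. Matching is on the exact allele pair, not position
#' alone, so a true causal site coinciding with a parental SNP position is
#' kept.
#'
#' @param candidates Candidate tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param parent_sites Tibble of parental variants with the same columns.
#' @param keep_flagged Return flagged rows too (default `FALSE`).
#' @return `candidates` with a logical `parental_polymorphism` column,
#'   filtered unless `keep_flagged`.
#' @export
subtract_parental <- function(candidates, parent_sites, keep_flagged = FALSE) {
  assert_columns(candidates, c("chrom", "pos", "ref", "alt"))
  if (nrow(candidates) == 0) {
    candidates$parental_polymorphism <- logical(0)
    return(candidates)
  }
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  parental_keys <- if (nrow(parent_sites) > 0) key(parent_sites) else character(0)
  candidates$parental_polymorphism <- key(candidates) %in% parental_keys
  if (keep_flagged) candidates else dplyr::filter(candidates, !.data$parental_polymorphism)
}

#' Annotate candidate variants with gene context
#'
#' Classifies each candidate as exonic (its affected reference bases overlap
#' an exon), intronic (inside a gene span but no exon) or intergenic, and
#' attaches the gene id for genic classes. For an InDel the affected span is
#' `[pos, pos + nchar(ref) - 1]`. Exonic InDels whose length difference is
#' not a multiple of 3 are flagged `frameshift`.
#'
#' @param candidates Candidate tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models Gene-model tibble from [read_gene_models()].
#' @return `candidates` with `location_class`, `gene_id` and `frameshift`
#'   columns.
#' @export
annotate_location <- function(candidates, gene_models) {
  assert_columns(candidates, c("chrom", "pos", "ref", "alt"))
  n <- nrow(candidates)
  candidates$location_class <- rep("intergenic", n)
  candidates$gene_id <- rep(NA_character_, n)
  candidates$frameshift <- rep(FALSE, n)
  if (n == 0 || nrow(gene_models) == 0) {
    return(candidates)
  }
  var_ir <- function(chr) {
    rows <- which(candidates$chrom == chr)
    IRanges::IRanges(
      start = candidates$pos[rows],
      end = candidates$pos[rows] + nchar(candidates$ref[rows]) - 1
    )
  }
  for (chr in unique(candidates$chrom)) {
    rows <- which(candidates$chrom == chr)
    ir <- var_ir(chr)
    for (feat in c("gene", "exon")) {
      f <- gene_models[gene_models$chrom == chr & gene_models$type == feat, ]
      if (nrow(f) == 0) next
      fir <- IRanges::IRanges(start = f$start, end = f$end)
      hits <- IRanges::findOverlaps(ir, fir)
      if (length(hits) == 0) next
      qh <- rows[S4Vectors::queryHits(hits)]
      gid <- f$gene_id[S4Vectors::subjectHits(hits)]
      first <- !duplicated(qh)
      qh <- qh[first]
      gid <- gid[first]
      candidates$gene_id[qh] <- gid
      candidates$location_class[qh] <- if (feat == "gene") "intronic" else "exonic"
    }
  }
  indel_len <- abs(nchar(candidates$ref) - nchar(candidates$alt))
  candidates$frameshift <- candidates$location_class == "exonic" &
    indel_len > 0 & indel_len %% 3 != 0
  candidates
}

#' Scan depth tracks for mutant-specific coverage gaps
#'
#' A large deletion in the mutant shows up as a run of near-zero read depth
#' in the mutant pool at positions where every control retains normal depth
#' (requiring normal control depth excludes unsequenceable repeats, which
#' drop out in every sample). Reports maximal bin runs with mutant depth
#' `<= gap_max_depth` and all control depths `>= ctrl_min_depth`, of total
#' length `>= min_len`.
#'
#' @param depth Long depth tibble with columns `chrom`, `start` (1-based bin
#'   start), `sample`, `depth`; all samples must share the same bin grid.
#' @param mutant Mutant sample label.
#' @param controls Character vector of control sample labels.
#' @param gap_max_depth Maximum mutant depth inside a gap (default 2).
#' @param ctrl_min_depth Minimum control depth inside a gap (default 10).
#' @param min_len Minimum gap length in bp (default 5000).
#' @return Tibble `chrom`, `start`, `end`, `length`, `mutant_mean_depth`,
#'   plus one `mean_depth_<control>` column per control.
#' @export
coverage_gap_scan <- function(depth, mutant, controls, gap_max_depth = 2,
                              ctrl_min_depth = 10, min_len = 5000) {
  assert_columns(depth, c("chrom", "start", "sample", "depth"))
  labels <- c(mutant, controls)
  missing <- setdiff(labels, unique(depth$sample))
  if (length(missing) > 0) {
    stop("sample(s) absent from depth track: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  wide <- depth |>
    dplyr::filter(.data$sample %in% labels) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "depth")
  if (anyNA(wide[labels])) {
    stop("bin grid mismatch: not all samples cover the same bins", call. = FALSE)
  }
  wide <- dplyr::arrange(wide, .data$chrom, .data$start)
  starts <- wide$start
  bin_size <- if (nrow(wide) > 1) {
    d <- diff(starts[wide$chrom == wide$chrom[1]])
    if (length(d) > 0) min(d) else NA_real_
  } else {
    NA_real_
  }
  ctrl_ok <- Reduce(`&`, lapply(controls, function(ct) wide[[ct]] >= ctrl_min_depth))
  gap_bin <- wide[[mutant]] <= gap_max_depth & ctrl_ok
  if (!any(gap_bin)) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(), length = numeric(),
      mutant_mean_depth = numeric(),
      !!!stats::setNames(
        rep(list(numeric()), length(controls)),
        paste0("mean_depth_", controls)
      )
    ))
  }
  out <- wide |>
    dplyr::mutate(gap_bin = gap_bin) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(.data$gap_bin & !dplyr::lag(.data$gap_bin, default = FALSE))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$gap_bin) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      end = max(.data$start) + bin_size - 1,
      start = min(.data$start),
      mutant_mean_depth = mean(.data[[mutant]]),
      dplyr::across(dplyr::all_of(controls), mean, .names = "mean_depth_{.col}"),
      .groups = "drop"
    ) |>
    dplyr::mutate(length = .data$end - .data$start + 1) |>
    dplyr::filter(.data$length >= min_len) |>
    dplyr::select(
      "chrom", "start", "end", "length", "mutant_mean_depth",
      dplyr::starts_with("mean_depth_")
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  out
}
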