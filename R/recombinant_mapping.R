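#' Declare a mapping design
#'
#' The design determines what genotype a selected mutant plant must carry at
#' the causal locus, and therefore what counts as a recombinant at a linked
#' marker:
#'
#' * `"hom_f2"` — homozygous mutants selected from an F2; the causal genotype
#'   is homozygous for the mutant-background (A) allele, linked markers sit
#'   near index 1, unlinked markers near 0.5.
#' * `"het_bc"` — heterozygous mutants selected from a BCnF1 backcross; the
#'   causal genotype is heterozygous, linked markers sit near index 0.5 and
#'   unlinked markers near `(1/2)^(n_backcross + 1)` (0.0625 after three
#'   backcrosses).
#'
#' @param mode `"hom_f2"` or `"het_bc"`.
#' @param n_backcross Number of backcrosses for `"het_bc"` (default 3).
#' @return A `mapping_design` list.
#' @export
mapping_design <- function(mode = c("hom_f2", "het_bc"), n_backcross = 3) {
  mode <- match.arg(mode)
  structure(
    list(
      mode = mode,
      n_backcross = if (mode == "het_bc") n_backcross else NA_integer_,
      causal_call = if (mode == "hom_f2") "HOM_A" else "HET",
      expected_linked_index = if (mode == "hom_f2") 1 else 0.5,
      expected_unlinked_index = if (mode == "hom_f2") 0.5 else 0.5^(n_backcross + 1)
    ),
    class = "mapping_design"
  )
}

#' @export
print.mapping_design <- function(x, ...) {
  cat(sprintf(
    "<mapping_design> mode=%s%s; causal genotype %s; expected linked/unlinked index %.4g/%.4g\n",
    x$mode,
    if (x$mode == "het_bc") sprintf(" (n_backcross=%d)", x$n_backcross) else "",
    x$causal_call, x$expected_linked_index, x$expected_unlinked_index
  ))
  invisible(x)
}

#' Marker index from individual-plant genotypes
#'
#' Fraction of mutant-background (A) alleles among the non-missing diploid
#' calls at one marker: `(2 * #HOM_A + #HET) / (2 * #non-missing)`. At a
#' marker fully linked to the causal locus this is exactly 1 in a homozygous
#' F2 design and exactly 0.5 in a heterozygous backcross design.
#'
#' @param calls Character vector of calls (`HOM_A`, `HET`, `HOM_B`,
#'   `MISSING`).
#' @return Fraction in `[0, 1]`, or `NA` if every call is missing.
#' @export
#' @examples
#' genotype_marker_index(c(rep("HET", 38), "HOM_B")) # 38/78 = 0.4872
genotype_marker_index <- function(calls) {
  d <- call_dosage(calls)
  n <- sum(!is.na(d))
  if (n == 0) {
    return(NA_real_)
  }
  sum(d, na.rm = TRUE) / (2 * n)
}

#' Per-marker index table from a genotype matrix
#'
#' Convenience wrapper applying [genotype_marker_index()] to every marker of
#' a long genotype table.
#'
#' @param genotypes Long genotype tibble (see [read_genotype_table()]).
#' @return Tibble `marker`, `chrom`, `pos`, `n_plants`, `n_missing`,
#'   `marker_index`, ordered by (`chrom`, `pos`).
#' @export
marker_index_by_marker <- function(genotypes) {
  assert_columns(genotypes, c("plant_id", "marker", "chrom", "pos", "call"))
  genotypes |>
    dplyr::group_by(.data$marker, .data$chrom, .data$pos) |>
    dplyr::summarise(
      n_plants = dplyr::n(),
      n_missing = sum(.data$call == "MISSING"),
      marker_index = genotype_marker_index(.data$call),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Identify recombinant plants at one marker
#'
#' A selected mutant plant is recombinant at a marker when its genotype is
#' inconsistent with full linkage to the causal locus: any call other than
#' `HOM_A` in a homozygous F2 design, any call other than `HET` in a
#' heterozygous backcross design. In a backcross, `HOM_A` is impossible
#' (one gamete always comes from the mapping parent) and is flagged as a
#' probable scoring error, excluded from narrowing. Missing calls are never
#' recombinant and are reported separately.
#'
#' @param genotypes Long genotype tibble of selected mutant plants.
#' @param marker Marker name.
#' @param design A [mapping_design()].
#' @return Character vector of recombinant plant ids, with attributes
#'   `missing` (plant ids with missing calls) and `inconsistent` (plant ids
#'   with impossible calls, `het_bc` only).
#' @export
find_recombinants <- function(genotypes, marker, design) {
  assert_columns(genotypes, c("plant_id", "marker", "call"))
  stopifnot(inherits(design, "mapping_design"))
  g <- genotypes[genotypes$marker == marker, ]
  if (nrow(g) == 0) stop("marker not present: ", marker, call. = FALSE)
  inconsistent <- character()
  if (design$mode == "het_bc" && any(g$call == "HOM_A")) {
    inconsistent <- g$plant_id[g$call == "HOM_A"]
    warning(sprintf(
      "marker %s: HOM_A call(s) are impossible in a backcross design (plants %s); excluded as probable scoring errors",
      marker, paste(inconsistent, collapse = ", ")
    ), call. = FALSE)
  }
  rec <- g$plant_id[g$call != design$causal_call & g$call != "MISSING" &
    !g$plant_id %in% inconsistent]
  structure(rec,
    missing = g$plant_id[g$call == "MISSING"],
    inconsistent = inconsistent
  )
}

# A-allele dosage sequence consistency for one plant against one candidate
# gap: under at most one crossover per gamete between the causal locus and
# any marker, the dosage sequence moving outward from the gap on each side
# must be non-increasing (each gamete carries the A allele up to its
# crossover point and the mapping-parent allele beyond).
.gap_consistent <- function(dosage, positions, gap_left_idx) {
  left <- dosage[seq_len(gap_left_idx)]
  right <- if (gap_left_idx < length(dosage)) dosage[(gap_left_idx + 1):length(dosage)] else numeric(0)
  left <- rev(left) # nearest marker first
  ok_side <- function(d) {
    d <- d[!is.na(d)]
    length(d) <= 1 || !is.unsorted(rev(d))
  }
  ok_side(left) && ok_side(right)
}

#' Narrow the causal interval from recombinant distributions
#'
#' Places the causal locus in a gap between adjacent markers (or beyond the
#' outermost markers) by testing, for every gap, whether each selected
#' mutant plant's genotypes are consistent with the causal locus lying
#' there. Consistency assumes no double crossover within a plant between the
#' causal locus and any single marker: each gamete then carries the
#' mutant-background allele from the causal locus out to at most one
#' crossover point per side, so the A-allele dosage across markers, read
#' outward from the candidate gap, must be non-increasing on each side.
#' Missing calls are ignored per plant-marker; in a backcross design,
#' impossible `HOM_A` calls are excluded with a warning (via
#' [find_recombinants()] semantics).
#'
#' The gap (or union of contiguous gaps) with zero inconsistent plants is
#' returned as the interval bounded by the flanking markers' positions;
#' a chromosome-end gap is bounded by position 1 (left) or `chrom_length`
#' (right, `NA` if unknown), exclusive of the outermost marker.
#'
#' @param genotypes Long genotype tibble of selected mutant plants, all
#'   markers on the causal chromosome.
#' @param design A [mapping_design()].
#' @param chrom_length Optional chromosome length for the right-end gap.
#' @return Object of class `interval_narrowing`: list with `interval`
#'   (tibble `chrom`, `start`, `end`, `label`, `source`), `gaps` (per-gap
#'   consistency report), `marker_report` (per-marker recombinants and
#'   marker index) and `design`.
#' @export
narrow_interval <- function(genotypes, design, chrom_length = NA) {
  assert_columns(genotypes, c("plant_id", "marker", "chrom", "pos", "call"))
  stopifnot(inherits(design, "mapping_design"))
  if (length(unique(genotypes$chrom)) != 1) {
    stop("narrow_interval expects markers on a single chromosome", call. = FALSE)
  }
  chrom <- genotypes$chrom[1]
  markers <- genotypes |>
    dplyr::distinct(.data$marker, .data$pos) |>
    dplyr::arrange(.data$pos)
  dup_pos <- duplicated(markers$pos)
  if (any(dup_pos)) {
    warning(
      "dropping marker(s) tied at the same position: ",
      paste(markers$marker[dup_pos], collapse = ", "),
      call. = FALSE
    )
    genotypes <- genotypes[!genotypes$marker %in% markers$marker[dup_pos], ]
    markers <- markers[!dup_pos, , drop = FALSE]
  }
  if (nrow(markers) < 2) stop("need at least 2 markers to narrow an interval", call. = FALSE)

  marker_report <- marker_index_by_marker(genotypes) |>
    dplyr::mutate(recombinants = purrr::map(.data$marker, function(m) {
      as.character(suppressWarnings(find_recombinants(genotypes, m, design)))
    }), n_recombinants = lengths(.data$recombinants))

  # dosage matrix plants x ordered markers; impossible HOM_A in het_bc -> NA
  g <- genotypes
  if (design$mode == "het_bc") {
    bad <- g$call == "HOM_A"
    if (any(bad)) {
      warning(sprintf(
        "%d HOM_A call(s) are impossible in a backcross design; treated as missing for narrowing",
        sum(bad)
      ), call. = FALSE)
      g$call[bad] <- "MISSING"
    }
  }
  g$dosage <- call_dosage(g$call)
  wide <- g |>
    dplyr::select("plant_id", "marker", "dosage") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "dosage")
  dm <- as.matrix(wide[, markers$marker, drop = FALSE])
  rownames(dm) <- wide$plant_id

  # gap 0 = left of the first marker, gap k = right of the last; internal gap
  # bounds are the flanking marker positions themselves, end gaps stop one bp
  # short of the outermost marker
  k <- nrow(markers)
  n_gaps <- k + 1
  gap_tbl <- tibble::tibble(
    gap = 0:k,
    left_marker = c(NA_character_, markers$marker),
    right_marker = c(markers$marker, NA_character_),
    start = c(1, markers$pos[-k], markers$pos[k] + 1),
    end = c(
      markers$pos[1] - 1, markers$pos[-1],
      if (is.na(chrom_length)) NA_real_ else chrom_length
    )
  )

  inconsistent <- lapply(seq_len(n_gaps), function(gi) {
    bad <- vapply(seq_len(nrow(dm)), function(pi) {
      !.gap_consistent(dm[pi, ], markers$pos, gap_left_idx = gi - 1L)
    }, logical(1))
    rownames(dm)[bad]
  })
  gap_tbl$inconsistent_plants <- inconsistent
  gap_tbl$n_inconsistent <- lengths(inconsistent)
  gap_tbl$consistent <- gap_tbl$n_inconsistent == 0

  if (!any(gap_tbl$consistent)) {
    best <- gap_tbl[which.min(gap_tbl$n_inconsistent), ]
    stop(sprintf(
      "no marker gap is consistent with a single causal locus; minimal conflict at gap %s-%s (%d plant(s): %s) - suspect genotyping error or two causal loci",
      ifelse(is.na(best$left_marker), "chrom_start", best$left_marker),
      ifelse(is.na(best$right_marker), "chrom_end", best$right_marker),
      best$n_inconsistent, paste(best$inconsistent_plants[[1]], collapse = ", ")
    ), call. = FALSE)
  }

  runs <- rle(gap_tbl$consistent)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  interval <- gap_tbl |>
    dplyr::mutate(run = run_id) |>
    dplyr::filter(.data$consistent) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::mutate(
      chrom = chrom,
      label = sprintf(
        "%s:%s-%s", chrom, format(.data$start, scientific = FALSE, trim = TRUE),
        ifelse(is.na(.data$end), "end", format(.data$end, scientific = FALSE, trim = TRUE))
      ),
      source = "marker_pair"
    ) |>
    dplyr::select("chrom", "start", "end", "label", "source")

  structure(
    list(
      interval = interval, gaps = gap_tbl,
      marker_report = marker_report, design = design, chrom = chrom
    ),
    class = "interval_narrowing"
  )
}

#' @export
print.interval_narrowing <- function(x, ...) {
  cat(sprintf(
    "<interval_narrowing> %s design, %d markers on %s\n",
    x$design$mode, nrow(x$marker_report), x$chrom
  ))
  cat("Candidate interval(s):\n")
  print(x$interval)
  cat("Per-marker recombinants:\n")
  print(dplyr::select(
    x$marker_report, "marker", "pos", "marker_index",
    "n_recombinants"
  ))
  invisible(x)
}

#' Interval span in megabases
#'
#' Absolute distance between two positions on the same chromosome, in Mbp,
#' rounded half-up to two decimals (the convention used when quoting mapping
#' interval sizes).
#'
#' @param a_pos,b_pos Positions in bp.
#' @return Span in Mbp (2 decimals).
#' @export
#' @examples
#' interval_size_mbp(10068751, 11595846) # 1.53
interval_size_mbp <- function(a_pos, b_pos) {
  round_half_up(abs(b_pos - a_pos) / 1e6, 2)
}
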