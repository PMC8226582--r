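#' Screen variants for gel-resolvable InDel markers
#'
#' Selects InDel variants whose parental allele lengths differ by strictly
#' more than `min_diff` bp — a length difference above 5 bp is resolvable as
#' a PCR product-size polymorphism on 4% agarose, which is what makes a site
#' usable as a mapping marker. With `require_fixed`, the site must
#' additionally look like a genuine fixed polymorphism between the two
#' parents: the control (mapping-parent) pool fixed for one allele
#' (index `<= fixed_low` or `>= fixed_high`) and at least one mutant-pool
#' read carrying the opposite allele. No floor is placed on the mutant-pool
#' index itself: at unlinked sites of a backcross population the
#' mutant-background allele is legitimately rare (about 0.0625 after three
#' backcrosses) yet the marker is still informative plant-by-plant.
#'
#' @param variants Pooled-variant tibble (columns as from
#'   [read_pooled_variants()]).
#' @param min_diff Minimum length difference in bp, exclusive (default 5).
#' @param require_fixed Require parental fixation evidence as above.
#' @param fixed_low,fixed_high Control-index fixation thresholds.
#' @return Marker tibble: `name` (`<chrom>_<pos>`), `chrom`, `pos`,
#'   `marker_type` (`"InDel"`), `length_diff`, `ref`, `alt`, in input order.
#' @export
screen_gel_markers <- function(variants, min_diff = 5, require_fixed = TRUE,
                               fixed_low = 0.1, fixed_high = 0.9) {
  assert_columns(variants, c("chrom", "pos", "ref", "alt"))
  diff <- abs(nchar(variants$ref) - nchar(variants$alt))
  vclass <- if ("vclass" %in% names(variants)) {
    variants$vclass
  } else {
    classify_variant(variants$ref, variants$alt)
  }
  keep <- vclass == "InDel" & diff > min_diff
  if (require_fixed) {
    assert_columns(variants, c("mut_ref", "mut_alt", "ctrl_ref", "ctrl_alt"))
    ctrl_idx <- marker_index(variants$ctrl_alt, variants$ctrl_ref)
    ctrl_fixed_ref <- !is.na(ctrl_idx) & ctrl_idx <= fixed_low
    ctrl_fixed_alt <- !is.na(ctrl_idx) & ctrl_idx >= fixed_high
    opposite_seen <- ifelse(ctrl_fixed_ref, variants$mut_alt > 0,
      ifelse(ctrl_fixed_alt, variants$mut_ref > 0, FALSE)
    )
    keep <- keep & (ctrl_fixed_ref | ctrl_fixed_alt) & opposite_seen
  }
  out <- variants[keep, , drop = FALSE]
  tibble::tibble(
    name = sprintf("%s_%d", out$chrom, out$pos),
    chrom = out$chrom,
    pos = out$pos,
    marker_type = "InDel",
    length_diff = diff[keep],
    ref = out$ref,
    alt = out$alt
  )
}

#' Verify externally supplied length-polymorphism markers
#'
#' Repeat-based (SSR/SSLP) markers downloaded from community databases are
#' verified against the resequencing variants by the same gel-resolvability
#' rule used for de novo InDel markers: a marker is confirmed when a variant
#' at its position has a parental length difference above `min_diff` bp.
#'
#' @param markers Tibble with `name`, `chrom`, `pos` (and optionally
#'   `marker_type`).
#' @param variants Pooled-variant tibble.
#' @param min_diff Minimum length difference in bp, exclusive (default 5).
#' @return `markers` with logical `verified` and numeric `length_diff`
#'   columns.
#' @export
verify_external_markers <- function(markers, variants, min_diff = 5) {
  assert_columns(markers, c("name", "chrom", "pos"))
  assert_columns(variants, c("chrom", "pos", "ref", "alt"))
  v <- variants |>
    dplyr::mutate(length_diff = abs(nchar(.data$ref) - nchar(.data$alt))) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(length_diff = max(.data$length_diff), .groups = "drop")
  markers |>
    dplyr::left_join(v, by = c("chrom", "pos")) |>
    dplyr::mutate(
      length_diff = dplyr::coalesce(.data$length_diff, 0),
      verified = .data$length_diff > min_diff
    )
}

#' Extract flanking sequence around markers
#'
#' Pulls `flank` bp of reference sequence on each side of every marker for
#' downstream primer design: the left flank ends at `pos - 1`, the right
#' flank starts just after the reference allele
#' (`pos + nchar(ref)`). Flanks are truncated at contig edges.
#'
#' @param markers Marker tibble from [screen_gel_markers()] (needs `chrom`,
#'   `pos`, `ref`).
#' @param reference Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param flank Flank length in bp (default 250).
#' @return `markers` with `flank_left` and `flank_right` character columns
#'   (uppercase).
#' @export
extract_flanks <- function(markers, reference, flank = 250) {
  assert_columns(markers, c("chrom", "pos", "ref"))
  seqs <- if (inherits(reference, "DNAStringSet")) {
    reference
  } else {
    Biostrings::readDNAStringSet(reference)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(markers$chrom), names(seqs))
  if (length(missing) > 0) {
    stop("chromosome(s) absent from reference: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  left <- character(nrow(markers))
  right <- character(nrow(markers))
  for (i in seq_len(nrow(markers))) {
    s <- seqs[[markers$chrom[i]]]
    p <- markers$pos[i]
    if (p < 1 || p > length(s)) {
      stop(sprintf("marker position %s:%d outside sequence bounds", markers$chrom[i], p), call. = FALSE)
    }
    lstart <- max(1, p - flank)
    left[i] <- if (p == 1) "" else toupper(as.character(Biostrings::subseq(s, lstart, p - 1)))
    rstart <- p + nchar(markers$ref[i])
    rend <- min(length(s), rstart + flank - 1)
    right[i] <- if (rstart > length(s)) "" else toupper(as.character(Biostrings::subseq(s, rstart, rend)))
  }
  markers$flank_left <- left
  markers$flank_right <- right
  markers
}

#' Write marker flanks as FASTA
#'
#' Two records per marker, named `<name>_L` and `<name>_R`.
#'
#' @param markers Marker tibble with `flank_left`/`flank_right` (see
#'   [extract_flanks()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_marker_flanks <- function(markers, path) {
  assert_columns(markers, c("name", "flank_left", "flank_right"))
  seqs <- Biostrings::DNAStringSet(c(
    stats::setNames(markers$flank_left, paste0(markers$name, "_L")),
    stats::setNames(markers$flank_right, paste0(markers$name, "_R"))
  ))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
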