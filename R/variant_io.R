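#' Classify variants by allele length
#'
#' SNP: both alleles a single base. InDel: alleles of unequal length, both no
#' longer than `sv_threshold`. Anything longer is an SV. Equal-length
#' multi-base substitutions are rare in two-parent crosses and are classed as
#' SV so that they never enter the index scan as point markers.
#'
#' @param ref,alt Allele strings (vectorized).
#' @param sv_threshold Maximum allele length (bp) for the InDel class.
#' @return Character vector in `c("SNP", "InDel", "SV")`.
#' @export
classify_variant <- function(ref, alt, sv_threshold = 50) {
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == 1 & la == 1 ~ "SNP",
    lr != la & lr <= sv_threshold & la <= sv_threshold ~ "InDel",
    .default = "SV"
  )
}

#' Read pooled variant calls from a VCF or TSV file
#'
#' Reads biallelic sites with per-pool allele depths for a mutant pool and a
#' control pool. For a VCF the named samples must carry the `AD` genotype
#' field (ref,alt depths); multi-allelic records are skipped and counted.
#' For a TSV (any non-`.vcf` extension) the file must already hold the
#' count columns written by [write_pooled_variants()].
#'
#' @param path VCF 4.x (`.vcf`/`.vcf.gz`) or tab-separated file.
#' @param mutant_sample,control_sample Sample names in the VCF (ignored for
#'   TSV input).
#' @param sv_threshold Passed to [classify_variant()].
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `mut_ref`,
#'   `mut_alt`, `ctrl_ref`, `ctrl_alt`, `vclass`, sorted by (`chrom`, `pos`),
#'   with attribute `skipped_multiallelic` giving the skip count.
#' @export
read_pooled_variants <- function(path, mutant_sample = NULL, control_sample = NULL,
                                 sv_threshold = 50) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_pooled_variants_vcf(path, mutant_sample, control_sample, sv_threshold)
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    assert_columns(out, c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt", "ctrl_ref", "ctrl_alt"))
    if (!"vclass" %in% names(out)) {
      out$vclass <- classify_variant(out$ref, out$alt, sv_threshold)
    }
    out <- dplyr::arrange(out, .data$chrom, .data$pos)
    attr(out, "skipped_multiallelic") <- 0L
    out
  }
}

read_pooled_variants_vcf <- function(path, mutant_sample, control_sample, sv_threshold) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(mutant_sample, control_sample)) {
    if (is.null(s) || !s %in% samples) {
      stop(sprintf(
        "sample '%s' not present in %s; available samples: %s",
        if (is.null(s)) "<NULL>" else s, path, paste(samples, collapse = ", ")
      ), call. = FALSE)
    }
  }
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE)
  skipped <- sum(!biallelic)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad & biallelic)) {
      warning(sprintf(
        "skipping %d record(s) with malformed AD (first at record %d)",
        sum(bad & biallelic), which(bad & biallelic)[1]
      ), call. = FALSE)
    }
    list(
      ref = suppressWarnings(as.integer(vapply(parts, `[`, "", 1))),
      alt = suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""))),
      ok = !bad
    )
  }
  mut <- parse_ad(ad[, mutant_sample])
  ctrl <- parse_ad(ad[, control_sample])
  keep <- biallelic & mut$ok & ctrl$ok
  out <- tibble::tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    mut_ref = mut$ref[keep],
    mut_alt = mut$alt[keep],
    ctrl_ref = ctrl$ref[keep],
    ctrl_alt = ctrl$alt[keep]
  )
  out$vclass <- classify_variant(out$ref, out$alt, sv_threshold)
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "skipped_multiallelic") <- skipped
  out
}

#' Write pooled variants to a TSV file
#'
#' Plain tab-separated form of the pooled-variant table; the exact inverse of
#' the TSV branch of [read_pooled_variants()].
#'
#' @param variants Pooled-variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pooled_variants <- function(variants, path) {
  assert_columns(variants, c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt", "ctrl_ref", "ctrl_alt"))
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Read an individual-plant genotype table
#'
#' Reads a plants-by-markers genotype table: first column `plant_id`, one
#' column per marker, cells coded per `coding` (default `A`/`H`/`B`/`-` for
#' homozygous mutant-background, heterozygous, homozygous mapping-parent and
#' missing; unknown tokens become `MISSING` with a warning). Marker
#' coordinates come from a side-car TSV (`name`, `chrom`, `pos`), by default
#' `<path>.markers`.
#'
#' @param path Genotype TSV.
#' @param markers_path Side-car marker coordinate TSV; default
#'   `paste0(path, ".markers")`.
#' @param coding Named character vector mapping cell tokens to call values.
#' @return Long tibble with columns `plant_id`, `marker`, `chrom`, `pos`,
#'   `call`, markers ordered by (`chrom`, `pos`).
#' @export
read_genotype_table <- function(path, markers_path = paste0(path, ".markers"),
                                coding = c(A = "HOM_A", H = "HET", B = "HOM_B", "-" = "MISSING")) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    stop("duplicate marker name(s): ",
      paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "),
      call. = FALSE
    )
  }
  raw <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop(sprintf(
      "malformed genotype table: row %d has the wrong number of fields",
      probs$row[1]
    ), call. = FALSE)
  }
  if (names(raw)[1] != "plant_id") {
    names(raw)[1] <- "plant_id"
  }
  marker_names <- names(raw)[-1]
  markers <- readr::read_tsv(markers_path, show_col_types = FALSE)
  assert_columns(markers, c("name", "chrom", "pos"), "marker side-car")
  missing_coords <- setdiff(marker_names, markers$name)
  if (length(missing_coords) > 0) {
    stop("marker(s) without coordinates in side-car: ",
      paste(missing_coords, collapse = ", "),
      call. = FALSE
    )
  }
  long <- tidyr::pivot_longer(raw, -"plant_id", names_to = "marker", values_to = "token")
  long$call <- unname(coding[long$token])
  unknown <- is.na(long$call) & !is.na(long$token)
  if (any(unknown)) {
    warning(sprintf(
      "%d cell(s) with unknown token(s) (%s) set to MISSING",
      sum(unknown), paste(unique(long$token[unknown]), collapse = ", ")
    ), call. = FALSE)
  }
  long$call[is.na(long$call)] <- "MISSING"
  long |>
    dplyr::left_join(markers, by = c(marker = "name")) |>
    dplyr::select("plant_id", "marker", "chrom", "pos", "call") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$plant_id)
}

#' Write a genotype table (with marker side-car)
#'
#' Inverse of [read_genotype_table()]: writes the wide plants-by-markers TSV
#' and the `<path>.markers` coordinate side-car.
#'
#' @param genotypes Long genotype tibble (`plant_id`, `marker`, `chrom`,
#'   `pos`, `call`).
#' @param path Output TSV path.
#' @param coding Named vector mapping call values to cell tokens (inverse of
#'   the reader's default coding).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path,
                                 coding = c(HOM_A = "A", HET = "H", HOM_B = "B", MISSING = "-")) {
  assert_columns(genotypes, c("plant_id", "marker", "chrom", "pos", "call"))
  markers <- genotypes |>
    dplyr::distinct(name = .data$marker, .data$chrom, .data$pos) |>
    dplyr::arrange(.data$chrom, .data$pos)
  wide <- genotypes |>
    dplyr::mutate(token = unname(coding[.data$call])) |>
    dplyr::select("plant_id", "marker", "token") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "token")
  wide <- wide[, c("plant_id", markers$name)]
  readr::write_tsv(wide, path)
  readr::write_tsv(markers, paste0(path, ".markers"))
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene and exon features and returns them as a tidy table with one
#' row per feature. Coordinates are 1-based inclusive as in GFF3; strand is
#' recorded but never used to flip coordinates. Genes without exon children
#' are kept (gene row only) with a warning.
#'
#' @param path GFF3 file.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `type`
#'   (`"gene"` or `"exon"`), `start`, `end`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    type = character(), start = integer(), end = integer()
  )
  if (file.size(path) == 0) {
    return(empty)
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) {
    return(empty)
  }
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = if (!is.null(gr$Parent)) {
      vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_, "")
    } else {
      NA_character_
    }
  )
  genes <- dplyr::filter(df, .data$type == "gene")
  mrna <- dplyr::filter(df, .data$type == "mRNA")
  exons <- dplyr::filter(df, .data$type == "exon")
  # resolve each exon to its gene: Parent may be the gene or an mRNA of it
  mrna_to_gene <- stats::setNames(mrna$parent, mrna$id)
  exon_gene <- ifelse(exons$parent %in% genes$id, exons$parent,
    unname(mrna_to_gene[exons$parent])
  )
  exons$gene_id <- exon_gene
  orphans <- is.na(exons$gene_id)
  if (any(orphans)) {
    warning(sprintf("%d exon(s) without a resolvable gene parent were dropped", sum(orphans)), call. = FALSE)
    exons <- exons[!orphans, , drop = FALSE]
  }
  genes$gene_id <- genes$id
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon) > 0) {
    warning("gene(s) without exons: ", paste(no_exon, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(
    dplyr::select(genes, "gene_id", "chrom", "strand", "type", "start", "end"),
    dplyr::select(exons, "gene_id", "chrom", "strand", "type", "start", "end")
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id, dplyr::desc(.data$type))
}

#' Write intervals to a BED file
#'
#' Converts 1-based inclusive intervals to the 0-based half-open BED
#' convention at the writer boundary (all internal coordinates in this
#' package are 1-based inclusive). The interval `label` becomes the BED name
#' column; output order is (`chrom`, `start`).
#'
#' @param regions Tibble with columns `chrom`, `start`, `end` and optionally
#'   `label`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  assert_columns(regions, c("chrom", "start", "end"))
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(regions$end < regions$start)) {
    stop("interval with end < start", call. = FALSE)
  }
  regions <- dplyr::arrange(regions, .data$chrom, .data$start)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    name = if ("label" %in% names(regions)) regions$label else paste0("region_", seq_len(nrow(regions)))
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
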