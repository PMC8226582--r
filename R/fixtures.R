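#' Write pooled variants as a two-sample VCF
#'
#' Minimal VCF 4.2 writer for simulator output: one biallelic record per
#' site with `GT:AD:DP` for a mutant-pool and a control-pool sample. The
#' files are read back by [read_pooled_variants()].
#'
#' @param variants Pooled-variant tibble.
#' @param path Output `.vcf` path.
#' @param contigs Named vector of chromosome lengths for the header.
#' @param mutant_sample,control_sample Sample column names.
#' @return `path`, invisibly.
#' @export
write_pooled_vcf <- function(variants, path, contigs = NULL,
                             mutant_sample = "mutant_pool",
                             control_sample = "control_pool") {
  assert_columns(variants, c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt", "ctrl_ref", "ctrl_alt"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamap-simulator",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      mutant_sample, control_sample,
      sep = "\t"
    )
  )
  v <- dplyr::arrange(variants, .data$chrom, .data$pos)
  records <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t./.:%d,%d:%d\t./.:%d,%d:%d",
    v$chrom, as.integer(v$pos), v$ref, v$alt,
    v$mut_ref, v$mut_alt, v$mut_ref + v$mut_alt,
    v$ctrl_ref, v$ctrl_alt, v$ctrl_ref + v$ctrl_alt
  )
  writeLines(c(header, records), path)
  invisible(path)
}

# Random reference sequences with the simulated reference alleles embedded at
# their positions, so flank extraction and allele lookup are self-consistent.
build_reference <- function(parents, seed = 1) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(derive_seed(seed, "reference"), {
    seqs <- lapply(names(parents$chrom_lengths), function(chr) {
      len <- parents$chrom_lengths[[chr]]
      chars <- sample(bases, len, replace = TRUE)
      s <- parents$sites[parents$sites$chrom == chr, ]
      for (i in seq_len(nrow(s))) {
        ref <- strsplit(s$ref[i], "")[[1]]
        chars[s$pos[i]:(s$pos[i] + length(ref) - 1)] <- ref
      }
      paste(chars, collapse = "")
    })
    Biostrings::DNAStringSet(stats::setNames(unlist(seqs), names(parents$chrom_lengths)))
  })
}

# Toy gene models: one gene whose exon contains the causal site, plus evenly
# spaced filler genes (two exons each) along every chromosome.
build_gene_models <- function(parents, n_filler = 5) {
  causal <- parents$causal
  rows <- list()
  gi <- 0
  for (chr in names(parents$chrom_lengths)) {
    len <- parents$chrom_lengths[[chr]]
    starts <- floor(seq(1000, max(2000, len - 5000), length.out = n_filler))
    for (s in starts) {
      gi <- gi + 1
      id <- sprintf("GENE%03d", gi)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = id, chrom = chr, strand = ifelse(gi %% 2 == 0, "-", "+"),
        type = c("gene", "exon", "exon"),
        start = c(s, s, s + 1200),
        end = c(s + 1999, s + 799, s + 1999)
      )
    }
  }
  causal_gene <- tibble::tibble(
    gene_id = "GENE_CAUSAL", chrom = causal$chrom, strand = "+",
    type = c("gene", "exon"),
    start = c(causal$pos - 400, causal$pos - 200),
    end = c(causal$pos + 400, causal$pos + 200)
  )
  # drop filler genes overlapping the causal gene so the causal site sits in
  # exactly one annotated gene
  gm <- dplyr::bind_rows(rows)
  span <- gm[gm$type == "gene", ]
  drop <- span$gene_id[span$chrom == causal$chrom &
    span$start <= causal_gene$end[1] & span$end >= causal_gene$start[1]]
  gm <- gm[!gm$gene_id %in% drop, ]
  dplyr::bind_rows(gm, causal_gene) |>
    dplyr::arrange(.data$chrom, .data$start)
}

write_gene_models_gff3 <- function(gene_models, path) {
  gm <- gene_models
  attrs <- ifelse(gm$type == "gene",
    sprintf("ID=%s", gm$gene_id),
    sprintf("ID=%s.exon%d;Parent=%s", gm$gene_id, seq_len(nrow(gm)), gm$gene_id)
  )
  lines <- sprintf(
    "%s\tbsamap\t%s\t%d\t%d\t.\t%s\t.\t%s",
    gm$chrom, gm$type, as.integer(gm$start), as.integer(gm$end), gm$strand, attrs
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# Binned depth track for the mutant pool and two controls, optionally with a
# deletion gap (mutant depth ~0) planted in the mutant sample.
build_depth_track <- function(parents, bin_size = 500, depth_mut = 40,
                              depth_ctrl = 20, deletion = NULL, seed = 1) {
  withr::with_seed(derive_seed(seed, "depth"), {
    purrr::map_dfr(names(parents$chrom_lengths), function(chr) {
      len <- parents$chrom_lengths[[chr]]
      starts <- seq(1, len, by = bin_size)
      samples <- c(mutant = depth_mut, control1 = depth_ctrl, control2 = depth_ctrl)
      out <- purrr::imap_dfr(samples, function(d, lab) {
        tibble::tibble(
          chrom = chr, start = starts, sample = lab,
          depth = round(stats::rpois(length(starts), d) + stats::runif(length(starts)) - 0.5, 1)
        )
      })
      if (!is.null(deletion) && deletion$chrom == chr) {
        in_gap <- out$sample == "mutant" &
          out$start >= deletion$start &
          out$start + bin_size - 1 <= deletion$start + deletion$length - 1
        out$depth[in_gap] <- 0
      }
      out
    })
  })
}

#' Write a complete synthetic mapping fixture to disk
#'
#' Generates parents, a selected mapping population, pooled reads, and every
#' file needed to run the whole pipeline end to end: a two-sample VCF of
#' pooled allele depths, a genotype TSV (PCR-marker subset of the selected
#' plants, with coordinate side-car), toy gene models (GFF3; the causal site
#' is exonic in `GENE_CAUSAL`), the reference FASTA, a binned depth TSV
#' (optionally with a planted deletion gap in the mutant), and a
#' `truth.json` recording the causal site and simulation settings.
#'
#' @param outdir Output directory (created if needed).
#' @param design A [mapping_design()].
#' @param n_plants Selected plants in the mapping pool.
#' @param n_sites Parental polymorphisms.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param pool_mut,pool_ctrl [pool_spec()]s for the pools.
#' @param n_markers PCR markers in the genotype table, chosen from
#'   gel-resolvable InDel sites spread over the causal chromosome.
#' @param deletion Optional planted deletion, list with `chrom`, `start`,
#'   `length` (e.g. 23,500 bp).
#' @param background Reference-genome orientation, passed to
#'   [simulate_parents()]; the default `"ref"` makes every parental
#'   polymorphism visible in the control pool, so parental subtraction can
#'   run from the pooled data alone.
#' @param cM_per_Mb Recombination rate.
#' @param seed Master seed; all stages derive named sub-seeds from it, so a
#'   fixed seed reproduces identical files.
#' @return Invisible named list of the written paths plus the in-memory
#'   `parents`, `population` and `truth` objects.
#' @export
make_fixture <- function(outdir, design = mapping_design("hom_f2"),
                         n_plants = 32, n_sites = 300,
                         chrom_lengths = c(chrA = 2e6, chrB = 1e6),
                         pool_mut = pool_spec(40), pool_ctrl = pool_spec(20),
                         n_markers = 6, deletion = NULL, background = "ref",
                         cM_per_Mb = 4, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  parents <- simulate_parents(n_sites, chrom_lengths,
    indel_fraction = 0.3,
    background = background, seed = seed
  )
  population <- simulate_population(parents, design, n_plants,
    cM_per_Mb = cM_per_Mb, seed = seed
  )
  variants <- simulate_pooled_variants(parents, population, pool_mut, pool_ctrl, seed = seed)

  paths <- list(
    vcf = file.path(outdir, "pools.vcf"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    gff3 = file.path(outdir, "genes.gff3"),
    fasta = file.path(outdir, "reference.fa"),
    depth = file.path(outdir, "depth.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_pooled_vcf(variants, paths$vcf, contigs = chrom_lengths)

  # PCR markers: gel-resolvable InDel sites on the causal chromosome, spread
  # from end to end so recombinant narrowing brackets the causal locus
  causal_chr <- parents$causal$chrom
  gel <- screen_gel_markers(variants, require_fixed = FALSE)
  gel <- gel[gel$chrom == causal_chr, ]
  if (nrow(gel) < n_markers) {
    stop("fixture has too few gel-resolvable InDel markers; raise n_sites or indel_fraction", call. = FALSE)
  }
  pick <- unique(round(seq(1, nrow(gel), length.out = n_markers)))
  marker_sites <- gel[pick, c("chrom", "pos")]
  genotypes <- population_genotypes(population, marker_sites)
  write_genotype_table(genotypes, paths$genotypes)

  gene_models <- build_gene_models(parents)
  write_gene_models_gff3(gene_models, paths$gff3)
  Biostrings::writeXStringSet(build_reference(parents, seed), paths$fasta)
  readr::write_tsv(
    build_depth_track(parents,
      depth_mut = pool_mut$depth, depth_ctrl = pool_ctrl$depth,
      deletion = deletion, seed = seed
    ),
    paths$depth
  )
  truth <- list(
    causal = as.list(parents$causal),
    mode = design$mode,
    n_backcross = design$n_backcross,
    n_plants = n_plants,
    n_sites = nrow(parents$sites),
    chrom_lengths = as.list(chrom_lengths),
    depth_mut = pool_mut$depth,
    depth_ctrl = pool_ctrl$depth,
    cM_per_Mb = cM_per_Mb,
    seed = seed,
    deletion = deletion
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(parents = parents, population = population, truth = truth)))
}
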