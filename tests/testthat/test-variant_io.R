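write_toy_vcf <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "mut", "ctl",
      sep = "\t"
    )
  )
  writeLines(c(header, records), path)
}

test_that("VCF reader maps AD fields to pool counts and skips multi-allelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:12,8\t0/0:20,0",
    "chr1\t200\t.\tG\tC,A\t.\tPASS\t.\tGT:AD\t0/1:5,5,5\t0/0:9,1,1",
    "chr1\t300\t.\tC\tCTTTT\t.\tPASS\t.\tGT:AD\t0/1:10,30\t1/1:0,25"
  ))
  v <- read_pooled_variants(path, "mut", "ctl")
  expect_equal(nrow(v), 2)
  expect_equal(attr(v, "skipped_multiallelic"), 1)
  expect_equal(v$mut_ref[1], 12)
  expect_equal(v$mut_alt[1], 8)
  expect_equal(v$ctrl_ref[1], 20)
  expect_equal(v$ctrl_alt[1], 0)
  expect_equal(v$vclass, c("SNP", "InDel"))
})

test_that("VCF reader fails with available sample names on a bad label", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:12,8\t0/0:20,0")
  expect_error(read_pooled_variants(path, "nope", "ctl"), "mut, ctl")
})

test_that("pooled variants round-trip through TSV and VCF with identical counts", {
  parents <- simulate_parents(100, c(chr1 = 1e6), indel_fraction = 0.3, seed = 5)
  pop <- simulate_population(parents, mapping_design("hom_f2"), 20, seed = 5)
  v <- simulate_pooled_variants(parents, pop, seed = 5)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pooled_variants(v, tsv)
  back_tsv <- read_pooled_variants(tsv)
  attr(back_tsv, "skipped_multiallelic") <- NULL
  expect_equal(as.data.frame(back_tsv), as.data.frame(v))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_pooled_vcf(v, vcf, contigs = c(chr1 = 1e6))
  back <- read_pooled_variants(vcf, "mutant_pool", "control_pool")
  expect_equal(back$pos, v$pos)
  expect_equal(back$mut_ref, v$mut_ref)
  expect_equal(back$mut_alt, v$mut_alt)
  expect_equal(back$ctrl_ref, v$ctrl_ref)
  expect_equal(back$ctrl_alt, v$ctrl_alt)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
})

test_that("genotype tables parse, sort markers by position, and round-trip", {
  path <- withr::local_tempfile()
  writeLines(c(
    "plant_id\tm2\tm1",
    "p1\tA\tH",
    "p2\tB\t-"
  ), path)
  readr::write_tsv(
    tibble::tibble(name = c("m2", "m1"), chrom = "chr1", pos = c(500, 100)),
    paste0(path, ".markers")
  )
  g <- read_genotype_table(path)
  expect_equal(unique(g$marker), c("m1", "m2")) # sorted by pos
  expect_equal(g$call[g$plant_id == "p1" & g$marker == "m2"], "HOM_A")
  expect_equal(g$call[g$plant_id == "p2" & g$marker == "m1"], "MISSING")

  out <- withr::local_tempfile()
  write_genotype_table(g, out)
  expect_equal(as.data.frame(read_genotype_table(out)), as.data.frame(g))
})

test_that("genotype reader rejects duplicate markers and ragged rows, warns on unknown tokens", {
  path <- withr::local_tempfile()
  writeLines(c("plant_id\tm1\tm1", "p1\tA\tB"), path)
  expect_error(read_genotype_table(path), "duplicate marker")

  path2 <- withr::local_tempfile()
  writeLines(c("plant_id\tm1\tm2", "p1\tA"), path2)
  readr::write_tsv(
    tibble::tibble(name = c("m1", "m2"), chrom = "chr1", pos = c(1, 2)),
    paste0(path2, ".markers")
  )
  expect_error(read_genotype_table(path2), "row")

  path3 <- withr::local_tempfile()
  writeLines(c("plant_id\tm1", "p1\tX"), path3)
  readr::write_tsv(
    tibble::tibble(name = "m1", chrom = "chr1", pos = 1),
    paste0(path3, ".markers")
  )
  expect_warning(g <- read_genotype_table(path3), "unknown token")
  expect_equal(g$call, "MISSING")
})

test_that("gene models load from GFF3 with exons grouped under genes", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t399\t.\t+\t.\tID=g1",
    "chr1\ttest\texon\t100\t199\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chr1\ttest\texon\t300\t399\t.\t+\t.\tID=g1.e2;Parent=g1",
    "chr1\ttest\tgene\t500\t700\t.\t-\t.\tID=g2",
    "chr1\ttest\texon\t500\t700\t.\t-\t.\tID=g2.e1;Parent=g2"
  ), path)
  gm <- read_gene_models(path)
  ex <- gm[gm$type == "exon" & gm$gene_id == "g1", ]
  expect_equal(nrow(ex), 2)
  expect_equal(sum(ex$end - ex$start + 1), 200)
  # minus strand recorded, coordinates unchanged
  g2 <- gm[gm$gene_id == "g2" & gm$type == "exon", ]
  expect_equal(g2$strand, "-")
  expect_equal(c(g2$start, g2$end), c(500, 700))
})

test_that("empty GFF3 gives an empty gene model set without error", {
  path <- withr::local_tempfile(fileext = ".gff3")
  file.create(path)
  expect_equal(nrow(read_gene_models(path)), 0)
})

test_that("BED writer converts 1-based inclusive intervals to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions(tibble::tibble(
    chrom = "Chr2", start = 10779026, end = 11328569, label = "target"
  ), path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(fields[1:3], c("Chr2", "10779025", "11328569"))

  write_regions(tibble::tibble(chrom = "c", start = 5, end = 5, label = "x"), path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(fields[2:3], c("4", "5"))

  write_regions(tibble::tibble(chrom = character(), start = numeric(), end = numeric()), path)
  expect_equal(length(readLines(path)), 0)

  expect_error(
    write_regions(tibble::tibble(chrom = "c", start = 10, end = 5), path),
    "end < start"
  )
})
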