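test_that("interval candidate filter is closed on bounds and threshold, vs brute force", {
  st <- tibble::tibble(
    chrom = "c", pos = c(90, 100, 150, 200, 210),
    ref = "A", alt = "T",
    delta_index = c(0.9, 0.5, 0.49, 0.8, 0.9)
  )
  iv <- tibble::tibble(chrom = "c", start = 100, end = 200)
  out <- candidates_in_interval(st, iv, delta_min = 0.5)
  expect_equal(sort(out$pos), c(100, 200)) # boundary site at delta == min kept, 0.49 dropped
  expect_equal(out$pos, c(200, 100)) # sorted by descending delta
  # brute-force double filter on random sites
  withr::with_seed(10, {
    st2 <- tibble::tibble(
      chrom = "c", pos = sample(1000, 50), ref = "A", alt = "T",
      delta_index = runif(50, -0.5, 1)
    )
  })
  brute <- st2[st2$pos >= 300 & st2$pos <= 700 & st2$delta_index >= 0.5, ]
  got <- candidates_in_interval(st2, tibble::tibble(chrom = "c", start = 300, end = 700), 0.5)
  expect_setequal(got$pos, brute$pos)
  # empty interval is empty output, not an error
  expect_equal(nrow(candidates_in_interval(st, tibble::tibble(chrom = "c", start = 1, end = 2), 0.5)), 0)
})

test_that("parental subtraction matches on the exact allele pair only", {
  cand <- tibble::tibble(
    chrom = "c", pos = c(10, 20, 30), ref = c("A", "A", "A"), alt = c("T", "T", "T"),
    delta_index = 1
  )
  parents <- tibble::tibble(chrom = "c", pos = c(10, 20), ref = c("A", "A"), alt = c("T", "G"))
  out <- subtract_parental(cand, parents)
  expect_equal(out$pos, c(20, 30)) # pos 20 retained: different alt allele
  flagged <- subtract_parental(cand, parents, keep_flagged = TRUE)
  expect_equal(flagged$parental_polymorphism, c(TRUE, FALSE, FALSE))
  # identity on an empty parent list
  expect_equal(subtract_parental(cand, parents[0, ])$pos, cand$pos)
})

test_that("interval filtering and parental subtraction commute", {
  withr::with_seed(11, {
    st <- tibble::tibble(
      chrom = "c", pos = sample(1000, 80), ref = "A",
      alt = sample(c("T", "G"), 80, replace = TRUE),
      delta_index = runif(80)
    )
    par <- st[sample(80, 30), c("chrom", "pos", "ref", "alt")]
  })
  iv <- tibble::tibble(chrom = "c", start = 200, end = 800)
  a <- subtract_parental(candidates_in_interval(st, iv, 0.3), par)
  b <- candidates_in_interval(subtract_parental(st, par), iv, 0.3)
  expect_setequal(a$pos, b$pos)
})

test_that("location annotation classifies exonic, intronic and intergenic variants", {
  gm <- tibble::tibble(
    gene_id = c("g1", "g1", "g1"), chrom = "c", strand = "+",
    type = c("gene", "exon", "exon"),
    start = c(100, 100, 300), end = c(399, 199, 399)
  )
  cand <- tibble::tibble(
    chrom = "c", pos = c(150, 250, 500), ref = c("A", "A", "A"), alt = c("T", "T", "T")
  )
  out <- annotate_location(cand, gm)
  expect_equal(out$location_class, c("exonic", "intronic", "intergenic"))
  expect_equal(out$gene_id, c("g1", "g1", NA))
  # of two candidate variants only the exonic one survives an exon filter
  exonic <- out[out$location_class == "exonic", ]
  expect_equal(nrow(exonic), 1)
})

test_that("InDel overlap uses the affected reference span and frameshift flags non-triples", {
  gm <- tibble::tibble(
    gene_id = "g1", chrom = "c", strand = "+",
    type = c("gene", "exon"), start = c(100, 150), end = c(400, 250)
  )
  cand <- tibble::tibble(
    chrom = "c", pos = c(145, 145, 260),
    ref = c("AAAAAAAAAA", "AAA", "AAAA"), # spans 145-154, 145-147, 260-263
    alt = c("A", "A", "A")
  )
  out <- annotate_location(cand, gm)
  expect_equal(out$location_class, c("exonic", "intronic", "intronic"))
  expect_equal(out$frameshift, c(FALSE, FALSE, FALSE)) # 9 bp deletion in frame
  cand2 <- tibble::tibble(chrom = "c", pos = 200, ref = "ACCCC", alt = "A")
  expect_true(annotate_location(cand2, gm)$frameshift) # 4 bp exonic deletion
})

test_that("coverage gap scan finds a planted 23.5 kb deletion exactly", {
  bins <- seq(1, 2e5, by = 500)
  grid <- tidyr::expand_grid(
    chrom = "c", start = bins,
    sample = c("mut", "hy", "zh")
  )
  grid$depth <- ifelse(grid$sample == "mut", 40, 30)
  gap <- grid$sample == "mut" & grid$start >= 50001 & grid$start <= 73001
  grid$depth[gap] <- 0
  out <- coverage_gap_scan(grid, "mut", c("hy", "zh"))
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 50001)
  expect_equal(out$length, 23500)
  expect_equal(out$mutant_mean_depth, 0)
  expect_equal(out$mean_depth_hy, 30)
})

test_that("coverage gaps require normal control depth and the minimum length", {
  bins <- seq(1, 5e4, by = 500)
  grid <- tidyr::expand_grid(chrom = "c", start = bins, sample = c("mut", "ctl"))
  grid$depth <- ifelse(grid$sample == "mut", 30, 25)
  # a repeat region where both drop out must not be called
  both <- grid$start >= 10001 & grid$start <= 20001
  grid$depth[both] <- 0
  expect_equal(nrow(coverage_gap_scan(grid, "mut", "ctl")), 0)
  # a mutant-only gap of 4,500 bp sits below the 5 kb length threshold
  grid$depth <- ifelse(grid$sample == "mut", 30, 25)
  short_gap <- grid$sample == "mut" & grid$start >= 30001 & grid$start <= 34001
  grid$depth[short_gap] <- 0
  expect_equal(nrow(coverage_gap_scan(grid, "mut", "ctl", min_len = 5000)), 0)
  expect_equal(coverage_gap_scan(grid, "mut", "ctl", min_len = 4500)$length, 4500)
})

test_that("every reported gap satisfies the depth conditions bin by bin", {
  withr::with_seed(12, {
    bins <- seq(1, 1e5, by = 500)
    grid <- tidyr::expand_grid(chrom = "c", start = bins, sample = c("mut", "ctl"))
    grid$depth <- rpois(nrow(grid), ifelse(grid$sample == "mut", 3, 30))
  })
  out <- coverage_gap_scan(grid, "mut", "ctl", gap_max_depth = 2, ctrl_min_depth = 10, min_len = 1000)
  for (i in seq_len(nrow(out))) {
    inside <- grid$start >= out$start[i] & grid$start <= out$end[i]
    expect_true(all(grid$depth[inside & grid$sample == "mut"] <= 2))
    expect_true(all(grid$depth[inside & grid$sample == "ctl"] >= 10))
  }
})

test_that("bin grid mismatches across samples are fatal", {
  grid <- dplyr::bind_rows(
    tibble::tibble(chrom = "c", start = seq(1, 5000, 500), sample = "mut", depth = 30),
    tibble::tibble(chrom = "c", start = seq(1, 4000, 500), sample = "ctl", depth = 30)
  )
  expect_error(coverage_gap_scan(grid, "mut", "ctl"), "grid mismatch")
  expect_error(coverage_gap_scan(grid, "mut", "nope"), "absent")
})
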