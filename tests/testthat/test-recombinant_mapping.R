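test_that("genotype marker index reproduces the worked backcross and F2 examples", {
  # 38 heterozygous + 1 homozygous mapping-parent among 39 backcross plants
  expect_equal(round(genotype_marker_index(c(rep("HET", 38), "HOM_B")), 4), 0.4872)
  # 6 homozygous background + 1 heterozygous among 7 F2 mutants
  expect_equal(round(genotype_marker_index(c(rep("HOM_A", 6), "HET")), 4), 0.9286)
  expect_equal(genotype_marker_index(rep("HOM_A", 10)), 1)
  expect_true(is.na(genotype_marker_index(rep("MISSING", 3))))
  # missing calls drop out of the denominator
  expect_equal(genotype_marker_index(c("HET", "HET", "MISSING")), 0.5)
})

test_that("recombinants are calls inconsistent with full linkage, per design", {
  des_bc <- mapping_design("het_bc")
  calls <- matrix(rep("HET", 39), ncol = 1, dimnames = list(paste0("plant_", 1:39), "F3P11"))
  calls[13, 1] <- "HOM_B"
  g <- geno_tibble(calls, 1000)
  expect_equal(as.character(find_recombinants(g, "F3P11", des_bc)), "plant_13")

  des_f2 <- mapping_design("hom_f2")
  calls2 <- matrix(rep("HOM_A", 25), ncol = 1, dimnames = list(paste0("plant_", 1:25), "RM1880"))
  calls2[c(4, 14), 1] <- "HET"
  g2 <- geno_tibble(calls2, 747262)
  expect_setequal(as.character(find_recombinants(g2, "RM1880", des_f2)), c("plant_4", "plant_14"))
  calls2[, 1] <- "HOM_A"
  expect_length(find_recombinants(geno_tibble(calls2, 747262), "RM1880", des_f2), 0)
})

test_that("impossible homozygous-background calls in a backcross are flagged, missing reported", {
  des <- mapping_design("het_bc")
  calls <- matrix(c("HET", "HOM_A", "MISSING", "HOM_B"),
    ncol = 1,
    dimnames = list(paste0("p", 1:4), "m1")
  )
  expect_warning(rec <- find_recombinants(geno_tibble(calls, 10), "m1", des), "impossible")
  expect_equal(as.character(rec), "p4")
  expect_equal(attr(rec, "inconsistent"), "p2")
  expect_equal(attr(rec, "missing"), "p3")
})

test_that("interval narrowing reproduces the fine-mapping of an F2 recombinant panel", {
  # 14 F2 recombinant plants x 6 markers on chromosome 12; seven plants
  # recombinant at the three left InDel markers, two at the right SSR pair
  markers <- c("InDel1", "InDel2", "InDel3", "InDel4", "RM27694", "RM27697")
  pos <- c(4070394, 4187138, 4400174, 4403614, 4814750, 4920770)
  plants <- paste0("plant_", c(1, 3, 5, 14, 17, 24, 29, 42, 64, 66, 84, 94, 104, 106))
  calls <- matrix("HOM_A", nrow = 14, ncol = 6, dimnames = list(plants, markers))
  left_rec <- paste0("plant_", c(17, 24, 42, 66, 84, 94, 104))
  calls[left_rec, c("InDel1", "InDel2", "InDel3", "InDel4")] <- "HET"
  right_rec <- paste0("plant_", c(14, 64))
  calls[right_rec, c("RM27694", "RM27697")] <- "HET"
  g <- geno_tibble(calls, pos, chrom = "chr12")

  nr <- narrow_interval(g, mapping_design("hom_f2"))
  expect_equal(nrow(nr$interval), 1)
  expect_equal(nr$interval$start, 4403614) # InDel4
  expect_equal(nr$interval$end, 4814750) # RM27694
  rep4 <- nr$marker_report[nr$marker_report$marker == "InDel4", ]
  expect_setequal(rep4$recombinants[[1]], left_rec)
})

test_that("flanking single recombinants bracket the middle gap", {
  calls <- matrix("HOM_A", 2, 3, dimnames = list(c("p", "q"), c("mL", "mM", "mR")))
  calls["p", "mL"] <- "HET"
  calls["q", "mR"] <- "HOM_B"
  nr <- narrow_interval(geno_tibble(calls, c(100, 200, 300)), mapping_design("hom_f2"))
  expect_equal(nrow(nr$interval), 1)
  expect_equal(c(nr$interval$start, nr$interval$end), c(100, 300))
  # with both recombinant markers adjacent the middle gaps split
  calls["p", "mM"] <- "HET"
  nr2 <- narrow_interval(geno_tibble(calls, c(100, 200, 300)), mapping_design("hom_f2"))
  expect_equal(c(nr2$interval$start, nr2$interval$end), c(200, 300))
})

test_that("a plant recombinant at every marker pushes the interval to the chromosome end", {
  # all recombinant markers on one side: causal locus beyond the marker run
  calls <- matrix("HOM_A", 25, 3, dimnames = list(
    paste0("plant_", 1:25),
    c("RM1880", "RM1080", "RM27618")
  ))
  calls["plant_4", ] <- "HET"
  calls["plant_14", c("RM1880", "RM1080")] <- "HET"
  calls["plant_14", "RM27618"] <- "HET"
  g <- geno_tibble(calls, c(747262, 906291, 3804685), chrom = "chr12")
  nr <- narrow_interval(g, mapping_design("hom_f2"), chrom_length = 27531856)
  # the left chromosome-end gap is consistent and bounded by the nearest marker
  left_gap <- nr$gaps[nr$gaps$gap == 0, ]
  expect_true(left_gap$consistent)
  expect_equal(c(left_gap$start, left_gap$end), c(1, 747261))
  expect_equal(nr$interval$start[1], 1)
})

test_that("no consistent gap is a hard error naming the conflicting plants", {
  # a plant keeping the background allele at both outer markers but losing it
  # in the middle needs a double crossover: impossible under the model
  calls <- matrix("HET", 3, 3, dimnames = list(paste0("p", 1:3), c("a", "b", "c")))
  calls["p1", "b"] <- "HOM_B"
  expect_error(
    narrow_interval(geno_tibble(calls, c(100, 200, 300)), mapping_design("het_bc")),
    "p1"
  )
})

test_that("gap consistency agrees with the exhaustive gamete-enumeration oracle", {
  des <- mapping_design("hom_f2")
  succeeded <- 0
  for (s in 1:50) {
    parents <- simulate_parents(6, c(chr12 = 2e6), indel_fraction = 0, seed = s)
    sites <- parents$sites[!parents$sites$is_causal, ]
    pop <- simulate_population(parents, des, 8, seed = s)
    g <- population_genotypes(pop, sites)
    dm <- dosage_matrix(g)
    oracle_ok <- narrow_oracle(dm, "hom_f2")
    nr <- tryCatch(narrow_interval(g, des, chrom_length = 2e6), error = function(e) NULL)
    cp <- parents$causal$pos
    true_gap <- sum(sites$pos < cp) + 1 # 1-based index into the gap list
    if (is.null(nr)) {
      expect_false(any(oracle_ok))
    } else {
      expect_equal(nr$gaps$consistent, oracle_ok)
      succeeded <- succeeded + 1
      if (oracle_ok[true_gap]) {
        # whenever the data admit the single-crossover reading of the true
        # gap, the returned interval must contain the causal position
        expect_true(any(nr$interval$start <= cp & nr$interval$end >= cp))
      }
    }
  }
  expect_gte(succeeded, 45) # narrowing succeeds in nearly all error-free draws
})

test_that("tied marker positions are dropped with a warning", {
  calls <- matrix("HOM_A", 2, 3, dimnames = list(c("p", "q"), c("m1", "m2", "m3")))
  calls["p", "m1"] <- "HET"
  calls["q", "m3"] <- "HET"
  g <- geno_tibble(calls, c(100, 100, 300))
  expect_warning(nr <- narrow_interval(g, mapping_design("hom_f2")), "tied")
  expect_equal(nrow(nr$marker_report), 2)
})

test_that("interval sizes in Mbp round half-up to two decimals", {
  expect_equal(interval_size_mbp(10068751, 11595846), 1.53)
  expect_equal(interval_size_mbp(5, 5), 0)
  expect_equal(interval_size_mbp(3804685, 5189063), 1.38)
})

test_that("recombinant counts grow with distance from the causal locus", {
  des <- mapping_design("hom_f2")
  cors <- vapply(1:10, function(s) {
    parents <- simulate_parents(8, c(chr1 = 2e7), indel_fraction = 0, seed = s)
    sites <- parents$sites[!parents$sites$is_causal, ]
    pop <- simulate_population(parents, des, 60, seed = s)
    g <- population_genotypes(pop, sites)
    n_rec <- vapply(unique(g$marker), function(m) {
      length(find_recombinants(g, m, des))
    }, numeric(1))
    d <- abs(sites$pos - parents$causal$pos)
    cor(d, n_rec[sprintf("%s_%d", sites$chrom, sites$pos)], method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.5)
})
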