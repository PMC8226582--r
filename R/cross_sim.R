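#' Pool sequencing specification
#'
#' Mean coverage and per-read miscall probability for pooled read sampling.
#'
#' @param depth Mean coverage (e.g. 40 for a mutant pool, 20 for a parent
#'   control pool).
#' @param error_rate Per-read probability of reporting the other allele
#'   (default 0.002).
#' @return A `pool_spec` list.
#' @export
pool_spec <- function(depth = 40, error_rate = 0.002) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.1)
  structure(list(depth = depth, error_rate = error_rate), class = "pool_spec")
}

#' Simulate two parental haplotypes and their polymorphic sites
#'
#' Generates biallelic polymorphisms between a mutant-background parent (A)
#' and a mapping parent (B) at random positions, plus a single causal
#' mutation unique to the mutant line (always a non-reference allele). With
#' `background = "ref"` the A parent is the reference, so the B parent
#' carries the alternate allele at every parental polymorphism; with
#' `background = "alt"` the reference is the mapping parent; `"mixed"`
#' assigns orientation at random per site — useful for exercising
#' [orient_to_mutant_background()].
#'
#' @param n_sites Number of parental polymorphisms (>= 1), distributed over
#'   chromosomes proportionally to length.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param indel_fraction Fraction of sites that are InDels; the rest are
#'   SNPs.
#' @param indel_len_range Inclusive range of InDel length differences in bp
#'   (default 1-12, straddling the 5 bp gel-resolvability cut).
#' @param causal Optional list/tibble with `chrom` and `pos` of the causal
#'   mutation; defaults to the midpoint of the first chromosome.
#' @param background `"ref"` (default: the reference genome is the mutant
#'   line's wild-type progenitor, so every parental polymorphism is visible
#'   as a non-reference allele in the mapping-parent control pool), `"alt"`
#'   or `"mixed"` (see above).
#' @param seed Integer seed; fixed seed gives a byte-identical truth table.
#' @return Object of class `parent_truth`: list with `sites` (tibble
#'   `chrom`, `pos`, `ref`, `alt`, `vclass`, `a_is_alt`, `is_causal`),
#'   `causal` (its row), `chrom_lengths`, `background`, `seed`.
#' @export
simulate_parents <- function(n_sites, chrom_lengths, indel_fraction = 0.2,
                             causal = NULL, background = c("ref", "alt", "mixed"),
                             indel_len_range = c(1, 12), seed = 1) {
  stopifnot(
    n_sites >= 1, all(chrom_lengths > 1000),
    length(indel_len_range) == 2, indel_len_range[1] >= 1,
    indel_len_range[2] <= 40, indel_len_range[1] <= indel_len_range[2]
  )
  background <- match.arg(background)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (is.null(causal)) {
    causal <- list(chrom = names(chrom_lengths)[1], pos = floor(chrom_lengths[[1]] / 2) + 25)
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(derive_seed(seed, "parents"), {
    per_chrom <- pmax(round(n_sites * chrom_lengths / sum(chrom_lengths)), 1)
    sites <- purrr::map_dfr(names(chrom_lengths), function(chr) {
      # positions on a 50 bp grid: keeps alleles from overlapping when the
      # reference sequence is materialized, and never collides with the
      # causal position (grid offset 25)
      grid <- seq(100, chrom_lengths[[chr]] - 100, by = 50)
      k <- min(per_chrom[[chr]], length(grid))
      pos <- sort(sample(grid, k))
      is_indel <- stats::runif(k) < indel_fraction
      ref <- sample(bases, k, replace = TRUE)
      lens <- seq(indel_len_range[1], indel_len_range[2])
      alt <- vapply(seq_len(k), function(i) {
        if (!is_indel[i]) {
          sample(setdiff(bases, ref[i]), 1)
        } else if (stats::runif(1) < 0.5) { # insertion
          paste0(ref[i], paste(sample(bases, lens[sample.int(length(lens), 1)], replace = TRUE), collapse = ""))
        } else {
          alt_i <- ref[i]
          ref_i <- paste0(ref[i], paste(sample(bases, lens[sample.int(length(lens), 1)], replace = TRUE), collapse = ""))
          ref[i] <<- ref_i
          alt_i
        }
      }, "")
      tibble::tibble(chrom = chr, pos = pos, ref = ref, alt = alt)
    })
    sites$vclass <- classify_variant(sites$ref, sites$alt)
    sites$a_is_alt <- switch(background,
      alt = TRUE,
      ref = FALSE,
      mixed = stats::runif(nrow(sites)) < 0.5
    )
    sites$is_causal <- FALSE
    causal_ref <- sample(bases, 1)
    causal_row <- tibble::tibble(
      chrom = causal$chrom, pos = as.numeric(causal$pos),
      ref = causal_ref, alt = sample(setdiff(bases, causal_ref), 1),
      vclass = "SNP", a_is_alt = TRUE, is_causal = TRUE
    )
    sites <- dplyr::bind_rows(sites, causal_row) |>
      dplyr::arrange(.data$chrom, .data$pos)
  })
  structure(
    list(
      sites = sites, causal = causal_row, chrom_lengths = chrom_lengths,
      background = background, seed = seed
    ),
    class = "parent_truth"
  )
}

# Crossover-phase machinery. For n gametes over one chromosome, draws
# Poisson(L_morgans) crossover counts with uniform positions (Haldane model,
# no interference) and returns the n x S logical matrix saying, per gamete
# and site, whether the site is inherited from haplotype 1. `anchor_pos`
# conditions the phase so haplotype 1 is transmitted at the anchor — the
# exact conditional law of a gamete given selection for the haplotype-1
# allele at that locus.
crossover_phase <- function(n, positions, chrom_length, cM_per_Mb, anchor_pos = NULL) {
  l_morgans <- chrom_length / 1e6 * cM_per_Mb / 100
  k <- stats::rpois(n, l_morgans)
  kmax <- max(k, 1L)
  xo <- matrix(Inf, nrow = n, ncol = kmax)
  if (sum(k) > 0) {
    rows <- rep(seq_len(n), k)
    cols <- unlist(lapply(k, seq_len), use.names = FALSE)
    xo[cbind(rows, cols)] <- stats::runif(sum(k)) * chrom_length
  }
  counts <- vapply(positions, function(p) rowSums(xo < p), numeric(n))
  counts <- matrix(counts, nrow = n) # guard against n == 1 dropping dims
  if (is.null(anchor_pos)) {
    phase <- sample(0:1, n, replace = TRUE)
    ((counts + phase) %% 2) == 0
  } else {
    c0 <- rowSums(xo < anchor_pos)
    ((counts - c0) %% 2) == 0
  }
}

#' Simulate unconditional gametes of an F1 plant
#'
#' Low-level access to the meiosis engine: gametes of an F1 whose two
#' haplotypes are all-A and all-B, without any selection. Useful for
#' checking the recombination model directly (e.g. Haldane's map function).
#'
#' @param n Number of gametes.
#' @param positions Site positions (bp) on one chromosome.
#' @param chrom_length Chromosome length (bp).
#' @param cM_per_Mb Recombination rate (default 4 cM/Mb).
#' @param seed Integer seed.
#' @return Logical matrix `n x length(positions)`; `TRUE` = A allele.
#' @export
simulate_gametes <- function(n, positions, chrom_length, cM_per_Mb = 4, seed = 1) {
  withr::with_seed(derive_seed(seed, "gametes"), {
    crossover_phase(n, positions, chrom_length, cM_per_Mb)
  })
}

#' Simulate a phenotype-selected mapping population
#'
#' Forward simulation of the crossing scheme under the Haldane map function
#' (interference-free crossovers at `cM_per_Mb`), with phenotype selection:
#'
#' * `hom_f2` — mutant (A, homozygous causal) x mapping parent (B); F2 by
#'   selfing; selected plants homozygous A at the causal locus.
#' * `het_bc` — heterozygous mutant (A background) x B, then `n_backcross`
#'   backcrosses to B, keeping a causal-allele carrier each generation;
#'   selected plants heterozygous at the causal locus.
#'
#' Selection is applied by exact conditional sampling: the selection event
#' is precisely "the A-carrying haplotype is transmitted at the causal
#' locus", so the crossover phase is conditioned there instead of rejecting
#' and redrawing gametes. With `select = FALSE` no conditioning is applied
#' (e.g. to check unselected F2 genotype ratios).
#'
#' @param parents A `parent_truth` from [simulate_parents()].
#' @param design A [mapping_design()].
#' @param n_plants Number of selected plants.
#' @param cM_per_Mb Recombination rate (default 4).
#' @param select Apply causal-locus selection (default `TRUE`).
#' @param seed Integer seed.
#' @return Object of class `bsa_population`: list with `dosage` (integer
#'   matrix `n_plants` x sites, A-allele dosage 0-2), `freq` (per-site
#'   A-allele frequency across plants), `sites`, `design`, `n_plants`.
#' @export
simulate_population <- function(parents, design, n_plants, cM_per_Mb = 4,
                                select = TRUE, seed = 1) {
  stopifnot(inherits(parents, "parent_truth"), inherits(design, "mapping_design"))
  sites <- parents$sites
  causal <- parents$causal
  dosage <- matrix(0L, nrow = n_plants, ncol = nrow(sites))
  withr::with_seed(derive_seed(seed, "population"), {
    for (chr in names(parents$chrom_lengths)) {
      cols <- which(sites$chrom == chr)
      if (length(cols) == 0) next
      pos <- sites$pos[cols]
      len <- parents$chrom_lengths[[chr]]
      anchor <- if (select && chr == causal$chrom) causal$pos else NULL
      if (design$mode == "hom_f2") {
        # F2 plant = two independent F1 gametes, each conditioned (if linked)
        # on transmitting the A haplotype at the causal locus
        u1 <- crossover_phase(n_plants, pos, len, cM_per_Mb, anchor)
        u2 <- crossover_phase(n_plants, pos, len, cM_per_Mb, anchor)
        dosage[, cols] <- u1 + u2
      } else {
        # BCnF1 mutant-derived gamete: chain of n_backcross meioses against
        # the recurrent all-B parent, keeping the causal carrier each round
        g <- matrix(TRUE, nrow = n_plants, ncol = length(pos))
        for (k in seq_len(design$n_backcross)) {
          g <- g & crossover_phase(n_plants, pos, len, cM_per_Mb, anchor)
        }
        dosage[, cols] <- g # second gamete is all-B
      }
    }
  })
  structure(
    list(
      dosage = dosage,
      freq = colSums(dosage) / (2 * n_plants),
      sites = sites,
      design = design,
      n_plants = n_plants
    ),
    class = "bsa_population"
  )
}

#' Genotype table of simulated plants at chosen markers
#'
#' Converts the dosage matrix of a simulated population into the long
#' genotype-tibble form used by the recombinant-mapping functions, at a
#' subset of sites used as PCR markers.
#'
#' @param population A `bsa_population` from [simulate_population()].
#' @param marker_sites Tibble (or site subset) with `chrom` and `pos` of the
#'   marker sites; must match rows of `population$sites`.
#' @return Long genotype tibble (`plant_id`, `marker`, `chrom`, `pos`,
#'   `call`), markers named `<chrom>_<pos>`.
#' @export
population_genotypes <- function(population, marker_sites) {
  stopifnot(inherits(population, "bsa_population"))
  assert_columns(marker_sites, c("chrom", "pos"))
  idx <- match(
    paste(marker_sites$chrom, marker_sites$pos),
    paste(population$sites$chrom, population$sites$pos)
  )
  if (anyNA(idx)) stop("marker site(s) not present in the simulated population", call. = FALSE)
  calls <- c("HOM_B", "HET", "HOM_A")
  purrr::map_dfr(seq_along(idx), function(i) {
    tibble::tibble(
      plant_id = paste0("plant_", seq_len(population$n_plants)),
      marker = sprintf("%s_%d", marker_sites$chrom[i], marker_sites$pos[i]),
      chrom = marker_sites$chrom[i],
      pos = marker_sites$pos[i],
      call = calls[population$dosage[, idx[i]] + 1L]
    )
  }) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$plant_id)
}

#' Sample pooled sequencing reads at given allele frequencies
#'
#' Per site, total depth is Poisson(`depth`) and the focal-allele read count
#' is Binomial(total, f') where `f' = f (1 - e) + (1 - f) e` folds the
#' symmetric per-read error rate `e` into the true frequency `f`.
#'
#' @param freqs Vector of true focal-allele frequencies in `[0, 1]`.
#' @param pool A [pool_spec()].
#' @param seed Integer seed.
#' @return Tibble with `total`, `alt` (focal allele) and `ref` counts.
#' @export
sample_pool_reads <- function(freqs, pool = pool_spec(), seed = 1) {
  stopifnot(inherits(pool, "pool_spec"), all(freqs >= 0 & freqs <= 1))
  withr::with_seed(derive_seed(seed, "reads"), {
    total <- stats::rpois(length(freqs), pool$depth)
    p <- freqs * (1 - pool$error_rate) + (1 - freqs) * pool$error_rate
    alt <- stats::rbinom(length(freqs), total, p)
    tibble::tibble(total = total, alt = alt, ref = total - alt)
  })
}

#' Pooled variant table from a simulated population
#'
#' Samples mutant-pool and control-pool reads at every parental site and
#' assembles the pooled-variant tibble the scan functions consume. The
#' control pool is a mapping-parent (B) pool, so its A-allele frequency is 0
#' everywhere; read counts are reported in reference orientation (`alt`
#' counts hold the A allele only where `a_is_alt`).
#'
#' @param parents A `parent_truth`.
#' @param population A `bsa_population` simulated from it.
#' @param pool_mut,pool_ctrl [pool_spec()]s for the two pools (defaults 40x
#'   and 20x).
#' @param seed Integer seed.
#' @return Pooled-variant tibble (`chrom`, `pos`, `ref`, `alt`, `mut_ref`,
#'   `mut_alt`, `ctrl_ref`, `ctrl_alt`, `vclass`).
#' @export
simulate_pooled_variants <- function(parents, population,
                                     pool_mut = pool_spec(40),
                                     pool_ctrl = pool_spec(20),
                                     seed = 1) {
  stopifnot(inherits(parents, "parent_truth"), inherits(population, "bsa_population"))
  sites <- parents$sites
  f_a_mut <- population$freq
  f_a_ctrl <- rep(0, nrow(sites))
  f_alt_mut <- ifelse(sites$a_is_alt, f_a_mut, 1 - f_a_mut)
  f_alt_ctrl <- ifelse(sites$a_is_alt, f_a_ctrl, 1 - f_a_ctrl)
  mut <- sample_pool_reads(f_alt_mut, pool_mut, seed = derive_seed(seed, "mut_pool"))
  ctrl <- sample_pool_reads(f_alt_ctrl, pool_ctrl, seed = derive_seed(seed, "ctrl_pool"))
  tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    mut_ref = mut$ref, mut_alt = mut$alt,
    ctrl_ref = ctrl$ref, ctrl_alt = ctrl$alt,
    vclass = sites$vclass
  )
}
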