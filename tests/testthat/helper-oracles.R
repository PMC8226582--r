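# Independent oracles used to check the package's own implementations.

# G statistic via the entropy decomposition of the log-likelihood ratio:
# G = 2 * (sum xlogx(n_i) - sum xlogx(row margins) - sum xlogx(col margins)
#          + xlogx(N)), an algebraically different route from the
# observed/expected form used in the package.
g_oracle <- function(n1, n2, n3, n4) {
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  n <- n1 + n2 + n3 + n4
  2 * (xlogx(n1) + xlogx(n2) + xlogx(n3) + xlogx(n4) -
    xlogx(n1 + n2) - xlogx(n3 + n4) -
    xlogx(n1 + n3) - xlogx(n2 + n4) + xlogx(n))
}

# Brute-force window membership: O(sites x windows).
window_oracle <- function(pos, delta, chrom_length, window, step, min_sites) {
  starts <- seq(1, chrom_length, by = step)
  means <- rep(NA_real_, length(starts))
  counts <- integer(length(starts))
  for (k in seq_along(starts)) {
    inside <- which(pos >= starts[k] & pos <= starts[k] + window - 1)
    counts[k] <- length(inside)
    if (length(inside) >= min_sites) means[k] <- mean(delta[inside])
  }
  list(starts = starts, means = means, counts = counts)
}

# Exhaustive single-crossover consistency oracle for interval narrowing.
# Enumerates, per plant and candidate gap, every gamete configuration
# (per-side crossover thresholds) and asks whether some configuration
# reproduces the observed A-allele dosages. Markers must be given in
# position order; dosage is 0/1/2 with NA for missing.
narrow_oracle_gap_ok <- function(dosage, gap_left_idx, mode) {
  m <- length(dosage)
  left_idx <- rev(seq_len(gap_left_idx)) # nearest-to-gap first
  right_idx <- if (gap_left_idx < m) (gap_left_idx + 1):m else integer(0)
  nl <- length(left_idx)
  nr <- length(right_idx)
  gamete_dose <- function(tl, tr) {
    d <- integer(m)
    if (nl > 0) d[left_idx] <- as.integer(seq_len(nl) <= tl)
    if (nr > 0) d[right_idx] <- as.integer(seq_len(nr) <= tr)
    d
  }
  obs_ok <- function(d) {
    keep <- !is.na(dosage)
    all(d[keep] == dosage[keep])
  }
  if (mode == "het_bc") {
    for (tl in 0:nl) {
      for (tr in 0:nr) {
        if (obs_ok(gamete_dose(tl, tr))) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  configs <- expand.grid(tl = 0:nl, tr = 0:nr)
  doses <- lapply(seq_len(nrow(configs)), function(i) gamete_dose(configs$tl[i], configs$tr[i]))
  for (i in seq_along(doses)) {
    for (j in seq_along(doses)) {
      if (obs_ok(doses[[i]] + doses[[j]])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

narrow_oracle <- function(dosage_matrix, mode) {
  m <- ncol(dosage_matrix)
  vapply(0:m, function(g) {
    all(vapply(seq_len(nrow(dosage_matrix)), function(p) {
      narrow_oracle_gap_ok(dosage_matrix[p, ], g, mode)
    }, logical(1)))
  }, logical(1))
}

# Long genotype tibble from a plants x markers call matrix (markers named,
# positions supplied in marker order).
geno_tibble <- function(calls, marker_pos, chrom = "chr12") {
  plants <- rownames(calls) %||% paste0("plant_", seq_len(nrow(calls)))
  purrr::map_dfr(seq_len(ncol(calls)), function(j) {
    tibble::tibble(
      plant_id = plants,
      marker = colnames(calls)[j],
      chrom = chrom,
      pos = marker_pos[j],
      call = calls[, j]
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plants x markers dosage matrix (markers in position order) from a long
# genotype tibble
dosage_matrix <- function(g) {
  d <- c(HOM_A = 2, HET = 1, HOM_B = 0, MISSING = NA_real_)
  markers <- unique(g[, c("marker", "pos")])
  markers <- markers[order(markers$pos), ]
  g$dos <- unname(d[g$call])
  wide <- tidyr::pivot_wider(g[, c("plant_id", "marker", "dos")],
    names_from = "marker", values_from = "dos"
  )
  m <- as.matrix(wide[, markers$marker, drop = FALSE])
  rownames(m) <- wide$plant_id
  m
}

# Small pooled-variant tibble builder for filter tests.
toy_variants <- function(n = 10, chrom = "chr1", seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      chrom = chrom,
      pos = sort(sample(1e6, n)),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      mut_ref = rpois(n, 20), mut_alt = rpois(n, 20),
      ctrl_ref = rpois(n, 20), ctrl_alt = rpois(n, 2)
    )
  })
}
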