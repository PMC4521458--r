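# Fixtures and independent oracles used across the test files.

# Build a haplo_matrix from explicit chromosome rows (one integer vector per
# chromosome; two consecutive rows per individual) and per-individual pops.
toy_matrix <- function(rows, pops = NULL, pos = NULL, n_alleles = NULL,
                       chrom = "chr1") {
  a <- do.call(rbind, rows)
  n <- nrow(a) / 2L
  l <- ncol(a)
  if (is.null(pos)) pos <- seq_len(l) * 100L
  if (is.null(n_alleles)) n_alleles <- apply(a, 2L, max) + 1L
  individuals <- sprintf("ind%02d", seq_len(n))
  labels <- if (!is.null(pops)) setNames(pops, individuals) else NULL
  haplo_matrix(
    a,
    data.frame(id = sprintf("m%02d", seq_len(l)), chrom = chrom,
               pos_bp = pos, pos_cm = NA_real_,
               n_alleles = as.integer(n_alleles),
               stringsAsFactors = FALSE),
    individuals, labels)
}

# Random labelled phased dataset: markers are drawn independently (linkage
# equilibrium) with population-specific allele frequencies.
random_haplo_matrix <- function(n_ind = 10L, l = 6L, K = 2L,
                                n_alleles = 2L, seed = 1L) {
  set.seed(seed)
  pops <- paste0("pop", rep(seq_len(K), length.out = n_ind))
  a <- matrix(0L, nrow = 2L * n_ind, ncol = l)
  for (j in seq_len(l)) {
    for (k in seq_len(K)) {
      p <- as.vector(stats::rgamma(n_alleles, 1))
      p <- p / sum(p)
      rows <- which(rep(pops, each = 2L) == paste0("pop", k))
      a[rows, j] <- sample(0:(n_alleles - 1L), length(rows),
                           replace = TRUE, prob = p)
    }
  }
  toy_matrix(asplit(a, 1L), pops)
}

# Mutual-information oracle for IA: I(allele; population) in nats under a
# uniform prior over the K populations, computed from Shannon entropies.
ia_mi_oracle <- function(f) {
  shannon <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  shannon(colMeans(f)) - mean(apply(f, 1L, shannon))
}

# Hudson's FST between two populations from per-chromosome biallelic codes,
# as a ratio of averages over loci.
hudson_fst <- function(a1, a2) {
  p1 <- colMeans(a1); p2 <- colMeans(a2)
  n1 <- nrow(a1); n2 <- nrow(a2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

# Independent oracle for the expected number of segregating sites under the
# three-population divergence model: event-driven simulation of the
# structured-coalescent lineage-count process (no recombination, which does
# not affect the expectation).  Time in units of 4*Ne generations, in which
# k lineages in one population coalesce at rate k*(k-1); mutations accrue at
# rate theta per unit branch length.
expected_segsites_oracle <- function(n_chrom_per_pop, t1, t2, theta,
                                     nrep = 300L, seed = 99L) {
  evolve <- function(k, t_max) {
    len <- 0
    t <- 0
    while (k > 1L) {
      dt <- stats::rexp(1L, k * (k - 1))
      if (!is.finite(t_max) || t + dt < t_max) {
        len <- len + k * dt
        t <- t + dt
        k <- k - 1L
      } else {
        len <- len + k * (t_max - t)
        return(list(k = k, len = len))
      }
    }
    if (is.finite(t_max) && t < t_max) len <- len + (t_max - t)  # k == 1
    list(k = k, len = len)
  }
  set.seed(seed)
  lens <- replicate(nrep, {
    p2 <- evolve(n_chrom_per_pop, t1)
    p3 <- evolve(n_chrom_per_pop, t1)
    p23 <- evolve(p2$k + p3$k, t2 - t1)
    p1 <- evolve(n_chrom_per_pop, t2)
    root <- evolve(p23$k + p1$k, Inf)
    p2$len + p3$len + p23$len + p1$len + root$len
  })
  list(mean = theta * mean(lens), se = theta * stats::sd(lens) / sqrt(nrep))
}

# Watterson's formulas for a panmictic sample of n chromosomes.
watterson <- function(n, theta) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  list(mean = theta * a1, sd = sqrt(theta * a1 + theta^2 * a2))
}

# Minimal phased VCF writer for io tests.
write_test_vcf <- function(path, samples, records) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  for (r in records) {
    lines <- c(lines, paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", ".",
                              ".", "GT", r$gt), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Simulated replicate cache so expensive msprime runs are shared within a
# test file.
local_sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(rho, seed, ...) {
  key <- paste0("r", rho, "s", seed, paste0(c(...), collapse = "_"))
  if (is.null(local_sim_cache[[key]])) {
    local_sim_cache[[key]] <- simulate_dataset(
      divergence_model(rho = rho, seed = seed, ...))
  }
  local_sim_cache[[key]]
}
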