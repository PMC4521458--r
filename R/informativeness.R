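#' Per-population allele frequency table
#'
#' Plug-in (maximum-likelihood) allele frequencies of one locus, estimated
#' from the chromosomes of a set of reference individuals.  Row `i`, column
#' `j` holds the frequency of allele `j` in population `i`; the attached
#' `mean_freqs` are the unweighted across-population means (each population
#' counts `1/K` regardless of its sample size).
#'
#' @param x a [haplo_matrix()] (or a recoded matrix from [apply_map()]).
#' @param locus column index of the locus.
#' @param training optional character vector of individual ids to use
#'   (default: all labelled individuals).  Every training individual must be
#'   labelled, and every population must contribute at least one chromosome.
#' @return Object of class `freq_table`: list with `freqs` (K x N matrix,
#'   rows named by population in sorted order, columns by allele code) and
#'   `mean_freqs`.
#' @export
freq_table <- function(x, locus, training = NULL) {
  stopifnot(inherits(x, c("haplo_matrix", "haplo_recoded")))
  if (is.null(training)) training <- names(x$labels)
  lab <- require_labels(x, training)
  idx <- match(training, x$individuals)
  rows <- chromosome_rows(idx)
  codes <- x$alleles[rows, locus]
  pops <- rep(lab, each = 2L)
  all_pops <- sort(unique(unname(x$labels)))
  n_alleles <- if (inherits(x, "haplo_recoded")) {
    x$loci[[locus]]$n_alleles
  } else {
    x$markers$n_alleles[locus]
  }
  freq_from_codes(codes, pops, n_alleles, levels = all_pops)
}

freq_from_codes <- function(codes, pops, n_alleles = max(codes) + 1L,
                            levels = sort(unique(pops))) {
  pf <- factor(pops, levels = levels)
  cnt <- table(pf, factor(codes, levels = 0:(n_alleles - 1L)))
  tot <- rowSums(cnt)
  if (any(tot == 0L)) {
    stop("population ", levels(pf)[tot == 0L][1L],
         " has no training chromosomes", call. = FALSE)
  }
  f <- unclass(cnt / tot)
  new_freq_table(f)
}

new_freq_table <- function(f) {
  f <- as.matrix(f)
  if (nrow(f) < 2L) stop("a frequency table needs K >= 2 populations",
                         call. = FALSE)
  if (any(f < 0) || any(abs(rowSums(f) - 1) > 1e-9)) {
    stop("frequency table rows must be probability vectors", call. = FALSE)
  }
  structure(list(freqs = f, mean_freqs = colMeans(f)), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Allele frequencies (", nrow(x$freqs), " populations x ",
      ncol(x$freqs), " alleles)\n", sep = "")
  print(round(x$freqs, 4))
  invisible(x)
}

#' Informativeness for assignment (IA)
#'
#' Entropy-based measure of how well the allele frequencies of one locus
#' discriminate K predefined populations:
#' \deqn{IA = \sum_j \left(-\bar p_j \log \bar p_j +
#'       \sum_i \frac{p_j^{(i)}}{K} \log p_j^{(i)}\right)}
#' with natural logarithms, the convention \eqn{0 \log 0 = 0}, and
#' \eqn{\bar p_j} the unweighted mean of the population frequencies.  IA is
#' the mutual information (in nats) between a random allele and its
#' population of origin under a uniform prior over populations, so
#' \eqn{0 \le IA \le \log K}.
#'
#' @param t a `freq_table`, or a plain K x N matrix of row-stochastic
#'   population allele frequencies.
#' @return IA in nats.
#' @export
ia <- function(t) {
  if (!inherits(t, "freq_table")) t <- new_freq_table(t)
  f <- t$freqs
  K <- nrow(f)
  pbar <- t$mean_freqs
  sum(-xlogx(pbar)) + sum(xlogx(f)) / K
}

# 0 log 0 = 0 by masking, never by pseudocounts
xlogx <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos])
  out
}

#' Gain of informativeness for assignment (GIA)
#'
#' The change in total informativeness from replacing two markers by their
#' haplotype combination: `ia(h) - ia(m1) - ia(m2)`.  A positive value means
#' assignment information is gained by treating the pair as one multi-allelic
#' haplotype locus; for markers in linkage equilibrium within every
#' population GIA is non-positive.
#'
#' @param h frequency table of the combined locus, whose alleles are the
#'   ordered pairs (allele of `m1`, allele of `m2`) observed on the same
#'   chromosomes.
#' @param m1,m2 frequency tables of the constituent markers.
#' @return GIA in nats.
#' @export
gia <- function(h, m1, m2) {
  ia(h) - ia(m1) - ia(m2)
}
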