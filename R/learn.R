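#' Learn informative haplotype loci from labelled phased data
#'
#' The LEARN step: within each genomic window, repeatedly merge the pair of
#' loci (original markers or previously merged haplotype loci) with the
#' largest gain of informativeness for assignment (GIA), while that maximum
#' exceeds `gia_threshold`.  Merging is recursive, so a haplotype locus can
#' absorb further markers; every merge strictly increases the total
#' informativeness for assignment of the partition.  The result is a
#' haplotype map: a partition of all markers into loci together with the
#' coding from constituent-allele tuples to haplotype-allele codes, learned
#' from the training chromosomes only.
#'
#' Haplotype-alleles are numbered from 0 in order of first appearance,
#' scanning training chromosomes in the order of the individual list.  A
#' warning is raised when a merged locus reaches one allele per training
#' chromosome (`2n` alleles): such private haplotypes carry no assignment
#' information and signal overfitting.
#'
#' @param x a labelled [haplo_matrix()].
#' @param training character vector of training individual ids (default: all
#'   labelled individuals).  All must be labelled; at least two populations
#'   must be present.
#' @param window a [window_spec()]; merging never crosses window boundaries.
#' @param gia_threshold merge only while the best GIA exceeds this value
#'   (default 0).
#' @param max_alleles if positive, veto any merge whose haplotype locus would
#'   exceed this many alleles (0 disables the cap).
#' @return Object of class `haplo_map`: fields `window`, `gia_threshold`,
#'   `loci` (list of haplotype loci with `marker_ids`, `members`, `coding`,
#'   `n_alleles`), `markers`, `training`, `populations` and the training
#'   objective `objective = c(genotype, haplotype)` (total IA before/after).
#' @seealso [apply_map()] / [predict.haplo_map()] for the APPLY step,
#'   [pca_assign()] for assignment.
#' @export
haplopop <- function(x, training = NULL, window = window_spec("bp", 5e4),
                     gia_threshold = 0, max_alleles = 0) {
  stopifnot(inherits(x, "haplo_matrix"))
  if (is.null(training)) training <- names(x$labels)
  lab <- require_labels(x, training)
  pops <- sort(unique(lab))
  K <- length(pops)
  if (K < 2L) stop("at least two populations are required", call. = FALSE)

  idx <- match(training, x$individuals)
  # keep storage order: "order of appearance in the list of individuals"
  idx <- sort(idx)
  training <- x$individuals[idx]
  lab <- lab[training]
  rows <- chromosome_rows(idx)
  pop0 <- as.integer(factor(lab, levels = pops))[rep(seq_along(idx), each = 2L)] - 1L
  popn <- as.integer(table(factor(lab, levels = pops))) * 2L
  A <- x$alleles[rows, , drop = FALSE]

  mk <- x$markers
  if (!"pos_cm" %in% names(mk)) mk$pos_cm <- NA_real_
  mk <- mk[, c("id", "chrom", "pos_bp", "pos_cm", "n_alleles")]
  rownames(mk) <- NULL

  windows <- make_windows(x$markers, window)
  loci <- list()
  n_merges <- 0L
  for (w in windows) {
    res <- greedy_window(A, w, pop0, K, popn, gia_threshold, max_alleles)
    n_merges <- n_merges + res$n_merges
    for (lc in res$loci) {
      members <- sort(lc$members)
      loci[[length(loci) + 1L]] <- make_locus(x$markers, A, members)
    }
  }
  # genomic order of the leftmost member marker
  loci <- loci[order(vapply(loci, function(l) min(l$members), 1L))]
  ia_geno <- sum(vapply(seq_len(ncol(A)), function(j)
    cpp_ia_codes(A[, j], pop0, K, popn), 0))
  ia_hap <- sum(vapply(loci, function(l)
    cpp_ia_codes(locus_codes(A, l$members), pop0, K, popn), 0))

  structure(list(
    window = window, gia_threshold = gia_threshold,
    max_alleles = max_alleles, loci = loci, markers = mk,
    training = training, populations = pops,
    objective = c(genotype = ia_geno, haplotype = ia_hap),
    n_merges = n_merges), class = "haplo_map")
}

# first-appearance dense codes of the tuple carried at `members` by each row
locus_codes <- function(A, members) {
  tup <- tuple_strings(A, members)
  match(tup, unique(tup)) - 1L
}

tuple_strings <- function(A, members) {
  if (length(members) == 1L) {
    as.character(A[, members])
  } else {
    do.call(paste, c(lapply(members, function(j) A[, j]), sep = ","))
  }
}

make_locus <- function(markers, A, members) {
  if (length(members) == 1L) {
    n_all <- markers$n_alleles[members]
    coding <- stats::setNames(0:(n_all - 1L), as.character(0:(n_all - 1L)))
  } else {
    tup <- tuple_strings(A, members)
    u <- unique(tup)
    coding <- stats::setNames(seq_along(u) - 1L, u)
    n_all <- length(u)
  }
  list(marker_ids = markers$id[members], members = members,
       chrom = markers$chrom[members[1L]], coding = coding,
       n_alleles = as.integer(n_all))
}

# Greedy GIA merging inside one window (compiled loop).  A: training
# chromosome rows x all markers; w: global column indices of this window.
greedy_window <- function(A, w, pop0, K, popn, threshold, max_alleles) {
  if (length(w) == 1L) {
    return(list(loci = list(list(members = w)), n_merges = 0L))
  }
  res <- cpp_greedy_window(A[, w, drop = FALSE], w, pop0, K, popn,
                           threshold, as.integer(max_alleles))
  for (k in seq_along(res$warn_lo)) {
    warning("haplotype locus spanning markers ", res$warn_lo[k], "-",
            res$warn_hi[k], " has one allele per training chromosome (",
            nrow(A), "); it is private to every chromosome and carries no ",
            "assignment information", call. = FALSE)
  }
  list(loci = lapply(res$members, function(m) list(members = m)),
       n_merges = res$n_merges)
}

#' @export
print.haplo_map <- function(x, ...) {
  cat("Haplotype map (LEARN output)\n")
  cat("  Window: ", x$window$size, " ", x$window$mode,
      ", GIA threshold ", x$gia_threshold, "\n", sep = "")
  cat("  ", nrow(x$markers), " markers -> ", length(x$loci),
      " loci (", x$n_merges, " merges)\n", sep = "")
  cat("  Training: ", length(x$training), " individuals, populations: ",
      paste(x$populations, collapse = ", "), "\n", sep = "")
  cat(sprintf("  Total IA (training): %.4f genotype -> %.4f haplotype\n",
              x$objective["genotype"], x$objective["haplotype"]))
  invisible(x)
}

#' @export
summary.haplo_map <- function(object, ...) {
  sizes <- lengths(lapply(object$loci, `[[`, "members"))
  nall <- vapply(object$loci, `[[`, 1L, "n_alleles")
  cat("Haplotype map summary\n")
  print(object)
  cat("  Locus sizes (markers): ")
  print(table(sizes))
  cat("  Haplotype-allele counts: min ", min(nall), ", median ",
      stats::median(nall), ", max ", max(nall), "\n", sep = "")
  invisible(list(sizes = sizes, n_alleles = nall))
}

#' Exact best partition of a small window by enumeration
#'
#' Enumerates every set partition of the given markers (Bell's number of
#' candidates, so at most 8 markers are allowed) and returns the partition
#' maximising the summed informativeness for assignment.  Intended as an
#' exact reference for bounding the greedy heuristic on small windows.
#'
#' @param x a labelled [haplo_matrix()].
#' @param training training individual ids (default all labelled).
#' @param window integer vector of at most 8 marker column indices.
#' @return List with `partition` (list of integer vectors of column indices)
#'   and `score` (the maximal summed IA).
#' @export
exhaustive_best_partition <- function(x, training = NULL, window) {
  stopifnot(inherits(x, "haplo_matrix"))
  if (length(window) > 8L) {
    stop("exhaustive enumeration is limited to 8 markers (Bell(8) = 4140)",
         call. = FALSE)
  }
  if (is.null(training)) training <- names(x$labels)
  lab <- require_labels(x, training)
  idx <- sort(match(training, x$individuals))
  lab <- lab[x$individuals[idx]]
  rows <- chromosome_rows(idx)
  A <- x$alleles[rows, , drop = FALSE]
  pops <- rep(as.character(lab), each = 2L)

  best <- -Inf
  best_part <- NULL
  for (assign in set_partitions(length(window))) {
    score <- 0
    for (b in seq_len(max(assign))) {
      members <- window[assign == b]
      codes <- locus_codes(A, members)
      score <- score + ia(freq_from_codes(codes, pops))
    }
    if (score > best + 1e-12) {
      best <- score
      best_part <- lapply(seq_len(max(assign)),
                          function(b) window[assign == b])
    }
  }
  list(partition = best_part, score = best)
}

# all set partitions of n elements as assignment vectors (restricted growth)
set_partitions <- function(n) {
  parts <- list(1L)
  if (n == 1L) return(parts)
  for (k in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(b) c(p, b))
    }), recursive = FALSE)
  }
  parts
}
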