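#' Phased haplotype matrix
#'
#' Container for phased diploid genotype data: a `2n x l` integer matrix of
#' allele codes in which rows `2i - 1` and `2i` hold the two chromosomes of
#' individual `i`, together with marker metadata, individual ids and
#' (optionally) population labels.
#'
#' @param alleles integer matrix with `2 * length(individuals)` rows and one
#'   column per marker; entry `(r, j)` is the allele code (0-based) carried by
#'   chromosome `r` at marker `j`.  No missing values are allowed.
#' @param markers data frame with columns `id`, `chrom`, `pos_bp`,
#'   `n_alleles` and optionally `pos_cm`; one row per marker, sorted by
#'   chromosome and strictly increasing physical position within chromosome.
#' @param individuals character vector of unique individual ids.
#' @param labels optional named character vector mapping individual ids to
#'   population ids; may cover only a subset of individuals.
#'
#' @return An object of class `haplo_matrix`.
#' @export
haplo_matrix <- function(alleles, markers, individuals, labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  individuals <- as.character(individuals)
  if (!is.null(labels)) {
    labels <- stats::setNames(as.character(labels), names(labels))
  }
  x <- structure(
    list(alleles = alleles, markers = markers,
         individuals = individuals, labels = labels),
    class = "haplo_matrix")
  validate_haplo_matrix(x)
  x
}

validate_haplo_matrix <- function(x) {
  a <- x$alleles
  m <- x$markers
  n <- length(x$individuals)
  if (nrow(a) != 2L * n) {
    stop("allele matrix must have exactly 2 rows per individual (",
         nrow(a), " rows for ", n, " individuals)", call. = FALSE)
  }
  if (anyDuplicated(x$individuals)) {
    stop("duplicate individual id: ",
         x$individuals[duplicated(x$individuals)][1L], call. = FALSE)
  }
  need <- c("id", "chrom", "pos_bp", "n_alleles")
  if (!all(need %in% names(m))) {
    stop("marker table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(m) != ncol(a)) {
    stop("marker table has ", nrow(m), " rows but allele matrix has ",
         ncol(a), " columns", call. = FALSE)
  }
  if (anyNA(a)) stop("missing allele codes are not supported", call. = FALSE)
  if (any(a < 0L)) stop("allele codes must be >= 0", call. = FALSE)
  if (any(m$n_alleles < 1L)) stop("n_alleles must be >= 1", call. = FALSE)
  if (nrow(m) > 0L) {
    maxcode <- apply(a, 2L, max)
    bad <- which(maxcode >= m$n_alleles)
    if (length(bad)) {
      stop("marker ", m$id[bad[1L]], " declares ", m$n_alleles[bad[1L]],
           " alleles but carries code ", maxcode[bad[1L]], call. = FALSE)
    }
    for (ch in unique(m$chrom)) {
      p <- m$pos_bp[m$chrom == ch]
      if (any(diff(p) <= 0)) {
        stop("marker positions on chromosome ", ch,
             " must be strictly increasing", call. = FALSE)
      }
    }
  }
  if (!is.null(x$labels)) {
    unknown <- setdiff(names(x$labels), x$individuals)
    if (length(unknown)) {
      stop("labels refer to unknown individual: ", unknown[1L], call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.haplo_matrix <- function(x, ...) {
  n <- length(x$individuals)
  cat("Phased haplotype matrix: ", n, " individuals (", nrow(x$alleles),
      " chromosomes) x ", ncol(x$alleles), " markers\n", sep = "")
  cat("Chromosomes: ", paste(unique(x$markers$chrom), collapse = ", "),
      "\n", sep = "")
  if (is.null(x$labels)) {
    cat("No population labels\n")
  } else {
    tab <- table(x$labels)
    cat("Labels: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.haplo_matrix <- function(x) dim(x$alleles)

#' Restrict a haplotype matrix to a subset of individuals
#'
#' @param x a [haplo_matrix()].
#' @param ids individual ids to keep, in the order of `x$individuals`.
#' @return A `haplo_matrix` with both chromosome rows of each kept individual.
#' @export
subset_individuals <- function(x, ids) {
  stopifnot(inherits(x, "haplo_matrix"))
  keep <- which(x$individuals %in% ids)
  if (length(keep) != length(unique(ids))) {
    stop("unknown individual id in subset", call. = FALSE)
  }
  rows <- chromosome_rows(keep)
  labels <- x$labels
  if (!is.null(labels)) {
    labels <- labels[names(labels) %in% x$individuals[keep]]
    if (!length(labels)) labels <- NULL
  }
  haplo_matrix(x$alleles[rows, , drop = FALSE], x$markers,
               x$individuals[keep], labels)
}

# rows of the two chromosomes of each individual index, in storage order
chromosome_rows <- function(ind_idx) {
  as.vector(rbind(2L * ind_idx - 1L, 2L * ind_idx))
}

# labels of the given individuals, erroring on missing ones
require_labels <- function(x, ids) {
  if (is.null(x$labels)) stop("population labels are required", call. = FALSE)
  lab <- x$labels[ids]
  if (anyNA(lab)) {
    stop("individual ", ids[which(is.na(lab))[1L]],
         " has no population label", call. = FALSE)
  }
  stats::setNames(as.character(lab), ids)
}
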