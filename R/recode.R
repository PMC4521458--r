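#' Recode phased data into haplotype loci (APPLY step)
#'
#' Applies a learned haplotype map to any phased dataset containing the same
#' markers: for each locus, each chromosome's tuple of constituent allele
#' codes is looked up in the locus coding.  Tuples never observed during
#' learning are appended with the next free code, scanning chromosomes in
#' storage order (extending the order-of-appearance numbering rule), and
#' flagged as novel.  The dataset may contain individuals of unknown origin
#' together with the reference individuals used for learning.
#'
#' @param x a [haplo_matrix()] whose markers match the map's markers exactly
#'   (same id, chromosome, position and allele count, in the same order).
#' @param map a `haplo_map` from [haplopop()] or [read_haplomap()].
#' @return Object of class `haplo_recoded`: fields `alleles` (2m x L matrix
#'   of haplotype-allele codes), `loci` (the map's loci, coding possibly
#'   extended, each with a logical `novel` flag per allele), `individuals`,
#'   `labels`.
#' @export
apply_map <- function(x, map) {
  stopifnot(inherits(x, "haplo_matrix"), inherits(map, "haplo_map"))
  check_marker_match(x$markers, map$markers)
  L <- length(map$loci)
  out <- matrix(0L, nrow = nrow(x$alleles), ncol = L)
  loci <- map$loci
  for (k in seq_len(L)) {
    lc <- loci[[k]]
    tup <- tuple_strings(x$alleles, lc$members)
    code <- unname(lc$coding[tup])
    novel <- rep(FALSE, lc$n_alleles)
    if (anyNA(code)) {
      unseen <- unique(tup[is.na(code)])   # storage-order first appearance
      extra <- stats::setNames(
        seq(lc$n_alleles, length.out = length(unseen)), unseen)
      lc$coding <- c(lc$coding, extra)
      lc$n_alleles <- lc$n_alleles + length(unseen)
      novel <- c(novel, rep(TRUE, length(unseen)))
      code <- unname(lc$coding[tup])
    }
    lc$novel <- novel
    loci[[k]] <- lc
    out[, k] <- code
  }
  structure(list(alleles = out, loci = loci,
                 individuals = x$individuals, labels = x$labels,
                 map = map), class = "haplo_recoded")
}

#' @rdname apply_map
#' @param object a `haplo_map`.
#' @param newdata a [haplo_matrix()] to recode.
#' @param ... unused.
#' @export
predict.haplo_map <- function(object, newdata, ...) {
  apply_map(newdata, object)
}

check_marker_match <- function(have, want) {
  if (nrow(have) != nrow(want)) {
    stop("dataset has ", nrow(have), " markers but the map was learned on ",
         nrow(want), call. = FALSE)
  }
  for (col in c("id", "chrom", "pos_bp", "n_alleles")) {
    bad <- which(have[[col]] != want[[col]])
    if (length(bad)) {
      stop("marker mismatch at column ", bad[1L], ": dataset has ", col,
           " '", have[[col]][bad[1L]], "' but map has '",
           want[[col]][bad[1L]], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.haplo_recoded <- function(x, ...) {
  nov <- sum(vapply(x$loci, function(l) sum(l$novel %||% FALSE), 0))
  cat("Recoded haplotype data: ", length(x$individuals), " individuals x ",
      ncol(x$alleles), " loci (", nov, " novel alleles)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Presence/absence encoding of haplotype-alleles
#'
#' Expands recoded haplotype data into a binary matrix with one column per
#' haplotype-allele: entry 1 when the chromosome carries that allele, 0
#' otherwise.  Each chromosome row therefore sums to the number of loci.
#'
#' @param x a `haplo_recoded` from [apply_map()] (a plain [haplo_matrix()]
#'   is accepted and treated as unmerged loci).
#' @return Object of class `haplo_onehot`: fields `X` (2m x sum of allele
#'   counts binary matrix), `meta` (data frame mapping columns to locus and
#'   allele, with the novel flag), `individuals`, `labels`.
#' @export
onehot <- function(x) {
  if (inherits(x, "haplo_matrix")) {
    n_all <- x$markers$n_alleles
    loc_id <- x$markers$id
    novel <- lapply(n_all, function(k) rep(FALSE, k))
  } else if (inherits(x, "haplo_recoded")) {
    n_all <- vapply(x$loci, `[[`, 1L, "n_alleles")
    loc_id <- vapply(x$loci, function(l) l$marker_ids[1L], "")
    novel <- lapply(x$loci, function(l) l$novel %||% rep(FALSE, l$n_alleles))
  } else {
    stop("onehot() expects a haplo_matrix or haplo_recoded object",
         call. = FALSE)
  }
  offs <- c(0L, cumsum(n_all))
  X <- matrix(0L, nrow = nrow(x$alleles), ncol = offs[length(offs)])
  for (k in seq_along(n_all)) {
    X[cbind(seq_len(nrow(X)), offs[k] + x$alleles[, k] + 1L)] <- 1L
  }
  meta <- data.frame(
    locus = rep(loc_id, n_all),
    allele = unlist(lapply(n_all, function(k) 0:(k - 1L))),
    novel = unlist(novel), stringsAsFactors = FALSE)
  structure(list(X = X, meta = meta, individuals = x$individuals,
                 labels = x$labels), class = "haplo_onehot")
}
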