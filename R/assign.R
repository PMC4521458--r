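#' Stratified training/validation split
#'
#' Randomly splits the labelled individuals of each population into a
#' training subset (used to learn haplotypes and compute barycenters) and a
#' validation subset (used to measure assignment accuracy).  The training
#' count per population is `round(fraction * size)` with halves rounded up,
#' and at least 1.  The split is deterministic given `seed` and leaves the
#' caller's random number generator state untouched.
#'
#' @param labels named character vector mapping individual id to population.
#' @param fraction_training fraction of each population assigned to the
#'   training set, in (0, 1).
#' @param seed integer seed for the split.
#' @return Object of class `haplo_split` with `training`, `validation`
#'   (character id vectors) and per-population counts.
#' @export
make_split <- function(labels, fraction_training, seed) {
  if (fraction_training <= 0 || fraction_training >= 1) {
    stop("fraction_training must be in (0, 1)", call. = FALSE)
  }
  pops <- sort(unique(labels))
  sizes <- table(factor(labels, levels = pops))
  if (any(sizes < 2L)) {
    stop("population ", names(sizes)[sizes < 2L][1L],
         " has fewer than 2 labelled individuals", call. = FALSE)
  }
  training <- character()
  with_seed(seed, {
    for (p in pops) {
      ids <- sort(names(labels)[labels == p])
      n_tr <- max(1L, as.integer(floor(fraction_training * length(ids) + 0.5)))
      training <- c(training, sample(ids, n_tr))
    }
  })
  validation <- setdiff(names(labels), training)
  counts <- data.frame(
    population = pops,
    training = as.integer(table(factor(labels[training], levels = pops))),
    validation = as.integer(table(factor(labels[validation], levels = pops))))
  structure(list(training = sort(training), validation = sort(validation),
                 counts = counts, fraction = fraction_training, seed = seed),
            class = "haplo_split")
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' @export
print.haplo_split <- function(x, ...) {
  cat("Split (seed ", x$seed, ", fraction ", x$fraction, "):\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' PCA-based population assignment with nearest barycenters
#'
#' Assigns individuals to populations from a presence/absence haplotype-
#' allele encoding: principal component axes are computed from the
#' chromosomes of all individuals in the split (training and validation
#' together, columns mean-centred, no scaling), the top `K - 1` components
#' are retained (K = number of populations), an individual's coordinate is
#' the mean of its two chromosome scores, and each individual is assigned to
#' the population whose training-set barycenter is closest in Euclidean
#' distance (ties broken towards the lexicographically smallest population
#' id).  The reported MIA is the percentage of validation individuals whose
#' assigned population differs from their label.
#'
#' @param encoded a `haplo_onehot` from [onehot()], with labels covering the
#'   split individuals.
#' @param split a [make_split()] result.
#' @param n_pcs number of components (default `K - 1`).
#' @param scale_columns if `TRUE` (default), scale columns to unit variance
#'   before the decomposition.  For a presence/absence column with carrier
#'   frequency `p` the standard deviation is `sqrt(p(1-p))`, so this is the
#'   allele-frequency normalisation smartpca-style PCA applies to SNP data;
#'   it downweights common alleles and is what makes overlarge windows (whose
#'   rare training-private haplotype-alleles would otherwise be ignored)
#'   visibly overfit.  `FALSE` gives plain centred PCA.
#' @return Object of class `assignment_report`: per-individual scores and
#'   predictions, per-population barycenters, `mia` (overall, validation),
#'   `mia_by_pop`, and `mia_training` (training individuals assessed on
#'   themselves, an overfitting diagnostic).
#' @export
pca_assign <- function(encoded, split, n_pcs = NULL, scale_columns = TRUE) {
  stopifnot(inherits(encoded, "haplo_onehot"), inherits(split, "haplo_split"))
  ids <- c(split$training, split$validation)
  lab <- require_labels(encoded, ids)
  pops <- sort(unique(lab[split$training]))
  K <- length(pops)
  d <- if (is.null(n_pcs)) K - 1L else as.integer(n_pcs)

  idx <- match(ids, encoded$individuals)
  if (anyNA(idx)) {
    stop("individual ", ids[which(is.na(idx))[1L]],
         " is not present in the encoded data", call. = FALSE)
  }
  rows <- chromosome_rows(idx)
  Xc <- encoded$X[rows, , drop = FALSE]
  Xc <- scale(Xc, center = TRUE, scale = scale_columns)
  Xc[is.nan(Xc)] <- 0  # constant columns under scaling
  if (d < 1L || d > min(dim(Xc))) {
    stop("cannot extract ", d, " components from a ", nrow(Xc), " x ",
         ncol(Xc), " encoding", call. = FALSE)
  }
  scores <- pc_scores(Xc, d)

  # individual coordinate = mean of its two chromosome scores
  m <- length(ids)
  ind_scores <- (scores[seq(1L, 2L * m, 2L), , drop = FALSE] +
                 scores[seq(2L, 2L * m, 2L), , drop = FALSE]) / 2
  rownames(ind_scores) <- ids
  colnames(ind_scores) <- paste0("PC", seq_len(d))

  bary <- do.call(rbind, lapply(pops, function(p) {
    colMeans(ind_scores[split$training[lab[split$training] == p], ,
                        drop = FALSE])
  }))
  rownames(bary) <- pops

  d2 <- outer(rowSums(ind_scores^2), rep(1, K)) -
    2 * ind_scores %*% t(bary) +
    outer(rep(1, m), rowSums(bary^2))
  predicted <- pops[apply(d2, 1L, which.min)]  # ties: first = smallest id
  names(predicted) <- ids

  set <- ifelse(ids %in% split$training, "training", "validation")
  wrong <- predicted != lab[ids]
  val <- set == "validation"
  mia <- 100 * mean(wrong[val])
  mia_by_pop <- vapply(pops, function(p) {
    sel <- val & lab[ids] == p
    if (any(sel)) 100 * mean(wrong[sel]) else NA_real_
  }, 0)
  mia_training <- 100 * mean(wrong[!val])

  structure(list(
    scores = data.frame(individual = ids, population = unname(lab[ids]),
                        set = set, predicted = unname(predicted),
                        ind_scores, stringsAsFactors = FALSE),
    barycenters = bary, predicted = predicted,
    mia = mia, mia_by_pop = mia_by_pop, mia_training = mia_training,
    n_pcs = d, populations = pops), class = "assignment_report")
}

# scores on the top d principal components of a centred matrix, via the
# eigendecomposition of the smaller of the two Gram matrices
pc_scores <- function(Xc, d) {
  n <- nrow(Xc); p <- ncol(Xc)
  if (p <= n) {
    e <- eigen(crossprod(Xc), symmetric = TRUE)
    v <- e$vectors[, seq_len(d), drop = FALSE]
    Xc %*% v
  } else {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    u <- e$vectors[, seq_len(d), drop = FALSE]
    val <- pmax(e$values[seq_len(d)], 0)
    sweep(u, 2L, sqrt(val), `*`)
  }
}

#' @export
print.assignment_report <- function(x, ...) {
  cat("PCA assignment (", x$n_pcs, " components, populations: ",
      paste(x$populations, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  Validation MIA: %.2f%%\n", x$mia))
  for (p in x$populations) {
    cat(sprintf("    %s: %.2f%%\n", p, x$mia_by_pop[[p]]))
  }
  cat(sprintf("  Training-set MIA (overfitting diagnostic): %.2f%%\n",
              x$mia_training))
  invisible(x)
}

#' @export
summary.assignment_report <- function(object, ...) print(object)

#' @export
plot.assignment_report <- function(x, pcs = c(1L, 2L), ...) {
  sc <- x$scores
  cols <- seq_along(x$populations)
  names(cols) <- x$populations
  pc_cols <- paste0("PC", pcs)
  plot(sc[[pc_cols[1L]]], sc[[pc_cols[2L]]],
       col = cols[sc$population],
       pch = ifelse(sc$set == "training", 1L, 19L),
       xlab = paste0("PC", pcs[1L]), ylab = paste0("PC", pcs[2L]), ...)
  points(x$barycenters[, pcs[1L]], x$barycenters[, pcs[2L]],
         pch = 4L, cex = 2, lwd = 2, col = cols)
  legend("topright", legend = x$populations, col = cols, pch = 19L,
         bty = "n")
  invisible(x)
}
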