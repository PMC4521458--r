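#' Assignment error as a function of window size
#'
#' Runs the full learn / apply / encode / assign pipeline on one fixed
#' training-validation split for each window size and reports the validation
#' MIA.  A window of size 1 (in any mode) isolates every marker in its own
#' window, so no merging occurs and the run measures the raw genotype
#' baseline.
#'
#' @param x a labelled [haplo_matrix()].
#' @param window_sizes numeric vector of window sizes.
#' @param mode window mode for all sizes (`"bp"`, `"markers"` or `"cm"`).
#' @param fraction_training training fraction for the split.
#' @param seed seed for the split.
#' @param gia_threshold,max_alleles passed to [haplopop()].
#' @return A data frame of class `mia_curve` with columns `window_size`,
#'   `mia`, `mia_training`, `n_loci`.
#' @export
mia_curve <- function(x, window_sizes, mode = "bp", fraction_training = 0.5,
                      seed = 1L, gia_threshold = 0, max_alleles = 0) {
  split <- make_split(x$labels, fraction_training, seed)
  rows <- lapply(window_sizes, function(s) {
    rep <- run_pipeline(x, split, window_spec(mode, s), gia_threshold,
                        max_alleles)
    data.frame(window_size = s, mia = rep$report$mia,
               mia_training = rep$report$mia_training,
               n_loci = length(rep$map$loci))
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  class(out) <- c("mia_curve", "data.frame")
  out
}

#' Assignment error as a function of training-set size
#'
#' For each training fraction, draws a stratified split with the same seed,
#' learns haplotypes at a fixed window on the training set and reports the
#' validation MIA.
#'
#' @param x a labelled [haplo_matrix()].
#' @param fractions numeric vector of training fractions in (0, 1).
#' @param window a [window_spec()] (default 50 kb).
#' @param seed seed for the splits.
#' @param gia_threshold,max_alleles passed to [haplopop()].
#' @return A data frame of class `mia_curve` with columns `fraction`,
#'   `n_training`, `mia`, `mia_training`.
#' @export
training_fraction_curve <- function(x, fractions,
                                    window = window_spec("bp", 5e4),
                                    seed = 1L, gia_threshold = 0,
                                    max_alleles = 0) {
  rows <- lapply(fractions, function(f) {
    split <- make_split(x$labels, f, seed)
    rep <- run_pipeline(x, split, window, gia_threshold, max_alleles)
    data.frame(fraction = f, n_training = length(split$training),
               mia = rep$report$mia, mia_training = rep$report$mia_training)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mia_curve", "data.frame")
  out
}

# learn on the split's training set, recode everyone, assign
run_pipeline <- function(x, split, window, gia_threshold = 0,
                         max_alleles = 0) {
  map <- haplopop(x, training = split$training, window = window,
                  gia_threshold = gia_threshold, max_alleles = max_alleles)
  enc <- onehot(apply_map(x, map))
  list(map = map, report = pca_assign(enc, split))
}

#' @export
plot.mia_curve <- function(x, ...) {
  xcol <- if ("window_size" %in% names(x)) "window_size" else "fraction"
  plot(x[[xcol]], x$mia, type = "b", pch = 19L,
       xlab = if (xcol == "window_size") {
         paste0("window size (", attr(x, "mode") %||% "bp", ")")
       } else "training fraction",
       ylab = "validation MIA (%)", ...)
  invisible(x)
}
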