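#' Window specification
#'
#' Haplotype construction is constrained to genomic windows: only markers in
#' the same window may be merged.  Windows are defined by a count of
#' consecutive markers, or by half-open tiles `[c*size, (c+1)*size)` of
#' physical (`bp`) or genetic (`cm`) distance anchored at coordinate 0 of
#' each chromosome.
#'
#' @param mode one of `"markers"`, `"bp"`, `"cm"`.
#' @param size positive window size in the mode's unit; must be a whole
#'   number for `mode = "markers"`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(mode = c("bp", "markers", "cm"), size) {
  mode <- match.arg(mode)
  size <- as.numeric(size)
  if (length(size) != 1L || !is.finite(size) || size <= 0) {
    stop("window size must be a single positive number", call. = FALSE)
  }
  if (mode == "markers" && size != as.integer(size)) {
    stop("window size in markers mode must be a positive integer",
         call. = FALSE)
  }
  structure(list(mode = mode, size = size), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("Window: ", x$size, " ", x$mode, "\n", sep = "")
  invisible(x)
}

#' Partition markers into contiguous windows
#'
#' @param markers marker data frame (see [haplo_matrix()]); must be sorted by
#'   chromosome and position.
#' @param spec a [window_spec()].
#' @return List of integer vectors of column indices; windows never span two
#'   chromosomes, and empty tiles are dropped.
#' @export
make_windows <- function(markers, spec) {
  stopifnot(inherits(spec, "window_spec"))
  out <- list()
  for (ch in unique(markers$chrom)) {
    j <- which(markers$chrom == ch)
    if (spec$mode == "markers") {
      grp <- (seq_along(j) - 1L) %/% as.integer(spec$size)
    } else {
      pos <- if (spec$mode == "bp") markers$pos_bp[j] else markers$pos_cm[j]
      if (spec$mode == "cm" && anyNA(pos)) {
        stop("cm windows require pos_cm for every marker (chromosome ",
             ch, ")", call. = FALSE)
      }
      grp <- floor(pos / spec$size)
    }
    out <- c(out, unname(split(j, grp)))
  }
  out
}
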