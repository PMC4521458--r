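#' Replicated simulation study of haplotype-based assignment
#'
#' Runs the full evaluation loop on the three-population divergence model:
#' for each recombination rate and replicate, simulate a dataset, draw a
#' stratified 50/50 (by default) training/validation split, and measure the
#' validation MIA for each window size (window size 1 is the raw-genotype
#' baseline).  All seeds are derived deterministically from `seed`.
#'
#' @param rhos locus-wide recombination rates to simulate.
#' @param n_reps replicates per recombination rate.
#' @param window_sizes window sizes in bp (1 = genotype baseline).
#' @param fraction_training training fraction of each population.
#' @param seed master seed for simulation and splits.
#' @param model_args named list of overrides passed to [divergence_model()]
#'   (e.g. smaller `n_ind` for quick runs).
#' @param verbose print one line per replicate.
#' @return Data frame with columns `rho`, `rep`, `window_size`, `mia`,
#'   `mia_training`, `n_snps`, `n_loci`.
#' @export
simulation_study <- function(rhos = c(30, 60, 120, 240), n_reps = 10L,
                             window_sizes = c(1, 5e4, 2e5),
                             fraction_training = 0.5, seed = 1L,
                             model_args = list(), verbose = FALSE) {
  n_runs <- length(rhos) * n_reps
  seeds <- with_seed(seed, matrix(sample.int(2^31 - 1L, 2L * n_runs),
                                  nrow = 2L))
  out <- list()
  run <- 0L
  for (rho in rhos) {
    for (r in seq_len(n_reps)) {
      run <- run + 1L
      model <- do.call(divergence_model,
                       c(list(rho = rho, seed = seeds[1L, run]), model_args))
      x <- simulate_dataset(model)
      split <- make_split(x$labels, fraction_training, seeds[2L, run])
      for (ws in window_sizes) {
        res <- run_pipeline(x, split, window_spec("bp", ws))
        out[[length(out) + 1L]] <- data.frame(
          rho = rho, rep = r, window_size = ws, mia = res$report$mia,
          mia_training = res$report$mia_training,
          n_snps = ncol(x$alleles), n_loci = length(res$map$loci))
      }
      if (verbose) {
        last <- out[seq(length(out) - length(window_sizes) + 1L,
                        length(out))]
        message(sprintf("rho=%g rep=%d: %s", rho, r,
                        paste(sprintf("%g bp -> %.1f%%", window_sizes,
                                      vapply(last, function(d) d$mia, 0)),
                              collapse = ", ")))
      }
    }
  }
  do.call(rbind, out)
}

#' Relative error reduction against the genotype baseline
#'
#' Summarises a [simulation_study()] table: per recombination rate, the mean
#' validation MIA at each window size and the relative reduction (in %)
#' versus the window-size-1 genotype baseline.
#'
#' @param study a data frame from [simulation_study()]; must include window
#'   size 1.
#' @return Data frame with one row per (rho, window_size): `mean_mia` and
#'   `reduction_pct`.
#' @export
study_reductions <- function(study) {
  agg <- stats::aggregate(mia ~ rho + window_size, data = study, FUN = mean)
  base <- agg[agg$window_size == 1, c("rho", "mia")]
  names(base)[2L] <- "baseline_mia"
  agg <- merge(agg, base, by = "rho")
  agg$reduction_pct <- 100 * (agg$baseline_mia - agg$mia) / agg$baseline_mia
  names(agg)[names(agg) == "mia"] <- "mean_mia"
  agg[order(agg$rho, agg$window_size), ]
}
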