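#' Three-population divergence model
#'
#' Parameterisation of the coalescent simulation used to evaluate the
#' method: three populations of constant diploid effective size `Ne`;
#' populations 2 and 3 diverged `t1` coalescent time units (of `4 * Ne`
#' generations) ago, and their common ancestor diverged from population 1 at
#' `t2`.  Mutation and recombination are population-scaled rates for the
#' whole locus (`theta = 4 * Ne * mu_locus`, `rho = 4 * Ne * r_locus`).  The
#' defaults describe the reference evaluation scenario: a 200 kb locus with
#' `theta = 48` (per-bp mutation rate 6e-8, i.e. mu = 0.012 for the locus),
#' `Ne = 1000`, 100 diploid individuals per population, and splits at 0.025
#' and 0.05 (100 and 200 generations).
#'
#' @param rho locus-wide population-scaled recombination rate (the reference
#'   study used 30, 60, 120 and 240).
#' @param seed positive integer seed; the simulation is deterministic given
#'   the model.
#' @param n_ind diploid individuals sampled per population.
#' @param Ne diploid effective size of every population.
#' @param theta locus-wide population-scaled mutation rate.
#' @param seq_len_bp locus length in base pairs.
#' @param t1,t2 split times in coalescent units of `4 * Ne` generations,
#'   `0 < t1 <= t2`.
#' @return Object of class `divergence_model`.
#' @export
divergence_model <- function(rho = 60, seed = 1L, n_ind = 100L, Ne = 1000,
                             theta = 48, seq_len_bp = 200000L,
                             t1 = 0.025, t2 = 0.05) {
  stopifnot(rho >= 0, theta > 0, n_ind >= 1, Ne > 0, seq_len_bp >= 1)
  if (!(t1 > 0 && t1 <= t2)) {
    stop("split times must satisfy 0 < t1 <= t2", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 1L) {
    stop("seed must be a positive integer", call. = FALSE)
  }
  structure(list(n_pops = 3L, rho = rho, seed = seed, n_ind = as.integer(n_ind),
                 Ne = Ne, theta = theta, seq_len_bp = as.integer(seq_len_bp),
                 t1 = t1, t2 = t2), class = "divergence_model")
}

#' @export
print.divergence_model <- function(x, ...) {
  cat("3-population divergence model\n")
  cat(sprintf("  Ne = %g, %d diploids/population, locus %d bp\n",
              x$Ne, x$n_ind, x$seq_len_bp))
  cat(sprintf("  theta = %g, rho = %g (locus-wide, 4*Ne scaled)\n",
              x$theta, x$rho))
  cat(sprintf("  splits: (pop2,pop3) at t1 = %g, with pop1 at t2 = %g (4*Ne units)\n",
              x$t1, x$t2))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a phased dataset under the divergence model
#'
#' Runs a coalescent simulation (msprime, via the bundled Python helper)
#' under the given [divergence_model()] and returns a fully labelled
#' [haplo_matrix()] of biallelic SNPs (ancestral allele 0, derived 1) with
#' integer bp positions; continuous infinite-sites positions are floored and
#' collisions bumped to the next free integer so positions stay strictly
#' increasing.  Populations are labelled `pop1`, `pop2`, `pop3`.
#'
#' @param model a [divergence_model()].
#' @param python name or path of the Python interpreter with msprime
#'   available (default: `HAPLOPOP_PYTHON` environment variable, or
#'   `"python"`).
#' @return A labelled [haplo_matrix()].
#' @export
simulate_dataset <- function(model,
                             python = Sys.getenv("HAPLOPOP_PYTHON", "python")) {
  stopifnot(inherits(model, "divergence_model"))
  script <- system.file("python", "simulate_divergence.py",
                        package = "haplopop", mustWork = TRUE)
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out))
  args <- c(script,
            "--ne", format(model$Ne, digits = 15),
            "--n-ind", model$n_ind,
            "--seq-len", model$seq_len_bp,
            "--theta", format(model$theta, digits = 15),
            "--rho", format(model$rho, digits = 15),
            "--t1", format(model$t1, digits = 15),
            "--t2", format(model$t2, digits = 15),
            "--seed", model$seed,
            "--out", out)
  err <- tempfile()
  status <- system2(python, args, stdout = FALSE, stderr = err)
  if (status != 0L) {
    msg <- paste(readLines(err, warn = FALSE), collapse = "\n")
    if (grepl("no segregating sites", msg)) {
      stop("the simulation produced no segregating sites; ",
           "re-run with a different seed or a larger theta", call. = FALSE)
    }
    stop("coalescent simulation failed (exit ", status, "):\n", msg,
         call. = FALSE)
  }
  parse_sim_output(out)
}

parse_sim_output <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1L], "#POS"), startsWith(lines[2L], "#POP"))
  pos <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L])
  pop <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][-1L]
  a <- matrix(as.integer(unlist(strsplit(lines[-(1:2)], "\t", fixed = TRUE))),
              nrow = length(lines) - 2L, byrow = TRUE)
  n <- length(pop)
  stopifnot(nrow(a) == 2L * n)
  # per-population running index: pop1_001, pop1_002, ...
  idx <- stats::ave(seq_along(pop), pop, FUN = seq_along)
  individuals <- sprintf("%s_%03d", pop, idx)
  markers <- data.frame(
    id = sprintf("s%05d", seq_along(pos)), chrom = "chr1", pos_bp = pos,
    pos_cm = NA_real_, n_alleles = 2L, stringsAsFactors = FALSE)
  haplo_matrix(a, markers, individuals,
               labels = stats::setNames(pop, individuals))
}
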