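# A dataset where each marker is individually uninformative but the phase
# distinguishes the populations: pop1 chromosomes are 00/11, pop2 are 01/10.
phase_only_matrix <- function(n_per_pop = 4L) {
  rows <- c(rep(list(c(0L, 0L), c(1L, 1L)), n_per_pop / 2L),
            rep(list(c(0L, 1L), c(1L, 0L)), n_per_pop / 2L))
  toy_matrix(rows, rep(c("pop1", "pop2"), each = n_per_pop / 2L))
}

test_that("duplicated informative markers are never merged", {
  # two perfectly correlated copies: GIA = -IA < 0
  x <- toy_matrix(list(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L)),
                  c("pop1", "pop2"))
  map <- haplopop(x, window = window_spec("markers", 2))
  expect_equal(length(map$loci), 2L)
  expect_equal(map$n_merges, 0L)
  expect_equal(unname(map$objective["haplotype"]),
               unname(map$objective["genotype"]))
})

test_that("phase-only signal is discovered by merging", {
  x <- phase_only_matrix()
  m1 <- freq_table(x, 1L)
  m2 <- freq_table(x, 2L)
  expect_equal(ia(m1), 0)
  expect_equal(ia(m2), 0)
  map <- haplopop(x, window = window_spec("markers", 2))
  expect_equal(length(map$loci), 1L)
  expect_equal(sort(map$loci[[1L]]$members), c(1L, 2L))
  expect_equal(unname(map$objective["genotype"]), 0)
  expect_equal(unname(map$objective["haplotype"]), log(2))
})

test_that("single-marker windows are left untouched", {
  x <- phase_only_matrix()
  map <- haplopop(x, window = window_spec("markers", 1))
  expect_equal(length(map$loci), 2L)
  expect_equal(map$n_merges, 0L)
})

test_that("a merge reaching one allele per chromosome warns but proceeds", {
  # 2 individuals/pop; merged locus has 4 alleles = 2n chromosomes
  x <- toy_matrix(list(c(0L, 0L), c(1L, 1L), c(0L, 1L), c(1L, 0L)),
                  c("pop1", "pop2"))
  expect_warning(
    map <- haplopop(x, window = window_spec("markers", 2)),
    "one allele per training chromosome")
  expect_equal(length(map$loci), 1L)
  expect_equal(map$loci[[1L]]$n_alleles, 4L)
})

test_that("max_alleles vetoes merges instead of warning", {
  x <- toy_matrix(list(c(0L, 0L), c(1L, 1L), c(0L, 1L), c(1L, 0L)),
                  c("pop1", "pop2"))
  expect_no_warning(
    map <- haplopop(x, window = window_spec("markers", 2), max_alleles = 3))
  expect_equal(length(map$loci), 2L)
  expect_equal(map$n_merges, 0L)
})

test_that("gia_threshold blocks merges with smaller gains", {
  x <- phase_only_matrix()  # merge gain is exactly log 2
  map <- haplopop(x, window = window_spec("markers", 2),
                  gia_threshold = log(2) + 0.01)
  expect_equal(map$n_merges, 0L)
  map <- haplopop(x, window = window_spec("markers", 2),
                  gia_threshold = log(2) - 0.01)
  expect_equal(map$n_merges, 1L)
})

test_that("learning requires labels and rejects unlabeled training ids", {
  x <- phase_only_matrix()
  expect_error(haplopop(x, training = c(x$individuals, "ghost")))
  x$labels <- x$labels[-1L]
  expect_error(haplopop(x, training = x$individuals), "no population label")
})

test_that("the objective never decreases and loci always partition markers", {
  for (i in 1:25) {
    x <- random_haplo_matrix(n_ind = 8L, l = sample(3:7, 1L),
                             K = sample(2:3, 1L), seed = 700 + i)
    thr <- sample(c(0, 0.01), 1L)
    map <- haplopop(x, window = window_spec("markers", sample(2:7, 1L)),
                    gia_threshold = thr)
    members <- sort(unlist(lapply(map$loci, `[[`, "members")))
    expect_equal(members, seq_len(ncol(x$alleles)))
    expect_gte(map$objective["haplotype"] + 1e-12, map$objective["genotype"])
    if (map$n_merges > 0L) {
      expect_gt(map$objective["haplotype"],
                map$objective["genotype"] + thr * map$n_merges - 1e-9)
    }
  }
})

test_that("loci never span window boundaries", {
  x <- random_haplo_matrix(n_ind = 10L, l = 8L, K = 2L, seed = 42)
  map <- haplopop(x, window = window_spec("markers", 3))
  wins <- make_windows(x$markers, window_spec("markers", 3))
  win_of <- rep(seq_along(wins), lengths(wins))[order(unlist(wins))]
  for (lc in map$loci) {
    expect_equal(length(unique(win_of[lc$members])), 1L)
  }
})

test_that("learning is deterministic: identical inputs, identical coding files", {
  x <- random_haplo_matrix(n_ind = 10L, l = 8L, K = 3L, seed = 77)
  f1 <- tempfile(); f2 <- tempfile()
  write_haplomap(haplopop(x, window = window_spec("markers", 4)), f1)
  write_haplomap(haplopop(x, window = window_spec("markers", 4)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("exhaustive enumeration handles the trivial windows", {
  x <- phase_only_matrix()
  one <- exhaustive_best_partition(x, window = 1L)
  expect_equal(one$partition, list(1L))
  expect_equal(one$score, 0)
  # 2 markers: combined beats separate exactly when GIA > 0
  two <- exhaustive_best_partition(x, window = c(1L, 2L))
  expect_equal(two$partition, list(c(1L, 2L)))
  expect_equal(two$score, log(2))
  expect_error(exhaustive_best_partition(x, window = rep(1L, 9L)), "8")
})

test_that("greedy never beats the exhaustive partition and often matches it", {
  agree <- 0L
  n <- 30L
  for (i in seq_len(n)) {
    x <- random_haplo_matrix(n_ind = 8L, l = 5L, K = 2L, seed = 900 + i)
    map <- haplopop(x, window = window_spec("markers", 5))
    greedy_score <- unname(map$objective["haplotype"])
    best <- exhaustive_best_partition(x, window = 1:5)
    expect_gte(best$score + 1e-9, greedy_score)
    canon <- function(p) sort(vapply(p, function(b)
      paste(sort(b), collapse = ","), ""))
    same_part <- identical(
      canon(best$partition),
      canon(lapply(map$loci, `[[`, "members")))
    if (same_part || abs(best$score - greedy_score) < 1e-9) {
      agree <- agree + 1L
    }
  }
  expect_gt(agree / n, 0.5)
})

test_that("linkage-equilibrium windows stop merging above the bias scale", {
  # Plug-in GIA estimates carry a positive finite-sample bias of order
  # (N1-1)(N2-1)/n, so unlinked markers can be merged at threshold 0; a
  # small positive threshold above that scale leaves them alone.
  le_matrix <- function(seed, n = 150L, l = 4L) {
    set.seed(seed)
    pops <- rep(c("pop1", "pop2"), length.out = n)
    a <- matrix(0L, 2L * n, l)
    for (j in seq_len(l)) {
      for (k in 1:2) {
        p <- stats::runif(1, 0.2, 0.8)
        rows <- which(rep(pops, each = 2L) == paste0("pop", k))
        a[rows, j] <- stats::rbinom(length(rows), 1L, p)
      }
    }
    inds <- sprintf("i%03d", seq_len(n))
    haplo_matrix(a, data.frame(id = paste0("m", seq_len(l)), chrom = "chr1",
                               pos_bp = seq_len(l) * 100L, pos_cm = NA_real_,
                               n_alleles = 2L), inds, setNames(pops, inds))
  }
  merges <- vapply(1:15, function(i) {
    haplopop(le_matrix(1700 + i), window = window_spec("markers", 4),
             gia_threshold = 0.02)$n_merges
  }, 0L)
  expect_lte(mean(merges), 0.2)
})
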