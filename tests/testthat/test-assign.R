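make_labels <- function(sizes) {
  pops <- rep(names(sizes), sizes)
  setNames(pops, sprintf("%s_%03d", pops, unlist(lapply(sizes, seq_len))))
}

test_that("splits are stratified with round-half-up training counts", {
  lab <- make_labels(c(pop1 = 100L, pop2 = 100L, pop3 = 100L))
  s <- make_split(lab, 0.5, seed = 1)
  expect_equal(s$counts$training, rep(50L, 3L))
  expect_equal(s$counts$validation, rep(50L, 3L))

  # 133 and 125 at fraction 0.5 -> 67/66 and 63/62
  lab2 <- make_labels(c(spain = 133L, portugal = 125L))
  s2 <- make_split(lab2, 0.5, seed = 1)
  expect_equal(s2$counts$training[s2$counts$population == "spain"], 67L)
  expect_equal(s2$counts$validation[s2$counts$population == "spain"], 66L)
  expect_equal(s2$counts$training[s2$counts$population == "portugal"], 63L)
  expect_equal(s2$counts$validation[s2$counts$population == "portugal"], 62L)
})

test_that("splits are deterministic and disjoint, and tiny pops error", {
  lab <- make_labels(c(pop1 = 9L, pop2 = 7L))
  s1 <- make_split(lab, 0.3, seed = 42)
  s2 <- make_split(lab, 0.3, seed = 42)
  expect_identical(s1, s2)
  expect_length(intersect(s1$training, s1$validation), 0L)
  expect_setequal(c(s1$training, s1$validation), names(lab))
  s3 <- make_split(lab, 0.3, seed = 43)
  expect_false(identical(s1$training, s3$training))

  expect_error(make_split(make_labels(c(pop1 = 1L, pop2 = 5L)), 0.5, 1),
               "fewer than 2")
  expect_error(make_split(lab, 0, 1), "fraction")
  # at least one training individual even at tiny fractions
  s4 <- make_split(lab, 0.01, seed = 1)
  expect_equal(s4$counts$training, c(1L, 1L))
})

test_that("perfectly separated clusters are assigned without error", {
  rows <- c(rep(list(0L), 8L), rep(list(1L), 8L))
  x <- toy_matrix(rows, rep(c("pop1", "pop2"), each = 4L))
  split <- make_split(x$labels, 0.5, seed = 1)
  rep <- pca_assign(onehot(x), split)
  expect_equal(rep$mia, 0)
  expect_equal(rep$mia_training, 0)
  expect_equal(unname(rep$mia_by_pop), c(0, 0))
})

test_that("mia lies in [0, 100] and predictions use known populations", {
  x <- random_haplo_matrix(n_ind = 20L, l = 10L, K = 3L, seed = 8)
  split <- make_split(x$labels, 0.5, seed = 2)
  rep <- pca_assign(onehot(x), split)
  expect_gte(rep$mia, 0)
  expect_lte(rep$mia, 100)
  expect_true(all(rep$predicted %in% c("pop1", "pop2", "pop3")))
  expect_equal(rep$n_pcs, 2L)
})

test_that("requesting more components than available errors", {
  x <- toy_matrix(list(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
                  rep(c("pop1", "pop2"), 2L))
  split <- make_split(x$labels, 0.5, seed = 1)
  expect_error(pca_assign(onehot(x), split, n_pcs = 10L), "components")
})

test_that("assignment is invariant to duplicating every column", {
  x <- cached_sim(60, 901, n_ind = 20L, theta = 12, seq_len_bp = 50000L)
  split <- make_split(x$labels, 0.5, seed = 3)
  enc <- onehot(x)
  dup <- enc
  dup$X <- cbind(enc$X, enc$X)
  dup$meta <- rbind(enc$meta, enc$meta)
  r1 <- pca_assign(enc, split)
  r2 <- pca_assign(dup, split)
  expect_identical(r1$predicted, r2$predicted)
})

test_that("assignment is invariant to individual order and code relabelling", {
  x <- random_haplo_matrix(n_ind = 16L, l = 8L, K = 2L, n_alleles = 3L,
                           seed = 31)
  split <- make_split(x$labels, 0.5, seed = 4)
  suppressWarnings(map <- haplopop(x, training = split$training,
                                   window = window_spec("markers", 4)))
  rec <- apply_map(x, map)
  r1 <- pca_assign(onehot(rec), split)

  # permute individuals (keeping chromosome pairs together)
  set.seed(9)
  perm <- sample(length(x$individuals))
  y <- rec
  y$individuals <- rec$individuals[perm]
  y$alleles <- rec$alleles[haplopop:::chromosome_rows(perm), , drop = FALSE]
  r2 <- pca_assign(onehot(y), split)
  expect_identical(r1$predicted[names(r2$predicted)], r2$predicted)

  # globally permute haplotype-allele codes within each locus
  z <- rec
  set.seed(10)
  for (k in seq_along(z$loci)) {
    n <- z$loci[[k]]$n_alleles
    p <- sample(n) - 1L
    z$alleles[, k] <- p[z$alleles[, k] + 1L]
  }
  r3 <- pca_assign(onehot(z), split)
  expect_identical(r1$predicted, r3$predicted)
})

test_that("a window of size 1 reproduces the raw genotype baseline", {
  x <- cached_sim(60, 901, n_ind = 20L, theta = 12, seq_len_bp = 50000L)
  curve <- mia_curve(x, window_sizes = c(1, 50000), mode = "bp", seed = 5)
  split <- make_split(x$labels, 0.5, seed = 5)
  base <- pca_assign(onehot(x), split)
  expect_equal(curve$mia[1L], base$mia)
  expect_equal(curve$n_loci[1L], ncol(x$alleles))
  # same seed, same curve
  curve2 <- mia_curve(x, window_sizes = c(1, 50000), mode = "bp", seed = 5)
  expect_identical(curve, curve2)
})
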