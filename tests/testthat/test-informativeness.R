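test_that("freq_table counts training chromosomes per population", {
  # pop1 chromosomes {0,0}, pop2 {1,1}
  x <- toy_matrix(list(c(0L), c(0L), c(1L), c(1L)), c("pop1", "pop2"))
  ft <- freq_table(x, 1L)
  expect_equal(unname(ft$freqs), rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(ft$mean_freqs), c(0.5, 0.5))

  x <- toy_matrix(list(c(0L), c(1L), c(0L), c(1L)), c("pop1", "pop2"))
  expect_equal(unname(freq_table(x, 1L)$freqs),
               rbind(c(.5, .5), c(.5, .5)))

  # unequal sample sizes: pop1 {0,0,0,1}, pop2 {1,1}; the mean frequency is
  # the unweighted average of the population frequencies, not pooled
  x <- toy_matrix(list(0L, 0L, 0L, 1L, 1L, 1L),
                  c("pop1", "pop1", "pop2"))
  ft <- freq_table(x, 1L)
  expect_equal(unname(ft$freqs), rbind(c(0.75, 0.25), c(0, 1)))
  expect_equal(unname(ft$mean_freqs), c(0.375, 0.625))
})

test_that("freq_table rejects a population without training chromosomes", {
  x <- toy_matrix(list(0L, 0L, 1L, 1L), c("pop1", "pop2"))
  expect_error(freq_table(x, 1L, training = "ind01"),
               "no training chromosomes")
})

test_that("ia matches hand-evaluated values", {
  expect_equal(ia(rbind(c(.5, .5), c(.5, .5))), 0)
  expect_equal(ia(rbind(c(1, 0), c(0, 1))), log(2))
  # fixed markers in 3 populations reach the upper bound log K
  expect_equal(ia(diag(3)), log(3))
})

test_that("ia equals the mutual-information oracle to 1e-12", {
  set.seed(42)
  for (i in 1:200) {
    K <- sample(2:5, 1L)
    N <- sample(1:6, 1L)
    f <- matrix(stats::rgamma(K * N, 0.5), K, N)
    # sprinkle structural zeros to exercise the 0*log(0) convention
    f[stats::runif(K * N) < 0.2] <- 0
    f[rowSums(f) == 0, 1L] <- 1
    f <- f / rowSums(f)
    expect_equal(ia(f), ia_mi_oracle(f), tolerance = 1e-12)
  }
  expect_equal(ia(rbind(c(0.75, 0.25), c(0, 1))),
               ia_mi_oracle(rbind(c(0.75, 0.25), c(0, 1))),
               tolerance = 1e-12)
})

test_that("ia is bounded by [0, log K] and vanishes iff rows are equal", {
  set.seed(7)
  for (i in 1:200) {
    K <- sample(2:4, 1L)
    N <- sample(1:5, 1L)
    f <- matrix(stats::rgamma(K * N, 1), K, N)
    f <- f / rowSums(f)
    v <- ia(f)
    expect_gte(v, 0)
    expect_lte(v, log(K) + 1e-12)
  }
  # identical rows => exactly 0
  f <- matrix(rep(c(.2, .3, .5), each = 3), 3, 3)
  expect_equal(ia(f), 0)
  # non-identical rows => strictly positive
  expect_gt(ia(rbind(c(.6, .4), c(.4, .6))), 0)
})

test_that("combining markers never loses information (data processing)", {
  set.seed(11)
  for (i in 1:40) {
    x <- random_haplo_matrix(n_ind = 12L, l = 2L, K = sample(2:3, 1L),
                             seed = 100 + i)
    lab <- x$labels
    pops <- rep(lab[x$individuals], each = 2L)
    m1 <- freq_table(x, 1L)
    m2 <- freq_table(x, 2L)
    h <- haplopop:::freq_from_codes(
      haplopop:::locus_codes(x$alleles, c(1L, 2L)), pops)
    expect_gte(ia(h) + 1e-12, max(ia(m1), ia(m2)))
  }
})

test_that("gia of perfectly correlated markers equals minus their IA", {
  # every chromosome carries allele pair (a, a)
  x <- toy_matrix(list(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L)),
                  c("pop1", "pop2"))
  pops <- rep(c("pop1", "pop2"), each = 2L)
  m1 <- freq_table(x, 1L)
  m2 <- freq_table(x, 2L)
  h <- haplopop:::freq_from_codes(
    haplopop:::locus_codes(x$alleles, c(1L, 2L)), pops)
  expect_equal(gia(h, m1, m2), -ia(m1))
  expect_equal(gia(h, m1, m2), -log(2))
})

test_that("gia with a monomorphic partner is zero", {
  x <- toy_matrix(list(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(1L, 0L)),
                  c("pop1", "pop2"))
  pops <- rep(c("pop1", "pop2"), each = 2L)
  m1 <- freq_table(x, 1L)
  m2 <- freq_table(x, 2L)
  h <- haplopop:::freq_from_codes(
    haplopop:::locus_codes(x$alleles, c(1L, 2L)), pops)
  expect_equal(ia(m2), 0)
  expect_equal(gia(h, m1, m2), 0)
})

test_that("gia is non-positive under within-population linkage equilibrium", {
  set.seed(13)
  for (i in 1:1000) {
    K <- sample(2:3, 1L)
    n1 <- sample(2:4, 1L)
    n2 <- sample(2:4, 1L)
    f1 <- matrix(stats::rgamma(K * n1, 1), K, n1)
    f1 <- f1 / rowSums(f1)
    f2 <- matrix(stats::rgamma(K * n2, 1), K, n2)
    f2 <- f2 / rowSums(f2)
    # haplotype frequencies factorise within every population
    fh <- t(vapply(seq_len(K), function(k) as.vector(outer(f1[k, ], f2[k, ])),
                   numeric(n1 * n2)))
    expect_lte(gia(fh, f1, f2), 1e-12)
  }
})

test_that("compiled IA kernel agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:50) {
    x <- random_haplo_matrix(n_ind = 8L, l = 1L, K = 3L,
                             n_alleles = sample(2:4, 1L), seed = 300 + i)
    pops <- rep(x$labels[x$individuals], each = 2L)
    codes <- x$alleles[, 1L]
    pop0 <- as.integer(factor(pops)) - 1L
    popn <- as.integer(table(factor(pops)))
    expect_equal(
      haplopop:::cpp_ia_codes(codes, pop0, 3L, popn),
      ia(haplopop:::freq_from_codes(codes, pops)),
      tolerance = 1e-12)
  }
})
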