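test_that("Gabor atoms are unit-norm, Gaussian where expected, degenerate genes rejected", {
  N <- 32L
  g <- gabor_gene(2, 3, 5, 7, N)
  a <- gabor_atom(g, N)
  expect_equal(sum(a^2), 1, tolerance = 1e-12)

  # k = 0, i = 0, mu = N/2: a pure Gaussian bump symmetric about t = N/2
  bump <- gabor_atom(c(1, 16, 0, 0), N)
  expect_true(all(bump > 0))
  expect_equal(which.max(bump), 17L)  # t = 16, 1-based index 17
  expect_lt(max(abs(bump[17 + (1:15)] - bump[17 - (1:15)])) / max(bump), 1e-9)

  # v = 0 with omega = pi/2: cos term is identically zero
  expect_error(gabor_atom(c(1, 4, 0, 3), N), "degenerate")
  expect_error(gabor_gene(9, 0, 0, 0, N), "out of range")
  expect_error(gabor_gene(1, 0, 0, 13, N), "out of range")
})

test_that("exhaustive selection equals an independently written brute-force loop", {
  N <- 32L
  # residual that IS a dictionary atom: recovered with inner product 1
  target <- gabor_atom(c(3, 2, 4, 2), N)
  sel <- select_atom_exhaustive(target, N)
  expect_equal(sel$fitness, 1, tolerance = 1e-9)
  expect_equal(abs(sum(target * gabor_atom(sel$gene, N))), 1, tolerance = 1e-9)

  # zero residual: defined to return the lexicographically first gene
  z <- select_atom_exhaustive(numeric(N), N)
  expect_equal(z$fitness, 0)
  expect_equal(z$index, 1L)

  set.seed(21)
  for (rep in 1:3) {
    r <- stats::rnorm(N)
    sel <- select_atom_exhaustive(r, N)
    oracle <- brute_force_best(r, N)
    expect_equal(sel$fitness, oracle$fitness, tolerance = 1e-9)
    expect_equal(unname(sel$gene), unname(oracle$gene))
  }
})

test_that("GA selection is seeded and near-exhaustive on planted atoms", {
  N <- 32L
  target <- gabor_atom(c(4, 1, 3, 5), N)
  g1 <- select_atom_ga(target, N, ga_config(seed = 2))
  g2 <- select_atom_ga(target, N, ga_config(seed = 2))
  expect_identical(g1$gene, g2$gene)

  # near-exact recovery: median over search seeds hits the planted atom
  fits <- vapply(1:10, function(s) {
    select_atom_ga(target, N, ga_config(seed = s))$fitness
  }, numeric(1))
  expect_gte(stats::median(fits), 0.99)
  expect_gte(min(fits), 0.9)
})

test_that("OMP recovers planted atoms, splits energy and is monotone", {
  N <- 32L
  atom <- gabor_atom(c(3, 2, 4, 2), N)
  ap <- omp_decompose(atom, 1, selector = "exhaustive")
  expect_lt(sqrt(sum(ap$residual^2)), 1e-6)

  genes <- list(c(1, 4, 1, 0), c(1, 20, 2, 0), c(4, 0, 9, 4))
  f3 <- 1.0 * gabor_atom(genes[[1]], N) + 0.7 * gabor_atom(genes[[2]], N) +
        0.5 * gabor_atom(genes[[3]], N)
  ap3 <- omp_decompose(f3, 3, selector = "exhaustive")
  expect_lt(sqrt(sum(ap3$residual^2)), 1e-4)
  expect_equal(ap3$approx + ap3$residual, f3, tolerance = 1e-9)

  # energy split by orthogonality of residual and approximant
  set.seed(33)
  f <- stats::rnorm(N)
  ap10 <- omp_decompose(f, 10, selector = "exhaustive")
  expect_equal(sum(f^2), sum(ap10$approx^2) + sum(ap10$residual^2),
               tolerance = 1e-6)

  # residual norm non-increasing in the atom budget
  norms <- vapply(1:10, function(M) {
    sqrt(sum(omp_decompose(f, M, selector = "exhaustive")$residual^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))

  # zero frame: empty approximation
  ap0 <- omp_decompose(numeric(N), 5, selector = "exhaustive")
  expect_equal(nrow(ap0$genes), 0L)
  expect_true(all(ap0$approx == 0))
})

test_that("sparse denoising preserves silence and improves a noisy tone burst", {
  expect_true(all(denoise_sparse(numeric(1024), 10L, N = 256L) == 0))

  # clean tone burst + white noise at 0 dB, small frames for speed
  set.seed(44)
  n <- 2048
  clean <- numeric(n)
  clean[513:1536] <- sin(2 * pi * 0.05 * (0:1023)) *
    sin(pi * (0:1023) / 1023)
  d <- stats::rnorm(n)
  d <- d * sqrt(sum(clean^2) / sum(d^2))
  noisy <- clean + d
  y <- denoise_sparse(noisy, 20L, N = 256L, cfg = ga_config(seed = 5))
  expect_gt(snr_db(clean, y), snr_db(clean, noisy))
})
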