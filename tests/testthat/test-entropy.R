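test_that("Shannon entropy: certainty, uniform, and frozen high-precision value", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(c(0.1, 0.2, 0.3, 0.4)), 1.2798542258336676,
               tolerance = 1e-15)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.3, 0.3)), "sum to 1")
})

test_that("Shannon entropy is bounded by log of support size, equality at uniform", {
  for (seed in 1:25) {
    p <- rand_probs(seed, n = sample(2:64, 1))
    expect_lte(shannon_entropy(p), log(length(p)) + 1e-12)
  }
  expect_equal(shannon_entropy(rep(1 / 32, 32)), log(32))
})

test_that("Tsallis entropy: closed forms and Shannon limit", {
  expect_equal(tsallis_entropy(c(0.5, 0.5), 2), 0.5)
  expect_equal(tsallis_entropy(c(0.25, 0.75), 0.5), 0.73205080756887719,
               tolerance = 1e-15)
  for (seed in 1:10) {
    p <- rand_probs(seed)
    expect_lt(abs(tsallis_entropy(p, 1 + 1e-6) - shannon_entropy(p)), 1e-5)
    expect_lt(abs(tsallis_entropy(p, 1 - 1e-6) - shannon_entropy(p)), 1e-5)
  }
})

test_that("Tsallis pseudo-additivity holds on product distributions", {
  for (seed in 1:100) {
    set.seed(seed)
    p <- rand_probs(seed, n = sample(2:6, 1))
    s <- rand_probs(seed + 1000L, n = sample(2:6, 1))
    q <- stats::runif(1, 0.1, 2.5)
    if (abs(q - 1) < 1e-3) q <- 0.5
    prod_dist <- as.vector(outer(p, s))
    lhs <- tsallis_entropy(prod_dist, q)
    sp <- tsallis_entropy(p, q); ss <- tsallis_entropy(s, q)
    rhs <- sp + ss + (1 - q) * sp * ss
    expect_lt(abs(lhs - rhs), 1e-10)
  }
})

test_that("Masi entropy: frozen value, Shannon limit, and validity domain", {
  expect_equal(masi_entropy(c(0.5, 0.5), 2), -log(1 - log(2)), tolerance = 1e-15)
  for (seed in 1:10) {
    p <- rand_probs(seed)
    expect_lt(abs(masi_entropy(p, 1 + 1e-6) - shannon_entropy(p)), 1e-5)
    expect_lt(abs(masi_entropy(p, 1 - 1e-6) - shannon_entropy(p)), 1e-5)
  }
  # uniform over 16 levels at r = 2: log argument 1 - log(16) < 0 -> invalid
  expect_true(is.na(masi_entropy(rep(1 / 16, 16), 2)))
  expect_error(masi_entropy(c(0.5, 0.5), -1), "positive")
})

test_that("Masi invalidity is monotone in r above 1", {
  for (seed in 1:20) {
    p <- rand_probs(seed, n = 32L)
    rs <- seq(1.05, 3, by = 0.05)
    ok <- !is.na(vapply(rs, function(r) masi_entropy(p, r), numeric(1)))
    # once invalid, invalid for all larger r
    expect_true(all(diff(as.integer(ok)) <= 0L))
  }
})

test_that("combined two-class objectives compose the class entropies", {
  # both classes certain -> objective 0 for every family
  h2 <- gray_histogram(matrix(c(0L, 1L), 1, 2), L = 1L)
  s <- split_classes(h2, 0L)
  expect_equal(combined_shannon(s), 0)
  expect_equal(combined_tsallis(s, 0.7), 0)
  expect_equal(combined_masi(s, 1.4), 0)

  # uniform over 4 levels, t = 1 -> 2 log 2
  h4 <- gray_histogram(matrix(0:3, 1, 4), L = 3L)
  expect_equal(combined_shannon(split_classes(h4, 1L)), 2 * log(2))

  # frozen composition value for probs [0.1, 0.2, 0.3, 0.4], t = 1
  img <- matrix(rep.int(0:3, c(1L, 2L, 3L, 4L)), 1)
  s <- split_classes(gray_histogram(img, L = 3L), 1L)
  expect_equal(combined_shannon(s), 1.3194222729952845, tolerance = 1e-15)

  # Tsallis composition matches independent recomputation on a random split
  h8 <- rand_hist(3, L = 7L)
  s8 <- split_classes(h8, 3L)
  expect_equal(combined_tsallis(s8, 0.8), oracle_tsallis_obj(0.8)(s8))

  # q -> 1 and r -> 1 recover the Shannon objective
  expect_lt(abs(combined_tsallis(s8, 1 + 1e-6) - combined_shannon(s8)), 1e-5)
  expect_lt(abs(combined_masi(s8, 1 + 1e-6) - combined_shannon(s8)), 1e-5)

  # high r invalidates at least one class on a near-uniform 256-level histogram
  set.seed(99)
  img <- matrix(sample(0:255, 4096, replace = TRUE), 64, 64)
  s256 <- split_classes(gray_histogram(img), 128L)
  expect_true(is.na(combined_masi(s256, 1.7)))
})
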