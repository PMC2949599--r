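test_that("spacing pdf and cdf match the Beta closed forms", {
  # direct evaluation of (N-1) C(N-2, i) x^i (1-x)^(N-2-i)
  closed_pdf <- function(N, i, x) (N - 1) * choose(N - 2, i) * x^i * (1 - x)^(N - 2 - i)
  xs <- seq(0, 1, by = 0.05)
  for (N in c(2, 3, 4, 7, 11, 23, 50)) {
    for (i in unique(pmin(c(0, 1, 2, N %/% 2, N - 2), N - 2))) {
      if (i < 0) next
      law <- spacing_law(N, i)
      expect_equal(spacing_pdf(law, xs), closed_pdf(N, i, xs), tolerance = 1e-8)
      # cdf against numeric integration of the pdf
      for (x in c(0.2, 0.5, 0.9)) {
        num <- stats::integrate(function(u) spacing_pdf(law, u), 0, x,
                                rel.tol = 1e-10)$value
        expect_equal(spacing_cdf(law, x), num, tolerance = 1e-8)
      }
    }
  }
  expect_equal(spacing_pdf(spacing_law(3, 0), 0.5), 1.0)
  expect_equal(spacing_pdf(spacing_law(4, 1), 0.5), 1.5)
})

test_that("spacing pdf integrates to one and the cdf is a proper repartition", {
  for (N in c(2, 5, 12, 30)) for (i in c(0, min(3, N - 2), N - 2)) {
    law <- spacing_law(N, i)
    expect_equal(stats::integrate(function(u) spacing_pdf(law, u), 0, 1,
                                  rel.tol = 1e-11)$value, 1, tolerance = 1e-9)
    expect_identical(spacing_cdf(law, 0), 0)
    expect_identical(spacing_cdf(law, 1), 1)
    xs <- seq(0, 1, by = 0.01)
    expect_true(all(diff(spacing_cdf(law, xs)) >= 0))
  }
  # i = 0 closed form: F(x) = 1 - (1 - x)^(N-1)
  expect_equal(spacing_cdf(spacing_law(3, 0), 0.5), 0.75)
})

test_that("law parameters are validated with informative bounds", {
  expect_error(spacing_law(1, 0), "N must be")
  expect_error(spacing_law(5, -1), "i must be")
  expect_error(spacing_law(5, 4), "i <= N - 2")
  expect_error(spacing_pdf(spacing_law(5, 2), 1.5), "\\[0, 1\\]")
  expect_error(pair_pvalue(3, 6, 0.5), "2j - 1 <= N - 2")
  expect_error(pair_less_pvalue(0.5, 0, 10), "g must be")
  expect_error(pair_less_pvalue(0.5, 10, 10), "g must be")
})

test_that("simulated circular spacings follow the stated law (index convention)", {
  # N uniform sites on the circle; the arc spanning g = i + 1 gaps (i
  # intermediate sites) must follow Beta(i + 1, N - 1 - i).
  # the reference site must be drawn uniformly: anchoring at the smallest
  # angle size-biases the arc containing the origin
  N <- 11
  set.seed(421)
  draws <- replicate(10000, {
    th <- sort(stats::runif(N))
    s <- sample.int(N, 1)
    (th[((s + 2) %% N) + 1] - th[((s - 1) %% N) + 1]) %% 1  # spans 3 gaps
  })
  law <- spacing_law(N, 2)
  ks <- stats::ks.test(draws, function(x) spacing_cdf(law, x))
  expect_gt(ks$p.value, 0.01)
})

test_that("pair p-values are two-sided, bounded by one half, and tail-symmetric", {
  qs <- c(0.001, 0.05, 0.2, 0.4)
  for (N in c(10, 20)) for (j in c(1, 2, 3)) {
    law_i <- 2 * j - 1
    x <- seq(0, 1, by = 0.01)
    p <- pair_pvalue(j, N, x)
    expect_true(all(p <= 0.5 + 1e-12))
    # p at quantile q equals p at quantile 1 - q
    xq <- stats::qbeta(qs, law_i + 1, N - 1 - law_i)
    xq2 <- stats::qbeta(1 - qs, law_i + 1, N - 1 - law_i)
    expect_equal(pair_pvalue(j, N, xq), pair_pvalue(j, N, xq2),
                 tolerance = 1e-10)
    # maximal (0.5) at the median
    med <- stats::qbeta(0.5, law_i + 1, N - 1 - law_i)
    expect_equal(pair_pvalue(j, N, med), 0.5, tolerance = 1e-12)
  }
  # dense-limit tail hits the configurable floor
  expect_identical(pair_pvalue(1, 20, 0), 1e-300)
  expect_identical(pair_pvalue(1, 20, 0, eps = 1e-10), 1e-10)
})

test_that("pair p-value matches the empirical two-sided tail frequency", {
  N <- 20
  set.seed(99)
  spac <- replicate(1e5, {
    th <- sort(stats::runif(N))
    s <- sample.int(N, 1)         # uniform reference site on the circle
    (th[((s + 1) %% N) + 1] - th[((s - 1) %% N) + 1]) %% 1  # j = 1 arc
  })
  for (x in c(0.03, 0.08, 0.25)) {
    Fhat <- mean(spac <= x)
    phat <- min(Fhat, 1 - Fhat)
    se <- sqrt(phat * (1 - phat) / length(spac))
    expect_lt(abs(pair_pvalue(1, N, x) - phat), 3 * se + 1e-12)
  }
})

test_that("lower-tail pair probability matches a sampling oracle", {
  expect_identical(pair_less_pvalue(0, 3, 12), 1e-300)
  expect_equal(pair_less_pvalue(1, 3, 12), 1)
  N <- 11; g <- 2
  set.seed(7)
  spac <- replicate(1e5, {
    th <- sort(stats::runif(N))
    s <- sample.int(N, 1)
    (th[((s + g - 1) %% N) + 1] - th[((s - 1) %% N) + 1]) %% 1
  })
  for (y in c(0.05, 0.15, 0.4)) {
    Fhat <- mean(spac <= y)
    se <- sqrt(Fhat * (1 - Fhat) / length(spac))
    expect_lt(abs(pair_less_pvalue(y, g, N) - Fhat), 3 * se + 1e-12)
  }
})
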