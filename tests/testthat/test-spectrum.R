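test_that("the raw spectrum is a deterministic per-period score sweep", {
  comb <- dirac_comb(1000, 20000)
  expect_error(compute_sos(comb, numeric(0)), "empty")
  expect_equal(suppressWarnings(compute_sos(comb, 730)),
               scs_score(comb, 730))
  grid <- seq(300, 3000, by = 10)
  s <- suppressWarnings(compute_sos(comb, grid))
  expect_identical(s, suppressWarnings(compute_sos(comb, grid)))
  # harmonics: both P and 2P exceed the null mean for a comb of spacing P
  nul <- cached_null(20, 1)
  expect_gt(suppressWarnings(scs_score(comb, 1000)), mean(nul$scores))
  expect_gt(suppressWarnings(scs_score(comb, 2000)), mean(nul$scores))
})

test_that("the global maximum sits at the comb spacing, not a divisor or multiple", {
  comb <- dirac_comb(1000, 20000)
  sp <- suppressWarnings(
    solenoid_spectrum(comb, seq(300, 3000, 10), null = cached_null(20, 1)))
  expect_equal(dominant_period(sp), 1000)
})

test_that("the null ensemble is reproducible and period-independent", {
  a <- null_ensemble(15, 1, R = 300, seed = 5)
  b <- null_ensemble(15, 1, R = 300, seed = 5)
  expect_identical(a$scores, b$scores)
  expect_false(identical(a$scores, null_ensemble(15, 1, R = 300, seed = 6)$scores))
  expect_true(all(is.finite(a$scores)))
  expect_gt(stats::sd(a$scores), 0)
  expect_warning(null_ensemble(10, 1, R = 50, seed = 1), "resolution")
  # discrete-lattice sampling: distribution does not depend on the period
  d1 <- null_ensemble(15, 1, R = 800, seed = 8, method = "discrete",
                      period = 1000, L = 1e5)
  d2 <- null_ensemble(15, 1, R = 800, seed = 9, method = "discrete",
                      period = 3333, L = 1e5)
  expect_gt(suppressWarnings(stats::ks.test(d1$scores, d2$scores))$p.value, 0.01)
})

test_that("pSoS p-values use the add-one estimator against the shared null", {
  nul <- cached_null(15, 1, R = 1000, seed = 2)
  R <- nul$R
  lo <- min(nul$scores); hi <- max(nul$scores); med <- stats::median(nul$scores)
  expect_equal(compute_psos(lo - 1, nul), 1)
  expect_equal(compute_psos(hi + 1, nul), 1 / (R + 1))
  expect_lt(abs(compute_psos(med, nul) - 0.5), 2 / sqrt(R))
  # brute-force counting agreement
  obs <- c(0.7, 0.85, 1.0, 1.2)
  expect_equal(compute_psos(obs, nul),
               vapply(obs, function(s) (1 + sum(nul$scores >= s)) / (R + 1),
                      numeric(1)))
  expect_error(compute_psos(1, nul, N = 16), "N = ")
  expect_error(compute_psos(1, nul, J = 2), "J = ")
})

test_that("null p-values of uniform sequences are themselves uniform", {
  N <- 20; J <- 1
  nul <- cached_null(N, J, R = 1000, seed = 3)
  set.seed(17)
  ps <- replicate(200, {
    s <- site_sequence(sort(sample(0:999999, N)), L = 1e6)
    compute_psos(scs_score(s, 12345), nul)
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("pure noise produces the nominal false-positive rate along the grid", {
  N <- 20; J <- 1
  nul <- cached_null(N, J, R = 1000, seed = 4)
  grid <- seq(1000, 20000, length.out = 100)
  set.seed(29)
  frac <- replicate(50, {
    s <- site_sequence(sort(sample(0:199999, N)), L = 2e5)
    mean(compute_psos(compute_sos(s, grid, J), nul) < 0.05)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.02)
})

test_that("peak finding groups harmonics under their fundamental", {
  comb <- dirac_comb(1000, 20000)
  sp <- suppressWarnings(
    solenoid_spectrum(comb, seq(600, 4100, 10), null = cached_null(20, 1)))
  pk <- find_peaks(sp, min_neglog10p = 2)
  expect_gt(nrow(pk), 1)
  top <- pk[pk$group == 1L, ]
  expect_equal(sort(top$period), c(1000, 2000, 3000, 4000), tolerance = 0.02)
  expect_equal(unique(top$fundamental), 1000)
  expect_equal(top_fundamental(sp), 1000)
})

test_that("a two-comb mixture yields harmonic groups at both spacings", {
  # both combs contain position 0; the shared site is deduplicated
  m <- suppressWarnings(mixture(dirac_comb(1000, 40000), dirac_comb(1470, 40000)))
  sp <- suppressWarnings(
    solenoid_spectrum(m, seq(600, 4200, 10),
                      null = cached_null(n_sites(m), default_J(n_sites(m)))))
  fp <- fundamental_periods(sp)
  expect_true(any(abs(fp / 1000 - 1) <= 0.02))
  expect_true(any(abs(fp / 1470 - 1) <= 0.02))
})

test_that("a flat spectrum from uniform sites yields no harmonic structure", {
  set.seed(41)
  s <- site_sequence(sort(sample(0:199999, 20)), L = 2e5)
  sp <- solenoid_spectrum(s, seq(1000, 20000, length.out = 150),
                          null = cached_null(20, 1))
  pk <- find_peaks(sp, min_neglog10p = 2)
  # no group may show a fundamental plus supporting harmonics
  if (nrow(pk) > 0) expect_lt(max(table(pk$group)), 3)
  expect_lt(nrow(pk), 5)
})

test_that("the family-wise peak correction matches direct evaluation", {
  expect_equal(family_correction(0.05, 1), 0.05)
  expect_equal(family_correction(0, 7), 0)
  expect_equal(family_correction(0.01, 10), 0.09561792499, tolerance = 1e-9)
  expect_equal(family_correction(0.3, 4), 1 - 0.7^4)
  expect_error(family_correction(1.2, 3), "p_star")
})

test_that("spectrum objects expose their contract invariants", {
  train <- canonical_train()
  sp <- solenoid_spectrum(train, seq(5000, 25000, 100),
                          null = cached_null(40, 2))
  expect_s3_class(sp, "solenoid_spectrum")
  expect_true(all(sp$pvalue > 0 & sp$pvalue <= 1))
  expect_identical(sp$neglog10p, -log10(sp$pvalue))
  df <- as.data.frame(sp)
  expect_identical(nrow(df), length(sp$periods))
  expect_output(print(sp), "dominant period")
})
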