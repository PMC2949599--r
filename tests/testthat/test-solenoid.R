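test_that("site sequences are canonicalized and validated", {
  expect_warning(s <- site_sequence(c(30, 10, 10, 20), L = 100), "duplicated")
  expect_identical(s$positions, c(10, 20, 30))
  expect_warning(site_sequence(c(0, 5)), "max\\(position\\)")
  expect_error(site_sequence(c(0, 5), L = 4), "smaller than")
  expect_error(site_sequence(c(0.5, 2), L = 10), "integers")
  expect_error(site_sequence(numeric(0), L = 10), "at least one")
  expect_identical(n_sites(s), 3L)
})

test_that("modular projection wraps positions onto the unit circle", {
  s <- site_sequence(25000, L = 30000)
  expect_equal(project_modulo(s, 10000)$theta, 0.5)
  comb <- dirac_comb(5000, 40000)
  expect_true(all(project_modulo(comb, 5000)$theta == 0))
  any_sites <- site_sequence(c(3, 1000, 4200, 9999), L = 10000)
  expect_equal(project_modulo(any_sites, any_sites$L)$theta,
               any_sites$positions / any_sites$L)
  expect_error(project_modulo(comb, 1), "period")
  expect_error(project_modulo(comb, 40001), "period")
})

test_that("neighbor distances follow circular geometry", {
  # regular N-gon: x_{i,j} = 2j / N for every i
  for (N in c(8, 13)) {
    s <- site_sequence(round(seq(0, 999, length.out = N + 1)[1:N]), L = 1000)
    proj <- project_modulo(s, 1000)
    for (j in 1:2) for (i in c(1, 3, N)) {
      expect_equal(neighbor_distance(proj, i, j), 2 * j / N, tolerance = 0.01)
    }
  }
  # hand-computed 3-site case: arc through the middle site
  s3 <- site_sequence(c(0, 100, 500), L = 1000)
  proj3 <- project_modulo(s3, 1000)
  expect_equal(neighbor_distance(proj3, 2, 1), 0.5)
  expect_error(neighbor_distance(proj3, 2, 2), "neighbor order")
})

test_that("rotating all angles leaves neighbor distances unchanged", {
  set.seed(3)
  base <- sort(sample(0:9999, 12))
  s1 <- site_sequence(base, L = 10000)
  s2 <- site_sequence((base + 4321) %% 10000, L = 10000)
  p1 <- project_modulo(s1, 10000); p2 <- project_modulo(s2, 10000)
  for (j in 1:3)
    expect_equal(sort(vapply(1:12, neighbor_distance, 0, proj = p1, j = j)),
                 sort(vapply(1:12, neighbor_distance, 0, proj = p2, j = j)),
                 tolerance = 1e-12)
})

test_that("default neighbor depth follows the integer-part rule with a cap", {
  expect_identical(default_J(90), 5)
  expect_identical(default_J(16), 1)
  expect_identical(default_J(2), 1)
  expect_identical(default_J(300), 18)
  # the cap keeps 2J - 1 <= N - 2 for small N
  for (N in 3:40) expect_lte(2 * default_J(N) - 1, max(N - 2, 1))
  expect_error(scs_score(site_sequence(c(0, 5), L = 10), 5), "at least 3")
})

test_that("the score is invariant under translation, reflection and rescaling", {
  set.seed(11)
  pos <- sort(sample(0:49999, 25))
  s <- site_sequence(pos, L = 50000)
  P <- 7350
  base <- scs_score(s, P)
  shifted <- site_sequence(pos + 12345, L = 70000)
  expect_equal(scs_score(shifted, P), base, tolerance = 1e-12)
  reflected <- site_sequence(s$L - 1 - pos, L = 50000)
  expect_equal(scs_score(reflected, P), base, tolerance = 1e-12)
  scaled <- site_sequence(pos * 3, L = 150000)
  expect_equal(scs_score(scaled, 3 * P), base, tolerance = 1e-12)
})

test_that("a comb scores higher at its spacing than at an unrelated period", {
  comb <- dirac_comb(10000, 200000)
  expect_gt(suppressWarnings(scs_score(comb, 10000)),
            scs_score(comb, round(10000 * 1.6180339)))
  expect_warning(scs_score(comb, 10000), "identical modulo")
})

test_that("uniform random sites score near the null ensemble", {
  set.seed(21)
  s <- site_sequence(sort(sample(0:99999, 30)), L = 100000)
  nul <- cached_null(30, default_J(30), R = 1000)
  sc <- scs_score(s, 8310)
  expect_lt(abs(sc - mean(nul$scores)), 4 * stats::sd(nul$scores))
})

test_that("mean score at the planted period decreases with jitter amplitude", {
  P <- 500; L <- 10000
  comb <- dirac_comb(P, L)            # 20 sites
  amps <- c(0, 0.1, 0.25, 0.5) * P
  set.seed(31)
  means <- vapply(amps, function(A) {
    mean(replicate(100, {
      j <- suppressWarnings(add_jitter(comb, A, seed = sample.int(1e6, 1)))
      if (n_sites(j) < 5) return(NA_real_)
      suppressWarnings(scs_score(j, P, J = 1))
    }), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
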