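test_that("lognormal bin boundaries and means follow the erfinv recursion", {
  b1 <- lognormal_bin_means(1)
  expect_identical(b1$t, c(-Inf, Inf))
  expect_equal(b1$m, 0)

  # M = 2 closed form: t2 = sqrt(2) erfinv(0) = 0, m = -/+ 2/sqrt(2 pi)
  b2 <- lognormal_bin_means(2)
  expect_equal(b2$t[2], 0)
  expect_equal(b2$m, c(-2, 2) / sqrt(2 * pi), tolerance = 1e-12)

  # literal recursion agreement on a mid-sized case
  M <- 40
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  erfinv <- function(x) qnorm((x + 1) / 2) / sqrt(2)
  t <- -Inf
  for (i in seq_len(M - 1)) t <- c(t, sqrt(2) * erfinv(2 / M + erf(t[i] / sqrt(2))))
  expect_equal(lognormal_bin_means(M)$t[seq_len(M)], t, tolerance = 1e-9)

  for (M in c(1, 2, 3, 10, 101, 5000)) {
    b <- lognormal_bin_means(M)
    expect_true(all(diff(b$t) > 0))
    expect_equal(sum(b$m), 0, tolerance = 1e-9)
    expect_equal(b$m, -rev(b$m), tolerance = 1e-9)
  }
  expect_error(lognormal_bin_means(0), "integer >= 1")
})

test_that("ranked abundances match each law and stay normalised", {
  expect_equal(rank_abundances(5, "pl", 0), rep(0.2, 5))
  expect_equal(rank_abundances(3, "exp", 1),
               exp(-(1:3)) / sum(exp(-(1:3))), tolerance = 1e-12)
  expect_equal(rank_abundances(3, "exp", 1),
               c(0.66524, 0.24473, 0.09003), tolerance = 1e-4)
  # M = 2 lognormal closed form via the bin means
  expect_equal(rank_abundances(2, "lgn", 2.5)[1],
               1 / (1 + exp(-2.5 * 4 / sqrt(2 * pi))), tolerance = 1e-12)

  grid <- expand.grid(M = c(1, 2, 7, 100, 2500, 10000),
                      d = c(0, 0.3, 1, 2.5, 5),
                      T = distribution_kinds(), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(grid))) {
    f <- rank_abundances(grid$M[k], grid$T[k], grid$d[k])
    expect_length(f, grid$M[k])
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(diff(f) <= 0))
    expect_true(all(f >= 0))
    if (grid$T[k] %in% c("pl", "log") || grid$d[k] * grid$M[k] <= 500)
      expect_true(all(f > 0))
  }
  expect_error(rank_abundances(10, "weibull", 1), "unknown distribution")
  expect_error(rank_abundances(10, "pl", -0.1), "non-negative")
})

test_that("long distribution names map onto the short codes", {
  expect_identical(match_distribution("power_law"), "pl")
  expect_identical(match_distribution("lognormal"), "lgn")
  expect_identical(rank_abundances(20, "exponential", 0.5),
                   rank_abundances(20, "exp", 0.5))
})

test_that("logarithmic law is invariant to the logarithm base", {
  for (M in c(5, 100, 1000)) for (d in c(0.3, 0.9, 2)) {
    w <- log10(seq_len(M) + 1)^(-d)
    expect_equal(rank_abundances(M, "log", d), sort(w / sum(w), TRUE),
                 tolerance = 1e-12)
  }
})

test_that("evenness is normalised entropy with the expected limits", {
  for (M in c(2, 10, 500)) expect_equal(evenness(rep(1 / M, M)), 1)
  # strictly decreasing in the shape parameter
  for (T in c("pl", "exp")) {
    ev <- sapply(seq(0, 2, by = 0.25), function(d)
      evenness(rank_abundances(50, T, d)))
    expect_true(all(diff(ev) < 0))
    expect_equal(ev[1], 1)
  }
  expect_warning(e1 <- evenness(1), "single-genotype")
  expect_equal(e1, 1)
  expect_error(evenness(c(0.7, 0.2)), "sum to 1")
  expect_error(evenness(c(1.2, -0.2)), ">= 0")
})

test_that("dominant abundance reports the top share in percent", {
  expect_equal(dominant_abundance(rep(0.25, 4)), 25)
  f <- rank_abundances(300, "exp", 0.03)
  expect_equal(dominant_abundance(f), 100 * f[1])
  expect_error(dominant_abundance(numeric(0)), "non-empty")
})
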