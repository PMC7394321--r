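test_that("simulated populations honour the truth parameters", {
  pop <- simulate_population(300, "exp", 0.03, 12500, v = 0, seed = 1)
  expect_length(pop$f, 300)
  expect_equal(sum(pop$f), 1, tolerance = 1e-12)
  expect_true(all(pop$lengths == 12500))
  expect_equal(100 * max(pop$f), 2.956, tolerance = 1e-3)

  # genome-length CV: sd of lengths ~ L0 * v (plus integer rounding)
  pop2 <- simulate_population(5000, "pl", 0.7, 50000, v = 1e-4, seed = 2)
  expect_equal(sd(pop2$lengths), 5, tolerance = 0.15)
  expect_true(all(pop2$lengths > 100))

  # law of large numbers on the mean length at v = 0.01
  pop3 <- simulate_population(1e5, "pl", 0.1, 50000, v = 0.01, seed = 3)
  se <- 50000 * 0.01 / sqrt(1e5)
  expect_lt(abs(mean(pop3$lengths) - 50000), 3 * se + 0.5)

  # seeded reproducibility
  expect_identical(simulate_population(100, "lgn", 2.5, 30000, 0.05, seed = 7),
                   simulate_population(100, "lgn", 2.5, 30000, 0.05, seed = 7))
  expect_error(simulate_population(10, "pl", 0.5, 50, v = 0), "exceed the read")
})

test_that("noiseless expected spectra are self-consistent", {
  sq <- default_seq()
  truth <- model_params(300, 12500, "exp", 0.03)
  obs <- expected_contig_spectrum(truth, sq, q_max = 60)
  expect_s3_class(obs, "contig_spectrum")
  expect_equal(model_error(obs, truth), 0, tolerance = 1e-20)
  # huge L: every read is a singleton
  obs0 <- expected_contig_spectrum(model_params(10, 1e9, "pl", 0.5), sq, 10)
  expect_equal(obs0$C[1], sq$R, tolerance = 1e-3)
  # rounding the spectrum misplaces at most half a contig per bin
  for (par in list(truth, model_params(1000, 50000, "pl", 0.7))) {
    ro <- expected_contig_spectrum(par, sq, q_max = 80, round = TRUE)
    expect_true(all(ro$C == round(ro$C)))
    expect_lte(abs(sum(ro$O) - sum(expected_spectrum(par, sq, 80)$E)), 80 / 2)
  }
})

test_that("Monte-Carlo spectra conserve reads and respect edge cases", {
  # a single read is always a singleton contig
  pop <- simulate_population(3, "pl", 0.5, 10000, seed = 1)
  one <- montecarlo_contig_spectrum(pop, seq_params(1, 100, 35), seed = 2)
  expect_equal(one$C, 1)

  # deep coverage of a tiny genome: all reads chain into one contig
  tiny <- simulate_population(1, "pl", 0, 200, seed = 1)
  for (s in 1:20) {
    mc <- montecarlo_contig_spectrum(tiny, seq_params(50, 100, 35), seed = s)
    expect_equal(mc$C[50], 1)
    expect_equal(sum(mc$C), 1)
  }

  # exact read conservation across random populations
  for (s in 1:20) {
    M0 <- sample(1:30, 1)
    pop <- simulate_population(M0, sample(distribution_kinds(), 1),
                               runif(1, 0, 1), 30000, v = runif(1, 0, 0.05),
                               seed = s)
    mc <- montecarlo_contig_spectrum(pop, seq_params(2000, 100, 35),
                                     seed = s + 100)
    expect_equal(sum(mc$O), 2000)
    expect_true(all(mc$C == round(mc$C)))
  }

  # seeded reproducibility
  pop <- simulate_population(5, "exp", 0.2, 40000, seed = 9)
  expect_identical(montecarlo_contig_spectrum(pop, default_seq(), seed = 4),
                   montecarlo_contig_spectrum(pop, default_seq(), seed = 4))
})

test_that("the varying-length scenario converges to fixed lengths as v -> 0", {
  sq <- seq_params(2000, 100, 35)
  c1_fixed <- c1_tiny <- numeric(200)
  for (k in 1:200) {
    p0 <- simulate_population(100, "pl", 0.7, 30000, v = 0, seed = 1000 + k)
    pv <- simulate_population(100, "pl", 0.7, 30000, v = 1e-4, seed = 1000 + k)
    c1_fixed[k] <- montecarlo_contig_spectrum(p0, sq, seed = 5000 + k)$C[1]
    c1_tiny[k] <- montecarlo_contig_spectrum(pv, sq, seed = 7000 + k)$C[1]
  }
  ks <- suppressWarnings(ks.test(c1_fixed, c1_tiny))
  expect_gt(ks$p.value, 0.01)
})

test_that("scenario presets encode the benchmark grids", {
  s1 <- scenario_presets(1)
  expect_equal(nrow(s1), 64)
  expect_setequal(unique(s1$M0), c(300, 1000, 5000, 10000))
  expect_setequal(unique(s1$L0), c(12500, 50000, 125000, 300000))
  expect_true(all(s1$v == 0))
  s2 <- scenario_presets(2)
  expect_equal(nrow(s2), 14)
  expect_setequal(unique(s2$v),
                  c(0.0001, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1))
  expect_true(all(s2$T0 == "pl" & s2$L0 == 50000))
  expect_error(scenario_presets(3), "scenario")
})
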