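test_that("length windows tile the axis with exact half overlap", {
  w1 <- length_windows(10000, 310000, 1)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start, w1$end), c(10000, 310000))

  w <- length_windows(10000, 310000, 29)
  W_L <- 2 * (310000 - 10000) / 30
  expect_equal(W_L, 20000)
  expect_equal(w$start, seq(10000, 290000, by = 10000))
  expect_equal(w$end - w$start, rep(W_L, 29))
  expect_equal(w$end[29], 310000)

  set.seed(99)
  for (k in 1:100) {
    lb <- runif(1, 1e3, 1e5); ub <- lb + runif(1, 1e3, 1e6)
    n <- sample(1:40, 1)
    w <- length_windows(lb, ub, n)
    width <- 2 * (ub - lb) / (n + 1)
    expect_equal(w$end - w$start, rep(width, n), tolerance = 1e-9)
    expect_equal(w$start[1], lb)
    expect_equal(w$end[n], ub, tolerance = 1e-9)
    if (n > 1) {
      expect_equal(diff(w$start), rep(width / 2, n - 1), tolerance = 1e-9)
      expect_equal(w$end[-n] - w$start[-1], rep(width / 2, n - 1),
                   tolerance = 1e-9)  # exact half-window overlap
    }
  }
  expect_error(length_windows(10, 5, 3), "L_UB > L_LB")
  expect_error(length_windows(1, 10, 0), "integer >= 1")
})

test_that("search_spec applies the documented step-size heuristics", {
  sp <- search_spec()
  expect_equal(sp$M_step, 1000)           # 10^(ceiling(log10(15000)) - 2)
  expect_equal(sp$d_step, 0.01)
  expect_equal(sp$L_step_frac, 0.025)
  expect_equal(search_spec(M_bounds = c(1, 100))$M_step, 1)
  expect_equal(search_spec(M_bounds = c(1, 9999))$M_step, 100)
  expect_error(search_spec(M_bounds = c(5, 2)), "bound")
})

test_that("GA finds trivial minima and is seed-deterministic", {
  sub <- list(M = c(10, 20, 30), L = 5000, d = 0.5)
  cost <- function(M, L, d) (M - 20)^2
  for (s in c(1, 7, 123)) {
    res <- ga_minimize(cost, sub, seed = s)
    expect_equal(res$M, 20)
    expect_equal(res$S, 0)
  }
  # determinism contract
  sub2 <- list(M = 1:20, L = seq(1000, 2000, by = 100), d = seq(0.1, 1, 0.1))
  cost2 <- function(M, L, d) (M - 7)^2 + (L - 1400)^2 / 1e4 + (d - 0.6)^2
  r1 <- ga_minimize(cost2, sub2, seed = 42)
  r2 <- ga_minimize(cost2, sub2, seed = 42)
  expect_identical(r1, r2)
  # convex cost: GA matches the exhaustive oracle
  ro <- grid_oracle(cost2, sub2)
  expect_equal(r1[c("M", "L", "d", "S")], ro[c("M", "L", "d", "S")])
  # result always on the grid
  expect_true(r1$M %in% sub2$M && r1$L %in% sub2$L && r1$d %in% sub2$d)
  expect_error(ga_minimize(cost2, list(M = numeric(0), L = 1, d = 1)),
               "empty")
})

test_that("grid oracle equals a naive scan and breaks ties toward small M", {
  sub <- list(M = c(3), L = c(10), d = c(0.2))
  expect_equal(grid_oracle(function(M, L, d) 5, sub)[c("M", "L", "d", "S")],
               list(M = 3, L = 10, d = 0.2, S = 5))
  set.seed(11)
  for (k in 1:10) {
    sub <- list(M = sort(sample(1:50, 5)), L = sort(runif(8, 1e3, 1e5)),
                d = sort(runif(5, 0, 2)))
    vals <- array(runif(200), dim = c(5, 8, 5))
    cost <- function(M, L, d)
      vals[match(M, sub$M), match(L, sub$L), match(d, sub$d)]
    res <- grid_oracle(cost, sub)
    idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    expect_equal(res$S, min(vals))
    expect_equal(res$M, sub$M[idx[1]])
  }
  # exact ties resolve to the smallest M (parsimony)
  sub <- list(M = c(5, 50), L = c(1e4, 2e4), d = 0.1)
  expect_equal(grid_oracle(function(M, L, d) 1, sub)$M, 5)
  expect_error(grid_oracle(function(M, L, d) 1, sub, cap = 2), "above the")
})

test_that("the joint fit recovers truth on a small noiseless problem", {
  obs <- noiseless_obs()
  fit <- fit_virome(obs, tiny_spec())
  expect_s3_class(fit, "virome_fit")
  expect_equal(fit$M, 300L)
  expect_equal(fit$L, 12500)
  expect_identical(fit$T, "exp")
  expect_equal(fit$d, 0.03, tolerance = 1e-9)
  expect_lt(fit$S_min, 1e-12)
  expect_equal(fit$evenness, 0.790, tolerance = 5e-4)
  expect_equal(fit$f_max, 2.956, tolerance = 5e-3)
  # refinement never does worse than the best raw subspace winner
  expect_lte(fit$S_min, min(fit$subspaces$S))
  # determinism: identical spec (including seed) gives identical solution
  fit2 <- fit_virome(obs, tiny_spec())
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$S_min, fit2$S_min)
})

test_that("fixed-length fit is consistent with the joint fit", {
  obs <- noiseless_obs()
  joint <- fit_virome(obs, tiny_spec())
  fixed <- fit_virome_fixed_length(obs, L = joint$L, spec = tiny_spec())
  expect_equal(fixed$M, joint$M)
  expect_identical(fixed$T, joint$T)
  expect_equal(fixed$d, joint$d)
  expect_lt(fixed$S_min, 1e-12)
  expect_error(fit_virome(obs, tiny_spec(), fixed_L = 5), "within the L bounds")
})

test_that("a maximally even community triggers the multiple-minima warning", {
  sq <- default_seq()
  obs <- expected_contig_spectrum(model_params(50, 12500, "exp", 0), sq, 60)
  sp <- search_spec(M_bounds = c(40, 60), L_bounds = c(12000, 13000),
                    d_bounds = c(0, 0.02), distributions = "exp", N_L = 1,
                    ga = list(pop_size = 15, generations = 25, patience = 8),
                    seed = 3)
  expect_warning(fit <- fit_virome(obs, sp), "maximally even")
  expect_equal(fit$evenness, 1)
})

test_that("fit methods expose the model sensibly", {
  obs <- noiseless_obs()
  fit <- fit_virome(obs, tiny_spec())
  co <- coef(fit)
  expect_named(co, c("M", "L", "d"))
  expect_identical(attr(co, "distribution"), "exp")
  expect_output(print(fit), "richness M")
  expect_output(print(summary(fit)), "winning niche")
  # fitted values reproduce the observed noiseless spectrum
  expect_equal(fitted(fit), obs$C[seq_len(fit$q_max)], tolerance = 1e-9)
  expect_equal(residuals(fit), numeric(fit$q_max), tolerance = 1e-6)
  expect_length(predict(fit, q_max = 80), 80)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_true(all(vapply(sims, function(s) sum(s$O) == obs$seq$R,
                         logical(1))))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
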