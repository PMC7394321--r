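#' Simulate a ground-truth viral population
#'
#' Builds a community of `M0` genotypes with relative abundances from
#' [rank_abundances()] and genome lengths either fixed at `L0` (`v = 0`,
#' the fixed-length scenario) or drawn i.i.d. from
#' \eqn{N(L_0, (L_0 v)^2)} (`v > 0`, the varying-length scenario), where
#' `v` is the coefficient of variation of genome length. Sampled lengths
#' are rounded to integer bp and redrawn while `<= r`, so every genome can
#' carry at least one read; at the small `v` values of interest this
#' truncation is negligible and the nominal normal shape is preserved.
#'
#' @param M0 true richness.
#' @param T0 true rank-abundance law.
#' @param d0 true shape parameter.
#' @param L0 true average genome length (bp), `> r`.
#' @param v coefficient of variation of genome lengths (`>= 0`).
#' @param seed optional seed.
#' @param r read length in bp used for the length floor.
#' @return A list of class `"simulated_population"`: `f` (abundances),
#'   `lengths` (bp), `truth = list(M0, L0, T0, d0, v)`, `seed`.
#' @export
#' @examples
#' pop <- simulate_population(300, "exp", 0.03, 12500, v = 0, seed = 1)
#' max(pop$f) * 100  # ~ 2.956 %
simulate_population <- function(M0, T0, d0, L0, v = 0, seed = NULL,
                                r = 100) {
  M0 <- check_count(M0, "M0")
  T0 <- match_distribution(T0)
  if (!is.numeric(v) || length(v) != 1L || v < 0)
    stop("v must be a single non-negative number", call. = FALSE)
  if (L0 <= r) stop("L0 must exceed the read length r", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- rank_abundances(M0, T0, d0)
  if (v == 0) {
    lengths <- rep(round(L0), M0)
  } else {
    lengths <- round(stats::rnorm(M0, L0, L0 * v))
    bad <- which(lengths <= r)
    while (length(bad) > 0L) {
      lengths[bad] <- round(stats::rnorm(length(bad), L0, L0 * v))
      bad <- bad[lengths[bad] <= r]
    }
  }
  structure(list(f = f, lengths = as.integer(lengths),
                 truth = list(M0 = M0, L0 = L0, T0 = T0, d0 = d0, v = v),
                 seed = seed),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("Simulated population: M0 = %d, L0 = %g bp, T0 = %s, d0 = %g, v = %g\n",
              tr$M0, tr$L0, tr$T0, tr$d0, tr$v))
  invisible(x)
}

#' Noiseless model-expected contig spectrum
#'
#' The expected contig spectrum `(E_1/1, E_2/2, ...)` of a parameter
#' point, packaged as a [contig_spectrum()] so it can be fed straight back
#' into the estimator. Unrounded, it reproduces its generating parameters
#' exactly (`model_error` at the truth is 0), making it the canonical
#' noiseless input for parameter-recovery experiments; with
#' `round = TRUE` counts are rounded to the nearest integer contig.
#'
#' @param params a [model_params()] point (fixed-length truth).
#' @param seq a [seq_params()].
#' @param q_max number of bins to generate.
#' @param round round contig counts to integers.
#' @return A [contig_spectrum()].
#' @export
#' @examples
#' obs <- expected_contig_spectrum(model_params(300, 12500, "exp", 0.03),
#'                                 seq_params(), 60)
#' model_error(obs, model_params(300, 12500, "exp", 0.03))  # 0
expected_contig_spectrum <- function(params, seq = seq_params(),
                                     q_max = 100, round = FALSE) {
  es <- expected_spectrum(params, seq, q_max)
  C <- if (round) round(es$C) else es$C
  contig_spectrum(C, seq = seq)
}

#' Monte-Carlo contig spectrum by random read placement
#'
#' Simulates shotgun sequencing and greedy overlap assembly of a
#' population: each of the `R` reads is assigned to genotype `i` with
#' probability `f[i]` (multinomially, so read conservation
#' `sum(q * C_q) == R` is exact), read start positions are uniform on
#' `[0, len_i - r]` (linear genomes), and within a genotype reads whose
#' start positions differ by at most `r - o` chain into one contig — the
#' Lander-Waterman island rule with effective read length `r - o`.
#'
#' @param pop a [simulate_population()] object.
#' @param seq a [seq_params()].
#' @param seed optional seed.
#' @return A [contig_spectrum()] with integer counts, trimmed at the
#'   largest occupied bin.
#' @export
montecarlo_contig_spectrum <- function(pop, seq = seq_params(),
                                       seed = NULL) {
  stopifnot(inherits(pop, "simulated_population"))
  if (any(pop$lengths < seq$r))
    stop("all genome lengths must be >= the read length r", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  R <- seq$R
  link <- seq$r - seq$o
  n <- as.integer(stats::rmultinom(1L, R, pop$f))
  counts <- integer(R)
  for (i in which(n > 0L)) {
    ni <- n[i]
    if (ni == 1L) {
      counts[1L] <- counts[1L] + 1L
      next
    }
    span <- pop$lengths[i] - seq$r
    starts <- sort(stats::runif(ni, 0, max(span, 0)))
    breaks <- which(diff(starts) > link)
    sizes <- diff(c(0L, breaks, ni))
    tab <- tabulate(sizes, nbins = R)
    counts <- counts + tab
  }
  q_max <- max(which(counts > 0L))
  contig_spectrum(counts[seq_len(q_max)], seq = seq)
}

#' Benchmark scenario presets
#'
#' Parameter grids for the two simulation scenarios used to benchmark the
#' estimator. Scenario 1 (fixed genome length) crosses four richness
#' values with four genome lengths under the four (law, shape) pairs
#' `(pl, 0.7)`, `(exp, 0.03)`, `(log, 0.9)`, `(lgn, 2.5)`. Scenario 2
#' (varying genome length) fixes `L0 = 50` kbp, uses the power-law with
#' `d0 = 0.7` only, and crosses `M0` in `{300, 10000}` with coefficients
#' of variation `v` in `{0.0001, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1}`.
#'
#' @param scenario 1 or 2.
#' @return A data.frame with one row per dataset: `M0`, `L0`, `T0`, `d0`,
#'   `v`, `scenario`.
#' @export
#' @examples
#' nrow(scenario_presets(1))  # 64 parameter combinations
scenario_presets <- function(scenario = 1) {
  if (scenario == 1) {
    pairs <- data.frame(T0 = c("pl", "exp", "log", "lgn"),
                        d0 = c(0.7, 0.03, 0.9, 2.5))
    g <- expand.grid(M0 = c(300, 1000, 5000, 10000),
                     L0 = c(12500, 50000, 125000, 300000),
                     pair = seq_len(4))
    out <- data.frame(M0 = g$M0, L0 = g$L0,
                      T0 = pairs$T0[g$pair], d0 = pairs$d0[g$pair],
                      v = 0, scenario = 1L)
  } else if (scenario == 2) {
    g <- expand.grid(M0 = c(300, 10000),
                     v = c(0.0001, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1))
    out <- data.frame(M0 = g$M0, L0 = 50000, T0 = "pl", d0 = 0.7,
                      v = g$v, scenario = 2L)
  } else stop("scenario must be 1 or 2", call. = FALSE)
  out[order(out$M0, out$L0, out$T0, out$v), , drop = FALSE]
}
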