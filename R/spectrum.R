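#' Sequencing and assembly parameters
#'
#' Bundles the metadata under which a contig spectrum was produced: total
#' read count `R`, mean read length `r` (bp) and the minimum overlap `o`
#' (bp) required to join two reads into a contig. The effective read length
#' `r - o` must be positive.
#'
#' @param R total number of reads (> 0).
#' @param r average read length in bp (> 0).
#' @param o minimum assembly overlap in bp (>= 0, < `r`).
#' @return A list of class `"seq_params"`.
#' @export
#' @examples
#' seq_params(10000, 100, 35)
seq_params <- function(R = 10000, r = 100, o = 35) {
  R <- check_count(R, "R")
  r <- check_count(r, "r")
  if (!is.numeric(o) || length(o) != 1L || is.na(o) || o < 0 ||
      abs(o - round(o)) > 1e-8)
    stop("o must be a single integer >= 0", call. = FALSE)
  o <- as.integer(round(o))
  if (r <= o) stop("r must exceed o (effective length r - o must be positive)",
                   call. = FALSE)
  structure(list(R = R, r = r, o = o), class = "seq_params")
}

#' Observed contig spectrum
#'
#' A contig spectrum is the vector `C` whose q-th entry counts the contigs
#' assembled from exactly `q` reads (`C[1]` = singletons). Monte-Carlo and
#' real spectra have integer counts with `sum(q * C[q]) == R`; unrounded
#' model-expected spectra (used as noiseless inputs in recovery studies)
#' may carry fractional counts, so integrality is not enforced here.
#'
#' @param C numeric vector of non-negative contig counts, `C[q]` indexed by
#'   `q = 1..length(C)`.
#' @param seq a [seq_params()] object (or `R`, `r`, `o` passed on to it).
#' @param R,r,o convenience scalars used when `seq` is missing.
#' @return A list of class `"contig_spectrum"` with fields `C`, `seq` and
#'   the read-weighted spectrum `O = q * C`.
#' @export
#' @examples
#' contig_spectrum(c(3, 1, 0, 1), R = 10, r = 100, o = 35)
contig_spectrum <- function(C, seq = NULL, R = NULL, r = 100, o = 35) {
  if (!is.numeric(C) || length(C) == 0L)
    stop("C must be a non-empty numeric vector of contig counts", call. = FALSE)
  if (any(!is.finite(C)) || any(C < 0))
    stop("contig counts must be finite and >= 0", call. = FALSE)
  if (is.null(seq)) {
    if (is.null(R)) stop("total read count R is required", call. = FALSE)
    seq <- seq_params(R, r, o)
  }
  if (length(C) > seq$R)
    stop("spectrum length q_max cannot exceed the read count R", call. = FALSE)
  q <- seq_along(C)
  structure(list(C = as.numeric(C), seq = seq, O = q * as.numeric(C)),
            class = "contig_spectrum")
}

#' @export
print.contig_spectrum <- function(x, ...) {
  nz <- which(x$C > 0)
  cat("Contig spectrum: q_max =", length(x$C),
      " reads in contigs =", round(sum(x$O), 2), "of R =", x$seq$R, "\n")
  cat("  r =", x$seq$r, "bp, o =", x$seq$o, "bp;",
      length(nz), "non-zero bins\n")
  invisible(x)
}

#' Model parameter point
#'
#' A candidate `(M, L, T, d)` point of the model: richness `M`, average
#' genome length `L` (bp), rank-abundance law `T` and shape `d`.
#'
#' @param M integer richness >= 1.
#' @param L average genome length in bp (> 0).
#' @param T distribution code, see [distribution_kinds()].
#' @param d shape parameter >= 0.
#' @return A list of class `"model_params"`.
#' @export
model_params <- function(M, L, T, d) {
  M <- check_count(M, "M")
  T <- match_distribution(T)
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0)
    stop("L must be a single positive length in bp", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("d must be a single non-negative number", call. = FALSE)
  structure(list(M = M, L = as.numeric(L), T = T, d = as.numeric(d)),
            class = "model_params")
}

#' Per-genotype read recruitment probability
#'
#' Under uniform random shotgun coverage, the probability that a read from
#' genotype `i` overlaps another read of the same genotype by at least `o`
#' bp is
#' \deqn{p_i = 1 - \exp\!\big(-(r - o)\, f_i\, R / L\big),}
#' the classical Lander-Waterman island statistic with effective read
#' length `r - o`. Computed via `expm1` for accuracy when the exponent is
#' small.
#'
#' @param params a [model_params()] point (or an abundance vector `f` via
#'   the `f` argument).
#' @param seq a [seq_params()] object.
#' @param f optional abundance vector overriding the one implied by
#'   `params` (used internally to avoid recomputation).
#' @return Numeric vector `p` of length `M`, aligned with the abundance
#'   ranks, each entry in `[0, 1)`.
#' @export
recruitment_prob <- function(params, seq, f = NULL) {
  stopifnot(inherits(seq, "seq_params"))
  if (is.null(f)) f <- rank_abundances(params$M, params$T, params$d)
  if (params$L <= 0) stop("L must be positive", call. = FALSE)
  -expm1(-(seq$r - seq$o) * f * seq$R / params$L)
}

#' Expected contig spectrum and variance weights
#'
#' The expected number of reads in contigs of exactly `q` reads is
#' \deqn{E_q = \sum_{i=1}^{M} f_i R\, q\, p_i^{q-1} (1 - p_i)^2,}
#' with variance
#' \deqn{V_q^2 = \sum_{i=1}^{M} f_i R\, q\, p_i^{q-1} (1 - p_i)^2
#'   \big(1 - q\, p_i^{q-1} (1 - p_i)^2\big).}
#' The expected contig spectrum itself is `E_q / q`. Summed over all `q`
#' the `E_q` recover the read count `R` (every read lies in exactly one
#' contig), so truncation at `q_max` loses only the tail mass.
#'
#' @param params a [model_params()] point.
#' @param seq a [seq_params()] object.
#' @param q_max largest contig size evaluated, `1 <= q_max <= R`.
#' @param f optional precomputed abundance vector.
#' @return A list of class `"expected_spectrum"` with `E`, `V2` (both
#'   length `q_max`) and `C = E / q`.
#' @export
#' @examples
#' es <- expected_spectrum(model_params(1, 650000, "pl", 0), seq_params(), 5)
#' es$E[1]  # R * (1 - p)^2 with p = 1 - exp(-1)
expected_spectrum <- function(params, seq, q_max, f = NULL) {
  stopifnot(inherits(seq, "seq_params"))
  q_max <- check_count(q_max, "q_max")
  if (q_max > seq$R) stop("q_max cannot exceed R", call. = FALSE)
  if (is.null(f)) f <- rank_abundances(params$M, params$T, params$d)
  ev <- .expected_spectrum_cpp(f, seq$R, seq$r, seq$o, params$L, q_max)
  structure(list(E = ev$E, V2 = ev$V2, C = ev$E / seq_len(q_max)),
            class = "expected_spectrum")
}

#' Variance-weighted model error
#'
#' The fit criterion minimised by the estimator:
#' \deqn{S(M, L, T, d) = \sum_{q=1}^{q_{max}}
#'   \frac{(O_q - E_q)^2}{V_q^2},}
#' where `O_q = q * C_q` is the observed read-weighted spectrum. The sum
#' runs to the largest `q` with a non-zero observed count (appending empty
#' bins does not change `S`); `q_max` can be overridden, e.g. to apply a
#' fixed trim for comparison runs. Bins whose model variance underflows
#' (`V2 <= 1e-12`) contribute 0 when the observation is also 0 and are
#' floored at `1e-12` otherwise.
#'
#' @param obs a [contig_spectrum()].
#' @param params a [model_params()] point.
#' @param q_max optional override of the summation cutoff; default is the
#'   largest `q` with `C[q] > 0`.
#' @param f optional precomputed abundance vector.
#' @return The scalar cost `S >= 0`; 0 iff the observed read-weighted
#'   spectrum equals the model expectation on the summation range.
#' @export
model_error <- function(obs, params, q_max = NULL, f = NULL) {
  stopifnot(inherits(obs, "contig_spectrum"))
  if (all(obs$C == 0))
    stop("all-zero contig spectrum carries no information", call. = FALSE)
  if (is.null(q_max)) q_max <- max(which(obs$C > 0))
  q_max <- check_count(q_max, "q_max")
  O <- obs$O[seq_len(q_max)]
  O[is.na(O)] <- 0
  if (is.null(f)) f <- rank_abundances(params$M, params$T, params$d)
  .model_error_cpp(f, obs$seq$R, obs$seq$r, obs$seq$o, params$L, O, 1e-12)
}
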