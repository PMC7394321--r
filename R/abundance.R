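#' Rank-abundance distribution codes
#'
#' The four candidate rank-abundance laws used throughout the package, in
#' their conventional short codes: `"pl"` (power-law), `"exp"` (exponential),
#' `"log"` (logarithmic) and `"lgn"` (lognormal).
#'
#' @return Character vector of the four distribution codes.
#' @export
#' @examples
#' distribution_kinds()
distribution_kinds <- function() c("pl", "exp", "log", "lgn")

#' Normalise a distribution name to its short code
#'
#' Accepts either a short code (`"pl"`, `"exp"`, `"log"`, `"lgn"`) or a long
#' name (`"power_law"`, `"exponential"`, `"logarithmic"`, `"lognormal"`).
#'
#' @param T character scalar naming the distribution.
#' @return One of `"pl"`, `"exp"`, `"log"`, `"lgn"`.
#' @export
match_distribution <- function(T) {
  if (!is.character(T) || length(T) != 1L || is.na(T))
    stop("distribution must be a single character string", call. = FALSE)
  long <- c(power_law = "pl", exponential = "exp",
            logarithmic = "log", lognormal = "lgn")
  if (T %in% distribution_kinds()) return(T)
  if (T %in% names(long)) return(unname(long[[T]]))
  stop("unknown distribution '", T, "'; expected one of ",
       paste(c(distribution_kinds(), names(long)), collapse = ", "),
       call. = FALSE)
}

#' Lognormal rank-abundance bin boundaries and bin means
#'
#' The lognormal rank-abundance law assigns genotype `i` the mean of the
#' `i`-th of `M` equal-probability slices of the standard normal. The slice
#' boundaries satisfy the inverse-error-function recursion
#' \deqn{t_{i+1} = \sqrt{2}\,\mathrm{erf}^{-1}\!\big(2/M +
#'   \mathrm{erf}(t_i/\sqrt{2})\big), \quad t_1 = -\infty,\ t_{M+1} = +\infty,}
#' which telescopes to the closed form \eqn{t_i = \Phi^{-1}((i-1)/M)}; the
#' closed form is used here because it carries no accumulated error at large
#' `M`. The bin means are
#' \deqn{m_i = \frac{M}{\sqrt{2\pi}}\left(e^{-t_i^2/2} -
#'   e^{-t_{i+1}^2/2}\right) = M\,(\phi(t_i) - \phi(t_{i+1})),}
#' with the boundary exponentials at \eqn{\pm\infty} evaluating to zero.
#' The means telescope to zero (`sum(m) == 0`) and are antisymmetric,
#' `m[i] == -m[M + 1 - i]`.
#'
#' @param M integer richness (number of genotypes), `M >= 1`.
#' @return A list of class `"lognormal_bins"` with components `M`, `t`
#'   (length `M + 1`, strictly increasing, `t[1] = -Inf`,
#'   `t[M + 1] = Inf`) and `m` (length `M` bin means).
#' @export
#' @examples
#' b <- lognormal_bin_means(2)
#' b$m  # +/- 2/sqrt(2*pi)
lognormal_bin_means <- function(M) {
  M <- check_count(M, "M")
  t <- stats::qnorm(seq.int(0L, M) / M)
  m <- M * (stats::dnorm(t[seq_len(M)]) - stats::dnorm(t[seq_len(M) + 1L]))
  structure(list(M = M, t = t, m = m), class = "lognormal_bins")
}

#' Ranked relative abundances under a candidate distribution
#'
#' Computes the relative abundance `f[i]` of the genotype of abundance rank
#' `i` (rank 1 = most abundant) for a community of `M` genotypes under one
#' of the four candidate laws with shape parameter `d`:
#' \deqn{\mathrm{power law:}\ f_i \propto i^{-d} \qquad
#'       \mathrm{exponential:}\ f_i \propto e^{-i d}}
#' \deqn{\mathrm{logarithmic:}\ f_i \propto (\log(i+1))^{-d} \qquad
#'       \mathrm{lognormal:}\ f_i \propto e^{m_i d}}
#' with the lognormal bin means \eqn{m_i} from [lognormal_bin_means()].
#' All laws are evaluated as log-weights with max-subtraction before
#' exponentiation, so large `d * M` cannot overflow, and the result is
#' sorted non-increasing (the raw lognormal weights increase with bin
#' index). The logarithmic law is base-invariant: any logarithm base
#' cancels in the normalisation.
#'
#' @param M integer richness, `M >= 1`.
#' @param T distribution code or long name, see [distribution_kinds()].
#' @param d shape parameter, `d >= 0`. `d = 0` gives the uniform community
#'   for every law.
#' @return Numeric vector of length `M`: positive, non-increasing, summing
#'   to 1.
#' @export
#' @examples
#' rank_abundances(5, "pl", 0)          # uniform
#' rank_abundances(3, "exp", 1)         # ~ (0.665, 0.245, 0.090)
#' max(rank_abundances(300, "exp", 0.03)) * 100  # f_max ~ 2.956 %
rank_abundances <- function(M, T, d) {
  M <- check_count(M, "M")
  T <- match_distribution(T)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("d must be a single non-negative number", call. = FALSE)
  i <- seq_len(M)
  lw <- switch(T,
    pl  = -d * log(i),
    exp = -d * i,
    log = -d * log(log(i + 1)),
    lgn = d * lognormal_bin_means(M)$m)
  lw <- lw - max(lw)
  f <- exp(lw)
  f <- f / sum(f)
  sort(f, decreasing = TRUE)
}

#' Community evenness (normalised Shannon entropy)
#'
#' \deqn{\mathrm{evenness} = \frac{-\sum_i f_i \ln f_i}{\ln M}}
#' Evenness is 1 when all genotypes are equally abundant and approaches 0
#' as the community becomes dominated by few genotypes. For `M = 1` the
#' ratio is 0/0; the single-genotype community is trivially even and the
#' conventional value 1 is returned (with a warning so the degenerate case
#' is visible in diagnostics).
#'
#' @param f relative-abundance vector (positive, sums to 1).
#' @return Evenness in (0, 1].
#' @export
#' @examples
#' evenness(rank_abundances(1000, "log", 0.9))  # 0.995
evenness <- function(f) {
  check_abundances(f)
  if (length(f) == 1L) {
    warning("evenness of a single-genotype community is undefined (0/0); ",
            "returning 1 by convention", call. = FALSE)
    return(1)
  }
  shannon_entropy(f) / log(length(f))
}

#' Relative abundance of the dominant genotype
#'
#' @param f relative-abundance vector.
#' @return `100 * max(f)`, the dominant genotype's share in percent.
#' @export
#' @examples
#' dominant_abundance(rank_abundances(5000, "lgn", 2.5))  # ~ 11.85 %
dominant_abundance <- function(f) {
  check_abundances(f)
  100 * max(f)
}

# x log x with the x -> 0 limit; abundances so extreme that they
# underflow to 0 in double precision contribute no entropy.
shannon_entropy <- function(f) {
  pos <- f > 0
  -sum(f[pos] * log(f[pos]))
}

check_abundances <- function(f) {
  if (!is.numeric(f) || length(f) == 0L)
    stop("f must be a non-empty numeric abundance vector", call. = FALSE)
  if (any(!is.finite(f)) || any(f < 0))
    stop("all abundances must be finite and >= 0", call. = FALSE)
  if (max(f) <= 0)
    stop("abundances cannot be all zero", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-8)
    stop("abundances must sum to 1", call. = FALSE)
  invisible(f)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      abs(x - round(x)) > 1e-8)
    stop(name, " must be a single integer >= 1", call. = FALSE)
  as.integer(round(x))
}
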