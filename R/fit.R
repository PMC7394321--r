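#' Fit the contig-spectrum model to an observed spectrum
#'
#' Jointly estimates viral richness `M`, community-average genome length
#' `L` (bp), the rank-abundance law `T` and its shape `d` by minimising the
#' variance-weighted residual [model_error()] between the observed
#' read-weighted contig spectrum and the extended Lander-Waterman
#' expectation.
#'
#' The cost surface is multimodal, so the search is niched twice: once
#' over the candidate distributions and once over `N_L` overlapping
#' genome-length windows ([length_windows()]). A genetic algorithm
#' ([ga_minimize()]) searches each of the `4 * N_L` discrete subspaces
#' independently (deterministically seeded per subspace), the best of the
#' subspace winners is selected, and the winning solution is then refined
#' by iteratively shrinking and re-searching a subspace centred on it with
#' halved `M` and `L` steps, down to unit steps (`d` stays on its 0.01
#' grid). Refinement never increases the residual.
#'
#' With `fixed_L` supplied, the fit is the 3-parameter variant: `L` is
#' pinned, niching runs over the distributions only, and `(M, d)` are
#' searched within each.
#'
#' When the fitted community is maximally even (evenness numerically 1,
#' i.e. `d` at 0) the model is not identifiable — any sufficiently even
#' community produces the same spectrum — and a multiple-minima warning is
#' issued.
#'
#' @param obs a [contig_spectrum()].
#' @param spec a [search_spec()].
#' @param fixed_L optional genome length in bp; pins `L` and fits only
#'   `(M, T, d)`.
#' @param q_max optional summation cutoff override; default is the largest
#'   `q` with a non-zero observed count.
#' @param verbose print per-subspace progress.
#' @return An object of class `"virome_fit"`: a list with the estimates
#'   (`M`, `L`, `T`, `d`), the residual `S_min`, derived `evenness` and
#'   `f_max` (percent), the winning niche, per-subspace diagnostics, the
#'   refinement trace, the effective `q_max`, seed, and the inputs.
#' @seealso [search_spec()], [model_error()], [simulate.virome_fit()]
#' @export
#' @examples
#' truth <- model_params(300, 12500, "exp", 0.03)
#' obs <- expected_contig_spectrum(truth, seq_params(), q_max = 60)
#' sp <- search_spec(M_bounds = c(200, 400), L_bounds = c(10000, 15000),
#'                   d_bounds = c(0.01, 0.1), distributions = "exp",
#'                   N_L = 1, ga = list(pop_size = 20, generations = 40))
#' \donttest{
#' fit <- fit_virome(obs, sp)
#' coef(fit)
#' }
fit_virome <- function(obs, spec = search_spec(), fixed_L = NULL,
                       q_max = NULL, verbose = FALSE) {
  stopifnot(inherits(obs, "contig_spectrum"), inherits(spec, "search_spec"))
  if (all(obs$C == 0))
    stop("all-zero contig spectrum carries no information", call. = FALSE)
  if (is.null(q_max)) q_max <- max(which(obs$C > 0))
  q_max <- min(q_max, length(obs$C))

  fixed <- !is.null(fixed_L)
  if (fixed) {
    if (fixed_L < spec$L_bounds[1] || fixed_L > spec$L_bounds[2])
      stop("fixed_L must lie within the L bounds", call. = FALSE)
    windows <- data.frame(j = 1L, start = fixed_L, end = fixed_L)
    W_L <- 0
  } else {
    windows <- length_windows(spec$L_bounds[1], spec$L_bounds[2], spec$N_L)
    W_L <- windows$end[1] - windows$start[1]
  }
  M_vals <- grid_axis(spec$M_bounds[1], spec$M_bounds[2], spec$M_step,
                      integer = TRUE)
  d_vals <- grid_axis(spec$d_bounds[1], spec$d_bounds[2], spec$d_step)
  L_step <- if (fixed) 1 else max(1, spec$L_step_frac * W_L)

  dist_order <- distribution_kinds()
  subspace_best <- list()
  costs <- list()
  for (T in spec$distributions) {
    cost <- make_cost(obs, T, q_max)
    costs[[T]] <- cost
    t_idx <- match(T, dist_order)
    for (j in windows$j) {
      L_vals <- if (fixed) fixed_L else
        grid_axis(windows$start[j], windows$end[j], L_step)
      sub <- make_subspace(T, M_vals, L_vals, d_vals)
      res <- ga_minimize(cost, sub, spec$ga,
                         seed = child_seed(spec$seed, t_idx, j))
      subspace_best[[paste(T, j, sep = ":")]] <-
        list(T = T, j = j, M = res$M, L = res$L, d = res$d, S = res$S,
             evals = res$evals)
      if (verbose)
        message(sprintf("  niche %s window %2d: S = %.4g at (M=%d, L=%g, d=%.2f)",
                        T, j, res$S, res$M, res$L, res$d))
    }
  }

  diag_tab <- do.call(rbind, lapply(subspace_best, function(b)
    data.frame(T = b$T, window = b$j, M = b$M, L = b$L, d = b$d, S = b$S,
               evals = b$evals)))
  rownames(diag_tab) <- NULL
  # global winner: smallest S, then smaller M, then smaller L, then the
  # fixed distribution order pl < exp < log < lgn
  ord <- order(diag_tab$S, diag_tab$M, diag_tab$L,
               match(diag_tab$T, dist_order))
  win <- diag_tab[ord[1L], ]

  sol <- list(M = win$M, L = win$L, d = win$d, S = win$S)
  trace <- NULL
  if (spec$refine$enabled) {
    steps <- list(M = spec$M_step, L = if (fixed) 1 else L_step)
    ref_spec <- spec
    if (fixed) ref_spec$L_bounds <- c(fixed_L, fixed_L)
    sol <- refine_solution(sol, costs[[win$T]], ref_spec, steps,
                           seed = child_seed(spec$seed, 997L, win$window))
    trace <- sol$trace
  }

  f_hat <- rank_abundances(sol$M, win$T, sol$d)
  even <- if (sol$M == 1) 1 else shannon_entropy(f_hat) / log(sol$M)
  fit <- structure(list(
    M = as.integer(sol$M), L = as.numeric(sol$L), T = win$T,
    d = round(sol$d, 8), S_min = sol$S,
    evenness = even, f_max = 100 * max(f_hat),
    niche = list(T = win$T, window = win$window),
    fixed_L = if (fixed) fixed_L else NULL,
    q_max = q_max, seed = spec$seed,
    subspaces = diag_tab, refine_trace = trace,
    obs = obs, spec = spec, call = match.call()),
    class = "virome_fit")
  if (even >= 1 - 1e-9)
    warning("fitted community is maximally even (evenness = 1): the model ",
            "has multiple equivalent minima and the reported (M, d) is not ",
            "unique", call. = FALSE)
  if (sol$M == 1L)
    warning("single-genotype fit: evenness is 1 by convention", call. = FALSE)
  fit
}

#' Fixed-genome-length fit
#'
#' Convenience wrapper around [fit_virome()] with `L` pinned: estimates
#' only richness, the abundance law and its shape, as database-assisted
#' estimators do when an external genome-length estimate is available.
#'
#' @inheritParams fit_virome
#' @param L genome length in bp at which to pin the model.
#' @return A `"virome_fit"` object, see [fit_virome()].
#' @export
fit_virome_fixed_length <- function(obs, L, spec = search_spec(),
                                    q_max = NULL, verbose = FALSE) {
  fit_virome(obs, spec, fixed_L = L, q_max = q_max, verbose = verbose)
}

#' @export
print.virome_fit <- function(x, ...) {
  cat("Contig-spectrum model fit\n")
  cat(sprintf("  richness M        : %d\n", x$M))
  cat(sprintf("  genome length L   : %s bp%s\n", format(x$L, big.mark = ","),
              if (!is.null(x$fixed_L)) " (fixed)" else ""))
  cat(sprintf("  abundance law T   : %s\n", x$T))
  cat(sprintf("  shape d           : %.3f\n", x$d))
  cat(sprintf("  residual S_min    : %.4g\n", x$S_min))
  cat(sprintf("  evenness          : %.3f   f_max: %.3f%%\n",
              x$evenness, x$f_max))
  invisible(x)
}

#' @export
summary.virome_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.virome_fit")
}

#' @export
print.summary.virome_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat(sprintf("  winning niche     : T = %s, L window %d\n",
              f$niche$T, f$niche$window))
  cat(sprintf("  fitted over q_max = %d bins, seed %d\n", f$q_max, f$seed))
  top <- f$subspaces[order(f$subspaces$S), , drop = FALSE]
  cat("  best subspaces:\n")
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.virome_fit <- function(object, ...) {
  structure(c(M = object$M, L = object$L, d = object$d),
            distribution = object$T)
}

#' Expected spectrum at the fitted parameters
#'
#' @param object a `"virome_fit"`.
#' @param ... unused.
#' @return Expected contig counts `E_q / q` for `q = 1..q_max`.
#' @export
fitted.virome_fit <- function(object, ...) {
  es <- expected_spectrum(model_params(object$M, object$L, object$T,
                                       object$d),
                          object$obs$seq, object$q_max)
  es$C
}

#' Residuals of a contig-spectrum fit
#'
#' @param object a `"virome_fit"`.
#' @param type `"pearson"` (default) for `(O_q - E_q) / V_q`, the terms
#'   whose squares sum to `S_min`, or `"response"` for `O_q - E_q` on the
#'   read-weighted scale.
#' @param ... unused.
#' @return Numeric vector of length `q_max`.
#' @export
residuals.virome_fit <- function(object, type = c("pearson", "response"),
                                 ...) {
  type <- match.arg(type)
  es <- expected_spectrum(model_params(object$M, object$L, object$T,
                                       object$d),
                          object$obs$seq, object$q_max)
  resp <- object$obs$O[seq_len(object$q_max)] - es$E
  if (type == "response") return(resp)
  v <- sqrt(pmax(es$V2, 1e-12))
  resp / v
}

#' Predict the expected contig spectrum from a fit
#'
#' @param object a `"virome_fit"`.
#' @param q_max number of contig-size bins to predict (default: the fitted
#'   range).
#' @param type `"contigs"` for expected contig counts `E_q / q`,
#'   `"reads"` for the read-weighted `E_q`.
#' @param ... unused.
#' @return Numeric vector of length `q_max`.
#' @export
predict.virome_fit <- function(object, q_max = object$q_max,
                               type = c("contigs", "reads"), ...) {
  type <- match.arg(type)
  es <- expected_spectrum(model_params(object$M, object$L, object$T,
                                       object$d),
                          object$obs$seq, q_max)
  if (type == "contigs") es$C else es$E
}

#' Simulate contig spectra from a fitted model
#'
#' Draws Monte-Carlo contig spectra from the fitted `(M, L, T, d)` under
#' the observed sequencing parameters, using the same read-placement
#' mechanism as [montecarlo_contig_spectrum()].
#'
#' @param object a `"virome_fit"`.
#' @param nsim number of spectra.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` [contig_spectrum()] objects.
#' @export
simulate.virome_fit <- function(object, nsim = 1, seed = NULL, ...) {
  pop <- simulate_population(object$M, object$T, object$d, object$L, v = 0,
                             seed = seed, r = object$obs$seq$r)
  lapply(seq_len(nsim), function(k)
    montecarlo_contig_spectrum(pop, object$obs$seq,
                               seed = if (is.null(seed)) NULL
                                      else seed + k))
}

#' Plot observed vs fitted contig spectrum
#'
#' @param x a `"virome_fit"`.
#' @param log plot counts on a log scale (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.virome_fit <- function(x, log = TRUE, ...) {
  q <- seq_len(x$q_max)
  obs <- x$obs$C[q]
  exp_c <- fitted(x)
  ylim <- range(c(obs[obs > 0], exp_c[exp_c > 0]))
  graphics::plot(q, pmax(obs, if (log) ylim[1] / 10 else 0),
                 log = if (log) "y" else "",
                 pch = 16, xlab = "contig size q (reads)",
                 ylab = expression(C[q]), ylim = ylim, ...)
  graphics::lines(q, pmax(exp_c, if (log) ylim[1] / 10 else 0),
                  col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("observed", "fitted"),
                   pch = c(16, NA), lty = c(NA, 1),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
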