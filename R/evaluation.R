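#' Signed relative estimation error
#'
#' `100 * (est - truth) / truth`, the signed percent convention used in
#' the benchmark summaries (an underestimate is negative).
#'
#' @param est estimated value(s).
#' @param truth true value (non-zero).
#' @return Signed percent error, vectorised over `est`.
#' @export
#' @examples
#' relative_error(8547, 10000)  # -14.53
relative_error <- function(est, truth) {
  if (!is.numeric(truth) || length(truth) != 1L || truth == 0)
    stop("truth must be a single non-zero number", call. = FALSE)
  100 * (est - truth) / truth
}

#' Coefficient of variation of the RMSE
#'
#' Root-mean-squared error of a set of estimates of one true value,
#' normalised by that true value:
#' \deqn{\mathrm{CV(RMSE)} = \frac{\sqrt{\mathrm{mean}((est - truth)^2)}}
#'   {truth}.}
#' The normalisation uses the true value (constant within a benchmark
#' cell) rather than the mean estimate; this interpretation is recorded in
#' the attribute `normalization`.
#'
#' @param estimates numeric vector of estimates (length >= 1).
#' @param truth true value, `> 0`.
#' @return Non-negative scalar; 0 iff every estimate equals the truth.
#' @export
#' @examples
#' cv_rmse(c(280, 320), 300)  # 0.0667
cv_rmse <- function(estimates, truth) {
  if (!is.numeric(estimates) || length(estimates) == 0L)
    stop("at least one estimate is required", call. = FALSE)
  if (!is.numeric(truth) || length(truth) != 1L || truth <= 0)
    stop("truth must be a single positive number", call. = FALSE)
  structure(sqrt(mean((estimates - truth)^2)) / truth,
            normalization = "true value")
}

#' Benchmark record
#'
#' Pairs one ground-truth parameter set with the fit obtained on a
#' spectrum generated from it.
#'
#' @param truth list with `M0`, `L0`, `T0`, `d0` and optionally `v`
#'   (e.g. `$truth` of a [simulate_population()]).
#' @param fit a `"virome_fit"`.
#' @param scenario scenario tag (e.g. `1` or `2`).
#' @param seed the per-run seed.
#' @return A list of class `"benchmark_record"`.
#' @export
benchmark_record <- function(truth, fit, scenario, seed = NA_integer_) {
  stopifnot(inherits(fit, "virome_fit"))
  if (is.null(truth$M0) || is.null(truth$L0))
    stop("truth must carry M0 and L0", call. = FALSE)
  structure(list(truth = truth, fit = fit, scenario = scenario,
                 seed = seed),
            class = "benchmark_record")
}

#' Summarise benchmark records into a recovery table
#'
#' Groups records by `(scenario, v, M0)` and reports, for richness and
#' genome length, the mean signed relative error, the mean absolute
#' relative error and the CV(RMSE). Row order is stable
#' (scenario, v, M0 ascending) and independent of input order; the result
#' is a plain data.frame, directly serialisable to TSV with
#' [utils::write.table()].
#'
#' @param records list of [benchmark_record()] objects.
#' @return A data.frame, one row per group, with columns `scenario`, `v`,
#'   `M0`, `n`, `M_err_pct`, `M_abs_err_pct`, `M_cv_rmse`, `L_err_pct`,
#'   `L_abs_err_pct`, `L_cv_rmse`, `T_match_rate`.
#' @export
benchmark_summary <- function(records) {
  if (length(records) == 0L)
    stop("no benchmark records supplied", call. = FALSE)
  ok <- vapply(records, inherits, logical(1), "benchmark_record")
  if (!all(ok)) stop("all elements must be benchmark_record objects",
                     call. = FALSE)
  scen <- vapply(records, function(x)
    if (is.null(x$scenario) || is.na(x$scenario[1])) NA_character_
    else as.character(x$scenario), character(1))
  if (anyNA(scen) && length(unique(scen)) > 1L)
    stop("records mix scenarios without tags", call. = FALSE)
  rows <- do.call(rbind, lapply(records, function(x) data.frame(
    scenario = as.character(x$scenario),
    v = if (is.null(x$truth$v)) 0 else x$truth$v,
    M0 = x$truth$M0, L0 = x$truth$L0,
    M = x$fit$M, L = x$fit$L,
    T_match = identical(match_distribution(x$truth$T0), x$fit$T))))
  groups <- split(rows, list(rows$scenario, rows$v, rows$M0), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    Me <- relative_error(g$M, g$M0[1])
    Le <- mapply(function(l, l0) relative_error(l, l0), g$L, g$L0)
    data.frame(scenario = g$scenario[1], v = g$v[1], M0 = g$M0[1],
               n = nrow(g),
               M_err_pct = mean(Me), M_abs_err_pct = mean(abs(Me)),
               M_cv_rmse = as.numeric(cv_rmse(g$M, g$M0[1])),
               L_err_pct = mean(Le), L_abs_err_pct = mean(abs(Le)),
               L_cv_rmse = sqrt(mean(((g$L - g$L0) / g$L0)^2)),
               T_match_rate = mean(g$T_match))
  }))
  out <- out[order(out$scenario, out$v, out$M0), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cv_rmse_normalization") <- "true value"
  out
}
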