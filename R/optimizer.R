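#' Overlapping genome-length search windows
#'
#' The genome-length axis `[L_LB, L_UB]` is split into `N_L` windows of
#' constant width
#' \deqn{W_L = \frac{2 (L_{UB} - L_{LB})}{N_L + 1}}
#' with half-window stride, so each consecutive pair overlaps by exactly
#' `W_L / 2` and values on one window's boundary fall in the middle of the
#' next (boundary points are never seen only at a search-space edge). The
#' first window starts at `L_LB` and the last ends exactly at `L_UB`.
#'
#' @param L_LB,L_UB lower/upper genome-length bounds in bp.
#' @param N_L number of windows, `>= 1`.
#' @return A data.frame with columns `j`, `start`, `end`.
#' @export
#' @examples
#' length_windows(10000, 310000, 29)  # W_L = 20000, starts 10k, 20k, ...
length_windows <- function(L_LB, L_UB, N_L) {
  if (!is.numeric(L_LB) || !is.numeric(L_UB) || L_UB <= L_LB)
    stop("need L_UB > L_LB", call. = FALSE)
  N_L <- check_count(N_L, "N_L")
  W_L <- 2 * (L_UB - L_LB) / (N_L + 1)
  start <- L_LB + (seq_len(N_L) - 1) * W_L / 2
  data.frame(j = seq_len(N_L), start = start, end = start + W_L)
}

#' Search specification for the spectrum fit
#'
#' Bounds, discretisation steps, niching and genetic-algorithm settings
#' for [fit_virome()]. Defaults follow the benchmark configuration used
#' throughout the package: `M` in `[1, 15000]`, `L` in `[10000, 310000]`
#' bp, `d` in `[0.01, 5]`, all four candidate distributions and `N_L = 29`
#' length windows.
#'
#' Discretisation: `d` is stepped at `d_step` (default 0.01, also the
#' refinement floor for `d`); `M` at `M_step`, defaulting to
#' `10^(ceiling(log10(M_UB)) - 2)` when `log10(M_UB) > 2` and 1 otherwise;
#' `L` at `L_step_frac * W_L` (default fraction 0.025) inside each window.
#' Refinement halves the `M` and `L` steps down to 1.
#'
#' @param M_bounds integer richness bounds `c(lower, upper)`.
#' @param L_bounds genome-length bounds in bp.
#' @param d_bounds shape-parameter bounds.
#' @param distributions candidate distribution codes (subset of
#'   [distribution_kinds()]).
#' @param N_L number of overlapping length windows.
#' @param d_step,M_step,L_step_frac discretisation controls (see Details);
#'   `M_step = NULL` applies the default rule.
#' @param ga list of genetic-algorithm settings: `pop_size`,
#'   `generations`, `crossover_rate`, `mutation_rate`, `tournament_k`,
#'   `patience` (generations without improvement before early stop),
#'   `immigrant_frac` (fraction of the population replaced by random
#'   individuals each generation), `sweep_L` / `sweep_M` (number of L and
#'   M anchors of the deterministic seed sweep; 0 disables it) and
#'   `exhaust_cap` (grids at or below this many points are enumerated
#'   exactly instead of searched stochastically).
#' @param refine list: `enabled`, `max_rounds`, `tol` (minimum cost
#'   improvement once steps reach their floor), `d_halfwidth` (refinement
#'   window half-width in `d_step` units).
#' @param seed master seed; per-subspace child seeds are derived from it
#'   by (distribution index, window index) so subspace searches are
#'   order-independent.
#' @return A list of class `"search_spec"`.
#' @export
search_spec <- function(M_bounds = c(1, 15000),
                        L_bounds = c(10000, 310000),
                        d_bounds = c(0.01, 5),
                        distributions = distribution_kinds(),
                        N_L = 29,
                        d_step = 0.01,
                        M_step = NULL,
                        L_step_frac = 0.025,
                        ga = list(),
                        refine = list(),
                        seed = 1L) {
  stopifnot(length(M_bounds) == 2L, length(L_bounds) == 2L,
            length(d_bounds) == 2L)
  if (M_bounds[1] < 1 || M_bounds[2] <= M_bounds[1])
    stop("need 1 <= M lower bound < upper bound", call. = FALSE)
  if (L_bounds[2] <= L_bounds[1] || L_bounds[1] <= 0)
    stop("need 0 < L lower bound < upper bound", call. = FALSE)
  if (d_bounds[1] < 0 || d_bounds[2] <= d_bounds[1])
    stop("need 0 <= d lower bound < upper bound", call. = FALSE)
  distributions <- vapply(distributions, match_distribution, character(1),
                          USE.NAMES = FALSE)
  if (length(distributions) == 0L)
    stop("at least one candidate distribution is required", call. = FALSE)
  N_L <- check_count(N_L, "N_L")
  if (is.null(M_step)) {
    M_step <- if (log10(M_bounds[2]) > 2)
      10^(ceiling(log10(M_bounds[2])) - 2) else 1
  }
  if (d_step <= 0 || M_step < 1 || L_step_frac <= 0)
    stop("steps must be positive (M_step >= 1)", call. = FALSE)
  ga <- utils::modifyList(ga_defaults(), ga)
  ref_def <- list(enabled = TRUE, max_rounds = 60L, tol = 1e-9,
                  d_halfwidth = 3L)
  refine <- utils::modifyList(ref_def, refine)
  structure(list(M_bounds = round(M_bounds), L_bounds = as.numeric(L_bounds),
                 d_bounds = as.numeric(d_bounds),
                 distributions = distributions, N_L = N_L,
                 d_step = d_step, M_step = M_step,
                 L_step_frac = L_step_frac,
                 ga = ga, refine = refine, seed = as.integer(seed)),
            class = "search_spec")
}

ga_defaults <- function() {
  list(pop_size = 50L, generations = 200L, crossover_rate = 0.8,
       mutation_rate = 0.1, tournament_k = 3L, patience = 30L,
       immigrant_frac = 0.15, sweep_L = 5L, sweep_M = 2L,
       exhaust_cap = 5000L)
}

# Discrete axis LB..UB in steps of `step`, always containing UB.
grid_axis <- function(lb, ub, step, integer = FALSE) {
  v <- seq(lb, ub, by = step)
  if (v[length(v)] < ub - 1e-9) v <- c(v, ub)
  if (integer) v <- unique(pmax(1, round(v)))
  v
}

# A subspace is the discrete grid searched by one GA run.
make_subspace <- function(T, M_vals, L_vals, d_vals) {
  if (length(M_vals) == 0L || length(L_vals) == 0L || length(d_vals) == 0L)
    stop("empty discrete grid", call. = FALSE)
  list(T = T, M = M_vals, L = L_vals, d = d_vals,
       size = length(M_vals) * length(L_vals) * length(d_vals))
}

# Cost closure for one candidate distribution: caches abundance vectors by
# (M, d) and lognormal bin means by M, and sums the variance-weighted
# residual against the observed read-weighted spectrum O[1..q_max].
make_cost <- function(obs, T, q_max) {
  O <- obs$O[seq_len(q_max)]
  seq <- obs$seq
  f_cache <- new.env(parent = emptyenv())
  m_cache <- new.env(parent = emptyenv())
  get_f <- function(M, d) {
    key <- paste0(M, "|", d)
    f <- f_cache[[key]]
    if (!is.null(f)) return(f)
    if (T == "lgn") {
      mk <- as.character(M)
      m <- m_cache[[mk]]
      if (is.null(m)) {
        m <- lognormal_bin_means(M)$m
        m_cache[[mk]] <- m
      }
      lw <- d * m
      lw <- lw - max(lw)
      f <- exp(lw)
      f <- sort(f / sum(f), decreasing = TRUE)
    } else {
      f <- rank_abundances(M, T, d)
    }
    if (length(ls(f_cache)) > 256L)
      rm(list = ls(f_cache), envir = f_cache)
    f_cache[[key]] <- f
    f
  }
  function(M, L, d) {
    f <- get_f(M, d)
    .model_error_cpp(f, seq$R, seq$r, seq$o, L, O, 1e-12)
  }
}

#' Genetic-algorithm minimisation over one discrete subspace
#'
#' Minimises a cost function of `(M, L, d)` over the discrete grid of one
#' subspace with an integer-index-coded genetic algorithm: tournament
#' selection, uniform crossover, per-gene geometric-step mutation, elitism,
#' random immigrants and early stopping after a fixed number of stagnant
#' generations. The initial population is seeded from a deterministic
#' coarse sweep of the shape axis (see the package vignette). Subspaces
#' with at most `exhaust_cap` grid points are scanned exhaustively instead
#' — on such small grids a stochastic search has no advantage over
#' enumeration and the exact discrete optimum is guaranteed. Exact cost
#' ties resolve to the smallest `(M, L, d)` in lexicographic order
#' (parsimony). Deterministic given `seed`; the returned point always lies
#' on the grid.
#'
#' @param cost function `(M, L, d) -> S`.
#' @param subspace list with grid vectors `M`, `L`, `d` (as built
#'   internally by [fit_virome()]; any list with those fields works).
#' @param ga genetic-algorithm settings, see [search_spec()].
#' @param seed integer seed for this run.
#' @return A list `(M, L, d, S, evals)`.
#' @export
ga_minimize <- function(cost, subspace, ga = list(), seed = 1L) {
  ga <- utils::modifyList(ga_defaults(), ga)
  nM <- length(subspace$M); nL <- length(subspace$L); nd <- length(subspace$d)
  if (nM * nL * nd < 1) stop("empty discrete grid", call. = FALSE)
  set.seed(as.integer(seed) %% 2147483647L)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  eval_idx <- function(i) {
    key <- paste(i, collapse = ",")
    s <- cache[[key]]
    if (is.null(s)) {
      s <- cost(subspace$M[i[1]], subspace$L[i[2]], subspace$d[i[3]])
      if (!is.finite(s)) s <- .Machine$double.xmax
      cache[[key]] <- s
      evals <<- evals + 1L
    }
    s
  }
  dims <- c(nM, nL, nd)
  if (prod(dims) <= ga$exhaust_cap) {
    # exhaustive scan in ascending (M, L, d) order; strict improvement
    # keeps the lexicographically smallest point among exact ties
    oM <- order(subspace$M); oL <- order(subspace$L); od <- order(subspace$d)
    best_i <- NULL; best_s <- Inf
    for (a in oM) for (b in oL) for (cc in od) {
      s <- eval_idx(c(a, b, cc))
      if (s < best_s) { best_s <- s; best_i <- c(a, b, cc) }
    }
    return(list(M = subspace$M[best_i[1]], L = subspace$L[best_i[2]],
                d = subspace$d[best_i[3]], S = best_s, evals = evals))
  }
  pop_n <- max(4L, as.integer(ga$pop_size))
  rand_ind <- function() c(sample.int(nM, 1L), sample.int(nL, 1L),
                           sample.int(nd, 1L))
  # stratified initialisation: each axis covered by a permuted even spread
  strat <- function(n) {
    pts <- round(seq(1L, n, length.out = pop_n))
    as.integer(pmin(pmax(sample(pts), 1L), n))
  }
  sm <- strat(nM); sl <- strat(nL); sd2 <- strat(nd)
  pop <- lapply(seq_len(pop_n), function(k) c(sm[k], sl[k], sd2[k]))
  # seed sweep: the shape axis is the least forgiving (narrow attractive
  # columns in d), so score every d value at a few (M, L) anchors and
  # seed the population with the best sweep points
  if (ga$sweep_L > 0L && ga$sweep_M > 0L) {
    iL <- unique(round(seq(1L, nL, length.out = min(nL, ga$sweep_L))))
    iM <- unique(round(seq(nM, max(1L, nM / 2), length.out = min(nM, ga$sweep_M))))
    sweep <- expand.grid(M = iM, L = iL, d = seq_len(nd))
    sw_s <- vapply(seq_len(nrow(sweep)), function(k)
      eval_idx(as.integer(sweep[k, ])), numeric(1))
    # second stage: the most promising d columns (ranked by their best
    # anchor value) are scanned across the full L axis, since attractive
    # basins can be much narrower in L than the anchor spacing
    col_best <- tapply(sw_s, sweep$d, min)
    n_cols <- min(nd, max(8L, ceiling(0.06 * nd)))
    top_d <- as.integer(names(sort(col_best)))[seq_len(n_cols)]
    iM2 <- unique(c(nM, max(1L, round(2 * nM / 3)), max(1L, round(nM / 3))))
    sweep2 <- expand.grid(M = iM2, L = seq_len(nL), d = top_d)
    sw2_s <- vapply(seq_len(nrow(sweep2)), function(k)
      eval_idx(as.integer(sweep2[k, ])), numeric(1))
    all_pts <- rbind(sweep, sweep2)
    all_s <- c(sw_s, sw2_s)
    keep <- order(all_s)[seq_len(min(floor(pop_n / 2), nrow(all_pts)))]
    for (k in seq_along(keep))
      pop[[k]] <- as.integer(all_pts[keep[k], ])
  }
  fit <- vapply(pop, eval_idx, numeric(1))
  best_i <- pop[[which.min(fit)]]
  best_s <- min(fit)
  stagnant <- 0L
  mut_gene <- function(v, n) {
    step <- 1L + stats::rgeom(1L, 0.5)
    v2 <- v + sample(c(-1L, 1L), 1L) * step
    min(max(v2, 1L), n)
  }
  for (gen in seq_len(as.integer(ga$generations))) {
    newpop <- vector("list", pop_n)
    newpop[[1L]] <- best_i                       # elitism
    for (k in 2:pop_n) {
      pick <- function() {
        cand <- sample.int(pop_n, min(ga$tournament_k, pop_n))
        pop[[cand[which.min(fit[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      child <- p1
      if (stats::runif(1) < ga$crossover_rate) {
        take2 <- stats::runif(3) < 0.5
        child[take2] <- p2[take2]
      }
      for (g in 1:3) if (stats::runif(1) < ga$mutation_rate)
        child[g] <- mut_gene(child[g], dims[g])
      newpop[[k]] <- child
    }
    # random immigrants keep the niche search exploratory
    n_imm <- floor(ga$immigrant_frac * pop_n)
    if (n_imm > 0L)
      for (k in seq.int(pop_n - n_imm + 1L, pop_n))
        newpop[[k]] <- rand_ind()
    pop <- newpop
    fit <- vapply(pop, eval_idx, numeric(1))
    cand <- pop[[which.min(fit)]]
    gen_best <- min(fit)
    lex_smaller <- gen_best == best_s &&
      !identical(cand, best_i) &&
      (cand[1] < best_i[1] ||
         (cand[1] == best_i[1] &&
            (cand[2] < best_i[2] ||
               (cand[2] == best_i[2] && cand[3] < best_i[3]))))
    if (gen_best < best_s - 1e-15) {
      best_s <- gen_best
      best_i <- cand
      stagnant <- 0L
    } else {
      if (lex_smaller) best_i <- cand   # parsimony on exact ties
      stagnant <- stagnant + 1L
    }
    if (stagnant >= ga$patience) break
  }
  list(M = subspace$M[best_i[1]], L = subspace$L[best_i[2]],
       d = subspace$d[best_i[3]], S = best_s, evals = evals)
}

#' Exhaustive grid search (test oracle)
#'
#' Enumerates every point of a discrete subspace and returns the exact
#' minimiser. Intended as an independent oracle for small grids; refuses
#' grids larger than `cap`. Ties are broken by smaller cost, then smaller
#' `M`, then smaller `L`, then smaller `d`.
#'
#' @inheritParams ga_minimize
#' @param cap maximum number of grid points the oracle will enumerate.
#' @return A list `(M, L, d, S, evals)`.
#' @export
grid_oracle <- function(cost, subspace, cap = 200000L) {
  n <- length(subspace$M) * length(subspace$L) * length(subspace$d)
  if (n < 1) stop("empty discrete grid", call. = FALSE)
  if (n > cap)
    stop("grid has ", n, " points, above the oracle cap of ", cap,
         call. = FALSE)
  best <- NULL
  best_s <- Inf
  for (M in sort(subspace$M)) for (L in sort(subspace$L))
    for (d in sort(subspace$d)) {
      s <- cost(M, L, d)
      if (is.finite(s) && s < best_s - 0) {
        best_s <- s
        best <- c(M, L, d)
      }
    }
  list(M = best[1], L = best[2], d = best[3], S = best_s, evals = n)
}

# Derive a per-subspace child seed from the master seed and the
# (distribution, window) niche indices; kept below 2^31.
child_seed <- function(seed, t_idx, j) {
  as.integer((as.double(seed) * 48271 + t_idx * 100003 + j * 257) %%
               2147483629)
}

# One refinement pass: shrink a subspace around `centre`, halving the M
# and L steps each round (d stays at its d_step floor), and search it
# exactly (small grids are enumerated; larger ones fall back to the GA).
# Continues until the M and L steps reach 1 and no improvement above
# `tol` remains. Never returns a worse point than `centre`.
refine_solution <- function(centre, cost, spec, steps, seed,
                            enum_cap = 50000L) {
  best <- centre                       # list(M, L, d, S)
  sM <- steps$M; sL <- steps$L; sd_ <- spec$d_step
  trace <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    if (round_i > spec$refine$max_rounds) break
    at_floor <- sM <= 1 && sL <= 1
    sM_new <- max(1, sM / 2)
    sL_new <- max(1, sL / 2)
    # while the M step is coarse the residual can be nearly flat in M
    # (abundance laws saturate once d * M is large), so scan the whole
    # axis as long as that is cheap; localise once the step is fine
    if ((spec$M_bounds[2] - spec$M_bounds[1]) / sM_new <= 64) {
      M_vals <- grid_axis(spec$M_bounds[1], spec$M_bounds[2], sM_new,
                          integer = TRUE)
    } else {
      M_vals <- unique(pmin(pmax(round(best$M + (-4:4) * sM_new), 1),
                            spec$M_bounds[2]))
      M_vals <- M_vals[M_vals >= spec$M_bounds[1]]
    }
    # near the floor the M <-> L valley is diagonal (roughly tens of bp
    # per unit of M), so the L window must be wide enough in unit steps
    # to admit the coupled move; L snaps to integer bp at fine steps
    kL <- if (sL_new <= 1) -32:32 else -4:4
    L_vals <- best$L + kL * sL_new
    if (sL_new <= 2) L_vals <- round(L_vals)
    L_vals <- unique(pmin(pmax(L_vals, spec$L_bounds[1]),
                          spec$L_bounds[2]))
    k <- spec$refine$d_halfwidth
    d_vals <- best$d + (-k:k) * sd_
    d_vals <- round(d_vals / sd_) * sd_
    d_vals <- unique(d_vals[d_vals >= spec$d_bounds[1] - 1e-12 &
                              d_vals <= spec$d_bounds[2] + 1e-12])
    sub <- make_subspace(NA, M_vals, L_vals, d_vals)
    res <- if (sub$size <= enum_cap) grid_oracle(cost, sub, cap = enum_cap)
           else ga_minimize(cost, sub, spec$ga, seed + round_i)
    improved <- res$S < best$S - spec$refine$tol
    if (improved) best <- res[c("M", "L", "d", "S")]
    trace[[round_i]] <- c(round = round_i, step_M = sM_new, step_L = sL_new,
                          M = best$M, L = best$L, d = best$d, S = best$S)
    if (at_floor && !improved) break
    sM <- sM_new; sL <- sL_new
    if (best$S <= 0) break
  }
  best$trace <- do.call(rbind, trace)
  best
}
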