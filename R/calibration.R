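# Calibration pipeline: histogram metrics based on the Bhattacharyya
# coefficient, the biological validity filter over the signal thresholds, the
# mixed nine-parameter search space, a multi-objective Bayesian-optimization
# loop with Gaussian-process surrogates and random-scalarization expected
# improvement, and Pareto-front extraction.

#' Normalized feature histogram
#'
#' Fixed binning per feature: longest-protrusion length (`"llp"`) uses 20-um
#' right-closed bins over (0, 200] with overflow folded into the last bin,
#' preceded by a dedicated bin for exact zeros (checkpoints with no
#' protrusion); protrusion count (`"np"`) uses unit-width integer bins over
#' 0..20 (overflow into 20). Frequencies are normalized to probabilities.
#'
#' @param values Nonnegative observations.
#' @param feature `"llp"` or `"np"`.
#' @return An object of class `migration_histogram`: list with `edges`,
#'   `freq`, `feature`.
#' @export
make_histogram <- function(values, feature = c("llp", "np")) {
  feature <- match.arg(feature)
  if (length(values) == 0) stop("empty data: no values to bin", call. = FALSE)
  if (any(values < 0)) stop("values must be nonnegative", call. = FALSE)
  if (feature == "llp") {
    edges <- c(-20, seq(0, 200, by = 20))
    v <- pmin(values, 200)
    counts <- tabulate(findInterval(v, edges, left.open = TRUE,
                                    rightmost.closed = FALSE),
                       nbins = length(edges) - 1L)
  } else {
    edges <- seq(-0.5, 20.5, by = 1)
    v <- pmin(round(values), 20)
    counts <- tabulate(v + 1L, nbins = 21L)
  }
  structure(list(edges = edges, freq = counts / sum(counts),
                 feature = feature),
            class = "migration_histogram")
}

#' @export
print.migration_histogram <- function(x, ...) {
  cat(sprintf("<migration_histogram %s: %d bins, mass %.6f>\n",
              x$feature, length(x$freq), sum(x$freq)))
  invisible(x)
}

#' Bhattacharyya coefficient of two histograms
#'
#' `BC = sum_i sqrt(p_i q_i)`: 1 for identical distributions, 0 for disjoint
#' supports. The two histograms must share bin edges.
#'
#' @param h1,h2 [make_histogram()] objects.
#' @return Scalar in [0, 1].
#' @export
bhattacharyya <- function(h1, h2) {
  if (length(h1$edges) != length(h2$edges) ||
      any(abs(h1$edges - h2$edges) > 1e-12)) {
    stop("histogram bin edges differ", call. = FALSE)
  }
  min(sum(sqrt(h1$freq * h2$freq)), 1)
}

#' Parametrization of the calibrated model
#'
#' One point of the mixed nine-parameter search space: the protrusion modulus
#' on a log grid `10^i, i = 4..10` Pa; integer signal thresholds in [0, 100];
#' real strain amplitudes `alpha` in [0.01, 0.2] mm and scales `beta` in
#' [0.1, 100]; and the binarization level on the arithmetic grid
#' `12500 + 2000 j, j = 0..100`.
#'
#' @param E_protrusion,s_birth,s_exp,s_ret,alpha_exp,beta_exp,alpha_ret,beta_ret,s_binary
#'   Parameter values; defaults are the calibrated optimum.
#' @return An object of class `parametrization`.
#' @export
parametrization <- function(E_protrusion = 1e7, s_birth = 85, s_exp = 76,
                            s_ret = 0, alpha_exp = 0.14, beta_exp = 100,
                            alpha_ret = 0.05, beta_ret = 54.86,
                            s_binary = 62500) {
  p <- structure(
    list(E_protrusion = E_protrusion, s_birth = as.integer(s_birth),
         s_exp = as.integer(s_exp), s_ret = as.integer(s_ret),
         alpha_exp = alpha_exp, beta_exp = beta_exp, alpha_ret = alpha_ret,
         beta_ret = beta_ret, s_binary = s_binary),
    class = "parametrization"
  )
  check_ranges(p)
  p
}

#' @export
print.parametrization <- function(x, ...) {
  cat("<parametrization>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Calibrated optimum of the migration model
#'
#' @return The selected [parametrization()] (the package default values).
#' @export
calibrated_parametrization <- function() parametrization()

# range check distinct from the biological validity filter
check_ranges <- function(p) {
  i <- log10(p$E_protrusion)
  if (abs(i - round(i)) > 1e-9 || round(i) < 4 || round(i) > 10) {
    stop("E_protrusion must be 10^i Pa, i in 4..10", call. = FALSE)
  }
  for (nm in c("s_birth", "s_exp", "s_ret")) {
    v <- p[[nm]]
    if (v < 0 || v > 100 || v != round(v)) {
      stop(sprintf("%s must be an integer in [0, 100]", nm), call. = FALSE)
    }
  }
  for (nm in c("alpha_exp", "alpha_ret")) {
    v <- p[[nm]]
    if (v < 0.01 || v > 0.2) {
      stop(sprintf("%s must lie in [0.01, 0.2] mm", nm), call. = FALSE)
    }
  }
  for (nm in c("beta_exp", "beta_ret")) {
    v <- p[[nm]]
    if (v < 0.1 || v > 100) {
      stop(sprintf("%s must lie in [0.1, 100]", nm), call. = FALSE)
    }
  }
  j <- (p$s_binary - 12500) / 2000
  if (abs(j - round(j)) > 1e-9 || round(j) < 0 || round(j) > 100) {
    stop("s_binary must be 12500 + 2000j, j in 0..100", call. = FALSE)
  }
  invisible(TRUE)
}

#' Biological validity filter
#'
#' Accepts a parametrization iff `s_ret < s_exp < s_birth`: the signal needed
#' to sprout or reinforce a protrusion cannot be below the signal needed
#' merely to survive. Out-of-range fields raise an error (a range violation,
#' distinct from validity rejection).
#'
#' @param params A [parametrization()] (or plain named list with the nine
#'   fields).
#' @return `TRUE` if biologically valid, `FALSE` otherwise.
#' @export
validity_filter <- function(params) {
  check_ranges(params)
  params$s_ret < params$s_exp && params$s_exp < params$s_birth
}

#' Evaluate a parametrization against target histograms
#'
#' Runs `n_sims` seeded simulations, builds per-seed histograms of the
#' longest-protrusion length and the protrusion count pooled over each run's
#' checkpoints, computes the per-seed Bhattacharyya coefficient against the
#' targets, and averages over seeds (one BC per seed per feature). The same
#' fixed seed set should be used across parametrizations to reduce comparison
#' noise.
#'
#' @param params A valid [parametrization()].
#' @param targets List with elements `llp` and `np`, both
#'   [make_histogram()] objects.
#' @param config Base [migration_config()].
#' @param n_sims Simulations per evaluation (default 20).
#' @param seeds Explicit seed vector (default derived from `master_seed`).
#' @param master_seed Master seed when `seeds` is NULL.
#' @param pool_seeds If TRUE, pool all seeds into one histogram per feature
#'   and compute a single BC (alternative reading; default FALSE).
#' @return List with `BC_llp` and `BC_np`, both in [0, 1].
#' @export
evaluate_parametrization <- function(params, targets, config, n_sims = 20,
                                     seeds = NULL, master_seed = 1L,
                                     pool_seeds = FALSE) {
  if (!validity_filter(params)) {
    stop("invalid parametrization: violates s_ret < s_exp < s_birth",
         call. = FALSE)
  }
  stopifnot(!is.null(targets$llp), !is.null(targets$np))
  if (is.null(seeds)) seeds <- ensemble_seeds(master_seed, n_sims)
  cfg <- apply_parametrization(config, params)
  trajs <- purrr::map(seeds, function(s) run_simulation(cfg, s))
  if (pool_seeds) {
    llp <- unlist(lapply(trajs, function(tr) tr$llp_um))
    np <- unlist(lapply(trajs, function(tr) tr$n_protrusions))
    return(list(BC_llp = bhattacharyya(make_histogram(llp, "llp"),
                                       targets$llp),
                BC_np = bhattacharyya(make_histogram(np, "np"), targets$np)))
  }
  bc <- vapply(trajs, function(tr) {
    c(bhattacharyya(make_histogram(tr$llp_um, "llp"), targets$llp),
      bhattacharyya(make_histogram(tr$n_protrusions, "np"), targets$np))
  }, numeric(2))
  list(BC_llp = mean(bc[1, ]), BC_np = mean(bc[2, ]))
}

# ---- search space -----------------------------------------------------------

#' The mixed nine-parameter search space
#'
#' @return An object of class `param_space` describing each dimension (kind
#'   and grid/range), used by the proposal engine.
#' @export
param_space <- function() {
  structure(list(
    E_protrusion = list(kind = "loggrid", values = 10^(4:10)),
    s_birth = list(kind = "int", lower = 0, upper = 100),
    s_exp = list(kind = "int", lower = 0, upper = 100),
    s_ret = list(kind = "int", lower = 0, upper = 100),
    alpha_exp = list(kind = "real", lower = 0.01, upper = 0.2),
    beta_exp = list(kind = "real", lower = 0.1, upper = 100),
    alpha_ret = list(kind = "real", lower = 0.01, upper = 0.2),
    beta_ret = list(kind = "real", lower = 0.1, upper = 100),
    s_binary = list(kind = "grid", values = 12500 + 2000 * (0:100))
  ), class = "param_space")
}

# map a unit-hypercube row to a parametrization (snapping discrete dims)
.unit_to_params <- function(u, space) {
  vals <- list()
  for (d in seq_along(space)) {
    nm <- names(space)[d]
    dim <- space[[d]]
    vals[[nm]] <- switch(dim$kind,
      loggrid = ,
      grid = dim$values[pmin(floor(u[d] * length(dim$values)) + 1,
                             length(dim$values))],
      int = round(dim$lower + u[d] * (dim$upper - dim$lower)),
      real = dim$lower + u[d] * (dim$upper - dim$lower)
    )
  }
  do.call(parametrization, vals)
}

# normalize a parametrization to the unit hypercube for GP distance
.params_to_unit <- function(p, space) {
  u <- numeric(length(space))
  for (d in seq_along(space)) {
    nm <- names(space)[d]
    dim <- space[[d]]
    u[d] <- switch(dim$kind,
      loggrid = ,
      grid = (match(p[[nm]], dim$values) - 0.5) / length(dim$values),
      int = ,
      real = (p[[nm]] - dim$lower) / (dim$upper - dim$lower)
    )
  }
  u
}

# rejection-sample a validity-passing uniform draw
.random_valid <- function(space, n = 1) {
  out <- vector("list", n)
  got <- 0
  while (got < n) {
    u <- runif(length(space))
    p <- try(.unit_to_params(u, space), silent = TRUE)
    if (!inherits(p, "try-error") && validity_filter(p)) {
      got <- got + 1
      out[[got]] <- p
    }
  }
  if (n == 1) out[[1]] else out
}

# ---- Gaussian-process surrogate --------------------------------------------

# zero-noise-floor GP with constant mean, squared-exponential kernel on the
# unit hypercube; hyperparameters by marginal-likelihood optimization
.gp_fit <- function(X, y) {
  n <- nrow(X)
  mu <- mean(y)
  yc <- y - mu
  D2 <- as.matrix(dist(X))^2
  nll <- function(theta) {
    ell <- exp(theta[1]); sf2 <- exp(theta[2]); sn2 <- exp(theta[3])
    K <- sf2 * exp(-D2 / (2 * ell^2)) + diag(sn2 + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  init <- c(log(0.5), log(max(var(y), 1e-4)), log(1e-3))
  opt <- optim(init, nll, method = "L-BFGS-B",
               lower = c(log(0.05), log(1e-6), log(1e-6)),
               upper = c(log(5), log(10), log(1)))
  ell <- exp(opt$par[1]); sf2 <- exp(opt$par[2]); sn2 <- exp(opt$par[3])
  K <- sf2 * exp(-D2 / (2 * ell^2)) + diag(sn2 + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(X = X, mu = mu, ell = ell, sf2 = sf2, sn2 = sn2, chol = ch,
       alpha = alpha)
}

.gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") -
    2 * Xnew %*% t(gp$X)
  d2[d2 < 0] <- 0
  Ks <- gp$sf2 * exp(-d2 / (2 * gp$ell^2))
  mean <- gp$mu + as.vector(Ks %*% gp$alpha)
  v <- backsolve(gp$chol, forwardsolve(t(gp$chol), t(Ks)))
  var <- pmax(gp$sf2 - colSums(v * v), 1e-12)
  list(mean = mean, var = var)
}

# expected improvement for maximization
.expected_improvement <- function(mean, var, best) {
  s <- sqrt(var)
  z <- (mean - best) / s
  (mean - best) * pnorm(z) + s * dnorm(z)
}

#' Propose the next parametrization to evaluate
#'
#' With fewer than `n_init` history points, draws a Latin-hypercube style
#' space-filling point (validity-filtered). Afterwards, fits independent
#' Gaussian-process surrogates to each metric, draws a random scalarization
#' weight, and maximizes expected improvement of the scalarized objective
#' over a pool of validity-passing candidates. Only valid points are ever
#' proposed.
#'
#' @param history Tibble of past evaluations (columns: the nine parameters
#'   plus `BC_llp`, `BC_np`); may be empty.
#' @param space A [param_space()].
#' @param n_init Space-filling initialization budget (default 10).
#' @param n_candidates Candidate-pool size for the acquisition (default 500).
#' @return A valid [parametrization()].
#' @export
propose_next <- function(history, space = param_space(), n_init = 10,
                         n_candidates = 500) {
  if (is.null(history) || nrow(history) < n_init) {
    # space-filling draw: first validity-passing row of a small LHS design
    U <- lhs::randomLHS(8, length(space))
    for (row in seq_len(nrow(U))) {
      p <- try(.unit_to_params(U[row, ], space), silent = TRUE)
      if (!inherits(p, "try-error") && validity_filter(p)) return(p)
    }
    return(.random_valid(space))
  }
  X <- t(vapply(seq_len(nrow(history)), function(i) {
    .params_to_unit(as.list(history[i, names(space)]), space)
  }, numeric(length(space))))
  w <- runif(1)
  gp1 <- .gp_fit(X, history$BC_llp)
  gp2 <- .gp_fit(X, history$BC_np)
  cands <- .random_valid(space, n_candidates)
  # local refinement pool: Gaussian perturbations of the best incumbents,
  # so expected improvement can be resolved below the random-pool grain
  score <- pmax(history$BC_llp, history$BC_np)
  top <- order(-score)[seq_len(min(5, nrow(history)))]
  for (i in top) {
    u0 <- X[i, ]
    for (r in seq_len(30)) {
      u <- pmin(pmax(u0 + rnorm(length(u0), 0, 0.05), 1e-9), 1 - 1e-9)
      p <- try(.unit_to_params(u, space), silent = TRUE)
      if (!inherits(p, "try-error") && validity_filter(p)) {
        cands[[length(cands) + 1]] <- p
      }
    }
  }
  Xc <- t(vapply(cands, .params_to_unit, numeric(length(space)),
                 space = space))
  p1 <- .gp_predict(gp1, Xc)
  p2 <- .gp_predict(gp2, Xc)
  mean_s <- w * p1$mean + (1 - w) * p2$mean
  var_s <- w^2 * p1$var + (1 - w)^2 * p2$var
  best <- max(w * history$BC_llp + (1 - w) * history$BC_np)
  ei <- .expected_improvement(mean_s, var_s, best)
  cands[[which.max(ei)]]
}

#' Pareto front of a calibration history
#'
#' Returns the subset of points not dominated in `(BC_llp, BC_np)` under
#' maximization of both; ties are kept.
#'
#' @param history Tibble with columns `BC_llp`, `BC_np`.
#' @return Logical vector marking the Pareto-optimal rows.
#' @export
pareto_front <- function(history) {
  n <- nrow(history)
  if (n == 0) return(logical(0))
  a <- history$BC_llp
  b <- history$BC_np
  flag <- logical(n)
  for (i in seq_len(n)) {
    dominated <- any((a >= a[i] & b >= b[i]) & (a > a[i] | b > b[i]))
    flag[i] <- !dominated
  }
  flag
}

#' Run the full calibration loop
#'
#' Alternates proposal (validity-gated Bayesian optimization) and evaluation
#' (seeded simulation ensembles scored by Bhattacharyya coefficients against
#' the targets) for `budget` iterations, then extracts the Pareto front and
#' selects the balanced optimum: the Pareto point maximizing
#' `min(BC_llp, BC_np)`, ties broken by the sum.
#'
#' @param targets List with `llp` and `np` target histograms.
#' @param config Base [migration_config()].
#' @param budget Number of evaluated parametrizations (>= 10).
#' @param n_sims Simulations per evaluation.
#' @param space A [param_space()].
#' @param master_seed Seed controlling both the shared evaluation seed set
#'   and the proposal randomness.
#' @param n_init Space-filling initialization size.
#' @param verbose Print progress.
#' @return An object of class `calibration_history`: list with `history`
#'   (tibble: parameters, metrics, `pareto` flag), `best` (the selected
#'   [parametrization()]), `best_metrics`.
#' @export
run_calibration <- function(targets, config, budget = 300, n_sims = 20,
                            space = param_space(), master_seed = 1L,
                            n_init = 10, verbose = FALSE) {
  stopifnot(budget >= 10)
  eval_seeds <- ensemble_seeds(master_seed, n_sims)
  rows <- vector("list", budget)
  history <- NULL
  for (it in seq_len(budget)) {
    set.seed(as.integer((as.double(master_seed) * 69621 + it * 7919) %%
                          2147483629))
    p <- propose_next(history, space, n_init = n_init)
    m <- evaluate_parametrization(p, targets, config, n_sims = n_sims,
                                  seeds = eval_seeds)
    rows[[it]] <- tibble::as_tibble(c(unclass(p), m))
    history <- dplyr::bind_rows(rows[seq_len(it)])
    if (verbose) {
      message(sprintf("iter %3d: BC_llp = %.3f BC_np = %.3f", it,
                      m$BC_llp, m$BC_np))
    }
  }
  history$pareto <- pareto_front(history)
  front <- history[history$pareto, , drop = FALSE]
  score <- pmin(front$BC_llp, front$BC_np)
  cand <- which(score == max(score))
  if (length(cand) > 1) {
    cand <- cand[which.max(front$BC_llp[cand] + front$BC_np[cand])]
  }
  best_row <- front[cand[1], ]
  best <- do.call(parametrization, as.list(best_row[names(space)]))
  structure(list(history = history, best = best,
                 best_metrics = list(BC_llp = best_row$BC_llp,
                                     BC_np = best_row$BC_np)),
            class = "calibration_history")
}

#' @export
print.calibration_history <- function(x, ...) {
  cat(sprintf("<calibration_history: %d evaluations, %d on the Pareto front>\n",
              nrow(x$history), sum(x$history$pareto)))
  cat(sprintf("balanced optimum: BC_llp = %.3f, BC_np = %.3f\n",
              x$best_metrics$BC_llp, x$best_metrics$BC_np))
  invisible(x)
}

#' @rdname run_calibration
#' @param x A `calibration_history`.
#' @param ... Unused.
#' @export
tidy.calibration_history <- function(x, ...) {
  x$history
}

#' @rdname run_calibration
#' @export
glance.calibration_history <- function(x, ...) {
  tibble::tibble(
    n_evaluations = nrow(x$history),
    n_pareto = sum(x$history$pareto),
    best_BC_llp = x$best_metrics$BC_llp,
    best_BC_np = x$best_metrics$BC_np,
    best_min_metric = min(x$best_metrics$BC_llp, x$best_metrics$BC_np)
  )
}
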