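# Synthetic in-vitro target generator. Raw microscopy quantifications are not
# shipped with the package; instead the generator emulates the published
# summary statistics of migrating fibroblasts in 2 mg/ml collagen: longest
# protrusion length with mean 63.71 um, sd 31.20 um, support (0, 140] um, and
# protrusion counts on 1..14 with mean 7.57, sd 3.27.

#' Specification of the synthetic in-vitro targets
#'
#' The longest-protrusion length is modelled as a truncated normal on
#' `(0, llp_max]` whose *truncated* moments match the printed mean/sd (the
#' underlying location/scale are solved at construction). The protrusion
#' count is a maximum-entropy discrete distribution on `np_range` matching
#' the printed mean/sd.
#'
#' @param llp_mean,llp_sd Target moments of the longest-protrusion length
#'   (micrometres).
#' @param llp_max Upper truncation (micrometres).
#' @param np_mean,np_sd Target moments of the protrusion count.
#' @param np_range Integer support of the count distribution.
#' @param n Sample size used when generating histograms.
#' @return An object of class `target_spec`.
#' @export
synthetic_target_spec <- function(llp_mean = 63.71, llp_sd = 31.20,
                                  llp_max = 140, np_mean = 7.57,
                                  np_sd = 3.27, np_range = 1:14,
                                  n = 1e5) {
  stopifnot(llp_mean > 0, llp_sd >= 0, llp_max > llp_mean, n >= 100)
  tn <- if (llp_sd == 0) {
    list(mu = llp_mean, sigma = 0)   # degenerate: point mass at the mean
  } else {
    .solve_truncnorm(llp_mean, llp_sd, 0, llp_max)
  }
  np <- .maxent_discrete(np_range, np_mean, np_sd)
  structure(list(llp_mean = llp_mean, llp_sd = llp_sd, llp_max = llp_max,
                 np_mean = np_mean, np_sd = np_sd, np_range = np_range,
                 n = n, llp_mu0 = tn$mu, llp_sigma0 = tn$sigma,
                 np_prob = np),
            class = "target_spec")
}

# moments of N(mu, sigma^2) truncated to (lo, hi]
.truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  m1 <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = m1, sd = sqrt(v))
}

# solve for the underlying (mu, sigma) so truncated moments hit the targets
.solve_truncnorm <- function(mean_t, sd_t, lo, hi) {
  obj <- function(par) {
    m <- .truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (m[["mean"]] - mean_t)^2 + (m[["sd"]] - sd_t)^2
  }
  opt <- optim(c(mean_t, log(sd_t)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  if (opt$value > 1e-6) {
    stop("infeasible truncated-normal moment pair on the stated support",
         call. = FALSE)
  }
  list(mu = opt$par[1], sigma = exp(opt$par[2]))
}

# maximum-entropy distribution on integer support with given mean and sd:
# p_k proportional to exp(l1*k + l2*k^2), Lagrange multipliers solved
.maxent_discrete <- function(support, mean_t, sd_t) {
  m2_t <- sd_t^2 + mean_t^2
  obj <- function(l) {
    w <- exp(l[1] * support + l[2] * support^2)
    p <- w / sum(w)
    m1 <- sum(p * support)
    m2 <- sum(p * support^2)
    (m1 - mean_t)^2 + (m2 - m2_t)^2
  }
  opt <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
  if (opt$value > 1e-6) {
    stop("infeasible moment pair on the stated support", call. = FALSE)
  }
  w <- exp(opt$par[1] * support + opt$par[2] * support^2)
  setNames(w / sum(w), support)
}

#' Sample synthetic longest-protrusion lengths
#'
#' Inverse-CDF sampling from the moment-matched truncated normal.
#'
#' @param spec A [synthetic_target_spec()].
#' @param n Sample size.
#' @return Numeric vector in `(0, llp_max]`.
#' @export
sample_llp <- function(spec, n = spec$n) {
  if (spec$llp_sigma0 == 0) return(rep(spec$llp_mu0, n))
  a <- pnorm((0 - spec$llp_mu0) / spec$llp_sigma0)
  b <- pnorm((spec$llp_max - spec$llp_mu0) / spec$llp_sigma0)
  u <- runif(n, a, b)
  spec$llp_mu0 + spec$llp_sigma0 * qnorm(u)
}

#' Sample synthetic protrusion counts
#'
#' @param spec A [synthetic_target_spec()].
#' @param n Sample size.
#' @return Integer vector in `np_range`.
#' @export
sample_np <- function(spec, n = spec$n) {
  sample(spec$np_range, n, replace = TRUE, prob = spec$np_prob)
}

#' Generate the pair of synthetic in-vitro target histograms
#'
#' @param spec A [synthetic_target_spec()].
#' @param seed Integer seed (deterministic histograms for a fixed seed).
#' @return List with `llp` and `np` [make_histogram()] objects.
#' @export
generate_targets <- function(spec = synthetic_target_spec(), seed = 1L) {
  set.seed(seed)
  list(llp = make_histogram(sample_llp(spec), "llp"),
       np = make_histogram(sample_np(spec), "np"))
}

# ---- I/O --------------------------------------------------------------------

#' Read and write histograms as JSON
#'
#' Round-trips are lossless (doubles serialized at full precision).
#'
#' @param hist A [make_histogram()] object.
#' @param path File path.
#' @return `write_histogram` returns `path` invisibly; `read_histogram`
#'   returns the histogram.
#' @export
write_histogram <- function(hist, path) {
  jsonlite::write_json(
    list(feature = hist$feature, edges = hist$edges, freq = hist$freq),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(edges = as.numeric(x$edges), freq = as.numeric(x$freq),
                 feature = x$feature),
            class = "migration_histogram")
}

#' Read and write target histogram pairs as JSON
#'
#' @param targets List with `llp` and `np` histograms.
#' @param path File path.
#' @export
write_targets <- function(targets, path) {
  jsonlite::write_json(
    lapply(targets, function(h) list(feature = h$feature, edges = h$edges,
                                     freq = h$freq)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(h) {
    structure(list(edges = as.numeric(h$edges), freq = as.numeric(h$freq),
                   feature = h$feature),
              class = "migration_histogram")
  })
}

#' Read and write cell trajectories as CSV
#'
#' @param traj A `cell_trajectory` tibble from [run_simulation()].
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            n_protrusions = readr::col_integer(),
                            .default = readr::col_double()))
  class(traj) <- c("cell_trajectory", class(traj))
  traj
}

#' Write a calibration history as CSV
#'
#' One row per evaluation: the nine parameters, the two metrics and the
#' Pareto flag.
#'
#' @param calib A `calibration_history` from [run_calibration()].
#' @param path File path.
#' @export
write_calibration_csv <- function(calib, path) {
  readr::write_csv(calib$history, path)
  invisible(path)
}

#' Read and write run configurations as YAML
#'
#' Serializes the scalar configuration of a run (field, kinetics rates,
#' grid, thresholds, strain, elasticity, motion, horizon, backend). Missing
#' required fields raise a parse error naming the field.
#'
#' @param config A [migration_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  net <- config$kinetics(0)
  yaml::write_yaml(list(
    field = list(c0_uM = config$field$c0, grad_uM_per_mm = config$field$grad,
                 origin_mm = config$field$origin),
    kinetics = list(k1 = net$k1, k2 = net$k2, k3 = net$k3, k4 = net$k4),
    initial_counts = as.list(config$initial_state$x),
    grid = list(n_alpha = config$grid$n_alpha, n_beta = config$grid$n_beta,
                radius_um = config$grid$radius_um),
    kernel = list(sigma = attr(config$kernel, "sigma"),
                  radius = attr(config$kernel, "radius")),
    thresholds = unclass(config$thresholds),
    strain = unclass(config$strain),
    elasticity = unclass(config$elasticity),
    motion = unclass(config$motion),
    horizon_min = config$horizon_min, dt_min = config$dt_min,
    policy = unclass(config$policy),
    backend = config$backend
  ), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("field", "kinetics", "grid", "thresholds", "strain",
                "elasticity", "motion", "horizon_min", "dt_min")
  for (nm in required) {
    if (is.null(y[[nm]])) {
      stop(sprintf("config parse error: missing required field '%s'", nm),
           call. = FALSE)
    }
  }
  k <- y$kinetics
  counts <- y$initial_counts
  if (is.null(counts)) counts <- list(RTK = 4275, RTKF = 0, PI3K = 75e3,
                                      PI3KA = 0)
  migration_config(
    field = chemoattractant_field(y$field$c0_uM,
                                  unlist(y$field$grad_uM_per_mm),
                                  unlist(y$field$origin_mm)),
    kinetics = function(F_nM) reaction_network(F_nM, k$k1, k$k2, k$k3, k$k4),
    initial_state = reaction_state(counts$RTK, counts$RTKF, counts$PI3K,
                                   counts$PI3KA),
    grid = surface_grid(y$grid$n_alpha, y$grid$n_beta, y$grid$radius_um),
    kernel = smoothing_kernel(y$kernel$sigma, y$kernel$radius),
    thresholds = threshold_set(y$thresholds$s_birth, y$thresholds$s_exp,
                               y$thresholds$s_ret, y$thresholds$s_binary,
                               check = FALSE),
    strain = strain_params(y$strain$alpha_exp, y$strain$beta_exp,
                           y$strain$alpha_ret, y$strain$beta_ret),
    elasticity = elasticity_params(y$elasticity$E_I, y$elasticity$E_M,
                                   y$elasticity$nu_I, y$elasticity$nu_M,
                                   y$elasticity$diameter_um),
    motion = motion_params(y$motion$eta, y$motion$alpha_adhesion),
    horizon_min = y$horizon_min, dt_min = y$dt_min,
    policy = leap_policy(y$policy$eps, y$policy$tau_min, y$policy$tau_max,
                         y$policy$tau_floor),
    backend = if (is.null(y$backend)) "cpp" else y$backend
  )
}

#' Write a run manifest as JSON
#'
#' Records the fully resolved configuration and the seeds of a run for
#' reproducibility.
#'
#' @param config A [migration_config()].
#' @param seeds Integer seed vector used.
#' @param path File path.
#' @param extra Optional named list of extra fields.
#' @export
write_manifest <- function(config, seeds, path, extra = list()) {
  net <- config$kinetics(0)
  manifest <- c(list(
    package = "protrusim",
    version = as.character(utils::packageVersion("protrusim")),
    seeds = seeds,
    field = list(c0_uM = config$field$c0, grad_uM_per_mm = config$field$grad),
    kinetics = list(k1 = net$k1, k2 = net$k2, k3 = net$k3, k4 = net$k4),
    grid = list(n_alpha = config$grid$n_alpha, n_beta = config$grid$n_beta,
                radius_um = config$grid$radius_um),
    thresholds = unclass(config$thresholds),
    strain = unclass(config$strain),
    elasticity = unclass(config$elasticity),
    motion = unclass(config$motion),
    horizon_min = config$horizon_min, dt_min = config$dt_min,
    backend = config$backend
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
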