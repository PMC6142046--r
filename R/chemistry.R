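# Four-reaction RTK/PI3K chemosensing network:
#   R1: RTK + F -> RTKF          (rate k1 * [F] * X_RTK)
#   R2: RTKF    -> RTK + F       (rate k2 * X_RTKF)
#   R3: RTKF + PI3K -> RTKF + PI3K_A   (rate k3 * X_RTKF * X_PI3K)
#   R4: PI3K_A  -> PI3K          (rate k4 * X_PI3KA)
# The chemoattractant F is an external, non-depleted parameter, so RTK + RTKF
# and PI3K + PI3K_A are conserved exactly along every trajectory.

.CHEM_SPECIES <- c("RTK", "RTKF", "PI3K", "PI3KA")

# stoichiometry, species x reactions
.CHEM_NU <- matrix(
  c(-1L, 1L, 0L, 0L,
    1L, -1L, 0L, 0L,
    0L, 0L, -1L, 1L,
    0L, 0L, 1L, -1L),
  nrow = 4L, ncol = 4L,
  dimnames = list(.CHEM_SPECIES, paste0("R", 1:4))
)

#' Chemosensing reaction network
#'
#' Defines the four-reaction receptor/kinase network through which the cell
#' senses the chemoattractant: reversible ligand binding of the receptor
#' tyrosine kinase (RTK \eqn{\rightleftharpoons} RTKF) and RTKF-catalysed
#' activation/spontaneous deactivation of PI3K. The local chemoattractant
#' concentration `F_nM` is treated as an external parameter that the cell does
#' not deplete.
#'
#' Default rate constants are the literature values used by the migration
#' model: `k1` is applied literally as `k1 * [F in nM] * X_RTK` and `k3` as a
#' second-order stochastic constant per RTKF-PI3K molecule pair; both unit
#' interpretations are deliberately exposed here so alternatives can be tested.
#'
#' @param F_nM Chemoattractant concentration at the cell (nM), `>= 0`.
#' @param k1 Binding rate constant (per nM per second).
#' @param k2 Unbinding rate constant (per second).
#' @param k3 PI3K activation rate constant (per RTKF-PI3K pair per second).
#' @param k4 PI3K_A deactivation rate constant (per second).
#' @return An object of class `reaction_network`.
#' @export
#' @examples
#' net <- reaction_network(F_nM = 50)
#' propensities(reaction_state(), net)
reaction_network <- function(F_nM, k1 = 735, k2 = 0.01, k3 = 4e-4, k4 = 1) {
  rates <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(F_nM) || F_nM < 0) {
    stop("F_nM must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, F_nM = F_nM,
         species = .CHEM_SPECIES, nu = .CHEM_NU),
    class = "reaction_network"
  )
}

#' Molecule-count state of the chemosensing network
#'
#' Integer molecule counts of the four species plus the simulation clock.
#' Defaults are the model's initial amounts (4275 receptors, 75e3 PI3K, no
#' bound receptor and no activated kinase).
#'
#' @param RTK,RTKF,PI3K,PI3KA Nonnegative molecule counts.
#' @param t Time (seconds).
#' @return An object of class `reaction_state`.
#' @export
reaction_state <- function(RTK = 4275, RTKF = 0, PI3K = 75e3, PI3KA = 0, t = 0) {
  x <- c(RTK = RTK, RTKF = RTKF, PI3K = PI3K, PI3KA = PI3KA)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("species counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(x = x, t = t), class = "reaction_state")
}

#' @export
format.reaction_state <- function(x, ...) {
  paste0("<reaction_state t=", signif(x$t, 6), "s ",
         paste(names(x$x), x$x, sep = "=", collapse = " "), ">")
}

#' @export
print.reaction_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Tau-leap error-control policy
#'
#' Bundles the leap-condition error parameter with the bounds that clamp the
#' candidate leap: the migration model advances chemistry with a variable step
#' in the range 0.5--1.5 s. Below `tau_floor` the stepper falls back to exact
#' SSA for the interval.
#'
#' @param eps Relative propensity-change bound (dimensionless), default 0.03.
#' @param tau_min,tau_max Clamp bounds for the leap (seconds).
#' @param tau_floor Rejection floor (seconds) below which exact SSA is used.
#' @return An object of class `leap_policy`.
#' @export
leap_policy <- function(eps = 0.03, tau_min = 0.5, tau_max = 1.5,
                        tau_floor = 1e-3) {
  stopifnot(eps > 0, tau_min > 0, tau_min <= tau_max, tau_floor > 0)
  structure(list(eps = eps, tau_min = tau_min, tau_max = tau_max,
                 tau_floor = tau_floor),
            class = "leap_policy")
}

#' Reaction propensities
#'
#' Mass-action propensities (events/s) of the four reactions at the current
#' state: `a1 = k1*[F]*X_RTK`, `a2 = k2*X_RTKF`, `a3 = k3*X_RTKF*X_PI3K`,
#' `a4 = k4*X_PI3KA`.
#'
#' @param state A [reaction_state()].
#' @param net A [reaction_network()].
#' @return Numeric vector of 4 nonnegative propensities.
#' @export
propensities <- function(state, net) {
  x <- state$x
  if (any(x < 0)) stop("negative species count", call. = FALSE)
  a <- c(net$k1 * net$F_nM * x[["RTK"]],
         net$k2 * x[["RTKF"]],
         net$k3 * x[["RTKF"]] * x[["PI3K"]],
         net$k4 * x[["PI3KA"]])
  if (any(!is.finite(a))) stop("non-finite propensity", call. = FALSE)
  a
}

# Shared channel-selection convention (also mirrored in the C++ backend):
# j = first index with cumsum(a) >= u * a0.
.pick_reaction <- function(a, a0, u) {
  target <- u * a0
  acc <- 0
  for (j in seq_along(a)) {
    acc <- acc + a[j]
    if (acc >= target) return(j)
  }
  length(a)
}

#' One exact SSA (Gillespie) step
#'
#' Advances the network by exactly one reaction event: the waiting time is
#' exponential with rate equal to the total propensity and the channel is
#' chosen with probability proportional to its propensity. If the total
#' propensity is zero the state is absorbing and is returned unchanged with
#' `absorbing = TRUE`.
#'
#' @inheritParams propensities
#' @return A list with elements `state` (the next [reaction_state()]), `tau`
#'   (elapsed seconds, `Inf` if absorbing), `reaction` (index 1--4 or `NA`) and
#'   `absorbing` (logical).
#' @export
ssa_step <- function(state, net) {
  a <- propensities(state, net)
  a0 <- sum(a)
  if (a0 <= 0) {
    return(list(state = state, tau = Inf, reaction = NA_integer_,
                absorbing = TRUE))
  }
  tau <- rexp(1) / a0
  j <- .pick_reaction(a, a0, runif(1))
  x <- state$x + .CHEM_NU[, j]
  list(state = structure(list(x = x, t = state$t + tau),
                         class = "reaction_state"),
       tau = tau, reaction = j, absorbing = FALSE)
}

# Exact SSA over a fixed duration; final partial waiting time is discarded
# (memorylessness). Returns state + per-reaction firing counts.
.ssa_advance <- function(x, net, duration) {
  firings <- c(0, 0, 0, 0)
  elapsed <- 0
  k1F <- net$k1 * net$F_nM
  repeat {
    a <- c(k1F * x[1L], net$k2 * x[2L], net$k3 * x[2L] * x[3L], net$k4 * x[4L])
    a0 <- a[1L] + a[2L] + a[3L] + a[4L]
    if (a0 <= 0) break
    dt <- rexp(1) / a0
    if (elapsed + dt > duration) break
    elapsed <- elapsed + dt
    j <- .pick_reaction(a, a0, runif(1))
    x <- x + .CHEM_NU[, j]
    firings[j] <- firings[j] + 1
  }
  list(x = x, firings = firings)
}

#' Select a leap length satisfying the leap condition
#'
#' Bounded relative-change criterion of Cao, Gillespie and Petzold (2006): the
#' candidate leap limits the expected relative change of every reactant
#' species to `eps` (scaled by the species' highest reaction order), and is
#' then clamped into `[tau_min, tau_max]`.
#'
#' @inheritParams propensities
#' @param policy A [leap_policy()].
#' @return List with `tau` (clamped, seconds) and `tau_unclamped`.
#' @export
select_tau <- function(state, net, policy = leap_policy()) {
  a <- propensities(state, net)
  if (sum(a) <= 0) stop("total propensity is zero; no leap defined",
                        call. = FALSE)
  x <- state$x
  # highest order of any reaction each species takes part in as a reactant
  g <- c(RTK = 1, RTKF = 2, PI3K = 2, PI3KA = 1)
  tau <- Inf
  for (i in 1:4) {
    mu <- sum(.CHEM_NU[i, ] * a)
    sig2 <- sum(.CHEM_NU[i, ]^2 * a)
    if (mu == 0 && sig2 == 0) next
    bound <- max(policy$eps * x[i] / g[i], 1)
    if (mu != 0) tau <- min(tau, bound / abs(mu))
    if (sig2 > 0) tau <- min(tau, bound * bound / sig2)
  }
  list(tau = min(max(tau, policy$tau_min), policy$tau_max),
       tau_unclamped = tau)
}

#' One tau-leap step
#'
#' Fires each reaction a Poisson number of times with mean `a_j * tau` and
#' applies the stoichiometry. If any species count would become negative the
#' step is rejected (`rejected = TRUE`) and the state is returned unchanged;
#' callers retry with a halved leap.
#'
#' @inheritParams propensities
#' @param tau Leap length (seconds), `> 0`.
#' @return List with `state`, `firings` (length-4 counts), `rejected`.
#' @export
tau_leap_step <- function(state, net, tau) {
  stopifnot(tau > 0)
  a <- propensities(state, net)
  k <- suppressWarnings(rpois(4, a * tau))
  if (anyNA(k)) {
    # a draw beyond integer range necessarily exceeds the conserved totals,
    # so it is a rejection in either backend
    return(list(state = state, firings = k, rejected = TRUE))
  }
  x <- state$x + as.vector(.CHEM_NU %*% k)
  if (any(x < 0)) {
    return(list(state = state, firings = k, rejected = TRUE))
  }
  list(state = structure(list(x = x, t = state$t + tau),
                         class = "reaction_state"),
       firings = k, rejected = FALSE)
}

#' Advance the network over a fixed interval by tau-leaping
#'
#' Reference (pure R) implementation of the window stepper used inside each
#' mechanical step: repeated leaps with the Cao criterion clamped into the
#' policy range, truncating the final leap so the window tiles exactly;
#' negative-count leaps are rejected and retried with halved tau, and below
#' `tau_floor` the stepper falls back to exact SSA for that short interval.
#' The compiled backend ([chem_window_cpp()]) mirrors this routine
#' call-for-call on R's RNG, so both produce bit-identical trajectories under
#' the same seed.
#'
#' @inheritParams propensities
#' @param duration Interval to advance (seconds), `> 0`.
#' @param policy A [leap_policy()].
#' @return List with `state` (at `t + duration`) and `firings`, the total
#'   per-reaction firing counts over the interval.
#' @export
advance_chemistry <- function(state, net, duration, policy = leap_policy()) {
  stopifnot(duration > 0)
  x <- state$x
  t0 <- state$t
  firings <- c(0, 0, 0, 0)
  remaining <- duration
  k1F <- net$k1 * net$F_nM
  g <- c(1, 2, 2, 1)
  nu <- .CHEM_NU
  while (remaining > 1e-9) {
    a <- c(k1F * x[1L], net$k2 * x[2L], net$k3 * x[2L] * x[3L], net$k4 * x[4L])
    a0 <- a[1L] + a[2L] + a[3L] + a[4L]
    if (a0 <= 0) break  # absorbing: nothing fires for the rest of the window
    # Cao bound, inlined
    tau <- Inf
    for (i in 1:4) {
      mu <- sum(nu[i, ] * a)
      sig2 <- sum(nu[i, ]^2 * a)
      if (mu == 0 && sig2 == 0) next
      bound <- max(policy$eps * x[i] / g[i], 1)
      if (mu != 0) tau <- min(tau, bound / abs(mu))
      if (sig2 > 0) tau <- min(tau, bound * bound / sig2)
    }
    tau <- min(max(tau, policy$tau_min), policy$tau_max, remaining)
    repeat {
      k <- suppressWarnings(rpois(4, a * tau))
      xn <- if (anyNA(k)) -1 else x + as.vector(nu %*% k)
      if (all(xn >= 0)) {
        x <- xn
        firings <- firings + k
        remaining <- remaining - tau
        break
      }
      tau <- tau / 2
      if (tau < policy$tau_floor) {
        # exact stochastic simulation for one floor-length interval
        dt <- min(policy$tau_floor, remaining)
        res <- .ssa_advance(x, net, dt)
        x <- res$x
        firings <- firings + res$firings
        remaining <- remaining - dt
        break
      }
    }
  }
  list(state = structure(list(x = x, t = t0 + duration),
                         class = "reaction_state"),
       firings = firings)
}

#' Deterministic mass-action limit
#'
#' Integrates the mass-action ODE system of the network (the deterministic
#' large-count limit of the stochastic dynamics); used as a cross-checking
#' oracle for the stochastic steppers.
#'
#' @inheritParams propensities
#' @param duration Integration horizon (seconds).
#' @param n_out Number of equally spaced output times.
#' @return A tibble with columns `t_s`, `RTK`, `RTKF`, `PI3K`, `PI3KA`.
#' @export
ode_limit <- function(net, state = reaction_state(), duration, n_out = 101) {
  stopifnot(duration > 0)
  deriv <- function(t, y, parms) {
    a <- c(parms$k1F * y[1], parms$k2 * y[2], parms$k3 * y[2] * y[3],
           parms$k4 * y[4])
    list(as.vector(.CHEM_NU %*% a))
  }
  times <- seq(0, duration, length.out = n_out)
  out <- deSolve::ode(
    y = as.numeric(state$x), times = times, func = deriv,
    parms = list(k1F = net$k1 * net$F_nM, k2 = net$k2, k3 = net$k3,
                 k4 = net$k4),
    method = "lsoda"
  )
  tibble::tibble(
    t_s = out[, 1] + state$t,
    RTK = out[, 2], RTKF = out[, 3], PI3K = out[, 4], PI3KA = out[, 5]
  )
}

#' Closed-form deterministic steady state
#'
#' Fixed point of the mass-action ODE system: the bound-receptor pool
#' equilibrates to `R_tot * k1[F] / (k1[F] + k2)` and the activated kinase to
#' `P_tot * k3*RTKF / (k3*RTKF + k4)`.
#'
#' @inheritParams propensities
#' @param state Initial state (supplies the conserved totals).
#' @return Named numeric vector of the four steady-state counts.
#' @export
chem_steady_state <- function(net, state = reaction_state()) {
  r_tot <- state$x[["RTK"]] + state$x[["RTKF"]]
  p_tot <- state$x[["PI3K"]] + state$x[["PI3KA"]]
  k1F <- net$k1 * net$F_nM
  rtkf <- if (k1F + net$k2 > 0) r_tot * k1F / (k1F + net$k2) else 0
  denom <- net$k3 * rtkf + net$k4
  pi3ka <- if (denom > 0) p_tot * net$k3 * rtkf / denom else 0
  c(RTK = r_tot - rtkf, RTKF = rtkf, PI3K = p_tot - pi3ka, PI3KA = pi3ka)
}

#' Write a chemistry trajectory as CSV
#'
#' @param traj Tibble as returned by [ode_limit()] (columns `t_s`, `RTK`,
#'   `RTKF`, `PI3K`, `PI3KA`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chemistry_csv <- function(traj, path) {
  readr::write_csv(traj, path)
  invisible(path)
}
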