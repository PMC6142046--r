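# Protrusion dynamics: signal-gated birth/reinforcement/retraction/death of
# one-dimensional protrusion bars, with growth increments constrained by the
# surrounding matrix through Eshelby's ellipsoidal-inclusion solution.

#' Signal threshold set
#'
#' The three signal filters gating protrusion dynamics (`s_birth` for the
#' onset of new protrusions, `s_exp` for reinforcement, `s_ret` below which a
#' protrusion dies) plus the binarization level `s_binary` used to locate
#' candidate centroids. Biological validity requires
#' `s_ret < s_exp < s_birth`.
#'
#' @param s_birth,s_exp,s_ret,s_binary Nonnegative signal levels.
#' @param check Validate the threshold ordering (default TRUE).
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(s_birth = 85, s_exp = 76, s_ret = 0,
                          s_binary = 62500, check = TRUE) {
  stopifnot(s_birth >= 0, s_exp >= 0, s_ret >= 0, s_binary >= 0)
  if (check && !(s_ret < s_exp && s_exp < s_birth)) {
    stop("invalid thresholds: require s_ret < s_exp < s_birth", call. = FALSE)
  }
  structure(list(s_birth = s_birth, s_exp = s_exp, s_ret = s_ret,
                 s_binary = s_binary),
            class = "threshold_set")
}

#' Free expansion/retraction strain parameters
#'
#' @param alpha_exp,alpha_ret Saturation amplitudes (mm) of the free length
#'   increment under expansion / retraction.
#' @param beta_exp,beta_ret Half-saturation signal-variation scales
#'   (dimensionless).
#' @return An object of class `strain_params`.
#' @export
strain_params <- function(alpha_exp = 0.14, beta_exp = 100,
                          alpha_ret = 0.05, beta_ret = 54.86) {
  stopifnot(alpha_exp > 0, alpha_ret > 0, beta_exp > 0, beta_ret > 0)
  structure(list(alpha_exp = alpha_exp, beta_exp = beta_exp,
                 alpha_ret = alpha_ret, beta_ret = beta_ret),
            class = "strain_params")
}

#' Elastic parameters of protrusion and matrix
#'
#' @param E_I Protrusion (inclusion) elastic modulus (Pa).
#' @param E_M Matrix (collagen ECM) elastic modulus (Pa); 1e4 Pa for a
#'   2 mg/ml collagen gel.
#' @param nu_I,nu_M Poisson ratios, in `[0, 0.5)`.
#' @param diameter_um Protrusion cross-section diameter (micrometres), sets
#'   the inclusion aspect ratio together with the length.
#' @return An object of class `elasticity_params`.
#' @export
elasticity_params <- function(E_I = 1e7, E_M = 1e4, nu_I = 0.3, nu_M = 0.3,
                              diameter_um = 2) {
  stopifnot(E_I > 0, E_M > 0, nu_I >= 0, nu_I < 0.5, nu_M >= 0, nu_M < 0.5,
            diameter_um > 0)
  structure(list(E_I = E_I, E_M = E_M, nu_I = nu_I, nu_M = nu_M,
                 diameter_um = diameter_um),
            class = "elasticity_params")
}

#' Free (unconstrained) strain from accumulated signal variation
#'
#' Saturating form of the free expansion/retraction deformation: the free
#' length increment is `alpha * ds / (beta + ds)`, bounded by `alpha`, and the
#' scalar strain is that increment divided by the current length. Expansion
#' (`ds >= 0`) uses `(alpha_exp, beta_exp)`; retraction (`ds < 0`) uses
#' `(alpha_ret, beta_ret)` and yields a negative increment. When
#' `beta_ret + ds <= 0` the retraction saturates into full collapse: the
#' increment is clamped to `-length`.
#'
#' @param ds Accumulated signal variation since the last mechanical step
#'   (signed, dimensionless).
#' @param length_um Current protrusion length (micrometres), `> 0`.
#' @param params A [strain_params()].
#' @return List with `eps_f` (scalar strain), `increment_um` (free length
#'   increment) and `mode` (`"exp"` or `"ret"`).
#' @export
free_strain <- function(ds, length_um, params = strain_params()) {
  stopifnot(length_um > 0)
  if (ds >= 0) {
    inc_mm <- params$alpha_exp * ds / (params$beta_exp + ds)
    mode <- "exp"
  } else {
    denom <- params$beta_ret + ds
    if (denom <= 0) {
      # retraction saturates into full collapse
      return(list(eps_f = -1, increment_um = -length_um, mode = "ret"))
    }
    inc_mm <- params$alpha_ret * ds / denom
    mode <- "ret"
  }
  inc_um <- inc_mm * 1000
  if (inc_um < -length_um) inc_um <- -length_um
  list(eps_f = inc_um / length_um, increment_um = inc_um, mode = mode)
}

# ---- Eshelby inclusion mechanics -------------------------------------------

#' Eshelby tensor of a prolate spheroidal inclusion
#'
#' Closed-form Eshelby tensor for a prolate spheroid (semi-axes a = b < c,
#' long axis along the local 3-direction) embedded in an infinite isotropic
#' matrix with Poisson ratio `nu`; the sphere is the `aspect = 1` special
#' case. Returned in 6x6 Voigt form acting on strain vectors
#' `(e11, e22, e33, g23, g13, g12)` with engineering shears.
#'
#' @param aspect Aspect ratio c/a, `>= 1`.
#' @param nu Matrix Poisson ratio, in `[0, 0.5)`.
#' @return A 6x6 matrix (Voigt form of S).
#' @export
eshelby_tensor <- function(aspect, nu = 0.3) {
  if (aspect < 1) stop("prolate convention requires aspect >= 1",
                       call. = FALSE)
  stopifnot(nu >= 0, nu < 0.5)
  t <- aspect
  if (abs(t - 1) < 1e-9) {
    I1 <- I3 <- 4 * pi / 3
    I11 <- I33 <- I13 <- 4 * pi / 5
  } else {
    # dimensionless I-integrals, semi-axes a1 = a2 = 1, a3 = t
    I1 <- 2 * pi * t / (t^2 - 1)^1.5 * (t * sqrt(t^2 - 1) - acosh(t))
    I3 <- 4 * pi - 2 * I1
    I13 <- (I1 - I3) / (t^2 - 1)
    I11 <- (4 * pi - I13) / 4          # from 3*I11 + I12 + I13 = 4*pi, I12 = I11
    I33 <- (4 * pi / t^2 - 2 * I13) / 3
  }
  I2 <- I1
  I12 <- I11
  q <- 8 * pi * (1 - nu)
  m <- 1 - 2 * nu
  S <- matrix(0, 6, 6)
  # normal block: S_iijj = (3/q) a_j^2 I_ij + (m/q) [i==j] ... standard forms
  S[1, 1] <- (3 * I11 + m * I1) / q
  S[2, 2] <- S[1, 1]
  S[3, 3] <- (3 * t^2 * I33 + m * I3) / q
  S[1, 2] <- (I12 - m * I1) / q
  S[2, 1] <- S[1, 2]
  S[1, 3] <- (t^2 * I13 - m * I1) / q
  S[2, 3] <- S[1, 3]
  S[3, 1] <- (I13 - m * I3) / q
  S[3, 2] <- S[3, 1]
  # shear block (engineering shear): entry = 2 * S_ijij
  S2323 <- ((1 + t^2) * I13 / 2 + m * (I1 + I3) / 2) / q
  S1212 <- (I11 + m * I1) / q
  S[4, 4] <- 2 * S2323
  S[5, 5] <- 2 * S2323
  S[6, 6] <- 2 * S1212
  S
}

#' Isotropic stiffness in Voigt form
#'
#' @param E Elastic modulus (Pa).
#' @param nu Poisson ratio.
#' @return 6x6 stiffness matrix (engineering-shear Voigt convention).
#' @export
isotropic_stiffness <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

#' Matrix-constrained strain of an inclusion
#'
#' Eshelby's equivalent-inclusion relation: the strain actually realised by a
#' transforming inclusion with free (stress-free) strain `eps_f` inside an
#' infinite elastic matrix is
#' `eps_c = S [ (C_I - C_M) S + C_M ]^{-1} C_I eps_f`.
#'
#' @param eps_f Free strain, as a Voigt 6-vector (engineering shears) or a
#'   scalar axial strain along the local 3-axis.
#' @param C_I,C_M Inclusion and matrix stiffness (6x6 Voigt), e.g. from
#'   [isotropic_stiffness()].
#' @param S Eshelby tensor from [eshelby_tensor()].
#' @return List with `eps_c` (Voigt 6-vector) and `axial` (the 33 component).
#' @export
constrained_strain <- function(eps_f, C_I, C_M, S) {
  if (length(eps_f) == 1) eps_f <- c(0, 0, eps_f, 0, 0, 0)
  bracket <- (C_I - C_M) %*% S + C_M
  eps_c <- S %*% solve(bracket, C_I %*% eps_f)
  list(eps_c = as.vector(eps_c), axial = eps_c[3])
}

# Axial constrained/free strain ratio for a protrusion of given length: the
# equivalent-inclusion relation is linear in the free strain, so the ratio
# depends only on geometry and moduli.
constrain_factor <- function(length_um, elast) {
  aspect <- max(length_um / elast$diameter_um, 1 + 1e-6)
  S <- eshelby_tensor(aspect, elast$nu_M)
  C_I <- isotropic_stiffness(elast$E_I, elast$nu_I)
  C_M <- isotropic_stiffness(elast$E_M, elast$nu_M)
  constrained_strain(1, C_I, C_M, S)$axial
}

# ---- protrusion bookkeeping -------------------------------------------------

# live protrusion table constructor
empty_protrusions <- function() {
  tibble::tibble(
    id = integer(0), birth_time_min = numeric(0),
    alpha = numeric(0), beta = numeric(0),
    site_i = integer(0), site_j = integer(0),
    ex = numeric(0), ey = numeric(0), ez = numeric(0),
    length_um = numeric(0), alive = logical(0)
  )
}

#' Create a newborn protrusion
#'
#' Direction is the unit vector from the cell centre through the centroid's
#' membrane point; the seed length is the Eshelby-constrained free increment
#' `alpha_exp * ds / (beta_exp + ds)`, so newborns stand on the same
#' mechanical footing as one growth step.
#'
#' @param id Integer identity.
#' @param alpha,beta Centroid coordinates.
#' @param site_i,site_j Centroid site indices.
#' @param ds Accumulated signal variation at the centroid, `> 0`.
#' @param t_min Birth time (minutes).
#' @param params A [strain_params()].
#' @param elast An [elasticity_params()].
#' @return One-row protrusion tibble.
#' @export
birth_protrusion <- function(id, alpha, beta, site_i, site_j, ds, t_min,
                             params = strain_params(),
                             elast = elasticity_params()) {
  stopifnot(ds > 0)
  e <- site_direction(alpha, beta)
  free_um <- params$alpha_exp * ds / (params$beta_exp + ds) * 1000
  len <- free_um * constrain_factor(free_um, elast)
  tibble::new_tibble(list(
    id = as.integer(id), birth_time_min = as.numeric(t_min),
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    site_i = as.integer(site_i), site_j = as.integer(site_j),
    ex = e[1], ey = e[2], ez = e[3],
    length_um = max(len, 1e-9), alive = TRUE
  ), nrow = 1L)
}

#' Classify per-protrusion actions from the signal
#'
#' Applies the threshold filter: a centroid with `s > s_birth`, positive
#' accumulated variation and no live protrusion in its component births a new
#' protrusion; a live protrusion with positive variation reinforces if
#' `s > s_exp` at its centroid (else holds); with negative variation it
#' retracts, or dies outright if `s < s_ret` (no death at equality).
#'
#' @param protrusions Live-protrusion tibble.
#' @param centroids Centroid tibble from [binarize_and_find_centroids()].
#' @param labels Component-label matrix.
#' @param s,ds Signal and net-variation matrices.
#' @param thresholds A [threshold_set()].
#' @return List with `actions` (character vector per live protrusion:
#'   `reinforce`, `hold`, `retract`, `die`) and `births` (subset of
#'   `centroids` eligible for birth).
#' @export
classify_events <- function(protrusions, centroids, labels, s, ds,
                            thresholds) {
  live <- protrusions[protrusions$alive, , drop = FALSE]
  n <- nrow(live)
  na <- nrow(s)
  flat <- function(i, j) (j - 1L) * na + i
  actions <- .classify_actions(live, s, ds, thresholds)
  births <- centroids[0, ]
  if (nrow(centroids) > 0) {
    occupied <- integer(0)
    if (n > 0) {
      occupied <- unique(labels[flat(live$site_i, live$site_j)])
      occupied <- occupied[occupied > 0L]
    }
    for (k in seq_len(nrow(centroids))) {
      p <- flat(centroids$site_i[k], centroids$site_j[k])
      if (s[p] > thresholds$s_birth && ds[p] > 0 &&
          !(centroids$component[k] %in% occupied)) {
        births <- dplyr::bind_rows(births, centroids[k, ])
      }
    }
  }
  list(actions = actions, births = births)
}

#' Update a protrusion length
#'
#' Applies the multiplicative length update `(1 + eps_EXP + eps_RET)`, floored
#' at zero; a result of zero (or the explicit death strain `eps_RET = -1`
#' with no expansion) kills the protrusion.
#'
#' @param length_um Current length (micrometres).
#' @param eps_exp Expansion strain, `>= 0`.
#' @param eps_ret Retraction strain, `<= 0` (or -1 for death).
#' @return List with `length_um` and `alive`.
#' @export
update_length <- function(length_um, eps_exp = 0, eps_ret = 0) {
  new_len <- (1 + eps_exp + eps_ret) * length_um
  if (new_len <= 1e-9) {
    list(length_um = 0, alive = FALSE)
  } else {
    list(length_um = new_len, alive = TRUE)
  }
}

# threshold-filter actions for the live protrusions (shared by both birth
# modes): positive accumulated variation reinforces above s_exp (else holds);
# negative variation retracts, or kills outright when s < s_ret (no death at
# equality)
.classify_actions <- function(live, s, ds, thresholds) {
  n <- nrow(live)
  actions <- character(n)
  na <- nrow(s)
  for (k in seq_len(n)) {
    p <- (live$site_j[k] - 1L) * na + live$site_i[k]
    s_p <- s[p]
    ds_p <- ds[p]
    if (ds_p >= 0) {
      actions[k] <- if (s_p > thresholds$s_exp) "reinforce" else "hold"
    } else if (s_p < thresholds$s_ret) {
      actions[k] <- "die"
    } else {
      actions[k] <- "retract"
    }
  }
  actions
}

# One mechanical update of the protrusion set (internal; orchestrated by the
# simulator). Strains are capped at |eps| <= 1 per step (infinitesimal-strain
# regime). Birth sites are located either as separated signal peaks within
# the binarized mask (default) or as connected-component centroids.
update_protrusions <- function(protrusions, signal, thresholds, params, elast,
                               t_min, next_id,
                               birth_mode = c("peaks", "components"),
                               min_separation = 6) {
  birth_mode <- match.arg(birth_mode)
  na <- nrow(signal$s)
  if (birth_mode == "components") {
    bf <- binarize_and_find_centroids(signal, thresholds$s_binary)
    cls <- classify_events(protrusions, bf$centroids, bf$labels,
                           signal$s, signal$ds, thresholds)
    births <- cls$births
    actions <- cls$actions
  } else {
    peaks <- find_signal_peaks(signal, thresholds$s_binary, min_separation)
    live <- protrusions[protrusions$alive, , drop = FALSE]
    actions <- .classify_actions(live, signal$s, signal$ds, thresholds)
    keep <- logical(nrow(peaks))
    for (k in seq_len(nrow(peaks))) {
      p <- (peaks$site_j[k] - 1L) * na + peaks$site_i[k]
      if (!(signal$s[p] > thresholds$s_birth && signal$ds[p] > 0)) next
      blocked <- FALSE
      if (nrow(live) > 0) {
        da <- abs(live$site_i - peaks$site_i[k])
        da <- pmin(da, na - da)
        db <- abs(live$site_j - peaks$site_j[k])
        blocked <- any(da * da + db * db < min_separation^2)
      }
      keep[k] <- !blocked
    }
    births <- peaks[keep, , drop = FALSE]
  }
  live_idx <- which(protrusions$alive)
  for (k in seq_along(live_idx)) {
    row <- live_idx[k]
    act <- actions[k]
    if (act == "die") {
      protrusions$length_um[row] <- 0
      protrusions$alive[row] <- FALSE
      next
    }
    if (act == "hold") next
    p <- (protrusions$site_j[row] - 1L) * na + protrusions$site_i[row]
    ds_p <- signal$ds[p]
    len <- protrusions$length_um[row]
    fs <- free_strain(ds_p, len, params)
    if (act == "retract" && fs$eps_f <= -1 + 1e-12) {
      # total retraction: the matrix constraint cannot rescue a protrusion
      # whose free configuration has collapsed
      protrusions$length_um[row] <- 0
      protrusions$alive[row] <- FALSE
      next
    }
    eps_f <- max(min(fs$eps_f, 1), -1)
    eps_c <- eps_f * constrain_factor(len, elast)
    upd <- if (act == "reinforce") {
      update_length(len, eps_exp = max(eps_c, 0), eps_ret = 0)
    } else {
      update_length(len, eps_exp = 0, eps_ret = min(eps_c, 0))
    }
    protrusions$length_um[row] <- upd$length_um
    protrusions$alive[row] <- upd$alive
  }
  if (nrow(births) > 0) {
    newborns <- vector("list", nrow(births))
    for (k in seq_len(nrow(births))) {
      b <- births[k, ]
      p <- (b$site_j - 1L) * na + b$site_i
      newborns[[k]] <- birth_protrusion(next_id, b$alpha, b$beta, b$site_i,
                                        b$site_j, signal$ds[p], t_min,
                                        params, elast)
      next_id <- next_id + 1L
    }
    protrusions <- dplyr::bind_rows(c(list(protrusions), newborns))
  }
  list(protrusions = protrusions, next_id = next_id)
}
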