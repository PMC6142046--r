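# Cell-body translocation: the longest (leading) protrusion is the only
# adherent one; its contractile traction is balanced against Stokes drag from
# the fluid component of the matrix, giving a piecewise-constant velocity.

#' Motion parameters
#'
#' @param eta_Pa_s Effective ECM viscosity (Pa s).
#' @param alpha_adhesion_pN_um Adhesion-traction coefficient: contractile
#'   force per unit protrusion length (pN per micrometre).
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(eta_Pa_s = 7.5, alpha_adhesion_pN_um = 1) {
  stopifnot(eta_Pa_s > 0, alpha_adhesion_pN_um >= 0)
  structure(list(eta = eta_Pa_s, alpha_adhesion = alpha_adhesion_pN_um),
            class = "motion_params")
}

#' Leading (longest live) protrusion
#'
#' Ties are broken by earliest birth time, then lowest id.
#'
#' @param protrusions Protrusion tibble.
#' @return One-row tibble (the leader) or `NULL` if none is alive.
#' @export
longest_protrusion <- function(protrusions) {
  live <- protrusions[protrusions$alive & protrusions$length_um > 0, ,
                      drop = FALSE]
  if (nrow(live) == 0) return(NULL)
  ord <- order(-live$length_um, live$birth_time_min, live$id)
  live[ord[1], ]
}

#' Cell velocity from the leading-protrusion force balance
#'
#' Solves `-6 pi r eta v + alpha_adhesion * p_lp = 0`: the velocity is
#' directed along the leading protrusion with magnitude
#' `alpha_adhesion * |p_lp| / (6 pi r eta)`, converted to micrometres per
#' minute. With no live protrusion the velocity is zero.
#'
#' @param leader One-row protrusion tibble (or `NULL`).
#' @param motion A [motion_params()].
#' @param radius_um Cell-body radius (micrometres).
#' @return Velocity 3-vector (micrometres/minute).
#' @export
velocity_from_balance <- function(leader, motion, radius_um) {
  stopifnot(radius_um > 0)
  if (is.null(leader) || leader$length_um <= 0) return(c(0, 0, 0))
  force_N <- motion$alpha_adhesion * leader$length_um * 1e-12   # pN -> N
  drag_coef <- 6 * pi * (radius_um * 1e-6) * motion$eta         # N s / m
  speed_um_min <- force_N / drag_coef * 1e6 * 60                # m/s -> um/min
  speed_um_min * c(leader$ex, leader$ey, leader$ez)
}

#' Advance the cell position by explicit Euler
#'
#' @param position_mm Current position (mm).
#' @param v_um_min Velocity (micrometres/minute).
#' @param dt_min Time step (minutes).
#' @return New position (mm).
#' @export
step_position <- function(position_mm, v_um_min, dt_min = 5) {
  stopifnot(dt_min > 0)
  position_mm + v_um_min * dt_min / 1000
}
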