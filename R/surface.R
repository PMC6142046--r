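# Discretized cell membrane and the PI3K_A persistence signal.
#
# The membrane is represented, as in the underlying migration model, as a
# flattened chart over polar coordinates alpha in [0, 2pi) (periodic) and
# beta in [0, pi]. Fields over the membrane are matrices with dimension
# (n_alpha, n_beta); site (i, j) is centred at alpha_i = (i - 0.5) * 2pi/n_a,
# beta_j = (j - 0.5) * pi/n_b. Convolution is periodic in alpha and reflective
# at the beta poles (implemented exactly via an even extension to a torus).

#' Membrane surface grid
#'
#' @param n_alpha,n_beta Grid resolution; both must be at least 8.
#' @param radius_um Cell radius (micrometres) used to map sites to 3D
#'   membrane points.
#' @return An object of class `surface_grid`.
#' @export
surface_grid <- function(n_alpha = 36, n_beta = 18, radius_um = 10) {
  stopifnot(n_alpha >= 8, n_beta >= 8, radius_um > 0)
  structure(
    list(
      n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
      radius_um = radius_um,
      alpha = (seq_len(n_alpha) - 0.5) * 2 * pi / n_alpha,
      beta = (seq_len(n_beta) - 0.5) * pi / n_beta
    ),
    class = "surface_grid"
  )
}

#' @export
format.surface_grid <- function(x, ...) {
  sprintf("<surface_grid %dx%d, r = %g um>", x$n_alpha, x$n_beta, x$radius_um)
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# 3D membrane points (mm) for every site, given the cell centre (mm).
# Returns an (n_alpha*n_beta) x 3 matrix in site-major (alpha fastest) order.
membrane_points <- function(grid, center_mm = c(0, 0, 0)) {
  r_mm <- grid$radius_um / 1000
  ab <- expand.grid(alpha = grid$alpha, beta = grid$beta)
  cbind(
    center_mm[1] + r_mm * cos(ab$alpha) * sin(ab$beta),
    center_mm[2] + r_mm * sin(ab$alpha) * sin(ab$beta),
    center_mm[3] + r_mm * cos(ab$beta)
  )
}

# unit outward direction of a site
site_direction <- function(alpha, beta) {
  c(cos(alpha) * sin(beta), sin(alpha) * sin(beta), cos(beta))
}

#' Linear chemoattractant field
#'
#' A time-invariant concentration profile: base concentration `c0_uM` at the
#' `origin_mm` plus a constant linear gradient, clamped at zero.
#'
#' @param c0_uM Concentration at the origin (micromolar).
#' @param grad_uM_per_mm Gradient vector (micromolar per millimetre),
#'   length 3 (scalars are taken along x).
#' @param origin_mm Reference point of `c0_uM` (mm).
#' @return An object of class `chemo_field`.
#' @export
chemoattractant_field <- function(c0_uM, grad_uM_per_mm = c(0, 0, 0),
                                  origin_mm = c(0, 0, 0)) {
  stopifnot(c0_uM >= 0)
  if (length(grad_uM_per_mm) == 1) grad_uM_per_mm <- c(grad_uM_per_mm, 0, 0)
  stopifnot(length(grad_uM_per_mm) == 3, length(origin_mm) == 3)
  structure(list(c0 = c0_uM, grad = as.numeric(grad_uM_per_mm),
                 origin = as.numeric(origin_mm)),
            class = "chemo_field")
}

#' Concentration at a point
#'
#' @param field A [chemoattractant_field()].
#' @param point_mm 3D position (mm), or an n x 3 matrix of positions.
#' @return Concentration(s) in micromolar, clamped at zero.
#' @export
concentration_at <- function(field, point_mm) {
  if (is.matrix(point_mm)) {
    d <- sweep(point_mm, 2, field$origin)
    pmax(0, field$c0 + as.vector(d %*% field$grad))
  } else {
    pmax(0, field$c0 + sum(field$grad * (point_mm - field$origin)))
  }
}

#' Per-site membrane concentration profile
#'
#' Evaluates the chemoattractant field at every membrane site of a cell of the
#' grid's radius centred at `center_mm`, converted to nM (x1000).
#'
#' @param field A [chemoattractant_field()].
#' @param center_mm Cell centre (mm).
#' @param grid A [surface_grid()].
#' @return Matrix `(n_alpha, n_beta)` of concentrations (nM).
#' @export
membrane_profile <- function(field, center_mm, grid) {
  conc <- concentration_at(field, membrane_points(grid, center_mm))
  matrix(conc * 1000, grid$n_alpha, grid$n_beta)
}

#' Sample activation sites from per-site weights
#'
#' Draws event sites independently with probability proportional to
#' `weights * area` (the inverse-CDF method over the flattened site list) --
#' the non-homogeneous Poisson allocation of receptor-activation events over
#' the membrane. The chart is treated as metrically flat, so `area` defaults
#' to uniform.
#'
#' @param n_events Number of events to place.
#' @param weights Nonnegative per-site weights (matrix or vector).
#' @param area Optional per-site area weights (defaults to uniform).
#' @return Integer vector of `n_events` flat site indices.
#' @export
sample_activation_sites <- function(n_events, weights, area = NULL) {
  stopifnot(n_events >= 0)
  w <- as.numeric(weights)
  if (!is.null(area)) w <- w * as.numeric(area)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (n_events == 0) return(integer(0))
  tot <- sum(w)
  if (tot <= 0) stop("all-zero weights with n_events > 0", call. = FALSE)
  cdf <- cumsum(w) / tot
  findInterval(runif(n_events), cdf, left.open = TRUE) + 1L
}

# Multinomial per-site allocation (aggregate of the same categorical law);
# used by the simulator where only per-site counts are needed.
allocate_events <- function(n_events, weights) {
  w <- as.numeric(weights)
  tot <- sum(w)
  if (n_events == 0 || tot <= 0) {
    if (n_events > 0) stop("all-zero weights with n_events > 0", call. = FALSE)
    return(numeric(length(w)))
  }
  as.numeric(stats::rmultinom(1, n_events, w / tot))
}

#' Gaussian smoothing kernel
#'
#' Isotropic Gaussian on the flattened (alpha, beta) chart, truncated at
#' `radius` sites and normalized to sum to one. The bandwidth is chosen so the
#' kernel footprint covers roughly the cross-section of one protrusion.
#'
#' @param sigma Bandwidth in grid sites.
#' @param radius Support radius in sites (default `ceiling(3 * sigma)`).
#' @return An object of class `smoothing_kernel`: a `(2r+1) x (2r+1)` matrix
#'   with attributes `sigma` and `radius`.
#' @export
smoothing_kernel <- function(sigma = 2, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  off <- -radius:radius
  k <- outer(off, off, function(di, dj) exp(-(di^2 + dj^2) / (2 * sigma^2)))
  k <- k / sum(k)
  structure(k, sigma = sigma, radius = as.integer(radius),
            class = c("smoothing_kernel", "matrix"))
}

# Build the kernel wrapped onto the (n_alpha x 2*n_beta) even-extension torus,
# centred at index (1,1), for FFT convolution.
.wrapped_kernel <- function(kernel, n_alpha, n_beta2) {
  r <- attr(kernel, "radius")
  if (2 * r + 1 > n_alpha || 2 * r + 1 > n_beta2) {
    stop("kernel support exceeds grid size", call. = FALSE)
  }
  kp <- matrix(0, n_alpha, n_beta2)
  off <- -r:r
  for (a in seq_along(off)) {
    i <- (off[a] %% n_alpha) + 1L
    for (b in seq_along(off)) {
      j <- (off[b] %% n_beta2) + 1L
      kp[i, j] <- kp[i, j] + kernel[a, b]
    }
  }
  kp
}

#' Deposit events and convolve over the membrane
#'
#' Smooths a per-site event-count map with the kernel: circular in alpha and
#' reflective at the beta poles (implemented exactly by an even extension in
#' beta followed by torus FFT convolution). Total mass is conserved: the
#' result sums to the number of deposited events.
#'
#' @param events Matrix `(n_alpha, n_beta)` of per-site event counts (may be
#'   signed, e.g. net variation maps).
#' @param grid A [surface_grid()].
#' @param kernel A [smoothing_kernel()].
#' @return Matrix `(n_alpha, n_beta)`, the smoothed field.
#' @export
deposit_and_convolve <- function(events, grid, kernel) {
  stopifnot(nrow(events) == grid$n_alpha, ncol(events) == grid$n_beta)
  nb2 <- 2L * grid$n_beta
  mp <- cbind(events, events[, grid$n_beta:1, drop = FALSE])
  kp <- .wrapped_kernel(kernel, grid$n_alpha, nb2)
  conv <- Re(fft(fft(mp) * fft(kp), inverse = TRUE)) / (grid$n_alpha * nb2)
  conv[, seq_len(grid$n_beta), drop = FALSE]
}

#' Cumulative membrane signal field
#'
#' Holds the cumulative PI3K_A persistence signal `s` (a monotone sum of
#' smoothed activation deposits) together with the net-variation accumulator
#' `ds` consumed by the mechanical step (smoothed activations minus
#' deactivations since the last protrusion update).
#'
#' @param grid A [surface_grid()].
#' @return An object of class `signal_field`.
#' @export
signal_field <- function(grid) {
  z <- matrix(0, grid$n_alpha, grid$n_beta)
  structure(list(s = z, ds = z, grid = grid), class = "signal_field")
}

#' Accumulate one epoch's increments into the signal field
#'
#' Adds the smoothed activation map `s_t` into the cumulative persistence
#' signal (which is therefore monotone non-decreasing) and the smoothed net
#' variation `ds_t` into the `ds` accumulator.
#'
#' @param signal A [signal_field()].
#' @param s_t Smoothed activation increment map (nonnegative).
#' @param ds_t Smoothed net variation map (defaults to `s_t`).
#' @return The updated [signal_field()].
#' @export
accumulate_signal <- function(signal, s_t, ds_t = s_t) {
  if (!all(dim(s_t) == dim(signal$s)) || !all(dim(ds_t) == dim(signal$s))) {
    stop("grid mismatch between signal field and increment", call. = FALSE)
  }
  signal$s <- signal$s + s_t
  signal$ds <- signal$ds + ds_t
  signal
}

#' Zero the per-window variation accumulator
#'
#' Called after the mechanical step has consumed the accumulated `ds`.
#'
#' @param signal A [signal_field()].
#' @return The updated [signal_field()].
#' @export
reset_ds <- function(signal) {
  signal$ds[] <- 0
  signal
}

# Label 8-connected components of a binary matrix, periodic in the first
# (alpha) dimension. Returns an integer matrix of labels (0 = background).
label_components <- function(b, wrap_alpha = TRUE) {
  na <- nrow(b)
  nb <- ncol(b)
  labels <- matrix(0L, na, nb)
  cur <- 0L
  idx <- which(b)
  if (length(idx) == 0) return(labels)
  stack <- integer(na * nb)
  for (start in idx) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- cur
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      i <- ((p - 1L) %% na) + 1L
      j <- ((p - 1L) %/% na) + 1L
      for (dj in -1L:1L) {
        jj <- j + dj
        if (jj < 1L || jj > nb) next
        for (di in -1L:1L) {
          if (di == 0L && dj == 0L) next
          ii <- i + di
          if (wrap_alpha) {
            if (ii < 1L) ii <- na else if (ii > na) ii <- 1L
          } else if (ii < 1L || ii > na) next
          q <- (jj - 1L) * na + ii
          if (b[q] && labels[q] == 0L) {
            labels[q] <- cur
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
  }
  labels
}

# circular mean of angles (radians)
circular_mean <- function(theta) {
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  if (m < 0) m <- m + 2 * pi
  m
}

#' Binarize the signal and locate candidate protrusion centroids
#'
#' Thresholds the cumulative signal at `s_binary` (sites with `s >= s_binary`
#' become 1), extracts 8-connected components (periodic in alpha) and returns
#' one centroid per component: the mean coordinate over the component's sites
#' on the flattened chart, circular in alpha.
#'
#' @param signal A [signal_field()] (or a plain signal matrix plus `grid`).
#' @param s_binary Threshold level, `>= 0`.
#' @param grid Required if `signal` is a plain matrix.
#' @return List with `centroids` (tibble: `component`, `alpha`, `beta`,
#'   `site_i`, `site_j`, `area` in sites) and `labels` (component-label
#'   matrix).
#' @export
binarize_and_find_centroids <- function(signal, s_binary, grid = NULL) {
  if (inherits(signal, "signal_field")) {
    s <- signal$s
    grid <- signal$grid
  } else {
    s <- signal
    if (is.null(grid)) stop("grid required with a plain matrix", call. = FALSE)
  }
  stopifnot(s_binary >= 0)
  b <- s >= s_binary
  labels <- label_components(b, wrap_alpha = TRUE)
  n_comp <- max(labels)
  if (n_comp == 0) {
    return(list(
      centroids = tibble::tibble(component = integer(0), alpha = numeric(0),
                                 beta = numeric(0), site_i = integer(0),
                                 site_j = integer(0), area = integer(0)),
      labels = labels
    ))
  }
  rows <- vector("list", n_comp)
  for (comp in seq_len(n_comp)) {
    p <- which(labels == comp)
    i <- ((p - 1L) %% grid$n_alpha) + 1L
    j <- ((p - 1L) %/% grid$n_alpha) + 1L
    am <- circular_mean(grid$alpha[i])
    bm <- mean(grid$beta[j])
    si <- (round(am / (2 * pi) * grid$n_alpha - 0.5) %% grid$n_alpha) + 1L
    sj <- min(max(round(bm / pi * grid$n_beta + 0.5), 1L), grid$n_beta)
    rows[[comp]] <- tibble::tibble(component = comp, alpha = am, beta = bm,
                                   site_i = as.integer(si),
                                   site_j = as.integer(sj),
                                   area = length(p))
  }
  list(centroids = dplyr::bind_rows(rows), labels = labels)
}

#' Locate signal peaks within the binarized mask
#'
#' Finds local maxima of the cumulative signal restricted to sites above
#' `s_binary` (8-neighbourhood, periodic in alpha) and thins them greedily by
#' descending signal value so that retained peaks are at least
#' `min_separation` sites apart (chart distance, alpha-wrapped). These are
#' the candidate protrusion centroids used by the simulator: the
#' binarization simplifies the peak search to the super-threshold region.
#'
#' @param signal A [signal_field()] (or plain matrix plus `grid`).
#' @param s_binary Threshold level, `>= 0`.
#' @param min_separation Minimum peak separation in sites.
#' @param grid Required if `signal` is a plain matrix.
#' @return Tibble: `component` (peak rank), `alpha`, `beta`, `site_i`,
#'   `site_j`, `area` (always 1).
#' @export
find_signal_peaks <- function(signal, s_binary, min_separation = 6,
                              grid = NULL) {
  if (inherits(signal, "signal_field")) {
    s <- signal$s
    grid <- signal$grid
  } else {
    s <- signal
    if (is.null(grid)) stop("grid required with a plain matrix", call. = FALSE)
  }
  stopifnot(s_binary >= 0, min_separation >= 1)
  na <- grid$n_alpha
  nb <- grid$n_beta
  cand_i <- integer(0)
  cand_j <- integer(0)
  cand_s <- numeric(0)
  for (j in seq_len(nb)) {
    for (i in seq_len(na)) {
      v <- s[i, j]
      if (v < s_binary) next
      is_peak <- TRUE
      for (dj in -1L:1L) {
        jj <- j + dj
        if (jj < 1L || jj > nb) next
        for (di in -1L:1L) {
          if (di == 0L && dj == 0L) next
          ii <- i + di
          if (ii < 1L) ii <- na else if (ii > na) ii <- 1L
          if (s[ii, jj] > v) {
            is_peak <- FALSE
            break
          }
        }
        if (!is_peak) break
      }
      if (is_peak) {
        cand_i <- c(cand_i, i)
        cand_j <- c(cand_j, j)
        cand_s <- c(cand_s, v)
      }
    }
  }
  if (length(cand_i) == 0) {
    return(tibble::tibble(component = integer(0), alpha = numeric(0),
                          beta = numeric(0), site_i = integer(0),
                          site_j = integer(0), area = integer(0)))
  }
  ord <- order(-cand_s, cand_j, cand_i)
  keep_i <- integer(0)
  keep_j <- integer(0)
  for (k in ord) {
    if (length(keep_i) > 0) {
      da <- abs(keep_i - cand_i[k])
      da <- pmin(da, na - da)
      db <- abs(keep_j - cand_j[k])
      if (any(da * da + db * db < min_separation^2)) next
    }
    keep_i <- c(keep_i, cand_i[k])
    keep_j <- c(keep_j, cand_j[k])
  }
  tibble::tibble(
    component = seq_along(keep_i),
    alpha = grid$alpha[keep_i], beta = grid$beta[keep_j],
    site_i = keep_i, site_j = keep_j, area = 1L
  )
}

#' Write a signal snapshot as a CSV matrix
#'
#' One row per beta index, for debugging.
#'
#' @param signal A [signal_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  m <- t(signal$s)
  df <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(df) <- paste0("alpha_", seq_len(ncol(m)))
  readr::write_csv(df, path)
  invisible(path)
}
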