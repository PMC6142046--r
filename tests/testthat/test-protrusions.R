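test_that("threshold set enforces the biological ordering", {
  expect_s3_class(threshold_set(85, 76, 0, 62500), "threshold_set")
  expect_error(threshold_set(50, 76, 0), "s_ret < s_exp < s_birth")
  expect_error(threshold_set(85, 76, 76), "s_ret < s_exp < s_birth")
})

test_that("free strain has the saturating form with the documented limits", {
  p <- strain_params()   # alpha_exp 0.14 mm, beta_exp 100

  expect_equal(free_strain(0, 50, p)$eps_f, 0)

  # saturation: the free increment approaches alpha_exp as ds grows
  big <- free_strain(1e9, 1e6, p)
  expect_equal(big$increment_um, 140, tolerance = 1e-6)

  # worked case: ds = 100 on a 70-um protrusion gives a 70-um increment
  w <- free_strain(100, 70, p)
  expect_equal(w$increment_um, 70)
  expect_equal(w$eps_f, 1)

  # retraction branch is negative and collapses when beta_ret + ds <= 0
  r <- free_strain(-10, 50, p)
  expect_lt(r$increment_um, 0)
  expect_identical(r$mode, "ret")
  col <- free_strain(-60, 50, p)   # beta_ret = 54.86 < 60
  expect_equal(col$increment_um, -50)
  expect_equal(col$eps_f, -1)
})

test_that("Eshelby tensor: sphere closed form, isotropy, needle limit", {
  nu <- 0.3
  S <- eshelby_tensor(1, nu)
  expect_equal(S[1, 1], (7 - 5 * nu) / (15 * (1 - nu)), tolerance = 1e-12)
  expect_equal(S[1, 1], S[2, 2], tolerance = 1e-12)
  expect_equal(S[1, 1], S[3, 3], tolerance = 1e-12)
  expect_equal(S[1, 2], S[1, 3], tolerance = 1e-12)

  # long-axis component vanishes in the needle limit
  expect_lt(abs(eshelby_tensor(1e4, nu)[3, 3]), 1e-4)

  expect_error(eshelby_tensor(0.5, nu), "aspect")
})

test_that("Eshelby tensor matches the numerical elliptic-integral oracle", {
  for (t in c(1.5, 3, 10)) {
    for (nu in c(0.2, 0.3, 0.45)) {
      delta <- function(s) sqrt((1 + s)^2 * (t^2 + s))
      I1 <- 2 * pi * t * integrate(function(s) 1 / ((1 + s) * delta(s)),
                                   0, Inf, rel.tol = 1e-12)$value
      I3 <- 2 * pi * t * integrate(function(s) 1 / ((t^2 + s) * delta(s)),
                                   0, Inf, rel.tol = 1e-12)$value
      I11 <- 2 * pi * t * integrate(function(s) 1 / ((1 + s)^2 * delta(s)),
                                    0, Inf, rel.tol = 1e-12)$value
      I13 <- 2 * pi * t *
        integrate(function(s) 1 / ((1 + s) * (t^2 + s) * delta(s)),
                  0, Inf, rel.tol = 1e-12)$value
      I33 <- 2 * pi * t * integrate(function(s) 1 / ((t^2 + s)^2 * delta(s)),
                                    0, Inf, rel.tol = 1e-12)$value
      q <- 8 * pi * (1 - nu)
      m <- 1 - 2 * nu
      S <- eshelby_tensor(t, nu)
      expect_equal(S[1, 1], (3 * I11 + m * I1) / q, tolerance = 1e-8)
      expect_equal(S[3, 3], (3 * t^2 * I33 + m * I3) / q, tolerance = 1e-8)
      expect_equal(S[1, 3], (t^2 * I13 - m * I1) / q, tolerance = 1e-8)
      expect_equal(S[3, 1], (I13 - m * I3) / q, tolerance = 1e-8)
      expect_equal(S[4, 4],
                   2 * ((1 + t^2) * I13 / 2 + m * (I1 + I3) / 2) / q,
                   tolerance = 1e-8)
    }
  }
})

test_that("constrained strain: limits and the dense tensor-algebra oracle", {
  S <- eshelby_tensor(3, 0.3)
  C <- isotropic_stiffness(1e6, 0.3)
  eps_f <- c(0.1, -0.05, 0.2, 0.03, 0, -0.01)

  # identical phases: eps_c = S eps_f exactly
  res <- constrained_strain(eps_f, C, C, S)
  expect_equal(res$eps_c, as.vector(S %*% eps_f), tolerance = 1e-12)

  # vanishing matrix stiffness: unconstrained
  soft <- constrained_strain(eps_f, isotropic_stiffness(1e7, 0.3),
                             isotropic_stiffness(1e7 * 1e-8, 0.3), S)
  expect_equal(soft$eps_c, eps_f, tolerance = 1e-4)

  # rigid matrix: fully suppressed
  rigid <- constrained_strain(eps_f, isotropic_stiffness(1e7, 0.3),
                              isotropic_stiffness(1e7 * 1e8, 0.3), S)
  expect_lt(max(abs(rigid$eps_c)), 1e-4)

  # 100 random admissible draws vs the 9x9 first-principles evaluation
  set.seed(8)
  for (i in 1:100) {
    E_I <- 10^runif(1, 4, 8)
    E_M <- 10^runif(1, 3, 7)
    nu_I <- runif(1, 0.05, 0.45)
    nu_M <- runif(1, 0.05, 0.45)
    aspect <- runif(1, 1, 20)
    ef <- runif(6, -0.5, 0.5)
    mine <- constrained_strain(ef, isotropic_stiffness(E_I, nu_I),
                               isotropic_stiffness(E_M, nu_M),
                               eshelby_tensor(aspect, nu_M))
    orc <- oracle_constrained(ef, E_I, nu_I, E_M, nu_M, aspect)
    got <- c(mine$eps_c[1], mine$eps_c[2], mine$eps_c[3],
             2 * orc[2, 3], 2 * orc[1, 3], 2 * orc[1, 2])
    expect_equal(mine$eps_c[1:3], diag(orc), tolerance = 1e-10)
    expect_equal(mine$eps_c[4:6],
                 c(2 * orc[2, 3], 2 * orc[1, 3], 2 * orc[1, 2]),
                 tolerance = 1e-10)
  }
})

test_that("a stiffer matrix shortens the constrained increment monotonically", {
  factors <- vapply(10^(3:7), function(EM) {
    constrain_factor(50, elasticity_params(E_I = 1e7, E_M = EM))
  }, numeric(1))
  expect_true(all(diff(factors) < 0))
  expect_true(all(factors > 0 & factors <= 1))
})

test_that("length update arithmetic, floor and death", {
  expect_equal(update_length(50, 0, 0)$length_um, 50)
  expect_equal(update_length(70, 0.1, 0)$length_um, 77)

  dead <- update_length(50, 0, -1)
  expect_equal(dead$length_um, 0)
  expect_false(dead$alive)

  over <- update_length(50, 0, -1.3)
  expect_equal(over$length_um, 0)
  expect_false(over$alive)
})

test_that("newborn protrusions point outward with mechanically seeded length", {
  p <- birth_protrusion(1, alpha = 0, beta = pi / 2, site_i = 1, site_j = 5,
                        ds = 50, t_min = 10)
  expect_equal(c(p$ex, p$ey, p$ez), c(1, 0, 0), tolerance = 1e-12)
  # seed length = Eshelby-constrained saturating increment
  free_um <- 0.14 * 50 / (100 + 50) * 1000
  expect_equal(p$length_um, free_um * constrain_factor(free_um,
                                                       elasticity_params()),
               tolerance = 1e-9)
  expect_true(p$length_um > 0)

  q <- birth_protrusion(2, alpha = pi, beta = pi / 2, site_i = 10,
                        site_j = 5, ds = 50, t_min = 10)
  expect_equal(p$ex * q$ex + p$ey * q$ey + p$ez * q$ez, -1,
               tolerance = 1e-12)

  expect_error(birth_protrusion(3, 0, pi / 2, 1, 5, ds = 0, t_min = 0))
})

test_that("threshold filter separates birth, reinforcement, retraction, death", {
  grid <- surface_grid(16, 8)
  thr <- threshold_set(s_birth = 85, s_exp = 76, s_ret = 10,
                       s_binary = 50, check = FALSE)
  s <- matrix(100, 16, 8)
  ds <- matrix(5, 16, 8)

  live <- dplyr::bind_rows(
    birth_protrusion(1, grid$alpha[4], grid$beta[4], 4, 4, 20, 0),
    birth_protrusion(2, grid$alpha[12], grid$beta[4], 12, 4, 20, 0)
  )
  # protrusion 2 sits where the signal has dropped below s_ret and ds < 0
  s[12, 4] <- 5
  ds[12, 4] <- -3
  bf <- binarize_and_find_centroids(s, 50, grid)
  cls <- classify_events(live, bf$centroids, bf$labels, s, ds, thr)
  expect_identical(cls$actions, c("reinforce", "die"))

  # hold when variation is nonnegative but s at or below s_exp
  s[4, 4] <- 76
  cls2 <- classify_events(live, bf$centroids, bf$labels, s, ds, thr)
  expect_identical(cls2$actions[1], "hold")

  # retract (not die) when ds < 0 but s still at s_ret: no death at equality
  s[12, 4] <- 10
  cls3 <- classify_events(live, bf$centroids, bf$labels, s, ds, thr)
  expect_identical(cls3$actions[2], "retract")

  # no candidate can be simultaneously a birth and a death site: births
  # require ds > 0, deaths ds < 0
  expect_true(all(cls$births$component %in% bf$centroids$component))
})

test_that("update cycle: births get fresh ids and the dead stay dead", {
  grid <- surface_grid(16, 8)
  sig <- signal_field(grid)
  s <- matrix(0, 16, 8)
  s[4, 4] <- 100
  sig <- accumulate_signal(sig, s)
  thr <- threshold_set(85, 76, 0, 90, check = FALSE)

  prot <- empty_protrusions()
  up1 <- update_protrusions(prot, sig, thr, strain_params(),
                            elasticity_params(), 5, 1L,
                            birth_mode = "peaks", min_separation = 2)
  expect_identical(sum(up1$protrusions$alive), 1L)
  expect_identical(up1$protrusions$id, 1L)

  # kill it via total signal collapse at its site, then re-birth elsewhere
  sig2 <- sig
  sig2$ds[4, 4] <- -1000
  sig2$s[4, 4] <- 100
  up2 <- update_protrusions(up1$protrusions, sig2, thr, strain_params(),
                            elasticity_params(), 10, up1$next_id,
                            birth_mode = "peaks", min_separation = 2)
  expect_false(up2$protrusions$alive[1])

  sig3 <- sig2
  sig3$ds[4, 4] <- 10
  up3 <- update_protrusions(up2$protrusions, sig3, thr, strain_params(),
                            elasticity_params(), 15, up2$next_id,
                            birth_mode = "peaks", min_separation = 2)
  born <- up3$protrusions[up3$protrusions$alive, ]
  expect_identical(nrow(born), 1L)
  expect_gt(born$id, 1L)              # a new identity, not a resurrection
  expect_false(up3$protrusions$alive[1])
})
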