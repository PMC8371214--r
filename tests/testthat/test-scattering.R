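test_that("Debye sum reproduces closed forms for two beads", {
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  cv <- debye_curve(two, Q = c(0, pi), bin_width = 0)
  expect_equal(cv$I[1], 4)                       # (sum f)^2
  expect_equal(cv$I[2], 2, tolerance = 1e-12)    # 2(1 + sin(pi)/pi)
})

test_that("bead sphere tracks the analytic sphere form factor", {
  P <- lattice_sphere(3, 0.37)
  expect_gte(nrow(P), 2000)
  Q <- seq(0.01, 4 / 3, length.out = 60)        # up to QR = 4
  cs <- debye_curve(P, Q, bin_width = 0.01)
  x <- Q * 3
  ff <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  expect_lt(max(abs(cs$I / cs$I[1] / (ff / ff[1]) - 1)), 0.02)
})

test_that("orientational-grid intensity converges to the Debye sum", {
  set.seed(3)
  M <- matrix(rnorm(600, sd = 2), 200, 3)
  Q <- seq(0, 1.5, length.out = 25)
  ref <- debye_curve(M, Q, bin_width = 0)
  grid <- orientational_grid_curve(M, Q, n_orientations = 1000)
  expect_lt(max(abs(grid$I / ref$I - 1)), 0.005)

  # isotropy: a rigid rotation barely changes the grid average
  R <- rotation_matrix(c(1, 1, 0), 1.1)
  grid_rot <- orientational_grid_curve(M %*% t(R), Q, n_orientations = 1000)
  expect_lt(max(abs(grid_rot$I / grid$I - 1)), 0.005)

  # error shrinks on average as orientations double
  errs <- vapply(c(125, 250, 500, 1000), function(n)
    mean(abs(orientational_grid_curve(M, Q, n)$I / ref$I - 1)), 0)
  expect_lt(errs[4], errs[1])

  # single bead: flat curve f^2
  one <- orientational_grid_curve(matrix(0, 1, 3), Q, n_orientations = 1)
  expect_equal(one$I, rep(1, length(Q)))
})

test_that("I(Q) is nonnegative with its maximum at zero angle", {
  set.seed(9)
  for (k in 1:5) {
    M <- matrix(rnorm(90, sd = 3), 30, 3)
    cv <- debye_curve(M, seq(0, 2, length.out = 80), bin_width = 0)
    expect_true(all(cv$I >= 0))
    expect_equal(which.max(cv$I), 1L)
  }
})

test_that("Guinier fit is exact on an exact Guinier curve", {
  Q <- seq(0.05, 0.5, by = 0.005)
  cv <- scattering_curve(Q, 7 * exp(-(Q * 2.3)^2 / 3))
  gf <- guinier_fit(cv, c(0.10, 0.30))
  expect_equal(gf$rg, 2.3, tolerance = 1e-10)
  expect_equal(gf$I0, 7, tolerance = 1e-10)
  expect_equal(gf$qrg_limits, c(0.10, 0.30) * 2.3, tolerance = 1e-9)
})

test_that("Guinier fit on a bead sphere recovers the coordinate R_G", {
  P <- lattice_sphere(3, 0.37)
  rg0 <- sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))  # direct moment
  expect_equal(rg0, sqrt(3 / 5) * 3, tolerance = 0.01)
  cs <- debye_curve(P, seq(0.01, 0.6, length.out = 80), bin_width = 0.01)
  gf <- guinier_fit(cs, c(0.01, 1.0 / rg0))
  expect_equal(gf$rg, rg0, tolerance = 0.02)
})

test_that("Guinier preconditions and failure modes are explicit", {
  Q <- seq(0.5, 1, by = 0.01)
  cv <- scattering_curve(Q, exp(-Q^2))
  expect_error(guinier_fit(cv, c(0.10, 0.22)), "fewer than 3")
  # increasing curve: slope positive, flagged not NaN
  up <- scattering_curve(Q, exp(+Q^2))
  gf <- guinier_fit(up, c(0.5, 1))
  expect_false(gf$valid)
  expect_true(is.na(gf$rg))
})

test_that("cross-sectional fits recover exact and rod-like R_XS", {
  # exact synthetic ln(IQ) line with R_XS = 1.41
  Q <- seq(0.2, 1.2, by = 0.01)
  I <- exp(-1.41^2 * Q^2 / 2) / Q
  cx <- cross_section_fits(scattering_curve(Q, I),
                           list(c(0.22, 0.28), c(0.5, 1.1)))
  expect_equal(cx$rxs1, 1.41, tolerance = 1e-6)
  expect_equal(cx$rxs2, 1.41, tolerance = 1e-6)

  # uniform rod, length 30 radius 1: R_XS -> R/sqrt(2) in the outer window
  gxy <- seq(-1, 1, by = 0.18)
  disk <- as.matrix(expand.grid(gxy, gxy))
  disk <- disk[rowSums(disk^2) <= 1, ]
  rod <- do.call(rbind, lapply(seq(-15, 15, by = 0.3), function(z)
    cbind(disk[, 1], disk[, 2], z)))
  rc <- debye_curve(rod, seq(0.3, 1.4, by = 0.01), bin_width = 0.01)
  cx2 <- cross_section_fits(rc, list(c(0.35, 0.6), c(0.7, 1.2)))
  expect_equal(cx2$rxs2, 1 / sqrt(2), tolerance = 0.05)

  expect_error(cross_section_fits(rc, list(c(0.3, 0.6), c(0.5, 1.1))),
               "disjoint")
})

test_that("dimensionless Kratky of a Guinier curve peaks at (sqrt(3), 3/e)", {
  Q <- seq(1e-3, 3, length.out = 4000)
  cv <- scattering_curve(Q, 5 * exp(-Q^2 / 3))  # R_G = 1
  kk <- kratky_dimensionless(cv, rg = 1, I0 = 5)
  expect_equal(kk$peak_x, sqrt(3), tolerance = 1e-3)
  expect_equal(kk$peak_y, 3 / exp(1), tolerance = 1e-4)

  # scale invariance
  kk2 <- kratky_dimensionless(scattering_curve(Q, 10 * exp(-Q^2 / 3)),
                              rg = 1, I0 = 10)
  expect_equal(kk2$y, kk$y)
})

test_that("three-body models show a single Kratky peak near QRG ~ 2", {
  truth <- cached_igg3_truth()
  cv <- debye_curve(truth$model, default_qgrid("xray"))
  kk <- kratky_dimensionless(cv, rg = truth$true_rg, I0 = cv$I[1])
  # one dominant maximum; no resolved second peak above 20% prominence
  pk <- analyze_pr(pr_curve(kk$x, kk$y, Dmax = max(kk$x)),
                   min_prominence = 0.2, smooth_window = 1)
  expect_identical(nrow(pk$peaks), 1L)
})
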