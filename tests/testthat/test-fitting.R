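test_that("preprocessing produces the standard uniform grids", {
  truth <- cached_igg3_truth()
  cur <- simulate_curve(truth, noise_spec("xray", seed = 9))
  pp <- preprocess_curve(cur, n_points = 825, qmax = 1.5)
  expect_length(pp$Q, 825)
  expect_equal(pp$Q[1], 0)
  expect_equal(pp$Q[825], 1.5)
  expect_true(is.finite(pp$I[1]))

  sans <- simulate_curve(truth, noise_spec("neutron", seed = 9))
  pps <- preprocess_curve(sans, n_points = 146, qmax = 1.5)
  expect_length(pps$Q, 146)

  # idempotence on an already-uniform curve
  again <- preprocess_curve(pp, n_points = 825, qmax = 1.5)
  expect_equal(again$I, pp$I, tolerance = 1e-12)

  # extrapolation fills Q below the first measured point via Guinier
  trunc <- scattering_curve(cur$Q[cur$Q >= 0.08], cur$I[cur$Q >= 0.08])
  ppt <- preprocess_curve(trunc, n_points = 825, qmax = 1.5)
  expect_true(all(is.finite(ppt$I)))
  expect_true(all(diff(ppt$I[ppt$Q < 0.08]) < 0))  # Guinier decay to I(0)

  expect_error(preprocess_curve(cur, n_points = 100, qmax = 5),
               "exceeds the measured")
})

test_that("R-factor and scale factor match hand-computable cases", {
  e <- scattering_curve(1:3, c(10, 8, 6))
  m <- scattering_curve(1:3, c(5, 4, 2))
  rf <- rfactor(e, m)
  expect_equal(rf$eta, 2, tolerance = 1e-5)
  expect_equal(rf$rfactor, 100 * 2 / 24, tolerance = 1e-4)

  # oracle: exhaustive eta grid scan
  etas <- seq(0.5, 5, by = 1e-4)
  obj <- vapply(etas, function(k) sum(abs(e$I - k * m$I)), 0)
  expect_equal(rf$eta, etas[which.min(obj)], tolerance = 1e-3)

  # self-fit and pure scaling
  self <- rfactor(e, e)
  expect_equal(self$rfactor, 0, tolerance = 1e-8)
  expect_equal(self$eta, 1, tolerance = 1e-5)
  twice <- rfactor(e, scattering_curve(1:3, c(5, 4, 3)))
  expect_equal(twice$eta, 2, tolerance = 1e-5)
  expect_equal(twice$rfactor, 0, tolerance = 1e-8)

  expect_error(rfactor(e, scattering_curve(c(1, 2, 4), c(5, 4, 2))),
               "different Q grids")
})

test_that("R-factor is invariant to positive rescaling of the model", {
  set.seed(21)
  Q <- seq(0, 1.5, length.out = 60)
  for (k in 1:5) {
    Ie <- abs(rnorm(60, 10, 2))
    Im <- abs(rnorm(60, 5, 1))
    base <- rfactor(scattering_curve(Q, Ie), scattering_curve(Q, Im))
    scl <- rfactor(scattering_curve(Q, Ie),
                   scattering_curve(Q, Im * runif(1, 0.1, 20)))
    expect_equal(scl$rfactor, base$rfactor, tolerance = 1e-3)
  }
})

test_that("the flat SANS background behaves as a 2% I(0) offset", {
  Q <- seq(0, 1.5, length.out = 50)
  m <- scattering_curve(Q, rep(5, 50), modality = "neutron")
  out <- apply_sans_background(m, I0_expt = 100)
  expect_equal(out$I, rep(5 + 2, 50))
  expect_equal(apply_sans_background(m, 0)$I, m$I)
  expect_error(apply_sans_background(scattering_curve(Q, rep(5, 50)), 100),
               "neutron")

  # fitting a background-carrying synthetic curve improves after correction
  truth <- cached_igg3_truth()
  base <- debye_curve(truth$model, Q, modality = "neutron")
  expt <- scattering_curve(Q, base$I + 0.02 * base$I[1], sigma = NULL,
                           modality = "neutron")
  r_plain <- rfactor(expt, base)
  r_corr <- rfactor(expt, apply_sans_background(base, expt$I[1]))
  expect_lt(r_corr$rfactor, r_plain$rfactor)
})

test_that("library screening ranks the generating model first", {
  truth <- cached_igg3_truth()
  lib <- cached_small_library()
  # noiseless self-curve: the start model (id 0) must win with R ~ 0
  cv <- debye_curve(truth$model, default_qgrid("neutron"), bin_width = 0.02)
  scr <- screen_library(lib, cv, n_select = 10)
  expect_identical(scr$records$model_id[1], 0L)
  expect_lt(scr$records$rfactor[1], 0.05)
  expect_true(all(diff(scr$records$rfactor) >= 0))

  # n_select = 0: empty top set, ranking retained
  scr0 <- screen_library(lib, cv, n_select = 0)
  expect_length(scr0$top_ids, 0)
  expect_identical(nrow(scr0$records), length(lib$coords))

  # n_select beyond the library warns and selects all
  expect_warning(scr_all <- screen_library(lib, cv,
                                           n_select = length(lib$coords) + 5),
                 "exceeds")
  expect_identical(sum(scr_all$records$selected), length(lib$coords))
})

test_that("ranking is stable under a consistent flat background", {
  truth <- cached_igg3_truth()
  lib <- cached_small_library()
  Q <- default_qgrid("neutron")
  base <- debye_curve(truth$model, Q, bin_width = 0.02)
  plain <- scattering_curve(Q, base$I, modality = "xray")
  withbg <- scattering_curve(Q, base$I + 0.02 * base$I[1],
                             modality = "neutron")
  scr1 <- screen_library(lib, plain, n_select = 20)
  scr2 <- screen_library(lib, withbg, n_select = 20)
  expect_identical(scr1$records$model_id[1:10], scr2$records$model_id[1:10])
})
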