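test_that("glycan stripping removes exactly the GLYCAN sites", {
  truth <- cached_igg3_truth()
  m <- truth$model
  stripped <- strip_glycans(m)
  expect_identical(nrow(stripped$sites), nrow(m$sites) - 22L)
  expect_false(any(stripped$sites$region == "GLYCAN"))
  # ordering of the surviving sites preserved
  expect_identical(stripped$sites$resno,
                   m$sites$resno[m$sites$region != "GLYCAN"])
  # idempotent on glycan-free models
  expect_identical(strip_glycans(stripped)$sites, stripped$sites)

  # matched deglycosylated construction has the same site count
  deg <- make_ground_truth("igg3_like", seed = truth$seed,
                           glycans = FALSE)$model
  expect_identical(nrow(stripped$sites), nrow(deg$sites))
  expect_lt(max(abs(model_coords(stripped) - model_coords(deg))), 1e-12)
})

test_that("region superposition recovers known rigid transforms", {
  m <- tiny_model()
  # self-superposition: identity
  self <- superpose(list(m), m, region = "FC")
  expect_lt(self$rmsd[1], 1e-9)
  expect_lt(max(abs(model_coords(self$models[[1]]) - model_coords(m))),
            1e-9)

  # known rotation + translation is exactly undone
  R <- rotation_matrix(c(1, -2, 0.5), 1.2)
  moved <- set_model_coords(m, sweep(model_coords(m) %*% t(R), 2,
                                     c(2, -1, 3), "+"))
  fit <- superpose(list(moved), m, region = "FC")
  expect_lt(fit$rmsd[1], 1e-6)
  expect_lt(max(abs(model_coords(fit$models[[1]]) - model_coords(m))), 1e-6)

  # RMSD agrees with the quaternion oracle on noisy pairs
  set.seed(12)
  for (k in 1:10) {
    P <- matrix(rnorm(60), 20, 3)
    Q <- sweep(P %*% t(rotation_matrix(rnorm(3), runif(1, 0, pi))), 2,
               rnorm(3), "+") + matrix(rnorm(60, 0, 0.1), 20, 3)
    expect_equal(kabsch(P, Q)$rmsd, quaternion_fit_rmsd(P, Q),
                 tolerance = 1e-8)
  }

  # topology mismatch is an explicit error
  odd <- m
  odd$sites$resno[odd$sites$region == "FC"][1] <- 99L
  expect_error(superpose(list(odd), m, region = "FC"), "differs")
})

test_that("PCA clustering obeys its algebraic identities", {
  m <- tiny_model()
  set.seed(4)
  ms <- lapply(1:40, function(i)
    set_model_coords(m, model_coords(m) +
                       matrix(rnorm(3 * nrow(m$sites), 0, 0.2), ncol = 3)))
  pc <- pca_cluster(ms, k = 3, seed = 1)
  # eigenvalues descending and nonnegative
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(all(pc$eigenvalues >= -1e-12))
  # trace identity: eigenvalue sum equals total coordinate variance
  flat <- t(vapply(ms, function(x) as.vector(model_coords(x)),
                   numeric(3 * nrow(m$sites))))
  expect_equal(sum(pc$eigenvalues), sum(apply(flat, 2, var)),
               tolerance = 1e-9)
  # independent oracle: direct eigendecomposition of the covariance
  ev <- eigen(stats::cov(flat), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$variance_captured_3,
               100 * sum(ev[1:3]) / sum(ev), tolerance = 1e-8)
  # centroid minimizes summed in-group projection distance
  pspace <- pc$projections[, 1:3]
  for (g in seq_along(pc$centroids)) {
    idx <- which(pc$groups == g)
    dsum <- vapply(idx, function(i)
      sum(sqrt(rowSums(sweep(pspace[idx, , drop = FALSE], 2,
                             pspace[i, ])^2))), 0)
    expect_equal(pc$centroids[g], idx[which.min(dsum)])
  }

  # degenerate: identical models collapse to eigenvalue zero, one group
  same <- pca_cluster(lapply(1:12, function(i) m), k = 4)
  expect_lt(max(same$eigenvalues), 1e-12)
  expect_identical(length(unique(same$groups)), 1L)

  expect_error(pca_cluster(ms[1:3], k = 5), "exceeds")
})

test_that("a constructed two-conformer mixture is cleanly separated", {
  m <- tiny_model()
  shift <- model_coords(m)
  shift[m$sites$region == "FAB1", 1] <- shift[m$sites$region == "FAB1", 1] + 6
  m_b <- set_model_coords(m, shift)
  set.seed(8)
  noise_model <- function(base) set_model_coords(base, model_coords(base) +
      matrix(rnorm(3 * nrow(base$sites), 0, 0.15), ncol = 3))
  ms <- c(lapply(1:50, function(i) noise_model(m)),
          lapply(1:50, function(i) noise_model(m_b)))
  pc <- pca_cluster(ms, k = 2, seed = 2)
  lab <- pc$groups
  agree <- max(mean(lab == c(rep(1, 50), rep(2, 50))),
               mean(lab == c(rep(2, 50), rep(1, 50))))
  expect_gte(agree, 0.98)
})

test_that("PCA projections survive a global rigid transform (up to sign)", {
  m <- tiny_model()
  set.seed(5)
  ms <- lapply(1:25, function(i)
    set_model_coords(m, model_coords(m) +
                       matrix(rnorm(3 * nrow(m$sites), 0, 0.2), ncol = 3)))
  pc1 <- pca_cluster(ms, k = 2, seed = 1)
  R <- rotation_matrix(c(0.3, 1, -2), 0.8)
  ms_rot <- lapply(ms, function(x)
    set_model_coords(x, sweep(model_coords(x) %*% t(R), 2, c(5, 5, 5), "+")))
  pc2 <- pca_cluster(ms_rot, k = 2, seed = 1)
  for (j in 1:3) {
    a <- pc1$projections[, j]; b <- pc2$projections[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-6)
  }
})

test_that("Fab tip separation is geometric and symmetric", {
  m <- tiny_model()
  tips <- c(which(m$sites$region == "FAB1")[2],
            which(m$sites$region == "FAB2")[2])
  xyz <- model_coords(m)
  expect_equal(fab_tip_separation(m, tips),
               sqrt(sum((xyz[tips[1], ] - xyz[tips[2], ])^2)))
  # mirror reflection through x = 0 keeps the separation
  refl <- xyz; refl[, 1] <- -refl[, 1]
  expect_equal(fab_tip_separation(set_model_coords(m, refl), tips),
               fab_tip_separation(m, tips), tolerance = 1e-12)
  expect_error(fab_tip_separation(m, tips[1]), "exactly one site")
  expect_error(fab_tip_separation(m, c(tips[1], tips[1])), "FAB2")
})
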