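test_that("torsion moves are exact rigid rotations about hinge pivots", {
  m <- tiny_model()

  # identity rotation leaves the model untouched
  m0 <- apply_torsion_move(m, torsion_move(218, "phi", 0, "FAB_SIDE"))
  expect_identical(model_coords(m0), model_coords(m))

  # 24 x 15 degrees is a full turn
  mv <- torsion_move(219, "psi", 1, "FAB_SIDE")
  cur <- m
  for (k in 1:24) cur <- apply_torsion_move(cur, mv)
  expect_lt(max(abs(model_coords(cur) - model_coords(m))), 1e-6)

  # intra-region distance matrices of the rigid blocks survive any move
  # (the HINGE itself bends at its pivots, so it is excluded)
  mv2 <- torsion_move(221, "phi", 7, "FC_SIDE")
  moved <- apply_torsion_move(m, mv2)
  for (rg in setdiff(names(rigid_regions(m)), "HINGE")) {
    idx <- rigid_regions(m)[[rg]]
    expect_lt(max(abs(dist(model_coords(moved)[idx, , drop = FALSE]) -
                        dist(model_coords(m)[idx, , drop = FALSE]))), 1e-9)
  }

  # non-moving side is bit-identical; chain bond lengths preserved
  side <- which(m$sites$chain == "H" & m$sites$resno <= 221)
  expect_identical(model_coords(moved)[side, ], model_coords(m)[side, ])
  hh <- which(m$sites$chain == "H")
  bonds <- function(x) sqrt(rowSums(diff(x[hh, ])^2))
  expect_lt(max(abs(bonds(model_coords(moved)) - bonds(model_coords(m)))),
            1e-9)
})

test_that("moves at undeclared pivots are refused", {
  m <- tiny_model()
  expect_error(apply_torsion_move(m, torsion_move(216, "phi", 3, "FAB_SIDE")),
               "pivot set")
  expect_error(torsion_move(218, "phi", 24, "FAB_SIDE"))
})

test_that("clash detection agrees with an exhaustive pair scan", {
  # constructed two-bead clash
  m <- tiny_model()
  xyz <- model_coords(m)
  fab1 <- which(m$sites$region == "FAB1")[1]
  fc1 <- which(m$sites$region == "FC")[1]
  xyz[fc1, ] <- xyz[fab1, ] + c(0.2, 0, 0)
  m_cl <- set_model_coords(m, xyz)
  rep1 <- detect_clash(m_cl, cutoff = 0.35)
  expect_identical(rep1$clash_count, 1L)
  expect_setequal(as.vector(rep1$offending_pairs), c(fab1, fc1))

  # random configurations versus the brute-force oracle
  set.seed(7)
  for (k in 1:25) {
    mk <- set_model_coords(m, model_coords(m) +
                             matrix(rnorm(3 * nrow(m$sites), 0, 0.8),
                                    ncol = 3))
    fast <- detect_clash(mk, cutoff = 0.5)
    slow <- brute_force_clashes(mk, cutoff = 0.5)
    expect_identical(fast$clash_count, slow$clash_count)
    if (fast$clash_count > 0) {
      key <- function(p) paste(p[, 1], p[, 2])
      expect_setequal(key(fast$offending_pairs), key(slow$offending_pairs))
    }
  }
})

test_that("torsion-angle Monte Carlo libraries behave as specified", {
  m <- cached_igg3_truth()$model

  # n_moves = 0 gives the bare start
  lib0 <- run_tamc(m, n_moves = 0, seed = 1)
  expect_length(lib0$coords, 1)
  expect_error(run_tamc(m, pivot_profile = list(), n_moves = 10), "empty")

  # determinism: identical seed, identical library
  lib_a <- cached_small_library()
  lib_b <- run_tamc(m, n_moves = 150, seed = 5)
  expect_identical(lib_a$coords, lib_b$coords)
  expect_identical(lib_a$meta, lib_b$meta)

  # every stored conformer is clash-free under the reference detector
  for (i in seq_along(lib_a$coords))
    expect_identical(detect_clash(library_model(lib_a, i))$clash_count, 0L)

  # replaying the accepted-move trace through apply_torsion_move
  # reproduces the fast-path coordinates exactly
  acc <- lib_a$meta[-1, ]
  side_of <- function(p) if (p %in% m$pivot_sets$FAB_SIDE) "FAB_SIDE"
                         else "FC_SIDE"
  cur <- m
  for (i in seq_len(nrow(acc))) {
    cur <- apply_torsion_move(cur, torsion_move(acc$pivot[i],
                                                acc$angle_kind[i],
                                                acc$step_index[i],
                                                side_of(acc$pivot[i])))
    expect_lt(max(abs(model_coords(cur) - lib_a$coords[[i + 1]])), 1e-9)
  }

  # rigid-body invariance of the block regions across the whole library
  rr <- rigid_regions(m)[c("FAB1", "FAB2", "FC", "GLYCAN")]
  d_ref <- lapply(rr, function(i) dist(lib_a$coords[[1]][i, , drop = FALSE]))
  last <- lib_a$coords[[length(lib_a$coords)]]
  for (rg in names(rr))
    expect_lt(max(abs(dist(last[rr[[rg]], , drop = FALSE]) - d_ref[[rg]])),
              1e-9)
})

test_that("raising the clash cutoff never gains accepted models", {
  m <- cached_igg3_truth()$model
  acc <- vapply(c(0.2, 0.35, 0.45, 5),
                function(ct) run_tamc(m, n_moves = 60, cutoff = ct,
                                      seed = 11)$params$accepted,
                numeric(1))
  expect_true(all(diff(acc) <= 0))
  # absurd cutoff: library stays {start}, every proposal rejected
  lib_huge <- run_tamc(m, n_moves = 60, cutoff = 5, seed = 11)
  expect_length(lib_huge$coords, 1)
  expect_equal(lib_huge$params$rejection_fraction, 1.0)
})

test_that("accepted-model R_G distribution is broad at default settings", {
  lib <- cached_small_library()
  rg <- lib$meta$rg
  expect_gt(diff(range(rg)) / mean(rg), 0.2)
})

test_that("hinge starts satisfy the disulfide constraint and cluster into 5", {
  hs <- generate_hinge_starts(60, seed = 3)
  expect_length(hs$centroids, 5)
  expect_length(hs$conformers, 60)
  n <- length(hs$cys_index) # 11 cysteines in the 70-mer
  expect_identical(length(hs$cys_index), 11L)
  for (X in hs$conformers[hs$centroids]) {
    nA <- nrow(X) / 2
    dd <- sqrt(rowSums((X[hs$cys_index, , drop = FALSE] -
                          X[nA + hs$cys_index, , drop = FALSE])^2))
    expect_true(all(dd >= 0.4 & dd <= 0.75))
  }
  # end-to-end lengths overlap the extended-hinge range 7.67-10.80 nm
  expect_true(any(hs$end_to_end >= 7.67 & hs$end_to_end <= 10.80))
  # determinism
  hs2 <- generate_hinge_starts(60, seed = 3)
  expect_identical(hs$conformers, hs2$conformers)
  expect_identical(hs$centroids, hs2$centroids)
})

test_that("pooled multi-run libraries keep bookkeeping consistent", {
  m <- cached_igg3_truth()$model
  l1 <- cached_small_library()
  l2 <- run_tamc(m, n_moves = 50, seed = 6)
  pooled <- merge_libraries(l1, l2)
  expect_length(pooled$coords, length(l1$coords) + length(l2$coords))
  expect_identical(pooled$meta$model_id, seq_len(nrow(pooled$meta)) - 1L)
  expect_equal(pooled$params$accepted,
               l1$params$accepted + l2$params$accepted)
})
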