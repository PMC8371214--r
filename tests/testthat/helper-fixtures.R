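# shared fixture builders; heavier objects are built once per test run

# a hand-sized model with all regions: 4 beads per block region,
# 8-bead hinge with pivots, used for fast unit tests
tiny_model <- function() {
  blk <- function(chain, region, center, resno_offset = 0L) {
    pts <- rbind(c(0, 0, 0), c(0.8, 0, 0), c(0, 0.8, 0), c(0, 0, 0.8))
    data.frame(chain = chain, resno = seq_len(4) + resno_offset,
               resname = "UNK", region = region,
               x = pts[, 1] + center[1], y = pts[, 2] + center[2],
               z = pts[, 3] + center[3], f = 1, mass = 110,
               stringsAsFactors = FALSE)
  }
  hinge <- data.frame(chain = "H", resno = 216:223, resname = "GLY",
                      region = "HINGE",
                      x = 0.15 * cos(0:7 * 2), y = 0.15 * sin(0:7 * 2),
                      z = -(0:7) * 0.36, f = 1, mass = 57.02,
                      stringsAsFactors = FALSE)
  s <- rbind(blk("A", "FAB1", c(3, 0, 1)), blk("B", "FAB2", c(-3.8, 0, 1)),
             hinge, blk("F", "FC", c(0, 0, -6)))
  s$index <- seq_len(nrow(s)) - 1L
  s <- s[, c("index", "chain", "resno", "resname", "region",
             "x", "y", "z", "f", "mass")]
  bead_model(s, pivot_sets = list(FAB_SIDE = 218:219, FC_SIDE = 221:222))
}

# deterministic lattice-filled sphere of bead coordinates
lattice_sphere <- function(radius = 3, spacing = 0.37) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(g, g, g))
  unname(pts[rowSums(pts^2) <= radius^2, , drop = FALSE])
}

# memoised default ground truth + library (expensive; built on first use)
.fixture_cache <- new.env(parent = emptyenv())

cached_igg3_truth <- function() {
  if (is.null(.fixture_cache$truth))
    .fixture_cache$truth <- make_ground_truth("igg3_like", seed = 2)
  .fixture_cache$truth
}

cached_small_library <- function() {
  if (is.null(.fixture_cache$lib))
    .fixture_cache$lib <- run_tamc(cached_igg3_truth()$model,
                                   n_moves = 150, seed = 5)
  .fixture_cache$lib
}

# Horn's quaternion absolute-orientation solution: independent oracle for
# the SVD-based rigid superposition
quaternion_fit_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  M <- crossprod(P0, Q0)
  N <- matrix(0, 4, 4)
  N[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  N[1, 2] <- N[2, 1] <- M[2, 3] - M[3, 2]
  N[1, 3] <- N[3, 1] <- M[3, 1] - M[1, 3]
  N[1, 4] <- N[4, 1] <- M[1, 2] - M[2, 1]
  N[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  N[2, 3] <- N[3, 2] <- M[1, 2] + M[2, 1]
  N[2, 4] <- N[4, 2] <- M[3, 1] + M[1, 3]
  N[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  N[3, 4] <- N[4, 3] <- M[2, 3] + M[3, 2]
  N[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
}

# brute-force clash scan implementing the published rule directly
brute_force_clashes <- function(m, cutoff) {
  s <- m$sites
  xyz <- model_coords(m)
  hits <- 0L
  pairs <- NULL
  n <- nrow(s)
  for (j in seq_len(n - 1)) for (i in (j + 1):n) {
    same_region <- s$region[i] == s$region[j]
    both_hinge <- same_region && s$region[i] == "HINGE"
    bonded <- s$chain[i] == s$chain[j] && abs(s$resno[i] - s$resno[j]) <= 2
    if ((same_region && !both_hinge) || bonded) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) {
      hits <- hits + 1L
      pairs <- rbind(pairs, c(j, i))
    }
  }
  list(clash_count = hits, offending_pairs = pairs)
}
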