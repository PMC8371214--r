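# Torsion-angle Monte Carlo: discrete backbone dihedral moves applied to a
# bead model with steric-clash rejection, plus a constrained hinge-start
# generator standing in for the MD step that seeds the full-length models.

#' Named pivot profiles for torsion-angle Monte Carlo
#'
#' Returns the pivot residue sets (continuous numbering) whose phi/psi
#' virtual-bond torsions are varied. N-terminal hinge pivots mobilize the
#' Fab pair (FAB_SIDE); C-terminal pivots next to the anchor mobilize the
#' Fc (FC_SIDE). The glycosylated profile uses pivots 217-222 and 285-286,
#' the deglycosylated one 217-220 and 283-284.
#'
#' @param name `"glycosylated"` or `"deglycosylated"`.
#' @return named list of integer residue-number vectors.
#' @export
tamc_pivot_profile <- function(name = c("glycosylated", "deglycosylated")) {
  name <- match.arg(name)
  if (name == "glycosylated")
    list(FAB_SIDE = 217:222, FC_SIDE = c(285L, 286L))
  else
    list(FAB_SIDE = 217:220, FC_SIDE = c(283L, 284L))
}

#' Construct a torsion move
#'
#' A move rotates everything on one side of a hinge pivot residue by a
#' multiple of 15 degrees about a local virtual-bond axis. `phi` uses the
#' bond entering the pivot bead, `psi` the bond leaving it.
#'
#' @param pivot continuous residue number of the pivot bead.
#' @param angle_kind `"phi"` or `"psi"`.
#' @param step_index integer in 0..23; rotation is `step_index * 15` degrees.
#' @param moving_side `"FAB_SIDE"` (sites N-terminal of the pivot plus both
#'   Fabs) or `"FC_SIDE"` (sites C-terminal plus Fc and glycans).
#' @return object of class `torsion_move`.
#' @export
torsion_move <- function(pivot, angle_kind = c("phi", "psi"),
                         step_index, moving_side = c("FAB_SIDE", "FC_SIDE")) {
  angle_kind <- match.arg(angle_kind)
  moving_side <- match.arg(moving_side)
  stopifnot(step_index %in% 0:23)
  structure(list(pivot = as.integer(pivot), angle_kind = angle_kind,
                 step_index = as.integer(step_index),
                 moving_side = moving_side),
            class = "torsion_move")
}

# site row indices moving with a given side, for the hinge chain "H"
.moving_set <- function(m, pivot, moving_side) {
  s <- m$sites
  if (moving_side == "FAB_SIDE") {
    which((s$chain == "H" & s$resno < pivot) |
            s$region %in% c("FAB1", "FAB2"))
  } else {
    which((s$chain == "H" & s$resno > pivot) |
            (s$chain != "H" & s$region %in% c("FC", "GLYCAN")))
  }
}

#' Apply a torsion move to a bead model
#'
#' Rigidly rotates all sites on the moving side of the pivot about the
#' local virtual-bond axis through the pivot bead; every other site is
#' returned bit-identical. The pivot must belong to one of the model's
#' declared pivot sets (the rest of the model is held rigid).
#'
#' @param m a `bead_model`.
#' @param move a [torsion_move()].
#' @return the moved `bead_model`.
#' @export
apply_torsion_move <- function(m, move) {
  ps <- m$pivot_sets[[move$moving_side]]
  if (is.null(ps) || !(move$pivot %in% ps))
    stop("pivot ", move$pivot, " is not in the declared ",
         move$moving_side, " pivot set")
  if (move$step_index == 0) return(m)
  s <- m$sites
  i_piv <- which(s$chain == "H" & s$resno == move$pivot)
  if (length(i_piv) != 1) stop("pivot residue ", move$pivot, " not found")
  xyz <- model_coords(m)
  p <- xyz[i_piv, ]
  nb <- if (move$angle_kind == "phi") {
    which(s$chain == "H" & s$resno == move$pivot - 1)
  } else {
    which(s$chain == "H" & s$resno == move$pivot + 1)
  }
  if (length(nb) != 1)
    stop("pivot ", move$pivot, " lacks the flanking residue needed for ",
         move$angle_kind)
  axis <- if (move$angle_kind == "phi") p - xyz[nb, ] else xyz[nb, ] - p
  R <- rotation_matrix(axis, move$step_index * pi / 12)
  mov <- .moving_set(m, move$pivot, move$moving_side)
  if (length(mov) < 2) stop("fewer than 2 beads on the moving side")
  xyz[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2, p) %*% t(R), 2, p, "+")
  set_model_coords(m, xyz)
}

# logical mask over dist-vector entries that are EXEMPT from clash checks:
# same rigid region, or sequence neighbors (|delta resno| <= 2, same chain)
.clash_exempt_mask <- function(m) {
  s <- m$sites
  n <- nrow(s)
  reg <- s$region
  same_region <- outer(reg, reg, "==") & !(outer(reg == "HINGE", reg == "HINGE", "&"))
  bonded <- outer(s$chain, s$chain, "==") &
    abs(outer(s$resno, s$resno, "-")) <= 2
  ex <- same_region | bonded
  ex[lower.tri(ex)]
}

#' Detect steric clashes in a bead model
#'
#' Reports every inter-region and non-bonded intra-hinge bead pair closer
#' than `cutoff`. Pairs within one rigid region and sequence neighbors
#' (|residue difference| <= 2 in the same chain) are exempt.
#'
#' @param m a `bead_model`.
#' @param cutoff center-to-center clash distance, nm (default 0.35, a
#'   Calpha excluded-volume scale).
#' @param exempt_mask optional precomputed mask from an identical-topology
#'   model (internal speed-up for the Monte Carlo loop).
#' @return list of class `clash_report`: `clash_count`, `min_separation`
#'   (nm, over checked pairs), `offending_pairs` (2-column site-row matrix).
#' @export
detect_clash <- function(m, cutoff = 0.35, exempt_mask = NULL) {
  stopifnot(cutoff > 0)
  if (is.null(exempt_mask)) exempt_mask <- .clash_exempt_mask(m)
  d <- stats::dist(model_coords(m))
  dv <- as.vector(d)
  checked <- !exempt_mask
  hits <- which(checked & dv < cutoff)
  n <- nrow(m$sites)
  pairs <- if (length(hits)) .dist_index_to_pair(hits, n) else
    matrix(integer(0), 0, 2)
  structure(list(clash_count = length(hits),
                 min_separation = if (any(checked)) min(dv[checked]) else Inf,
                 offending_pairs = pairs),
            class = "clash_report")
}

# map indices in a dist vector (lower triangle, column order) to (i, j)
.dist_index_to_pair <- function(k, n) {
  j <- ceiling((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  i <- k - n * (j - 1) + j * (j - 1) / 2 + j
  cbind(as.integer(j), as.integer(i))
}

#' Run torsion-angle Monte Carlo to build a conformer library
#'
#' Attempts `n_moves` random torsion moves from `start`: each proposal
#' samples a pivot (uniformly over the profile), an angle kind and one of
#' the 24 discrete 15-degree steps, applies the rotation and accepts the
#' conformer iff it is free of steric clashes. Accepted conformers extend
#' the current state (a random walk in torsion space); rejected moves are
#' discarded and the previous state retained. Acceptance is clash-only:
#' no energy function or Metropolis criterion is applied.
#'
#' @param start the starting `bead_model` (always the library's first
#'   entry). If the start already violates the cutoff, no local rigid move
#'   can certify a clash-free descendant, so every proposal is rejected
#'   and the library is just `{start}`.
#' @param pivot_profile named pivot sets; default the model's own.
#' @param n_moves number of attempted moves (> 0 unless 0 for a bare
#'   single-model library).
#' @param cutoff clash cutoff, nm.
#' @param seed integer RNG seed; the library is fully determined by
#'   (start, profile, n_moves, cutoff, seed).
#' @param thin keep every `thin`-th accepted conformer (1 = keep all).
#' @return object of class `model_library`: `template` (the start model),
#'   `coords` (list of coordinate matrices, first = start), `meta`
#'   (data.frame with model_id, rg, move_index, pivot, angle_kind,
#'   step_index), and `params` (including the rejection fraction).
#' @export
run_tamc <- function(start, pivot_profile = start$pivot_sets, n_moves,
                     cutoff = 0.35, seed = 1, thin = 1L) {
  if (length(pivot_profile) == 0) stop("empty pivot profile")
  if (n_moves < 0) stop("n_moves must be >= 0")
  validate_bead_model(start)
  ex <- .clash_exempt_mask(start)
  cr0 <- detect_clash(start, cutoff, exempt_mask = ex)
  # a start that already violates the cutoff can never spawn a certified
  # clash-free conformer by a rigid local move: reject every proposal
  start_clashed <- cr0$clash_count > 0
  set.seed(seed)
  sides <- rep(names(pivot_profile), lengths(pivot_profile))
  pivots <- unlist(pivot_profile, use.names = FALSE)
  s <- start$sites
  # precomputed geometry so the hot loop works on bare matrices
  piv_row <- vapply(pivots, function(p)
    which(s$chain == "H" & s$resno == p), integer(1))
  nb_prev <- vapply(pivots, function(p)
    which(s$chain == "H" & s$resno == p - 1), integer(1))
  nb_next <- vapply(pivots, function(p)
    which(s$chain == "H" & s$resno == p + 1), integer(1))
  mov_rows <- lapply(seq_along(pivots), function(i)
    .moving_set(start, pivots[i], sides[i]))
  n_sites <- nrow(s)
  stat_rows <- lapply(mov_rows, function(r) setdiff(seq_len(n_sites), r))
  # a rigid move can only create clashes between moving and static sites;
  # sequence neighbors (|delta resno| <= 2, same chain) spanning the cut
  # are exempt, everything else across the cut is checked
  exempt_cells <- lapply(seq_along(pivots), function(i) {
    a <- mov_rows[[i]]; b <- stat_rows[[i]]
    ae <- which(outer(s$chain[a], s$chain[b], "==") &
                  abs(outer(s$resno[a], s$resno[b], "-")) <= 2)
    ae
  })
  xyz <- model_coords(start)
  f <- s$f
  coords <- vector("list", n_moves + 1)
  coords[[1]] <- xyz
  rec <- vector("list", n_moves + 1)
  rec[[1]] <- list(0L, coord_rg(xyz, f), 0L, NA_integer_,
                   NA_character_, NA_integer_)
  keep <- 1L
  accepted <- 0L
  for (k in seq_len(n_moves)) {
    ip <- sample.int(length(pivots), 1)
    kind <- sample(c("phi", "psi"), 1)
    step <- sample.int(24, 1) - 1L
    if (start_clashed) {
      next
    } else if (step == 0L) {   # identity rotation: trivially clash-free
      accepted <- accepted + 1L
    } else {
      p <- xyz[piv_row[ip], ]
      axis <- if (kind == "phi") p - xyz[nb_prev[ip], ]
              else xyz[nb_next[ip], ] - p
      R <- rotation_matrix(axis, step * pi / 12)
      rows <- mov_rows[[ip]]
      A <- sweep(sweep(xyz[rows, , drop = FALSE], 2, p) %*% t(R), 2, p, "+")
      B <- xyz[stat_rows[[ip]], , drop = FALSE]
      D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      D2[exempt_cells[[ip]]] <- Inf
      if (min(D2) < cutoff^2) next
      xyz[rows, ] <- A
      accepted <- accepted + 1L
    }
    if (accepted %% thin == 0L) {
      keep <- keep + 1L
      coords[[keep]] <- xyz
      rec[[keep]] <- list(keep - 1L, coord_rg(xyz, f), k,
                          pivots[ip], kind, step)
    }
  }
  meta <- do.call(rbind, lapply(rec[seq_len(keep)], function(r)
    data.frame(model_id = r[[1]], rg = r[[2]], move_index = r[[3]],
               pivot = r[[4]], angle_kind = r[[5]], step_index = r[[6]])))
  structure(list(template = start, coords = coords[seq_len(keep)],
                 meta = meta,
                 params = list(n_moves = n_moves, cutoff = cutoff,
                               seed = seed, thin = thin,
                               accepted = accepted,
                               rejection_fraction =
                                 if (n_moves > 0) 1 - accepted / n_moves else 0)),
            class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat("model_library:", length(x$coords), "stored conformers (",
      x$params$accepted, "accepted of", x$params$n_moves, "moves; rejection",
      sprintf("%.2f", x$params$rejection_fraction), ")\n")
  invisible(x)
}

#' Merge conformer libraries from independent Monte Carlo runs
#'
#' The standard protocol samples several independent chains (e.g. one per
#' starting hinge conformation) and pools the accepted models into one
#' library before screening. Templates must share site topology.
#'
#' @param ... `model_library` objects.
#' @return a pooled `model_library` (template and params from the first;
#'   model ids renumbered; rejection fraction pooled).
#' @export
merge_libraries <- function(...) {
  libs <- list(...)
  stopifnot(length(libs) >= 1,
            all(vapply(libs, inherits, logical(1), "model_library")))
  n_sites <- vapply(libs, function(l) nrow(l$template$sites), integer(1))
  if (length(unique(n_sites)) != 1)
    stop("libraries have differing site counts")
  coords <- do.call(c, lapply(libs, `[[`, "coords"))
  meta <- do.call(rbind, lapply(seq_along(libs), function(i) {
    mt <- libs[[i]]$meta
    mt$run <- i
    mt
  }))
  meta$model_id <- seq_len(nrow(meta)) - 1L
  tot_moves <- sum(vapply(libs, function(l) l$params$n_moves, 0))
  tot_acc <- sum(vapply(libs, function(l) l$params$accepted, 0))
  p <- libs[[1]]$params
  p$n_moves <- tot_moves; p$accepted <- tot_acc
  p$rejection_fraction <- if (tot_moves > 0) 1 - tot_acc / tot_moves else 0
  p$n_runs <- length(libs)
  structure(list(template = libs[[1]]$template, coords = coords,
                 meta = meta, params = p),
            class = "model_library")
}

#' Materialize one library conformer as a bead model
#' @param lib a `model_library`.
#' @param i conformer position (1 = start model).
#' @return a `bead_model`.
#' @export
library_model <- function(lib, i) {
  set_model_coords(lib$template, lib$coords[[i]])
}

# ---- hinge-start generation -------------------------------------------

#' Generate clustered disulfide-constrained hinge starting conformations
#'
#' Stand-in for the molecular-dynamics stage that seeds the pipeline:
#' draws self-avoiding two-strand hinge backbones (one bead per residue,
#' strands paired laterally) in which all 11 inter-strand cysteine pairs
#' sit at disulfide-like separations (0.4-0.75 nm), then clusters the
#' conformers by PCA + k-means into 5 groups and reports the centroid of
#' each (the member minimizing summed in-cluster distance).
#'
#' @param n_conformers number of conformers to draw (>= 5).
#' @param seed integer RNG seed.
#' @param hinge_residues single-letter codes; default the 70-residue hinge.
#' @param stiffness angular diffusion scale of the worm-like backbone walk;
#'   smaller is stiffer/more extended.
#' @param max_attempts per-conformer cap on constraint-satisfaction retries.
#' @return object of class `hinge_start_set`: `conformers` (list of
#'   2n x 3 matrices, strand A rows then strand B), `cluster_labels`,
#'   `centroids` (5 conformer indices), `end_to_end` (nm),
#'   `cys_index` (cysteine positions within a strand).
#' @export
generate_hinge_starts <- function(n_conformers, seed = 1,
                                  hinge_residues = expand_hinge_sequence(igg3_hinge_pattern),
                                  stiffness = 0.30,
                                  max_attempts = 500) {
  stopifnot(n_conformers >= 5)
  set.seed(seed)
  n <- length(hinge_residues)
  cys <- which(hinge_residues == "C")
  bond <- 0.38
  draw_one <- function() {
    for (att in seq_len(max_attempts)) {
      dirs <- matrix(0, n - 1, 3)
      d <- c(0, 0, -1)
      for (i in seq_len(n - 1)) {
        d <- d + stiffness * stats::rnorm(3)
        d <- d / sqrt(sum(d^2))
        dirs[i, ] <- d
      }
      A <- rbind(c(0, 0, 0), apply(dirs * bond, 2, cumsum))
      # lateral pairing direction: perpendicular to the end-to-end vector
      e <- A[n, ] - A[1, ]; e <- e / sqrt(sum(e^2))
      ref <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      w <- ref - sum(ref * e) * e; w <- w / sqrt(sum(w^2))
      B <- A + matrix(w, n, 3, byrow = TRUE) * 0.55 +
        matrix(stats::rnorm(3 * n, 0, 0.02), n, 3)
      X <- rbind(A, B)
      # self-avoidance: non-bonded, non-paired beads at >= 0.3 nm
      dm <- as.matrix(stats::dist(X))
      res <- c(seq_len(n), seq_len(n))
      strand <- rep(1:2, each = n)
      near <- (abs(outer(res, res, "-")) <= 2 &
                 outer(strand, strand, "==")) |
        (abs(outer(res, res, "-")) <= 1 & outer(strand, strand, "!="))
      diag(dm) <- Inf
      dm[near] <- Inf
      if (min(dm) < 0.30) next
      dd <- sqrt(rowSums((A[cys, , drop = FALSE] - B[cys, , drop = FALSE])^2))
      if (all(dd >= 0.4 & dd <= 0.75)) return(X)
    }
    stop("hinge start generation failed after ", max_attempts, " attempts")
  }
  conf <- lapply(seq_len(n_conformers), function(i) draw_one())
  flat <- t(vapply(conf, as.vector, numeric(6 * n)))
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  k <- 5L
  proj <- pc$x[, seq_len(min(3, ncol(pc$x))), drop = FALSE]
  km <- stats::kmeans(proj, centers = k, nstart = 10)
  centroids <- vapply(seq_len(k), function(g) {
    idx <- which(km$cluster == g)
    dsum <- vapply(idx, function(i)
      sum(sqrt(rowSums(sweep(proj[idx, , drop = FALSE], 2, proj[i, ])^2))), 0)
    idx[which.min(dsum)]
  }, integer(1))
  e2e <- vapply(conf, function(X) {
    nA <- nrow(X) / 2
    (sqrt(sum((X[nA, ] - X[1, ])^2)) +
       sqrt(sum((X[2 * nA, ] - X[nA + 1, ])^2))) / 2
  }, 0)
  structure(list(conformers = conf, cluster_labels = km$cluster,
                 centroids = centroids, end_to_end = e2e,
                 cys_index = cys, seed = seed),
            class = "hinge_start_set")
}

#' @export
print.hinge_start_set <- function(x, ...) {
  cat("hinge_start_set:", length(x$conformers), "conformers, 5 clusters;",
      "end-to-end", sprintf("%.1f-%.1f nm", min(x$end_to_end),
                            max(x$end_to_end)), "\n")
  invisible(x)
}
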