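# Hydrodynamics: sedimentation-coefficient standardization to water at
# 20 C and a convex-hull predictor of s from bead models (hull volume ->
# hydrated equivalent sphere -> Perrin-type shape correction).

#' Solvent conditions for sedimentation analysis
#'
#' @param temperature degrees C.
#' @param density solvent density rho, g/ml.
#' @param viscosity solvent viscosity, poise.
#' @param vbar partial specific volume of the solute, ml/g.
#' @return object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature = 20, density = 0.99823,
                               viscosity = 0.010019, vbar = 0.776) {
  stopifnot(density > 0, viscosity > 0, vbar > 0)
  structure(list(temperature = temperature, density = density,
                 viscosity = viscosity, vbar = vbar),
            class = "solvent_conditions")
}

#' Standardize an observed sedimentation coefficient to s20,w
#'
#' s20,w = s_T,B (eta_T,B / eta_20,w) (1 - vbar rho)_20,w / (1 - vbar rho)_T,B,
#' referencing standard water at 20 C (rho = 0.99823 g/ml,
#' eta = 0.010019 P).
#'
#' @param s_obs observed sedimentation coefficient, Svedberg.
#' @param cond a [solvent_conditions()] describing the buffer.
#' @return s20,w in Svedberg.
#' @export
s20w_standardize <- function(s_obs, cond) {
  buoy_tb <- 1 - cond$vbar * cond$density
  if (buoy_tb <= 0)
    stop("(1 - vbar rho) <= 0 in the buffer: solute does not sediment")
  buoy_w <- 1 - cond$vbar * water20[["density"]]
  s_obs * (cond$viscosity / water20[["viscosity"]]) * buoy_w / buoy_tb
}

# ---- 3D convex hull (incremental) -------------------------------------

#' Convex hull of a 3D point set
#'
#' Incremental hull construction: faces of the current hull visible from
#' each new point are replaced by a cone of faces through its horizon
#' edges. Returns outward-oriented triangular faces, the hull vertices
#' and the enclosed volume.
#'
#' @param pts n x 3 coordinate matrix (n >= 4, not all coplanar).
#' @param eps visibility tolerance (absolute, same units as `pts`).
#' @return list with `faces` (m x 3 row indices into `pts`), `vertices`
#'   (unique row indices on the hull) and `volume`.
#' @export
convex_hull_3d <- function(pts, eps = 1e-9) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) stop("degenerate hull: fewer than 4 points")
  # initial tetrahedron from spread-out, non-coplanar points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (max(abs(pts[i1, ] - pts[i2, ])) < eps) stop("degenerate hull")
  e1 <- pts[i2, ] - pts[i1, ]
  # distance from the line (i1, i2)
  rel <- sweep(pts, 2, pts[i1, ])
  proj <- (rel %*% e1) / sum(e1^2)
  d_line <- sqrt(rowSums((rel - proj %*% t(e1))^2))
  i3 <- which.max(d_line)
  if (d_line[i3] < eps) stop("degenerate hull: points are collinear")
  nrm <- .cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  d_plane <- abs(sweep(pts, 2, pts[i1, ]) %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(d_plane)
  if (d_plane[i4] < eps) stop("degenerate hull: points are coplanar")
  verts <- c(i1, i2, i3, i4)
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(pts[verts, ])
  faces <- t(apply(faces, 1, function(f) .orient_out(f, pts, ctr)))
  for (p in setdiff(seq_len(n), verts)) {
    vis <- vapply(seq_len(nrow(faces)), function(k)
      .face_dist(faces[k, ], pts, pts[p, ]) > eps, logical(1))
    if (!any(vis)) next
    # horizon: edges appearing exactly once among the visible faces
    edges <- do.call(rbind, lapply(which(vis), function(k) {
      f <- faces[k, ]
      rbind(sort(c(f[1], f[2])), sort(c(f[2], f[3])), sort(c(f[1], f[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    newf <- t(apply(horizon, 1, function(e) .orient_out(c(e, p), pts, ctr)))
    faces <- rbind(faces, newf)
  }
  vol <- sum(apply(faces, 1, function(f) {
    a <- pts[f[1], ] - ctr; b <- pts[f[2], ] - ctr; c3 <- pts[f[3], ] - ctr
    det(cbind(a, b, c3)) / 6
  }))
  list(faces = faces, vertices = sort(unique(as.vector(faces))),
       volume = abs(vol))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed distance of point x above the plane of face f (outward positive)
.face_dist <- function(f, pts, x) {
  nrm <- .cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  sum(nrm * (x - pts[f[1], ])) / sqrt(sum(nrm^2))
}

# order face vertices so the normal points away from the interior point ctr
.orient_out <- function(f, pts, ctr) {
  if (.face_dist(f, pts, ctr) > 0) f[c(1, 3, 2)] else f
}

#' Hull-based sedimentation coefficient of a bead model
#'
#' Predicts s from shape: the convex hull of the bead centers gives the
#' molecular volume; its equivalent sphere, grown by a hydration increment,
#' gives the Stokes radius; the hull's principal-axis anisotropy supplies a
#' Perrin-type frictional shape factor (prolate-equivalent axial ratio
#' a/sqrt(bc)). Then s = M (1 - vbar rho) / (N_A 6 pi eta R_s F). GLYCAN
#' beads participate in the hull like every other site.
#'
#' @param m a `bead_model` (>= 4 non-coplanar sites).
#' @param mass molecular mass, Da.
#' @param vbar partial specific volume, ml/g.
#' @param cond a [solvent_conditions()]; default standard water at 20 C.
#' @param hydration hydration increment added to the equivalent-sphere
#'   radius, nm (default 0.28, one water layer).
#' @return object of class `hydro_result`: `s` (S, in `cond`), `s20w`,
#'   `stokes_radius` (nm), `f_f0`, `hull_volume` (nm^3), `shape_factor`,
#'   `axes` (hull semi-axes, nm).
#' @export
hull_s_estimate <- function(m, mass, vbar = 0.776,
                            cond = solvent_conditions(vbar = vbar),
                            hydration = 0.28) {
  stopifnot(mass > 0, vbar > 0)
  cond$vbar <- vbar
  xyz <- if (inherits(m, "bead_model")) model_coords(m) else as.matrix(m)
  hull <- convex_hull_3d(xyz)
  r_eq <- (3 * hull$volume / (4 * pi))^(1 / 3)
  r_s <- r_eq + hydration
  hv <- xyz[hull$vertices, , drop = FALSE]
  ev <- eigen(stats::cov(hv), symmetric = TRUE)$vectors
  prj <- hv %*% ev
  axes <- sort((apply(prj, 2, max) - apply(prj, 2, min)) / 2,
               decreasing = TRUE)
  p <- axes[1] / sqrt(axes[2] * axes[3])
  shape <- .perrin_prolate(max(1, p))
  buoy <- 1 - vbar * cond$density
  if (buoy <= 0) stop("(1 - vbar rho) <= 0: solute does not sediment")
  r_s_cm <- r_s * 1e-7
  s_sec <- mass * buoy / (.N_AVOGADRO * 6 * pi * cond$viscosity *
                            r_s_cm * shape)
  s <- s_sec * 1e13
  v0 <- mass * vbar / .N_AVOGADRO * 1e21       # anhydrous volume, nm^3
  r0 <- (3 * v0 / (4 * pi))^(1 / 3)
  structure(list(s = s, s20w = s20w_standardize(s, cond),
                 stokes_radius = r_s, f_f0 = r_s * shape / r0,
                 hull_volume = hull$volume, shape_factor = shape,
                 axes = axes),
            class = "hydro_result")
}

# Perrin translational friction factor of a prolate spheroid, axial ratio
# p = a/b >= 1 (1 = sphere)
.perrin_prolate <- function(p) {
  if (p < 1 + 1e-9) return(1)
  q <- 1 / p
  sqrt(1 - q^2) / (q^(2 / 3) * log((1 + sqrt(1 - q^2)) / q))
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf(
    "hydro_result: s = %.2f S (s20,w = %.2f S), R_s = %.2f nm, f/f0 = %.2f, hull %.0f nm^3\n",
    x$s, x$s20w, x$stokes_radius, x$f_f0, x$hull_volume))
  invisible(x)
}
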