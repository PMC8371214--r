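# Conformational analysis of best-fit model sets: glycan stripping,
# region-based rigid superposition, PCA + k-means clustering with centroid
# models, and the Fab-tip separation statistic.

#' Remove GLYCAN-tagged sites from a model
#'
#' Coordinate sets are compared across glycosylated and deglycosylated
#' ensembles after stripping glycans, so both share one site topology.
#'
#' @param m a `bead_model`.
#' @return the model without GLYCAN sites (ordering otherwise preserved).
#' @export
strip_glycans <- function(m) {
  keep <- m$sites$region != "GLYCAN"
  m$sites <- m$sites[keep, , drop = FALSE]
  m$sites$index <- seq_len(nrow(m$sites)) - 1L
  rownames(m$sites) <- NULL
  m
}

#' Superpose models onto a reference by one rigid region
#'
#' Least-squares rigid-body superposition (rotation + translation, no
#' scaling) of each model onto `reference`, fitting on the sites of the
#' chosen region (e.g. all Fc beads) and applying the transform to the
#' whole model. The per-model RMSD over the fitted region is reported.
#'
#' @param models list of `bead_model`s sharing site topology on `region`.
#' @param reference the target `bead_model`.
#' @param region region name to fit on (default `"FC"`).
#' @return list with `models` (aligned) and `rmsd` (nm, over the region).
#' @export
superpose <- function(models, reference, region = "FC") {
  ref_sel <- reference$sites$region == region
  if (!any(ref_sel)) stop("reference has no sites in region ", region)
  ref_key <- paste(reference$sites$chain[ref_sel],
                   reference$sites$resno[ref_sel])
  Q <- model_coords(reference)[ref_sel, , drop = FALSE]
  aligned <- vector("list", length(models))
  rmsd <- numeric(length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    sel <- m$sites$region == region
    key <- paste(m$sites$chain[sel], m$sites$resno[sel])
    if (!identical(key, ref_key)) {
      diff1 <- c(setdiff(key, ref_key), setdiff(ref_key, key), "ordering")[1]
      stop("model ", i, ": region topology differs from reference at site ",
           diff1)
    }
    P <- model_coords(m)[sel, , drop = FALSE]
    kb <- kabsch(P, Q)
    xyz <- sweep(model_coords(m) %*% kb$R, 2, kb$t, "+")
    aligned[[i]] <- set_model_coords(m, xyz)
    rmsd[i] <- kb$rmsd
  }
  list(models = aligned, rmsd = rmsd)
}

#' PCA clustering of a superposed model set
#'
#' Flattens the (pre-superposed, glycan-stripped) coordinates, mean
#' centers them, eigendecomposes the covariance, clusters the models by
#' k-means on the first three principal components, and identifies each
#' group's centroid model (the member minimizing summed within-group
#' distance in projection space). Eigenvector signs are fixed by making
#' each component's largest-magnitude loading positive.
#'
#' @param models list of `bead_model`s with identical site counts.
#' @param k number of groups (5 is typical for X-ray antibody ensembles,
#'   3 for neutron ones).
#' @param seed RNG seed for the k-means restarts.
#' @param n_components components used for clustering (default 3).
#' @return object of class `pca_result`: `projections`, `eigenvalues`,
#'   `variance_captured_3` (percent), `groups`, `centroids` (model index
#'   per group).
#' @export
pca_cluster <- function(models, k, seed = 1, n_components = 3) {
  n <- length(models)
  if (k > n) stop("k exceeds the number of models")
  flat <- t(vapply(models, function(m) as.vector(model_coords(m)),
                   numeric(3 * nrow(models[[1]]$sites))))
  ctr <- colMeans(flat)
  X <- sweep(flat, 2, ctr)
  sv <- svd(X)
  eigenvalues <- sv$d^2 / max(1, n - 1)
  V <- sv$v
  # sign convention: largest |loading| positive
  for (j in seq_len(ncol(V))) {
    jj <- which.max(abs(V[, j]))
    if (V[jj, j] < 0) { V[, j] <- -V[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  proj <- X %*% V
  nc <- min(n_components, ncol(proj))
  total_var <- sum(eigenvalues)
  vc3 <- if (total_var > 0)
    100 * sum(eigenvalues[seq_len(min(3, length(eigenvalues)))]) / total_var
  else 0
  pspace <- proj[, seq_len(nc), drop = FALSE]
  if (total_var < 1e-12) {
    groups <- rep(1L, n)
    k_eff <- 1L
  } else {
    set.seed(seed)
    km <- stats::kmeans(pspace, centers = k, nstart = 20)
    groups <- km$cluster
    k_eff <- k
  }
  centroids <- vapply(seq_len(k_eff), function(g) {
    idx <- which(groups == g)
    dsum <- vapply(idx, function(i)
      sum(sqrt(rowSums(sweep(pspace[idx, , drop = FALSE], 2,
                             pspace[i, ])^2))), 0)
    idx[which.min(dsum)]
  }, integer(1))
  structure(list(projections = proj, eigenvalues = eigenvalues,
                 variance_captured_3 = vc3, groups = groups,
                 centroids = centroids),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "pca_result: %d models, %d groups; PC1-3 capture %.1f%% of variance\n",
    nrow(x$projections), length(x$centroids), x$variance_captured_3))
  invisible(x)
}

#' Separation of the Fab tips
#'
#' Euclidean distance between one tip site on each Fab. By default the tip
#' of a Fab is its most hinge-distal bead (the site farthest from the
#' hinge-region center), mirroring how antigen-binding reach is measured
#' on best-fit ensembles.
#'
#' @param m a `bead_model` with FAB1, FAB2 and HINGE regions.
#' @param tip_selector optional integer vector of exactly two site rows
#'   (one in FAB1, one in FAB2) overriding the default.
#' @return separation, nm.
#' @export
fab_tip_separation <- function(m, tip_selector = NULL) {
  xyz <- model_coords(m)
  if (is.null(tip_selector)) {
    h <- which(m$sites$region == "HINGE")
    if (!length(h)) stop("model has no HINGE region")
    hc <- colMeans(xyz[h, , drop = FALSE])
    tip_selector <- vapply(c("FAB1", "FAB2"), function(rg) {
      idx <- which(m$sites$region == rg)
      if (!length(idx)) stop("model has no ", rg, " region")
      idx[which.max(rowSums(sweep(xyz[idx, , drop = FALSE], 2, hc)^2))]
    }, integer(1))
  } else {
    if (length(tip_selector) != 2)
      stop("tip_selector must name exactly one site per Fab")
    regs <- sort(m$sites$region[tip_selector])
    if (!identical(regs, c("FAB1", "FAB2")))
      stop("tip_selector must select one FAB1 and one FAB2 site")
  }
  sqrt(sum((xyz[tip_selector[1], ] - xyz[tip_selector[2], ])^2))
}
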