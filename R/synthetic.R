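# Ground-truth generator: antibody-like three-body models with known
# geometry, instrument-like noisy scattering curves, and a fixture suite
# so the whole pipeline can be exercised end to end without any deposited
# data.

#' Build a ground-truth model with recorded geometric truths
#'
#' Presets: `"igg3_like"` is the long-hinged three-body default whose
#' P(r) shows three maxima and whose maximum dimension falls in the
#' 25-28 nm band characteristic of IgG3; `"compact_control"` is a
#' short-hinge (IgG1-like, 15-residue hinge) antibody with only two
#' resolvable maxima and Dmax below 18 nm; `"custom"` forwards
#' `geometry` to [build_three_body_model()].
#'
#' @param preset `"igg3_like"`, `"compact_control"` or `"custom"`.
#' @param seed integer seed (construction jitter).
#' @param glycans logical; include GLYCAN chains (the deglycosylated
#'   partner of a glycosylated truth uses the same seed with
#'   `glycans = FALSE`).
#' @param geometry named list of [build_three_body_model()] arguments,
#'   required for `"custom"`.
#' @return object of class `ground_truth`: `model` plus `true_rg`,
#'   `true_dmax`, `true_fab_fab`, `true_fab_fc` (length 2),
#'   `true_tip_separation` (all nm, recomputable from the coordinates),
#'   `seed`, `preset`.
#' @export
make_ground_truth <- function(preset = c("igg3_like", "compact_control",
                                         "custom"),
                              seed = 1, glycans = TRUE, geometry = NULL) {
  preset <- match.arg(preset)
  args <- switch(preset,
    igg3_like = list(),
    compact_control = list(
      hinge_residues = expand_hinge_sequence("EPKSCDKTHTCPPCP"),
      fab_lateral = 3.6, fab_axial = 1.4,
      fab_semiaxes = c(3.6, 2.3, 2.3), fc_semiaxes = c(2.9, 2.9, 3.1),
      pivot_profile = list(FAB_SIDE = 217:219, FC_SIDE = 227:228)),
    custom = {
      if (is.null(geometry))
        stop("custom preset requires a geometry argument list")
      geometry
    })
  args$seed <- seed
  args$glycans <- glycans
  model <- do.call(build_three_body_model, args)
  xyz <- model_coords(model)
  rr <- rigid_regions(model)
  com <- function(rg) colMeans(xyz[rr[[rg]], , drop = FALSE])
  dmax <- max(stats::dist(xyz))
  structure(list(
    model = model,
    true_rg = model_rg(model),
    true_dmax = dmax,
    true_fab_fab = sqrt(sum((com("FAB1") - com("FAB2"))^2)),
    true_fab_fc = c(sqrt(sum((com("FAB1") - com("FC"))^2)),
                    sqrt(sum((com("FAB2") - com("FC"))^2))),
    true_tip_separation = fab_tip_separation(model),
    seed = seed, preset = preset),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth [%s]: R_G %.2f nm, Dmax %.2f nm, Fab-Fab %.2f nm, tips %.2f nm\n",
    x$preset, x$true_rg, x$true_dmax, x$true_fab_fab,
    x$true_tip_separation))
  invisible(x)
}

#' Noise specification for simulated curves
#'
#' Defaults emulate reduced instrument data: X-ray curves on the 825-point
#' grid with low multiplicative noise and no background; neutron curves on
#' the 146-point grid, noisier (especially at high Q) and carrying a flat
#' incoherent background of 2 percent of I(0).
#'
#' @param modality `"xray"` or `"neutron"`.
#' @param relative_sigma0 base noise fraction of I(Q).
#' @param sigma_growth exponent of the (Q/Qmax) noise growth term.
#' @param background_fraction flat background as a fraction of I(0).
#' @param n_points grid size.
#' @param seed RNG seed for the noise draw.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(modality = c("xray", "neutron"),
                       relative_sigma0 = NULL, sigma_growth = 2,
                       background_fraction = NULL, n_points = NULL,
                       seed = 1) {
  modality <- match.arg(modality)
  if (is.null(relative_sigma0))
    relative_sigma0 <- if (modality == "xray") 0.01 else 0.04
  if (is.null(background_fraction))
    background_fraction <- if (modality == "xray") 0 else 0.02
  if (is.null(n_points)) n_points <- if (modality == "xray") 825L else 146L
  stopifnot(relative_sigma0 >= 0, sigma_growth >= 0,
            background_fraction >= 0, n_points >= 16)
  structure(list(modality = modality, relative_sigma0 = relative_sigma0,
                 sigma_growth = sigma_growth,
                 background_fraction = background_fraction,
                 n_points = as.integer(n_points), seed = seed),
            class = "noise_spec")
}

#' Simulate an instrument-like scattering curve from a ground truth
#'
#' Debye curve of the truth model on the modality grid, plus (neutron) a
#' flat background of `background_fraction` I(0), plus multiplicative
#' Gaussian noise with sigma(Q) = relative_sigma0 (1 + (Q/Qmax)^growth)
#' I(Q). The sigma column is emitted with the curve. Deterministic given
#' the noise seed.
#'
#' @param truth a `ground_truth`.
#' @param noise a [noise_spec()].
#' @param qmax upper Q, 1/nm.
#' @return a `scattering_curve` with `sigma`.
#' @export
simulate_curve <- function(truth, noise = noise_spec("xray"), qmax = 1.5) {
  Q <- seq(0, qmax, length.out = noise$n_points)
  base <- debye_curve(truth$model, Q, modality = noise$modality)
  I <- base$I + noise$background_fraction * base$I[1]
  sigma <- noise$relative_sigma0 * (1 + (Q / qmax)^noise$sigma_growth) * I
  set.seed(noise$seed)
  I_noisy <- I + stats::rnorm(length(I)) * sigma
  scattering_curve(Q, I_noisy, sigma = sigma, modality = noise$modality,
                   label = sprintf("synthetic-%s seed=%d", noise$modality,
                                   noise$seed))
}

#' Emit a complete synthetic fixture suite to a directory
#'
#' Writes a glycosylated/deglycosylated ground-truth model pair (same
#' construction seed, differing only in GLYCAN beads), four SAXS and four
#' SANS curves (two noise levels per model, emulating a concentration
#' series), light- and heavy-water buffer condition files, and a
#' `manifest.txt` of all recorded truths.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed integer master seed.
#' @return invisible list with `truths` (glyc/deglyc) and `files`.
#' @export
make_fixture_suite <- function(out_dir, seed = 17) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth_g <- make_ground_truth("igg3_like", seed = seed, glycans = TRUE)
  truth_d <- make_ground_truth("igg3_like", seed = seed, glycans = FALSE)
  files <- character(0)
  p <- function(...) file.path(out_dir, paste0(...))
  write_model(truth_g$model, p("model_glyc.txt"))
  write_model(truth_d$model, p("model_deglyc.txt"))
  files <- c(files, "model_glyc.txt", "model_deglyc.txt")
  saxs_noise <- c(0.01, 0.02)
  sans_noise <- c(0.04, 0.06)
  truths <- list(glyc = truth_g, deglyc = truth_d)
  k <- 0
  for (nm in names(truths)) {
    for (j in seq_along(saxs_noise)) {
      k <- k + 1
      cur <- simulate_curve(truths[[nm]],
                            noise_spec("xray", relative_sigma0 = saxs_noise[j],
                                       seed = seed + 100 + k))
      fn <- sprintf("saxs_%s_c%d.dat", nm, j)
      write_curve(cur, file.path(out_dir, fn)); files <- c(files, fn)
    }
    for (j in seq_along(sans_noise)) {
      k <- k + 1
      cur <- simulate_curve(truths[[nm]],
                            noise_spec("neutron",
                                       relative_sigma0 = sans_noise[j],
                                       seed = seed + 100 + k))
      fn <- sprintf("sans_%s_c%d.dat", nm, j)
      write_curve(cur, file.path(out_dir, fn)); files <- c(files, fn)
    }
  }
  writeLines(c("temperature 20", "density 1.00578", "viscosity 0.010190",
               "vbar 0.776"), p("buffer_light_water.txt"))
  writeLines(c("temperature 20", "density 1.11106", "viscosity 0.01384",
               "vbar 0.776"), p("buffer_heavy_water.txt"))
  files <- c(files, "buffer_light_water.txt", "buffer_heavy_water.txt")
  man <- unlist(lapply(names(truths), function(nm) {
    tr <- truths[[nm]]
    c(sprintf("%s_true_rg %.6f", nm, tr$true_rg),
      sprintf("%s_true_dmax %.6f", nm, tr$true_dmax),
      sprintf("%s_true_fab_fab %.6f", nm, tr$true_fab_fab),
      sprintf("%s_true_fab_fc1 %.6f", nm, tr$true_fab_fc[1]),
      sprintf("%s_true_fab_fc2 %.6f", nm, tr$true_fab_fc[2]),
      sprintf("%s_true_tip_separation %.6f", nm, tr$true_tip_separation))
  }))
  writeLines(c(sprintf("seed %d", seed), man), p("manifest.txt"))
  files <- c(files, "manifest.txt")
  invisible(list(truths = truths, files = file.path(out_dir, files)))
}
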