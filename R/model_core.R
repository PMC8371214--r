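#' The 70-residue IgG3 hinge in repeat notation
#'
#' The long IgG3 upper+core hinge written with its triple repeat; expanding
#' it with [expand_hinge_sequence()] gives 70 residues containing the 11
#' cysteines that form the inter-chain disulfide bridges.
#' @export
igg3_hinge_pattern <- "ELKTPLGDTTHTCPRCP(EPKSCDTPPPCPRCP)3APELLGGP"

#' Expand a repeat-notation sequence pattern
#'
#' Parses a single-letter amino-acid pattern with optional parenthesized
#' repeat groups, e.g. `"(AB)2C"` expands to `A B A B C`. Used for the
#' IgG3 hinge whose core region is a 15-residue triple repeat.
#'
#' @param pattern character scalar; single-letter codes with optional
#'   `"(...)"` groups followed by an integer repeat count (default 1).
#' @return character vector of single-letter residue codes.
#' @export
#' @examples
#' length(expand_hinge_sequence(igg3_hinge_pattern)) # 70
expand_hinge_sequence <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  chars <- strsplit(pattern, "")[[1]]
  out <- character(0)
  group <- NULL   # NULL = outside parentheses
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (!is.null(group)) stop("nested '(' at position ", i)
      group <- character(0)
      i <- i + 1
    } else if (ch == ")") {
      if (is.null(group)) stop("unmatched ')' at position ", i)
      j <- i + 1
      digits <- ""
      while (j <= n && grepl("[0-9]", chars[j])) {
        digits <- paste0(digits, chars[j]); j <- j + 1
      }
      rep_count <- if (nzchar(digits)) as.integer(digits) else 1L
      out <- c(out, rep(group, rep_count))
      group <- NULL
      i <- j
    } else if (ch %in% c(names(.AA1TO3), "B", "J", "O", "U", "X", "Z")) {
      # the 20 standard codes plus the IUPAC extended letters
      if (is.null(group)) out <- c(out, ch) else group <- c(group, ch)
      i <- i + 1
    } else {
      stop("invalid residue code '", ch, "' at position ", i)
    }
  }
  if (!is.null(group)) stop("unclosed '(' in pattern")
  out
}

#' Count cysteines in a residue list
#'
#' @param residues character vector of single-letter codes.
#' @return integer count of `"C"` entries.
#' @export
count_cysteines <- function(residues) {
  sum(residues == "C")
}

#' Per-glycan mass from deconvoluted intact masses
#'
#' Computes the mass of a single N-glycan chain from the deconvoluted
#' masses of the glycosylated and deglycosylated protein: the difference is
#' divided by the number of glycosylation sites (two for an IgG Fc).
#'
#' @param m_glyc,m_deglyc deconvoluted masses, Da; `m_glyc >= m_deglyc`.
#' @param n_sites number of glycan chains removed (>= 1).
#' @return mass per glycan chain, Da.
#' @export
glycan_mass_from_deconvolution <- function(m_glyc, m_deglyc, n_sites = 2) {
  stopifnot(n_sites >= 1)
  if (m_glyc < m_deglyc)
    stop("glycosylated mass is smaller than deglycosylated mass")
  (m_glyc - m_deglyc) / n_sites
}

#' Mass of a glycan from its residue-class composition
#'
#' Sums monoisotopic residue masses (monosaccharide minus water, as
#' attached) over a composition such as Gal2Man3GlcNAc4 =
#' `c(Hex = 5, HexNAc = 4)`.
#'
#' @param composition named numeric vector or list of residue-class counts;
#'   names from `c("Hex","HexNAc","NeuNAc","dHex")` (amino acids also allowed).
#' @return total mass, Da.
#' @export
glycan_composition_mass <- function(composition) {
  composition <- unlist(composition)
  if (length(composition) == 0) return(0)
  counts <- as.numeric(composition)
  stopifnot(all(counts >= 0))
  unknown <- setdiff(names(composition), names(composition_table))
  if (length(unknown))
    stop("unknown residue class: ", paste(unknown, collapse = ", "))
  sum(counts * composition_table[names(composition)])
}

# ---- BeadModel ---------------------------------------------------------

#' Construct a bead model
#'
#' A bead model is the conformer unit of the pipeline: an ordered table of
#' coarse-grained sites (one bead per residue) tagged with rigid regions
#' (FAB1, FAB2, FC, HINGE, GLYCAN), plus hinge pivot sets for torsion-angle
#' Monte Carlo and a continuous-to-EU numbering offset.
#'
#' @param sites data.frame with columns `index`, `chain`, `resno`,
#'   `resname`, `region`, `x`, `y`, `z` (nm), `f` (scattering weight),
#'   `mass` (Da).
#' @param pivot_sets named list of integer residue-number vectors; names
#'   are the moving side (`"FAB_SIDE"` or `"FC_SIDE"`). Pivot residues must
#'   lie in the HINGE region or its immediate anchor continuation.
#' @param provenance free-text origin note.
#' @param eu_offset integer added to continuous residue numbers to obtain
#'   EU numbering in the Fc (Asn344 continuous = Asn297 EU gives -47).
#' @return object of class `bead_model`.
#' @export
bead_model <- function(sites, pivot_sets = list(), provenance = "",
                       eu_offset = -47L) {
  m <- structure(list(sites = sites, pivot_sets = pivot_sets,
                      provenance = provenance, eu_offset = eu_offset),
                 class = "bead_model")
  validate_bead_model(m)
  m
}

#' Validate bead-model invariants
#'
#' Checks finite positions, region assignment, uniqueness of
#' (chain, residue number) and strictly increasing residue numbers within
#' each chain. Called by the constructor and the readers.
#'
#' @param m a `bead_model`.
#' @return the model, invisibly; errors describe the violated invariant.
#' @export
validate_bead_model <- function(m) {
  s <- m$sites
  need <- c("index", "chain", "resno", "resname", "region",
            "x", "y", "z", "f", "mass")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols))
    stop("sites table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(as.matrix(s[, c("x", "y", "z")]))))
    stop("non-finite coordinates in sites table")
  bad <- setdiff(unique(s$region), .REGIONS)
  if (length(bad)) stop("unknown region tag: ", paste(bad, collapse = ", "))
  key <- paste(s$chain, s$resno)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (chain, residue number): ", d)
  }
  for (ch in unique(s$chain)) {
    r <- s$resno[s$chain == ch]
    if (any(diff(r) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  invisible(m)
}

#' Coordinates of a bead model
#' @param m a `bead_model`.
#' @return numeric matrix, one row per site, columns x/y/z in nm.
#' @export
model_coords <- function(m) {
  as.matrix(m$sites[, c("x", "y", "z")])
}

#' Replace the coordinates of a bead model
#' @param m a `bead_model`.
#' @param xyz matrix with as many rows as sites.
#' @return the model with new coordinates.
#' @export
set_model_coords <- function(m, xyz) {
  stopifnot(nrow(xyz) == nrow(m$sites))
  m$sites[, c("x", "y", "z")] <- xyz
  m
}

#' Rigid-region site index sets
#' @param m a `bead_model`.
#' @return named list mapping each region present to its site indices.
#' @export
rigid_regions <- function(m) {
  split(seq_len(nrow(m$sites)), m$sites$region)
}

#' Radius of gyration from bead coordinates
#'
#' Scattering-weight-weighted second moment of the bead positions about
#' their center; the real-space counterpart of the Guinier radius.
#'
#' @param m a `bead_model`.
#' @return radius of gyration, nm.
#' @export
model_rg <- function(m) {
  coord_rg(model_coords(m), m$sites$f)
}

#' @export
print.bead_model <- function(x, ...) {
  tab <- table(x$sites$region)
  cat("bead_model:", nrow(x$sites), "sites |",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  if (length(x$pivot_sets))
    cat("  pivots:", paste(names(x$pivot_sets),
        vapply(x$pivot_sets, function(p) paste(range(p), collapse = "-"), ""),
        sep = " ", collapse = "; "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# ---- three-body construction ------------------------------------------

# lattice points filling an ellipsoid (semi-axes sa, nm) centered at origin
.ellipsoid_lattice <- function(sa, spacing) {
  g <- lapply(sa, function(a) {
    k <- floor(a / spacing)
    seq(-k, k) * spacing
  })
  pts <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
  keep <- rowSums(sweep(pts, 2, sa, "/")^2) <= 1
  unname(pts[keep, , drop = FALSE])
}

# regular helix of n beads: per-residue rise (nm) and twist (rad); radius
# chosen so consecutive beads sit `bond` nm apart. Starts at z = 0, goes -z.
.helix_chain <- function(n, bond, rise, twist) {
  r <- sqrt(bond^2 - rise^2) / (2 * sin(twist / 2))
  i <- seq_len(n) - 1
  cbind(r * cos(i * twist), r * sin(i * twist), -i * rise)
}

#' Build a coarse-grained three-body antibody model
#'
#' Constructs a full-length antibody-like bead model: two Fab ellipsoids
#' attached at the N-terminal end of an extended hinge bead chain, and an
#' Fc ellipsoid carried by a rigid anchor segment (the SVFLFPPK peptide of
#' the Fc, shared with the FC region) at the hinge C-terminus. Optionally
#' two 11-residue biantennary glycan chains are placed on the Fc surface.
#' One bead per residue; coordinates in nm; unit scattering lengths.
#'
#' @param hinge_residues character vector of single-letter hinge codes;
#'   default is the expanded 70-residue IgG3 hinge.
#' @param fab_semiaxes,fc_semiaxes ellipsoid semi-axes, nm.
#' @param bead_spacing lattice spacing for the Fab/Fc bead fill, nm.
#' @param hinge_rise per-residue axial rise of the hinge chain, nm; the
#'   default gives an end-to-end hinge length near 10 nm.
#' @param hinge_twist per-residue twist, radians.
#' @param bond virtual bond length between consecutive hinge beads, nm.
#' @param fab_lateral lateral (x) offset of each Fab center from the hinge
#'   axis, nm; the Fab-Fab center separation is twice this value.
#' @param fab_axial axial (z) offset of the Fab centers above the hinge
#'   N-terminus, nm.
#' @param fab_tilt tilt of each Fab long axis from the hinge axis, radians
#'   (0 = both Fabs parallel to the hinge, pointing away from the Fc).
#' @param fc_gap clearance between the anchor end and the Fc surface, nm.
#' @param glycans logical; add two GLYCAN chains on the Fc.
#' @param jitter amplitude of uniform coordinate jitter applied to the
#'   Fab/Fc lattice beads, nm (roughens the artificial lattice).
#' @param min_region_separation construction check: minimum allowed
#'   distance between region centers of mass, nm.
#' @param pivot_profile pivot sets recorded on the model; default
#'   [tamc_pivot_profile()]`("glycosylated")`.
#' @param seed integer seed controlling the lattice jitter.
#' @return a `bead_model`.
#' @export
build_three_body_model <- function(hinge_residues = expand_hinge_sequence(igg3_hinge_pattern),
                                   fab_semiaxes = c(4.4, 2.4, 2.4),
                                   fc_semiaxes = c(3.1, 3.1, 3.6),
                                   bead_spacing = 0.8,
                                   hinge_rise = 0.152,
                                   hinge_twist = 2 * pi / 3,
                                   bond = 0.38,
                                   fab_lateral = 4.5,
                                   fab_axial = 3.1,
                                   fab_tilt = 25 * pi / 180,
                                   fc_gap = 0.45,
                                   glycans = TRUE,
                                   jitter = 0.06,
                                   min_region_separation = 1.5,
                                   pivot_profile = tamc_pivot_profile("glycosylated"),
                                   seed = 1) {
  stopifnot(length(hinge_residues) >= 10, bead_spacing > 0, bond > hinge_rise)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  n_h <- length(hinge_residues)
  hinge_start_resno <- 216L

  hinge_xyz <- .helix_chain(n_h, bond, hinge_rise, hinge_twist)
  z_end <- hinge_xyz[n_h, 3]

  # rigid anchor segment (SVFLFPPK), straight continuation on the hinge axis
  anchor_seq <- c("S", "V", "F", "L", "F", "P", "P", "K")
  n_a <- length(anchor_seq)
  anchor_xyz <- cbind(0, 0, z_end - 0.35 * seq_len(n_a))
  z_anchor_end <- anchor_xyz[n_a, 3]

  # Fc ellipsoid, top surface near the hinge end so the anchor is embedded
  fc_center <- c(0, 0, z_end - fc_gap - fc_semiaxes[3])
  fc_pts <- sweep(.ellipsoid_lattice(fc_semiaxes, bead_spacing),
                  2, fc_center, "+")
  glyc_df <- .glycan_chains(fc_center, fc_semiaxes)
  # carve lattice beads that overlap the embedded anchor or the glycan
  # attachment region (before jitter, so the topology is seed-invariant)
  obstacles <- rbind(anchor_xyz, as.matrix(glyc_df[, c("x", "y", "z")]))
  keep <- apply(fc_pts, 1, function(p)
    min(sqrt(colSums((t(obstacles) - p)^2))) > 0.45)
  fc_pts <- fc_pts[keep, , drop = FALSE]
  fc_pts <- fc_pts + matrix(stats::runif(length(fc_pts), -jitter, jitter),
                            nrow(fc_pts), 3)
  if (!glycans) glyc_df <- NULL

  # Fabs: tilted ellipsoids, long axes pointing up and away from the hinge
  attach <- c(0, 0, 0.2)
  fab_sites <- lapply(c(1, -1), function(s) {
    center <- attach + c(s * fab_lateral, 0, fab_axial)
    u <- c(s * sin(fab_tilt), 0, cos(fab_tilt))
    # rotate lattice so its first (long) axis lies along u
    ref <- c(1, 0, 0)
    ax <- c(ref[2] * u[3] - ref[3] * u[2],
            ref[3] * u[1] - ref[1] * u[3],
            ref[1] * u[2] - ref[2] * u[1])
    ang <- acos(max(-1, min(1, sum(ref * u))))
    R <- if (sqrt(sum(ax^2)) < 1e-9) diag(3) else rotation_matrix(ax, ang)
    pts <- .ellipsoid_lattice(fab_semiaxes, bead_spacing) %*% t(R)
    pts <- pts + matrix(stats::runif(length(pts), -jitter, jitter),
                        nrow(pts), 3)
    sweep(pts, 2, center, "+")
  })

  site_block <- function(xyz, chain, resno, resname, region, mass) {
    data.frame(chain = chain, resno = resno, resname = resname,
               region = region, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               f = 1, mass = mass, stringsAsFactors = FALSE)
  }
  aa_mass <- function(codes) unname(composition_table[codes])

  blocks <- list(
    site_block(fab_sites[[1]], "A", seq_len(nrow(fab_sites[[1]])), "UNK",
               "FAB1", .MASS_UNK),
    site_block(fab_sites[[2]], "B", seq_len(nrow(fab_sites[[2]])), "UNK",
               "FAB2", .MASS_UNK),
    site_block(hinge_xyz, "H",
               hinge_start_resno + seq_len(n_h) - 1L,
               unname(.AA1TO3[hinge_residues]), "HINGE",
               aa_mass(hinge_residues)),
    site_block(anchor_xyz, "H",
               hinge_start_resno + n_h + seq_len(n_a) - 1L,
               unname(.AA1TO3[anchor_seq]), "FC", aa_mass(anchor_seq)),
    site_block(fc_pts, "F", seq_len(nrow(fc_pts)), "UNK", "FC", .MASS_UNK)
  )

  if (glycans) blocks <- c(blocks, list(glyc_df))

  sites <- do.call(rbind, blocks)
  sites$index <- seq_len(nrow(sites)) - 1L
  sites <- sites[, c("index", "chain", "resno", "resname", "region",
                     "x", "y", "z", "f", "mass")]

  m <- bead_model(sites, pivot_sets = pivot_profile,
                  provenance = sprintf("build_three_body_model seed=%d", seed))

  # construction sanity: region centers well separated, no inter-region clash
  coms <- lapply(rigid_regions(m), function(i)
    colMeans(model_coords(m)[i, , drop = FALSE]))
  nm <- names(coms)
  for (i in seq_along(coms)) for (j in seq_len(i - 1)) {
    d <- sqrt(sum((coms[[i]] - coms[[j]])^2))
    if (d < min_region_separation)
      stop("region centers ", nm[i], "/", nm[j],
           " closer than min_region_separation (", round(d, 2), " nm)")
  }
  cr <- detect_clash(m, cutoff = 0.35)
  if (cr$clash_count > 0)
    stop("construction produced ", cr$clash_count, " steric clashes")
  m
}

# two biantennary 11-residue glycan bead chains on the Fc surface
.glycan_chains <- function(fc_center, fc_semiaxes) {
  resname <- c("NAG", "NAG", "BMA", "MAN", "MAN",
               "NAG", "GAL", "SIA", "NAG", "GAL", "SIA")
  classes <- c("HexNAc", "HexNAc", "Hex", "Hex", "Hex",
               "HexNAc", "Hex", "NeuNAc", "HexNAc", "Hex", "NeuNAc")
  mk <- function(side, chain) {
    start <- fc_center + c(side * (fc_semiaxes[1] * 0.75 + 0.55), 0,
                           fc_semiaxes[3] * 0.55)
    u <- c(side * 0.8, 0.2, 0.55); u <- u / sqrt(sum(u^2))
    v <- c(side * 0.3, 0.9, 0.3);  v <- v / sqrt(sum(v^2))
    core <- t(sapply(0:4, function(k) start + k * 0.45 * u))
    b5 <- core[5, ]
    br1 <- t(sapply(1:3, function(k) b5 + k * 0.45 * (0.7 * u + 0.7 * v)))
    br2 <- t(sapply(1:3, function(k) b5 + k * 0.45 * (0.7 * u - 0.7 * v)))
    xyz <- rbind(core, br1, br2)
    data.frame(chain = chain, resno = 1:11, resname = resname,
               region = "GLYCAN", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               f = 1, mass = unname(composition_table[classes]),
               stringsAsFactors = FALSE)
  }
  rbind(mk(1, "Y"), mk(-1, "Z"))
}
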