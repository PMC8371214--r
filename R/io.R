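# Coordinate I/O: PDB fixed-column atom records (through bio3d) and a
# plain whitespace bead-table dialect. Internal units are nm; PDB files
# are written/read in Angstrom.

.SEGID_OF <- c(FAB1 = "FAB1", FAB2 = "FAB2", FC = "FC", HINGE = "HING",
               GLYCAN = "GLYC")
.REGION_OF <- structure(names(.SEGID_OF), names = unname(.SEGID_OF))

# residue mass lookup from a 3-letter (or glycan) residue name
.resname_mass <- function(resname) {
  one <- .AA3TO1[resname]
  gly <- c(NAG = "HexNAc", BMA = "Hex", MAN = "Hex", GAL = "Hex",
           SIA = "NeuNAc", FUC = "dHex")[resname]
  m <- ifelse(!is.na(one), composition_table[one],
              ifelse(!is.na(gly), composition_table[gly], .MASS_UNK))
  unname(m)
}

#' Write a bead model to disk
#'
#' Formats: `"pdb"` writes fixed-column atom records (one CA pseudo-atom
#' per bead, coordinates in Angstrom, region tag in the segid column);
#' `"bead"` writes the whitespace table
#' `index chain resno resname region x y z` with coordinates in nm.
#'
#' @param m a `bead_model`.
#' @param path output file; with `format = "auto"`, a `.pdb` extension
#'   selects PDB, anything else the bead table.
#' @param format `"auto"`, `"pdb"` or `"bead"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path, format = c("auto", "pdb", "bead")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "bead"
  s <- m$sites
  if (format == "pdb") {
    n <- nrow(s)
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(model_coords(m) * 10)),
                     resno = s$resno, resid = s$resname,
                     chain = s$chain, elety = rep("CA", n),
                     eleno = seq_len(n), o = rep(1, n), b = rep(0, n),
                     segid = unname(.SEGID_OF[s$region]),
                     print.segid = TRUE)
  } else {
    df <- data.frame(index = s$index, chain = s$chain, resno = s$resno,
                     resname = s$resname, region = s$region,
                     x = sprintf("%.6f", s$x), y = sprintf("%.6f", s$y),
                     z = sprintf("%.6f", s$z))
    utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a bead model from disk
#'
#' Inverse of [write_model()]: reads PDB atom records (extra columns such
#' as occupancy/B-factor are ignored; region recovered from segid) or the
#' bead-table dialect. Round-trips preserve coordinates to better than
#' 0.001 nm and region tags exactly.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"bead"`.
#' @param pivot_sets pivot sets to attach to the model (not stored in
#'   coordinate files); default the glycosylated profile.
#' @return a validated `bead_model`.
#' @export
read_model <- function(path, format = c("auto", "pdb", "bead"),
                       pivot_sets = tamc_pivot_profile("glycosylated")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "bead"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    region <- .REGION_OF[trimws(a$segid)]
    if (anyNA(region))
      stop("unrecognized region segid in ", path, ": ",
           paste(unique(a$segid[is.na(region)]), collapse = ", "))
    s <- data.frame(index = seq_len(nrow(a)) - 1L, chain = a$chain,
                    resno = a$resno, resname = a$resid,
                    region = unname(region),
                    x = a$x / 10, y = a$y / 10, z = a$z / 10,
                    f = 1, mass = .resname_mass(a$resid),
                    stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    need <- c("index", "chain", "resno", "resname", "region", "x", "y", "z")
    if (!identical(header, need))
      stop("line 1: expected header '", paste(need, collapse = " "), "'")
    rows <- lapply(seq_along(lines)[-1], function(i) {
      fld <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(fld) != 8) stop("line ", i, ": expected 8 fields")
      num <- suppressWarnings(as.numeric(fld[c(1, 3, 6, 7, 8)]))
      if (anyNA(num)) stop("line ", i, ": non-numeric value")
      data.frame(index = as.integer(num[1]), chain = fld[2],
                 resno = as.integer(num[2]), resname = fld[4],
                 region = fld[5], x = num[3], y = num[4], z = num[5],
                 f = 1, mass = .resname_mass(fld[4]),
                 stringsAsFactors = FALSE)
    })
    s <- do.call(rbind, rows)
  }
  bead_model(s, pivot_sets = pivot_sets,
             provenance = paste("read from", path))
}

#' Write a scattering curve as a 2-3 column text file
#' @param curve a `scattering_curve`.
#' @param path output path; columns Q, I and (when present) sigma.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(Q = curve$Q, I = curve$I)
  if (!is.null(curve$sigma)) df$sigma <- curve$sigma
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scattering curve from a 2-3 column text file
#' @param path input path (whitespace or comma separated; optional header).
#' @param modality `"xray"` or `"neutron"`.
#' @param label free-text label.
#' @return a `scattering_curve`.
#' @export
read_curve <- function(path, modality = "xray", label = basename(path)) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), if (sep == ",") "," else "\\s+")[[1]][1])))
  df <- utils::read.table(path, header = has_header, sep = sep)
  scattering_curve(Q = df[[1]], I = df[[2]],
                   sigma = if (ncol(df) >= 3) df[[3]] else NULL,
                   modality = modality, label = label)
}
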