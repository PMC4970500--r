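## File readers and writers: PDB atomic models, CCP4/MRC density maps,
## CXI/HDF5 output, and synthetic fixture generation.

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records of the first model into an `fxi_atoms`
#' particle. Elements come from the element column with an atom-name
#' heuristic as fallback; coordinates are converted from Angstrom to m and
#' centred on the model's centre of geometry. Waters and hydrogens are
#' included by default. When alternate locations are present, only the
#' highest-occupancy conformer of each atom is kept.
#'
#' @param path Path to a PDB file.
#' @param drop_waters Drop water residues (HOH/WAT/DOD)?
#' @param drop_hydrogens Drop hydrogen (and deuterium) atoms?
#' @param center Subtract the centre of geometry (default `TRUE`).
#' @return An `fxi_atoms` particle.
#' @export
read_pdb <- function(path, drop_waters = FALSE, drop_hydrogens = FALSE,
                     center = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  ## alternate locations: keep the highest-occupancy conformer per atom
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    occ <- at$o
    occ[is.na(occ)] <- 1
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt != ""])) {
      sel <- which(key == k)
      if (length(sel) > 1) {
        best <- sel[which.max(occ[sel])]
        keep[setdiff(sel, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  sym <- toupper(trimws(at$elesy))
  miss <- is.na(sym) | sym == ""
  if (any(miss)) sym[miss] <- .element_from_atom_name(at$elety[miss])
  if (drop_waters) {
    w <- toupper(at$resid) %in% c("HOH", "WAT", "DOD")
    at <- at[!w, , drop = FALSE]; sym <- sym[!w]
  }
  if (drop_hydrogens) {
    h <- sym %in% c("H", "D")
    at <- at[!h, , drop = FALSE]; sym <- sym[!h]
  }
  sym[sym == "D"] <- "H"
  pos <- cbind(at$x, at$y, at$z) * 1e-10
  if (center) pos <- sweep(pos, 2, colMeans(pos))
  particle_atoms(pos, element_number(sym))
}

## guess the element from a PDB atom name: strip digits, prefer known
## two-letter symbols (metal ions etc.), else the first letter
.element_from_atom_name <- function(name) {
  s <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(s, 1, 2)
  known2 <- c("FE", "ZN", "MG", "MN", "SE", "BR", "CL", "CU")
  ifelse(two %in% known2, two, substr(s, 1, 1))
}

## ---- CCP4/MRC maps ---------------------------------------------------------

#' Read a CCP4/MRC 2014 density map
#'
#' Reads a mode-2 (float32) map on a cubic grid. The MAPC/MAPR/MAPS axis
#' permutation in the header is honoured, so the returned array is always
#' indexed `[x, y, z]` in the lab frame. Non-cubic maps are rejected.
#'
#' @param path Path to an MRC/CCP4 file.
#' @param kind Interpretation of the voxel values, as in [particle_map()].
#' @param material Material for `kind = "atom_density"`.
#' @return An `fxi_map` particle with spacing from the header (converted
#'   Angstrom to m).
#' @export
read_map <- function(path, kind = "electron_density", material = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, integer(), n = 10, size = 4, endian = "little")
  cella <- readBin(con, numeric(), n = 3, size = 4, endian = "little")
  cellb <- readBin(con, numeric(), n = 3, size = 4, endian = "little")
  axes <- readBin(con, integer(), n = 3, size = 4, endian = "little")
  readBin(con, numeric(), n = 3, size = 4, endian = "little")  # dmin/max/mean
  readBin(con, integer(), n = 2, size = 4, endian = "little")  # ispg, nsymbt
  readBin(con, raw(), n = 1024 - 24 * 4)                       # rest of header
  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  if (mode != 2) stop("unsupported MRC mode word: ", mode,
                      " (only mode 2, float32, is supported)")
  if (!all(axes %in% 1:3) || length(unique(axes)) != 3) {
    stop("invalid MAPC/MAPR/MAPS axis permutation in header")
  }
  vals <- readBin(con, numeric(), n = nc * nr * ns, size = 4,
                  endian = "little")
  a <- array(vals, dim = c(nc, nr, ns))
  vol <- aperm(a, match(1:3, axes))
  d <- dim(vol)
  if (length(unique(d)) != 1) {
    stop("map is not cubic (", paste(d, collapse = " x "),
         "); only cubic grids are supported")
  }
  spacing <- cella / c(mx, my, mz) * 1e-10
  if (diff(range(spacing)) > 1e-6 * mean(spacing)) {
    stop("anisotropic voxel spacing; only cubic grids are supported")
  }
  particle_map(vol, spacing[1], kind = kind, material = material)
}

#' Write a map to CCP4/MRC 2014 format
#'
#' Writes real voxel values as a mode-2 (float32) map. Mainly intended for
#' generating test fixtures and for exporting [map_from_geometry()] output.
#'
#' @param values Cubic 3-D array, indexed `[x, y, z]`.
#' @param dx Voxel spacing in m.
#' @param path Output path.
#' @param axis_order Length-3 permutation written as MAPC/MAPR/MAPS
#'   (default `c(1, 2, 3)`: x fastest).
#' @return `path`, invisibly.
#' @export
write_map <- function(values, dx, path, axis_order = c(1, 2, 3)) {
  d <- dim(values)
  stopifnot(length(d) == 3, length(unique(d)) == 1,
            all(sort(axis_order) == 1:3))
  n <- d[1]
  ## permute so that the file's column axis is axis_order[1], etc.
  a <- aperm(values, axis_order)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(n, n, n, 2L, 0L, 0L, 0L, n, n, n)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(rep(n * dx * 1e10, 3), 90, 90, 90)), con,
           size = 4, endian = "little")
  writeBin(as.integer(axis_order), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(a), max(a), mean(a))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  extra <- integer(25)
  extra[3] <- 20140L  # NVERSION
  writeBin(extra, con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  writeBin(as.numeric(stats::sd(a)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                     # nlabl
  writeBin(raw(200 * 4), con)                                        # labels
  writeBin(as.numeric(a), con, size = 4, endian = "little")
  invisible(path)
}

## ---- CXI/HDF5 output -------------------------------------------------------

#' Write shot results to a CXI (HDF5) file
#'
#' Writes the sampled detector frames, mask and geometry in the Coherent
#' X-ray Imaging layout (`/entry_1/instrument_1/detector_1/data` etc.),
#' plus per-shot simulation ground truth (particle species, positions,
#' orientations, beam tilt, pulse energy) under the non-standard group
#' `/entry_1/simulation_1` so downstream algorithm development has labels.
#'
#' @param results List of shot results from [propagate()].
#' @param path Output path (overwritten if it exists).
#' @param config The `fxi_experiment` the shots came from.
#' @return `path`, invisibly.
#' @export
write_cxi <- function(results, path, config) {
  stopifnot(length(results) >= 1, inherits(config, "fxi_experiment"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  det <- config$detector; src <- config$source
  nsh <- length(results)
  ## shots x ny x nx arrays
  data <- array(0L, dim = c(nsh, det$ny, det$nx))
  mask <- array(0L, dim = c(nsh, det$ny, det$nx))
  for (s in seq_len(nsh)) {
    data[s, , ] <- results[[s]]$intensity$sampled
    mask[s, , ] <- results[[s]]$intensity$mask
  }
  for (g in c("entry_1", "entry_1/instrument_1",
              "entry_1/instrument_1/detector_1",
              "entry_1/instrument_1/source_1",
              "entry_1/simulation_1")) {
    rhdf5::h5createGroup(path, g)
  }
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  h5w(data, "entry_1/instrument_1/detector_1/data")
  h5w(mask, "entry_1/instrument_1/detector_1/mask")
  h5w(det$detector_distance, "entry_1/instrument_1/detector_1/distance")
  h5w(det$pixel_size, "entry_1/instrument_1/detector_1/x_pixel_size")
  h5w(det$pixel_size, "entry_1/instrument_1/detector_1/y_pixel_size")
  h5w(src$photon_energy * .const$e, "entry_1/instrument_1/source_1/energy")
  h5w(src$wavelength, "entry_1/instrument_1/source_1/wavelength")
  ## ground truth: one flat table of particle instances across shots
  rows <- list()
  for (s in seq_len(nsh)) {
    for (inst in results[[s]]$instances) {
      p <- inst$particle
      q <- if (!is.null(p$orientation)) as.numeric(p$orientation)
           else c(1, 0, 0, 0)
      rows[[length(rows) + 1]] <- c(
        s, inst$position,
        if (!is.null(p$diameter)) p$diameter else NA_real_,
        if (!is.null(p$flattening)) p$flattening else NA_real_,
        q)
    }
  }
  if (length(rows) > 0) {
    tab <- do.call(rbind, rows)
    colnames(tab) <- c("shot", "x", "y", "z", "diameter", "flattening",
                       "quat_w", "quat_x", "quat_y", "quat_z")
    h5w(tab, "entry_1/simulation_1/particles")
    labels <- unlist(lapply(seq_len(nsh), function(s)
      vapply(results[[s]]$instances, function(i) i$label, character(1))))
    h5w(labels, "entry_1/simulation_1/particle_species")
  }
  h5w(vapply(results, function(r) r$pulse_energy, numeric(1)),
      "entry_1/simulation_1/pulse_energy")
  h5w(t(vapply(results, function(r) r$beam_tilt, numeric(2))),
      "entry_1/simulation_1/beam_tilt")
  rhdf5::h5closeAll()
  invisible(path)
}

## ---- synthetic fixtures ----------------------------------------------------

#' Generate synthetic test inputs
#'
#' Produces deterministic (per seed) synthetic stand-ins for the external
#' inputs a simulation can consume: coil-like random atom clusters with
#' protein-like element frequencies, filled-shape density maps, matching
#' PDB and MRC files, and a minimal configuration file.
#'
#' @param kind One of `"atoms"`, `"map"`, `"pdb-file"`, `"mrc-file"`,
#'   `"config"`.
#' @param seed Integer RNG seed.
#' @param n Number of atoms (atom kinds).
#' @param radius Bounding-sphere radius of the atom cluster, m.
#' @param shape,diameter,dx Map parameters, see [map_from_geometry()].
#' @param path Output path for the file kinds.
#' @return The generated object, or `path` for file kinds.
#' @export
#' @examples
#' a <- generate_fixtures("atoms", seed = 1, n = 100)
generate_fixtures <- function(kind = c("atoms", "map", "pdb-file",
                                       "mrc-file", "config"),
                              seed = 1, n = 500, radius = 5e-9,
                              shape = "icosahedron", diameter = 3.2e-8,
                              dx = 1e-9, path = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "atoms" || kind == "pdb-file") {
    ## self-avoiding-ish random coil confined to a bounding sphere
    step <- 1.5e-10
    pos <- matrix(0, nrow = n, ncol = 3)
    for (i in 2:n) {
      repeat {
        cand <- pos[i - 1, ] + stats::rnorm(3) * step
        if (sum(cand^2) < radius^2) break
      }
      pos[i, ] <- cand
    }
    ## protein-like element frequencies (heavy-atom skew, H included)
    sym <- sample(c("H", "C", "N", "O", "S"), n, replace = TRUE,
                  prob = c(0.48, 0.31, 0.09, 0.11, 0.01))
    at <- particle_atoms(sweep(pos, 2, colMeans(pos)), element_number(sym))
    if (kind == "atoms") return(at)
    if (is.null(path)) path <- tempfile(fileext = ".pdb")
    return(write_pdb_atoms(at, path))
  }
  if (kind == "map" || kind == "mrc-file") {
    m <- map_from_geometry(shape, diameter, dx, "water")
    if (kind == "map") return(m)
    if (is.null(path)) path <- tempfile(fileext = ".mrc")
    ## store as electron-density-like values for generic consumption
    return(write_map(Re(m$values), m$dx, path))
  }
  ## minimal config
  if (is.null(path)) path <- tempfile(fileext = ".conf")
  writeLines(c(
    "[source]",
    "photon_energy = 1000",
    "pulse_energy = 1e-3",
    "focus_diameter = 1e-6",
    "",
    "[particle_sphere1]",
    "model = sphere",
    "diameter = 2e-8",
    "material = water",
    "",
    "[detector]",
    "nx = 32",
    "ny = 32",
    "pixel_size = 300e-6",
    "distance = 0.74"
  ), path)
  path
}

#' Write an atomic particle as a PDB file
#'
#' Writes an `fxi_atoms` particle as HETATM records (coordinates converted
#' m to Angstrom). Used to build synthetic PDB fixtures.
#'
#' @param at An `fxi_atoms` particle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(at, path) {
  stopifnot(inherits(at, "fxi_atoms"))
  sym <- toupper(element_symbol(at$elements))
  xyz <- at$positions * 1e10
  lines <- vapply(seq_along(at$elements), function(i) {
    sprintf("HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i %% 100000, substr(sym[i], 1, 4), "LIG", "A",
            ((i - 1) %/% 9999) + 1,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0, sym[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
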