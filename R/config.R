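## INI-style experiment configuration: three mandatory section types
## ([source], one or more [particle_*], [detector]) plus an optional
## [simulation] section. All quantities are SI; unspecified keys take the
## documented defaults; unknown keys fail fast.

## valid keys and defaults per section type; NA means "no default,
## computed or required elsewhere"
.config_schema <- function() {
  list(
    source = list(
      photon_energy = NA,          # eV (give this or wavelength)
      wavelength = NA,             # m
      pulse_energy = 1e-3,         # J
      focus_diameter = 1e-6,       # m
      profile = "flat-top",        # flat-top | gaussian
      pulse_energy_jitter = 0,     # J (sigma, truncated at 0)
      beam_tilt_sigma = 0          # rad (per-shot 2-D normal)
    ),
    detector = list(
      nx = 64, ny = 64,
      pixel_size = 75e-6,          # m
      distance = 0.74,             # m
      center_x = NA, center_y = NA,  # pixel units; default (n-1)/2
      saturation_level = Inf,      # photons
      quantum_efficiency = 1,
      polarization = "ignore",     # ignore|horizontal|vertical|unpolarized
      read_noise_sigma = 0         # photons
    ),
    particle = list(
      model = NA_character_,       # sphere | spheroid | map | atoms (required)
      material = "water",
      diameter = 1e-8,             # m (sphere/spheroid; equal-volume sphere)
      diameter_sigma = 0,          # m
      flattening = 1,
      flattening_min = NA, flattening_max = NA,
      map_file = NA_character_,    # MRC path (map model)
      map_values = "electron_density",
      shape = NA_character_,       # sphere|spheroid|icosahedron (geometric map)
      map_dx = 1e-9,               # m
      pdb_file = NA_character_,    # PDB path (atoms model)
      arrival_rate = NA,           # Poisson mean; omit for a fixed count
      count = 1,                   # fixed instances/shot when no arrival_rate
      position = "fixed",          # fixed | uniform-in-focus | normal
      position_x = 0, position_y = 0,  # m (fixed)
      position_sigma = 0,          # m (normal)
      orientation = "fixed",       # fixed | random
      euler_angles = "0,0,0",      # rad, comma triple (fixed orientation)
      euler_order = "xyz"
    ),
    simulation = list(
      seed = 1,
      shots = 1,
      output = "fxisim_out.cxi"
    )
  )
}

.parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); sect <- NULL
  for (ln in lines) {
    ln <- sub("[#;].*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      sect <- gsub("^\\[|\\]$", "", ln)
      out[[sect]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(sect)) stop("key outside any section: ", ln)
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      out[[sect]][[trimws(kv[1])]] <- trimws(kv[2])
    } else {
      stop("malformed configuration line: ", ln)
    }
  }
  out
}

.coerce_value <- function(raw, default) {
  if (is.character(default) || is.na(suppressWarnings(as.numeric(raw)))) {
    num <- suppressWarnings(as.numeric(raw))
    if (is.character(default)) return(raw)
    if (tolower(raw) %in% c("inf", "infinity")) return(Inf)
    if (is.na(num)) stop("malformed numeric value: '", raw, "'")
    return(num)
  }
  as.numeric(raw)
}

.apply_schema <- function(given, schema, section) {
  unknown <- setdiff(names(given), names(schema))
  if (length(unknown) > 0) {
    nearest <- names(schema)[apply(utils::adist(unknown, names(schema)),
                                   1, which.min)]
    stop(sprintf("unknown key(s) in [%s]: %s (did you mean: %s?)",
                 section, paste(unknown, collapse = ", "),
                 paste(nearest, collapse = ", ")))
  }
  out <- schema
  for (k in names(given)) out[[k]] <- .coerce_value(given[[k]], schema[[k]])
  out
}

.species_from_config <- function(cfg, section, base_dir) {
  model <- cfg$model
  if (is.na(model)) stop("[", section, "] must name a model ",
                         "(sphere, spheroid, map or atoms)")
  resolve_path <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  orientation <- if (identical(cfg$orientation, "fixed")) {
    ang <- as.numeric(strsplit(cfg$euler_angles, ",")[[1]])
    if (length(ang) != 3 || anyNA(ang)) {
      stop("euler_angles must be a comma-separated triple")
    }
    rotation_from_euler(ang, cfg$euler_order)
  } else NULL
  template <- switch(model,
    sphere = particle_sphere(cfg$diameter, cfg$material),
    spheroid = particle_spheroid(cfg$diameter, cfg$flattening, cfg$material,
                                 orientation %||% rotation_identity()),
    map = {
      if (!is.na(cfg$shape)) {
        map_from_geometry(cfg$shape, cfg$diameter, cfg$map_dx, cfg$material)
      } else if (!is.na(cfg$map_file)) {
        read_map(resolve_path(cfg$map_file), kind = cfg$map_values,
                 material = if (cfg$map_values == "atom_density")
                   cfg$material else NULL)
      } else stop("[", section, "]: map model needs map_file or shape")
    },
    atoms = {
      if (is.na(cfg$pdb_file)) stop("[", section, "]: atoms model needs pdb_file")
      read_pdb(resolve_path(cfg$pdb_file))
    },
    stop("[", section, "]: unknown model '", model, "'"))
  if (!is.null(orientation) && !inherits(template, "fxi_sphere")) {
    template$orientation <- orientation
  }
  flat_range <- if (!is.na(cfg$flattening_min) && !is.na(cfg$flattening_max)) {
    c(cfg$flattening_min, cfg$flattening_max)
  } else NULL
  species_spec(
    template,
    arrival_rate = if (is.na(cfg$arrival_rate)) 1 else cfg$arrival_rate,
    count = if (is.na(cfg$arrival_rate)) cfg$count else NULL,
    diameter_sigma = cfg$diameter_sigma,
    flattening_range = flat_range,
    position = if (cfg$position == "uniform-in-focus") "uniform-in-focus"
               else cfg$position,
    position_value = c(cfg$position_x, cfg$position_y),
    position_sigma = cfg$position_sigma,
    orientation = if (identical(cfg$orientation, "random"))
      "uniform-random" else "fixed",
    label = sub("^particle_?", "", section))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an experiment configuration file
#'
#' Reads an INI-style configuration with sections `[source]`, `[detector]`,
#' one or more `[particle_*]` sections, and an optional `[simulation]`
#' section. All quantities are SI units (energies in eV where noted);
#' unspecified keys take documented defaults; unknown keys raise an error
#' naming the nearest valid key. See the package vignette for the full key
#' reference.
#'
#' @param path Path to the configuration file.
#' @return An `fxi_experiment` object (see [experiment()]).
#' @export
#' @examples
#' conf <- generate_fixtures("config", path = tempfile())
#' parse_config(conf)
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- .parse_ini(path)
  schema <- .config_schema()
  if (!"source" %in% names(raw)) stop("missing mandatory [source] section")
  if (!"detector" %in% names(raw)) stop("missing mandatory [detector] section")
  psec <- grep("^particle", names(raw), value = TRUE)
  if (length(psec) == 0) stop("need at least one [particle_*] section")
  src_cfg <- .apply_schema(raw$source, schema$source, "source")
  det_cfg <- .apply_schema(raw$detector, schema$detector, "detector")
  sim_cfg <- .apply_schema(raw$simulation %||% list(), schema$simulation,
                           "simulation")
  if (is.na(src_cfg$photon_energy) && is.na(src_cfg$wavelength)) {
    stop("[source] needs photon_energy (eV) or wavelength (m)")
  }
  src <- photon_source(
    photon_energy = if (!is.na(src_cfg$photon_energy)) src_cfg$photon_energy,
    wavelength = if (is.na(src_cfg$photon_energy)) src_cfg$wavelength,
    pulse_energy = src_cfg$pulse_energy,
    focus_diameter = src_cfg$focus_diameter,
    profile = src_cfg$profile,
    pulse_energy_jitter_sigma = src_cfg$pulse_energy_jitter)
  det <- detector_geometry(
    nx = det_cfg$nx, ny = det_cfg$ny, pixel_size = det_cfg$pixel_size,
    detector_distance = det_cfg$distance,
    center_x = if (is.na(det_cfg$center_x)) (det_cfg$nx - 1) / 2
               else det_cfg$center_x,
    center_y = if (is.na(det_cfg$center_y)) (det_cfg$ny - 1) / 2
               else det_cfg$center_y,
    saturation_level = det_cfg$saturation_level,
    quantum_efficiency = det_cfg$quantum_efficiency)
  base_dir <- dirname(normalizePath(path))
  species <- lapply(psec, function(s)
    .species_from_config(.apply_schema(raw[[s]], schema$particle, s),
                         s, base_dir))
  experiment(src, species, det,
             pol_mode = det_cfg$polarization,
             read_noise_sigma = det_cfg$read_noise_sigma,
             beam_tilt_sigma = src_cfg$beam_tilt_sigma,
             seed = sim_cfg$seed, shots = sim_cfg$shots,
             output = sim_cfg$output)
}
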