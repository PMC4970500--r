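## The experiment object and per-shot orchestration: sample the stochastic
## state, compute amplitudes, superpose, convert to photon counts.

#' Assemble an experiment
#'
#' An experiment couples an X-ray source, one or more particle species and
#' a detector, plus the per-shot stochastic settings (beam tilt jitter,
#' polarization mode, read noise) and the global simulation parameters.
#'
#' @param source An `fxi_source`.
#' @param species An `fxi_species` or list of them.
#' @param detector An `fxi_detector`.
#' @param pol_mode Polarization mode, see [polarization_factor()].
#' @param read_noise_sigma Detector read noise (photons), applied after
#'   Poisson sampling.
#' @param beam_tilt_sigma Per-shot beam tilt jitter, rad (2-D normal).
#' @param seed Base RNG seed.
#' @param shots Number of shots for [run_experiment()].
#' @param output Output path for [run_experiment()].
#' @return Object of class `fxi_experiment`.
#' @export
#' @examples
#' exp <- experiment(
#'   photon_source(photon_energy = 1000, pulse_energy = 1e-3,
#'                 focus_diameter = 1e-6),
#'   species_spec(particle_sphere(2e-8, "water")),
#'   detector_geometry(32, 32, 300e-6, 0.74))
experiment <- function(source, species, detector, pol_mode = "ignore",
                       read_noise_sigma = 0, beam_tilt_sigma = 0,
                       seed = 1, shots = 1, output = "fxisim_out.cxi") {
  if (inherits(species, "fxi_species")) species <- list(species)
  stopifnot(inherits(source, "fxi_source"),
            inherits(detector, "fxi_detector"),
            all(vapply(species, inherits, logical(1), "fxi_species")),
            read_noise_sigma >= 0, beam_tilt_sigma >= 0)
  structure(list(source = source, species = species, detector = detector,
                 pol_mode = pol_mode, read_noise_sigma = read_noise_sigma,
                 beam_tilt_sigma = beam_tilt_sigma,
                 seed = as.integer(seed), shots = as.integer(shots),
                 output = output),
            class = "fxi_experiment")
}

#' @export
print.fxi_experiment <- function(x, ...) {
  cat("<fxi_experiment>\n")
  print(x$source); print(x$detector)
  cat(sprintf("  %d particle species, %d shot(s), seed %d\n",
              length(x$species), x$shots, x$seed))
  invisible(x)
}

## stable per-shot seed derived from the base seed (kept inside 32-bit
## integer range)
.shot_seed <- function(seed, shot_index) {
  as.integer((as.double(seed) * 48271 + shot_index * 16807) %% 2147483647)
}

## deterministic expected intensity from a resolved shot state (the replay
## path shared by propagate() and replay_shot())
.expected_from_state <- function(config, instances, beam_tilt, pulse_energy) {
  src <- config$source; det <- config$detector
  qmap <- qmap_from_detector(det, src$wavelength, beam_tilt)
  if (length(instances) == 0) {
    amp <- .amplitude_pattern(complex(length.out = nrow(qmap$q)), qmap,
                              "empty shot")
  } else {
    pats <- lapply(instances, function(inst)
      amplitude(inst$particle, qmap, src$photon_energy))
    amp <- superpose(pats, lapply(instances, function(i) i$position),
                     src = src, pulse_energy = pulse_energy)
  }
  intens <- expected_intensity(amp, det, src, config$pol_mode, pulse_energy)
  list(amplitude = amp, intensity = intens)
}

#' Simulate one shot
#'
#' Orchestrates a single pulse: samples the pulse energy and beam tilt,
#' builds the scattering-vector map, draws the particle ensemble, computes
#' and superposes per-particle amplitudes, converts to expected photon
#' counts, applies Poisson noise and the detector mask/saturation. The
#' result is deterministic given `(config, seed, shot_index)` and carries
#' the complete ground truth needed to re-run the shot.
#'
#' @param config An `fxi_experiment`.
#' @param shot_index Shot number (used to derive the per-shot seed).
#' @param seed Base seed; defaults to the experiment's.
#' @return A shot result: list with `amplitude` (`fxi_amplitude`),
#'   `intensity` (`fxi_intensity` with expected and sampled counts and
#'   mask), `instances` (ground-truth particle list), `beam_tilt`,
#'   `pulse_energy` and `shot_index`.
#' @export
propagate <- function(config, shot_index = 1, seed = config$seed) {
  stopifnot(inherits(config, "fxi_experiment"))
  set.seed(.shot_seed(seed, shot_index))
  src <- config$source
  pulse_energy <- if (src$pulse_energy_jitter_sigma > 0) {
    .sample_truncated_normal(src$pulse_energy, src$pulse_energy_jitter_sigma)
  } else src$pulse_energy
  beam_tilt <- if (config$beam_tilt_sigma > 0) {
    stats::rnorm(2, 0, config$beam_tilt_sigma)
  } else c(0, 0)
  instances <- sample_shot_ensemble(config$species,
                                    focus_diameter = src$focus_diameter)
  state <- .expected_from_state(config, instances, beam_tilt, pulse_energy)
  intens <- apply_poisson(state$intensity,
                          read_noise_sigma = config$read_noise_sigma)
  intens <- apply_mask_and_saturation(intens, config$detector)
  structure(list(amplitude = state$amplitude, intensity = intens,
                 instances = instances, beam_tilt = beam_tilt,
                 pulse_energy = pulse_energy, shot_index = shot_index),
            class = "fxi_shot")
}

#' Recompute a shot's expected intensity from its ground truth
#'
#' Replays the deterministic part of a recorded shot (no new randomness):
#' the same particle instances, beam tilt and pulse energy yield the same
#' expected intensity, which is the consistency contract for the stored
#' ground truth.
#'
#' @param config An `fxi_experiment`.
#' @param shot An `fxi_shot` from [propagate()].
#' @return An `fxi_intensity` with expected counts.
#' @export
replay_shot <- function(config, shot) {
  stopifnot(inherits(shot, "fxi_shot"))
  .expected_from_state(config, shot$instances, shot$beam_tilt,
                       shot$pulse_energy)$intensity
}

#' Run all shots of an experiment and write the CXI file
#'
#' @param config An `fxi_experiment`.
#' @param output Output path override.
#' @param quiet Suppress per-shot progress lines?
#' @return List of `fxi_shot` results, invisibly; the CXI file is written
#'   to the configured output path.
#' @export
run_experiment <- function(config, output = config$output, quiet = FALSE) {
  stopifnot(inherits(config, "fxi_experiment"))
  if (config$shots < 1) stop("number of shots must be >= 1")
  results <- vector("list", config$shots)
  for (s in seq_len(config$shots)) {
    results[[s]] <- propagate(config, s)
    if (!quiet) {
      r <- results[[s]]
      message(sprintf(
        "shot %d/%d: %d particle(s), %.4g photons, peak pixel %d",
        s, config$shots, length(r$instances), sum(r$intensity$sampled),
        max(r$intensity$sampled)))
    }
  }
  write_cxi(results, output, config)
  invisible(results)
}

#' Command-line entry point
#'
#' Runs an experiment defined by a configuration file and writes a CXI
#' file. Flags: `--config` (default `./fxisim.conf`), `--output`,
#' `--shots`, `--seed`, `--quiet`. Returns an exit status instead of
#' quitting, so it can be driven programmatically; the installed
#' `bin/fxisim` script forwards the status to the shell.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success, 2 on usage errors), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fxisim [--config FILE] [--output FILE] [--shots N]",
    "[--seed N] [--quiet]")
  opts <- list(config = "fxisim.conf", output = NULL, shots = NULL,
               seed = NULL, quiet = FALSE)
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--quiet") { opts$quiet <- TRUE; i <- i + 1; next }
    if (a %in% c("--config", "--output", "--shots", "--seed")) {
      if (i == length(argv)) { message("missing value for ", a, "\n", usage)
        return(invisible(2L)) }
      opts[[sub("^--", "", a)]] <- argv[i + 1]
      i <- i + 2; next
    }
    message("unknown argument: ", a, "\n", usage)
    return(invisible(2L))
  }
  if (!file.exists(opts$config)) {
    message("configuration file not found: ", opts$config, "\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    config <- parse_config(opts$config)
    if (!is.null(opts$shots)) config$shots <- as.integer(opts$shots)
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    if (!is.null(opts$output)) config$output <- opts$output
    if (is.na(config$shots) || config$shots < 1) {
      stop("number of shots must be a positive integer")
    }
    run_experiment(config, quiet = opts$quiet)
    if (!opts$quiet) message("wrote ", config$output)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
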