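# Run configuration: one flat, schema-validated list of every physics, noise
# and reconstruction knob, serialisable to/from YAML. Units are cm, ns, MeV.

.pg_config_defaults <- function() {
  list(
    seed = 1L,
    ## spectrometer
    R_spec = 8,              # internal radius, cm
    crystal_length = 5.08,   # cm (2 inches)
    crystal_radius = 1.905,  # cm (0.75 inches)
    ## beam
    E0 = 180,                # nominal proton energy, MeV
    ref_energy = 180,        # energy whose Bragg peak sits at the origin, MeV
    alpha = 2.2e-3,          # Bragg-Kleeman coefficient, cm/MeV^p
    p = 1.77,                # Bragg-Kleeman exponent
    sigma_E = 1,             # beam energy spread, MeV
    sigma_lateral = 0.4,     # pencil-beam lateral spread, cm
    ## cross-section bump
    xs_E_peak = 13.5,        # MeV
    xs_threshold = 8.9,      # MeV
    xs_width = 0.12,         # dimensionless log-normal width
    ## phantom: 4 x 4 x 30 cm^3 water box, entrance face placed so that the
    ## reference-energy Bragg peak sits at the origin
    phantom_size = c(4, 4, 30),
    ## event generator
    n_couples = 1000L,
    p_fe = 0.2,              # full-energy detection probability per gamma
    energy_res_fwhm = 0.03,  # fractional FWHM energy resolution
    hit_sigma = 0.3,         # hit-position scatter, cm
    timing_sigma = 0,        # timing jitter, ns (280 ps resolution knob)
    attenuation_length = 6,  # interaction-depth sampling length, cm
    background_rate = 0,     # background singles per couple
    source = NULL,           # optional fixed emission point c(x,y,z), cm
    ## reconstruction
    coincidence_window = 2,  # ns
    minor_radius = 0.3,      # torus tube radius, cm
    n_u = 240L,              # mesh subdivisions around the spine
    n_v = 24L,               # mesh subdivisions around the tube
    cluster_eps = 0.1,       # component clustering tolerance, cm
    voxel = 0.1,             # histogram voxel size, cm
    escape_peaks = FALSE
  )
}

#' Build a validated run configuration
#'
#' Merges the supplied keys into the defaults; unknown keys are rejected.
#' Units are fixed: cm, ns, MeV.
#'
#' @param ... Named configuration values overriding the defaults (see
#'   `pgrange:::.pg_config_defaults()` for the full key list).
#' @return Object of class `pg_config`.
#' @export
pg_config <- function(...) {
  cfg <- .pg_config_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration values must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  .validate_config(cfg)
  structure(cfg, class = "pg_config")
}

.validate_config <- function(cfg) {
  pos <- c("R_spec", "crystal_length", "crystal_radius", "E0", "ref_energy",
           "alpha", "coincidence_window", "minor_radius", "cluster_eps",
           "voxel", "attenuation_length")
  for (k in pos) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
    stop("config key '", k, "' must be positive")
  nonneg <- c("sigma_E", "sigma_lateral", "energy_res_fwhm", "hit_sigma",
              "timing_sigma", "background_rate", "n_couples")
  for (k in nonneg) if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
    stop("config key '", k, "' must be non-negative")
  if (!(cfg$p > 1 && cfg$p < 2)) stop("config key 'p' must lie in (1, 2)")
  if (!(cfg$p_fe > 0 && cfg$p_fe <= 1)) stop("p_fe must lie in (0, 1]")
  if (cfg$n_u < 8 || cfg$n_v < 6) stop("mesh resolution too coarse")
  if (!is.null(cfg$source) &&
      (length(cfg$source) != 3 || !all(is.finite(cfg$source))))
    stop("source must be NULL or a finite length-3 point")
  if (length(cfg$phantom_size) != 3 || any(cfg$phantom_size <= 0))
    stop("phantom_size must be three positive extents")
  invisible(cfg)
}

#' @export
print.pg_config <- function(x, ...) {
  cat("pgrange run configuration\n")
  cat(sprintf("  beam: %.4g MeV (sigma_E %.3g MeV), R_spec %.4g cm, %d couples\n",
              x$E0, x$sigma_E, x$R_spec, as.integer(x$n_couples)))
  cat(sprintf("  response: %.3g%% FWHM, hit scatter %.3g cm, timing jitter %.3g ns, p_fe %.3g\n",
              100 * x$energy_res_fwhm, x$hit_sigma, x$timing_sigma, x$p_fe))
  cat(sprintf("  reconstruction: tube %.3g cm, mesh %d x %d, voxel %.3g cm\n",
              x$minor_radius, as.integer(x$n_u), as.integer(x$n_v), x$voxel))
  invisible(x)
}

## derived views of the configuration
as_beam_params <- function(cfg) {
  beam_params(E0 = cfg$E0, alpha = cfg$alpha, p = cfg$p, sigma_E = cfg$sigma_E,
              sigma_lateral = cfg$sigma_lateral)
}

as_xs_model <- function(cfg, line = "2.742") {
  cross_section_model(line, E_peak = cfg$xs_E_peak,
                      threshold = cfg$xs_threshold, width = cfg$xs_width)
}

as_spectrometer <- function(cfg) {
  build_spectrometer(cfg$R_spec, cfg$crystal_length, cfg$crystal_radius)
}

## phantom bounds in the spectrometer frame: the reference-energy Bragg peak
## sits at the origin, so the entrance face is at z = -R(ref_energy)
phantom_bounds <- function(cfg) {
  bp <- as_beam_params(cfg)
  z0 <- -range_from_energy(cfg$ref_energy, bp)
  list(x = c(-1, 1) * cfg$phantom_size[1] / 2,
       y = c(-1, 1) * cfg$phantom_size[2] / 2,
       z = c(z0, z0 + cfg$phantom_size[3]))
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @return `pg_read_config()` returns a validated `pg_config`.
#' @export
pg_read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$source)) raw$source <- as.numeric(raw$source)
  if (!is.null(raw$phantom_size)) raw$phantom_size <- as.numeric(raw$phantom_size)
  do.call(pg_config, raw)
}

#' @rdname pg_read_config
#' @param cfg A `pg_config` object.
#' @export
pg_write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pg_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## short stable fingerprint of a configuration (polynomial hash of its deparse)
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
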