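#' Convert an acoustic absorption spec to nepers per meter
#'
#' Converts the customary soft-tissue absorption specification
#' (dB/m/MHz with a frequency power law) to the Np/m value used by the
#' heating term: \eqn{\alpha = (\mathrm{dB}/8.686) \, f^y} with \eqn{f} in
#' MHz.
#'
#' @param db_per_m_mhz absorption in dB/m/MHz (soft tissue: 58).
#' @param f_mhz frequency in MHz.
#' @param y frequency power-law exponent (typically 1 to 2).
#' @return Absorption coefficient (Np/m).
#' @examples
#' acoustic_absorption(58, 2.5, 2)  # ~41.7 Np/m
#' @export
acoustic_absorption <- function(db_per_m_mhz = 58, f_mhz = 2.5, y = 2) {
  stopifnot(db_per_m_mhz >= 0, f_mhz > 0, y >= 0)
  db_per_m_mhz / 8.686 * f_mhz^y
}

#' Default simulation configuration
#'
#' Builds the nested run configuration with the canonical soft-tissue /
#' liposome-nanoagent parameter set: 2.5 MHz focused ultrasound
#' (Pa = 2.4 MPa, beam parameter 0.5 mm, focus 10 mm deep), soft-tissue
#' acoustic and thermal constants, erfc switching curve (Q0 = 0.05,
#' R0 = 2.6, T_th = 38.41 C, T_sa = 38.97 C), and 808/830 nm diffuse
#' optical properties. All units are SI with temperatures in degrees C.
#'
#' @param ... named overrides as \code{block$key} replacements, e.g.
#'   \code{timing = list(exposure = 0.2)} replaces keys inside a block.
#' @return Nested list of class \code{"usf_config"}.
#' @export
usf_config <- function(...) {
  cfg <- list(
    transducer = list(Pa = 2.4e6, a_bar = 0.5e-3, f = 2.5e6, c0 = 1540,
                      focus_depth = 10e-3),
    tissue = list(alpha_db_per_m_mhz = 58, alpha_power = 2,
                  rho0 = 1064, rho_b = 1060, Ct = 4200, Cb = 3780,
                  kt = 0.6, omega_b = 0.0189, T_BG = 37),
    nanoagent = list(Q0 = 0.05, R0 = 2.6, T_th = 38.41, T_sa = 38.97),
    optics = list(
      ex = list(mu_a = 15, mu_s_prime = 1500, n = 1.333, R_eff = 0.475,
                epsilon = 6.09e6),
      fl = list(mu_a = 12, mu_s_prime = 1700, n = 1.333, R_eff = 0.475,
                epsilon = 6.54e5)
    ),
    geometry = list(orientation = "top", sd_offset = c(0, 0),
                    shared_ezb = FALSE),
    timing = list(exposure = 0.4, total = 1.0, cadence = 0.01),
    source = list(M0 = 0.003),
    scenario = list(type = "single_voxel", C0 = 4.4e-11,
                    separation = 0.3e-3, axis = "x"),
    grids = list(
      acoustic = list(dx = 12.5e-6, dy = 12.5e-6, dz = 43.75e-6,
                      Lx = 3e-3, Ly = 3e-3, Lz = 7e-3),
      thermal = list(dx = 50e-6, dy = 50e-6, dz = 175e-6,
                     Lx = 3e-3, Ly = 3e-3, Lz = 7e-3),
      dynamics = list(dx = 1e-4, dy = 1e-4, dz = 3.5e-4,
                      Lx = 1.5e-3, Ly = 1.5e-3, Lz = 4e-3)
    ),
    attenuation = "axial"
  )
  over <- list(...)
  for (blk in names(over)) {
    if (!blk %in% names(cfg))
      stop(sprintf("unknown configuration block '%s'", blk))
    if (is.list(over[[blk]])) {
      for (key in names(over[[blk]])) {
        if (!key %in% names(cfg[[blk]]))
          stop(sprintf("unknown key '%s' in block '%s'", key, blk))
        cfg[[blk]][[key]] <- over[[blk]][[key]]
      }
    } else {
      cfg[[blk]] <- over[[blk]]
    }
  }
  structure(cfg, class = "usf_config")
}

# block/key structure of a valid config (for load-time validation)
config_schema <- function() {
  tmpl <- unclass(usf_config())
  lapply(tmpl, function(b) if (is.list(b)) names(b) else NA)
}

#' Validate a configuration list
#'
#' Checks block and key names against the schema and enforces the physical
#' invariants (positive spacings, valid switching range, reflection
#' coefficient in [0, 1), exposure within the simulated interval).
#'
#' @param cfg a configuration list.
#' @return The validated config with class \code{"usf_config"}, invisibly
#'   usable downstream.
#' @export
validate_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop(sprintf("unknown configuration block(s): %s",
                 paste(unknown, collapse = ", ")))
  missing <- setdiff(names(schema), names(cfg))
  if (length(missing))
    stop(sprintf("missing configuration block(s): %s",
                 paste(missing, collapse = ", ")))
  for (blk in names(schema)) {
    if (all(is.na(schema[[blk]]))) next
    unknown <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(unknown))
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(unknown, collapse = ", ")))
  }
  na <- cfg$nanoagent
  if (na$R0 <= 1 || na$R0 >= 1 / na$Q0)
    stop("nanoagent block violates 1 < R0 < 1/Q0")
  if (!is.null(na$T_th) && !is.null(na$T_sa) && na$T_sa <= na$T_th)
    stop("nanoagent block requires T_sa > T_th")
  for (w in c("ex", "fl")) {
    op <- cfg$optics[[w]]
    if (op$R_eff < 0 || op$R_eff >= 1)
      stop("R_eff must lie in [0, 1)")
  }
  if (cfg$timing$exposure <= 0 || cfg$timing$exposure > cfg$timing$total)
    stop("exposure must be positive and within the simulated interval")
  if (!cfg$attenuation %in% c("axial", "uniform", "none"))
    stop("attenuation must be one of axial/uniform/none")
  structure(cfg, class = "usf_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a complete configuration file; partial files are not merged over
#' the defaults (use \code{\link{write_config}} to materialize the defaults
#' first and edit from there). Unknown blocks or keys are rejected. The
#' acoustic absorption is specified in dB/m/MHz with a power exponent and
#' converted with \code{\link{acoustic_absorption}} at use time.
#'
#' @param path file path; format chosen by extension (\code{.yaml} /
#'   \code{.yml} / \code{.json}).
#' @return A validated \code{"usf_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext)
  )
  validate_config(cfg)
}

#' Write a configuration to YAML or JSON
#'
#' @param cfg a \code{"usf_config"}.
#' @param path output path (\code{.yaml} / \code{.yml} / \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(unclass(cfg), path),
    json = jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("unsupported config format: ", ext)
  )
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' Expands a validated configuration into the physics objects the pipeline
#' consumes: transducer, tissue, nanoagent, the two optical media, the
#' boundary geometry, the source-detector config, and the absorption in
#' Np/m.
#'
#' @param cfg a \code{"usf_config"}.
#' @return Named list of model objects.
#' @export
config_objects <- function(cfg) {
  cfg <- validate_config(cfg)
  tr <- cfg$transducer
  spec <- transducer_spec(tr$Pa, tr$a_bar, tr$f, tr$c0, tr$focus_depth)
  ts <- cfg$tissue
  tissue <- tissue_thermal(ts$rho0, ts$rho_b, ts$Ct, ts$Cb, ts$kt,
                           ts$omega_b, ts$T_BG)
  na <- cfg$nanoagent
  agent <- nanoagent_spec(na$Q0, na$R0, T_th = na$T_th, T_sa = na$T_sa,
                          T_BG = ts$T_BG)
  oe <- cfg$optics$ex
  of <- cfg$optics$fl
  optics_ex <- optical_medium(oe$mu_a, oe$mu_s_prime, oe$n, oe$R_eff,
                              oe$epsilon)
  optics_fl <- optical_medium(of$mu_a, of$mu_s_prime, of$n, of$R_eff,
                              of$epsilon)
  geom <- boundary_geometry(tr$focus_depth, optics_ex, optics_fl,
                            orientation = cfg$geometry$orientation,
                            sd_offset = cfg$geometry$sd_offset,
                            shared_ezb = cfg$geometry$shared_ezb)
  list(
    spec = spec, tissue = tissue, agent = agent,
    optics_ex = optics_ex, optics_fl = optics_fl, geom = geom,
    sd = sd_config(M0 = cfg$source$M0, epsilon_fl = of$epsilon),
    alpha_np = acoustic_absorption(ts$alpha_db_per_m_mhz, tr$f / 1e6,
                                   ts$alpha_power)
  )
}

#' Generate a scenario fixture
#'
#' Deterministic concentration-map generator for the standard scenarios
#' plus a seeded random-blob map for synthetic-phantom studies.
#'
#' @param tag scenario: \code{"single_voxel"}, \code{"two_voxel"},
#'   \code{"uniform"}, or \code{"random_blobs"}.
#' @param grid a \code{\link{usf_grid}}.
#' @param C0 fill concentration (mol/L).
#' @param separation,axis two-voxel placement.
#' @param n_blobs,blob_sigma random-blob count and Gaussian radius (m).
#' @param seed RNG seed for \code{"random_blobs"} (same seed, same map).
#' @return A \code{\link{nanoagent_map}}.
#' @export
make_fixture <- function(tag = c("single_voxel", "two_voxel", "uniform",
                                 "random_blobs"),
                         grid, C0 = 4.4e-11, separation = 0.3e-3,
                         axis = "x", n_blobs = 3, blob_sigma = 0.3e-3,
                         seed = 1) {
  tag <- match.arg(tag)
  if (tag != "random_blobs")
    return(nanoagent_map(grid, tag, C0 = C0, separation = separation,
                         axis = axis))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  co <- grid_coords(grid)
  C <- numeric(nrow(co))
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, min(grid$x) / 2, max(grid$x) / 2)
    cy <- stats::runif(1, min(grid$y) / 2, max(grid$y) / 2)
    cz <- stats::runif(1, min(grid$z) / 2, max(grid$z) / 2)
    d2 <- (co[, 1] - cx)^2 + (co[, 2] - cy)^2 + (co[, 3] - cz)^2
    C <- C + C0 * exp(-d2 / (2 * blob_sigma^2))
  }
  dim(C) <- grid$dim
  nanoagent_map(grid, "custom", C = C)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
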