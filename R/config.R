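#' Read a run configuration file
#'
#' Parses a YAML (or JSON) configuration into the package's domain objects.
#' Recognized sections (all optional, with package defaults otherwise):
#'
#' * `pipe`: `length_m`, `diameter_m`
#' * `gas`: `density`, `viscosity`
#' * `flow`: `mean_velocity`, `regime` (`auto`/`laminar`/`turbulent`)
#' * `particle`: `diameter_um`, `density`, `youngs_modulus`, `poisson_ratio`
#' * `tracking`: any [tracking_config()] argument
#' * `pair`: any [contact_pair()] argument
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with `geometry`, `gas`, `mean_velocity`, `regime`,
#'   `particle` (or `NULL`), `tracking`, `pair` and the `raw` parsed list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  pipe <- raw$pipe
  geometry <- pipe_geometry(
    length = if (is.null(pipe$length_m)) 1 else pipe$length_m,
    inner_diameter = if (is.null(pipe$diameter_m)) 4.76e-3 else pipe$diameter_m)
  gasr <- raw$gas
  gas <- gas_properties(
    density = if (is.null(gasr$density)) 1.2 else gasr$density,
    dynamic_viscosity = if (is.null(gasr$viscosity)) 1.81e-5 else gasr$viscosity)
  flow <- raw$flow
  mean_velocity <- if (is.null(flow$mean_velocity)) 8.4 else flow$mean_velocity
  regime <- if (is.null(flow$regime)) "auto" else flow$regime

  particle <- NULL
  if (!is.null(raw$particle)) {
    p <- raw$particle
    particle <- particle_spec(
      diameter = p$diameter_um * 1e-6,
      density = if (is.null(p$density)) 1440 else p$density,
      youngs_modulus = if (is.null(p$youngs_modulus)) 2e9 else p$youngs_modulus,
      poisson_ratio = if (is.null(p$poisson_ratio)) 0.3 else p$poisson_ratio)
  }
  tracking <- do.call(tracking_config,
                      if (is.null(raw$tracking)) list() else raw$tracking)
  pair <- do.call(contact_pair, if (is.null(raw$pair)) list() else raw$pair)

  list(geometry = geometry, gas = gas, mean_velocity = mean_velocity,
       regime = regime, particle = particle, tracking = tracking,
       pair = pair, raw = raw)
}

## Tiny FNV-1a hash over the deparsed object; enough to detect config drift
## between runs without an external digest dependency.
fnv1a_digest <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    ## multiply mod 2^32 in 16-bit halves to stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write a run manifest
#'
#' Records the master seed, a digest of the configuration, the package
#' version and a timestamp next to a CLI output, so a rerun with equal
#' digest and seed can declare bitwise reproducibility.
#'
#' @param path Output JSON path.
#' @param seed Master seed of the run.
#' @param config Any R object describing the run configuration.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config) {
  doc <- list(master_seed = as.integer(seed),
              config_digest = fnv1a_digest(config),
              tool_version = as.character(utils::packageVersion("tribochar")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}
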