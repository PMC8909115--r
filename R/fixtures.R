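FIXTURE_FILES <- c(table2 = "table2_pea_fractions.csv",
                   table3 = "table3_densities.csv")

#' Load a packaged data table
#'
#' `"table2"` is the sieved yellow-pea fraction table (mesh label, volume
#' mean diameter D4,3 with spread, protein content with spread, measured
#' charge-to-mass ratio in nC/g with spread). `"table3"` lists the material
#' densities used in the simulation studies. Spreads are stored in separate
#' `_sd` columns.
#'
#' @param name `"table2"` or `"table3"`.
#' @return A data frame.
#' @export
#' @examples
#' load_fixture("table3")
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% names(FIXTURE_FILES))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(names(FIXTURE_FILES), collapse = ", "),
         call. = FALSE)
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "tribochar",
                      mustWork = TRUE)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Particle size distribution specification
#'
#' A mixture of log-normal modes describing a sieved fraction's size
#' distribution: each mode has a median diameter (micron), a geometric
#' standard deviation (> 1, or exactly 1 for a monodisperse delta) and a
#' mixture weight. Weights must sum to 1.
#'
#' @param modes Data frame with columns `median_um`, `gsd`, `weight`.
#' @return An object of class `size_distribution` with `kind`
#'   `"monomodal"` or `"bimodal"` (by number of modes).
#' @export
#' @examples
#' size_distribution(data.frame(median_um = 380, gsd = 1.3, weight = 1))
size_distribution <- function(modes) {
  stopifnot(is.data.frame(modes),
            all(c("median_um", "gsd", "weight") %in% names(modes)))
  if (any(modes$median_um <= 0)) stop_invalid("mode medians must be positive")
  if (any(modes$gsd < 1)) stop_invalid("geometric sd must be >= 1")
  if (abs(sum(modes$weight) - 1) > 1e-8)
    stop_invalid("mixture weights must sum to 1")
  if (any(modes$weight < 0)) stop_invalid("mixture weights must be >= 0")
  structure(list(modes = modes,
                 kind = if (nrow(modes) == 1) "monomodal" else "bimodal"),
            class = "size_distribution")
}

#' Sample a particle size distribution
#'
#' Draws diameters from the log-normal mixture and reports the volume
#' (De Brouckere) mean diameter `D4,3 = sum(d^4)/sum(d^3)` together with
#' the Sauter mean `D3,2` and the arithmetic mean. A mode with geometric
#' standard deviation exactly 1 is treated as a monodisperse delta.
#'
#' @param spec A [size_distribution()].
#' @param n_samples Number of diameters to draw, >= 1.
#' @param seed Integer seed.
#' @return A list: `diameters_um`, `d43_um`, `d32_um`, `mean_um`.
#' @export
generate_size_distribution <- function(spec, n_samples, seed = 1L) {
  stopifnot(inherits(spec, "size_distribution"))
  if (n_samples < 1) stop_invalid("n_samples must be >= 1")
  set.seed(seed)
  comp <- sample.int(nrow(spec$modes), n_samples, replace = TRUE,
                     prob = spec$modes$weight)
  d <- numeric(n_samples)
  for (j in seq_len(nrow(spec$modes))) {
    idx <- comp == j
    if (!any(idx)) next
    gsd <- spec$modes$gsd[j]
    med <- spec$modes$median_um[j]
    d[idx] <- if (gsd == 1) med else
      rlnorm(sum(idx), meanlog = log(med), sdlog = log(gsd))
  }
  list(diameters_um = d,
       d43_um = sum(d^4) / sum(d^3),
       d32_um = sum(d^3) / sum(d^2),
       mean_um = mean(d))
}
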