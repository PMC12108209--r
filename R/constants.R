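#' Physical constants of the roGFP2 Nernst mapping
#'
#' Bundles the constants that map a degree of sensor oxidation to a
#' glutathione redox potential: the sensor midpoint potential, the gas
#' constant, the absolute temperature, the number of transferred electrons
#' and the Faraday constant. The derived Nernst slope (mV per decade of the
#' reduced/oxidized ratio) is
#' \deqn{s = 1000 \ln(10) \, R T / (z F)}
#' which is approximately 29.59 mV with the defaults.
#'
#' The default midpoint potential of roGFP2 is -272 mV; the default
#' temperature is 298.15 K. Both are exposed so either convention can be
#' overridden.
#'
#' @param midpoint_potential Sensor midpoint potential E0 in millivolts
#'   (potential at which the sensor is 50% oxidized). Default -272.
#' @param gas_constant Gas constant in J K^-1 mol^-1. Default 8.315.
#' @param temperature Absolute temperature in kelvin. Default 298.15.
#' @param electrons_transferred Number of electrons transferred by the
#'   engineered dithiol/disulfide pair. Default 2.
#' @param faraday Faraday constant in C mol^-1. Default 96485.
#'
#' @return An object of class `rogfp_constants`: a list with the five
#'   constants plus the derived `nernst_slope` in millivolts.
#' @examples
#' k <- rogfp_constants()
#' k$nernst_slope # ~29.59 mV
#' @export
rogfp_constants <- function(midpoint_potential = -272,
                            gas_constant = 8.315,
                            temperature = 298.15,
                            electrons_transferred = 2L,
                            faraday = 96485) {
  stopifnot(
    is.numeric(midpoint_potential), length(midpoint_potential) == 1L,
    is.finite(midpoint_potential), midpoint_potential < 0,
    is.numeric(gas_constant), gas_constant > 0,
    is.numeric(temperature), temperature > 0,
    is.numeric(electrons_transferred), electrons_transferred > 0,
    is.numeric(faraday), faraday > 0
  )
  out <- list(
    midpoint_potential = midpoint_potential,
    gas_constant = gas_constant,
    temperature = temperature,
    electrons_transferred = as.integer(electrons_transferred),
    faraday = faraday
  )
  out$nernst_slope <- 1000 * log(10) * gas_constant * temperature /
    (electrons_transferred * faraday)
  class(out) <- "rogfp_constants"
  out
}

#' @export
print.rogfp_constants <- function(x, ...) {
  cat("roGFP2 Nernst constants\n")
  cat(sprintf("  midpoint potential E0: %.2f mV\n", x$midpoint_potential))
  cat(sprintf("  R = %.4g J/K/mol, T = %.2f K, z = %d, F = %.0f C/mol\n",
              x$gas_constant, x$temperature, x$electrons_transferred,
              x$faraday))
  cat(sprintf("  Nernst slope: %.4f mV/decade\n", x$nernst_slope))
  invisible(x)
}

#' Calibration endpoints of the ratiometric sensor
#'
#' Holds the fully reduced and fully oxidized calibration state of the
#' sensor: the 405/488 excitation ratios of the fully reduced (10 mM DTT)
#' and fully oxidized (20 mM H2O2) forms, and the 488-nm-excited intensities
#' of the two forms. Oxidation raises the 405-excited signal and lowers the
#' 488-excited signal, so `r_ox > r_red` is required.
#'
#' @param r_red 405/488 ratio of the fully reduced sensor (dimensionless, > 0).
#' @param r_ox 405/488 ratio of the fully oxidized sensor (> `r_red`).
#' @param i488_red 488-excited intensity of the fully reduced form (a.u., > 0).
#' @param i488_ox 488-excited intensity of the fully oxidized form (a.u., > 0).
#'
#' @return An object of class `rogfp_calibration`.
#' @examples
#' rogfp_calibration(r_red = 0.2, r_ox = 1.4, i488_red = 1, i488_ox = 0.4)
#' @export
rogfp_calibration <- function(r_red, r_ox, i488_red, i488_ox) {
  vals <- c(r_red = r_red, r_ox = r_ox, i488_red = i488_red,
            i488_ox = i488_ox)
  if (!all(is.finite(vals))) {
    stop("calibration values must be finite numbers", call. = FALSE)
  }
  if (r_red <= 0 || i488_red <= 0 || i488_ox <= 0) {
    stop("calibration ratios and intensities must be positive", call. = FALSE)
  }
  if (r_ox <= r_red) {
    stop("calibration error: r_ox must exceed r_red ",
         "(oxidation raises the 405/488 ratio)", call. = FALSE)
  }
  structure(list(r_red = r_red, r_ox = r_ox,
                 i488_red = i488_red, i488_ox = i488_ox),
            class = "rogfp_calibration")
}

#' @export
print.rogfp_calibration <- function(x, ...) {
  cat("roGFP2 calibration state\n")
  cat(sprintf("  R_red = %.4g (10 mM DTT), R_ox = %.4g (20 mM H2O2)\n",
              x$r_red, x$r_ox))
  cat(sprintf("  I488_red = %.4g, I488_ox = %.4g (a.u.), I488_red/I488_ox = %.4g\n",
              x$i488_red, x$i488_ox, x$i488_red / x$i488_ox))
  invisible(x)
}

#' Read constants and calibration from a plain-text config
#'
#' Reads a YAML (or simple `key: value`) file. Keys under `constants` override
#' [rogfp_constants()] defaults; keys under `calibration` are passed to
#' [rogfp_calibration()]. Top-level keys with the same names are also
#' accepted.
#'
#' @param path Path to the config file.
#' @return A list with elements `constants` (`rogfp_constants`) and
#'   `calibration` (`rogfp_calibration` or `NULL` if not given).
#' @export
read_redox_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  const_args <- cfg$constants
  if (is.null(const_args)) {
    const_args <- cfg[intersect(names(cfg), names(formals(rogfp_constants)))]
  }
  constants <- do.call(rogfp_constants, const_args %||% list())
  calib <- NULL
  calib_args <- cfg$calibration
  if (is.null(calib_args)) {
    calib_args <- cfg[intersect(names(cfg), names(formals(rogfp_calibration)))]
    if (length(calib_args) == 0L) calib_args <- NULL
  }
  if (!is.null(calib_args)) calib <- do.call(rogfp_calibration, calib_args)
  list(constants = constants, calibration = calib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
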