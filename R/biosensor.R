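#' One background-corrected ratiometric measurement
#'
#' A measurement of the sensor in one region of interest: the
#' background-corrected mean intensities under 405 nm and 488 nm excitation
#' and their ratio R = I405 / I488.
#'
#' @param i405 Background-corrected 405-excited mean intensity (a.u.).
#' @param i488 Background-corrected 488-excited mean intensity (a.u., > 0).
#' @return An object of class `biosensor_measurement`.
#' @export
biosensor_measurement <- function(i405, i488) {
  if (!all(is.finite(c(i405, i488)))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(i488 <= 0)) {
    stop("signal error: i488 must be positive", call. = FALSE)
  }
  if (any(i405 < 0)) stop("signal error: i405 must be nonnegative",
                          call. = FALSE)
  structure(list(i405 = i405, i488 = i488, ratio = i405 / i488),
            class = "biosensor_measurement")
}

#' @export
print.biosensor_measurement <- function(x, ...) {
  cat(sprintf("biosensor measurement: I405 = %.4g, I488 = %.4g, R = %.4g\n",
              mean(x$i405), mean(x$i488), mean(x$ratio)))
  invisible(x)
}

#' Degree of oxidation from a fluorescence ratio
#'
#' Maps the 405/488 excitation ratio R of the sensor to its degree of
#' oxidation
#' \deqn{OxD = \frac{R - R_{red}}{\frac{I488_{red}}{I488_{ox}}(R_{ox} - R) + (R - R_{red})}}
#' using the fully reduced / fully oxidized calibration endpoints. OxD is 0
#' at R = R_red, 1 at R = R_ox, and strictly increasing in between. Ratios
#' outside the calibration interval (noise can push them there) are clamped
#' to the nearest endpoint and flagged via the `"clamped"` attribute.
#'
#' The reciprocal intensity-factor convention (I488_ox / I488_red) also
#' satisfies the endpoint conditions and exists in the literature; it is
#' available via `i488_factor = "ox_over_red"`.
#'
#' @param ratio Numeric vector of 405/488 ratios, or a
#'   [biosensor_measurement()].
#' @param calib A [rogfp_calibration()].
#' @param i488_factor Orientation of the 488-intensity factor multiplying
#'   (R_ox - R): `"red_over_ox"` (default) or `"ox_over_red"`.
#' @param clamp If `TRUE` (default) out-of-range ratios are clamped to the
#'   calibration interval; if `FALSE` they are an error.
#' @return Numeric vector of OxD values in [0, 1] with a logical attribute
#'   `"clamped"` marking entries whose ratio was out of range.
#' @examples
#' cal <- rogfp_calibration(0.2, 1.4, 1, 1)
#' compute_oxd(0.8, cal) # midpoint of a symmetric calibration: 0.5
#' @export
compute_oxd <- function(ratio, calib,
                        i488_factor = c("red_over_ox", "ox_over_red"),
                        clamp = TRUE) {
  if (inherits(ratio, "biosensor_measurement")) ratio <- ratio$ratio
  i488_factor <- match.arg(i488_factor)
  stopifnot(inherits(calib, "rogfp_calibration"))
  if (!all(is.finite(ratio))) {
    stop("input error: ratios must be finite", call. = FALSE)
  }
  clamped <- ratio < calib$r_red | ratio > calib$r_ox
  if (any(clamped) && !clamp) {
    stop("ratio outside calibration interval [r_red, r_ox] and clamp = FALSE",
         call. = FALSE)
  }
  r <- pmin(pmax(ratio, calib$r_red), calib$r_ox)
  k <- if (i488_factor == "red_over_ox") {
    calib$i488_red / calib$i488_ox
  } else {
    calib$i488_ox / calib$i488_red
  }
  num <- r - calib$r_red
  oxd <- num / (k * (calib$r_ox - r) + num)
  # endpoints are exact by construction; guard 0/0 at r = r_red
  oxd[num == 0] <- 0
  attr(oxd, "clamped") <- clamped
  oxd
}

#' Glutathione redox potential from the degree of oxidation
#'
#' Applies the Nernst equation
#' \deqn{E_{GSH} = E^0 - s \log_{10}\frac{1 - OxD}{OxD}}
#' where s is the Nernst slope (about 29.59 mV per decade with default
#' constants). At OxD = 0.5 the potential equals the midpoint E0; more
#' oxidized sensor gives a less negative potential. OxD is clamped into
#' [eps, 1 - eps] before the logarithm so boundary values from clamped
#' ratios stay finite.
#'
#' @param oxd Numeric vector of degrees of oxidation.
#' @param constants A [rogfp_constants()].
#' @param eps Clamping margin on OxD before the log (default 1e-6).
#' @param clamp If `FALSE`, OxD outside (0, 1) is a domain error instead of
#'   being clamped.
#' @return Redox potential(s) in millivolts, attribute `"clamped"` marking
#'   entries clamped into the open interval.
#' @examples
#' egsh_from_oxd(0.5) # -272 mV, the midpoint
#' @export
egsh_from_oxd <- function(oxd, constants = rogfp_constants(),
                          eps = 1e-6, clamp = TRUE) {
  stopifnot(inherits(constants, "rogfp_constants"), eps > 0, eps < 0.5)
  if (!all(is.finite(oxd))) stop("input error: OxD must be finite",
                                 call. = FALSE)
  clamped <- oxd < eps | oxd > 1 - eps
  if (any(oxd <= 0 | oxd >= 1) && !clamp) {
    stop("domain error: OxD must lie in (0, 1) when clamp = FALSE",
         call. = FALSE)
  }
  x <- pmin(pmax(oxd, eps), 1 - eps)
  e <- constants$midpoint_potential -
    constants$nernst_slope * log10((1 - x) / x)
  attr(e, "clamped") <- clamped
  e
}

#' Degree of oxidation from a redox potential
#'
#' Closed-form inverse of [egsh_from_oxd()]: the logistic
#' \deqn{OxD = \left(1 + 10^{(E^0 - E)/s}\right)^{-1}.}
#' Total on the real line; OxD(E0) = 0.5 and OxD tends to 0 / 1 as E tends
#' to minus / plus infinity.
#'
#' @param egsh Redox potential(s) in millivolts.
#' @inheritParams egsh_from_oxd
#' @return Degree(s) of oxidation in (0, 1).
#' @examples
#' oxd_from_egsh(-302.27) # ~0.0866 with default constants
#' @export
oxd_from_egsh <- function(egsh, constants = rogfp_constants()) {
  stopifnot(inherits(constants, "rogfp_constants"))
  if (!all(is.finite(egsh))) stop("input error: potential must be finite",
                                  call. = FALSE)
  1 / (1 + 10^((constants$midpoint_potential - egsh) / constants$nernst_slope))
}

#' Redox potential straight from channel intensities
#'
#' Composition of the ratio, [compute_oxd()] and [egsh_from_oxd()] steps for
#' background-corrected channel intensities of one or more ROIs. The
#' clamping flag from the ratio step is carried through.
#'
#' @param i405,i488 Background-corrected mean intensities (a.u.); `i488`
#'   must be positive.
#' @param calib A [rogfp_calibration()].
#' @param constants A [rogfp_constants()].
#' @inheritParams compute_oxd
#' @inheritParams egsh_from_oxd
#' @return A data frame with columns `ratio`, `oxd`, `egsh` (mV) and
#'   `clamped`.
#' @export
egsh_from_intensities <- function(i405, i488, calib,
                                  constants = rogfp_constants(),
                                  i488_factor = c("red_over_ox",
                                                  "ox_over_red"),
                                  eps = 1e-6, clamp = TRUE) {
  m <- biosensor_measurement(i405, i488)
  oxd <- compute_oxd(m$ratio, calib, i488_factor = i488_factor,
                     clamp = clamp)
  egsh <- egsh_from_oxd(as.numeric(oxd), constants, eps = eps, clamp = clamp)
  data.frame(ratio = m$ratio,
             oxd = as.numeric(oxd),
             egsh = as.numeric(egsh),
             clamped = attr(oxd, "clamped") | attr(egsh, "clamped"))
}
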