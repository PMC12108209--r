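#' Ratio of a sensor at a given degree of oxidation
#'
#' The sensor intensity model used by the synthetic generator: the
#' 488-excited intensity interpolates linearly between the reduced and
#' oxidized endpoint intensities,
#' I488(OxD) = I488_red + OxD (I488_ox - I488_red), and the ratio is the
#' unique R for which the OxD calibration formula returns OxD,
#' \deqn{R(OxD) = \frac{(1 - OxD) R_{red} + OxD\,k\,R_{ox}}{1 - OxD + OxD\,k}, \quad k = I488_{red}/I488_{ox}.}
#' This is the minimal model consistent with the calibration formula and
#' makes the pipeline exactly invertible at zero noise.
#'
#' @param oxd Degree(s) of oxidation in [0, 1].
#' @param calib A [rogfp_calibration()].
#' @return The 405/488 ratio(s).
#' @export
sensor_ratio <- function(oxd, calib) {
  stopifnot(inherits(calib, "rogfp_calibration"), all(oxd >= 0 & oxd <= 1))
  k <- calib$i488_red / calib$i488_ox
  ((1 - oxd) * calib$r_red + oxd * k * calib$r_ox) / (1 - oxd + oxd * k)
}

#' @rdname sensor_ratio
#' @export
sensor_i488 <- function(oxd, calib) {
  stopifnot(inherits(calib, "rogfp_calibration"), all(oxd >= 0 & oxd <= 1))
  calib$i488_red + oxd * (calib$i488_ox - calib$i488_red)
}

#' Specification of a synthetic biosensor scene
#'
#' Describes one two-channel biosensor image plus its matched calibration
#' pair: the ground-truth OxD field, the calibration state to emulate, and
#' the noise model (shot noise as Poisson counts at `photon_scale` photons
#' per intensity unit, plus Gaussian read noise).
#'
#' Default calibration (`r_red` 0.25, `r_ox` 2.0, `i488_red` 0.5,
#' `i488_ox` 0.15) mimics the roughly 4-8 fold ratio dynamic range of
#' cytosolic roGFP2 between 10 mM DTT and 20 mM H2O2, with the 488 signal
#' dropping on oxidation; intensities are normalized a.u. in [0, 1].
#' Default noise (400 photons per intensity unit, read noise sd 0.005
#' a.u.) corresponds to confocal imaging at moderate laser power with tens
#' to low hundreds of detected photons per pixel.
#'
#' @param oxd Ground-truth OxD field: a scalar (uniform), a matrix in
#'   [0, 1], or a list `list(type = "gradient", from =, to =)` /
#'   `list(type = "two_region", left =, right =)`.
#' @param dim Image dimensions (rows, cols) when `oxd` is not a matrix.
#' @param calib Calibration state to emulate ([rogfp_calibration()]).
#' @param pixel_size_um Micrometers per pixel.
#' @param photon_scale Photons per intensity unit for the Poisson shot
#'   noise; 0 disables shot noise.
#' @param read_noise_sd Gaussian read noise sd in a.u.; 0 disables it.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @return An object of class `biosensor_scene`.
#' @export
biosensor_scene <- function(oxd = 0.5, dim = c(64L, 64L),
                            calib = rogfp_calibration(0.25, 2.0, 0.5, 0.15),
                            pixel_size_um = 1,
                            photon_scale = 400,
                            read_noise_sd = 0.005,
                            seed = 1L) {
  if (is.list(oxd)) {
    oxd_map <- switch(oxd$type,
      gradient = matrix(rep(seq(oxd$from, oxd$to, length.out = dim[2]),
                            each = dim[1]), dim[1], dim[2]),
      two_region = {
        m <- matrix(oxd$left, dim[1], dim[2])
        m[, seq(floor(dim[2] / 2) + 1L, dim[2])] <- oxd$right
        m
      },
      stop("unknown oxd field type: ", oxd$type, call. = FALSE))
  } else if (is.matrix(oxd)) {
    oxd_map <- oxd
  } else {
    stopifnot(length(oxd) == 1L)
    oxd_map <- matrix(oxd, dim[1], dim[2])
  }
  if (any(oxd_map < 0 | oxd_map > 1)) {
    stop("OxD values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(photon_scale >= 0, read_noise_sd >= 0)
  structure(list(oxd_map = oxd_map, calib = calib,
                 pixel_size_um = pixel_size_um,
                 photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "biosensor_scene")
}

# Apply the scene's noise model to a noiseless intensity image.
add_scene_noise <- function(img, scene) {
  if (scene$photon_scale > 0) {
    img <- matrix(stats::rpois(length(img), img * scene$photon_scale) /
                    scene$photon_scale, nrow(img), ncol(img))
  }
  if (scene$read_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = scene$read_noise_sd),
                        nrow(img), ncol(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic biosensor stack with calibration pair
#'
#' Renders the scene into a sample stack plus its fully reduced (DTT-like,
#' OxD = 0) and fully oxidized (H2O2-like, OxD = 1) calibration stacks,
#' each with `exc405` and `exc488` channels, under the sensor intensity
#' model of [sensor_ratio()] and the scene's noise model. At zero noise the
#' measurement pipeline inverts the stack exactly.
#'
#' @param scene A [biosensor_scene()].
#' @param dir Optional directory: when given, the three stacks are written
#'   as float TIFFs and the ground truth as CSV there.
#' @return A list of class `biosensor_stack_set`: `sample`, `calib_red`,
#'   `calib_ox` ([image_stack()]s) and `truth` (list with `oxd_map`,
#'   `calib`, `seed`, and the matching `egsh_map` in mV).
#' @export
generate_biosensor_stack <- function(scene, dir = NULL) {
  stopifnot(inherits(scene, "biosensor_scene"))
  set.seed(scene$seed)
  d <- dim(scene$oxd_map)
  render <- function(oxd_map) {
    i488 <- matrix(sensor_i488(oxd_map, scene$calib), d[1], d[2])
    i405 <- matrix(sensor_ratio(oxd_map, scene$calib), d[1], d[2]) * i488
    image_stack(list(exc405 = add_scene_noise(i405, scene),
                     exc488 = add_scene_noise(i488, scene)),
                scene$pixel_size_um)
  }
  out <- list(
    sample = render(scene$oxd_map),
    calib_red = render(matrix(0, d[1], d[2])),
    calib_ox = render(matrix(1, d[1], d[2])),
    truth = list(oxd_map = scene$oxd_map, calib = scene$calib,
                 egsh_map = matrix(as.numeric(
                   egsh_from_oxd(pmin(pmax(scene$oxd_map, 1e-6), 1 - 1e-6))),
                   d[1], d[2]),
                 seed = scene$seed))
  class(out) <- "biosensor_stack_set"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_stack_tiff(out$sample, file.path(dir, "sample.tif"))
    write_stack_tiff(out$calib_red, file.path(dir, "calib_red.tif"))
    write_stack_tiff(out$calib_ox, file.path(dir, "calib_ox.tif"))
    truth <- data.frame(row = as.vector(row(scene$oxd_map)),
                        col = as.vector(col(scene$oxd_map)),
                        oxd = as.vector(scene$oxd_map))
    write_table_csv(truth, file.path(dir, "truth.csv"), seed = scene$seed)
    write_table_csv(data.frame(r_red = scene$calib$r_red,
                               r_ox = scene$calib$r_ox,
                               i488_red = scene$calib$i488_red,
                               i488_ox = scene$calib$i488_ox),
                    file.path(dir, "calibration.csv"), seed = scene$seed)
  }
  out
}

#' Estimate calibration endpoints from calibration stacks
#'
#' Measures the fully reduced and fully oxidized stacks in the given ROI
#' and returns the empirical calibration state (ratios and 488
#' intensities), as a wet-lab DTT / H2O2 calibration would.
#'
#' @param calib_red,calib_ox [image_stack()]s of the fully reduced /
#'   oxidized sensor.
#' @param roi A [circular_roi()]; default covers the image center at half
#'   the smaller image dimension.
#' @inheritParams ratio_measurement
#' @return A [rogfp_calibration()].
#' @export
estimate_calibration <- function(calib_red, calib_ox, roi = NULL,
                                 backgrounds = c(exc405 = 0, exc488 = 0)) {
  if (is.null(roi)) roi <- default_center_roi(calib_red)
  mr <- ratio_measurement(calib_red, roi, backgrounds)
  mo <- ratio_measurement(calib_ox, roi, backgrounds)
  rogfp_calibration(r_red = mr$ratio, r_ox = mo$ratio,
                    i488_red = mr$i488, i488_ox = mo$i488)
}

default_center_roi <- function(stack) {
  d <- dim(stack$channels[[1]])
  px <- stack$pixel_size_um
  circular_roi(d[2] / 2 * px, d[1] / 2 * px, min(d) / 2 * px * 0.9)
}

#' Recover OxD and E_GSH from a synthetic (or real) stack set
#'
#' Full measurement chain: estimate calibration from the calibration
#' stacks, measure the sample ROI ratio, and convert to OxD and E_GSH.
#'
#' @param stacks A `biosensor_stack_set` (or list with `sample`,
#'   `calib_red`, `calib_ox`).
#' @param roi ROI for all three stacks; default center ROI.
#' @param constants A [rogfp_constants()].
#' @inheritParams ratio_measurement
#' @return One-row data frame: `ratio`, `oxd`, `egsh`, `clamped`.
#' @export
measure_stack_set <- function(stacks, roi = NULL,
                              constants = rogfp_constants(),
                              mode = c("ratio_of_means", "pixelwise")) {
  mode <- match.arg(mode)
  if (is.null(roi)) roi <- default_center_roi(stacks$sample)
  calib <- estimate_calibration(stacks$calib_red, stacks$calib_ox, roi)
  m <- ratio_measurement(stacks$sample, roi, mode = mode)
  egsh_from_intensities(m$i405, m$i488, calib, constants)
}
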