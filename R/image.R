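#' Multi-channel image stack
#'
#' A set of equally sized 2-D grayscale intensity images (one per named
#' channel) with a physical pixel size. Intensities are normalized
#' arbitrary units in [0, 1] so stacks round-trip losslessly through 32-bit
#' float grayscale TIFF.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions and nonnegative values.
#' @param pixel_size_um Physical size of one pixel in micrometers (> 0).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_um = 1) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))),
            is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0)
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1)))) {
    stop("each channel must be a numeric matrix", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channels must share dimensions", call. = FALSE)
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("pixel intensities must be nonnegative", call. = FALSE)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image stack: %d x %d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Circular region of interest in physical coordinates
#'
#' Center and radius in micrometers. A pixel belongs to the ROI when its
#' center lies inside the circle; pixel (row i, column j) has its center at
#' x = (j - 0.5) * pixel_size, y = (i - 0.5) * pixel_size.
#'
#' @param cx_um,cy_um ROI center in micrometers (x = column direction,
#'   y = row direction).
#' @param radius_um ROI radius in micrometers (> 0).
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(cx_um, cy_um, radius_um) {
  stopifnot(is.finite(cx_um), is.finite(cy_um), is.finite(radius_um),
            radius_um > 0)
  structure(list(cx_um = cx_um, cy_um = cy_um, radius_um = radius_um),
            class = "circular_roi")
}

# Logical membership mask for an ROI on an image of the stack's geometry.
roi_mask <- function(dim, pixel_size_um, roi) {
  xc <- (seq_len(dim[2]) - 0.5) * pixel_size_um
  yc <- (seq_len(dim[1]) - 0.5) * pixel_size_um
  dx2 <- outer(rep(1, dim[1]), (xc - roi$cx_um)^2)
  dy2 <- outer((yc - roi$cy_um)^2, rep(1, dim[2]))
  dx2 + dy2 <= roi$radius_um^2
}

#' Background-corrected mean intensity inside a circular ROI
#'
#' Averages background-subtracted pixel values over the ROI (pixel-center
#' membership rule) and floors the mean at 0. Pixels at or above an
#' optional saturation level are excluded from the mean and flagged, since
#' saturated pixels bias ratio measurements.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param roi A [circular_roi()].
#' @param background Scalar background level (a.u.) subtracted from the
#'   mean, e.g. the mean of a background ROI. Default 0.
#' @param saturation_level Intensity at or above which a pixel is treated
#'   as saturated and excluded (`NULL` to disable).
#' @return A list of class `intensity_result`: `mean_intensity` (floored at
#'   0), `background`, `n_pixels`, `n_saturated`, and `flags` (character,
#'   possibly "saturation" / "floored").
#' @export
roi_mean <- function(stack, channel, roi, background = 0,
                     saturation_level = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "circular_roi"))
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("unknown channel: ", channel, call. = FALSE)
  mask <- roi_mask(dim(img), stack$pixel_size_um, roi)
  if (!any(mask)) {
    stop("geometry error: ROI contains no pixel centers", call. = FALSE)
  }
  vals <- img[mask]
  n_sat <- 0L
  if (!is.null(saturation_level)) {
    sat <- vals >= saturation_level
    n_sat <- sum(sat)
    vals <- vals[!sat]
    if (length(vals) == 0L) {
      stop("geometry error: all ROI pixels saturated", call. = FALSE)
    }
  }
  m <- mean(vals) - background
  flags <- character(0)
  if (n_sat > 0L) flags <- c(flags, "saturation")
  if (m < 0) {
    m <- 0
    flags <- c(flags, "floored")
  }
  structure(list(mean_intensity = m, background = background,
                 n_pixels = length(vals), n_saturated = n_sat,
                 flags = flags),
            class = "intensity_result")
}

#' @export
print.intensity_result <- function(x, ...) {
  cat(sprintf("ROI mean %.5g a.u. (background %.4g, %d px%s)\n",
              x$mean_intensity, x$background, x$n_pixels,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Ratiometric measurement of a two-channel stack in one ROI
#'
#' Computes the 405/488 excitation ratio from background-corrected ROI-mean
#' intensities (ratio of means — robust at low 488 signal). A per-pixel
#' mode (mean of pixelwise ratios over the ROI) is available for
#' comparison; both agree exactly on spatially uniform fields.
#'
#' @param stack An [image_stack()] with the two excitation channels.
#' @param roi A [circular_roi()].
#' @param backgrounds Named numeric vector of per-channel background levels
#'   (a.u.), e.g. `c(exc405 = 0.01, exc488 = 0.01)`. Missing channels get 0.
#' @param channels Names of the 405- and 488-excited channels.
#' @param mode `"ratio_of_means"` (default) or `"pixelwise"`.
#' @inheritParams roi_mean
#' @return A [biosensor_measurement()]; attribute `"n_pixels"` carries the
#'   ROI size and `"flags"` any saturation/floor flags.
#' @export
ratio_measurement <- function(stack, roi, backgrounds = c(exc405 = 0,
                                                          exc488 = 0),
                              channels = c("exc405", "exc488"),
                              mode = c("ratio_of_means", "pixelwise"),
                              saturation_level = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(channels) == 2L)
  bg <- function(ch) if (ch %in% names(backgrounds)) backgrounds[[ch]] else 0
  r405 <- roi_mean(stack, channels[1], roi, bg(channels[1]),
                   saturation_level)
  r488 <- roi_mean(stack, channels[2], roi, bg(channels[2]),
                   saturation_level)
  flags <- union(r405$flags, r488$flags)
  if (r488$mean_intensity <= 0) {
    stop("signal error: mean 488 intensity is nonpositive after background ",
         "correction", call. = FALSE)
  }
  if (mode == "ratio_of_means") {
    m <- biosensor_measurement(r405$mean_intensity, r488$mean_intensity)
  } else {
    img405 <- stack$channels[[channels[1]]]
    img488 <- stack$channels[[channels[2]]]
    mask <- roi_mask(dim(img488), stack$pixel_size_um, roi)
    v405 <- pmax(img405[mask] - bg(channels[1]), 0)
    v488 <- img488[mask] - bg(channels[2])
    keep <- v488 > 0
    if (!any(keep)) {
      stop("signal error: no positive 488 pixels after background correction",
           call. = FALSE)
    }
    ratio <- mean(v405[keep] / v488[keep])
    m <- biosensor_measurement(ratio * r488$mean_intensity,
                               r488$mean_intensity)
    m$ratio <- ratio
  }
  attr(m, "n_pixels") <- r488$n_pixels
  attr(m, "flags") <- flags
  m
}

#' Express intensities as percent of an untreated control
#'
#' Scales each value by 100 / mean(control), so the control group mean maps
#' to exactly 100%.
#'
#' @param values Numeric vector of per-sample intensities.
#' @param control_values Intensities of the untreated wild-type control
#'   group (nonempty, positive mean).
#' @return `values` in percent of the control mean.
#' @examples
#' percent_of_control(c(1.59, 1.37), c(0.9, 1.1)) # 159, 137
#' @export
percent_of_control <- function(values, control_values) {
  if (length(control_values) == 0L || !all(is.finite(control_values))) {
    stop("input error: control group must be nonempty and finite",
         call. = FALSE)
  }
  cm <- mean(control_values)
  if (cm <= 0) stop("input error: control mean must be positive",
                    call. = FALSE)
  100 * values / cm
}

#' Write / read an image stack as multi-page 32-bit float TIFF
#'
#' Pages are the channels, in order; channel names and pixel size are
#' recorded in a plain-text sidecar file (`<path>.meta`) so a written
#' stack reads back identically. Third-party TIFFs without a sidecar get
#' the supplied `channel_names` / `pixel_size_um`.
#'
#' @param stack An [image_stack()] (intensities in [0, 1]).
#' @param path Output TIFF path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (any(vapply(stack$channels, function(m) any(m > 1), logical(1)))) {
    stop("intensities must be in [0, 1] for float TIFF storage",
         call. = FALSE)
  }
  tiff::writeTIFF(unname(stack$channels), path, bits.per.sample = 32L)
  writeLines(c(paste0("channels: ",
                      paste(names(stack$channels), collapse = ",")),
               paste0("pixel_size_um: ",
                      format(stack$pixel_size_um, digits = 17))),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param channel_names Channel names to use if no sidecar is present
#'   (e.g. third-party TIFFs).
#' @param pixel_size_um Pixel size override if no sidecar is present.
#' @export
read_stack_tiff <- function(path, channel_names = NULL, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    channel_names <- strsplit(meta$channels, ",", fixed = TRUE)[[1]]
    pixel_size_um <- as.numeric(meta$pixel_size_um)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_along(pages))
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L] # collapse gray-written-as-RGB
    attributes(p) <- list(dim = dim(p))
    p
  })
  image_stack(stats::setNames(pages, channel_names), pixel_size_um)
}

#' Quantify a table of ROIs on image files
#'
#' Batch driver for the manual-ROI workflow: an ROI table names, per image
#' and channel, sample and background circles; each sample ROI is
#' quantified with the mean of its image/channel background ROI (0 when
#' none is given) subtracted.
#'
#' @param roi_table Data frame with columns `image_id`, `path`, `channel`,
#'   `cx_um`, `cy_um`, `radius_um`, `role` (`"sample"` or `"background"`)
#'   and optionally `roi_id`. Alternatively a path to such a CSV.
#' @param image_dir Directory against which relative `path` entries are
#'   resolved.
#' @inheritParams roi_mean
#' @return Data frame with one row per sample ROI: `image_id`, `channel`,
#'   `roi_id`, `mean_intensity`, `background`, `n_pixels`, `flags`.
#' @export
quantify_rois <- function(roi_table, image_dir = ".",
                          saturation_level = NULL) {
  if (is.character(roi_table)) roi_table <- read_table_csv(roi_table)
  need <- c("image_id", "path", "channel", "cx_um", "cy_um", "radius_um",
            "role")
  if (!all(need %in% names(roi_table))) {
    stop("ROI table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(roi_table$roi_id)) roi_table$roi_id <- seq_len(nrow(roi_table))
  out <- list()
  for (img_id in unique(roi_table$image_id)) {
    sub <- roi_table[roi_table$image_id == img_id, , drop = FALSE]
    p <- sub$path[1]
    if (!file.exists(p)) p <- file.path(image_dir, p)
    stack <- read_stack_tiff(p)
    for (ch in unique(sub$channel)) {
      chsub <- sub[sub$channel == ch, , drop = FALSE]
      bgrows <- chsub[chsub$role == "background", , drop = FALSE]
      bg <- 0
      if (nrow(bgrows) > 0L) {
        bg <- mean(vapply(seq_len(nrow(bgrows)), function(i) {
          roi_mean(stack, ch,
                   circular_roi(bgrows$cx_um[i], bgrows$cy_um[i],
                                bgrows$radius_um[i]))$mean_intensity
        }, numeric(1)))
      }
      srows <- chsub[chsub$role == "sample", , drop = FALSE]
      for (i in seq_len(nrow(srows))) {
        res <- roi_mean(stack, ch,
                        circular_roi(srows$cx_um[i], srows$cy_um[i],
                                     srows$radius_um[i]),
                        background = bg,
                        saturation_level = saturation_level)
        out[[length(out) + 1L]] <- data.frame(
          image_id = img_id, channel = ch, roi_id = srows$roi_id[i],
          mean_intensity = res$mean_intensity, background = bg,
          n_pixels = res$n_pixels,
          flags = paste(res$flags, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
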