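# Synthetic two-channel vessel micrographs (endothelial CD31 + AQP4) with
# controllable perivascular AQP4 enrichment, and single-channel chromogenic
# sections with a known positive-pixel fraction.  These are validation
# fixtures for the polarization, coverage and immunoreactivity estimators;
# the geometry (circular vessel, annular endfoot ring) is idealized.

#' Two-channel image container
#'
#' @param channels named list of 2D numeric matrices of identical shape
#'   (e.g. `CD31`, `AQP4`).
#' @param pixel_size micrometres per pixel (> 0).
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(channels, pixel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L, pixel_size > 0)
  d <- dim(channels[[1L]])
  for (ch in channels)
    if (!identical(dim(ch), d))
      stop("all channels must share the same shape", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 channel_names = names(channels)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("channel_image: %d x %d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

radius_grid <- function(shape, center) {
  dx <- matrix(rep(seq_len(shape[1]) - center[1], shape[2]), shape[1])
  dy <- matrix(rep(seq_len(shape[2]) - center[2], each = shape[1]), shape[1])
  sqrt(dx^2 + dy^2)
}

#' Specification of a synthetic vessel micrograph
#'
#' A circular vessel (lumen + endothelial wall marked in the CD31 channel)
#' with a perivascular AQP4 ring of known intensity; the surrounding
#' parenchyma is partitioned so that `target_polarization` percent of the
#' analysis region (image minus lumen and wall) falls strictly below the
#' perivascular median AQP4 intensity, up to one-pixel discretization.
#'
#' @param image_shape pixels per axis (length 2).
#' @param pixel_size micrometres per pixel.
#' @param vessel_center pixel coordinates of the vessel centre.
#' @param vessel_radius outer lumen radius, pixels.
#' @param wall_width endothelial wall thickness, micrometres.
#' @param ring_width perivascular (endfoot) ring width, micrometres.
#' @param aqp4_perivascular AQP4 intensity of the perivascular ring.
#' @param aqp4_low parenchymal AQP4 intensity of "polarized" (below-median)
#'   pixels; must be < `aqp4_perivascular`.
#' @param aqp4_high parenchymal AQP4 intensity of pixels at or above the
#'   perivascular level (default equal to it, so a zero-polarization image
#'   is uniform over ring plus parenchyma).
#' @param cd31_level endothelial channel intensity on the wall.
#' @param target_polarization percent of the analysis region below the
#'   perivascular median AQP4 intensity, in `[0, 100]`.
#' @param target_vessel_coverage percent of wall pixels that are
#'   AQP4-positive, in `[0, 100]`.
#' @param background_level additive offset on every pixel of every channel.
#' @param noise_sd additive Gaussian noise SD (0 = noiseless; keep small
#'   relative to the intensity separation or ties at the median blur).
#' @param seed integer seed; identical specs give identical images.
#' @return an object of class `vessel_image_spec`.
#' @export
vessel_image_spec <- function(image_shape = c(192L, 192L),
                              pixel_size = 0.2,
                              vessel_center = NULL,
                              vessel_radius = 2,
                              wall_width = 0.4,
                              ring_width = 1,
                              aqp4_perivascular = 200,
                              aqp4_low = 60,
                              aqp4_high = aqp4_perivascular,
                              cd31_level = 180,
                              target_polarization = 80,
                              target_vessel_coverage = 100,
                              background_level = 10,
                              noise_sd = 0,
                              seed = 1L) {
  if (target_polarization < 0 || target_polarization > 100)
    stop("'target_polarization' must be in [0, 100]", call. = FALSE)
  if (target_vessel_coverage < 0 || target_vessel_coverage > 100)
    stop("'target_vessel_coverage' must be in [0, 100]", call. = FALSE)
  if (aqp4_low >= aqp4_perivascular)
    stop("'aqp4_low' must be below 'aqp4_perivascular'", call. = FALSE)
  if (is.null(vessel_center)) vessel_center <- (image_shape + 1) / 2
  ring_outer <- vessel_radius + (wall_width + ring_width) / pixel_size
  if (vessel_center[1] - ring_outer < 1 || vessel_center[2] - ring_outer < 1 ||
      vessel_center[1] + ring_outer > image_shape[1] ||
      vessel_center[2] + ring_outer > image_shape[2])
    stop("perivascular ring exceeds image bounds", call. = FALSE)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, vessel_center = vessel_center,
                 vessel_radius = vessel_radius, wall_width = wall_width,
                 ring_width = ring_width,
                 aqp4_perivascular = aqp4_perivascular, aqp4_low = aqp4_low,
                 aqp4_high = aqp4_high, cd31_level = cd31_level,
                 target_polarization = target_polarization,
                 target_vessel_coverage = target_vessel_coverage,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "vessel_image_spec")
}

vessel_zones <- function(spec) {
  r <- radius_grid(spec$image_shape, spec$vessel_center)
  wall_outer <- spec$vessel_radius + spec$wall_width / spec$pixel_size
  ring_outer <- wall_outer + spec$ring_width / spec$pixel_size
  list(lumen = r < spec$vessel_radius,
       wall = r >= spec$vessel_radius & r < wall_outer,
       ring = r >= wall_outer & r < ring_outer,
       parenchyma = r >= ring_outer)
}

#' Generate a synthetic two-channel vessel image
#'
#' @param spec a [vessel_image_spec].
#' @return an object of class `vessel_phantom`: list with `image`
#'   ([channel_image] with `CD31` and `AQP4` channels), `record` (the
#'   matching [vessel_record]), `truth` (realized polarization and coverage
#'   percentages) and `spec`.
#' @export
generate_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "vessel_image_spec"))
  with_seed(spec$seed, {
    z <- vessel_zones(spec)
    aqp4 <- matrix(spec$background_level, spec$image_shape[1],
                   spec$image_shape[2])
    cd31 <- matrix(spec$background_level, spec$image_shape[1],
                   spec$image_shape[2])
    aqp4[z$ring] <- spec$background_level + spec$aqp4_perivascular
    cd31[z$wall] <- spec$background_level + spec$cd31_level
    # AQP4 over the delineated vessel (lumen + wall): exactly the target
    # fraction of vessel pixels positive
    vessel_idx <- which(z$wall | z$lumen)
    n_pos <- round(spec$target_vessel_coverage / 100 * length(vessel_idx))
    pos <- sample(vessel_idx, n_pos)
    aqp4[pos] <- spec$background_level + spec$aqp4_perivascular
    # analysis region = image minus lumen+wall (ring pixels sit exactly at
    # the perivascular median, so they count as >= under the tie rule).
    # The background normalization patch stays unstained (below median);
    # it is part of the analysis region, so it counts toward the low pool.
    region_idx <- which(!(z$lumen | z$wall))
    bg_idx <- background_corner(spec)
    par_idx <- setdiff(which(z$parenchyma), bg_idx)
    k <- round(spec$target_polarization / 100 * length(region_idx))
    k <- min(max(k - length(bg_idx), 0L), length(par_idx))
    low <- sample(par_idx, k)
    high <- setdiff(par_idx, low)
    aqp4[low] <- spec$background_level + spec$aqp4_low
    aqp4[high] <- spec$background_level + spec$aqp4_high
    if (spec$noise_sd > 0) {
      aqp4 <- aqp4 + stats::rnorm(length(aqp4), 0, spec$noise_sd)
      cd31 <- cd31 + stats::rnorm(length(cd31), 0, spec$noise_sd)
    }
    img <- channel_image(list(CD31 = cd31, AQP4 = aqp4), spec$pixel_size)
    med <- stats::median(aqp4[z$ring])
    truth <- c(polarization_pct = 100 * sum(aqp4[region_idx] < med) /
                 length(region_idx),
               vessel_coverage_pct = 100 * n_pos / length(vessel_idx))
    rec <- vessel_record(
      vessel_region = which(z$wall | z$lumen),
      perivascular_region = which(z$ring),
      axis = profile_axis(spec),
      background_region = background_corner(spec),
      image_shape = spec$image_shape, pixel_size = spec$pixel_size)
    structure(list(image = img, record = rec, truth = truth, spec = spec),
              class = "vessel_phantom")
  })
}

# Horizontal 4-um cross-section axis through the vessel centre.
profile_axis <- function(spec) {
  half <- 2 / spec$pixel_size
  rbind(c(spec$vessel_center[1] - half, spec$vessel_center[2]),
        c(spec$vessel_center[1] + half, spec$vessel_center[2]))
}

# Small background patch in the image corner, clear of the vessel.
background_corner <- function(spec) {
  n <- min(10L, spec$image_shape)
  idx <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  idx[, 1] + (idx[, 2] - 1L) * spec$image_shape[1]
}

#' Per-vessel analysis annotation
#'
#' Records the pixel sets and cross-section axis used to quantify one
#' vessel: the vessel region (lumen + endothelial wall), the perivascular
#' (endfoot) region, a 4 micrometre profile axis perpendicular to the
#' vessel, and the background patch used for profile normalization (the
#' choice is recorded rather than random so results are reproducible).
#'
#' @param vessel_region,perivascular_region,background_region integer pixel
#'   (linear) indices into the image.
#' @param axis 2 x 2 matrix, endpoint pixel coordinates of the profile axis.
#' @param image_shape image dimensions the indices refer to.
#' @param pixel_size micrometres per pixel.
#' @return an object of class `vessel_record`.
#' @export
vessel_record <- function(vessel_region, perivascular_region, axis,
                          background_region, image_shape, pixel_size) {
  stopifnot(length(vessel_region) > 0, length(background_region) > 0)
  npx <- prod(image_shape)
  for (v in list(vessel_region, perivascular_region, background_region))
    if (any(v < 1L | v > npx))
      stop("region indices outside image bounds", call. = FALSE)
  if (length(intersect(vessel_region, background_region)))
    stop("background region must be disjoint from the vessel", call. = FALSE)
  len_um <- sqrt(sum((axis[2, ] - axis[1, ])^2)) * pixel_size
  if (abs(len_um - 4) > pixel_size * 2)
    warning(sprintf("profile axis length %.2f um differs from 4 um", len_um),
            call. = FALSE)
  structure(list(vessel_region = as.integer(vessel_region),
                 perivascular_region = as.integer(perivascular_region),
                 axis = axis,
                 background_region = as.integer(background_region),
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size),
            class = "vessel_record")
}

#' Specification of a synthetic chromogenic section
#'
#' One or more polygonal regions in which a known fraction of pixels is
#' raised above a stain threshold.
#'
#' @param image_shape pixels per axis.
#' @param regions named list of polygons (n x 2 matrices of pixel
#'   coordinates, vertices in order).
#' @param positive_fraction percent of each region's pixels above threshold;
#'   scalar or one value per region, each in `[0, 100]`.
#' @param positive_level,negative_level,background_level stain intensities.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return an object of class `section_spec`.
#' @export
section_spec <- function(image_shape = c(128L, 128L), regions,
                         positive_fraction, positive_level = 200,
                         negative_level = 40, background_level = 10,
                         noise_sd = 0, seed = 1L) {
  if (any(positive_fraction < 0) || any(positive_fraction > 100))
    stop("'positive_fraction' must be in [0, 100]", call. = FALSE)
  if (is.null(names(regions)))
    names(regions) <- paste0("region_", seq_along(regions))
  for (nm in names(regions))
    if (nrow(regions[[nm]]) < 3L)
      stop(sprintf("region '%s' polygon is degenerate", nm), call. = FALSE)
  positive_fraction <- rep(positive_fraction, length.out = length(regions))
  structure(list(image_shape = as.integer(image_shape), regions = regions,
                 positive_fraction = positive_fraction,
                 positive_level = positive_level,
                 negative_level = negative_level,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "section_spec")
}

# Pixels of an image grid inside a polygon (even-odd rule via mgcv).
polygon_pixels <- function(poly, shape) {
  g <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2])))
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, g)
  idx <- which(inside)
  if (length(idx) == 0L)
    stop("region polygon encloses no pixels", call. = FALSE)
  g[idx, 1] + (g[idx, 2] - 1L) * shape[1]
}

#' Generate a synthetic chromogenic section
#'
#' @param spec a [section_spec].
#' @return an object of class `section_phantom`: list with `image` (matrix),
#'   `region_pixels` (named list of linear indices), `truth` (named realized
#'   positive percentages) and `spec`.
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  with_seed(spec$seed, {
    img <- matrix(spec$background_level, spec$image_shape[1],
                  spec$image_shape[2])
    region_pixels <- list(); truth <- numeric(0)
    for (li in seq_along(spec$regions)) {
      nm <- names(spec$regions)[li]
      px <- polygon_pixels(spec$regions[[li]], spec$image_shape)
      k <- round(spec$positive_fraction[li] / 100 * length(px))
      pos <- sample(px, k)
      img[px] <- spec$negative_level
      img[pos] <- spec$positive_level
      region_pixels[[nm]] <- px
      truth[nm] <- 100 * k / length(px)
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    structure(list(image = img, region_pixels = region_pixels, truth = truth,
                   spec = spec),
              class = "section_phantom")
  })
}

#' Write a channel image as TIFF
#'
#' Channels are written as separate pages of one multi-page TIFF, scaled to
#' `[0, 1]` by `scale_max`.
#'
#' @param image a [channel_image].
#' @param path output `.tif` path.
#' @param scale_max intensity mapped to full scale.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path, scale_max = NULL) {
  stopifnot(inherits(image, "channel_image"))
  if (is.null(scale_max))
    scale_max <- max(vapply(image$channels, max, numeric(1)))
  pages <- lapply(image$channels, function(ch) pmin(pmax(ch / scale_max, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
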