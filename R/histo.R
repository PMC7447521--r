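# Micrograph quantification: positive-pixel immunoreactivity and regional
# ratios, vessel cross-section line profiles, perivascular AQP4
# polarization and vessel coverage.

get_channel <- function(image, channel) {
  if (inherits(image, "channel_image")) {
    if (is.numeric(channel)) return(image$channels[[channel]])
    if (!channel %in% image$channel_names)
      stop(sprintf("no channel '%s'", channel), call. = FALSE)
    return(image$channels[[channel]])
  }
  if (is.matrix(image)) return(image)
  stop("'image' must be a channel_image or a matrix", call. = FALSE)
}

#' Percent immunoreactivity of a region
#'
#' Fraction (as a percentage) of region pixels whose stain intensity is at
#' or above a uniform threshold.
#'
#' @param image a [channel_image] or single-channel matrix.
#' @param region integer linear pixel indices of the region.
#' @param threshold intensity threshold.
#' @param channel channel name or index when `image` is multi-channel.
#' @return percentage in `[0, 100]`.
#' @export
percent_immunoreactivity <- function(image, region, threshold, channel = 1L) {
  px <- get_channel(image, channel)
  if (length(region) == 0L) stop("empty region", call. = FALSE)
  if (any(region < 1L | region > length(px)))
    stop("region indices outside image", call. = FALSE)
  100 * sum(px[region] >= threshold) / length(region)
}

#' Mean regional ratio across animals
#'
#' Paired regional measurements (e.g. rostral and caudal percent coverage
#' per animal) are converted to a per-animal ratio first; the mean and SEM
#' are then taken across animals.  This is the mean of per-animal ratios,
#' not the ratio of group means.
#'
#' @param numerator,denominator numeric vectors, one value per animal.
#' @return list with `ratios` (per animal), `mean`, `sem` (`NA` with a flag
#'   when n = 1) and `n`.
#' @export
region_ratio <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator),
            length(numerator) >= 1L)
  bad <- denominator == 0
  if (any(bad)) {
    warning(sprintf("%d animal(s) excluded: zero denominator", sum(bad)),
            call. = FALSE)
    numerator <- numerator[!bad]; denominator <- denominator[!bad]
  }
  if (length(numerator) == 0L)
    stop("no animals with nonzero denominator", call. = FALSE)
  r <- numerator / denominator
  n <- length(r)
  list(ratios = r, mean = mean(r),
       sem = if (n > 1L) stats::sd(r) / sqrt(n) else NA_real_,
       n = n)
}

# Bilinear interpolation of a matrix at fractional coordinates.
bilinear <- function(px, x, y) {
  d <- dim(px)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  fx <- x - x0; fy <- y - y0
  px[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    px[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    px[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    px[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Normalized intensity profile across a vessel
#'
#' Samples each requested channel along the recorded 4 micrometre axis
#' perpendicular to the vessel (bilinear interpolation between pixels) and
#' divides by the mean intensity of the recorded background region for that
#' channel, yielding background-normalized fluorescence versus position.
#'
#' @param image a [channel_image].
#' @param record a [vessel_record].
#' @param channels channel names to profile (default: all).
#' @param n_samples samples along the axis.
#' @return data frame with `position_um` (0 at the axis start) and one
#'   normalized-intensity column per channel.
#' @export
vessel_line_profile <- function(image, record, channels = NULL,
                                n_samples = 41L) {
  stopifnot(inherits(image, "channel_image"), inherits(record, "vessel_record"))
  if (is.null(channels)) channels <- image$channel_names
  a <- record$axis
  tt <- seq(0, 1, length.out = n_samples)
  xs <- a[1, 1] + tt * (a[2, 1] - a[1, 1])
  ys <- a[1, 2] + tt * (a[2, 2] - a[1, 2])
  len_um <- sqrt(sum((a[2, ] - a[1, ])^2)) * record$pixel_size
  out <- data.frame(position_um = tt * len_um)
  for (ch in channels) {
    px <- get_channel(image, ch)
    bg <- mean(px[record$background_region])
    if (bg == 0)
      stop(sprintf("background mean is zero for channel '%s'", ch),
           call. = FALSE)
    out[[ch]] <- bilinear(px, xs, ys) / bg
  }
  out
}

#' Perivascular AQP4 polarization
#'
#' The threshold is the median AQP4 intensity over the perivascular
#' (endfoot) region.  `aqp4_area_pct` is the percentage of the analysis
#' region with AQP4 intensity greater than or equal to that threshold
#' (ties count as at-threshold expression); polarization is its complement,
#' the percentage of the region expressing less AQP4 than the endfeet.
#'
#' @param image a [channel_image] (or matrix of AQP4 intensities).
#' @param record a [vessel_record].
#' @param channel AQP4 channel name or index.
#' @param analysis_region linear pixel indices over which area percentages
#'   are computed; default the whole image minus the vessel region.
#' @return an object of class `polarization_result` with `polarization_pct`,
#'   `aqp4_area_pct` and the `threshold` used.
#' @export
polarization_index <- function(image, record, channel = "AQP4",
                               analysis_region = NULL) {
  px <- get_channel(image, channel)
  if (length(record$perivascular_region) == 0L)
    stop("empty perivascular region", call. = FALSE)
  if (is.null(analysis_region))
    analysis_region <- setdiff(seq_along(px), record$vessel_region)
  if (length(analysis_region) == 0L)
    stop("empty analysis region", call. = FALSE)
  thr <- stats::median(px[record$perivascular_region])
  area <- 100 * sum(px[analysis_region] >= thr) / length(analysis_region)
  structure(list(polarization_pct = 100 - area, aqp4_area_pct = area,
                 threshold = thr),
            class = "polarization_result")
}

#' @export
print.polarization_result <- function(x, ...) {
  cat(sprintf("AQP4 polarization %.1f %% (AQP4 area %.1f %%, threshold %.3g)\n",
              x$polarization_pct, x$aqp4_area_pct, x$threshold))
  invisible(x)
}

#' AQP4 vessel coverage
#'
#' Percentage of the endothelially delineated vessel region whose AQP4
#' intensity is at or above the immunoreactivity threshold.
#'
#' @param image a [channel_image] (or AQP4 matrix).
#' @param record a [vessel_record].
#' @param aqp4_threshold intensity threshold for AQP4 positivity.
#' @param channel AQP4 channel name or index.
#' @return percentage in `[0, 100]`.
#' @export
vessel_coverage <- function(image, record, aqp4_threshold, channel = "AQP4") {
  px <- get_channel(image, channel)
  if (length(record$vessel_region) == 0L)
    stop("empty vessel region", call. = FALSE)
  100 * sum(px[record$vessel_region] >= aqp4_threshold) /
    length(record$vessel_region)
}

#' Delineate a vessel from the endothelial channel
#'
#' Thresholds the endothelial (CD31) channel, keeps the largest connected
#' component and fills its contour, giving the vessel region (wall + lumen).
#' The perivascular region is the annulus of configurable width immediately
#' outside that boundary.
#'
#' @param image a [channel_image].
#' @param threshold endothelial intensity threshold.
#' @param channel endothelial channel name or index.
#' @param perivascular_width annulus width in micrometres (default 1).
#' @param axis optional 2 x 2 profile-axis endpoint matrix; default a
#'   horizontal 4 micrometre axis through the region centroid.
#' @param background_region optional linear indices of the normalization
#'   patch; default the largest-margin image corner, clear of the vessel.
#' @return a [vessel_record].
#' @export
delineate_vessel <- function(image, threshold, channel = "CD31",
                             perivascular_width = 1, axis = NULL,
                             background_region = NULL) {
  px <- get_channel(image, channel)
  d <- dim(px)
  bw <- EBImage::bwlabel(px >= threshold)
  if (max(bw) == 0) stop("no endothelial signal above threshold",
                         call. = FALSE)
  sizes <- tabulate(bw[bw > 0])
  comp <- bw == which.max(sizes)
  filled <- EBImage::fillHull(comp) > 0
  vessel_idx <- which(filled)
  # annulus: dilate by the perivascular width and subtract the vessel
  r_px <- max(1L, round(perivascular_width / image$pixel_size))
  kern <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  ring <- EBImage::dilate(filled, kern) & !filled
  cen <- colMeans(which(filled, arr.ind = TRUE))
  if (is.null(axis)) {
    half <- 2 / image$pixel_size
    axis <- rbind(c(cen[1] - half, cen[2]), c(cen[1] + half, cen[2]))
  }
  if (is.null(background_region)) {
    n <- min(10L, d)
    corners <- list(expand.grid(seq_len(n), seq_len(n)),
                    expand.grid(d[1] - seq_len(n) + 1L, seq_len(n)),
                    expand.grid(seq_len(n), d[2] - seq_len(n) + 1L),
                    expand.grid(d[1] - seq_len(n) + 1L,
                                d[2] - seq_len(n) + 1L))
    for (co in corners) {
      idx <- co[, 1] + (co[, 2] - 1L) * d[1]
      if (!length(intersect(idx, vessel_idx))) {
        background_region <- idx
        break
      }
    }
    if (is.null(background_region))
      stop("no vessel-free corner for background; supply one", call. = FALSE)
  }
  vessel_record(vessel_idx, which(ring), axis, background_region,
                d, image$pixel_size)
}
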