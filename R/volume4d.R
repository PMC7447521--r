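#' 4D dynamic image series
#'
#' Container for a T1-weighted dynamic contrast-enhanced series: a 4D array
#' indexed (i, j, k, frame) with voxel spacing in mm, frame times in minutes
#' from the start of intrathecal infusion (baseline frames carry non-positive
#' times) and the number of pre-infusion baseline frames.
#'
#' @param data 4D numeric array, dimensions x, y, z, frame.
#' @param voxel_size numeric length-3, mm per voxel along each axis.
#' @param frame_times numeric, minutes; strictly increasing, one per frame.
#' @param n_baseline number of leading baseline frames (>= 1).
#' @return an object of class `volume4d`.
#' @export
volume4d <- function(data, voxel_size, frame_times, n_baseline) {
  d <- dim(data)
  if (length(d) != 4L) stop("'data' must be a 4D array", call. = FALSE)
  if (any(d[1:3] < 1L)) stop("spatial dimensions must be positive", call. = FALSE)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (length(frame_times) != d[4L])
    stop("'frame_times' must have one entry per frame", call. = FALSE)
  if (any(diff(frame_times) <= 0))
    stop("'frame_times' must be strictly increasing", call. = FALSE)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L) stop("'n_baseline' must be >= 1", call. = FALSE)
  if (n_baseline >= d[4L])
    stop("need at least one post-baseline frame", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 frame_times = as.numeric(frame_times),
                 n_baseline = n_baseline),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume4d: %d x %d x %d voxels, %d frames (%d baseline)\n",
              d[1], d[2], d[3], d[4], x$n_baseline))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g mm; t = %.4g .. %.4g min\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

n_frames <- function(vol) dim(vol$data)[4L]

frame_at <- function(vol, i) vol$data[, , , i, drop = TRUE]

#' Average baseline image
#'
#' Voxelwise arithmetic mean of the leading baseline frames; the reference
#' image against which difference images and percent change are computed.
#'
#' @param vol a [volume4d].
#' @return 3D numeric array.
#' @export
average_baseline <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  nb <- vol$n_baseline
  b <- frame_at(vol, 1L)
  if (nb > 1L) for (i in 2L:nb) b <- b + frame_at(vol, i)
  b / nb
}

#' Difference image for one frame
#'
#' Voxelwise subtraction of the average baseline image from a post-baseline
#' frame, `D = I - B`.
#'
#' @param vol a [volume4d].
#' @param frame frame index (must be post-baseline).
#' @param baseline optional precomputed baseline average.
#' @return 3D numeric array.
#' @export
difference_image <- function(vol, frame, baseline = NULL) {
  stopifnot(inherits(vol, "volume4d"))
  frame <- as.integer(frame)
  if (frame < 1L || frame > n_frames(vol))
    stop("'frame' out of range", call. = FALSE)
  if (frame <= vol$n_baseline)
    stop("'frame' must index a post-baseline frame", call. = FALSE)
  if (is.null(baseline)) baseline <- average_baseline(vol)
  frame_at(vol, frame) - baseline
}

#' Labelled region-of-interest mask
#'
#' @param labels 3D integer array on the same grid as the volume it
#'   annotates; 0 marks voxels outside every region.
#' @param label_names named character vector or list mapping label value
#'   (as character) to region name; defaults to `"region_<label>"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(labels, label_names = NULL) {
  if (length(dim(labels)) != 3L) stop("'labels' must be 3D", call. = FALSE)
  labs <- sort(unique(as.integer(labels[labels != 0])))
  if (is.null(label_names))
    label_names <- stats::setNames(paste0("region_", labs), as.character(labs))
  structure(list(labels = labels, label_names = as.list(label_names)),
            class = "roi_mask")
}

#' Extract ROI percent-change time series
#'
#' For each labelled region and each frame, the mean intensity over the
#' region is expressed as a percent change from the mean of the average
#' baseline image over the same region:
#' `100 * (mean_ROI(I) - mean_ROI(B)) / mean_ROI(B)`.
#' Baseline frames are included and sit near zero.
#'
#' @param vol a [volume4d].
#' @param mask an [roi_mask] on the same spatial grid.
#' @return a `roi_series` data frame with columns `region`, `time_min`,
#'   `pct_change`, `n_voxels`.
#' @export
extract_roi_timeseries <- function(vol, mask) {
  stopifnot(inherits(vol, "volume4d"), inherits(mask, "roi_mask"))
  if (!identical(dim(mask$labels), dim(vol$data)[1:3]))
    stop("mask grid does not match volume grid", call. = FALSE)
  B <- average_baseline(vol)
  labs <- names(mask$label_names)
  out <- vector("list", length(labs))
  for (li in seq_along(labs)) {
    lab <- as.integer(labs[[li]])
    idx <- which(mask$labels == lab)
    if (length(idx) == 0L)
      stop(sprintf("region label %d ('%s') selects no voxels", lab,
                   mask$label_names[[li]]), call. = FALSE)
    b_mean <- mean(B[idx])
    pc <- vapply(seq_len(n_frames(vol)), function(fr) {
      100 * (mean(frame_at(vol, fr)[idx]) - b_mean) / b_mean
    }, numeric(1))
    out[[li]] <- data.frame(region = mask$label_names[[li]],
                            time_min = vol$frame_times,
                            pct_change = pc,
                            n_voxels = length(idx))
  }
  res <- do.call(rbind, out)
  class(res) <- c("roi_series", class(res))
  res
}

#' Read / write a 4D series as NIfTI-1
#'
#' The image is stored as a standard NIfTI-1 volume; frame times and the
#' baseline-frame count travel in a JSON sidecar next to the image.
#'
#' @param vol a [volume4d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_volume4d` returns `path` invisibly; `read_volume4d`
#'   returns a [volume4d].
#' @export
write_volume4d <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  img <- RNifti::asNifti(vol$data, pixdim = c(vol$voxel_size, 1))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(frame_times = vol$frame_times,
                            n_baseline = vol$n_baseline,
                            voxel_size = vol$voxel_size),
                       side, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_volume4d
#' @export
read_volume4d <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  volume4d(array(as.numeric(img), dim = dim(img)),
           voxel_size = meta$voxel_size,
           frame_times = meta$frame_times,
           n_baseline = meta$n_baseline)
}
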