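# Synthetic dynamic contrast-enhanced phantom with known sigmoidal inflow
# ground truth.  The forward model for each enhancing region is exactly the
# logistic inflow curve (percent change over baseline, zero pre-infusion);
# corruption is applied in the order enhancement -> multiplicative bias
# (anatomy frame) -> per-frame translation -> additive Gaussian noise, i.e.
# the inverse of the correction chain register -> bias-correct.

#' Cuboid enhancing region for a phantom
#'
#' @param name region name.
#' @param center integer voxel centre (length 3).
#' @param halfwidth integer half extent per axis; the region spans
#'   `center - halfwidth .. center + halfwidth`.
#' @param intensity_max,time_50,slope generating sigmoid parameters
#'   (percent, minutes, minutes).
#' @return a region specification usable in [phantom_spec].
#' @export
cuboid_region <- function(name, center, halfwidth, intensity_max, time_50,
                          slope) {
  stopifnot(length(center) == 3L, length(halfwidth) %in% c(1L, 3L))
  halfwidth <- rep(as.integer(halfwidth), length.out = 3L)
  g <- expand.grid(x = (center[1] - halfwidth[1]):(center[1] + halfwidth[1]),
                   y = (center[2] - halfwidth[2]):(center[2] + halfwidth[2]),
                   z = (center[3] - halfwidth[3]):(center[3] + halfwidth[3]))
  list(name = name, voxels = as.matrix(g),
       intensity_max = intensity_max, time_50 = time_50, slope = slope)
}

#' Specification of a dynamic contrast-enhanced phantom
#'
#' Defaults mirror the acquisition the pipeline was designed around
#' (12-minute frames, 3 pre-infusion baseline frames, 180 minutes of
#' post-infusion imaging, 0.1 x 0.1 x 0.15 mm voxels) at a reduced 32^3
#' grid; geometry scales through the arguments.
#'
#' @param regions list of region specifications (see [cuboid_region]); each
#'   has a `name`, an n x 3 integer `voxels` matrix and generating
#'   `intensity_max`, `time_50`, `slope`.
#' @param grid_shape voxels per axis.
#' @param voxel_size mm per voxel.
#' @param frame_interval minutes per frame.
#' @param n_baseline number of pre-infusion baseline frames (>= 1).
#' @param n_frames total frames (> `n_baseline`).
#' @param frame_times optional explicit times (minutes from infusion start,
#'   baseline frames non-positive); default
#'   `(seq_len(n_frames) - n_baseline) * frame_interval`.
#' @param noise_sd additive Gaussian noise SD in percent-of-baseline units.
#' @param bias_amplitude multiplicative non-uniformity range: 1 = flat
#'   field, 1.1 = up to +10 percent at the corners (quadratic profile).
#' @param motion_amplitude maximum per-axis translation of post-baseline
#'   frames, voxels (uniform, possibly sub-voxel).
#' @param baseline_value mean baseline intensity (arbitrary units).
#' @param baseline_structure amplitude of the smooth deterministic texture
#'   multiplying the baseline (0 = uniform).  Texture gives the registration
#'   problem contrast; it cancels exactly in ROI percent change.
#' @param seed integer seed; identical specs give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(regions,
                         grid_shape = c(32L, 32L, 32L),
                         voxel_size = c(0.1, 0.1, 0.15),
                         frame_interval = 12,
                         n_baseline = 3L,
                         n_frames = 18L,
                         frame_times = NULL,
                         noise_sd = 0,
                         bias_amplitude = 1,
                         motion_amplitude = 0,
                         baseline_value = 100,
                         baseline_structure = 0.15,
                         seed = 1L) {
  n_baseline <- as.integer(n_baseline); n_frames <- as.integer(n_frames)
  if (n_baseline < 1L) stop("'n_baseline' must be >= 1", call. = FALSE)
  if (n_frames <= n_baseline)
    stop("'n_frames' must exceed 'n_baseline'", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (is.null(frame_times))
    frame_times <- (seq_len(n_frames) - n_baseline) * frame_interval
  else n_frames <- length(frame_times)
  if (n_frames <= n_baseline)
    stop("'n_frames' must exceed 'n_baseline'", call. = FALSE)
  if (length(frame_times) != n_frames || any(diff(frame_times) <= 0))
    stop("'frame_times' must be increasing with one entry per frame",
         call. = FALSE)
  t_max <- max(frame_times)
  seen <- array(FALSE, dim = grid_shape)
  for (r in regions) {
    v <- r$voxels
    if (any(v < 1L) || any(sweep(v, 2, grid_shape, ">") ))
      stop(sprintf("region '%s' has voxels outside the grid", r$name),
           call. = FALSE)
    idx <- v[, 1] + (v[, 2] - 1L) * grid_shape[1] +
      (v[, 3] - 1L) * prod(grid_shape[1:2])
    if (any(seen[idx]))
      stop(sprintf("region '%s' overlaps another region", r$name),
           call. = FALSE)
    seen[idx] <- TRUE
    if (r$time_50 < 0 || r$time_50 > t_max)
      stop(sprintf("region '%s' has time_50 outside the acquisition window",
                   r$name), call. = FALSE)
  }
  structure(list(regions = regions, grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, frame_interval = frame_interval,
                 n_baseline = n_baseline, n_frames = n_frames,
                 frame_times = as.numeric(frame_times), noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 motion_amplitude = motion_amplitude,
                 baseline_value = baseline_value,
                 baseline_structure = baseline_structure,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic smooth texture in (0, +/- amplitude) multiplying the
# baseline; sums of per-axis cosines keep every translation identifiable.
phantom_texture <- function(d, amplitude) {
  if (amplitude == 0) return(array(1, dim = d))
  u <- seq(0, 1, length.out = d[1])
  v <- seq(0, 1, length.out = d[2])
  w <- seq(0, 1, length.out = d[3])
  U <- array(rep(cos(2.3 * pi * u), times = d[2] * d[3]), dim = d)
  V <- array(rep(rep(cos(1.7 * pi * v + 0.5), each = d[1]), times = d[3]),
             dim = d)
  W <- array(rep(cos(2.9 * pi * w + 1.1), each = d[1] * d[2]), dim = d)
  1 + amplitude * (U + V + W) / 3
}

phantom_bias_field <- function(d, amplitude) {
  if (amplitude == 1) return(array(1, dim = d))
  u2 <- seq(-1, 1, length.out = d[1])^2
  v2 <- seq(-1, 1, length.out = d[2])^2
  w2 <- seq(-1, 1, length.out = d[3])^2
  Q <- (array(rep(u2, times = d[2] * d[3]), dim = d) +
          array(rep(rep(v2, each = d[1]), times = d[3]), dim = d) +
          array(rep(w2, each = d[1] * d[2]), dim = d)) / 3
  1 + (amplitude - 1) * Q
}

#' Generate a dynamic contrast-enhanced phantom
#'
#' Builds a [volume4d] whose enhancing regions follow the logistic inflow
#' model exactly (before corruption) together with the ground-truth
#' parameter table.  Baseline frames have zero enhancement; each region's
#' noiseless voxel time course is `baseline * (1 + y(t)/100)`.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `dce_phantom`: list with `volume`
#'   ([volume4d]), `truth` (data frame region / intensity_max / time_50 /
#'   slope), `applied_shifts` (per-frame injected motion, voxels), `bias`
#'   (injected field) and the `spec`.
#' @export
generate_dce_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$grid_shape
    base <- spec$baseline_value * phantom_texture(d, spec$baseline_structure)
    bias <- phantom_bias_field(d, spec$bias_amplitude)
    nf <- spec$n_frames
    vol <- array(0, dim = c(d, nf))
    shifts <- matrix(0, nrow = nf, ncol = 3)
    for (fr in seq_len(nf)) {
      t <- spec$frame_times[fr]
      img <- base
      for (r in spec$regions) {
        e <- if (t > 0)
          sigmoid_model(sigmoid_params(r$intensity_max, r$time_50, r$slope), t)
        else 0
        img[r$voxels] <- base[r$voxels] * (1 + e / 100)
      }
      img <- img * bias
      if (fr > spec$n_baseline && spec$motion_amplitude > 0) {
        s <- stats::runif(3, -spec$motion_amplitude, spec$motion_amplitude)
        shifts[fr, ] <- s
        img <- shift_volume(img, s)
      }
      if (spec$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0,
                                  spec$noise_sd * spec$baseline_value / 100)
      vol[, , , fr] <- img
    }
    truth <- data.frame(
      region = vapply(spec$regions, `[[`, character(1), "name"),
      intensity_max = vapply(spec$regions, `[[`, numeric(1), "intensity_max"),
      time_50 = vapply(spec$regions, `[[`, numeric(1), "time_50"),
      slope = vapply(spec$regions, `[[`, numeric(1), "slope"))
    structure(list(volume = volume4d(vol, spec$voxel_size, spec$frame_times,
                                     spec$n_baseline),
                   truth = truth,
                   applied_shifts = data.frame(frame = seq_len(nf),
                                               dx = shifts[, 1],
                                               dy = shifts[, 2],
                                               dz = shifts[, 3]),
                   bias = bias, spec = spec),
              class = "dce_phantom")
  })
}

#' ROI mask for a phantom
#'
#' Builds the labelled mask of the phantom's enhancing territories,
#' optionally eroded by a voxel margin.  An eroded mask keeps ROI means
#' clear of partial-volume edge effects from smoothing and residual
#' sub-voxel motion, mirroring conservative interior ROI placement on real
#' anatomy.
#'
#' @param x a `dce_phantom` or [phantom_spec].
#' @param erode Chebyshev erosion radius in voxels (default 0).
#' @return an [roi_mask]; labels follow region order.
#' @export
phantom_roi_mask <- function(x, erode = 0L) {
  spec <- if (inherits(x, "dce_phantom")) x$spec else x
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  labels <- array(0L, dim = d)
  nm <- list()
  for (li in seq_along(spec$regions)) {
    r <- spec$regions[[li]]
    inset <- array(FALSE, dim = d)
    inset[r$voxels] <- TRUE
    if (erode > 0L) inset <- erode_mask(inset, as.integer(erode))
    if (!any(inset))
      stop(sprintf("region '%s' vanishes at erosion %d", r$name, erode),
           call. = FALSE)
    labels[inset] <- li
    nm[[as.character(li)]] <- r$name
  }
  roi_mask(labels, nm)
}

# Chebyshev erosion of a logical 3D mask (FALSE padding).
erode_mask <- function(m, r) {
  d <- dim(m)
  out <- m
  for (ox in -r:r) for (oy in -r:r) for (oz in -r:r) {
    if (ox == 0 && oy == 0 && oz == 0) next
    sh <- array(FALSE, dim = d)
    xs <- intersect(seq_len(d[1]), seq_len(d[1]) + ox)
    ys <- intersect(seq_len(d[2]), seq_len(d[2]) + oy)
    zs <- intersect(seq_len(d[3]), seq_len(d[3]) + oz)
    sh[xs, ys, zs] <- m[xs - ox, ys - oy, zs - oz]
    out <- out & sh
  }
  out
}

#' Write a phantom to disk
#'
#' The image series goes to NIfTI-1 (with a JSON sidecar for frame timing)
#' and the ground-truth parameter table to CSV alongside.
#'
#' @param phantom a `dce_phantom`.
#' @param path path of the NIfTI output (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "dce_phantom"))
  write_volume4d(phantom$volume, path)
  utils::write.csv(phantom$truth,
                   sub("\\.nii(\\.gz)?$", "_truth.csv", path),
                   row.names = FALSE)
  invisible(path)
}
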