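# Spatial preprocessing for dynamic contrast-enhanced series:
# translation registration, baseline bias-field correction, Gaussian
# smoothing.  The conformant stage order is register -> bias-correct ->
# smooth -> difference/extract (see pipeline_order()).

#' Conformant preprocessing order
#'
#' The processing chain is defined as alignment first (motion is a property
#' of the acquisition), then division by the baseline-derived intensity
#' non-uniformity field, then smoothing, then difference images / ROI
#' extraction.  `check_pipeline_order()` flags any other ordering.
#'
#' @return character vector of stage names in conformant order.
#' @export
pipeline_order <- function() c("register", "bias_correct", "smooth", "extract")

#' @rdname pipeline_order
#' @param stages character vector of stages actually applied, in order.
#' @return `TRUE` invisibly if conformant, otherwise a warning is raised and
#'   `FALSE` returned.
#' @export
check_pipeline_order <- function(stages) {
  ref <- pipeline_order()
  ok <- identical(match(stages, ref), sort(match(stages, ref)))
  if (!ok)
    warning("nonconformant stage order: expected subset of ",
            paste(ref, collapse = " -> "), call. = FALSE)
  invisible(ok)
}

# Translate a 3D array by a (possibly fractional) voxel shift using
# trilinear interpolation with edge replication: out(x) = in(x - shift).
shift_volume <- function(a, shift) {
  d <- dim(a)
  ax <- function(n, s) {
    x <- seq_len(n) - s
    x <- pmin(pmax(x, 1), n)
    i0 <- pmin(floor(x), n - 1L)
    list(i0 = as.integer(i0), f = x - i0)
  }
  gx <- ax(d[1], shift[1]); gy <- ax(d[2], shift[2]); gz <- ax(d[3], shift[3])
  w3 <- function(wx, wy, wz)
    array(outer(outer(wx, wy), wz), dim = d)
  out <- array(0, dim = d)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- w3(if (cx) gx$f else 1 - gx$f,
            if (cy) gy$f else 1 - gy$f,
            if (cz) gz$f else 1 - gz$f)
    out <- out + w * a[gx$i0 + cx, gy$i0 + cy, gz$i0 + cz]
  }
  out
}

gauss3 <- function(a, sigma) {
  k <- gauss_kernel(sigma)
  if (length(k) == 1L) return(a)
  for (ax in 1:3) a <- conv_axis(a, k, ax)
  a
}

central_gradient <- function(a, axis) {
  d <- dim(a); n <- d[axis]
  hi <- pmin(seq_len(n) + 1L, n); lo <- pmax(seq_len(n) - 1L, 1L)
  g <- switch(axis,
              a[hi, , , drop = FALSE] - a[lo, , , drop = FALSE],
              a[, hi, , drop = FALSE] - a[, lo, , drop = FALSE],
              a[, , hi, drop = FALSE] - a[, , lo, drop = FALSE])
  g / 2
}

#' Estimate the translation of one frame relative to a reference
#'
#' Robust iterative gradient-based (Gauss-Newton) estimation of a pure
#' translation: both images are lightly smoothed, the residual against the
#' reference is linearized in the shift, and the top fraction of absolute
#' residuals is trimmed at each iteration so that genuine signal change
#' (tracer enhancement, which is not motion) does not bias the estimate.
#' The returned shift is the displacement of the frame: applying its
#' negative realigns the frame to the reference.
#'
#' @param moving,fixed 3D arrays of identical dimension.
#' @param presmooth Gaussian sigma (voxels) applied to both images before
#'   estimation.
#' @param trim fraction of voxels kept (by absolute residual) in each
#'   update.
#' @param max_iter,tol iteration cap and convergence threshold (voxels).
#' @return numeric length-3 shift in voxels.
#' @export
estimate_shift <- function(moving, fixed, presmooth = 1, trim = 0.8,
                           max_iter = 50L, tol = 1e-4) {
  stopifnot(identical(dim(moving), dim(fixed)))
  f <- gauss3(fixed, presmooth)
  m <- gauss3(moving, presmooth)
  gx <- central_gradient(f, 1L)
  gy <- central_gradient(f, 2L)
  gz <- central_gradient(f, 3L)
  d <- dim(f)
  interior <- array(FALSE, dim = d)
  mar <- 3L
  interior[(1L + mar):(d[1] - mar), (1L + mar):(d[2] - mar),
           (1L + mar):(d[3] - mar)] <- TRUE
  s <- c(0, 0, 0)
  for (it in seq_len(max_iter)) {
    w <- shift_volume(m, -s)
    r <- w - f
    keep <- interior & (abs(r) <= stats::quantile(abs(r[interior]), trim))
    G <- cbind(gx[keep], gy[keep], gz[keep])
    delta <- tryCatch(solve(crossprod(G), crossprod(G, r[keep])),
                      error = function(e) matrix(0, 3, 1))
    s <- s - drop(delta)
    if (max(abs(delta)) < tol) break
  }
  s
}

#' Rigid translation alignment of a dynamic series
#'
#' Aligns every frame to the average baseline image.  Motion under
#' anaesthesia at this resolution is treated as translational; each frame's
#' displacement is estimated ([estimate_shift]) and removed by trilinear
#' resampling.  An all-zero frame cannot be registered: it is flagged and
#' passed through unshifted.
#'
#' @param vol a [volume4d].
#' @return list with `volume` (aligned [volume4d]) and `shifts`, a data
#'   frame of per-frame estimated displacements (voxels) and failure flags.
#' @export
register_series <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  B <- average_baseline(vol)
  nf <- n_frames(vol)
  out <- vol$data
  rows <- vector("list", nf)
  for (fr in seq_len(nf)) {
    img <- frame_at(vol, fr)
    if (all(img == 0)) {
      rows[[fr]] <- data.frame(frame = fr, dx = 0, dy = 0, dz = 0,
                               failed = TRUE)
      next
    }
    s <- estimate_shift(img, B)
    out[, , , fr] <- shift_volume(img, -s)
    rows[[fr]] <- data.frame(frame = fr, dx = s[1], dy = s[2], dz = s[3],
                             failed = FALSE)
  }
  list(volume = volume4d(out, vol$voxel_size, vol$frame_times,
                         vol$n_baseline),
       shifts = do.call(rbind, rows))
}

# Second-order polynomial design matrix on normalized [-1, 1] coordinates.
poly2_design <- function(d) {
  u <- seq(-1, 1, length.out = d[1])
  v <- seq(-1, 1, length.out = d[2])
  w <- seq(-1, 1, length.out = d[3])
  U <- array(rep(u, times = d[2] * d[3]), dim = d)
  V <- array(rep(rep(v, each = d[1]), times = d[3]), dim = d)
  W <- array(rep(w, each = d[1] * d[2]), dim = d)
  cbind(1, c(U), c(V), c(W), c(U)^2, c(V)^2, c(W)^2,
        c(U) * c(V), c(U) * c(W), c(V) * c(W))
}

#' Baseline intensity non-uniformity correction
#'
#' The non-uniformity field is estimated once, from the average baseline
#' image only, as the exponential of a second-order 3D polynomial fitted to
#' the log intensities; the same field (normalized to unit mean) is divided
#' out of every frame in the series.  Changes occurring after baseline
#' (tracer enhancement) therefore cannot leak into the field estimate.
#'
#' @param vol a [volume4d]; baseline intensities must be positive.
#' @return list with `volume` (corrected [volume4d]) and `field`, the
#'   estimated multiplicative field (3D array, mean 1).
#' @export
bias_correct <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  B <- average_baseline(vol)
  if (any(B <= 0))
    stop("baseline average must be positive to estimate a log-domain field",
         call. = FALSE)
  X <- poly2_design(dim(B))
  beta <- stats::lm.fit(X, log(c(B)))$coefficients
  field <- array(exp(X %*% beta), dim = dim(B))
  field <- field / mean(field)
  if (any(field <= 0) || any(!is.finite(field)))
    stop("estimated field is non-physical (non-positive)", call. = FALSE)
  out <- vol$data
  for (fr in seq_len(n_frames(vol)))
    out[, , , fr] <- frame_at(vol, fr) / field
  list(volume = volume4d(out, vol$voxel_size, vol$frame_times,
                         vol$n_baseline),
       field = field)
}

# 1D Gaussian convolution along one axis of a 3D array, edge replication.
conv_axis <- function(a, kern, axis) {
  r <- (length(kern) - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  out <- array(0, dim = d)
  for (k in seq_along(kern)) {
    off <- k - 1L - r
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kern[k] * switch(axis,
                                  a[idx, , , drop = FALSE],
                                  a[, idx, , drop = FALSE],
                                  a[, , idx, drop = FALSE])
  }
  out
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Isotropic Gaussian smoothing of a dynamic series
#'
#' Separable Gaussian smoothing with a kernel specified by its full width at
#' half maximum in millimetres; `sigma = fwhm / (2 sqrt(2 ln 2))` per axis,
#' converted to voxels through the voxel size.  `fwhm_mm = 0` is the
#' identity.
#'
#' @param vol a [volume4d].
#' @param fwhm_mm kernel FWHM in mm (>= 0); default 0.1 mm.
#' @return smoothed [volume4d].
#' @export
smooth_series <- function(vol, fwhm_mm = 0.1) {
  stopifnot(inherits(vol, "volume4d"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sig_vox <- sigma_mm / vol$voxel_size
  kerns <- lapply(sig_vox, gauss_kernel)
  out <- vol$data
  for (fr in seq_len(n_frames(vol))) {
    img <- frame_at(vol, fr)
    for (ax in 1:3)
      if (length(kerns[[ax]]) > 1L) img <- conv_axis(img, kerns[[ax]], ax)
    out[, , , fr] <- img
  }
  volume4d(out, vol$voxel_size, vol$frame_times, vol$n_baseline)
}
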