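#' Sigmoidal CSF-ISF inflow model
#'
#' Logistic time-intensity model used to describe the inflow of an
#' intrathecally infused tracer into a brain region:
#' \deqn{y(t) = Intensity_{Max} / (1 + e^{(Time_{50} - t)/Slope})}
#' where `intensity_max` is the plateau percent signal change, `time_50` the
#' time (minutes) at which half-maximal enhancement is reached and `slope`
#' the time scale (minutes) of the rising portion.  By construction
#' `y(time_50) == intensity_max / 2` and, for `slope > 0`,
#' `y -> intensity_max` as `t -> Inf`.
#'
#' @param params a [sigmoid_params] object (or list with elements
#'   `intensity_max`, `time_50`, `slope`).
#' @param t numeric vector of times in minutes.
#' @return numeric vector of percent signal change, same length as `t`.
#' @examples
#' p <- sigmoid_params(60.17, 39.66, 10)
#' sigmoid_model(p, 39.66)  # exactly half the plateau: 30.085
#' @export
sigmoid_model <- function(params, t) {
  params <- as_sigmoid_params(params)
  if (params$slope == 0)
    stop("'slope' must be nonzero", call. = FALSE)
  params$intensity_max / (1 + exp((params$time_50 - t) / params$slope))
}

#' Sigmoid parameter triple
#'
#' @param intensity_max plateau percent signal change.
#' @param time_50 time to half-maximal enhancement, minutes.
#' @param slope rise time scale, minutes; must be nonzero (positive for
#'   inflow data).
#' @return an object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(intensity_max, time_50, slope) {
  stopifnot(is.finite(intensity_max), is.finite(time_50), is.finite(slope))
  if (slope == 0) stop("'slope' must be nonzero", call. = FALSE)
  structure(list(intensity_max = intensity_max, time_50 = time_50,
                 slope = slope), class = "sigmoid_params")
}

as_sigmoid_params <- function(x) {
  if (inherits(x, "sigmoid_params")) return(x)
  if (is.numeric(x) && length(x) == 3L && is.null(names(x)))
    return(sigmoid_params(x[[1L]], x[[2L]], x[[3L]]))
  sigmoid_params(x[["intensity_max"]], x[["time_50"]], x[["slope"]])
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("sigmoid parameters: Intensity_Max = %.4g %%, Time_50 = %.4g min, Slope = %.4g min\n",
              x$intensity_max, x$time_50, x$slope))
  invisible(x)
}

#' Simulate a region-of-interest inflow time series
#'
#' Draws noisy percent-change measurements from the sigmoidal inflow model,
#' optionally replicated over several simulated animals at the same time
#' grid (as when a group curve is fitted to pooled data).  Enhancement is
#' zero at non-positive times (pre-infusion baseline).
#'
#' @param params generating [sigmoid_params].
#' @param times acquisition times in minutes (baseline frames non-positive).
#' @param noise_sd additive Gaussian noise standard deviation, percent units.
#' @param n_subjects number of replicate series sharing `times`.
#' @param region region name attached to the output.
#' @param seed optional integer seed (local RNG state).
#' @return a `roi_series` data frame with columns `region`, `subject`,
#'   `time_min`, `pct_change`.
#' @export
simulate_roi_series <- function(params, times, noise_sd = 0, n_subjects = 1L,
                                region = "region", seed = NULL) {
  params <- as_sigmoid_params(params)
  stopifnot(noise_sd >= 0, n_subjects >= 1L)
  mu <- ifelse(times > 0, sigmoid_model(params, times), 0)
  run <- function() {
    y <- rep(mu, n_subjects) +
      if (noise_sd > 0) stats::rnorm(length(mu) * n_subjects, 0, noise_sd) else 0
    data.frame(region = region,
               subject = rep(seq_len(n_subjects), each = length(times)),
               time_min = rep(times, n_subjects),
               pct_change = y)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  class(out) <- c("roi_series", class(out))
  out
}

# Evaluate an expression under a temporary RNG state; restores (or removes)
# .Random.seed afterwards so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
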