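# Tabular assay quantification: four-parameter-logistic ELISA standard
# curves and back-calculation, blood-contamination absorbance ratios,
# homogenate tau ratios, 2^-ddCt relative expression and infusion
# arithmetic.

#' Standard concentration series for the tau ELISAs
#'
#' The kit standard series used for CSF tau quantification: eight levels
#' from 0 to 2000 pg/ml for total tau and 0 to 1000 pg/ml for
#' phospho (pS199) tau (two-fold dilutions above the blank).
#'
#' @param assay `"total"` or `"phospho"`.
#' @return numeric vector of concentrations, pg/ml.
#' @export
tau_standard_series <- function(assay = c("total", "phospho")) {
  assay <- match.arg(assay)
  switch(assay,
         total = c(0, 31.25, 62.5, 125, 250, 500, 1000, 2000),
         phospho = c(0, 15.625, 31.25, 62.5, 125, 250, 500, 1000))
}

# 4PL: A = lower asymptote (blank), D = upper asymptote, C = inflection
# concentration, B = Hill slope; increasing in x for B > 0, D > A.
fpl <- function(x, a, b, c_, d) d + (a - d) / (1 + (x / c_)^b)

fpl_inverse <- function(y, a, b, c_, d) {
  c_ * ((a - d) / (y - d) - 1)^(1 / b)
}

#' Generate a synthetic ELISA plate
#'
#' Builds absorbance records for the standard series (exactly the printed
#' concentration levels) and for samples of known concentration and
#' dilution, from a four-parameter-logistic response with optional additive
#' Gaussian noise.  Noiseless plates are strictly monotone in
#' concentration.
#'
#' @param curve named numeric: `a` (blank absorbance), `d` (saturating
#'   absorbance), `c` (inflection concentration, pg/ml), `b` (Hill slope
#'   > 0).
#' @param sample_conc numeric, true sample concentrations in pg/ml (>= 0).
#' @param dilution dilution factors (>= 1), recycled along samples; the
#'   well sees `conc / dilution`.
#' @param standards standard concentration series (default the total-tau
#'   series, [tau_standard_series]).
#' @param noise_sd absorbance noise SD.
#' @param seed integer seed.
#' @return an `assay_table` data frame with columns `well_type`
#'   (`standard` / `sample`), `sample_id`, `true_conc`, `dilution`,
#'   `absorbance`.
#' @export
generate_elisa_plate <- function(curve = c(a = 0.05, d = 2.2, c = 300,
                                           b = 1.1),
                                 sample_conc = numeric(0), dilution = 1,
                                 standards = tau_standard_series("total"),
                                 noise_sd = 0, seed = 1L) {
  stopifnot(all(sample_conc >= 0), all(dilution >= 1), noise_sd >= 0,
            curve[["b"]] > 0, curve[["d"]] > curve[["a"]])
  dilution <- rep(dilution, length.out = length(sample_conc))
  with_seed(seed, {
    std <- data.frame(well_type = "standard",
                      sample_id = paste0("std_", seq_along(standards)),
                      true_conc = standards, dilution = 1,
                      absorbance = fpl(standards, curve[["a"]], curve[["b"]],
                                       curve[["c"]], curve[["d"]]))
    smp <- if (length(sample_conc)) {
      data.frame(well_type = "sample",
                 sample_id = paste0("sample_", seq_along(sample_conc)),
                 true_conc = sample_conc, dilution = dilution,
                 absorbance = fpl(sample_conc / dilution, curve[["a"]],
                                  curve[["b"]], curve[["c"]], curve[["d"]]))
    } else NULL
    out <- rbind(std, smp)
    if (noise_sd > 0)
      out$absorbance <- out$absorbance + stats::rnorm(nrow(out), 0, noise_sd)
    class(out) <- c("assay_table", class(out))
    out
  })
}

#' Fit an ELISA standard curve
#'
#' Four-parameter-logistic fit of absorbance against standard
#' concentration (the kit-standard model); if the standards are not
#' monotone beyond `monotone_tol`, a warning is raised and a linear fit is
#' used instead.
#'
#' @param standards data frame with columns `true_conc` (or
#'   `concentration`) and `absorbance`, including a blank; at least 4
#'   distinct concentrations.
#' @param model `"4pl"` (default) or `"linear"`.
#' @param monotone_tol tolerated non-monotonicity as a fraction of the
#'   absorbance range.
#' @return an object of class `standard_curve`: `model`, `coefficients`,
#'   `calibration_range` (pg/ml), `residual_ss`, `back_calc` (back-computed
#'   standards).
#' @export
fit_standard_curve <- function(standards, model = c("4pl", "linear"),
                               monotone_tol = 0.05) {
  model <- match.arg(model)
  conc <- standards$true_conc
  if (is.null(conc)) conc <- standards$concentration
  ab <- standards$absorbance
  stopifnot(!is.null(conc), !is.null(ab))
  o <- order(conc); conc <- conc[o]; ab <- ab[o]
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct standards (including a blank)",
         call. = FALSE)
  rng <- diff(range(ab))
  if (model == "4pl" && any(diff(ab) < -monotone_tol * rng)) {
    warning("standards not monotone in concentration; linear fallback",
            call. = FALSE)
    model <- "linear"
  }
  if (model == "4pl") {
    start <- list(a = min(ab), d = max(ab) * 1.05,
                  c_ = stats::median(conc[conc > 0]), b = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(ab ~ d + (a - d) / (1 + (conc / c_)^b),
                        start = start,
                        lower = c(a = -Inf, d = max(ab), c_ = 1e-9, b = 1e-3),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("4PL fit failed; linear fallback", call. = FALSE)
      model <- "linear"
    } else {
      cf <- stats::coef(fit)
      obj <- structure(list(model = "4pl", coefficients = cf,
                            calibration_range = range(conc),
                            residual_ss = stats::deviance(fit)),
                       class = "standard_curve")
      obj$back_calc <- data.frame(
        nominal = conc, absorbance = ab,
        back = vapply(ab, function(y) interp_raw(obj, y), numeric(1)))
      return(obj)
    }
  }
  lf <- stats::lm(ab ~ conc)
  obj <- structure(list(model = "linear", coefficients = stats::coef(lf),
                        calibration_range = range(conc),
                        residual_ss = sum(stats::resid(lf)^2)),
                   class = "standard_curve")
  obj$back_calc <- data.frame(
    nominal = conc, absorbance = ab,
    back = vapply(ab, function(y) interp_raw(obj, y), numeric(1)))
  obj
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve (%s): calibration range %.4g-%.4g pg/ml\n",
              x$model, x$calibration_range[1], x$calibration_range[2]))
  print(signif(x$coefficients, 5))
  invisible(x)
}

# Raw inverse of the curve at absorbance y (no dilution, no flags);
# NA outside the invertible band.
interp_raw <- function(curve, y) {
  if (curve$model == "4pl") {
    cf <- curve$coefficients
    if (y >= cf[["d"]] || y <= cf[["a"]] - 1e-12) return(NA_real_)
    if (y <= cf[["a"]]) return(0)
    fpl_inverse(y, cf[["a"]], cf[["b"]], cf[["c_"]], cf[["d"]])
  } else {
    cf <- curve$coefficients
    if (cf[["conc"]] == 0) return(NA_real_)
    (y - cf[["(Intercept)"]]) / cf[["conc"]]
  }
}

#' Back-calculate a sample concentration from a standard curve
#'
#' Inverts the fitted curve at the sample absorbance and multiplies by the
#' dilution factor.  Samples outside the calibration range are flagged
#' (`below_range` / `above_range`) and not extrapolated: the returned
#' concentration is `NA` above range and clamped at zero below the blank.
#'
#' @param absorbance sample optical density.
#' @param curve a [fit_standard_curve] result.
#' @param dilution dilution factor (>= 1).
#' @return list with `concentration` (pg/ml, dilution-corrected), `flag`
#'   (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
interpolate_concentration <- function(absorbance, curve, dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"), dilution >= 1)
  raw <- interp_raw(curve, absorbance)
  if (is.na(raw)) {
    if (curve$model == "4pl" && absorbance >= curve$coefficients[["d"]])
      return(list(concentration = NA_real_, flag = "above_range"))
    return(list(concentration = 0, flag = "below_range"))
  }
  flag <- "ok"
  if (raw > curve$calibration_range[2]) {
    return(list(concentration = NA_real_, flag = "above_range"))
  }
  if (raw < curve$calibration_range[1]) flag <- "below_range"
  list(concentration = raw * dilution, flag = flag)
}

#' Blood contamination of a CSF sample
#'
#' Percentage contamination from 417 nm (haemoglobin Soret band)
#' absorbances of the CSF sample and a volume-matched whole-blood
#' reference: `100 * csf / blood`.
#'
#' @param csf_abs417 CSF absorbance at 417 nm.
#' @param blood_abs417 whole-blood reference absorbance at 417 nm (> 0).
#' @return percentage.
#' @export
blood_contamination <- function(csf_abs417, blood_abs417) {
  if (any(blood_abs417 <= 0))
    stop("blood reference absorbance must be positive", call. = FALSE)
  100 * csf_abs417 / blood_abs417
}

#' Homogenate tau ratios
#'
#' Simple ratios characterizing a brain homogenate (phosphorylated to total
#' tau; insoluble to soluble tau) with SEM propagated to first order when
#' replicate measurements are given:
#' `SEM(r)^2 = r^2 (sem_num^2/num^2 + sem_den^2/den^2)`.
#'
#' @param numerator,denominator replicate measurements (same units); the
#'   ratio of means is reported.
#' @return list with `ratio`, `sem` (`NA` without replication) and `n`
#'   (replicates per arm).
#' @export
homogenate_ratio <- function(numerator, denominator) {
  stopifnot(length(numerator) >= 1L, length(denominator) >= 1L)
  mn <- mean(numerator); md <- mean(denominator)
  if (md == 0) stop("zero denominator", call. = FALSE)
  r <- mn / md
  n1 <- length(numerator); n2 <- length(denominator)
  sem <- if (n1 > 1L || n2 > 1L) {
    s1 <- if (n1 > 1L) stats::sd(numerator) / sqrt(n1) else 0
    s2 <- if (n2 > 1L) stats::sd(denominator) / sqrt(n2) else 0
    abs(r) * sqrt((s1 / mn)^2 + (s2 / md)^2)
  } else NA_real_
  list(ratio = r, sem = sem, n = c(numerator = n1, denominator = n2))
}

#' Mean of replicate ratios
#'
#' For replicate ratio determinations (one ratio per replicate), the mean
#' and SEM across replicates.
#'
#' @param ratios numeric vector of replicate ratio values.
#' @return list with `ratio`, `sem`, `n`.
#' @export
replicate_ratio <- function(ratios) {
  n <- length(ratios)
  list(ratio = mean(ratios),
       sem = if (n > 1L) stats::sd(ratios) / sqrt(n) else NA_real_,
       n = n)
}

#' Relative gene expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_gene - mean(Ct of reference genes)`; the fold
#' change of a sample against the calibrator is `2^-(dCt_sample -
#' dCt_calibrator)`.  Invariant to any constant offset added to every Ct.
#'
#' @param ct data frame with columns `sample`, `gene`, `ct` (replicate rows
#'   allowed; replicates are averaged).
#' @param gene gene of interest.
#' @param sample sample (or condition) to quantify.
#' @param reference_genes character vector of reference genes (e.g. Actb,
#'   Gapdh); all must be measured in both `sample` and `calibrator`.
#' @param calibrator calibrator sample name (e.g. wild-type whole brain).
#' @return fold change (numeric).
#' @export
delta_delta_ct <- function(ct, gene, sample, reference_genes, calibrator) {
  get_ct <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (length(v) == 0L)
      stop(sprintf("no Ct for gene '%s' in sample '%s'", g, s),
           call. = FALSE)
    mean(v)
  }
  dct <- function(s)
    get_ct(s, gene) - mean(vapply(reference_genes, function(g) get_ct(s, g),
                                  numeric(1)))
  2^-(dct(sample) - dct(calibrator))
}

#' Infusion arithmetic
#'
#' `infusion_dose` converts an infusate concentration and volume into the
#' delivered mass (e.g. 20 ug/ml in 2.5 ul gives 50 ng);
#' `infusion_duration` converts a volume and pump rate into the infusion
#' time (e.g. 30 ul at 0.6 ul/min gives 50 min).
#'
#' @param conc_ug_ml infusate concentration, micrograms per millilitre.
#' @param volume_ul infused volume, microlitres (>= 0).
#' @param rate_ul_min pump rate, microlitres per minute (> 0).
#' @return dose in nanograms, or duration in minutes.
#' @export
infusion_dose <- function(conc_ug_ml, volume_ul) {
  stopifnot(conc_ug_ml >= 0, volume_ul >= 0)
  conc_ug_ml * volume_ul  # ug/ml * ul = ng
}

#' @rdname infusion_dose
#' @export
infusion_duration <- function(volume_ul, rate_ul_min) {
  if (rate_ul_min <= 0) stop("rate must be positive", call. = FALSE)
  stopifnot(volume_ul >= 0)
  volume_ul / rate_ul_min
}
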