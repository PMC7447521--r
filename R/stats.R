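# Group statistics used across the experiments: one-way / two-way /
# repeated-measures ANOVA and unpaired t-tests, with Bonferroni-corrected
# post hoc group contrasts.  Model fitting is delegated to stats::aov /
# stats::t.test; the post hoc contrasts use the design's pooled error term.

#' Compare groups in a tidy measurement table
#'
#' Runs the named design on a tidy table of per-animal measurements and,
#' for the two-factor designs, Bonferroni-corrected post hoc group
#' contrasts at each level of the second factor (pooled-error t tests, the
#' conventional follow-up to the ANOVA).  The repeated-measures design
#' requires a balanced table: exactly one row per animal and time; missing
#' (animal, time) cells are an error, listed, rather than approximated.
#'
#' @param table data frame with columns named by `value`, `group` and (for
#'   the two-factor designs) `time`, plus `animal` for the
#'   repeated-measures design.
#' @param design `"rm_twoway"` (group between, time within animal),
#'   `"twoway"`, `"oneway"` or `"ttest"`.
#' @param value,group,time,animal column names.
#' @return an object of class `group_comparison`: `design`, `anova` (term /
#'   df / F / p table; for `"ttest"` the t statistic), `posthoc` (per-time
#'   contrasts with raw and Bonferroni-adjusted p), `n_comparisons`.
#' @export
group_compare <- function(table, design = c("rm_twoway", "twoway", "oneway",
                                            "ttest"),
                          value = "value", group = "group", time = "time",
                          animal = "animal") {
  design <- match.arg(design)
  y <- table[[value]]
  g <- factor(table[[group]])
  if (design == "ttest") {
    if (nlevels(g) != 2L) stop("t-test needs exactly 2 groups", call. = FALSE)
    tt <- stats::t.test(y ~ g, var.equal = TRUE)
    out <- list(design = design,
                anova = data.frame(term = group, df = unname(tt$parameter),
                                   statistic = unname(tt$statistic),
                                   p = tt$p.value),
                posthoc = NULL, n_comparisons = 1L)
    class(out) <- "group_comparison"
    return(out)
  }
  if (design == "oneway") {
    fit <- stats::aov(y ~ g)
    s <- summary(fit)[[1]]
    out <- list(design = design,
                anova = data.frame(term = group, df = s[1, "Df"],
                                   statistic = s[1, "F value"],
                                   p = s[1, "Pr(>F)"]),
                posthoc = NULL, n_comparisons = 0L)
    class(out) <- "group_comparison"
    return(out)
  }
  tm <- factor(table[[time]])
  if (design == "twoway") {
    fit <- stats::aov(y ~ g * tm)
    s <- summary(fit)[[1]]
    an <- data.frame(term = c(group, time, paste0(group, ":", time)),
                     df = s[1:3, "Df"], statistic = s[1:3, "F value"],
                     p = s[1:3, "Pr(>F)"])
    mse <- s["Residuals", "Mean Sq"]
    dfe <- s["Residuals", "Df"]
  } else {
    an_id <- factor(table[[animal]])
    cells <- table(an_id, tm)
    if (any(cells != 1L)) {
      miss <- which(cells == 0L, arr.ind = TRUE)
      msg <- if (nrow(miss))
        paste(apply(miss, 1, function(r)
          sprintf("(%s, %s)", rownames(cells)[r[1]], colnames(cells)[r[2]])),
          collapse = ", ")
      else "duplicated (animal, time) rows"
      stop("repeated-measures design needs one row per (animal, time); ",
           "problem cells: ", msg, call. = FALSE)
    }
    fit <- stats::aov(y ~ g * tm + Error(an_id))
    s_between <- summary(fit)[["Error: an_id"]][[1]]
    s_within <- summary(fit)[["Error: Within"]][[1]]
    an <- data.frame(
      term = c(group, time, paste0(group, ":", time)),
      df = c(s_between["g", "Df"], s_within["tm", "Df"],
             s_within["g:tm", "Df"]),
      statistic = c(s_between["g", "F value"], s_within["tm", "F value"],
                    s_within["g:tm", "F value"]),
      p = c(s_between["g", "Pr(>F)"], s_within["tm", "Pr(>F)"],
            s_within["g:tm", "Pr(>F)"]))
    mse <- s_within["Residuals", "Mean Sq"]
    dfe <- s_within["Residuals", "Df"]
  }
  # post hoc: group contrast at each time, pooled error, Bonferroni over times
  if (nlevels(g) != 2L) {
    ph <- NULL; m <- 0L
  } else {
    lv <- levels(g)
    rows <- lapply(levels(tm), function(tl) {
      sel <- tm == tl
      y1 <- y[sel & g == lv[1]]; y2 <- y[sel & g == lv[2]]
      est <- mean(y2) - mean(y1)
      se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
      tt <- est / se
      data.frame(time = tl, estimate = est, t = tt, df = dfe,
                 p = 2 * stats::pt(-abs(tt), dfe))
    })
    ph <- do.call(rbind, rows)
    m <- nrow(ph)
    ph$p_adj <- stats::p.adjust(ph$p, method = "bonferroni")
  }
  out <- list(design = design, anova = an, posthoc = ph, n_comparisons = m)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s design)\n", x$design))
  print(x$anova, digits = 4, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat(sprintf("Bonferroni post hoc (%d comparisons):\n", x$n_comparisons))
    print(x$posthoc, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
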