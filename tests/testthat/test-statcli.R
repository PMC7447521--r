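test_that("identical groups give a null t-test", {
  tab <- data.frame(group = rep(c("a", "b"), each = 4),
                    value = rep(c(1, 2, 3, 4), 2))
  res <- group_compare(tab, "ttest")
  expect_equal(res$anova$statistic, 0)
  expect_equal(res$anova$p, 1)
})

test_that("two-way ANOVA matches a hand-computed decomposition", {
  # 2 groups x 3 times x 2 replicates: 12 values, balanced
  tab <- expand.grid(rep = 1:2, group = c("g1", "g2"),
                     time = c("t1", "t2", "t3"))
  tab$value <- c(3, 5, 7, 9, 4, 6, 10, 12, 5, 7, 13, 15)
  res <- group_compare(tab, "twoway")

  # oracle: textbook sums-of-squares arithmetic, independent of aov
  y <- tab$value
  gm <- mean(y)
  cell <- tapply(y, list(tab$group, tab$time), mean)
  gmeans <- tapply(y, tab$group, mean)
  tmeans <- tapply(y, tab$time, mean)
  ss_g <- 6 * sum((gmeans - gm)^2)
  ss_t <- 4 * sum((tmeans - gm)^2)
  ss_cells <- 2 * sum((cell - gm)^2)
  ss_gt <- ss_cells - ss_g - ss_t
  ss_e <- sum((y - cell[cbind(as.character(tab$group),
                              as.character(tab$time))])^2)
  f_g <- (ss_g / 1) / (ss_e / 6)
  f_t <- (ss_t / 2) / (ss_e / 6)
  f_gt <- (ss_gt / 2) / (ss_e / 6)

  expect_equal(res$anova$statistic, c(f_g, f_t, f_gt), tolerance = 1e-8)
  expect_equal(res$anova$p,
               pf(c(f_g, f_t, f_gt), c(1, 2, 2), 6, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("Bonferroni adjustment multiplies p by the comparison count, capped", {
  set.seed(8)
  tab <- expand.grid(animal = 1:8, time = c("t1", "t2", "t3"))
  tab$group <- rep(c("a", "b"), 4)[tab$animal]
  tab$animal <- paste0(tab$group, tab$animal)
  tab$value <- rnorm(nrow(tab)) + 2 * (tab$group == "b") * (tab$time == "t1")
  res <- group_compare(tab, "rm_twoway")
  expect_equal(res$posthoc$p_adj, pmin(res$posthoc$p * res$n_comparisons, 1))
  expect_equal(res$n_comparisons, 3L)
})

test_that("repeated-measures design requires complete (animal, time) cells", {
  tab <- expand.grid(animal = 1:4, time = c("t1", "t2"))
  tab$group <- rep(c("a", "b"), 2)[tab$animal]
  tab$animal <- paste0("m", tab$animal)
  tab$value <- rnorm(nrow(tab))
  expect_silent(group_compare(tab, "rm_twoway"))
  expect_error(group_compare(tab[-3, ], "rm_twoway"), "m3, t1")
})

test_that("repeated-measures F statistics match a manual mixed decomposition", {
  # balanced 2-group x 2-time, 2 animals per group
  tab <- expand.grid(animal = 1:4, time = c("t1", "t2"))
  tab$group <- rep(c("a", "b"), 2)[tab$animal]
  tab$animal <- paste0("m", tab$animal)
  tab$value <- c(10, 12, 20, 24, 11, 14, 23, 26)
  res <- group_compare(tab, "rm_twoway")

  y <- tab$value; gm <- mean(y)
  a_means <- tapply(y, tab$animal, mean)
  g_means <- tapply(y, tab$group, mean)
  t_means <- tapply(y, tab$time, mean)
  cell <- tapply(y, list(tab$group, tab$time), mean)
  ss_g <- 4 * sum((g_means - gm)^2)
  ss_sub <- 2 * sum((a_means - gm)^2)
  ss_sub_within <- ss_sub - ss_g           # animals within groups
  ss_t <- 4 * sum((t_means - gm)^2)
  ss_cells <- 2 * sum((cell - gm)^2)
  ss_gt <- ss_cells - ss_g - ss_t
  ss_tot <- sum((y - gm)^2)
  ss_e <- ss_tot - ss_sub - ss_t - ss_gt   # time x animal-within-group
  f_g <- (ss_g / 1) / (ss_sub_within / 2)
  f_t <- (ss_t / 1) / (ss_e / 2)
  f_gt <- (ss_gt / 1) / (ss_e / 2)
  expect_equal(res$anova$statistic, c(f_g, f_t, f_gt), tolerance = 1e-8)
})

test_that("experiments are reproducible byte-for-byte and recover truth", {
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  cfg <- list(experiment = "inflow", output_dir = d1, seed = 9,
              noise_sd = 0, n_subjects = 1)
  r1 <- run_experiment(cfg)
  cfg$output_dir <- d2
  r2 <- run_experiment(cfg)
  f1 <- file.path(d1, "inflow_fit_summary.csv")
  f2 <- file.path(d2, "inflow_fit_summary.csv")
  expect_identical(readLines(f1), readLines(f2))
  # noiseless demo recovers the generating parameters
  ref <- reference_inflow_fits()
  wt <- ref[ref$region == "caudal_cortex" & ref$group == "wild_type", ]
  expect_equal(r1$fits$wild_type$params$intensity_max, wt$intensity_max,
               tolerance = 1e-6)
  expect_equal(r1$fits$wild_type$params$time_50, wt$time_50,
               tolerance = 1e-6)
  expect_true(file.exists(file.path(d1, "run_log.json")))
  log <- jsonlite::read_json(file.path(d1, "run_log.json"))
  expect_equal(log$seed, 9L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("clearance and polarization experiments produce group summaries", {
  d <- file.path(tempdir(), "exp3")
  rc <- run_experiment(list(experiment = "clearance", output_dir = d,
                            seed = 2, n_per_group = 4))
  expect_equal(sort(rc$summary$group), c("caudal", "rostral"))
  expect_gt(rc$summary$mean_ng_ml[rc$summary$group == "caudal"],
            rc$summary$mean_ng_ml[rc$summary$group == "rostral"])
  expect_lt(rc$test$anova$p, 0.01)
  rp <- run_experiment(list(experiment = "polarization", output_dir = d,
                            seed = 2, n_vessels = 3))
  m <- aggregate(polarization_pct ~ group, rp$measurements, mean)
  expect_gt(m$polarization_pct[m$group == "wild_type"],
            m$polarization_pct[m$group == "rTg4510"])
  expect_error(run_experiment(list(experiment = "nope", output_dir = d)),
               "unknown experiment")
  unlink(d, recursive = TRUE)
})
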