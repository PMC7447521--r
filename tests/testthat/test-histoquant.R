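test_that("percent immunoreactivity counts thresholded region pixels", {
  img <- matrix(100, 10, 10)
  expect_equal(percent_immunoreactivity(img, 1:100, threshold = 50), 100)
  expect_equal(percent_immunoreactivity(img, 1:100, threshold = 101), 0)
  expect_error(percent_immunoreactivity(img, integer(0), 50), "empty")
  # synthetic section with known positive fraction
  sp <- section_spec(regions = list(roi = square_poly(20, 20, 60)),
                     positive_fraction = 25, seed = 5)
  sec <- generate_section(sp)
  pct <- percent_immunoreactivity(sec$image, sec$region_pixels$roi,
                                  threshold = 120)
  expect_equal(pct, 25, tolerance = 1)
  expect_equal(pct, unname(sec$truth["roi"]))
})

test_that("section generator realizes paired-region ratios", {
  sp <- section_spec(regions = list(rostral = square_poly(10, 10, 40),
                                    caudal = square_poly(70, 70, 40)),
                     positive_fraction = c(6, 3), seed = 9)
  sec <- generate_section(sp)
  r <- percent_immunoreactivity(sec$image, sec$region_pixels$rostral, 120)
  c_ <- percent_immunoreactivity(sec$image, sec$region_pixels$caudal, 120)
  expect_equal(r / c_, 2, tolerance = 0.1)
  expect_equal(sec$truth[["rostral"]] / sec$truth[["caudal"]], 2,
               tolerance = 0.05)
  # degenerate polygon is refused
  expect_error(section_spec(regions = list(bad = rbind(c(1, 1), c(2, 2))),
                            positive_fraction = 10), "degenerate")
  expect_error(section_spec(regions = list(r = square_poly(1, 1, 5)),
                            positive_fraction = 120), "0, 100")
})

test_that("regional ratios are means of per-animal ratios", {
  one <- region_ratio(6, 3)
  expect_equal(one$mean, 2)
  expect_true(is.na(one$sem))
  expect_equal(one$n, 1L)
  two <- region_ratio(c(4, 6), c(2, 2))
  expect_equal(two$mean, 2.5)
  expect_equal(two$sem, 0.5)
  # NOT the ratio of group means (which would be 10/4 = 2.5 here too;
  # use an asymmetric case to tell the definitions apart)
  three <- region_ratio(c(2, 9), c(1, 3))
  expect_equal(three$mean, 2.5)        # mean(2, 3)
  expect_false(isTRUE(all.equal(three$mean, 11 / 4)))
  # common scaling of both regions leaves ratios unchanged
  expect_equal(region_ratio(c(4, 6) * 7, c(2, 2) * 7)$ratios, two$ratios)
  expect_warning(z <- region_ratio(c(4, 6), c(2, 0)), "zero denominator")
  expect_equal(z$n, 1L)
})

test_that("line profiles are background-normalized and scale-invariant", {
  vs <- vessel_image_spec(background_level = 10, aqp4_perivascular = 20,
                          aqp4_low = 2, target_polarization = 50)
  vp <- generate_vessel_image(vs)
  prof <- vessel_line_profile(vp$image, vp$record)
  # AQP4 ring sits at 3x background (10 + 20 over background 10)
  expect_equal(max(prof$AQP4), 3, tolerance = 0.05)
  # uniform channel at background level profiles identically to 1
  flat <- channel_image(list(AQP4 = matrix(7, 192, 192),
                             CD31 = matrix(7, 192, 192)), 0.2)
  pf <- vessel_line_profile(flat, vp$record)
  expect_equal(pf$AQP4, rep(1, nrow(pf)))
  # doubling all intensities changes nothing after normalization
  dbl <- channel_image(lapply(vp$image$channels, function(m) 2 * m), 0.2)
  expect_equal(vessel_line_profile(dbl, vp$record)$AQP4, prof$AQP4)
  # zero background mean is an error
  zero <- channel_image(list(AQP4 = matrix(0, 192, 192)), 0.2)
  expect_error(vessel_line_profile(zero, vp$record), "background")
})

test_that("polarization is the complement of AQP4 area at the endfoot median", {
  vp <- generate_vessel_image(vessel_image_spec(target_polarization = 80))
  pol <- polarization_index(vp$image, vp$record)
  expect_equal(pol$polarization_pct, 80, tolerance = 1)
  expect_identical(pol$polarization_pct + pol$aqp4_area_pct, 100)
  # uniform AQP4: everything at or above the median
  uni <- channel_image(list(AQP4 = matrix(50, 192, 192)), 0.2)
  p2 <- polarization_index(uni, vp$record)
  expect_equal(p2$aqp4_area_pct, 100)
  expect_equal(p2$polarization_pct, 0)
  # adding a constant shifts the threshold with the data
  shifted <- channel_image(list(AQP4 = vp$image$channels$AQP4 + 37,
                                CD31 = vp$image$channels$CD31), 0.2)
  expect_equal(polarization_index(shifted, vp$record)$polarization_pct,
               pol$polarization_pct)
})

test_that("raising perivascular AQP4 cannot decrease polarization", {
  vp <- generate_vessel_image(vessel_image_spec(target_polarization = 50,
                                                aqp4_high = 250,
                                                noise_sd = 3, seed = 13))
  base <- polarization_index(vp$image, vp$record)$polarization_pct
  boosted <- vp$image$channels$AQP4
  boosted[vp$record$perivascular_region] <-
    boosted[vp$record$perivascular_region] + 100
  img2 <- channel_image(list(CD31 = vp$image$channels$CD31, AQP4 = boosted),
                        0.2)
  expect_gte(polarization_index(img2, vp$record)$polarization_pct, base)
})

test_that("polarization recovery tracks the generating target", {
  for (target in c(0, 25, 50, 80, 100)) {
    vp <- generate_vessel_image(
      vessel_image_spec(target_polarization = target, seed = 17))
    pol <- polarization_index(vp$image, vp$record)
    expect_lt(abs(pol$polarization_pct - target), 2)
    expect_true(pol$polarization_pct >= 0 && pol$polarization_pct <= 100)
  }
})

test_that("vessel coverage counts AQP4-positive vessel pixels", {
  thr <- 110  # midway between background and perivascular level
  full <- generate_vessel_image(
    vessel_image_spec(target_vessel_coverage = 100))
  expect_equal(vessel_coverage(full$image, full$record, thr), 100)
  half <- generate_vessel_image(
    vessel_image_spec(target_vessel_coverage = 50, seed = 4))
  expect_equal(vessel_coverage(half$image, half$record, thr), 50,
               tolerance = 1)
  expect_equal(vessel_coverage(half$image, half$record, thr),
               unname(half$truth["vessel_coverage_pct"]))
  none <- channel_image(list(AQP4 = matrix(0, 192, 192)), 0.2)
  expect_equal(vessel_coverage(none, full$record, thr), 0)
})

test_that("automatic vessel delineation matches the generating geometry", {
  vp <- generate_vessel_image(vessel_image_spec(target_polarization = 80))
  rec <- delineate_vessel(vp$image, threshold = 100)
  expect_setequal(rec$vessel_region, vp$record$vessel_region)
  pol <- polarization_index(vp$image, rec)
  expect_equal(pol$polarization_pct, 80, tolerance = 1)
})

test_that("vessel records validate their geometry", {
  expect_error(vessel_record(1:10, 11:20, rbind(c(1, 1), c(21, 1)),
                             5000:5010, c(50, 50), 0.2),
               "outside image bounds")
  expect_error(vessel_record(1:10, 11:20, rbind(c(1, 1), c(21, 1)),
                             5:12, c(50, 50), 0.2), "disjoint")
  expect_warning(vessel_record(1:10, 11:20, rbind(c(1, 1), c(4, 1)),
                               101:110, c(50, 50), 0.2), "4 um")
  expect_error(vessel_image_spec(target_polarization = 101), "0, 100")
  expect_error(vessel_image_spec(vessel_center = c(3, 3)), "bounds")
})

test_that("channel images round-trip through multi-page TIFF", {
  vp <- generate_vessel_image(vessel_image_spec(seed = 6))
  f <- file.path(tempdir(), "vessel_rt.tif")
  write_channel_tiff(vp$image, f, scale_max = 256)
  pages <- tiff::readTIFF(f, all = TRUE)
  expect_length(pages, 2L)
  expect_equal(pages[[2]] * 256, vp$image$channels$AQP4, tolerance = 0.01)
  unlink(f)
})
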