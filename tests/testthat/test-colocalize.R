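make_mask <- function(lab) structure(list(labels = lab, channel = "cav1",
                                          params = detection_params()),
                                     class = "LabeledMask")

test_that("mask means reproduce hand-computed values", {
  lab <- matrix(0L, 5, 5)
  lab[2, 2] <- 1L; lab[2, 3] <- 1L
  raster <- matrix(1, 5, 5)
  raster[2, 2] <- 10; raster[2, 3] <- 20
  m <- measure_channel(make_mask(lab), raster)
  expect_equal(unname(m$means), 15)          # mean of {10, 20}
  expect_equal(m$reference, mean(raster))
  # constant raster: every vesicle mean and the image mean are the constant
  m2 <- measure_channel(make_mask(lab), matrix(7, 5, 5))
  expect_equal(unname(m2$means), 7)
  expect_equal(m2$reference, 7)
  expect_error(measure_channel(make_mask(lab), matrix(1, 4, 4)), "shapes differ")
})

test_that("reference scope selects which pixels define the baseline", {
  lab <- matrix(0L, 4, 4); lab[1, 1] <- 1L
  raster <- matrix(2, 4, 4); raster[1, 1] <- 18
  expect_equal(measure_channel(make_mask(lab), raster, "image")$reference, 3)
  expect_equal(measure_channel(make_mask(lab), raster, "outside")$reference, 2)
  expect_equal(measure_channel(make_mask(lab), raster, "vesicles")$reference, 18)
})

test_that("mask means match the per-pixel accumulation oracle", {
  for (seed in 1:6) {
    p <- simulation_params(field_shape = c(96, 96), vesicle_density = 1.5,
                           seed = seed)
    sim <- simulate_field(p)
    det <- detect_vesicles(sim$field, "cav1")
    if (nrow(det$table) == 0) next
    m <- measure_channel(det$mask, sim$field$channels$endoglin)
    ref <- oracle_label_means(det$mask$labels, sim$field$channels$endoglin)
    expect_equal(unname(m$means), unname(ref), tolerance = 1e-9)
  }
})

test_that("the 15%-above-image-mean rule has an inclusive boundary", {
  cls <- classify_positive(c(114.999, 115, 115.001, 130, 100),
                           image_mean = 100)
  expect_equal(cls$positive, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(cls$ratio, c(1.14999, 1.15, 1.15001, 1.30, 1.00))
  # strict mode excludes the exact boundary
  strict <- classify_positive(c(115), 100, classification_params(strict = TRUE))
  expect_false(strict$positive)
  # constant image: vesicle mean equals image mean, never positive for f > 0
  expect_false(classify_positive(50, 50)$positive)
  expect_error(classify_positive(10, 0), "degenerate reference")
})

test_that("flags are invariant to rescaling the secondary raster", {
  p <- simulation_params(field_shape = c(128, 128), vesicle_density = 1.5, seed = 7)
  sim <- simulate_field(p)
  det <- detect_vesicles(sim$field, "cav1")
  t1 <- classify_vesicles(det$table, det$mask, sim$field, "endoglin")
  scaled <- sim$field
  scaled$channels$endoglin <- scaled$channels$endoglin * 37.5
  t2 <- classify_vesicles(det$table, det$mask, scaled, "endoglin")
  expect_equal(t1$pos_endoglin, t2$pos_endoglin)
  expect_equal(t1$ratio_endoglin, t2$ratio_endoglin, tolerance = 1e-12)
})

test_that("raising f shrinks the positive set monotonically; f = 0 means above-mean", {
  p <- simulation_params(field_shape = c(128, 128), vesicle_density = 1.5, seed = 13)
  sim <- simulate_field(p)
  det <- detect_vesicles(sim$field, "cav1")
  sets <- lapply(c(0, 0.15, 0.5, 1), function(f) {
    tb <- classify_vesicles(det$table, det$mask, sim$field, "endoglin",
                            classification_params(f = f))
    which(tb$pos_endoglin)
  })
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  tb0 <- classify_vesicles(det$table, det$mask, sim$field, "endoglin",
                           classification_params(f = 0))
  expect_equal(tb0$pos_endoglin, tb0$ratio_endoglin >= 1)
})

test_that("co-positivity is the conjunction of base and screen flags", {
  lab <- matrix(0L, 8, 8); lab[2, 2] <- 1L; lab[5, 5] <- 2L; lab[7, 2] <- 3L
  mask <- make_mask(lab)
  eng <- matrix(100, 8, 8); eng[2, 2] <- 200         # vesicle 1 endoglin+
  smad <- matrix(100, 8, 8)
  smad[2, 2] <- 250; smad[5, 5] <- 250; smad[7, 2] <- 250  # all smad-bright
  field <- field_of_view(list(cav1 = matrix(1, 8, 8), endoglin = eng, smad1 = smad))
  tb <- data.frame(label = 1:3, row = c(1, 4, 6), col = c(1, 4, 1),
                   area = 1, circularity = 1)
  tb <- classify_vesicles(tb, mask, field, "endoglin")
  expect_equal(tb$pos_endoglin, c(TRUE, FALSE, FALSE))
  tb <- screen_copositive(tb, "endoglin", "smad1", mask, field)
  # vesicles 2 and 3 are SMAD1-bright but endoglin-negative: flag FALSE, not NA
  expect_equal(tb$copos_smad1, c(TRUE, FALSE, FALSE))
  expect_false(anyNA(tb$copos_smad1))
  expect_error(screen_copositive(tb, "endoglin", "nope", mask, field),
               "not present")
  expect_error(screen_copositive(tb[, 1:5], "endoglin", "smad1", mask, field),
               "flags missing")
})

test_that("per-marker f overrides apply to the screen channel", {
  lab <- matrix(0L, 8, 8); lab[2, 2] <- 1L
  mask <- make_mask(lab)
  eng <- matrix(100, 8, 8); eng[2, 2] <- 200
  smad <- matrix(100, 8, 8); smad[2, 2] <- 125      # ratio ~1.25
  field <- field_of_view(list(cav1 = matrix(1, 8, 8), endoglin = eng, smad1 = smad))
  tb <- data.frame(label = 1L, row = 1, col = 1, area = 1, circularity = 1)
  tb <- classify_vesicles(tb, mask, field, "endoglin")
  loose <- screen_copositive(tb, "endoglin", "smad1", mask, field)
  expect_true(loose$copos_smad1)
  tight <- screen_copositive(tb, "endoglin", "smad1", mask, field,
                             classification_params(overrides = list(smad1 = list(f = 0.5))))
  expect_false(tight$copos_smad1)
})

test_that("line profiles sample, interpolate and localize peaks correctly", {
  field <- field_of_view(list(cav1 = matrix(3, 64, 64)), pixel_size = 0.2)
  pr <- line_profile(field, "cav1", p0 = c(10, 5), p1 = c(10, 55),
                     n_samples = 50)
  expect_equal(nrow(pr), 50)
  expect_equal(pr$position_px[1], 0)
  expect_equal(pr$position_px[50], 50)
  expect_equal(pr$position_um, pr$position_px * 0.2)
  expect_true(all(pr$cav1 == 3))  # constant image gives a flat profile

  img <- blob_image(64, 64, cbind(30, 40), amp = 80, sd_px = 2, bg = 5)
  f2 <- field_of_view(list(cav1 = img))
  pr2 <- line_profile(f2, "cav1", p0 = c(30, 10), p1 = c(30, 60),
                      width = 3, n_samples = 101)
  peak_pos <- pr2$position_px[which.max(pr2$cav1)]
  expect_lt(abs(peak_pos - 30), 0.5 + 1e-9)  # blob at col 40, 30 px from start
  expect_error(line_profile(f2, "cav1", c(-1, 0), c(10, 10)), "outside image")
  expect_error(line_profile(f2, "cav1", c(5, 5), c(5, 5)), "coincide")
})
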