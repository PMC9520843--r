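test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(true_positive_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_params(vesicle_density = -1), "non-negative")
  expect_error(simulation_params(radius_range = c(5, 2)), "min <= max")
  expect_error(simulation_params(primary_amplitude = NaN), "finite")
})

test_that("zero density gives background-only field and empty truth", {
  p <- simulation_params(field_shape = c(64, 64), vesicle_density = 0, seed = 1)
  sim <- simulate_field(p)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(dim(sim$field$channels$cav1), c(64, 64))
  # background plus noise only: nothing approaching a vesicle peak
  expect_lt(max(sim$field$channels$cav1),
            p$background_level + p$primary_amplitude)
})

test_that("the same seed reproduces a bit-identical field", {
  p <- simulation_params(field_shape = c(96, 96), vesicle_density = 1, seed = 42)
  a <- simulate_field(p)
  b <- simulate_field(p)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
  p2 <- p; p2$seed <- 43L
  expect_false(identical(simulate_field(p2)$truth, a$truth))
})

test_that("vesicle count follows the stated Poisson law", {
  # ground-truth-only path: mean over many seeds within 3 SD of the
  # Poisson mean density * area / 1000
  p <- simulation_params(field_shape = c(512, 512), vesicle_density = 2.0)
  counts <- vapply(1:200, function(s) {
    p$seed <- s
    nrow(simulate_field(p, render = FALSE)$truth)
  }, numeric(1))
  lambda <- 2.0 * 512^2 / 1000  # 524.288
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_lt(abs(var(counts) / lambda - 1), 0.35)  # Poisson variance ~ mean
})

test_that("ground truth geometry and ids are valid", {
  p <- simulation_params(field_shape = c(128, 160), vesicle_density = 2,
                         min_separation = 10, seed = 5)
  tr <- simulate_field(p, render = FALSE)$truth
  expect_false(any(duplicated(tr$id)))
  expect_true(all(tr$row >= 0 & tr$row < 128))
  expect_true(all(tr$col >= 0 & tr$col < 160))
  d <- as.matrix(dist(tr[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 10)
})

test_that("noise-free field mean matches the analytic blob-integral oracle", {
  # mean = background_level + sum of Gaussian blob masses / n_pixels;
  # oracle uses the closed-form separable Gaussian integral (pnorm),
  # evaluated over each blob's +/- 6 SD render patch
  # radii >= 4 keep the continuous-integral approximation of the discrete
  # pixel sum well below the 1e-6 tolerance even for edge-truncated blobs
  p <- simulation_params(field_shape = c(200, 200), vesicle_density = 1.0,
                         radius_range = c(4, 6),
                         gaussian_noise_sd = 0, poisson_noise = FALSE,
                         min_separation = 0, seed = 8)
  sim <- simulate_field(p)
  tr <- sim$truth
  # closed-form sum of exp(-(x - c)^2 / 2 s^2) over integer x in [lo, hi]:
  # the Gaussian integral over [lo - 1/2, hi + 1/2] plus the first
  # Euler-Maclaurin boundary term (matters for blobs cut by the field edge)
  mass <- function(center, sd_px, amp, n) {
    R <- ceiling(6 * sd_px)
    lo <- max(0, floor(center) - R); hi <- min(n - 1, ceiling(center) + R)
    g <- function(x) exp(-(x - center)^2 / (2 * sd_px^2))
    gp <- function(x) -(x - center) / sd_px^2 * g(x)
    amp * (sd_px * sqrt(2 * pi) *
             (pnorm((hi + 0.5 - center) / sd_px) -
                pnorm((lo - 0.5 - center) / sd_px)) +
             (gp(lo - 0.5) - gp(hi + 0.5)) / 24)
  }
  for (ch in c("cav1", "endoglin")) {
    total <- sum(vapply(seq_len(nrow(tr)), function(i) {
      s <- tr$radius[i] / 2
      mass(tr$row[i], s, 1, 200) * mass(tr$col[i], s, 1, 200) *
        tr[[paste0("amp_", ch)]][i]
    }, numeric(1)))
    expected <- p$background_level + total / (200 * 200)
    expect_equal(mean(sim$field$channels[[ch]]), expected,
                 tolerance = 1e-6)
  }
})

test_that("true-positive labels are binomial at the requested fraction", {
  p <- simulation_params(field_shape = c(512, 512), vesicle_density = 1.5,
                         true_positive_fraction = 0.3)
  pos <- unlist(lapply(1:30, function(s) {
    p$seed <- s
    simulate_field(p, render = FALSE)$truth$pos_endoglin
  }))
  ci <- binom.test(sum(pos), length(pos), p = 0.3)$conf.int
  expect_true(ci[1] <= 0.3 && 0.3 <= ci[2] ||
                abs(mean(pos) - 0.3) < 0.02)
})

test_that("conditional secondary channels give nested positivity", {
  p <- simulation_params(
    field_shape = c(512, 512), vesicle_density = 1.5,
    secondary_channels = list(
      endoglin = list(enrichment_factor = 3, positive_fraction = 0.6),
      smad1 = list(enrichment_factor = 3, positive_fraction = 0.3,
                   conditional_on = "endoglin")),
    seed = 2)
  tr <- simulate_field(p, render = FALSE)$truth
  # smad1-positive implies endoglin-positive
  expect_true(all(tr$pos_endoglin[tr$pos_smad1]))
  frac <- mean(tr$pos_smad1[tr$pos_endoglin])
  expect_lt(abs(frac - 0.3), 0.12)
})

test_that("simulate_experiment derives independent per-field sub-seeds", {
  pr <- shear_presets(field_shape = c(64, 64))
  expect_error(simulate_experiment(pr$LSS, pr$HSS, 0), ">= 1")
  sims <- simulate_experiment(pr$LSS, pr$HSS, 1, seed = 9)
  expect_length(sims, 2)
  labs <- vapply(sims, function(s) s$field$condition_label, character(1))
  expect_equal(labs, c("LSS", "HSS"))
  # replay is identical; different master seed differs
  sims2 <- simulate_experiment(pr$LSS, pr$HSS, 1, seed = 9)
  expect_identical(sims[[1]]$field$channels, sims2[[1]]$field$channels)
  sims3 <- simulate_experiment(pr$LSS, pr$HSS, 1, seed = 10)
  expect_false(identical(sims[[1]]$truth, sims3[[1]]$truth))
})

test_that("default presets put more vesicles in LSS than HSS", {
  pr <- shear_presets()
  sims <- simulate_experiment(pr$LSS, pr$HSS, 10, seed = 4, render = FALSE)
  counts <- vapply(sims, function(s) nrow(s$truth), numeric(1))
  cond <- vapply(sims, function(s) attr(s$truth, "condition_label"), character(1))
  expect_gt(mean(counts[cond == "LSS"]), mean(counts[cond == "HSS"]))
})
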