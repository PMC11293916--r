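test_that("a zero-amplitude spine is straight with zero Cobb everywhere", {
  p <- spine_params(curves = curve_spec("T9", 0, 0.1, flexibility = 0.5),
                    kyphosis_t5_t12 = 0, landmark_noise_sd = 0)
  sim <- simulate_case(p)
  expect_equal(sim$truth$region$cobb, rep(0, 3))
  expect_equal(max(abs(sim$truth$tilt$coronal)), 0)
  osc <- build_oscillogram(get_view(sim$views, "coronal"))
  expect_equal(osc$tilt, rep(0, 34), tolerance = 1e-9)
})

test_that("simulation is deterministic in the seed", {
  p1 <- preset_for_type(2, landmark_noise_sd = 2, seed = 7)
  s1 <- simulate_case(p1)
  s2 <- simulate_case(p1)
  expect_identical(s1$views, s2$views)
  p3 <- preset_for_type(2, landmark_noise_sd = 2, seed = 8)
  s3 <- simulate_case(p3)
  expect_false(isTRUE(all.equal(s1$views$x, s3$views$x)))
  # noise-free output does not depend on the seed at all
  a <- simulate_case(preset_for_type(2, landmark_noise_sd = 0, seed = 1))
  b <- simulate_case(preset_for_type(2, landmark_noise_sd = 0, seed = 999))
  expect_identical(a$views, b$views)
})

test_that("ground truth is self-consistent with the pipeline (core property)", {
  for (k in 1:6) {
    sim <- simulate_case(preset_for_type(k, landmark_noise_sd = 0))
    m <- measure_case(sim$views)
    td <- tidy(m)
    tr <- sim$truth$region
    expect_equal(c(td$pt, td$mt, td$tll),
                 tr$cobb[match(c("PT", "MT", "TLL"), tr$region)],
                 tolerance = 1e-6)
    expect_equal(c(td$bend_pt, td$bend_mt, td$bend_tll),
                 tr$residual[match(c("PT", "MT", "TLL"), tr$region)],
                 tolerance = 1e-6)
    expect_equal(td$t5_t12_kyphosis, sim$truth$kyphosis_t5_t12,
                 tolerance = 1e-6)
    expect_identical(td$lenke_type, sim$truth$lenke_type)
    expect_identical(td$sagittal_modifier, sim$truth$sagittal_modifier)
    st <- m$lenke$structural
    expect_equal(st$structural[match(tr$region, st$region)], tr$structural)
  }
})

test_that("presets express their defining structural patterns", {
  want <- list(`1` = c(FALSE, TRUE, FALSE), `2` = c(TRUE, TRUE, FALSE),
               `3` = c(FALSE, TRUE, TRUE), `4` = c(TRUE, TRUE, TRUE),
               `5` = c(FALSE, FALSE, TRUE), `6` = c(FALSE, TRUE, TRUE))
  major <- c("MT", "MT", "MT", "MT", "TLL", "TLL")
  for (k in 1:6) {
    tr <- simulate_case(preset_for_type(k, landmark_noise_sd = 0))$truth
    expect_equal(tr$region$structural[match(c("PT", "MT", "TLL"),
                                            tr$region$region)],
                 want[[as.character(k)]], label = paste("type", k))
    expect_equal(tr$region$region[tr$region$is_major], major[k])
    expect_identical(tr$lenke_type, as.integer(k))
  }
  # type 5's defining signature: TL/L over 25 coronal, corrects under 25
  tr5 <- simulate_case(preset_for_type(5, landmark_noise_sd = 0))$truth
  tll <- tr5$region[tr5$region$region == "TLL", ]
  expect_gt(tll$cobb, 25)
  expect_lt(tll$residual, 25)
  expect_error(preset_for_type(9), "1..6")
})

test_that("mirroring every curve's convexity mirrors x and keeps truth angles", {
  p <- preset_for_type(3, landmark_noise_sd = 0)
  q <- p
  q$curves$convexity <- ifelse(q$curves$convexity == "image_left",
                               "image_right", "image_left")
  a <- simulate_case(p); b <- simulate_case(q)
  expect_equal(b$truth$region$cobb, a$truth$region$cobb, tolerance = 1e-9)
  expect_equal(b$truth$region$residual, a$truth$region$residual,
               tolerance = 1e-9)
  # coronal x-coordinates mirror about the T1 entry point (x = 0 line)
  ac <- a$views[a$views$view == "coronal", ]
  bc <- b$views[b$views$view == "coronal", ]
  swap <- c(ul = "ur", ur = "ul", ll = "lr", lr = "ll")
  key <- function(d) paste(d$vertebra, d$corner)
  i <- match(paste(ac$vertebra, swap[ac$corner]), key(bc))
  expect_equal(bc$x[i], -ac$x, tolerance = 1e-9)
  expect_equal(bc$y[i], ac$y, tolerance = 1e-9)
})

test_that("batches are reproducible and cover the requested types", {
  b1 <- batch_simulate(12, preset = 1:6, seed = 5, landmark_noise_sd = 1)
  b2 <- batch_simulate(12, preset = 1:6, seed = 5, landmark_noise_sd = 1)
  expect_identical(purrr::map(b1, "views"), purrr::map(b2, "views"))
  types <- purrr::map_int(b1, ~ .x$truth$lenke_type)
  expect_equal(sort(unique(types)), 1:6)
  expect_equal(purrr::map_chr(b1, ~ .x$truth$case_id)[1:2],
               c("case_001", "case_002"))
  expect_error(batch_simulate(0), "positive")
})

test_that("parameter validation rejects impossible geometry", {
  expect_error(spine_params(vertebra_height = -1))
  expect_error(spine_params(wedging_fraction = 1.5))
  expect_error(curve_spec("T9", -3), "amplitude")
  expect_error(curve_spec("T20", 10), "unknown apex")
  expect_error(curve_spec("T9", 10, width = 0))
})
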