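test_that("mae reports mean and sample sd of absolute differences", {
  x <- c(1, 2, 3); y <- x
  expect_equal(unlist(mae(x, y)[c("mean", "sd")]), c(mean = 0, sd = 0))
  m <- mae(c(3, 0), c(0, 5))       # differences +3, -5
  expect_equal(m$mean, 4)
  expect_equal(m$sd, sqrt(2), tolerance = 1e-9)
  expect_error(mae(1:3, 1:4), "length")
  # symmetry and elementwise oracle
  set.seed(61)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(mae(a, b), mae(b, a))
  d <- abs(a - b)
  expect_equal(mae(a, b)$mean, sum(d) / 50, tolerance = 1e-12)
  expect_equal(mae(a, b)$sd, sqrt(sum((d - mean(d))^2) / 49),
               tolerance = 1e-12)
})

test_that("two identical raters give ICC 1; an offset lowers absolute agreement", {
  x <- c(4, 7, 1, 9, 5, 3)
  expect_equal(icc(cbind(x, x))$estimate, 1)
  with_offset <- icc(cbind(x, x + 3))$estimate
  expect_lt(with_offset, 1)
  # consistency form ignores the constant offset
  expect_equal(icc(cbind(x, x + 3), type = "ICC3")$estimate, 1,
               tolerance = 1e-9)
})

test_that("ICC(2,1) matches a from-scratch ANOVA oracle on random matrices", {
  set.seed(62)
  for (rep in 1:20) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 10, 3), n, k) +
      outer(rep(0, n), rnorm(k, 0, 1), `+`)
    expect_equal(icc(m)$estimate, icc2_oracle(m), tolerance = 1e-10)
  }
  # the spec'd small case: 6 subjects x 2 raters
  m62 <- matrix(c(9, 6, 8, 7, 10, 6, 2, 1, 4, 1, 5, 2), ncol = 2)
  expect_equal(icc(m62)$estimate, icc2_oracle(m62), tolerance = 1e-10)
})

test_that("estimates and intervals match an independent reference implementation", {
  # values computed with an independent Python implementation (pingouin)
  # on this fixed 6 x 3 matrix
  m <- matrix(c(9, 2, 5, 6, 1, 3, 8, 4, 6, 7, 1, 2, 10, 5, 6, 6, 2, 4),
              nrow = 6, byrow = TRUE)
  ref <- list(
    ICC2 = list(est = 0.22352941176470587, ci = c(-0.01, 0.71)),
    ICC3 = list(est = 0.788381742738589, ci = c(0.38, 0.96)),
    ICC2k = list(est = 0.4634146341463414, ci = c(-0.03, 0.88)),
    ICC3k = list(est = 0.9178743961352656, ci = c(0.65, 0.99)))
  for (ty in names(ref)) {
    got <- icc(m, type = ty)
    expect_equal(got$estimate, ref[[ty]]$est, tolerance = 1e-9)
    # reference interval bounds are printed to two decimals
    expect_lt(max(abs(c(got$ci_low, got$ci_high) - ref[[ty]]$ci)), 0.006)
  }
})

test_that("CI brackets the estimate and narrows with more subjects", {
  set.seed(63)
  mk <- function(n) {
    truth <- rnorm(n, 20, 8)
    cbind(truth + rnorm(n, 0, 3), truth + rnorm(n, 0, 3))
  }
  small <- icc(mk(10)); big <- icc(mk(100))
  for (z in list(small, big)) {
    expect_lte(z$ci_low, z$estimate)
    expect_gte(z$ci_high, z$estimate)
    expect_gte(z$ci_low, -1); expect_lte(z$ci_high, 1)
  }
  expect_lt(big$ci_high - big$ci_low, small$ci_high - small$ci_low)
})

test_that("ICC is invariant to relabelling raters; degenerate input warns", {
  set.seed(64)
  m <- matrix(rnorm(18), 6, 3)
  expect_equal(icc(m)$estimate, icc(m[, c(2, 3, 1)])$estimate,
               tolerance = 1e-12)
  expect_warning(z <- icc(matrix(5, 4, 2)), "constant")
  expect_equal(z$estimate, 1)
  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(icc(matrix(1:3, ncol = 1)), "raters")
})

test_that("kappa matches an independent implementation and handles agreement", {
  expect_equal(cohen_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)
  set.seed(65)
  x <- sample(1:4, 60, replace = TRUE)
  y <- ifelse(stats::runif(60) < 0.7, x, sample(1:4, 60, replace = TRUE))
  ref <- e1071::classAgreement(table(factor(x, 1:4), factor(y, 1:4)))$kappa
  expect_equal(cohen_kappa(x, y), ref, tolerance = 1e-12)
})

test_that("perfect prediction gives MAE 0 and ICC 1 across the report", {
  sims <- batch_simulate(8, preset = 1:6, seed = 12, landmark_noise_sd = 1)
  ms <- purrr::map(sims, ~ measure_case(.x$views))
  rep <- compare_measurements(ms, ms)
  angles <- rep[rep$indicator != "lenke_type", ]
  expect_equal(angles$mae_mean, rep(0, nrow(angles)))
  expect_equal(angles$icc, rep(1, nrow(angles)), tolerance = 1e-9)
  expect_equal(rep$kappa[rep$indicator == "lenke_type"], 1)
  expect_equal(nrow(rep), 8)   # 7 angles + the type row
})

test_that("injected normal noise appears as sigma*sqrt(2/pi) in the MAE", {
  set.seed(66)
  n <- 1000; sigma <- 5
  base <- tibble::tibble(case_id = sprintf("c%04d", 1:n),
                         pt = runif(n, 10, 40), mt = runif(n, 20, 60),
                         tll = runif(n, 10, 40),
                         t5_t12_kyphosis = runif(n, 5, 45),
                         bend_pt = runif(n, 0, 20), bend_mt = runif(n, 10, 40),
                         bend_tll = runif(n, 0, 20),
                         lenke_type = sample(1:6, n, TRUE),
                         lumbar_modifier = NA_character_,
                         sagittal_modifier = "N")
  noisy <- base
  for (col in c("pt", "mt", "tll")) {
    noisy[[col]] <- noisy[[col]] + rnorm(n, 0, sigma)
  }
  rep <- compare_measurements(noisy, base)
  want <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(n)
  for (col in c("pt", "mt", "tll")) {
    expect_lt(abs(rep$mae_mean[rep$indicator == col] - want), 5 * se)
  }
})

test_that("disjoint or partially missing cases are handled explicitly", {
  sims <- batch_simulate(4, preset = c(1, 2, 5, 6), seed = 13,
                         landmark_noise_sd = 1)
  ms <- purrr::map(sims, ~ measure_case(.x$views))
  t1 <- tidy_measurements(ms)
  t2 <- t1; t2$case_id <- paste0("other_", t2$case_id)
  expect_error(compare_measurements(t1, t2), "overlapping")
  t3 <- t1; t3$t5_t12_kyphosis[1] <- NA
  expect_message(rep <- compare_measurements(t3, t1), "dropped 1")
  expect_equal(rep$n[rep$indicator == "t5_t12_kyphosis"], 3)
})
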