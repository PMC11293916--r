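# Test-side constructors and brute-force oracles, independent of the
# package's generator geometry.

# spine of axis-aligned rectangles: all 34 tilts are exactly zero
straight_lm <- function(view = "coronal", case_id = "fix", x0 = 500,
                        width = 80, vheight = 40, pitch = 60) {
  v <- vertebra_levels()
  y_top <- (seq_along(v) - 1) * pitch
  df <- tibble::tibble(
    vertebra = rep(v, each = 4),
    corner = rep(corner_levels(), length(v)),
    x = rep(c(x0 - width / 2, x0 + width / 2,
              x0 - width / 2, x0 + width / 2), length(v)),
    y = as.vector(vapply(y_top, function(t)
      c(t, t, t + vheight, t + vheight), numeric(4))))
  landmark_set(df, case_id = case_id, view = view)
}

# spine whose 34 endplate tilts are prescribed exactly (degrees);
# corners are placed by explicit rotation about each endplate centre
lm_from_tilts <- function(tilts, view = "coronal", case_id = "fix",
                          x0 = 500, width = 80, vheight = 40, pitch = 60) {
  stopifnot(length(tilts) == 34)
  v <- vertebra_levels()
  rows <- list()
  for (i in seq_along(v)) {
    y_sup <- (i - 1) * pitch
    y_inf <- y_sup + vheight
    t_sup <- tilts[2 * i - 1] * pi / 180
    t_inf <- tilts[2 * i] * pi / 180
    rows[[i]] <- tibble::tibble(
      vertebra = v[i],
      corner = corner_levels(),
      x = c(x0 - width / 2 * cos(t_sup), x0 + width / 2 * cos(t_sup),
            x0 - width / 2 * cos(t_inf), x0 + width / 2 * cos(t_inf)),
      y = c(y_sup - width / 2 * sin(t_sup), y_sup + width / 2 * sin(t_sup),
            y_inf - width / 2 * sin(t_inf), y_inf + width / 2 * sin(t_inf)))
  }
  landmark_set(dplyr::bind_rows(rows), case_id = case_id, view = view)
}

# mirror a landmark set left-right about x = axis (corner labels swap so
# the set stays valid)
mirror_lm <- function(lm, axis = 500) {
  out <- tibble::as_tibble(lm)
  out$x <- 2 * axis - out$x
  swap <- c(ul = "ur", ur = "ul", ll = "lr", lr = "ll")
  out$corner <- unname(swap[out$corner])
  landmark_set(out)
}

# brute-force local-extrema scan (no prominence, no plateaus expected):
# index i is a peak iff strictly above both neighbours, endpoints compare
# to their single neighbour
scan_extrema <- function(v) {
  n <- length(v)
  out <- data.frame(idx = integer(), polarity = character())
  for (i in seq_len(n)) {
    left <- if (i > 1) v[i - 1] else NULL
    right <- if (i < n) v[i + 1] else NULL
    up <- all(c(left, right) < v[i])
    dn <- all(c(left, right) > v[i])
    if (up) out <- rbind(out, data.frame(idx = i, polarity = "peak"))
    if (dn) out <- rbind(out, data.frame(idx = i, polarity = "trough"))
  }
  out
}

# from-scratch two-way ANOVA mean squares via stats::aov, then the
# published single-measure agreement formula
icc2_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(score = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(score ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# random smooth multi-curve simulation parameters for property tests
random_spine_params <- function(noise_sd = 0) {
  n_curves <- sample(1:3, 1)
  apexes <- sort(runif(n_curves, 0.1, 0.9))
  curves <- purrr::map(seq_len(n_curves), function(k) {
    curve_spec(apexes[k], runif(1, 5, 25), runif(1, 0.07, 0.16),
               sample(c("image_left", "image_right"), 1),
               runif(1))
  }) |> dplyr::bind_rows()
  spine_params(curves = curves, kyphosis_t5_t12 = runif(1, 5, 45),
               landmark_noise_sd = noise_sd,
               seed = sample.int(1e6, 1))
}
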