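#' Specify one scoliotic curve for simulation
#'
#' Each curve contributes a signed derivative-of-Gaussian lobe pair to the
#' spine's tilt profile: tilt is zero at the apex (the apex endplates are
#' the most level), reaches `-amplitude` at one end vertebra and
#' `+amplitude` at the other (at apex position +/- `width` along the
#' spine), and decays beyond. The coronal Cobb contributed by an isolated
#' curve is therefore about `2 * amplitude`.
#'
#' For an image-right-convex curve the upper end is a trough and the lower
#' end a peak of the oscillogram (positive tilt = endplate sloping down
#' toward image-right), and vice versa.
#'
#' @param apex Apex position: a vertebra label (e.g. `"T9"`) or a fraction
#'   of spine length in `[0, 1]`.
#' @param amplitude Peak endplate-tilt contribution in degrees (>= 0).
#' @param width Gaussian sigma as a fraction of spine length (> 0); the end
#'   vertebrae sit one `width` above and below the apex.
#' @param convexity `"image_left"` or `"image_right"`.
#' @param flexibility Fraction in `[0, 1]` of the amplitude removed on the
#'   corrective side-bending view (bending toward the convexity); low
#'   flexibility leaves a large residual, i.e. a structural curve.
#' @return One-row tibble.
#' @export
curve_spec <- function(apex, amplitude, width = 0.12,
                       convexity = c("image_right", "image_left"),
                       flexibility = 0.5) {
  convexity <- match.arg(convexity)
  stopifnot(amplitude >= 0, width > 0,
            flexibility >= 0, flexibility <= 1)
  if (is.character(apex) && !apex %in% vertebra_levels()) {
    abort(paste0("unknown apex vertebra '", apex, "'"))
  }
  if (is.numeric(apex)) stopifnot(apex >= 0, apex <= 1)
  tibble::tibble(apex = as.character(apex), amplitude = amplitude,
                 width = width, convexity = convexity,
                 flexibility = flexibility)
}

#' Simulation parameters for a synthetic spine
#'
#' Defines the full generative model for one case: the coronal curve set,
#' the target T5-T12 kyphosis, vertebral geometry, how much of the local
#' tilt is expressed as endplate wedging (non-parallel endplates, as seen
#' in progressing deformities) versus rigid vertebral rotation, and the
#' landmark noise.
#'
#' Geometry defaults (vertebra 25 x 35 mm, disc 8 mm) give a T1-L5 spine of
#' 553 mm; landmarks are emitted in pixels with the spine scaled to
#' `spine_height_px` (default 1500 px, a typical full-spine radiograph), so
#' `landmark_noise_sd` is in pixels at that scale.
#'
#' @param curves Tibble of [curve_spec()] rows (may be empty for a straight
#'   spine).
#' @param kyphosis_t5_t12 Target sagittal kyphosis in degrees.
#' @param vertebra_height,vertebra_width,disc_height Dimensions in mm.
#' @param wedging_fraction Fraction in `[0, 1]` of local tilt expressed as
#'   endplate non-parallelism (0 = rigid bodies with parallel endplates).
#' @param landmark_noise_sd Gaussian noise sd added to every landmark
#'   coordinate, in px (0 = noise-free).
#' @param spine_height_px Output spine height in px.
#' @param seed Integer seed for the landmark noise.
#' @return A `spine_sim_params` list.
#' @export
spine_params <- function(curves = curve_spec("T9", 20, 0.15, "image_right", 0.3),
                         kyphosis_t5_t12 = 20,
                         vertebra_height = 25, vertebra_width = 35,
                         disc_height = 8, wedging_fraction = 0.3,
                         landmark_noise_sd = 1.5, spine_height_px = 1500,
                         seed = 1L) {
  stopifnot(vertebra_height > 0, vertebra_width > 0, disc_height > 0,
            wedging_fraction >= 0, wedging_fraction <= 1,
            landmark_noise_sd >= 0, kyphosis_t5_t12 >= 0,
            spine_height_px > 0)
  curves <- tibble::as_tibble(curves)
  structure(list(curves = curves, kyphosis_t5_t12 = kyphosis_t5_t12,
                 vertebra_height = vertebra_height,
                 vertebra_width = vertebra_width,
                 disc_height = disc_height,
                 wedging_fraction = wedging_fraction,
                 landmark_noise_sd = landmark_noise_sd,
                 spine_height_px = spine_height_px,
                 seed = as.integer(seed)),
            class = "spine_sim_params")
}

# normalized arc-length positions of vertebral landmarks along the spine
spine_stations <- function(params) {
  h <- params$vertebra_height; d <- params$disc_height
  L <- n_vertebrae * h + (n_vertebrae - 1) * d
  top <- (seq_len(n_vertebrae) - 1) * (h + d)
  tibble::tibble(vertebra = vertebra_levels(),
                 s_sup = top / L, s_c = (top + h / 2) / L,
                 s_inf = (top + h) / L)
}

# derivative-of-Gaussian lobe, normalised to +/-1 at u = +/-1
dog_lobe <- function(u) u * exp((1 - u^2) / 2)

# coronal tilt profile in degrees at normalized position s, with per-curve
# amplitude multipliers (for bending views)
coronal_tilt_profile <- function(s, curves, stations, amp_scale = NULL) {
  if (nrow(curves) == 0) return(rep(0, length(s)))
  if (is.null(amp_scale)) amp_scale <- rep(1, nrow(curves))
  tot <- rep(0, length(s))
  for (k in seq_len(nrow(curves))) {
    apx <- curves$apex[k]
    s0 <- if (apx %in% vertebra_levels()) {
      stations$s_c[match(apx, stations$vertebra)]
    } else {
      as.numeric(apx)
    }
    dir <- if (curves$convexity[k] == "image_right") 1 else -1
    tot <- tot + dir * curves$amplitude[k] * amp_scale[k] *
      dog_lobe((s - s0) / curves$width[k])
  }
  tot
}

# sagittal tilt profile: smooth half-cosine ramp between T5 and T12, flat
# across each of the two vertebrae themselves so that wedging cannot move
# the endpoint tilts; the T5-sup to T12-inf difference is exactly K
sagittal_tilt_profile <- function(s, K, stations) {
  s_lo <- stations$s_inf[5]; s_hi <- stations$s_sup[12]
  t <- pmin(pmax((s - s_lo) / (s_hi - s_lo), 0), 1)
  -K / 2 * cos(pi * t)
}

# place 17 vertebral boxes along a tilt profile; returns landmarks plus the
# exact 34-entry tilt series the corners encode
build_view_geometry <- function(tilt_fun, params, view, case_id) {
  st <- spine_stations(params)
  L_mm <- n_vertebrae * params$vertebra_height +
    (n_vertebrae - 1) * params$disc_height
  px <- params$spine_height_px / L_mm
  W <- params$vertebra_width * px
  wf <- params$wedging_fraction

  t_c <- tilt_fun(st$s_c)
  t_sup <- t_c + wf * (tilt_fun(st$s_sup) - t_c)
  t_inf <- t_c + wf * (tilt_fun(st$s_inf) - t_c)

  # centerline by integrating the lean angle over a fine grid
  # (positive tilt = axis leaning image-left going caudal)
  grid <- seq(0, 1, length.out = 1001)
  th <- tilt_fun(grid) * pi / 180
  step <- diff(grid) * params$spine_height_px
  dx <- -tan(th)
  x_g <- cumsum(c(0, (dx[-1] + dx[-length(dx)]) / 2 * step))
  cx <- stats::approxfun(grid, x_g)

  # endplate centres on the centerline; corners half a width out along the
  # endplate direction (vertebra-major order ul, ur, ll, lr)
  s_end <- as.vector(rbind(st$s_sup, st$s_inf))            # 34 endplates
  t_end <- as.vector(rbind(t_sup, t_inf)) * pi / 180
  ex_c <- cx(s_end); ey_c <- s_end * params$spine_height_px
  hx <- W / 2 * cos(t_end); hy <- W / 2 * sin(t_end)
  # each endplate yields its left then right corner
  x_all <- as.vector(rbind(ex_c - hx, ex_c + hx))          # 68 corners
  y_all <- as.vector(rbind(ey_c - hy, ey_c + hy))
  corner_rows <- tibble::tibble(
    case_id = case_id, view = view, units = "px",
    vertebra = rep(st$vertebra, each = 4L),
    corner = rep(corner_levels(), n_vertebrae),
    x = x_all, y = y_all)

  tilt_series <- as.vector(rbind(t_sup, t_inf))
  list(landmarks = corner_rows, tilt = tilt_series)
}

truth_assessment <- function(tilts, threshold = 25, min_cobb = 10) {
  spans <- region_spans()
  reg <- purrr::map(spans$region, function(r) {
    rc <- region_cobb(tilts$coronal, r)
    bends <- c(left_bending = region_cobb(tilts$left_bending, r)$cobb,
               right_bending = region_cobb(tilts$right_bending, r)$cobb)
    tibble::tibble(region = r, cobb = rc$cobb,
                   upper_endplate = min(rc$max_endplate, rc$min_endplate),
                   lower_endplate = max(rc$max_endplate, rc$min_endplate),
                   bend_left = bends[["left_bending"]],
                   bend_right = bends[["right_bending"]],
                   residual = min(bends))
  }) |> dplyr::bind_rows()
  precedence <- c(MT = 1, TLL = 2, PT = 3)
  major <- reg$region[order(-reg$cobb, precedence[reg$region])][1]
  reg$is_major <- reg$region == major
  reg$structural <- reg$residual > threshold | reg$is_major
  lt <- if (max(reg$cobb) < min_cobb) {
    list(curve_type = NA_integer_)
  } else {
    lenke_type(reg)
  }
  list(region = reg, lenke_type = lt$curve_type)
}

#' Simulate one annotated case with known ground truth
#'
#' Generates the four landmark views (coronal, sagittal, left and right
#' bending) of a synthetic scoliotic spine, plus the ground truth the
#' generator knows analytically. The coronal tilt profile is the sum of
#' the curves' lobes ([curve_spec()]); each side-bending view rescales the
#' amplitude of every curve whose convexity matches the bend side by
#' `1 - flexibility`, leaving opposite-convexity curves unchanged; the
#' sagittal view ramps smoothly so the T5-T12 tilt difference equals the
#' target kyphosis exactly. Landmark noise is added last, seeded; with
#' `landmark_noise_sd = 0` the output is identical across runs regardless
#' of seed.
#'
#' Ground truth is computed from the generator's own noise-free tilt
#' series by the same region max-minus-min rule that [region_cobb()]
#' applies, so noise-free measurement must reproduce it to numerical
#' precision.
#'
#' @param params A [spine_params()] object.
#' @param case_id Case identifier.
#' @return List with `views` (a `case_views` tibble of all four views) and
#'   `truth` (region tibble with coronal/bending Cobb, residuals,
#'   structural and major flags; `lenke_type`; `kyphosis_t5_t12`;
#'   `sagittal_modifier`; per-curve apex labels; the noise-free tilt
#'   series).
#' @export
simulate_case <- function(params, case_id = "sim") {
  stopifnot(inherits(params, "spine_sim_params"))
  st <- spine_stations(params)
  cv <- params$curves

  profiles <- list(
    coronal = function(s) coronal_tilt_profile(s, cv, st),
    left_bending = function(s)
      coronal_tilt_profile(s, cv, st, amp_scale = ifelse(
        cv$convexity == "image_left", 1 - cv$flexibility, 1)),
    right_bending = function(s)
      coronal_tilt_profile(s, cv, st, amp_scale = ifelse(
        cv$convexity == "image_right", 1 - cv$flexibility, 1)),
    sagittal = function(s)
      sagittal_tilt_profile(s, params$kyphosis_t5_t12, st))

  built <- purrr::imap(profiles, function(f, vw)
    build_view_geometry(f, params, vw, case_id))
  views <- purrr::map(built, "landmarks") |> dplyr::bind_rows()
  tilts <- purrr::map(built, "tilt")

  if (params$landmark_noise_sd > 0) {
    set.seed(params$seed)
    views$x <- views$x + rnorm(nrow(views), 0, params$landmark_noise_sd)
    views$y <- views$y + rnorm(nrow(views), 0, params$landmark_noise_sd)
  }
  views <- views[c("case_id", "view", "units", "vertebra", "corner", "x", "y")]
  class(views) <- c("case_views", class(views))

  ta <- truth_assessment(tilts)
  apexes <- if (nrow(cv) > 0) {
    vapply(cv$apex, function(a) {
      if (a %in% vertebra_levels()) a else
        st$vertebra[which.min(abs(st$s_c - as.numeric(a)))]
    }, character(1))
  } else {
    character(0)
  }
  truth <- list(
    case_id = case_id,
    region = ta$region,
    lenke_type = ta$lenke_type,
    kyphosis_t5_t12 = params$kyphosis_t5_t12,
    sagittal_modifier = sagittal_modifier(params$kyphosis_t5_t12),
    curve_apex = apexes,
    tilt = tilts)
  list(views = views, truth = truth)
}

#' Preset simulation parameters for each Lenke curve type
#'
#' Clear-cut prototype cases for types 1-6, with coronal magnitudes guided
#' by typical AIS cohorts (main thoracic around 40-50 degrees,
#' thoracolumbar around 35-45 degrees) and flexibilities chosen so that
#' structural residuals sit well above, and nonstructural residuals well
#' below, the 25-degree rule:
#' \itemize{
#'   \item type 1: single structural MT (apex T9), flexible minor curves
#'   \item type 2: structural PT (apex T3) and MT, MT major
#'   \item type 3: structural MT and TL/L (apex L2), MT major
#'   \item type 4: PT, MT and TL/L all structural
#'   \item type 5: single TL/L curve, structural only as the major curve
#'     (its bending residual corrects below 25 degrees)
#'   \item type 6: structural MT and TL/L, TL/L major
#' }
#' Convexity alternates (PT left, MT right, TL/L left) as in typical curve
#' patterns; default T5-T12 kyphosis targets vary by type between 18 and
#' 30 degrees, all within the normal band (modifier "N").
#'
#' @param lenke_type Integer 1..6.
#' @param ... Overrides passed on to [spine_params()] (e.g. `seed`,
#'   `landmark_noise_sd`).
#' @return A `spine_sim_params` object.
#' @export
preset_for_type <- function(lenke_type, ...) {
  if (!is.numeric(lenke_type) || length(lenke_type) != 1 ||
      !lenke_type %in% 1:6) {
    abort("lenke_type must be an integer in 1..6")
  }
  pt <- function(a, fl) curve_spec("T3", a, 0.09, "image_left", fl)
  mt <- function(a, fl) curve_spec("T9", a, 0.15, "image_right", fl)
  tll <- function(a, fl) curve_spec("L2", a, 0.12, "image_left", fl)
  curves <- switch(as.character(lenke_type),
    "1" = dplyr::bind_rows(pt(4, 0.85), mt(19, 0.30), tll(4, 0.90)),
    "2" = dplyr::bind_rows(pt(16, 0.00), mt(22, 0.30), tll(2, 0.90)),
    "3" = dplyr::bind_rows(pt(3, 0.85), mt(21, 0.22), tll(14, 0.03)),
    "4" = dplyr::bind_rows(pt(15, 0.00), mt(22, 0.27), tll(16, 0.05)),
    "5" = dplyr::bind_rows(pt(2, 0.90), mt(4, 0.90), tll(17, 0.50)),
    "6" = dplyr::bind_rows(pt(4, 0.85), mt(12, 0.05), tll(25, 0.25)))
  # kyphosis varies by type within the normal band (modifier "N")
  kyph <- c(18, 22, 26, 30, 20, 24)[lenke_type]
  spine_params(curves = curves, kyphosis_t5_t12 = kyph, ...)
}

#' Simulate a reproducible batch of cases
#'
#' Draws `n` independent cases with per-case seeds derived from the master
#' seed, so the whole batch is reproducible. Presets may be a single type,
#' a vector of types recycled across the batch, or full
#' [spine_params()] objects.
#'
#' @param n Number of cases (>= 1).
#' @param preset Integer type(s) in 1..6 passed to [preset_for_type()], or
#'   a `spine_sim_params` object, or a list of them (recycled).
#' @param seed Master seed.
#' @param ... Overrides forwarded to [preset_for_type()] (e.g.
#'   `landmark_noise_sd`).
#' @return List of `n` elements, each `list(views, truth)`; case ids are
#'   `case_001` ...
#' @export
batch_simulate <- function(n, preset = 1:6, seed = 1L, ...) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive integer")
  }
  n <- as.integer(n)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  specs <- if (inherits(preset, "spine_sim_params")) {
    list(preset)
  } else if (is.numeric(preset)) {
    purrr::map(preset, preset_for_type, ...)
  } else {
    preset
  }
  purrr::map(seq_len(n), function(i) {
    sp <- specs[[(i - 1L) %% length(specs) + 1L]]
    sp$seed <- case_seeds[i]
    simulate_case(sp, case_id = sprintf("case_%03d", i))
  })
}
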