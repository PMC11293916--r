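#' Tilt of one endplate line
#'
#' The tilt of the line from the endplate's left corner to its right corner,
#' in degrees, using the raster convention (origin top-left, y down).
#' Positive tilt means the endplate slopes downward toward image-right.
#' Vectorised over its arguments.
#'
#' A vertical endplate (equal x) is rejected as degenerate rather than
#' returned as +/-90 degrees: at radiographic scales it can only be an
#' annotation mistake.
#'
#' @param x1,y1 Left corner coordinates.
#' @param x2,y2 Right corner coordinates.
#' @return Tilt angle(s) in degrees, in (-90, 90).
#' @export
endplate_tilt <- function(x1, y1, x2, y2) {
  if (any(x1 == x2)) {
    abort("degenerate geometry: vertical endplate (left and right corners share x)")
  }
  atan2(y2 - y1, x2 - x1) * 180 / pi
}

#' Build the endplate-tilt oscillogram
#'
#' Converts a landmark set into the ordered series of 34 endplate tilt
#' angles, cranial to caudal: endplate index 1 is the superior endplate of
#' T1, index 34 the inferior endplate of L5. Odd indices are superior
#' surfaces, even indices inferior. Peaks and troughs of this series mark
#' the maximally tilted endplates, i.e. the end vertebrae of the scoliotic
#' curves; the vertical distance between a peak and a trough is a Cobb angle.
#'
#' The series is invariant under translation and uniform scaling of the
#' landmarks, and a global rotation by phi shifts every tilt by phi.
#'
#' @param lm A landmark tibble; may contain several views (each processed
#'   separately).
#' @return An `oscillogram` tibble with columns `case_id`, `view`,
#'   `endplate` (1..34), `vertebra`, `surface` (`"sup"`/`"inf"`), `tilt`
#'   (degrees).
#' @export
build_oscillogram <- function(lm) {
  lm <- tibble::as_tibble(lm)
  one_view <- function(sub) {
    m <- landmark_matrices(sub)
    x <- m$x; y <- m$y
    deg <- x[1, ] == x[2, ] | x[3, ] == x[4, ]
    if (any(deg)) {
      abort(paste0("degenerate geometry: vertical endplate (left and right ",
                   "corners share x) at vertebra ",
                   vertebra_levels()[which(deg)[1]]))
    }
    t_sup <- atan2(y[2, ] - y[1, ], x[2, ] - x[1, ]) * 180 / pi
    t_inf <- atan2(y[4, ] - y[3, ], x[4, ] - x[3, ]) * 180 / pi
    tibble::tibble(case_id = sub$case_id[1], view = sub$view[1],
                   endplate = seq_len(n_endplates),
                   vertebra = rep(vertebra_levels(), each = 2),
                   surface = rep(c("sup", "inf"), n_vertebrae),
                   tilt = as.vector(rbind(t_sup, t_inf)))
  }
  out <- lm |>
    dplyr::group_split(.data$view) |>
    purrr::map(one_view) |>
    dplyr::bind_rows()
  class(out) <- c("oscillogram", class(out))
  out
}

# reshape one complete view into 4 x 17 coordinate matrices
# (corner order ul, ur, ll, lr per vertebra)
landmark_matrices <- function(sub) {
  ord <- order(match(sub$vertebra, vertebra_levels()),
               match(sub$corner, corner_levels()))
  sub <- sub[ord, ]
  if (nrow(sub) != n_corners ||
      !identical(sub$corner, rep(corner_levels(), n_vertebrae)) ||
      !identical(sub$vertebra, rep(vertebra_levels(), each = 4L))) {
    abort("incomplete or invalid landmark set; run validate_landmarks()")
  }
  list(x = matrix(sub$x, nrow = 4), y = matrix(sub$y, nrow = 4))
}

tilt_vector <- function(osc, view = NULL) {
  if (!is.null(view)) osc <- osc[osc$view == view, ]
  if (length(unique(osc$view)) != 1) {
    abort("expected an oscillogram for exactly one view")
  }
  if (nrow(osc) != n_endplates) {
    abort(paste0("oscillogram must have ", n_endplates, " entries, got ",
                 nrow(osc)))
  }
  osc$tilt[order(osc$endplate)]
}

#' Locate peaks and troughs of a tilt series
#'
#' Plain local-extrema scan with a topographic-prominence filter; no
#' smoothing (the series has only 34 points). Endpoints are eligible,
#' plateaus are represented by their most cranial index, and after
#' filtering, runs of same-polarity extrema are collapsed to the most
#' extreme one (ties break cranial) so that peaks and troughs strictly
#' alternate. A flat series yields no extrema.
#'
#' Prominence of a peak is its height above the higher of the two minima
#' separating it from higher terrain (or the series end) on each side;
#' troughs are scored on the negated series.
#'
#' @param series An `oscillogram` tibble (single view) or a numeric vector
#'   of 34 tilts.
#' @param min_prominence Minimum prominence in degrees to keep an extremum
#'   (default 5).
#' @return Tibble with columns `endplate`, `tilt`, `polarity`
#'   (`"peak"`/`"trough"`), `prominence`, ordered cranial to caudal.
#' @export
find_extrema <- function(series, min_prominence = 5) {
  v <- if (is.numeric(series)) series else tilt_vector(series)
  n <- length(v)
  empty <- tibble::tibble(endplate = integer(), tilt = double(),
                          polarity = character(), prominence = double())
  r <- rle(v)
  k <- length(r$values)
  if (k < 2) return(empty)
  run_start <- cumsum(c(1L, head(r$lengths, -1L)))
  cand <- list()
  for (j in seq_len(k)) {
    val <- r$values[j]
    left <- if (j > 1) r$values[j - 1] else NULL
    right <- if (j < k) r$values[j + 1] else NULL
    is_max <- (is.null(left) || val > left) && (is.null(right) || val > right)
    is_min <- (is.null(left) || val < left) && (is.null(right) || val < right)
    if (is_max || is_min) {
      cand[[length(cand) + 1L]] <- list(
        idx = run_start[j], value = val,
        polarity = if (is_max) "peak" else "trough")
    }
  }
  if (length(cand) == 0) return(empty)
  prominence_at <- function(i, sign) {
    w <- sign * v
    val <- w[i]
    side_min <- function(ids) {
      m <- Inf
      for (q in ids) {
        if (w[q] > val) break
        m <- min(m, w[q])
      }
      m
    }
    lm <- if (i > 1) side_min((i - 1):1) else Inf
    rm_ <- if (i < n) side_min((i + 1):n) else Inf
    base <- max(lm[is.finite(lm)], rm_[is.finite(rm_)], -Inf)
    if (!is.finite(base)) return(0)
    val - base
  }
  ex <- purrr::map(cand, function(cc) {
    tibble::tibble(
      endplate = cc$idx, tilt = cc$value, polarity = cc$polarity,
      prominence = prominence_at(cc$idx, if (cc$polarity == "peak") 1 else -1))
  }) |> dplyr::bind_rows()
  ex <- ex[ex$prominence >= min_prominence, ]
  # collapse same-polarity runs left after filtering, keep the most extreme
  repeat {
    if (nrow(ex) < 2) break
    same <- which(ex$polarity[-1] == ex$polarity[-nrow(ex)])
    if (length(same) == 0) break
    i <- same[1]
    a <- ex[i, ]; b <- ex[i + 1, ]
    keep_a <- if (a$polarity == "peak") a$tilt >= b$tilt else a$tilt <= b$tilt
    ex <- ex[-(if (keep_a) i + 1 else i), ]
  }
  ex
}

#' Region spans of the oscillogram
#'
#' Inclusive endplate-index spans for the proximal thoracic (PT), main
#' thoracic (MT) and thoracolumbar/lumbar (TL/L) regions: PT covers T1
#' superior through T6 inferior, MT T5 superior through T12 inferior, TL/L
#' T10 superior through L4 inferior. Adjacent spans overlap deliberately,
#' because neighbouring curves share end vertebrae.
#'
#' @return Tibble with columns `region`, `lo`, `hi` (endplate indices).
#' @export
region_spans <- function() {
  tibble::tibble(region = c("PT", "MT", "TLL"),
                 lo = c(1L, 9L, 19L),
                 hi = c(12L, 24L, 32L))
}

apex_region <- function(vertebra_index) {
  dplyr::case_when(
    vertebra_index <= 5 ~ "PT",      # T1 falls back to nearest region
    vertebra_index <= 11 ~ "MT",
    TRUE ~ "TLL"                     # T12..L5
  )
}

#' Brute-force region Cobb angle
#'
#' The Cobb angle of a region taken directly as the range of the tilt
#' series over the region's span: maximum tilt minus minimum tilt, with the
#' extremal endplates reported. Ties break toward the cranial index. This
#' is the oracle that curve detection must agree with whenever the region
#' contains a single peak-trough pair.
#'
#' @param series Oscillogram tibble (single view) or numeric vector of 34.
#' @param region `"PT"`, `"MT"` or `"TLL"`, or a custom span as
#'   `c(lo, hi)` endplate indices.
#' @return One-row tibble: `region`, `cobb`, `max_endplate`, `min_endplate`.
#' @export
region_cobb <- function(series, region) {
  v <- if (is.numeric(series)) series else tilt_vector(series)
  if (is.character(region)) {
    sp <- region_spans()
    row <- sp[sp$region == region, ]
    if (nrow(row) == 0) abort(paste0("unknown region '", region, "'"))
    lo <- row$lo; hi <- row$hi; name <- region
  } else {
    lo <- region[1]; hi <- region[2]; name <- paste0("span_", lo, "_", hi)
  }
  stopifnot(lo >= 1, hi <= length(v), lo <= hi)
  w <- v[lo:hi]
  i_max <- lo + which.max(w) - 1L
  i_min <- lo + which.min(w) - 1L
  tibble::tibble(region = name, cobb = v[i_max] - v[i_min],
                 max_endplate = i_max, min_endplate = i_min)
}

vertebra_centroids <- function(lm) {
  m <- landmark_matrices(lm)
  tibble::tibble(vertebra = vertebra_levels(),
                 x = colMeans(m$x), y = colMeans(m$y))
}

apex_core <- function(iu, il, cen) {
  pu <- c(cen$x[iu], cen$y[iu])
  pl <- c(cen$x[il], cen$y[il])
  d <- pl - pu
  len <- sqrt(sum(d^2))
  cand <- if (il - iu >= 2) (iu + 1L):(il - 1L) else iu:il
  dist <- abs((cen$x[cand] - pu[1]) * d[2] - (cen$y[cand] - pu[2]) * d[1]) /
    max(len, .Machine$double.eps)
  cand[which.max(dist)]
}

apex_side_core <- function(iu, il, ia, cen) {
  d <- c(cen$x[il] - cen$x[iu], cen$y[il] - cen$y[iu])
  (cen$x[ia] - cen$x[iu]) * d[2] - (cen$y[ia] - cen$y[iu]) * d[1]
}

#' Apex of a curve segment
#'
#' The apex is the vertebra between the two end vertebrae whose centroid
#' lies farthest (perpendicular distance) from the straight line joining
#' the end-vertebra centroids; ties break toward the cranial vertebra. On a
#' straight segment every distance is zero and the vertebra just below the
#' upper end is returned.
#'
#' @param upper_end,lower_end Vertebra labels (e.g. `"T5"`) or indices
#'   1..17; `upper_end` must be cranial to `lower_end`.
#' @param lm Single-view landmark tibble supplying the centroids.
#' @return Apex vertebra label.
#' @export
apex_of <- function(upper_end, lower_end, lm) {
  iu <- if (is.character(upper_end)) match(upper_end, vertebra_levels()) else upper_end
  il <- if (is.character(lower_end)) match(lower_end, vertebra_levels()) else lower_end
  stopifnot(iu < il)
  vertebra_levels()[apex_core(iu, il, vertebra_centroids(lm))]
}

# signed lateral offset of the apex centroid from the end-centroid line;
# > 0 means the apex bulges toward image-right
apex_side <- function(upper_v, lower_v, apex_v, lm) {
  apex_side_core(match(upper_v, vertebra_levels()),
                 match(lower_v, vertebra_levels()),
                 match(apex_v, vertebra_levels()),
                 vertebra_centroids(lm))
}

endplate_vertebra <- function(e) vertebra_levels()[ceiling(e / 2)]
endplate_surface <- function(e) ifelse(e %% 2 == 1, "sup", "inf")

#' Detect scoliotic curves from an oscillogram
#'
#' Adjacent peak-trough pairs from [find_extrema()] whose tilt difference
#' reaches `min_cobb` become candidate curves; the curve's end endplates
#' are the paired extrema (whichever surface the extremum falls on - the
#' classical superior-of-upper/inferior-of-lower convention is not forced,
#' because the oscillogram selects endplates, not vertebra surfaces). Each
#' candidate is assigned to PT, MT or TL/L by its apex vertebra (apex in
#' T2-T5: PT, T6-T11: MT, T12-L4: TL/L; T1 and L5 map to the nearest
#' region), and at most the largest candidate is kept per region. A region
#' with no candidate falls back to [region_cobb()] over its span, so every
#' region always reports a (possibly small) angle.
#'
#' A curve owns the monotone slopes flanking its extremum pair: its
#' interval is widened to the neighbouring retained extremum (inclusive,
#' since adjacent curves share their end vertebrae) or to the series end
#' - so a spine that enters the image already tilted
#' still contributes its boundary shoulder to the curve it belongs to -
#' and is then clipped to the assigned region's span, with the curve ends
#' re-located at the extreme tilts inside that interval. This keeps every
#' reported curve consistent with the region definition and guarantees
#' `detect_curves()` never exceeds [region_cobb()] for the same region,
#' with equality whenever the span contains a single peak-trough pair.
#'
#' @param series Oscillogram tibble for one view, or numeric vector of 34
#'   tilts (then `lm` must still be supplied for apex geometry).
#' @param lm The landmark set the oscillogram came from.
#' @param config A [run_config()] list (uses `min_prominence`, `min_cobb`).
#' @return Tibble with one row per region (PT, MT, TLL): end endplates and
#'   vertebrae, apex, `cobb` (degrees, >= 0), `convexity` (`"image_left"`,
#'   `"image_right"` or `"none"`), and `source` (`"extrema"` or
#'   `"fallback"`).
#' @export
detect_curves <- function(series, lm, config = run_config()) {
  v <- if (is.numeric(series)) series else tilt_vector(series)
  ex <- find_extrema(v, config$min_prominence)
  cen <- vertebra_centroids(lm)
  spans <- region_spans()

  # candidate pairs: region (by apex), extremum interval widened across the
  # flanking monotone slopes to the neighbouring retained extremum
  # (inclusive - adjacent curves share end vertebrae) or the series ends
  cands <- NULL
  if (nrow(ex) >= 2) {
    i <- seq_len(nrow(ex) - 1L)
    delta <- abs(ex$tilt[i + 1L] - ex$tilt[i])
    keep <- which(delta >= config$min_cobb)
    if (length(keep) > 0) {
      e_up <- ex$endplate[keep]; e_lo <- ex$endplate[keep + 1L]
      ext_up <- ifelse(keep > 1L, ex$endplate[pmax(keep - 1L, 1L)], 1L)
      ext_lo <- ifelse(keep + 2L <= nrow(ex),
                       ex$endplate[pmin(keep + 2L, nrow(ex))],
                       n_endplates)
      iv_up <- ceiling(e_up / 2); iv_lo <- ceiling(e_lo / 2)
      apex_i <- mapply(function(a, b) if (a < b) apex_core(a, b, cen) else a,
                       iv_up, iv_lo)
      cands <- data.frame(region = apex_region(apex_i),
                          e_up = ext_up, e_lo = ext_lo)
    }
  }

  rows <- lapply(seq_len(nrow(spans)), function(ri) {
    reg <- spans$region[ri]; lo <- spans$lo[ri]; hi <- spans$hi[ri]
    pick <- NULL
    if (!is.null(cands)) {
      mine <- cands[cands$region == reg, , drop = FALSE]
      if (nrow(mine) > 0) {
        # clip each candidate interval to the region span and score it by
        # the tilt range inside the clipped interval
        mine$a <- pmax(mine$e_up, lo); mine$b <- pmin(mine$e_lo, hi)
        mine <- mine[mine$a < mine$b, , drop = FALSE]
        if (nrow(mine) > 0) {
          sc <- t(vapply(seq_len(nrow(mine)), function(j) {
            w <- v[mine$a[j]:mine$b[j]]
            i_max <- mine$a[j] + which.max(w) - 1L
            i_min <- mine$a[j] + which.min(w) - 1L
            c(v[i_max] - v[i_min], min(i_max, i_min), max(i_max, i_min))
          }, numeric(3)))
          mine$cobb <- sc[, 1]; mine$ce_up <- sc[, 2]; mine$ce_lo <- sc[, 3]
          mine <- mine[order(-mine$cobb, mine$ce_up), , drop = FALSE]
          pick <- list(e_up = as.integer(mine$ce_up[1]),
                       e_lo = as.integer(mine$ce_lo[1]),
                       cobb = mine$cobb[1], source = "extrema")
        }
      }
    }
    if (is.null(pick)) {
      rc <- region_cobb(v, reg)
      pick <- list(e_up = min(rc$max_endplate, rc$min_endplate),
                   e_lo = max(rc$max_endplate, rc$min_endplate),
                   cobb = rc$cobb, source = "fallback")
    }
    iv_up <- ceiling(pick$e_up / 2); iv_lo <- ceiling(pick$e_lo / 2)
    apex_i <- if (iv_up < iv_lo) apex_core(iv_up, iv_lo, cen) else iv_up
    convexity <- "none"
    if (pick$cobb > 0 && iv_up < iv_lo) {
      s <- apex_side_core(iv_up, iv_lo, apex_i, cen)
      if (abs(s) >= 1e-9) {
        convexity <- if (s > 0) "image_right" else "image_left"
      }
    }
    tibble::tibble(region = reg,
                   upper_endplate = pick$e_up,
                   upper_vertebra = endplate_vertebra(pick$e_up),
                   upper_surface = endplate_surface(pick$e_up),
                   lower_endplate = pick$e_lo,
                   lower_vertebra = endplate_vertebra(pick$e_lo),
                   lower_surface = endplate_surface(pick$e_lo),
                   apex = vertebra_levels()[apex_i],
                   cobb = pick$cobb, convexity = convexity,
                   source = pick$source)
  })
  dplyr::bind_rows(rows)
}

#' T5-T12 sagittal kyphosis
#'
#' On the sagittal oscillogram only the T5-T12 segment represents thoracic
#' kyphosis: the angle is the absolute difference between the tilt of the
#' inferior endplate of T12 (endplate 24) and the superior endplate of T5
#' (endplate 9).
#'
#' @param series Sagittal oscillogram tibble, or numeric vector of 34 tilts
#'   with `view = "sagittal"`.
#' @param view View tag override when `series` is a bare numeric vector.
#' @return Kyphosis angle in degrees (>= 0).
#' @export
sagittal_kyphosis_t5_t12 <- function(series, view = NULL) {
  if (is.numeric(series)) {
    if (!identical(view, "sagittal")) {
      abort("kyphosis is defined on the sagittal view")
    }
    v <- series
    stopifnot(length(v) == n_endplates)
  } else {
    vw <- unique(series$view)
    if (!identical(vw, "sagittal")) {
      abort(paste0("kyphosis is defined on the sagittal view, got '",
                   paste(vw, collapse = ","), "'"))
    }
    v <- tilt_vector(series)
  }
  abs(v[24] - v[9])
}
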