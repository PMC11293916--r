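#' Measurement configuration
#'
#' Bundles the tunable thresholds of the pipeline. All angles are degrees.
#'
#' @param min_prominence Minimum peak/trough prominence for
#'   [find_extrema()] (default 5). The series has 34 points; no smoothing
#'   is applied by default.
#' @param min_cobb Minimum tilt difference for an extremum pair to count as
#'   a curve candidate in [detect_curves()] (default 10).
#' @param structural_threshold Side-bending residual above which a curve is
#'   structural; strictly greater-than (default 25).
#' @param modifier_low,modifier_high Sagittal modifier boundaries: kyphosis
#'   strictly below `modifier_low` is hypokyphotic ("-"), strictly above
#'   `modifier_high` hyperkyphotic ("+"), otherwise normal ("N"). Defaults
#'   10 and 40.
#' @param lock_end_vertebrae_on_bending If `TRUE`, bending-view Cobb is
#'   evaluated at the coronal end endplates; default `FALSE` re-detects
#'   extrema freely on each bending view.
#' @param canonical_lenke_sagittal_criteria Reserved switch for the
#'   original Lenke sagittal structural criteria (regional kyphosis at
#'   T2-T5 / T10-L2); the oscillogram protocol uses only the bending rule,
#'   so this is off by default and requires a sagittal view when enabled.
#' @param seed Integer seed recorded with results for auditability.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(min_prominence = 5, min_cobb = 10,
                       structural_threshold = 25,
                       modifier_low = 10, modifier_high = 40,
                       lock_end_vertebrae_on_bending = FALSE,
                       canonical_lenke_sagittal_criteria = FALSE,
                       seed = 1L) {
  stopifnot(min_prominence > 0, min_cobb > 0, structural_threshold > 0,
            modifier_low > 0, modifier_high > 0, modifier_low < modifier_high)
  structure(list(
    min_prominence = min_prominence, min_cobb = min_cobb,
    structural_threshold = structural_threshold,
    modifier_low = modifier_low, modifier_high = modifier_high,
    lock_end_vertebrae_on_bending = isTRUE(lock_end_vertebrae_on_bending),
    canonical_lenke_sagittal_criteria =
      isTRUE(canonical_lenke_sagittal_criteria),
    seed = as.integer(seed)), class = "run_config")
}

#' Measure a patient case
#'
#' The full measurement pipeline for one case: builds the coronal
#' oscillogram and detects the PT/MT/TL-L curves, evaluates each available
#' side-bending view per region, computes T5-T12 kyphosis from the sagittal
#' view, and classifies the curve pattern (structural flags, Lenke type
#' 1-6, sagittal modifier). The lumbar modifier is always `NA`: it needs
#' the centre sacral vertical line, which corner landmarks of T1-L5 cannot
#' supply.
#'
#' Missing optional views degrade gracefully: without bending views the
#' structural flags and Lenke type are `NA` with an explanatory note;
#' without the sagittal view the kyphosis and modifier are `NA`.
#'
#' @param case A `case_views` tibble (coronal view required).
#' @param config A [run_config()].
#' @return A `case_measurement` object; see [tidy.case_measurement()] for
#'   the flat 10-indicator form.
#' @export
measure_case <- function(case, config = run_config()) {
  viol <- validate_case(case)
  if (nrow(viol) > 0) {
    abort(paste0("case fails validation:\n",
                 paste0("  - [", viol$view, "/", viol$vertebra, "] ",
                        viol$rule, ": ", viol$message, collapse = "\n")))
  }
  case_id <- unique(case$case_id)[1]
  coronal <- get_view(case, "coronal")
  osc_cor <- build_oscillogram(coronal)
  curves <- detect_curves(osc_cor, coronal, config)

  bend_views <- intersect(c("left_bending", "right_bending"),
                          unique(case$view))
  bending <- tibble::tibble(view = character(), region = character(),
                            cobb = double())
  bending <- dplyr::bind_rows(bending, purrr::map(bend_views, function(bv) {
    lmb <- get_view(case, bv)
    oscb <- build_oscillogram(lmb)
    vb <- tilt_vector(oscb)
    if (config$lock_end_vertebrae_on_bending) {
      tibble::tibble(view = bv, region = curves$region,
                     cobb = abs(vb[curves$lower_endplate] -
                                  vb[curves$upper_endplate]))
    } else {
      cb <- detect_curves(oscb, lmb, config)
      tibble::tibble(view = bv, region = cb$region, cobb = cb$cobb)
    }
  }))

  sagittal <- get_view(case, "sagittal")
  kyphosis <- if (is.null(sagittal)) {
    NA_real_
  } else {
    sagittal_kyphosis_t5_t12(build_oscillogram(sagittal))
  }

  m <- structure(list(case_id = case_id, curves = curves, bending = bending,
                      kyphosis_t5_t12 = kyphosis,
                      views = unique(case$view), config = config),
                 class = "case_measurement")
  m$lenke <- classify(m, config)
  m
}

#' @export
print.case_measurement <- function(x, ...) {
  cat("<case_measurement> case:", x$case_id, "\n")
  cat("views:", paste(x$views, collapse = ", "), "\n\n")
  print(tidy(x))
  invisible(x)
}

#' Flatten a case measurement to the 10-indicator row
#'
#' One row per case with the standard indicator set: coronal Cobb of PT, MT
#' and TL/L, T5-T12 kyphosis, the per-region side-bending residual (minimum
#' over available bending views), the Lenke type, lumbar modifier (always
#' `NA`) and sagittal modifier.
#'
#' @param x A `case_measurement`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy case_measurement
#' @export
tidy.case_measurement <- function(x, ...) {
  cobb_of <- function(reg) x$curves$cobb[x$curves$region == reg]
  resid_of <- function(reg) {
    b <- x$bending[x$bending$region == reg, ]
    if (nrow(b) == 0) NA_real_ else min(b$cobb)
  }
  tibble::tibble(
    case_id = x$case_id,
    pt = cobb_of("PT"), mt = cobb_of("MT"), tll = cobb_of("TLL"),
    t5_t12_kyphosis = x$kyphosis_t5_t12,
    bend_pt = resid_of("PT"), bend_mt = resid_of("MT"),
    bend_tll = resid_of("TLL"),
    lenke_type = x$lenke$curve_type,
    lumbar_modifier = NA_character_,
    sagittal_modifier = x$lenke$sagittal_modifier %||% NA_character_)
}

#' @rdname tidy.case_measurement
#' @method glance case_measurement
#' @export
glance.case_measurement <- function(x, ...) {
  st <- x$lenke$structural
  major <- if (!is.null(st) && any(st$is_major)) st$region[st$is_major] else NA_character_
  tibble::tibble(
    case_id = x$case_id,
    n_views = length(x$views),
    major_region = major,
    major_cobb = max(x$curves$cobb),
    classified = !is.na(x$lenke$curve_type),
    notes = paste(x$lenke$notes, collapse = "; "))
}

#' Tidy a batch of measurements
#'
#' @param measurements List of `case_measurement` objects.
#' @return Tibble with one indicator row per case.
#' @export
tidy_measurements <- function(measurements) {
  purrr::map(measurements, tidy) |> dplyr::bind_rows()
}
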