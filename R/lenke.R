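#' Structural-curve assessment
#'
#' A curve counts as structural when its Cobb angle on side-bending
#' radiographs stays strictly above the threshold (default 25 degrees): the
#' bending residual is taken as the minimum over the available bending
#' views, i.e. the best correction achieved, whichever side achieves it.
#' The region with the largest coronal Cobb is the major curve and is
#' structural by definition, regardless of its residual. Exactly one major
#' curve is designated; a Cobb tie is broken by thoracic precedence
#' (MT, then TL/L, then PT) and flagged in downstream notes.
#'
#' @param measurement A `case_measurement` (or a list with `curves` and
#'   `bending` tibbles as produced by [measure_case()]).
#' @param threshold Structural threshold in degrees; strict inequality
#'   (a residual of exactly 25 is nonstructural).
#' @return Tibble with one row per region: `region`, `coronal_cobb`,
#'   `residual_cobb`, `bending_view_used`, `structural`, `is_major`.
#'   Without bending views `residual_cobb` and `structural` are `NA`.
#' @export
assess_structural <- function(measurement, threshold = 25) {
  curves <- measurement$curves
  bending <- measurement$bending
  precedence <- c(MT = 1, TLL = 2, PT = 3)
  ord <- order(-curves$cobb, precedence[curves$region])
  major_region <- curves$region[ord[1]]
  out <- purrr::map(curves$region, function(reg) {
    cc <- curves$cobb[curves$region == reg]
    b <- if (is.null(bending) || nrow(bending) == 0) {
      bending[0, ]
    } else {
      bending[bending$region == reg, ]
    }
    if (nrow(b) == 0) {
      res <- NA_real_; used <- NA_character_; structural <- NA
    } else {
      i <- which.min(b$cobb)
      res <- b$cobb[i]; used <- b$view[i]
      structural <- res > threshold
    }
    is_major <- reg == major_region
    if (is_major && !is.na(structural)) structural <- TRUE
    tibble::tibble(region = reg, coronal_cobb = cc, residual_cobb = res,
                   bending_view_used = used, structural = structural,
                   is_major = is_major)
  }) |> dplyr::bind_rows()
  out
}

#' Lenke curve type from structural flags
#'
#' Maps the (PT, MT, TL/L) structural pattern and the major region onto
#' curve types 1-6:
#' \itemize{
#'   \item MT only structural, MT major: type 1 (main thoracic)
#'   \item PT and MT structural: type 2 (double thoracic)
#'   \item MT and TL/L structural, MT major: type 3 (double major)
#'   \item all three structural: type 4 (triple major)
#'   \item TL/L only structural, TL/L major: type 5 (thoracolumbar/lumbar)
#'   \item MT and TL/L structural, TL/L major: type 6 (TL/L - main thoracic)
#' }
#' Any other pattern (for example a PT-major case) has no defined type and
#' returns `NA` with an explanatory note; the function never throws.
#'
#' @param assessments Tibble from [assess_structural()].
#' @return List with `curve_type` (integer 1..6 or `NA`) and `notes`
#'   (character vector).
#' @export
lenke_type <- function(assessments) {
  a <- assessments
  flag <- function(reg) a$structural[a$region == reg]
  s <- c(PT = flag("PT"), MT = flag("MT"), TLL = flag("TLL"))
  major <- a$region[a$is_major]
  if (any(is.na(s))) {
    return(list(curve_type = NA_integer_,
                notes = "bending views required to resolve structural curves"))
  }
  pat <- paste0(ifelse(s, "T", "F"), collapse = "")
  type <- switch(
    pat,
    "FTF" = if (major == "MT") 1L else NA_integer_,
    "TTF" = 2L,
    "FTT" = if (major == "MT") 3L else if (major == "TLL") 6L else NA_integer_,
    "TTT" = 4L,
    "FFT" = if (major == "TLL") 5L else NA_integer_,
    NA_integer_)
  notes <- character()
  if (is.na(type)) {
    notes <- paste0("structural pattern (PT,MT,TL/L) = (", pat,
                    ") with major ", major,
                    " has no defined curve type")
  }
  list(curve_type = type, notes = notes)
}

#' Sagittal thoracic modifier
#'
#' Classifies T5-T12 kyphosis: strictly below `low` is hypokyphotic
#' (`"-"`), strictly above `high` hyperkyphotic (`"+"`), otherwise normal
#' (`"N"`). Boundary values map to `"N"`.
#'
#' @param kyphosis_t5_t12 Kyphosis in degrees, >= 0.
#' @param low,high Band boundaries (defaults 10 and 40 degrees).
#' @return `"-"`, `"N"` or `"+"` (vectorised).
#' @export
sagittal_modifier <- function(kyphosis_t5_t12, low = 10, high = 40) {
  if (any(is.na(kyphosis_t5_t12)) || any(kyphosis_t5_t12 < 0)) {
    abort("kyphosis must be a non-negative angle")
  }
  dplyr::case_when(kyphosis_t5_t12 < low ~ "-",
                   kyphosis_t5_t12 > high ~ "+",
                   TRUE ~ "N")
}

#' Classify a measured case
#'
#' Composes [assess_structural()], [lenke_type()] and
#' [sagittal_modifier()]. All `NA` outputs carry human-readable notes; the
#' lumbar modifier is always `NA` (not derivable from T1-L5 corner
#' landmarks).
#'
#' Classification is invariant under left-right mirroring of the
#' landmarks: convexity side never enters the type.
#'
#' @param measurement A `case_measurement`.
#' @param config A [run_config()].
#' @return A `lenke_result` list: `curve_type`, `sagittal_modifier`,
#'   `lumbar_modifier` (`NA`), `structural` (assessment tibble), `notes`.
#' @export
classify <- function(measurement, config = run_config()) {
  st <- assess_structural(measurement, config$structural_threshold)
  if (max(measurement$curves$cobb) < config$min_cobb) {
    lt <- list(curve_type = NA_integer_,
               notes = paste0("no curve >= min_cobb (",
                              config$min_cobb, " degrees)"))
  } else {
    lt <- lenke_type(st)
  }
  notes <- lt$notes
  ties <- sum(measurement$curves$cobb == max(measurement$curves$cobb))
  if (ties > 1) {
    notes <- c(notes, "major-curve Cobb tie broken by thoracic precedence")
  }
  modifier <- NA_character_
  if (is.na(measurement$kyphosis_t5_t12)) {
    notes <- c(notes, "sagittal view required for the thoracic modifier")
  } else {
    modifier <- sagittal_modifier(measurement$kyphosis_t5_t12,
                                  config$modifier_low, config$modifier_high)
  }
  structure(list(curve_type = lt$curve_type, sagittal_modifier = modifier,
                 lumbar_modifier = NA_character_, structural = st,
                 notes = notes),
            class = "lenke_result")
}

#' @export
print.lenke_result <- function(x, ...) {
  cat("<lenke_result> type:",
      if (is.na(x$curve_type)) "unclassified" else x$curve_type,
      " sagittal modifier:", x$sagittal_modifier %||% NA, "\n")
  print(x$structural)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
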