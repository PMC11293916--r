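#' Vertebra and corner vocabularies
#'
#' The spine segment covered by a landmark set runs from the first thoracic
#' to the fifth lumbar vertebra: 17 vertebrae, each annotated with its four
#' body corners, giving 68 points per view.
#'
#' Corners are named in image coordinates (origin top-left, y down):
#' `ul`/`ur` are the superior endplate's left/right ends, `ll`/`lr` the
#' inferior endplate's. On sagittal views the same keys denote the
#' anterior/posterior ends of the superior and inferior endplates. Whether
#' image-left is patient-left depends on the projection (AP vs PA), which the
#' annotation does not record, so no patient side is ever asserted.
#'
#' @return Character vectors of valid labels.
#' @export
vertebra_levels <- function() {
  c(paste0("T", 1:12), paste0("L", 1:5))
}

#' @rdname vertebra_levels
#' @export
corner_levels <- function() {
  c("ul", "ur", "ll", "lr")
}

#' @rdname vertebra_levels
#' @export
view_levels <- function() {
  c("coronal", "sagittal", "left_bending", "right_bending")
}

n_vertebrae <- 17L
n_endplates <- 34L
n_corners <- 68L

#' Build a landmark set tibble
#'
#' A landmark set is a tidy tibble with one row per annotated corner point
#' and columns `case_id`, `view`, `units`, `vertebra`, `corner`, `x`, `y`.
#' A complete single-view set has exactly 68 rows (17 vertebrae x 4 corners).
#' Rows are normalised to anatomical order (T1 cranial to L5 caudal, corners
#' ul, ur, ll, lr) regardless of input order.
#'
#' @param df Data frame with at least `vertebra`, `corner`, `x`, `y`; optional
#'   `case_id`, `view`, `units` columns override the arguments.
#' @param case_id Case identifier.
#' @param view One of `view_levels()`.
#' @param units `"px"` or `"mm"`. Angle computations are unit-invariant, so
#'   no conversion is ever applied.
#' @param validate If `TRUE` (default), abort on invariant violations.
#' @return A `landmark_set` tibble.
#' @export
landmark_set <- function(df, case_id = "case", view = "coronal", units = "px",
                         validate = TRUE) {
  df <- tibble::as_tibble(df)
  if (!"case_id" %in% names(df)) df$case_id <- case_id
  if (!"view" %in% names(df)) df$view <- view
  if (!"units" %in% names(df)) df$units <- units
  required <- c("case_id", "view", "units", "vertebra", "corner", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark set is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[required]
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df <- dplyr::arrange(
    df,
    .data$view,
    match(.data$vertebra, vertebra_levels()),
    match(.data$corner, corner_levels())
  )
  class(df) <- c("landmark_set", class(df))
  if (validate) {
    v <- validate_landmarks(df)
    if (nrow(v) > 0) {
      abort(paste0(
        "invalid landmark set:\n",
        paste0("  - [", v$view, "/", v$vertebra, "] ", v$rule, ": ",
               v$message, collapse = "\n")
      ))
    }
  }
  df
}

#' Validate a landmark set or multi-view case
#'
#' Checks every view present in `lm` against the landmark-set invariants and
#' returns the violations as data rather than raising: one row per violation
#' with the view, vertebra (or `NA` for set-level rules), a stable rule id
#' and a human-readable message. An empty tibble means the set is valid.
#'
#' Rules checked per view: known view/units tags, exactly 17 uniquely
#' labelled vertebrae with known labels, all four corners per vertebra
#' (68 points), finite coordinates, left corner strictly left of right
#' corner on both endplates, and superior corners above inferior corners
#' on average (y-down convention).
#'
#' @param lm Landmark tibble (one or several views; grouped by `view`).
#' @return Tibble with columns `view`, `vertebra`, `rule`, `message`.
#' @export
validate_landmarks <- function(lm) {
  lm <- tibble::as_tibble(lm)
  out <- list()
  bad <- function(view, vertebra, rule, message) {
    tibble::tibble(view = view, vertebra = vertebra, rule = rule,
                   message = message)
  }
  for (vw in unique(lm$view)) {
    sub <- lm[lm$view == vw, ]
    if (!vw %in% view_levels()) {
      out[[length(out) + 1L]] <- bad(vw, NA_character_, "unknown_view",
                                     paste0("view tag '", vw, "' not one of ",
                                            paste(view_levels(), collapse = "/")))
    }
    if (!all(sub$units %in% c("px", "mm"))) {
      out[[length(out) + 1L]] <- bad(vw, NA_character_, "unknown_units",
                                     "units must be 'px' or 'mm'")
    }
    unknown <- setdiff(unique(sub$vertebra), vertebra_levels())
    for (u in unknown) {
      out[[length(out) + 1L]] <- bad(vw, u, "unknown_vertebra",
                                     paste0("unknown vertebra label '", u, "'"))
    }
    missing_v <- setdiff(vertebra_levels(), unique(sub$vertebra))
    for (m in missing_v) {
      out[[length(out) + 1L]] <- bad(vw, m, "missing_vertebra",
                                     paste0("vertebra ", m, " absent"))
    }
    unknown_c <- setdiff(unique(sub$corner), corner_levels())
    for (u in unknown_c) {
      v <- sub$vertebra[sub$corner == u][1]
      out[[length(out) + 1L]] <- bad(vw, v, "unknown_corner",
                                     paste0("unknown corner '", u, "'"))
    }
    cnt <- table(factor(sub$vertebra, levels = vertebra_levels()),
                 factor(sub$corner, levels = corner_levels()))
    complete <- rowSums(cnt == 1L) == 4L
    dup <- rownames(cnt)[apply(cnt > 1L, 1, any)]
    for (v in dup) {
      off <- corner_levels()[cnt[v, ] > 1L]
      out[[length(out) + 1L]] <- bad(vw, v, "duplicate_corner",
                                     paste0("corner(s) ",
                                            paste(off, collapse = ","),
                                            " duplicated"))
    }
    part <- rownames(cnt)[!complete & rowSums(cnt) > 0 &
                            !rownames(cnt) %in% dup]
    for (v in part) {
      off <- corner_levels()[cnt[v, ] == 0L]
      out[[length(out) + 1L]] <- bad(vw, v, "missing_corner",
                                     paste0("corner(s) ",
                                            paste(off, collapse = ","),
                                            " absent"))
    }
    # geometric checks, vectorised over the vertebrae with complete corners
    ok_v <- rownames(cnt)[complete]
    geo <- sub[sub$vertebra %in% ok_v & sub$corner %in% corner_levels(), ]
    if (nrow(geo) > 0) {
      ord <- order(match(geo$vertebra, vertebra_levels()),
                   match(geo$corner, corner_levels()))
      geo <- geo[ord, ]
      x <- matrix(geo$x, nrow = 4); y <- matrix(geo$y, nrow = 4)
      labs <- geo$vertebra[seq(1, nrow(geo), by = 4)]
      nonfin <- !apply(is.finite(x) & is.finite(y), 2, all)
      for (v in labs[nonfin]) {
        out[[length(out) + 1L]] <- bad(vw, v, "nonfinite_coordinate",
                                       "corner coordinates must be finite")
      }
      bad_order <- !nonfin & (x[1, ] >= x[2, ] | x[3, ] >= x[4, ])
      for (v in labs[bad_order]) {
        out[[length(out) + 1L]] <- bad(vw, v, "corner_order",
                                       "left corner must lie strictly left of right corner")
      }
      bad_orient <- !nonfin & (y[1, ] + y[2, ] >= y[3, ] + y[4, ])
      for (v in labs[bad_orient]) {
        out[[length(out) + 1L]] <- bad(vw, v, "orientation",
                                       "superior corners must lie above inferior corners on average")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(view = character(), vertebra = character(),
                          rule = character(), message = character()))
  }
  dplyr::bind_rows(out)
}

#' Parse a landmark annotation file
#'
#' Reads one view's annotation from JSON or CSV text (schemas below) into a
#' validated `landmark_set` tibble, normalised to anatomical order.
#'
#' JSON schema (one object per view):
#' \preformatted{
#' {"case_id": "...", "view": "coronal", "units": "px",
#'  "vertebrae": {"T1": {"ul":[x,y],"ur":[x,y],"ll":[x,y],"lr":[x,y]}, ...}}
#' }
#' CSV schema: header `case_id,view,vertebra,corner,x,y`, 68 rows per view.
#'
#' @param content Text of the annotation, or a file path (for `read_landmarks`).
#' @param format `"json"` or `"csv"`; `read_landmarks` infers it from the
#'   file extension.
#' @return A validated `landmark_set` tibble.
#' @export
parse_landmarks <- function(content, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- tryCatch(jsonlite::fromJSON(content, simplifyVector = TRUE),
                    error = function(e) abort(paste0("malformed JSON: ",
                                                     conditionMessage(e))))
    for (f in c("view", "units", "vertebrae")) {
      if (is.null(obj[[f]])) abort(paste0("JSON missing field '", f, "'"))
    }
    rows <- purrr::imap(obj$vertebrae, function(corners, vlab) {
      purrr::imap(corners, function(pt, clab) {
        if (length(pt) != 2 || !is.numeric(pt)) {
          abort(paste0("malformed corner ", vlab, "/", clab,
                       ": expected [x, y]"))
        }
        tibble::tibble(vertebra = vlab, corner = clab,
                       x = pt[[1]], y = pt[[2]])
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    landmark_set(rows, case_id = obj$case_id %||% "case",
                 view = obj$view, units = obj$units)
  } else {
    df <- tryCatch(
      readr::read_csv(I(content), col_types = readr::cols(
        case_id = readr::col_character(), view = readr::col_character(),
        vertebra = readr::col_character(), corner = readr::col_character(),
        x = readr::col_double(), y = readr::col_double())),
      error = function(e) abort(paste0("malformed CSV: ", conditionMessage(e))))
    missing_cols <- setdiff(c("case_id", "view", "vertebra", "corner", "x", "y"),
                            names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("CSV missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    landmark_set(df)
  }
}

#' @rdname parse_landmarks
#' @param path File to read (`.json` or `.csv`).
#' @export
read_landmarks <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  parse_landmarks(paste(readLines(path, warn = FALSE), collapse = "\n"), format)
}

#' Serialise a landmark set
#'
#' Inverse of [parse_landmarks()]: `parse_landmarks(write_landmarks(s))`
#' reproduces `s` up to floating-point text representation. Full `digits = NA`
#' precision is used so the round trip is exact for typical coordinates.
#'
#' @param lm A single-view `landmark_set` tibble.
#' @param format `"json"` or `"csv"`.
#' @return A single string.
#' @export
write_landmarks <- function(lm, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(length(unique(lm$view)) == 1)
  if (format == "csv") {
    return(readr::format_csv(lm[c("case_id", "view", "vertebra",
                                  "corner", "x", "y")]))
  }
  verts <- split(lm, factor(lm$vertebra, levels = vertebra_levels()))
  vert_list <- purrr::map(verts, function(rows) {
    purrr::map(stats::setNames(corner_levels(), corner_levels()), function(cl) {
      c(rows$x[rows$corner == cl], rows$y[rows$corner == cl])
    })
  })
  jsonlite::toJSON(list(case_id = lm$case_id[1], view = lm$view[1],
                        units = lm$units[1], vertebrae = vert_list),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE) |>
    as.character()
}

#' @rdname write_landmarks
#' @param path Output file.
#' @export
write_landmarks_file <- function(lm, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  writeLines(write_landmarks(lm, format), path)
  invisible(path)
}

#' Assemble a multi-view case
#'
#' Binds up to four single-view landmark sets into one case tibble. The
#' coronal view is required; sagittal and bending views are optional and
#' downstream measurements degrade gracefully without them (Lenke typing
#' needs bending views, the sagittal modifier needs the sagittal view).
#'
#' @param coronal,sagittal,left_bending,right_bending `landmark_set` tibbles
#'   whose `view` tag must match the slot they are passed in.
#' @param case_id Optional case id override applied to all views.
#' @return A `case_views` tibble (all views stacked).
#' @export
case_views <- function(coronal, sagittal = NULL, left_bending = NULL,
                       right_bending = NULL, case_id = NULL) {
  slots <- list(coronal = coronal, sagittal = sagittal,
                left_bending = left_bending, right_bending = right_bending)
  slots <- slots[!vapply(slots, is.null, logical(1))]
  for (slot in names(slots)) {
    vw <- unique(slots[[slot]]$view)
    if (!identical(vw, slot)) {
      abort(paste0("view tagged '", paste(vw, collapse = ","),
                   "' passed in the ", slot, " slot"))
    }
  }
  out <- dplyr::bind_rows(slots)
  if (!is.null(case_id)) out$case_id <- case_id
  class(out) <- c("case_views", setdiff(class(out), "case_views"))
  out
}

#' Validate a multi-view case
#'
#' Runs [validate_landmarks()] on every view and additionally reports a
#' missing coronal view and duplicated view tags. Violations are data, not
#' errors; an empty result means the case is measurable.
#'
#' @param case A `case_views` tibble (or any stacked landmark tibble).
#' @return Violations tibble (`view`, `vertebra`, `rule`, `message`).
#' @export
validate_case <- function(case) {
  v <- validate_landmarks(case)
  if (!"coronal" %in% unique(case$view)) {
    v <- dplyr::bind_rows(v, tibble::tibble(
      view = "coronal", vertebra = NA_character_, rule = "missing_view",
      message = "coronal view is required"))
  }
  v
}

#' Extract one view from a case
#' @param case A stacked multi-view landmark tibble.
#' @param view View name.
#' @return The single-view `landmark_set`, or `NULL` if absent.
#' @export
get_view <- function(case, view) {
  sub <- case[case$view == view, ]
  if (nrow(sub) == 0) return(NULL)
  landmark_set(sub, validate = FALSE)
}
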