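# Initialization records and measurement CSV I/O.
#
# The initialization mirrors the manual step of the method: the user marks a
# line AB on the bottom boundary of the fascicle band (deep aponeurosis) plus
# a box thickness, a line CD on its top boundary (superficial aponeurosis)
# plus a thickness, and a fascicle-direction line EF. All coordinates are
# 0-based (x, y) pixel pairs.

seg_as_matrix <- function(p, what) {
  m <- if (is.matrix(p)) {
    apply(p, 2, as.numeric)
  } else {
    # list of two (x, y) pairs, as read from YAML/JSON
    matrix(as.numeric(unlist(p)), ncol = 2, byrow = TRUE)
  }
  if (nrow(m) != 2L || any(!is.finite(m))) {
    stop(sprintf("%s must be two finite (x, y) points", what), call. = FALSE)
  }
  colnames(m) <- c("x", "y")
  m
}

seg_angle <- function(seg) atan2(seg[2, 2] - seg[1, 2], seg[2, 1] - seg[1, 1])

#' Construct and validate an initialization record
#'
#' @param deep_line 2x2 matrix (rows = points, cols = x, y): segment AB along
#'   the bottom boundary of the fascicle band.
#' @param deep_thickness Positive box thickness in px (extends downwards,
#'   enclosing the deep aponeurosis).
#' @param superficial_line Segment CD along the top boundary of the fascicle
#'   band.
#' @param superficial_thickness Positive box thickness in px (extends
#'   upwards).
#' @param fascicle_line Segment EF parallel to the fascicle direction.
#' @param frame_shape Optional `c(rows, cols)`; when given, all points are
#'   checked to lie inside the frame.
#' @return An object of class `init_record`.
#' @export
init_record <- function(deep_line, deep_thickness, superficial_line,
                        superficial_thickness, fascicle_line,
                        frame_shape = NULL) {
  deep_line <- seg_as_matrix(deep_line, "deep_line")
  superficial_line <- seg_as_matrix(superficial_line, "superficial_line")
  fascicle_line <- seg_as_matrix(fascicle_line, "fascicle_line")
  for (nm in c("deep_thickness", "superficial_thickness")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a positive scalar", nm), call. = FALSE)
    }
  }
  segs <- list(deep_line = deep_line, superficial_line = superficial_line,
               fascicle_line = fascicle_line)
  for (nm in names(segs)) {
    s <- segs[[nm]]
    if (sqrt(sum((s[2, ] - s[1, ])^2)) < 1e-9) {
      stop(sprintf("%s is a degenerate (zero-length) segment", nm), call. = FALSE)
    }
  }
  if (!is.null(frame_shape)) {
    nr <- frame_shape[1]; nc <- frame_shape[2]
    for (nm in names(segs)) {
      s <- segs[[nm]]
      if (any(s[, "x"] < 0 | s[, "x"] > nc - 1 | s[, "y"] < 0 | s[, "y"] > nr - 1)) {
        stop(sprintf("%s has a point outside the frame bounds", nm), call. = FALSE)
      }
    }
  }
  if (mean(deep_line[, "y"]) <= mean(superficial_line[, "y"])) {
    stop("deep_line must lie below superficial_line (larger y)", call. = FALSE)
  }
  min_angle <- 1e-3
  for (nm in c("deep_line", "superficial_line")) {
    d <- abs(seg_angle(fascicle_line) - seg_angle(segs[[nm]]))
    d <- min(d %% pi, pi - d %% pi)
    if (d <= min_angle) {
      stop(sprintf("fascicle line parallel to aponeurosis (%s)", nm), call. = FALSE)
    }
  }
  structure(
    list(
      deep_line = deep_line, deep_thickness = deep_thickness,
      superficial_line = superficial_line,
      superficial_thickness = superficial_thickness,
      fascicle_line = fascicle_line
    ),
    class = "init_record"
  )
}

#' @export
print.init_record <- function(x, ...) {
  cat("<init_record>\n")
  cat(sprintf("  deep line AB: (%g,%g)-(%g,%g), thickness %g px\n",
              x$deep_line[1, 1], x$deep_line[1, 2], x$deep_line[2, 1],
              x$deep_line[2, 2], x$deep_thickness))
  cat(sprintf("  superficial line CD: (%g,%g)-(%g,%g), thickness %g px\n",
              x$superficial_line[1, 1], x$superficial_line[1, 2],
              x$superficial_line[2, 1], x$superficial_line[2, 2],
              x$superficial_thickness))
  cat(sprintf("  fascicle line EF: (%g,%g)-(%g,%g)\n",
              x$fascicle_line[1, 1], x$fascicle_line[1, 2],
              x$fascicle_line[2, 1], x$fascicle_line[2, 2]))
  invisible(x)
}

#' Read an initialization record from a YAML or JSON config file
#'
#' The file must contain keys `deep_line`, `deep_thickness`,
#' `superficial_line`, `superficial_thickness`, `fascicle_line`; each line is
#' a list of two `(x, y)` pixel pairs (0-based).
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @param frame_shape Optional `c(rows, cols)` for bounds checking.
#' @return An [init_record].
#' @export
load_init <- function(path, frame_shape = NULL) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  req <- c("deep_line", "deep_thickness", "superficial_line",
           "superficial_thickness", "fascicle_line")
  missing <- setdiff(req, names(cfg))
  if (length(missing) > 0) {
    stop(sprintf("config missing key(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  init_record(
    deep_line = cfg$deep_line,
    deep_thickness = cfg$deep_thickness,
    superficial_line = cfg$superficial_line,
    superficial_thickness = cfg$superficial_thickness,
    fascicle_line = cfg$fascicle_line,
    frame_shape = frame_shape
  )
}

#' Write an initialization record to a YAML config file
#'
#' @param init An [init_record].
#' @param path Output file path (`.yaml`).
#' @export
write_init <- function(init, path) {
  stopifnot(inherits(init, "init_record"))
  seg_list <- function(s) list(as.numeric(s[1, ]), as.numeric(s[2, ]))
  yaml::write_yaml(list(
    deep_line = seg_list(init$deep_line),
    deep_thickness = init$deep_thickness,
    superficial_line = seg_list(init$superficial_line),
    superficial_thickness = init$superficial_thickness,
    fascicle_line = seg_list(init$fascicle_line)
  ), path)
  invisible(path)
}

#' Write a measurement series to CSV
#'
#' Columns: `frame, fl_mm, pa_deg, ax, ay, bx, by, n_inliers`. Floats are
#' written with enough digits for a lossless round trip at 8 significant
#' digits.
#'
#' @param series Measurement tibble as returned by [run_pipeline()].
#' @param path Output CSV path.
#' @export
write_measurements <- function(series, path) {
  if (is.null(series) || nrow(series) == 0L) {
    stop("empty measurement series", call. = FALSE)
  }
  cols <- c("frame", "fl_mm", "pa_deg", "ax", "ay", "bx", "by", "n_inliers")
  df <- as.data.frame(series)[, cols]
  num <- setdiff(cols, c("frame", "n_inliers"))
  for (nm in num) df[[nm]] <- trimws(formatC(df[[nm]], digits = 8, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement series CSV written by [write_measurements()]
#'
#' Also accepts ground-truth CSVs with columns `frame, fl_mm, pa_deg`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "fl_mm", "pa_deg") %in% names(df))) {
    stop("not a measurement CSV (needs frame, fl_mm, pa_deg)", call. = FALSE)
  }
  tibble::as_tibble(df)
}
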