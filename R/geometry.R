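# Fascicle geometry: insertion points, fascicle length, pennation angle.

#' Intersect the fascicle direction line with a fitted boundary line
#'
#' Both lines are extended to infinity; the intersection may fall outside the
#' image (the caller flags extrapolated frames). Near-parallel configurations
#' (angle below 1e-3 rad) are an error.
#'
#' @param line 2x2 matrix, fascicle segment EF as rows `(x, y)`.
#' @param boundary A `boundary_line` (slope/intercept), or a list with
#'   `slope` and `intercept`.
#' @return Numeric `c(x, y)` of the intersection.
#' @export
intersect_line_boundary <- function(line, boundary) {
  line <- as.matrix(line)
  d <- line[2, ] - line[1, ]
  if (sqrt(sum(d^2)) < 1e-12) stop("degenerate fascicle segment", call. = FALSE)
  m <- boundary$slope
  b <- boundary$intercept
  ang <- abs(atan2(d[2], d[1]) - atan(m))
  ang <- min(ang %% pi, pi - ang %% pi)
  if (ang <= 1e-3) stop("near-parallel lines: no stable intersection", call. = FALSE)
  # solve line[1] + t d  on  y = m x + b
  t <- (m * line[1, 1] + b - line[1, 2]) / (d[2] - m * d[1])
  c(x = line[1, 1] + t * d[1], y = line[1, 2] + t * d[2])
}

#' Fascicle length from the two insertion points
#'
#' Euclidean distance between the superficial insertion point A and the deep
#' insertion point B, scaled by the calibration.
#'
#' @param A,B Numeric `c(x, y)` pixel coordinates.
#' @param mm_per_pixel Positive calibration.
#' @return Fascicle length in mm.
#' @export
compute_fl <- function(A, B, mm_per_pixel) {
  d <- sqrt(sum((A - B)^2))
  if (d < 1e-12) stop("coincident insertion points", call. = FALSE)
  d * mm_per_pixel
}

#' Pennation angle between the fascicle line and the deep aponeurosis
#'
#' The acute angle between the fascicle direction and the fitted deep
#' boundary line, in degrees in (0, 90].
#'
#' @param line 2x2 matrix, fascicle segment as rows `(x, y)`; or a length-2
#'   direction vector.
#' @param deep A `boundary_line` for the deep aponeurosis.
#' @return Angle in degrees.
#' @export
compute_pa <- function(line, deep) {
  u <- if (is.matrix(line)) as.numeric(line[2, ] - line[1, ]) else as.numeric(line)
  if (sqrt(sum(u^2)) < 1e-12) stop("degenerate fascicle direction", call. = FALSE)
  v <- c(1, deep$slope)
  cosang <- abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}
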