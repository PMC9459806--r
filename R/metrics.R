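# Agreement metrics between paired measurement series, and the
# initialization-sensitivity harness.

#' Root mean squared error between two paired series
#'
#' @param a,b Numeric vectors of equal length, paired by frame.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("series length mismatch", call. = FALSE)
  if (length(a) < 1L) stop("empty series", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Pairwise within-subject coefficient of variation (percent)
#'
#' For each pair `(a_i, b_i)` the standard deviation is `|a_i - b_i| / sqrt(2)`
#' and the CV is that SD over the pair mean; the returned CoV is the mean CV
#' across pairs, times 100. This is the pairwise within-subject CV standard
#' in the measurement-reliability literature; other CoV definitions give
#' different numbers, so comparisons across software should check the
#' formula.
#'
#' @param a,b Numeric vectors of equal length with positive pair means.
#' @return CoV in percent.
#' @export
cov_paired <- function(a, b) {
  if (length(a) != length(b)) stop("series length mismatch", call. = FALSE)
  m <- (a + b) / 2
  if (any(m <= 0)) stop("non-positive pair mean", call. = FALSE)
  s <- abs(a - b) / sqrt(2)
  mean(s / m) * 100
}

#' Agreement report between two measurement series
#'
#' @param auto,ref Tibbles/data frames with columns `fl_mm` and `pa_deg`
#'   (e.g. from [run_pipeline()] and a ground-truth CSV), paired by row.
#' @return One-row tibble: `rmse_fl`, `rmse_pa`, `cov_fl`, `cov_pa`,
#'   `n_pairs`.
#' @export
agreement_report <- function(auto, ref) {
  if (nrow(auto) != nrow(ref)) stop("series length mismatch", call. = FALSE)
  tibble::tibble(
    rmse_fl = rmse(auto$fl_mm, ref$fl_mm),
    rmse_pa = rmse(auto$pa_deg, ref$pa_deg),
    cov_fl = cov_paired(auto$fl_mm, ref$fl_mm),
    cov_pa = cov_paired(auto$pa_deg, ref$pa_deg),
    n_pairs = nrow(auto)
  )
}

#' Initialization-sensitivity experiment harness
#'
#' Re-runs the full pipeline with perturbed initializations of the fascicle
#' direction line -- signed parallel shifts along the deep boundary, small
#' rotations obtained by displacing E and F in opposite directions along the
#' line normal -- and with perturbed aponeurosis box thicknesses, all with
#' the same RNG seed as the reference run. Reports per-frame differences to
#' the reference run and, when ground truth is supplied, RMSE against it.
#'
#' @param video A [us_video].
#' @param init Reference [init_record].
#' @param shifts_px Signed parallel shifts in px (default the published
#'   scenario set `c(-20, -10, 10, 20)`).
#' @param rotations_px Endpoint displacements `d` in px (E by `+d`, F by
#'   `-d`; default `c(-10, 10)`).
#' @param thickness_deltas Box-thickness changes in px (default none).
#' @param ground_truth Optional tibble with `fl_mm`, `pa_deg` per frame.
#' @param seed Integer seed shared by all runs.
#' @param params Pipeline parameters, see [pipeline_params()].
#' @return Long tibble: `perturbation`, `value`, `frame`, `fl_mm`, `pa_deg`,
#'   `d_fl`, `d_pa` (differences to the reference run), and `rmse_fl`,
#'   `rmse_pa` per perturbation when ground truth is given.
#' @export
run_sensitivity <- function(video, init, shifts_px = c(-20, -10, 10, 20),
                            rotations_px = c(-10, 10),
                            thickness_deltas = numeric(0),
                            ground_truth = NULL, seed = 1L,
                            params = pipeline_params()) {
  perturb_init <- function(init, shift = 0, rot = 0, dth = 0) {
    E <- init$fascicle_line[1, ]
    F <- init$fascicle_line[2, ]
    if (shift != 0) {
      dd <- c(1, line_through(init$deep_line[1, ], init$deep_line[2, ])[1])
      dd <- dd / sqrt(sum(dd^2))
      E <- E + shift * dd
      F <- F + shift * dd
    }
    if (rot != 0) {
      u <- F - E
      u <- u / sqrt(sum(u^2))
      nrml <- c(-u[2], u[1])
      E <- E + rot * nrml
      F <- F - rot * nrml
    }
    init_record(init$deep_line, init$deep_thickness + dth,
                init$superficial_line, init$superficial_thickness + dth,
                rbind(E, F))
  }
  scenarios <- list(list(perturbation = "reference", value = 0,
                         init = init))
  for (s in shifts_px) {
    scenarios[[length(scenarios) + 1L]] <-
      list(perturbation = "shift_px", value = s, init = perturb_init(init, shift = s))
  }
  for (r in rotations_px) {
    scenarios[[length(scenarios) + 1L]] <-
      list(perturbation = "rotation_px", value = r, init = perturb_init(init, rot = r))
  }
  for (d in thickness_deltas) {
    scenarios[[length(scenarios) + 1L]] <-
      list(perturbation = "thickness_px", value = d, init = perturb_init(init, dth = d))
  }
  rows <- vector("list", length(scenarios))
  ref_series <- NULL
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    series <- run_pipeline(video, sc$init, params = params, seed = seed)
    if (i == 1L) ref_series <- series
    df <- tibble::tibble(
      perturbation = sc$perturbation, value = sc$value,
      frame = series$frame, fl_mm = series$fl_mm, pa_deg = series$pa_deg,
      d_fl = series$fl_mm - ref_series$fl_mm,
      d_pa = series$pa_deg - ref_series$pa_deg
    )
    if (!is.null(ground_truth)) {
      df$rmse_fl <- rmse(series$fl_mm, ground_truth$fl_mm)
      df$rmse_pa <- rmse(series$pa_deg, ground_truth$pa_deg)
    }
    rows[[i]] <- df
  }
  do.call(rbind, rows)
}
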