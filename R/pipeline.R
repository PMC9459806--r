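# Full measurement pipeline: initialization -> particle-filter aponeurosis
# tracking -> level-set delineation and boundary fitting -> fascicle-band
# distortion tracking -> fascicle length / pennation angle per frame.

#' Bundle of all pipeline parameters
#'
#' @param mcv [mcv_params()] for aponeurosis delineation.
#' @param pf [pf_params()] for the particle filter.
#' @param kaze [kaze_params()] for interest-point detection.
#' @param klt [klt_params()] for optical-flow point tracking.
#' @param msac [msac_params()] for affine estimation.
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(mcv = mcv_params(), pf = pf_params(),
                            kaze = kaze_params(), klt = klt_params(),
                            msac = msac_params()) {
  structure(list(mcv = mcv, pf = pf, kaze = kaze, klt = klt, msac = msac),
            class = "pipeline_params")
}

# The two tracking boxes implied by an init record: parallelograms extruded
# vertically from the user lines by the box thickness (downwards for the
# deep aponeurosis, upwards for the superficial one). Corners are ordered
# p1 -> p2 along the top edge so state_from_box sees a positive height.
boxes_from_init <- function(init) {
  th_d <- c(0, init$deep_thickness)
  th_s <- c(0, init$superficial_thickness)
  deep <- rbind(init$deep_line[1, ], init$deep_line[2, ],
                init$deep_line[2, ] + th_d, init$deep_line[1, ] + th_d)
  sup <- rbind(init$superficial_line[1, ] - th_s, init$superficial_line[2, ] - th_s,
               init$superficial_line[2, ], init$superficial_line[1, ])
  list(superficial = sup, deep = deep)
}

#' Run the full fascicle-tracking pipeline on a video
#'
#' Frame 0 is measured from the initialization geometry (aponeurosis
#' boundaries delineated by the level-set model inside the user boxes, the
#' fascicle line intersected with the fitted boundary lines). For each
#' subsequent frame the particle filter propagates both boxes, the level-set
#' model re-delineates the aponeuroses, the fascicle-band distortion between
#' the previous (reference) and current (tracked) frame propagates the
#' fascicle direction line, and the insertion points, fascicle length and
#' pennation angle are recomputed; the tracked frame then becomes the new
#' reference. Stage failures in a frame are flagged and the last valid
#' transform or boundary is carried forward.
#'
#' @param video A [us_video].
#' @param init An [init_record].
#' @param params [pipeline_params()].
#' @param seed Integer seed; all stochastic stages (particle filter, MSAC)
#'   draw from one stream seeded here, making runs reproducible.
#' @return Tibble with one row per frame: `frame`, `fl_mm`, `pa_deg`, `ax`,
#'   `ay`, `bx`, `by`, `n_inliers`, `flags`. Per-frame fascicle segments and
#'   boundary lines are attached as attribute `"details"`.
#' @export
run_pipeline <- function(video, init, params = pipeline_params(), seed = 1L) {
  stopifnot(inherits(video, "us_video"), inherits(init, "init_record"))
  set.seed(as.integer(seed))
  n <- length(video$frames)
  mpp <- video$frames[[1]]$mm_per_pixel
  shape <- dim(video$frames[[1]]$pixels)
  boxes0 <- boxes_from_init(init)

  pf_sup <- track_box(video, boxes0$superficial, params$pf)
  pf_deep <- track_box(video, boxes0$deep, params$pf)

  measure_frame <- function(frame, ef, line_sup, line_deep) {
    A <- intersect_line_boundary(ef, line_sup)
    B <- intersect_line_boundary(ef, line_deep)
    list(A = A, B = B,
         fl = compute_fl(A, B, mpp),
         pa = compute_pa(rbind(A, B), line_deep))
  }
  delineate_or <- function(frame, box, side, fallback) {
    tryCatch(
      list(line = delineate_boundary(frame, box, side, params$mcv)$line, ok = TRUE),
      error = function(e) list(line = fallback, ok = FALSE)
    )
  }

  d0_sup <- delineate_boundary(video$frames[[1]], boxes0$superficial,
                               "superficial", params$mcv)
  d0_deep <- delineate_boundary(video$frames[[1]], boxes0$deep, "deep", params$mcv)
  line_sup <- d0_sup$line
  line_deep <- d0_deep$line
  ef <- init$fascicle_line

  fl <- pa <- ax <- ay <- bx <- by <- rep(NA_real_, n)
  n_inl <- rep(NA_integer_, n)
  flags <- character(n)
  efs <- vector("list", n)
  lines <- vector("list", n)

  m0 <- measure_frame(video$frames[[1]], ef, line_sup, line_deep)
  fl[1] <- m0$fl; pa[1] <- m0$pa
  ax[1] <- m0$A[1]; ay[1] <- m0$A[2]; bx[1] <- m0$B[1]; by[1] <- m0$B[2]
  efs[[1]] <- ef
  lines[[1]] <- list(superficial = line_sup, deep = line_deep)
  A_prev <- m0$A; B_prev <- m0$B
  last_transform <- cbind(diag(2), c(0, 0))

  if (n > 1) {
    for (t in 2:n) {
      frm <- video$frames[[t]]
      fflags <- character(0)
      ds <- delineate_or(frm, pf_sup$boxes[[t]], "superficial", line_sup)
      dd <- delineate_or(frm, pf_deep$boxes[[t]], "deep", line_deep)
      if (!ds$ok || !dd$ok) fflags <- c(fflags, "mcv_failed")
      line_sup <- ds$line
      line_deep <- dd$line

      transform <- last_transform
      inl <- NA_integer_
      step_ok <- FALSE
      ref <- video$frames[[t - 1]]
      pts <- tryCatch({
        roi <- define_roi(A_prev, B_prev, shape)
        detect_kaze(ref, roi, params$kaze)
      }, error = function(e) NULL)
      if (!is.null(pts)) {
        tr <- track_points(ref, frm, pts[, 1:2, drop = FALSE], params$klt, mpp)
        if (sum(tr$valid) >= 3L) {
          est <- tryCatch(
            estimate_affine_msac(pts[tr$valid, 1:2, drop = FALSE],
                                 tr$points[tr$valid, , drop = FALSE],
                                 params$msac),
            error = function(e) NULL
          )
          if (!is.null(est)) {
            transform <- est$transform
            inl <- sum(est$inliers)
            step_ok <- TRUE
          }
        }
      }
      if (!step_ok) fflags <- c(fflags, "distortion_carried")
      last_transform <- transform
      ef <- propagate_line(ef, transform)

      m <- tryCatch(measure_frame(frm, ef, line_sup, line_deep),
                    error = function(e) NULL)
      if (is.null(m)) {
        fflags <- c(fflags, "measurement_failed")
        fl[t] <- fl[t - 1]; pa[t] <- pa[t - 1]
        ax[t] <- ax[t - 1]; ay[t] <- ay[t - 1]
        bx[t] <- bx[t - 1]; by[t] <- by[t - 1]
      } else {
        fl[t] <- m$fl; pa[t] <- m$pa
        ax[t] <- m$A[1]; ay[t] <- m$A[2]; bx[t] <- m$B[1]; by[t] <- m$B[2]
        if (m$A[1] < 0 || m$A[1] > shape[2] - 1 || m$A[2] < 0 ||
            m$A[2] > shape[1] - 1 || m$B[1] < 0 || m$B[1] > shape[2] - 1 ||
            m$B[2] < 0 || m$B[2] > shape[1] - 1) {
          fflags <- c(fflags, "extrapolated")
        }
        A_prev <- m$A; B_prev <- m$B
      }
      n_inl[t] <- inl
      flags[t] <- paste(fflags, collapse = ";")
      efs[[t]] <- ef
      lines[[t]] <- list(superficial = line_sup, deep = line_deep)
    }
  }
  out <- tibble::tibble(frame = seq_len(n) - 1L, fl_mm = fl, pa_deg = pa,
                        ax = ax, ay = ay, bx = bx, by = by,
                        n_inliers = n_inl, flags = flags)
  attr(out, "details") <- list(fascicle_lines = efs, boundary_lines = lines,
                               pf_superficial = pf_sup$diagnostics,
                               pf_deep = pf_deep$diagnostics,
                               mm_per_pixel = mpp, seed = as.integer(seed))
  out
}
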