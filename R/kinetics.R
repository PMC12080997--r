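#' Frame schedule for a dynamic PET acquisition
#'
#' @param start_min Frame start times, minutes, strictly increasing.
#' @param duration_min Frame durations, minutes, positive; frames must not
#'   overlap.
#' @return A `frame_schedule` object with computed `mid_min`.
#' @examples
#' sched <- frame_schedule(0:79, rep(1, 80))   # eighty 1-min frames
#' head(sched$mid_min)
#' @export
frame_schedule <- function(start_min, duration_min) {
  start_min <- as.numeric(start_min)
  duration_min <- as.numeric(duration_min)
  if (length(start_min) != length(duration_min)) {
    stop("start_min and duration_min must have equal length")
  }
  if (any(duration_min <= 0)) stop("frame durations must be positive")
  if (any(diff(start_min) <= 0)) stop("frame starts must be strictly increasing")
  ends <- start_min + duration_min
  if (any(ends[-length(ends)] > start_min[-1] + 1e-9)) {
    stop("frames overlap")
  }
  structure(list(start_min = start_min, duration_min = duration_min,
                 mid_min = start_min + duration_min / 2),
            class = "frame_schedule")
}

#' Construct a dynamic image
#'
#' A 4D intensity array with its acquisition timing: a [frame_schedule()] for
#' PET, or a repetition time (seconds) for BOLD. BOLD volume midpoints are
#' placed at `(k - 1/2) * TR`.
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param timing A `frame_schedule` (PET) or a single repetition time in
#'   seconds (BOLD).
#' @param voxel_size_mm Numeric length-3.
#' @param modality `"PET"` or `"BOLD"`.
#' @return A `dynamic_image` object.
#' @export
dynamic_image <- function(data, timing, voxel_size_mm = c(1, 1, 1),
                          modality = c("PET", "BOLD")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  if (any(!is.finite(data))) stop("image intensities must be finite")
  n_frames <- dim(data)[4]
  if (inherits(timing, "frame_schedule")) {
    if (length(timing$start_min) != n_frames) {
      stop("frame schedule length (", length(timing$start_min),
           ") != number of frames (", n_frames, ")")
    }
  } else if (is.numeric(timing) && length(timing) == 1L && timing > 0) {
    # repetition time in seconds
  } else {
    stop("timing must be a frame_schedule or a positive repetition time (s)")
  }
  structure(list(data = data, timing = timing,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 modality = modality),
            class = "dynamic_image")
}

#' Frame/volume midpoint times of a dynamic image, in minutes
#' @param image A `dynamic_image`.
#' @return Numeric vector of midpoints (minutes).
#' @export
frame_mid_min <- function(image) {
  if (inherits(image$timing, "frame_schedule")) {
    image$timing$mid_min
  } else {
    n <- dim(image$data)[4]
    (seq_len(n) - 0.5) * image$timing / 60
  }
}

#' Framewise DVR-1 binding potential
#'
#' Computes the non-displaceable binding potential BP_ND = DVR - 1 frame by
#' frame as the instantaneous target/reference activity ratio minus one,
#'
#'   BP(r, t) = A(r, t) / A(ref, t) - 1 ,
#'
#' which equals (V_T - V_ND)/V_ND at the secular equilibrium established by a
#' bolus-plus-constant-infusion protocol. The reference row is removed from
#' the output.
#'
#' @param ts A `regional_ts` containing the reference region as one of its
#'   rows (matched by row abbreviation).
#' @param reference Abbreviation of the reference region (default `"Cer"`,
#'   cerebellar grey matter).
#' @return A `bp_series` object: region-by-frame BP_ND values.
#' @examples
#' sched <- frame_schedule(0:9, rep(1, 10))
#' vals <- rbind(A = rep(30, 10), Cer = rep(10, 10))
#' ts <- regional_ts(vals, c(1L, 49L), sched$mid_min, "PET",
#'                   abbreviations = c("A", "Cer"))
#' framewise_bpnd(ts)$values[1, 1]   # 2
#' @export
framewise_bpnd <- function(ts, reference = "Cer") {
  stopifnot(inherits(ts, "regional_ts"))
  abbrs <- rownames(ts$values)
  ref_row <- which(abbrs == reference)
  if (length(ref_row) != 1L) {
    stop("reference region '", reference, "' not found exactly once among rows")
  }
  ref <- ts$values[ref_row, ]
  bad <- which(ref <= 0)
  if (length(bad) > 0L) {
    stop("non-positive reference activity in frame(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (t = ", round(ts$frame_mid_min[bad[1L]], 2), " min)")
  }
  values <- sweep(ts$values[-ref_row, , drop = FALSE], 2, ref, "/") - 1
  bp_series(values,
            region_positions = ts$region_positions[-ref_row],
            frame_mid_min = ts$frame_mid_min,
            reference = reference)
}

#' Construct a BP_ND time-series object
#'
#' @param values Region-by-frame DVR-1 matrix (unitless).
#' @param region_positions Integer positions.
#' @param frame_mid_min Frame midpoints, minutes.
#' @param reference Reference-region abbreviation (not among rows).
#' @param retained_window_min Length-2 window actually retained, minutes.
#' @return A `bp_series` object.
#' @export
bp_series <- function(values, region_positions, frame_mid_min,
                      reference = "Cer", retained_window_min = NULL) {
  values <- as.matrix(values)
  if (!is.null(rownames(values)) && reference %in% rownames(values)) {
    stop("reference region must not appear among the rows")
  }
  if (is.null(retained_window_min)) {
    retained_window_min <- range(frame_mid_min)
  }
  structure(list(values = values,
                 region_positions = as.integer(region_positions),
                 frame_mid_min = as.numeric(frame_mid_min),
                 reference = reference,
                 retained_window_min = as.numeric(retained_window_min),
                 modality = "PET"),
            class = c("bp_series"))
}

#' @export
print.bp_series <- function(x, ...) {
  cat("<bp_series> ", nrow(x$values), " regions x ", ncol(x$values),
      " frames, reference = ", x$reference, ", window = [",
      paste(round(x$retained_window_min, 1), collapse = ", "), "] min\n",
      sep = "")
  invisible(x)
}

# linear-spline design matrix: continuous piecewise-linear basis with knots
# every `knot_interval` from `t0`; hinge terms only for interior knots
spline_design <- function(t, t0, knot_interval) {
  knots <- seq(t0, max(t), by = knot_interval)
  interior <- knots[knots > t0 & knots < max(t)]
  X <- cbind(1, t - t0)
  for (k in interior) X <- cbind(X, pmax(0, t - k))
  X
}

#' Discard early frames and piecewise-linearly detrend a BP_ND series
#'
#' The first `discard_min` minutes (perfusion-dominated uptake) are dropped;
#' each region's remaining series is detrended by subtracting a least-squares
#' piecewise-linear fit with knots every `knot_interval_min` minutes aligned
#' to the retained-window start. The default fit is a continuous linear
#' spline; `continuous = FALSE` fits an independent line per segment instead.
#' Residuals have zero mean per region.
#'
#' @param bp A `bp_series`.
#' @param discard_min Minutes discarded from the start of the scan.
#' @param knot_interval_min Knot spacing, minutes.
#' @param continuous Logical; continuous spline (default) or independent
#'   per-segment lines.
#' @return A detrended `bp_series` whose time axis starts at `discard_min`.
#' @export
discard_and_detrend <- function(bp, discard_min = 20, knot_interval_min = 20,
                                continuous = TRUE) {
  stopifnot(inherits(bp, "bp_series"))
  keep <- bp$frame_mid_min >= discard_min
  if (!any(keep)) stop("no frames left after discarding the first ",
                       discard_min, " min")
  t <- bp$frame_mid_min[keep]
  Y <- bp$values[, keep, drop = FALSE]
  span <- max(t) - min(t)
  single_line <- span < 2 * knot_interval_min
  if (single_line) {
    warning("retained series shorter than two knot intervals; ",
            "fitting a single line")
  }
  if (continuous || single_line) {
    X <- if (single_line) cbind(1, t - discard_min)
         else spline_design(t, discard_min, knot_interval_min)
    beta <- solve(crossprod(X), crossprod(X, t(Y)))
    resid <- Y - t(X %*% beta)
  } else {
    knots <- seq(discard_min, max(t), by = knot_interval_min)
    if (knots[length(knots)] < max(t)) knots <- c(knots, max(t))
    resid <- Y
    for (i in seq_len(length(knots) - 1L)) {
      last <- i == length(knots) - 1L
      in_seg <- t >= knots[i] & (if (last) t <= knots[i + 1L] else t < knots[i + 1L])
      if (sum(in_seg) < 2L) next
      Xs <- cbind(1, t[in_seg])
      beta <- solve(crossprod(Xs), crossprod(Xs, t(Y[, in_seg, drop = FALSE])))
      resid[, in_seg] <- Y[, in_seg, drop = FALSE] - t(Xs %*% beta)
    }
  }
  out <- bp
  out$values <- resid
  out$frame_mid_min <- t
  out$retained_window_min <- c(discard_min, max(bp$retained_window_min))
  out
}

#' Static uptake image from a dynamic PET scan
#'
#' Sums the frames whose midpoints fall in the half-open window
#' `[start, end)` and optionally scales the result to a whole-brain mean of
#' one (the normalization applied before between-period t-maps).
#'
#' @param image A PET `dynamic_image`.
#' @param window_min Length-2 numeric, minutes.
#' @param normalization `"whole_brain_mean"` (default) or `"none"`.
#' @param mask Optional 3D logical array defining the brain; defaults to all
#'   voxels.
#' @return A `static_image` object: 3D `data`, `window_min`, `normalization`.
#' @export
static_uptake <- function(image, window_min,
                          normalization = c("whole_brain_mean", "none"),
                          mask = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(image, "dynamic_image"))
  mids <- frame_mid_min(image)
  sel <- mids >= window_min[1] & mids < window_min[2]
  if (!any(sel)) stop("no frames with midpoints in [", window_min[1], ", ",
                      window_min[2], ")")
  d <- dim(image$data)
  mat <- matrix(image$data, nrow = prod(d[1:3]), ncol = d[4])
  s <- rowSums(mat[, sel, drop = FALSE])
  vol <- array(s, dim = d[1:3])
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (normalization == "whole_brain_mean") {
    m <- mean(vol[mask])
    if (m == 0) stop("in-mask mean is zero; cannot normalize")
    vol <- vol / m
  }
  structure(list(data = vol, window_min = as.numeric(window_min),
                 normalization = normalization, mask = mask),
            class = "static_image")
}
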