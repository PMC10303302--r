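#' Construct a polar cross-section image
#'
#' Greyscale IVUS-like cross-section resampled to polar coordinates: rows are
#' angle bins, columns are radius bins, intensities increase from the dark
#' lumen to the bright vessel wall.
#'
#' @param intensity Numeric matrix, `angular_bins x radial_bins`, finite.
#' @param mm_per_radius_bin Radial pixel size (mm per bin), positive.
#' @return An object of class `polar_image`.
#' @export
polar_image <- function(intensity, mm_per_radius_bin) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix (angle x radius).")
  }
  if (nrow(intensity) < 8L || ncol(intensity) < 8L) {
    abort("Polar images need at least 8 angular and 8 radial bins.")
  }
  if (!all(is.finite(intensity))) abort("Intensities must be finite.")
  if (!is.numeric(mm_per_radius_bin) || mm_per_radius_bin <= 0) {
    abort("`mm_per_radius_bin` must be a positive scalar.")
  }
  structure(
    list(intensity = intensity,
         angular_bins = nrow(intensity),
         radial_bins = ncol(intensity),
         mm_per_radius_bin = mm_per_radius_bin),
    class = "polar_image"
  )
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image> %d angle x %d radius bins, %.4f mm/bin\n",
              x$angular_bins, x$radial_bins, x$mm_per_radius_bin))
  invisible(x)
}

# Outward radial gradient (central differences, one-sided at the ends).
# Positive at a dark-to-bright (lumen-to-wall) transition.
radial_gradient <- function(intensity) {
  nr <- ncol(intensity)
  g <- matrix(0, nrow(intensity), nr)
  g[, 2:(nr - 1L)] <- (intensity[, 3:nr] - intensity[, 1:(nr - 2L)]) / 2
  g[, 1L] <- intensity[, 2L] - intensity[, 1L]
  g[, nr] <- intensity[, nr] - intensity[, nr - 1L]
  g
}

# Node cost used by the tracer and by any independent path oracle:
# negative outward gradient (strong lumen/wall edges are cheap) plus a small
# curvature penalty per unit radial jump between adjacent angle bins.
#' Minimal-path node costs and smoothness penalty for a polar image
#'
#' Exposed so that independent shortest-path checks can share the exact cost
#' contract of [trace_lumen()].
#'
#' @param image A [polar_image()].
#' @return A list with `node_cost` (matrix, angle x radius) and
#'   `jump_penalty` (cost per radial bin of jump).
#' @export
lumen_path_costs <- function(image) {
  g <- radial_gradient(image$intensity)
  list(node_cost = -g, jump_penalty = 0.01 * max(abs(g)))
}

#' Trace the lumen boundary on a polar image by a minimal closed path
#'
#' Finds the minimum-cost closed path visiting one radius per angle bin, with
#' node cost equal to the negative outward radial intensity gradient (the
#' lumen is dark, the wall bright) plus a small curvature penalty, and radial
#' jumps between adjacent angle bins limited to `smoothness_max_jump_bins`.
#' The path over the angle-ordered graph is solved exactly by dynamic
#' programming; closure is enforced by solving the path for each candidate
#' start radius (every 2 bins) and keeping the cheapest, ties broken toward
#' the smaller radius.
#'
#' @param image A [polar_image()].
#' @param smoothness_max_jump_bins Maximum radial jump (bins) between
#'   adjacent angle bins, including the wrap-around pair. Default 2.
#' @return A tibble of class `lumen_contour` with columns `angle_bin`,
#'   `theta_rad`, `radius_bin`, `radius_mm`; attributes `total_cost` and
#'   `mm_per_radius_bin`.
#' @export
trace_lumen <- function(image, smoothness_max_jump_bins = 2L) {
  stopifnot(inherits(image, "polar_image"))
  mj <- as.integer(smoothness_max_jump_bins)
  if (mj < 0L) abort("`smoothness_max_jump_bins` must be >= 0.")
  costs <- lumen_path_costs(image)
  g_range <- diff(range(image$intensity))
  if (g_range <= sqrt(.Machine$double.eps) || max(abs(costs$node_cost)) == 0) {
    abort("No gradient structure: frame is unsegmentable.",
          class = "vffr_unsegmentable")
  }
  nc <- costs$node_cost
  lambda <- costs$jump_penalty
  na <- nrow(nc)
  nr <- ncol(nc)
  starts <- seq(1L, nr, by = 2L)
  ns <- length(starts)

  # D: nr x ns running cost; back[[i]]: chosen previous radius per (j, start)
  D <- matrix(Inf, nr, ns)
  D[cbind(starts, seq_len(ns))] <- nc[1L, starts]
  back <- vector("list", na)
  offsets <- seq(-mj, mj)
  for (i in 2:na) {
    best <- matrix(Inf, nr, ns)
    arg <- matrix(NA_integer_, nr, ns)
    for (o in offsets) {
      src <- seq_len(nr) - o
      ok <- src >= 1L & src <= nr
      cand <- matrix(Inf, nr, ns)
      cand[ok, ] <- D[src[ok], , drop = FALSE] + lambda * abs(o)
      upd <- cand < best
      best[upd] <- cand[upd]
      arg[upd] <- rep(src, ns)[upd]
    }
    D <- best + nc[i, ]
    back[[i]] <- arg
  }
  # closure: last angle must be within mj of the start radius
  close_cost <- rep(Inf, ns)
  close_arg <- rep(NA_integer_, ns)
  for (k in seq_len(ns)) {
    j0 <- starts[k]
    jj <- seq(max(1L, j0 - mj), min(nr, j0 + mj))
    tot <- D[jj, k] + lambda * abs(jj - j0)
    w <- which.min(tot)
    close_cost[k] <- tot[w]
    close_arg[k] <- jj[w]
  }
  kbest <- which.min(close_cost)  # ties -> first -> smaller start radius
  path <- integer(na)
  path[na] <- close_arg[kbest]
  for (i in na:2) path[i - 1L] <- back[[i]][path[i], kbest]

  out <- tibble(
    angle_bin = seq_len(na),
    theta_rad = (seq_len(na) - 1L) * 2 * pi / na,
    radius_bin = path,
    radius_mm = path * image$mm_per_radius_bin
  )
  class(out) <- c("lumen_contour", class(out))
  attr(out, "total_cost") <- unname(close_cost[kbest])
  attr(out, "mm_per_radius_bin") <- image$mm_per_radius_bin
  out
}

#' Lumen area enclosed by a polar contour
#'
#' Polar integration `A = 1/2 * sum(r_i^2 * dtheta)`, exact for a constant
#' radius.
#'
#' @param contour A `lumen_contour` (or any tibble with `radius_mm`).
#' @return Area in mm^2.
#' @export
contour_area <- function(contour) {
  r <- contour$radius_mm
  sum(r^2) * pi / length(r)
}

#' Select end-diastolic frames from an ECG R-wave train
#'
#' For each R wave, picks the frame whose timestamp is nearest to
#' `r_time - end_diastole_offset_s`; duplicate picks are dropped, order
#' preserved. Frame indices are 0-based (frame `k` is acquired at
#' `frame_times_s[k + 1]`), matching the pullback arithmetic of
#' [map_pullback()].
#'
#' @param frame_times_s Sorted frame acquisition times (s).
#' @param r_wave_times_s Sorted R-wave times (s).
#' @param end_diastole_offset_s Time before the R wave taken as end-diastole
#'   (s); default 0 (the R-wave frame is the end-diastolic proxy).
#' @return Integer vector of 0-based gated frame indices.
#' @export
gate_frames <- function(frame_times_s, r_wave_times_s, end_diastole_offset_s = 0) {
  if (length(frame_times_s) == 0L || length(r_wave_times_s) == 0L) {
    abort("Frame and R-wave time sequences must be non-empty.")
  }
  if (is.unsorted(frame_times_s) || is.unsorted(r_wave_times_s)) {
    abort("Time sequences must be sorted.")
  }
  idx <- vapply(r_wave_times_s - end_diastole_offset_s, function(target) {
    which.min(abs(frame_times_s - target)) - 1L
  }, integer(1))
  unique(idx)
}

#' Map gated frames to pullback arc-length
#'
#' Under uniform motorized pullback, frame `k` (0-based) sits at
#' `k * speed / rate` mm; positions are re-zeroed so the first gated frame is
#' at `s = 0`. Gated indices are canonically sorted (the original input order
#' is remembered so per-frame contours can be aligned).
#'
#' @param gated 0-based gated frame indices.
#' @param frame_rate_per_s Acquisition frame rate (frames/s), positive.
#' @param pullback_speed_mm_per_s Pullback speed (mm/s), positive.
#' @return A tibble of class `pullback_map` with columns `frame_index`,
#'   `s_mm`; attributes `frame_rate_per_s`, `pullback_speed_mm_per_s`,
#'   `input_order`.
#' @export
map_pullback <- function(gated, frame_rate_per_s, pullback_speed_mm_per_s) {
  if (!is.numeric(frame_rate_per_s) || frame_rate_per_s <= 0) {
    abort("`frame_rate_per_s` must be positive.")
  }
  if (!is.numeric(pullback_speed_mm_per_s) || pullback_speed_mm_per_s <= 0) {
    abort("`pullback_speed_mm_per_s` must be positive.")
  }
  if (length(gated) == 0L) abort("`gated` must be non-empty.")
  ord <- order(gated)
  k <- as.integer(gated[ord])
  s <- (k - k[1L]) * pullback_speed_mm_per_s / frame_rate_per_s
  out <- tibble(frame_index = k, s_mm = s)
  class(out) <- c("pullback_map", class(out))
  attr(out, "frame_rate_per_s") <- frame_rate_per_s
  attr(out, "pullback_speed_mm_per_s") <- pullback_speed_mm_per_s
  attr(out, "input_order") <- ord
  out
}

#' Assemble a vessel profile from per-frame lumen contours
#'
#' Assigns each gated frame's contour area to its pullback arc-length,
#' producing the `A(s)` profile the hemodynamic model consumes. Contours are
#' given in the same order as the `gated` vector passed to [map_pullback()];
#' they are re-sorted with the map.
#'
#' @param contours List of `lumen_contour` objects, one per gated frame.
#' @param pullback A `pullback_map` from [map_pullback()].
#' @return A [vessel_profile()].
#' @export
contours_to_profile <- function(contours, pullback) {
  stopifnot(inherits(pullback, "pullback_map"))
  if (length(contours) != nrow(pullback)) {
    abort("One contour per gated frame is required.")
  }
  contours <- contours[attr(pullback, "input_order")]
  areas <- vapply(contours, contour_area, numeric(1))
  vessel_profile(pullback$s_mm, areas)
}
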