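#' Build a vessel lumen profile
#'
#' A vessel profile is the geometric substrate for all hemodynamic
#' computations: lumen (and optionally external elastic membrane, EEM)
#' cross-sectional area sampled along the centerline arc-length. Diameter is
#' derived from area assuming a circular-equivalent cross-section,
#' `d = 2 * sqrt(A / pi)`, since IVUS areas are the primitive measurement.
#'
#' Arc-length is re-zeroed to start at 0 at the proximal end; duplicated
#' arc-length samples are dropped (first kept).
#'
#' @param s_mm Numeric vector of arc-length positions (mm), non-decreasing.
#' @param lumen_area_mm2 Positive lumen areas (mm^2), same length as `s_mm`.
#' @param eem_area_mm2 Optional EEM areas (mm^2), elementwise `>=` lumen area.
#'
#' @return A tibble of class `vessel_profile` with columns `s_mm`,
#'   `lumen_area_mm2`, `diameter_mm` and, when supplied, `eem_area_mm2`.
#' @export
#' @examples
#' vessel_profile(c(0, 10, 20), c(7, 3, 7))
vessel_profile <- function(s_mm, lumen_area_mm2, eem_area_mm2 = NULL) {
  if (length(s_mm) != length(lumen_area_mm2)) {
    abort("`s_mm` and `lumen_area_mm2` must have the same length.")
  }
  if (length(s_mm) < 2L) abort("A vessel profile needs at least 2 samples.")
  if (anyNA(s_mm) || anyNA(lumen_area_mm2)) abort("Profile values must be non-missing.")
  if (is.unsorted(s_mm)) abort("`s_mm` must be non-decreasing along the pullback.")
  if (any(lumen_area_mm2 <= 0)) abort("All lumen areas must be positive.")
  keep <- !duplicated(s_mm)
  s <- s_mm[keep] - s_mm[1L]
  a <- lumen_area_mm2[keep]
  if (length(s) < 2L) abort("Fewer than 2 distinct arc-length samples.")
  out <- tibble(
    s_mm = as.numeric(s),
    lumen_area_mm2 = as.numeric(a),
    diameter_mm = 2 * sqrt(a / pi)
  )
  if (!is.null(eem_area_mm2)) {
    if (length(eem_area_mm2) != length(s_mm)) {
      abort("`eem_area_mm2` must match `s_mm` in length.")
    }
    eem <- eem_area_mm2[keep]
    if (any(eem < a)) abort("EEM area must be >= lumen area everywhere.")
    out$eem_area_mm2 <- as.numeric(eem)
  }
  class(out) <- c("vessel_profile", class(out))
  out
}

#' Coerce a data frame to a vessel profile
#'
#' @param data A data frame with columns `s_mm`, `lumen_area_mm2` and
#'   optionally `eem_area_mm2`.
#' @return A [vessel_profile()].
#' @export
as_vessel_profile <- function(data) {
  if (inherits(data, "vessel_profile")) return(data)
  need <- c("s_mm", "lumen_area_mm2")
  if (!all(need %in% names(data))) {
    abort(paste0("Missing column(s): ",
                 paste(setdiff(need, names(data)), collapse = ", ")))
  }
  vessel_profile(data$s_mm, data$lumen_area_mm2,
                 if ("eem_area_mm2" %in% names(data)) data$eem_area_mm2)
}

#' Resample a vessel profile onto a uniform arc-length grid
#'
#' Linear interpolation of areas onto `seq(0, L, by = step_mm)`; the distal
#' endpoint is always retained so the grid covers the full segment.
#'
#' @param profile A [vessel_profile()].
#' @param step_mm Positive grid step (mm). Default 0.1 mm, the resolution at
#'   which all hemodynamic computations operate.
#' @return A [vessel_profile()] on the uniform grid.
#' @export
resample_profile <- function(profile, step_mm = 0.1) {
  profile <- as_vessel_profile(profile)
  if (!is.numeric(step_mm) || length(step_mm) != 1L || step_mm <= 0) {
    abort("`step_mm` must be a positive scalar.")
  }
  L <- max(profile$s_mm)
  grid <- seq(0, L, by = step_mm)
  if (grid[length(grid)] < L) grid <- c(grid, L)
  a <- approx(profile$s_mm, profile$lumen_area_mm2, xout = grid)$y
  eem <- if ("eem_area_mm2" %in% names(profile)) {
    approx(profile$s_mm, profile$eem_area_mm2, xout = grid)$y
  }
  vessel_profile(grid, a, eem)
}

#' Fit the reference vessel diameter line
#'
#' Ordinary least-squares fit of lumen diameter against arc-length over the
#' presumed-healthy samples, giving the expected healthy ("reference")
#' diameter at any position. Lesion samples are excluded via
#' `lesion_exclusion`.
#'
#' @param profile A [vessel_profile()].
#' @param lesion_exclusion Optional `c(start_mm, end_mm)` interval to exclude
#'   from the fit (the diseased segment).
#' @return An object of class `reference_line` with fields
#'   `slope_mm_per_mm`, `intercept_mm` and logical `fit_mask`.
#' @export
fit_reference <- function(profile, lesion_exclusion = NULL) {
  profile <- as_vessel_profile(profile)
  mask <- rep(TRUE, nrow(profile))
  if (!is.null(lesion_exclusion)) {
    if (length(lesion_exclusion) != 2L || lesion_exclusion[1] > lesion_exclusion[2]) {
      abort("`lesion_exclusion` must be c(start_mm, end_mm) with start <= end.")
    }
    mask <- profile$s_mm < lesion_exclusion[1] | profile$s_mm > lesion_exclusion[2]
  }
  if (sum(mask) < 2L) abort("Fewer than 2 samples remain outside the excluded interval.")
  s <- profile$s_mm[mask]
  d <- profile$diameter_mm[mask]
  if (length(unique(s)) == 1L) abort("Reference fit needs at least 2 distinct positions.")
  fit <- lm(d ~ s)
  structure(
    list(
      slope_mm_per_mm = unname(coef(fit)[2L]),
      intercept_mm = unname(coef(fit)[1L]),
      fit_mask = mask
    ),
    class = "reference_line"
  )
}

#' Evaluate a reference line at arc-length positions
#'
#' @param reference A `reference_line` from [fit_reference()].
#' @param s_mm Positions (mm).
#' @return Reference diameters (mm).
#' @export
reference_diameter <- function(reference, s_mm) {
  stopifnot(inherits(reference, "reference_line"))
  reference$intercept_mm + reference$slope_mm_per_mm * s_mm
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("<reference_line> d(s) = %.4f %+.5f * s mm (%d of %d samples)\n",
              x$intercept_mm, x$slope_mm_per_mm,
              sum(x$fit_mask), length(x$fit_mask)))
  invisible(x)
}

#' @export
tidy.reference_line <- function(x, ...) {
  tibble(
    term = c("intercept_mm", "slope_mm_per_mm"),
    estimate = c(x$intercept_mm, x$slope_mm_per_mm)
  )
}

# pointwise percent diameter stenosis against the reference line
pointwise_ds <- function(profile, reference) {
  d_ref <- reference_diameter(reference, profile$s_mm)
  100 * (1 - profile$diameter_mm / d_ref)
}

#' Delimit the lesion interval
#'
#' Finds the maximal contiguous interval around the deepest relative
#' narrowing where the pointwise diameter stenosis (vs the reference line)
#' exceeds `ds_threshold_pct`. Returns `NULL` when no sample exceeds the
#' threshold (no lesion).
#'
#' @param profile A [vessel_profile()].
#' @param reference A `reference_line`.
#' @param ds_threshold_pct Pointwise DS% threshold delimiting the lesion
#'   (default 20).
#' @return `c(start_mm, end_mm)` or `NULL`.
#' @export
detect_lesion <- function(profile, reference, ds_threshold_pct = 20) {
  profile <- as_vessel_profile(profile)
  ds <- pointwise_ds(profile, reference)
  above <- ds > ds_threshold_pct
  if (!any(above)) return(NULL)
  seed <- which.max(ds)
  i0 <- seed
  while (i0 > 1L && above[i0 - 1L]) i0 <- i0 - 1L
  i1 <- seed
  while (i1 < length(above) && above[i1 + 1L]) i1 <- i1 + 1L
  c(profile$s_mm[i0], profile$s_mm[i1])
}

#' Anatomical stenosis metrics
#'
#' Computes the standard IVUS lesion quantities: minimum lumen area (MLA) and
#' diameter (MLD), reference vessel diameter/area (RVD/RVA) at the MLA
#' position from the fitted reference line, percent diameter and area
#' stenosis (DS%, AS%), and plaque burden at the MLA when EEM areas are
#' available.
#'
#' When `reference` is `NULL` it is fitted with [fit_reference()] excluding
#' the lesion found by a first threshold pass; when `lesion` is `NULL` it is
#' delimited with [detect_lesion()]. An empty lesion scans the whole vessel.
#'
#' @param profile A [vessel_profile()].
#' @param reference Optional `reference_line`.
#' @param lesion Optional `c(start_mm, end_mm)` interval.
#' @param ds_threshold_pct Threshold forwarded to [detect_lesion()].
#' @return A one-row tibble of class `stenosis_metrics` with columns
#'   `mla_mm2`, `mld_mm`, `rvd_mm`, `rva_mm2`, `ds_pct`, `as_pct`,
#'   `plaque_burden_pct`, `lesion_start_mm`, `lesion_end_mm`,
#'   `mla_position_mm`.
#' @export
#' @examples
#' prof <- make_vessel(length_mm = 30, proximal_diameter_mm = 3,
#'                     stenoses = list(list(center_mm = 15, length_mm = 10,
#'                                          ds_pct = 50)))$profile
#' stenosis_metrics(prof)
stenosis_metrics <- function(profile, reference = NULL, lesion = NULL,
                             ds_threshold_pct = 20) {
  profile <- as_vessel_profile(profile)
  if (is.null(reference)) {
    ref0 <- fit_reference(profile)
    les0 <- detect_lesion(profile, ref0, ds_threshold_pct)
    reference <- if (is.null(les0)) ref0 else fit_reference(profile, les0)
  }
  if (is.null(lesion)) lesion <- detect_lesion(profile, reference, ds_threshold_pct)

  in_lesion <- if (is.null(lesion)) {
    rep(TRUE, nrow(profile))
  } else {
    profile$s_mm >= lesion[1] & profile$s_mm <= lesion[2]
  }
  idx <- which(in_lesion)[which.min(profile$lumen_area_mm2[in_lesion])]
  mla <- profile$lumen_area_mm2[idx]
  mld <- profile$diameter_mm[idx]
  s_mla <- profile$s_mm[idx]
  rvd <- reference_diameter(reference, s_mla)
  rva <- pi * (rvd / 2)^2
  if (rvd <= mld) {
    warn("Reference diameter <= minimum lumen diameter; DS% clamped at 0 (check the reference fit).")
    ds <- 0
    as_ <- max(0, 100 * (1 - mla / rva))
  } else {
    ds <- 100 * (1 - mld / rvd)
    as_ <- 100 * (1 - mla / rva)
  }
  pb <- if ("eem_area_mm2" %in% names(profile)) {
    eem <- profile$eem_area_mm2[idx]
    100 * (eem - mla) / eem
  } else {
    NA_real_
  }
  out <- tibble(
    mla_mm2 = mla, mld_mm = mld, rvd_mm = rvd, rva_mm2 = rva,
    ds_pct = ds, as_pct = as_, plaque_burden_pct = pb,
    lesion_start_mm = if (is.null(lesion)) NA_real_ else lesion[1],
    lesion_end_mm = if (is.null(lesion)) NA_real_ else lesion[2],
    mla_position_mm = s_mla
  )
  class(out) <- c("stenosis_metrics", class(out))
  out
}

#' @export
autoplot.vessel_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_mm, y = .data$diameter_mm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Arc-length (mm)", y = "Lumen diameter (mm)") +
    ggplot2::theme_minimal()
}
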