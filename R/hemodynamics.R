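#' Blood rheology parameters
#'
#' @param viscosity_pa_s Dynamic viscosity (Pa s). Default 0.0035, standard
#'   for blood at high shear.
#' @param density_kg_m3 Density (kg/m^3). Default 1060.
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(viscosity_pa_s = 0.0035, density_kg_m3 = 1060) {
  if (viscosity_pa_s <= 0 || density_kg_m3 <= 0) {
    abort("Blood viscosity and density must be positive.")
  }
  structure(list(viscosity_pa_s = viscosity_pa_s, density_kg_m3 = density_kg_m3),
            class = "blood_properties")
}

#' Hyperemic flow through the vessel segment
#'
#' Determines the hyperemic volumetric flow `Q`, conserved along the
#' unbranched segment. Two physiological closures are offered: the
#' diameter-scaling law, in which hyperemic velocity is proportional to the
#' square of the reference diameter (`v = k * d_ref^2`), and the frame-count
#' transit estimate `v = length / (n_frames / frame_rate)`. In both,
#' `Q = v * A_ref` with the reference area taken at the proximal end. A fixed
#' flow can also be imposed directly.
#'
#' @param profile A [vessel_profile()].
#' @param reference A `reference_line` from [fit_reference()].
#' @param mode One of `"diameter_scaling"`, `"frame_count"`, `"fixed"`.
#' @param k_velocity_m_s_per_mm2 Velocity-scaling constant (m/s per mm^2 of
#'   squared diameter). The default 0.0389 makes a 3.0 mm reference vessel
#'   run at 0.35 m/s, a typical adenosine-hyperemia velocity.
#' @param frame_transit For `mode = "frame_count"`: a list with `n_frames`,
#'   `frame_rate_per_s`, `length_mm`.
#' @param q_ml_s For `mode = "fixed"`: the imposed flow (mL/s).
#' @return An object of class `flow_state` with fields `q_ml_s`,
#'   `v_ref_m_s`, `d_ref_mm`, `a_ref_mm2`, `source`.
#' @export
#' @examples
#' prof <- make_vessel(length_mm = 30, proximal_diameter_mm = 3)$profile
#' ref <- fit_reference(prof)
#' hyperemic_flow(prof, ref)
hyperemic_flow <- function(profile, reference,
                           mode = c("diameter_scaling", "frame_count", "fixed"),
                           k_velocity_m_s_per_mm2 = 0.0389,
                           frame_transit = NULL, q_ml_s = NULL) {
  mode <- match.arg(mode)
  profile <- as_vessel_profile(profile)
  d_ref <- reference_diameter(reference, 0)
  if (d_ref <= 0) abort("Reference diameter at the proximal end must be positive.")
  a_ref <- pi * (d_ref / 2)^2
  if (mode == "diameter_scaling") {
    v <- k_velocity_m_s_per_mm2 * d_ref^2
    q <- v * a_ref  # (m/s) * mm^2 == mL/s
  } else if (mode == "frame_count") {
    if (is.null(frame_transit)) {
      abort("`frame_count` mode needs `frame_transit = list(n_frames, frame_rate_per_s, length_mm)`.")
    }
    need <- c("n_frames", "frame_rate_per_s", "length_mm")
    if (!all(need %in% names(frame_transit))) {
      abort(paste0("`frame_transit` must supply: ", paste(need, collapse = ", ")))
    }
    transit_s <- frame_transit$n_frames / frame_transit$frame_rate_per_s
    v <- (frame_transit$length_mm / transit_s) / 1000  # mm/s -> m/s
    q <- v * a_ref
  } else {
    if (is.null(q_ml_s) || q_ml_s < 0) abort("`fixed` mode needs a non-negative `q_ml_s`.")
    q <- q_ml_s
    v <- q / a_ref
  }
  structure(
    list(q_ml_s = q, v_ref_m_s = v, d_ref_mm = d_ref, a_ref_mm2 = a_ref,
         source = mode),
    class = "flow_state"
  )
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> Q = %.3f mL/s (v_ref = %.3f m/s at d_ref = %.2f mm, %s)\n",
              x$q_ml_s, x$v_ref_m_s, x$d_ref_mm, x$source))
  invisible(x)
}

# internal constructor for pressure fields on a grid
new_pressure_field <- function(s_mm, viscous_pa, expansion_pa,
                               convective_pa = NULL, engine, q_ml_s) {
  cum_pa <- viscous_pa + expansion_pa + (convective_pa %||% 0)
  out <- tibble(
    s_mm = s_mm,
    viscous_mmhg = viscous_pa / MMHG_PA,
    expansion_mmhg = expansion_pa / MMHG_PA,
    cum_drop_mmhg = cum_pa / MMHG_PA
  )
  if (!is.null(convective_pa)) out$convective_mmhg <- convective_pa / MMHG_PA
  class(out) <- c("pressure_field", class(out))
  attr(out, "engine") <- engine
  attr(out, "q_ml_s") <- q_ml_s
  out
}

#' Reduced-order pressure drop along the vessel
#'
#' Cumulative trans-lesion pressure drop composed of a friction-related
#' viscous term and an irreversible expansion term. Per grid interval of
#' length `ds`:
#' * viscous (local Poiseuille): `dP_v = 8 pi mu Q / A(s)^2 * ds`,
#' * expansion (Borda-Carnot, only where the area increases):
#'   `dP_e = k_expansion * rho/2 * Q^2 * (1/A_in - 1/A_out)^2`.
#'
#' Contractions are treated as loss-free apart from viscosity. The profile is
#' resampled internally to a uniform 0.1 mm grid; all internal arithmetic is
#' SI, converted to mmHg (/133.322) only in the returned field.
#'
#' @param profile A [vessel_profile()].
#' @param flow A `flow_state` from [hyperemic_flow()].
#' @param blood [blood_properties()].
#' @param k_expansion Energy-loss coefficient for expansions. Default 1.0
#'   (full Borda-Carnot loss).
#' @param step_mm Resampling step (mm), default 0.1.
#' @return A tibble of class `pressure_field` with columns `s_mm`,
#'   `viscous_mmhg`, `expansion_mmhg`, `cum_drop_mmhg` (cumulative,
#'   non-decreasing, 0 at `s = 0`).
#' @export
pressure_drop <- function(profile, flow, blood = blood_properties(),
                          k_expansion = 1.0, step_mm = 0.1) {
  stopifnot(inherits(flow, "flow_state"))
  stopifnot(inherits(blood, "blood_properties"))
  profile <- resample_profile(as_vessel_profile(profile), step_mm)
  A <- profile$lumen_area_mm2 * 1e-6            # m^2
  if (any(A <= 0)) abort("Areas must be positive.")
  s <- profile$s_mm * 1e-3                      # m
  Q <- flow$q_ml_s * 1e-6                       # m^3/s
  mu <- blood$viscosity_pa_s
  rho <- blood$density_kg_m3
  n <- length(A)
  ds <- diff(s)
  inv2 <- 1 / A^2
  dPv <- 8 * pi * mu * Q * (inv2[-n] + inv2[-1L]) / 2 * ds
  dA <- diff(A)
  dPe <- ifelse(dA > 0,
                k_expansion * rho / 2 * Q^2 * (1 / A[-n] - 1 / A[-1L])^2,
                0)
  new_pressure_field(
    s_mm = profile$s_mm,
    viscous_pa = c(0, cumsum(dPv)),
    expansion_pa = c(0, cumsum(dPe)),
    engine = "reduced_order", q_ml_s = flow$q_ml_s
  )
}

#' Steady 1D finite-volume solver for the area-averaged momentum balance
#'
#' Discretizes the steady one-dimensional momentum equation over `n_cells`
#' uniform cells: Poiseuille-profile wall friction (`8 pi mu Q / A^2`), the
#' convective term `rho Q^2 d(1/A)/ds` integrated exactly across each cell
#' face (Bernoulli exchange between pressure and kinetic energy), and
#' pressure recovery on expanding faces limited by the same Borda-Carnot
#' energy-loss coefficient as the reduced-order model, so the two engines
#' share one physical contract. The convective term makes the pressure field
#' locally non-monotone through a stenosis (throat dip followed by partial
#' recovery), which is physical.
#'
#' @inheritParams pressure_drop
#' @param n_cells Number of finite-volume cells, `>= 16`.
#' @return A tibble of class `pressure_field` on cell centers, with an
#'   additional `convective_mmhg` component;
#'   `cum_drop_mmhg = viscous + expansion + convective`.
#' @export
solve_1d_steady <- function(profile, flow, blood = blood_properties(),
                            n_cells = 200, k_expansion = 1.0) {
  stopifnot(inherits(flow, "flow_state"))
  stopifnot(inherits(blood, "blood_properties"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 16L) abort("`n_cells` must be >= 16.")
  profile <- as_vessel_profile(profile)
  L <- max(profile$s_mm)
  edges_mm <- seq(0, L, length.out = n_cells + 1L)
  A <- approx(profile$s_mm, profile$lumen_area_mm2, xout = edges_mm)$y * 1e-6
  if (any(A <= 0)) abort("Areas must be positive.")
  Q <- flow$q_ml_s * 1e-6
  mu <- blood$viscosity_pa_s
  rho <- blood$density_kg_m3
  ds <- (L * 1e-3) / n_cells
  inv2 <- 1 / A^2
  nE <- length(A)
  fric <- 8 * pi * mu * Q * (inv2[-nE] + inv2[-1L]) / 2 * ds
  conv <- rho * Q^2 / 2 * (inv2[-1L] - inv2[-nE])   # drop on contraction, recovery on expansion
  dA <- diff(A)
  loss <- ifelse(dA > 0,
                 k_expansion * rho / 2 * Q^2 * (1 / A[-nE] - 1 / A[-1L])^2,
                 0)
  visc_e <- c(0, cumsum(fric))
  conv_e <- c(0, cumsum(conv))
  loss_e <- c(0, cumsum(loss))
  if (!all(is.finite(visc_e + conv_e + loss_e))) {
    bad <- which(!is.finite(visc_e + conv_e + loss_e))[1L]
    abort(sprintf("Finite-volume solve diverged near cell %d (s = %.2f mm).",
                  bad, edges_mm[bad]))
  }
  mid <- function(x) (x[-nE] + x[-1L]) / 2
  new_pressure_field(
    s_mm = mid(edges_mm),
    viscous_pa = mid(visc_e),
    expansion_pa = mid(loss_e),
    convective_pa = mid(conv_e),
    engine = "fv1d", q_ml_s = flow$q_ml_s
  )
}

#' FFR pullback curve from a pressure field
#'
#' `FFR(s) = (Pa - dP(s)) / Pa`: the ratio of distal coronary pressure to
#' mean aortic pressure at every arc-length position. The distal reading
#' `ffr_distal` is taken at `measurement_point_mm` (default: the distal end
#' of the profile; clinically the sensor sits 2-3 cm distal to the lesion,
#' placement is the caller's choice).
#'
#' @param field A `pressure_field`.
#' @param pa_mmHg Mean aortic pressure (mmHg), default 90.
#' @param measurement_point_mm Optional measurement position (mm).
#' @return A tibble of class `pullback_curve` with columns `s_mm`, `ffr`,
#'   `cum_drop_mmhg`, `viscous_mmhg`, `expansion_mmhg`; attributes
#'   `pa_mmhg`, `ffr_distal`, `measurement_point_mm`, `engine`.
#' @export
ffr_pullback <- function(field, pa_mmHg = 90, measurement_point_mm = NULL) {
  stopifnot(inherits(field, "pressure_field"))
  if (pa_mmHg <= 0) abort("`pa_mmHg` must be positive.")
  ffr <- (pa_mmHg - field$cum_drop_mmhg) / pa_mmHg
  mp <- measurement_point_mm %||% max(field$s_mm)
  if (mp < min(field$s_mm) || mp > max(field$s_mm)) {
    abort("`measurement_point_mm` lies outside the profile.")
  }
  drop_mp <- approx(field$s_mm, field$cum_drop_mmhg, xout = mp)$y
  if (drop_mp >= pa_mmHg) {
    abort(paste0("Pressure drop at the measurement point reaches the aortic ",
                 "pressure: the constant-flow assumption is non-physical for ",
                 "this lesion."),
          class = "vffr_nonphysical")
  }
  ffr_distal <- approx(field$s_mm, ffr, xout = mp)$y
  out <- tibble(
    s_mm = field$s_mm, ffr = ffr,
    cum_drop_mmhg = field$cum_drop_mmhg,
    viscous_mmhg = field$viscous_mmhg,
    expansion_mmhg = field$expansion_mmhg
  )
  class(out) <- c("pullback_curve", class(out))
  attr(out, "pa_mmhg") <- pa_mmHg
  attr(out, "ffr_distal") <- ffr_distal
  attr(out, "measurement_point_mm") <- mp
  attr(out, "engine") <- attr(field, "engine")
  out
}

#' Virtual FFR in one call
#'
#' Pipeline facade: reference-line fit (lesion-excluded), hyperemic flow,
#' pressure drop by the chosen engine, FFR pullback. All parameters are
#' recorded in a `provenance` attribute.
#'
#' @param profile A [vessel_profile()].
#' @param reference Optional `reference_line`; fitted automatically (lesion
#'   excluded) when `NULL`.
#' @param flow Optional `flow_state`; defaults to diameter-scaling hyperemia.
#' @param blood [blood_properties()].
#' @param pa_mmHg Mean aortic pressure (mmHg).
#' @param engine `"reduced_order"` (default) or `"fv1d"`.
#' @param k_expansion Expansion energy-loss coefficient.
#' @param step_mm Grid resolution (mm) for the reduced-order engine; the
#'   finite-volume engine uses `n_cells`.
#' @param n_cells Cells for the `fv1d` engine; default matches `step_mm`.
#' @param measurement_point_mm Optional FFR measurement position.
#' @param k_velocity_m_s_per_mm2 Forwarded to [hyperemic_flow()].
#' @return A `pullback_curve` (see [ffr_pullback()]).
#' @export
#' @examples
#' ves <- make_vessel(length_mm = 30, proximal_diameter_mm = 3,
#'                    stenoses = list(list(center_mm = 15, length_mm = 10,
#'                                         ds_pct = 55)))
#' curve <- compute_vffr(ves$profile)
#' glance(curve)
compute_vffr <- function(profile, reference = NULL, flow = NULL,
                         blood = blood_properties(), pa_mmHg = 90,
                         engine = c("reduced_order", "fv1d"),
                         k_expansion = 1.0, step_mm = 0.1, n_cells = NULL,
                         measurement_point_mm = NULL,
                         k_velocity_m_s_per_mm2 = 0.0389) {
  engine <- match.arg(engine)
  profile <- as_vessel_profile(profile)
  if (is.null(reference)) {
    ref0 <- fit_reference(profile)
    les <- detect_lesion(profile, ref0)
    reference <- if (is.null(les)) ref0 else fit_reference(profile, les)
  }
  if (is.null(flow)) {
    flow <- hyperemic_flow(profile, reference,
                           mode = "diameter_scaling",
                           k_velocity_m_s_per_mm2 = k_velocity_m_s_per_mm2)
  }
  field <- if (engine == "reduced_order") {
    pressure_drop(profile, flow, blood, k_expansion, step_mm)
  } else {
    nc <- n_cells %||% max(16L, round(max(profile$s_mm) / step_mm))
    solve_1d_steady(profile, flow, blood, nc, k_expansion)
  }
  curve <- ffr_pullback(field, pa_mmHg, measurement_point_mm)
  attr(curve, "provenance") <- list(
    engine = engine, pa_mmhg = pa_mmHg, k_expansion = k_expansion,
    step_mm = step_mm, n_cells = if (engine == "fv1d") nc else NA_integer_,
    flow_source = flow$source, q_ml_s = flow$q_ml_s,
    viscosity_pa_s = blood$viscosity_pa_s, density_kg_m3 = blood$density_kg_m3
  )
  curve
}

#' @export
glance.pullback_curve <- function(x, ...) {
  tibble(
    ffr_distal = attr(x, "ffr_distal"),
    pa_mmhg = attr(x, "pa_mmhg"),
    total_drop_mmhg = max(x$cum_drop_mmhg),
    measurement_point_mm = attr(x, "measurement_point_mm"),
    engine = attr(x, "engine") %||% NA_character_
  )
}

#' @export
autoplot.pullback_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_mm, y = .data$ffr)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0.80, linetype = "dashed", colour = "firebrick") +
    ggplot2::ylim(min(object$ffr, 0.75), 1) +
    ggplot2::labs(x = "Arc-length (mm)", y = "FFR (Pd/Pa)") +
    ggplot2::theme_minimal()
}
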