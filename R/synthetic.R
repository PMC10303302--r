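# run code under a private RNG stream without touching the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# unit-peak narrowing shapes, compactly supported on [center - len/2, center + len/2]
stenosis_bump <- function(s, center, len, shape) {
  x <- s - center
  inside <- abs(x) <= len / 2
  b <- numeric(length(s))
  if (shape == "cosine") {
    b[inside] <- 0.5 * (1 + cos(2 * pi * x[inside] / len))
  } else if (shape == "gaussian") {
    sigma <- len / 6
    b[inside] <- exp(-x[inside]^2 / (2 * sigma^2))
  } else {
    abort("`shape` must be 'cosine' or 'gaussian'.")
  }
  b
}

#' Generate a parametric stenosed vessel with known ground truth
#'
#' The healthy vessel is a linearly tapered tube
#' `d_healthy(s) = d0 + taper * s`; each stenosis multiplies the diameter by
#' `1 - (ds_pct/100) * bump(s)` with a unit-peak cosine or Gaussian bump, so
#' the generated percent diameter stenosis at the bump peak equals `ds_pct`
#' by construction. Ground-truth anatomical metrics are evaluated on a dense
#' 0.005 mm grid against the known healthy taper line.
#'
#' @param length_mm Vessel length (mm).
#' @param proximal_diameter_mm Healthy diameter at `s = 0` (mm).
#' @param taper_mm_per_mm Healthy diameter slope (mm per mm, usually <= 0).
#' @param stenoses List of stenoses, each
#'   `list(center_mm, length_mm, ds_pct, shape)`; `shape` defaults to
#'   `"cosine"`; `ds_pct` must lie in `[0, 95]`; intervals must be inside the
#'   vessel and must not overlap.
#' @param eem_margin_pct Optional EEM margin: the EEM diameter is the healthy
#'   taper-line diameter inflated by this percentage, so plaque burden at the
#'   MLA is well defined.
#' @param step_mm Output sampling step (mm), default 0.1.
#' @return A list: `profile` (a [vessel_profile()]), `truth` (one-row tibble
#'   with `ds_pct`, `mla_mm2`, `mld_mm`, `mla_position_mm`,
#'   `lesion_start_mm`, `lesion_end_mm`), and `healthy_line`
#'   (`list(intercept_mm, slope_mm_per_mm)`).
#' @export
#' @examples
#' ves <- make_vessel(stenoses = list(list(center_mm = 15, length_mm = 10,
#'                                         ds_pct = 60)))
#' ves$truth
make_vessel <- function(length_mm = 30, proximal_diameter_mm = 3,
                        taper_mm_per_mm = 0, stenoses = list(),
                        eem_margin_pct = NULL, step_mm = 0.1) {
  if (length_mm <= 0 || proximal_diameter_mm <= 0) {
    abort("Vessel length and proximal diameter must be positive.")
  }
  for (st in stenoses) {
    need <- c("center_mm", "length_mm", "ds_pct")
    if (!all(need %in% names(st))) {
      abort(paste0("Each stenosis needs: ", paste(need, collapse = ", ")))
    }
    if (st$ds_pct < 0 || st$ds_pct > 95) {
      abort("`ds_pct` must lie in [0, 95].")
    }
    if (st$center_mm - st$length_mm / 2 < 0 ||
        st$center_mm + st$length_mm / 2 > length_mm) {
      abort("Stenosis interval must lie within the vessel.")
    }
  }
  if (length(stenoses) > 1L) {
    iv <- t(vapply(stenoses, function(st) {
      c(st$center_mm - st$length_mm / 2, st$center_mm + st$length_mm / 2)
    }, numeric(2)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) abort("Stenoses must not overlap.")
  }

  diam_at <- function(s) {
    d <- proximal_diameter_mm + taper_mm_per_mm * s
    for (st in stenoses) {
      shape <- st$shape %||% "cosine"
      d <- d * (1 - st$ds_pct / 100 * stenosis_bump(s, st$center_mm, st$length_mm, shape))
    }
    d
  }

  s <- seq(0, length_mm, by = step_mm)
  if (s[length(s)] < length_mm) s <- c(s, length_mm)
  d <- diam_at(s)
  area <- pi * (d / 2)^2
  eem <- if (!is.null(eem_margin_pct)) {
    d_h <- proximal_diameter_mm + taper_mm_per_mm * s
    pi * (d_h * (1 + eem_margin_pct / 100) / 2)^2
  }
  profile <- vessel_profile(s, area, eem)

  s_f <- seq(0, length_mm, by = 0.005)
  d_f <- diam_at(s_f)
  d_hf <- proximal_diameter_mm + taper_mm_per_mm * s_f
  ds_f <- 100 * (1 - d_f / d_hf)
  i_min <- which.min(d_f)
  above <- ds_f > 20
  if (any(above)) {
    seed <- which.max(ds_f)
    i0 <- seed; while (i0 > 1L && above[i0 - 1L]) i0 <- i0 - 1L
    i1 <- seed; while (i1 < length(above) && above[i1 + 1L]) i1 <- i1 + 1L
    bounds <- c(s_f[i0], s_f[i1])
  } else {
    bounds <- c(NA_real_, NA_real_)
  }
  truth <- tibble(
    ds_pct = max(ds_f),
    mla_mm2 = pi * (d_f[i_min] / 2)^2,
    mld_mm = d_f[i_min],
    mla_position_mm = s_f[i_min],
    lesion_start_mm = bounds[1],
    lesion_end_mm = bounds[2]
  )
  list(profile = profile, truth = truth,
       healthy_line = list(intercept_mm = proximal_diameter_mm,
                           slope_mm_per_mm = taper_mm_per_mm))
}

#' Generate a synthetic polar IVUS pullback stack with ground-truth contours
#'
#' Each frame is a polar greyscale image of the cross-section at the frame's
#' pullback position: dark lumen, bright wall, with a smooth lumen/wall edge
#' one radial bin wide and additive Gaussian noise. The lumen is circular
#' with the local profile radius, optionally squeezed into an ellipse of
#' equal area.
#'
#' @param profile A [vessel_profile()].
#' @param pullback_speed_mm_per_s Pullback speed (mm/s), default 0.5.
#' @param frame_rate_per_s Frame rate (frames/s), default 30.
#' @param noise_sd Noise SD as a fraction of `edge_contrast`, default 0.05.
#' @param edge_contrast Lumen-to-wall intensity difference, must be > 0.
#' @param angular_bins,radial_bins Polar grid size.
#' @param mm_per_radius_bin Radial pixel size; by default chosen so the
#'   largest lumen radius spans 70% of the radial extent.
#' @param eccentricity Ellipse eccentricity factor (0 = circle); axes are
#'   `r * (1 + e)` and `r / (1 + e)`.
#' @param seed RNG seed; stacks are bit-identical for identical arguments.
#' @return A list: `frames` (list of [polar_image()]), `frame_times_s`,
#'   `frame_s_mm` (pullback position per frame), `truth_contours` (list of
#'   tibbles `theta_rad`, `radius_mm`), `params`.
#' @export
make_polar_stack <- function(profile, pullback_speed_mm_per_s = 0.5,
                             frame_rate_per_s = 30, noise_sd = 0.05,
                             edge_contrast = 1, angular_bins = 64L,
                             radial_bins = 48L, mm_per_radius_bin = NULL,
                             eccentricity = 0, seed = 1L) {
  profile <- as_vessel_profile(profile)
  if (edge_contrast <= 0) abort("`edge_contrast` must be positive.")
  if (pullback_speed_mm_per_s <= 0 || frame_rate_per_s <= 0) {
    abort("Pullback speed and frame rate must be positive.")
  }
  L <- max(profile$s_mm)
  n_frames <- floor(L / pullback_speed_mm_per_s * frame_rate_per_s) + 1L
  k <- seq_len(n_frames) - 1L
  t_s <- k / frame_rate_per_s
  s_k <- k * pullback_speed_mm_per_s / frame_rate_per_s
  r_k <- approx(profile$s_mm, profile$diameter_mm / 2, xout = s_k)$y
  if (is.null(mm_per_radius_bin)) {
    mm_per_radius_bin <- max(r_k) * (1 + abs(eccentricity)) / (0.7 * radial_bins)
  }
  theta <- (seq_len(angular_bins) - 1L) * 2 * pi / angular_bins
  rho_mm <- seq_len(radial_bins) * mm_per_radius_bin
  edge_w <- mm_per_radius_bin  # one-bin-wide smooth edge

  with_seed(seed, {
    frames <- vector("list", n_frames)
    truth <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      r0 <- r_k[i]
      if (eccentricity != 0) {
        a <- r0 * (1 + eccentricity); b <- r0 / (1 + eccentricity)
        r_theta <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
      } else {
        r_theta <- rep(r0, angular_bins)
      }
      clean <- 0.5 * edge_contrast *
        (1 + tanh(outer(-r_theta, rho_mm, `+`) / edge_w))
      noisy <- clean + matrix(rnorm(angular_bins * radial_bins,
                                    sd = noise_sd * edge_contrast),
                              angular_bins, radial_bins)
      frames[[i]] <- polar_image(noisy, mm_per_radius_bin)
      truth[[i]] <- tibble(theta_rad = theta, radius_mm = r_theta)
    }
    list(frames = frames, frame_times_s = t_s, frame_s_mm = s_k,
         truth_contours = truth,
         params = list(pullback_speed_mm_per_s = pullback_speed_mm_per_s,
                       frame_rate_per_s = frame_rate_per_s,
                       noise_sd = noise_sd, edge_contrast = edge_contrast,
                       mm_per_radius_bin = mm_per_radius_bin,
                       eccentricity = eccentricity, seed = seed))
  })
}

#' Simulate an ECG R-wave train
#'
#' R waves at `60 / heart_rate_bpm` spacing (phase 0) with optional
#' truncated Gaussian jitter (clamped at 45% of the beat period so beats
#' never reorder).
#'
#' @param duration_s Recording duration (s).
#' @param heart_rate_bpm Heart rate (beats/min), positive.
#' @param jitter_sd_s Jitter SD (s), default 0.
#' @param seed RNG seed.
#' @return Sorted numeric vector of R-wave times within `[0, duration_s]`.
#' @export
simulate_ecg <- function(duration_s, heart_rate_bpm = 60, jitter_sd_s = 0,
                         seed = 1L) {
  if (heart_rate_bpm <= 0) abort("`heart_rate_bpm` must be positive.")
  period <- 60 / heart_rate_bpm
  base <- seq(0, duration_s, by = period)
  base <- base[base < duration_s]  # half-open window, phase 0
  if (jitter_sd_s > 0) {
    with_seed(seed, {
      j <- rnorm(length(base), sd = jitter_sd_s)
      j <- pmin(pmax(j, -0.45 * period), 0.45 * period)
      sort(pmin(pmax(base + j, 0), duration_s))
    })
  } else {
    base
  }
}

#' Specification for a correlated trivariate index cohort
#'
#' Defaults are the study conditions of the emulated paired cohort: means
#' 0.72 (IVUS-derived index), 0.74 (CT-derived index), 0.73 (invasive FFR),
#' SDs 0.10 / 0.09 / 0.09, and pairwise correlations 0.7913 (IVUS-FFR),
#' 0.6296 (CT-FFR), 0.7323 (IVUS-CT).
#'
#' @param n_vessels Cohort size, default 36.
#' @param means,sds Named numeric of length 3 (`ivus`, `ct`, `ffr`).
#' @param r_ivus_ffr,r_ct_ffr,r_ivus_ct Pairwise correlations.
#' @param lower,upper Truncation bounds; draws outside `(lower, upper]` in
#'   any coordinate are rejected and resampled.
#' @param round_2 Round simulated values to 2 decimals (clinical FFR
#'   reporting convention)? Default `FALSE`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_vessels = 36,
                        means = c(ivus = 0.72, ct = 0.74, ffr = 0.73),
                        sds = c(ivus = 0.10, ct = 0.09, ffr = 0.09),
                        r_ivus_ffr = 0.7913, r_ct_ffr = 0.6296,
                        r_ivus_ct = 0.7323,
                        lower = 0.2, upper = 1.0, round_2 = FALSE) {
  R <- matrix(c(1,         r_ivus_ct, r_ivus_ffr,
                r_ivus_ct, 1,         r_ct_ffr,
                r_ivus_ffr, r_ct_ffr, 1), 3, 3,
              dimnames = list(c("ivus", "ct", "ffr"), c("ivus", "ct", "ffr")))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    abort(sprintf("Correlation matrix is not positive definite (eigenvalue %.4g <= 0).",
                  min(ev)))
  }
  if (any(sds <= 0)) abort("All SDs must be positive.")
  structure(
    list(n_vessels = n_vessels, means = means, sds = sds,
         correlation = R, lower = lower, upper = upper, round_2 = round_2),
    class = "cohort_spec"
  )
}

#' Simulate a paired cohort of two indices against invasive FFR
#'
#' Draws trivariate Gaussian vectors (Cholesky factorization of the
#' correlation matrix), rejecting and resampling any vessel with a
#' coordinate outside `(lower, upper]` so correlations stay interpretable.
#' The two returned paired cohorts share the invasive FFR column.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; identical `(spec, seed)` give identical cohorts.
#' @return A list: `data` (tibble `vessel_id`, `index_ivus`, `index_ct`,
#'   `ffr`), `ivus` and `ct` (both [paired_cohort()]s vs the shared FFR).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n_vessels = 36), seed = 7)
#' confusion_at_cutoff(co$ivus, 0.80)
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  Lc <- chol(spec$correlation)  # upper triangular, R = t(Lc) %*% Lc
  n <- spec$n_vessels
  with_seed(seed, {
    out <- matrix(NA_real_, n, 3)
    filled <- 0L
    while (filled < n) {
      m <- max(n - filled, 16L)
      Z <- matrix(rnorm(m * 3), m, 3)
      X <- Z %*% Lc
      X <- sweep(X, 2, spec$sds[c("ivus", "ct", "ffr")], `*`)
      X <- sweep(X, 2, spec$means[c("ivus", "ct", "ffr")], `+`)
      ok <- rowSums(X > spec$lower & X <= spec$upper) == 3L
      X <- X[ok, , drop = FALSE]
      take <- min(nrow(X), n - filled)
      if (take > 0L) {
        out[(filled + 1L):(filled + take), ] <- X[seq_len(take), ]
        filled <- filled + take
      }
    }
    if (spec$round_2) out <- round(out, 2)
    data <- tibble(
      vessel_id = sprintf("V%03d", seq_len(n)),
      index_ivus = out[, 1], index_ct = out[, 2], ffr = out[, 3]
    )
    list(
      data = data,
      ivus = paired_cohort(data$vessel_id, data$index_ivus, data$ffr),
      ct = paired_cohort(data$vessel_id, data$index_ct, data$ffr)
    )
  })
}
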