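# shared fixture builders: everything is generated in code at test time

tube_profile <- function(d_mm = 3, length_mm = 30, n = 61) {
  s <- seq(0, length_mm, length.out = n)
  vessel_profile(s, rep(pi * (d_mm / 2)^2, n))
}

# polar image of a sharp dark-lumen/bright-wall boundary at radius r(theta) bins
boundary_image <- function(n_angle, n_radius, radius_bins, noise_sd = 0,
                           contrast = 1, edge_w = 1, seed = NULL) {
  rho <- seq_len(n_radius)
  img <- 0.5 * contrast * (1 + tanh(outer(-radius_bins, rho, `+`) / edge_w))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(rnorm(n_angle * n_radius, sd = noise_sd), n_angle, n_radius)
  }
  polar_image(img, mm_per_radius_bin = 1)
}

ellipse_radius_bins <- function(n_angle, a, b) {
  theta <- (seq_len(n_angle) - 1) * 2 * pi / n_angle
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# 20 generated lesions spanning DS 30-80%, lengths 5-25 mm (fixed deterministic sweep)
lesion_library <- function() {
  lapply(1:20, function(i) {
    ds <- 30 + (80 - 30) * (i - 1) / 19
    len <- 5 + (25 - 5) * ((i * 7) %% 20) / 19
    L <- max(30, len + 14)
    make_vessel(length_mm = L, proximal_diameter_mm = 3,
                taper_mm_per_mm = -0.005,
                stenoses = list(list(center_mm = L / 2, length_mm = len,
                                     ds_pct = ds)))
  })
}

# random paired cohort with both classes guaranteed
random_cohort <- function(n, seed) {
  set.seed(seed)
  repeat {
    ffr <- round(runif(n, 0.45, 1.0), 3)
    idx <- pmin(pmax(ffr + rnorm(n, sd = 0.08), 0.3), 1.0)
    if (any(ffr <= 0.80) && any(ffr > 0.80)) break
  }
  paired_cohort(sprintf("v%03d", seq_len(n)), idx, ffr)
}

# cohort engineered to produce exact confusion counts at cutoff 0.80
# (index values jittered so correlations are well defined)
engineered_cohort_pair <- function(seed = 1) {
  set.seed(seed)
  n_pos <- 29; n_neg <- 7
  ffr <- c(runif(n_pos, 0.55, 0.78), runif(n_neg, 0.84, 0.95))
  id <- sprintf("V%02d", 1:36)
  pos_call <- function() runif(1, 0.55, 0.78)
  neg_call <- function() runif(1, 0.84, 0.95)
  # ivus: TP 28, FN 1 (positive called negative), FP 1, TN 6
  ivus <- c(replicate(28, pos_call()), neg_call(),
            pos_call(), replicate(6, neg_call()))
  # ct: TP 26, FN 3, FP 1, TN 6
  ct <- c(replicate(26, pos_call()), replicate(3, neg_call()),
          pos_call(), replicate(6, neg_call()))
  list(
    ivus = paired_cohort(id, ivus, ffr),
    ct = paired_cohort(id, ct, ffr),
    data = tibble::tibble(vessel_id = id, index_ct = ct, index_ivus = ivus,
                          ffr = ffr)
  )
}

# independent exhaustive dynamic-programming oracle for the closed minimal
# path on a polar image: plain loops, one run per admissible start radius
brute_min_path_cost <- function(image, max_jump = 2) {
  costs <- lumen_path_costs(image)
  nc <- costs$node_cost
  lam <- costs$jump_penalty
  na <- nrow(nc); nr <- ncol(nc)
  best_total <- Inf
  for (j0 in seq(1, nr, by = 2)) {
    D <- rep(Inf, nr)
    D[j0] <- nc[1, j0]
    for (i in 2:na) {
      Dn <- rep(Inf, nr)
      for (j in 1:nr) {
        for (jp in max(1, j - max_jump):min(nr, j + max_jump)) {
          v <- D[jp] + lam * abs(j - jp) + nc[i, j]
          if (v < Dn[j]) Dn[j] <- v
        }
      }
      D <- Dn
    }
    for (j in max(1, j0 - max_jump):min(nr, j0 + max_jump)) {
      v <- D[j] + lam * abs(j - j0)
      if (v < best_total) best_total <- v
    }
  }
  best_total
}

# trapezoid area under the empirical ROC built from a cutoff sweep
trapezoid_auc <- function(roc) {
  sw <- roc$sweep
  fpr <- c(0, 1 - sw$spec, 1)
  tpr <- c(0, sw$sens, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# synthetic pullback -> traced contours -> profile -> stenosis metrics
run_end_to_end <- function(ds_pct = 55, seed = 11, noise_sd = 0.05) {
  ves <- make_vessel(length_mm = 20, proximal_diameter_mm = 3,
                     stenoses = list(list(center_mm = 10, length_mm = 8,
                                          ds_pct = ds_pct)))
  st <- make_polar_stack(ves$profile, pullback_speed_mm_per_s = 0.5,
                         frame_rate_per_s = 10, noise_sd = noise_sd,
                         seed = seed)
  r_waves <- simulate_ecg(max(st$frame_times_s), heart_rate_bpm = 60)
  gated <- gate_frames(st$frame_times_s, r_waves)
  pm <- map_pullback(gated, frame_rate_per_s = 10, pullback_speed_mm_per_s = 0.5)
  contours <- lapply(gated + 1L, function(i) trace_lumen(st$frames[[i]]))
  profile <- contours_to_profile(contours, pm)
  list(truth = ves$truth, metrics = stenosis_metrics(profile),
       profile = profile)
}
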