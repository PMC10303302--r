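# CSV dialect fixed package-wide: comma separator, '.' decimal, UTF-8, header row.

#' Read and write vessel profile CSVs
#'
#' Columns `s_mm,lumen_area_mm2[,eem_area_mm2]`, header required.
#'
#' @param path File path.
#' @return [read_vessel_profile()] returns a [vessel_profile()].
#' @export
read_vessel_profile <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("s_mm", "lumen_area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    abort(paste0("Vessel CSV is missing column(s): ", paste(miss, collapse = ", ")),
          class = "vffr_bad_input")
  }
  bad <- which(!is.finite(df$s_mm) | !is.finite(df$lumen_area_mm2))
  if (length(bad) > 0L) {
    abort(sprintf("Vessel CSV has a non-numeric/missing value at data row %d.", bad[1L]),
          class = "vffr_bad_input")
  }
  as_vessel_profile(df)
}

#' @rdname read_vessel_profile
#' @param profile A [vessel_profile()].
#' @export
write_vessel_profile <- function(profile, path) {
  profile <- as_vessel_profile(profile)
  cols <- intersect(c("s_mm", "lumen_area_mm2", "eem_area_mm2"), names(profile))
  readr::write_csv(as_tibble(profile)[, cols], path)
  invisible(path)
}

#' Read and write paired-cohort CSVs
#'
#' Columns `vessel_id,index_ct,index_ivus,ffr`.
#'
#' @param path File path.
#' @return [read_cohort_csv()] returns a list with the raw `data` tibble and
#'   the two [paired_cohort()]s (`ivus`, `ct`) sharing the FFR column.
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("vessel_id", "index_ct", "index_ivus", "ffr")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    abort(paste0("Cohort CSV is missing column(s): ", paste(miss, collapse = ", ")),
          class = "vffr_bad_input")
  }
  list(
    data = as_tibble(df),
    ivus = paired_cohort(df$vessel_id, df$index_ivus, df$ffr),
    ct = paired_cohort(df$vessel_id, df$index_ct, df$ffr)
  )
}

#' @rdname read_cohort_csv
#' @param data Tibble with columns `vessel_id`, `index_ct`, `index_ivus`,
#'   `ffr` (e.g. `simulate_cohort(...)$data`).
#' @export
write_cohort_csv <- function(data, path) {
  need <- c("vessel_id", "index_ct", "index_ivus", "ffr")
  if (!all(need %in% names(data))) {
    abort(paste0("Need columns: ", paste(need, collapse = ", ")))
  }
  readr::write_csv(data[, need], path)
  invisible(path)
}

#' Write an FFR pullback curve CSV
#'
#' Columns `s_mm,ffr,cum_drop_mmHg,viscous_mmHg,expansion_mmHg`.
#'
#' @param curve A `pullback_curve`.
#' @param path File path.
#' @export
write_pullback_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pullback_curve"))
  out <- tibble(
    s_mm = curve$s_mm, ffr = curve$ffr,
    cum_drop_mmHg = curve$cum_drop_mmhg,
    viscous_mmHg = curve$viscous_mmhg,
    expansion_mmHg = curve$expansion_mmhg
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Run configuration: JSON round trip and provenance
#'
#' A run configuration is a named list of subcommand parameters. It
#' round-trips through JSON losslessly and is echoed, together with the
#' package version, a timestamp and a config hash, in every provenance
#' block.
#'
#' @param config Named list.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

provenance_block <- function(config, seed = NULL) {
  list(
    package = "vffr",
    version = as.character(utils::packageVersion("vffr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config)
  )
}

write_json_flat <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compute a virtual FFR pullback from a vessel CSV
#'
#' Pipeline command: reads the vessel geometry, quantifies the stenosis,
#' computes the FFR pullback with the chosen engine, and writes
#' `pullback.csv`, `metrics.json` (anatomical metrics plus `ffr_distal`) and
#' `provenance.json` into `out_dir`.
#'
#' @param vessel_csv Path to a vessel profile CSV.
#' @param out_dir Output directory (created if missing).
#' @param engine `"reduced_order"` or `"fv1d"`.
#' @param pa_mmHg Mean aortic pressure (mmHg).
#' @param k_expansion Expansion loss coefficient.
#' @param k_velocity_m_s_per_mm2 Hyperemic velocity-scaling constant.
#' @param measurement_point_mm Optional FFR measurement position (mm).
#' @return Invisibly, a list with the `curve`, `metrics` and output paths.
#' @export
run_vffr <- function(vessel_csv, out_dir, engine = "reduced_order",
                     pa_mmHg = 90, k_expansion = 1.0,
                     k_velocity_m_s_per_mm2 = 0.0389,
                     measurement_point_mm = NULL) {
  profile <- read_vessel_profile(vessel_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- stenosis_metrics(profile)
  curve <- compute_vffr(profile, engine = engine, pa_mmHg = pa_mmHg,
                        k_expansion = k_expansion,
                        k_velocity_m_s_per_mm2 = k_velocity_m_s_per_mm2,
                        measurement_point_mm = measurement_point_mm)
  paths <- list(
    pullback = file.path(out_dir, "pullback.csv"),
    metrics = file.path(out_dir, "metrics.json"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_pullback_csv(curve, paths$pullback)
  write_json_flat(c(as.list(metrics),
                    list(ffr_distal = attr(curve, "ffr_distal"),
                         pa_mmHg = attr(curve, "pa_mmhg"),
                         engine = engine)),
                  paths$metrics)
  write_json_flat(provenance_block(attr(curve, "provenance")), paths$provenance)
  invisible(list(curve = curve, metrics = metrics, paths = paths))
}

#' Evaluate two index methods against invasive FFR from a cohort CSV
#'
#' Pipeline command: reads the cohort, runs [compare_methods()] at the given
#' cutoff, and writes `report.json`, `report.md` and `provenance.json` into
#' `out_dir`.
#'
#' @param cohort_csv Path to a cohort CSV
#'   (`vessel_id,index_ct,index_ivus,ffr`).
#' @param out_dir Output directory.
#' @param cutoff Index cutoff (default 0.80).
#' @param ci_level Confidence level (default 0.95).
#' @return Invisibly, a list with the `comparison` and output paths.
#' @export
run_evaluate <- function(cohort_csv, out_dir, cutoff = 0.80, ci_level = 0.95) {
  co <- read_cohort_csv(cohort_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_methods(co$ivus, co$ct, cutoff = cutoff, ci_level = ci_level,
                         labels = c("index_ivus", "index_ct"))
  paths <- list(
    json = file.path(out_dir, "report.json"),
    md = file.path(out_dir, "report.md"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_json_flat(tidy(cmp), paths$json)
  writeLines(report_markdown(cmp), paths$md)
  write_json_flat(provenance_block(list(cohort_csv = cohort_csv,
                                        cutoff = cutoff,
                                        ci_level = ci_level)),
                  paths$provenance)
  invisible(list(comparison = cmp, paths = paths))
}

#' Generate a deterministic synthetic fixture bundle on disk
#'
#' Pipeline command: writes a stenosed vessel CSV with its ground-truth
#' sidecar, an ECG R-wave CSV, and a simulated paired-cohort CSV with its
#' generating parameters, all reproducible from `seed`.
#'
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @param vessel Arguments for [make_vessel()] (list).
#' @param cohort A [cohort_spec()].
#' @param ecg Arguments for [simulate_ecg()] (list), `NULL` to skip.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, seed = 1L,
                         vessel = list(length_mm = 30, proximal_diameter_mm = 3,
                                       stenoses = list(list(center_mm = 15,
                                                            length_mm = 10,
                                                            ds_pct = 60))),
                         cohort = cohort_spec(),
                         ecg = list(duration_s = 60, heart_rate_bpm = 60,
                                    jitter_sd_s = 0.02)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  ves <- do.call(make_vessel, vessel)
  paths$vessel <- write_vessel_profile(ves$profile, file.path(out_dir, "vessel.csv"))
  paths$vessel_truth <- write_json_flat(as.list(ves$truth),
                                        file.path(out_dir, "vessel_truth.json"))
  if (!is.null(ecg)) {
    r <- do.call(simulate_ecg, c(ecg, list(seed = seed)))
    paths$ecg <- file.path(out_dir, "ecg_r_waves.csv")
    readr::write_csv(tibble(r_wave_time_s = r), paths$ecg)
  }
  co <- simulate_cohort(cohort, seed = seed)
  paths$cohort <- write_cohort_csv(co$data, file.path(out_dir, "cohort.csv"))
  paths$provenance <- write_json_flat(
    provenance_block(list(vessel = vessel,
                          cohort = list(n_vessels = cohort$n_vessels,
                                        means = as.list(cohort$means),
                                        sds = as.list(cohort$sds),
                                        correlation = cohort$correlation,
                                        lower = cohort$lower,
                                        upper = cohort$upper),
                          ecg = ecg),
                     seed = seed),
    file.path(out_dir, "provenance.json"))
  invisible(paths)
}
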