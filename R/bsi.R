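#' Clip intensities into a window and rescale to \[0, 1\]
#'
#' `(min(max(I, low), high) - low) / (high - low)`: intensities below the
#' window map to 0, above it to 1, and linearly in between. The clipped
#' difference between time points is what the boundary shift integral sums,
#' so intensity changes outside the tissue-transition band contribute
#' nothing.
#'
#' @param values numeric vector or array of intensities.
#' @param window an [intensity_window()].
#' @return Values in \[0, 1\], same shape as `values`.
#' @export
clip_intensity <- function(values, window) {
  stopifnot(inherits(window, "intensity_window"))
  (pmin(pmax(values, window$low), window$high) - window$low) /
    (window$high - window$low)
}

#' Boundary shift integral over one intensity window
#'
#' `D * sum(R * (clip(I_baseline) - clip(I_repeat)))` over the whole volume,
#' where D is the voxel volume in mm^3 and R the boundary-region weights.
#' Positive values mean the baseline is brighter inside the region
#' (tissue replaced by CSF on T1, i.e. atrophy).
#'
#' @param baseline,repeat_ normalized, bias-corrected [volume_grid()]s.
#' @param region a `boundary_region`.
#' @param window an [intensity_window()].
#' @return Signed volume change in mm^3.
#' @export
integrate_bsi <- function(baseline, repeat_, region, window) {
  stopifnot(inherits(baseline, "volume_grid"),
            inherits(repeat_, "volume_grid"),
            inherits(region, "boundary_region"))
  check_same_grid(baseline$data, repeat_$data, "baseline and repeat")
  check_same_grid(baseline$data, region$weights, "images and region")
  d <- clip_intensity(baseline$data, window) -
    clip_intensity(repeat_$data, window)
  baseline$voxel_volume * sum(region$weights * d)
}

#' Boundary shift integral with a double intensity window
#'
#' For a structure bordered by CSF on one side and white matter on the other
#' (the hippocampus), loss at the CSF border makes the repeat darker while
#' loss at the WM border makes it brighter. The total is the CSF-GM-window
#' integral minus the GM-WM-window integral, so loss contributes positively
#' at both borders.
#'
#' @inheritParams integrate_bsi
#' @param window_csf_gm,window_gm_wm the two [intensity_window()]s from
#'   [double_window()].
#' @return Signed volume change in mm^3.
#' @export
integrate_double_window <- function(baseline, repeat_, region,
                                    window_csf_gm, window_gm_wm) {
  integrate_bsi(baseline, repeat_, region, window_csf_gm) -
    integrate_bsi(baseline, repeat_, region, window_gm_wm)
}

#' Annualized percentage volume change
#'
#' `100 * bsi_mm3 / (volume of the 0.5-binarized baseline mask) /
#' interval_years`.
#'
#' @param bsi_mm3 signed volume change, mm^3.
#' @param baseline_mask baseline [prob_mask()].
#' @param interval_years scan interval, years (> 0).
#' @param threshold binarization threshold (default 0.5).
#' @return Percent volume change per year (positive = loss).
#' @export
pbvc <- function(bsi_mm3, baseline_mask, interval_years, threshold = 0.5) {
  stopifnot(inherits(baseline_mask, "prob_mask"))
  if (interval_years <= 0) stop("interval_years must be positive")
  nvox <- sum(binarize(baseline_mask, threshold)$prob)
  if (nvox == 0) stop("degenerate input: binarized baseline mask is empty")
  vol <- nvox * baseline_mask$grid$voxel_volume
  100 * bsi_mm3 / vol / interval_years
}

#' Run the full atrophy pipeline on a scan pair
#'
#' Stages, in order: (optional) symmetric differential bias correction;
#' k-means tissue-mean estimation per time point; linear-regression intensity
#' normalization of the repeat onto the baseline; automatic intensity-window
#' selection (single or double) from time-point-averaged tissue statistics;
#' boundary-region construction (gBSI probabilistic XOR, classic binary XOR,
#' or fuzzy pBSI); integration; annualized PBVC.
#'
#' @param pair a [scan_pair()].
#' @param config a [pipeline_config()].
#' @param keep_contribution if `TRUE`, the per-voxel contribution map
#'   (mm^3 per voxel) is stored in the result for export.
#' @return A `bsi_result` with the integral (mm^3), the PBVC (%/yr), the
#'   variant, window(s), gain factor kappa (gBSI only), active region voxel
#'   count, baseline volume, normalization coefficients, and the effective
#'   configuration.
#' @export
run_bsi <- function(pair, config = pipeline_config(),
                    keep_contribution = FALSE) {
  stopifnot(inherits(pair, "scan_pair"), inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  base <- pair$baseline
  rep_ <- pair$repeat_
  A <- pair$baseline_mask
  B <- pair$repeat_mask

  if (config$dbc) {
    dbc_mask <- stage("dbc", {
      u <- pmax(A$prob, B$prob)
      prob_mask(dilate3d(u >= config$binarize_threshold, 3L,
                         config$connectivity), base)
    })
    corr <- stage("dbc",
      differential_bias_correct(base, rep_, dbc_mask,
                                kernel_radius = config$dbc_kernel_radius))
    base <- corr$baseline
    rep_ <- corr$repeat_
  }

  tm_base <- stage("normalization", {
    reg <- kmeans_region(A, config$kmeans_dilations, config$connectivity)
    estimate_tissue_means(base, reg, mask = A,
                          connectivity = config$connectivity)
  })
  tm_rep <- stage("normalization", {
    reg <- kmeans_region(B, config$kmeans_dilations, config$connectivity)
    estimate_tissue_means(rep_, reg, mask = B,
                          connectivity = config$connectivity)
  })
  norm <- stage("normalization", normalize_pair(base, rep_, tm_base, tm_rep))
  rep_n <- norm$repeat_norm

  tm_avg <- average_tissue_means(tm_base, norm$tm_rep_norm)
  windows <- stage("window", {
    if (config$window_mode == "single") {
      list(csf_gm = single_window(tm_avg))
    } else {
      double_window(tm_avg)
    }
  })

  region <- stage("region", switch(
    config$variant,
    gbsi = gbsi_region(A, B, kappa_override = config$kappa_override),
    kn = binary_xor_region(A, B, config$xor_dilate, config$xor_erode,
                           config$connectivity),
    pbsi1 = pbsi_region(A, B, pbsi_params(config$pbsi_eta, config$pbsi_zeta,
                                          config$pbsi_ne, config$pbsi_nd,
                                          gamma = 1),
                        config$connectivity),
    pbsig = pbsi_region(A, B, pbsi_params(config$pbsi_eta, config$pbsi_zeta,
                                          config$pbsi_ne, config$pbsi_nd,
                                          gamma = config$pbsi_gamma),
                        config$connectivity)))

  bsi_mm3 <- stage("integral", {
    if (config$window_mode == "single") {
      integrate_bsi(base, rep_n, region, windows$csf_gm)
    } else {
      integrate_double_window(base, rep_n, region, windows$csf_gm,
                              windows$gm_wm)
    }
  })
  pbvc_val <- stage("pbvc",
    pbvc(bsi_mm3, A, pair$interval_years, config$binarize_threshold))

  contribution <- NULL
  if (keep_contribution) {
    d <- clip_intensity(base$data, windows$csf_gm) -
      clip_intensity(rep_n$data, windows$csf_gm)
    if (config$window_mode == "double")
      d <- d - (clip_intensity(base$data, windows$gm_wm) -
                  clip_intensity(rep_n$data, windows$gm_wm))
    contribution <- base$voxel_volume * region$weights * d
  }

  baseline_volume <- sum(binarize(A, config$binarize_threshold)$prob) *
    base$voxel_volume

  structure(list(
    bsi_mm3 = bsi_mm3,
    pbvc_percent_per_year = pbvc_val,
    variant = region$variant,
    windows = windows,
    kappa = region$kappa,
    region_voxels = sum(region$weights > 0),
    baseline_volume_mm3 = baseline_volume,
    interval_years = pair$interval_years,
    norm_slope = norm$slope,
    norm_intercept = norm$intercept,
    tissue_means = list(baseline = tm_base, repeat_norm = norm$tm_rep_norm),
    contribution = contribution,
    config = config),
    class = "bsi_result")
}

#' @export
print.bsi_result <- function(x, ...) {
  cat("<bsi_result> variant ", x$variant, "\n",
      "  BSI:  ", signif(x$bsi_mm3, 6), " mm^3\n",
      "  PBVC: ", signif(x$pbvc_percent_per_year, 5), " %/yr over ",
      x$interval_years, " yr\n",
      "  baseline volume: ", signif(x$baseline_volume_mm3, 6), " mm^3, ",
      x$region_voxels, " region voxels\n", sep = "")
  if (!is.na(x$kappa))
    cat("  kappa: ", signif(x$kappa, 5), "\n", sep = "")
  w <- x$windows
  cat("  window CSF-GM: [", signif(w$csf_gm$low, 5), ", ",
      signif(w$csf_gm$high, 5), "]\n", sep = "")
  if (!is.null(w$gm_wm))
    cat("  window GM-WM:  [", signif(w$gm_wm$low, 5), ", ",
        signif(w$gm_wm$high, 5), "]\n", sep = "")
  invisible(x)
}

#' Flatten a BSI result to a key-value list for serialization
#'
#' @param result a `bsi_result` from [run_bsi()].
#' @return A named list of scalars suitable for JSON serialization.
#' @export
bsi_report <- function(result) {
  stopifnot(inherits(result, "bsi_result"))
  w <- result$windows
  out <- list(
    variant = result$variant,
    bsi_mm3 = result$bsi_mm3,
    pbvc_percent_per_year = result$pbvc_percent_per_year,
    interval_years = result$interval_years,
    baseline_volume_mm3 = result$baseline_volume_mm3,
    region_voxels = result$region_voxels,
    kappa = if (is.na(result$kappa)) NULL else result$kappa,
    window_csf_gm_low = w$csf_gm$low,
    window_csf_gm_high = w$csf_gm$high,
    norm_slope = result$norm_slope,
    norm_intercept = result$norm_intercept)
  if (!is.null(w$gm_wm)) {
    out$window_gm_wm_low <- w$gm_wm$low
    out$window_gm_wm_high <- w$gm_wm$high
  }
  cfg <- result$config
  for (nm in names(cfg))
    if (!is.null(cfg[[nm]]))
      out[[paste0("config_", nm)]] <- cfg[[nm]]
  out
}
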