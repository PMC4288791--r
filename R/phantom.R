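# Separable Gaussian blur via weighted array shifts; kernel truncated at
# 3 sigma and renormalized, so the field sum is preserved away from edges.
blur3d <- function(x, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(x))
    for (j in seq_along(k)) {
      off <- c(0, 0, 0)
      off[axis] <- j - r - 1L
      acc <- acc + k[j] * shift3d(x, off, fill = 0)
    }
    x <- acc
  }
  x
}

#' Specification of a synthetic paired-scan phantom
#'
#' The phantom is a nested-ellipsoid T1-like object: a bright white-matter
#' core inside a grey-matter shell, surrounded by dark CSF. The measured
#' structure is either the whole outer ellipsoid (`structure = "brain"`,
#' single CSF-GM boundary) or the GM shell itself (`structure = "shell"`,
#' a CSF-facing outer border and a WM-facing inner border, the hippocampus
#' analogue). Atrophy is imposed by uniformly rescaling semi-axes so the
#' structure's analytic volume drops by exactly `atrophy_fraction` between
#' time points, keeping the ground truth in closed form.
#'
#' @param grid_shape 3 integers, array dimensions (default 96^3).
#' @param voxel_size isotropic voxel edge length, mm (default 1).
#' @param structure `"brain"` or `"shell"`.
#' @param outer_semi_axes,inner_semi_axes ellipsoid semi-axes, mm.
#' @param intensities named vector with components `csf`, `gm`, `wm`
#'   (ordering CSF < GM < WM enforced).
#' @param atrophy_fraction true fractional volume loss in \[0, 0.2\].
#' @param pv_sigma smoothing width, mm, applied to intensities and masks on
#'   top of the supersampled partial volume (models acquisition blur and
#'   segmentation smoothness).
#' @param noise_sd additive Gaussian noise SD, intensity units (default 0).
#' @param bias_amplitude peak deviation from 1 of the smooth multiplicative
#'   bias field applied to the repeat image only (default 0).
#' @param interval_years scan interval (default 1, so PBVC equals percent
#'   volume change).
#' @param supersample per-axis subdivisions for the inside-fraction
#'   rasterization (default 4).
#' @param seed integer seed for the noise draws.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), voxel_size = 1,
                         structure = c("brain", "shell"),
                         outer_semi_axes = c(30, 36, 28),
                         inner_semi_axes = 0.55 * outer_semi_axes,
                         intensities = c(csf = 40, gm = 110, wm = 160),
                         atrophy_fraction = 0.02,
                         pv_sigma = 1, noise_sd = 0, bias_amplitude = 0,
                         interval_years = 1, supersample = 4L, seed = 1L) {
  structure_ <- match.arg(structure)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(voxel_size) == 1L, voxel_size > 0,
            length(outer_semi_axes) == 3L, all(outer_semi_axes > 0),
            length(inner_semi_axes) == 3L, all(inner_semi_axes > 0),
            all(inner_semi_axes < outer_semi_axes),
            atrophy_fraction >= 0, atrophy_fraction <= 0.2,
            pv_sigma >= 0, noise_sd >= 0, bias_amplitude >= 0,
            bias_amplitude < 1, interval_years > 0, supersample >= 1)
  iv <- intensities[c("csf", "gm", "wm")]
  if (any(is.na(iv)) || !(iv[1] < iv[2] && iv[2] < iv[3]))
    stop("intensities must be named csf/gm/wm with CSF < GM < WM")
  half_extent <- grid_shape / 2 * voxel_size
  if (any(outer_semi_axes >= half_extent - 2 * voxel_size))
    stop("geometry error: outer ellipsoid does not fit in the grid ",
         "with a 2-voxel margin")
  structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    structure = structure_,
    outer_semi_axes = outer_semi_axes, inner_semi_axes = inner_semi_axes,
    intensities = iv, atrophy_fraction = atrophy_fraction,
    pv_sigma = pv_sigma, noise_sd = noise_sd,
    bias_amplitude = bias_amplitude, interval_years = interval_years,
    supersample = as.integer(supersample), seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Analytic ellipsoid volume
#'
#' @param semi_axes numeric vector of 3 semi-axes, mm.
#' @return Volume in mm^3, `(4/3) * pi * a * b * c`.
#' @export
ellipsoid_volume <- function(semi_axes) {
  4 / 3 * pi * prod(semi_axes)
}

# Per-voxel inside-fraction of an ellipsoid, by supersampling each voxel
# with an s^3 grid of sample points.
inside_fraction <- function(grid_shape, voxel_size, semi_axes, s = 4L) {
  center <- (grid_shape + 1) / 2
  coord <- lapply(1:3, function(k)
    (seq_len(grid_shape[k]) - center[k]) * voxel_size)
  sub <- ((seq_len(s) - (s + 1) / 2) / s) * voxel_size
  n <- prod(grid_shape)
  acc <- numeric(n)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  for (ox in sub) for (oy in sub) for (oz in sub) {
    ux <- ((coord[[1]] + ox) / semi_axes[1])^2
    uy <- ((coord[[2]] + oy) / semi_axes[2])^2
    uz <- ((coord[[3]] + oz) / semi_axes[3])^2
    tot <- rep(ux, times = ny * nz) +
      rep(rep(uy, each = nx), times = nz) +
      rep(uz, each = nx * ny)
    acc <- acc + (tot <= 1)
  }
  array(acc / s^3, grid_shape)
}

# Smooth low-order polynomial field with peak |deviation| = 1 over the grid.
# Contains even terms so its integral against a symmetric region does not
# cancel.
bias_field_unit <- function(grid_shape) {
  u <- lapply(1:3, function(k) {
    n <- grid_shape[k]
    2 * (seq_len(n) - (n + 1) / 2) / n
  })
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  U <- rep(u[[1]], times = ny * nz)
  V <- rep(rep(u[[2]], each = nx), times = nz)
  W <- rep(u[[3]], each = nx * ny)
  g <- 0.6 * U + 0.3 * V - 0.4 * W + 0.5 * U * V - 0.7 * U^2 + 0.4 * W^2
  array(g / max(abs(g)), grid_shape)
}

#' Generate a synthetic scan pair with known volume change
#'
#' Rasterizes the nested ellipsoids with supersampled partial volume,
#' shrinks the structure for the repeat time point by uniform semi-axis
#' scaling (for `"shell"` structures the outer border recedes and the inner
#' border advances, each accounting for half of the loss), mixes compartment
#' intensities by inside fraction, uses the (optionally smoothed) inside
#' fractions as the probabilistic masks, and finally applies noise to both
#' images and a smooth multiplicative bias field to the repeat image.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `pair` (a [scan_pair()]) and `truth` with
#'   `true_volume_baseline_mm3`, `true_volume_repeat_mm3`,
#'   `true_pbvc_percent_per_year`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size; s <- spec$supersample
  f <- spec$atrophy_fraction
  v_out <- ellipsoid_volume(spec$outer_semi_axes)
  v_in <- ellipsoid_volume(spec$inner_semi_axes)

  if (spec$structure == "brain") {
    vol_base <- v_out
    vol_rep <- (1 - f) * v_out
    out_rep <- spec$outer_semi_axes * (1 - f)^(1 / 3)
    in_rep <- spec$inner_semi_axes
  } else {
    shell <- v_out - v_in
    vol_base <- shell
    vol_rep <- (1 - f) * shell
    v_out_rep <- v_out - f / 2 * shell
    v_in_rep <- v_in + f / 2 * shell
    out_rep <- spec$outer_semi_axes * (v_out_rep / v_out)^(1 / 3)
    in_rep <- spec$inner_semi_axes * (v_in_rep / v_in)^(1 / 3)
  }

  fo_b <- inside_fraction(gs, vs, spec$outer_semi_axes, s)
  fi_b <- inside_fraction(gs, vs, spec$inner_semi_axes, s)
  if (f == 0) {
    fo_r <- fo_b; fi_r <- fi_b
  } else {
    fo_r <- inside_fraction(gs, vs, out_rep, s)
    fi_r <- if (all(in_rep == spec$inner_semi_axes)) fi_b else
      inside_fraction(gs, vs, in_rep, s)
  }

  iv <- spec$intensities
  img_b <- iv[["csf"]] + (iv[["gm"]] - iv[["csf"]]) * fo_b +
    (iv[["wm"]] - iv[["gm"]]) * fi_b
  img_r <- iv[["csf"]] + (iv[["gm"]] - iv[["csf"]]) * fo_r +
    (iv[["wm"]] - iv[["gm"]]) * fi_r
  mask_b <- if (spec$structure == "brain") fo_b else fo_b - fi_b
  mask_r <- if (spec$structure == "brain") fo_r else fo_r - fi_r

  if (spec$pv_sigma > 0) {
    sg <- rep(spec$pv_sigma / vs, 3)
    img_b <- blur3d(img_b, sg); img_r <- blur3d(img_r, sg)
    mask_b <- blur3d(mask_b, sg); mask_r <- blur3d(mask_r, sg)
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img_b <- img_b + array(stats::rnorm(length(img_b), 0, spec$noise_sd), gs)
    img_r <- img_r + array(stats::rnorm(length(img_r), 0, spec$noise_sd), gs)
  }
  if (spec$bias_amplitude > 0) {
    img_r <- img_r * (1 + spec$bias_amplitude * bias_field_unit(gs))
  }

  grid_b <- volume_grid(img_b, voxel_size = rep(vs, 3))
  grid_r <- volume_grid(img_r, voxel_size = rep(vs, 3))
  pair <- scan_pair(grid_b, grid_r,
                    prob_mask(pmin(pmax(mask_b, 0), 1), grid_b),
                    prob_mask(pmin(pmax(mask_r, 0), 1), grid_r),
                    interval_years = spec$interval_years)
  truth <- list(
    true_volume_baseline_mm3 = vol_base,
    true_volume_repeat_mm3 = vol_rep,
    true_pbvc_percent_per_year =
      100 * (vol_base - vol_rep) / vol_base / spec$interval_years)
  list(pair = pair, truth = truth)
}

#' Refine the resolution of a phantom specification
#'
#' Divides the voxel size by `factor` and multiplies the grid shape by it,
#' leaving the geometry (and hence the analytic truth volumes) unchanged.
#' Used for the convergence check: measured BSI error against the analytic
#' truth must not grow as resolution increases.
#'
#' @param spec a [phantom_spec()].
#' @param factor integer refinement factor (>= 1).
#' @param max_voxels memory guard on the refined grid's voxel count.
#' @return A refined [phantom_spec()].
#' @export
refine_resolution <- function(spec, factor, max_voxels = 2.5e8) {
  stopifnot(inherits(spec, "phantom_spec"), factor >= 1,
            factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(spec)
  new_shape <- spec$grid_shape * factor
  if (prod(new_shape) > max_voxels)
    stop("resource error: refined grid would have ", prod(new_shape),
         " voxels (cap ", max_voxels, ")")
  phantom_spec(grid_shape = new_shape,
               voxel_size = spec$voxel_size / factor,
               structure = spec$structure,
               outer_semi_axes = spec$outer_semi_axes,
               inner_semi_axes = spec$inner_semi_axes,
               intensities = spec$intensities,
               atrophy_fraction = spec$atrophy_fraction,
               pv_sigma = spec$pv_sigma, noise_sd = spec$noise_sd,
               bias_amplitude = spec$bias_amplitude,
               interval_years = spec$interval_years,
               supersample = spec$supersample, seed = spec$seed)
}

#' Write a phantom pair to disk as NIfTI plus a truth side-car
#'
#' @param phantom result of [make_phantom()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- phantom$pair
  paths <- c(
    baseline = file.path(dir, paste0(prefix, "_baseline.nii.gz")),
    repeat_ = file.path(dir, paste0(prefix, "_repeat.nii.gz")),
    baseline_mask = file.path(dir, paste0(prefix, "_baseline_mask.nii.gz")),
    repeat_mask = file.path(dir, paste0(prefix, "_repeat_mask.nii.gz")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  save_volume(p$baseline, paths[["baseline"]], datatype = "float")
  save_volume(p$repeat_, paths[["repeat_"]], datatype = "float")
  save_volume(volume_grid(p$baseline_mask$prob, p$baseline$voxel_size),
              paths[["baseline_mask"]], datatype = "float")
  save_volume(volume_grid(p$repeat_mask$prob, p$repeat_$voxel_size),
              paths[["repeat_mask"]], datatype = "float")
  truth <- c(phantom$truth, list(interval_years = p$interval_years))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
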