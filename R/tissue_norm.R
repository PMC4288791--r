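#' Region of interest for tissue-mean estimation
#'
#' Binarizes the probabilistic mask at 0.5 and dilates it; the default 3
#' dilations extend the brain mask outward to include some CSF, so that the
#' CSF cluster is represented when tissue means are estimated.
#'
#' @param mask a [prob_mask()].
#' @param dilations non-negative dilation count (default 3).
#' @param connectivity structuring element connectivity, 6 or 26.
#' @return A binary [prob_mask()].
#' @export
kmeans_region <- function(mask, dilations = 3L, connectivity = 6L) {
  stopifnot(inherits(mask, "prob_mask"), dilations >= 0)
  bin <- binarize(mask, 0.5)
  if (sum(bin$prob) == 0)
    stop("degenerate input: binarized mask is empty")
  prob_mask(dilate3d(bin$prob, dilations, connectivity), mask$grid)
}

#' Estimate CSF/GM/WM tissue intensity statistics
#'
#' Runs one-dimensional k-means (k = 3, Lloyd iterations, deterministic
#' initialization at the 10th/50th/90th intensity percentiles of the region)
#' on the intensities inside `region`, labels the clusters CSF/GM/WM in
#' ascending order of cluster mean, and additionally computes the mean
#' intensity of the interior region (the 0.5-binarized mask eroded once),
#' which excludes the partial-volume rim.
#'
#' @param image a [volume_grid()].
#' @param region binary [prob_mask()] within which intensities are clustered
#'   (typically from [kmeans_region()]).
#' @param mask the structure's probabilistic mask, used for the interior
#'   mean; defaults to `region` itself.
#' @param iter_max Lloyd iteration cap.
#' @param connectivity connectivity for the interior erosion.
#' @return A `tissue_means` object: `csf_mean`, `csf_sd`, `gm_mean`, `gm_sd`,
#'   `wm_mean`, `wm_sd`, `interior_mean`, plus cluster sizes.
#' @export
estimate_tissue_means <- function(image, region, mask = region,
                                  iter_max = 300L, connectivity = 6L) {
  stopifnot(inherits(image, "volume_grid"), inherits(region, "prob_mask"))
  check_same_grid(image$data, region$prob, "image and region")
  inside <- region$prob >= 0.5
  vals <- image$data[inside]
  if (length(vals) < 9L)
    stop("degenerate input: region has ", length(vals),
         " voxels; at least 9 required for k = 3 clustering")
  centers <- unname(stats::quantile(vals, c(0.1, 0.5, 0.9), names = FALSE))
  if (length(unique(vals)) < 3L)
    stop("degenerate input: fewer than 3 distinct intensity values in region")
  # percentile starts can coincide on heavily quantized data; nudge apart
  if (anyDuplicated(centers)) {
    uv <- sort(unique(vals))
    centers <- uv[round(stats::quantile(seq_along(uv), c(0.1, 0.5, 0.9)))]
    centers <- unique(centers)
    if (length(centers) < 3L)
      centers <- uv[unique(pmin(length(uv), c(1L, ceiling(length(uv) / 2), length(uv))))]
  }
  km <- suppressWarnings(
    stats::kmeans(vals, centers = matrix(centers, ncol = 1),
                  iter.max = iter_max, algorithm = "Lloyd"))
  if (km$iter >= iter_max)
    stop("k-means did not converge within ", iter_max, " iterations")
  ord <- order(km$centers[, 1])
  means <- unname(km$centers[ord, 1])
  sds <- sizes <- numeric(3)
  for (j in 1:3) {
    cl <- vals[km$cluster == ord[j]]
    sizes[j] <- length(cl)
    sds[j] <- if (length(cl) > 1L) stats::sd(cl) else 0
  }
  interior <- erode3d(binarize(mask, 0.5)$prob, 1L, connectivity)
  interior_mean <- if (sum(interior) > 0) {
    mean(image$data[interior > 0])
  } else {
    # structure thinner than one erosion: fall back to the binarized mask
    mean(image$data[binarize(mask, 0.5)$prob > 0])
  }
  tm <- structure(
    list(csf_mean = means[1], csf_sd = sds[1],
         gm_mean = means[2], gm_sd = sds[2],
         wm_mean = means[3], wm_sd = sds[3],
         interior_mean = interior_mean,
         cluster_sizes = sizes),
    class = "tissue_means")
  validate_tissue_means(tm)
  tm
}

validate_tissue_means <- function(tm) {
  if (!(tm$csf_mean < tm$gm_mean && tm$gm_mean < tm$wm_mean))
    stop("tissue mean ordering violated (need CSF < GM < WM): ",
         signif(tm$csf_mean, 5), ", ", signif(tm$gm_mean, 5), ", ",
         signif(tm$wm_mean, 5))
  if (any(c(tm$csf_sd, tm$gm_sd, tm$wm_sd) < 0))
    stop("negative tissue SD")
  invisible(tm)
}

#' Assemble tissue statistics by hand
#'
#' Mainly for testing and for window calculations from known statistics.
#' @param csf_mean,csf_sd,gm_mean,gm_sd,wm_mean,wm_sd,interior_mean tissue
#'   intensity statistics (T1-weighted ordering CSF < GM < WM enforced).
#' @return A `tissue_means` object.
#' @export
tissue_means <- function(csf_mean, csf_sd, gm_mean, gm_sd, wm_mean, wm_sd,
                         interior_mean = (gm_mean + wm_mean) / 2) {
  tm <- structure(
    list(csf_mean = csf_mean, csf_sd = csf_sd, gm_mean = gm_mean,
         gm_sd = gm_sd, wm_mean = wm_mean, wm_sd = wm_sd,
         interior_mean = interior_mean, cluster_sizes = rep(NA_real_, 3)),
    class = "tissue_means")
  validate_tissue_means(tm)
  tm
}

#' @export
print.tissue_means <- function(x, ...) {
  cat("<tissue_means> CSF ", signif(x$csf_mean, 5), " (", signif(x$csf_sd, 4),
      "), GM ", signif(x$gm_mean, 5), " (", signif(x$gm_sd, 4),
      "), WM ", signif(x$wm_mean, 5), " (", signif(x$wm_sd, 4),
      "), interior ", signif(x$interior_mean, 5), "\n", sep = "")
  invisible(x)
}

#' Intensity normalization of the repeat image onto the baseline
#'
#' Fits slope and intercept by ordinary least squares through the four paired
#' points (repeat tissue mean, baseline tissue mean) for CSF, GM, WM and the
#' interior region, and applies the map voxelwise to the repeat image. The
#' baseline is left untouched so the baseline intensity scale defines the
#' clipping windows.
#'
#' @param baseline,repeat_ the two [volume_grid()]s.
#' @param tm_base,tm_rep their `tissue_means`.
#' @return A list: `repeat_norm` (normalized repeat [volume_grid()]),
#'   `slope`, `intercept`, and `tm_rep_norm` (the repeat tissue statistics
#'   mapped through the fit).
#' @export
normalize_pair <- function(baseline, repeat_, tm_base, tm_rep) {
  stopifnot(inherits(tm_base, "tissue_means"), inherits(tm_rep, "tissue_means"))
  x <- c(tm_rep$csf_mean, tm_rep$gm_mean, tm_rep$wm_mean, tm_rep$interior_mean)
  y <- c(tm_base$csf_mean, tm_base$gm_mean, tm_base$wm_mean,
         tm_base$interior_mean)
  if (stats::sd(x) == 0)
    stop("degenerate fit: repeat tissue means have zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- fit$coefficients[1]; a <- fit$coefficients[2]
  rep_norm <- volume_grid(a * repeat_$data + b,
                          voxel_size = repeat_$voxel_size,
                          affine = repeat_$affine)
  tm_rep_norm <- tissue_means(
    csf_mean = a * tm_rep$csf_mean + b, csf_sd = abs(a) * tm_rep$csf_sd,
    gm_mean = a * tm_rep$gm_mean + b, gm_sd = abs(a) * tm_rep$gm_sd,
    wm_mean = a * tm_rep$wm_mean + b, wm_sd = abs(a) * tm_rep$wm_sd,
    interior_mean = a * tm_rep$interior_mean + b)
  list(repeat_norm = rep_norm, slope = unname(a), intercept = unname(b),
       tm_rep_norm = tm_rep_norm)
}

#' Intensity clipping window
#'
#' @param low,high window bounds in intensity units; `low < high` required.
#' @return An `intensity_window` object.
#' @export
intensity_window <- function(low, high) {
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("window collapse: low (", signif(low, 5), ") >= high (",
         signif(high, 5), ") - tissue intensity distributions overlap")
  structure(list(low = low, high = high), class = "intensity_window")
}

#' @export
print.intensity_window <- function(x, ...) {
  cat("<intensity_window> [", signif(x$low, 6), ", ", signif(x$high, 6),
      "]\n", sep = "")
  invisible(x)
}

#' Automatic single intensity window (CSF-GM border)
#'
#' The window is `[csf_mean + csf_sd, gm_mean - gm_sd]`, computed from tissue
#' statistics averaged across the two time points. It brackets the intensity
#' ramp a voxel traverses when brain tissue at the CSF border is lost.
#'
#' @param tm_avg averaged `tissue_means` (see [average_tissue_means()]).
#' @return An [intensity_window()].
#' @export
single_window <- function(tm_avg) {
  stopifnot(inherits(tm_avg, "tissue_means"))
  lo <- tm_avg$csf_mean + tm_avg$csf_sd
  hi <- tm_avg$gm_mean - tm_avg$gm_sd
  tryCatch(intensity_window(lo, hi), error = function(e)
    stop("CSF-GM window collapse: [", signif(lo, 5), ", ", signif(hi, 5),
         "] - CSF and GM intensity distributions overlap"))
}

#' Automatic double intensity window (CSF-GM and GM-WM borders)
#'
#' For structures bordered by both CSF and white matter (the hippocampus),
#' boundary shift occurs at two tissue interfaces; the same selection rule is
#' applied to each flanking tissue pair: `[csf_mean + csf_sd, gm_mean -
#' gm_sd]` and `[gm_mean + gm_sd, wm_mean - wm_sd]`.
#'
#' @param tm_avg averaged `tissue_means`.
#' @return A list with [intensity_window()]s `csf_gm` and `gm_wm`.
#' @export
double_window <- function(tm_avg) {
  stopifnot(inherits(tm_avg, "tissue_means"))
  w1 <- single_window(tm_avg)
  lo <- tm_avg$gm_mean + tm_avg$gm_sd
  hi <- tm_avg$wm_mean - tm_avg$wm_sd
  w2 <- tryCatch(intensity_window(lo, hi), error = function(e)
    stop("GM-WM window collapse: [", signif(lo, 5), ", ", signif(hi, 5),
         "] - GM and WM intensity distributions overlap"))
  list(csf_gm = w1, gm_wm = w2)
}

#' Average tissue statistics across the two time points
#'
#' Averaging the per-time-point statistics and then forming the window is
#' equivalent to averaging the two windows' bounds, since the window formulas
#' are linear in the statistics.
#'
#' @param tm_a,tm_b `tissue_means` of the two time points.
#' @return A `tissue_means` object of elementwise averages.
#' @export
average_tissue_means <- function(tm_a, tm_b) {
  stopifnot(inherits(tm_a, "tissue_means"), inherits(tm_b, "tissue_means"))
  tissue_means(
    csf_mean = (tm_a$csf_mean + tm_b$csf_mean) / 2,
    csf_sd = (tm_a$csf_sd + tm_b$csf_sd) / 2,
    gm_mean = (tm_a$gm_mean + tm_b$gm_mean) / 2,
    gm_sd = (tm_a$gm_sd + tm_b$gm_sd) / 2,
    wm_mean = (tm_a$wm_mean + tm_b$wm_mean) / 2,
    wm_sd = (tm_a$wm_sd + tm_b$wm_sd) / 2,
    interior_mean = (tm_a$interior_mean + tm_b$interior_mean) / 2)
}
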