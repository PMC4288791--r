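#' Construct a volume grid
#'
#' A `volume_grid` is a 3D scalar intensity image together with its voxel
#' dimensions (mm) and affine orientation matrix. The voxel volume `D`
#' (product of the voxel sizes, in mm^3) is the measure element of the
#' boundary shift integral.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param affine 4x4 orientation matrix; defaults to a diagonal scaling
#'   matrix built from `voxel_size`.
#' @return An object of class `volume_grid` with fields `data`, `voxel_size`,
#'   `affine` and `voxel_volume` (mm^3).
#' @export
volume_grid <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive values (mm)")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  data <- array(as.double(data), dim(data))  # drop foreign attributes
  structure(
    list(data = data, voxel_size = voxel_size, affine = affine,
         voxel_volume = prod(voxel_size)),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm (D = ", signif(x$voxel_volume, 6), " mm^3)\n", sep = "")
  invisible(x)
}

#' Construct a probabilistic mask
#'
#' A `prob_mask` annotates every voxel of a [volume_grid()] with a
#' region-membership probability in \[0, 1\]. Probabilistic segmentations
#' carry partial-volume information at the structure boundary that binary
#' masks discard.
#'
#' @param prob 3D numeric array of membership probabilities.
#' @param grid the [volume_grid()] the mask annotates.
#' @param tol values in `[-tol, 0)` or `(1, 1 + tol]` are clamped into
#'   \[0, 1\] (small overshoots arise from resampling); larger violations
#'   are an error.
#' @return An object of class `prob_mask` with fields `prob` and `grid`.
#' @export
prob_mask <- function(prob, grid, tol = 1e-3) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.array(prob) || length(dim(prob)) != 3L)
    stop("`prob` must be a 3D array")
  if (!all(dim(prob) == dim(grid$data)))
    stop("mask shape (", paste(dim(prob), collapse = "x"),
         ") does not match grid shape (",
         paste(dim(grid$data), collapse = "x"), ")")
  if (any(!is.finite(prob)))
    stop("mask contains non-finite values")
  lo <- min(prob); hi <- max(prob)
  if (lo < -tol || hi > 1 + tol)
    stop("mask values outside [", -tol, ", ", 1 + tol, "]: range [",
         signif(lo, 6), ", ", signif(hi, 6),
         "] - not a probability map")
  prob[prob < 0] <- 0
  prob[prob > 1] <- 1
  storage.mode(prob) <- "double"
  structure(list(prob = prob, grid = grid), class = "prob_mask")
}

#' @export
print.prob_mask <- function(x, ...) {
  cat("<prob_mask> ", paste(dim(x$prob), collapse = " x "),
      " voxels, prob range [", signif(min(x$prob), 4), ", ",
      signif(max(x$prob), 4), "]\n", sep = "")
  invisible(x)
}

#' Load a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file (optionally gzip-compressed). 4D files with a
#' singleton trailing dimension are squeezed to 3D; genuinely >3D files are
#' rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  dm <- dim(dat)
  if (length(dm) > 3L) {
    keep <- which(dm > 1L)
    if (length(keep) > 3L)
      stop("volume has ", length(keep),
           " non-singleton dimensions; a 3D scalar volume is required")
    dat <- array(dat, dim = dm[seq_len(max(3L, max(keep)))])
    dim(dat) <- dm[1:3]
  } else if (length(dm) < 3L) {
    stop("volume has fewer than 3 dimensions")
  }
  pd <- RNifti::pixdim(img)[1:3]
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  volume_grid(dat, voxel_size = pd, affine = aff)
}

#' Save a volume grid as NIfTI
#'
#' @param grid a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype; `"auto"` stores integer-valued data as
#'   int32 (lossless round trip) and everything else as float32.
#' @return `path`, invisibly.
#' @export
save_volume <- function(grid, path, datatype = "auto") {
  stopifnot(inherits(grid, "volume_grid"))
  dat <- grid$data
  if (identical(datatype, "auto")) {
    is_int <- all(dat == round(dat)) && max(abs(dat)) < 2^31
    datatype <- if (is_int) "int32" else "float"
  }
  img <- RNifti::asNifti(structure(dat, pixdim = grid$voxel_size),
                         datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Load a probabilistic mask and attach it to a grid
#'
#' @param path NIfTI file of membership probabilities in \[0, 1\].
#' @param grid the [volume_grid()] the mask must match.
#' @param tol clamping tolerance passed to [prob_mask()].
#' @return A [prob_mask()].
#' @export
load_prob_mask <- function(path, grid, tol = 1e-3) {
  vol <- load_volume(path)
  if (!all(dim(vol$data) == dim(grid$data)))
    stop("mask grid mismatch: mask is ",
         paste(dim(vol$data), collapse = "x"), ", image grid is ",
         paste(dim(grid$data), collapse = "x"))
  prob_mask(vol$data, grid, tol = tol)
}

#' Binarize a probabilistic mask
#'
#' Voxels with probability greater than or equal to `threshold` are set to 1,
#' the rest to 0. Ties at the threshold count as inside, so a uniform-0.5 mask
#' binarized at 0.5 is full.
#'
#' @param mask a [prob_mask()].
#' @param threshold probability cut in (0, 1); default 0.5.
#' @return A binary-valued [prob_mask()].
#' @export
binarize <- function(mask, threshold = 0.5) {
  stopifnot(inherits(mask, "prob_mask"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single value in (0, 1)")
  out <- array(0, dim(mask$prob))
  out[mask$prob >= threshold] <- 1
  prob_mask(out, mask$grid)
}

#' Bundle a registered scan pair
#'
#' The two images and their probabilistic masks are assumed to be resampled
#' into a common half-way space already: all four arrays must share one shape
#' and one voxel geometry.
#'
#' @param baseline,repeat_ baseline and repeat [volume_grid()]s.
#' @param baseline_mask,repeat_mask their [prob_mask()]s.
#' @param interval_years scan interval in years (> 0).
#' @return An object of class `scan_pair`.
#' @export
scan_pair <- function(baseline, repeat_, baseline_mask, repeat_mask,
                      interval_years = 1) {
  stopifnot(inherits(baseline, "volume_grid"),
            inherits(repeat_, "volume_grid"),
            inherits(baseline_mask, "prob_mask"),
            inherits(repeat_mask, "prob_mask"))
  shp <- dim(baseline$data)
  for (nm in list(list("repeat image", dim(repeat_$data)),
                  list("baseline mask", dim(baseline_mask$prob)),
                  list("repeat mask", dim(repeat_mask$prob)))) {
    if (!all(nm[[2]] == shp))
      stop("grid mismatch: ", nm[[1]], " is ",
           paste(nm[[2]], collapse = "x"), ", baseline is ",
           paste(shp, collapse = "x"))
  }
  if (max(abs(baseline$voxel_size - repeat_$voxel_size)) > 1e-6)
    stop("grid mismatch: baseline and repeat voxel sizes differ")
  if (!is.numeric(interval_years) || length(interval_years) != 1L ||
      !is.finite(interval_years) || interval_years <= 0)
    stop("`interval_years` must be a single positive number")
  structure(list(baseline = baseline, repeat_ = repeat_,
                 baseline_mask = baseline_mask, repeat_mask = repeat_mask,
                 interval_years = interval_years),
            class = "scan_pair")
}

# shared internal: insist two 3D arrays live on one grid
check_same_grid <- function(a, b, what = "inputs") {
  if (!all(dim(a) == dim(b)))
    stop("grid mismatch: ", what, " have shapes ",
         paste(dim(a), collapse = "x"), " and ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
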