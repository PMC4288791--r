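#' Probabilistic exclusive OR of two segmentations
#'
#' The probabilistic XOR of membership probabilities A and B is
#' `A(1-B) + (1-A)B - A(1-B)(1-A)B` (probabilistic union of the two
#' disagreement events). It approaches 1 where the two time points'
#' segmentations disagree strongly and is exactly 0 wherever both are 0 or
#' both are 1.
#'
#' @param A,B [prob_mask()]s on one grid, or plain arrays in \[0, 1\].
#' @return A 3D array in \[0, 1\].
#' @export
pxor <- function(A, B) {
  a <- if (inherits(A, "prob_mask")) A$prob else A
  b <- if (inherits(B, "prob_mask")) B$prob else B
  check_same_grid(a, b, "masks")
  ab <- a * (1 - b)
  ba <- (1 - a) * b
  ab + ba - ab * ba
}

#' Adaptive gain factor
#'
#' The mean of the strictly positive voxels of the probabilistic XOR field.
#' Using the mean rather than a fixed value adapts the gain to the boundary
#' uncertainty of the particular scan pair.
#'
#' @param pxor_field 3D array from [pxor()].
#' @return A single value in (0, 1\].
#' @export
adaptive_kappa <- function(pxor_field) {
  pos <- pxor_field[pxor_field > 0]
  if (length(pos) == 0L)
    stop("degenerate region: pXOR field is identically zero ",
         "(identical masks)")
  mean(pos)
}

new_boundary_region <- function(weights, variant, kappa = NA_real_,
                                params = list()) {
  structure(list(weights = weights, variant = variant, kappa = kappa,
                 params = params),
            class = "boundary_region")
}

#' @export
print.boundary_region <- function(x, ...) {
  cat("<boundary_region> variant ", x$variant, ", ",
      sum(x$weights > 0), " active voxels",
      if (!is.na(x$kappa)) paste0(", kappa = ", signif(x$kappa, 4)),
      "\n", sep = "")
  invisible(x)
}

#' gBSI probabilistic boundary region
#'
#' Computes the probabilistic XOR of the two masks and rescales it by the
#' gain factor kappa: weights are `pXOR/kappa` where `pXOR < kappa` and 1
#' otherwise (values equal to kappa map to 1). The gain acts like the
#' dilation/erosion of the classic binary region, widening the effective
#' region of interest adaptively. With `kappa_override = 1` and binary
#' masks this reverts exactly to the classic binary XOR region.
#'
#' @param A,B baseline and repeat [prob_mask()]s.
#' @param kappa_override optional fixed gain in (0, 1\]; by default
#'   [adaptive_kappa()] of the pXOR field is used.
#' @return A `boundary_region` (variant `"pxor_gbsi"`) storing the kappa used.
#' @export
gbsi_region <- function(A, B, kappa_override = NULL) {
  px <- pxor(A, B)
  if (is.null(kappa_override)) {
    kappa <- if (any(px > 0)) adaptive_kappa(px) else 1
  } else {
    if (kappa_override <= 0 || kappa_override > 1)
      stop("kappa_override must be in (0, 1]")
    kappa <- kappa_override
  }
  w <- px / kappa
  w[px >= kappa] <- 1
  new_boundary_region(w, "pxor_gbsi", kappa = kappa)
}

#' Classic binary XOR boundary region (KN-BSI)
#'
#' Binarizes both masks at 0.5, dilates their union and erodes their
#' intersection, and takes the set difference: weights are 1 on
#' `dilate(A | B) & !erode(A & B)`, 0 elsewhere.
#'
#' @param A,B baseline and repeat [prob_mask()]s.
#' @param n_dilate,n_erode morphology iteration counts (defaults 1 and 1).
#' @param connectivity 6 (default) or 26.
#' @return A `boundary_region` (variant `"binary_xor"`).
#' @export
binary_xor_region <- function(A, B, n_dilate = 1L, n_erode = 1L,
                              connectivity = 6L) {
  stopifnot(inherits(A, "prob_mask"), inherits(B, "prob_mask"),
            n_dilate >= 0, n_erode >= 0)
  check_same_grid(A$prob, B$prob, "masks")
  a <- binarize(A, 0.5)$prob
  b <- binarize(B, 0.5)$prob
  U <- dilate3d(pmax(a, b), n_dilate, connectivity)
  N <- erode3d(pmin(a, b), n_erode, connectivity)
  w <- U * (1 - N)
  new_boundary_region(w, "binary_xor",
                      params = list(n_dilate = n_dilate, n_erode = n_erode,
                                    connectivity = connectivity))
}

#' Fuzzy pBSI parameters
#'
#' @param eta threshold for the fuzzy intersection (default 0.95).
#' @param zeta threshold for the fuzzy union (default 0.90).
#' @param n_e erosions of the thresholded intersection (default 0).
#' @param n_d dilations of the thresholded union (default 1).
#' @param gamma weighting floor: 1 gives the unweighted pBSI_1 region,
#'   0.5 the probability-weighted pBSI_gamma region.
#' @return A `pbsi_params` list.
#' @export
pbsi_params <- function(eta = 0.95, zeta = 0.90, n_e = 0L, n_d = 1L,
                        gamma = 1) {
  stopifnot(eta > 0, eta <= 1, zeta > 0, zeta <= 1, gamma > 0, gamma <= 1,
            n_e >= 0, n_d >= 0)
  structure(list(eta = eta, zeta = zeta, n_e = as.integer(n_e),
                 n_d = as.integer(n_d), gamma = gamma),
            class = "pbsi_params")
}

#' Fuzzy pBSI boundary region
#'
#' The fuzzy union `max(A, B)` is thresholded at `zeta` and dilated `n_d`
#' times; the fuzzy intersection `min(A, B)` is thresholded at `eta` and
#' eroded `n_e` times; the binary XOR region is their set difference. On that
#' region each voxel is weighted by `max(gamma, (A + B)/2)`; with `gamma = 1`
#' the weights are identically 1.
#'
#' @param A,B baseline and repeat [prob_mask()]s.
#' @param params a [pbsi_params()] record.
#' @param connectivity 6 (default) or 26.
#' @param combine how the two time points' probabilities enter the weight:
#'   `"mean"` (default) or `"max"`.
#' @return A `boundary_region` (variant `"pbsi_1"` when `gamma == 1`, else
#'   `"pbsi_gamma"`).
#' @export
pbsi_region <- function(A, B, params = pbsi_params(), connectivity = 6L,
                        combine = c("mean", "max")) {
  stopifnot(inherits(A, "prob_mask"), inherits(B, "prob_mask"),
            inherits(params, "pbsi_params"))
  combine <- match.arg(combine)
  check_same_grid(A$prob, B$prob, "masks")
  a <- A$prob; b <- B$prob
  U <- dilate3d((pmax(a, b) >= params$zeta) * 1, params$n_d, connectivity)
  N <- erode3d((pmin(a, b) >= params$eta) * 1, params$n_e, connectivity)
  X <- U * (1 - N)
  p <- if (combine == "mean") (a + b) / 2 else pmax(a, b)
  w <- X * pmax(params$gamma, p)
  variant <- if (params$gamma == 1) "pbsi_1" else "pbsi_gamma"
  new_boundary_region(w, variant, params = unclass(params))
}
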