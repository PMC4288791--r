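# Binary 3D morphology on arrays, via whole-array shifts. One iteration uses
# the 6-connected (face-adjacent) or 26-connected structuring element; voxels
# outside the grid count as background for both operations.

shift3d <- function(x, off, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) {
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- src[[k]] + o
    } else {
      dst[[k]] <- seq_len(d[k] + o)
      src[[k]] <- dst[[k]] - o
    }
    if (length(src[[k]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

conn_offsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
         c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offs <- offs[rowSums(abs(offs)) > 0, ]
    lapply(seq_len(nrow(offs)), function(i) as.numeric(offs[i, ]))
  } else {
    stop("connectivity must be 6 or 26")
  }
}

#' Binary dilation of a 3D array
#'
#' @param x 3D array of 0/1 (or logical) values.
#' @param iterations number of dilation passes (0 returns `x` unchanged).
#' @param connectivity 6 (face-adjacent, default) or 26 (full cube).
#' @return 0/1 double array of the same shape.
#' @export
dilate3d <- function(x, iterations = 1L, connectivity = 6L) {
  stopifnot(iterations >= 0)
  out <- array(as.double(x != 0), dim(x))
  if (iterations == 0L) return(out)
  offs <- conn_offsets(connectivity)
  for (i in seq_len(iterations)) {
    acc <- out
    for (o in offs) acc <- pmax(acc, shift3d(out, o, fill = 0))
    out <- acc
  }
  out
}

#' Binary erosion of a 3D array
#'
#' Voxels outside the grid are background, so foreground touching the grid
#' border erodes.
#'
#' @inheritParams dilate3d
#' @return 0/1 double array of the same shape.
#' @export
erode3d <- function(x, iterations = 1L, connectivity = 6L) {
  stopifnot(iterations >= 0)
  out <- array(as.double(x != 0), dim(x))
  if (iterations == 0L) return(out)
  offs <- conn_offsets(connectivity)
  for (i in seq_len(iterations)) {
    acc <- out
    for (o in offs) acc <- pmin(acc, shift3d(out, o, fill = 0))
    out <- acc
  }
  out
}
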