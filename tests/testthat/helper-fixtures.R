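# Shared fixture builders. Everything is generated in code; tests that need
# files write them under withr-style tempdirs via base tempfile().

# a tiny grid with constant-plus-index intensities
toy_grid <- function(shape = c(6, 6, 6), voxel_size = c(1, 1, 1),
                     data = NULL) {
  if (is.null(data)) data <- array(seq_len(prod(shape)), shape)
  volume_grid(data, voxel_size = voxel_size)
}

# a binary prob_mask from an indicator function over 1-based voxel indices
mask_from_predicate <- function(grid, pred) {
  shape <- dim(grid$data)
  idx <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                     k = seq_len(shape[3]))
  m <- array(as.double(pred(idx$i, idx$j, idx$k)), shape)
  prob_mask(m, grid)
}

# random probabilistic mask pair on a shared grid
random_mask_pair <- function(shape = c(9, 9, 9), seed = 1, binary = FALSE) {
  set.seed(seed)
  g <- volume_grid(array(stats::runif(prod(shape), 50, 150), shape))
  a <- array(stats::runif(prod(shape)), shape)
  b <- array(stats::runif(prod(shape)), shape)
  if (binary) {
    a <- (a > 0.5) * 1
    b <- (b > 0.5) * 1
  }
  list(grid = g, A = prob_mask(a, g), B = prob_mask(b, g))
}

# small fast phantom for end-to-end tests (coarse grid, big voxels)
small_phantom <- function(atrophy = 0.02, ...) {
  make_phantom(phantom_spec(grid_shape = c(40, 40, 40), voxel_size = 2.5,
                            outer_semi_axes = c(30, 36, 28),
                            atrophy_fraction = atrophy, ...))
}

# brute-force binary dilation oracle: neighborhood enumeration
brute_dilate <- function(x, iterations, connectivity = 6L) {
  offs <- rbind(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  d <- dim(x)
  for (it in seq_len(iterations)) {
    out <- x
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (x[i, j, k] == 0) next
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs$dx[r]; jj <- j + offs$dy[r]; kk <- k + offs$dz[r]
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            kk >= 1 && kk <= d[3])
          out[ii, jj, kk] <- 1
      }
    }
    x <- out
  }
  x
}

# brute-force erosion: a voxel survives iff every structuring-element
# neighbor is foreground; neighbors outside the grid count as background
brute_erode <- function(x, iterations, connectivity = 6L) {
  offs <- rbind(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  d <- dim(x)
  for (it in seq_len(iterations)) {
    out <- x
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (x[i, j, k] == 0) next
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs$dx[r]; jj <- j + offs$dy[r]; kk <- k + offs$dz[r]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3] || x[ii, jj, kk] == 0) {
          out[i, j, k] <- 0
          break
        }
      }
    }
    x <- out
  }
  x
}
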