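# Shape builders and lattice enumerations used as test fixtures/oracles.

mk_mask <- function(dim, fg, spacing = c(1, 1, 1), label = "whole") {
  g <- array(FALSE, dim)
  g[fg] <- TRUE
  volume_mask(g, spacing, label)
}

# digital ball: voxel centers within distance r of the grid center
mk_ball <- function(r, spacing = c(1, 1, 1), pad = 2) {
  n <- 2 * r + 1 + 2 * pad
  ctr <- rep((n + 1) / 2, 3)
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
  mk_mask(c(n, n, n), idx[d2 <= r^2, , drop = FALSE], spacing)
}

mk_cuboid <- function(a, b, c, spacing = c(1, 1, 1)) {
  g <- array(FALSE, c(a + 4, b + 4, c + 4))
  g[3:(a + 2), 3:(b + 2), 3:(c + 2)] <- TRUE
  volume_mask(g, spacing)
}

# digital solid ellipsoid with given semi-axes
mk_ellipsoid <- function(a, b, c) {
  dim <- c(2 * a + 5, 2 * b + 5, 2 * c + 5)
  ctr <- (dim + 1) / 2
  idx <- which(array(TRUE, dim), arr.ind = TRUE)
  ins <- ((idx[, 1] - ctr[1]) / a)^2 + ((idx[, 2] - ctr[2]) / b)^2 +
    ((idx[, 3] - ctr[3]) / c)^2 <= 1
  mk_mask(dim, idx[ins, , drop = FALSE])
}

# L-shape: two 10^3 cubes sharing a face edge-on (non-convex)
mk_L <- function(side = 10) {
  g <- array(FALSE, c(2 * side + 4, 2 * side + 4, side + 4))
  g[2:(side + 1), 2:(side + 1), 2:(side + 1)] <- TRUE
  g[(side + 2):(2 * side + 1), 2:(side + 1), 2:(side + 1)] <- TRUE
  g[2:(side + 1), (side + 2):(2 * side + 1), 2:(side + 1)] <- TRUE
  volume_mask(g)
}

# random connected blob grown by seeded neighbor accretion
mk_blob <- function(n_vox = 60, seed = 1, dim = c(24, 24, 24)) {
  stopifnot(n_vox >= 8)
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  set.seed(seed)
  ctr <- floor(dim / 2)
  fg <- matrix(ctr, 1, 3)
  keyify <- function(m) paste(m[, 1], m[, 2], m[, 3])
  occupied <- new.env(parent = emptyenv())
  assign(keyify(fg), TRUE, envir = occupied)
  frontier <- sweep(nbr, 2, ctr, "+")
  while (nrow(fg) < n_vox && nrow(frontier) > 0) {
    i <- sample.int(nrow(frontier), 1)
    v <- frontier[i, ]
    frontier <- frontier[-i, , drop = FALSE]
    k <- paste(v[1], v[2], v[3])
    if (!is.null(occupied[[k]])) next
    if (any(v < 2) || any(v > dim - 1)) next
    occupied[[k]] <- TRUE
    fg <- rbind(fg, v)
    cand <- sweep(nbr, 2, v, "+")
    frontier <- rbind(frontier, cand)
  }
  mk_mask(dim, fg)
}
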