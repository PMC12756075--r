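# Independent oracles: brute-force convex-hull lattice counting and a naive
# pure-R coordinate-descent LASSO. Deliberately written against different
# algorithms/code paths than the package implementation.

# All planes through point triples that have every point on one side
# (classic O(n^3) facet enumeration), then count bounding-box lattice points
# inside the half-space intersection.
oracle_hull_lattice_count <- function(pts, tol = NULL) {
  pts <- unique(pts)
  n <- nrow(pts)
  stopifnot(n >= 4, n <= 400)
  if (is.null(tol)) tol <- 1e-7 * max(1, abs(pts))
  tri <- utils::combn(n, 3)
  planes <- NULL
  for (chunk in split(seq_len(ncol(tri)),
                      ceiling(seq_len(ncol(tri)) / 20000))) {
    a <- pts[tri[1, chunk], , drop = FALSE]
    u <- pts[tri[2, chunk], , drop = FALSE] - a
    v <- pts[tri[3, chunk], , drop = FALSE] - a
    nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
    len <- sqrt(rowSums(nrm^2))
    ok <- len > 1e-9
    nrm <- nrm[ok, , drop = FALSE] / len[ok]
    off <- rowSums(nrm * a[ok, , drop = FALSE])
    # signed distances of all points to every candidate plane
    d <- nrm %*% t(pts) - off          # planes x points
    below <- rowSums(d > tol) == 0
    above <- rowSums(d < -tol) == 0
    planes <- rbind(planes,
                    cbind(nrm[below, , drop = FALSE], off[below]),
                    cbind(-nrm[above, , drop = FALSE], -off[above]))
    # coplanar triples generate the same facet many times over; dedupe to
    # keep the final half-space test small
    planes <- unique(round(planes, 9))
  }
  stopifnot(nrow(planes) >= 4)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  grid <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  s <- grid %*% t(planes[, 1:3, drop = FALSE])
  inside <- rowSums(s > matrix(planes[, 4], nrow(grid), nrow(planes),
                               byrow = TRUE) + tol) == 0
  sum(inside)
}

# hull-vertex candidates: surface voxels only (interior voxels cannot be hull
# vertices), keeps the O(n^3) enumeration tractable
surface_coords <- function(mask) {
  g <- mask$grid
  d <- dim(g)
  xyz <- which(g, arr.ind = TRUE)
  on_surface <- vapply(seq_len(nrow(xyz)), function(i) {
    p <- xyz[i, ]
    for (ax in 1:3) for (s in c(-1, 1)) {
      q <- p; q[ax] <- q[ax] + s
      if (any(q < 1) || any(q > d)) return(TRUE)
      if (!g[q[1], q[2], q[3]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  out <- xyz[on_surface, , drop = FALSE]
  storage.mode(out) <- "double"
  out
}

# cold-start, residual-update coordinate descent; intercept via centering
naive_cd_lasso <- function(X, y, lambda, tol = 1e-13, maxit = 200000) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  d <- colMeans(Xc^2)
  beta <- matrix(0, p, length(lambda))
  a0 <- numeric(length(lambda))
  for (l in seq_along(lambda)) {
    lam <- lambda[l]
    b <- numeric(p)
    r <- yc
    for (it in seq_len(maxit)) {
      delmax <- 0
      for (j in seq_len(p)) {
        if (d[j] < 1e-12) next
        rho <- sum(Xc[, j] * r) / n + d[j] * b[j]
        bj <- sign(rho) * max(abs(rho) - lam, 0) / d[j]
        if (bj != b[j]) {
          r <- r - Xc[, j] * (bj - b[j])
          delmax <- max(delmax, abs(bj - b[j]))
          b[j] <- bj
        }
      }
      if (delmax < tol) break
    }
    beta[, l] <- b
    a0[l] <- ym - sum(b * xm)
  }
  list(beta = beta, a0 = a0)
}
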