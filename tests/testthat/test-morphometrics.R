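# Expected values are either exact lattice enumerations computed in the test,
# closed forms, or analytic continuum values with the tolerance the estimator
# was designed for.

test_that("volume counts voxels and converts to mL via spacing", {
  cube <- mk_cuboid(10, 10, 10)
  expect_equal(compute_volume(cube), list(volume_vox = 1000, volume_ml = 1))
  one <- mk_mask(c(3, 3, 3), matrix(c(2, 2, 2), 1), spacing = c(2, 2, 2))
  expect_equal(compute_volume(one), list(volume_vox = 1, volume_ml = 0.008))
  ball <- mk_ball(20)
  v <- compute_volume(ball)$volume_vox
  expect_equal(v, sum(ball$grid))  # lattice enumeration
  expect_lt(abs(v / (4 / 3 * pi * 20^3) - 1), 0.01)
})

test_that("centroid is the mean foreground coordinate (1-based voxel centers)", {
  expect_equal(compute_centroid(mk_mask(c(16, 9, 5), matrix(c(14, 6, 3), 1))),
               c(14, 6, 3))
  cube <- mk_mask(c(12, 12, 12), as.matrix(expand.grid(1:10, 1:10, 1:10)))
  expect_equal(compute_centroid(cube), c(5.5, 5.5, 5.5))
  two <- mk_mask(c(5, 3, 3), rbind(c(1, 1, 1), c(3, 1, 1)))
  expect_equal(compute_centroid(two), c(2, 1, 1))
})

test_that("bounding box uses the max - min + 1 voxel convention", {
  bb <- compute_bounding_box(mk_cuboid(20, 10, 5))
  expect_equal(bb$bb, c(20, 10, 5))
  expect_equal(bb$bb_volume_vox, 1000)
  expect_equal(compute_bounding_box(mk_mask(c(3, 3, 3), matrix(c(2, 2, 2), 1))),
               list(bb = c(1, 1, 1), bb_volume_vox = 1))
  corners <- mk_mask(c(9, 9, 9), rbind(c(2, 2, 2), c(8, 8, 8)))
  expect_equal(compute_bounding_box(corners)$bb_volume_vox, 343)
})

test_that("equivalent diameter inverts the sphere volume formula", {
  expect_equal(compute_equiv_diameter(pi / 6), 1)
  expect_equal(compute_equiv_diameter(1000), 12.4070098179, tolerance = 1e-10)
  v0 <- 137
  expect_equal(compute_equiv_diameter(8 * v0), 2 * compute_equiv_diameter(v0))
  expect_error(compute_equiv_diameter(0), "empty")
})

test_that("extent is the volume to bounding-box ratio", {
  expect_equal(compute_extent(1000, 1000), 1)
  expect_equal(compute_extent(2, 343), 2 / 343)
  expect_error(compute_extent(10, 5), "invariant")
  ball <- mk_ball(20)
  v <- sum(ball$grid)
  ext <- compute_extent(v, 41^3)
  expect_equal(ext, v / 41^3)  # lattice enumeration oracle
  # continuum value adjusted for the half-voxel border of the +1 box
  # convention: pi/6 * (2r / (2r+1))^3
  expect_lt(abs(ext / (pi / 6 * (40 / 41)^3) - 1), 0.03)
})

test_that("principal axis lengths follow the solid-ellipsoid moment convention", {
  one <- mk_mask(c(3, 3, 3), matrix(c(2, 2, 2), 1))
  expect_equal(compute_principal_axis_lengths(one), rep(2 * sqrt(5 / 12), 3),
               tolerance = 1e-12)
  pal_ball <- compute_principal_axis_lengths(mk_ball(20))
  expect_true(all(abs(pal_ball / 40 - 1) < 0.02))
  pal_ell <- compute_principal_axis_lengths(mk_ellipsoid(30, 15, 8))
  expect_true(all(abs(pal_ell / c(60, 30, 16) - 1) < 0.03))
  expect_true(all(diff(pal_ell) <= 0))
  # the two exposed constants behave as documented
  pal_nocorr <- compute_principal_axis_lengths(one, voxel_correction = 0.25)
  expect_equal(pal_nocorr, rep(2 * sqrt(5 * 0.25), 3))
})

test_that("convex volume counts lattice points inside the hull", {
  cub <- mk_cuboid(9, 7, 5)
  expect_equal(compute_convex_volume(cub), compute_volume(cub)$volume_vox)
  # degenerate rank-1 hull: the lattice segment
  seg <- mk_mask(c(7, 3, 3), rbind(c(1, 1, 1), c(5, 1, 1)))
  expect_equal(compute_convex_volume(seg), 5)
  # degenerate rank-2 hull: a one-voxel-thick plate (convex rectangle)
  plate <- mk_mask(c(10, 8, 4), as.matrix(expand.grid(2:8, 2:6, 3)))
  expect_equal(compute_convex_volume(plate), 7 * 5)
  # rank-2 triangle plate vs direct 2D enumeration: lattice points of the
  # triangle (1,1),(7,1),(1,7) at z = 2: sum_{x=1..7} (9 - x) ... = 28
  tri <- rbind(c(1, 1), c(7, 1), c(1, 7))
  fg <- cbind(tri, 2)
  expect_equal(compute_convex_volume(mk_mask(c(8, 8, 3), fg)), 28)
  # non-convex L-shape vs brute-force point-in-hull enumeration
  L <- mk_L(5)
  expect_equal(compute_convex_volume(L),
               oracle_hull_lattice_count(surface_coords(L)))
})

test_that("solidity is volume over convex volume and detects cavities", {
  cub <- mk_cuboid(6, 5, 4)
  m <- compute_all_metrics(cub)
  expect_equal(m$solidity, 1)
  expect_equal(compute_solidity(2000, 2500), 0.8)
  expect_error(compute_solidity(10, 5), "invariant")
  # hollow shell: hull fills the cavity, solidity strictly < 1
  g <- array(FALSE, c(12, 12, 12))
  g[3:10, 3:10, 3:10] <- TRUE
  g[5:8, 5:8, 5:8] <- FALSE
  shell <- volume_mask(g)
  sh <- compute_all_metrics(shell)
  expect_lt(sh$solidity, 1)
  expect_equal(sh$convex_volume_vox, 512)  # hull of the 8^3 cube
})

test_that("isosurface area matches analytic areas within design tolerances", {
  ball <- mk_ball(20)
  expect_lt(abs(compute_surface_area(ball) / (4 * pi * 400 / 100) - 1), 0.05)
  cube <- mk_cuboid(10, 10, 10)
  expect_lt(abs(compute_surface_area(cube) / 6 - 1), 0.10)
  one <- mk_mask(c(5, 5, 5), matrix(c(3, 3, 3), 1))
  a1 <- compute_surface_area(one) * 100  # mm^2
  expect_gt(a1, 0)
  expect_lt(a1, 6)
  # anisotropic spacing scales area quadratically
  ball10 <- mk_ball(10)
  expect_equal(compute_surface_area(volume_mask(ball10$grid, c(2, 2, 2))),
               4 * compute_surface_area(ball10), tolerance = 1e-10)
})

test_that("the assembled metric record is internally consistent", {
  m <- compute_all_metrics(mk_cuboid(12, 7, 4))
  expect_equal(m$extent, 1)
  expect_equal(m$solidity, 1)
  expect_equal(m$bounding_box, c(12, 7, 4))
  df <- as.data.frame(m)
  expect_identical(names(df)[1:4], c("region", "Volume", "Volume_mL", "SurfaceArea"))
  expect_equal(df$BoundingBoxVolume, 12 * 7 * 4)
})

test_that("metrics are translation-invariant except the centroid", {
  b <- mk_blob(50, seed = 3)
  fg <- which(b$grid, arr.ind = TRUE)
  shifted <- mk_mask(dim(b$grid) + 5, fg + 5)
  m0 <- compute_all_metrics(b)
  m1 <- compute_all_metrics(shifted)
  expect_equal(m1$centroid, m0$centroid + 5)
  for (f in c("volume_vox", "volume_ml", "surface_area_cm2", "bounding_box",
              "bb_volume_vox", "equiv_diameter_vox", "extent",
              "principal_axis_lengths", "convex_volume_vox", "solidity"))
    expect_equal(m1[[f]], m0[[f]], tolerance = 1e-9, label = f)
})

test_that("permuting grid axes permutes coordinates and preserves scalars", {
  b <- mk_blob(60, seed = 8)
  perm <- c(3, 1, 2)
  m0 <- compute_all_metrics(b)
  m1 <- compute_all_metrics(volume_mask(aperm(b$grid, perm)))
  expect_equal(m1$centroid, m0$centroid[perm])
  expect_equal(m1$bounding_box, m0$bounding_box[perm])
  for (f in c("volume_vox", "equiv_diameter_vox", "extent",
              "convex_volume_vox", "solidity"))
    expect_equal(m1[[f]], m0[[f]], label = f)
  expect_equal(m1$principal_axis_lengths, m0$principal_axis_lengths,
               tolerance = 1e-9)
  expect_equal(m1$surface_area_cm2, m0$surface_area_cm2, tolerance = 1e-9)
})

test_that("integer upsampling scales volume by k^3 and axis lengths by k", {
  b <- mk_blob(120, seed = 5, dim = c(20, 20, 20))
  k <- 2
  g <- b$grid
  up <- array(FALSE, dim(g) * k)
  idx <- which(g, arr.ind = TRUE)
  for (dx in 0:(k - 1)) for (dy in 0:(k - 1)) for (dz in 0:(k - 1)) {
    shifted <- cbind((idx[, 1] - 1) * k + 1 + dx, (idx[, 2] - 1) * k + 1 + dy,
                     (idx[, 3] - 1) * k + 1 + dz)
    up[shifted] <- TRUE
  }
  m0 <- compute_all_metrics(b)
  m1 <- compute_all_metrics(volume_mask(up))
  expect_equal(m1$volume_vox, k^3 * m0$volume_vox)
  expect_true(all(abs(m1$principal_axis_lengths /
                        (k * m0$principal_axis_lengths) - 1) < 0.02))
})

test_that("random blobs satisfy all metric invariants and match enumeration", {
  for (s in 1:8) {
    b <- mk_blob(40 + 5 * s, seed = s)
    m <- compute_all_metrics(b)
    fg <- which(b$grid, arr.ind = TRUE)
    expect_equal(m$volume_vox, nrow(fg))
    expect_equal(m$centroid, unname(colMeans(fg)), tolerance = 1e-12)
    expect_equal(m$bounding_box,
                 unname(apply(fg, 2, function(v) diff(range(v)) + 1)))
    expect_true(all(diff(m$principal_axis_lengths) <= 0))
    expect_true(m$volume_vox <= m$convex_volume_vox)
    expect_true(m$convex_volume_vox <= m$bb_volume_vox)
    expect_true(m$extent > 0 && m$extent <= 1)
    expect_true(m$solidity > 0 && m$solidity <= 1)
    expect_equal(m$bb_volume_vox, prod(m$bounding_box))
  }
})

test_that("per-file failures do not abort a cohort morphometrics run", {
  dir <- tempfile("masks")
  dir.create(dir)
  for (i in 1:3) {
    mk <- generate_pancreas_mask(dim = c(56, 48, 28), head_radius = 7,
                                 tail_radius = 3, seed = i)
    write_pancreas_mask(mk$labels, mk$spacing,
                        file.path(dir, sprintf("S%02d.nii.gz", i)))
  }
  writeLines("not a nifti", file.path(dir, "broken.nii"))
  expect_warning(tab <- run_morphometrics(dir), "broken")
  expect_equal(nrow(tab), 12)  # 3 subjects x 4 regions
  expect_identical(attr(tab, "failures"), "broken")
  expect_error(run_morphometrics(tempfile("empty")), "no NIfTI")
})
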